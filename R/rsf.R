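#' Min-max then z-score standardization of continuous covariates
#'
#' Continuous covariates (by default slope and NDVI) are first normalized
#' to [0, 1] over the supplied rows (used + available combined) and then
#' z-score standardized with the population (n-denominator) standard
#' deviation.  Binary covariates are untouched.  The transform parameters
#' are stored so predictions can be mapped back to raw units.
#'
#' @param data observation data.frame.
#' @param continuous names of continuous covariate columns present in
#'   \code{data}.
#' @return \code{data} with transformed columns and an attribute
#'   \code{"standardization"}: data.frame(covariate, min, max, mean_norm,
#'   sd_norm).
#' @export
standardize_covariates <- function(data, continuous = c("slope", "ndvi")) {
  continuous <- intersect(continuous, names(data))
  rec <- data.frame(covariate = character(0), min = numeric(0),
                    max = numeric(0), mean_norm = numeric(0),
                    sd_norm = numeric(0))
  for (nm in continuous) {
    v <- data[[nm]]
    rng <- range(v)
    if (diff(rng) == 0)
      stop("constant-covariate error: '", nm, "' has zero variance")
    u <- (v - rng[1]) / diff(rng)
    mu <- mean(u)
    sdp <- sqrt(mean((u - mu)^2))
    data[[nm]] <- (u - mu) / sdp
    rec <- rbind(rec, data.frame(covariate = nm, min = rng[1], max = rng[2],
                                 mean_norm = mu, sd_norm = sdp))
  }
  attr(data, "standardization") <- rec
  data
}

#' Highest-density posterior interval
#'
#' Shortest contiguous interval containing \code{ceiling(mass * n)} of
#' the sorted draws; on ties the leftmost such interval is reported.
#'
#' @param draws numeric vector of posterior draws (>= 100).
#' @param mass interval mass (default 0.95).
#' @return numeric length-2 \code{c(lower, upper)}.
#' @export
hdpi <- function(draws, mass = 0.95) {
  n <- length(draws)
  if (n < 100L) stop("insufficient-sample error: need >= 100 draws")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1L])
}

#' Prior settings for the hierarchical RSF
#'
#' Group-level coefficient means get independent Normal(0, mean_sd^2)
#' priors (default sd 10, i.e. variance 100 -- uninformative on the logit
#' scale); group-level standard deviations get half-Normal(sigma_sd)
#' priors (default 5), the interpretive reading of a "Gaussian" prior on
#' a necessarily positive spread parameter.
#'
#' @param mean_sd prior sd on group-level means.
#' @param sigma_sd half-normal scale on group-level sds.
#' @export
rsf_prior <- function(mean_sd = 10, sigma_sd = 5) {
  stopifnot(mean_sd > 0, sigma_sd > 0)
  list(mean_sd = mean_sd, sigma_sd = sigma_sd)
}

# penalized logistic estimate and proposal factor for one individual:
# a few Newton steps on binomial log-likelihood with ridge penalty,
# returning the estimate and the Cholesky factor of the inverse
# (penalized) Fisher information.
penalized_logit_mle <- function(X, y, m, ridge = 0.5, steps = 25L) {
  p <- ncol(X)
  b <- numeric(p)
  for (s in seq_len(steps)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- pmax(m * mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - m * mu)) - ridge * b
    H <- crossprod(X * w, X) + diag(ridge, p)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% b)
  mu <- plogis(eta)
  w <- pmax(m * mu * (1 - mu), 1e-10)
  H <- crossprod(X * w, X) + diag(ridge, p)
  list(coef = b, chol_cov = chol(solve(H)))
}

# one MCMC chain for the (possibly hierarchical) Bernoulli RSF; the
# iteration loop lives in compiled code (src/rsf_sampler.cpp).  Data are
# pre-aggregated per individual into unique covariate rows with binomial
# counts, which leaves the likelihood unchanged.
run_rsf_chain <- function(agg, p, n_ind, hierarchical, prior,
                          iter, warmup, init) {
  run_rsf_chain_cpp(lapply(agg, `[[`, "X"), lapply(agg, `[[`, "y"),
                    lapply(agg, `[[`, "m"), lapply(agg, `[[`, "L"),
                    init$B, init$mu, init$sigma, hierarchical,
                    prior$mean_sd, prior$sigma_sd,
                    as.integer(iter), as.integer(warmup))
}

#' Fit a (hierarchical) Bayesian resource selection function
#'
#' Bernoulli likelihood on the use-available indicator with a logistic
#' link: \code{logit(theta) = beta_0i + sum_k beta_ik x_k}.  With
#' \code{hierarchical = TRUE} every coefficient (including the intercept)
#' is individual-level and drawn from a group-level Gaussian,
#' \code{beta_ik ~ N(mu_k, sigma_k^2)}, with a Normal(0, 100) prior on
#' each \code{mu_k} and a half-Normal(5) prior on each \code{sigma_k}.
#' With \code{hierarchical = FALSE} a single coefficient vector is shared
#' by all rows (prior Normal(0, 100) per coefficient).
#'
#' Posterior draws come from an adaptive Metropolis-within-Gibbs sampler:
#' individual coefficient blocks use random-walk proposals shaped by the
#' penalized Fisher information, group means have a conjugate Gaussian
#' update, and group sds a log-scale random walk.  Identical covariate
#' rows within an individual are aggregated to binomial counts, which
#' leaves the posterior unchanged.
#'
#' @param formula model formula, e.g. \code{used ~ slope + drains + ndvi}.
#'   The response must be the 0/1 use indicator.
#' @param data observation data.frame (one row per used/available point).
#' @param individual name of the grouping column (default
#'   \code{"individual_id"}).
#' @param hierarchical logical; hierarchical (default) or pooled fit.
#' @param prior a \code{\link{rsf_prior}}.
#' @param iter post-warmup draws per chain.
#' @param warmup adaptation iterations per chain (discarded).
#' @param chains number of independent chains.
#' @param seed optional integer seed.
#' @param hdpi_mass mass of reported highest-density intervals.
#' @return object of class \code{"rsf"}; see \code{\link{summary.rsf}},
#'   \code{\link{coef.rsf}}, \code{\link{predict.rsf}},
#'   \code{\link{plot.rsf}}, \code{\link{simulate.rsf}}.
#' @export
rsf <- function(formula, data, individual = "individual_id",
                hierarchical = TRUE, prior = rsf_prior(),
                iter = 1000L, warmup = 1000L, chains = 2L, seed = NULL,
                hdpi_mass = 0.95) {
  cl <- match.call()
  if (!is.null(seed)) set.seed(seed)
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be the 0/1 use indicator")
  X <- model.matrix(attr(mf, "terms"), mf)
  p <- ncol(X)
  covariates <- colnames(X)
  nonconst <- apply(X[, setdiff(covariates, "(Intercept)"), drop = FALSE],
                    2, function(v) diff(range(v)) > 0)
  if (!all(nonconst))
    stop("constant-covariate error: ",
         paste(names(nonconst)[!nonconst], collapse = ", "),
         " do(es) not vary")
  ind <- as.character(data[[individual]])
  if (is.null(ind)) stop("individual column '", individual, "' not found")
  ids <- unique(ind)
  n_ind <- length(ids)
  if (hierarchical && n_ind < 2L)
    stop("hierarchical fit needs >= 2 individuals")
  if (!hierarchical) { ind <- rep(ids[1], length(ind)); ids <- ids[1]; n_ind <- 1L }

  # aggregate identical covariate rows within individual
  agg <- lapply(ids, function(id) {
    sel <- ind == id
    Xi <- X[sel, , drop = FALSE]
    yi <- y[sel]
    key <- do.call(paste, c(as.data.frame(Xi), sep = "\r"))
    grp <- match(key, unique(key))
    Xu <- Xi[!duplicated(grp), , drop = FALSE]
    list(X = Xu,
         y = as.vector(rowsum(yi, grp)),
         m = as.vector(rowsum(rep(1, length(yi)), grp)),
         n_used = sum(yi), n_total = length(yi))
  })
  for (i in seq_len(n_ind)) {
    pm <- penalized_logit_mle(agg[[i]]$X, agg[[i]]$y, agg[[i]]$m)
    agg[[i]]$init <- pm$coef
    agg[[i]]$L <- pm$chol_cov
  }
  B0 <- do.call(rbind, lapply(agg, `[[`, "init"))
  init <- list(B = B0, mu = colMeans(B0),
               sigma = pmax(apply(B0, 2, sd), 0.1))
  if (!hierarchical) init$sigma <- rep(1, p)

  res <- lapply(seq_len(chains), function(ch) {
    if (!is.null(seed)) set.seed(seed + ch * 1009L)
    run_rsf_chain(agg, p, n_ind, hierarchical, prior, iter, warmup, init)
  })
  mu_draws <- do.call(rbind, lapply(res, `[[`, "mu"))
  sigma_draws <- if (hierarchical)
    do.call(rbind, lapply(res, `[[`, "sigma")) else NULL
  B_draws <- do.call(abind1, lapply(res, `[[`, "B"))
  colnames(mu_draws) <- covariates
  if (!is.null(sigma_draws)) colnames(sigma_draws) <- covariates
  dimnames(B_draws) <- list(NULL, ids, covariates)
  chain_id <- rep(seq_len(chains), each = iter)

  rhat_mu <- apply_rhat(mu_draws, chain_id)
  rhat_sig <- if (hierarchical) apply_rhat(sigma_draws, chain_id) else NULL
  ess_mu <- apply(mu_draws, 2, ess_draws, chain_id = chain_id)
  converged <- all(c(rhat_mu, rhat_sig) < 1.05, na.rm = TRUE)
  if (!converged)
    warning("convergence not reached (max split-Rhat = ",
            round(max(c(rhat_mu, rhat_sig), na.rm = TRUE), 3),
            "); treat summaries with caution")

  structure(list(call = cl, formula = formula, terms = attr(mf, "terms"),
                 covariates = covariates, individuals = ids,
                 hierarchical = hierarchical, prior = prior,
                 hdpi_mass = hdpi_mass,
                 draws = list(mu = mu_draws, sigma = sigma_draws,
                              B = B_draws),
                 chain_id = chain_id,
                 diagnostics = list(rhat_mu = rhat_mu, rhat_sigma = rhat_sig,
                                    ess_mu = ess_mu,
                                    accept_ind = rowMeans(matrix(
                                      sapply(res, `[[`, "accept_ind"),
                                      ncol = chains))),
                 converged = converged,
                 data = list(X = X, y = y, individual = ind),
                 standardization = attr(data, "standardization"),
                 n_obs = length(y), n_used = sum(y)),
            class = "rsf")
}

# bind 3-d arrays along the first dimension
abind1 <- function(...) {
  args <- list(...)
  d <- dim(args[[1]])
  out <- array(NA_real_, c(sum(vapply(args, function(a) dim(a)[1], 0)),
                           d[2], d[3]))
  at <- 0L
  for (a in args) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# split-chain potential scale reduction factor
split_rhat <- function(x, chain_id) {
  halves <- unlist(lapply(split(x, chain_id), function(v) {
    n2 <- length(v) %/% 2L
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  Bv <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

apply_rhat <- function(draws, chain_id)
  apply(draws, 2, split_rhat, chain_id = chain_id)

# effective sample size via Geyer's initial positive sequence, averaged
# over chains
ess_draws <- function(x, chain_id) {
  per_chain <- split(x, chain_id)
  n <- length(per_chain[[1]])
  if (var(x) == 0) return(length(x))
  rho <- Reduce(`+`, lapply(per_chain, function(v) {
    if (var(v) == 0) return(rep(0, min(n - 1L, 200L)))
    drop(acf(v, lag.max = min(n - 1L, 200L), plot = FALSE)$acf)[-1]
  })) / length(per_chain)
  s <- 0
  for (k in seq(1, length(rho) - 1L, by = 2)) {
    pair <- rho[k] + rho[k + 1L]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  length(x) / (1 + 2 * s)
}
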