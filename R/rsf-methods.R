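#' @export
print.rsf <- function(x, ...) {
  cat(sprintf("%s Bayesian RSF: %d observations (%d used), %d individual(s)\n",
              if (x$hierarchical) "Hierarchical" else "Pooled",
              x$n_obs, x$n_used, length(x$individuals)))
  cat("Formula: ", deparse(x$formula), "\n")
  cat(sprintf("Draws: %d (in %d chains); converged: %s\n",
              nrow(x$draws$mu), length(unique(x$chain_id)),
              ifelse(x$converged, "yes", "NO")))
  print(round(colMeans(x$draws$mu), 3))
  invisible(x)
}

#' Posterior summary of an RSF fit
#'
#' Group-level coefficient means and (for hierarchical fits) group-level
#' sds, each with posterior mean, sd, highest-density interval,
#' split-Rhat and effective sample size.
#'
#' @param object an \code{rsf} fit.
#' @param ... unused.
#' @return object of class \code{"summary.rsf"}: data.frame with one row
#'   per parameter.
#' @export
summary.rsf <- function(object, ...) {
  mass <- object$hdpi_mass
  sum_block <- function(draws, label, rhat, ess) {
    hd <- apply(draws, 2, hdpi, mass = mass)
    data.frame(parameter = paste0(label, colnames(draws)),
               covariate = colnames(draws),
               mean = colMeans(draws),
               sd = apply(draws, 2, sd),
               hdpi_low = hd[1, ], hdpi_high = hd[2, ],
               rhat = rhat, ess = ess, row.names = NULL)
  }
  out <- sum_block(object$draws$mu, "mu_", object$diagnostics$rhat_mu,
                   object$diagnostics$ess_mu)
  if (object$hierarchical)
    out <- rbind(out, sum_block(object$draws$sigma, "sigma_",
                                object$diagnostics$rhat_sigma,
                                apply(object$draws$sigma, 2, ess_draws,
                                      chain_id = object$chain_id)))
  attr(out, "converged") <- object$converged
  attr(out, "hdpi_mass") <- mass
  class(out) <- c("summary.rsf", "data.frame")
  out
}

#' @export
print.summary.rsf <- function(x, ...) {
  cat(sprintf("Posterior summaries (%.0f%% HDPI); converged: %s\n",
              100 * attr(x, "hdpi_mass"),
              ifelse(attr(x, "converged"), "yes", "NO")))
  df <- as.data.frame(x)
  df[, sapply(df, is.numeric)] <- round(df[, sapply(df, is.numeric)], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract RSF coefficients
#'
#' @param object an \code{rsf} fit.
#' @param type \code{"group"} (posterior means of the group-level means;
#'   default) or \code{"individual"} (matrix individual x covariate of
#'   posterior means of the individual coefficients).
#' @param ... unused.
#' @export
coef.rsf <- function(object, type = c("group", "individual"), ...) {
  type <- match.arg(type)
  if (type == "group") colMeans(object$draws$mu)
  else apply(object$draws$B, c(2, 3), mean)
}

#' Predict relative selection from an RSF fit
#'
#' Uses posterior-mean coefficients.  With \code{level = "group"} the
#' group-level means are used for every row; with \code{"individual"}
#' each row uses its own individual's coefficients.  Remember that
#' standardized covariates must be supplied on the standardized scale
#' (see the fit's \code{$standardization} record).
#'
#' @param object an \code{rsf} fit.
#' @param newdata data.frame with the model covariates (default: the
#'   training data).
#' @param type \code{"link"} (linear predictor; default) or
#'   \code{"response"} (Bernoulli probability under the use-available
#'   design).
#' @param level \code{"group"} or \code{"individual"}.
#' @param ... unused.
#' @export
predict.rsf <- function(object, newdata = NULL,
                        type = c("link", "response"),
                        level = c("group", "individual"), ...) {
  type <- match.arg(type)
  level <- match.arg(level)
  if (is.null(newdata)) {
    X <- object$data$X
    ind <- object$data$individual
  } else {
    X <- model.matrix(delete.response(object$terms), newdata)
    ind <- as.character(newdata$individual_id)
  }
  if (level == "group" || is.null(ind)) {
    eta <- drop(X %*% coef(object, "group"))
  } else {
    Bi <- coef(object, "individual")
    eta <- rowSums(X * Bi[match(ind, rownames(Bi)), , drop = FALSE])
  }
  if (type == "response") plogis(eta) else eta
}

#' Simulate use indicators from the posterior predictive distribution
#'
#' For each requested simulation a joint posterior draw is selected and a
#' Bernoulli outcome is generated for every observation row using its
#' individual's coefficients from that draw.
#'
#' @param object an \code{rsf} fit.
#' @param nsim number of replicated datasets.
#' @param seed optional seed.
#' @param ... unused.
#' @return integer matrix n_obs x nsim.
#' @export
simulate.rsf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$draws$mu)
  take <- sample.int(S, nsim, replace = nsim > S)
  X <- object$data$X
  ii <- match(object$data$individual, object$individuals)
  out <- matrix(0L, nrow(X), nsim)
  for (j in seq_len(nsim)) {
    Bs <- object$draws$B[take[j], , , drop = FALSE]
    dim(Bs) <- dim(object$draws$B)[2:3]
    eta <- rowSums(X * Bs[ii, , drop = FALSE])
    out[, j] <- rbinom(nrow(X), 1L, plogis(eta))
  }
  out
}

#' Response residuals at the posterior mean
#'
#' @param object an \code{rsf} fit.
#' @param ... unused.
#' @export
residuals.rsf <- function(object, ...) {
  object$data$y - predict(object, type = "response", level = "individual")
}

#' Forest plot of group-level selection coefficients
#'
#' Posterior means with highest-density intervals per covariate, the
#' conventional display for standardized selection coefficients.
#'
#' @param x an \code{rsf} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.rsf <- function(x, ...) {
  s <- summary(x)
  s <- s[startsWith(s$parameter, "mu_"), ]
  s <- s[s$covariate != "(Intercept)", ]
  n <- nrow(s)
  op <- par(mar = c(4, 9, 2, 1))
  on.exit(par(op))
  plot(s$mean, seq_len(n), xlim = range(c(s$hdpi_low, s$hdpi_high, 0)),
       yaxt = "n", xlab = "standardized selection coefficient", ylab = "",
       pch = 16, panel.first = abline(v = 0, lty = 2, col = "grey60"), ...)
  segments(s$hdpi_low, seq_len(n), s$hdpi_high, seq_len(n))
  axis(2, at = seq_len(n), labels = s$covariate, las = 1)
  invisible(x)
}

#' Posterior predictive check of an RSF fit
#'
#' Replicates the use indicator from the posterior predictive
#' distribution and compares the replicated used fraction -- overall and
#' within each binary-covariate stratum -- to the observed value.  The
#' reported tail probability is the Bayesian p-value
#' \code{P(T_rep <= T_obs)} (ties split); values near 0 or 1 flag misfit.
#'
#' @param fit an \code{rsf} fit.
#' @param ndraws posterior draws to replicate (default 200).
#' @param seed optional seed.
#' @return data.frame: statistic, observed, replicate mean, tail
#'   probability.
#' @export
posterior_predictive_check <- function(fit, ndraws = 200L, seed = NULL) {
  reps <- simulate(fit, nsim = ndraws, seed = seed)
  X <- fit$data$X
  y <- fit$data$y
  stats <- list(used_fraction = rep(TRUE, length(y)))
  for (nm in setdiff(colnames(X), "(Intercept)")) {
    v <- X[, nm]
    if (all(v %in% c(0, 1)) && any(v == 1))
      stats[[paste0("used_fraction|", nm, "=1")]] <- v == 1
  }
  out <- do.call(rbind, lapply(names(stats), function(nm) {
    sel <- stats[[nm]]
    obs <- mean(y[sel])
    rep_stat <- colMeans(reps[sel, , drop = FALSE])
    p <- (sum(rep_stat < obs) + 0.5 * sum(rep_stat == obs)) / ndraws
    data.frame(statistic = nm, observed = obs,
               replicated_mean = mean(rep_stat), tail_prob = p)
  }))
  out
}

#' Spread of individual-level coefficients around the group mean
#'
#' Summaries of the group-level sds and of each individual's deviation
#' \code{beta_ik - mu_k}, for assessing how much selection behaviour
#' varies between individuals.
#'
#' @param fit a hierarchical \code{rsf} fit.
#' @return list with \code{sigma} (data.frame per covariate: posterior
#'   mean and HDPI of the group sd) and \code{deviations} (data.frame per
#'   individual x covariate: posterior mean and HDPI of the deviation).
#' @export
random_effect_spread <- function(fit) {
  if (!fit$hierarchical) stop("random_effect_spread needs a hierarchical fit")
  mass <- fit$hdpi_mass
  hd <- apply(fit$draws$sigma, 2, hdpi, mass = mass)
  sig <- data.frame(covariate = colnames(fit$draws$sigma),
                    mean = colMeans(fit$draws$sigma),
                    hdpi_low = hd[1, ], hdpi_high = hd[2, ],
                    row.names = NULL)
  devs <- do.call(rbind, lapply(seq_along(fit$individuals), function(i) {
    d <- fit$draws$B[, i, ] - fit$draws$mu
    hd <- apply(d, 2, hdpi, mass = mass)
    data.frame(individual_id = fit$individuals[i],
               covariate = colnames(fit$draws$mu),
               mean = colMeans(d), hdpi_low = hd[1, ], hdpi_high = hd[2, ],
               row.names = NULL)
  }))
  list(sigma = sig, deviations = devs)
}
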