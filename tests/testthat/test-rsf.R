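# simulated use-available rows for known coefficients, independent of the
# landscape machinery: covariates drawn directly
sim_rows <- function(n, beta, intercept = -2.4, x_gen = NULL, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  X <- if (is.null(x_gen)) matrix(rbinom(n * p, 1, 0.35), n, p) else x_gen(n, p)
  colnames(X) <- names(beta)
  eta <- intercept + drop(X %*% beta)
  data.frame(used = rbinom(n, 1, plogis(eta)), X)
}

test_that("standardization is min-max then population z-score", {
  d <- data.frame(slope = c(0, 5, 10), drains = c(0, 1, 1),
                  ndvi = c(0.2, 0.4, 0.9))
  out <- standardize_covariates(d)
  expect_equal(out$slope, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(out$slope), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(out$slope^2)), 1, tolerance = 1e-12)
  expect_identical(out$drains, d$drains)   # binary untouched
  rec <- attr(out, "standardization")
  expect_equal(rec$min[rec$covariate == "slope"], 0)
  expect_equal(rec$max[rec$covariate == "slope"], 10)
  expect_error(standardize_covariates(data.frame(slope = rep(2, 4))),
               "constant-covariate.*slope")
})

test_that("hdpi is the shortest interval and matches closed forms", {
  set.seed(1)
  z <- rnorm(1e5)
  h <- hdpi(z, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.05)
  expect_lt(abs(h[2] - 1.96), 0.05)
  u <- runif(5000)
  hu <- hdpi(u, 0.95)
  expect_equal(diff(hu), 0.95, tolerance = 0.02)
  expect_equal(diff(hdpi(rep(3, 200), 0.95)), 0)
  expect_error(hdpi(rnorm(50)), "insufficient-sample")
})

test_that("hdpi agrees with coda's HPD interval on a skewed posterior", {
  set.seed(2)
  g <- rgamma(5e4, shape = 2, rate = 1)
  h <- hdpi(g, 0.95)
  ref <- coda::HPDinterval(coda::as.mcmc(g), prob = 0.95)
  expect_equal(h[1], ref[1, "lower"], tolerance = 0.02)
  expect_equal(h[2], ref[1, "upper"], tolerance = 0.02)
})

test_that("pooled single-covariate posterior matches dense-grid quadrature", {
  d <- sim_rows(1000, c(x = 0.9), intercept = -1.2, seed = 3)
  d$individual_id <- rep(c("a", "b"), each = 500)
  fit <- rsf(used ~ x, d, hierarchical = FALSE, iter = 2500, warmup = 1000,
             chains = 2, seed = 4)
  # independent quadrature over (b0, b1) with the same N(0, 100) priors
  g <- glm(used ~ x, binomial(), d)
  ct <- coef(g); se <- sqrt(diag(vcov(g)))
  b0g <- seq(ct[1] - 6 * se[1], ct[1] + 6 * se[1], length.out = 161)
  b1g <- seq(ct[2] - 6 * se[2], ct[2] + 6 * se[2], length.out = 161)
  X <- cbind(1, d$x); y <- d$used
  lp <- outer(seq_along(b0g), seq_along(b1g), Vectorize(function(i, j) {
    eta <- X %*% c(b0g[i], b1g[j])
    sum(y * eta - log1p(exp(eta))) +
      dnorm(b0g[i], 0, 10, log = TRUE) + dnorm(b1g[j], 0, 10, log = TRUE)
  }))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  quad_mean <- c(sum(rowSums(w) * b0g), sum(colSums(w) * b1g))
  post <- coef(fit)
  expect_lt(abs(post["(Intercept)"] - quad_mean[1]), 0.05)
  expect_lt(abs(post["x"] - quad_mean[2]), 0.05)
})

test_that("hierarchical posterior agrees with an independent JAGS fit", {
  set.seed(5)
  n_ind <- 3; n <- 400
  b_i <- rnorm(n_ind, 0.8, 0.3)
  d <- do.call(rbind, lapply(seq_len(n_ind), function(i) {
    x <- rbinom(n, 1, 0.4)
    data.frame(individual_id = paste0("i", i), x = x,
               used = rbinom(n, 1, plogis(-1 + b_i[i] * x)))
  }))
  fit <- rsf(used ~ x, d, iter = 2000, warmup = 1000, chains = 2, seed = 6)

  m <- "model {
    for (r in 1:N) { y[r] ~ dbern(ilogit(b0[g[r]] + b1[g[r]] * x[r])) }
    for (i in 1:I) {
      b0[i] ~ dnorm(mu0, pow(s0, -2))
      b1[i] ~ dnorm(mu1, pow(s1, -2))
    }
    mu0 ~ dnorm(0, 0.01); mu1 ~ dnorm(0, 0.01)
    s0 ~ dnorm(0, pow(5, -2)) T(0,); s1 ~ dnorm(0, pow(5, -2)) T(0,)
  }"
  jm <- rjags::jags.model(textConnection(m),
                          data = list(N = nrow(d), I = n_ind, x = d$x,
                                      y = d$used,
                                      g = as.integer(factor(d$individual_id))),
                          n.chains = 1, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  s <- rjags::coda.samples(jm, c("mu0", "mu1"), 4000,
                           progress.bar = "none")
  ref <- summary(s)$statistics[, "Mean"]
  post <- coef(fit)
  expect_lt(abs(post["(Intercept)"] - ref["mu0"]), 0.1)
  expect_lt(abs(post["x"] - ref["mu1"]), 0.1)
})

test_that("constant columns are rejected, not absorbed", {
  d <- sim_rows(300, c(x = 0.5), seed = 7)
  d$individual_id <- rep(c("a", "b"), 150)
  d$flat <- 1
  expect_error(rsf(used ~ x + flat, d), "constant-covariate.*flat")
})

test_that("intercept posterior concentrates at logit(1/11) for null data", {
  d <- do.call(rbind, lapply(c("a", "b", "c"), function(id)
    data.frame(individual_id = id, used = rep(c(1L, 0L), c(200, 2000)))))
  fit <- rsf(used ~ 1, d, iter = 1500, warmup = 750, chains = 2, seed = 8)
  expect_lt(abs(coef(fit)["(Intercept)"] - qlogis(1 / 11)), 0.1)
})

test_that("covariate order does not change the posterior", {
  d <- sim_rows(1500, c(x1 = 0.8, x2 = -0.5), seed = 9)
  d$individual_id <- rep(c("a", "b", "c"), 500)
  f1 <- rsf(used ~ x1 + x2, d, iter = 1500, warmup = 750, chains = 2,
            seed = 10)
  f2 <- rsf(used ~ x2 + x1, d, iter = 1500, warmup = 750, chains = 2,
            seed = 11)
  expect_lt(max(abs(coef(f1)[c("x1", "x2")] - coef(f2)[c("x1", "x2")])),
            0.1)
})

test_that("posterior predictive checks behave for well-fit and null models", {
  d <- sim_rows(1200, c(x = 0.9), seed = 12)
  d$individual_id <- rep(c("a", "b"), 600)
  fit <- rsf(used ~ x, d, iter = 1000, warmup = 500, chains = 2, seed = 13)
  ppc <- posterior_predictive_check(fit, ndraws = 200, seed = 14)
  overall <- ppc[ppc$statistic == "used_fraction", ]
  expect_equal(overall$replicated_mean, overall$observed, tolerance = 0.02)
  expect_gt(overall$tail_prob, 0.01)
  expect_lt(overall$tail_prob, 0.99)

  # intercept-only model on 1:10 design replicates the design fraction
  dn <- do.call(rbind, lapply(c("a", "b"), function(id)
    data.frame(individual_id = id, used = rep(c(1L, 0L), c(100, 1000)))))
  fn <- rsf(used ~ 1, dn, iter = 1000, warmup = 500, chains = 2, seed = 15)
  ppn <- posterior_predictive_check(fn, ndraws = 200, seed = 16)
  expect_lt(abs(ppn$replicated_mean[1] - 1 / 11), 0.01)

  # gross misfit is flagged by an extreme tail probability
  broken <- fit
  broken$data$y <- rbinom(length(fit$data$y), 1, 0.5)
  ppb <- posterior_predictive_check(broken, ndraws = 200, seed = 17)
  pb <- ppb$tail_prob[ppb$statistic == "used_fraction"]
  expect_true(pb < 0.05 || pb > 0.95)
})

test_that("random-effect spread recovers zero and ordered group sds", {
  make_d <- function(sig, seed) {
    set.seed(seed)
    do.call(rbind, lapply(1:10, function(i) {
      b <- 0.8 + rnorm(1, 0, sig)
      x <- rbinom(600, 1, 0.4)
      data.frame(individual_id = paste0("i", i), x = x,
                 used = rbinom(600, 1, plogis(-1 + b * x)))
    }))
  }
  f0 <- rsf(used ~ x, make_d(0, 18), iter = 1000, warmup = 500,
            chains = 2, seed = 19)
  sp0 <- random_effect_spread(f0)
  expect_lt(sp0$sigma$hdpi_high[sp0$sigma$covariate == "x"], 0.2)

  f5 <- rsf(used ~ x, make_d(0.5, 20), iter = 1000, warmup = 500,
            chains = 2, seed = 21)
  sp5 <- random_effect_spread(f5)
  expect_gt(sp5$sigma$mean[sp5$sigma$covariate == "x"],
            sp0$sigma$mean[sp0$sigma$covariate == "x"])

  # shrinkage symmetry: deviations average out across individuals
  dv <- sp5$deviations
  dx <- dv[dv$covariate == "x", ]
  pooled_se <- sd(dx$mean) / sqrt(nrow(dx))
  expect_lt(abs(mean(dx$mean)), 3 * pooled_se + 0.05)
})

test_that("rsf fit object supports the standard modelling verbs", {
  d <- sim_rows(900, c(x = 0.7), seed = 22)
  d$individual_id <- rep(c("a", "b", "c"), 300)
  fit <- rsf(used ~ x, d, iter = 600, warmup = 400, chains = 2, seed = 23)
  expect_s3_class(fit, "rsf")
  expect_output(print(fit), "Hierarchical Bayesian RSF")
  s <- summary(fit)
  expect_true(all(c("mu_x", "sigma_x") %in% s$parameter))
  expect_true(all(s$hdpi_low <= s$mean & s$mean <= s$hdpi_high))
  expect_equal(dim(coef(fit, "individual")), c(3L, 2L))
  pr <- predict(fit, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(length(residuals(fit)), nrow(d))
  sims <- simulate(fit, nsim = 5, seed = 24)
  expect_equal(dim(sims), c(nrow(d), 5L))
  expect_true(all(sims %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
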