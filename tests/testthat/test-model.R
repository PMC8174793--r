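test_that("the stacked log-likelihood matches a brute-force Bernoulli product", {
  sch <- toy_schema()
  d <- build_design(toy_attempts(), sch)
  beta <- seq(-0.5, 0.3, length.out = 9)
  # independent oracle: per-record product of Bernoulli terms
  brute <- 0
  for (i in seq_len(nrow(d$x))) {
    eta <- sum(d$x[i, ] * beta)
    p <- exp(eta) / (1 + exp(eta))
    brute <- brute + log(ifelse(d$y[i] == 1, p, 1 - p))
  }
  expect_equal(log_likelihood(beta, d), brute, tolerance = 1e-12)
  # empty product
  empty <- build_design(toy_attempts()[0, ], sch)
  expect_identical(log_likelihood(rep(0, 9), empty), 0)
  # one record at beta = 0 -> log(1/2)
  one <- build_design(toy_attempts()[1, ], sch)
  expect_equal(log_likelihood(rep(0, 9), one), log(0.5))
  expect_error(log_likelihood(rep(0, 3), d), "length")
})

test_that("the MLE agrees with glm and has a null score", {
  fx <- toy_quarter(n_cases = 250, seed = 8)
  d <- build_design(fx$attempts, fx$cfg$schema)
  fit <- fit_propensity(d)
  expect_true(fit$converged)
  expect_false(fit$ridged)
  # independent route: IRLS in stats::glm on the same matrix
  ref <- stats::glm.fit(d$x, d$y, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
  # score at the optimum vanishes
  p <- stats::plogis(drop(d$x %*% fit$coefficients))
  expect_lt(max(abs(crossprod(d$x, d$y - p))), 1e-6)
  # SEs match the observed-information route in summary.glm
  w <- p * (1 - p)
  vr <- solve(crossprod(d$x * w, d$x))
  expect_equal(unname(sqrt(diag(fit$vcov))), unname(sqrt(diag(vr))),
               tolerance = 1e-6)
})

test_that("a diffuse prior reproduces the MLE; an empty design returns the prior", {
  fx <- toy_quarter(n_cases = 80, seed = 21)
  sch <- fx$cfg$schema
  d <- build_design(fx$attempts, sch)
  mle <- fit_propensity(d)
  flat <- tibble::tibble(term = coef_names(sch), mean = 0, se = 1e6,
                         n_contributors = 20L, source = "expert")
  class(flat) <- c("prior_table", class(flat))
  map <- fit_propensity(d, prior = flat, method = "expert_map")
  expect_lt(max(abs(map$coefficients - mle$coefficients)), 1e-4)
  # prior-only posterior: mode is exactly the prior mean
  mu <- seq(-1, 1, length.out = n_coefficients(sch))
  pri <- tibble::tibble(term = coef_names(sch), mean = mu, se = 0.7,
                        n_contributors = 20L, source = "expert")
  class(pri) <- c("prior_table", class(pri))
  empty <- build_design(fx$attempts[0, ], sch)
  map0 <- fit_propensity(empty, prior = pri, method = "expert_map")
  expect_identical(unname(map0$coefficients), mu)
  expect_equal(unname(diag(map0$vcov)), rep(0.49, length(mu)))
  expect_error(fit_propensity(empty), "prior")
  expect_error(fit_propensity(d, prior = pri, method = "standard_mle"),
               "no prior")
})

test_that("separated data trips the ridge fallback; the MAP stays finite", {
  sch <- covariate_schema(covariate_spec("x", "categorical",
                                         c("lo", "hi")))
  att <- dplyr::bind_rows(
    att_row("A", 1, 1, outcome = 0), att_row("B", 1, 1, outcome = 0),
    att_row("C", 2, 1, outcome = 1), att_row("D", 2, 1, outcome = 1))
  att$region <- NULL
  att$x <- c("lo", "lo", "hi", "hi")  # perfect separation
  mle <- fit_propensity(att, sch)
  expect_true(mle$ridged)
  pri <- tibble::tibble(term = coef_names(sch), mean = 0, se = 1,
                        n_contributors = 20L, source = "expert")
  class(pri) <- c("prior_table", class(pri))
  map <- fit_propensity(att, sch, prior = pri, method = "expert_map")
  expect_true(map$converged)
  expect_true(all(is.finite(map$coefficients)))
  # grid-search oracle for the penalised optimum
  d <- build_design(att, sch)
  grid <- expand.grid(b0 = seq(-3, 3, 0.01), b1 = seq(-3, 3, 0.01))
  obj <- log_likelihood_grid <- apply(grid, 1, function(b) {
    log_likelihood(b, d) - 0.5 * sum(b^2)
  })
  best <- grid[which.max(obj), ]
  expect_equal(unname(map$coefficients),
               unname(unlist(best)), tolerance = 0.02)
})

test_that("predictions are inverse-logit and reproduce the attempt
          extrapolation arithmetic", {
  sch <- covariate_schema(covariate_spec("attempt_number", "continuous"))
  pri <- tibble::tibble(term = coef_names(sch),
                        mean = c(stats::qlogis(0.24), 0.26),
                        se = 0.5, n_contributors = 20L, source = "expert")
  class(pri) <- c("prior_table", class(pri))
  empty_att <- att_row("A", 1, 1)[0, ]
  fit <- fit_propensity(empty_att, sch, prior = pri,
                        method = "expert_map")
  rows <- tibble::tibble(attempt_number = c(0, 5, 10))
  p <- predict(fit, rows)
  expect_equal(p[1], 0.24, tolerance = 1e-12)
  # five attempts raise the propensity to 54%, ten to 81%
  expect_equal(round(100 * p[2]), 54)
  expect_equal(round(100 * p[3]), 81)
  expect_equal(round(p[3], 4), 0.8096)
  expect_true(all(p > 0 & p < 1))
  # monotone in a positive coefficient
  expect_true(all(diff(p) > 0))
  expect_error(predict(fit, matrix(1, 1, 5)), "columns")
})

test_that("the MAP shrinks between prior mean and MLE and is overtaken
          by the likelihood", {
  # one-coefficient model: intercept only
  sch <- covariate_schema()
  att <- dplyr::bind_rows(lapply(1:40, function(i) {
    r <- att_row(sprintf("C%02d", i), 1 + (i %% 5), 1,
                 outcome = as.integer(i %% 4 == 0))
    r$region <- NULL
    r
  }))
  mle <- fit_propensity(att, sch)$coefficients
  pri <- tibble::tibble(term = "(Intercept)", mean = 1, se = 0.8,
                        n_contributors = 20L, source = "expert")
  class(pri) <- c("prior_table", class(pri))
  map <- fit_propensity(att, sch, prior = pri)$coefficients
  expect_gt(map, mle)
  expect_lt(map, 1)
  # tighter prior sits closer to its mean
  pri2 <- pri; pri2$se <- 0.1
  map2 <- fit_propensity(att, sch, prior = pri2)$coefficients
  expect_gt(map2, map)
  # with more data the MAP approaches the MLE
  fx <- toy_quarter(n_cases = 400, seed = 13)
  sch2 <- fx$cfg$schema
  pri3 <- tibble::tibble(term = coef_names(sch2), mean = 0, se = 0.3,
                         n_contributors = 20L, source = "expert")
  class(pri3) <- c("prior_table", class(pri3))
  gaps <- vapply(c(10, 84), function(day) {
    d <- build_design(fx$attempts, sch2, through_day = day)
    max(abs(fit_propensity(d, prior = pri3)$coefficients -
              fit_propensity(d)$coefficients))
  }, numeric(1))
  expect_lt(gaps[2], gaps[1])
})

test_that("a full-covariance historical prior steers the MAP", {
  fx <- toy_quarter(n_cases = 150, seed = 17)
  sch <- fx$cfg$schema
  hp <- build_pwp_prior(list(Q = fx$attempts), sch)
  d <- build_design(fx$attempts, sch, through_day = 20)
  fit <- fit_propensity(d, prior = hp, method = "pwp_map")
  expect_true(fit$converged)
  expect_equal(fit$method, "pwp_map")
  # a non-PSD covariance is rejected
  hp_bad <- hp
  hp_bad$covariance[1, 2] <- hp_bad$covariance[2, 1] <- 10
  expect_error(fit_propensity(d, prior = hp_bad, method = "pwp_map"),
               "positive-definite")
})

test_that("MCMC posterior means agree with the Laplace MAP", {
  fx <- toy_quarter(n_cases = 200, seed = 23)
  sch <- fx$cfg$schema
  pri <- tibble::tibble(term = coef_names(sch), mean = 0, se = 1,
                        n_contributors = 20L, source = "expert")
  class(pri) <- c("prior_table", class(pri))
  d <- build_design(fx$attempts, sch)
  map <- fit_propensity(d, prior = pri, method = "expert_map")
  post <- fit_propensity(d, prior = pri, method = "mcmc",
                         mcmc = list(seed = 99, n_iter = 6000,
                                     burn = 2000))
  expect_error(fit_propensity(d, prior = pri, method = "mcmc"), "seed")
  draws <- post$mcmc$draws
  ess_floor <- nrow(draws) / 40  # conservative for a random-walk chain
  mcse <- apply(draws, 2, stats::sd) / sqrt(ess_floor)
  expect_true(all(abs(post$coefficients - map$coefficients) <= 3 * mcse))
})

test_that("tidy and glance expose the fit in broom shape", {
  fx <- toy_quarter(n_cases = 100, seed = 29)
  fit <- fit_propensity(fx$attempts, fx$cfg$schema)
  td <- tidy(fit)
  expect_equal(names(td), c("term", "estimate", "std.error"))
  expect_equal(td$term, coef_names(fx$cfg$schema))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(fx$attempts))
  expect_equal(gl$method, "standard_mle")
  expect_lt(gl$logLik, 0)
})
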