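test_that("rate-to-coefficient conversions match hand-computed odds ratios", {
  # worked example: 85% vs a 70% reference
  expect_equal(round(categorical_beta(0.85, 0.70), 4), 0.8873)
  # +5 points from the 24% attempt-level baseline
  expect_equal(round(continuous_beta(0.05, 0.24), 4), 0.2573)
  expect_equal(categorical_beta(0.37, 0.37), 0)
  expect_equal(categorical_beta(0.50, 0.25), log(3), tolerance = 1e-12)
  expect_equal(continuous_beta(0, 0.6), 0)
  expect_equal(continuous_beta(-0.10, 0.24),
               log((0.14 / 0.86) / (0.24 / 0.76)), tolerance = 1e-12)
  expect_equal(round(continuous_beta(-0.10, 0.24), 4), -0.6626)
})

test_that("degenerate rates are clipped with a warning, invalid ones rejected", {
  expect_error(categorical_beta(1.2, 0.5), "\\[0, 1\\]")
  expect_error(categorical_beta(0.5, -0.1), "\\[0, 1\\]")
  expect_warning(b <- categorical_beta(1, 0.5), "clipped")
  expect_equal(b, stats::qlogis(0.995) - stats::qlogis(0.5))
  expect_warning(continuous_beta(0.76, 0.24), "clipped")
  expect_error(continuous_beta(0.9, 0.24), "\\[0, 1\\]")
  expect_error(continuous_beta(0.1, 1.1), "baseline")
})

test_that("conversions are antisymmetric and monotone", {
  ps <- seq(0.05, 0.95, by = 0.09)
  for (a in ps) for (b in ps) {
    expect_equal(categorical_beta(a, b), -categorical_beta(b, a),
                 tolerance = 1e-12)
  }
  expect_true(all(diff(categorical_beta(ps, 0.4)) > 0))
  expect_true(all(diff(categorical_beta(0.4, ps)) < 0))
  expect_true(all(diff(continuous_beta(seq(-0.2, 0.5, 0.05), 0.24)) > 0))
})

test_that("arithmetic pooling gives mean and sd/sqrt(n)", {
  p <- pool_betas(c(0.8873, 0.2573, 0))
  expect_equal(round(p$mean, 4), 0.3815)
  expect_equal(round(p$se, 4), 0.2636)
  expect_equal(p$n, 3)
  expect_false(p$degenerate)
  # identical answers pool to a degenerate zero SE
  p2 <- pool_betas(rep(0.4, 5))
  expect_equal(p2$mean, 0.4)
  expect_equal(p2$se, 0)
  expect_true(p2$degenerate)
  # singleton: undefined SE, flagged
  p1 <- pool_betas(0.2)
  expect_true(is.na(p1$se) && p1$degenerate)
  expect_error(pool_betas(numeric(0)), "zero")
  # shifting all inputs shifts the mean and leaves the SE alone
  x <- c(-0.2, 0.1, 0.5, 0.9)
  expect_equal(pool_betas(x + 0.3)$mean, pool_betas(x)$mean + 0.3)
  expect_equal(pool_betas(x + 0.3)$se, pool_betas(x)$se)
})

test_that("prior tables apply the three-contributor rule and fallbacks", {
  sch <- toy_schema()
  # two experts answer region; three answer attempt_number
  panel <- dplyr::bind_rows(
    tidyr::expand_grid(expert_id = c("E1", "E2"), item = "region",
                       category = c("north", "south", "west")) |>
      dplyr::mutate(organization = "ISR", experience_band = "5-15",
                    elicited_value = rep(c(0.24, 0.20, 0.30), 2)),
    tibble::tibble(expert_id = c("E1", "E2", "E3"), organization = "ISR",
                   experience_band = "5-15", item = "attempt_number",
                   category = "(unit-change)",
                   elicited_value = c(-0.02, -0.01, -0.03)))
  pt <- build_prior_table(panel, sch, baseline = 0.24)
  expect_equal(pt$term, coef_names(sch))
  south <- pt[pt$term == "region=south", ]
  expect_equal(south$source, "diffuse_fallback")
  expect_equal(south$n_contributors, 2L)
  expect_equal(south$mean, 0)
  expect_equal(south$se, 10)
  att <- pt[pt$term == "attempt_number", ]
  expect_equal(att$source, "expert")
  expect_equal(att$n_contributors, 3L)
  expect_equal(att$mean, mean(continuous_beta(c(-0.02, -0.01, -0.03), 0.24)))
  # unanswered items fall back too
  expect_equal(pt$source[pt$term == "contact_status=ever"],
               "diffuse_fallback")
  # intercept is anchored at the baseline log-odds
  expect_equal(pt$mean[pt$term == "(Intercept)"], stats::qlogis(0.24))
  expect_equal(pt$se[pt$term == "(Intercept)"], 0.5)
  # pseudo_m = n is the identity; pseudo_m = 4n halves the SE
  pt_m <- build_prior_table(panel, sch, pseudo_m = 3)
  expect_equal(pt_m$se[pt_m$term == "attempt_number"], att$se)
  pt_m4 <- build_prior_table(panel, sch, pseudo_m = 12)
  expect_equal(pt_m4$se[pt_m4$term == "attempt_number"], att$se / 2)
  expect_error(build_prior_table(panel[0, ], sch), "empty")
  bad <- panel; bad$item[1] <- "shoe_size"
  expect_error(build_prior_table(bad, sch), "shoe_size")
})

test_that("identical answers floor the pooled SE so the prior stays proper", {
  sch <- covariate_schema(covariate_spec("flag", "categorical",
                                         c("no", "yes")))
  panel <- tibble::tibble(
    expert_id = paste0("E", 1:4), organization = "ISR",
    experience_band = "0-4", item = "flag", category = rep("yes", 4),
    elicited_value = 0.30) |>
    dplyr::bind_rows(tibble::tibble(
      expert_id = paste0("E", 1:4), organization = "ISR",
      experience_band = "0-4", item = "flag", category = "no",
      elicited_value = 0.24))
  pt <- build_prior_table(panel, sch)
  expect_equal(pt$se[pt$term == "flag=yes"], 1e-3)
  expect_gt(pt$se[pt$term == "flag=yes"], 0)
})

test_that("a noise-free synthetic panel inverts to beta_true exactly", {
  fx <- toy_quarter(n_cases = 1)
  pan <- simulate_expert_panel(fx$cfg, expert_panel_config(
    n_experts = 6, between_expert_sd = 0, within_item_sd = 0,
    item_nonresponse_prob = 0, seed = 2))
  eb <- expert_betas(pan, fx$cfg$schema, baseline = fx$cfg$baseline_rate)
  truth <- fx$cfg$beta_true[eb$term]
  expect_lt(max(abs(eb$beta - truth)), 1e-12)
  pt <- build_prior_table(pan, fx$cfg$schema,
                          baseline = fx$cfg$baseline_rate)
  keep <- pt$source == "expert"
  expect_lt(max(abs(pt$mean[keep] - fx$cfg$beta_true[pt$term[keep]])),
            1e-12)
})

test_that("subgroup summaries describe distributions without testing", {
  sch <- covariate_schema(covariate_spec("flag", "categorical",
                                         c("no", "yes")))
  set.seed(31)
  mk <- function(ids, org, shift) {
    dplyr::bind_rows(
      tibble::tibble(expert_id = ids, organization = org,
                     experience_band = "5-15", item = "flag",
                     category = "no", elicited_value = 0.24),
      tibble::tibble(expert_id = ids, organization = org,
                     experience_band = "5-15", item = "flag",
                     category = "yes",
                     elicited_value = stats::plogis(
                       stats::qlogis(0.24) + 0.4 + shift +
                         stats::rnorm(length(ids), 0, 0.05))))
  }
  panel <- dplyr::bind_rows(mk(sprintf("A%02d", 1:40), "ISR", 0),
                            mk(sprintf("B%02d", 1:40), "Census", 0.3))
  s <- summarize_expert_betas(panel, sch, by = "organization")
  expect_setequal(names(s), c("term", "organization", "n", "mean", "sd",
                              "min", "q1", "median", "q3", "max"))
  diff <- s$mean[s$organization == "Census"] -
    s$mean[s$organization == "ISR"]
  expect_equal(diff, 0.3, tolerance = 0.05)
  # two identical groups summarise identically
  panel2 <- dplyr::bind_rows(mk(sprintf("A%02d", 1:5), "ISR", 0.1))
  panel3 <- panel2; panel3$organization <- "Census"
  panel3$expert_id <- sub("A", "B", panel3$expert_id)
  s2 <- summarize_expert_betas(dplyr::bind_rows(panel2, panel3), sch,
                               by = "organization")
  expect_equal(s2$mean[1], s2$mean[2])
  expect_equal(s2$sd[1], s2$sd[2])
  # a single-expert group has no SD
  s3 <- summarize_expert_betas(mk("A01", "ISR", 0), sch,
                               by = "organization")
  expect_true(is.na(s3$sd))
})

test_that("panel and prior-table CSVs round-trip", {
  fx <- toy_quarter(n_cases = 1)
  pan <- simulate_expert_panel(fx$cfg, expert_panel_config(n_experts = 4,
                                                           seed = 5))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_expert_panel(pan, p1)
  expect_equal(read_expert_panel(p1), pan)
  pt <- build_prior_table(pan, fx$cfg$schema)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_prior_table(pt, p2)
  back <- read_prior_table(p2)
  expect_equal(back$mean, pt$mean)
  expect_equal(back$se, pt$se)
  expect_s3_class(back, "prior_table")
})
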