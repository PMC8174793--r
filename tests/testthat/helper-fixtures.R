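# Shared fixtures: a minimal schema and hand-built attempt histories.

toy_schema <- function() {
  covariate_schema(
    covariate_spec("region", "categorical", c("north", "south", "west")),
    covariate_spec("contact_status", "categorical",
                   c("never", "ever", "previous_attempt")),
    covariate_spec("concerns_status", "categorical",
                   c("none", "ever", "previous_attempt", "strong_ever")),
    covariate_spec("attempt_number", "continuous")
  )
}

# One attempt row with sensible defaults.
att_row <- function(case_id, day, attempt_index, outcome = 0,
                    contact_made = 0, concerns_expressed = 0,
                    strong_concerns_expressed = 0, region = "north") {
  tibble::tibble(case_id = case_id, day = day,
                 attempt_index = attempt_index, outcome = outcome,
                 contact_made = contact_made,
                 concerns_expressed = concerns_expressed,
                 strong_concerns_expressed = strong_concerns_expressed,
                 region = region)
}

toy_attempts <- function() {
  dplyr::bind_rows(
    att_row("A", 2, 1),
    att_row("A", 5, 2, contact_made = 1),
    att_row("A", 9, 3, outcome = 1, contact_made = 1),
    att_row("B", 3, 1, concerns_expressed = 1, region = "south"),
    att_row("B", 11, 2, region = "south"),
    att_row("C", 15, 1, strong_concerns_expressed = 1,
            concerns_expressed = 1, region = "west")
  )
}

# Small reproducible logistic fixture on the toy schema.
toy_quarter <- function(n_cases = 120, seed = 42) {
  cfg <- truth_config(
    schema = toy_schema(),
    beta_true = c("(Intercept)" = stats::qlogis(0.24),
                  "region=south" = -0.3, "region=west" = 0.25,
                  "contact_status=ever" = 0.5,
                  "contact_status=previous_attempt" = 0.8,
                  "concerns_status=ever" = -0.3,
                  "concerns_status=previous_attempt" = -0.5,
                  "concerns_status=strong_ever" = -0.9,
                  "attempt_number" = -0.06),
    n_cases = n_cases, seed = seed)
  list(cfg = cfg, attempts = simulate_quarter(cfg))
}
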