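#' Default true coefficient vector for the simulation schema
#'
#' Log-odds-scale effects paired with [sim_schema()]: an intercept at
#' `logit(0.24)` (the overall attempt-level response rate), moderate fixed
#' effects, positive contact-history effects, negative concern effects,
#' and a small per-attempt decline.
#'
#' @param baseline_rate Attempt-level response rate anchoring the
#'   intercept (default 0.24).
#' @return Named numeric vector aligned to `coef_names(sim_schema())`.
#' @export
sim_beta_true <- function(baseline_rate = 0.24) {
  c("(Intercept)" = stats::qlogis(baseline_rate),
    "domain=moderate_minority" = -0.10,
    "domain=high_minority" = -0.25,
    "msa_status=msa_non_self_rep" = -0.10,
    "msa_status=non_msa" = 0.15,
    "age_householder=45_59" = 0.20,
    "age_householder=missing" = -0.30,
    "non_english_evidence=yes" = -0.40,
    "contact_status=ever" = 0.50,
    "contact_status=previous_attempt" = 0.80,
    "concerns_status=ever" = -0.30,
    "concerns_status=previous_attempt" = -0.50,
    "concerns_status=strong_ever" = -0.90,
    "attempt_number" = -0.06)
}

#' Configure the synthetic paradata truth
#'
#' Bundles the data-generating process for one 84-day quarter of
#' two-stage screener contact attempts: the covariate schema, the true
#' coefficient vector of the discrete-time logistic response process, the
#' distributions of fixed covariates, and the attempt scheduling and
#' event-flag rates.
#'
#' @param schema A [covariate_schema()] whose fixed covariates are all
#'   categorical; defaults to [sim_schema()].
#' @param beta_true Named coefficient vector aligned to
#'   `coef_names(schema)`; defaults to [sim_beta_true()] for the default
#'   schema.
#' @param baseline_rate Overall expected attempt-level response rate
#'   (default 0.24); used as the intercept anchor and as the elicitation
#'   reference for continuous items.
#' @param n_cases Number of sampled housing units.
#' @param category_probs Optional named list: per fixed covariate, a
#'   probability vector over its categories (default uniform).
#' @param attempt_gap_mean Mean days between successive attempts on a
#'   case at mid-quarter (default 6).
#' @param attempt_gap_ramp Ratio of the day-1 attempt gap to the day-84
#'   attempt gap (default 20): field effort ramps up over the quarter
#'   (assignment ramp-up early, closeout push late), so contact attempt
#'   records accumulate sparsely early and densely late. `1` gives a
#'   constant attempt intensity.
#' @param contact_prob,concerns_prob,strong_concerns_prob Per-attempt
#'   event-flag probabilities (strong concerns imply concerns).
#' @param early_drift_sd SD (log-odds scale) of the per-quarter
#'   early-period coefficient drift (default 0.15). Each quarter draws a
#'   random deviation vector `delta ~ N(0, early_drift_sd^2)` applied to
#'   the response process with weight `max(0, 1 - day/drift_span)`: the
#'   process governing early attempts differs quarter by quarter and
#'   settles onto the long-run coefficients as collection proceeds. This
#'   is the generator's rendering of early-collection data that is
#'   systematically unrepresentative of the end-of-collection model —
#'   the condition that motivates informative priors in the first place.
#'   `0` gives a stationary within-quarter process.
#' @param drift_span Day by which the early drift has decayed to zero
#'   (default 60).
#' @param first_attempt_days Days over which first attempts are spread
#'   uniformly (default 1..7).
#' @param quarter_length Field period length in days (default 84).
#' @param seed Integer RNG seed.
#' @return A `truth_config` object.
#' @export
truth_config <- function(schema = sim_schema(), beta_true = NULL,
                         baseline_rate = 0.24, n_cases = 1000,
                         category_probs = NULL, attempt_gap_mean = 6,
                         attempt_gap_ramp = 20,
                         contact_prob = 0.35, concerns_prob = 0.15,
                         strong_concerns_prob = 0.05,
                         early_drift_sd = 0.15, drift_span = 60,
                         first_attempt_days = 1:7, quarter_length = 84,
                         seed = 1L) {
  stopifnot(inherits(schema, "covariate_schema"))
  if (is.null(beta_true)) {
    beta_true <- sim_beta_true(baseline_rate)
    if (!identical(names(beta_true), coef_names(schema))) {
      stop("beta_true must be supplied for a non-default schema",
           call. = FALSE)
    }
  }
  if (length(beta_true) != n_coefficients(schema)) {
    stop("beta_true length (", length(beta_true),
         ") does not match schema coefficient count (",
         n_coefficients(schema), ")", call. = FALSE)
  }
  if (is.null(names(beta_true))) names(beta_true) <- coef_names(schema)
  for (p in c(baseline_rate, contact_prob, concerns_prob,
              strong_concerns_prob)) {
    if (!is.finite(p) || p <= 0 || p >= 1) {
      stop("probabilities must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  stopifnot(attempt_gap_mean >= 1, attempt_gap_ramp >= 1, n_cases >= 0,
            quarter_length >= 1, early_drift_sd >= 0, drift_span >= 1)
  structure(
    list(schema = schema, beta_true = beta_true,
         baseline_rate = baseline_rate, n_cases = as.integer(n_cases),
         category_probs = category_probs,
         attempt_gap_mean = attempt_gap_mean,
         attempt_gap_ramp = attempt_gap_ramp, contact_prob = contact_prob,
         concerns_prob = concerns_prob,
         strong_concerns_prob = strong_concerns_prob,
         early_drift_sd = early_drift_sd, drift_span = drift_span,
         first_attempt_days = first_attempt_days,
         quarter_length = as.integer(quarter_length), seed = as.integer(seed)),
    class = "truth_config")
}

#' Simulate one quarter of contact-attempt paradata
#'
#' Draws fixed covariates per case, schedules attempts from day 1 with a
#' uniform first-attempt day and 1 + geometric inter-attempt gaps
#' truncated at the end of the quarter, draws per-attempt event flags,
#' and generates each attempt's response from the discrete-time logistic
#' truth — with the design row including the time-varying covariates
#' derived from the case's earlier attempts. A case stops attempting at
#' its first response. The schedule and event flags are drawn before the
#' outcomes, so under a fixed seed they are common random numbers across
#' different `beta_true` values.
#'
#' @param cfg A [truth_config()].
#' @return Attempts tibble (see [load_attempts()] for columns), valid
#'   under [validate_attempts()].
#' @export
simulate_quarter <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  set.seed(cfg$seed)
  simulate_quarter_impl(cfg)
}

# Body shared with simulate_history(): uses the current RNG state.
simulate_quarter_impl <- function(cfg) {
  schema <- cfg$schema
  n <- cfg$n_cases
  empty <- tibble::tibble(
    case_id = character(0), day = integer(0), attempt_index = integer(0),
    outcome = integer(0), contact_made = integer(0),
    concerns_expressed = integer(0), strong_concerns_expressed = integer(0))
  for (nm in fixed_spec_names(schema)) empty[[nm]] <- character(0)
  if (n == 0) return(empty)

  # per-quarter early-period process drift (drawn first so the rest of
  # the stream is common random numbers across beta_true values)
  delta <- stats::rnorm(n_coefficients(schema), 0, cfg$early_drift_sd)

  case_id <- sprintf("C%05d", seq_len(n))
  fixed <- tibble::tibble(case_id = case_id)
  for (nm in fixed_spec_names(schema)) {
    s <- schema_spec(schema, nm)
    if (s$kind != "categorical") {
      stop("the generator draws categorical fixed covariates only; '",
           nm, "' is continuous", call. = FALSE)
    }
    lev <- s$categories[[1]]
    pr <- cfg$category_probs[[nm]]
    if (is.null(pr)) pr <- rep(1 / length(lev), length(lev))
    fixed[[nm]] <- sample(lev, n, replace = TRUE, prob = pr)
  }

  # stage 1: full potential attempt schedule + event flags (outcome-free)
  day1 <- sample(cfg$first_attempt_days, n, replace = TRUE)
  sched <- vector("list", 40)
  cur <- day1
  w <- 0
  repeat {
    alive <- which(cur <= cfg$quarter_length)
    if (!length(alive)) break
    w <- w + 1
    sched[[w]] <- tibble::tibble(case = alive, day = cur[alive],
                                 attempt_index = w)
    # day-dependent gap: effort ramps from sparse to dense over the quarter
    gm <- pmax(1, cfg$attempt_gap_mean *
                 cfg$attempt_gap_ramp^(0.5 - cur[alive] / cfg$quarter_length))
    gap <- 1 + stats::rgeom(length(alive), prob = 1 / gm)
    cur[alive] <- cur[alive] + gap
    cur[-alive] <- cfg$quarter_length + 1
  }
  att <- dplyr::bind_rows(sched[seq_len(w)])
  att <- dplyr::arrange(att, .data$case, .data$attempt_index)
  m <- nrow(att)
  strong <- stats::rbinom(m, 1, cfg$strong_concerns_prob)
  concerns <- pmax(stats::rbinom(m, 1, cfg$concerns_prob), strong)
  contact <- stats::rbinom(m, 1, cfg$contact_prob)
  u <- stats::runif(m)

  rows <- tibble::tibble(
    case_id = case_id[att$case], day = as.integer(att$day),
    attempt_index = as.integer(att$attempt_index),
    outcome = 0L, contact_made = contact, concerns_expressed = concerns,
    strong_concerns_expressed = strong)
  rows <- dplyr::left_join(rows, fixed, by = "case_id")

  # stage 2: causal time-varying covariates, then sequential outcomes
  rows <- add_time_varying(rows)
  x <- rows_to_matrix(rows, schema)
  w_drift <- pmax(0, 1 - rows$day / cfg$drift_span)
  eta <- drop(x %*% cfg$beta_true) + w_drift * drop(x %*% delta)
  p <- stats::plogis(eta)
  rows$outcome <- as.integer(u < p)

  # truncate each case at its first response
  rows <- rows |>
    dplyr::group_by(.data$case_id) |>
    dplyr::mutate(.resp_before = dplyr::lag(cumsum(.data$outcome),
                                            default = 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$.resp_before == 0) |>
    dplyr::select(-".resp_before",
                  -"contact_status", -"concerns_status", -"attempt_number")
  dplyr::arrange(rows, .data$case_id, .data$attempt_index)
}

#' Configure a simulated expert panel
#'
#' Describes how elicited attempt-level response rates are generated from
#' the truth: an expert-level offset and an item-level error, both on the
#' log-odds scale, plus item nonresponse and panel composition metadata.
#'
#' @param n_experts Number of experts (default 20).
#' @param between_expert_sd SD of the per-expert log-odds offset shared
#'   across that expert's answers (default 0.15). For categorical items
#'   this offset cancels in the within-expert odds ratio, mimicking a
#'   consistent personal anchor.
#' @param within_item_sd SD of the per-answer log-odds error
#'   (default 0.2).
#' @param item_nonresponse_prob Probability an expert skips a whole item
#'   (default 0.1).
#' @param organizations Named probability vector over organization labels
#'   (default `c(ISR = 0.4, Census = 0.6)`, matching an 8 + 12 panel).
#' @param experience_bands Named probability vector over experience
#'   labels (default over `0-4`, `5-15`, `15+` years).
#' @param seed Integer RNG seed.
#' @return An `expert_panel_config` object.
#' @export
expert_panel_config <- function(n_experts = 20, between_expert_sd = 0.15,
                                within_item_sd = 0.2,
                                item_nonresponse_prob = 0.1,
                                organizations = c(ISR = 0.4, Census = 0.6),
                                experience_bands = c("0-4" = 0.25,
                                                     "5-15" = 0.5,
                                                     "15+" = 0.25),
                                seed = 1L) {
  stopifnot(n_experts >= 1, between_expert_sd >= 0, within_item_sd >= 0,
            item_nonresponse_prob >= 0, item_nonresponse_prob < 1)
  structure(
    list(n_experts = as.integer(n_experts),
         between_expert_sd = between_expert_sd,
         within_item_sd = within_item_sd,
         item_nonresponse_prob = item_nonresponse_prob,
         organizations = organizations,
         experience_bands = experience_bands, seed = as.integer(seed)),
    class = "expert_panel_config")
}

#' Simulate an expert elicitation panel
#'
#' Each expert's elicited rate for category k of a categorical item is
#' `plogis(qlogis(p_k_true) + b_i + e_ik)` where `p_k_true` is the
#' truth-implied attempt-level rate at the baseline
#' (`plogis(qlogis(baseline) + beta_true_k)`, the reference category
#' sitting at the baseline itself), `b_i` is the expert offset and `e_ik`
#' the answer error. Continuous items are elicited as rate changes: the
#' truth-implied change per unit is perturbed the same way on the
#' log-odds scale. Experts answer every category of an item or skip the
#' item entirely. With both SDs at zero the elicitation conversion
#' recovers `beta_true` exactly.
#'
#' @param truth A [truth_config()].
#' @param cfg An [expert_panel_config()].
#' @return Expert-response tibble with columns `expert_id`,
#'   `organization`, `experience_band`, `item`, `category`,
#'   `elicited_value`. Continuous items use category `"(unit-change)"`
#'   and an elicited change in rate; categorical items an elicited rate.
#' @export
simulate_expert_panel <- function(truth, cfg) {
  stopifnot(inherits(truth, "truth_config"),
            inherits(cfg, "expert_panel_config"))
  set.seed(cfg$seed)
  schema <- truth$schema
  base <- truth$baseline_rate
  l0 <- stats::qlogis(base)
  beta <- truth$beta_true

  ids <- sprintf("E%02d", seq_len(cfg$n_experts))
  orgs <- sample(names(cfg$organizations), cfg$n_experts, replace = TRUE,
                 prob = cfg$organizations)
  bands <- sample(names(cfg$experience_bands), cfg$n_experts, replace = TRUE,
                  prob = cfg$experience_bands)
  b_i <- stats::rnorm(cfg$n_experts, 0, cfg$between_expert_sd)

  out <- list()
  for (e in seq_len(cfg$n_experts)) {
    for (i in seq_len(nrow(schema$specs))) {
      s <- schema$specs[i, ]
      if (stats::runif(1) < cfg$item_nonresponse_prob) next
      if (s$kind == "categorical") {
        lev <- s$categories[[1]]
        coefs <- ifelse(lev == s$reference, 0,
                        beta[paste0(s$name, "=", lev)])
        err <- stats::rnorm(length(lev), 0, cfg$within_item_sd)
        rate <- stats::plogis(l0 + coefs + b_i[e] + err)
        out[[length(out) + 1]] <- tibble::tibble(
          expert_id = ids[e], organization = orgs[e],
          experience_band = bands[e], item = s$name, category = lev,
          elicited_value = unname(rate))
      } else {
        delta_true <- stats::plogis(l0 + beta[s$name]) - base
        err <- stats::rnorm(1, 0, cfg$within_item_sd)
        delta <- stats::plogis(stats::qlogis(base + delta_true) +
                                 b_i[e] + err) - base
        out[[length(out) + 1]] <- tibble::tibble(
          expert_id = ids[e], organization = orgs[e],
          experience_band = bands[e], item = s$name,
          category = "(unit-change)", elicited_value = unname(delta))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(expert_id = character(0),
                          organization = character(0),
                          experience_band = character(0),
                          item = character(0), category = character(0),
                          elicited_value = numeric(0)))
  }
  dplyr::bind_rows(out)
}

#' Simulate a collection of historical quarters
#'
#' Generates `n_quarters` independent quarters from the same truth, each
#' with a deterministically derived seed, optionally offsetting
#' `beta_true` by `drift` to emulate a historical period whose response
#' process differed from the current one.
#'
#' @param truth A [truth_config()].
#' @param n_quarters Number of historical quarters (>= 1).
#' @param drift Optional numeric offset added to `beta_true` (scalar or
#'   aligned vector).
#' @return A list of attempts tibbles, named `Q1`, `Q2`, ...
#' @export
simulate_history <- function(truth, n_quarters, drift = NULL) {
  stopifnot(inherits(truth, "truth_config"))
  if (n_quarters < 1) stop("n_quarters must be >= 1", call. = FALSE)
  cfg <- truth
  if (!is.null(drift)) cfg$beta_true <- cfg$beta_true + drift
  out <- vector("list", n_quarters)
  for (q in seq_len(n_quarters)) {
    cfg$seed <- derive_seed(truth$seed, q)
    out[[q]] <- simulate_quarter(cfg)
  }
  names(out) <- paste0("Q", seq_len(n_quarters))
  out
}

# Deterministic per-component substream seed, kept inside 32-bit range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 10007) %% 2147483647L)
}
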