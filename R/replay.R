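#' Fit the end-of-quarter target propensities
#'
#' Fits the discrete-time model by maximum likelihood to all contact
#' attempt records of the quarter and evaluates, for every case with at
#' least one attempt, the predicted response probability at that case's
#' last observed contact attempt. These per-case values are the
#' benchmark the daily replay predictions are scored against.
#'
#' @param attempts Validated attempts tibble.
#' @param schema A [covariate_schema()].
#' @return Tibble with `case_id` and `rho` (all strictly in (0, 1));
#'   the full-quarter `propensity_fit` is attached as attribute `"fit"`.
#' @export
fit_target <- function(attempts, schema) {
  design <- build_design(attempts, schema)
  if (design$empty) stop("cannot fit a target on an empty quarter",
                         call. = FALSE)
  fit <- fit_propensity(design)
  p <- predict(fit, design)
  last <- tibble::tibble(case_id = design$case_id,
                         attempt_index = design$attempt_index, rho = p) |>
    dplyr::group_by(.data$case_id) |>
    dplyr::slice_max(.data$attempt_index, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("case_id", "rho")
  attr(last, "fit") <- fit
  last
}

#' Replay a quarter day by day under several methods
#'
#' For each day `d` of the replay window, refits each method on the
#' contact attempt records accumulated through day `d` and predicts the
#' response propensity at the next contact attempt for every active
#' nonrespondent case on day `d` ([select_active()]). The standard
#' method is the current-data-only MLE; the expert method is MAP under
#' the elicited diagonal prior; the pwp method is MAP under the
#' historical precision-weighted prior.
#'
#' @param attempts Validated attempts tibble.
#' @param schema A [covariate_schema()].
#' @param priors Named list supplying `expert` (a `prior_table`) and/or
#'   `pwp` (a `historical_prior`) as the requested methods need.
#' @param methods Subset of `c("standard", "expert", "pwp")`.
#' @param days Replay days (default 7:84, the 78 evaluation days).
#' @return A `replay_result`: `predictions` tibble (`method`, `day`,
#'   `case_id`, `p_hat`) and `fits` tibble (`method`, `day`,
#'   `n_records`, `n_active`, `converged`, `ridged`).
#' @export
replay_daily <- function(attempts, schema, priors = list(),
                         methods = c("standard", "expert", "pwp"),
                         days = 7:84) {
  methods <- match.arg(methods, several.ok = TRUE)
  if ("expert" %in% methods && !inherits(priors$expert, "prior_table")) {
    stop("method 'expert' needs priors$expert (a prior_table)",
         call. = FALSE)
  }
  if ("pwp" %in% methods && !inherits(priors$pwp, "historical_prior")) {
    stop("method 'pwp' needs priors$pwp (a historical_prior)",
         call. = FALSE)
  }
  full <- build_design(attempts, schema)
  nxt <- next_attempt_states(attempts, schema)
  preds <- list()
  fits <- list()
  for (d in days) {
    idx <- full$day <= d
    day_design <- structure(
      list(x = full$x[idx, , drop = FALSE], y = full$y[idx],
           case_id = full$case_id[idx], day = full$day[idx],
           attempt_index = full$attempt_index[idx], empty = !any(idx),
           schema = schema),
      class = "design_matrix")
    sel <- nxt$day <= d & nxt$next_day > d & nxt$responded_by == 0 &
      (is.na(nxt$finalized_day) | nxt$finalized_day > d)
    active <- list(case_id = nxt$case_id[sel],
                   x = nxt$x[sel, , drop = FALSE])
    for (m in methods) {
      fit <- switch(m,
        standard = fit_propensity(day_design),
        expert = fit_propensity(day_design, prior = priors$expert,
                                method = "expert_map"),
        pwp = fit_propensity(day_design, prior = priors$pwp,
                             method = "pwp_map"))
      n_active <- length(active$case_id)
      fits[[length(fits) + 1]] <- tibble::tibble(
        method = m, day = d, n_records = fit$n_records,
        n_active = n_active, converged = fit$converged,
        ridged = fit$ridged)
      if (n_active > 0) {
        preds[[length(preds) + 1]] <- tibble::tibble(
          method = m, day = d, case_id = active$case_id,
          p_hat = predict(fit, active$x))
      }
    }
  }
  structure(
    list(predictions = dplyr::bind_rows(preds),
         fits = dplyr::bind_rows(fits), days = days, methods = methods),
    class = "replay_result")
}

# Precompute, for every observed attempt row, the covariate row of the
# hypothetical *next* attempt on that case together with the day window
# over which that row is the case's latest attempt. Lets the daily
# replay select each day's active set by a plain logical filter; agrees
# row-for-row with select_active().
next_attempt_states <- function(attempts, schema) {
  rows <- attempts |>
    dplyr::group_by(.data$case_id) |>
    dplyr::arrange(.data$attempt_index, .by_group = TRUE) |>
    dplyr::mutate(
      .contact_ever = cumsum(.data$contact_made) > 0,
      .concern_ever = cumsum(.data$concerns_expressed) > 0,
      .strong_ever = cumsum(.data$strong_concerns_expressed) > 0,
      contact_status = dplyr::case_when(
        .data$contact_made == 1 ~ "previous_attempt",
        .data$.contact_ever ~ "ever",
        TRUE ~ "never"),
      concerns_status = dplyr::case_when(
        .data$.strong_ever ~ "strong_ever",
        .data$concerns_expressed == 1 ~ "previous_attempt",
        .data$.concern_ever ~ "ever",
        TRUE ~ "none"),
      attempt_number = as.numeric(.data$attempt_index) + 1,
      responded_by = cummax(.data$outcome),
      next_day = dplyr::lead(as.numeric(.data$day), default = Inf)
    ) |>
    dplyr::ungroup()
  fin <- if ("finalized_day" %in% names(attempts)) {
    rows$finalized_day
  } else {
    rep(NA_real_, nrow(rows))
  }
  list(x = rows_to_matrix(rows, schema), case_id = rows$case_id,
       day = rows$day, next_day = rows$next_day,
       responded_by = rows$responded_by, finalized_day = fin)
}

#' @export
print.replay_result <- function(x, ...) {
  cat("<replay_result> methods ", paste(x$methods, collapse = "/"),
      "; days ", min(x$days), "-", max(x$days), "; ",
      nrow(x$predictions), " case-day predictions\n", sep = "")
  invisible(x)
}

#' Score one day's predictions against the target
#'
#' Daily mean bias `mean(p_hat - rho)` and daily RMSE
#' `sqrt(mean((p_hat - rho)^2))` over the day's active cases.
#'
#' @param predicted Predicted propensities for the day's active set.
#' @param target Matching target propensities, aligned element-wise.
#' @return One-row tibble with `bias`, `rmse`, `n`; an empty set yields
#'   `n = 0` with `NA` metrics (the day is flagged and omitted from
#'   summaries).
#' @export
evaluate_day <- function(predicted, target) {
  if (length(predicted) != length(target)) {
    stop("predicted and target must be aligned", call. = FALSE)
  }
  n <- length(predicted)
  if (n == 0) {
    return(tibble::tibble(bias = NA_real_, rmse = NA_real_, n = 0L))
  }
  err <- predicted - target
  tibble::tibble(bias = mean(err), rmse = sqrt(mean(err^2)), n = n)
}

#' Daily bias and RMSE series for a replay
#'
#' Joins the replay's case-day predictions to the per-case target
#' propensities and computes the daily bias and RMSE per method.
#'
#' @param replay A `replay_result` from [replay_daily()].
#' @param target Target tibble from [fit_target()].
#' @return A `propensity_eval` tibble: `method`, `day`, `n_active`,
#'   `bias`, `rmse`, `converged`. Days with no active cases appear with
#'   `n_active = 0` and `NA` metrics.
#' @export
evaluate_replay <- function(replay, target) {
  stopifnot(inherits(replay, "replay_result"))
  joined <- dplyr::inner_join(replay$predictions, target, by = "case_id")
  daily <- joined |>
    dplyr::group_by(.data$method, .data$day) |>
    dplyr::summarise(evaluate_day(.data$p_hat, .data$rho),
                     .groups = "drop") |>
    dplyr::rename(n_active = "n")
  grid <- tidyr::expand_grid(method = replay$methods, day = replay$days)
  out <- grid |>
    dplyr::left_join(daily, by = c("method", "day")) |>
    dplyr::mutate(n_active = dplyr::coalesce(.data$n_active, 0L)) |>
    dplyr::left_join(
      dplyr::select(replay$fits, "method", "day", "converged"),
      by = c("method", "day"))
  class(out) <- c("propensity_eval", class(out))
  out
}

phase_of <- function(day) {
  dplyr::case_when(day >= 7 & day <= 30 ~ "early",
                   day >= 31 & day <= 60 ~ "middle",
                   day >= 61 & day <= 84 ~ "late")
}

#' Phase summaries of the daily evaluation series
#'
#' Summarises the daily bias and RMSE values over the three parts of the
#' data collection period — early (days 7–30), middle (days 31–60) and
#' late (days 61–84) — with the five-number summary plus the mean, per
#' method and metric: the numbers behind phase boxplots. Quartiles use
#' linear interpolation between order statistics (type 7). Days with no
#' active cases or missing metrics are excluded; `n_days` reports how
#' many daily values each summary covers.
#'
#' @param eval_series A `propensity_eval` from [evaluate_replay()].
#' @return Tibble with `method`, `phase`, `metric`, `n_days`, `min`,
#'   `q1`, `median`, `mean`, `q3`, `max`.
#' @export
phase_summary <- function(eval_series) {
  long <- eval_series |>
    dplyr::mutate(phase = phase_of(.data$day)) |>
    dplyr::filter(!is.na(.data$phase)) |>
    tidyr::pivot_longer(c("bias", "rmse"), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  long |>
    dplyr::group_by(.data$method, .data$phase, .data$metric) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      min = min(.data$value),
      q1 = stats::quantile(.data$value, 0.25, type = 7, names = FALSE),
      median = stats::median(.data$value),
      mean = mean(.data$value),
      q3 = stats::quantile(.data$value, 0.75, type = 7, names = FALSE),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(phase = factor(.data$phase,
                                 levels = c("early", "middle", "late"))) |>
    dplyr::arrange(.data$metric, .data$phase, .data$method)
}
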