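#' Convert elicited rates to log-odds-ratio coefficients
#'
#' `categorical_beta()` turns an expert's elicited attempt-level response
#' rate for a category, together with that expert's rate for the
#' reference category, into a logistic-regression coefficient:
#' `log(odds(p_k) / odds(p_ref))`. `continuous_beta()` does the same for
#' an elicited change in rate per unit of a continuous predictor, with
#' the overall attempt-level baseline rate as the reference:
#' `log(odds(baseline + delta) / odds(baseline))`.
#'
#' Rates exactly at 0 or 1 (or changes driving the rate there) carry
#' infinite log-odds; they are clipped into `clip` with a warning so a
#' single extreme answer does not discard an expert.
#'
#' @param p_k Elicited rate for the category of interest, in `[0, 1]`.
#' @param p_ref Elicited rate for the reference category, in `[0, 1]`.
#' @param delta Elicited change in rate per unit increase.
#' @param baseline Overall attempt-level response rate (default 0.24).
#' @param clip Two-element clipping range applied to rates before the
#'   log-odds transform.
#' @return Log-odds-ratio coefficient(s); vectorised.
#' @export
#' @examples
#' categorical_beta(0.85, 0.70) # 0.8873
#' continuous_beta(0.05, 0.24)  # 0.2573
categorical_beta <- function(p_k, p_ref, clip = c(0.005, 0.995)) {
  p_k <- clip_rate(p_k, clip, "p_k")
  p_ref <- clip_rate(p_ref, clip, "p_ref")
  stats::qlogis(p_k) - stats::qlogis(p_ref)
}

#' @rdname categorical_beta
#' @export
continuous_beta <- function(delta, baseline = 0.24, clip = c(0.005, 0.995)) {
  if (any(!is.finite(baseline) | baseline <= 0 | baseline >= 1)) {
    stop("baseline must lie strictly in (0, 1)", call. = FALSE)
  }
  shifted <- clip_rate(baseline + delta, clip, "baseline + delta")
  stats::qlogis(shifted) - stats::qlogis(baseline)
}

clip_rate <- function(p, clip, what) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  out <- pmin(pmax(p, clip[1]), clip[2])
  if (any(out != p)) {
    warning(what, " at the boundary of (0, 1); clipped to [",
            clip[1], ", ", clip[2], "]", call. = FALSE)
  }
  out
}

#' Arithmetically pool per-expert coefficients
#'
#' The pooled prior mean is the arithmetic mean of the experts'
#' coefficients; its standard error is the sample standard deviation
#' divided by the square root of the number of contributing experts.
#'
#' @param betas Numeric vector of per-expert log-odds coefficients.
#' @return One-row tibble with `mean`, `se`, `n`, and `degenerate`
#'   (`TRUE` when `se` is 0 or undefined: identical answers or a single
#'   contributor). A single contributor yields `se = NA` (flagged); an
#'   empty input is an error.
#' @export
#' @examples
#' pool_betas(c(0.8873, 0.2573, 0))
pool_betas <- function(betas) {
  betas <- betas[is.finite(betas)]
  n <- length(betas)
  if (n == 0) stop("cannot pool zero coefficients", call. = FALSE)
  m <- mean(betas)
  se <- if (n >= 2) stats::sd(betas) / sqrt(n) else NA_real_
  tibble::tibble(mean = m, se = se, n = n,
                 degenerate = is.na(se) || se == 0)
}

#' Per-expert coefficients implied by an elicitation panel
#'
#' Applies [categorical_beta()] within each expert and item (using that
#' expert's own reference-category answer) and [continuous_beta()] for
#' unit-change items, yielding one coefficient per expert per
#' non-reference coefficient. Experts missing the reference category of
#' an item contribute nothing for that item.
#'
#' @param panel Expert-response tibble (see [simulate_expert_panel()] or
#'   [read_expert_panel()]).
#' @param schema A [covariate_schema()].
#' @param baseline Overall attempt-level response rate used as the
#'   continuous-item reference (default 0.24).
#' @param clip Rate clipping range (see [categorical_beta()]).
#' @return Tibble with `expert_id`, `organization`, `experience_band`,
#'   `term`, `beta`.
#' @export
expert_betas <- function(panel, schema, baseline = 0.24,
                         clip = c(0.005, 0.995)) {
  stopifnot(inherits(schema, "covariate_schema"))
  if (nrow(panel) == 0) stop("empty expert panel", call. = FALSE)
  unknown <- setdiff(unique(panel$item), schema$specs$name)
  if (length(unknown)) {
    stop("panel contains unknown item(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (nm in unique(panel$item)) {
    s <- schema_spec(schema, nm)
    sub <- panel[panel$item == nm, , drop = FALSE]
    if (s$kind == "categorical") {
      bad <- setdiff(unique(sub$category), s$categories[[1]])
      if (length(bad)) {
        stop("item '", nm, "' has unknown category '", bad[1], "'",
             call. = FALSE)
      }
      ref <- sub[sub$category == s$reference,
                 c("expert_id", "elicited_value")]
      names(ref)[2] <- ".ref_rate"
      oth <- sub[sub$category != s$reference, , drop = FALSE]
      oth <- dplyr::inner_join(oth, ref, by = "expert_id")
      if (nrow(oth) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        expert_id = oth$expert_id, organization = oth$organization,
        experience_band = oth$experience_band,
        term = paste0(nm, "=", oth$category),
        beta = categorical_beta(oth$elicited_value, oth$.ref_rate,
                                clip = clip))
    } else {
      out[[length(out) + 1]] <- tibble::tibble(
        expert_id = sub$expert_id, organization = sub$organization,
        experience_band = sub$experience_band, term = nm,
        beta = continuous_beta(sub$elicited_value, baseline, clip = clip))
    }
  }
  if (!length(out)) stop("panel contributed no coefficients", call. = FALSE)
  dplyr::bind_rows(out)
}

#' Build a pooled normal prior table from an expert panel
#'
#' Converts each expert's answers to coefficients ([expert_betas()]),
#' pools them per coefficient ([pool_betas()]), and assembles the
#' diagonal normal prior for the propensity model. Coefficients with
#' fewer than three contributing experts receive a diffuse fallback
#' prior `N(0, fallback_se^2)` (their contributor count is still
#' recorded); the intercept receives `N(qlogis(baseline),
#' intercept_se^2)`. Pooled standard errors of exactly zero (identical
#' answers) are floored at `se_floor` so the prior stays proper. Setting
#' `pseudo_m` rescales every expert-sourced SE as if it had been pooled
#' over `m` experts (`se = sd / sqrt(m)`).
#'
#' The prior covariance is diagonal by construction: with a panel of
#' this size the between-coefficient covariance of elicited answers is
#' ignored.
#'
#' @inheritParams expert_betas
#' @param min_contributors Minimum experts per coefficient before the
#'   pooled prior is used (default 3).
#' @param pseudo_m Optional pseudo sample size for SE rescaling.
#' @param fallback_se Diffuse fallback SD (default 10).
#' @param intercept_se Intercept prior SD (default 0.5).
#' @param se_floor Lower bound on pooled SEs (default 1e-3).
#' @return A `prior_table` tibble: `term`, `mean`, `se`,
#'   `n_contributors`, `source` (`expert`, `intercept_anchor` or
#'   `diffuse_fallback`), ordered as [coef_names()]; the baseline rate
#'   is carried as an attribute.
#' @export
build_prior_table <- function(panel, schema, baseline = 0.24,
                              min_contributors = 3, pseudo_m = NULL,
                              fallback_se = 10, intercept_se = 0.5,
                              se_floor = 1e-3, clip = c(0.005, 0.995)) {
  eb <- expert_betas(panel, schema, baseline = baseline, clip = clip)
  pooled <- eb |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(pool_betas(.data$beta), .groups = "drop")
  if (!is.null(pseudo_m)) {
    pooled$se <- pooled$se * sqrt(pooled$n) / sqrt(pseudo_m)
  }
  terms <- coef_names(schema)
  out <- tibble::tibble(term = terms) |>
    dplyr::left_join(pooled, by = "term") |>
    dplyr::mutate(
      n_contributors = dplyr::coalesce(.data$n, 0L),
      source = dplyr::case_when(
        .data$term == "(Intercept)" ~ "intercept_anchor",
        .data$n_contributors >= min_contributors ~ "expert",
        TRUE ~ "diffuse_fallback"
      ),
      mean = dplyr::case_when(
        .data$source == "intercept_anchor" ~ stats::qlogis(baseline),
        .data$source == "expert" ~ .data$mean,
        TRUE ~ 0
      ),
      se = dplyr::case_when(
        .data$source == "intercept_anchor" ~ intercept_se,
        .data$source == "expert" ~ pmax(dplyr::coalesce(.data$se, se_floor),
                                        se_floor),
        TRUE ~ fallback_se
      )
    ) |>
    dplyr::select("term", "mean", "se", "n_contributors", "source")
  attr(out, "baseline_rate") <- baseline
  class(out) <- c("prior_table", class(out))
  out
}

#' Summarise per-expert coefficients by panel subgroup
#'
#' Descriptive distribution summaries of the individual experts'
#' coefficients by organization or experience band — counts, means, SDs
#' and five-number summaries per group per coefficient. Panels of this
#' size do not support significance testing, and none is performed.
#'
#' @inheritParams expert_betas
#' @param by Grouping variable: `"organization"` or `"experience_band"`.
#' @return Tibble with `term`, the grouping column, `n`, `mean`, `sd`
#'   (`NA` for single-expert groups), `min`, `q1`, `median`, `q3`,
#'   `max`.
#' @export
summarize_expert_betas <- function(panel, schema,
                                   by = c("organization",
                                          "experience_band"),
                                   baseline = 0.24) {
  by <- match.arg(by)
  eb <- expert_betas(panel, schema, baseline = baseline)
  if (any(is.na(eb[[by]]))) {
    stop("grouping label '", by, "' missing for some experts",
         call. = FALSE)
  }
  eb |>
    dplyr::group_by(.data$term, .data[[by]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$beta),
      sd = if (dplyr::n() >= 2) stats::sd(.data$beta) else NA_real_,
      min = min(.data$beta),
      q1 = stats::quantile(.data$beta, 0.25, names = FALSE),
      median = stats::median(.data$beta),
      q3 = stats::quantile(.data$beta, 0.75, names = FALSE),
      max = max(.data$beta),
      .groups = "drop"
    )
}

#' Read or write an expert panel or prior table as CSV
#'
#' Panel CSVs carry `expert_id`, `organization`, `experience_band`,
#' `item`, `category`, `elicited_value`; prior-table CSVs carry `term`,
#' `mean`, `se`, `n_contributors`, `source`.
#'
#' @param path CSV file path.
#' @param x Object to write.
#' @param baseline Baseline rate restored onto a read prior table.
#' @return The read tibble, or `path` invisibly for writers.
#' @export
read_expert_panel <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("expert_id", "organization", "experience_band", "item",
            "category", "elicited_value")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("expert panel is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_expert_panel
#' @export
write_expert_panel <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_expert_panel
#' @export
read_prior_table <- function(path, baseline = 0.24) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("term", "mean", "se", "n_contributors", "source")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("prior table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(df, "baseline_rate") <- baseline
  class(df) <- c("prior_table", class(df))
  df
}

#' @rdname read_expert_panel
#' @export
write_prior_table <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}
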