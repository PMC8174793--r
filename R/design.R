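#' Build the stacked design matrix for the discrete-time model
#'
#' Expands the attempts accumulated through a given field day into the
#' person-attempt design matrix of the discrete-time logistic model: one
#' row per attempt record, an intercept column of ones, reference-coded
#' indicator columns for categorical covariates, continuous covariates
#' passed through, and the derived time-varying covariates
#' (contact/concerns status entering the attempt, attempt number).
#'
#' @param attempts Validated attempts tibble (see [load_attempts()]).
#' @param schema A [covariate_schema()].
#' @param through_day Last field day whose records are included
#'   (default `Inf`, i.e. the full quarter).
#' @return An object of class `design_matrix`: list with the numeric
#'   matrix `x` (columns ordered as [coef_names()]), response `y`, and
#'   aligned `case_id`, `day`, `attempt_index` vectors. `empty` flags a
#'   zero-row design.
#' @export
build_design <- function(attempts, schema, through_day = Inf) {
  stopifnot(inherits(schema, "covariate_schema"), through_day >= 1)
  sub <- dplyr::filter(attempts, .data$day <= through_day)
  sub <- dplyr::arrange(sub, .data$case_id, .data$attempt_index)
  if (nrow(sub) == 0) {
    return(structure(
      list(x = matrix(numeric(0), 0, n_coefficients(schema),
                      dimnames = list(NULL, coef_names(schema))),
           y = numeric(0), case_id = character(0), day = integer(0),
           attempt_index = integer(0), empty = TRUE, schema = schema),
      class = "design_matrix"))
  }
  sub <- add_time_varying(sub)
  x <- rows_to_matrix(sub, schema)
  structure(
    list(x = x, y = as.numeric(sub$outcome), case_id = sub$case_id,
         day = sub$day, attempt_index = sub$attempt_index, empty = FALSE,
         schema = schema),
    class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix> ", nrow(x$x), " attempt records x ", ncol(x$x),
      " coefficients; ", sum(x$y), " responses\n", sep = "")
  invisible(x)
}

# Turn covariate rows (one column per schema spec name; time-varying
# columns already present) into the numeric design matrix.
rows_to_matrix <- function(rows, schema) {
  cn <- coef_names(schema)
  x <- matrix(0, nrow(rows), length(cn), dimnames = list(NULL, cn))
  x[, "(Intercept)"] <- 1
  for (i in seq_len(nrow(schema$specs))) {
    s <- schema$specs[i, ]
    v <- rows[[s$name]]
    if (is.null(v)) stop("missing covariate column '", s$name, "'",
                         call. = FALSE)
    if (s$kind == "categorical") {
      v <- as.character(v)
      for (lev in setdiff(s$categories[[1]], s$reference)) {
        x[, paste0(s$name, "=", lev)] <- as.numeric(v == lev)
      }
    } else {
      x[, s$name] <- as.numeric(v)
    }
  }
  x
}

#' Select the active nonrespondent risk set on a field day
#'
#' Active cases on day `d` are those with at least one attempt on or
#' before `d`, no response on or before `d`, and (when a `finalized_day`
#' column is present) not finalized by `d`. Each active case is paired
#' with the covariates of a hypothetical next attempt: attempt number one
#' past its last observed attempt, and contact/concerns status derived
#' from its full history through `d`. Cases never attempted by day `d`
#' are excluded — there is no attempt history from which to derive the
#' time-varying covariates.
#'
#' @param attempts Validated attempts tibble.
#' @param schema A [covariate_schema()].
#' @param day Field day, 1..84.
#' @return A `design_matrix` whose rows are next-attempt covariate rows
#'   for active cases (its `y` is `NA`; `case_id` identifies the cases).
#'   Zero active cases yields an empty design.
#' @export
select_active <- function(attempts, schema, day) {
  stopifnot(day >= 1)
  seen <- dplyr::filter(attempts, .data$day <= !!day)
  if ("finalized_day" %in% names(seen)) {
    fin <- seen$finalized_day
    seen <- seen[is.na(fin) | fin > day, , drop = FALSE]
  }
  if (nrow(seen) == 0) {
    d <- build_design(attempts[0, , drop = FALSE], schema)
    d$y <- numeric(0)
    return(d)
  }
  last <- seen |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(responded = any(.data$outcome == 1),
                     last_index = max(.data$attempt_index),
                     .groups = "drop") |>
    dplyr::filter(!.data$responded)
  if (nrow(last) == 0) {
    d <- build_design(attempts[0, , drop = FALSE], schema)
    d$y <- numeric(0)
    return(d)
  }
  # next-attempt state: derive per case from full history through `day`
  rows <- seen |>
    dplyr::semi_join(last, by = "case_id") |>
    dplyr::group_by(.data$case_id) |>
    dplyr::arrange(.data$attempt_index, .by_group = TRUE) |>
    dplyr::summarise(
      contact_status = dplyr::case_when(
        .data$contact_made[dplyr::n()] == 1 ~ "previous_attempt",
        any(.data$contact_made == 1) ~ "ever",
        TRUE ~ "never"
      ),
      concerns_status = dplyr::case_when(
        any(.data$strong_concerns_expressed == 1) ~ "strong_ever",
        .data$concerns_expressed[dplyr::n()] == 1 ~ "previous_attempt",
        any(.data$concerns_expressed == 1) ~ "ever",
        TRUE ~ "none"
      ),
      attempt_number = max(.data$attempt_index) + 1,
      dplyr::across(dplyr::all_of(fixed_spec_names(schema)), dplyr::first),
      .groups = "drop"
    )
  x <- rows_to_matrix(rows, schema)
  structure(
    list(x = x, y = rep(NA_real_, nrow(rows)), case_id = rows$case_id,
         day = rep(day, nrow(rows)),
         attempt_index = rows$attempt_number, empty = nrow(rows) == 0,
         schema = schema),
    class = "design_matrix")
}
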