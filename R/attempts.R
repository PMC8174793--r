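#' Load contact-attempt paradata from CSV
#'
#' One row per contact attempt: `case_id`, `day` (1-based day of the
#' 84-day quarter), `attempt_index` (1-based within case), binary
#' `outcome` (screener completed on that attempt), the per-attempt event
#' flags `contact_made`, `concerns_expressed`, `strong_concerns_expressed`,
#' and one column per fixed covariate declared in the schema. An optional
#' `finalized_day` column (refusal/ineligible) removes a case from the
#' risk set from that day onward.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param schema A [covariate_schema()]; fixed covariates are validated
#'   against it.
#' @param quarter_length Last valid field day (default 84).
#' @return A validated attempts tibble sorted by (`case_id`,
#'   `attempt_index`).
#' @export
load_attempts <- function(path, schema, quarter_length = 84) {
  if (!file.exists(path)) stop("attempts file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_attempts(df, schema, quarter_length = quarter_length)
}

#' @rdname load_attempts
#' @param attempts An attempts tibble to validate in place of a file.
#' @export
validate_attempts <- function(attempts, schema, quarter_length = 84) {
  stopifnot(inherits(schema, "covariate_schema"))
  required <- c("case_id", "day", "attempt_index", "outcome", "contact_made",
                "concerns_expressed", "strong_concerns_expressed",
                fixed_spec_names(schema))
  missing <- setdiff(required, names(attempts))
  if (length(missing)) {
    stop("attempts data is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  attempts <- dplyr::arrange(tibble::as_tibble(attempts),
                             .data$case_id, .data$attempt_index)
  if (nrow(attempts) == 0) return(attempts)

  bad_day <- attempts$day < 1 | attempts$day > quarter_length |
    attempts$day != floor(attempts$day)
  if (any(bad_day)) {
    stop("day outside 1..", quarter_length, " for case(s): ",
         paste(utils::head(unique(attempts$case_id[bad_day]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (!all(attempts$outcome %in% c(0, 1))) {
    stop("outcome must be 0/1", call. = FALSE)
  }
  for (fl in c("contact_made", "concerns_expressed",
               "strong_concerns_expressed")) {
    if (!all(attempts[[fl]] %in% c(0, 1))) {
      stop(fl, " must be 0/1", call. = FALSE)
    }
  }

  # per-case ordering and terminal-response invariants
  chk <- attempts |>
    dplyr::group_by(.data$case_id) |>
    dplyr::summarise(
      idx_ok = all(diff(.data$attempt_index) > 0) &&
        all(diff(.data$day) >= 0),
      one_resp = sum(.data$outcome) <= 1,
      resp_last = sum(.data$outcome) == 0 ||
        .data$outcome[dplyr::n()] == 1,
      .groups = "drop"
    )
  if (!all(chk$idx_ok)) {
    stop("attempt_index must be strictly increasing (and day non-decreasing)",
         " within case; offending case(s): ",
         paste(utils::head(chk$case_id[!chk$idx_ok], 5), collapse = ", "),
         call. = FALSE)
  }
  if (!all(chk$one_resp & chk$resp_last)) {
    bad <- chk$case_id[!(chk$one_resp & chk$resp_last)]
    stop("a case may respond at most once and only on its last attempt; ",
         "offending case(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }

  # categorical values must be declared
  for (nm in fixed_spec_names(schema)) {
    s <- schema_spec(schema, nm)
    if (s$kind == "categorical") {
      vals <- as.character(attempts[[nm]])
      bad <- !vals %in% s$categories[[1]]
      if (any(bad)) {
        stop("covariate '", nm, "' has undeclared value '",
             vals[which(bad)[1]], "' (case ",
             attempts$case_id[which(bad)[1]], ")", call. = FALSE)
      }
      attempts[[nm]] <- vals
    } else {
      attempts[[nm]] <- as.numeric(attempts[[nm]])
    }
  }
  attempts
}

#' @rdname load_attempts
#' @export
write_attempts <- function(attempts, path) {
  readr::write_csv(attempts, path, progress = FALSE)
  invisible(path)
}

#' Derive time-varying covariates from a case's attempt history
#'
#' Statuses for the `up_to_attempt`-th attempt are functions of the
#' strictly earlier attempts only (indices `< up_to_attempt`):
#' * `contact_status`: `previous_attempt` if contact was made on the
#'   immediately preceding attempt, else `ever` if on any earlier attempt,
#'   else `never`.
#' * `concerns_status`: `strong_ever` if strong concerns were ever
#'   expressed, else `previous_attempt` if concerns were expressed on the
#'   immediately preceding attempt, else `ever` if on any earlier attempt,
#'   else `none`. The most specific/severe label wins.
#' * `attempt_number`: `up_to_attempt` itself.
#'
#' @param history Attempts tibble for a single case, sorted by
#'   `attempt_index`.
#' @param up_to_attempt 1-based index of the attempt whose covariates are
#'   wanted (may be one past the observed history for a hypothetical next
#'   attempt).
#' @return Named list with `contact_status`, `concerns_status`,
#'   `attempt_number`.
#' @export
#' @examples
#' derive_time_varying(data.frame(
#'   case_id = 1, day = 1, attempt_index = 1, outcome = 0,
#'   contact_made = 1, concerns_expressed = 0,
#'   strong_concerns_expressed = 0), up_to_attempt = 2)
derive_time_varying <- function(history, up_to_attempt) {
  stopifnot(up_to_attempt >= 1)
  if (nrow(history) > 1 && length(unique(history$case_id)) > 1) {
    stop("history must belong to a single case", call. = FALSE)
  }
  if (is.unsorted(history$attempt_index, strictly = TRUE)) {
    stop("history must be sorted by attempt_index", call. = FALSE)
  }
  prior <- history[history$attempt_index < up_to_attempt, , drop = FALSE]
  prev <- prior[which.max(prior$attempt_index), , drop = FALSE]

  contact <- if (nrow(prior) == 0 || !any(prior$contact_made == 1)) {
    "never"
  } else if (nrow(prev) && prev$contact_made == 1) {
    "previous_attempt"
  } else {
    "ever"
  }
  concerns <- if (nrow(prior) && any(prior$strong_concerns_expressed == 1)) {
    "strong_ever"
  } else if (nrow(prev) && prev$concerns_expressed == 1) {
    "previous_attempt"
  } else if (nrow(prior) && any(prior$concerns_expressed == 1)) {
    "ever"
  } else {
    "none"
  }
  list(contact_status = contact, concerns_status = concerns,
       attempt_number = as.numeric(up_to_attempt))
}

# Vectorised version over a full attempts tibble: adds contact_status,
# concerns_status, attempt_number columns giving the state *entering* each
# observed attempt. Matches derive_time_varying row by row.
add_time_varying <- function(attempts) {
  attempts |>
    dplyr::group_by(.data$case_id) |>
    dplyr::arrange(.data$attempt_index, .by_group = TRUE) |>
    dplyr::mutate(
      .contact_prev = dplyr::lag(.data$contact_made, default = 0),
      .contact_ever = dplyr::lag(cumsum(.data$contact_made), default = 0) > 0,
      .concern_prev = dplyr::lag(.data$concerns_expressed, default = 0),
      .concern_ever =
        dplyr::lag(cumsum(.data$concerns_expressed), default = 0) > 0,
      .strong_ever =
        dplyr::lag(cumsum(.data$strong_concerns_expressed), default = 0) > 0,
      contact_status = dplyr::case_when(
        .data$.contact_prev == 1 ~ "previous_attempt",
        .data$.contact_ever ~ "ever",
        TRUE ~ "never"
      ),
      concerns_status = dplyr::case_when(
        .data$.strong_ever ~ "strong_ever",
        .data$.concern_prev == 1 ~ "previous_attempt",
        .data$.concern_ever ~ "ever",
        TRUE ~ "none"
      ),
      attempt_number = as.numeric(.data$attempt_index)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::starts_with("."))
}
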