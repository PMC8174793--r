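#' Define a single covariate
#'
#' A covariate specification describes one predictor of attempt-level
#' response: its name, whether it is categorical or continuous, its
#' categories and reference category (categorical only), and how experts
#' are asked about it (a rate per category, or a rate change per unit).
#'
#' Three names are reserved for time-varying covariates derived from the
#' contact-attempt history rather than read from the data: `contact_status`
#' (never / ever / previous_attempt), `concerns_status` (none / ever /
#' previous_attempt / strong_ever) and `attempt_number` (continuous count).
#'
#' @param name Covariate name (unique within a schema).
#' @param kind `"categorical"` or `"continuous"`.
#' @param categories Ordered character vector of category labels
#'   (categorical only; length >= 2, unique).
#' @param reference Reference category label; must be one of `categories`.
#'   Defaults to the first category.
#' @param elicitation_mode `"rate_per_category"` (categorical default) or
#'   `"change_per_unit"` (required for continuous covariates).
#' @return A one-row tibble representing the spec.
#' @export
#' @examples
#' covariate_spec("domain", "categorical", c("low", "high"))
covariate_spec <- function(name, kind = c("categorical", "continuous"),
                           categories = NULL, reference = NULL,
                           elicitation_mode = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2) {
      stop("categorical covariate '", name, "' needs >= 2 categories",
           call. = FALSE)
    }
    if (anyDuplicated(categories)) {
      stop("categories of '", name, "' must be unique", call. = FALSE)
    }
    if (is.null(reference)) reference <- categories[[1]]
    if (!reference %in% categories) {
      stop("reference '", reference, "' of '", name,
           "' is not among its categories", call. = FALSE)
    }
    if (is.null(elicitation_mode)) elicitation_mode <- "rate_per_category"
  } else {
    if (!is.null(categories)) {
      stop("continuous covariate '", name, "' cannot have categories",
           call. = FALSE)
    }
    if (!is.null(elicitation_mode) && elicitation_mode != "change_per_unit") {
      stop("continuous covariate '", name,
           "' must use elicitation_mode 'change_per_unit'", call. = FALSE)
    }
    elicitation_mode <- "change_per_unit"
    reference <- NA_character_
  }
  elicitation_mode <- match.arg(elicitation_mode,
                                c("rate_per_category", "change_per_unit"))
  tibble::tibble(
    name = as.character(name), kind = kind,
    categories = list(categories), reference = reference,
    elicitation_mode = elicitation_mode,
    time_varying = name %in% time_varying_names()
  )
}

time_varying_names <- function() {
  c("contact_status", "concerns_status", "attempt_number")
}

#' Assemble a covariate schema
#'
#' Collects covariate specs into an ordered schema for the discrete-time
#' propensity model. The intercept is implicit and always occupies
#' coefficient position 0; categorical covariates contribute one
#' coefficient per non-reference category, continuous covariates one each.
#'
#' @param ... One or more specs created by [covariate_spec()], or a single
#'   data frame of stacked specs.
#' @return An object of class `covariate_schema`.
#' @seealso [coef_names()], [nsfg_schema()], [sim_schema()]
#' @export
covariate_schema <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.data.frame(dots[[1]])) {
    specs <- tibble::as_tibble(dots[[1]])
  } else if (length(dots) == 0) {
    specs <- covariate_spec("x", "continuous")[0, ]  # typed empty prototype
  } else {
    specs <- dplyr::bind_rows(dots)
  }
  if (anyDuplicated(specs$name)) {
    stop("covariate names must be unique", call. = FALSE)
  }
  out <- list(specs = specs)
  class(out) <- "covariate_schema"
  out
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("<covariate_schema> ", nrow(x$specs), " covariates, ",
      n_coefficients(x), " coefficients (incl. intercept)\n", sep = "")
  for (i in seq_len(nrow(x$specs))) {
    s <- x$specs[i, ]
    if (s$kind == "categorical") {
      cat("  ", s$name, ": ", paste(s$categories[[1]], collapse = "/"),
          " (ref ", s$reference, ")",
          if (s$time_varying) " [time-varying]", "\n", sep = "")
    } else {
      cat("  ", s$name, ": continuous",
          if (s$time_varying) " [time-varying]", "\n", sep = "")
    }
  }
  invisible(x)
}

#' Coefficient labels implied by a schema
#'
#' Labels follow the `name=category` convention for non-reference
#' categories of categorical covariates, the bare name for continuous
#' covariates, and `(Intercept)` first. Prior tables, design matrices and
#' fitted coefficient vectors all share this ordering.
#'
#' @param schema A [covariate_schema()].
#' @return Character vector of coefficient names, intercept first.
#' @export
coef_names <- function(schema) {
  stopifnot(inherits(schema, "covariate_schema"))
  out <- "(Intercept)"
  for (i in seq_len(nrow(schema$specs))) {
    s <- schema$specs[i, ]
    if (s$kind == "categorical") {
      lev <- setdiff(s$categories[[1]], s$reference)
      out <- c(out, paste0(s$name, "=", lev))
    } else {
      out <- c(out, s$name)
    }
  }
  out
}

#' @rdname coef_names
#' @export
n_coefficients <- function(schema) length(coef_names(schema))

schema_spec <- function(schema, name) {
  i <- match(name, schema$specs$name)
  if (is.na(i)) stop("unknown covariate '", name, "'", call. = FALSE)
  schema$specs[i, ]
}

fixed_spec_names <- function(schema) {
  schema$specs$name[!schema$specs$time_varying]
}

#' Default NSFG-style screener schema
#'
#' A reconstruction of the predictor set used for screener response
#' propensity in a two-stage national in-person survey: sampling-frame
#' geography (9-level Census division, self-representing / MSA status),
#' sociodemographic sampling domain, household characteristics from
#' commercial data (age of householder with an explicit Missing category,
#' household income, mail delivery point type, listing procedure, evidence
#' of a non-English-speaking household), and the time-varying paradata
#' covariates (contact status, concerns status, attempt count). The exact
#' production covariate list is not public; this schema is a faithful
#' reconstruction, intended as a realistic default and as configuration
#' for the elicitation templates.
#'
#' @return A [covariate_schema()].
#' @export
nsfg_schema <- function() {
  covariate_schema(
    covariate_spec("census_division", "categorical",
                   c("new_england", "middle_atlantic", "east_north_central",
                     "west_north_central", "south_atlantic",
                     "east_south_central", "west_south_central", "mountain",
                     "pacific")),
    covariate_spec("msa_status", "categorical",
                   c("self_representing", "msa_non_self_rep", "non_msa")),
    covariate_spec("domain", "categorical",
                   c("low_minority", "moderate_minority", "high_minority")),
    covariate_spec("age_householder", "categorical",
                   c("18_44", "45_59", "60_plus", "missing")),
    covariate_spec("income_10k", "continuous"),
    covariate_spec("mail_delivery", "categorical",
                   c("curbline", "door_slot", "central", "other")),
    covariate_spec("listing_procedure", "categorical",
                   c("on_foot_alone", "on_foot_pair", "car_alone",
                     "car_pair")),
    covariate_spec("non_english_evidence", "categorical", c("no", "yes")),
    covariate_spec("contact_status", "categorical",
                   c("never", "ever", "previous_attempt")),
    covariate_spec("concerns_status", "categorical",
                   c("none", "ever", "previous_attempt", "strong_ever")),
    covariate_spec("attempt_number", "continuous")
  )
}

#' Compact schema used by the synthetic-data defaults
#'
#' A reduced covariate set (14 coefficients) that keeps simulation studies
#' fast while retaining the structural features of the full screener
#' model: fixed categorical covariates, an explicit Missing category, and
#' all three derived time-varying covariates.
#'
#' @return A [covariate_schema()].
#' @export
sim_schema <- function() {
  covariate_schema(
    covariate_spec("domain", "categorical",
                   c("low_minority", "moderate_minority", "high_minority")),
    covariate_spec("msa_status", "categorical",
                   c("self_representing", "msa_non_self_rep", "non_msa")),
    covariate_spec("age_householder", "categorical",
                   c("18_44", "45_59", "missing")),
    covariate_spec("non_english_evidence", "categorical", c("no", "yes")),
    covariate_spec("contact_status", "categorical",
                   c("never", "ever", "previous_attempt")),
    covariate_spec("concerns_status", "categorical",
                   c("none", "ever", "previous_attempt", "strong_ever")),
    covariate_spec("attempt_number", "continuous")
  )
}

#' Read or write a schema as YAML or JSON
#'
#' The on-disk form mirrors [covariate_spec()] fields exactly: a list of
#' specs each with `name`, `kind`, and for categorical covariates
#' `categories` and `reference`; `elicitation_mode` is optional and
#' defaults as in [covariate_spec()].
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param schema A [covariate_schema()] (for writing).
#' @return `read_schema()` returns a [covariate_schema()];
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop("schema file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  specs <- purrr::map(raw$specs, function(s) {
    covariate_spec(
      name = s$name, kind = s$kind,
      categories = if (!is.null(s$categories)) unlist(s$categories),
      reference = s$reference, elicitation_mode = s$elicitation_mode
    )
  })
  covariate_schema(dplyr::bind_rows(specs))
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "covariate_schema"))
  specs <- purrr::pmap(schema$specs, function(name, kind, categories,
                                              reference, elicitation_mode,
                                              time_varying) {
    s <- list(name = name, kind = kind)
    if (kind == "categorical") {
      s$categories <- as.list(categories)
      s$reference <- reference
    }
    s$elicitation_mode <- elicitation_mode
    s
  })
  obj <- list(specs = specs)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path)
  }
  invisible(path)
}
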