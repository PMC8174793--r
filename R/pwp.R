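#' Build a precision-weighted prior from historical quarters
#'
#' The historical comparator to expert elicitation: each historical
#' quarter is fit by full-quarter maximum likelihood, and the per-quarter
#' estimates are pooled by inverse-variance weighting. The prior
#' precision is the sum of the per-quarter precisions (optionally
#' deflated by `kappa`), and the prior mean is the precision-weighted
#' average of the per-quarter coefficient vectors. Unlike the expert
#' prior, the covariance is carried in full — historical fits supply
#' estimated between-coefficient covariances.
#'
#' Quarters whose maximum-likelihood fit does not converge are excluded
#' with a warning; a near-singular per-quarter covariance is
#' ridge-stabilised with a warning. This construction is a
#' reconstruction of the precision-weighted prior approach from its
#' description (inverse-variance pooling of per-quarter fits); a stacked
#' single fit over all historical quarters is available by concatenating
#' the quarters and calling [fit_propensity()] directly.
#'
#' @param history List of attempts tibbles (e.g. from
#'   [simulate_history()]), or a single tibble.
#' @param schema A [covariate_schema()].
#' @param kappa Precision inflation factor `>= 1`: the pooled covariance
#'   is multiplied by `kappa`, widening the prior (default 1).
#' @return A `historical_prior`: named `mean` vector, full `covariance`
#'   matrix, `quarters` used, `kappa`.
#' @export
build_pwp_prior <- function(history, schema, kappa = 1) {
  stopifnot(inherits(schema, "covariate_schema"), kappa >= 1)
  if (is.data.frame(history)) history <- list(Q1 = history)
  if (length(history) < 1) stop("need at least one historical quarter",
                                call. = FALSE)
  if (is.null(names(history)) || any(names(history) == "")) {
    names(history) <- paste0("Q", seq_along(history))
  }
  terms <- coef_names(schema)
  p <- length(terms)
  prec_sum <- matrix(0, p, p)
  wmean_sum <- rep(0, p)
  used <- character(0)
  for (q in names(history)) {
    fit <- fit_propensity(history[[q]], schema)
    if (!fit$converged) {
      warning("historical quarter ", q,
              " failed to converge; excluded from the prior",
              call. = FALSE)
      next
    }
    prec_q <- tryCatch(solve(fit$vcov), error = function(e) NULL)
    if (is.null(prec_q)) {
      warning("historical quarter ", q,
              " has a singular covariance; ridge-stabilised",
              call. = FALSE)
      prec_q <- solve(fit$vcov + diag(1e-8, p))
    }
    prec_sum <- prec_sum + prec_q
    wmean_sum <- wmean_sum + drop(prec_q %*% fit$coefficients)
    used <- c(used, q)
  }
  if (!length(used)) {
    stop("no historical quarter produced a usable fit", call. = FALSE)
  }
  mean <- drop(solve(prec_sum, wmean_sum))
  covariance <- kappa * solve(prec_sum)
  covariance <- (covariance + t(covariance)) / 2
  structure(
    list(mean = stats::setNames(mean, terms),
         covariance = structure(covariance, dimnames = list(terms, terms)),
         quarters = used, kappa = kappa),
    class = "historical_prior")
}

#' @export
print.historical_prior <- function(x, ...) {
  cat("<historical_prior> ", length(x$quarters), " quarter(s): ",
      paste(x$quarters, collapse = ", "), "; kappa=", x$kappa, "\n",
      sep = "")
  print(round(x$mean, 4))
  invisible(x)
}

#' Read or write a historical prior as JSON
#'
#' @param path JSON file path.
#' @param x A `historical_prior` to write.
#' @return The read `historical_prior`, or `path` invisibly.
#' @export
read_historical_prior <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- obj$terms
  structure(
    list(mean = stats::setNames(as.numeric(obj$mean), terms),
         covariance = structure(matrix(as.numeric(unlist(obj$covariance)),
                                       length(terms), length(terms),
                                       byrow = TRUE),
                                dimnames = list(terms, terms)),
         quarters = obj$quarters, kappa = obj$kappa),
    class = "historical_prior")
}

#' @rdname read_historical_prior
#' @export
write_historical_prior <- function(x, path) {
  obj <- list(terms = names(x$mean), mean = unname(x$mean),
              covariance = apply(x$covariance, 1, as.numeric,
                                 simplify = FALSE),
              quarters = x$quarters, kappa = x$kappa)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
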