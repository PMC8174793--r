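#' In-sample fit metrics for a propensity model
#'
#' ROC-AUC — the probability that a randomly chosen responding attempt
#' record scores above a randomly chosen non-responding one, ties
#' counted one half — and the Nagelkerke pseudo-R², computed over the
#' attempt records of the supplied design (all attempt records by
#' default, matching the in-sample use of these statistics for the
#' full-quarter target model).
#'
#' Nagelkerke's R² rescales Cox–Snell:
#' `[1 - exp((2/n) * (ll0 - ll1))] / [1 - exp((2/n) * ll0)]`
#' with `ll0` the intercept-only log-likelihood.
#'
#' @param fit A `propensity_fit`.
#' @param design The in-sample `design_matrix` the fit is evaluated on.
#' @return One-row tibble with `roc_auc`, `nagelkerke_r2`, `n`. A
#'   single-class response leaves `roc_auc` as `NA` with a warning.
#' @export
fit_metrics <- function(fit, design) {
  stopifnot(inherits(fit, "propensity_fit"),
            inherits(design, "design_matrix"))
  y <- design$y
  n <- length(y)
  if (n == 0) stop("empty design", call. = FALSE)
  score <- predict(fit, design)
  auc <- if (length(unique(y)) < 2) {
    warning("single-class response; ROC-AUC undefined", call. = FALSE)
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                   levels = c(0, 1), direction = "<",
                                   quiet = TRUE)))
  }
  ll1 <- log_likelihood(fit$coefficients, design)
  pbar <- mean(y)
  ll0 <- if (pbar %in% c(0, 1)) 0 else
    sum(y * log(pbar) + (1 - y) * log(1 - pbar))
  r2_cs <- 1 - exp((2 / n) * (ll0 - ll1))
  r2_n <- r2_cs / (1 - exp((2 / n) * ll0))
  tibble::tibble(roc_auc = auc, nagelkerke_r2 = r2_n, n = n)
}
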