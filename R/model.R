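#' Discrete-time logistic log-likelihood
#'
#' The stacked person-attempt Bernoulli log-likelihood: each attempt
#' record contributes `y * log(p) + (1 - y) * log(1 - p)` with
#' `p = plogis(x' beta)`. An empty design contributes 0 (the empty
#' product).
#'
#' @param beta Coefficient vector aligned to the design columns.
#' @param design A `design_matrix` from [build_design()].
#' @return Scalar log-likelihood, finite for finite `beta`.
#' @export
log_likelihood <- function(beta, design) {
  stopifnot(inherits(design, "design_matrix"))
  if (length(beta) != ncol(design$x)) {
    stop("beta length (", length(beta), ") does not match design columns (",
         ncol(design$x), ")", call. = FALSE)
  }
  if (nrow(design$x) == 0) return(0)
  eta <- drop(design$x %*% beta)
  sum(design$y * stats::plogis(eta, log.p = TRUE) +
        (1 - design$y) * stats::plogis(-eta, log.p = TRUE))
}

# Normalise any supported prior object to list(mu, prec, cov) in the
# order of `terms`.
as_prior_gaussian <- function(prior, terms) {
  if (is.null(prior)) return(NULL)
  p <- length(terms)
  if (inherits(prior, "prior_table")) {
    i <- match(terms, prior$term)
    if (anyNA(i)) {
      stop("prior table is missing term(s): ",
           paste(terms[is.na(i)], collapse = ", "), call. = FALSE)
    }
    mu <- prior$mean[i]
    se <- prior$se[i]
    if (any(!is.finite(se) | se <= 0)) {
      stop("prior SEs must be positive and finite", call. = FALSE)
    }
    return(list(mu = stats::setNames(mu, terms),
                prec = diag(1 / se^2, p), cov = diag(se^2, p)))
  }
  if (inherits(prior, "historical_prior")) {
    if (!identical(names(prior$mean), terms)) {
      i <- match(terms, names(prior$mean))
      if (anyNA(i)) stop("historical prior terms do not match the schema",
                         call. = FALSE)
      prior$mean <- prior$mean[i]
      prior$covariance <- prior$covariance[i, i, drop = FALSE]
    }
    ev <- eigen(prior$covariance, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      stop("historical prior covariance is not positive-definite",
           call. = FALSE)
    }
    return(list(mu = prior$mean, prec = solve(prior$covariance),
                cov = prior$covariance))
  }
  if (is.list(prior) && !is.null(prior$mu)) return(prior)
  stop("unsupported prior object", call. = FALSE)
}

#' Fit the response propensity model
#'
#' Maximum-likelihood or maximum-a-posteriori estimation of the
#' discrete-time logistic model by Newton–Raphson with step-halving.
#' With a prior, the objective is the log-posterior: the log-likelihood
#' penalised by `-(beta - mu)' Sigma^{-1} (beta - mu) / 2` — a diagonal
#' Gaussian penalty for expert prior tables, a full-covariance penalty
#' for historical precision-weighted priors. The reported covariance is
#' the inverse observed information at the optimum (Laplace
#' approximation for the Bayesian fits).
#'
#' A pure MLE on sparse early-quarter data can fail to converge
#' (separation); it is then refit under a weak ridge pseudo-prior
#' `N(0, 10^2)` and flagged via `ridged`. Fitting an empty design with a
#' prior returns the prior itself (mode = prior mean); an empty design
#' without a prior is an error.
#'
#' @param x Attempts tibble (with `schema`) or a `design_matrix`.
#' @param schema A [covariate_schema()] (when `x` is a tibble).
#' @param prior `NULL` for MLE, a `prior_table`, or a
#'   `historical_prior`.
#' @param method `"standard_mle"`, `"expert_map"`, `"pwp_map"` or
#'   `"mcmc"`; defaults to match the prior supplied.
#' @param through_day Restrict to records on or before this day (tibble
#'   input only).
#' @param control List of optimiser settings: `tol_score` (1e-8),
#'   `tol_obj` (1e-10), `max_iter` (100), `ridge_se` (10).
#' @param mcmc List of sampler settings when `method = "mcmc"`:
#'   `n_iter` (4000), `burn` (1000), `seed` (required), `scale` (2.4).
#' @return A `propensity_fit`: coefficients, covariance, `method`,
#'   `converged`, `ridged`, `n_records`, `logLik` (data part at the
#'   estimate).
#' @export
fit_propensity <- function(x, schema = NULL, prior = NULL,
                           method = NULL, through_day = Inf,
                           control = list(), mcmc = list()) {
  if (inherits(x, "design_matrix")) {
    design <- x
  } else {
    if (is.null(schema)) stop("schema required with tibble input",
                              call. = FALSE)
    design <- build_design(x, schema, through_day = through_day)
  }
  terms <- colnames(design$x)
  pg <- as_prior_gaussian(prior, terms)
  if (is.null(method)) {
    method <- if (is.null(pg)) "standard_mle"
      else if (inherits(prior, "historical_prior")) "pwp_map"
      else "expert_map"
  }
  method <- match.arg(method,
                      c("standard_mle", "expert_map", "pwp_map", "mcmc"))
  if (method == "standard_mle" && !is.null(pg)) {
    stop("standard_mle takes no prior", call. = FALSE)
  }
  if (method %in% c("expert_map", "pwp_map", "mcmc") && is.null(pg)) {
    stop("method '", method, "' requires a prior", call. = FALSE)
  }
  ctl <- utils::modifyList(
    list(tol_score = 1e-8, tol_obj = 1e-10, max_iter = 100, ridge_se = 10),
    control)

  if (nrow(design$x) == 0) {
    if (is.null(pg)) {
      stop("cannot fit an empty design without a prior", call. = FALSE)
    }
    fit <- list(coefficients = pg$mu, vcov = pg$cov, converged = TRUE,
                ridged = FALSE, iterations = 0)
  } else {
    fit <- newton_logistic(design$x, design$y, pg, ctl)
    if (!fit$converged && is.null(pg)) {
      ridge <- list(mu = stats::setNames(rep(0, length(terms)), terms),
                    prec = diag(1 / ctl$ridge_se^2, length(terms)),
                    cov = diag(ctl$ridge_se^2, length(terms)))
      fit <- newton_logistic(design$x, design$y, ridge, ctl)
      fit$ridged <- TRUE
    }
  }
  out <- structure(
    list(coefficients = stats::setNames(drop(fit$coefficients), terms),
         vcov = structure(fit$vcov, dimnames = list(terms, terms)),
         method = method, converged = fit$converged,
         ridged = isTRUE(fit$ridged), n_records = nrow(design$x),
         iterations = fit$iterations, schema = design$schema,
         prior = pg),
    class = "propensity_fit")
  out$logLik <- log_likelihood(out$coefficients, design)
  if (method == "mcmc") out <- mcmc_refine(out, design, pg, mcmc)
  out
}

# Newton-Raphson with step-halving for the (penalised) logistic
# log-likelihood. prior = NULL gives plain MLE.
newton_logistic <- function(x, y, prior, ctl) {
  p <- ncol(x)
  beta <- if (!is.null(prior)) as.numeric(prior$mu) else rep(0, p)
  objective <- function(b) {
    eta <- drop(x %*% b)
    ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
                (1 - y) * stats::plogis(-eta, log.p = TRUE))
    if (!is.null(prior)) {
      d <- b - as.numeric(prior$mu)
      ll <- ll - 0.5 * drop(crossprod(d, prior$prec %*% d))
    }
    ll
  }
  obj <- objective(beta)
  converged <- FALSE
  it <- 0
  H <- NULL
  while (it < ctl$max_iter) {
    it <- it + 1
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(x, y - mu))
    w <- mu * (1 - mu)
    H <- crossprod(x * w, x)
    if (!is.null(prior)) {
      g <- g - drop(prior$prec %*% (beta - as.numeric(prior$mu)))
      H <- H + prior$prec
    }
    if (max(abs(g)) < ctl$tol_score) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8, p), g)
    })
    new_beta <- beta + step
    new_obj <- objective(new_beta)
    halves <- 0
    while ((!is.finite(new_obj) || new_obj < obj) && halves < 30) {
      step <- step / 2
      new_beta <- beta + step
      new_obj <- objective(new_beta)
      halves <- halves + 1
    }
    rel <- abs(new_obj - obj) / (abs(obj) + 1e-10)
    beta <- new_beta
    obj <- new_obj
    if (rel < ctl$tol_obj) {
      # recheck the score at the accepted point
      eta <- drop(x %*% beta)
      mu <- stats::plogis(eta)
      g <- drop(crossprod(x, y - mu))
      if (!is.null(prior)) {
        g <- g - drop(prior$prec %*% (beta - as.numeric(prior$mu)))
      }
      converged <- max(abs(g)) < 1e-4
      break
    }
  }
  # observed information at the optimum
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  H <- crossprod(x * w, x)
  if (!is.null(prior)) H <- H + prior$prec
  vc <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-8, p)))
  if (any(abs(beta) > 30) && is.null(prior)) converged <- FALSE
  list(coefficients = beta, vcov = vc, converged = converged,
       ridged = FALSE, iterations = it)
}

# Random-walk Metropolis refinement of a MAP fit: posterior mean and
# covariance replace the mode and Laplace covariance.
mcmc_refine <- function(fit, design, pg, mcmc) {
  opts <- utils::modifyList(list(n_iter = 4000, burn = 1000, scale = 2.4),
                            mcmc)
  if (is.null(opts$seed)) stop("mcmc requires a seed", call. = FALSE)
  set.seed(opts$seed)
  p <- length(fit$coefficients)
  prop_chol <- chol(fit$vcov * (opts$scale^2 / p))
  log_post <- function(b) {
    d <- b - as.numeric(pg$mu)
    log_likelihood(stats::setNames(b, names(fit$coefficients)), design) -
      0.5 * drop(crossprod(d, pg$prec %*% d))
  }
  cur <- as.numeric(fit$coefficients)
  cur_lp <- log_post(cur)
  draws <- matrix(NA_real_, opts$n_iter, p)
  acc <- 0
  for (i in seq_len(opts$n_iter)) {
    cand <- cur + drop(crossprod(prop_chol, stats::rnorm(p)))
    cand_lp <- log_post(cand)
    if (log(stats::runif(1)) < cand_lp - cur_lp) {
      cur <- cand; cur_lp <- cand_lp; acc <- acc + 1
    }
    draws[i, ] <- cur
  }
  keep <- draws[(opts$burn + 1):opts$n_iter, , drop = FALSE]
  fit$coefficients[] <- colMeans(keep)
  fit$vcov[] <- stats::cov(keep)
  fit$mcmc <- list(n_iter = opts$n_iter, burn = opts$burn,
                   acceptance = acc / opts$n_iter, seed = opts$seed,
                   draws = keep)
  fit$logLik <- log_likelihood(fit$coefficients, design)
  fit
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat("<propensity_fit> method=", x$method,
      if (!x$converged) " (NOT converged)",
      if (x$ridged) " [ridge fallback]",
      ", n=", x$n_records, ", logLik=", format(x$logLik, digits = 6),
      "\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict next-attempt response propensities
#'
#' Inverse-logit of the linear predictor at the supplied covariate rows;
#' predictions are strictly inside (0, 1).
#'
#' @param object A `propensity_fit`.
#' @param newdata A `design_matrix` (e.g. from [select_active()]), a
#'   numeric matrix with matching columns, or a data frame of covariate
#'   rows (one column per schema covariate, time-varying included).
#' @param ... Unused.
#' @return Numeric vector of propensities.
#' @export
predict.propensity_fit <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "design_matrix")) {
    newdata$x
  } else if (is.matrix(newdata)) {
    newdata
  } else {
    rows_to_matrix(tibble::as_tibble(newdata), object$schema)
  }
  if (ncol(x) != length(object$coefficients)) {
    stop("newdata has ", ncol(x), " columns; fit has ",
         length(object$coefficients), " coefficients", call. = FALSE)
  }
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), names(object$coefficients))) {
    x <- x[, names(object$coefficients), drop = FALSE]
  }
  stats::plogis(drop(x %*% object$coefficients))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted propensity model
#'
#' @param x A `propensity_fit`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `term`, `estimate`, `std.error`;
#'   `glance()`: one-row tibble with `method`, `converged`, `ridged`,
#'   `nobs`, `logLik`, `df`.
#' @method tidy propensity_fit
#' @export
tidy.propensity_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = sqrt(diag(x$vcov)))
}

#' @rdname tidy.propensity_fit
#' @method glance propensity_fit
#' @export
glance.propensity_fit <- function(x, ...) {
  tibble::tibble(method = x$method, converged = x$converged,
                 ridged = x$ridged, nobs = x$n_records,
                 logLik = x$logLik, df = length(x$coefficients))
}
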