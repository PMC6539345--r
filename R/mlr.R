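backtick <- function(x) paste0("`", x, "`")

qsrr_formula <- function(response, descriptors) {
  stats::as.formula(paste(backtick(response), "~",
                          paste(backtick(descriptors), collapse = " + ")))
}

#' Fit a QSRR multilinear regression model
#'
#' Ordinary least-squares fit of one McReynolds constant (or any response
#' column) on a chosen descriptor subset. Standard errors use the unbiased
#' residual variance (denominator n - p - 1); the calibration error SDEC is
#' root-mean-square with denominator n, the usual QSAR convention.
#'
#' @param data tibble containing the response and descriptor columns (and
#'   optionally `code`).
#' @param response response column name (e.g. `"X"`).
#' @param descriptors character vector of descriptor column names (at most a
#'   handful; must leave positive residual degrees of freedom).
#' @return object of class `qsrr_mlr`.
#' @examples
#' d <- tibble::tibble(x1 = 1:6, y = 2 * (1:6) + 5)
#' fit_qsrr(d, "y", "x1")
#' @export
fit_qsrr <- function(data, response, descriptors) {
  if (!response %in% names(data)) abort(paste0("no response column ", response))
  missing <- setdiff(descriptors, names(data))
  if (length(missing)) {
    abort(paste0("missing descriptor column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(data); p <- length(descriptors)
  if (n <= p + 1) abort("need more rows than descriptors + 1")
  fit <- stats::lm(qsrr_formula(response, descriptors), data = data)
  if (fit$rank < p + 1) {
    aliased <- names(which(is.na(stats::coef(fit))))
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(aliased, collapse = ", ")))
  }
  kappa_x <- kappa(stats::model.matrix(fit), exact = FALSE)
  if (kappa_x > 1e10) {
    warn(paste0("ill-conditioned design (condition number ",
                format(kappa_x, digits = 3), ")"))
  }
  res <- stats::residuals(fit)
  y <- data[[response]]
  structure(
    list(response = response, descriptors = descriptors, lm = fit,
         data = data, n = n, p = p,
         r_squared = summary(fit)$r.squared,
         sdec = sdec(res), residuals = as.numeric(res),
         # LOO can be singular (e.g. a lone carrier of a binary descriptor)
         q2_loo = tryCatch(q2_loo(data, response, descriptors),
                           error = function(e) NA_real_)),
    class = "qsrr_mlr")
}

#' Standard deviation of the calibration error (SDEC)
#'
#' Root-mean-square residual, `sqrt(sum(e^2)/n)`.
#'
#' @param residuals numeric residual vector.
#' @param denominator `"n"` (default) or `"n_minus_p_1"` with `p` supplied.
#' @param p number of descriptors (only for `"n_minus_p_1"`).
#' @return non-negative number in response units.
#' @export
sdec <- function(residuals, denominator = c("n", "n_minus_p_1"), p = NULL) {
  denominator <- match.arg(denominator)
  n <- length(residuals)
  d <- if (denominator == "n") n else {
    if (is.null(p)) abort("p required for n_minus_p_1")
    n - p - 1
  }
  sqrt(sum(residuals^2) / d)
}

#' Standardised regression coefficients
#'
#' `b'_i = b_i * sd(x_i) / sd(y)` over the calibration rows; defined for
#' slopes only, never the intercept. Invariant to affine rescaling of the
#' descriptors.
#'
#' @param model a `qsrr_mlr`.
#' @return named numeric vector of standardised slopes.
#' @export
standardize_coefficients <- function(model) {
  y_sd <- stats::sd(model$data[[model$response]])
  x_sd <- purrr::map_dbl(model$descriptors, ~ stats::sd(model$data[[.x]]))
  if (any(x_sd == 0)) abort("zero-variance descriptor column")
  b <- stats::coef(model$lm)[-1]
  stats::setNames(as.numeric(b) * x_sd / y_sd, model$descriptors)
}

#' Leave-one-out cross-validated determination coefficient
#'
#' `Q2_loo = 1 - PRESS/TSS`, with each prediction made by the model fitted
#' without that row. Computed through the leverage shortcut
#' `e_loo = e / (1 - h)`, which is algebraically identical to refitting n
#' times for OLS.
#'
#' @inheritParams fit_qsrr
#' @return list-free single number (can be negative for models worse than
#'   the mean).
#' @export
q2_loo <- function(data, response, descriptors) {
  n <- nrow(data)
  if (length(descriptors) > n - 2) abort("too many descriptors for LOO")
  fit <- stats::lm(qsrr_formula(response, descriptors), data = data)
  if (anyNA(stats::coef(fit))) abort("rank-deficient design in LOO fit")
  h <- stats::hatvalues(fit)
  if (any(h > 1 - 1e-10)) abort("singular leave-one-out fit (leverage 1)")
  e_loo <- stats::residuals(fit) / (1 - h)
  y <- data[[response]]
  1 - sum(e_loo^2) / sum((y - mean(y))^2)
}

#' Predictive residual sum of squares (PRESS)
#' @inheritParams fit_qsrr
#' @return PRESS in squared response units.
#' @export
press <- function(data, response, descriptors) {
  fit <- stats::lm(qsrr_formula(response, descriptors), data = data)
  h <- stats::hatvalues(fit)
  sum((stats::residuals(fit) / (1 - h))^2)
}

#' Predict a QSRR response for new phases
#'
#' @param object a `qsrr_mlr`.
#' @param newdata tibble with the model's descriptor columns.
#' @param ... unused.
#' @return numeric predictions in response units.
#' @export
predict.qsrr_mlr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$lm))
  as.numeric(stats::predict(object$lm, newdata = newdata))
}

#' @export
print.qsrr_mlr <- function(x, ...) {
  cat("QSRR model for", x$response, "on", x$p, "descriptors (n =", x$n, ")\n")
  cat("  R2 =", format(x$r_squared, digits = 4),
      " SDEC =", format(x$sdec, digits = 3),
      " Q2_loo =", format(x$q2_loo, digits = 4), "\n")
  cat("  terms:", paste(x$descriptors, collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a QSRR model into one row per term
#'
#' @param x a `qsrr_mlr`.
#' @param ... unused.
#' @return tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` and `std.coef` (NA for the intercept).
#' @method tidy qsrr_mlr
#' @export
tidy.qsrr_mlr <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  terms <- c("(Intercept)", x$descriptors)
  tibble::tibble(
    term = terms,
    estimate = as.numeric(s[, 1]),
    std.error = as.numeric(s[, 2]),
    statistic = as.numeric(s[, 3]),
    p.value = as.numeric(s[, 4]),
    std.coef = c(NA_real_, as.numeric(standardize_coefficients(x))))
}

#' One-row summary of a QSRR model
#'
#' @param x a `qsrr_mlr`.
#' @param ... unused.
#' @return tibble with `response`, `r.squared`, `sdec`, `q2.loo`, `nobs`,
#'   `n.descriptors`.
#' @method glance qsrr_mlr
#' @export
glance.qsrr_mlr <- function(x, ...) {
  tibble::tibble(response = x$response, r.squared = x$r_squared,
                 sdec = x$sdec, q2.loo = x$q2_loo, nobs = x$n,
                 n.descriptors = x$p)
}

#' Join responses and descriptors into one modelling table
#'
#' @param phases phase table from [load_phases()].
#' @param descriptors descriptor matrix from [load_descriptors()].
#' @return tibble keyed by `code` with responses and descriptors.
#' @export
qsrr_data <- function(phases = NULL, descriptors = NULL) {
  phases <- phases %||% load_phases()
  descriptors <- descriptors %||% load_descriptors()
  out <- dplyr::inner_join(
    dplyr::select(phases, "code", "subgroup",
                  dplyr::all_of(mcreynolds_responses)),
    descriptors, by = "code")
  if (nrow(out) != nrow(phases)) {
    abort("descriptor table does not cover all phases")
  }
  out
}

#' Refit the reference descriptor sets on the calibration phases
#'
#' For each response, takes the previously reported model's descriptor set
#' and refits it by OLS on the 24 calibration phases of the given data
#' table.
#'
#' @param data modelling table from [qsrr_data()].
#' @param responses responses to refit (default all five).
#' @return named list of `qsrr_mlr` objects.
#' @export
refit_reference_models <- function(data = qsrr_data(),
                                   responses = mcreynolds_responses) {
  reference <- load_reference_models()
  calib <- split_external(data)$calibration
  purrr::map(stats::setNames(responses, responses), function(resp) {
    terms <- reference$term[reference$response == resp &
                              reference$term != "(Intercept)"]
    fit_qsrr(calib, resp, terms)
  })
}
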