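#' Standard deviation of the error in prediction (SDEP)
#'
#' Root-mean-square prediction error on an external set,
#' `sqrt(sum((y - yhat)^2) / n_ext)`.
#'
#' @param y_true observed responses.
#' @param y_pred predicted responses (same length).
#' @return non-negative number in response units.
#' @export
sdep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true)) {
    abort("y_true and y_pred must be equal non-zero length")
  }
  sqrt(mean((y_true - y_pred)^2))
}

#' External-validation determination coefficients (three variants)
#'
#' The three standard external Q2 definitions:
#' * `F1`: `1 - PRESS_ext / sum((y_ext - mean(y_cal))^2)` — total sum of
#'   squares about the calibration mean, over the external points;
#' * `F2`: as F1 but about the external-set mean;
#' * `F3`: `1 - (PRESS_ext / n_ext) / (sum((y_cal - mean(y_cal))^2) /
#'   n_cal)` — error variance normalised by the calibration variance.
#'
#' @param y_true_ext,y_pred_ext observed and predicted external responses.
#' @param y_calibration calibration-set responses.
#' @return tibble with one row: `F1`, `F2`, `F3`.
#' @export
q2_external <- function(y_true_ext, y_pred_ext, y_calibration) {
  if (length(y_true_ext) < 2) abort("need at least 2 external points")
  press_ext <- sum((y_true_ext - y_pred_ext)^2)
  m_cal <- mean(y_calibration)
  tss_cal_ext <- sum((y_true_ext - m_cal)^2)
  tss_ext <- sum((y_true_ext - mean(y_true_ext))^2)
  var_cal <- sum((y_calibration - m_cal)^2) / length(y_calibration)
  if (tss_cal_ext == 0 || tss_ext == 0 || var_cal == 0) {
    abort("zero reference variance")
  }
  tibble::tibble(
    F1 = 1 - press_ext / tss_cal_ext,
    F2 = 1 - press_ext / tss_ext,
    F3 = 1 - (press_ext / length(y_true_ext)) / var_cal)
}

#' External validation of a fixed descriptor support
#'
#' Fits the support on the calibration rows and predicts the external rows.
#'
#' @param calibration,prediction tibbles with response and descriptors (e.g.
#'   from [split_external()] applied to [qsrr_data()]).
#' @param response response column name.
#' @param support descriptor subset.
#' @return object of class `qsrr_validation`: per-phase residuals, SDEP and
#'   the three external Q2 variants (`q2` reports F1).
#' @export
validate_external <- function(calibration, prediction, response, support) {
  model <- fit_qsrr(calibration, response, support)
  pred <- predict(model, prediction)
  y_ext <- prediction[[response]]
  q2 <- q2_external(y_ext, pred, calibration[[response]])
  structure(
    list(response = response, support = support, model = model,
         residuals = tibble::tibble(
           code = prediction[["code"]] %||% seq_along(pred),
           observed = y_ext, predicted = pred,
           residual = y_ext - pred),
         sdep = sdep(y_ext, pred),
         q2 = q2$F1, q2_variants = q2),
    class = "qsrr_validation")
}

#' @export
print.qsrr_validation <- function(x, ...) {
  cat("External validation of", x$response, "model:",
      "Q2 =", format(x$q2, digits = 4),
      " SDEP =", format(x$sdep, digits = 3), "\n")
  invisible(x)
}

#' @method tidy qsrr_validation
#' @export
tidy.qsrr_validation <- function(x, ...) x$residuals

#' @method glance qsrr_validation
#' @export
glance.qsrr_validation <- function(x, ...) {
  tibble::tibble(response = x$response, q2.external = x$q2,
                 q2.F2 = x$q2_variants$F2, q2.F3 = x$q2_variants$F3,
                 sdep = x$sdep, n.external = nrow(x$residuals))
}

#' Monte Carlo (repeated random split) validation
#'
#' Repeatedly assigns each phase to the test set independently with
#' probability `p_test`, refits the *fixed* descriptor support on the
#' training rows and records the SDEP on the test rows. Draws with fewer
#' than 2 test rows, or too few training rows to fit the support, are
#' redrawn (bounded attempts). Reports the per-repetition SDEP series, its
#' mean and SD, and the pooled-predictions SDEP over all repetitions.
#'
#' @param data modelling table.
#' @param response response column name.
#' @param support descriptor subset (fixed across repetitions: models are
#'   re-fit, not re-selected).
#' @param n_rep number of random partitions (default 30).
#' @param p_test assignment probability to the test set (default 0.2).
#' @param seed integer RNG seed.
#' @param max_redraws bound on redraw attempts per repetition.
#' @return object of class `qsrr_mc`: tibble of per-repetition SDEP and
#'   test sizes, `mc_mean`, `mc_sd`, `sdep_pooled`.
#' @export
monte_carlo <- function(data, response, support, n_rep = 30L, p_test = 0.2,
                        seed = 1L, max_redraws = 1000L) {
  n <- nrow(data)
  if (n < length(support) + 3) abort("too few rows for the support")
  with_seed(seed, {
    reps <- purrr::map_dfr(seq_len(n_rep), function(r) {
      for (attempt in seq_len(max_redraws)) {
        test <- stats::runif(n) < p_test
        n_test <- sum(test)
        if (n_test >= 2 && (n - n_test) > length(support) + 2) break
        if (attempt == max_redraws) {
          abort("could not draw a valid partition; raise p_test")
        }
      }
      model <- fit_qsrr(data[!test, , drop = FALSE], response, support)
      pred <- predict(model, data[test, , drop = FALSE])
      err <- data[[response]][test] - pred
      tibble::tibble(repetition = r, n_test = sum(test),
                     sdep = sqrt(mean(err^2)),
                     errors = list(err))
    })
  })
  all_err <- unlist(reps$errors)
  structure(
    list(response = response, support = support,
         repetitions = dplyr::select(reps, -"errors"),
         mc_mean = mean(reps$sdep), mc_sd = stats::sd(reps$sdep),
         sdep_pooled = sqrt(mean(all_err^2)),
         n_rep = n_rep, p_test = p_test, seed = seed),
    class = "qsrr_mc")
}

#' @export
print.qsrr_mc <- function(x, ...) {
  cat("Monte Carlo validation of", x$response, "model over", x$n_rep,
      "splits (p_test =", x$p_test, ")\n  SDEP mean =",
      format(x$mc_mean, digits = 3), "+/-", format(x$mc_sd, digits = 2),
      " pooled =", format(x$sdep_pooled, digits = 3), "\n")
  invisible(x)
}

#' @method tidy qsrr_mc
#' @export
tidy.qsrr_mc <- function(x, ...) x$repetitions

#' @method glance qsrr_mc
#' @export
glance.qsrr_mc <- function(x, ...) {
  tibble::tibble(response = x$response, mc.sdep.mean = x$mc_mean,
                 mc.sdep.sd = x$mc_sd, sdep.pooled = x$sdep_pooled,
                 n.rep = x$n_rep, p.test = x$p_test)
}
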