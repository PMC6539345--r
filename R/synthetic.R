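#' Specification of a synthetic QSRR dataset
#'
#' Emulates the statistical shape of the real problem: a small sample of
#' phases, a wide matrix of block-correlated candidate descriptors (Dragon
#' descriptors remain clustered even after correlation pruning), and a
#' response that is a sparse linear combination of at most six candidates
#' plus Gaussian noise, on the McReynolds scale (tens to hundreds of
#' retention-index units).
#'
#' @param n_samples number of rows (default 29, the phase count).
#' @param n_candidates number of candidate descriptors (default 177, the
#'   post-filter pool size).
#' @param true_support indices of the active descriptors (<= 6); default
#'   `NULL` spreads `length(true_coefficients)` descriptors evenly across
#'   the candidate range (distinct correlation blocks).
#' @param true_coefficients response-unit slopes of the active descriptors.
#' @param intercept response units (default 300).
#' @param noise_sd Gaussian noise SD in response units; default `NULL`
#'   calibrates it with [noise_sd_for_r2()] to a true-model R2 of 0.997,
#'   the fit quality regime of the real models.
#' @param block_size descriptors per correlation block (default 5).
#' @param block_correlation within-block correlation (default 0.6).
#' @param target_r2 used when `noise_sd` is NULL.
#' @param seed integer RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_samples = 29L, n_candidates = 177L,
                           true_support = NULL,
                           true_coefficients = c(150, 90, -60, 40),
                           intercept = 300, noise_sd = NULL,
                           block_size = 5L, block_correlation = 0.6,
                           target_r2 = 0.997, seed = 1L) {
  if (is.null(true_support)) {
    # spread the active descriptors over distinct correlation blocks
    true_support <- unique(round(seq(1, n_candidates,
                                     length.out = length(true_coefficients))))
    if (length(true_support) < length(true_coefficients)) {
      abort("n_candidates too small for the default support")
    }
  }
  if (length(true_support) > 6) abort("at most 6 active descriptors")
  if (length(true_support) != length(true_coefficients)) {
    abort("support and coefficients lengths differ")
  }
  if (any(true_support > n_candidates)) abort("support index out of range")
  if (block_correlation < 0 || block_correlation >= 1) {
    abort("block_correlation must be in [0, 1)")
  }
  spec <- structure(
    list(n_samples = as.integer(n_samples),
         n_candidates = as.integer(n_candidates),
         true_support = as.integer(true_support),
         true_coefficients = true_coefficients,
         intercept = intercept, noise_sd = noise_sd,
         block_size = as.integer(block_size),
         block_correlation = block_correlation,
         target_r2 = target_r2, seed = as.integer(seed)),
    class = "synthetic_spec")
  if (is.null(spec$noise_sd)) spec$noise_sd <- noise_sd_for_r2(spec)
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0")
  spec
}

support_covariance <- function(spec) {
  blocks <- (spec$true_support - 1L) %/% spec$block_size
  sigma <- outer(blocks, blocks,
                 function(a, b) ifelse(a == b, spec$block_correlation, 0))
  diag(sigma) <- 1
  sigma
}

#' Noise level for a target true-model R2
#'
#' Solves `R2 = var_signal / (var_signal + noise_sd^2)` for the noise SD,
#' with `var_signal = b' Sigma b` under the spec's block-correlation
#' structure.
#'
#' @param spec a `synthetic_spec` (its `noise_sd` is ignored).
#' @param target_r2 target population R2 of the true-support model.
#' @return noise SD in response units.
#' @export
noise_sd_for_r2 <- function(spec, target_r2 = spec$target_r2) {
  b <- spec$true_coefficients
  var_signal <- as.numeric(t(b) %*% support_covariance(spec) %*% b)
  sqrt(var_signal * (1 - target_r2) / target_r2)
}

#' Generate a synthetic QSRR dataset
#'
#' Candidate descriptors are standard Gaussians with within-block
#' correlation `block_correlation` (shared block factor construction);
#' the response is `intercept + X[, support] %*% b + noise`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (tibble: `code`, `D001`..., `y`) and `truth`
#'   (support names, coefficients, intercept, noise SD, the spec).
#' @export
generate_qsrr <- function(spec = synthetic_spec()) {
  n <- spec$n_samples; p <- spec$n_candidates
  names_p <- sprintf("D%03d", seq_len(p))
  with_seed(spec$seed, {
    n_blocks <- ceiling(p / spec$block_size)
    z <- matrix(stats::rnorm(n * n_blocks), n, n_blocks)
    e <- matrix(stats::rnorm(n * p), n, p)
    block_of <- ((seq_len(p) - 1L) %/% spec$block_size) + 1L
    rho <- spec$block_correlation
    x <- sqrt(rho) * z[, block_of, drop = FALSE] + sqrt(1 - rho) * e
    noise <- stats::rnorm(n, 0, spec$noise_sd)
  })
  colnames(x) <- names_p
  y <- spec$intercept +
    as.numeric(x[, spec$true_support, drop = FALSE] %*% spec$true_coefficients) +
    noise
  data <- dplyr::bind_cols(
    tibble::tibble(code = sprintf("S%02d", seq_len(n))),
    tibble::as_tibble(x),
    tibble::tibble(y = y))
  list(data = data,
       truth = list(support = names_p[spec$true_support],
                    coefficients = stats::setNames(spec$true_coefficients,
                                                   names_p[spec$true_support]),
                    intercept = spec$intercept,
                    noise_sd = spec$noise_sd,
                    spec = spec))
}

#' Support-recovery experiment for the GA-MLR selector
#'
#' Generates `n_trials` independent datasets from the spec (seeds `seed`,
#' `seed + 1`, ...), runs the multi-start GA-MLR protocol on each, and
#' summarises how often the exact true support is recovered and how close
#' the recovered coefficients are to the truth.
#'
#' @param spec a [synthetic_spec()].
#' @param config a [ga_config()] for the GA runs.
#' @param n_trials number of independent datasets.
#' @param n_runs stage-1 GA runs per trial (see [multi_start_pool()]).
#' @return object of class `qsrr_recovery`: per-trial tibble, recovery
#'   rate with a 95% binomial confidence interval, and coefficient
#'   bias/RMSE over recovered trials.
#' @export
recovery_experiment <- function(spec = synthetic_spec(),
                                config = ga_config(), n_trials = 10L,
                                n_runs = 10L) {
  if (n_trials < 1) abort("n_trials must be >= 1")
  trials <- purrr::map_dfr(seq_len(n_trials), function(t) {
    sp <- spec; sp$seed <- spec$seed + t - 1L
    gen <- generate_qsrr(sp)
    cfg <- config; cfg$seed <- config$seed + 1000L * t
    model <- multi_start_pool(
      gen$data, "y",
      candidates = sprintf("D%03d", seq_len(sp$n_candidates)),
      n_runs = n_runs, config = cfg)
    recovered <- setequal(model$descriptors, gen$truth$support)
    est <- stats::setNames(as.numeric(stats::coef(model$lm)[-1]),
                           model$descriptors)
    err <- if (recovered) {
      est[gen$truth$support] - gen$truth$coefficients
    } else {
      rep(NA_real_, length(gen$truth$support))
    }
    tibble::tibble(trial = t, recovered = recovered,
                   n_selected = length(model$descriptors),
                   q2_loo = model$q2_loo,
                   coef_errors = list(err))
  })
  rate <- mean(trials$recovered)
  ci <- stats::binom.test(sum(trials$recovered), n_trials)$conf.int
  errs <- unlist(trials$coef_errors[trials$recovered])
  structure(
    list(trials = dplyr::select(trials, -"coef_errors"),
         recovery_rate = rate, ci_low = ci[1], ci_high = ci[2],
         coef_bias = if (length(errs)) mean(errs) else NA_real_,
         coef_rmse = if (length(errs)) sqrt(mean(errs^2)) else NA_real_,
         n_trials = n_trials),
    class = "qsrr_recovery")
}

#' @export
print.qsrr_recovery <- function(x, ...) {
  cat("Support recovery over", x$n_trials, "trials: rate =",
      format(x$recovery_rate, digits = 3),
      sprintf("(95%% CI %.2f-%.2f)", x$ci_low, x$ci_high), "\n")
  if (!is.na(x$coef_rmse)) {
    cat("  coefficient bias =", format(x$coef_bias, digits = 3),
        " RMSE =", format(x$coef_rmse, digits = 3), "\n")
  }
  invisible(x)
}

#' @method tidy qsrr_recovery
#' @export
tidy.qsrr_recovery <- function(x, ...) x$trials

#' @method glance qsrr_recovery
#' @export
glance.qsrr_recovery <- function(x, ...) {
  tibble::tibble(recovery.rate = x$recovery_rate, ci.low = x$ci_low,
                 ci.high = x$ci_high, coef.bias = x$coef_bias,
                 coef.rmse = x$coef_rmse, n.trials = x$n_trials)
}
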