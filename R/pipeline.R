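#' Run the full QSRR characterisation pipeline
#'
#' For each requested McReynolds constant: obtain a descriptor support
#' (either the reference model's set, or GA selection on the calibration
#' phases), fit the OLS model on the 24 calibration phases, validate on the
#' fixed five-phase external set and by Monte Carlo repeated splitting, and
#' run the per-response PCA used for column classification. Deterministic
#' for a given `seed`.
#'
#' @param phases phase table ([load_phases()] if omitted).
#' @param descriptors descriptor matrix ([load_descriptors()] if omitted).
#' @param responses responses to model (default all five).
#' @param select if `TRUE`, run multi-start GA selection per response;
#'   otherwise refit the reference descriptor sets.
#' @param n_runs stage-1 GA runs when `select = TRUE`.
#' @param config GA configuration.
#' @param n_rep,p_test Monte Carlo repetitions and test probability.
#' @param seed master seed for GA and Monte Carlo randomness.
#' @return object of class `qsrr_pipeline`: named list of per-response
#'   results (`model`, `external`, `mc`, `pca`) plus the resolved settings.
#' @export
run_qsrr_pipeline <- function(phases = NULL, descriptors = NULL,
                              responses = mcreynolds_responses,
                              select = FALSE, n_runs = 20L,
                              config = ga_config(), n_rep = 30L,
                              p_test = 0.2, seed = 1L) {
  unknown <- setdiff(responses, mcreynolds_responses)
  if (length(unknown)) {
    abort(paste0("unknown response name(s): ", paste(unknown, collapse = ", ")))
  }
  data <- qsrr_data(phases, descriptors)
  sets <- split_external(data)
  results <- purrr::map(stats::setNames(responses, responses), function(resp) {
    support <- if (select) {
      cfg <- config
      cfg$seed <- seed + match(resp, mcreynolds_responses) * 10000L
      multi_start_pool(sets$calibration, resp, n_runs = n_runs,
                       config = cfg)$descriptors
    } else {
      reference <- load_reference_models()
      reference$term[reference$response == resp &
                       reference$term != "(Intercept)"]
    }
    model <- fit_qsrr(sets$calibration, resp, support)
    external <- validate_external(sets$calibration, sets$prediction,
                                  resp, support)
    mc <- monte_carlo(data, resp, support, n_rep = n_rep, p_test = p_test,
                      seed = seed + match(resp, mcreynolds_responses))
    pca <- response_pca(resp, data, support = support)
    list(model = model, external = external, mc = mc, pca = pca)
  })
  structure(list(results = results, responses = responses, select = select,
                 n_rep = n_rep, p_test = p_test, seed = seed),
            class = "qsrr_pipeline")
}

#' @export
print.qsrr_pipeline <- function(x, ...) {
  cat("QSRR pipeline:", length(x$responses), "response model(s)",
      if (x$select) "(GA-selected)" else "(reference supports)", "\n")
  print(glance(x))
  invisible(x)
}

#' Per-response summary of a pipeline run
#'
#' @param x a `qsrr_pipeline`.
#' @param ... unused.
#' @return tibble, one row per response: calibration R2 and SDEC, external
#'   Q2 and SDEP, Monte Carlo SDEP mean and SD, PC1+PC2 explained variance.
#' @method glance qsrr_pipeline
#' @export
glance.qsrr_pipeline <- function(x, ...) {
  purrr::map_dfr(x$responses, function(resp) {
    r <- x$results[[resp]]
    tibble::tibble(
      response = resp,
      n_descriptors = r$model$p,
      r.squared = r$model$r_squared,
      sdec = r$model$sdec,
      q2.loo = r$model$q2_loo,
      q2.external = r$external$q2,
      sdep.external = r$external$sdep,
      mc.sdep.mean = r$mc$mc_mean,
      mc.sdep.sd = r$mc$mc_sd,
      pc12.explained = sum(r$pca$explained_fraction[1:2]))
  })
}

#' SDEP trend across Monte Carlo repetitions
#'
#' @param object a `qsrr_mc`.
#' @param ... unused.
#' @return ggplot of per-repetition SDEP with the mean as a reference line.
#' @method autoplot qsrr_mc
#' @export
autoplot.qsrr_mc <- function(object, ...) {
  ggplot2::ggplot(object$repetitions,
                  ggplot2::aes(x = .data$repetition, y = .data$sdep)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_test), alpha = 0.8,
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mc_mean, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_size_continuous(name = "test phases", range = c(1, 4)) +
    ggplot2::labs(x = "repetition",
                  y = paste0("SDEP (", object$response,
                             ", retention-index units)")) +
    ggplot2::theme_minimal()
}

#' GA fitness trajectory
#'
#' @param object a `qsrr_ga`.
#' @param ... unused.
#' @return ggplot of the best leave-one-out fitness per generation.
#' @method autoplot qsrr_ga
#' @export
autoplot.qsrr_ga <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$generation,
                               y = .data$best_fitness)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "generation",
                  y = expression(best ~ Q[loo]^2)) +
    ggplot2::theme_minimal()
}
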