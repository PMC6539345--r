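#' Simulate a stand-in descriptor table for the 29 phases
#'
#' Produces a phases-by-descriptors table in the layout expected by
#' [load_descriptors()]. The two graph-computable descriptors — `RBN`
#' (rotatable-bond count) and `B04[N-Si]` — are genuinely computed from the
#' package's 20-unit oligomer graphs; the twelve remaining descriptors
#' (autocorrelation, edge-adjacency, Burden, GETAWAY, 3D-MoRSE and property
#' descriptors, which require optimised 3D geometries and are outside this
#' package's scope) are *synthetic*: independent Gaussian columns whose
#' means and spreads merely mimic the magnitude of each descriptor family.
#' The packaged fixture `descriptors_synthetic.csv` is this function's
#' output at the default seed; it exercises the pipeline but carries no
#' measured structural information beyond RBN and B04\[N-Si\].
#'
#' @param phases phase table (loaded if omitted).
#' @param seed RNG seed for the synthetic columns.
#' @return tibble: `code` plus the 14 descriptor columns of
#'   [qsrr_descriptor_names].
#' @export
simulate_descriptor_table <- function(phases = NULL, seed = 20260922L) {
  phases <- phases %||% load_phases()
  graph_part <- graph_descriptors(phases)
  # plausible location/scale per simulated descriptor family (dimensionless)
  scales <- list(
    MATS7i            = c(0.02, 0.015),
    `SpMAD_AEA(dm)`   = c(0.15, 0.05),
    `SpMAD_AEA(bo)`   = c(0.10, 0.03),
    `SpMax_B(s)`      = c(4.0, 1.3),
    H5u               = c(2.0, 0.5),
    `R3u+`            = c(0.02, 0.002),
    Mor02v            = c(-30, 18),
    Mor10v            = c(-5, 1.6),
    Mor10m            = c(-8, 2.7),
    Mor12m            = c(-6, 3.5),
    Mor04p            = c(10, 6.5),
    BLTF96            = c(-10, 4.5))
  n <- nrow(phases)
  synth <- with_seed(seed, {
    purrr::map_dfc(scales, ~ stats::rnorm(n, .x[1], .x[2]))
  })
  out <- dplyr::bind_cols(graph_part, synth)
  out[, c("code", qsrr_descriptor_names)]
}
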