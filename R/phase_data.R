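#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom generics tidy glance
#' @import tibble
NULL

#' Descriptor names used by the reference QSRR models
#'
#' The 14 molecular descriptors selected across the five McReynolds-constant
#' models: RBN (rotatable-bond count) and B04\[N-Si\] (N and Si at topological
#' distance 4) are computable from the molecular graph; the remainder are 2D
#' autocorrelation, edge-adjacency, Burden-matrix, GETAWAY, 3D-MoRSE and
#' property descriptors taken as data.
#'
#' @format Character vector of length 14.
#' @export
qsrr_descriptor_names <- c(
  "RBN", "B04[N-Si]", "MATS7i", "SpMAD_AEA(dm)", "SpMAD_AEA(bo)",
  "SpMax_B(s)", "H5u", "R3u+", "Mor02v", "Mor10v", "Mor10m", "Mor12m",
  "Mor04p", "BLTF96"
)

#' McReynolds response names
#' @format Character vector: X, Y, Z, U, S (benzene, butanol, 2-pentanone,
#'   nitropropane, pyridine probes).
#' @export
mcreynolds_responses <- c("X", "Y", "Z", "U", "S")

#' The five phases held out as the external prediction set
#' @format Character vector of phase codes.
#' @export
external_phase_codes <- c("OV-7", "OV-25", "SILAR 7CP", "XE-60", "FS-328")

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "siloxqsrr")
  if (!nzchar(path)) abort(paste0("packaged fixture not found: ", file))
  path
}

#' Normalise phase codes for reliable joins
#'
#' Replaces unicode minus/dashes with ASCII hyphen and collapses whitespace.
#'
#' @param x character vector of phase codes.
#' @return character vector.
#' @export
normalize_phase_code <- function(x) {
  x <- gsub("[−–—]", "-", x)
  gsub("\\s+", " ", trimws(x))
}

read_fixture <- function(file, col_types) {
  readr::read_csv(extdata_path(file), comment = "#", col_types = col_types,
                  progress = FALSE)
}

#' Load the McReynolds constants of the 29 poly(siloxane) phases
#'
#' One row per stationary phase: commercial column code, structural subgroup,
#' and the first five McReynolds constants X, Y, Z, U, S in retention-index
#' units. Compositions are attached as nested tibbles (`composition`), with
#' nominal and 20-unit geometric-model mole percentages per comonomer.
#'
#' @param path optional path to an alternative CSV in the packaged layout.
#' @return tibble with columns `code`, `subgroup`, `X`, `Y`, `Z`, `U`, `S`,
#'   and list-column `composition` (tibbles with `unit`, `pct_nominal`,
#'   `pct_model`).
#' @examples
#' phases <- load_phases()
#' dplyr::filter(phases, code == "OV-17")
#' @export
load_phases <- function(path = NULL) {
  constants <- if (is.null(path)) {
    read_fixture("mcreynolds_constants.csv", "ccddddd")
  } else {
    readr::read_csv(path, comment = "#", col_types = "ccddddd",
                    progress = FALSE)
  }
  required <- c("code", "subgroup", mcreynolds_responses)
  missing <- setdiff(required, names(constants))
  if (length(missing)) {
    abort(paste0("malformed phase table: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(constants) |
                 rowSums(constants[mcreynolds_responses] < 0) > 0)
  if (length(bad)) {
    abort(paste0("malformed phase table row(s): ",
                 paste(bad, collapse = ", ")))
  }
  constants$code <- normalize_phase_code(constants$code)
  comp <- load_phase_compositions()
  comp_nested <- tidyr::nest(comp, composition = -"code")
  out <- dplyr::left_join(constants, comp_nested, by = "code")
  if (any(purrr::map_lgl(out$composition, is.null))) {
    abort("phase without composition entry")
  }
  # nominal compositions must close to 100 mole percent
  sums <- purrr::map_dbl(out$composition, ~ sum(.x$pct_nominal))
  stray <- out$code[abs(sums - 100) > 0.5]
  if (length(stray)) {
    abort(paste0("composition does not sum to 100 for: ",
                 paste(stray, collapse = ", ")))
  }
  out
}

#' Load the comonomer compositions (long form)
#'
#' @param path optional alternative CSV path.
#' @return tibble with columns `code`, `unit`, `pct_nominal`, `pct_model`.
#' @export
load_phase_compositions <- function(path = NULL) {
  comp <- if (is.null(path)) {
    read_fixture("phase_compositions.csv", "ccdd")
  } else {
    readr::read_csv(path, comment = "#", col_types = "ccdd", progress = FALSE)
  }
  if (any(!stats::complete.cases(comp)) || any(comp$pct_nominal < 0)) {
    abort("malformed composition table")
  }
  comp$code <- normalize_phase_code(comp$code)
  comp
}

#' Load a phases-by-descriptors matrix
#'
#' By default loads the packaged descriptor table
#' (`descriptors_synthetic.csv`), a *synthetic stand-in*: its `RBN` and
#' `B04[N-Si]` columns are computed from the package's own 20-unit oligomer
#' graphs, while the remaining twelve geometry- and spectrum-based descriptor
#' columns are simulated (seeded) with realistic scales. Supply `path` to use
#' a measured descriptor table in the same layout.
#'
#' @param path optional CSV path; first column `code`, remaining columns
#'   descriptors.
#' @param descriptors character vector of descriptor columns that must be
#'   present; defaults to [qsrr_descriptor_names].
#' @return tibble, first column `code`, then one numeric column per
#'   descriptor.
#' @export
load_descriptors <- function(path = NULL,
                             descriptors = qsrr_descriptor_names) {
  file <- path %||% extdata_path("descriptors_synthetic.csv")
  mat <- readr::read_csv(file, comment = "#",
                         col_types = readr::cols(
                           code = readr::col_character(),
                           .default = readr::col_double()),
                         progress = FALSE)
  if (nrow(mat) == 0) abort("empty descriptor table")
  if (names(mat)[1] != "code") abort("descriptor table must start with 'code'")
  missing <- setdiff(descriptors, names(mat))
  if (length(missing)) {
    abort(paste0("descriptor table missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(names(mat))) abort("duplicate descriptor names")
  if (any(!stats::complete.cases(mat))) abort("descriptor table has missing entries")
  mat$code <- normalize_phase_code(mat$code)
  if (anyDuplicated(mat$code)) abort("duplicate phase codes in descriptor table")
  mat
}

#' Load the reference QSRR model definitions
#'
#' The previously reported GA-MLR model for each McReynolds constant:
#' intercept and per-descriptor slopes with standard errors and standardised
#' slopes.
#'
#' @return tibble with columns `response`, `term`, `estimate`, `std_error`,
#'   `std_coef`.
#' @export
load_reference_models <- function() {
  read_fixture("reference_models.csv", "ccddd")
}

#' Load the reported fit/validation statistics of the reference models
#' @return tibble with one row per response.
#' @export
load_reference_model_stats <- function() {
  read_fixture("reference_model_stats.csv", "cdddddd")
}

#' Split phases into the calibration and external prediction sets
#'
#' The external set is the fixed five-phase design covering the structural
#' variability of the 29 phases: OV-7, OV-25, SILAR 7CP, XE-60 and FS-328.
#'
#' @param phases tibble with a `code` column (e.g. from [load_phases()]).
#' @param external character vector of phase codes to hold out.
#' @return named list of two tibbles, `calibration` and `prediction`.
#' @examples
#' sets <- split_external(load_phases())
#' nrow(sets$calibration) # 24
#' @export
split_external <- function(phases, external = external_phase_codes) {
  codes <- normalize_phase_code(phases$code)
  missing <- setdiff(external, codes)
  if (length(missing)) {
    abort(paste0("phase(s) not present: ", paste(missing, collapse = ", ")))
  }
  list(
    calibration = phases[!codes %in% external, , drop = FALSE],
    prediction  = phases[match(external, codes), , drop = FALSE]
  )
}
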