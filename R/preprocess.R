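#' Descriptor filter configuration
#'
#' @param rsd_threshold minimum relative standard deviation (sd/|mean|, or sd
#'   when the mean is ~0) for a column to count as varying.
#' @param identical_fraction columns where more than this fraction of values
#'   are identical are removed.
#' @param correlation_threshold pairwise Pearson |r| above which two
#'   descriptors are considered redundant (default 0.85).
#' @param representative one of `"highest_variance"` (keep the most variable
#'   member of a correlated group) or `"first_listed"`.
#' @param grouping `"greedy"` (prune anything correlated with an already
#'   retained column) or `"components"` (connected components of the
#'   correlation graph, one representative each).
#' @return a `filter_config` list.
#' @export
filter_config <- function(rsd_threshold = 1e-4, identical_fraction = 0.9,
                          correlation_threshold = 0.85,
                          representative = c("highest_variance", "first_listed"),
                          grouping = c("greedy", "components")) {
  if (correlation_threshold <= 0 || correlation_threshold >= 1) {
    abort("correlation_threshold must be in (0, 1)")
  }
  structure(list(rsd_threshold = rsd_threshold,
                 identical_fraction = identical_fraction,
                 correlation_threshold = correlation_threshold,
                 representative = match.arg(representative),
                 grouping = match.arg(grouping)),
            class = "filter_config")
}

descriptor_columns <- function(matrix) {
  setdiff(names(matrix), "code")
}

#' Remove near-constant descriptors
#'
#' Drops columns whose relative spread falls below `rsd_threshold` or where
#' more than `identical_fraction` of the values coincide; exactly constant
#' columns are always dropped.
#'
#' @param matrix tibble with optional `code` column and numeric descriptor
#'   columns.
#' @param config a [filter_config()].
#' @return the matrix restricted to the retained columns.
#' @export
remove_low_variance <- function(matrix, config = filter_config()) {
  cols <- descriptor_columns(matrix)
  if (nrow(matrix) < 2) abort("need at least 2 rows")
  keep <- purrr::map_lgl(cols, function(nm) {
    x <- matrix[[nm]]
    s <- stats::sd(x)
    if (s == 0) return(FALSE)
    m <- mean(abs(x))
    rsd <- if (m > .Machine$double.eps) s / m else s
    frac_same <- max(table(x)) / length(x)
    rsd >= config$rsd_threshold && frac_same <= config$identical_fraction
  })
  if (!any(keep)) abort("all descriptor columns removed by variance filter")
  matrix[, c(intersect("code", names(matrix)), cols[keep]), drop = FALSE]
}

#' Keep one representative per group of highly correlated descriptors
#'
#' Deterministic redundancy pruning at pairwise Pearson `|r| >` the
#' configured threshold. Under `"greedy"` grouping, columns are visited in
#' representative order (highest variance first by default) and a column is
#' dropped when it correlates above threshold with one already retained;
#' under `"components"`, connected components of the |r|-threshold graph are
#' formed and the representative of each is kept.
#'
#' @inheritParams remove_low_variance
#' @return the matrix restricted to retained columns; all retained pairwise
#'   |r| are <= threshold under greedy grouping.
#' @export
decorrelate <- function(matrix, config = filter_config()) {
  cols <- descriptor_columns(matrix)
  if (nrow(matrix) < 3) abort("need at least 3 rows")
  if (length(cols) < 2) return(matrix)
  x <- as.matrix(matrix[, cols])
  variances <- apply(x, 2, stats::var)
  ord <- if (config$representative == "highest_variance") {
    order(-variances, seq_along(cols))
  } else {
    seq_along(cols)
  }
  cmat <- abs(suppressWarnings(stats::cor(x)))
  cmat[is.na(cmat)] <- 1  # constant columns: treat as fully redundant
  th <- config$correlation_threshold
  keep <- if (config$grouping == "greedy") {
    kept <- integer(0)
    for (k in ord) {
      if (!length(kept) || all(cmat[k, kept] <= th)) kept <- c(kept, k)
    }
    sort(kept)
  } else {
    adjacency <- cmat > th
    diag(adjacency) <- FALSE
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected"))
    vapply(seq_len(comp$no),
           function(cc) intersect(ord, which(comp$membership == cc))[1],
           integer(1))
  }
  matrix[, c(intersect("code", names(matrix)), cols[sort(keep)]), drop = FALSE]
}

#' Full pre-filter: variance rule then correlation pruning
#'
#' @inheritParams remove_low_variance
#' @return filtered matrix.
#' @export
prefilter_descriptors <- function(matrix, config = filter_config()) {
  decorrelate(remove_low_variance(matrix, config), config)
}
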