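#' Autoscale columns to zero mean and unit sample standard deviation
#'
#' @param matrix tibble with optional `code` column; all other columns must
#'   be non-constant numerics.
#' @return tibble of the same shape.
#' @export
autoscale <- function(matrix) {
  cols <- setdiff(names(matrix), "code")
  sds <- purrr::map_dbl(cols, ~ stats::sd(matrix[[.x]]))
  if (any(sds == 0)) {
    abort(paste0("constant column(s): ",
                 paste(cols[sds == 0], collapse = ", ")))
  }
  out <- matrix
  for (nm in cols) out[[nm]] <- as.numeric(scale(matrix[[nm]]))
  out
}

#' Principal component analysis on the correlation matrix
#'
#' Diagonalises the correlation matrix of the variables (equivalently, PCA
#' of the autoscaled data): eigenvalues are the PC variances and sum to the
#' number of variables, loadings are orthonormal, and scores are the
#' autoscaled data projected on the loadings. The sign of each PC is fixed
#' by making its largest-magnitude loading positive.
#'
#' @param matrix tibble with optional `code` column and numeric variables.
#' @return object of class `qsrr_pca`: `eigenvalues`,
#'   `explained_fraction`, `scores` (rows x PCs, with `code`), `loadings`
#'   (variables x PCs).
#' @export
qsrr_pca <- function(matrix) {
  if (nrow(matrix) <= 2) abort("need more than 2 rows")
  codes <- matrix[["code"]] %||% as.character(seq_len(nrow(matrix)))
  scaled <- autoscale(matrix)
  x <- as.matrix(scaled[, setdiff(names(scaled), "code")])
  eig <- eigen(stats::cor(as.matrix(matrix[, setdiff(names(matrix), "code")])),
               symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  for (k in seq_len(ncol(vectors))) {
    top <- which.max(abs(vectors[, k]))
    if (vectors[top, k] < 0) vectors[, k] <- -vectors[, k]
  }
  pcs <- paste0("PC", seq_along(values))
  colnames(vectors) <- pcs
  rownames(vectors) <- colnames(x)
  scores <- x %*% vectors
  structure(
    list(eigenvalues = values,
         explained_fraction = values / sum(values),
         scores = dplyr::bind_cols(tibble::tibble(code = codes),
                                   tibble::as_tibble(scores)),
         loadings = vectors,
         n_variables = ncol(x)),
    class = "qsrr_pca")
}

#' @export
print.qsrr_pca <- function(x, ...) {
  cat("PCA of", x$n_variables, "autoscaled variables\n")
  ev <- round(100 * x$explained_fraction[1:min(3, x$n_variables)], 1)
  cat("  explained variance:", paste0("PC", seq_along(ev), " ", ev, "%",
                                      collapse = ", "), "\n")
  invisible(x)
}

#' Tidy PCA output
#'
#' @param x a `qsrr_pca`.
#' @param matrix `"scores"`, `"loadings"` or `"eigenvalues"`.
#' @param ... unused.
#' @return tibble in long or wide form depending on `matrix`.
#' @method tidy qsrr_pca
#' @export
tidy.qsrr_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = dplyr::bind_cols(
      tibble::tibble(variable = rownames(x$loadings)),
      tibble::as_tibble(x$loadings)),
    eigenvalues = tibble::tibble(
      PC = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      explained = x$explained_fraction,
      cumulative = cumsum(x$explained_fraction)))
}

#' @method glance qsrr_pca
#' @export
glance.qsrr_pca <- function(x, ...) {
  tibble::tibble(n.variables = x$n_variables,
                 pc1.explained = x$explained_fraction[1],
                 pc12.explained = sum(x$explained_fraction[1:2]))
}

#' Truncated scores and loadings for a biplot
#'
#' Pure truncation of an existing PCA to the first `k` components, with
#' explained-variance labels; nothing is recomputed.
#'
#' @param result a `qsrr_pca`.
#' @param k number of components (default 2).
#' @return list with `scores`, `loadings` (tibbles) and `axis_labels`.
#' @export
biplot_data <- function(result, k = 2L) {
  if (k > result$n_variables) abort("k exceeds the number of PCs")
  pcs <- paste0("PC", seq_len(k))
  list(
    scores = result$scores[, c("code", pcs)],
    loadings = tidy(result, "loadings")[, c("variable", pcs)],
    axis_labels = stats::setNames(
      sprintf("%s (%.1f%%)", pcs, 100 * result$explained_fraction[seq_len(k)]),
      pcs))
}

#' PCA biplot of phases and variables
#'
#' Scores (phases) as points, loadings (variables) as labelled arrows scaled
#' to the score range.
#'
#' @param object a `qsrr_pca`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qsrr_pca
#' @export
autoplot.qsrr_pca <- function(object, ...) {
  bd <- biplot_data(object, 2L)
  s <- bd$scores; l <- bd$loadings
  scale_f <- 0.8 * max(abs(c(s$PC1, s$PC2))) / max(abs(as.matrix(l[, -1])))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$code), size = 2.6,
                       vjust = -0.7) +
    ggplot2::geom_segment(
      data = l,
      ggplot2::aes(x = 0, y = 0, xend = scale_f * .data$PC1,
                   yend = scale_f * .data$PC2),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "firebrick") +
    ggplot2::geom_text(
      data = l,
      ggplot2::aes(x = scale_f * .data$PC1, y = scale_f * .data$PC2,
                   label = .data$variable),
      colour = "firebrick", size = 2.8, vjust = 1.5) +
    ggplot2::labs(x = bd$axis_labels["PC1"], y = bd$axis_labels["PC2"]) +
    ggplot2::theme_minimal()
}

#' PCA of one response's model variable set
#'
#' Runs the correlation-matrix PCA on the selected descriptors of a
#' response's reference model, together with (by default) the response
#' itself, across all 29 phases — the variable sets whose first two PCs are
#' used to classify the columns.
#'
#' @param response one of X, Y, Z, U, S.
#' @param data modelling table from [qsrr_data()].
#' @param include_response include the response among the PCA variables?
#' @param support optional explicit descriptor set; default: the reference
#'   model's descriptors.
#' @return a `qsrr_pca`.
#' @export
response_pca <- function(response, data = qsrr_data(),
                         include_response = TRUE, support = NULL) {
  if (is.null(support)) {
    reference <- load_reference_models()
    support <- reference$term[reference$response == response &
                                reference$term != "(Intercept)"]
  }
  vars <- c(support, if (include_response) response)
  qsrr_pca(data[, c("code", vars)])
}
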