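# Independent oracles used to check the package's fast paths.

# leave-one-out Q2 by explicit n-fold refitting (no leverage shortcut)
q2_loo_refit_oracle <- function(data, response, descriptors) {
  n <- nrow(data)
  f <- stats::as.formula(paste0(
    "`", response, "` ~ ", paste0("`", descriptors, "`", collapse = " + ")))
  preds <- vapply(seq_len(n), function(i) {
    fit <- stats::lm(f, data = data[-i, , drop = FALSE])
    as.numeric(stats::predict(fit, newdata = data[i, , drop = FALSE]))
  }, numeric(1))
  y <- data[[response]]
  1 - sum((y - preds)^2) / sum((y - mean(y))^2)
}

# exhaustive best-subset search over all supports of size <= max_size
best_subset_oracle <- function(data, response, candidates, max_size) {
  best <- -Inf; best_set <- character(0)
  for (k in seq_len(max_size)) {
    sets <- utils::combn(candidates, k, simplify = FALSE)
    for (s in sets) {
      v <- tryCatch(q2_loo(data, response, s), error = function(e) -Inf)
      if (v > best) { best <- v; best_set <- s }
    }
  }
  list(fitness = best, support = best_set)
}

# OLS coefficients straight from the normal equations
normal_equations_oracle <- function(X, y) {
  X1 <- cbind(1, X)
  as.numeric(solve(t(X1) %*% X1, t(X1) %*% y))
}

# tiny hand-buildable molecular graphs
molgraph_chain <- function(elements, hydrogens, orders = NULL) {
  n <- length(elements)
  orders <- orders %||% rep(1, n - 1)
  structure(
    list(atoms = tibble::tibble(element = elements, hydrogens = hydrogens),
         bonds = tibble::tibble(i = seq_len(n - 1), j = 2:n, order = orders)),
    class = "molgraph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_modelling_data <- function(n = 20, p = 4, seed = 42, noise = 0.5) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- 3 + x %*% seq_len(p) + rnorm(n, 0, noise)
  dplyr::bind_cols(tibble::as_tibble(x), tibble::tibble(y = as.numeric(y)))
}
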