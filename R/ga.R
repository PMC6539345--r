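#' Genetic-algorithm configuration for descriptor selection
#'
#' Defaults follow the selection protocol used throughout: population of 100
#' binary chromosomes, per-gene mutation probability 0.1%, 1% elitism,
#' termination after five generations without improvement of the best
#' leave-one-out fitness, and at most six descriptors per model.
#'
#' @param population_size chromosomes per generation.
#' @param mutation_rate per-gene flip probability.
#' @param elitism_fraction fraction of best chromosomes copied unchanged;
#'   must give at least one elite.
#' @param patience stagnant generations before stopping.
#' @param max_descriptors maximum genes active after repair.
#' @param max_generations hard cap on generations.
#' @param init_prob probability a gene starts active; default `NULL` means
#'   `3 / n_candidates` so initial models average about three descriptors.
#' @param seed integer RNG seed; runs with the same seed are identical.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population_size = 100L, mutation_rate = 0.001,
                      elitism_fraction = 0.01, patience = 5L,
                      max_descriptors = 6L, max_generations = 500L,
                      init_prob = NULL, seed = 1L) {
  if (mutation_rate <= 0 || mutation_rate >= 1) {
    abort("mutation_rate must be in (0, 1)")
  }
  if (elitism_fraction * population_size < 1) {
    abort("elitism_fraction * population_size must be >= 1")
  }
  structure(list(population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 elitism_fraction = elitism_fraction,
                 patience = as.integer(patience),
                 max_descriptors = as.integer(max_descriptors),
                 max_generations = as.integer(max_generations),
                 init_prob = init_prob, seed = as.integer(seed)),
            class = "ga_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# leverage-shortcut Q2_loo on a bare design matrix; -Inf on degeneracy
q2_loo_matrix <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  if (nrow(X1) < ncol(X1) + 1) return(-Inf)
  qr_x <- qr(X1)
  if (qr_x$rank < ncol(X1)) return(-Inf)
  b <- qr.coef(qr_x, y)
  e <- y - X1 %*% b
  q <- qr.Q(qr_x)
  h <- rowSums(q^2)
  if (any(h > 1 - 1e-10)) return(-Inf)
  1 - sum((e / (1 - h))^2) / sum((y - mean(y))^2)
}

make_fitness <- function(X, y, cache = new.env(parent = emptyenv())) {
  function(genes) {
    idx <- which(genes)
    if (!length(idx)) return(-Inf)
    key <- paste(idx, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- q2_loo_matrix(X[, idx, drop = FALSE], y)
    cache[[key]] <- val
    val
  }
}

repair_chromosome <- function(genes, max_descriptors) {
  excess <- sum(genes) - max_descriptors
  if (excess > 0) {
    on_idx <- which(genes)
    genes[sample(on_idx, excess)] <- FALSE
  }
  genes
}

#' Evolve a descriptor subset by genetic algorithm
#'
#' Chromosomes are binary vectors over the candidate descriptors; fitness is
#' the leave-one-out cross-validated determination coefficient of the OLS
#' model on the active descriptors. Selection is fitness-rank roulette,
#' recombination is uniform crossover, mutation flips each gene with the
#' configured probability, elites pass unchanged, and offspring exceeding
#' the descriptor cap are repaired by switching off random excess genes.
#' Evolution stops after `patience` generations without improvement.
#'
#' @param data modelling table (response + candidate columns).
#' @param response response column name.
#' @param candidates candidate descriptor columns; default: every numeric
#'   column except `code`, `subgroup` and the five responses.
#' @param config a [ga_config()].
#' @return object of class `qsrr_ga`: best support, fitness, generation
#'   history and bookkeeping.
#' @export
ga_evolve <- function(data, response, candidates = NULL,
                      config = ga_config()) {
  candidates <- candidates %||%
    setdiff(names(data), c("code", "subgroup", response, mcreynolds_responses))
  p <- length(candidates)
  if (p < 1) abort("no candidate descriptors")
  y <- data[[response]]
  X <- as.matrix(data[, candidates, drop = FALSE])
  max_desc <- min(config$max_descriptors, p, nrow(data) - 2L)
  fitness <- make_fitness(X, y)
  pop_size <- config$population_size
  n_elite <- max(1L, floor(config$elitism_fraction * pop_size))
  init_prob <- config$init_prob %||% min(1, 3 / p)

  with_seed(config$seed, {
    pop <- matrix(stats::runif(pop_size * p) < init_prob, pop_size, p)
    pop <- t(apply(pop, 1, repair_chromosome, max_descriptors = max_desc))
    if (p == 1) pop <- matrix(as.logical(pop), pop_size, 1)
    history <- numeric(0)
    best_fit <- -Inf; best_genes <- rep(FALSE, p)
    stagnant <- 0L; gen <- 0L
    while (gen < config$max_generations) {
      gen <- gen + 1L
      fits <- apply(pop, 1, fitness)
      gen_best <- max(fits)
      # among fitness ties prefer the smallest model (parsimony)
      top <- which(fits >= gen_best - 1e-12)
      top <- top[which.min(rowSums(pop[top, , drop = FALSE]))]
      if (gen_best > best_fit + 1e-12) {
        best_fit <- gen_best
        best_genes <- pop[top, ]
        stagnant <- 0L
      } else {
        if (abs(gen_best - best_fit) <= 1e-12 &&
            sum(pop[top, ]) < sum(best_genes)) {
          best_genes <- pop[top, ]
        }
        stagnant <- stagnant + 1L
      }
      history <- c(history, best_fit)
      if (stagnant >= config$patience) break
      # rank roulette: weight 1..pop_size from worst to best
      ranks <- rank(fits, ties.method = "first")
      elite_idx <- order(fits, decreasing = TRUE)[seq_len(n_elite)]
      offspring <- matrix(FALSE, pop_size, p)
      offspring[seq_len(n_elite), ] <- pop[elite_idx, ]
      for (k in (n_elite + 1L):pop_size) {
        parents <- sample.int(pop_size, 2, prob = ranks)
        mask <- stats::runif(p) < 0.5
        child <- ifelse(mask, pop[parents[1], ], pop[parents[2], ])
        flip <- stats::runif(p) < config$mutation_rate
        child <- xor(child, flip)
        offspring[k, ] <- repair_chromosome(child, max_desc)
      }
      pop <- offspring
    }
  })

  structure(
    list(support = candidates[best_genes], genes = best_genes,
         fitness = best_fit,
         history = tibble::tibble(generation = seq_along(history),
                                  best_fitness = history),
         candidates = candidates, response = response,
         generations = gen, config = config),
    class = "qsrr_ga")
}

#' @export
print.qsrr_ga <- function(x, ...) {
  cat("GA descriptor selection for", x$response, "-", x$generations,
      "generations\n  best Q2_loo =", format(x$fitness, digits = 4),
      "\n  support:", paste(x$support, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy qsrr_ga
#' @export
tidy.qsrr_ga <- function(x, ...) x$history

#' @method glance qsrr_ga
#' @export
glance.qsrr_ga <- function(x, ...) {
  tibble::tibble(response = x$response, q2.loo = x$fitness,
                 n.selected = length(x$support),
                 generations = x$generations)
}

#' Multi-start GA selection with descriptor pooling
#'
#' Stage 1 runs the GA `n_runs` times from different seeded starting
#' populations (seeds `seed`, `seed + 1`, ...); every descriptor selected at
#' least once is pooled into a reduced candidate set. Stage 2 runs a final
#' GA on the pooled set and the best-support model is fitted by OLS and
#' returned.
#'
#' @inheritParams ga_evolve
#' @param n_runs number of stage-1 GA runs.
#' @return a `qsrr_mlr` fitted on the winning support, with attributes
#'   `pooled` (the stage-1 descriptor union), `stage1` (list of stage-1
#'   supports) and `ga` (the stage-2 `qsrr_ga`).
#' @export
multi_start_pool <- function(data, response, candidates = NULL,
                             n_runs = 100L, config = ga_config()) {
  if (n_runs < 1) abort("n_runs must be >= 1")
  candidates <- candidates %||%
    setdiff(names(data), c("code", "subgroup", response, mcreynolds_responses))
  stage1 <- purrr::map(seq_len(n_runs), function(i) {
    cfg <- config; cfg$seed <- config$seed + i - 1L
    ga_evolve(data, response, candidates, cfg)$support
  })
  pooled <- sort(unique(unlist(stage1)))
  if (!length(pooled)) abort("no descriptor was ever selected")
  cfg2 <- config; cfg2$seed <- config$seed + n_runs
  ga2 <- ga_evolve(data, response, pooled, cfg2)
  model <- fit_qsrr(data, response, ga2$support)
  attr(model, "pooled") <- pooled
  attr(model, "stage1") <- stage1
  attr(model, "ga") <- ga2
  model
}
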