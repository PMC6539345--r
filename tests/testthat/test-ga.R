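test_that("a single candidate descriptor is selected immediately", {
  d <- toy_modelling_data(n = 12, p = 1, seed = 3)
  ga <- ga_evolve(d, "y", "x1", ga_config(seed = 1))
  expect_equal(ga$support, "x1")
})

test_that("seeded runs are reproducible and the best fitness never decreases", {
  gen <- generate_qsrr(synthetic_spec(n_candidates = 25, seed = 8))
  ga1 <- ga_evolve(gen$data, "y", config = ga_config(seed = 21))
  ga2 <- ga_evolve(gen$data, "y", config = ga_config(seed = 21))
  expect_identical(ga1$history, ga2$history)
  expect_identical(ga1$support, ga2$support)
  expect_true(all(diff(ga1$history$best_fitness) >= 0))
  expect_gte(ga1$fitness, ga1$history$best_fitness[1])
})

test_that("the GA finds the exhaustive-search optimum on a small instance", {
  gen <- generate_qsrr(synthetic_spec(
    n_samples = 20, n_candidates = 12,
    true_coefficients = c(120, -70, 45), noise_sd = 1, seed = 6))
  cands <- sprintf("D%03d", 1:12)
  oracle <- best_subset_oracle(gen$data, "y", cands, 3)
  ga <- ga_evolve(gen$data, "y", cands,
                  ga_config(max_descriptors = 3, seed = 2))
  expect_equal(ga$fitness, oracle$fitness, tolerance = 1e-9)
})

test_that("chromosome repair respects the descriptor cap", {
  gen <- generate_qsrr(synthetic_spec(n_candidates = 30, seed = 10))
  ga <- ga_evolve(gen$data, "y", config = ga_config(seed = 4))
  expect_lte(length(ga$support), 6)
})

test_that("multi-start pooling unions stage-1 supports and never does worse", {
  gen <- generate_qsrr(synthetic_spec(n_candidates = 20, seed = 14))
  cfg <- ga_config(seed = 30)
  single <- ga_evolve(gen$data, "y", config = cfg)
  pooled_model <- multi_start_pool(gen$data, "y", n_runs = 3, config = cfg)
  stage1 <- attr(pooled_model, "stage1")
  expect_length(stage1, 3)
  expect_setequal(attr(pooled_model, "pooled"), sort(unique(unlist(stage1))))
  expect_true(all(pooled_model$descriptors %in% attr(pooled_model, "pooled")))
  expect_gte(pooled_model$q2_loo + 1e-9, single$fitness)
  # n_runs = 1 reduces to evolve + fit on the single run's pool
  one <- multi_start_pool(gen$data, "y", n_runs = 1, config = cfg)
  expect_setequal(attr(one, "pooled"), stage1[[1]])
})

test_that("the leverage-shortcut fitness agrees with explicit refitting inside the GA", {
  d <- toy_modelling_data(n = 20, p = 4, seed = 17)
  desc <- paste0("x", 1:4)
  shortcut <- siloxqsrr:::q2_loo_matrix(as.matrix(d[, desc]), d$y)
  expect_equal(shortcut, q2_loo_refit_oracle(d, "y", desc), tolerance = 1e-9)
})
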