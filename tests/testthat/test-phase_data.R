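test_that("the 29-phase table matches the printed constants", {
  phases <- load_phases()
  expect_equal(nrow(phases), 29)
  expect_equal(sum(phases$subgroup == "methylphenyl"), 14)
  ov1 <- dplyr::filter(phases, code == "OV-1")
  expect_equal(unlist(ov1[, c("X", "Y", "Z", "U", "S")], use.names = FALSE),
               c(16, 55, 44, 65, 42))
  expect_equal(phases$S[phases$code == "SILAR 10CP"], 801)
  expect_true(all(phases[mcreynolds_responses] >= 0))
  sums <- purrr::map_dbl(phases$composition, ~ sum(.x$pct_nominal))
  expect_true(all(abs(sums - 100) <= 0.5))
  model_sums <- purrr::map_dbl(phases$composition, ~ sum(.x$pct_model))
  expect_true(all(model_sums == 100))
})

test_that("nitropropane and 2-pentanone responses are highly correlated", {
  phases <- load_phases()
  expect_gt(stats::cor(phases$Z, phases$U), 0.99)
})

test_that("descriptor table covers the model descriptors and the graph column", {
  d <- load_descriptors()
  expect_equal(nrow(d), 29)
  expect_setequal(setdiff(names(d), "code"), qsrr_descriptor_names)
  expect_length(setdiff(names(d), "code"), 14)
  cyanoethyl <- c("NPS-100", "NSKI-25", "NSKT-33", "XE-60")
  expect_equal(sort(d$code[d$`B04[N-Si]` == 1]), sort(cyanoethyl))
  expect_true(all(d$`B04[N-Si]`[!d$code %in% cyanoethyl] == 0))
})

test_that("loaders reject malformed and empty fixtures", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("code,RBN", empty)
  expect_error(load_descriptors(empty), "empty")

  missing_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,RBN", "OV-1,42"), missing_col)
  expect_error(load_descriptors(missing_col), "missing column")

  bad_row <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,subgroup,X,Y,Z,U,S", "OV-1,methylphenyl,16,55,44,65,NA"),
             bad_row)
  expect_error(load_phases(bad_row), "row")
})

test_that("phase table round-trips through the CSV format", {
  phases <- load_phases()
  flat <- dplyr::select(phases, -"composition")
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(flat, tmp)
  again <- load_phases(tmp)
  expect_equal(dplyr::select(again, -"composition"), flat)
})

test_that("the external split is the fixed five-phase design", {
  phases <- load_phases()
  sets <- split_external(phases)
  expect_equal(nrow(sets$calibration), 24)
  expect_equal(nrow(sets$prediction), 5)
  expect_setequal(sets$prediction$code, external_phase_codes)
  expect_length(intersect(sets$calibration$code, sets$prediction$code), 0)
  expect_setequal(c(sets$calibration$code, sets$prediction$code), phases$code)
  # one phase from each structural neighbourhood
  units_of <- function(code) {
    comp <- phases$composition[[which(phases$code == code)]]
    comp$unit[comp$pct_nominal > 0]
  }
  expect_true("methylphenyl" %in% units_of("OV-7"))
  expect_true("diphenyl" %in% units_of("OV-25"))
  expect_true(all(c("cyanopropylphenyl", "dicyanopropyl") %in%
                    units_of("SILAR 7CP")))
  expect_true("cyanoethylmethyl" %in% units_of("XE-60"))
  expect_true("trifluoropropylmethyl" %in% units_of("FS-328"))

  expect_error(split_external(phases[phases$code != "XE-60", ]), "XE-60")
})
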