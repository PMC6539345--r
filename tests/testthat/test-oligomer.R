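test_that("allocation reproduces the recorded geometric-model compositions", {
  expect_equal(allocate_units(c(trifluoropropylmethyl = 23, dimethyl = 77)),
               c(trifluoropropylmethyl = 5L, dimethyl = 15L))
  expect_equal(allocate_units(c(trifluoropropylmethyl = 31, dimethyl = 69)),
               c(trifluoropropylmethyl = 6L, dimethyl = 14L))
  expect_equal(allocate_units(c(dimethyl = 67, cyanoethylmethyl = 33)),
               c(dimethyl = 13L, cyanoethylmethyl = 7L))
  expect_equal(allocate_units(c(A = 100)), c(A = 20L))
  expect_error(allocate_units(c(A = -5, B = 105)), "negative")
  # counts always close to the chain length
  for (pct in list(c(a = 50, b = 50), c(a = 33, b = 33, c = 34),
                   c(a = 5, b = 95), c(a = 12.5, b = 37.5, c = 50))) {
    expect_equal(sum(allocate_units(pct, 20L)), 20L)
  }
})

test_that("the OV-61 recorded model composition departs from the rounding rule", {
  report <- allocation_report()
  off <- unique(report$code[!report$agrees])
  expect_equal(off, "OV-61")
})

test_that("interleaving is maximally even and order-invariant", {
  expect_equal(interleave_units(c(A = 10, B = 10)), rep(c("A", "B"), 10))
  expect_equal(interleave_units(c(A = 20)), rep("A", 20))
  expect_equal(interleave_units(c(B = 6, A = 14)),
               interleave_units(c(A = 14, B = 6)))
  # two-unit mixes: successive positions differ by floor/ceiling of n/c
  for (counts in list(c(A = 14, B = 6), c(A = 13, B = 7), c(A = 18, B = 2))) {
    seqn <- interleave_units(counts)
    n <- length(seqn)
    for (u in names(counts)) {
      gaps <- diff(which(seqn == u))
      expect_true(all(gaps %in% c(floor(n / counts[u]), ceiling(n / counts[u]))),
                  info = paste("unit", u, "counts",
                               paste(counts, collapse = "/")))
    }
  }
  # general mixes: every occurrence stays within one period of its ideal
  # evenly-spaced position
  for (counts in list(c(A = 10, B = 7, C = 3), c(A = 9, B = 6, C = 5))) {
    seqn <- interleave_units(counts)
    n <- length(seqn)
    for (u in names(counts)) {
      pos <- which(seqn == u)
      ideal <- (seq_along(pos) - 0.5) * n / counts[u]
      expect_lt(max(abs(pos - ideal)), n / counts[u],
                label = paste("deviation of", u))
    }
  }
  seq146 <- interleave_units(c(A = 14, B = 6))
  expect_false(any(seq146[-1] == "B" & seq146[-20] == "B"))
  runs <- rle(seq146)
  expect_lte(max(runs$lengths[runs$values == "A"]), 3)
})

test_that("oligomer graphs have the constructed atom counts and valid valences", {
  g <- build_oligomer(c(dimethyl = 100))
  counts <- table(g$atoms$element)
  expect_equal(unname(counts[c("Si", "O", "C")]), c(22, 21, 46),
               ignore_attr = TRUE)
  expect_silent(validate_molgraph(g))

  rtx65 <- build_oligomer(c(dimethyl = 35, diphenyl = 65))
  # cyclomatic number counts the aromatic rings: 2 per diphenyl unit
  n_rings <- nrow(rtx65$bonds) - nrow(rtx65$atoms) + 1
  expect_equal(n_rings, 2 * 13)

  expect_error(build_oligomer(c(foo = 100)), "unknown")

  phases <- load_phases()
  for (code in c("OV-210", "SILAR 7CP", "OV-225", "XE-60")) {
    expect_silent(validate_molgraph(phase_oligomer(code, phases)))
  }
})

test_that("topological distances follow shortest bond paths", {
  pentane <- molgraph_chain(rep("C", 5), c(3, 2, 2, 2, 3))
  expect_equal(topological_distance(pentane, 1, 5), 4)
  expect_equal(topological_distance(pentane, 1, 2), 1)
  expect_equal(topological_distance(pentane, 3, 3), 0)
  expect_error(topological_distance(pentane, 1, 9), "range")
})

test_that("N-Si atom-pair presence at distance 4 flags cyanoethyl phases only", {
  phases <- load_phases()
  gd <- graph_descriptors(phases)
  cyanoethyl <- c("NPS-100", "NSKI-25", "NSKT-33", "XE-60")
  expect_equal(sort(gd$code[gd$`B04[N-Si]` == 1]), sort(cyanoethyl))
  expect_true(all(gd$`B04[N-Si]`[!gd$code %in% cyanoethyl] == 0))
  # a graph without nitrogen can never show the pair
  g <- build_oligomer(c(dimethyl = 100))
  expect_equal(atom_pair_presence(g, "N", "Si", 4), 0L)
})

test_that("rotatable-bond counting follows the stated convention", {
  ethane <- molgraph_chain(c("C", "C"), c(3, 3))
  expect_equal(count_rotatable_bonds(ethane), 0)
  pentane <- molgraph_chain(rep("C", 5), c(3, 2, 2, 2, 3))
  expect_equal(count_rotatable_bonds(pentane), 2)
  # propionitrile: bonds into the sp carbon and the triple bond are rigid
  nitrile <- molgraph_chain(c("C", "C", "C", "N"), c(3, 2, 0, 0),
                            orders = c(1, 1, 3))
  expect_equal(count_rotatable_bonds(nitrile), 0)
})

test_that("substituent RBN increments are ordered methyl < phenyl < cyanoethyl < tfp = cyanopropyl", {
  rbn_of <- function(comp) count_rotatable_bonds(build_oligomer(comp))
  base <- rbn_of(c(dimethyl = 100))
  inc <- c(
    methyl = 0,
    phenyl = (rbn_of(c(methylphenyl = 100)) - base) / 20,
    cyanoethyl = (rbn_of(c(cyanoethylmethyl = 100)) - base) / 20,
    trifluoropropyl = (rbn_of(c(trifluoropropylmethyl = 100)) - base) / 20,
    cyanopropyl = (rbn_of(c(cyanopropylmethyl = 100)) - base) / 20)
  expect_lt(inc["methyl"], inc["phenyl"])
  expect_lt(inc["phenyl"], inc["cyanoethyl"])
  expect_lt(inc["cyanoethyl"], inc["trifluoropropyl"])
  expect_equal(unname(inc["trifluoropropyl"]), unname(inc["cyanopropyl"]))
})

test_that("substituting a dimethyl unit never decreases the rotatable-bond count", {
  base <- count_rotatable_bonds(build_oligomer(c(dimethyl = 100)))
  for (unit in setdiff(names(siloxane_units()), "dimethyl")) {
    comp <- stats::setNames(c(95, 5), c("dimethyl", unit))
    expect_gte(count_rotatable_bonds(build_oligomer(comp)), base)
  }
})
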