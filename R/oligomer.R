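#' Siloxane comonomer unit catalogue
#'
#' Each 20-unit oligomer backbone position carries one comonomer unit, i.e.
#' a silicon atom bearing two substituents. The catalogue maps unit names to
#' substituent pairs; it is exposed (rather than hard-coded in the builder)
#' so alternative readings of mixed cyanoalkyl units can be explored.
#'
#' @return named list: unit name -> character vector of two substituents
#'   (among "methyl", "phenyl", "trifluoropropyl", "cyanoethyl",
#'   "cyanopropyl").
#' @export
siloxane_units <- function() {
  list(
    dimethyl              = c("methyl", "methyl"),
    methylphenyl          = c("methyl", "phenyl"),
    diphenyl              = c("phenyl", "phenyl"),
    trifluoropropylmethyl = c("trifluoropropyl", "methyl"),
    cyanoethylmethyl      = c("cyanoethyl", "methyl"),
    dicyanoethyl          = c("cyanoethyl", "cyanoethyl"),
    cyanopropylmethyl     = c("cyanopropyl", "methyl"),
    cyanopropylphenyl     = c("cyanopropyl", "phenyl"),
    dicyanopropyl         = c("cyanopropyl", "cyanopropyl")
  )
}

#' Allocate comonomer mole percentages to an integer unit count
#'
#' Nearest-integer allocation of `pct/100 * chain_length` per comonomer, with
#' a largest-remainder correction when the rounded counts do not close to
#' `chain_length` (ties broken by unit name for determinism).
#'
#' @param composition named numeric vector or 2-column data frame
#'   (`unit`, percentage) of mole percentages, summing to ~100.
#' @param chain_length number of siloxane units in the oligomer (default 20).
#' @return named integer vector summing to `chain_length`.
#' @examples
#' allocate_units(c(trifluoropropylmethyl = 23, dimethyl = 77)) # 5 and 15
#' @export
allocate_units <- function(composition, chain_length = 20L) {
  if (is.data.frame(composition)) {
    composition <- stats::setNames(composition[[2]], composition[[1]])
  }
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    abort("composition must be named by comonomer unit")
  }
  if (any(composition < 0)) abort("negative mole percentage")
  if (abs(sum(composition) - 100) > 0.5) {
    abort("composition percentages must sum to ~100")
  }
  exact <- composition * chain_length / 100
  counts <- round(exact)
  # round() half-to-even can leave a deficit/surplus; repair by largest
  # remainder, ties broken by name order
  deficit <- chain_length - sum(counts)
  if (deficit != 0) {
    resid <- exact - counts
    ord <- order(if (deficit > 0) -resid else resid, names(composition))
    for (i in ord[seq_len(abs(deficit))]) {
      counts[i] <- counts[i] + sign(deficit)
    }
  }
  stats::setNames(as.integer(counts), names(composition))
}

#' Interleave comonomer units uniformly along the chain
#'
#' Produces a maximally even, deterministic arrangement: at each backbone
#' position the unit with the largest accumulated quota deficit is placed
#' (error-diffusion / Bresenham schedule). The result is invariant to the
#' ordering of the input counts.
#'
#' @param unit_counts named integer vector (e.g. from [allocate_units()]).
#' @return character vector of unit names, length `sum(unit_counts)`.
#' @examples
#' interleave_units(c(A = 10, B = 10)) # strict alternation
#' @export
interleave_units <- function(unit_counts) {
  unit_counts <- unit_counts[unit_counts > 0]
  units <- sort(names(unit_counts))
  counts <- as.numeric(unit_counts[units])
  n <- sum(counts)
  placed <- stats::setNames(numeric(length(units)), units)
  sequence <- character(n)
  for (pos in seq_len(n)) {
    deficit <- counts * pos / n - placed
    pick <- units[which.max(deficit)]  # which.max: first (alphabetical) on tie
    sequence[pos] <- pick
    placed[pick] <- placed[pick] + 1
  }
  sequence
}

#' Oligomer specification for a phase composition
#'
#' @param composition named mole percentages (see [allocate_units()]).
#' @param chain_length backbone length in siloxane units (default 20, the
#'   geometric-model convention used throughout).
#' @return object of class `oligomer_spec`: chain length, integer unit
#'   counts, uniform unit sequence and the fixed trimethylsiloxy end group.
#' @export
oligomer_spec <- function(composition, chain_length = 20L) {
  counts <- allocate_units(composition, chain_length)
  structure(
    list(chain_length = as.integer(chain_length),
         unit_counts = counts,
         unit_sequence = interleave_units(counts),
         end_group = "trimethylsiloxy"),
    class = "oligomer_spec")
}

#' @export
print.oligomer_spec <- function(x, ...) {
  cat("Oligomer spec:", x$chain_length, "siloxane units,",
      x$end_group, "ends\n")
  counts <- x$unit_counts[x$unit_counts > 0]
  cat(paste0("  ", names(counts), ": ", counts, collapse = "\n"), "\n")
  invisible(x)
}

element_valence <- c(Si = 4, O = 2, C = 4, N = 3, F = 1)

new_molgraph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$element <- character()
  env$hydrogens <- integer()
  env$i <- integer(); env$j <- integer(); env$order <- numeric()
  env
}

add_atom <- function(b, element, hydrogens) {
  b$element <- c(b$element, element)
  b$hydrogens <- c(b$hydrogens, as.integer(hydrogens))
  length(b$element)
}

add_bond <- function(b, i, j, order = 1) {
  b$i <- c(b$i, i); b$j <- c(b$j, j); b$order <- c(b$order, order)
  invisible(NULL)
}

builder_to_graph <- function(b) {
  g <- structure(
    list(atoms = tibble::tibble(element = b$element, hydrogens = b$hydrogens),
         bonds = tibble::tibble(i = b$i, j = b$j, order = b$order)),
    class = "molgraph")
  validate_molgraph(g)
  g
}

# substituent builders attach to silicon index `si`
attach_substituent <- function(b, si, kind) {
  switch(kind,
    methyl = {
      c1 <- add_atom(b, "C", 3); add_bond(b, si, c1)
    },
    phenyl = {
      ring <- c(add_atom(b, "C", 0),
                replicate(5, add_atom(b, "C", 1)))
      add_bond(b, si, ring[1])
      for (k in 1:5) add_bond(b, ring[k], ring[k + 1], 1.5)
      add_bond(b, ring[6], ring[1], 1.5)
    },
    trifluoropropyl = {
      c1 <- add_atom(b, "C", 2); c2 <- add_atom(b, "C", 2)
      c3 <- add_atom(b, "C", 0)
      add_bond(b, si, c1); add_bond(b, c1, c2); add_bond(b, c2, c3)
      for (k in 1:3) add_bond(b, c3, add_atom(b, "F", 0))
    },
    cyanoethyl = {
      c1 <- add_atom(b, "C", 2); c2 <- add_atom(b, "C", 2)
      c3 <- add_atom(b, "C", 0); n <- add_atom(b, "N", 0)
      add_bond(b, si, c1); add_bond(b, c1, c2); add_bond(b, c2, c3)
      add_bond(b, c3, n, 3)
    },
    cyanopropyl = {
      c1 <- add_atom(b, "C", 2); c2 <- add_atom(b, "C", 2)
      c3 <- add_atom(b, "C", 2); c4 <- add_atom(b, "C", 0)
      n <- add_atom(b, "N", 0)
      add_bond(b, si, c1); add_bond(b, c1, c2); add_bond(b, c2, c3)
      add_bond(b, c3, c4); add_bond(b, c4, n, 3)
    },
    abort(paste0("unknown substituent: ", kind))
  )
  invisible(NULL)
}

add_trimethylsilyl <- function(b) {
  si <- add_atom(b, "Si", 0)
  for (k in 1:3) attach_substituent(b, si, "methyl")
  si
}

#' Build the hydrogen-suppressed molecular graph of an oligomer
#'
#' Assembles a linear Si-O backbone of `chain_length` substituted siloxane
#' units terminated on both ends by trimethylsiloxy groups, attaching the
#' substituent pair of each comonomer unit in the spec's uniform sequence.
#'
#' @param spec an `oligomer_spec`, or a named composition vector which is
#'   passed through [oligomer_spec()].
#' @param catalogue unit catalogue, see [siloxane_units()].
#' @return object of class `molgraph` with tibbles `atoms` (element,
#'   implicit-hydrogen count) and `bonds` (i, j, order; 1.5 = aromatic).
#' @examples
#' g <- build_oligomer(c(dimethyl = 100))
#' sum(g$atoms$element == "Si") # 22
#' @export
build_oligomer <- function(spec, catalogue = siloxane_units()) {
  if (!inherits(spec, "oligomer_spec")) spec <- oligomer_spec(spec)
  unknown <- setdiff(unique(spec$unit_sequence), names(catalogue))
  if (length(unknown)) {
    abort(paste0("unknown comonomer unit(s): ", paste(unknown, collapse = ", ")))
  }
  b <- new_molgraph_builder()
  prev_si <- add_trimethylsilyl(b)
  for (unit in spec$unit_sequence) {
    o <- add_atom(b, "O", 0)
    si <- add_atom(b, "Si", 0)
    add_bond(b, prev_si, o); add_bond(b, o, si)
    for (sub in catalogue[[unit]]) attach_substituent(b, si, sub)
    prev_si <- si
  }
  o <- add_atom(b, "O", 0)
  end_si <- add_trimethylsilyl(b)
  add_bond(b, prev_si, o); add_bond(b, o, end_si)
  builder_to_graph(b)
}

#' Build the oligomer graph of a named stationary phase
#'
#' @param code phase code (e.g. "NPS-100").
#' @param phases phase table from [load_phases()] (loaded if omitted).
#' @param chain_length backbone length (default 20).
#' @inheritParams build_oligomer
#' @return `molgraph`.
#' @export
phase_oligomer <- function(code, phases = NULL, chain_length = 20L,
                           catalogue = siloxane_units()) {
  phases <- phases %||% load_phases()
  code <- normalize_phase_code(code)
  row <- which(phases$code == code)
  if (!length(row)) abort(paste0("unknown phase code: ", code))
  comp <- phases$composition[[row]]
  build_oligomer(
    oligomer_spec(stats::setNames(comp$pct_nominal, comp$unit), chain_length),
    catalogue)
}

#' @export
print.molgraph <- function(x, ...) {
  counts <- table(x$atoms$element)
  cat("Molecular graph:", nrow(x$atoms), "heavy atoms (",
      paste0(names(counts), ":", counts, collapse = " "), "),",
      nrow(x$bonds), "bonds\n")
  invisible(x)
}

molgraph_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$atoms))))
}

#' Validate a molecular graph (connectivity and valences)
#'
#' Checks that the hydrogen-suppressed graph is connected and that the sum of
#' bond orders plus implicit hydrogens at every atom equals the element's
#' valence (Si 4, C 4, N 3, O 2, F 1; aromatic bonds count 1.5).
#'
#' @param graph a `molgraph`.
#' @return the graph, invisibly; errors describe the first violation.
#' @export
validate_molgraph <- function(graph) {
  atoms <- graph$atoms; bonds <- graph$bonds
  bad <- setdiff(atoms$element, names(element_valence))
  if (length(bad)) abort(paste0("unsupported element: ", bad[1]))
  bsum <- numeric(nrow(atoms))
  for (k in seq_len(nrow(bonds))) {
    bsum[bonds$i[k]] <- bsum[bonds$i[k]] + bonds$order[k]
    bsum[bonds$j[k]] <- bsum[bonds$j[k]] + bonds$order[k]
  }
  total <- bsum + atoms$hydrogens
  expected <- element_valence[atoms$element]
  off <- which(abs(total - expected) > 1e-9)
  if (length(off)) {
    abort(paste0("valence violation at atom ", off[1], " (",
                 atoms$element[off[1]], "): ", total[off[1]],
                 " != ", expected[off[1]]))
  }
  if (nrow(atoms) > 1 &&
      igraph::components(molgraph_igraph(graph))$no != 1) {
    abort("molecular graph is disconnected")
  }
  invisible(graph)
}

#' Topological distance between two atoms
#'
#' Shortest bond-path length in the hydrogen-suppressed graph.
#'
#' @param graph a `molgraph`.
#' @param i,j atom indices.
#' @return integer path length; 0 iff `i == j`; `Inf` for a disconnected
#'   pair.
#' @export
topological_distance <- function(graph, i, j) {
  n <- nrow(graph$atoms)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) abort("atom index out of range")
  if (i == j) return(0L)
  d <- igraph::distances(molgraph_igraph(graph), v = as.character(i),
                         to = as.character(j))[1, 1]
  if (is.finite(d)) as.integer(d) else Inf
}

#' Presence of an element pair at an exact topological distance
#'
#' The 2D atom-pair descriptor family: returns 1 if any atom of `elem_a` and
#' any atom of `elem_b` lie at shortest-path distance exactly `k`, else 0.
#' `B04[N-Si]` is `atom_pair_presence(g, "N", "Si", 4)`.
#'
#' @param graph a `molgraph`.
#' @param elem_a,elem_b element symbols.
#' @param k topological distance (>= 1).
#' @return 0 or 1.
#' @examples
#' g <- build_oligomer(c(cyanoethylmethyl = 100))
#' atom_pair_presence(g, "N", "Si", 4) # 1
#' @export
atom_pair_presence <- function(graph, elem_a, elem_b, k) {
  if (k < 1) abort("k must be >= 1")
  a <- which(graph$atoms$element == elem_a)
  b <- which(graph$atoms$element == elem_b)
  if (!length(a) || !length(b)) return(0L)
  d <- igraph::distances(molgraph_igraph(graph),
                         v = as.character(a), to = as.character(b))
  as.integer(any(abs(d - k) < 0.5))
}

#' Count rotatable bonds (RBN)
#'
#' A bond is rotatable when it is a single (order-1), acyclic bond whose two
#' endpoints are both non-terminal heavy atoms, and neither endpoint is an
#' sp-hybridised (triple-bonded) atom; under this convention bonds into a
#' nitrile carbon are rigid, so trifluoropropyl and cyanopropyl substituents
#' contribute equally. Backbone Si-O bonds count as rotatable (a constant
#' offset across equal-length chains). Aromatic-ring bonds are never
#' rotatable.
#'
#' @param graph a `molgraph`.
#' @return integer count.
#' @export
count_rotatable_bonds <- function(graph) {
  bonds <- graph$bonds
  degree <- tabulate(c(bonds$i, bonds$j), nbins = nrow(graph$atoms))
  sp <- unique(c(bonds$i[bonds$order == 3], bonds$j[bonds$order == 3]))
  ig <- molgraph_igraph(graph)
  bridge_ids <- as.integer(igraph::bridges(ig))
  is_bridge <- logical(nrow(bonds)); is_bridge[bridge_ids] <- TRUE
  rotatable <- bonds$order == 1 & is_bridge &
    degree[bonds$i] > 1 & degree[bonds$j] > 1 &
    !(bonds$i %in% sp) & !(bonds$j %in% sp)
  sum(rotatable)
}

#' Compute the graph-derived descriptors for every phase
#'
#' Builds the 20-unit oligomer of each phase and evaluates `RBN` and
#' `B04[N-Si]`.
#'
#' @param phases phase table from [load_phases()] (loaded if omitted).
#' @inheritParams phase_oligomer
#' @return tibble: `code`, `RBN`, `B04[N-Si]`.
#' @export
graph_descriptors <- function(phases = NULL, chain_length = 20L,
                              catalogue = siloxane_units()) {
  phases <- phases %||% load_phases()
  purrr::map_dfr(phases$code, function(code) {
    g <- phase_oligomer(code, phases, chain_length, catalogue)
    tibble::tibble(code = code,
                   RBN = count_rotatable_bonds(g),
                   `B04[N-Si]` = atom_pair_presence(g, "N", "Si", 4))
  })
}

#' Compare the allocation rule with the recorded geometric-model compositions
#'
#' Applies [allocate_units()] to every phase's nominal composition and joins
#' the resulting model mole percentages against the recorded ones, flagging
#' disagreements (OV-61 is the known case where the recorded model
#' composition departs from the nearest-integer rule).
#'
#' @param phases phase table (loaded if omitted).
#' @param chain_length backbone length (default 20).
#' @return tibble: `code`, `unit`, `pct_nominal`, `pct_model_recorded`,
#'   `pct_model_rule`, `agrees`.
#' @export
allocation_report <- function(phases = NULL, chain_length = 20L) {
  phases <- phases %||% load_phases()
  purrr::map_dfr(seq_len(nrow(phases)), function(r) {
    comp <- phases$composition[[r]]
    counts <- allocate_units(stats::setNames(comp$pct_nominal, comp$unit),
                             chain_length)
    rule_pct <- 100 * as.numeric(counts[comp$unit]) / chain_length
    tibble::tibble(
      code = phases$code[r], unit = comp$unit,
      pct_nominal = comp$pct_nominal,
      pct_model_recorded = comp$pct_model,
      pct_model_rule = rule_pct,
      agrees = abs(rule_pct - comp$pct_model) < 1e-9)
  })
}
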