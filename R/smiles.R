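#' Serialise a molecular graph to SMILES
#'
#' Deterministic depth-first writer: branches follow increasing atom index,
#' aromatic carbons are written lowercase, silicon in brackets, and ring
#' closures get reusable digit labels. The graph is validated (valences,
#' connectivity) before writing.
#'
#' @param graph a `molgraph`.
#' @return single SMILES string.
#' @examples
#' write_smiles(build_oligomer(c(dimethyl = 100)))
#' @export
write_smiles <- function(graph) {
  validate_molgraph(graph)
  n <- nrow(graph$atoms)
  if (n == 0) abort("empty graph")
  bonds <- graph$bonds
  nb <- nrow(bonds)
  adj <- vector("list", n)
  for (k in seq_len(nb)) {
    adj[[bonds$i[k]]] <- rbind(adj[[bonds$i[k]]], c(bonds$j[k], k))
    adj[[bonds$j[k]]] <- rbind(adj[[bonds$j[k]]], c(bonds$i[k], k))
  }
  aromatic <- logical(n)
  ar <- bonds$order == 1.5
  aromatic[c(bonds$i[ar], bonds$j[ar])] <- TRUE

  # pass 1: iterative DFS for tree edges and visit order
  visited <- logical(n)
  tree_edge <- logical(nb)
  dfs_rank <- integer(n)
  parent_bond <- integer(n)
  children <- vector("list", n)
  stack <- list(c(1L, 0L))
  rank <- 0L
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top[1]; via <- top[2]
    if (visited[v]) next
    visited[v] <- TRUE
    rank <- rank + 1L
    dfs_rank[v] <- rank
    parent_bond[v] <- via
    if (via > 0) {
      tree_edge[via] <- TRUE
      p <- bonds$i[via] + bonds$j[via] - v
      children[[p]] <- c(children[[p]], v)
    }
    nbrs <- adj[[v]]
    if (!is.null(nbrs)) {
      ord <- order(-nbrs[, 1])  # stack reverses: visit lowest index first
      for (r in ord) {
        if (!visited[nbrs[r, 1]]) stack[[length(stack) + 1L]] <- nbrs[r, ]
      }
    }
  }

  # ring (non-tree) bonds: assign closure digits, reusing freed ones
  ring_ids <- which(!tree_edge)
  open_atom <- integer(0)   # per ring bond: endpoint visited first
  close_atom <- integer(0)
  if (length(ring_ids)) {
    first <- ifelse(dfs_rank[bonds$i[ring_ids]] < dfs_rank[bonds$j[ring_ids]],
                    bonds$i[ring_ids], bonds$j[ring_ids])
    second <- bonds$i[ring_ids] + bonds$j[ring_ids] - first
    open_atom <- first; close_atom <- second
  }
  ring_digit <- integer(length(ring_ids))
  events <- data.frame(
    atom = c(open_atom, close_atom),
    ring = rep(seq_along(ring_ids), 2),
    open = rep(c(TRUE, FALSE), each = length(ring_ids)))
  events <- events[order(dfs_rank[events$atom], !events$open), , drop = FALSE]
  free <- 1:99; in_use <- integer(0)
  for (r in seq_len(nrow(events))) {
    rg <- events$ring[r]
    if (events$open[r]) {
      d <- free[1]; free <- free[-1]
      ring_digit[rg] <- d
    } else {
      free <- sort(c(free, ring_digit[rg]))
    }
  }
  digit_token <- function(d) if (d < 10) as.character(d) else sprintf("%%%02d", d)
  atom_ring_tokens <- vector("list", n)
  for (rg in seq_along(ring_ids)) {
    tok <- digit_token(ring_digit[rg])
    for (a in c(open_atom[rg], close_atom[rg])) {
      atom_ring_tokens[[a]] <- c(atom_ring_tokens[[a]], tok)
    }
  }

  atom_token <- function(v) {
    el <- graph$atoms$element[v]
    if (el == "Si") return("[Si]")
    if (aromatic[v] && el %in% c("C", "N")) return(tolower(el))
    el
  }
  bond_token <- function(order) {
    if (order == 2) "=" else if (order == 3) "#" else ""
  }

  # pass 2: recursive emission with branch parentheses
  emit <- function(v) {
    via <- parent_bond[v]
    parts <- c(if (via > 0) bond_token(bonds$order[via]) else "",
               atom_token(v),
               paste0(atom_ring_tokens[[v]], collapse = ""))
    kids <- children[[v]]
    if (length(kids) > 1) {
      kids <- kids[order(kids)]
      for (k in kids[-length(kids)]) parts <- c(parts, "(", emit(k), ")")
      kids <- kids[length(kids)]
    }
    if (length(kids) == 1) parts <- c(parts, emit(kids))
    paste0(parts, collapse = "")
  }
  emit(1L)
}

#' SMILES for every stationary phase oligomer
#'
#' @param phases phase table (loaded if omitted).
#' @inheritParams phase_oligomer
#' @return tibble with `code` and `smiles`.
#' @export
write_phase_smiles <- function(phases = NULL, chain_length = 20L,
                               catalogue = siloxane_units()) {
  phases <- phases %||% load_phases()
  tibble::tibble(
    code = phases$code,
    smiles = purrr::map_chr(
      phases$code,
      ~ write_smiles(phase_oligomer(.x, phases, chain_length, catalogue))))
}
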