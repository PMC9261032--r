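# Multiscale graph views of a polymer.
#
# The atom-level ("atomic") graph has one node per heavy atom (C/O) with
# element, aromaticity, owning monomer and bonding availability; one edge
# per bond with order and linkage annotation.  Coarse-graining aggregates
# every atom of a monomer into a single node, giving the "big" graph: one
# node per monomer, one edge per linkage (a b-b resinol contributes a
# single linkage edge even though it closes through several bonds).

#' Atom-level graph of a polymer
#'
#' @param p A `lignin_polymer`.
#' @return An undirected [igraph::igraph] with vertex attributes `element`,
#'   `aromatic`, `mtype`, `index`, `bonding`, `monomer_id` and edge
#'   attributes `order`, `aromatic`, `btype` (`NA` for intra-monomer
#'   bonds).
#' @export
as_atomic_graph <- function(p) {
  .check_polymer(p)
  v <- data.frame(
    name = seq_along(p$a_mono),
    element = p$a_elem, aromatic = p$a_arom,
    mtype = p$m_type[p$a_mono], index = p$a_idx,
    bonding = p$a_bond, monomer_id = p$a_mono
  )
  e <- data.frame(from = p$b_i, to = p$b_j, order = p$b_order,
                  aromatic = p$b_arom, btype = p$b_btype)
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = v)
}

#' Coarse-grain a polymer into its big (monomer-level) graph
#'
#' @param p A `lignin_polymer`.
#' @return An undirected [igraph::igraph] with one vertex per monomer
#'   (attribute `mtype`) and one edge per linkage (attribute `ltype`).
#' @export
coarse_grain <- function(p) {
  .check_polymer(p)
  g <- igraph::make_empty_graph(n = polymer_size(p), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(polymer_size(p))))
  g <- igraph::set_vertex_attr(g, "mtype", value = p$m_type)
  if (length(p$l_type)) {
    g <- igraph::add_edges(g, rbind(p$l_m1, p$l_m2))
    g <- igraph::set_edge_attr(g, "ltype", value = p$l_type)
  }
  g
}

#' Validate a polymer's atomic graph
#'
#' Report-based structural audit: checks valence limits (total bond order
#' at most 4 for C and 2 for O after implicit hydrogens), connectivity,
#' linkage annotation consistency (inter-monomer bonds must carry a linkage
#' type, intra-monomer bonds must not) and agreement between the bonding
#' flags and the ledger.  An empty report means the structure is valid.
#'
#' @param p A `lignin_polymer`.
#' @return Character vector of violation messages (length zero if valid).
#' @export
validate_polymer <- function(p) {
  .check_polymer(p)
  bad <- character(0)
  n <- length(p$a_mono)
  if (n == 0L) return("polymer has no atoms")
  osum <- numeric(n)
  for (k in seq_along(p$b_i)) {
    osum[p$b_i[k]] <- osum[p$b_i[k]] + p$b_order[k]
    osum[p$b_j[k]] <- osum[p$b_j[k]] + p$b_order[k]
  }
  vmax <- ifelse(p$a_elem == "C", 4, 2)
  over <- which(osum > vmax)
  for (a in over) {
    bad <- c(bad, sprintf("valence violation: atom %d (%s, monomer %d index %d) has bond order %g",
                          a, p$a_elem[a], p$a_mono[a], p$a_idx[a], osum[a]))
  }
  if (anyDuplicated(paste(p$a_mono, p$a_idx))) {
    bad <- c(bad, "duplicated (monomer_id, atomic index)")
  }
  inter <- p$a_mono[p$b_i] != p$a_mono[p$b_j]
  if (any(inter & is.na(p$b_btype))) {
    bad <- c(bad, "inter-monomer bond lacking a linkage type")
  }
  if (any(!inter & !is.na(p$b_btype))) {
    bad <- c(bad, "intra-monomer bond carrying a linkage type")
  }
  g <- as_atomic_graph(p)
  if (igraph::components(g)$no != 1L) {
    bad <- c(bad, "atomic graph is disconnected")
  }
  if (sum(p$a_bond) != length(p$led_idx) ||
      !all(p$a_bond[mapply(function(m, i) .atom_at(p, m, i), p$led_mono, p$led_idx)])) {
    bad <- c(bad, "ledger inconsistent with bonding flags")
  }
  bad
}

.mono_colors <- c(H = "#d62728", G = "#2ca02c", S = "#1f77b4")

#' Plot the atomic or big graph of a polymer
#'
#' Nodes are coloured by monomer type (H red, G green, S blue).  When
#' `path` is given the plot is written to a PNG file, otherwise it is drawn
#' on the current device.
#'
#' @param p A `lignin_polymer` with at least one atom.
#' @param path Optional output file path (PNG).
#' @param ... Passed to [igraph::plot.igraph()].
#' @return Invisibly, the igraph object that was plotted.
#' @export
plot_atomic_graph <- function(p, path = NULL, ...) {
  .check_polymer(p)
  if (length(p$a_mono) == 0L) .abort("cannot plot an empty graph")
  g <- as_atomic_graph(p)
  cols <- .mono_colors[igraph::V(g)$mtype]
  .plot_graph(g, path,
              vertex.color = cols,
              vertex.label = paste0(igraph::V(g)$element, igraph::V(g)$index),
              ...)
}

#' @rdname plot_atomic_graph
#' @export
plot_big_graph <- function(p, path = NULL, ...) {
  .check_polymer(p)
  if (polymer_size(p) == 0L) .abort("cannot plot an empty graph")
  g <- coarse_grain(p)
  lab <- if (length(p$l_type)) linkage_label(igraph::E(g)$ltype) else NULL
  .plot_graph(g, path,
              vertex.color = .mono_colors[igraph::V(g)$mtype],
              vertex.label = igraph::V(g)$mtype,
              edge.label = lab, ...)
}

.plot_graph <- function(g, path, ...) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  igraph::plot.igraph(g, vertex.size = 9, vertex.label.cex = 0.7, ...)
  invisible(g)
}
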