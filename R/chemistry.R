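# Monomer templates and linkage bonding rules.
#
# Atomic indexing convention (per monomer): ring carbons 1-6 (aromatic),
# side-chain alpha = C7, beta = C8, gamma = C9, phenolic oxygen (the "4-O")
# = 10, gamma-hydroxyl oxygen = 11, 3-methoxy O/C = 12/13 (G and S),
# 5-methoxy O/C = 14/15 (S only).  The benzylic hydroxyl oxygen installed by
# a b-O-4 coupling is stored at index 16.  Linkage names containing "O" bond
# through the 4-O, so an index of 4 in a (C1, C2) pair stands for the
# phenolic oxygen carried by C4.

.lignin_cache <- new.env(parent = emptyenv())

.ATOMIC_MASS <- c(C = 12.011, O = 15.999, H = 1.008)
.METHOXY <- c(H = 0L, G = 1L, S = 2L)

.abort <- function(msg, class = "ligninsim_invalid_input") {
  stop(structure(
    class = c(class, "ligninsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

.check_mtype <- function(mtype) {
  if (length(mtype) != 1L || !mtype %in% monomer_types()) {
    .abort(sprintf("unknown monomer type: %s", paste(mtype, collapse = ",")))
  }
  mtype
}

.check_ltype <- function(ltype) {
  if (length(ltype) != 1L || !ltype %in% linkage_types()) {
    .abort(sprintf("unknown linkage type: %s", paste(ltype, collapse = ",")))
  }
  ltype
}

#' Monomer and linkage type codes
#'
#' The three monolignols are p-hydroxyphenyl (`"H"`, no methoxy group),
#' guaiacyl (`"G"`, one methoxy) and syringyl (`"S"`, two methoxy groups).
#' The six common inter-monomer linkages are coded in ASCII: `"4-O-5"`,
#' `"a-O-4"` (\eqn{\alpha}-O-4), `"b-O-4"` (\eqn{\beta}-O-4), `"5-5"`,
#' `"b-5"` (\eqn{\beta}-5) and `"b-b"` (\eqn{\beta}-\eqn{\beta}).
#'
#' @return A character vector of type codes.
#' @export
monomer_types <- function() c("H", "G", "S")

#' @rdname monomer_types
#' @export
linkage_types <- function() c("4-O-5", "a-O-4", "b-O-4", "5-5", "b-5", "b-b")

#' @rdname monomer_types
#' @param ltype A linkage type code.
#' @export
linkage_label <- function(ltype) {
  lab <- c("4-O-5" = "4-O-5", "a-O-4" = "α-O-4", "b-O-4" = "β-O-4",
           "5-5" = "5-5", "b-5" = "β-5", "b-b" = "β-β")
  unname(lab[ltype])
}

#' Number of methoxy groups on a monomer type
#'
#' @param mtype Monomer type code (`"H"`, `"G"` or `"S"`).
#' @return Integer count of methoxy (-OCH3) groups (0, 1 or 2).
#' @export
methoxy_count <- function(mtype) {
  .check_mtype(mtype)
  unname(.METHOXY[mtype])
}

#' Canonical monolignol template
#'
#' Returns the atom and bond lists for a free monolignol with canonical
#' atomic indexing.  Hydrogens are implicit; ring bonds carry a Kekule
#' order (alternating 1/2) and an `aromatic` flag.  The coniferyl-type side
#' chain has a 7-8 double bond and a gamma hydroxyl.
#'
#' @param mtype Monomer type code.
#' @return A list with elements `mtype`, `atoms` (data frame with columns
#'   `index`, `element`, `aromatic`) and `bonds` (data frame with columns
#'   `i`, `j` (atomic indices), `order`, `aromatic`).
#' @export
monomer_template <- function(mtype) {
  .check_mtype(mtype)
  key <- paste0("tpl_", mtype)
  if (!is.null(.lignin_cache[[key]])) return(.lignin_cache[[key]])
  atoms <- data.frame(
    index = 1:11,
    element = c(rep("C", 9), "O", "O"),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    i = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 9, 4),
    j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 11, 10),
    order = c(2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 1L, 1L),
    aromatic = c(rep(TRUE, 6), rep(FALSE, 5))
  )
  if (mtype %in% c("G", "S")) {
    atoms <- rbind(atoms, data.frame(index = 12:13, element = c("O", "C"),
                                     aromatic = FALSE))
    bonds <- rbind(bonds, data.frame(i = c(3, 12), j = c(12, 13),
                                     order = 1L, aromatic = FALSE))
  }
  if (mtype == "S") {
    atoms <- rbind(atoms, data.frame(index = 14:15, element = c("O", "C"),
                                     aromatic = FALSE))
    bonds <- rbind(bonds, data.frame(i = c(5, 14), j = c(14, 15),
                                     order = 1L, aromatic = FALSE))
  }
  tpl <- list(mtype = mtype, atoms = atoms, bonds = bonds)
  .lignin_cache[[key]] <- tpl
  tpl
}

#' Free monolignol mass
#'
#' Molecular mass of the free monomer in daltons, computed from the template
#' graph with implicit hydrogens and average atomic masses (C 12.011,
#' H 1.008, O 15.999).
#'
#' @param mtype Monomer type code.
#' @return Mass in Da.
#' @export
monomer_mass <- function(mtype) {
  tpl <- monomer_template(mtype)
  osum <- numeric(nrow(tpl$atoms))
  pi <- match(tpl$bonds$i, tpl$atoms$index)
  pj <- match(tpl$bonds$j, tpl$atoms$index)
  for (k in seq_along(pi)) {
    osum[pi[k]] <- osum[pi[k]] + tpl$bonds$order[k]
    osum[pj[k]] <- osum[pj[k]] + tpl$bonds$order[k]
  }
  vmax <- ifelse(tpl$atoms$element == "C", 4, 2)
  sum(.ATOMIC_MASS[tpl$atoms$element]) + sum(pmax(vmax - osum, 0)) * .ATOMIC_MASS[["H"]]
}

#' Linkage bonding rule tables
#'
#' The rule tables map linkage types to admissible atomic-index pairs,
#' monomer types to the indices at which they can donate a bonding atom, and
#' record which indices are retired on each side when a linkage forms.  They
#' are read once from the editable YAML file shipped in
#' `inst/extdata/linkage_rules.yaml` and cached, so that subsequent lookups
#' are constant-time.
#'
#' @return A list with elements `linkage_pairs`, `feasible_c1` and
#'   `retired_on_bond`.
#' @export
linkage_rules <- function() {
  if (is.null(.lignin_cache$rules)) {
    path <- system.file("extdata", "linkage_rules.yaml", package = "ligninsim")
    if (path == "") .abort("linkage rule file not found", "ligninsim_corrupt")
    raw <- yaml::read_yaml(path)
    pairs <- lapply(raw$linkage_pairs, function(ps) {
      m <- do.call(rbind, lapply(ps, as.integer))
      colnames(m) <- c("c1", "c2")
      m
    })
    .lignin_cache$rules <- list(
      linkage_pairs = pairs,
      feasible_c1 = lapply(raw$feasible_c1, as.integer),
      retired_on_bond = lapply(raw$retired_on_bond, function(x) lapply(x, as.integer))
    )
  }
  .lignin_cache$rules
}

#' Admissible atomic-index pairs for a linkage type
#'
#' @param ltype Linkage type code.
#' @return An integer matrix with columns `c1`, `c2`; one row per admissible
#'   (C1, C2) pair, C1 on the growing-polymer side and C2 on the incoming
#'   monomer side.
#' @export
linkage_index_pairs <- function(ltype) {
  .check_ltype(ltype)
  linkage_rules()$linkage_pairs[[ltype]]
}

#' Feasible bonding indices for a monomer type
#'
#' Indices at which a fresh monomer of the given type can take part in a new
#' inter-monomer linkage.  Syringyl excludes position 5, which is occupied
#' by the second methoxy group.
#'
#' @param mtype Monomer type code.
#' @return Sorted integer vector of atomic indices.
#' @export
feasible_c1 <- function(mtype) {
  .check_mtype(mtype)
  linkage_rules()$feasible_c1[[mtype]]
}

#' Monomer types that can donate a given C2 for a linkage
#'
#' Reverse lookup used during polymer growth: given the atomic index C2 the
#' incoming monomer must donate for linkage `ltype`, return the monomer
#' types whose bonding rules admit that index.
#'
#' @param c2 Atomic index donated by the incoming monomer.
#' @param ltype Linkage type code.
#' @return Character vector of admissible monomer type codes.
#' @export
monomers_for_c2 <- function(c2, ltype) {
  .check_ltype(ltype)
  prs <- linkage_index_pairs(ltype)
  if (!c2 %in% prs[, "c2"]) {
    .abort(sprintf("index %d is not a C2 of linkage %s", as.integer(c2), ltype),
           "ligninsim_infeasible")
  }
  types <- monomer_types()
  types[vapply(types, function(m) c2 %in% feasible_c1(m), logical(1))]
}

# Indices whose bonding availability is withdrawn on the side that donated
# `donated` when a `ltype` linkage forms.
.retired_indices <- function(ltype, donated) {
  r <- linkage_rules()$retired_on_bond[[ltype]][[as.character(donated)]]
  if (is.null(r)) .abort("no retirement rule for this index", "ligninsim_corrupt")
  r
}
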