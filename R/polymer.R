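# Rejection-free polymer growth.
#
# A polymer is a flat list of parallel vectors (atoms, bonds, monomers,
# linkages, ledger) so that Monte Carlo additions stay cheap.  Every
# executed addition leaves the structure chemically valid; feasibility is
# checked up front against the rule tables and a ledger of available
# bonding atoms, so no move ever needs to be rolled back.

#' Start a new polymer from a seed monomer
#'
#' @param seed_mtype Monomer type code for the first unit.
#' @return An object of class `lignin_polymer`.  The bonding-atom ledger is
#'   initialised with the seed monomer's feasible bonding indices.
#' @export
new_polymer <- function(seed_mtype) {
  .check_mtype(seed_mtype)
  p <- structure(list(
    a_mono = integer(0), a_idx = integer(0), a_elem = character(0),
    a_arom = logical(0), a_bond = logical(0),
    b_i = integer(0), b_j = integer(0), b_order = integer(0),
    b_arom = logical(0), b_btype = character(0),
    m_type = character(0), m_degree = integer(0),
    l_type = character(0), l_m1 = integer(0), l_m2 = integer(0),
    ops = 0
  ), class = "lignin_polymer")
  .instantiate_monomer(p, seed_mtype)
}

#' Polymer size (number of monomers)
#' @param p A `lignin_polymer`.
#' @return Integer count of monomer units.
#' @export
polymer_size <- function(p) length(p$m_type)

.check_polymer <- function(p) {
  if (!inherits(p, "lignin_polymer")) .abort("not a lignin_polymer")
  p
}

# Append a fresh monomer's atoms/bonds and ledger entries; returns the
# modified polymer with the new monomer id in attr "new_monomer".
.instantiate_monomer <- function(p, mtype) {
  tpl <- monomer_template(mtype)
  mid <- length(p$m_type) + 1L
  n0 <- length(p$a_mono)
  na <- nrow(tpl$atoms)
  fc <- feasible_c1(mtype)
  p$a_mono <- c(p$a_mono, rep.int(mid, na))
  p$a_idx <- c(p$a_idx, tpl$atoms$index)
  p$a_elem <- c(p$a_elem, tpl$atoms$element)
  p$a_arom <- c(p$a_arom, tpl$atoms$aromatic)
  p$a_bond <- c(p$a_bond, tpl$atoms$index %in% fc)
  p$b_i <- c(p$b_i, n0 + match(tpl$bonds$i, tpl$atoms$index))
  p$b_j <- c(p$b_j, n0 + match(tpl$bonds$j, tpl$atoms$index))
  p$b_order <- c(p$b_order, tpl$bonds$order)
  p$b_arom <- c(p$b_arom, tpl$bonds$aromatic)
  p$b_btype <- c(p$b_btype, rep(NA_character_, nrow(tpl$bonds)))
  p$m_type <- c(p$m_type, mtype)
  p$m_degree <- c(p$m_degree, 0L)
  p$led_mono <- c(p$led_mono, rep.int(mid, length(fc)))
  p$led_idx <- c(p$led_idx, fc)
  p$ops <- p$ops + na + nrow(tpl$bonds)
  attr(p, "new_monomer") <- mid
  p
}

.atom_at <- function(p, mono, idx) {
  w <- which(p$a_mono == mono & p$a_idx == idx)
  if (length(w) != 1L) {
    .abort(sprintf("atom (%d, %d) not found", mono, idx), "ligninsim_corrupt")
  }
  w
}

.add_bond <- function(p, i, j, order = 1L, arom = FALSE, btype = NA_character_) {
  p$b_i <- c(p$b_i, i); p$b_j <- c(p$b_j, j)
  p$b_order <- c(p$b_order, order)
  p$b_arom <- c(p$b_arom, arom)
  p$b_btype <- c(p$b_btype, btype)
  p
}

# Set the 7-8 side-chain bond of monomer `mono` to a single bond (the
# double bond is consumed whenever the alpha or beta position couples).
.saturate_side_chain <- function(p, mono) {
  i <- .atom_at(p, mono, 7L); j <- .atom_at(p, mono, 8L)
  w <- which((p$b_i == i & p$b_j == j) | (p$b_i == j & p$b_j == i))
  p$b_order[w] <- 1L
  p
}

.retire <- function(p, mono, idxs) {
  hit <- p$a_mono == mono & p$a_idx %in% idxs
  p$a_bond[hit] <- FALSE
  drop <- p$led_mono == mono & p$led_idx %in% idxs
  p$led_mono <- p$led_mono[!drop]
  p$led_idx <- p$led_idx[!drop]
  p
}

#' Form a linkage between two monomers already in the polymer
#'
#' Applies the bond-level chemistry of the requested linkage type between
#' monomer `m1` donating atomic index `c1` and monomer `m2` donating `c2`:
#' creates the new bond(s), consumes the side-chain 7-8 double bond where
#' the alpha/beta positions engage, installs the alpha-hydroxyl for b-O-4,
#' retires the consumed bonding atoms and records the linkage in the
#' coarse-grained bookkeeping.  Used by [add_monomer()] and [add_ring()];
#' exported so that specific structures can be assembled directly.
#'
#' @param p A `lignin_polymer`.
#' @param m1,m2 Monomer ids (1-based, order of addition).
#' @param c1,c2 Donated atomic indices; `(c1, c2)` must be an admissible
#'   pair for `ltype` and both atoms must still be available for bonding.
#' @param ltype Linkage type code.
#' @return The updated polymer.
#' @export
apply_linkage <- function(p, m1, c1, m2, c2, ltype) {
  .check_polymer(p); .check_ltype(ltype)
  prs <- linkage_index_pairs(ltype)
  if (!any(prs[, 1] == c1 & prs[, 2] == c2)) {
    .abort(sprintf("(%d,%d) is not an admissible pair for %s", c1, c2, ltype),
           "ligninsim_infeasible")
  }
  avail <- function(mono, idx) any(p$led_mono == mono & p$led_idx == idx)
  if (!avail(m1, c1) || !avail(m2, c2) || m1 == m2) {
    .abort("bonding atoms not available", "ligninsim_infeasible")
  }
  # side resolution: for ether linkages an index of 4 bonds through the 4-O
  o4 <- function(mono) .atom_at(p, mono, 10L)
  if (ltype == "4-O-5") {
    m4 <- if (c1 == 4L) m1 else m2; m5 <- if (c1 == 4L) m2 else m1
    p <- .add_bond(p, o4(m4), .atom_at(p, m5, 5L), btype = ltype)
  } else if (ltype == "5-5") {
    p <- .add_bond(p, .atom_at(p, m1, 5L), .atom_at(p, m2, 5L), btype = ltype)
  } else if (ltype == "a-O-4") {
    m4 <- if (c1 == 4L) m1 else m2; m7 <- if (c1 == 4L) m2 else m1
    p <- .saturate_side_chain(p, m7)
    p <- .add_bond(p, o4(m4), .atom_at(p, m7, 7L), btype = ltype)
  } else if (ltype == "b-O-4") {
    m4 <- if (c1 == 4L) m1 else m2; m8 <- if (c1 == 4L) m2 else m1
    p <- .saturate_side_chain(p, m8)
    p <- .add_bond(p, o4(m4), .atom_at(p, m8, 8L), btype = ltype)
    # benzylic (alpha) hydroxyl on the beta-side unit
    p$a_mono <- c(p$a_mono, m8); p$a_idx <- c(p$a_idx, 16L)
    p$a_elem <- c(p$a_elem, "O"); p$a_arom <- c(p$a_arom, FALSE)
    p$a_bond <- c(p$a_bond, FALSE)
    p <- .add_bond(p, .atom_at(p, m8, 7L), length(p$a_mono))
  } else if (ltype == "b-5") {
    m8 <- if (c1 == 8L) m1 else m2; m5 <- if (c1 == 8L) m2 else m1
    p <- .saturate_side_chain(p, m8)
    p <- .add_bond(p, .atom_at(p, m8, 8L), .atom_at(p, m5, 5L), btype = ltype)
    # phenylcoumaran ring closes alpha to the 4-O of the 5-side unit
    p <- .add_bond(p, .atom_at(p, m8, 7L), o4(m5), btype = ltype)
  } else if (ltype == "b-b") {
    p <- .saturate_side_chain(p, m1)
    p <- .saturate_side_chain(p, m2)
    p <- .add_bond(p, .atom_at(p, m1, 8L), .atom_at(p, m2, 8L), btype = ltype)
    # resinol: each alpha bonds the gamma-oxygen of the partner unit
    p <- .add_bond(p, .atom_at(p, m1, 7L), .atom_at(p, m2, 11L), btype = ltype)
    p <- .add_bond(p, .atom_at(p, m2, 7L), .atom_at(p, m1, 11L), btype = ltype)
  }
  p <- .retire(p, m1, .retired_indices(ltype, c1))
  p <- .retire(p, m2, .retired_indices(ltype, c2))
  p$l_type <- c(p$l_type, ltype)
  p$l_m1 <- c(p$l_m1, m1)
  p$l_m2 <- c(p$l_m2, m2)
  p$m_degree[m1] <- p$m_degree[m1] + 1L
  p$m_degree[m2] <- p$m_degree[m2] + 1L
  # atom lookups and retirements each scan the atom/ledger vectors once
  p$ops <- p$ops + length(p$a_mono) + length(p$led_idx)
  p
}

#' Describe a Monte Carlo addition proposal
#'
#' @param ltype Linkage type code.
#' @param m2 Monomer type for the incoming unit, or `NULL` to resolve it
#'   from the chosen site via [monomers_for_c2()].
#' @param branching If `TRUE` the addition must attach to a monomer already
#'   holding two or more linkages (creating or extending a branch point);
#'   if `FALSE` it must attach to a terminal monomer.
#' @param ring If `TRUE` the proposal is an intramolecular linkage between
#'   two existing monomers and no monomer is added (`m2` must be `NULL`).
#' @return An object of class `lignin_proposal`.
#' @export
proposal <- function(ltype, m2 = NULL, branching = FALSE, ring = FALSE) {
  .check_ltype(ltype)
  if (!is.null(m2)) .check_mtype(m2)
  if (ring && !is.null(m2)) .abort("ring proposals do not add a monomer")
  structure(list(ltype = ltype, m2 = m2, branching = isTRUE(branching),
                 ring = isTRUE(ring)),
            class = "lignin_proposal")
}

#' Enumerate feasible addition sites
#'
#' Intersects the polymer's bonding-atom ledger with the C1 indices
#' admissible for the proposed linkage, applies the branching filter
#' (terminal vs. branched attachment), and pairs each candidate C1 with the
#' C2 the incoming monomer must donate.  For ring proposals, returns
#' feasible intramolecular pairs instead (see [feasible_ring_sites()]).
#'
#' @param p A `lignin_polymer`.
#' @param prop A `lignin_proposal`.
#' @return A data frame with columns `monomer_id`, `c1`, `c2` (possibly
#'   zero rows).
#' @export
feasible_sites <- function(p, prop) {
  .check_polymer(p)
  if (isTRUE(prop$ring)) return(feasible_ring_sites(p, prop$ltype))
  prs <- linkage_index_pairs(prop$ltype)
  keep <- p$led_idx %in% prs[, 1]
  deg <- p$m_degree[p$led_mono]
  keep <- keep & if (prop$branching) deg >= 2L else deg <= 1L
  mono <- p$led_mono[keep]; c1 <- p$led_idx[keep]
  out <- vector("list", nrow(prs))
  for (k in seq_len(nrow(prs))) {
    sel <- c1 == prs[k, 1]
    if (any(sel)) {
      out[[k]] <- data.frame(monomer_id = unname(mono[sel]),
                             c1 = unname(c1[sel]), c2 = unname(prs[k, 2]))
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(monomer_id = integer(0), c1 = integer(0),
                                      c2 = integer(0))
  # if the proposal pins the incoming monomer type, its rules must admit c2
  if (!is.null(prop$m2) && nrow(out)) {
    out <- out[out$c2 %in% feasible_c1(prop$m2), , drop = FALSE]
  }
  out
}

#' Enumerate feasible intramolecular (ring) linkage sites
#'
#' @param p A `lignin_polymer`.
#' @param ltype Linkage type code, or `NULL` to enumerate over all six
#'   types.
#' @return A data frame with columns `m1`, `c1`, `m2`, `c2`, `ltype`.
#' @export
feasible_ring_sites <- function(p, ltype = NULL) {
  .check_polymer(p)
  ltypes <- if (is.null(ltype)) linkage_types() else .check_ltype(ltype)
  # intramolecular coupling joins two phenolic units: each endpoint must
  # either donate its 4-O or still carry a free one
  free4 <- unique(p$led_mono[p$led_idx == 4L])
  ok_end <- function(mono, idx) idx == 4L | mono %in% free4
  res <- list()
  for (lt in ltypes) {
    prs <- linkage_index_pairs(lt)
    for (k in seq_len(nrow(prs))) {
      w1 <- which(p$led_idx == prs[k, 1] & ok_end(p$led_mono, prs[k, 1]))
      w2 <- which(p$led_idx == prs[k, 2] & ok_end(p$led_mono, prs[k, 2]))
      if (!length(w1) || !length(w2)) next
      g <- expand.grid(i = w1, j = w2)
      g <- g[p$led_mono[g$i] != p$led_mono[g$j], , drop = FALSE]
      if (!nrow(g)) next
      res[[length(res) + 1L]] <- data.frame(
        m1 = p$led_mono[g$i], c1 = p$led_idx[g$i],
        m2 = p$led_mono[g$j], c2 = p$led_idx[g$j], ltype = lt
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(m1 = integer(0), c1 = integer(0), m2 = integer(0),
               c2 = integer(0), ltype = character(0))
  if (nrow(out)) {
    # drop symmetric duplicates of the same unordered atom pair
    key <- ifelse(
      out$m1 < out$m2,
      paste(out$m1, out$c1, out$m2, out$c2, out$ltype),
      paste(out$m2, out$c2, out$m1, out$c1, out$ltype)
    )
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Add a monomer to the polymer via a proposed linkage
#'
#' A rejection-free Monte Carlo event: one feasible site is chosen uniformly
#' at random, the incoming monomer type is resolved from the mandated C2
#' (sampled from `monomer_weights` when several types are admissible), and
#' the linkage chemistry is applied.  The returned structure is always
#' chemically valid; if no feasible site exists an `ligninsim_infeasible`
#' condition is signalled and the polymer is left untouched (the caller
#' resamples the proposal).
#'
#' @param p A `lignin_polymer`.
#' @param prop A `lignin_proposal` (with `ring = FALSE`).
#' @param monomer_weights Optional named weights over `c("H","G","S")` used
#'   to draw the incoming monomer type among the admissible ones (e.g. the
#'   experimental monomer distribution).
#' @param site Optional row index into `feasible_sites(p, prop)` to force a
#'   specific attachment (used for deterministic construction and testing).
#' @return The updated polymer; the executed addition record (site, linkage
#'   and monomer type) is stored in `attr(p, "last_addition")`.
#' @export
add_monomer <- function(p, prop, monomer_weights = NULL, site = NULL) {
  .check_polymer(p)
  if (isTRUE(prop$ring)) .abort("use add_ring() for ring proposals")
  sites <- feasible_sites(p, prop)
  p$ops <- p$ops + length(p$led_idx)
  if (!nrow(sites)) .abort("no feasible site for this proposal", "ligninsim_infeasible")
  row <- if (is.null(site)) sites[sample.int(nrow(sites), 1L), ] else sites[site, ]
  adm <- monomers_for_c2(row$c2, prop$ltype)
  m2t <- prop$m2
  if (is.null(m2t) || !m2t %in% adm) {
    w <- if (is.null(monomer_weights)) rep(1, length(adm)) else monomer_weights[adm]
    if (all(w <= 0) || anyNA(w)) w <- rep(1, length(adm))
    m2t <- if (length(adm) == 1L) adm else sample(adm, 1L, prob = w)
  }
  p <- .instantiate_monomer(p, m2t)
  m2 <- attr(p, "new_monomer")
  p <- apply_linkage(p, row$monomer_id, row$c1, m2, row$c2, prop$ltype)
  attr(p, "last_addition") <- list(ltype = prop$ltype, m1 = row$monomer_id,
                                   c1 = row$c1, m2 = m2, c2 = row$c2,
                                   mtype = m2t)
  p
}

#' Add an intramolecular linkage (ring) between existing monomers
#'
#' Chooses one feasible intramolecular pair uniformly at random and applies
#' the linkage chemistry; no monomer is added and the polymer size is
#' unchanged.  Signals `ligninsim_infeasible` when no compatible pair of
#' free bonding atoms exists.
#'
#' @param p A `lignin_polymer` with at least two monomers.
#' @param ltype Linkage type code, or `NULL` to draw uniformly over all
#'   feasible sites of any type.
#' @param site Optional row index into `feasible_ring_sites(p, ltype)`.
#' @return The updated polymer, with the executed record in
#'   `attr(p, "last_addition")`.
#' @export
add_ring <- function(p, ltype = NULL, site = NULL) {
  .check_polymer(p)
  sites <- feasible_ring_sites(p, ltype)
  p$ops <- p$ops + length(p$led_idx)
  if (!nrow(sites)) .abort("no feasible intramolecular pair", "ligninsim_infeasible")
  row <- if (is.null(site)) sites[sample.int(nrow(sites), 1L), ] else sites[site, ]
  p <- apply_linkage(p, row$m1, row$c1, row$m2, row$c2, row$ltype)
  attr(p, "last_addition") <- list(ltype = row$ltype, m1 = row$m1, c1 = row$c1,
                                   m2 = row$m2, c2 = row$c2, mtype = NA_character_,
                                   ring = TRUE)
  p
}

#' Current bonding-atom ledger
#'
#' @param p A `lignin_polymer`.
#' @return Data frame with columns `monomer_id`, `index`, `mtype`: the
#'   atoms currently available to donate a C1 in a new linkage.
#' @export
ledger <- function(p) {
  .check_polymer(p)
  data.frame(monomer_id = p$led_mono, index = p$led_idx,
             mtype = p$m_type[p$led_mono], stringsAsFactors = FALSE)
}

#' @export
print.lignin_polymer <- function(x, ...) {
  cat(sprintf("<lignin_polymer> %d monomers (%s), %d linkages, %d heavy atoms\n",
              polymer_size(x), paste(x$m_type, collapse = ""),
              length(x$l_type), length(x$a_mono)))
  if (length(x$l_type)) {
    tab <- table(factor(x$l_type, levels = linkage_types()))
    cat("  linkages:", paste(sprintf("%s=%d", linkage_label(names(tab)), tab),
                             collapse = " "), "\n")
  }
  invisible(x)
}
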