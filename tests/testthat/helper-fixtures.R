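# Shared fixture builders and independent oracles.

# Build a dimer joined by a specific linkage; `c1` pins the polymer-side
# bonding index when several directions are admissible.
make_dimer <- function(lt, mt1 = "G", mt2 = "G", c1 = NULL) {
  p <- new_polymer(mt1)
  prop <- proposal(lt, m2 = mt2)
  sites <- feasible_sites(p, prop)
  stopifnot(nrow(sites) > 0)
  i <- if (is.null(c1)) 1L else which(sites$c1 == c1)[1]
  stopifnot(!is.na(i))
  add_monomer(p, prop, site = i)
}

# Linear chain of `n` monomers joined by beta-O-4 (terminal growth).
make_chain <- function(n, mt = "G") {
  p <- new_polymer(mt)
  for (k in seq_len(n - 1L)) p <- add_monomer(p, proposal("b-O-4", m2 = mt))
  p
}

# Star: one G centre carrying three arms (degree 3).
make_star <- function() {
  p <- new_polymer("G")
  p <- add_monomer(p, proposal("b-O-4", m2 = "G"), site = 1L) # centre donates 4
  s <- feasible_sites(p, proposal("b-5", m2 = "G"))
  p <- add_monomer(p, proposal("b-5", m2 = "G"),
                   site = which(s$monomer_id == 1L & s$c1 == 8L)[1])
  p <- add_monomer(p, proposal("5-5", m2 = "G", branching = TRUE))
  p
}

# Independent site oracle: scan every atom of the polymer against the rule
# tables instead of consulting the ledger.
brute_force_sites <- function(p, prop) {
  prs <- linkage_index_pairs(prop$ltype)
  out <- list()
  for (a in seq_along(p$a_mono)) {
    if (!p$a_bond[a]) next
    mono <- p$a_mono[a]
    deg <- sum(p$l_m1 == mono) + sum(p$l_m2 == mono)
    if (prop$branching && deg < 2L) next
    if (!prop$branching && deg > 1L) next
    for (k in seq_len(nrow(prs))) {
      if (p$a_idx[a] == prs[k, 1]) {
        out[[length(out) + 1L]] <- data.frame(
          monomer_id = mono, c1 = unname(prs[k, 1]), c2 = unname(prs[k, 2]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(monomer_id = integer(0), c1 = integer(0), c2 = integer(0)))
  }
  do.call(rbind, out)
}

sort_sites <- function(s) {
  s <- s[order(s$monomer_id, s$c1, s$c2), , drop = FALSE]
  rownames(s) <- NULL
  s
}

# Fast valence audit (total bond order within C<=4 / O<=2).
valence_ok <- function(p) {
  n <- length(p$a_mono)
  osum <- tabulate(rep(c(p$b_i, p$b_j), times = rep(p$b_order, 2L)), nbins = n)
  all(osum <= ifelse(p$a_elem == "C", 4, 2))
}

# OpenBabel as an independent oracle for SMILES formula and mass.
obabel_report <- function(smiles) {
  out <- suppressWarnings(system2("obabel",
                                  c(shQuote(paste0("-:", smiles)), "-oreport"),
                                  stdout = TRUE, stderr = FALSE))
  formula <- sub("^FORMULA: ", "", grep("^FORMULA: ", out, value = TRUE)[1])
  mass <- as.numeric(sub("^MASS: ", "", grep("^MASS: ", out, value = TRUE)[1]))
  list(formula = formula, mass = mass)
}

obabel_canonical <- function(smiles) {
  out <- suppressWarnings(system2("obabel",
                                  c(shQuote(paste0("-:", smiles)), "-ocan"),
                                  stdout = TRUE, stderr = FALSE))
  trimws(out[1])
}

formula_string <- function(p) {
  f <- polymer_formula(p)
  paste0("C", f[["C"]], "H", f[["H"]], if (f[["O"]] > 0) paste0("O", f[["O"]]) else "")
}
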