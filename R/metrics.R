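# Per-polymer and population structure metrics.

.pct <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) counts * 0 else 100 * counts / tot
}

.monomer_counts <- function(p) {
  c(table(factor(p$m_type, levels = monomer_types())))
}

.linkage_counts <- function(p) {
  c(table(factor(p$l_type, levels = linkage_types())))
}

#' Polymer molecular weight
#'
#' Mass in daltons computed from the atomic graph's heavy atoms plus
#' implicit hydrogens (average atomic masses C 12.011, H 1.008, O 15.999).
#'
#' @param p A `lignin_polymer`.
#' @return Mass in Da.
#' @export
polymer_mw <- function(p) {
  .check_polymer(p)
  n <- length(p$a_mono)
  osum <- numeric(n)
  for (k in seq_along(p$b_i)) {
    osum[p$b_i[k]] <- osum[p$b_i[k]] + p$b_order[k]
    osum[p$b_j[k]] <- osum[p$b_j[k]] + p$b_order[k]
  }
  vmax <- ifelse(p$a_elem == "C", 4, 2)
  sum(.ATOMIC_MASS[p$a_elem]) + sum(pmax(vmax - osum, 0)) * .ATOMIC_MASS[["H"]]
}

#' Count free phenolic hydroxyls
#'
#' A phenolic OH is a 4-position oxygen not engaged in an ether or ring
#' linkage, i.e. an index-10 oxygen with a single heavy-atom bond.
#'
#' @param p A `lignin_polymer`.
#' @return Integer count.
#' @export
phenolic_oh_count <- function(p) {
  .check_polymer(p)
  deg <- integer(length(p$a_mono))
  for (k in seq_along(p$b_i)) {
    deg[p$b_i[k]] <- deg[p$b_i[k]] + 1L
    deg[p$b_j[k]] <- deg[p$b_j[k]] + 1L
  }
  sum(p$a_idx == 10L & deg == 1L)
}

#' Structure metrics of a single polymer
#'
#' @param p A `lignin_polymer`.
#' @return An object of class `lignin_polymer_metrics`: a list with
#'   `monomer_pct` (named, percent, sums to 100), `linkage_pct` (named,
#'   percent, sums to 100 when at least one linkage exists, all zero
#'   otherwise), `monomer_counts`, `linkage_counts`, `n_monomers`,
#'   `n_linkages`, `mw` (Da), `branching_coefficient` (fraction of monomers
#'   connected to three or more monomers), `n_methoxy` and
#'   `n_phenolic_oh`.
#' @export
polymer_metrics <- function(p) {
  .check_polymer(p)
  if (length(p$a_mono) == 0L) .abort("empty polymer", "ligninsim_corrupt")
  mc <- .monomer_counts(p)
  lc <- .linkage_counts(p)
  n <- polymer_size(p)
  structure(list(
    monomer_pct = .pct(mc),
    linkage_pct = .pct(lc),
    monomer_counts = mc,
    linkage_counts = lc,
    n_monomers = n,
    n_linkages = length(p$l_type),
    mw = polymer_mw(p),
    branching_coefficient = sum(p$m_degree >= 3L) / n,
    n_branched = sum(p$m_degree >= 3L),
    n_methoxy = sum(.METHOXY[p$m_type]),
    n_phenolic_oh = phenolic_oh_count(p)
  ), class = "lignin_polymer_metrics")
}

#' Population metrics of a structure library
#'
#' Global percentages pool monomer and linkage instances over the whole
#' library (count-weighted, as an NMR integration over a bulk sample would),
#' not unweighted means of per-polymer percentages.  The number-average
#' molecular weight is the arithmetic mean of the polymer MWs.  For each
#' per-polymer metric a Gaussian fit (sample mean and standard deviation)
#' is reported alongside the per-polymer values for histogramming.
#'
#' @param polymers A non-empty list of `lignin_polymer` objects (or a
#'   `lignin_library`).
#' @return An object of class `lignin_population_metrics`: a list with
#'   `monomer_pct`, `linkage_pct` (pooled, percent), `mean_mw` (Da),
#'   `mean_size`, `branching_coefficient` (pooled fraction), `n_polymers`,
#'   `per_polymer` (data frame, one row per polymer) and `fits` (data
#'   frame of Gaussian mu/sigma per metric).
#' @export
population_metrics <- function(polymers) {
  if (inherits(polymers, "lignin_library")) polymers <- polymers$polymers
  if (!is.list(polymers) || length(polymers) == 0L) {
    .abort("population_metrics() needs a non-empty list of polymers")
  }
  pm <- lapply(polymers, polymer_metrics)
  per <- do.call(rbind, lapply(seq_along(pm), function(i) {
    m <- pm[[i]]
    cbind(data.frame(polymer = i),
          as.data.frame(as.list(m$monomer_pct)),
          stats::setNames(as.data.frame(as.list(m$linkage_pct)),
                          make.names(names(m$linkage_pct))),
          data.frame(n_monomers = m$n_monomers, mw = m$mw,
                     branching_coefficient = m$branching_coefficient))
  }))
  mono <- Reduce(`+`, lapply(pm, `[[`, "monomer_counts"))
  link <- Reduce(`+`, lapply(pm, `[[`, "linkage_counts"))
  n_mono <- sum(vapply(pm, `[[`, numeric(1), "n_monomers"))
  n_branched <- sum(vapply(pm, `[[`, numeric(1), "n_branched"))
  metric_cols <- setdiff(names(per), "polymer")
  fits <- data.frame(
    metric = metric_cols,
    mu = vapply(metric_cols, function(cl) mean(per[[cl]]), numeric(1)),
    sigma = vapply(metric_cols, function(cl) stats::sd(per[[cl]]), numeric(1)),
    row.names = NULL
  )
  if (length(polymers) == 1L) fits$sigma <- 0
  structure(list(
    monomer_pct = .pct(mono),
    linkage_pct = .pct(link),
    monomer_counts = mono,
    linkage_counts = link,
    mean_mw = mean(per$mw),
    mean_size = mean(per$n_monomers),
    branching_coefficient = n_branched / n_mono,
    n_polymers = length(polymers),
    per_polymer = per,
    fits = fits
  ), class = "lignin_population_metrics")
}

#' @export
print.lignin_polymer_metrics <- function(x, ...) {
  cat(sprintf("<lignin_polymer_metrics> size %d, MW %.1f Da, BC %.3f\n",
              x$n_monomers, x$mw, x$branching_coefficient))
  cat("  monomers (%):", paste(sprintf("%s %.1f", names(x$monomer_pct), x$monomer_pct),
                               collapse = ", "), "\n")
  cat("  linkages (%):", paste(sprintf("%s %.1f", linkage_label(names(x$linkage_pct)),
                                       x$linkage_pct), collapse = ", "), "\n")
  cat(sprintf("  methoxy %d, phenolic OH %d\n", x$n_methoxy, x$n_phenolic_oh))
  invisible(x)
}

#' @export
print.lignin_population_metrics <- function(x, ...) {
  cat(sprintf("<lignin_population_metrics> %d polymers, mean size %.2f, MW %.0f Da, BC %.3f\n",
              x$n_polymers, x$mean_size, x$mean_mw, x$branching_coefficient))
  cat("  monomers (%):", paste(sprintf("%s %.1f", names(x$monomer_pct), x$monomer_pct),
                               collapse = ", "), "\n")
  cat("  linkages (%):", paste(sprintf("%s %.1f", linkage_label(names(x$linkage_pct)),
                                       x$linkage_pct), collapse = ", "), "\n")
  invisible(x)
}
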