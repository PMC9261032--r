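# Feedstock presets: experimentally measured monomer/linkage distributions
# for three lignin feedstocks (pine and poplar from 2D-HSQC NMR plus
# thioacidolysis; miscanthus from literature HSQC NMR and size-exclusion
# chromatography).

#' Feedstock target presets
#'
#' Experimental target metrics for three lignin feedstocks.  Pine
#' (softwood): pure guaiacyl lignin, beta-O-4 66 %, 5-5 0.1 %, beta-5 18 %,
#' beta-beta 16 %.  Poplar (hardwood): G 37 / S 63, beta-O-4 78 %, 5-5
#' 0.1 %, beta-5 7 %, beta-beta 15 %.  Miscanthus (herbaceous): H 4 / G 46
#' / S 50, beta-O-4 68 %, beta-5 15 %, beta-beta 17 %, number-average MW
#' 1240 Da.  The small herbaceous H fraction is reported inconsistently
#' across sources; `h_unit = "zero"` selects the variant without H units
#' (the G/S percentages are then renormalized to 48/52).
#'
#' @param name One of `"pine"`, `"poplar"`, `"miscanthus"`.
#' @param h_unit For miscanthus only: `"literature"` (default, H = 4 %) or
#'   `"zero"` (no H units).
#' @return A `lignin_targets`.
#' @export
preset_targets <- function(name = c("pine", "poplar", "miscanthus"),
                           h_unit = c("literature", "zero")) {
  name <- match.arg(name)
  h_unit <- match.arg(h_unit)
  switch(name,
    pine = target_metrics(
      monomer_pct = c(H = 0, G = 100, S = 0),
      linkage_pct = c("b-O-4" = 66, "5-5" = 0.1, "b-5" = 18, "b-b" = 16),
      branching_coefficient = 0, name = "pine"
    ),
    poplar = target_metrics(
      monomer_pct = c(H = 0, G = 37, S = 63),
      linkage_pct = c("b-O-4" = 78, "5-5" = 0.1, "b-5" = 7, "b-b" = 15),
      branching_coefficient = 0, name = "poplar"
    ),
    miscanthus = target_metrics(
      monomer_pct = if (h_unit == "literature") c(H = 4, G = 46, S = 50)
                    else c(H = 0, G = 48, S = 52),
      linkage_pct = c("b-O-4" = 68, "b-5" = 15, "b-b" = 17),
      branching_coefficient = 0, mw = 1240, name = "miscanthus"
    )
  )
}

#' Default hyperparameters per feedstock
#'
#' Pine and poplar use an expected polymer size of 5 monomers (matching the
#' reported average polymer sizes of about 5) and a small branching
#' propensity (pine 0.05, poplar 0.3); miscanthus, a linear herbaceous
#' lignin, uses zero branching propensity, an expected size of 6.6 monomers
#' with a narrow spread (so the population loop cannot trade the MW target
#' away for linkage fit by stockpiling short chains), and a slightly warmer
#' population temperature.
#'
#' @param name One of `"pine"`, `"poplar"`, `"miscanthus"`.
#' @param ... Overrides passed to [lignin_hyperparameters()].
#' @return A `lignin_hyperparameters`.
#' @export
preset_hyperparameters <- function(name = c("pine", "poplar", "miscanthus"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    pine = list(size_mean = 5, branching_propensity = 0.05),
    poplar = list(size_mean = 5, branching_propensity = 0.3),
    miscanthus = list(size_mean = 6.6, size_sd = 0.8,
                      branching_propensity = 0, t_population = 1e-4)
  )
  over <- list(...)
  defaults[names(over)] <- over
  do.call(lignin_hyperparameters, defaults)
}
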