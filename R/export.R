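# Library serialization: per-polymer CSV table, run summary, resolved
# configuration and per-metric histograms.

.fmt4 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 4), format = "fg", flag = "#"))
}

#' Tabulate a structure library
#'
#' One row per polymer: counts of monomers, linkages and functional groups,
#' molecular weight, branching coefficient and the SMILES string.
#'
#' @param lib A `lignin_library` or list of polymers.
#' @return A data frame.
#' @export
library_table <- function(lib) {
  polymers <- if (inherits(lib, "lignin_library")) lib$polymers else lib
  if (!length(polymers)) .abort("empty library")
  rows <- lapply(seq_along(polymers), function(i) {
    p <- polymers[[i]]
    m <- polymer_metrics(p)
    cbind(
      data.frame(polymer = i),
      stats::setNames(as.data.frame(as.list(m$monomer_counts)),
                      paste0("n_", monomer_types())),
      stats::setNames(as.data.frame(as.list(m$linkage_counts)),
                      paste0("n_", make.names(linkage_types()))),
      data.frame(n_monomers = m$n_monomers, n_linkages = m$n_linkages,
                 n_methoxy = m$n_methoxy, n_phenolic_oh = m$n_phenolic_oh,
                 mw = m$mw, branching_coefficient = m$branching_coefficient,
                 smiles = to_smiles(p))
    )
  })
  do.call(rbind, rows)
}

#' Export a structure library to disk
#'
#' Writes `library.csv` (the [library_table()], fixed column order, floats
#' at 4 significant digits so re-exports are byte-identical),
#' `summary.txt` (final distance, acceptance ratio, MC attempts and pooled
#' population metrics), `config.yaml` (the resolved targets,
#' hyperparameters and seed, sufficient to reproduce the run), and, when
#' `plots = TRUE`, one histogram per metric with the Gaussian fit
#' annotation.
#'
#' @param lib A `lignin_library`.
#' @param outdir Output directory (created if missing).
#' @param plots Write histogram PNGs (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
export_library <- function(lib, outdir, plots = TRUE) {
  if (!inherits(lib, "lignin_library")) .abort("need a lignin_library")
  if (!length(lib$polymers)) .abort("empty library")
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(outdir, 2) != 0) .abort(sprintf("cannot write to %s", outdir))
  paths <- character(0)
  tab <- library_table(lib)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], .fmt4)
  csv <- file.path(outdir, "library.csv")
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  paths <- c(paths, csv)

  pop <- lib$population
  s <- lib$summary
  rpt <- file.path(outdir, "summary.txt")
  lines <- c(
    sprintf("ligninsim %s structure library", lib$version),
    sprintf("feedstock: %s", if (is.null(lib$targets$name)) "custom" else lib$targets$name),
    sprintf("seed: %s", if (is.null(lib$seed)) "unset" else lib$seed),
    sprintf("polymers: %d", s$n_polymers),
    sprintf("final distance d: %s", .fmt4(s$final_d)),
    sprintf("outer acceptance ratio: %s", .fmt4(s$acceptance_ratio)),
    sprintf("total MC attempts: %d", s$total_attempts),
    sprintf("rings accepted: %d", s$ring_accepted),
    "",
    "pooled population metrics:",
    sprintf("  monomer %% : %s",
            paste(sprintf("%s %s", names(pop$monomer_pct), .fmt4(pop$monomer_pct)),
                  collapse = ", ")),
    sprintf("  linkage %% : %s",
            paste(sprintf("%s %s", names(pop$linkage_pct), .fmt4(pop$linkage_pct)),
                  collapse = ", ")),
    sprintf("  mean size: %s monomers", .fmt4(pop$mean_size)),
    sprintf("  number-average MW: %s Da", .fmt4(pop$mean_mw)),
    sprintf("  branching coefficient: %s", .fmt4(pop$branching_coefficient))
  )
  writeLines(lines, rpt)
  paths <- c(paths, rpt)

  cfg <- file.path(outdir, "config.yaml")
  write_config(lib$targets, lib$hyper, cfg, seed = lib$seed)
  paths <- c(paths, cfg)

  if (plots) {
    paths <- c(paths, .plot_histograms(pop, lib$targets, outdir))
  }
  invisible(paths)
}

.plot_histograms <- function(pop, targets, outdir) {
  per <- pop$per_polymer
  specs <- c(stats::setNames(monomer_types(), monomer_types()),
             stats::setNames(make.names(linkage_types()), linkage_types()))
  tvals <- c(targets$monomer_pct, stats::setNames(targets$linkage_pct, make.names(linkage_types())))
  out <- character(0)
  for (nm in names(specs)) {
    col <- specs[[nm]]
    mu <- mean(per[[col]]); sig <- stats::sd(per[[col]])
    gg <- ggplot2::ggplot(per, ggplot2::aes(x = .data[[col]])) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              binwidth = 2, boundary = 0,
                              fill = "grey70", colour = "grey30") +
      ggplot2::geom_vline(xintercept = tvals[[col]], colour = "red",
                          linetype = "dashed") +
      ggplot2::labs(
        title = sprintf("%s: μ = %.1f, σ = %.1f",
                        if (nm %in% linkage_types()) linkage_label(nm) else nm,
                        mu, sig),
        x = "percent of population", y = "density") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, sprintf("hist_%s.png", col))
    suppressMessages(ggplot2::ggsave(f, gg, width = 4, height = 3, dpi = 120))
    out <- c(out, f)
  }
  out
}

#' Write / read a run configuration
#'
#' The YAML configuration stores the resolved targets, hyperparameters and
#' seed; loading it and re-running [optimize_population()] reproduces the
#' run exactly.
#'
#' @param targets A `lignin_targets`.
#' @param hyper A `lignin_hyperparameters`.
#' @param path File path.
#' @param seed Optional integer seed to record.
#' @return `write_config()` returns the path invisibly; `read_config()`
#'   returns a list with `targets`, `hyper` and `seed`.
#' @export
write_config <- function(targets, hyper, path, seed = NULL) {
  cfg <- list(
    feedstock = targets$name,
    seed = seed,
    targets = list(
      monomer_pct = as.list(targets$monomer_pct),
      linkage_pct = as.list(targets$linkage_pct),
      branching_coefficient = targets$branching_coefficient,
      mw = targets$mw
    ),
    hyperparameters = unclass(hyper)
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  t <- target_metrics(
    monomer_pct = unlist(cfg$targets$monomer_pct),
    linkage_pct = unlist(cfg$targets$linkage_pct),
    branching_coefficient = cfg$targets$branching_coefficient,
    mw = cfg$targets$mw,
    name = cfg$feedstock
  )
  hp <- cfg$hyperparameters
  h <- lignin_hyperparameters(
    t_polymer = hp$t_polymer, t_population = hp$t_population,
    t_ring = hp$t_ring, branching_propensity = hp$branching_propensity,
    size_mean = hp$size_mean, size_sd = hp$size_sd,
    max_iter_inner = hp$max_iter_inner, max_iter_outer = hp$max_iter_outer,
    max_iter_ring = hp$max_iter_ring, population_size = hp$population_size,
    mw_max = hp$mw_max, feasibility_cap = hp$feasibility_cap
  )
  list(targets = t, hyper = h, seed = cfg$seed)
}
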