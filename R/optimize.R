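# Distance-to-target objective and the hierarchical Metropolis Monte Carlo
# optimization: an inner loop grows one polymer at a time by rejection-free
# additions, an outer loop assembles the population, and a fine-tuning loop
# adds intramolecular linkages (rings).

#' Experimental target metrics
#'
#' Bundle of the experimental observables a simulated library should match:
#' monomer percentages, linkage percentages, and optionally a branching
#' coefficient and a number-average molecular weight.
#'
#' @param monomer_pct Named numeric vector over `c("H","G","S")`, percent
#'   (missing names default to 0).
#' @param linkage_pct Named numeric vector over the six linkage codes,
#'   percent (missing names default to 0).
#' @param branching_coefficient Optional target branching coefficient
#'   (fraction in 0-1).
#' @param mw Optional target number-average molecular weight in Da.
#' @param name Optional label (e.g. feedstock name).
#' @return An object of class `lignin_targets`.
#' @export
target_metrics <- function(monomer_pct, linkage_pct, branching_coefficient = NULL,
                           mw = NULL, name = NULL) {
  m <- stats::setNames(numeric(3), monomer_types())
  m[names(monomer_pct)] <- monomer_pct
  l <- stats::setNames(numeric(6), linkage_types())
  if (!all(names(linkage_pct) %in% linkage_types())) {
    .abort("unknown linkage name in linkage_pct")
  }
  l[names(linkage_pct)] <- linkage_pct
  if (any(m < 0) || any(l < 0) || any(m > 100) || any(l > 100)) {
    .abort("percentages must lie in [0, 100]")
  }
  # experimental rows may overshoot 100 slightly (rounding of NMR integrals)
  if (sum(m) > 100.5 || sum(l) > 100.5) {
    .abort("percentage groups must sum to at most 100")
  }
  if (!is.null(mw) && mw <= 0) .abort("mw target must be positive")
  if (!is.null(branching_coefficient) &&
      (branching_coefficient < 0 || branching_coefficient > 1)) {
    .abort("branching coefficient target must lie in [0, 1]")
  }
  structure(list(monomer_pct = m, linkage_pct = l,
                 branching_coefficient = branching_coefficient,
                 mw = mw, name = name),
            class = "lignin_targets")
}

#' Optimization hyperparameters
#'
#' @param t_polymer Metropolis temperature of the inner (single-polymer)
#'   loop; dimensionless, on the scale of the squared-error distance.
#' @param t_population Metropolis temperature of the outer (population)
#'   loop.  Adding one polymer changes pooled percentages by roughly the
#'   per-polymer spread divided by the library size, so population-level
#'   distance increments are orders of magnitude smaller than polymer-level
#'   ones, hence the smaller default.
#' @param t_ring Metropolis temperature of the ring fine-tuning loop.  A
#'   single intramolecular linkage shifts pooled percentages by only one
#'   linkage instance out of several hundred, so the ring loop runs colder
#'   still; together with the ring budget this pins the equilibrium uptake
#'   of off-target ring types (5-5, 4-O-5) at a few percent.
#' @param branching_propensity Probability that an addition proposal targets
#'   a branched (non-terminal) site.
#' @param size_mean,size_sd Mean and sd of the per-polymer stopping size in
#'   monomers, drawn from a normal distribution (rounded, truncated at 1).
#'   When `size_mean` is `NULL` it is derived at run time from the MW
#'   target as `mw / mean monomer mass`; `size_sd` defaults to
#'   `0.25 * size_mean`.
#' @param max_iter_inner Iteration cap of the inner growth loop.
#' @param max_iter_outer Attempt cap of the outer population loop.
#' @param max_iter_ring Proposal budget of the ring fine-tuning loop
#'   (`NULL` = `10 * population_size`).
#' @param population_size Number of polymers in the library.
#' @param mw_max Normalizer of the MW term of the population distance (Da).
#' @param feasibility_cap Consecutive infeasible proposals tolerated before
#'   a growing polymer is declared stuck (infeasible resamples are not
#'   Metropolis rejections).
#' @return An object of class `lignin_hyperparameters`.
#' @export
lignin_hyperparameters <- function(t_polymer = 0.05, t_population = 5e-5,
                                   t_ring = 2e-5, branching_propensity = 0.1,
                                   size_mean = NULL, size_sd = NULL,
                                   max_iter_inner = 200L, max_iter_outer = 1000L,
                                   max_iter_ring = NULL, population_size = 100L,
                                   mw_max = 10000, feasibility_cap = 50L) {
  if (t_polymer <= 0 || t_population <= 0 || t_ring <= 0) {
    .abort("temperatures must be positive")
  }
  if (branching_propensity < 0 || branching_propensity > 1) {
    .abort("branching_propensity must lie in [0, 1]")
  }
  if (population_size < 1) .abort("population_size must be at least 1")
  if (mw_max <= 0) .abort("mw_max must be positive")
  structure(list(
    t_polymer = t_polymer, t_population = t_population, t_ring = t_ring,
    branching_propensity = branching_propensity,
    size_mean = size_mean, size_sd = size_sd,
    max_iter_inner = as.integer(max_iter_inner),
    max_iter_outer = as.integer(max_iter_outer),
    max_iter_ring = if (is.null(max_iter_ring)) 10L * as.integer(population_size)
                    else as.integer(max_iter_ring),
    population_size = as.integer(population_size),
    mw_max = mw_max, feasibility_cap = as.integer(feasibility_cap)
  ), class = "lignin_hyperparameters")
}

# expected monomer mass under the target monomer distribution
.mean_monomer_mass <- function(t) {
  w <- t$monomer_pct / sum(t$monomer_pct)
  sum(w * vapply(names(w), monomer_mass, numeric(1)))
}

.resolve_size <- function(t, h) {
  size_mean <- h$size_mean
  if (is.null(size_mean)) {
    if (is.null(t$mw)) .abort("size_mean or an MW target is required")
    size_mean <- t$mw / .mean_monomer_mass(t)
  }
  size_sd <- if (is.null(h$size_sd)) 0.25 * size_mean else h$size_sd
  c(mean = size_mean, sd = size_sd)
}

# Shared sum-of-squares core; percentages enter as fractions in [0, 1] so
# all terms (including the normalized MW term) share a common scale.
.sq_terms <- function(sim_m, sim_l, tar) {
  sum((tar$monomer_pct / 100 - sim_m / 100)^2) +
    sum((tar$linkage_pct / 100 - sim_l / 100)^2)
}

#' Distance of one polymer from the targets
#'
#' Sum of squared errors over monomer percentages, linkage percentages and
#' any additional target metrics (branching coefficient), with percentages
#' on the fractional scale.  Target metrics that are absent contribute
#' nothing.
#'
#' @param m A `lignin_polymer_metrics` (or a `lignin_polymer`).
#' @param t A `lignin_targets`.
#' @return Non-negative distance.
#' @export
distance_polymer <- function(m, t) {
  if (inherits(m, "lignin_polymer")) m <- polymer_metrics(m)
  if (!inherits(m, "lignin_polymer_metrics")) .abort("need polymer metrics")
  if (!inherits(t, "lignin_targets")) .abort("need lignin_targets")
  d <- .sq_terms(m$monomer_pct, m$linkage_pct, t)
  if (!is.null(t$branching_coefficient)) {
    d <- d + (t$branching_coefficient - m$branching_coefficient)^2
  }
  d
}

#' Distance of a population from the targets
#'
#' Same squared-error form as [distance_polymer()] applied to the pooled
#' population metrics, plus `(MW_exp - MW_sim)^2 / mw_max^2` when an MW
#' target is present.
#'
#' @param pm A `lignin_population_metrics` (or a list of polymers).
#' @param t A `lignin_targets`.
#' @param h A `lignin_hyperparameters` (supplies `mw_max`).
#' @return Non-negative distance.
#' @export
distance_population <- function(pm, t, h = lignin_hyperparameters()) {
  if (!inherits(pm, "lignin_population_metrics")) pm <- population_metrics(pm)
  if (!inherits(t, "lignin_targets")) .abort("need lignin_targets")
  d <- .sq_terms(pm$monomer_pct, pm$linkage_pct, t)
  if (!is.null(t$branching_coefficient)) {
    d <- d + (t$branching_coefficient - pm$branching_coefficient)^2
  }
  if (!is.null(t$mw)) {
    d <- d + (t$mw - pm$mean_mw)^2 / h$mw_max^2
  }
  d
}

# population distance from pooled count summaries (hot path of the outer
# and ring loops; avoids rebuilding full metric objects)
.pooled_distance <- function(mono, link, mw_sum, n_poly, n_branched, n_mono, t, h) {
  d <- .sq_terms(.pct(mono), .pct(link), t)
  if (!is.null(t$branching_coefficient)) {
    d <- d + (t$branching_coefficient - n_branched / n_mono)^2
  }
  if (!is.null(t$mw)) d <- d + (t$mw - mw_sum / n_poly)^2 / h$mw_max^2
  d
}

#' Metropolis acceptance rule
#'
#' Accepts every move that does not increase the distance; an uphill move
#' of size `delta_d` is accepted with probability `exp(-delta_d / temperature)`.
#'
#' @param delta_d Change in distance caused by the move.
#' @param temperature Positive Metropolis temperature.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_d, temperature) {
  if (!is.numeric(temperature) || temperature <= 0) {
    .abort("temperature must be positive")
  }
  if (delta_d <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_d / temperature)
}

#' Sample an addition proposal from the target distributions
#'
#' The incoming monomer type is drawn proportionally to the target monomer
#' percentages, the linkage type proportionally to the target linkage
#' percentages, and the branching state is `TRUE` with probability
#' `branching_propensity`.
#'
#' @param t A `lignin_targets`.
#' @param h A `lignin_hyperparameters`.
#' @return A `lignin_proposal`.
#' @export
sample_proposal <- function(t, h = lignin_hyperparameters()) {
  if (!inherits(t, "lignin_targets")) .abort("need lignin_targets")
  if (sum(t$monomer_pct) <= 0 || sum(t$linkage_pct) <= 0) {
    .abort("target distributions must have positive mass")
  }
  mono <- sample(monomer_types(), 1L, prob = t$monomer_pct)
  link <- sample(linkage_types(), 1L, prob = t$linkage_pct)
  branch <- stats::runif(1) < h$branching_propensity
  proposal(link, m2 = mono, branching = branch)
}

#' Grow one polymer toward the targets (inner optimization loop)
#'
#' Starting from a seed monomer drawn from the target monomer distribution,
#' monomers are added one at a time.  Each proposal is sampled from the
#' target distributions; feasible proposals are executed rejection-free and
#' then accepted or rolled back by the Metropolis criterion on the change
#' in the polymer distance.  Growth stops at a per-polymer stopping size
#' drawn from `Normal(size_mean, size_sd)` or at the iteration cap.
#'
#' @param t A `lignin_targets`.
#' @param h A `lignin_hyperparameters`.
#' @param trajectory If `TRUE`, record one row per Metropolis event.
#' @return A `lignin_polymer`.  `attr(p, "growth")` holds a list with the
#'   final distance `d`, the number of Metropolis `attempts`, `iterations`,
#'   the drawn stopping size `n_stop`, a `stuck` flag (feasibility cap
#'   exhausted), and the `trajectory` data frame when requested.
#' @export
grow_polymer <- function(t, h = lignin_hyperparameters(), trajectory = FALSE) {
  if (!inherits(t, "lignin_targets")) .abort("need lignin_targets")
  sz <- .resolve_size(t, h)
  n_stop <- max(1L, as.integer(round(stats::rnorm(1, sz["mean"], sz["sd"]))))
  seed <- sample(monomer_types(), 1L, prob = t$monomer_pct)
  p <- new_polymer(seed)
  d <- distance_polymer(polymer_metrics(p), t)
  iter <- 0L; attempts <- 0L; infeas <- 0L; stuck <- FALSE
  traj <- if (trajectory) vector("list", h$max_iter_inner) else NULL
  while (polymer_size(p) < n_stop && iter < h$max_iter_inner) {
    iter <- iter + 1L
    prop <- sample_proposal(t, h)
    if (prop$branching) {
      # prune the decision tree to linkage types with a feasible branched
      # site, reweighting by the targets, so the event can always execute;
      # with no branch site available the addition falls back to a
      # terminal attachment
      feas <- vapply(linkage_types(), function(lt) {
        nrow(feasible_sites(p, proposal(lt, branching = TRUE))) > 0L
      }, logical(1))
      if (any(feas)) {
        w <- t$linkage_pct[linkage_types()[feas]]
        if (sum(w) <= 0) w[] <- 1
        lt <- if (length(w) == 1L) names(w) else sample(names(w), 1L, prob = w)
        prop <- proposal(lt, m2 = prop$m2, branching = TRUE)
      } else {
        prop <- proposal(prop$ltype, m2 = prop$m2, branching = FALSE)
      }
    }
    p2 <- tryCatch(add_monomer(p, prop, monomer_weights = t$monomer_pct),
                   ligninsim_infeasible = function(e) NULL)
    if (is.null(p2)) {
      infeas <- infeas + 1L
      if (infeas >= h$feasibility_cap) { stuck <- TRUE; break }
      next
    }
    infeas <- 0L
    attempts <- attempts + 1L
    d2 <- distance_polymer(polymer_metrics(p2), t)
    acc <- metropolis_accept(d2 - d, h$t_polymer)
    if (trajectory) {
      traj[[iter]] <- data.frame(iteration = iter, ltype = prop$ltype,
                                 mtype = prop$m2, branching = prop$branching,
                                 delta_d = d2 - d, accepted = acc,
                                 d = if (acc) d2 else d)
    }
    if (acc) { p <- p2; d <- d2 }
  }
  attr(p, "growth") <- list(
    d = d, attempts = attempts, iterations = iter, n_stop = n_stop,
    stuck = stuck,
    trajectory = if (trajectory) do.call(rbind, traj) else NULL
  )
  p
}

#' Assemble an optimized structure library (outer + ring loops)
#'
#' Polymers optimized by the inner loop are proposed one at a time and
#' accepted into the library by the Metropolis criterion on the change in
#' the population distance; a rejected polymer is discarded and a fresh one
#' grown.  Once the library is full (or the attempt cap is reached) a
#' fine-tuning loop proposes intramolecular linkages (rings) on randomly
#' chosen polymers, each again gated by the Metropolis criterion, to nudge
#' the pooled linkage distribution toward the targets.
#'
#' @param t A `lignin_targets`.
#' @param h A `lignin_hyperparameters`.
#' @param seed Optional integer seed (recorded in the library for exact
#'   reproduction).
#' @param trajectory If `TRUE`, record the outer-loop distance trajectory.
#' @return An object of class `lignin_library`: a list with `polymers`,
#'   `population` (a `lignin_population_metrics`), `targets`, `hyper`,
#'   `seed` and `summary` (final distance, acceptance ratio, total MC
#'   attempts, ring statistics).  A partial library (attempt cap hit) is
#'   returned with a warning.
#' @export
optimize_population <- function(t, h = lignin_hyperparameters(), seed = NULL,
                                trajectory = FALSE) {
  if (!inherits(t, "lignin_targets")) .abort("need lignin_targets")
  if (!is.null(seed)) set.seed(seed)
  polymers <- vector("list", h$population_size)
  n_poly <- 0L
  mono <- stats::setNames(numeric(3), monomer_types())
  link <- stats::setNames(numeric(6), linkage_types())
  mw_sum <- 0; n_mono <- 0; n_branched <- 0
  d <- NA_real_
  outer_attempts <- 0L; inner_attempts <- 0L; accepted <- 0L; streak <- 0L
  traj <- if (trajectory) list() else NULL
  while (n_poly < h$population_size && outer_attempts < h$max_iter_outer) {
    outer_attempts <- outer_attempts + 1L
    g <- grow_polymer(t, h)
    gi <- attr(g, "growth")
    inner_attempts <- inner_attempts + gi$attempts
    m <- polymer_metrics(g)
    d2 <- .pooled_distance(mono + m$monomer_counts, link + m$linkage_counts,
                           mw_sum + m$mw, n_poly + 1L,
                           n_branched + m$n_branched, n_mono + m$n_monomers,
                           t, h)
    # one polymer shifts pooled metrics by ~1/n_poly, so while the pool is
    # small the acceptance temperature tracks that scale (avoiding a greedy
    # freeze on a lucky early pool); from quarter-fill on, the nominal
    # t_population applies
    t_eff <- h$t_population * max(1, h$population_size / (4 * max(n_poly, 1L)))
    # rescue from a frozen pool: reheat geometrically with the rejection
    # streak so a lucky low-d pool cannot lock the library out forever
    t_eff <- t_eff * 2^(streak %/% 25L)
    acc <- if (is.na(d)) TRUE else metropolis_accept(d2 - d, t_eff)
    streak <- if (acc) 0L else streak + 1L
    if (trajectory) {
      traj[[length(traj) + 1L]] <- data.frame(
        event = "polymer", attempt = outer_attempts,
        delta_d = if (is.na(d)) NA_real_ else d2 - d, accepted = acc,
        d = if (acc) d2 else d)
    }
    if (acc) {
      n_poly <- n_poly + 1L
      polymers[[n_poly]] <- g
      mono <- mono + m$monomer_counts; link <- link + m$linkage_counts
      mw_sum <- mw_sum + m$mw
      n_mono <- n_mono + m$n_monomers; n_branched <- n_branched + m$n_branched
      d <- d2
      accepted <- accepted + 1L
    }
  }
  if (n_poly < h$population_size) {
    warning(sprintf("attempt cap reached: partial library of %d/%d polymers",
                    n_poly, h$population_size))
    polymers <- polymers[seq_len(max(n_poly, 1L))]
  }
  # ring fine-tuning loop
  ring_attempts <- 0L; ring_accepted <- 0L
  if (n_poly > 0L) {
    ring_w <- t$linkage_pct
    for (k in seq_len(h$max_iter_ring)) {
      i <- sample.int(n_poly, 1L)
      # ring type drawn from the target linkage distribution, like additions
      lt <- sample(linkage_types(), 1L, prob = ring_w)
      p2 <- tryCatch(add_ring(polymers[[i]], ltype = lt),
                     ligninsim_infeasible = function(e) NULL)
      if (is.null(p2)) next
      ring_attempts <- ring_attempts + 1L
      lt <- attr(p2, "last_addition")$ltype
      link2 <- link; link2[lt] <- link2[lt] + 1
      m_old <- polymers[[i]]; dm <- polymer_mw(p2) - polymer_mw(m_old)
      branched2 <- n_branched - sum(m_old$m_degree >= 3L) + sum(p2$m_degree >= 3L)
      d2 <- .pooled_distance(mono, link2, mw_sum + dm, n_poly,
                             branched2, n_mono, t, h)
      acc <- metropolis_accept(d2 - d, h$t_ring)
      if (trajectory) {
        traj[[length(traj) + 1L]] <- data.frame(
          event = "ring", attempt = k, delta_d = d2 - d, accepted = acc,
          d = if (acc) d2 else d)
      }
      if (acc) {
        polymers[[i]] <- p2
        link <- link2; mw_sum <- mw_sum + dm; n_branched <- branched2
        d <- d2; ring_accepted <- ring_accepted + 1L
      }
    }
  }
  total_attempts <- inner_attempts + outer_attempts + ring_attempts
  structure(list(
    polymers = polymers,
    population = population_metrics(polymers),
    targets = t, hyper = h, seed = seed,
    summary = list(
      final_d = d, n_polymers = n_poly,
      outer_attempts = outer_attempts, inner_attempts = inner_attempts,
      ring_attempts = ring_attempts, ring_accepted = ring_accepted,
      total_attempts = total_attempts,
      acceptance_ratio = accepted / max(1L, outer_attempts)
    ),
    trajectory = if (trajectory) do.call(rbind, traj) else NULL,
    version = as.character(utils::packageVersion("ligninsim"))
  ), class = "lignin_library")
}

#' Sweep the branching propensity and correlate linkages with branching
#'
#' Optimizes one library per (target set, branching propensity) grid point
#' and reports, per library, the pooled linkage percentages and the global
#' branching coefficient, together with the Pearson correlation of each
#' linkage percentage with the branching coefficient across libraries.
#'
#' @param targets A `lignin_targets` or a (possibly named) list of them
#'   (e.g. pine and poplar presets).
#' @param propensities Numeric vector of at least 3 branching-propensity
#'   values.
#' @param h A `lignin_hyperparameters`; its `branching_propensity` is
#'   overridden by the grid.
#' @return A data frame with one row per optimized library (columns:
#'   `target`, `branching_propensity`, the six pooled `pct_*` linkage
#'   percentages, `branching_coefficient`, `mean_mw`, `mean_size`) with the
#'   correlations in `attr(x, "correlations")` (named by linkage code;
#'   `NA` for constant columns).
#' @export
branching_sweep <- function(targets, propensities, h = lignin_hyperparameters()) {
  if (inherits(targets, "lignin_targets")) targets <- list(targets)
  if (length(propensities) < 3L) .abort("need at least 3 propensity grid points")
  if (anyDuplicated(propensities) && length(unique(propensities)) < 3L) {
    .abort("degenerate propensity grid")
  }
  nm <- names(targets)
  if (is.null(nm)) nm <- paste0("target", seq_along(targets))
  rows <- list()
  for (ti in seq_along(targets)) {
    for (bp in propensities) {
      h2 <- h; h2$branching_propensity <- bp
      lib <- optimize_population(targets[[ti]], h2)
      pop <- lib$population
      rows[[length(rows) + 1L]] <- data.frame(
        target = nm[ti], branching_propensity = bp,
        stats::setNames(as.data.frame(as.list(pop$linkage_pct)),
                        paste0("pct_", make.names(linkage_types()))),
        branching_coefficient = pop$branching_coefficient,
        mean_mw = pop$mean_mw, mean_size = pop$mean_size
      )
    }
  }
  out <- do.call(rbind, rows)
  pct_cols <- paste0("pct_", make.names(linkage_types()))
  cors <- vapply(pct_cols, function(cl) {
    x <- out[[cl]]
    if (stats::sd(x) == 0 || stats::sd(out$branching_coefficient) == 0) {
      return(NA_real_)
    }
    stats::cor(x, out$branching_coefficient)
  }, numeric(1))
  names(cors) <- linkage_types()
  attr(out, "correlations") <- cors
  out
}

#' @export
print.lignin_library <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<lignin_library> %d polymers%s\n", s$n_polymers,
              if (!is.null(x$targets$name)) paste0(" (", x$targets$name, ")") else ""))
  cat(sprintf("  final distance %.3g, acceptance ratio %.2f, %d MC attempts (%d rings accepted)\n",
              s$final_d, s$acceptance_ratio, s$total_attempts, s$ring_accepted))
  print(x$population)
  invisible(x)
}

#' @export
print.lignin_targets <- function(x, ...) {
  cat(sprintf("<lignin_targets>%s\n",
              if (!is.null(x$name)) paste0(" ", x$name) else ""))
  cat("  monomers (%):", paste(sprintf("%s %.1f", names(x$monomer_pct), x$monomer_pct),
                               collapse = ", "), "\n")
  cat("  linkages (%):", paste(sprintf("%s %.1f", linkage_label(names(x$linkage_pct)),
                                       x$linkage_pct), collapse = ", "), "\n")
  if (!is.null(x$branching_coefficient))
    cat(sprintf("  branching coefficient: %.3f\n", x$branching_coefficient))
  if (!is.null(x$mw)) cat(sprintf("  number-average MW: %.0f Da\n", x$mw))
  invisible(x)
}
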