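# Distance functions, Metropolis rule, proposal sampling and the
# hierarchical optimization loops.

test_that("the polymer distance matches hand-computed sums of squares", {
  pine <- preset_targets("pine")
  # identical metrics give zero
  gpoly <- make_chain(4)
  m <- polymer_metrics(gpoly)
  t0 <- target_metrics(monomer_pct = m$monomer_pct, linkage_pct = m$linkage_pct,
                       branching_coefficient = 0)
  expect_equal(distance_polymer(m, t0), 0)
  # pine targets against an all-b-O-4 G polymer, worked by hand on the
  # fractional scale: (0.66-1)^2 + 0.001^2 + 0.18^2 + 0.16^2
  d_hand <- (0.66 - 1)^2 + (0.001 - 0)^2 + 0.18^2 + 0.16^2
  expect_equal(distance_polymer(m, pine), d_hand, tolerance = 1e-12)
  # label symmetry: swapping two equal-valued metrics leaves d unchanged
  tswap <- target_metrics(monomer_pct = c(H = 0, G = 100, S = 0),
                          linkage_pct = c("b-5" = 66, "b-O-4" = 18,
                                          "5-5" = 0.1, "b-b" = 16),
                          branching_coefficient = 0)
  mswap <- m
  mswap$linkage_pct[c("b-5", "b-O-4")] <- m$linkage_pct[c("b-O-4", "b-5")]
  expect_equal(distance_polymer(mswap, tswap), distance_polymer(m, pine))
})

test_that("the population distance adds the normalized MW term", {
  d <- make_dimer("b-O-4")
  pop <- population_metrics(list(d))
  t_match <- target_metrics(monomer_pct = pop$monomer_pct,
                            linkage_pct = pop$linkage_pct,
                            branching_coefficient = 0)
  h <- lignin_hyperparameters()
  expect_equal(distance_population(pop, t_match, h), 0)
  # MW term alone: (1240 - 1272)^2 / 10000^2
  pop2 <- pop; pop2$mean_mw <- 1272
  t_mw <- target_metrics(monomer_pct = pop$monomer_pct,
                         linkage_pct = pop$linkage_pct,
                         branching_coefficient = 0, mw = 1240)
  expect_equal(distance_population(pop2, t_mw, h), (1240 - 1272)^2 / 1e8,
               tolerance = 1e-12)
  # widening the MW normalizer strictly shrinks the term
  h2 <- lignin_hyperparameters(mw_max = 20000)
  expect_lt(distance_population(pop2, t_mw, h2),
            distance_population(pop2, t_mw, h))
})

test_that("metropolis acceptance follows exp(-delta/T)", {
  expect_true(metropolis_accept(-0.01, 1e-6))
  expect_true(metropolis_accept(0, 1e-6)) # boundary: exp(0) = 1
  expect_error(metropolis_accept(0.1, 0), class = "ligninsim_invalid_input")
  set.seed(99)
  n <- 1e5
  acc <- sum(replicate(n, metropolis_accept(0.02, 0.01)))
  p <- exp(-2)
  expect_lt(abs(acc / n - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("proposals are drawn from the experimental distributions", {
  t <- target_metrics(monomer_pct = c(G = 60, S = 40),
                      linkage_pct = c("b-O-4" = 100))
  h <- lignin_hyperparameters(branching_propensity = 0)
  set.seed(7)
  props <- replicate(1e4, sample_proposal(t, h), simplify = FALSE)
  pg <- mean(vapply(props, function(p) p$m2 == "G", logical(1)))
  expect_lt(abs(pg - 0.6), 3 * sqrt(0.6 * 0.4 / 1e4))
  expect_true(all(vapply(props, function(p) p$ltype == "b-O-4", logical(1))))
  expect_false(any(vapply(props, `[[`, logical(1), "branching")))
  h2 <- lignin_hyperparameters(branching_propensity = 1)
  expect_true(sample_proposal(t, h2)$branching)
  t_bad <- t; t_bad$monomer_pct[] <- 0
  expect_error(sample_proposal(t_bad, h), class = "ligninsim_invalid_input")
})

test_that("single-polymer growth respects targets and stopping rules", {
  set.seed(13)
  pine <- preset_targets("pine")
  h <- preset_hyperparameters("pine")
  p <- grow_polymer(pine, h)
  expect_true(all(p$m_type == "G")) # pure guaiacyl feedstock
  expect_length(validate_polymer(p), 0)
  h1 <- preset_hyperparameters("pine", size_mean = 1, size_sd = 1e-9)
  p1 <- grow_polymer(pine, h1)
  expect_equal(polymer_size(p1), 1)
  expect_equal(length(p1$l_type), 0)
})

test_that("zero-temperature growth only ever improves the distance", {
  set.seed(17)
  t <- target_metrics(monomer_pct = c(G = 100),
                      linkage_pct = c("b-O-4" = 100))
  h <- lignin_hyperparameters(t_polymer = 1e-12, size_mean = 12, size_sd = 1e-9,
                              branching_propensity = 0)
  p <- grow_polymer(t, h, trajectory = TRUE)
  traj <- attr(p, "growth")$trajectory
  dacc <- traj$d[traj$accepted]
  expect_true(all(diff(dacc) <= 1e-12))
  expect_true(all(traj$ltype[traj$accepted] == "b-O-4"))
})

test_that("identical seeds reproduce identical libraries", {
  t <- preset_targets("poplar")
  h <- preset_hyperparameters("poplar", population_size = 15L)
  lib1 <- optimize_population(t, h, seed = 123)
  lib2 <- optimize_population(t, h, seed = 123)
  s1 <- vapply(lib1$polymers, to_smiles, character(1))
  s2 <- vapply(lib2$polymers, to_smiles, character(1))
  expect_identical(s1, s2)
  expect_identical(lib1$summary$total_attempts, lib2$summary$total_attempts)
  lib3 <- optimize_population(t, h, seed = 124)
  expect_false(identical(s1, vapply(lib3$polymers, to_smiles, character(1))))
})

test_that("population optimization converges toward the targets", {
  t <- preset_targets("pine")
  h <- preset_hyperparameters("pine", population_size = 40L)
  lib <- optimize_population(t, h, seed = 5)
  pop <- lib$population
  expect_equal(lib$summary$n_polymers, 40)
  expect_equal(unname(pop$monomer_pct["G"]), 100)
  expect_lt(abs(pop$linkage_pct["b-O-4"] - 66), 6)
  expect_gt(lib$summary$total_attempts, 0)
  expect_length(validate_polymer(lib$polymers[[1]]), 0)
})

test_that("the branching sweep reports per-library metrics and correlations", {
  set.seed(77)
  t <- preset_targets("pine")
  h <- preset_hyperparameters("pine", population_size = 12L, max_iter_ring = 60L)
  expect_error(branching_sweep(t, c(0, 0.5), h), class = "ligninsim_invalid_input")
  sw <- branching_sweep(t, c(0, 0.25, 0.5), h)
  expect_equal(nrow(sw), 3)
  cors <- attr(sw, "correlations")
  expect_named(cors, linkage_types())
  # a constant column yields a missing correlation, not an error
  expect_true(is.na(cors["a-O-4"]) || !is.nan(cors["a-O-4"]))
})
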