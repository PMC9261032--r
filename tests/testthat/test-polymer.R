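# Rejection-free polymer growth, the bonding-atom ledger and rings.

test_that("a fresh polymer exposes the seed monomer's bonding atoms", {
  g <- new_polymer("G")
  expect_equal(polymer_size(g), 1)
  expect_equal(polymer_mw(g), monomer_mass("G"), tolerance = 1e-9)
  expect_setequal(ledger(new_polymer("H"))$index, c(4, 5, 7, 8))
  expect_false(5 %in% ledger(new_polymer("S"))$index)
  expect_error(new_polymer("Z"), class = "ligninsim_invalid_input")
})

test_that("feasible sites follow the ledger, the rules and the branching filter", {
  p <- new_polymer("G")
  s <- feasible_sites(p, proposal("b-O-4"))
  expect_setequal(paste(s$c1, s$c2), c("4 8", "8 4"))
  expect_equal(nrow(feasible_sites(new_polymer("S"), proposal("5-5"))), 0)
  # branching filter: a single monomer has degree 0, so no branched site
  expect_equal(nrow(feasible_sites(p, proposal("b-O-4", branching = TRUE))), 0)
  star <- make_star()
  sb <- feasible_sites(star, proposal("5-5", branching = TRUE))
  expect_true(all(star$m_degree[sb$monomer_id] >= 2))
})

test_that("ledger feasibility equals brute-force atom-pair enumeration", {
  set.seed(11)
  for (rep in 1:30) {
    p <- new_polymer(sample(monomer_types(), 1))
    steps <- sample(0:5, 1)
    for (k in seq_len(steps)) {
      prop <- proposal(sample(linkage_types(), 1),
                       branching = stats::runif(1) < 0.2)
      p <- tryCatch(add_monomer(p, prop), ligninsim_infeasible = function(e) p)
    }
    for (lt in linkage_types()) {
      for (br in c(FALSE, TRUE)) {
        prop <- proposal(lt, branching = br)
        expect_equal(sort_sites(feasible_sites(p, prop)),
                     sort_sites(brute_force_sites(p, prop)),
                     label = paste(lt, br))
      }
    }
  }
})

test_that("additions are executed rejection-free into valid structures", {
  # H + alpha-O-4 + S at (4,7) gives the H-(4,7)-S dimer
  d <- make_dimer("a-O-4", "H", "S", c1 = 4L)
  expect_equal(polymer_size(d), 2)
  expect_length(validate_polymer(d), 0)

  # three successive b-O-4 additions give a linear tetramer, no branches
  p <- make_chain(4)
  expect_equal(polymer_size(p), 4)
  expect_equal(unname(table(p$l_type)["b-O-4"]), 3L)
  expect_true(all(p$m_degree <= 2))
  expect_length(validate_polymer(p), 0)

  # infeasible proposals leave the polymer untouched and signal cleanly
  s <- new_polymer("S")
  expect_error(add_monomer(s, proposal("5-5")), class = "ligninsim_infeasible")
})

test_that("ledger length always equals the count of free bonding atoms", {
  set.seed(5)
  p <- new_polymer("G")
  for (k in 1:40) {
    prop <- proposal(sample(linkage_types(), 1),
                     branching = stats::runif(1) < 0.15)
    p2 <- tryCatch(add_monomer(p, prop), ligninsim_infeasible = function(e) NULL)
    if (is.null(p2)) next
    p <- p2
    expect_equal(sum(p$a_bond), length(p$led_idx))
    expect_true(all(mapply(function(m, i) {
      p$a_bond[which(p$a_mono == m & p$a_idx == i)]
    }, p$led_mono, p$led_idx)))
  }
})

test_that("intramolecular linkages close rings without adding monomers", {
  # a b-b dimer retains two free phenolic 4-Os and two free 5s: 4-O-5 and
  # 5-5 rings are both available
  bb <- make_dimer("b-b")
  rs <- feasible_ring_sites(bb)
  expect_true("4-O-5" %in% rs$ltype)
  expect_true("5-5" %in% rs$ltype)
  r <- add_ring(bb, "4-O-5")
  expect_equal(polymer_size(r), 2)
  expect_equal(sort(r$l_type), c("4-O-5", "b-b"))
  expect_length(validate_polymer(r), 0)
  expect_equal(igraph::ecount(coarse_grain(r)), 2) # cycle in the big graph

  expect_error(add_ring(new_polymer("G")), class = "ligninsim_infeasible")

  # ring endpoints must both be phenolic: in a b-O-4 chain the internal
  # units have lost their 4-O, so their free 5s cannot couple
  ch <- make_chain(6)
  rs2 <- feasible_ring_sites(ch, "5-5")
  if (nrow(rs2)) {
    free4 <- unique(ch$led_mono[ch$led_idx == 4])
    expect_true(all(rs2$m1 %in% free4 & rs2$m2 %in% free4))
  }
})

test_that("per-addition work grows at most linearly (quadratic totals)", {
  grow_ops <- function(n) {
    p <- new_polymer("G")
    per <- numeric(0)
    while (polymer_size(p) < n) {
      before <- p$ops
      p <- add_monomer(p, proposal("b-O-4", m2 = "G"))
      per <- c(per, p$ops - before)
    }
    list(total = p$ops, per = per)
  }
  a <- grow_ops(50); b <- grow_ops(100); c2 <- grow_ops(200)
  # doubling the size at most ~doubles the per-addition work ...
  expect_lt(mean(tail(c2$per, 10)) / mean(tail(b$per, 10)), 2.6)
  # ... and at most ~quadruples the total work
  expect_lt(c2$total / b$total, 4.6)
  expect_lt(b$total / a$total, 4.6)
})
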