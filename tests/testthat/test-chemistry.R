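# Monomer templates and linkage rule tables.

test_that("monomer templates carry the canonical indexing and chemistry", {
  expect_error(monomer_template("X"), class = "ligninsim_invalid_input")
  h <- monomer_template("H")
  # 9 carbon skeleton positions plus phenolic and gamma oxygens, no methoxy
  expect_equal(sum(h$atoms$element == "C"), 9)
  expect_equal(sum(h$atoms$element == "O"), 2)
  expect_equal(methoxy_count("H"), 0)
  expect_equal(methoxy_count("S"), 2)
  s <- monomer_template("S")
  expect_equal(sum(s$atoms$element == "O"), 4) # 2 methoxy + phenolic + gamma
  # the 4-position is an aromatic carbon bearing the phenolic oxygen
  for (m in monomer_types()) {
    tpl <- monomer_template(m)
    expect_true(tpl$atoms$aromatic[tpl$atoms$index == 4])
    expect_true(any((tpl$bonds$i == 4 & tpl$bonds$j == 10) |
                    (tpl$bonds$i == 10 & tpl$bonds$j == 4)))
    # alpha (7) and beta (8) joined by the side-chain double bond
    w <- which((tpl$bonds$i == 7 & tpl$bonds$j == 8))
    expect_equal(tpl$bonds$order[w], 2L)
    # unique atomic indices
    expect_false(anyDuplicated(tpl$atoms$index) > 0)
  }
  # methoxy placement: position 3 for G, positions 3 and 5 for S
  g <- monomer_template("G")
  expect_true(any(g$bonds$i == 3 & g$bonds$j == 12))
  expect_true(any(s$bonds$i == 5 & s$bonds$j == 14))
})

test_that("free monolignol masses match their molecular formulas", {
  # p-coumaryl C9H10O2, coniferyl C10H12O3, sinapyl C11H14O4 with average
  # atomic masses
  expect_equal(monomer_mass("H"), 9 * 12.011 + 10 * 1.008 + 2 * 15.999,
               tolerance = 1e-6)
  expect_equal(monomer_mass("G"), 180.2, tolerance = 0.1 / 180)
  expect_equal(monomer_mass("S"), 210.2, tolerance = 0.1 / 210)
  m <- vapply(monomer_types(), monomer_mass, numeric(1))
  expect_true(all(diff(m) > 0)) # 150.2 < 180.2 < 210.2
})

test_that("linkage pair tables follow the index-pair naming convention", {
  expect_error(linkage_index_pairs("b-1"), class = "ligninsim_invalid_input")
  expect_setequal(asplit(linkage_index_pairs("a-O-4"), 1),
                  list(c(c1 = 4L, c2 = 7L), c(c1 = 7L, c2 = 4L)))
  expect_setequal(asplit(linkage_index_pairs("b-O-4"), 1),
                  list(c(c1 = 4L, c2 = 8L), c(c1 = 8L, c2 = 4L)))
  expect_equal(nrow(linkage_index_pairs("5-5")), 1L)
  expect_equal(unname(linkage_index_pairs("5-5")[1, ]), c(5L, 5L))
  # b-5 is directional: the chain end donates beta, the incoming unit C5
  expect_equal(unname(linkage_index_pairs("b-5")[1, ]), c(8L, 5L))
  for (lt in linkage_types()) expect_gt(nrow(linkage_index_pairs(lt)), 0)
})

test_that("feasible bonding indices honour methoxy blocking", {
  # oracle: union of all indices appearing in any pair set, minus blocked
  all_idx <- sort(unique(unlist(lapply(linkage_types(), linkage_index_pairs))))
  expect_equal(feasible_c1("G"), all_idx)          # {4, 5, 7, 8}
  expect_equal(feasible_c1("H"), all_idx)          # no methoxy blocking
  expect_equal(feasible_c1("S"), setdiff(all_idx, 5L)) # 5-position methoxylated
  expect_true(all(feasible_c1("G") %in% feasible_c1("H")))
  expect_error(feasible_c1("Q"), class = "ligninsim_invalid_input")
})

test_that("reverse monomer lookup for a donated C2 is complete and typed", {
  expect_setequal(monomers_for_c2(5, "5-5"), c("H", "G"))
  expect_setequal(monomers_for_c2(8, "b-O-4"), c("H", "G", "S"))
  expect_error(monomers_for_c2(3, "b-O-4"), class = "ligninsim_infeasible")
  # round-trip: every admissible pair is realisable by some monomer pair
  for (lt in linkage_types()) {
    prs <- linkage_index_pairs(lt)
    for (k in seq_len(nrow(prs))) {
      donors_c1 <- Filter(function(m) prs[k, 1] %in% feasible_c1(m), monomer_types())
      expect_gt(length(donors_c1), 0)
      expect_gt(length(monomers_for_c2(prs[k, 2], lt)), 0)
    }
  }
})

test_that("each linkage transform yields the reference dimer formula", {
  # heavy-atom formulas of the G-G dimers: the three C-C/ring couplings
  # (5-5, b-5, b-b) and the 4-O-5 ether lose one H per coupling position;
  # a-O-4 keeps the H count (the consumed 7-8 double bond absorbs them);
  # b-O-4 installs the benzylic alpha-OH (one extra O)
  expected <- c("4-O-5" = "C20H22O6", "a-O-4" = "C20H24O6",
                "b-O-4" = "C20H24O7", "5-5" = "C20H22O6",
                "b-5" = "C20H22O6", "b-b" = "C20H22O6")
  for (lt in linkage_types()) {
    d <- make_dimer(lt, "G", "G")
    expect_length(validate_polymer(d), 0)
    expect_equal(formula_string(d), unname(expected[lt]), label = lt)
  }
  # worked naming example: an H unit joined to S through (4,7) is alpha-O-4
  d <- make_dimer("a-O-4", "H", "S", c1 = 4L)
  rec <- attr(d, "last_addition")
  expect_equal(rec$ltype, "a-O-4")
  expect_equal(c(rec$c1, rec$c2), c(4L, 7L))
  expect_equal(sort(d$m_type), c("H", "S"))
})

test_that("rule lookups are cached constant-size tables", {
  r <- linkage_rules()
  expect_named(r, c("linkage_pairs", "feasible_c1", "retired_on_bond"))
  expect_length(r$linkage_pairs, 6)
  expect_length(r$feasible_c1, 3)
  expect_identical(linkage_rules(), r) # cached object, not re-parsed
})
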