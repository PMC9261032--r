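---
title: "Reconstructing lignin structure libraries from NMR-derived distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing lignin structure libraries from NMR-derived distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Lignin is a polydisperse, hyperbranched aromatic polymer. Bulk experiments —
2D-HSQC NMR, thioacidolysis, size-exclusion chromatography — measure only
*distributions*: the percentages of the three monolignols
(p-hydroxyphenyl H, guaiacyl G, syringyl S), the percentages of the six
common inter-unit linkages (4-O-5, α-O-4, β-O-4, 5-5, β-5, β-β), sometimes a
number-average molecular weight (MW̄) and a degree of branching. They do not
give molecular structures. `ligninsim` inverts this: given target
distributions, it grows an ensemble ("library") of explicit, chemically
valid polymer structures whose pooled metrics match the targets, suitable as
input for kinetic models, group-additivity energetics or 3D building.

## Multiscale graph representation

Each polymer is held at two resolutions:

* an **atomic graph** — one node per heavy atom (C or O; hydrogens are
  implicit) annotated with element, aromaticity, owning monomer, canonical
  atomic index and a bonding-availability flag; one edge per bond with its
  order and, for inter-monomer bonds, the linkage type;
* a **big graph** — the coarse-graining of the atomic graph: one node per
  monomer, one edge per linkage (`coarse_grain()`).

Atomic indexing follows the standard monolignol convention: ring carbons
1–6, side-chain α = C7, β = C8, γ = C9; the phenolic oxygen on C4 is atom
10, the γ-hydroxyl oxygen atom 11, methoxy O/C pairs 12/13 (3-position) and
14/15 (5-position). Monomer ids are 1-based in order of addition (an
equivalent 0-based convention is sometimes used elsewhere; only the offset
differs). A linkage name containing "O" bonds through the 4-O, so the pair
(4, 7) means "phenolic oxygen of unit 1 to α-carbon of unit 2", i.e. α-O-4.

A β-β coupling creates the bicyclic resinol (one C8–C8 bond plus two
α–O(γ) ring closures) and a β-5 the phenylcoumaran (C8–C5 plus the α–O(4)
ring closure); both are counted as **one** linkage edge in the big graph —
linkage percentages only sum to 100 under single counting.

## Bonding rules

The rule tables live in an editable YAML file
(`system.file("extdata", "linkage_rules.yaml", package = "ligninsim")`) and
are cached after one read, so every lookup during growth is a constant-time
table access. Three tables are kept:

* **linkage → (C1, C2) pairs** — which atomic indices each linkage may join;
* **monomer → feasible C1** — where a unit can bond at all. These sets are
  reconstructed as the union of all indices appearing in any pair set minus
  methoxy-blocked positions: H and G can use {4, 5, 7, 8}, S is blocked at 5
  by its second methoxy group;
* **retired indices** — availability withdrawn on each side once a linkage
  forms. The α/β pair always retires together: any coupling through C7 or
  C8 consumes the 7–8 side-chain double bond, so the partner position can
  never enter a later linkage. The 5-side of a β-5 also loses its 4-O (it
  is consumed by the coumaran ring).

Two rules are **directional or conditional**, and this is a deliberate
design choice rather than a transcription:

* **β-5 is directional, (8, 5) only**: the β radical sits on the chain end
  and couples to C5 of a fresh phenolic unit. With a symmetric β-5, a unit
  buried in a β-O-4 chain (whose only free index is 5) could sprout β-5
  branches; branch formation would then track the β-5 percentage instead of
  the 5-5 percentage. Observed branching in softwood/hardwood simulations
  correlates strongly with 5-5 and only weakly (negatively) with β-5, and
  the directional rule reproduces exactly that (see *Branching* below).
* **Intramolecular (ring) coupling requires two phenolic partners**: both
  endpoint units must either donate their 4-O or still carry a free one.
  Radical coupling proceeds through oxidized phenols; etherified internal
  units cannot supply the radical. Practically this sends rings to chain
  ends, where they adjust linkage percentages without inflating the
  branching coefficient.

Bond-formation transforms per linkage: ethers (4-O-5, α-O-4, β-O-4) engage
the phenolic oxygen of the 4-side; β-O-4 additionally installs the benzylic
α-hydroxyl (one extra oxygen — the classic guaiacylglycerol-β-aryl ether);
β-β and β-5 close their rings through existing oxygens. The resulting G–G
dimers have heavy-atom formulas C20(H22|H24)O6 and C20H24O7 (β-O-4),
matching the reference dimer structures; each transform is valence-audited
in the tests.

## Rejection-free growth

A polymer starts from a seed monomer drawn from the target monomer
distribution. The builder keeps a **ledger** of available bonding atoms
(monomer id, atomic index); a proposed (linkage, monomer, branching-state)
addition is resolved by intersecting the ledger with the linkage's C1 set,
filtering by the branching state (terminal units, degree ≤ 1, vs. branched
attachment points, degree ≥ 2), picking one site uniformly at random, and
resolving the incoming monomer type from the mandated C2 (sampled from the
target monomer distribution when several types are admissible — e.g. a 5-5
can only recruit H or G). Every *executed* addition therefore yields a
valid structure — no move is ever rolled back — and costs work linear in
the polymer size (the ledger scan), giving near-quadratic total
polymerization cost; the tests assert both via an operation counter rather
than wall-clock time.

An infeasible proposal (empty site list) is not an error and not a
Metropolis rejection: the caller simply resamples, up to a configurable cap
(default 50 consecutive failures) after which the polymer is returned with
a `stuck` flag.

## Objective and Metropolis acceptance

For a single polymer the distance to target is a sum of squared errors over
monomer percentages, linkage percentages and any extra scalar metrics (the
branching coefficient), with percentages on the fractional 0–1 scale. For
a population the same form applies to the pooled metrics, plus
`(MW̄_exp − MW̄_sim)² / MW_max²` when an MW target exists, with
`MW_max = 10 000 Da` placing the term on the same 0–1 scale.

Pooling is count-weighted across all linkage/monomer instances in the
library — the way an NMR integral sees a bulk sample — not an unweighted
mean of per-polymer percentages. The branching coefficient is the fraction
of monomers connected to three or more monomers (big-graph degree ≥ 3),
pooled the same way; a connected polymer has coefficient 0 exactly when its
big graph is a path.

A move that changes the distance by Δd is accepted if Δd ≤ 0 and with
probability `exp(−Δd/T)` otherwise — the standard Metropolis rule
(`metropolis_accept()`).

## The hierarchical optimization

`optimize_population()` nests three loops:

1. **Inner (polymer) loop** — `grow_polymer()` repeatedly samples
   proposals from the target distributions and Metropolis-gates each
   executed addition on the per-polymer Δd at temperature `t_polymer`
   (default 0.05). Growth stops at a per-polymer size drawn from
   `Normal(size_mean, size_sd)` (rounded, truncated at 1). When a proposal
   requests a branched attachment, the linkage is re-drawn from the target
   distribution *restricted to types with a feasible branched site* (the
   decision tree is pruned so the event can always execute); with no branch
   site available the addition falls back to a terminal attachment.
2. **Outer (population) loop** — grown polymers are offered to the library
   one at a time and Metropolis-gated on the pooled Δd. One polymer moves
   the pooled percentages by roughly the per-polymer spread divided by the
   current pool size, so the nominal `t_population` (default 5e-5) is
   rescaled by `max(1, N_pop/(4·N))` while the pool is small, and reheated
   geometrically (×2 per 25 consecutive rejections) if a lucky early pool
   freezes the chain. Rejected polymers are discarded and grown afresh.
3. **Ring loop** — after the library is assembled, up to
   `10 × population_size` intramolecular linkages are proposed on randomly
   chosen polymers, the type drawn from the target linkage distribution,
   each gated at `t_ring` (default 2e-5). A single ring shifts pooled
   percentages by one linkage instance in several hundred, hence the colder
   temperature: it pins the equilibrium uptake of off-target ring types at
   a few percent instead of letting them run away.

The three temperatures reflect the three natural Δd scales (≈ 10⁻², 10⁻⁴
and 10⁻⁵ per move); a single shared temperature either freezes the outer
loop or floods the library with rings.

## Branching

The branching propensity sets the probability that an addition targets a
branched site. Because internal chain units retain only their C5 (the 4-O
and α/β positions are consumed by chain formation) and β-5 is directional,
the only linkage that can realize a branch-state addition is **5-5**:
branch events and 5-5 events are largely the same events. Sweeping the
propensity over a grid (`branching_sweep()`) therefore yields a strong
positive Pearson correlation (≈ 0.95–1.0 in the packaged tests) between the
pooled 5-5 percentage and the global branching coefficient, a weak
correlation for β-5 and β-β, and only a minor direct effect of the
propensity dial itself — branch additions still have to pass the Metropolis
gate against a 5-5 target of ~0.1 %.

## Hyperparameters

| parameter | default | units | role |
|---|---|---|---|
| `t_polymer` | 0.05 | – | inner-loop temperature on the squared-error scale |
| `t_population` | 5e-5 (miscanthus preset 1e-4) | – | outer-loop temperature |
| `t_ring` | 2e-5 | – | ring-loop temperature |
| `branching_propensity` | pine 0.05, poplar 0.3, miscanthus 0 | – | probability of targeting a branched site |
| `size_mean`, `size_sd` | pine/poplar 5 ± 1.25; miscanthus 6.6 ± 0.8 | monomers | stopping-size distribution |
| `population_size` | 100 | polymers | library size |
| `mw_max` | 10 000 | Da | MW-term normalizer |
| `max_iter_inner/outer/ring` | 200 / 1000 / 10·pop | – | iteration caps |
| `feasibility_cap` | 50 | – | consecutive infeasible proposals before "stuck" |

`size_sd` defaults to `0.25 × size_mean`; the miscanthus preset narrows it
to 0.8 monomers because with a wide spread the outer loop can lower its
distance by stockpiling short chains, trading the MW target away for
linkage fit. When only an MW target is given, `size_mean` is derived as
`mw / (mean monomer mass under the target monomer distribution)`.

The temperatures, propensities and size parameters are this package's own
calibration, chosen once so that the three shipped presets yield libraries
consistent with reported softwood/hardwood/herbaceous benchmarks: monomer
and linkage percentages within a few points of their targets, miscanthus
MW̄ within a few percent, and a softwood/hardwood β-O-4 gap of ≈ 11–13
points.

## Feedstock presets

`preset_targets()` ships the experimental columns for pine (G 100;
β-O-4 66, 5-5 0.1, β-5 18, β-β 16), poplar (G 37/S 63; β-O-4 78, 5-5 0.1,
β-5 7, β-β 15) and miscanthus (H 4/G 46/S 50; β-O-4 68, β-5 15, β-β 17;
MW̄ 1240 Da). Two recorded ambiguities in the source tables: the small
herbaceous H fraction is reported inconsistently, so
`preset_targets("miscanthus", h_unit = "zero")` exposes the H-free variant
with G/S renormalized to 48/52; and the published MW column prints fewer
values than columns, so only the miscanthus MW (unambiguous) is used as a
target. Experimental branching-coefficient targets are taken as 0. Target
percentage groups may sum to slightly over 100 (rounded NMR integrals); a
0.5-point overshoot is tolerated and proposal sampling normalizes.

## What the generator does and does not emulate

Passing tests show that libraries match the *target distributions* under
the model's chemistry. They do not show that real lignin looks like these
structures beyond the measured observables: the model has no β-1 /
spiro-dienone or caffeyl (C-unit) chemistry, no dibenzodioxocin, no
kinetics or energetics (all feasible sites are equally likely; acceptance
is distance-driven, not Boltzmann-weighted by bond energies), no 3D
conformations, and hydrogens are implicit. Gaussian fits to per-polymer
histograms are a display summary (sample mean/SD), not a claim of
normality. Hydroxyl accounting is limited to phenolic OH (index-10 oxygens
with a single heavy neighbour) and methoxy counts, which no linkage type
consumes.

## Numerical and degenerate-input choices

* Stopping sizes: `max(1, round(rnorm))`; a size-1 "polymer" is a free
  monomer with all-zero linkage percentages (not an error).
* Site tie-breaks: uniform random with the run's seeded RNG; with
  `set.seed()` (or `optimize_population(seed = )`) libraries are
  bit-identical, SMILES included.
* Empty libraries, unknown type codes, non-positive temperatures and
  incompatible (C2, linkage) queries raise typed conditions
  (`ligninsim_invalid_input`, `ligninsim_infeasible`,
  `ligninsim_corrupt`).
* CSV exports round floats to 4 significant digits so re-exports are
  byte-identical.
* SMILES are written by a deterministic depth-first walk with ring-closure
  digit reuse; aromatic rings are emitted aromatically (lowercase), the
  5-5 biphenyl bond as an explicit single bond between aromatic atoms.

## Problem sizes used in the packaged checks

The test suite and the reproduction script use the presets at their default
population of 100 polymers per library, a 2 × 5 propensity grid at the same
library size for the branching sweep, 10⁴ random additions for the
structural-validity property, and chains up to 200 monomers for the
complexity property; together they run in a few minutes on one CPU.

## Known limitations

* β-5 percentages land 2–4 points below hardwood/herbaceous targets: the
  directional rule makes β-5 compete for free chain-end β positions with
  β-O-4 and β-β. Distance-matching reconstructions generally share this
  deficit, trading it against the dominant β-O-4 term.
* The outer loop can only select among whole polymers, so pooled metrics
  that demand "one rare linkage in every fourth polymer" (e.g. poplar β-5
  at 7 %) converge through selection noise; expect ±1–2 point run-to-run
  spread at population 100.
* Very high branching propensities (> 0.5) mostly generate infeasible
  proposals; the dial saturates rather than producing highly branched
  structures.
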