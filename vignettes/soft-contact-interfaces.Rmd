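---
title: "Quantifying soft protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying soft protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softcontact)
library(dplyr)
library(ggplot2)
```

Most protein–protein complexes bind through a sizeable desolvated patch:
hundreds of square Angstroms of buried surface, backbone atoms a few
Angstroms apart, waters squeezed out. Transient electron-transfer pairs can
work differently: the partners touch only through a few long, charged side
chains reaching across a wide gap, and the gap stays filled with ordered
water. This vignette explains how the package measures that "soft and
specific" mode of interaction and why its defaults are what they are.

## The water census

A crystallographic water is represented by its oxygen (deposited waters
carry no hydrogens). Two thresholds drive everything:

* **Interface shell, 7 Å.** A water belongs to the interface when its
  oxygen is within 7 Å of at least one atom of protein A *and* one atom of
  protein B. The two-sided rule keeps the census focused on the gap rather
  than on either protein's bulk hydration shell. A one-sided variant is
  possible by calling `select_interface_waters()` per side, but the
  two-sided form is the default because it is the one under which the four
  categories partition cleanly.
* **Interaction cutoff, 3.5 Å, strict.** A water *interacts* with a protein
  when its oxygen is strictly closer than 3.5 Å to some atom of it — the
  conventional heavy-atom hydrogen-bond distance. The boundary case of
  exactly 3.5 Å therefore counts as *not* interacting; with measured
  coordinates the choice is immaterial, but it makes the partition
  unambiguous and testable.

`classify_waters()` assigns `bridging` (both sides), `nonbridging_A` /
`nonbridging_B` (one side), `noninteracting` (neither). The four categories
are exhaustive and exclusive by construction, which the test suite asserts
as a partition property over many generated complexes, together with
monotonicity: widening the cutoff can only grow the bridging class, and
widening the shell can only grow the census.

Hydrogen-bond edges (`build_hbond_network()`) use the same heavy-atom
distance rule, with no angular term: without hydrogens an angle criterion
would be guesswork, and the scientific claim being checked — that the water
layers form a connected polar network linking the two proteins — is a
distance-graph property.

## Surface areas

`sasa()` is a from-scratch Shrake–Rupley implementation: each atom's sphere
of radius r(element) + probe is sampled at `n_points` quasi-uniform
positions from a golden-section spiral, and a point is accessible when it
lies outside every neighbour's probe-expanded sphere. The spiral is
deterministic, so a given structure and `n_points` always give the same
area, bit for bit. The default 960 points per atom keeps single-sphere
errors well under 1% (the suite checks against the closed-form sphere and
two-sphere-cap areas, and against an independent implementation on a random
cluster); doubling the density moves totals by less than 0.5%.

Radii are a documented, configurable table (C 1.70, N 1.55, O 1.52, S 1.80,
P 1.80, metals 1.40 Å); an element missing from the table is an error, never
a silent default.

The contact surface area uses the half-buried-area convention,
CSA = (SASA(A) + SASA(B) − SASA(A∪B))/2 — the average area each partner
buries. Conventions differ between programs, so `convention = "full"`
exposes the raw difference; comparisons between complexes are unaffected by
the choice as long as it is applied consistently. Waters are always
stripped before the calculation (the metric concerns direct protein
burial), while hetero cofactors such as hemes travel with their protein.

## B-factor fulcrum profiles

If a protein rocks about its anchoring contacts like a rigid body, atomic
displacement parameters should grow with distance from those anchors.
`fulcrum_profile()` pairs every atom's B with its distance to the nearest
anchor atom and summarizes the trend two ways: a **Spearman** rank
correlation — chosen because the claim is monotonicity, not linearity — and
mean B in 5 Å distance bins, whose least-squares slope estimates the
gradient in Å²/Å. Distances are rounded to 10⁻⁶ Å before ranking so that
exact geometric ties keep identical ranks under rigid motion of the whole
model (an invariance the tests assert). Profiles from fewer than 10 atoms
are flagged unreliable. Anchors default, in the pipeline, to the A-side
atoms of the polar-contact inventory — the atoms that actually hold the
interface.

Mean-B summaries (`mean_b()`) are plain arithmetic means over atoms,
occupancy-unweighted, waters excluded by selection.

## Tunneling pathways

The empirical Pathways model scores a route from a donor atom to an
acceptor atom as the product of per-step decay factors:

* covalent bond: ε = 0.6;
* hydrogen bond: ε = 0.36·exp[−1.7(R − 2.8)], R the heavy-atom distance;
* through-space jump: ε = 0.6·exp[−1.7(R − 1.4)].

These are the standard parameter values of the model's common software
implementations; all are exposed through `et_params()`. Each law is clamped
at its prefactor below its equilibrium distance so factors stay in (0, 1]
and decay monotonically. Hydrogens are not modelled as graph nodes:
hydrogen-bond edges connect the heavy atoms directly, with the 2.8 Å
equilibrium calibrated to heavy-atom separations. This keeps the search
free of any force-field dependency; it changes individual couplings
slightly but not route rankings, which is the level at which the model is
meaningful.

Covalent topology comes from distance-based bond detection (1.9 Å for
light-atom pairs, 2.1 Å for sulfur, 2.6 Å for metal coordination) plus an
explicit bond-patch table for anything unusual — heme thioether links or
metal-site ligations can be forced by name. Maximizing ∏ε is a shortest
path under weight −ln ε (`best_path()`, Dijkstra; ties broken by the
lexicographically smallest node sequence so results are deterministic), and
`k_best_paths()` enumerates alternatives with Yen's algorithm. Both are
verified against exhaustive simple-path enumeration on small random graphs.
A disconnected donor/acceptor pair yields an explicit no-path result, not
an error.

## Crystal symmetry

`symmetry_expand()` applies the space-group operators combined with lattice
translations in the −1..1 cell neighbourhood, in fractional coordinates via
the standard orthogonalization matrix; that is sufficient for contact
shells up to about one cell edge, which covers packing-contact questions.
Operators are read from `REMARK 290` records when present, otherwise from a
built-in table (P 1, P 1 2₁ 1, P 2₁2₁2₁, C 1 2 1). Image isometry and a
brute-force minimum over all images are asserted in the tests.

## The synthetic generator

`make_toy_complex()` emulates exactly the statistical structure the water
census consumes: two rigid chains (backbone N, CA, C, O plus a surface CB
per residue) separated by a controlled gap, each extending one long charged
"arm" (a lysine-like NZ against an aspartate-like OD2, tips 3 Å apart) into
the gap — the minimal geometry that supports simultaneously a specific
polar contact, bridging waters near the arms, per-side non-bridging waters,
and a non-interacting mid-gap layer. Waters are placed by rejection
sampling against exact per-category distance bands with safety margins
(e.g. bridging demands 2.3–3.4 Å to both chains) so that PDB coordinate
rounding at 10⁻³ Å cannot flip a category; an infeasible request — a
non-interacting water with a gap under 7.4 Å, or more waters than the
region holds — fails loudly rather than degrading. The default gap of 10 Å
places the mid-gap layer at ~5 Å from both chains, comfortably inside the
7 Å shell and outside the 3.5 Å interaction range, mirroring the wide
water-filled span that motivates the analysis.

B-factors are planted as base + slope·(distance to the arm anchor) +
Gaussian noise (defaults 20 Å², 1.5 Å²/Å, SD 2 Å²), giving the fulcrum
profile a known gradient to recover. Output is written through the
package's deterministic PDB writer, so one seed yields one byte-exact file.

What the generator does **not** emulate: real side-chain rotamers and
packing, anisotropic displacement, correlated water networks, partial
occupancy, disorder. Passing tests on toy complexes therefore demonstrate
the *bookkeeping* — classification, partition, network, surface and graph
algorithms — not crystallographic realism; applying the pipeline to a
deposited structure exercises the same code paths on real coordinates.

## Problem sizes and determinism

The validation suite runs entirely from generated data: fifty seeded
complexes for the census properties, hundred-graph oracle comparisons for
the path search (5–12 nodes, where exhaustive enumeration is exact and
fast), 25-fold census round-trips in the acceptance script. These sizes
were chosen so that each property is exercised across the generator's
parameter space while any single failure remains attributable. All
randomness flows through explicit integer seeds; the generator restores the
caller's RNG state.

## Known limitations

* Water-site conservation across crystal forms (matching a water in the
  complex to "the same" water in a partner's own crystal) needs
  cross-crystal site registration and is out of scope.
* Symmetry expansion is exact only for shells up to about one cell edge;
  larger shells would need a wider translation range.
* The polar-contact inventory considers N/O atoms only; weak C–H···O
  interactions are not counted.
* Tunneling couplings are empirical ranking scores, not quantum-chemical
  matrix elements; only route membership and relative ordering should be
  interpreted.
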