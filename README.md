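# softcontact

Quantitative analysis of **"soft and specific" protein–protein interfaces** —
the unusual binding mode of transient electron-transfer complexes such as
cytochrome *c* bound to cytochrome *c* oxidase, where two proteins recognize
each other through a handful of long charged side chains across a wide,
water-filled gap instead of a tight desolvated patch.

The package is for structural biologists who want to put numbers on that
picture from a crystal structure:

- **Interfacial water triage.** Waters within a 7 Å shell of *both* proteins
  are classified by the strict `< 3.5 Å` water-oxygen–to–nearest-protein-atom
  rule into *bridging* (interacting with both proteins), *non-bridging*
  (one protein) and *non-interacting* (neither) categories, with per-water
  contact counts, residue-type tallies, B-factor statistics and the
  heavy-atom hydrogen-bond network that links the two proteins through the
  water layers.
- **Interface geometry.** Exact minimum atom–atom and Cα–Cα inter-chain
  distances, a polar-contact inventory (N/O pairs ≤ 3.5 Å, labelled salt
  bridge vs hydrogen bond), Kabsch least-squares superposition, and
  closest-contact distances to crystal symmetry mates from the cell and
  space-group operators.
- **Surface burial.** Shrake–Rupley solvent-accessible surface area with a
  1.4 Å probe and a deterministic golden-spiral point set, and the contact
  surface area CSA = (SASA(A) + SASA(B) − SASA(A∪B))/2.
- **B-factor "fulcrum" profiling.** Spearman correlation and binned means of
  atomic B-factors against distance from the interface anchor residues,
  quantifying rigid-body-like rocking about the contact.
- **Empirical tunneling pathways.** The Pathways model: per-step decay
  factors ε (covalent 0.6; hydrogen bond 0.36·e^(−1.7(R−2.8)); through-space
  0.6·e^(−1.7(R−1.4))), best route by Dijkstra on −ln ε, alternatives by
  Yen's k-shortest-paths, reporting the total coupling T_DA = ∏ε, the
  running distance and the through-space jumps.
- **A seeded toy-complex generator** that emits valid PDB files of two-chain
  pseudo-proteins with ground-truth water categories and a planted
  B-gradient, so the whole pipeline is testable without downloading
  anything.

Everything is tidyverse-native: atom tables are tibbles, results are
tibbles or small S3 objects with `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(softcontact)

tc   <- make_toy_complex(seed = 42)          # two chains, 11 placed waters
spec <- complex_spec("A", "B", donor_atom = "A/4/NZ",
                     acceptor_atom = "B/4/OD2")
rep  <- run_report(tc$model, spec)

glance(rep$stages$water_census$value)
#>   n_waters n_bridging n_nonbridging_A n_nonbridging_B n_noninteracting mean_b
#> 1       11          3               3               3                2   49.4

rep$stages$et_pathway$value$best
#> <et_path> 1 steps, T_DA = 0.256, running distance = 3.0 A
#>   A/4/NZ -> B/4/OD2
#>   non-covalent jumps: hbond (3.0 A)
```

The census partitions the 11 interface waters exactly as the generator
planted them (3 bridging, 3 per-side non-bridging, 2 non-interacting); the
mean water B of 49.4 Å² sits between the rigid and mobile chains, as at a
real soft interface. The tunneling search finds the single hydrogen-bond
step between the two arm atoms, with coupling ε = 0.36·e^(−1.7·(3.0−2.8)) ≈
0.256. The same report also carries the shortest inter-chain Cα distance
(12.4 Å), the contact surface area (26.4 Å²), the fulcrum profile and the
closest symmetry-mate contact (9.9 Å).

For a deposited structure the calls are identical —
`run_report("complex.pdb", "spec.yaml")` — with the chain sets, cofactor
residue names and donor/acceptor atoms declared in a small YAML file, and
`inst/cli/softcontact` wraps `report`, `survey` (many complexes, one table)
and `synth` as shell subcommands.

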