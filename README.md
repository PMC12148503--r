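# cystinescan

Geometric and statistical analysis of disulfide bonds in protein
structures, built around one question: when two cysteines face each other
across a dimer interface, can they actually form a disulfide, and at what
torsional cost?

The package grew out of the structural biology of TGF-beta family growth
factors such as BMP-9 and BMP-10, which are secreted largely as monomers
even though their relatives dimerise covalently. Their interchain
disulfide is forced into a maximally strained syn-periplanar conformation
(chi3 = 0), and sweeping the cysteine rotamer shows no relaxed geometry is
reachable at the observed interface registration. `cystinescan` provides
that analysis as reusable functions for anyone studying disulfide
geometry, strain, or engineerability: structural biologists validating a
modeled disulfide, protein engineers testing whether a designed cysteine
pair can bond, and students of side-chain conformational analysis.

## What it computes

- **Cystine dihedral quintet** (chi1, chi2, chi3, chi2', chi1') under the
  standard definitions chi1 = N-CA-CB-SG, chi2 = CA-CB-SG-SG',
  chi3 = CB-SG-SG'-CB', from PDB/mmCIF models (bio3d-backed parsing,
  altloc resolution, disulfide detection at 2.3 A SG-SG).
- **AMBER torsion strain** per dihedral, kcal/mol:
  E(chi1) = 2.0(1 + cos 3chi1), E(chi2) = 1.0(1 + cos 3chi2),
  E(chi3) = 3.5(1 + cos 2chi3) + 0.6(1 + cos 3chi3) — maximal (8.2) at
  the syn-periplanar chi3.
- **Background dihedral histograms** over a structure collection
  (resolution filter 2.5 A, 5-degree bins) and a rarity score for any
  observed angle.
- **The chi1 accessibility scan**: virtual sulfurs placed every degree on
  the CB-S cone (1.81 A, 114.3 degrees), steric elimination by van der
  Waals overlap (> 0.4 A), minimum cross-protomer S-S distances, and a
  feasibility verdict against the maximum permissible bond distance
  (2.0 +/- 0.1 A), optionally under rigid registration shifts of one
  protomer.
- **Synthetic structures** for testing: ideal cysteines, C2 dimers with a
  closed-form engineered closest approach, clash probes covering chosen
  arcs, wrapped-normal dihedral ensembles.

## Worked example

Build a cystine whose quintet is known exactly, then measure and score
it:

```r
library(cystinescan)

m <- make_c2_dimer(dimer_spec(target_quintet = c(-120, -80, 0, -80, -120)))
pair <- detect_disulfides(find_cysteines(m))$pairs[[1]]
cystine_dihedrals(pair)
#>  chi1  chi2  chi3 chi2p chi1p
#>  -120   -80     0   -80  -120
torsion_energies(cystine_dihedrals(pair))$total
#> [1] 17.2
screw_signs(cystine_dihedrals(pair))$handedness
#> [1] NA     # chi3 = 0 is a boundary: no handedness is assigned
```

17.2 kcal/mol of torsion strain, 8.2 of it from the syn-periplanar chi3
alone — against 1.6 kcal/mol for the same cystine relaxed to chi3 = -90.
Now ask whether two facing free cysteines can bond at all:

```r
params <- sweep_params()
m <- make_c2_dimer(dimer_spec_for_min_distance(2.05, -120, params), params)
sites <- find_cysteines(m)
for (s in sites) m <- add_clash_probe(m, s, 82.5, 97.5, params)

res <- accessibility_scan(sites[[1]], sites[[2]], m, params)$result
res$best_pair
#>   theta_a theta_b distance
#> 1    -120    -120     2.05
range(res$feasible_pairs$theta_a)
#> [1] -133 -107
```

The valine-like probe eliminates every rotamer from -15 through +60 to
180 degrees; of what remains, only the narrow chi1 window around -120
degrees brings the sulfurs within bonding distance — the geometry of an
interface that can only close its disulfide under strain. A dimer built
with `cb_separation = 30` returns `any_feasible = FALSE`: out of reach at
any rotamer.

The numbered scripts under `analysis/` run this pipeline end to end
(simulate, tabulate cystines, energy profiles, survey, scan, interface
distances), writing TSV/JSON outputs under `results/`. The interface
script measures published contacts (Ser-385 OG to Glu-351 carboxylate,
Arg-353 guanidinium to the opposing Lys-383 carbonyl) when given the
PDB entry 6SF3 coordinate file, which is not redistributed here:

```sh
Rscript analysis/06_interface_distances.R path/to/6sf3.pdb
```

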