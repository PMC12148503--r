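---
title: "Cystine geometry, torsion strain and the chi1 accessibility scan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cystine geometry, torsion strain and the chi1 accessibility scan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystinescan)
```

## The problem this package addresses

TGF-beta family growth factors are covalent homodimers: two protomers
joined by a single interchain disulfide next to the conserved cystine
knot. BMP-9 and BMP-10 are outliers — a large fraction of their secreted
protein stays monomeric, with the interchain cysteine capped by a free
cysteine (cysteinylation, a +119 Da adduct on intact mass spectra).
Crystal structures of the covalent dimer show why: the interchain
disulfide is forced into a syn-periplanar chi3 of 0 degrees, the most
strained conformation a disulfide can adopt, and the dimer interface
leaves no relaxed rotamer through which the bond could form instead.

`cystinescan` re-implements the geometric and statistical analysis behind
that argument as reusable, tested code:

1. **Cystine geometry** — the dihedral quintet (chi1, chi2, chi3, chi2',
   chi1'), screw signs and chi3 handedness, measured from PDB/mmCIF
   models.
2. **Torsion strain** — classic AMBER cosine terms for each dihedral.
3. **Background distributions** — survey histograms of cystine dihedrals
   over a structure collection, with resolution filtering, and a rarity
   score for an observed angle.
4. **The chi1 accessibility scan** — virtual sulfurs swept around each
   opposing free cysteine, steric elimination, minimum cross-protomer
   S-S distances, and a feasibility verdict, optionally under rigid
   registration shifts of one protomer.
5. **A synthetic-structure generator** so every stage is testable with
   geometry known in closed form, without downloads.

## Conventions

Torsions follow the IUPAC sign convention and live in `(-180, 180]`;
`-180` maps to `+180`. The quintet is canonical: the unprimed site is the
one sorting first on (chain, residue number), and chi3 (CB-SG-SG'-CB') is
identical whichever side is unprimed. A chi3 of exactly 0 is a genuine
boundary: `screw_signs()` records the conventional "+" sign but assigns
*no* handedness (`NA`) rather than letting the syn-periplanar case
silently become "right-handed".

Hydrogens are ignored throughout — the crystallographic models in scope
do not include them — and the clash criterion compensates with heavy-atom
van der Waals radii. Alternate locations are resolved before analysis;
the default policy keeps the highest-occupancy conformer (ties broken by
altloc label order), which matters because the structures motivating this
package model the interchain cysteine as a bonded/free conformer mixture.
Multi-model files contribute their first model only.

## Torsion strain terms

The package evaluates the original AMBER torsion terms, in kcal/mol:

$$E_{\chi_1} = 2.0\,(1 + \cos 3\chi_1), \qquad
  E_{\chi_2} = 1.0\,(1 + \cos 3\chi_2),$$
$$E_{\chi_3} = 3.5\,(1 + \cos 2\chi_3) + 0.6\,(1 + \cos 3\chi_3).$$

All three are non-negative, even, and 360-periodic, with analytic maxima
4.0, 2.0 and 8.2. The chi3 term's unique global maximum at 0 degrees is
the quantitative statement that syn-periplanar is the worst possible
disulfide conformation; its minima (0.6 at the grid, 0.5 off-grid near
±83 degrees) flank the relaxed ±90-degree wells. No other force-field
terms are computed: the analysis isolates torsion strain, not total
energy.

```{r energies}
e_chi3(c(0, 90, 180))
attr(energy_profile("chi3", step = 1), "argmax")
```

## The accessibility scan

For a free cysteine, every chi1 rotamer places the sulfur on a circle:
at distance 1.81 Angstrom from CB (the CB-S bond length), making a
114.3-degree CA-CB-S angle. `place_sulfur()` realises this by
internal-coordinate placement — equivalent to the radial/height
construction with height $1.81\cos(\pi - 114.3^\circ)$ along the CA-CB
axis and radius $1.81\sin(\pi - 114.3^\circ) \approx 1.65$ Angstrom —
and `sweep_positions()` walks the full circle in 1-degree increments
(the grid is anchored at `-180 + step`, so the canonical m/p/t wells at
-60/+60/180 are grid points).

A rotamer is eliminated when its virtual sulfur overlaps a non-exempt
heavy atom by more than 0.4 Angstrom, with radii S 1.80, C 1.70, N 1.55,
O 1.52 (others 1.70). Exempt are the sulfur's own residue and the
backbone N/C/O of its immediate sequence neighbours (the 1-2/1-3/1-4
relationships a bonded sulfur would have). The published analysis judged
clashes by eye in a graphics program; an explicit overlap criterion is
used here instead, so arc endpoints can shift by a few degrees under
defensible alternative thresholds — every constant is a `sweep_params()`
field for exactly that reason.

`min_cross_distances()` reports, for each rotamer of one site, the
minimum S-S distance over all rotamers of the opposing site. By default
minima are taken over the full grid and clash filtering happens at the
feasibility stage (whether the published minimum-distance curves excluded
clashing angles first is not stated; `use_clash_mask = TRUE` exposes the
other reading). `feasibility()` then accepts a rotamer pair when both
angles are clash-free and the distance does not exceed the maximum
permissible bond length, 2.0 + 0.1 Angstrom. Only the upper bound is
applied by default — the criterion is phrased as *exceeding the maximum
permissible distance*, and a sub-1.9-Angstrom approach already registers
physically as a clash — but `lower_bound = TRUE` enables the symmetric
[1.9, 2.1] band.

`registration_shift_scan()` repeats the verdict under rigid transforms of
one protomer and reports whether any feasible pair achieves an unstrained
chi3 (within 30 degrees of ±90 by default, computed from the placed
sulfurs and fixed CB positions) — the rigid-shift reading of the
heterodimer hypothesis, in which a half-register displacement of the
interface opens relaxed disulfide geometry.

Disulfide *detection* (distinct from feasibility) pairs modeled SG atoms
greedily by ascending distance under a 2.3-Angstrom cutoff — the ideal
bond plus refinement slack, chosen because the source structures assign
bonds from density rather than a printed threshold — and flags leftover
sites free.

## Survey histograms

`collect_cystines()` turns a list of parsed models into per-cystine
records under the survey filters: entries excluded by id, models kept
only when their stated resolution is 2.5 Angstrom or better (a model
without a stated resolution cannot satisfy the filter and is dropped),
cysteines used only when the sulfur has exactly one partner within the
detection threshold and both sides carry complete N/CA/CB/SG. The
thousands-strong background sizes published for such surveys are
database-snapshot dependent, so the package takes an explicit file list
and treats those counts as historical context, not targets.

Histograms use half-open 5-degree bins over [-180, 180] with +180 closing
the last bin; `freq` is per-bin probability summing to 1 (density is
`freq / bin_width`; per-bin probability is the default reading of the
published normalised axes). chi1 and chi2 histograms pool both sides of
each cystine by default. Records count 1 regardless of conformer
occupancy — the altloc policy has already reduced each residue to one
conformer upstream, and this is deliberate, since partial-occupancy mixed
states are exactly what the motivating structures contain.

`empirical_percentile()` scores an observed angle by the fraction of
background mass in bins no more populated than its own: near 0 for an
extreme outlier such as a syn-periplanar chi3 against the ±90-bimodal
disulfide background, 1 at the mode.

## The synthetic generator

`make_ideal_cysteine()` builds N, CA, CB (plus C and O) at fixed ideal
internal coordinates (N-CA 1.458, CA-CB 1.530, N-CA-CB 110.5; the exact
values only set absolute coordinates). `make_c2_dimer()` arranges two
such stubs about a two-fold axis with a closed-form guarantee: each
sulfur cone is tilted 45 degrees against the inter-protomer direction,
which makes the x-coordinate of the circle strictly extremal at one
rotamer, so the closest S-S approach over all rotamer pairs is attained
at exactly one pair `(approach_angle, approach_angle)` with distance
`cb_separation - c2_margin()`. `dimer_spec_for_min_distance(2.05)`
inverts that relation; the engineered minimum, its location and its
uniqueness are verified against exhaustive 360x360 oracles in the tests.
With `target_quintet`, the partner cysteine is instead chain-built by
internal coordinates so the cystine realises any requested quintet
exactly (the CB-CB separation is then implied, and a conflicting request
is an error naming the obstruction).

`add_clash_probe()` places one carbon pseudoatom in the circle plane so
the clash criterion marks a requested chi1 arc; the radial distance is
solved from the overlap equation, with the boundary nudged 1e-9 Angstrom
inside so edge angles clash strictly. The contract is accuracy to one
grid step; note that an arc edge near the probe's antipode (half-widths
approaching 180 degrees) has a vanishing distance margin, so masks meant
to survive the 0.001-Angstrom quantisation of a PDB round trip should
keep edges away from 180 degrees (the analysis drivers use a 97.5-degree
half-width valine-like probe).

`sample_dihedral_ensemble()` draws wrapped-normal mixtures per angle
(wrapped normal rather than von Mises so component-recovery formulas stay
elementary), seeded and reproducible, emitted in the survey-record
layout with resolution 1.5 Angstrom so filters under test pass them. The
default chi3 mixture (equal weights at +95 and -87, sd 8) emulates the
bimodal disulfide background; chi1 mixes the m/t/p wells 0.5/0.3/0.2.

What the generator does **not** emulate: real side-chain environments
(probes are single atoms), backbone flexibility, coordinate error,
crystal contacts, or partial occupancy. Passing tests therefore
demonstrate that the machinery is correct on geometry known exactly —
not that any particular biological structure is strained; for that the
user supplies the deposited coordinates and runs the same functions.

## Problem sizes and runtime choices

Tests and the acceptance script use 1-degree grids (360 positions per
site, 360x360 pair matrices), 10,000-draw placement round-trips and
10,000-sample ensembles; each oracle comparison is exhaustive at that
size. These sizes keep the whole suite to about a minute while leaving
every comparison exact rather than sampled.

## Known limitations

- Only chi1 is swept; chi2 of an existing partner sulfur is honoured but
  not searched, and there is no continuous optimisation between grid
  points (a 0.1-degree grid changes reported minima by under 0.06
  Angstrom, the circle-arc Lipschitz bound).
- No energy weighting of rotamers and no terms beyond the three torsion
  potentials.
- The published free-cysteine elimination arc (-15 through 180 degrees)
  and the bonded chi1 of -120.3 degrees on the deposited coordinates are
  documented expectations, runnable when the user supplies those files;
  they are not bundled because the coordinates are not redistributable
  inside the package.
- `measure_distance()` reports to 0.01 Angstrom by design, matching the
  precision at which interface contacts are quoted.
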