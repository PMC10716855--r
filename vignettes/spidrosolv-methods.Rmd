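---
title: "Methods: secondary structure, hydrogen bonding and solvation analysis of spidroins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secondary structure, hydrogen bonding and solvation analysis of spidroins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidrosolv)
```

## The scientific problem

Engineered spider-silk proteins built from ADF3 dragline consensus repeats
alternate glycine-rich, intrinsically disordered stretches with short
alanine-rich stretches that tend to form α-helices. Ethanol in the solvent
shifts this balance toward ordered structure and drives aggregation.
Quantifying the shift from atomistic simulation requires a chain of
analyses — per-residue secondary-structure assignment, hydrogen-bond
classification, per-residue solvation densities, solvent cluster statistics —
and, on the experimental side, post-processing of circular-dichroism (CD)
spectra of a CBM–silk–CBM fusion construct so that the disordered midblock
can be compared with the simulated chain. `spidrosolv` implements this
analysis chain; synthetic generators stand in for MD output so that every
stage is testable at desk scale.

All coordinates are nanometres internally (PDB Ångström converted on
read/write), residues are indexed from 1, boxes are orthorhombic, and all
cutoff analyses use the component-wise minimum-image convention.

## The AQ3 model sequence

The simulated chain, AQ3, is three tandem copies of an engineered ADF3
consensus repeat: an alanine-rich "A" module (`GPYGPGASAAAAAAGGYGPGSGQQ`)
followed by a glutamine/glycine-rich "Q" module (`(GPGQQ)×4`), 132 residues
in all. The repeat period of 44 residues places the alanine-rich,
helix-forming stretches at residue indices 7–14, 51–58 and 95–102, and the
chain mass (11.63 kDa) gives ~25.6 g/L for a single chain in the 9.1 nm
pure-water box — both consistent with the published description of the
system. The shipped constant `AQ3_SEQUENCE` is a reconstruction from that
repeat architecture, not a deposited sequence; every function that needs a
sequence takes it as an argument.

```{r}
protein_mass_concentration(AQ3_SEQUENCE, sim_box(9.1))
```

## Secondary-structure assignment

`assign_secondary_structure()` implements the classic dictionary-of-protein-
secondary-structure scheme. A backbone hydrogen bond between the amide of
residue *i* and the carbonyl of residue *j* is scored with the
electrostatic energy

$$E = k\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} - \frac{1}{r_{OH}} -
\frac{1}{r_{CN}}\right), \qquad k = 27.888\ \text{kcal·Å/mol},$$

and exists when $E < -0.5$ kcal/mol. Two conventions matter for agreement
with reference implementations and are easy to get wrong: the
backward-adjacent bond NH(i+1)→CO(i) is never evaluated, and each residue
retains only its two lowest-energy partners on either side of the bond. The
amide hydrogen is taken from the structure when present and otherwise placed
0.101 nm from N, anti to the preceding carbonyl; prolines never donate.
Helices (H/G/I) come from consecutive n-turns (n = 4/3/5), strands and
bridges (E/B) from parallel/antiparallel bridge patterns assembled into
ladders (bulge-linked ladders merge), turns (T) from residues spanned by
n-turns, and bends (S) from a Cα virtual angle above 70°. The final code per
residue follows the priority H > G > I > E > B > T > S, remainder C; the
π-helix is mapped with the helices in both grouping schemes, a containment
choice since π-helix content is never reported for these systems. Residues
missing backbone atoms are forced to C (with a warning mid-chain).

The test suite compares the assignment with an independent reference
implementation (mdtraj's DSSP, derived from DSSP 2.2.0) on a 20-structure
synthetic library of helices, extended chains, random coils and antiparallel
sheet dimers; agreement is 99–100% of residues. The one known divergence
zone is bifurcated β-ladders (two ladders sharing a strand at in-between
hydrogen-bond register), where ladder bookkeeping details can swap B and E
at ladder ends; the fixtures and the agreement threshold absorb this.

Two grouping schemes mirror the conventions used when summarising such
simulations: `four_group` (helical = H,G,I; turn-related = T,E,B; coil;
bend) and `three_group` (ordered = H,G,I,E,B; turns = T; other = S,C).
Isolated β-bridges travel with the sheets in the three-group scheme,
mirroring the published grouping of sheets with ordered structure; the
mapping is configurable (`grouping_scheme("custom", ...)`). Errors on
fractions are population standard deviations over frames — the convention
behind "errors were calculated as standard deviations" style reporting —
and per-frame group fractions always sum to exactly 1.
`fraction_distribution()` presents per-frame fractions as a Gaussian KDE
with Scott's-rule bandwidth ($h = \sigma n^{-1/5}$), evaluated on a grid
clipped to [0, 1] with no boundary correction; a constant ensemble falls
back to a fixed 0.003 bandwidth. Clipping means a distribution piled up
against 0 or 1 integrates below 1 on the grid; for ensembles a few
bandwidths from the boundary the integral is 1 within 0.01.

## Hydrogen-bond analysis

`detect_hbonds()` uses the geometric criterion of the common MD analysis
tool family: donor–acceptor distance ≤ 0.35 nm and H–D–A (donor-centred)
angle ≤ 30°, both configurable, since the criteria are conventions rather
than published numbers. Donors are N/O atoms with a covalently attached
hydrogen; attachment is resolved geometrically (a hydrogen belongs to the
nearest in-residue N/O within 0.12 nm), which makes carbon-bound hydrogens
non-donors without any per-residue template table — ethanol's hydroxyl
donates, its CH hydrogens never do. Every N/O is a potential acceptor;
same-residue pairs are excluded; i,i±1 backbone pairs are allowed (they are
geometrically possible and counted); a donor hydrogen may satisfy several
acceptors (no exclusivity), matching count-based reporting. Bonds are
classified by the species of the donor and acceptor molecules into
intramolecular protein, protein–solvent and solvent–solvent classes, which
partition the records by construction. Per-amino-acid-type means credit a
protein–protein bond to both residues. Detection equals a brute-force
O(N²) oracle on random mixtures in the test suite, and tightening either
criterion can only shrink the bond set.

## Solvation analysis

Shell membership follows the any-atom rule: a solvent molecule (or another
protein residue) is in residue *i*'s shell when any of its atoms is within
0.25 nm (default) of any atom of residue *i*. For protein–protein shells,
residues i−1, i, i+1 are excluded so bonded neighbours do not register as
"contacts"; that exclusion is a documented choice, since the convention for
counting neighbouring amino acids is not fixed by the published figures.

The per-residue local density is
$\rho(i) = \langle N_i \rangle / \langle V_i \rangle$ over
post-equilibration frames. The normalising volume $V_i$ is estimated by
Monte-Carlo sampling of the union of spheres (radius = cutoff) centred on
the residue's atoms, minus the region claimed by other residues' shells —
an explicit, testable estimator adopted because the published normalisation
lives in supporting material that is not part of the package's inputs. The
estimator is validated against closed forms (isolated sphere, disjoint
spheres, the two-sphere lens). Two consequences of the any-atom counting
rule are worth knowing: for extended solvent molecules the capture region
is larger than the shell volume, so absolute densities are convention-
dependent; and exact parameter recovery holds for point particles, which is
how the calibration tests are built (uniform point solvent recovered within
5% at 100 frames). A 5-residue centred moving average (configurable)
smooths the profile along the chain, truncated at the termini.

Bulk densities are N/V from the composition table, e.g.

```{r}
bulk_density(1301, sim_box(8.8))   # water in the 94% (v/v) ethanol system
bulk_density(1408, sim_box(8.8))   # ethanol in the 20% system
```

`region_rdf()` computes g(r) between disjoint selections (atom–atom or
centre-of-mass) with left-closed bins, normalised per frame by the
ideal-gas shell expectation $n_A n_B \, 4\pi r^2 \mathrm{d}r / V$; it
converges to 1 for uniform placements and its histogram total equals the
pair count. r_max must stay below half the smallest box edge.

## Solvent clustering

Two molecules of the same species cluster when any atoms are within 0.25 nm
(hydrogens included by default — "any atom" means any; a heavy-atom-only
toggle supports sensitivity checks). Clusters are connected components of
that contact graph, computed by union-find over a periodic cell-list
neighbour search; the tests require exact equality with a brute-force BFS
on 200 random periodic configurations, including clusters straddling the
box boundary. Size distributions are reported cluster-weighted (default)
and molecule-weighted, pooled over frames (per-frame averaging available),
with unit bins up to size 10 and logarithmic bins above, because the
distribution spans singletons to near-system-size clusters. The
with/without-protein comparison puts both distributions on a shared binning
and reports the change in small-cluster counts (size < 10) and in the
largest cluster, the two effects a protein's adsorbed solvent layer
produces. Clusters are strictly single-species, and no angular criterion is
applied — the criterion is distance-only by design.

## CD post-processing

`to_molar_ellipticity()` applies $[\theta] = m \, M / (10 \, c \, l)$ with
m in millidegrees, M the construct's average molecular weight (g/mol) — the
whole-protein mass, not the mean-residue weight — c in g/L and l in cm; the
conversion is linear and exactly invertible. High-tension voltages above
1000 V flag unreliable wavelengths. External spectral-decomposition fraction
tables enter as TSV and are grouped as ordered (helix + sheet), turns, and
other (coil + bend), conserving the total.

For the three-block fusion construct, the disordered midblock's fractions
are recovered by length-weighted subtraction:
$f_t = (f_{\text{total}} - \sum_{b \ne t} w_b f_b)/w_t$ with
$w_b = L_b / \sum L$. Subtracting noisy fraction estimates routinely
produces small negatives; components above −0.05 are clipped to zero and
the table renormalised, anything below that is an infeasibility error. The
block lengths and terminal-block fractions are inputs, not constants — the
published construct's exact block lengths are not part of the package's
inputs, so the regeneration of experimental tables depends on what the user
supplies.

## Synthetic systems: what they emulate and what they do not

The generators provide deterministic (seeded) fixtures:

* `build_chain()` builds backbone (N, H, CA, C, O) + Cβ geometry from
  standard internal coordinates at fixed (φ, ψ) — ideal helix (−57°, −47°),
  extended (180°, 180°) — or draws dihedrals uniformly with clash rejection
  (heavy atoms of residues ≥ 2 apart closer than 0.22 nm trigger a redraw,
  with backtracking on dead ends and a 10⁴-draw cap). The random coil is a
  geometric fixture, not a Boltzmann ensemble.
* `build_sheet_dimer()` pairs a β-strand with its point reflection at an
  offset inside a broad region of well-formed antiparallel register; the
  mirror strand is a geometric fixture (D-chirality is irrelevant to
  hydrogen-bond-pattern assignment).
* `solvate_box()` packs rigid 3-site water and 9-site all-atom ethanol (and
  Na⁺/Cl⁻) at the studied compositions by random insertion with a 0.22 nm
  any-atom rejection distance — just below the 0.25 nm analysis cutoff, so
  packed boxes exercise both contact and non-contact regimes. Larger
  molecules insert first; achieved counts are exact or the call errors. A
  3-site water suffices because the analyses only need positions and
  elements; the simulation water model's virtual site is an MD-engine
  concern. Packed boxes are random, not equilibrated liquid structure.
* `perturb_trajectory()` adds i.i.d. Gaussian jitter per frame — a
  stationary ensemble with no dynamics, sufficient for distribution and
  equilibration-diagnostic machinery.
* `synthetic_cd_table()` mixes per-block fraction tables by length weighting
  with optional truncated Gaussian noise, the exact inverse of the
  subtraction stage.

Passing tests on these fixtures validates the analysis machinery —
geometry, bookkeeping, normalisation, determinism — not the physics of
solvated spidroins: the published ensemble values (fraction tables,
hydrogen-bond counts, solvation profiles from μs trajectories) are
explicitly out of reach at desk scale and are not asserted anywhere.

## Equilibration diagnostics and the pipeline

`equilibration_report()` computes the three published diagnostics: heavy-
atom RMSD to the first frame (superposed, by default), intramolecular vs
protein–solvent hydrogen-bond counts, and mean cluster size per solvent
species. Series are smoothed with a centred moving average (truncated
windows at the ends), and the trajectory is flagged equilibrated from the
first time every smoothed series stays within one standard deviation of its
tail mean. Two numerical details make this robust on short series: the
tolerance is floored by the detrended noise scale (otherwise an
accidentally constant tail gives a zero tolerance), and the first sample —
truncated window, RMSD pinned to zero by the reference — inherits its
neighbour's status. The default equilibration cut in `pipeline_config()` is
300 ns, the published value, and the 0.25 nm cutoffs likewise; everything
else defaults to the documented design choices above. `run_pipeline()`
writes per-stage TSVs, a log, and a JSON manifest with every parameter and
seed; reruns from the same configuration are byte-identical. The package's
interface is its functions and this document; the analysis entry points are
ordinary R calls rather than shell subcommands.

## Problem sizes and numerical choices

The test and acceptance computations use desk-scale sizes chosen to keep
statistical errors comfortably inside the asserted tolerances: 20-structure
DSSP libraries (~250 residues), 200 random cluster configurations (up to
500 molecules), 100 random hydrogen-bond configurations (up to ~300
molecules), 100-frame × 1000-molecule density and RDF calibrations, and
Monte-Carlo shell volumes at 5–50 thousand samples (standard errors
reported alongside). Ties in the RMSD superposition (degenerate covariance)
resolve toward the identity rotation; RDF bins are left-closed; KDE support
is clipped without renormalisation. Known limitations: triclinic boxes,
velocities, Boltzmann-weighted conformer ensembles, bond-graph
reconstruction beyond what donor typing needs, STRIDE-style alternative
assignments, and mixed-species clusters are all out of scope.
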