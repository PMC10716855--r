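# spidrosolv

Analysis machinery for molecular-dynamics studies of engineered spider-silk
proteins (spidroins) in water–ethanol mixtures.

Spidroins such as the engineered ADF3-derived AQ repeat proteins alternate
glycine-rich, intrinsically disordered stretches with alanine-rich,
helix-forming ones. Ethanol added to the solvent drives these proteins toward
more ordered structure and aggregation; resolving *how* requires a stack of
trajectory analyses — per-residue secondary structure, hydrogen-bond
bookkeeping, solvation-shell densities, solvent microheterogeneity — plus the
post-processing that links simulation to circular-dichroism (CD)
experiments. `spidrosolv` implements that stack as a reusable, tested R
package, together with synthetic-system generators so every stage can be
exercised at desk scale without running MD.

## What it computes

* **Data model and I/O** — a lightweight topology/frame/trajectory container
  with PDB and GRO reading and writing, multi-model-PDB trajectories,
  orthorhombic periodic boxes, configurable residue-name → species mapping,
  minimum-image geometry, mass-weighted radius of gyration
  (`radius_of_gyration`), and Kabsch-superposed RMSD (`rmsd_to_reference`).
* **Secondary structure** (`assign_secondary_structure`,
  `assign_trajectory`) — a DSSP-style assignment from Kabsch–Sander backbone
  hydrogen-bond energies,
  `E = k (1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` with `k = 27.888` kcal·Å/mol
  and bond cutoff −0.5 kcal/mol, yielding the eight codes H/G/I/E/B/T/S/C;
  grouped fraction statistics over frames (`group_fractions`), kernel-density
  summaries (`fraction_distribution`), amino-acid-type decompositions
  (`per_aatype_contributions`) and solvent-to-solvent difference tables
  (`delta_table`).
* **Hydrogen bonds** (`detect_hbonds`) — geometric detection with
  donor–acceptor distance ≤ 0.35 nm and H–D–A angle ≤ 30°, classified as
  intramolecular protein, protein–solvent, or solvent–solvent; per-residue
  and per-type means and equilibration time series.
* **Solvation** — any-atom solvation-shell membership at a 0.25 nm cutoff
  (`shell_members`), Monte-Carlo shell volumes (`shell_volume`), per-residue
  local density profiles along the chain (`local_density_profile`), bulk
  number densities (`bulk_density`), region–region radial distribution
  functions (`region_rdf`), and the protein mass concentration of a chain in
  a box (`protein_mass_concentration`).
* **Solvent clustering** (`build_clusters`) — single-species clusters as
  connected components under a 0.25 nm any-atom contact criterion with
  periodic boundaries, size distributions in cluster- and molecule-weighted
  form, and with/without-protein comparisons.
* **CD post-processing** — millidegree → molar ellipticity conversion
  `[θ] = m·M/(10·c·l)` (`to_molar_ellipticity`), high-tension reliability
  masks, grouping of external fraction tables into ordered/turns/other, and
  subtraction of terminal-block contributions from whole-construct fraction
  tables (`subtract_block_contribution`).
* **Orchestration** — `run_pipeline()` executes the stages over a trajectory
  and writes TSV tables plus a reproducibility manifest;
  `equilibration_report()` computes the RMSD / hydrogen-bond / cluster-size
  diagnostics used to pick an equilibration cut.
* **Synthetic systems** — ideal-helix, extended and clash-rejecting
  random-coil peptide builders (`build_chain`), an antiparallel sheet fixture
  (`build_sheet_dimer`), water/ethanol box packing at the studied
  compositions (`table1_compositions`, `solvate_box`), jittered
  pseudo-trajectories (`perturb_trajectory`) and synthetic CD fraction
  tables (`synthetic_cd_table`).

## Worked example

```r
library(spidrosolv)

# bulk water density in the 94% (v/v) ethanol system: N/V from the
# simulated compositions
bulk_density(1301, sim_box(8.8))
#> [1] 1.909103

# one AQ3 chain in the 9.1 nm pure-water box
protein_mass_concentration(AQ3_SEQUENCE, sim_box(9.1))
#> [1] 25.63635
#> attr(,"molecular_mass")
#> [1] 11634.06

# build an ideal 12-alanine helix and assign secondary structure
ch <- build_chain(strrep("A", 12), "ideal_helix")
assign_secondary_structure(ch$frame, ch$topology)
#>  [1] "C" "H" "H" "H" "H" "H" "H" "H" "H" "H" "H" "C"

# grouped fractions over a jittered 30-frame ensemble
traj <- perturb_trajectory(ch, 30, generator_config(seed = 1,
                                                    jitter_sigma = 0.005))
group_fractions(assign_trajectory(traj), grouping_scheme("four_group"))
#>          group      mean std
#> 1      helical 0.8333333   0
#> 2 turn_related 0.0000000   0
#> 3         bend 0.0000000   0
#> 4         coil 0.1666667   0

# the helix's own backbone hydrogen bonds
classify_and_count(detect_hbonds(ch$frame, ch$topology))
#>   INTRA_PROTEIN PROTEIN_SOLVENT SOLVENT_SOLVENT
#>               8               0               0
```

The first two numbers match the published bulk water density (~1.89 nm⁻³)
and protein concentration (~26 g/L); the helix fixture shows the i→i+4
hydrogen-bond pattern (8 bonds in a 12-mer) that drives the `H` assignment
of all interior residues.

## Scope

The package analyses trajectories; it does not run MD, derive force fields,
or re-implement BeStSel's spectral decomposition (whose fraction tables it
consumes as TSV). Reproducing the published μs-trajectory ensemble values
(fraction tables, hydrogen-bond counts, solvation profiles) is out of scope
at desk scale; the synthetic generators validate the *machinery*, not the
physics of the solvated protein. See the methods vignette
(`vignettes/spidrosolv-methods.Rmd`) for the model, parameter and design
discussion.
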