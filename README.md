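# denatens

Analysis of protein conformational ensembles from molecular-dynamics-style
trajectories, aimed at the *denatured state*: the disordered population in
equilibrium with the native fold that high-temperature MD is commonly used
to sample. The package is for structural bioinformaticians who have
multi-frame structures (multi-model PDB or GRO sequences) and want the
standard residual-structure observables of a heat-denaturation study:

* **Salt bridges** — a positively charged residue (Lys Cε, Arg Cδ) and a
  negatively charged residue (Glu Cδ, Asp Cγ, or the C-terminal
  carboxylate carbon) are bridged in a frame when their criterion carbons
  are < 0.6 nm apart. Reported as per-pair occupancy (% of window frames;
  per-residue sums may exceed 100%), and as binned count trajectories
  (mean number of partners per 0.4 ns bin).
* **Accessible surface area and hydrophobic energy** — Shrake–Rupley ASA
  on a deterministic 960-point lattice, partitioned into hydrophobic
  (C, S) and hydrophilic (N, O) totals, windowed into ensemble mean ± SD,
  and fed into the transfer-energy model

  ΔG_HP (kJ/mol) = 15.4·ΔASA_non-polar − 2.6·ΔASA_polar,

  with ΔASA (nm²) the denatured-minus-native difference of ensemble
  means.
* **Secondary structure** — Kabsch–Sander backbone H-bond energies
  (E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol, bond below
  −0.5) drive a DSSP-style assignment (H/E/B/T/C); the "structure"
  aggregate is H + E + B + T, and per-residue helicity is the windowed
  H-fraction.
* **Geometry** — Kabsch-superposition Cα RMSD series and mass-weighted
  radius-of-gyration series.
* **Synthetic ensembles** — seeded generators with known ground truth
  (per-pair contact occupancy via two-state Markov chains, per-residue
  helicity via toggled ideal-dihedral segments, exact Rg profiles), so
  every analysis stage is testable by parameter recovery without MD.

## Worked example

Hydrophobic energies of three CutA1 variants from their published
ensemble-average ASA table (300 K native window vs 450 K denatured
window), differenced against the Ec0SH template:

```r
library(denatens)
tab <- cuta1_asa_table()
native <- tab[tab$temperature_k == 300, c("label", "class", "mean_nm2")]
den450 <- tab[tab$temperature_k == 450, c("label", "class", "mean_nm2")]
res <- hpenergy_from_tables(native, den450, baselines = "Ec0SH")
res$energies
#>     label delta_nonpolar_nm2 delta_polar_nm2 dg_hp_kj_mol
#> 1 Ec0VV_6              12.54            7.76      172.940
#> 2   Ec0VV              12.91            8.14      177.650
#> 3   Ec0SH              11.69            7.90      159.486
res$differences
#>   variant baseline ddg_hp_kj_mol
#> 1 Ec0VV_6    Ec0SH        13.454
#> 2   Ec0VV    Ec0SH        18.164
#> 3   Ec0SH    Ec0SH         0.000
```

The 18.2 kJ/mol Ec0VV−Ec0SH difference is the extra hydrophobic
stabilization the Val/Val substitutions buy, estimated entirely from how
much more hydrophobic surface the template exposes on unfolding.

Salt-bridge occupancy recovery on a synthetic ensemble:

```r
spec <- ensemble_spec(
  sequence = c("LYS", "ALA", "GLU", "ALA", "ARG", "ALA", "ASP", "ALA"),
  pair_targets = data.frame(donor = c(1, 5), acceptor = c(3, 7),
                            occupancy = c(0.8, 0.4)),
  n_frames = 1000, seed = 42)
g <- generate_contact_trajectory(spec)
g$truth$pairs
#>   donor acceptor target realized
#> 1     1        3    0.8    0.812
#> 2     5        7    0.4    0.495
occupancy(g$trajectory, targets = c(1, 5))
#> Salt-bridge occupancy (window 0-399.6 ns, 1000 frames)
#>  residue partner occupancy_pct
#>        1       3          81.2
#>        1       7           0.0
#>        1       8           0.0
#>        5       3           0.0
#>        5       7          49.5
#>        5       8           0.0
#> per-residue sums:
#>  residue sum_pct
#>        1    81.2
#>        5    49.5
```

The measured occupancies (81.2%, 49.5%) equal the generator's *realized*
contact fractions exactly — the distance bands make the 0.6 nm classifier
unambiguous — while the realized fractions scatter around the targets
with the correlated-frame standard error of the dwell-5 Markov chain
(residue 8 rows are the C-terminal carboxylate site, never occupied
here). `count_series(g$trajectory, 1)` gives a mean salt-bridge count of
0.812 for residue 1, which is its occupancy sum divided by 100.

`run_pipeline(analysis_config(...))` chains all of the above per input,
averages subunits sharing a variant label, and returns tidy report
tables; `inst/scripts/denatens.R` wraps `synth`/`run`/`hpenergy` for
shell use.

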