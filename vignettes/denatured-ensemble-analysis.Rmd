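---
title: "Characterizing denatured-state ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing denatured-state ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denatens)
```

## The problem

The denatured state of a protein is in equilibrium with its native state,
but at physiological conditions it is a vanishingly small fraction of the
population, so its structural features are hard to observe directly.
High-temperature molecular-dynamics ensembles are a common surrogate: a
monomer is simulated for microseconds at 400-450 K, the early part of the
run is discarded as unfolding transient, and the remaining frames are
treated as a sample of the heat-denatured ensemble. The scientific
questions this package serves are about *residual structure* in that
ensemble: do engineered charged residues keep forming salt bridges after
unfolding (and thereby lower the denatured state's conformational entropy,
much as a disulfide bond does), how much hydrophobic surface becomes
exposed (and hence how much hydrophobic stabilization a mutation buys),
and what secondary structure persists?

The concrete system motivating the defaults is the CutA1 protein from
*Escherichia coli* and three engineered variants of its 112-residue
monomer: an SH-free template (Ec0SH), a hydrophobic mutant (Ec0VV) and an
ionic mutant carrying six substituted charged residues (Ec0VV_6). The
package does not run MD; it analyzes trajectories, and it ships a seeded
synthetic-trajectory generator so every analysis stage can be tested
against known ground truth at desk scale.

## Observables and their definitions

### Salt bridges

A salt bridge is operationalized purely geometrically: a positively
charged residue (Lys or Arg) and a negatively charged residue (Glu or
Asp) form a salt bridge in a frame when the distance between their
side-chain criterion carbons is **less than 0.6 nm** (strict inequality;
a distance of exactly 0.6 nm does not count, which keeps tie handling
deterministic). The criterion atoms are

| residue | atom |
|---------|------|
| Lys | CE |
| Arg | CD (CZ available by option) |
| Glu | CD |
| Asp | CG |

The phrase "Cε or Cδ of a positively charged residue (Lys or Arg)" is
read distributively - Lys uses its Cε, Arg its Cδ. The C-terminal
carboxylate participates as an additional negative site (the terminal
residue's backbone carbonyl carbon); the free N-terminus can be enabled
as a positive site but is off by default. Histidine is not treated as
charged. Pairs at sequence separation 1 are allowed; only self-pairs are
excluded.

*Occupancy* of a pair is the percentage of sampled window frames
satisfying the criterion. Per-residue occupancy sums over all partners
and can exceed 100%, meaning the residue holds more than one bridge on
average. A reporting prefilter (default off; the `gmx saltbr -t`
convention) omits pairs whose minimum distance over the whole run never
comes below a threshold - it only hides rows, never changes retained
values. The *count series* bins the trajectory (default 0.4 ns) and
reports, per bin, the mean number of distinct partners within the
cutoff; its overall mean equals the per-pair occupancy sum divided by
100 when both are computed on the same frames, a consistency the tests
assert exactly. Averaging across subunits is an elementwise arithmetic
mean with absent pairs counted as zero, which for equal-length runs is
identical to pooling all frames.

### Accessible surface area and hydrophobic energy

Per-atom solvent-accessible surface area uses the Shrake-Rupley
construction: each heavy atom's van der Waals sphere is expanded by the
probe radius (0.14 nm, water) and sampled with a deterministic
golden-spiral lattice of 960 points; the accessible fraction is the
fraction of points not inside any other expanded sphere. Radii are Bondi
values (C 0.170, N 0.155, O 0.152, S 0.180 nm) and are configurable -
the exact radii table used by any particular MD toolchain is rarely
stated, which is a known source of small systematic offsets when
comparing absolute ASA values across programs. Hydrogens are excluded
from surface and occlusion by default (united-atom view). Class totals
partition heavy atoms by element: hydrophobic = C and S, hydrophilic =
N and O.

Numerical behaviour of the lattice: an isolated sphere is exact by
construction; refining 960 to 3840 points moves dimer values by under
1%; translation invariance is exact, while rotation invariance is only
approximate (the lattice is fixed in space) with class totals moving by
a few tenths of a percent on small structures - well inside the 1%
convergence contract, and irrelevant to window averages, which sample
many orientations.

Ensemble statistics are means and population SDs of the class totals
over a time window; the study design uses 50-400 ns at 300 K as the
native window and 400-1400 ns at 400/450 K as the denatured window. The
hydrophobic stabilization estimate is the linear transfer-energy model

$$\Delta G_\mathrm{HP}\ (\mathrm{kJ/mol}) =
  15.4\,\Delta ASA_\mathrm{non\text{-}polar} -
  2.6\,\Delta ASA_\mathrm{polar},$$

with both differences (denatured minus native ensemble mean) in nm² and
coefficients in kJ mol⁻¹ nm⁻². For the shipped CutA1 table this
reproduces the published energies to the printed precision, e.g.

```{r}
tab <- cuta1_asa_table()
native <- tab[tab$temperature_k == 300, c("label", "class", "mean_nm2")]
den400 <- tab[tab$temperature_k == 400, c("label", "class", "mean_nm2")]
hpenergy_from_tables(native, den400, baselines = "Ec0SH")
```

### Secondary structure

Backbone hydrogen bonds use the Kabsch-Sander electrostatic model,
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol with distances in Å, a bond being assigned below -0.5
kcal/mol. Amide hydrogens absent from the input are placed geometrically
(1.00 Å from N along the bisector of the C(i-1)-N and CA-N directions),
as DSSP does; proline cannot donate. The assignment is a minimal
DSSP-style rule set: two consecutive i→i+4 turns make an α-helix (H);
Kabsch-Sander bridge patterns in ladders of length ≥ 2 make β-sheet
(E), isolated bridges β-bridge (B); residues inside 3/4/5-turns that are
nothing else are turn (T); everything else is C. 3₁₀- and π-helices are
deliberately folded into T/C rather than H because the accounting being
emulated reports α-helix only. The "structure" aggregate is defined as
H + E + B + T. Helicity of a residue over a window is its H-fraction;
deriving it from the same assignment as the category counts (rather than
from a separate helix-axis fit) is a deliberate internal-consistency
choice.

### Geometry

RMSD uses Kabsch superposition (SVD with the proper-rotation correction
so chirality is never inverted; degenerate point sets are rejected) over
Cα atoms by default, against the first frame unless another reference is
given - the reference structure used by any particular published RMSD
trace is often unstated, so it is configurable. Radius of gyration is
mass-weighted by default with standard atomic masses. No
periodic-boundary unwrapping is attempted: inputs are assumed to be
whole molecules, which is the MD engine's post-processing concern.

## The synthetic generator

`ensemble_spec()` plus the three generators give trajectories whose
ground truth is known by construction:

* `generate_contact_trajectory()` places residues far apart on a planar
  grid (3 nm spacing) and toggles each targeted pair with a two-state
  Markov chain whose stationary bonded probability is the target
  occupancy. Bonded frames draw the criterion distance uniformly in
  [0.35, 0.55] nm, unbonded in [0.8, 2.5] nm, so the 0.6 nm classifier
  is unambiguous away from the boundary. Transition rates are
  $(1-p)/\tau$ and $p/\tau$ with $\tau = 2.5$ sampled steps - dwell
  times of about five frames at $p = 0.5$ - so occupancy, not kinetics,
  is the controlled quantity. A consequence worth stating plainly: the
  lag-1 autocorrelation is 0.6 for every $p$, so the realized fraction
  of $n$ frames concentrates around the target with a standard error
  about **twice** the iid binomial $\sqrt{p(1-p)/n}$. Tests of the
  estimator therefore check two separable things: the measured occupancy
  equals the realized contact fraction *exactly* (the classifier cannot
  miss, by the band construction), and the realized fraction approaches
  the target at the correlation-adjusted rate.
* `generate_rg_trajectory()` rescales isotropic Gaussian clouds so the
  exact per-frame Rg follows a linear profile plus optional seeded
  noise.
* `generate_helicity_trajectory()` toggles helix segments on/off with
  the same Markov scheme and builds each frame's conformation from
  per-residue backbone dihedrals (helix φ = -57°, ψ = -47°; extended
  φ = -139°, ψ = 135°), cached per segment-state combination. Interior
  residues of a segment are assigned H exactly when the segment is on;
  the 1-2 residues at segment termini show DSSP end effects, which is
  an assignment property, not a generator defect.

What the generator does *not* emulate - excluded volume, solvent, real
kinetics, cooperative unfolding, accidental long-range contacts - means
that passing parameter recovery demonstrates correctness of the
*analysis operators*, not realism of any force field. Conclusions about
real proteins still require real trajectories.

All generators run under a locally seeded RNG (Mersenne-Twister via
`set.seed`) and restore the caller's RNG state, so runs are bitwise
reproducible and side-effect free.

## Problem sizes and defaults

Synthetic test ensembles use 12-40 residue chains and 100-2000 frames at
0.4 ns spacing - the reporting granularity of the emulated study - which
keeps the full test suite under a minute while leaving binomial standard
errors small enough for meaningful recovery checks (at 2000 frames,
3·SE ≈ 2-3 percentage points). SASA fixtures are single atoms, dimers
and short chains, where closed forms (isolated sphere, spherical-cap
overlap) and a 10⁵-point Monte-Carlo oracle are available. Default
windows mirror the study design (native 50-400 ns, denatured
400-1400 ns, helicity 1200-1400 ns); windows wider than a run are
clipped with a warning rather than erroring, since synthetic runs are
much shorter than the microsecond originals - a window that collapses
entirely yields NULL summaries while per-frame series are still
reported.

## Degenerate inputs and tie-breaks

* Exactly-at-cutoff distances do not count as bridges (strict `<`).
* Superposition refuses < 3 atoms or collinear/coincident sets, where
  the rotation is not unique.
* Windowed mean/SD requires ≥ 2 frames; SDs are population SDs (the
  frames *are* the ensemble being summarized, not a sample from it).
* Occupancy reports use 1-based residue numbers throughout, matching
  conventional residue numbering (internally R's native 1-based indexing
  is used as well).
* XTC input is not read; trajectories arrive as multi-model PDB or
  concatenated GRO frames (times are taken from GRO `t=` title fields,
  in ps, when present).

## Known limitations

Absolute ASA values depend on the radii table and lattice resolution, so
cross-program comparisons should difference within one toolchain, as the
energy model does. The secondary-structure rules are a minimal subset of
DSSP (no bends, no π/3₁₀ helix classes of their own, no chirality
angles); category counts on real structures can differ slightly from
full DSSP at helix termini and irregular strands. The salt-bridge
definition is a distance criterion on specific carbons, not a
hydrogen-bond or charge-center definition; occupancies quoted by tools
that use charge-group centroids can differ by a few percent for the
same trajectory.
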