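---
title: "Models and methods behind amykin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind amykin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amykin)
```

amykin quantifies how a sub-stoichiometric chaperone inhibits amyloid
formation, using islet amyloid polypeptide (IAPP, amylin) and the
heterohexameric co-chaperone prefoldin as the model system. Four
experimental readouts are covered: thioflavin-T (ThT) aggregation time
courses, NMR titrations of the monomeric peptide, paramagnetic relaxation
enhancement (PRE) on the chaperone, and biolayer interferometry (BLI).
Because raw instrument data are not bundled, a synthetic-data module
generates every input with the structure such experiments exhibit, so the
whole analysis chain is exercised by parameter-recovery round-trips.

## ThT kinetic-parameter extraction

A ThT curve reports fibril mass versus time as fluorescence intensity (FI).
`extract_parameters()` implements a fixed processing order:

1. **Smoothing** — centred unweighted moving average over 11 points
   (`smooth_ma()`). At the boundaries the window shrinks symmetrically,
   never asymmetrically, so the output length equals the input length and a
   constant or linear stretch is left unchanged.
2. **Derivatives** — symmetric difference quotients (`sym_derivative()`)
   with a depth window of 4 points. We read "4 points" as the full index
   span of the stencil, i.e. half-width $h = 2$:
   $d_i = (y_{i+2} - y_{i-2}) / (t_{i+2} - t_{i-2})$. The reading is
   genuinely ambiguous (an offset of 4 is also defensible), so the depth is
   a plain argument (`deriv_depth`) and either convention is reproducible.
   Near the edges the largest available symmetric half-width (minimum 1) is
   used, with a one-sided difference at the two endpoints. The second
   derivative applies the same operator to the smoothed first derivative —
   smoothing always precedes differentiation.
3. **Segmentation** — growth start is the *first* index where the first
   derivative reaches 5% of its maximum; growth end is the first index
   *after* the derivative maximum where it falls back to that threshold
   (taking the first crossing makes the start robust to pre-growth noise
   spikes, and placing the end search after the maximum makes it robust to
   mid-growth dips). The lag time is the time at growth start. A flat or
   decreasing curve has no defined growth: parameters are reported as
   undefined with a reason, never as zeros.

Six parameters follow: lag time; growth duration (end minus start); maximal
growth rate (max of the first derivative); average growth rate (FI
difference across the growth phase over its duration); initial growth rate
(mean of the first 20 derivative values *of the recording* — in seeded
elongation assays the linear regime starts at $t = 0$, which is why the
window is anchored there rather than at growth start); plateau height (mean
of the 50 points after growth end, or all remaining points with a warning
flag when fewer are available); and the acceleration maximum (max of the
second derivative).

Replicates of one condition are aligned by shifting each curve along the
time axis by (mean lag − own lag) with linear re-interpolation onto the
common grid, holding shifted-out edges at the boundary value
(`align_replicates()`). Shifts sum to zero, so the condition mean lag is
preserved. If any replicate has no defined lag the whole set is left
unaligned with a warning.

Dose series use `build_dose_series()`: a geometric progression of
inhibitor:monomer ratios with exact endpoints, by default ten ratios from
1:5000 to 1:1 plus an inhibitor-free control. `compare_normalization()`
re-extracts every parameter from per-curve max-normalised data and reports
the Spearman rank correlation of the condition-mean trends, the standard
control that conclusions do not hinge on normalisation.

## The aggregation simulator

The generator solves the standard nucleation–elongation moment equations
for fibril number $P$ and fibril mass $M$ ($m = m_{tot} - M$ free monomer):

$$\frac{dP}{dt} = k_n m^{n_c} + \theta_{surf}\, k_2\, m^{n_2} M, \qquad
  \frac{dM}{dt} = 2 k_+ \theta_{end}\, m P$$

The factor 2 counts the two growing ends per fibril (the convention of the
moment-equation literature). The inhibitor acts through fast (equilibrium)
Langmuir binding to fibril ends and surfaces, leaving free fractions
$\theta_{end} = 1/(1 + c_{inh}/K_{end})$ and
$\theta_{surf} = 1/(1 + c_{inh}/K_{surf})$ — the simplest mechanism
consistent with sub-stoichiometric inhibition of elongation and secondary
nucleation. The reported (dye-visible) mass is additionally scaled by a
monotone plateau factor $1/(1 + c_{inh}/K_{plat})$, an empirical stand-in
for the reduced end-point fluorescence at high inhibitor; no mechanism is
asserted. Integration uses `deSolve::lsoda` at rtol $10^{-8}$ / atol
$10^{-10}$ µM, and the monomer is carried as its own state so that the
reported $m + M = m_{tot}$ conservation reflects true integration accuracy
(worst case below $10^{-6} m_{tot}$ across the tested parameter grid).

Defaults describe a 5 µM de novo assay sampled every 6 min for 50 h:
$k_n = 10^{-8}$ µM$^{-1}$h$^{-1}$ ($n_c = 2$), $k_+ = 30$
µM$^{-1}$h$^{-1}$, $k_2 = 3\times10^{-4}$ µM$^{-2}$h$^{-1}$ ($n_2 = 2$),
giving a lag of roughly 5 h and a growth phase of several hours, with
$K_{end} = 0.1$ µM, $K_{surf} = 0.05$ µM and $K_{plat} = 1$ µM so that
inhibition is visible well below equimolar ratios. Plate noise is additive
Gaussian (SD 2 FI on a ~500 FI plateau) and replicate lag jitter is a
horizontal shift (SD 0.3 h, about 6% of the lag). Seeded modes add
preformed fibrils at 8.5% monomer equivalent: sonicated seeds are short
(mean 50 monomers, many ends — elongation-dominated), non-sonicated seeds
long (mean 1000 — surface for secondary nucleation). Each well draws its
noise from a substream derived deterministically from the single design
seed, so generation is bit-reproducible and independent of well order.

What the generator does *not* emulate: baseline drift and photobleaching,
dye-binding saturation, evaporation, well-to-well gain variation, fibril
fragmentation and higher-order secondary processes, and inhibitor depletion
by binding. Passing round-trips therefore demonstrate correctness of the
extraction and fitting machinery under the stated model, not robustness to
every artefact of real plates.

## Fast-exchange titration and K_D fitting

Binding of the peptide (total $L_0$) to the chaperone complex treated as a
single 1:1 binding unit (total $P_0$) follows the exact quadratic isotherm;
`bound_fraction()` returns $p_b = [PL]/L_0$. In fast exchange every residue
resonates at the population-weighted average position, so the chemical
shift perturbation (CSP)

$$\Delta\delta = \sqrt{0.14\,\Delta N^2 + \Delta H^2}$$

grows as $\Delta\delta_{bound}\, p_b$. `compute_csp()` flags residues with
above-average CSP, averaging over residues quantifiable in both peak lists
(prolines and overlap-flagged peaks simply never enter a peak list).
`fit_kd_titration()` fits one global $K_D$ with per-residue bound-state
amplitudes profiled out analytically, reducing the problem to a 1-D search
over $\log K_D$; the error is the SD of $K_D$ over residue-resampling
bootstrap replicates (default 1000, seeded). Residues whose maximal CSP
stays below a noise floor (default 0.02 ppm) are excluded — the analysis
analogue of selecting well-responding, overlap-free reporter residues. A
series in which the bound fraction never exceeds 20% triggers an
identifiability warning.

The synthetic titration uses the experimental design (29 µM peptide,
chaperone ratios 0–8) with a ground-truth $K_D$ of 61 µM, bound-state shift
changes of 0.25 ppm (composite) in the two binding segments plus residue 6
— the set {6, 10–13, 17–19, 24, 26–28} — and 0.02 ppm elsewhere, so that
the above-average rule recovers exactly that set. Realistic peak-position
noise is taken as 0.005 ppm in ¹H (typical peak-picking precision at 850
MHz), scaled by $1/\sqrt{0.14}$ in ¹⁵N. Because a noisy recovery is a
stochastic quantity, the recovery tests assert the median error over
replicate simulations: within 2% noise-free and 15% at realistic noise.

## Two-site exchange lineshape and k_off

The off-rate is estimated from a reduced 1-D two-site exchange model
(`lineshape_two_site()`): the absorptive spectrum of a spin exchanging
between free and bound environments, from the 2×2 frequency-domain
McConnell matrix with rates $k_{b\to f} = k_{off}$ and
$k_{f\to b} = k_{off}\, p_b/p_f$, site frequencies from the ppm shifts, and
widths $R_{2,free}$/$R_{2,bound}$. The model collapses to a single
population-averaged line in the fast limit and splits into two lines with
area ratio $p_f : p_b$ in the slow limit; the integrated intensity is
independent of $k_{off}$. `fit_koff_lineshape()` performs a joint
least-squares fit of one shared $k_{off}$ across residues and titration
points — a deliberate 1-D reduction of full 2-D global lineshape fitting,
kept separate from the CSP-based $K_D$ estimator (no merged likelihood).
The round-trip at the experimentally relevant magnitude
($k_{off} = 6000$ s$^{-1}$, fast exchange) recovers the rate within 20%.

## PRE interface mapping and docking restraints

Interface residues on the chaperone are those losing more than 50% of
signal intensity in the paramagnetic sample relative to the diamagnetic
reference ($1 - I_{para}/I_{dia} > 0.5$, `classify_pre()`), with the α, β
and β′ subunits kept as separate chains. The synthetic PRE ground truth
enforces the recoverability invariant (active loss > 0.5 > inactive loss)
so the noiseless round-trip is exact. On the peptide side,
`select_ligand_actives()` takes residues above-average in CSP for *most*
titration ratios, formalised as a strict majority (configurable). Both
rules are monotone in their thresholds: raising a threshold never adds a
residue. `export_restraints()` writes either a plain per-chain list (which
round-trips through `read_restraints()`) or ambiguous-interaction-restraint
stanzas (one per active residue, allowing contact with any partner-chain
active) in a TBL-like plain-text dialect. The docking computation itself is
out of scope; the module ends at the restraint files.

## Peptide construct accounting

`average_mass()` sums standard average residue masses plus one water, with
−0.985 Da for C-terminal amidation, −2.016 Da per disulfide, and, per
N-terminal adduct, the adduct's average mass minus one water per amide bond
formed (β-alanine, biotinyl, acetyl, DOTA are registered). Computed masses
for the synthesized constructs agree with the vendor-printed values to
about 0.1 Da — residual differences at that scale trace to the mass table
used, not the bookkeeping. The DOTA construct is deliberately not asserted
against its printed mass: the computed value depends on which acetate arm
forms the amide linkage, a detail the synthesis description leaves open.
`net_charge()` defaults to the side-chain-only convention at neutral pH
(Arg/Lys +1, Asp/Glu −1, His 0, termini 0 when modified), the convention
under which the peptide carries +2; the full-termini convention is
available but non-default.

## Numerical choices and problem sizes

All times are hours, shifts ppm, concentrations µM; converters live at the
IO boundary only. File writers are deterministic (stable column order, 6
significant digits), provenance indices are 0-based while residue numbering
is 1-based. Every stochastic step takes an explicit integer seed. The test
suite runs the simulators at moderate sizes — 50 h plates at 6–30 min
sampling, 8-point titrations over 37 residues, 1000-curve segmentation
property sweeps, 5×5 rate-constant conservation grids — sizes chosen so the
full suite and the demonstration pipeline (`run_pipeline()`, which finishes
in well under a minute) stay quick on a laptop while still exercising every
code path at realistic signal-to-noise.

## Known limitations

Mechanistic rate constants are never fitted to ThT data (the kinetic
analysis is descriptive, by design); the lineshape model is 1-D and assumes
populations known from the isotherm; the BLI fit covers the steady state
only, not association/dissociation kinetics; and the aggregation model's
inhibitor action is a minimal equilibrium-occupancy picture — adequate as a
test-bed for the extraction pipeline, not a mechanistic claim about the
chaperone.
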