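---
title: "Models and methods behind crbpflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crbpflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crbpflex)
```

crbpflex implements the downstream numerics of an inhibitor-discovery
campaign against cellular retinol-binding protein 1 (CRBP1): screening,
affinity determination, and three independent flexibility readouts
(crystallographic B-factors and ensembles, H/D exchange, trajectory
statistics) that together ask whether ligand binding rigidifies the
portal region of the β-barrel. This vignette explains each model, its
assumptions, the conventions in force, and what the synthetic-data
generators do and do not emulate.

## Screening score

Holo CRBP1 excited at 285 nm shows FRET between the protein tryptophans
(350 nm) and the bound retinoid (480 nm); displacement raises the 350 nm
emission and lowers the 480 nm emission. A compound well is scored by
how closely its background-subtracted changes duplicate the
positive-control signature. With ratios
$r_{350} = (\mathrm{CMP}_{350}-\mathrm{NC}_{350})/(\mathrm{PC}_{350}-\mathrm{NC}_{350})$
and $r_{480}$ defined analogously (signed, so the 480 nm *decrease*
yields a positive ratio), the default score is

$$\mathrm{score} = 2 - |1 - r_{350}| - |1 - r_{480}|.$$

Properties that motivated this form: it is maximal (2.0) exactly for a
control-duplicate; it penalises "no change" and "stronger than the
control" symmetrically; it depends only on the two ratios, hence is
invariant under a common rescaling of all plate signals; and the hit
band score ≥ 1.5 corresponds to a combined relative deviation of at
most 0.5 from the control signature. The published campaign used an
equation of this general character whose exact printed form is not
machine-readable in our sources, so `binding_score()` accepts a
replacement `score_fn(r350, r480)` should a different functional form be
preferred; every downstream step (exclusion, threshold, ordering) is
unchanged under substitution. Background subtraction uses the per-plate
mean of the negative-control wells, because plate-level drift is
otherwise unidentifiable. Wells flagged for UV/vis absorbance or
autofluorescence are excluded with a recorded reason regardless of
score; the threshold boundary is inclusive (a score of exactly 1.5 is a
hit); hit ordering is by descending score with ties broken by well id.

## Inhibition constants

Titrations are fitted with the one-site saturation model plus a
nonspecific component,

$$F(c) = F_0 + \Delta F\,\frac{c}{K_i + c} + m\,c,$$

by Levenberg–Marquardt nonlinear least squares (minpack.lm). The fitted
half-saturation constant is reported directly as $K_i$, which is how
such assays report it; no competition correction is applied. Numerical
choices:

* **Scaling.** The fit runs in dimensionless units (concentration
  divided by the grid maximum, emission divided by its mean); molar
  concentrations of order $10^{-6}$ otherwise make the Jacobian
  numerically singular.
* **Starts.** Deterministic and data-driven: $F_0$ from the minimum
  emission, $m$ from the terminal-segment slope, $\Delta F$ from the
  slope-corrected range, $K_i$ from the half-range crossing.
* **Bounds.** $K_i \in (0, 10\,c_\max]$ (a constant beyond ten times
  the measured range is not identified), $\Delta F \ge 0$ for a
  displacement titration, and $m \ge 0$ because nonspecific binding can
  only add signal. The relative tolerance on the residual sum of
  squares is $10^{-10}$; the solver's objective is non-increasing
  across iterations, which a test asserts on the returned trace.
* **Uncertainty.** `se_ki` comes from the variance–covariance estimate
  at the optimum with an analytic Jacobian. Replicates are fitted
  independently and summarised as arithmetic mean ± sample (n−1) SD;
  pooled fitting of all replicate points is available by simply passing
  the full series to `fit_titration()`.
* **Degenerate input.** A series whose emission range is below 0.1% of
  its mean carries no displacement information; the fit returns
  `converged = FALSE` with a reason rather than a spurious constant.

### The forward model behind the assay, and a deliberate choice

`competitive_equilibrium()` solves the exact two-ligand competition
(P + L ⇌ PL, P + I ⇌ PI) by reducing both isotherms to a single
monotone equation in free protein, solved with `uniroot` to a relative
tolerance of $10^{-14}$; mass balance holds to better than $10^{-10}$
and the solution is cross-checked in the tests against an independent
nested-bisection oracle.

The titration *generator*, however, defaults to placing the emission
half-saturation exactly at the nominal $K_i$ (`signal_model =
"apparent"`). The reason is physical: at the assay's probe conditions
(1 µM protein saturated with 1 µM retinol whose dissociation constant
is ~10 nM), a strict equilibrium-displacement signal would put the
curve midpoint near $K_i\,(1 + [L]_\mathrm{free}/K_d)$ — an order of
magnitude above $K_i$ — and a 0–1 µM titration of a ~67 nM binder
against 1 µM protein is stoichiometric, not hyperbolic. Real
displacement titrations of this kind nevertheless saturate near the
reported $K_i$, because the measured signal is dominated by inhibitor
occupancy rather than by full equilibrium displacement of a tight
probe. Since $K_i$ *is defined* as the half-saturation constant of the
measured curve, the generator's truth lives on the same scale. The
mechanistic mode (`signal_model = "equilibrium"`) remains available,
and a test documents its midpoint inflation.

### Generator calibration

Multiplicative Gaussian noise with a 2% coefficient of variation
represents plate-reader repeatability. The saturable amplitude defaults
to $\Delta F = 250$ on a baseline of $F_0 = 100$ — a 2.5-fold recovery
of the quenched tryptophan emission, typical for retinoid displacement —
and the nonspecific slope contributes 10% of $\Delta F$ at the top of
the grid. This calibration was chosen so that the replicate-to-replicate
SD of fitted $K_i$ values reproduces the order of the dispersion such
assays actually report (tens of percent of the mean). A consequence
worth stating plainly: for a true constant near or above the top of the
0–10 µM window, the per-replicate estimate is weakly identified (the
information bound puts its relative SE above 100%), so three-replicate
means scatter broadly around the truth; the Monte-Carlo bias stays
under 20%, which the tests assert, but any single seeded triple can
land tens of percent off. That is a property of the assay design, not
of the optimizer, and the package reports it honestly rather than
tightening the synthetic noise below the stated conditions.

## Crystallographic flexibility

Per-residue equivalent isotropic B-factors use the main-chain atoms N,
CA, C, O (unweighted mean; residues missing all four are excluded with
a warning). Where ANISOU records are present,
$B_{eq} = 8\pi^2\,(U_{11}+U_{22}+U_{33})/3$; a consistency test checks
that an isotropic tensor reproduces the recorded B. Each structure is
z-score normalized — mean 0, unit sample SD across residues — making
structures refined with different overall B scales comparable; the
transform is affine-invariant and idempotent, and a constant-B
structure is an explicit error. State comparisons subtract holo from
apo z-scores per residue (positive = rigidified in holo), per holo
structure and cumulatively; residues absent from any structure are
reported as NA, never as zero. Residue alignment is by residue number
(isomorphous crystals); no sequence alignment is attempted.

Ensemble spread is measured after superposing every model onto the
first by Kabsch's SVD solution over the β-strand main chain, with the
determinant constrained to +1 so reflections are never returned. The
per-residue statistic is the RMS deviation, over models and main-chain
atoms, from the across-model mean position (`method = "to_mean"`); the
all-pairs convention is implemented as an option because visualization
packages differ and the original convention is not recorded. The
to-mean default was chosen as the variance-like statistic with the
cleaner closed-form behaviour (a single displaced atom of magnitude d
between two models reads d/2).

PDB input goes through bio3d (multi-model aware); ANISOU records, which
bio3d drops, are recovered by a fixed-column supplementary parser.
Multi-model output (MODEL/ENDMDL) is written directly, since bio3d
writes single models only.

## H/D exchange

Uptake is the centroid shift of the isotopic envelope times the charge;
percent uptake divides by the theoretical maximum
$N_{ex}\cdot f_{D_2O}$, with $N_{ex}$ = peptide length − 1 − (prolines
after position 1): the N-terminal amide back-exchanges too fast to
retain label and prolines have none. The buffer deuterium fraction
defaults to 0.975 (2 µL protein into 78 µL of 99.9% D₂O) and is an
explicit, overridable parameter; no back-exchange correction is applied
because the upstream protocol defines none. Values above 100% are
clipped with a warning (they arise legitimately because a deuteron adds
1.0063 Da, slightly more than the 1 Da the percent convention assumes);
small negative uptakes from noise are reported unclipped at the Da
level. Peptide-to-residue projection averages all covering peptides
(unweighted by default, inverse-length weighting available); residues
with no coverage are flagged absent.

Two natural-language statements of the differential-map sign convention
contradict each other in our sources; the package resolves the conflict
in favour of "negative differences indicate stabilization", i.e.
Δ = holo − apo by default, records the convention in the output's
attributes, and lets `convention = "apo_minus_holo"` flip it.

The generator models exchange as per-residue single-exponential with
intrinsic rate 1 min⁻¹ slowed by a protection factor, timepoints
1/2/5/10 min; envelopes are the natural carbon-isotope binomial
(1.07% ¹³C) convolved with the Poisson-binomial deuteration
distribution, with multiplicative intensity noise. The protein sequence
is a deterministic *synthetic* 133-residue chain (the package never
claims the real sequence); protection profiles put fast exchange in the
portal for apo (P ≈ 3) and protect it in holo (P ≈ 60) against a slow
scaffold (P ≈ 200).

## Trajectory statistics

Frames are superposed onto frame 1 over the main-chain atoms of the ten
printed β-strand ranges; the portal loops are derived as the
inter-strand gaps (helices I/II = 15–38, β3–β4 = 55–59, β5–β6 = 74–80,
with β7–β8 = 99–104 tracked separately), and the portal is their union.
RMSF is the per-atom RMS deviation from the time-average position,
aggregated per residue over heavy atoms (element ≠ H, decided from the
element column, never from atom names); simulated B-factors are
$(8\pi^2/3)\,\mathrm{RMSF}^2$. Region RMSD is heavy-atom RMSD to frame
1 *without refitting* (the single global alignment is the only
superposition), and replicates are combined by computing statistics per
replicate, then averaging, with SD across replicates. Correlations are
ordinary least squares with $R^2 = 1 - SS_{res}/SS_{tot}$, computed on
per-system means by default and on per-replicate points as a secondary
report; the affinity axis is linear in µM with a log option.

The generator produces AR(1) (Ornstein–Uhlenbeck-like) jitter around
the reference fold — each residue one rigid unit, each ligand atom
independent — with memory ρ = 0.5 and stationary per-coordinate SD from
the flexibility profile. Frame 1 carries no thermal displacement: it
stands for the minimized starting structure that no-fit RMSD is
measured against. Small per-frame rigid wobble is added so the
alignment step has real work to do. For the nine-system study, portal
amplitudes rise linearly across systems (0.3–1.0 Å) and ligand
amplitudes follow them with Gaussian scatter sized so the *population*
R² between the mobility summaries equals the requested coupling
(default 0.9); nominal inhibition constants increase with portal
amplitude (15 µM/Å, 15% lognormal scatter), so more portal motion
predicts a weaker binder by construction. A Monte-Carlo test checks the
realized R² over 20 seeds against the requested value within ±0.1.

## What the synthetic data do and do not show

The generators reproduce the *statistical contracts* the analyses rely
on — control-like signal signatures, saturation curves with assay-level
noise, flexibility profiles with a rigidifiable portal,
protection-modulated exchange, mobility coupling — under fixed seeds
and byte-reproducibly. They do not attempt force-field realism,
photophysics beyond a monotone signal model, real β-barrel geometry
(the reference fold is a smooth synthetic curve with correct residue
bookkeeping), or MS peak-picking artifacts. Passing tests therefore
demonstrate that the analysis chain measures what it claims on data
with known ground truth; they do not re-derive the original study's
experimental values, and the package nowhere claims to reproduce
500 ns simulation observables from desk-scale runs.

## Problem sizes and runtime

Defaults were sized for interactive use: 384-well plates; 12-point
titrations in triplicate; 12-model ensembles of a 133-residue chain;
22 tiled peptides × 4 timepoints; nine trajectory systems × 2
replicates × 150 frames. The full test suite runs in about a minute on
one CPU; the end-to-end pipeline demo (`run_pipeline()`) in a few
seconds.

## Known limitations

* The screening stage models no spatial plate effects (no Z′/B-score
  machinery) — deliberately out of scope.
* Ki estimation near or above the titration window is
  information-limited, as quantified above; report the SD, not just the
  mean.
* The ANISOU parser reads the tensor trace only; full anisotropy
  analysis (ellipticity, directionality) is not implemented.
* HDX significance testing of Δ-uptake is not implemented; the
  differential map is descriptive.
* Binary trajectory formats are not read natively; the documented
  whitespace frame format is the interchange, and adapters can wrap it.
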