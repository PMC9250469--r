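---
title: "Methods: corticostriatal PET/fMRI network analysis of processing speed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corticostriatal PET/fMRI network analysis of processing speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectsnet)
```

## The problem

Epilepsy with centrotemporal spikes (ECTS, rolandic epilepsy) is the most
common focal epilepsy of childhood. Although seizures are infrequent, the
abundant interictal discharges that originate in the rolandic (pericentral)
cortex are suspected to disturb the cortical–striatal circuit — the pathway
running from sensorimotor cortex through caudate, putamen, nucleus accumbens
and pallidum to the thalamus and back to frontal cortex — and with it the
*processing speed* of affected children, measured by the WISC-IV processing
speed index (PSI).

`ectsnet` implements the complete analysis such a study needs on two imaging
arms plus a clinical table:

* **PET arm** — ¹⁸F-FDG uptake volumes are intensity-normalised to SUVR
  (standardised uptake value ratio) against cerebellar gray matter, screened
  voxelwise with a cluster-thresholded two-sample t-map, summarised per atlas
  ROI as GM-probability-weighted means, compared between groups with
  Benjamini–Hochberg FDR control, and correlated with PSI in patients.
* **fMRI arm** — ROI-level BOLD series are cleaned (frame dropping, linear
  detrending, 0.01–0.08 Hz band-pass, Friston-24 + WM/CSF nuisance
  regression, framewise-displacement scrubbing), converted to Fisher-z
  functional connectivity (FC), screened for non-null edges, reduced to
  PSI-related edges, and tested with the network-based statistic (NBS).
* **Clinical statistics** — two-sample t-tests and the Pearson chi-square on
  the subjects table, and stepwise multivariate regression of clinical
  factors on the WISC-IV indices.

Because no raw images are publicly available for this design, the package
ships a first-class synthetic-data generator that reproduces the study's
group structure, so every stage is exercised end to end by code alone.

## The network-based statistic

For each candidate edge $e$ the observed statistic is the absolute
difference in group mean Fisher-z FC,
$T_e = |\bar z^{pat}_e - \bar z^{con}_e|$. Subjects are randomly
re-allocated into two groups of the original sizes; each edge's p-value is
the rank of its observed statistic in the joint relabelling distribution
(the observed labelling is included, so $p \ge 1/(n_{perm}+1)$ and p-values
are never zero). Edges with $p < \alpha_{edge}$ form the suprathreshold
graph. Familywise control works on connected components: each relabelling is
put through the same edge-level thresholding and the size (in **edges**) of
its largest component is recorded; the observed components are compared
against that null distribution, with the top 5% of null maximal sizes as the
significance threshold. On small cohorts `nbs(..., exact = TRUE)` enumerates
every distinct relabelling, making the p-values exact.

Choices worth stating explicitly:

* **Absolute-difference statistic.** The hypothesis is a change in
  connectivity *strength*; decreases in positive FC and attenuation of
  negative FC are the same phenomenon on this scale. A signed variant is
  available via `statistic = "diff"`.
* **Component size in edges, not nodes.** A subnetwork of 20 connections
  among 16 ROIs with a size threshold of 12 is only coherent when size
  counts edges; all sizes and thresholds in the package use that scale.
* **Whole-subject relabelling.** Permutation re-assigns subjects, never
  individual edges, preserving the dependence between edges within one
  subject's FC matrix.
* **PSI-related edge selection.** An edge enters the NBS if its FC–PSI
  Pearson correlation has $p < 0.05$ in either group; screening beforehand
  keeps only edges whose FC differs from zero (FDR-corrected one-sample t)
  in at least one group. Selecting on patients only is available via
  `scope = "patients"`.

## The synthetic cohort

`simulation_config()` defaults encode the study conditions: 28 patients and
20 controls; a 16-ROI corticostriatal parcellation (bilateral pre/postcentral,
caudate, putamen, pallidum, accumbens, thalamus, and right rostral middle
frontal and frontal pole); 200 BOLD frames at TR = 2 s; control PSI centred
at 102.55 with SD ≈ 13.

The base inter-ROI correlation matrix is block structured — within the
rolandic, striatal, thalamic and cortical blocks $r = 0.3$, between blocks
$r = 0.1$ — projected to the nearest positive-definite correlation matrix.
Patients have the planted edge set (by default a 12-edge connected
subnetwork along the rolandic → striatum → thalamus → frontal pathway)
lowered by `edge_effect` = 0.4 on the correlation scale, re-projected to
positive definite; if the projection would move a planted entry by more than
0.02 the configuration is rejected with the offending edges named. Series
are zero-mean multivariate Gaussian draws with optional AR(1) smoothing
(`ar_coef` = 0.3; the same coefficient on every ROI leaves lag-0
cross-correlations untouched). Motion parameters follow a random walk with a
configurable rate of spike frames exceeding the 0.2 mm FD threshold, so
scrubbing is exercised.

Two design choices go beyond a fixed group shift:

* **Latent severity.** Each patient carries a severity factor (mean 1, SD
  `severity_sd` = 0.15, symmetric truncation) scaling both the connectivity
  decrement and the regional SUVR decrement. Group means are unchanged, but
  within-patient variation in circuit disruption now propagates coherently
  to both imaging modalities — without it, patient-only correlations between
  SUVR and PSI would be identically null, which contradicts the design being
  emulated.
* **PSI couples to measured connectivity.** PSI is
  `psi_mean_control + psi_coupling × (subject's empirical planted-edge mean
  z − control population mean) + N(0, psi_sd)`. The coupling of 25 was
  chosen once so that the expected patient–control PSI gap under the default
  planted effect (Δz ≈ −0.41 × 25 ≈ −10) matches the clinical-table scale
  (≈ 93 vs 103), and `psi_sd` = 13 reproduces the control SD.

PET volumes (`simulate_pet_volume()`) place the ROIs as disjoint cubes on a
small grid (default 24³ voxels of 2 mm) above a cerebellar reference slab;
intensity is the ROI mean (lowered by `suvr_effect` × severity on affected
ROIs for patients, default 0.06 SUVR on the striatal and right-frontal
labels) plus i.i.d. Gaussian noise, with GM probability 0.9 in ROI cores,
0.5 in shells, 0.2 outside, so the GM > 60% mask matters.

What the generator does **not** emulate: hemodynamic response shapes,
spatially correlated scanner noise, anatomical variability, registration
error, or partial-volume effects beyond plain Gaussian smoothing. Passing
tests therefore demonstrate correctness of the statistical machinery under
the declared model, not robustness to the full physics of PET/fMRI.

## Numerical and procedural choices

* **t-tests.** Pooled-variance Student's t is the default for clinical and
  regional comparisons (it reproduces the published clinical p-values from
  the printed summaries); Welch is available via `variant = "welch"`. The
  printed clinical table is internally more consistent with pooled t on some
  rows and Welch on others, so no per-row rule is encoded.
* **Chi-square** on 2×2 tables is uncorrected by default (Yates available).
* **BH-FDR** wraps `stats::p.adjust`; q-values are monotone and the
  rejection set is order invariant.
* **Stepwise regression** uses the classical p-value procedure — forward
  entry at partial-F $p \le 0.05$, backward removal at $p > 0.10$, ties
  broken by p then alphabetical name — not AIC-based selection, and skips
  candidates collinear with the selected set ($R^2 > 1 - 10^{-10}$).
* **Band-pass** is a frequency-domain ideal filter with a raised-cosine
  taper of half-width 0.004 Hz at each band edge and DC always removed:
  exact band edges, simple contracts on sinusoid probes.
* **Framewise displacement** follows the Power definition (sum of absolute
  parameter differences, rotations as arc length on a 50 mm sphere);
  scrubbing runs after filtering, mirroring the common ROI-pipeline order.
* **Cluster connectivity** defaults to 18-neighbour (the SPM convention);
  6 and 26 are selectable everywhere clusters are formed. Voxelwise tests
  are two-sided and uncorrected at the screening stage.
* **Smoothing** uses a separable Gaussian with σ = FWHM/(2√(2 ln 2)) per
  axis and half-sample reflective boundaries, which conserve total image
  mass and avoid edge darkening on small grids.
* **Regional SUVR weights** are the GM probabilities themselves (the most
  natural reading of a GM-weighted regional mean); an unweighted switch is
  provided.
* **Degenerate inputs** fail loudly and specifically: zero-variance t-tests,
  perfectly correlated ROI pairs (Fisher z infinite), empty reference masks,
  non-positive-definite planted correlation targets, and subjects with fewer
  than two frames after scrubbing (rejected by name, and excluded rather
  than fatal inside `run_pipeline()`).

## A note on sign conventions in the planted model

Subtracting a large `edge_effect` (0.4) from a base correlation of 0.3
carries planted edges *through zero* (to −0.1). On such edges the
subnetwork summary used for PSI correlations — the mean **absolute** z —
becomes anti-monotone in the signed disruption, so the patient-only
correlation between subnetwork strength and PSI flips sign. Real
connectivity tables in this design show attenuation toward zero without
sign crossing, which is the regime in which |FC| is the right strength
summary. The sign-consistency checks in the test suite therefore use a
within-block planted set with `edge_effect` = 0.2 (patient correlations
0.3 → 0.1), while the stronger through-zero effect remains the default for
subnetwork *detection*, where only |Δz| matters.

## Problem sizes used by the test suite

The suite and the acceptance script run entirely on simulated data at desk
scale, chosen once as sizes a reviewer can re-run on a laptop: 200 null
cohorts at 500 relabellings for the familywise-error estimate, 50 default
cohorts for planted-subnetwork recovery, exhaustive enumeration on a
4-vs-3 cohort (35 relabellings), 40 cohorts of 200 patients for the
coupling-sign check, 10 000-frame series for correlation-scale effect
recovery, and 10³-voxel grids for the cluster-labelling oracles.

## Known limitations

* Spatial preprocessing (registration, segmentation, template construction)
  is out of scope; inputs are assumed atlas-aligned, as the generator
  guarantees.
* The generator is calibrated to the published group means only; per-subject
  FC variance in real cohorts is unknown, so power statements from the
  simulations do not transfer to real data.
* No graph metrics beyond connected components, and no partial-volume or
  attenuation corrections on the PET side.
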