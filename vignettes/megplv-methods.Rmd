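---
title: "Methods: simulating and analyzing resting-state MEG phase-locking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing resting-state MEG phase-locking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`megplv` implements a complete source-space MEG resting-state
functional-connectivity analysis — phase-locking-value (PLV) networks in
an individually-defined alpha band, compared across three diagnostic
groups (healthy controls, subjective cognitive decline, mild cognitive
impairment) with an age-adjusted permutation ANCOVA — together with a
synthetic-data generator that produces magnetometer-like cohorts with a
*known* connectivity ground truth, so that every stage of the pipeline
is testable without access to any recording.

This vignette explains the models, the numerical choices, and what the
synthetic cohorts do and do not establish about real data.

# The connectivity model

For two signals with instantaneous phases $\varphi_k(t)$, $\varphi_l(t)$
on a segment of $T$ samples, the phase locking value is the norm of the
average unit phasor of the phase difference:

$$\mathrm{PLV}_{k,l} \;=\; \Bigl|\tfrac1T \sum_t
  e^{-j\,(\varphi_k(t)-\varphi_l(t))}\Bigr| \in [0,1].$$

Per-subject PLV is the arithmetic mean of segment (epoch) PLVs; the
alternative of averaging complex phasors across epochs before the
modulus would estimate a different (lag-consistent) quantity and is not
used. Area-level connectivity between areas $A$ and $B$ with $N_A$ and
$N_B$ sources averages the *magnitudes* over all cross-area source
pairs:

$$\mathrm{PLV}_{A,B} \;=\; \frac{1}{N_A N_B} \sum_{k \in A}\sum_{l \in B}
  \Bigl|\tfrac1T \sum_t e^{-j(\varphi_{A_k}(t)-\varphi_{B_l}(t))}\Bigr|.$$

`plv_area()` implements this literally; a property-based test checks it
against the brute-force double sum on random instances to `1e-12`.

Two estimator properties matter for interpretation:

* **Positive bias at finite $T$.** For independent phases the expected
  segment PLV is the Rayleigh resultant mean $\sqrt{\pi/(4T_{\rm eff})}$,
  where $T_{\rm eff}$ is the number of effectively independent samples
  (much smaller than $T$ for narrowband signals). Estimated PLVs are
  therefore noticeably above their asymptotic targets on 4-s epochs.
  Group *contrasts* are preserved, which is what the statistics test.
* **Analytic link significance.** `plv_significance()` is a Rayleigh
  resultant test with the classical finite-$T$ series correction,
  $p = e^{-Z}\bigl[1 + \frac{2Z - Z^2}{4T} -
  \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288T^2}\bigr]$, $Z = T\,\mathrm{PLV}^2$,
  clipped to $[0,1]$. Nominal $T$ overstates the degrees of freedom of
  band-limited signals; the caller may pass a deflated `T_effective`.

# The synthetic cohort generator

## Phase model

The generator produces per-source phases

$$\varphi_k(t) = 2\pi f_0 t + \psi_k + \sigma z_k(t),$$

with a carrier at the subject's alpha frequency $f_0$, a static
per-source offset $\psi_k \sim U(-\pi,\pi]$, and wrapped-Gaussian phase
noise: $z(t)$ is a stationary multivariate AR(1) process with unit
marginal variance, cross-source correlation matrix $R$, and correlation
time `ar_tau`. Because the phase difference of a pair is Gaussian with
variance $2\sigma^2(1-R_{kl})$, its circular resultant has the closed
form

$$\mathrm{PLV}_{kl} = \exp\{-\sigma^2 (1 - R_{kl})\},$$

which is inverted entrywise to choose $R$ for any achievable target
matrix. This replaces a driver-mixing construction with a tabulated
calibration curve: the closed form needs no calibration table and makes
the realized PLV *provable* rather than approximated, at the price of a
feasibility constraint ($R$ positive semidefinite, targets at least
$e^{-2\sigma^2}$). A target of exactly 0 requests independent noise and
lands on the decoherence floor $e^{-\sigma^2}$ (≈ 0.018 at the default
$\sigma = 2$), which the tests treat as "zero" at their tolerance.

Two generator choices deserve emphasis:

* **Static phase offsets.** Without $\psi_k$, all coupling is zero-lag
  and coupled sources are strongly correlated *instantaneously*; a
  minimum-variance beamformer then partially cancels them (the
  classical correlated-source problem) and the planted group contrasts
  do not survive source reconstruction. The offsets leave every PLV
  unchanged while randomizing the signs of zero-lag correlations —
  and they are also the physiologically sensible choice, since cortical
  phase coupling is generally lagged.
* **Noise correlation time.** `ar_tau` controls the alpha linewidth,
  approximately $\sigma^2/(2\pi\,\texttt{ar\_tau})$ Hz. The cohort
  default of 0.5 s gives a ≈ 1.3 Hz line: narrow enough that a 4.5-Hz
  alpha band retains the oscillation and its coupling, wide enough to
  be resolved on 4-s epochs. Wider lines transmit group contrasts much
  more weakly through the band-pass + beamformer chain.

## Feasibility projection and ground truth

Per-subject between-edge jitter (SD 0.03 by default) individualizes the
target matrix. Jittered targets can leave the positive-semidefinite
cone; `generate_cohort()` projects onto the nearest feasible coupling
matrix (alternating projection between the PSD cone and the
unit-diagonal set) and records the *realized* (projected) PLV matrix as
that subject's ground truth, from which the synthetic scores are also
computed. `simulate_coupled_phases()` itself does not project: an
infeasible explicit target is a caller error and is reported as such,
naming the most implicated pair.

## Geometry and forward model

The toy source space has 12 areas (6 anterior, 6 posterior, left/right
symmetric) with centroids on a 7-cm shell and 2 point sources per area
with tangential orientations, observed by 60 radially oriented
magnetometers on a 12-cm spherical cap. Area centroids are spaced at
least ≈ 2.5 cm apart: closer centroids (an early layout had a pair at
1.5 cm) are so entangled by beamformer leakage that their edges carry
no recoverable contrast.

Sensor fields use the closed-form solution for a current dipole in a
homogeneous conducting sphere. The implementation is validated against
two exact properties (a central dipole and a radially oriented dipole
produce no external field) and against an independent oracle: the
radial field component is unaffected by volume currents and must equal
the radial component of the free-space dipole field. A three-shell BEM
is out of scope; the spherical model preserves the mathematical
structure the beamformer relies on.

## Study conditions

Defaults mirror a typical clinical MEG cohort of this kind: groups of 39/41/51 subjects
(HC/SCD/MCI); 4-s epochs at 1,000 Hz; per-group clean-epoch counts
47.6 ± 7.3, 46.2 ± 9.4, 42.2 ± 7.0 truncated at the 15-epoch inclusion
minimum; ages 70.4 ± 3.7, 71.6 ± 4.5, 73.0 ± 3.7 years; normalized
hippocampal volumes 5.0, 5.0, 4.4 (×10⁻³) with the MCI group lowered;
population alpha frequency 9.4 ± 0.5 Hz. The effect geometry plants
3 hyper-synchronized anterior edges (+0.15 in SCD and MCI) and 14
hypo-synchronized posterior edges (−0.12 in SCD on 11 of them, −0.18 in
MCI on all 14), i.e. an anterior increase common to both groups and a
posterior decrease that deepens from SCD to MCI. Effect magnitudes are
calibrated to the generator's own noise so that the planted geometry is
recoverable at the cohort sizes used — clinical reports rarely state
effect sizes in PLV units, so these are generator properties, not
estimates of any real cohort. Source amplitudes and sensor SNR (white
sensor noise at 10% of the clean signal RMS) are likewise package
defaults rather than measured quantities.

# The analysis pipeline

1. **Artifact rejection.** Per-epoch maximum amplitude z-score and
   maximum first-difference ("jump") z-score against per-channel pooled
   statistics; epochs over threshold are dropped and logged. This is a
   transparent stand-in for interactive artifact screening. The
   function's own defaults (z = 6) match Gaussian expectations; the
   *pipeline* defaults are amplitude 8 / jump 12, because clean
   narrowband oscillations have heavy-tailed first differences
   (instantaneous-frequency fluctuations) that z = 6 would misclassify
   wholesale, while genuine artifact spikes are orders of magnitude
   larger.
2. **Inclusion rule.** Subjects with fewer than 15 clean epochs are
   excluded.
3. **Alpha band.** The individual alpha frequency is the highest local
   maximum in 6–13 Hz of the epoch-averaged, Hann-tapered periodogram
   (resolution ≤ 0.25 Hz) over posterior channels (y < 0 in the toy
   frame); a peakless spectrum raises an explicit error rather than
   returning a range edge. The analysis band is IAF − 2.5 Hz to
   IAF + 2.0 Hz. By default one band is built from the sample-average
   IAF (per-subject banding is a config switch), so a 9.4-Hz average
   yields 6.9–11.4 Hz.
4. **Filtering.** Windowed-sinc FIR (Hann window), order 1800 at
   1,000 Hz, scaled proportionally at other rates; applied
   forward-and-reverse for zero phase, with 2,000 samples (at 1,000 Hz)
   of reflection padding per epoch side, removed after filtering.
   Epochs are padded by reflection because padding with adjacent
   recorded data is only possible for continuous recordings.
5. **Beamforming.** LCMV on the epoch-averaged covariance of the
   band-limited data, $w_s^\top = (l_s^\top C^{-1} l_s)^{-1} l_s^\top C^{-1}$,
   with diagonal loading $C + \lambda\,\mathrm{tr}(C)/n_{\rm ch}\, I$,
   $\lambda = 0.05$ by default (a conventional loading; published
   analyses rarely state one). Unit gain at every source is enforced to 1e−6. The
   default uses the known fixed source orientations; a max-power
   scalar orientation (generalized-eigenvector within the magnetically
   visible subspace, excluding the silent radial direction) is provided
   for free-orientation leadfields.
6. **Connectivity.** Hilbert analytic-signal phases per epoch with the
   same reflection padding, then Eq.-style pair and area PLV.
7. **Statistics.** Edge-wise ANCOVA F for group adjusted for age
   (group after age, i.e. Type-II sums of squares; a fixed,
   documented choice), permutation null from relabeling groups over subjects
   while each subject keeps its own age and values (group sizes
   preserved), $p = (1 + \#\{F^\pi \ge F\})/(1 + n_{\rm perm})$,
   Benjamini–Hochberg FDR at Q = 0.05, and for surviving edges
   age-adjusted Tukey contrasts (HC–SCD, HC–MCI, SCD–MCI) corrected
   against the permutation null of the maximum studentized-range
   statistic across the three pairs. The same machinery serves the
   RSN means, the beamformer-weight leakage diagnostic and the
   hippocampal-volume comparison; Pearson score correlations are
   FDR-corrected jointly across the full (edge, score) family — the
   conservative reading of an unspecified correction family.

Degenerate cases are fixed choices: a 0/0 F statistic (no residual and
no effect variance) is reported as 0; permutation p-values use the
add-one correction and never reach 0; zero-variance inputs to
correlations are errors, not NAs.

# Problem sizes used by the tests

The packaged test-and-acceptance runs use desk-scale versions of the
study conditions, chosen to exercise every stage at full fidelity while
keeping a complete run on one CPU in minutes: 250 Hz sampling (filter
order and padding scale proportionally, as they would at any rate),
20–25 epochs per subject, 12 areas / 24 sources / 60 magnetometers, and
500–1,000 permutations. The effect-geometry recovery check runs the
entire pipeline on a generated cohort of 40 subjects per group and
requires ≥ 80% of the 17 planted edges to be rediscovered after FDR
with no sign errors. Null-calibration checks (type-I rate of the
permutation ANCOVA, FDR control, absence of leakage differences under
identical forward models) run over ≥ 20 cohort seeds.

# What passing tests do and do not show

The generator provides phase-coupled narrowband oscillators with known
coupling, realistic epoch structure and spherical-conductor magnetometer
physics. It does **not** emulate: real head anatomy or a BEM forward
model, ocular/cardiac/muscle artifacts (the rejection stage is
exercised with injected amplitude spikes instead), sensor-array
interference or its spatiotemporal filtering, 1/f background activity
outside the alpha line, amplitude dynamics (amplitudes are constant up
to additive noise), or gradiometers. Consequently, passing the
recovery criteria shows that the *pipeline* is correct and well
calibrated — that true anterior/posterior contrasts of the stated size
survive filtering, beamforming and multiple-testing control — not that
the same sensitivities would be attained on clinical recordings.

# Known limitations

* Area-level PLV inherits beamformer leakage: absolute levels are
  biased toward a geometry-dependent baseline and group contrasts are
  attenuated (by roughly a factor of 3 in the default toy geometry).
  The weight-correlation diagnostic tests whether *filters* differ
  between groups, mirroring the published control analysis; it does not
  remove leakage.
* The closed-form phase model cannot realize arbitrarily low PLV
  between otherwise coupled sources (floor $e^{-2\sigma^2}$), and very
  heterogeneous target matrices may require the feasibility projection,
  which slightly moves realized targets (recorded per subject).
* `T_effective` for the analytic link test defaults to nominal $T$;
  for the default narrowband generator this overstates significance.
  The pipeline uses it only as the published-style per-link screen
  (which, on cohorts like these, excludes no link), not for the
  group comparisons.
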