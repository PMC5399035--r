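# megplv

Source-space MEG resting-state functional connectivity: phase-locking
networks in an individually-defined alpha band, compared across three
diagnostic groups with an age-adjusted permutation ANCOVA.

## What this package is for

Resting-state MEG studies of early Alzheimer-spectrum conditions
(healthy controls, subjective cognitive decline, mild cognitive
impairment) compare cortical phase synchronization between groups and
typically report an *anterior hyper-synchronized* and a *posterior
hypo-synchronized* network in the alpha band. Raw clinical MEG
recordings are generally not shareable, so the analysis methodology is
hard to exercise, validate or teach.

`megplv` provides the full analysis chain as tested R functions, plus a
synthetic-data generator that produces magnetometer-like cohorts with a
**known connectivity ground truth**, so the whole pipeline — from
sensor time series to FDR-corrected edge statistics — can be validated
end to end on a desk machine.

## The method

For signals with instantaneous phases φ_k, φ_l on a segment of T
samples, the phase locking value is

    PLV(k,l) = | (1/T) Σ_t exp(-j (φ_k(t) - φ_l(t))) |  ∈ [0,1]

and area-level connectivity averages PLV magnitudes over all cross-area
source pairs: PLV(A,B) = (1/N_A N_B) Σ_{k∈A} Σ_{l∈B} PLV(A_k, B_l).

The pipeline: artifact-epoch rejection and a 15-clean-epoch inclusion
rule → individual alpha frequency (IAF) from posterior-channel spectra
and the band IAF−2.5 to IAF+2.0 Hz → zero-phase windowed-sinc FIR
band-pass (order 1800 at 1 kHz, reflection padding) → LCMV beamformer
on the epoch-averaged covariance (unit gain per source) → Hilbert
phases → pair and area PLV → edge-wise ANCOVA F for group with age as
covariate, permutation-corrected (group labels relabeled over subjects,
group sizes preserved), Benjamini–Hochberg FDR at Q = 0.05, and
permutation-corrected Tukey pairwise contrasts for surviving edges.
Resting-state-network (DAN/aDMN/pDMN) means, Pearson correlations of
edges with neuropsychological-like scores and hippocampal volume, and a
beamformer-weight correlation diagnostic for source leakage round out
the analysis.

The generator simulates phase-coupled alpha oscillators whose pairwise
PLV is known in closed form (wrapped-Gaussian phase noise:
PLV = exp(−σ²(1−R))), projects them to sensors through the analytic
spherical-conductor (current dipole in a conducting sphere) forward
model, and draws ages, scores and hippocampal volumes with group
structure. See `vignette("megplv-methods")` for the model, its
assumptions, and what the synthetic cohorts do and do not establish.

## Worked example

```r
library(megplv)

spec <- ground_truth_spec(
  n_subjects = c(HC = 8, SCD = 8, MCI = 8),
  n_epochs = 20, rate = 250, seed = 1
)
cohort <- generate_cohort(spec)
#> <meg_cohort> 24 subjects (HC: 8, SCD: 8, MCI: 8), 24 sources / 12 areas, 60 sensors

config <- default_config(seed = 2)
config$stats$n_perm <- 500
result <- run_pipeline(config, cohort = cohort)
#> <pipeline_result> 24 subjects, band 7.04-11.5 Hz (IAF 9.54 Hz), 66 edges, 0 FDR discoveries

tab <- result$edge_stats$table
head(tab[order(tab$p), ], 5)
#>          edge     F       p fdr_rejected
#> 62 lSOC--rPCu  8.41 0.00200        FALSE
#> 64 lSMG--rPCu 15.69 0.00200        FALSE
#> 65 rSMG--rPCu  9.80 0.00399        FALSE
#> 55 rSMG--lPCu 11.88 0.00599        FALSE
#> 52 lSOC--lPCu  6.45 0.00998        FALSE

sapply(result$rsn$tests, function(t) c(F = unname(t$F), p = unname(t$p)))
#>      DAN  aDMN    pDMN
#> F 12.606 0.241 4.73704
#> p  0.002 0.818 0.00798

result$hippocampus$p
#> [1] 0.003992016
```

Reading the output: the detected sample-average IAF (9.54 Hz here)
anchors the band at IAF−2.5/IAF+2.0 Hz. The strongest edges are the
planted posterior hypo-synchronized links, at the permutation floor
p = 1/(n_perm+1); at this toy size (8 subjects/group, 66 edges) none
survives the BH step-up, while the dorsal attention network and the
posterior default-mode component already show clear group effects
(p = 0.002 and 0.008) with the anterior component null (p = 0.82), and
the MCI hippocampal-volume reduction is detected (p = 0.004). At 40
subjects per group the edge-level analysis recovers 16 of the 17
planted edges after FDR with no sign errors — that full-scale run is
part of the test suite (`tests/testthat/test-acceptance.R`).

## Command line

A thin wrapper over the same functions:

```sh
Rscript inst/cli/megplv-run.R --config run.yaml --out results/ --seed 42
```

with YAML keys overriding `default_config()` (band mode, filter order
and padding, beamformer regularization, `n_perm`, `Q`, RSN membership,
generator sizes).
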