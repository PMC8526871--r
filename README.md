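# spfm — stochastic hierarchical Bayesian modelling of functional brain modes

Resting-state fMRI decomposes into *functional modes*: sets of brain
voxels that co-fluctuate, each with a spatial map, a timecourse, an
amplitude and between-mode connectivity. Group-average decompositions
(spatial ICA) followed by dual regression estimate subject-specific maps
only derivationally, and degrade when subjects are spatially misaligned,
modes overlap, or modes are small. `spfm` is for researchers who want
*subject-level* mode estimates from cohorts far larger than memory.

The model is a hierarchical Bayesian matrix factorisation: per subject `s`
and run `r`,

    D^sr = P^s H^sr A^sr + e^sr

with a double-Gaussian signal/noise mixture and per-voxel membership
probabilities on the spatial maps `P^s` (shared across a subject's runs,
tied hierarchically to group posteriors), HRF-constrained timecourses
`A^sr` whose between-mode precision matrices follow hierarchical Wishart
distributions, positive diagonal amplitudes `H^sr` with a hierarchical
log-normal model, and Gamma-precision Gaussian residuals. Inference is
stochastic variational Bayes: the group posteriors are *global* variables
updated from weighted random subject batches, blended in natural-parameter
space with step size `rho_t = (t + tau)^(-beta)`, with a final alignment
pass over all subjects. Peak memory scales with the batch size, not the
cohort.

The package also ships

* a calibrated multi-subject fMRI simulator with known ground truth
  (`simulate_study()`, `scenario_presets()`),
* incremental group PCA (`migp()`) and a deterministic spatial-ICA
  initialiser (`spatial_ica_init()`),
* the ICA + dual-regression baseline with Tikhonov partial-correlation
  NetMats (`icadr_pipeline()`, `dual_regression()`, `partial_netmat()`),
* evaluation machinery: assignment-based mode pairing (`pair_modes()`),
  accuracy against ground truth (`accuracy_report()`), consistency
  summaries (`consistency()`), NetMats (`spatial_netmat()`).

## Worked example

Simulate a small cohort, fit the hierarchical model, and compare with
dual regression:

```r
library(spfm)

cfg   <- scenario_presets("set1_default", n_subjects = 12, n_voxels = 1000,
                          n_timepoints = 120, seed = 1)
truth <- simulate_study(cfg)
truth
#> Simulated functional-mode study
#>   12 subjects x 2 runs, 1000 voxels x 120 timepoints (TR 0.72s)
#>   15 modes, 1.30 modes per active voxel, mean subject-group overlap 85.3%

data  <- lapply(1:12, function(s) lapply(1:2, function(r)
  preprocess(truth_dataset(truth, s, r))$data))
basis <- migp(lapply(unlist(data, recursive = FALSE), masked_dataset),
              n_components = 30)
init  <- spatial_ica_init(basis, n_modes = 15, seed = 1)

fit <- spfm_fit(data, init,
                stochastic_config(batch_size = 4, n_batches = 8,
                                  n_initial_updates = 2, n_full_updates = 4,
                                  seed = 1),
                tr = cfg$tr)

accuracy_report(truth, fitted_group_maps(fit),
                subject_maps = fitted_subject_maps(fit),
                timecourses  = fitted_timecourses(fit))
#> accuracy_report (correlation with ground truth)
#>   group maps:          0.710
#>   subject maps:        0.710
#>   subject timecourses: 0.801

icadr <- icadr_pipeline(basis, data, n_modes = 15, seed = 1)
accuracy_report(truth, icadr$group_maps, subject_maps = icadr$maps)
#> accuracy_report (correlation with ground truth)
#>   group maps:          0.566
#>   subject maps:        0.488
```

The three numbers in each report are mean Pearson correlations between
estimates and ground truth after optimal mode pairing: for group maps
(per mode), subject maps (per subject, then averaged) and subject
timecourses. On this small cohort the hierarchical model recovers subject
topographies substantially better than dual regression — the gap widens
under stronger misalignment, overlap, or smaller modes (see
`scenario_presets()`); absolute values rise with more voxels, timepoints
and subjects. `tidy(fit)` returns the per-batch convergence monitors
(free energy, step size, group-map and precision deltas) and
`autoplot(fit)` plots them.

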