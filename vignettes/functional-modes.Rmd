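---
title: "Hierarchical Bayesian modelling of functional brain modes with stochastic variational inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian modelling of functional brain modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`spfm` decomposes multi-subject resting-state fMRI into probabilistic
functional modes. For subject $s$ and run $r$, the in-mask data matrix
$D^{sr} \in \mathbb{R}^{N_v \times N_t}$ is modelled as an outer product

$$D^{sr} = P^s \, H^{sr} A^{sr} + \varepsilon^{sr},$$

where $P^s$ ($N_v \times N_m$) holds the subject's spatial mode maps,
$H^{sr}$ is a positive diagonal matrix of mode amplitudes, $A^{sr}$
($N_m \times N_t$) holds the mode timecourses, and
$\varepsilon^{sr}$ is i.i.d. Gaussian residual noise with a Gamma-distributed
precision. Maps are shared across a subject's runs; timecourses and
amplitudes are not.

The factors carry the following structure:

* **Spatial maps — double-Gaussian mixture (DGMM).** Each voxel–mode entry
  is either *signal* or *background noise*: a Bernoulli membership with
  probability $\pi_{vm}$ selects between a Gaussian signal component (mean
  and variance tied hierarchically to the group) and a zero-mean Gaussian
  noise component. The subject posterior therefore consists of five maps:
  signal mean, signal variance, noise mean, noise variance and membership
  probability. At the group level we infer conjugate posteriors over the
  signal means (Gaussian), signal and noise precisions (Gamma) and
  membership probabilities (Beta), per voxel and mode. Group-level noise
  means are fixed at zero.
* **Timecourses — HRF-constrained matrix normal.** $A^{sr}$ has a
  matrix-normal prior $\mathcal{MN}(0, \alpha^{-1}, K)$: the row (mode)
  precision $\alpha^{sr}$ couples modes, and the column covariance $K$
  encodes the temporal autocorrelation of BOLD-like signal. $K$ is built
  from the spectrum of HRF-filtered low-frequency (< 0.1 Hz) activity,
  mixed with an identity component (`hrf_weight`, default 0.8). Building
  $K$ from the HRF-filtered signal class rather than the bare HRF kernel is
  deliberate: if the prior is much whiter than the series it models, the
  Wishart scatter under-counts smooth series and the precision posterior
  inflates, dragging the whole factorisation to a degenerate scale.
* **Between-mode precisions — hierarchical Wishart.** Each run's
  $\alpha^{sr}$ has a Wishart prior whose inverse scale $R_g$ is itself
  Wishart-distributed and learned from the population, so partial temporal
  correlations have a consensus structure across subjects. The posterior
  degrees of freedom are the prior dof plus the number of timepoints.
* **Amplitudes — hierarchical log-normal.** $h^{sr}_m = e^{g^{sr}_m}$ with a
  Gaussian posterior on $g$, regularised by a group Gaussian–Gamma model.
  Positivity is structural. The fixed-form Gaussian is optimised against
  its closed-form local free-energy contribution with a safeguard that
  keeps the previous posterior when the optimiser fails to improve, so the
  global objective cannot decrease.

All other updates are exact conjugate coordinate-ascent steps, derived from
the model structure; each is unit-tested against an independent dense or
numeric oracle (grid integration for the DGMM, a dense generalised-ridge
solve for the timecourses, closed-form Gamma/Wishart updates for precisions
and noise).

## Stochastic inference

Classic variational Bayes for this model must touch every subject in every
iteration. `spfm` instead treats the group posteriors as *global* variables
updated from random subject batches:

1. A batch of $K$ subjects is drawn without replacement with weights
   $w_i \propto 1/(1 + n_i)$, decreasing in the visit count $n_i$, so
   everyone is visited several times in expectation.
2. First-visit subjects are initialised from the ICA initial maps;
   revisited subjects resume their stored posteriors.
3. The batch receives `n_initial_updates` subject-only sweeps with the
   group frozen, then `n_full_updates` joint sweeps in which the
   intermediate group model $\hat\theta_t$ is re-accumulated with every
   subject's sufficient statistics multiplied by the number of batches $N$,
   so the batch acts as if the full population were present.
4. The global state is blended in natural-parameter space,
   $\theta_t = (1-\rho_t)\,\theta_{t-1} + \rho_t\,\hat\theta_t$ with step
   size $\rho_t = (t+\tau)^{-\beta}$, $\tau > 0$, $\beta \in (0.5, 1]$.
   Natural-parameter blending is precision-weighted for Gaussians,
   pseudo-count-wise for Beta/Gamma factors and inverse-scale-wise for the
   Wishart, which is what makes the convex combination the correct
   stochastic update for each conjugate family.
5. After the last batch, a final pass revisits every subject against the
   frozen final group so that all subject posteriors refer to one group
   model.

Defaults mirror a large-cohort analysis: batches of 50, $\tau = 5$,
$\beta = 0.6$, 10 initial and 20 full updates per batch. With one batch
containing the whole population and $\rho = 1$ the engine reproduces
classic full-batch VB bit for bit (this is a test). Peak memory scales with
the batch size, not the population; subject posteriors can be stored on
disk between visits (`store = "disk"`).

Within a subject sweep the update order is: timecourses, amplitudes,
residual noise (per run), then three inner passes of the per-mode spatial
mean-field (overlapping modes need a few alternations to residualise each
other), and the Wishart precisions last, once timecourse scales have
adapted to the current maps. Each step is an exact conditional maximiser,
so the free energy is monotone over sweeps — also a test, along with the
per-term ledger summing to the total.

### Initialisation

The spatial basis comes from incremental group PCA (MIGP): subjects are
visited one at a time, concatenated in time with the running reduced
matrix, and reduced back to `2 * n_modes` orthonormal columns, so memory
never exceeds one subject plus the running basis. A deterministic
fixed-point spatial ICA (tanh contrast, symmetric decorrelation, fixed
seed; unit-variance maps, nonnegative skewness, explained-variance order)
extracts the initial maps. The same ICA is the group stage of the
dual-regression baseline, so method comparisons share their PCA and
initialisation. Initial maps are rescaled at model entry so the implied
per-voxel signal variance share matches variance-normalised data, and
initial map variances enter small; both choices avoid a first-sweep scale
drift (tiny timecourses, inflated precisions) that otherwise traps the
optimiser in a poor basin.

### Hyperpriors

Hyperpriors are weakly informative and exposed in `spfm_hyperpriors()`:
membership prior mean 0.05 (modes are sparse), background noise component
tight around zero (Gamma(2, 0.02) on the precision), signal precision
Gamma(2, 2) for unit-variance data, subject Wishart dof `n_modes + 2`
centred on the identity, log-amplitude prior centred at 0. SPD repairs
(symmetrise plus trace-scaled jitter) are applied wherever matrix inverses
could go slightly indefinite; mode sign and label switching is handled only
at evaluation time by the pairing step, never inside inference.

## The simulator

`simulate_study()` generates multi-subject data with known ground truth:

* **Group maps.** Each of $N_m$ modes is a union of one to three contiguous
  voxel blocks with i.i.d. Gamma(3, 1) weights. Blocks are placed
  fill-first inside a region sized so the average number of modes per
  active voxel matches the configured overlap target (1.3 on the default
  configuration of 15 modes of 8.6% mean size on 10,000 voxels).
* **Subject maps.** A smooth, order-preserving 1-D diffeomorphism of the
  grid (the integral of a positive smooth expansion field, correlation
  length about two blocks) displaces, stretches and compresses modes
  without interleaving them, plus background Gaussian noise. The field
  amplitude is bisected within each call so the realised mean retained
  support overlap equals $1 - \sqrt{3}\,w/2$ for misalignment level $w$:
  80% retained at the 23.1% level, about half at 57.7%, ~85% at the
  default 17%. The uniform-displacement convention is what ties these
  percentage labels to the retained-overlap anchors. Maps are identical
  across a subject's runs.
* **Timecourses.** Subject precision matrices are Wishart draws centred on
  a group precision; neural series are correlated Gaussians with spectral
  weight concentrated below 0.1 Hz; BOLD series convolve them with a
  random nonnegative-dominant mixture of the canonical double-gamma HRF
  and its temporal and dispersion derivatives, one kernel per subject-run.
* **Data.** $D = P\,\mathrm{diag}(h)\,A + \varepsilon$ with log-normal
  amplitudes (log-sd 0.25) and Gaussian noise scaled to the configured
  SNR (default 2: two parts signal variance to one part noise).

Scenario presets reproduce the evaluation grid: `set1_default`,
`misalignment_{23.1,34.6,46.2,57.7}` (15 minimally-overlapping modes,
increasing warp), `overlap_{20,30,40}` (1.7–3.5 modes per voxel at a fixed
displacement budget of 3% of the voxels per mode) and
`modesize_{20,30,40}` (modes shrinking from 6.5% to 3.25% of voxels at
constant overlap and default misalignment). Fixed seeds give bit-identical
bundles.

What the simulator does *not* emulate: 3-D geometry and spatial smoothness
of real maps (the grid is 1-D), haemodynamic variability across voxels,
physiological-noise modes, scanner drift and motion artefacts. Passing
tests on these simulations therefore demonstrate correct recovery under
the stated generative assumptions, not performance on real scans.

## Problem sizes and what to expect

The full study configuration (500 subjects, 10,000 voxels, 300 timepoints)
is not practical for routine testing, so the packaged checks run reduced
problems, chosen once as a compromise between fidelity and runtime:

* acceptance script and test-suite scenarios: 2,000 voxels, 150
  timepoints, 100 subjects, batches of 10, 16–25 batches, 3 initial + 6
  full updates, 2 final-pass sweeps, one seed per scenario;
* robustness checks: 800 voxels, 100 timepoints, 30 subjects.

Reducing timepoints and voxels lowers the information ceiling of *all*
methods: with 150 timepoints per run and SNR 2, even regression on the
true timecourses recovers subject maps at about $r \approx 0.8$, so
absolute accuracies at reduced scale sit below the full-scale reference
values, while the ordering of methods (hierarchical model above plain
dual regression, most pronounced for subject maps) is preserved. The
subject-map background noise in the generator (sd 0.15 relative to the
mean weight) similarly caps attainable correlation near 0.9 at any scale.

## Numerical choices

* Variance floor $10^{-8}$ in preprocessing; constant voxels are zeroed and
  flagged.
* Membership probabilities clamped to $[10^{-8}, 1-10^{-8}]$ for entropy
  stability.
* The temporal system is solved exactly per eigenmode of $K$ by
  simultaneous diagonalisation of the evidence and precision matrices (one
  eigendecomposition per run update, then a diagonal solve per eigenmode).
* Wishart/SPD repairs: symmetrise and add `1e-8 * trace / n` jitter only
  when an eigenvalue is non-positive.
* MIGP drops numerically null singular directions (below $10^{-7}$ of the
  leading one) rather than returning spurious basis columns.
* Mode pairing solves the rectangular assignment problem by maximum-weight
  bipartite matching on $|r|$; the one-to-one flag requires $|r| > 0.7$ and
  a margin of two standard deviations over the row's other correlations.

## Known limitations

* The temporal signal/noise split is realised through the mixed prior
  covariance $K$ rather than explicit per-timepoint responsibilities; the
  reported `signal` component is the full posterior timecourse.
* Group membership probabilities are treated with a conjugate Beta model,
  a choice the underlying framework leaves open.
* From a group-level initialisation the optimiser can settle in partially
  mixed local optima under extreme misalignment; accuracies then track the
  information available at the chosen scale rather than the model's
  full-scale behaviour (see the acceptance notes above).
* Surface (CIFTI) data, task HRF fitting and missing-mode curation
  heuristics are out of scope.
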