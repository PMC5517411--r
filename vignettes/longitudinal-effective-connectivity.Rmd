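---
title: "Longitudinal effective connectivity: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal effective connectivity: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(longdcm)
```

## The scientific problem

Focal interventions in the motor system — such as thalamotomy of the
ventralis intermedius nucleus for essential tremor — produce changes in the
*directed* coupling between motor regions that evolve over weeks to months.
Distinguishing transient perturbations (which recover to baseline) from
sustained treatment effects, and relating either to clinical symptom scores,
requires (i) a per-session estimate of effective connectivity from
resting-state BOLD and (ii) a hierarchical model of how those estimates vary
over sessions and subjects. `longdcm` implements both stages, together with
a synthetic-cohort generator rich enough to test every stage end to end
without any patient data.

## The generative model

### Neural dynamics and haemodynamics

Hidden neural states $x(t) \in \mathbb{R}^n$ follow a linear stochastic
differential equation

$$\dot x = A_{\mathrm{eff}}\, x + v,$$

where the off-diagonal entries of the coupling matrix are rates (1/s) with
the convention that $A[i,k]$ is the influence of source region $k$ on target
region $i$, and the diagonal entries are *log-scale* self-connection
parameters: the effective self-inhibition rate is $-\tfrac12 e^{a_{ii}}$, so
$a_{ii} = 0$ corresponds to $-0.5$/s and positivity of self-inhibition is
guaranteed by construction. The endogenous fluctuations $v$ are scale-free:
each region receives independent noise with two-sided spectral density
$\alpha_v f^{-\beta_v}$.

BOLD observation passes each region's neural state through the
Balloon–Windkessel model (vasodilatory signal, inflow, venous volume,
deoxyhemoglobin) and the classical static output nonlinearity

$$y = 100\, V_0 \left(k_1 (1 - q) + k_2 (1 - q/v) + k_3 (1 - v)\right),$$

in percent signal change. The haemodynamic constants
($\kappa = 0.64\,\mathrm{s}^{-1}$, $\gamma = 0.32\,\mathrm{s}^{-1}$,
$\tau = 2\,\mathrm{s}$, $\alpha = 0.32$, $E_0 = 0.4$, $\epsilon = 1$,
$V_0 = 0.04$, $k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$) follow the
canonical Balloon–Windkessel literature and are recorded in every run
manifest, because the BOLD output constants are field-strength dependent and
results are only reproducible if they are pinned down.

### Second-order (spectral) formulation

Rather than fitting the time series, the first-level model fits their
second-order statistics: the cross-spectral density (CSD). Linearizing the
combined neural + haemodynamic system at its fixed point gives the transfer
function $H(f) = L\,(i 2\pi f I - J)^{-1} B$, and the predicted CSD

$$G_y(f) = H(f)\, G_v(f)\, H(f)^{\mathsf H} + G_e(f),$$

with power-law state noise $G_v$ and observation noise $G_e$ on the
diagonals. The analytic Jacobian $J$ is validated against central
differences in the test suite, and the predicted CSD is validated against
the sample CSD of long forward simulations — the central cross-module
oracle: the simulator and the estimator implement the *same* physics through
entirely different code paths (stochastic integration vs frequency-domain
algebra), so their agreement is a strong correctness check on both.

### Hierarchical (three-level) structure

Writing $\theta^{(1)}_{ij}$ for the coupling parameters of session $i$,
subject $j$:

$$
\theta^{(1)}_{ij} = X_1[i,]\,\beta^{(2)}_j + \varepsilon^{(2)}, \qquad
\beta^{(2)}_j = X_2[j,]\,\beta^{(3)} + \varepsilon^{(3)},
$$

with the session design $X_1$ holding a baseline column $[1\,1\,1\,1]$, a
transient contrast $[1\,{-1}\,{-1}\,1]$ and a sustained treatment contrast
$[1\,1\,{-1}\,{-1}]$ over the four sessions (one day before, and one day,
seven days and three months after treatment), and $X_2$ an all-ones column
over subjects for group means. The symptom-covariate analysis replaces
$X_1$ by `[1, centred score]` over the three scored sessions (the day-after
session carries no score).

## First-level inversion (variational Laplace)

`invert_spdcm()` performs iterated Gauss–Newton ascent on the variational
free energy of a Gaussian posterior, treating the real and imaginary parts
of the CSD at each frequency as independent Gaussian channels, with
log-precision hyperparameters shared within two channel classes (diagonal
vs off-diagonal entries) and updated by safeguarded Newton (EM) steps.
Levenberg-style damping is applied to parameter steps and only steps that
increase the free energy are accepted, so the recorded free-energy trace is
non-decreasing by construction. Convergence is declared after the change
stays below 0.01 nat for 3 consecutive iterations (cap 128 iterations, with
a flag when the cap is hit).

Two numerical choices deserve explanation:

* **Per-frequency whitening.** Resting-state CSDs are steep (roughly
  $f^{-1}$ shaped through a haemodynamic low-pass), so under a uniform
  channel precision the lowest one or two frequency bins dominate the
  likelihood and the mid-band — where coupling information lives — is
  effectively ignored. Each frequency's channels are therefore normalized by
  the data's mean diagonal power at that frequency. The weights are a fixed,
  recorded function of the data, i.e. part of the likelihood definition, not
  a tuning knob.
* **Amplitude-centred priors.** The noise log-amplitude priors are centred
  so that the prior-mean model matches the overall power of the (rescaled)
  data, and carry unit prior variance; without this the inversion starts
  orders of magnitude from the data and the shrinkage priors cannot bridge
  the gap, stalling in a local optimum in which the error precision simply
  collapses. Coupling priors are conservative: off-diagonals
  $\mathcal N(0, 1/64)$, log-scale diagonals $\mathcal N(0, 1/256)$,
  haemodynamic log-deviations (transit time and neurovascular gain only)
  $\mathcal N(0, 1/256)$, spectral exponents $\mathcal N(1, 1/64)$.

The priors shrink couplings toward zero, so single-session posterior means
under-estimate large couplings (a planted 0.4 coupling typically reads
0.1–0.2 from one 160-volume session); the hierarchical pooling below is what
turns many noisy shrunken sessions into a well-powered group estimate.

## Second and third levels (PEB)

`peb_fit()` implements the Bayesian GLM over lower-level posteriors with the
observation model $m_i \sim \mathcal N(\theta_i, C_i)$ — the first-level
posterior mean *and covariance* both enter, so uncertain sessions are
down-weighted — and between-level residuals
$\varepsilon \sim \mathcal N(0, e^{-\gamma} I)$ with a single shared
log-precision $\gamma$ per level. Given $\gamma$ the posterior over the
effect matrix $\beta$ is the generalized-least-squares closed form (checked
against a direct matrix oracle to $10^{-8}$); $\gamma$ is optimized by exact
1-D maximization of the marginal likelihood plus a mild
$\mathcal N(0, 4^2)$ hyperprior, which keeps the EM free energy
non-decreasing trivially. All $n^2$ coupling-matrix entries are carried
between levels; haemodynamic and noise parameters stay at the first level.

One empirical-prior pass is performed by default: after the first fit, each
lower-level posterior is re-evaluated under its empirical prior by Gaussian
conditioning on the carried subset (swapping the original prior marginal for
the empirical one), and the level is refit. The conditioning uses marginal
covariances over the carried subset, an approximation that is exact when
carried and non-carried parameters are a posteriori uncorrelated.

Group inferences use a 95% credible-interval non-zero criterion
($\mathrm{mean} \pm 1.959964\,\mathrm{sd}$ excluding 0); a single
multivariate model underlies all intervals, so no multiplicity correction is
applied.

## What the synthetic generator emulates — and what it does not

The generator reproduces the statistical structure of the study design it
emulates: 8 subjects x 4 sessions, 6 regions (a motor network:
precentral gyrus, SMA, ventrolateral thalamus, non-VL thalamus, putamen,
contralateral dentate nucleus), TR = 2 s, 165 volumes per session with the
first 5 discarded, scale-free neuronal fluctuations, Balloon haemodynamics,
power-law observation noise, slow drifts, motion-like confounds that leak
into the data, and symptom scores at three of the four time points linearly
coupled to designated connections, clipped at zero as clinical scales are.

Defaults chosen where the emulated design is silent, fixed once and stated
here:

* Baseline networks: off-diagonals $\mathcal N(0, 0.05^2)$, diagonals 0,
  re-drawn until stable (at most 100 retries) — a weakly coupled stable
  default mirroring conservative DCM priors.
* Neuronal fluctuation amplitude $\alpha_v = 10^{-4}$ (exponent 1) puts the
  simulated BOLD around 2% signal change while keeping neural excursions
  small enough that the Balloon linearization used by the spectral model is
  accurate; observation noise $\alpha_e = 10^{-3}$ (exponent 1) gives
  roughly 0.3% measurement noise; drift amplitude 0.2% over a session.
* Both random-effect levels apply to all $n^2$ coupling entries (the design
  does not say which parameters carry between-level variability); planted
  fixed effects only where the effect specification names them.
* Haemodynamic parameters are homogeneous across regions, sessions and
  subjects in generation (per-region overrides exist); the inversion still
  estimates per-region transit-time and gain deviations.
* Two symptom scales ("posture"- and "action"-like) share the cohort's
  coupling structure with independent measurement noise, and are analysed
  in separate covariate PEBs — a joint two-covariate design was considered
  and left out of the default because the emulated analysis reports the
  scales separately.

Features of real data deliberately *not* modelled: image-space artefacts
(motion is emulated only as confound time courses), physiological noise
beyond power laws, session-to-session haemodynamic variability, nonlinear
(bilinear/two-state) neural dynamics, and lesion anatomy. Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions plus realistic measurement nuisances — not
robustness to every failure mode of patient fMRI.

## Preprocessing conventions

The conditioning pipeline is discard (5 volumes) → confound regression
(least-squares residuals on the confound matrix plus intercept) → joint
detrending and frequency filtering. The filter is a single joint regression
on linear and quadratic trends plus a discrete-cosine set — one projection,
hence exactly idempotent and free of the edge transients IIR filters produce
on 160-sample series.

The emulated protocol's filtering description ("low pass filtered up to
0.009 Hz" while retaining frequencies above 0.1 Hz) is internally
inconsistent; it is implemented as a **high-pass at 0.009 Hz** (removing
components slower than 0.009 Hz), which matches the stated retention of
high frequencies. Both directions are exposed (`highpass_hz`,
`lowpass_hz`), with the low-pass disabled by default.

Voxel blocks are summarized by the principal eigenvariate: the first left
singular vector of the demeaned time-by-voxel matrix, scaled so its variance
is the first eigenvalue over the voxel count and signed to correlate
positively with the voxel mean.

## Spectral estimation choices

Cross-spectra are estimated parametrically from a multivariate
autoregression (default order 8) — a smooth estimator appropriate for
160-sample sessions — with a Welch cross-periodogram (Hann window, 50%
overlap) available as an independent validation route. The default fitting
grid is 24–32 log-spaced frequencies; the pipeline fits from 0.01 Hz
(respecting the 0.009 Hz high-pass, below which the data carry no power by
construction) to 0.25 Hz (the Nyquist frequency of a 2-s TR). Frequencies
are in Hz throughout; angular frequency appears only inside the transfer
function.

## Problem sizes and numerical tolerances

Forward integration uses exact matrix-exponential propagation of the linear
drift (zero-order hold on the noise) at dt = 0.05 s, with the Balloon states
advanced by classical fixed-step fourth-order Runge–Kutta on the same grid;
power-law noise is synthesized in the frequency domain (zero-frequency bin
zeroed), which realizes the target spectrum exactly rather than through an
autoregressive approximation.

The package's own validation experiments run at a deliberately desk-sized
scale, chosen once: 3-region networks for inversion studies (8 subjects x 4
sessions for the hierarchical experiments, 10 random seeds for recovery
rates, 5 seeds for null-cohort calibration, 16 log-spaced frequencies at the
reduced spectral resolution). At this scale a full cohort run — 32 session
simulations, inversions and the complete PEB stack — takes about a minute on
one core, and the documented recovery properties (planted-effect sign
recovery, ≥ 80% across seeds; null survival fraction ≤ 10%) are stable
across seeds. The 6-region default configuration runs the identical code
path, only slower.

Degenerate inputs are handled explicitly: unstable coupling matrices raise
classed stability errors before any integration; rank-deficient confound
matrices drop dependent columns with a warning; an all-constant voxel block
is a degenerate-input error; a constant symptom score yields a zero centred
regressor and the association posterior collapses to its prior (by design,
through a rank-deficiency-tolerant covariate design). Posterior covariances
are projected to the PSD cone (eigenvalue clipping) whenever numerical
round-off leaves a marginally negative eigenvalue.

## Known limitations

* Single-session coupling estimates are strongly shrunk; the package is
  designed for group-level longitudinal inference, not single-session
  point estimation.
* The CSD likelihood treats channels as independent Gaussians; the true
  sampling distribution of MAR-derived spectra has cross-frequency
  dependence that is absorbed, not modelled, by the precision
  hyperparameters.
* The empirical-prior downward pass uses marginal (carried-subset)
  conditioning rather than full-covariance model reduction.
* No Bayesian model reduction over reduced model spaces, no automatic
  pruning, and no random effects on model structure: inference is over
  parameters of one full model throughout.
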