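---
title: "Methods: spectral-cue manipulation, cluster statistics and the joint LBA model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-cue manipulation, cluster statistics and the joint LBA model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(loomingbias)
```

`loomingbias` re-implements, as a tested and reusable pipeline, the
computational chain of an auditory-looming-bias experiment in which the
spectral shape cues of a listener's head-related transfer functions
(HRTFs) are manipulated to dissociate acoustic stimulus properties from
spatial percepts. This vignette documents the models, the choices behind
every tunable parameter, and what the synthetic-data module does and does
not emulate.

## 1. Spectral-contrast manipulation of HRTF magnitude spectra

The central acoustic manipulation rescales a dB magnitude spectrum about
its auditory-weighted mean within a manipulation band (1–16 kHz by
default):

$$M_c(f) = C\,M_1(f) + (1 - C)\,\frac{1}{N_f}\sum_{k} w'(k)\,M_1(k),$$

where $C$ is the spectral contrast factor ($C = 1$ native, $C = 0$ flat,
$C = -1$ inverted "novel" cues), $N_f$ the number of in-band bins, and
$w'$ a frequency weighting approximating auditory resolution by the
across-frequency derivative of the equivalent-rectangular-bandwidth
(ERB) rate scale. We realize $w'(f) \propto 1/\mathrm{ERB}(f)$ with
$\mathrm{ERB}(f) = 24.7\,(4.37 f/1000 + 1)$ Hz, normalized to mean 1 over
the in-band bins, which makes the weighted term a proper weighted mean
and gives the manipulation three exact invariants that the test suite
asserts: identity at $C = 1$, conservation of the weighted in-band mean
for every $C$, and multiplicative composition
($C_1$ then $C_2$ $\equiv$ $C_1 C_2$).

Design choices that the source procedure leaves open:

* **Magnitude domain.** The transform operates on dB magnitudes.
  Inversion in linear amplitude would create non-physical negative
  magnitudes; on the log scale, $C=-1$ mirrors peaks into notches of
  equal auditory salience.
* **Flat constant.** With $C = 0$ each (direction, ear) spectrum
  collapses onto *its own* weighted mean rather than one global
  constant; this is what the equation implies, and it preserves the
  direction-dependent broadband level (and hence interaural level
  differences) while removing spectral shape.
* **Smoothing.** Pre-manipulation smoothing uses a frequency-domain
  kernel shaped like a 4th-order gammatone power response,
  $(1 + ((f - f_c)/b)^2)^{-2}$, with $b$ set so the kernel's equivalent
  rectangular width equals `bandwidth_factor` $\times$ ERB$(f_c)$ and
  kernel rows normalized to unit sum (constants pass through
  unchanged). The exact bandwidth semantics of the cited filterbank
  method are not fully specified, so the factor is exposed and defaults
  to 1 ERB.
* **Phase.** Only magnitudes are manipulated. For rendering, filters
  are reconstructed as minimum phase via the real cepstrum; a flat 0 dB
  spectrum therefore maps to an exact identity filter.
* **Out-of-band bins** pass through unchanged.

## 2. Stimulus synthesis

Localization stimuli are 500 ms Gaussian noise bursts with 10 ms
raised-cosine ramps. Looming stimuli are Schroeder-phase harmonic
complexes (12 fundamentals evenly spaced over 100–140 Hz, bandwidth
1–16 kHz, phase curvature 0.5, realized as
$\varphi_n = c\,\pi\,n(n+1)/N$), combined in pairs by a raised-cosine
crossfade of 10 ms initiated 600 ms after onset with ±50 ms uniform
jitter. The crossfade weights are complementary at every sample, so for
the highly correlated tonal endpoints the transition conserves
intensity; for identical endpoints it is waveform-invisible (asserted to
1e−10). The iterative model-based loudness equalization of the original
procedure is replaced by RMS equalization at −20 dBFS (configurable):
the pipeline needs level-matched endpoints, not an auditory loudness
model, and the divergence is documented here. All synthesis is
deterministic under a seed.

## 3. Localization metrics and the chance-level virtual experiment

Directions use interaural coordinates: lateral angle in $[-90°, 90°]$
(no wrapping; errors are linear distances) and polar angle in
$[-90°, 270°)$ with circular arithmetic. Per trial the polar error is
the absolute circular difference wrapped into $[0°, 180°]$. Trials with
polar error above 90° are quadrant errors; the quadrant error rate is
their percentage, and the local polar error averages the remaining
trials (the threshold is configurable, fixed at 90° by convention).
When every trial is a quadrant error the local polar error is undefined
and reported as `NA` with a warning rather than silently dropped.

Chance references come from a virtual experiment: targets are resampled
from the actual target list, responses are drawn uniformly inside the
response range, replicates are scored and averaged. For i.i.d. uniform
lateral targets and responses on an interval of length $L$ the expected
absolute difference is $L/3 = 60°$, which the Monte-Carlo simulation
must reproduce within 0.5° at $10^5$ trials. Observed/chance ratios
(1 = chance, 0 = error-free) normalize the three measures. The exact
91-loudspeaker geometry of the original apparatus is not public, so
target grids are user-supplied and the packaged generators use regular
grids spanning both hemifields.

## 4. ERP cluster statistics

The ERP chain assumes preprocessed epochs (subjects × conditions ×
channels × time × trials; acquisition, filtering, ICA and channel
interpolation are out of scope). Baseline correction subtracts the
per-trial, per-channel mean over the 100 ms before the transition.
Blind trial equalization retains `min(counts)` trials per condition,
removing surplus trials at session positions `ceiling(k * n / r)`
(`k = 1..r`), i.e. as evenly spaced as possible and deterministic.

The cluster test is the standard nonparametric permutation scheme for
paired contrasts: dependent-samples t per (channel, time) sample in the
0–300 ms analysis window; suprathreshold samples (two-tailed t critical
value at the sample-level alpha, participant df) grouped into
spatiotemporally connected clusters — neighbouring channels at the same
sample or adjacent time samples at the same channel, no diagonal
connectivity, positive and negative clusters never merging; cluster
mass = summed t. The null distribution is the maximal same-sign cluster
mass under random within-participant condition swaps (sign flips),
each tail tested against its own null; Monte-Carlo p values use
$(b+1)/(n_{perm}+1)$ so p is never 0 and are doubled (capped at 1) to
correct for two-tailed testing. This per-tail construction makes the
procedure collapse exactly onto a paired sign-flip permutation t test
for a single channel and sample, which the suite verifies against an
independent oracle; the doubled-tail correction makes the test mildly
conservative (measured family-wise error ~0.03–0.05 at nominal 0.05).
Channel neighbourhoods use a distance threshold; when none is given the
threshold is chosen so the mean neighbour count is ~7, a typical
density for mid-sized caps, and is reported on the adjacency object.
Cluster scores average, per trial, over the rectangular window [cluster
onset, cluster offset] × all channels that contributed to the cluster
at any point — not the ragged member set — matching how single-trial
amplitudes are extracted for the joint model.

## 5. The linear ballistic accumulator and its hierarchy

Each response option is a linear ballistic accumulator: start point
uniform on $[0, A]$, deterministic within-trial slope drawn per trial
from a normal with mean $v_i$ and SD $s_v$, response issued when the
first accumulator reaches threshold $b = A + B$ ($B > 0$ keeps the
threshold above the start-point range); non-decision time $t_0$ shifts
the observed RT. The defective density of (choice, RT) is
$f_{win}(t - t_0)\prod_{lose}(1 - F_{lose}(t - t_0))$ with the standard
closed forms for $f$ and $F$.

* **Drift truncation.** Drifts are truncated at zero (configurable).
  Untruncated drifts leave a non-terminating race with positive
  probability and defective densities that integrate to less than one;
  with truncation the closed-form CDF is rescaled by $\Phi(v/s_v)$ and
  the suite verifies normalization to 1e−4 and agreement with a
  Monte-Carlo oracle (KS < 0.01 at $10^5$ draws) over a parameter grid.
* **Identifiability.** $s_v = 1$ fixes the evidence scale.
* **Design.** Each trial expands into one row per accumulator (looming,
  receding); the latent `match` factor marks the accumulator that the
  stimulus direction maps onto (looming for flattened, receding for
  shaped). The drift formula
  `~ match * direction * cue + vertical * horizontal + eeg` expands via
  the standard model matrix (12 columns for the full model); the
  per-trial cluster amplitude enters as a continuous `eeg` term,
  z-scored within subject for sampler conditioning, with the raw
  1/(µV·s) slope recovered by rescaling with the within-subject
  amplitude SD.
* **Hierarchy and sampler.** Subject parameter vectors
  $(\log A, \log B, \log t_0, \beta)$ are exchangeable draws from
  $N(\mu, \mathrm{diag}(\sigma^2))$. Estimation is by adaptive
  Metropolis-within-Gibbs: joint random-walk Metropolis per subject
  block (step size adapted toward ~25% acceptance during burn-in) and
  conjugate Gibbs updates for $\mu$ (normal) and $\sigma^2$
  (inverse-gamma). The inverse-gamma variance prior replaces a
  half-normal SD prior to keep the group updates conjugate; both are
  weakly informative at this scale. The contract is convergence, not
  sampler identity: split-chain Gelman-Rubin diagnostics are computed
  for every group-level parameter and any $\hat R > 1.1$ raises a
  warning. A `prior_only` mode samples the hierarchy ancestrally so
  prior-to-posterior contraction (one minus the posterior/prior
  variance ratio) can be inspected.
* **Comparison and contrasts.** Models are compared by BPIC
  $= \bar D + 2 p_D$ with $p_D = \bar D - D(\bar\theta)$, the deviance
  evaluated at the posterior mean of the subject-level parameters;
  a BIC-difference Bayes-factor approximation
  $BF = \exp(\Delta BIC / 2)$ covers the fixed-effect model family.
  Drift contrasts $\Delta$ between design cells are computed per
  posterior sample of the group-level coefficients, reported with the
  posterior mean, an equal-tailed 95% credible interval and the
  one-sided posterior masses $P(\Delta > 0)$ / $P(\Delta < 0)$.

## 6. What the synthetic generator emulates

`synthetic_config()` pins the study conditions: 14 subjects, 8 blocks of
100 trials alternating native/novel cue blocks with 50 flattened and 50
shaped trials each, four positions (FU 45°, FD 135°, BU 225°, BD 270°),
a group drift contrast of 0.36 s⁻¹ for the matching accumulator, and an
EEG-to-drift slope of −0.017 1/(µV·s). Single-trial cluster amplitudes
are condition means (native: flattened 2 µV more negative than shaped;
novel: reversed) plus Gaussian noise; the amplitude SD defaults to
10 µV, a realistic single-trial level for cluster-mean amplitudes that
the source does not report, chosen once for plausible power at
experiment scale and exposed in the configuration. Amplitudes are drawn
first and enter the generating drifts, so the dependence between neural
marker and behaviour is exactly the one the joint model assumes.

Epochs are spatially correlated Gaussian noise (exponential decay with
channel distance, 4 cm length) plus a boxcar deflection of 0.5 µV in
the 80–170 ms window on a compact 5-channel patch, on a [−0.1, 1.5] s
axis at 100 Hz. The default cap has 32 channels — the module is
layout-agnostic and the desk-scale simulations use a mid-density cap;
high-density layouts only change the adjacency input. What the
generator does *not* emulate: 1/f background spectra, trial-to-trial
latency jitter, eye or muscle artifacts, volume-conduction topographies
of real dipoles, or RT contaminants (a uniform-guess contaminant flag
exists but is off by default). Passing tests therefore demonstrate the
statistical machinery under the assumed generative structure, not
robustness to every property of real recordings.

Localization responses follow gain/bias/scatter per dimension plus a
configurable quadrant-confusion probability in which the polar response
is redrawn near a rear bias centre (180°), reproducing the qualitative
rear-bias pattern seen with non-native cues.

All draws flow from one master seed through fixed substreams per stage,
so any stage regenerates independently and the whole bundle is
bit-identical under (config, seed).

## 7. Numerical choices and degenerate inputs

* Monte-Carlo p values include the observed statistic
  ($(b+1)/(n_{perm}+1)$), so p = 0 never occurs.
* A zero-variance t denominator (identical conditions) maps to t = 0,
  yielding an empty cluster set rather than NaN.
* `rt <= t0` contributes zero likelihood (−Inf log-likelihood with a
  diagnostic count) instead of an error mid-sampler.
* The deterministic LBA limit ($A \to 0$, $s_v \to 0$) is handled by
  dedicated branches: passage time exactly $B/v$.
* Self-contrasts report $\Delta = 0$ with both one-sided masses 0,
  avoiding the misleading 0.5/0.5 of a strict-inequality convention on
  ties.
* Simulation scales in tests and drivers (sampler lengths of a few
  hundred kept iterations, 200–500 permutation replicates) were chosen
  as the smallest sizes at which the monitored posterior quantities and
  rejection rates are stable across seeds; every size is a visible
  argument, not a constant.

## 8. Known limitations

* The sampler is a generic adaptive Metropolis-within-Gibbs; it matches
  the estimation contract (convergence-checked hierarchical posteriors)
  but is slower per effective sample than the particle-based samplers
  used in specialist toolboxes, and short chains can leave
  $\hat R$ slightly above 1.1 on group-SD parameters.
* SOFA (AES69) HRTF container I/O is not included; spectra enter as
  plain delimited tables or arrays.
* The ERP module tests paired two-condition contrasts; factorial
  cluster tests must be expressed as contrasts of differences (as the
  analysis drivers do).
* Chance references for the original loudspeaker grid cannot be
  reproduced exactly without the unpublished grid coordinates.
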