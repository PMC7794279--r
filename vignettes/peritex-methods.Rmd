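---
title: "Modeling contextual modulation of peripheral texture perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling contextual modulation of peripheral texture perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`peritex` implements the computational machinery of a peripheral-vision
texture-discrimination study within the summary-statistics (SS) framework:
the visual input is represented by a fixed set of statistics of oriented
filter activations, pooled over a window whose size follows Bouma's law of
crowding. The package covers four stages:

1. **Filtering** — a complex steerable pyramid (`build_pyramid()`), the
   V1-like multi-scale, multi-orientation decomposition.
2. **Statistics** — Portilla–Simoncelli (PS) summary statistics over a
   circular pooling window (`compute_ps_statistics()`).
3. **Task simulation** — an image-computable observer for the 3-AFC
   naturalistic-vs-phase-scrambled discrimination task
   (`simulate_experiment()`).
4. **Analysis** — binomial GLM/GLMM log-odds-ratio analysis of trial data
   (`fit_participant_glm()`, `fit_glmm()`), identical for human and model
   observers.

Human participants and photographic source textures are replaced by
generators: procedural structured textures (`generate_texture()`) and a
logistic trial simulator with known effect sizes (`simulate_behavior()`).

# The steerable pyramid

Filters are polar-separable in the frequency domain. Radial profiles are
raised cosines on a log2 axis spanning one octave, so squared high- and
lowpass responses sum to one at every frequency; orientation tuning is
$\cos^{K-1}(\theta-\theta_k)$, normalized so the $K$ squared responses sum
to one. Oriented bands keep a single frequency half-plane (analytic
filters, amplitude $\sqrt{2}$ on the kept lobe), so the coefficient
magnitude is a smooth local-energy envelope and the real part an
even-symmetric filter output. Together the bank is a tight frame: the
symmetrized squared responses tile the spectrum exactly, which the test
suite asserts both on the filter stack and as a spatial-domain Parseval
identity.

Boundary handling is circular and downsampling is by spectral cropping
(alias-free), with the retained spectrum scaled by the area ratio so
coefficients equal samples of the filtered full-resolution signal; a
constant image therefore reproduces its value in the lowpass band
unchanged. With $\cos^{K-1}$ tuning at $K=4$, a grating aligned with one
band necessarily places $\cos^6(\pi/4)=12.5\%$ of the aligned band's
energy in each 45° neighbor; the orientation-selectivity test asserts the
derived ~25% off-band total, not a smaller figure.

# The statistic set

With $N_{sc}$ scales, $N_{or}$ orientations and an $N_a \times N_a$
correlation neighborhood, the retained set is:

| group | count at (4, 4, 7) |
|---|---|
| pixel marginals (mean, var, skew, kurt, min, max) | 6 |
| skew/kurtosis of the lowpass reconstruction per scale | 2(N~sc~+1) = 10 |
| central autocorrelation of the lowpass reconstructions | 25(N~sc~+1) = 125 |
| central autocorrelation of band magnitudes | 25·N~sc~·N~or~ = 400 |
| band magnitude means | N~sc~·N~or~ = 16 |
| within-scale magnitude covariances (upper triangle incl. diagonal) | 10·N~sc~ = 40 |
| adjacent-scale magnitude covariances (vs upsampled parent) | 16(N~sc~−1) = 48 |
| within-scale real-part covariances | 10·N~sc~ = 40 |
| cross-scale phase covariances (real part vs phase-doubled parent) | 32(N~sc~−1) = 96 |
| highpass variance | 1 |
| **total** | **782** |

Autocorrelation neighborhoods keep the centrally-symmetric half (25 of 49
lags): the zero-lag entry stores the weighted variance and off-center lags
are symmetrized covariances normalized by it. Cross-band matrices store
covariances; symmetric matrices keep the upper triangle including the
diagonal. Highpass and lowpass magnitude means are omitted as degenerate
(the former is identically near zero, the latter duplicates the pixel
mean). This enumeration reproduces the reference count of 782 exactly and
is validated by `ps_stat_count()`; the count, not an external listing,
pins down the deduplication scheme, so the enumeration above is the
package's documented resolution of that ambiguity.

Every averaging operation is weighted by the pooling window — a binary
disk at full resolution (a raised-cosine edge is available as an option),
block-averaged to each pyramid resolution and renormalized. The default
diameter is 360 px: twice the Bouma fraction (0.5) times the 12°
eccentricity at 30 px/deg (`bouma_pooling_diameter()`). Degenerate inputs
(zero variance) report zero skewness/kurtosis/correlations rather than
`NaN`, so classifier training never sees missing values.

# Stimulus construction

`phase_scramble()` replaces an image's phases with those of a seeded
uniform noise image, preserving the amplitude spectrum exactly; only the
noise phases are used, so the noise distribution is immaterial.
`texture_pair()` additionally co-matches the pixel histograms of the
naturalistic and scrambled images to the average of the two (elementwise
mean of their sorted value vectors) and re-imposes the common amplitude
spectrum, iterating both steps (default 30 rounds) and ending on the
spectrum step; the pair then shares the spectrum exactly and the histogram
to a fraction of a percent, so only higher-order statistics distinguish
its members. For dissimilar surrounds, `iterative_fas_hist_match()` runs
the converse loop (ending on the histogram step, convergence reported, not
enforced), and the structural-similarity preservation term sometimes used
with such loops is deliberately omitted — no parameters for it are
available, and a configuration hook is left in its place.

Stimulus geometry (`stimulus_spec()`, `compose_stimulus()`): disk or
split-disk targets, ring or half-ring surrounds of width equal to the
nominal target diameter (1.4× in the first experiment's geometry), and a
background gap created either by shrinking the target (surround geometry
fixed) or enlarging the surround (width preserved); at zero gap the two
modes render identical images, which is asserted in the tests. Every
texture boundary carries a 4-px linear transparency gradient (defined at
30 px/deg and scaled proportionally at reduced resolutions). The target
is composited over the surround, which underlaps by one gradient length at
continuous borders so adjoining textures cross-fade without exposing the
background. The split target is rendered as two half-disks with their
straight sides facing outward, flush with the surround's inner edge,
keeping the disk target's texture area; this is a geometric reading of a
figure, and rendered output (`write_image_png()`) is the reference for
visual comparison rather than further specification. Half-ring surrounds
are cut along the vertical line through the target center; *inward* is the
fixation side, taken to be the left edge of the canvas.

# The model observer

For each stimulus pair the observer computes the statistic difference
(782 predictors), adds zero-mean Gaussian noise per predictor with SD
equal to that predictor's SD over the pooled training set of all
conditions, normalizes predictors to unit variance, and fits a 3-class
logistic regression with L2 penalty; the penalty weight is selected by
10-fold cross-validation over 50 logarithmically spaced values spanning
six decades ($10^{-3}$–$10^3$). Test trials draw fresh noise using the
SDs and scale divisors frozen at training — whether the reference protocol
re-estimated them at test is not stated, so the frozen-at-training
reading is documented here as a package decision, not asserted as the
original one. Noise is drawn independently per trial and per predictor
(the draw granularity is likewise unstated). Ties in the class
probabilities are broken by the fixed class order (scrambled-left,
scrambled-right, none).

At full scale the protocol per surround condition is 750 training pairs
and 1500 test pairs (250/500 per class), with eight model observers
differing in noise samples and training-set composition.
`simulate_experiment()` reproduces this protocol with a `scale_factor`
that shrinks pair counts proportionally (desk-scale default 0.2). Two
further desk-scale devices keep runtimes practical without changing the
design: stimulus images are drawn from per-condition pools whose size
scales with the pair counts (pairs resample the pools; a floor of 150
test pairs per class keeps per-observer accuracy estimates usable), and
rendering may use a reduced pixels-per-degree factor, with all geometry —
target, surround, gap, gradients, pooling window — scaled proportionally.
Between-condition contrasts additionally use common random numbers: the
test-stage noise draw is shared across conditions within an observer
(test sets have equal sizes), the standard unbiased variance-reduction
device for comparing configurations of a stochastic simulation; marginal
accuracies are unaffected, only the paired contrast variance shrinks.
The test suite and the acceptance script run experiments at 10 px/deg
(20 px/deg for the discontinuity experiment, whose 0.35° gap is the
smallest manipulated feature and needs the extra resolution; the other
experiments manipulate surround content, not fine geometry), with
`scale_factor` 0.1 and 8 observers; these sizes are the package's
desk-scale study conditions and are reported alongside every result.
Replicates are spread over four texture ensembles for the dissimilarity
and naturalness experiments (two observers each), mirroring the
multi-texture reference designs, and use a single texture for the
surround-presence and discontinuity experiments.

# Behavioral analysis

Trial outcomes are reduced to the binary `correct` variable and analyzed
on the log-odds scale. Per-session GLMs use Wald intervals and p-values;
perfect separation is flagged with an infinite-interval marker. The
population model is a binomial GLMM with, for the intercept and each
fixed effect, a random effect for texture and one for participants nested
within texture (participant-only when a single texture is present);
random-effect correlations are fixed at zero, following the reference
analysis, by expanding condition factors into numeric dummies under `||`.
Estimation is maximum likelihood with the Laplace approximation (adaptive
quadrature available through `nAGQ` for scalar-random-effect models);
p-values are likelihood-ratio tests of the full model against the model
with the fixed effect deleted; confidence intervals are profile-likelihood
with a flagged Wald fallback. Whether texture-level random effects in the
reference analysis comprised slopes, intercepts, or both is not printed;
the package uses both and logs the composition with every fit, and the
recovery tests show the headline estimates are insensitive to dropping
the texture slopes at the simulated effect sizes. The session-exclusion
rule removes sessions below 45% correct in *every* condition; the filter
is idempotent and order-independent. The 100-simulation
recovery/coverage study runs with Wald intervals: on its design (20
participants, 2,800 trials) they coincide with the profile intervals to
well under 0.001 log-odds units, and profiling each of 100 fits is an
order of magnitude slower for an identical conclusion.

The three-level dissimilarity factor is coded with nested dummies (any
dissimilarity; spectrum dissimilarity on top), so the spectrum effect is
the change from the higher-order-dissimilar condition, matching the
reference parameterization.

# The synthetic generators

Procedural textures place sparse positive elements (oriented ridges,
blobs, or a jittered lattice) on a dark ground: sparse phase-aligned
structure yields strong pixel skewness, band-magnitude correlations and
cross-scale phase alignment — the higher-order structure that phase
scrambling destroys. They emulate the *statistical dissociation* the task
depends on (shared spectrum and histogram, different higher-order
statistics) and elementary texture variety (orientation bandwidth,
regularity); they do not emulate photographic content, luminance
calibration, or the particular statistic values of any catalogued texture,
so directional model results transfer but absolute accuracies do not. The
"dissimilar texture" used for dissimilarity experiments comes from a
different element family, as the dissimilar source textures in the
reference experiments came from different photographs.

The behavioral generator is the generative twin of the GLMM: seeded
Gaussian random intercepts and slopes per texture and per participant
(diagonal covariance), inverse-logit success probabilities, Bernoulli
outcomes; it defaults to the reference scale of one experiment (8
participants, 90 trials per condition, surround effect −1.07 from a
0.74 baseline, participant SD 0.5, texture SD 0.3 — moderate variability
consistent with the spread of individual estimates in the reference
figures).

# Numerical choices and limitations

* Weighted autocorrelations are circularly symmetrized
  ($(c(\delta)+c(-\delta))/2$) because window weighting breaks exact
  central symmetry.
* Cross-correlation maps are computed by FFT; all lags agree with direct
  shift-and-sum to machine precision (tested).
* Zero-variance maps yield zero correlations by convention, never `NaN`.
* The lowpass residual is cropped one final time only when the dimensions
  allow a centered even-sized spectrum; otherwise it remains at the last
  band resolution.
* Filter-induced structure dominates autocorrelation statistics of the
  bandlimited maps — on white noise these entries are large and
  deterministic (~0.6–0.8 at the first lags), so the white-noise test
  asserts *reproducibility across seeds* of the statistic vector rather
  than literal zero off-center correlations, which only hold for raw
  pixel autocorrelations.
* The model observer's directional effects for surround dissimilarity and
  naturalness depend on the texture ensemble (the reference work itself
  traces its model's naturalness effect partly to its stimulus-generation
  process); the package reports these directions at its own documented
  study conditions.
* Half-ring (surround position) manipulations have no model simulation,
  matching the reference protocol.
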