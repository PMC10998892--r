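---
title: "Spectral desynchronization scoring and post-surgery connectome prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral desynchronization scoring and post-surgery connectome prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasnet)
```

dasnet implements an analysis chain for studying how brain tumors and
their surgical resection reorganize functional and structural brain
networks: frequency-domain scoring of resting-state BOLD signals,
functional-network complexity and similarity scores, connectome
assembly arithmetic for hybrid tractography outputs, and a
prior-guided neural predictor of post-surgery structural connectomes.
Because the MRI processing that produces the package's inputs (fMRI
preprocessing, fiber-orientation modelling, tractography, streamline
filtering) happens in external tools, every analysis stage is driven
here by a synthetic cohort generator with a known ground truth. This
vignette explains the models, the parameters that matter, what the
generator does and does not emulate, and the design decisions taken
where the design was genuinely open.

## Spectral dynamics of BOLD signals

A BOLD series is a regularly sampled signal with repetition time TR
(seconds per volume). Its one-sided discrete Fourier transform gives
squared amplitudes $|A_\omega|^2$ at frequencies up to Nyquist
($1/(2\,\mathrm{TR})$ Hz), and the total power
$P_T = \sum_\omega |A_\omega|^2$. The DC component is excluded by
default because the intended inputs are demeaned, nuisance-regressed
residual series; a constant series then carries zero power and is
flagged degenerate so that percentage-based operations refuse it
rather than divide by zero.

Two derived distributions support all comparisons:

* the **binned power distribution**, percentages of $P_T$ in
  fixed-width frequency bins tiling $[0, f_{\mathrm{Nyq}}]$. The bin
  width is tuned per input by bisection so the first occupied bin
  holds approximately a target fraction (default 10%) of total power.
  The width rule is deliberately loose — the distribution is a
  reporting device and results do not hinge on the exact width — so
  the bisection tolerance is accepted as is, and an equal-power
  (variable-width) mode is provided as an alternative;
* the **cumulative power distribution** (CP), the percentage of $P_T$
  accumulated up to each frequency threshold. Decile thresholds are
  expressed as fractions of the Nyquist frequency; the reference
  quantity for "percent" thresholds is a convention, so it is
  documented and configurable rather than hard-coded.

The **Dynamics Alteration Score** between signals $i$ and $j$ is the
area between their cumulative power curves,

$$\mathrm{DAS}(i,j) = \int d\omega\, \left(CP^i_\omega - CP^j_\omega\right)
  = -\mathrm{DAS}(j,i),$$

positive when signal $i$ accumulates power at lower frequencies, i.e.
oscillates more slowly. Design choices:

* DAS integrates **full-resolution** CP curves (one threshold per
  frequency sample, prefixed with 0 Hz at 0%) by the trapezoidal
  rule; decile curves are for reporting only, since the score is an
  integral.
* By default the raw area (% · Hz) is divided by the frequency range,
  making scores comparable across the two TR dialects. On full
  resolution grids this normalization gives the closed form
  $100\,(f_2 - f_1)/f_{\mathrm{Nyq}}$ for two pure sinusoids, which
  the test suite checks to $10^{-9}$.
* When the two CP grids differ (different TRs), the curves are
  linearly interpolated onto the union grid restricted to the common
  range. CP is monotone and bounded, so interpolation is safe there;
  raw spectra are never interpolated.
* Signals are harmonized before transforming: equal TRs zero-pad the
  shorter series; different TRs (2.1 s vs 2.4 s in the targeted
  acquisitions) pad or truncate both to the longer common duration,
  leaving a residual mismatch below one sample of the coarser TR.

Aggregating per-region DAS values over a network uses either the
signed mean (directionality) or the mean of absolute values
(magnitude); the absolute value is taken per region *before*
averaging, and the two operations are deliberately not
interchangeable.

## Functional-network scores

Functional connectivity is the pairwise Pearson correlation matrix of
region series. Three scores summarize it:

* **Θ richness**, comparing the $m$-bin histogram $P_\mu$ of
  off-diagonal correlations with a uniform histogram:
  $\Theta = 1 - \tfrac{m}{2(m-1)} \sum_\mu |P_\mu - 1/m|$, with
  $m = 15$ by default and sensible values from 10 to 20. The
  histogram support is fixed to $[-1, 1]$ — not the data range — so
  scores are comparable across subjects. Θ is 1 for a uniform
  correlation distribution and 0 when all correlations share a bin;
  ΔΘ is the signed difference from the richness of the entrywise mean
  network of the healthy pool.
* **node similarity**: every row of the patient's adjacency matrix is
  correlated with the same row of each healthy subject's matrix, with
  the diagonal entry removed first (a shared unit diagonal would
  inflate the correlations; the alternative of keeping it is noted
  but not used), then averaged over (node, healthy subject) pairs.
* **tumor–network geometry**: the overlap
  $|\mathrm{Tumor} \cap \mathrm{DMN}| / |\mathrm{DMN}|$ (a pure voxel
  count ratio, 1 when a tumor covers the whole network) and the mean
  Euclidean distance from the tumor centroid to each region centroid.

## Connectome assembly

Structural connectomes are symmetric, zero-diagonal, non-negative
matrices over a 170-label atlas dialect in which 4 labels are empty,
leaving 166 active nodes and $166 \cdot 165 / 2 = 13695$ distinct
edges. Assembly arithmetic for the hybrid (healthy + lesion)
tractography design:

* the **lesion streamline budget** is the mean over control subjects
  of the number of streamlines intersecting the lesion mask, rounded
  half-up (a streamline count must be integral; the rounding rule is a
  package choice). Intersection is vertex-in-voxel — a streamline
  counts if any vertex falls in a lesion voxel after `floor()` — which
  is adequate at sub-voxel integration step sizes and much cheaper
  than segment–voxel clipping;
* the **greedy merge** takes the elementwise maximum
  $\omega_{ij} = \max(\omega^{\mathrm{healthy}}_{ij},
  \omega^{\mathrm{lesion}}_{ij})$; it is commutative, idempotent,
  monotone and associative, and the merge is applied to whatever
  common scale both inputs share;
* **log-weight normalization** maps native streamline weights
  (reaching $\sim 10^3$) through $\log(1 + w)$, with exact inverse
  $e^x - 1$; a scale flag prevents double application;
* the **power-law tail diagnostic** fits the upper tail of the
  weighted degree distribution by continuous maximum likelihood,
  $\hat\alpha = 1 + n / \sum_i \ln(x_i / x_{\min})$, with $x_{\min}$
  chosen to minimize the Kolmogorov–Smirnov distance between the
  empirical and fitted tails, and
  $\sigma = (\hat\alpha - 1)/\sqrt{n}$. The KS scan considers up to
  100 quantile-spaced candidates and requires at least 10 tail
  points.

## The post-surgery connectome predictor

The predictor maps the vectorized pre-surgery log-weight edge vector
(13695 values at default atlas size) to the post-surgery vector.

**Anatomical prior.** Each edge's plausibility is the fraction of
healthy-cohort subjects whose native weight on that edge is positive.
The support keeps edges with plausibility at least τ (default 0.5 —
present in at least half of the controls; the threshold is exposed
because its optimum is data-dependent). Predictions are multiplied
elementwise by the prior *inside* the training loss, so the prior is
backpropagated: plausible edges dominate the loss and edges outside
the support are exactly zero for every model kind, trained or not.
The exact Bayesian formulation behind this gating is an
interpretation adopted here as multiplicative output weighting; it is
the one point of the predictor where the package fixes a reading of
an under-specified design.

**FCNET.** One fully connected hidden layer of rectified-linear units
(width 256 by default — the width is a free choice in this
small-sample regime) with a linear output layer, so negative
log-weights are representable. Training minimizes the gated mean
squared error by stochastic gradient descent, learning rate 0.01, 100
epochs, with an 80/20 train/validation split and validation loss
recorded every 20 epochs; no regularization is applied. Two numerical
choices matter:

* gradient steps are **per-sample** by default (`batch_size = 1`,
  reshuffled every epoch). One hundred full-batch steps at this
  learning rate and problem size leave the model essentially at its
  initialization, whereas per-sample updates give the protocol's
  epoch count real optimization power; full-batch and mini-batch
  remain available through `batch_size`;
* weights start from a **scaled-uniform fan-in** initialization,
  $U(\pm 1/\sqrt{\mathrm{fan\,in}})$. Variance-preserving
  initializations twice as large produce first steps big enough to
  silence most rectified units permanently at this learning rate and
  input magnitude (log-weights up to ~8), stalling training.

The trained map is deterministic given the configuration seed: the
initialization and all epoch shuffles are drawn in R before the
compiled training loop runs.

**Benchmarks.** The Huber benchmark pools all (pre-edge, post-edge)
scalar pairs across training subjects and support edges into a single
robust linear regression (Huber M-estimation, transition constant
1.345); pooling to one global line is deliberate, since per-edge fits
are unidentifiable with ~18 subjects and ~10^4 edges, and the pooling
granularity is exposed as the place where other choices could be
made. The null benchmark is an untrained random linear map; it is
stored in factored form (edges × hidden times hidden × edges) so the
full edge-by-edge matrix — 1.5 GB dense at this size — is never
materialized, while remaining exactly a fixed random linear map.
Both benchmarks' outputs pass through the same prior gating as
FCNET's.

**Outputs and filtering.** Predicted edges whose implied native
weight $e^x - 1$ falls below 1.0 (less than one streamline) are set
to zero in the output matrix; negative log-weight predictions
therefore vanish from the output graph. Metrics are computed on the
**raw** (unfiltered) vectors, and graph-level divergences on the
**filtered** output, which is the package's resolution of whether
evaluation should see the filter: numerical reconstruction metrics
measure the regressor, topological metrics measure the graph it
actually outputs.

**Evaluation.** Leave-one-out cross-validation trains one model per
patient on all others and evaluates six metrics on the left-out pair:
MSE, MAE, Pearson correlation and cosine similarity on flattened
log-scale vectors, plus Kullback–Leibler and Jensen–Shannon
divergences between weight probability distributions (histograms of
positive log-weights on a binning shared by the compared pair,
50 bins over the pooled range, ε-smoothed at $10^{-10}$ and
renormalized). Logarithms are base 2 so JS is bounded by 1 and
interpretable as a distance; the bound is what fixes the base, since
reported null-model JS values above $\ln 2$ are only consistent with
base-2 logs. Fold-level z-scores use the sample (n−1) standard
deviation throughout, single-outlier screening uses the Grubbs test
(Student-t critical value at α/(2n) two-tailed), and normality of
fold scores is checked by the correlation between sorted values and
standard-normal quantiles at plotting positions $(i - 0.5)/n$.

## The synthetic cohort generator

The generator produces the cohort conditions the analyses assume: by
default 10 controls and 20 patients; 41 default-mode regions of 183
volumes each; repetition times alternating round-robin between 2.1 s
and 2.4 s to exercise harmonization; a 170-label atlas with 4 empty
labels; tumor volumes lognormal around a median of 480 voxels (about
13 cm³ at 3 mm voxels); and lobe labels cycling through frontal,
temporal and parietal with a quarter of tumors flagged
periventricular (metadata only — the flag drives reporting, not the
generative model).

**BOLD.** Each region's series is a mixture of sinusoids on the
discrete frequency comb with power envelope $\propto f^{-\mathrm{tilt}}$,
random phases, unit root-mean-square, plus white noise (sd 0.1).
Positive tilt concentrates power at low frequencies, so the sign of
the expected DAS against an untilted reference equals the sign of the
tilt; patient tilts are evenly spaced on $[-2, 2]$ and controls are
untilted. The envelope was chosen over an autoregressive model
because it makes spectral ground truth analytic.

**Masks.** The voxel grid is an abstract integer lattice with no
affine or world coordinates. Default-mode regions are disjoint cuboid
blobs on a lattice with one-voxel gaps; the tumor grows as a single
6-connected blob that first claims the requested number of region
voxels (steering through the gaps when needed) and then expands
outside, so the realized overlap matches the request to within one
voxel in $|\mathrm{DMN}|$.

**Connectomes.** All subjects share one sparse backbone (edge
probability 0.15 over active-node pairs). Log weights decompose as

$$\log w_{se} = \mu_e + g_s + \varepsilon_{se},$$

with edge identity $\mu_e$ carrying 88% of the configured variance
$\sigma^2$, a per-subject global gain $g_s$ 10%, and i.i.d. residual
2%; pooled log-weights are exactly $N(\mu, \sigma^2)$
($\mu = \log 1000$, $\sigma = 1$ by default, putting native weights
at the $\sim 10^3$ scale of streamline counts). The gain-dominated
decomposition mirrors real cohorts, where overall connectivity
strength differences dominate inter-subject variability; a purely
i.i.d. per-edge deviation would be an adversarial artifact — a
full-rank signal that no bottlenecked network can copy while a scalar
identity map can. Each subject additionally carries spurious
non-backbone edges at rate 0.02, giving the prior threshold something
real to remove.

**Lesion and surgery.** A lobe label names a fixed anatomical
territory: the first $k$ nodes of that lobe's block of the atlas,
with $k$ scaled by tumor volume, so territories are nested and
similar tumors produce similar, learnable rewiring. The tumor
attenuates territory edges already in the **pre**-surgery matrix
(factor 0.7 per endpoint inside the territory) — a patient's
pre-surgery network is itself a lesioned network, and this signature
is what makes the surgical outcome predictable from the input. The
surgery operator multiplies each territory edge by 0.5 per endpoint
inside the resected core, so core edges lose twice as much in log
scale as boundary edges (the removed-vs-spared gradation of a real
resection). Post-surgery matrices additionally receive a normative
plasticity shift — one per-edge log-shift $\delta_e \sim N(0, 0.3^2)$
drawn per cohort and shared by all patients, emulating normative
reorganization that a fully connected output layer can learn but a
single pooled regression line cannot — and mild multiplicative noise
(log-sd 0.05, the cohort's scan-rescan level). Altered edge indices
are recorded as the ground truth `true_surgery_edges`. Setting
attenuations to 1 and all stochastic terms to 0 makes the operator
exactly the identity, which the tests pin.

**What the generator does not emulate.** No hemodynamics (no balloon
model, no hemodynamic response), no head geometry or NIfTI volumes,
no spatial autocorrelation in BOLD noise, no distance-dependent
wiring costs, no age or sex structure, and no cognitive covariates.
Passing tests on this cohort therefore show that the chain measures
what it claims on data whose spectral and surgical structure is
known — not that effect sizes on real cohorts will match.

## Measurement conventions worth knowing

* The surgery-recovery check correlates predicted with true pre→post
  changes over `true_surgery_edges` **within the prior support**.
  Outside the support every gated model predicts exactly zero by
  construction, so including a patient's own spurious lesioned edges
  would measure the gating, not recovery. The low-noise condition for
  this check is the default generator with post-surgery noise lowered
  to 0.01.
* Distribution comparisons always rebuild the two histograms on a
  shared binning from the pooled pair; divergences refuse mismatched
  binnings rather than resampling silently.
* All randomness flows from explicit integer seeds; cohort
  generation, training and the pipeline are bit-reproducible, and the
  pipeline skips completed stages whose configuration hash is
  unchanged.

## Problem sizes

The shipped tests and the acceptance script run the full default
cohort (10 controls, 20 patients, 166 active nodes, 13695 edges) for
the cross-validated benchmark, 200 simulated subjects for tilt-sign
recovery, 500 random curve pairs for DAS antisymmetry, 1000 random
networks for the Θ bounds, 1000 random histogram pairs for the
divergence properties, and $10^4$ samples for power-law recovery;
pipeline determinism is demonstrated on a reduced cohort (4 + 4
subjects, 24 atlas labels), since determinism does not depend on
size. Unit tests use further-reduced cohorts to keep the suite fast.

## Known limitations

* The predictor's hidden width, initialization and batch regime are
  package choices; only the learning rate, epoch count, split and
  validation cadence are fixed by the protocol it follows.
* The Huber benchmark's pooled-scalar granularity is one of several
  defensible designs; per-edge or multivariate variants would need
  more subjects than the intended regime provides.
* The power-law fitter assumes a continuous tail; heavily tied data
  (many identical degrees) can defeat the KS scan, which then errors
  rather than guessing.
* Grubbs screening tests one outlier at a time; masked multiple
  outliers require repeated application, which the package leaves to
  the caller.
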