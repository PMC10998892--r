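# dasnet

Brain tumors alter resting-state BOLD oscillations and, after
surgical resection, the structural wiring of the brain. `dasnet` is an
R package for quantifying both effects and for predicting the
post-surgery structural connectome from the pre-surgery one. It is
aimed at researchers working with resting-state fMRI time series and
streamline-count connectomes in neuro-oncological cohorts, and at
methodologists who want a fully seeded, synthetic test bed for this
class of analysis.

## What it computes

**Spectral dynamics.** For a BOLD series with repetition time TR, the
one-sided power spectrum gives the total power
$P_T = \sum_\omega |A_\omega|^2$, a binned power distribution
(percent of $P_T$ per frequency bin), and the cumulative power
distribution $CP_\omega$ (percent of $P_T$ accumulated up to
frequency $\omega$). The **Dynamics Alteration Score** between two
signals is the area between their cumulative power curves,

$$\mathrm{DAS}(i,j) \;=\; \int d\omega \,\bigl(CP^i_\omega - CP^j_\omega\bigr)
 \;=\; -\mathrm{DAS}(j,i),$$

positive when signal *i* oscillates more slowly (power concentrated
at low frequencies). Mixed acquisitions with TR 2.1 s and 2.4 s are
harmonized by zero-padding/truncation to a common duration before
comparison.

**Functional networks.** Pairwise-Pearson connectivity matrices; the
Θ richness score
$\Theta = 1 - \frac{m}{2(m-1)}\sum_{\mu=1}^{m}\bigl|P_\mu(r_{ij}) - \frac1m\bigr|$
comparing the histogram of correlations with a uniform one
(m = 15 bins by default); node-wise similarity against a healthy
pool; tumor–network overlap
$|\mathrm{Tumor}\cap\mathrm{DMN}|/|\mathrm{DMN}|$ and centroid
distances.

**Connectome assembly.** The streamline budget for lesion seeding
(mean lesion-intersection count over controls), the greedy merge
$\omega_{ij} = \max(\omega^{\mathrm{healthy}}_{ij}, \omega^{\mathrm{lesion}}_{ij})$
of healthy and lesion matrices, $\log(1+w)$ weight normalization, and
maximum-likelihood power-law tail fits
($\hat\alpha$, KS distance $D$, $\sigma$) of weighted degree
distributions.

**Post-surgery prediction.** A one-hidden-layer fully connected
network (FCNET) maps the 13695-edge pre-surgery log-weight vector to
the post-surgery vector, gated elementwise by an **anatomical
prior** — the thresholded fraction of healthy subjects carrying each
edge — inside the training loss (SGD, learning rate 0.01, 100 epochs,
80/20 validation split). Huber-regression and untrained-random-map
benchmarks pass through the same gating. Leave-one-out
cross-validation scores every model with six metrics: MSE, MAE,
Pearson correlation, cosine similarity, and base-2 KL and JS
divergences between weight probability distributions. Fold z-scores,
Grubbs outlier screening and Q–Q normality checks round out the
evaluation.

**Synthetic cohorts.** Everything runs against a generator with known
ground truth: BOLD series with a controlled spectral tilt, voxel
masks with controlled tumor/DMN overlap, and control/patient
connectome cohorts with a shared lognormal backbone and a
lesion-territory surgery operator that records exactly which edges it
altered.

## Worked example

```r
library(dasnet)

# spectral scoring: a slow (tilted) signal against an untilted reference
cfg <- sim_config()
slow <- generate_bold(cfg, tilt = 2, seed = 1)
ref  <- generate_bold(cfg, tilt = 0, seed = 2)
das_between_series(slow, ref)
#> <das_score> 46.762 (raw area 11.073 %*Hz over [0, 0.2368] Hz)
```

The score is positive — the tilted signal accumulates its spectral
power at lower frequencies than the reference, i.e. it oscillates
more slowly — and is normalized by the frequency range, so 46.8 means
the two cumulative power curves are separated by almost 47 percentage
points on average across the spectrum.

```r
# functional complexity of one synthetic subject's DMN
net <- build_fc_matrix(generate_connectome_cohort(
  sim_config(n_controls = 2, n_patients = 2), seed = 1)$subjects[[1]]$bold)
theta_richness(net)
#> <richness_score> Theta = 0.1520 (m = 15)
```

Θ near 0 says the correlation histogram is far from uniform (most
region pairs here are weakly correlated, so they pile into few bins);
Θ near 1 would indicate a maximally rich correlation structure.

```r
# cross-validated prediction benchmark on a reduced synthetic cohort
co <- generate_connectome_cohort(
  sim_config(n_controls = 6, n_patients = 6, n_atlas_labels = 60,
             n_empty_labels = 2), seed = 1,
  include_bold = FALSE, include_masks = FALSE)
parts <- split_cohort(co)
prior <- build_anatomical_prior(lapply(parts$controls, `[[`, "pre_connectome"))
prior
#> <anatomical_prior> 1653 edges, tau = 0.50, 270 retained (16.3%)

cohort <- lapply(parts$patients, function(s)
  list(id = s$subject_id, pre = s$pre_connectome, post = s$post_connectome))
loo_cross_validate(cohort, prior, predictor_config(seed = 1), "fcnet")
#>   left_out_id   mse   mae   pcc    cs    kl     js
#> 1       PAT01 0.623 0.146 0.950 0.958 0.717 0.0528
#> 2       PAT02 1.191 0.224 0.915 0.929 0.448 0.0740
#> 3       PAT03 0.667 0.164 0.944 0.953 0.208 0.0579
#> 4       PAT04 0.860 0.173 0.938 0.948 0.301 0.0565
#> 5       PAT05 0.435 0.115 0.971 0.976 0.611 0.0713
#> 6       PAT06 0.905 0.177 0.942 0.951 0.731 0.0550
```

Each row is one leave-one-out fold: the network trained on the other
five patients reconstructs the left-out post-surgery graph with
Pearson correlations above 0.9 on the flattened log-weight vectors,
and JS divergences near 0.05 bits say the predicted and true weight
distributions nearly coincide.

The end-to-end study replica — simulate, spectral scores, functional
scores, assembly diagnostics, prior + LOO benchmark of
FCNET/Huber/null, evaluation report — is one call:

```r
run_pipeline(run_config(out_dir = "replica", seed = 1))
```

or from a shell, `Rscript inst/cli/dasnet-pipeline.R --out replica
--seed 1`. Outputs are deterministic TSV/JSON tables; re-running with
an unchanged configuration is a no-op.

## Package layout

- `R/` — spectral analysis, functional scores, connectome assembly,
  predictor + benchmarks, evaluation metrics, synthetic generator,
  pipeline.
- `src/` — the SGD training loop (RcppArmadillo).
- `vignettes/dasnet-methods.Rmd` — models, assumptions, parameter
  choices, generator design, limitations.
- `tests/testthat/` — oracle-backed unit tests and the end-to-end
  property suite.
- `inst/cli/dasnet-pipeline.R` — thin command-line wrapper over
  `run_pipeline()`.
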