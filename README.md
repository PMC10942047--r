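# readerprob

Quantifying *reader variability* in screening image interpretation, and
testing whether a classifier's output tracks it.

Low-salience findings on screening radiographs — an apical pleural cap, a
mild spinal curvature — are called inconsistently by physicians: the same
image may be read positive by one reader and negative by another. This
package treats each physician's call as a Bernoulli draw with an unknown
per-image probability *p* ("obviousness" of the finding), derives the exact
Bayesian posterior of *p* from a two-stage annotation protocol, and provides
the machinery to test whether a trained classifier's output is, after a
one-parameter calibration, an estimate of *p* rather than a mere binary
discriminator. It is aimed at researchers evaluating CAD models against
variable annotations.

## The model

**Two-stage annotation.** In the first (screening) stage two physicians read
independently and the record is positive (P) if either flags the finding, so
P(P | x) = x² + 2x(1−x) and P(N | x) = (1−x)². In the second (recheck) stage
two further physicians read blindly and both calls are kept: PP, PN
(unordered), or NN with probabilities x², 2x(1−x), (1−x)². Crossing the
stages gives six diagnosis groups
D ∈ {(P,PP), (P,PN), (P,NN), (N,PP), (N,PN), (N,NN)}.

**Posterior.** With a uniform prior p₀(x) ≡ 1,

```
p(x | D) = p(D | x) / ∫₀¹ p(D | x) dx
```

Every group likelihood is a degree-≤4 polynomial, so all normalisers and
posterior means are exact rationals via ∫₀¹ xᵃ(1−x)ᵇ dx = a! b!/(a+b+1)!.
The six expected posteriors are **7/9, 4/7, 3/8, 1/2, 1/3, 1/6**.

**Calibration.** A classifier trained with BCE-with-logits outputs a logit
u per finding. A single scale λ > 0 maps it onto the posterior logit scale,
u\* = −λu, p\* = σ(u\*); λ is fitted by minimising the mean L2 distance
between the kernel density of {−λuᵢ : i ∈ D} and the analytic posterior
logit density p_u(u | D), averaged over the six groups.

**Evaluation.** Subjects are grouped by D; the Pearson correlation between
the per-group mean of p\* and the six expected posteriors measures how well
the model output tracks reader probability. Cohen's κ and cross-validation
model-pair correlations quantify the two sources of variability
(reader-side and model-side).

Because screening archives with this annotation structure are private,
the package ships a
first-class synthetic generator: latent severities, the logistic link to
*p*, four Bernoulli reads per subject, classifier logits with a known true
scale, and toy grayscale images (bright apical band ∝ severity 1, laterally
displaced spine ridge ∝ severity 2) for the trainable CNN backend and
Grad-CAM.

## Worked example

```r
library(readerprob)

posterior_table()[, c("group", "normalizer_frac", "expectation_frac", "expectation")]
#> # A tibble: 6 × 4
#>   group normalizer_frac expectation_frac expectation
#>   <chr> <chr>           <chr>                  <dbl>
#> 1 P,PP  10/3            7/9                    0.778
#> 2 P,PN  30/7            4/7                    0.571
#> 3 P,NN  15/2            3/8                    0.375
#> 4 N,PP  30              1/2                    0.5
#> 5 N,PN  10              1/3                    0.333
#> 6 N,NN  5               1/6                    0.167

cfg <- pipeline_config(
  simulation = sim_config(n_subjects = 10000, latent = "uniform"),
  cv = list(k = 10L, test_n = 10000L), n_models = 10L, seed = 42L
)
res <- run_pipeline(cfg)
res
#> Synthetic evaluation pipeline: 10000 subjects, 2 findings
#>   pleural_thickening: lambda_hat = 0.775, group-mean correlation r = 1.000
#>   scoliosis: lambda_hat = 0.217, group-mean correlation r = 1.000

res$report$group_table[res$report$group_table$finding == "scoliosis", ]
#> # A tibble: 6 × 6
#>   finding   group     n  mean    sd expected
#> 1 scoliosis P,PP   3016 0.774 0.174    0.778
#> 2 scoliosis P,PN   2290 0.569 0.200    0.571
#> 3 scoliosis P,NN   1301 0.371 0.193    0.375
#> 4 scoliosis N,PP    344 0.503 0.185    0.5
#> 5 scoliosis N,PN    964 0.345 0.178    0.333
#> 6 scoliosis N,NN   2085 0.167 0.139    0.167
```

The generator used true scales λ = 0.79 and 0.22 with logit noise 0.3; the
fit recovers 0.775 and 0.217, and the six group means of the calibrated
probabilities sit on the identity line against the analytic expected
posteriors (r ≈ 1.0) — the mechanism the package exists to test.
`plot_group_means()` and `autoplot()` on a calibration visualise both.

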