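---
title: "Modelling reader variability: the Bayesian posterior, logit calibration, and what the synthetic benchmark shows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reader variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerprob)
```

## The problem

Findings such as apical pleural thickening or mild scoliosis sit near the
boundary of "within normal range": different physicians legitimately call
the same radiograph differently. A classifier trained on such binary labels
is usually scored as a detector (AUC, accuracy), which ignores the fact
that the labels themselves are draws from a per-image probability. This
package takes the opposite view: each read is Bernoulli(*p*) with a latent,
image-specific *p*, and the interesting question is whether a trained
model's output estimates *p*.

## The posterior model

The annotation protocol has two stages. Two screeners read independently
and the record is merged by union, so the merged call is positive with
probability $x^2 + 2x(1-x)$ and negative with $(1-x)^2$, where $x$ is the
latent reader-positive probability. Two rechecking pulmonologists then read
blindly and both calls are kept, giving PP, PN (unordered) or NN with
probabilities $x^2$, $2x(1-x)$, $(1-x)^2$. The cross of both stages yields
six diagnosis groups $D$.

Assuming a uniform prior $p_0(x) \equiv 1$ (the package exposes only this
prior; a conjugate Beta prior would be a one-line extension of the Beta
integral identity but is deliberately not offered, as nothing validates it
here), the posterior is

$$ p(x \mid D) = \frac{p(D \mid x)}{\int_0^1 p(D \mid x)\,dx}. $$

Every $p(D \mid x)$ is a polynomial of degree at most four with small
integer coefficients, so every normaliser and posterior mean is an exact
rational number via
$\int_0^1 x^a (1-x)^b\,dx = \frac{a!\,b!}{(a+b+1)!}$.
`expected_posterior()` and `posterior_table()` do this arithmetic on
integer fractions; floating-point quadrature appears only as an independent
oracle in the test suite. The six expectations are

```{r}
posterior_table()[, c("group", "normalizer_frac", "expectation_frac")]
```

Note the deliberate non-ordering across stages: $(P,NN) = 3/8$ is *below*
$(N,PP) = 1/2$ — two fresh positive reads outweigh a single-stage positive
followed by two negatives. Within a stage the expectations are monotone in
the evidence, and the tests assert exactly that partial order.

The second-stage PN likelihood carries the combinatorial factor $2x(1-x)$
(two orderings of a discordant pair). The factor cancels in the normalised
posterior, so expectations are unaffected; it is kept so that raw stage
likelihoods are genuine probabilities that sum to one over outcomes.

For calibration the posterior is needed on the logit scale
$u = \mathrm{logit}(x)$:
$p_u(u \mid D) = p(x(u) \mid D)\,\sigma(u)(1-\sigma(u))$,
implemented as `posterior_logit_density()` and tested to integrate to one
and to satisfy the change-of-variables identity pointwise.

## The synthetic cohort

No public dataset with this two-stage annotation structure exists, so
the generator is a
first-class, tested module rather than a fixture. It emulates:

* **Severity and the link.** Per finding, severity $s$ comes from a
  two-component mixture — a lognormal background (most subjects,
  $p \approx 0$) and a folded-normal affected component — and
  $p = \sigma(a(s - s_0))$. Defaults ($a$ = 2.2/3.5, $s_0 = 3$, affected
  means 3.2/3.4) spread affected-subject $p$ over roughly (0.2, 0.95),
  with the steeper slope for scoliosis reflecting its more obvious
  radiographic appearance.
* **Class imbalance.** Mixture weights (0.0561, 0.0217) were solved from
  the analytic prevalence integral (`expected_prevalence()`) so the merged
  first-stage prevalence is 4.46% (pleural thickening) and 1.58%
  (scoliosis), screening prevalences representative of the two findings in
  a young-adult checkup population.
* **Annotations.** Four independent Bernoulli($p$) reads per subject and
  finding; union rule for the merged call; the group is derived, never
  stored independently of the calls (readers re-derive it on load too).
* **Classifier logits.** $u = -(\mathrm{logit}(p) + \varepsilon)/\lambda_\mathrm{true}$
  with $\varepsilon \sim N(0, \sigma^2)$, one replicate per simulated CV
  model, so $-\lambda_\mathrm{true} u$ recovers the latent logit up to
  noise. $p$ is clamped to $[10^{-6}, 1-10^{-6}]$ before the logit to
  avoid infinities. Default true scales 0.79 and 0.22 and noise 0.3 match
  the regime the calibration is meant to recover.
* **Images.** Toy grayscale squares: smooth background texture, a bright
  apical band (top 15% of rows) with contrast proportional to finding-1
  severity, and a centre spine ridge displaced laterally by a sinusoid
  with amplitude proportional to finding-2 severity. The geometry is
  chosen so saliency checks have an unambiguous ground-truth region.

A key regime: with `latent = "uniform"` the latent $p$ is uniform on
(0, 1), which is precisely the situation in which the group-conditional
distribution of true $p$ *equals* the uniform-prior posterior. All
consistency and end-to-end checks therefore run in that regime. Under the
default low-prevalence mixture the latent-$p$ density is far from uniform
and group means of true $p$ do **not** match (7/9, …, 1/6); that is a
property of the population, not a bug, and the package makes no contrary
claim.

What the generator does *not* emulate: reader correlation or fatigue,
severity-dependent reader bias, non-exchangeable readers, and anything
resembling real radiographic texture. Passing tests show the pipeline's
statistical machinery is correct, not that any real classifier tracks real
reader probabilities.

## Calibration

Raw logits are mapped by $u^\star = -\lambda u$, $p^\star = \sigma(u^\star)$
(sign flipped relative to the raw output; backends whose logit already
increases with probability can pass `sign = +1`). `fit_lambda()` minimises
the unweighted mean, over the six groups, of the L2 distance on a fixed
grid ([−10, 10], 512 points) between the Gaussian KDE (Silverman
bandwidth) of the scaled logits in a group and the analytic
$p_u(u \mid D)$, using bounded scalar minimisation on
$\lambda \in [10^{-3}, 10]$ with tolerance $10^{-4}$.

Choices worth recording, since "distance between distributions" is
under-determined:

* KDE-vs-density L2 on a fixed grid is the default; a CDF-based
  (Cramér–von Mises style) alternative is available via
  `distance_config(metric = "cvm")` and recorded in the result object.
* Per-subject logits are **averaged across the CV models** before scaling
  (the `per_model = TRUE` option pools instead); with ideal simulated
  logits both give the same optimum up to noise.
* Groups enter the objective with equal weight regardless of size; groups
  with fewer than `min_members` (default 10) subjects are dropped, and a
  single-group fit only warns, since the scale is still identifiable from
  one group.
* For samples above 500 points the KDE is evaluated with the FFT-binned
  estimator; a test pins it against a direct Gaussian-kernel evaluation.

The fit is scaling-equivariant ($\hat\lambda(cu) = \hat\lambda(u)/c$) by
construction, and recovers the generator's true scales 0.79 / 0.22 within
10% (median over seeds) at 20,000 subjects with noise 0.3 — both properties
are asserted in the acceptance tests at exactly those scales.

## Classifier and training protocol

The training protocol mirrors full-scale screening practice: centre-crop to the largest
shared square, bilinear resize (256 px for real-scale inputs), augmentation
by ±5° rotation then integer shifts of at most `round(0.05 × side)` pixels
(13 at side 256 — the round-half-up convention reproduces the documented
13 where plain truncation would give 12), 10-fold cross-validation with a
held-out rechecked set, ADAM, and the multi-target loss = sum of the two
per-finding BCE-with-logits terms (numerically stable form; a test pins it
to the naive formula to $10^{-9}$).

The default backend is a deliberately small convolutional network — three
3×3 conv blocks (8/16/32 channels, ReLU, 2×2 mean-pooling after the first
two), global average pooling, and a dense head with one logit per finding —
written directly in vectorised R (im2col convolutions, manual backprop,
verified against finite differences during development). Inputs are
centred by their per-image mean before entering the network; with
small-sample training this conditioning step is the difference between
reliable and erratic optimisation. Any other model can plug in through the
backend contract (`fit`, `predict_logits`, `feature_maps_and_grads`).
Batch size defaults to 64 and training is single-threaded and fully
deterministic given the seed.

Two scale regimes matter:

* **Full protocol** (reference): learning rate $10^{-4}$, 5 epochs —
  appropriate for ~75,000 training images (~5,800 ADAM steps).
* **Desk scale** (what the tests run): ~2,000 images, 32×32 pixels,
  5 epochs ≈ 130 steps. Because ADAM's update magnitude is bounded by the
  learning rate, total parameter movement scales with rate × steps, so the
  desk-scale runs use $10^{-2}$–$2\times10^{-2}$. The property checked at
  this scale is held-out ensemble AUC ≥ 0.9 per finding on the separable
  configuration (steep link, enriched positives), under the full 10-fold
  protocol.

Grad-CAM weights each final-layer feature map by the spatial mean of the
logit's gradient and ReLUs the weighted sum; with a GAP head the gradient
is constant per map and equals the dense weight over the map area, making
the toy-model test analytic. One empirical caveat the tests encode: an
under-trained head on heavily imbalanced data can express finding evidence
entirely through *negative* channel weights, leaving an empty (all-zero)
CAM; the trained-saliency check therefore runs on a balanced synthetic
cohort, where the apex band receives the overwhelming share of saliency
mass.

`compute_metrics()` implements AUC as the midrank Mann–Whitney statistic
(ties count ½) with F1/precision/recall/specificity/accuracy at a fixed 0.5
threshold (0.5 by convention; it is a declared default, not a fitted
quantity). Empty positive predictions define precision as 0 with a
warning rather than NaN. The tests compare against a brute-force
pair-counting oracle on every label pattern of size ≤ 8, with and without
ties.

## Evaluation statistics

Group means are computed on the calibrated probabilities $p^\star$ by
default (raw outputs are one argument away); the spread uses the sample
(n−1) SD convention. The headline statistic is the Pearson correlation
between the six group means and the six expected posteriors — Pearson,
because the claim is proportional tracking of six paired values, and the
pairs are matched by group label so the statistic is invariant to row
order. Empty groups are flagged, excluded, and at least three populated
groups are required. Cohen's κ uses the standard two-rater binary form;
model-side variability is the Pearson correlation of held-out logits for
each of the $K(K-1)/2$ model pairs, optionally stratified by second-stage
outcome.

## Scales, tolerances and degenerate inputs

The suite's problem sizes are chosen so the whole run stays in the
minutes range on one CPU: exact posterior identities at machine precision;
density normalisations at $10^{-10}$ (probability space) and $10^{-8}$
(logit space, integrating over [−40, 40]); generator frequency checks at
n = 50,000–200,000 within 3–4 standard errors; λ recovery at n = 20,000
over 10 seeds; the end-to-end ideal-logit pipeline at n = 10,000; CNN
training at n = 2,000, 32×32. Degenerate inputs fail loudly and early:
λ ≤ 0, empty samples, single-class AUC, degenerate κ marginals,
inconsistent annotation rows (with line numbers), incomplete prediction
grids (with the offending cell named), and n_subjects = 0 before any
training.

## Known limitations

* The uniform prior is assumed, not estimated; under a non-uniform latent
  population the six expectations are not the group-conditional truth.
* Exactly 2 + 2 exchangeable readers; no per-reader sensitivity model.
* The λ family is a pure scale (no offset); affine temperature-style
  calibration is out of scope.
* The pure-R backend is adequate for desk-scale experiments only, and toy
  images are not radiographs: published real-data performance figures for
  these findings are reference points, not reproduction targets, for
  everything downstream of the posterior table.
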