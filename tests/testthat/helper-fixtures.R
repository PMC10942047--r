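# Shared fixtures, all generated in code under fixed seeds.

# Cohort with uniform latent probability: the regime in which the groups'
# conditional distributions equal the uniform-prior posteriors.
make_uniform_cohort <- function(n, seed = 101L) {
  config <- sim_config(n_subjects = n, latent = "uniform")
  truth <- sample_subjects(config, seed = seed)
  annotations <- simulate_annotations(truth, seed = seed + 1L)
  list(config = config, truth = truth, annotations = annotations,
       groups = group_assignments(annotations))
}

# Strongly separable imaging cohort: steep severity-to-probability link
# so the merged screening label is essentially deterministic in severity,
# and enriched mixture weight so both classes are well represented.
separable_sim_config <- function(n) {
  sim_config(n_subjects = n, mixture_weight = c(0.3, 0.3),
             link_slope = c(50, 50))
}

# Brute-force AUC: fraction of concordant positive-negative pairs, ties
# counted 1/2.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Cohen's kappa straight from its definition on a 2x2 table.
kappa_by_definition <- function(a, b, c, d) {
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}
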