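test_that("stage likelihoods follow the Bernoulli reader model", {
  expect_equal(stage_likelihood("first", "P", 0.5), 0.75)
  expect_equal(stage_likelihood("first", "N", 0), 1.0)
  # union rule: P is the complement of both readers negative
  x <- seq(0, 1, by = 0.1)
  expect_equal(stage_likelihood("first", "P", x), 1 - (1 - x)^2)
  # discordant second stage: enumerate the 4 ordered reader outcomes
  p <- 0.5
  ordered_pn <- p * (1 - p) + (1 - p) * p
  expect_equal(stage_likelihood("second", "PN", p), ordered_pn)
  expect_equal(stage_likelihood("second", "PN", 0.5), 0.5)
  # outcome/stage mismatches are rejected
  expect_error(stage_likelihood("first", "PP", 0.5), "not valid")
  expect_error(stage_likelihood("second", "P", 0.5), "not valid")
})

test_that("group likelihood is the product of the stage likelihoods", {
  expect_equal(group_likelihood("P,PP", 0.5), 0.1875)
  expect_equal(group_likelihood("N,NN", 0), 1.0)
  expect_equal(group_likelihood("P,PP", 0), 0.0)
  x <- seq(0, 1, length.out = 21)
  for (g in diagnosis_groups()$group) {
    parts <- strsplit(g, ",")[[1]]
    expect_equal(group_likelihood(g, x),
                 stage_likelihood("first", parts[1], x) *
                   stage_likelihood("second", parts[2], x))
    expect_true(all(group_likelihood(g, x) >= 0))
  }
  expect_error(group_likelihood("Q,PP", 0.5), "unknown")
})

test_that("posterior densities are correctly normalised", {
  expect_equal(posterior_density("P,PP", 0.5), 0.625)
  expect_equal(posterior_density("N,NN", 0), 5.0)
  for (g in diagnosis_groups()$group) {
    mass <- stats::integrate(function(x) posterior_density(g, x), 0, 1,
                             rel.tol = 1e-12)$value
    expect_equal(mass, 1, tolerance = 1e-10)
  }
})

test_that("logit-space density is the change of variables of the posterior", {
  expect_equal(posterior_logit_density("P,PP", 0), 0.15625)
  for (g in diagnosis_groups()$group) {
    expect_lt(posterior_logit_density(g, 30), 1e-9)
    expect_lt(posterior_logit_density(g, -30), 1e-9)
    mass <- stats::integrate(function(u) posterior_logit_density(g, u),
                             -40, 40, rel.tol = 1e-10)$value
    expect_equal(mass, 1, tolerance = 1e-8)
  }
  # identity holds pointwise at random logits
  set.seed(7)
  u <- stats::runif(100, -8, 8)
  for (g in diagnosis_groups()$group) {
    s <- sigmoid(u)
    expect_equal(posterior_logit_density(g, u),
                 posterior_density(g, s) * s * (1 - s))
  }
})

test_that("expected posteriors match the numeric quadrature oracle exactly", {
  for (g in diagnosis_groups()$group) {
    num <- stats::integrate(function(x) x * group_likelihood(g, x), 0, 1,
                            rel.tol = 1e-13)$value
    den <- stats::integrate(function(x) group_likelihood(g, x), 0, 1,
                            rel.tol = 1e-13)$value
    expect_equal(expected_posterior(g), num / den, tolerance = 1e-12)
  }
})

test_that("the six expected posteriors take their exact rational values", {
  expect_identical(expected_posterior("P,PP", exact = TRUE),
                   list(num = 7, den = 9))
  expect_identical(expected_posterior("N,PP", exact = TRUE),
                   list(num = 1, den = 2))
  expect_identical(expected_posterior("N,NN", exact = TRUE),
                   list(num = 1, den = 6))
  tbl <- posterior_table()
  expect_equal(tbl$expectation_num / tbl$expectation_den,
               c(7 / 9, 4 / 7, 3 / 8, 1 / 2, 1 / 3, 1 / 6))
  expect_identical(tbl$expectation_frac,
                   c("7/9", "4/7", "3/8", "1/2", "1/3", "1/6"))
  expect_identical(tbl$normalizer_frac[tbl$group == "P,PP"], "10/3")
})

test_that("expectations are monotone in the evidence within each stage", {
  e <- function(g) expected_posterior(g)
  # fixed second stage: positive first stage dominates
  for (s in c("PP", "PN", "NN")) {
    expect_gt(e(paste0("P,", s)), e(paste0("N,", s)))
  }
  # fixed first stage: more second-stage positives dominate
  for (f in c("P", "N")) {
    expect_gt(e(paste0(f, ",PP")), e(paste0(f, ",PN")))
    expect_gt(e(paste0(f, ",PN")), e(paste0(f, ",NN")))
  }
  # but no total order across stages
  expect_lt(e("P,NN"), e("N,PP"))
})
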