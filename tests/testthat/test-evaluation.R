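test_that("group assignment recomputes groups from calls", {
  ann <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    finding = "f",
    merged_stage1 = c("P", "P", "N"),
    r1_stage2 = c(1L, 0L, 0L),
    r2_stage2 = c(0L, 1L, 0L)
  )
  g <- group_assignments(ann)
  # discordant second stage is unordered: (P,N) and (N,P) land together
  expect_equal(g$group, c("P,PN", "P,PN", "N,NN"))
  # partition: one group per subject and finding
  cohort <- make_uniform_cohort(2000L, seed = 81)
  expect_equal(nrow(cohort$groups), nrow(cohort$annotations))
  sizes <- table(cohort$groups$finding)
  expect_true(all(sizes == 2000))
  # missing stage information is a record-level error naming the subject
  ann$r1_stage2[2] <- NA
  expect_error(group_assignments(ann), "subject\\(s\\): b")
})

test_that("group statistics summarise outputs per group without fabrication", {
  groups <- tibble::tibble(
    subject_id = c("a", "b", "c", "d"),
    finding = "f",
    group = c("P,PP", "P,PP", "N,NN", "N,NN")
  )
  outputs <- tibble::tibble(subject_id = c("a", "b", "c", "d"),
                            p_star = c(0.2, 0.6, 0.4, 0.4))
  st <- group_statistics(outputs, groups)
  expect_equal(nrow(st), 6L)  # all groups present, empty ones flagged
  ppp <- st[st$group == "P,PP", ]
  expect_equal(ppp$mean, 0.4)
  expect_equal(ppp$sd, sd(c(0.2, 0.6)))  # sample convention
  pop <- group_statistics(outputs, groups, sd_type = "population")
  expect_equal(pop$sd[pop$group == "P,PP"], 0.2)
  nn <- st[st$group == "N,NN", ]
  expect_equal(nn$mean, 0.4)
  expect_equal(nn$sd, 0)
  empty <- st[st$group == "P,PN", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$mean))
  # constant output gives zero spread everywhere populated
  const <- dplyr::mutate(outputs, p_star = 0.4)
  stc <- group_statistics(const, groups)
  expect_true(all(stc$mean[stc$n > 0] == 0.4))
})

test_that("posterior correlation hits +/-1 on exact and reversed means", {
  tbl <- posterior_table()
  st <- tibble::tibble(group = tbl$group, n = 10L, mean = tbl$expectation,
                       sd = 0.1, expected = tbl$expectation)
  expect_equal(posterior_correlation(st), 1)
  st$mean <- 1 - tbl$expectation
  expect_equal(posterior_correlation(st), -1)
  # invariant to row order: pairs are matched by group, not position
  expect_equal(posterior_correlation(st[sample(6), ]), -1)
  expect_error(posterior_correlation(st[1:2, ]), "at least 3")
  st$mean <- 0.5
  expect_error(posterior_correlation(st), "zero variance")
})

test_that("cv output correlations cover all model pairs", {
  # 3 models x 4 subjects, hand-checkable
  logits <- c(1, 2, 3, 4)
  pred <- tibble::tibble(
    subject_id = rep(letters[1:4], 3),
    finding = "f",
    model_index = rep(1:3, each = 4),
    logit = c(logits, 2 * logits, c(4, 3, 2, 1))
  )
  cc <- cv_output_correlations(pred)
  expect_equal(nrow(cc$pairs), 3L)  # 3 * 2 / 2 pairs
  r12 <- cc$pairs$r[cc$pairs$model_a == 1 & cc$pairs$model_b == 2]
  expect_equal(r12, 1)
  r13 <- cc$pairs$r[cc$pairs$model_a == 1 & cc$pairs$model_b == 3]
  expect_equal(r13, cor(logits, c(4, 3, 2, 1)))
  # identical models: every pair correlates perfectly with zero spread
  pred10 <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:20),
                               finding = "f", model_index = 1:10)
  pred10$logit <- rep(rnorm(20), each = 1)[
    match(pred10$subject_id, sprintf("s%02d", 1:20))]
  cc10 <- cv_output_correlations(pred10)
  expect_equal(nrow(cc10$pairs), 45L)
  expect_true(all(abs(cc10$pairs$r - 1) < 1e-12))
  expect_equal(cc10$summary$sd_r, 0, tolerance = 1e-12)
})

test_that("cv correlations can be stratified by second-stage outcome", {
  cohort <- make_uniform_cohort(1000L, seed = 83)
  lg <- simulate_logits(cohort$truth, lambda_true = 0.5, sigma = 0.4,
                        seed = 84, model_index = 1:3)
  cc <- cv_output_correlations(lg, cohort$groups)
  expect_setequal(unique(cc$summary$stratum), c("all", "PP", "PN", "NN"))
  expect_true(all(cc$pairs$r <= 1 & cc$pairs$r >= -1))
})

test_that("Cohen's kappa matches its definition on all small tables", {
  expect_equal(cohens_kappa(matrix(c(25, 0, 0, 25), 2)), 1)
  expect_equal(cohens_kappa(matrix(c(40, 10, 10, 40), 2, byrow = TRUE)), 0.6)
  for (n in 1:6) {
    for (a in 0:n) for (b in 0:(n - a)) for (c_ in 0:(n - a - b)) {
      d <- n - a - b - c_
      tab <- matrix(c(a, b, c_, d), 2, 2, byrow = TRUE)
      oracle <- kappa_by_definition(a, b, c_, d)
      if (is.na(oracle)) {
        expect_error(cohens_kappa(tab), "degenerate|empty")
      } else {
        expect_equal(cohens_kappa(tab), oracle)
      }
    }
  }
})

test_that("independent raters give near-zero kappa", {
  set.seed(85)
  r1 <- rbinom(100000, 1, 0.3)
  r2 <- rbinom(100000, 1, 0.6)
  tab <- agreement_table(r1, r2)
  expect_equal(sum(tab), 100000)
  expect_lt(abs(cohens_kappa(tab)), 0.01)
})

test_that("group-means plot is a ggplot with the populated groups", {
  cohort <- make_uniform_cohort(2000L, seed = 86)
  lg <- simulate_logits(cohort$truth, lambda_true = 1, sigma = 0.2,
                        seed = 87)
  f <- "scoliosis"
  scaled <- scale_outputs(lg[lg$finding == f, ], lambda = 1)
  st <- group_statistics(scaled, cohort$groups[cohort$groups$finding == f, ])
  expect_s3_class(plot_group_means(st, f), "ggplot")
})
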