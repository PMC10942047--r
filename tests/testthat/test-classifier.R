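test_that("preprocess crops centrally and resizes to the target side", {
  img <- matrix(runif(120 * 100), 120, 100)
  out <- preprocess(img, crop_side = 96, out_side = 32)
  expect_equal(dim(out), c(32L, 32L))
  expect_true(all(out >= 0 & out <= 1))
  # constant image stays constant at the same value
  const <- matrix(0.4, 64, 64)
  expect_equal(preprocess(const, crop_side = 64, out_side = 32),
               matrix(0.4, 32, 32))
  # an image smaller than the crop is rejected
  expect_error(preprocess(matrix(0, 50, 50), crop_side = 96, out_side = 32),
               "smaller than the crop")
  # crop happens before resize: off-centre content outside the crop is lost
  big <- matrix(0, 100, 100)
  big[1, 1] <- 1          # corner pixel, outside the central 64x64 crop
  out <- preprocess(big, crop_side = 64, out_side = 64)
  expect_equal(max(out), 0)
})

test_that("augmentation draws stay inside the policy bounds", {
  pol <- augment_policy()
  expect_equal(max_shift(pol, 256), 13L)  # 5% of 256 rounds half-up to 13
  expect_equal(max_shift(pol, 64), 3L)
  pars <- augment_params(pol, 256, n = 10000, seed = 42)
  expect_lte(max(abs(pars$shift_x)), 13)
  expect_lte(max(abs(pars$shift_y)), 13)
  expect_true(all(pars$angle > -5 & pars$angle < 5))
  # null policy is the identity
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(augment(img, augment_policy(0, 0), seed = 1), img)
  # out-of-frame pixels are zero-filled
  shifted <- readerprob:::apply_augment(img, 0, 5, 0)
  expect_true(all(shifted[, 1:5] == 0))
  expect_equal(shifted[, 6:64], img[, 1:59], ignore_attr = TRUE)
})

test_that("multi-target loss equals the sum of per-finding BCE terms", {
  expect_equal(multi_target_loss(c(0, 0), c(0, 0)), 2 * log(2))
  expect_lt(multi_target_loss(c(30, 30), c(1, 1)), 1e-9)
  set.seed(31)
  for (i in 1:20) {
    u <- runif(2, -8, 8)
    y <- rbinom(2, 1, 0.5)
    naive <- -sum(y * log(sigmoid(u)) + (1 - y) * log(1 - sigmoid(u)))
    expect_equal(multi_target_loss(u, y), naive, tolerance = 1e-9)
    expect_equal(multi_target_loss(u, y),
                 multi_target_loss(u[1], y[1]) + multi_target_loss(u[2], y[2]))
  }
})

test_that("cv plan partitions subjects into a test set and balanced folds", {
  ids <- sprintf("S%05d", 1:1100)
  plan <- make_cv_plan(ids, k = 10, test_n = 100, seed = 3)
  expect_length(plan$test_ids, 100)
  expect_length(plan$folds, 10)
  expect_true(all(lengths(plan$folds) == 100))
  all_ids <- c(plan$test_ids, unlist(plan$folds))
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  # uneven split: fold sizes differ by at most one
  plan2 <- make_cv_plan(ids, k = 7, test_n = 101, seed = 3)
  expect_lte(diff(range(lengths(plan2$folds))), 1L)
  expect_identical(make_cv_plan(ids, 10, 100, seed = 3), plan)
  expect_error(make_cv_plan(ids[1:50], test_n = 50), "must be smaller")
})

test_that("metrics match brute-force oracles on exhaustive small instances", {
  expect_equal(
    compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)),
    tibble::tibble(auc = 1, f1 = 1, precision = 1, recall = 1,
                   specificity = 1, accuracy = 1)
  )
  expect_error(compute_metrics(c(0.2, 0.8), c(1, 1)), "single class")
  set.seed(17)
  for (n in 2:8) {
    scores_plain <- runif(n)
    scores_tied <- sample(c(0.2, 0.5, 0.8), n, replace = TRUE)
    for (labs_int in 0:(2^n - 1)) {
      labels <- as.integer(intToBits(labs_int))[1:n]
      if (sum(labels) == 0 || sum(labels) == n) next
      for (scores in list(scores_plain, scores_tied)) {
        m <- suppressWarnings(compute_metrics(scores, labels))
        expect_equal(m$auc, pairwise_auc(scores, labels))
        pred <- as.integer(scores >= 0.5)
        expect_equal(m$accuracy, mean(pred == labels))
        expect_equal(m$recall, sum(pred & labels) / sum(labels))
        expect_equal(m$specificity,
                     sum(!pred & !labels) / sum(labels == 0))
      }
    }
  }
})

test_that("a random 50-point instance matches the pair-counting oracle", {
  set.seed(23)
  scores <- round(runif(50), 1)  # forces ties
  labels <- rbinom(50, 1, 0.4)
  expect_equal(compute_metrics(scores, labels)$auc,
               pairwise_auc(scores, labels))
})

test_that("training is deterministic and the loss descends", {
  cfg <- separable_sim_config(120)
  truth <- sample_subjects(cfg, seed = 41)
  ann <- simulate_annotations(truth, seed = 42)
  imgs <- render_images(truth, image_config(side = 32), seed = 43)
  labels <- labels_from_annotations(ann)
  plan <- make_cv_plan(names(imgs), k = 2, test_n = 20, seed = 44)
  tc <- train_config(learning_rate = 1e-2, epochs = 3, batch_size = 32,
                     seed = 45)
  fit1 <- train_and_predict(imgs, labels, plan, tc)
  fit2 <- train_and_predict(imgs, labels, plan, tc)
  expect_identical(fit1$predictions, fit2$predictions)
  # every test subject carries one logit per model and finding
  counts <- table(fit1$predictions$subject_id)
  expect_true(all(counts == 2 * 2))
  expect_setequal(unique(fit1$predictions$subject_id), plan$test_ids)
  expect_true(all(is.finite(fit1$predictions$logit)))
  # optimisation makes progress on the training loss
  hist <- fit1$models[[1]]$history
  expect_lt(hist[length(hist)], hist[1])
})

test_that("grad_cam reduces to the ReLU of the map for a mean-logit toy model", {
  set.seed(51)
  map1 <- matrix(rnorm(16), 4, 4)
  map2 <- matrix(rnorm(16), 4, 4)
  toy_backend <- list(
    feature_maps_and_grads = function(model, image, finding) {
      # logit = mean(map1): gradient is 1/16 on map 1, zero on map 2
      list(maps = array(c(map1, map2), c(4, 4, 2)),
           grads = array(c(matrix(1 / 16, 4, 4), matrix(0, 4, 4)),
                         c(4, 4, 2)))
    }
  )
  model <- structure(list(backend = toy_backend), class = "rp_model")
  heat <- grad_cam(model, matrix(0, 4, 4), finding = 1)
  expected <- pmax(map1, 0) / 16
  expected <- expected / max(expected)
  expect_equal(heat, expected)
  expect_true(all(heat >= 0 & heat <= 1))
  # backend without feature-map access is unsupported
  bare <- structure(list(backend = list(name = "none")), class = "rp_model")
  expect_error(grad_cam(bare, matrix(0, 4, 4)), "unsupported")
})

test_that("grad_cam on a trained model highlights the apical band", {
  # balanced classes so the head learns positive finding evidence
  cfg <- sim_config(n_subjects = 1000, mixture_weight = c(0.65, 0.65),
                    link_slope = c(50, 50))
  truth <- sample_subjects(cfg, seed = 61)
  ann <- simulate_annotations(truth, seed = 62)
  imgs <- render_images(truth, image_config(side = 32), seed = 63)
  labels <- labels_from_annotations(ann)
  wide <- tidyr::pivot_wider(labels, names_from = "finding",
                             values_from = "label")
  y <- as.matrix(wide[, -1])
  backend <- cnn_backend()
  model <- backend$fit(imgs, y,
                       train_config(learning_rate = 2e-2, epochs = 8,
                                    batch_size = 64, seed = 64,
                                    augment = FALSE))
  # pick a high-severity finding-1 subject
  sev <- subset(truth, finding == "pleural_thickening")
  id <- sev$subject_id[which.max(sev$severity)]
  heat <- grad_cam(model, imgs[[id]], finding = 1)
  expect_true(all(heat >= 0 & heat <= 1))
  apex <- 1:5  # top 15% of 32 rows
  apex_share <- sum(heat[apex, ]) / sum(heat)
  expect_gt(apex_share, length(apex) / 32)
})
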