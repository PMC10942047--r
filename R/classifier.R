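#' Centre-crop and resize a grayscale image
#'
#' Reproduces the standard preprocessing of screening radiographs: a
#' centred square crop of the largest shared side (3000 px for the full
#' protocol), bilinear resize to the model input side (256 px), and
#' intensity rescaling to `[0, 1]`.
#'
#' @param image Numeric matrix (grayscale, any range).
#' @param crop_side Side of the centred square crop; both image sides must
#'   be at least this.
#' @param out_side Output side length after resizing.
#' @return A `out_side x out_side` matrix with intensities in `[0, 1]`.
#' @export
preprocess <- function(image, crop_side = 3000L, out_side = 256L) {
  stopifnot(is.matrix(image))
  if (nrow(image) < crop_side || ncol(image) < crop_side) {
    stop("image (", nrow(image), "x", ncol(image),
         ") is smaller than the crop side ", crop_side, call. = FALSE)
  }
  r0 <- floor((nrow(image) - crop_side) / 2)
  c0 <- floor((ncol(image) - crop_side) / 2)
  crop <- image[r0 + seq_len(crop_side), c0 + seq_len(crop_side),
                drop = FALSE]
  out <- if (crop_side == out_side) crop else resize_bilinear(crop, out_side)
  # integer-range inputs (8/16-bit) are brought into [0,1]; inputs already
  # in [0,1] pass through unchanged
  mx <- max(out)
  if (mx > 1) out <- out / mx
  pmin(pmax(out, 0), 1)
}

#' Augmentation policy
#'
#' Random shift of at most 5% of the side per axis (13 px at side 256) and
#' rotation within (-5, 5) degrees, bilinear interpolation, zero fill —
#' the augmentation used when training the classifier.
#'
#' @param shift_fraction Maximum shift as a fraction of the side.
#' @param rotation_limit Rotation limit in degrees (uniform in +/- limit).
#' @return A list of class `augment_policy`.
#' @export
augment_policy <- function(shift_fraction = 0.05, rotation_limit = 5) {
  stopifnot(shift_fraction >= 0, rotation_limit >= 0)
  structure(list(shift_fraction = shift_fraction,
                 rotation_limit = rotation_limit),
            class = "augment_policy")
}

#' Maximum integer shift for a policy at a given image side
#'
#' Round-half-up of `shift_fraction * side`, so side 256 gives 13.
#'
#' @param policy An [augment_policy()].
#' @param side Image side in pixels.
#' @return Integer maximum absolute shift per axis.
#' @export
max_shift <- function(policy, side) as.integer(floor(policy$shift_fraction * side + 0.5))

#' Draw augmentation parameters
#'
#' @param policy An [augment_policy()].
#' @param side Image side.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Tibble with `angle` (degrees), `shift_x`, `shift_y` (pixels).
#' @export
augment_params <- function(policy, side, n = 1L, seed = 1L) {
  m <- max_shift(policy, side)
  withr::with_seed(seed, {
    tibble::tibble(
      angle   = stats::runif(n, -policy$rotation_limit, policy$rotation_limit),
      shift_x = sample(seq(-m, m), n, replace = TRUE),
      shift_y = sample(seq(-m, m), n, replace = TRUE)
    )
  })
}

# Apply one random augmentation using the current RNG stream (training path).
augment_once <- function(image, policy) {
  side <- nrow(image)
  m <- max_shift(policy, side)
  angle <- stats::runif(1L, -policy$rotation_limit, policy$rotation_limit)
  sx <- sample.int(2L * m + 1L, 1L) - m - 1L
  sy <- sample.int(2L * m + 1L, 1L) - m - 1L
  apply_augment(image, angle, sx, sy)
}

#' Randomly augment an image (rotation then shift)
#'
#' Rotation by an angle uniform in the policy's limit about the image
#' centre (bilinear interpolation), followed by an integer pixel shift
#' uniform in `{-m, ..., m}` per axis with `m = ` [max_shift()];
#' out-of-frame pixels are filled with 0.
#'
#' @param image Square numeric matrix.
#' @param policy An [augment_policy()].
#' @param seed Integer seed.
#' @return Augmented matrix of the same size.
#' @export
augment <- function(image, policy = augment_policy(), seed = 1L) {
  stopifnot(is.matrix(image), nrow(image) == ncol(image))
  pars <- augment_params(policy, nrow(image), 1L, seed)
  apply_augment(image, pars$angle, pars$shift_x, pars$shift_y)
}

# Deterministic rotation + shift with zero fill.
apply_augment <- function(image, angle, shift_x, shift_y) {
  side <- nrow(image)
  out <- image
  if (angle != 0) {
    th <- angle * pi / 180
    ctr <- (side + 1) / 2
    # inverse map: for each output pixel, sample the input at -angle
    xs <- matrix(seq_len(side), side, side, byrow = TRUE) - ctr
    ys <- matrix(seq_len(side), side, side) - ctr
    sx <- cos(th) * xs + sin(th) * ys + ctr
    sy <- -sin(th) * xs + cos(th) * ys + ctr
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0;  fy <- sy - y0
    val <- function(yy, xx) {
      ok <- yy >= 1 & yy <= side & xx >= 1 & xx <= side
      v <- numeric(length(yy))
      v[ok] <- image[cbind(yy[ok], xx[ok])]
      v
    }
    v <- (1 - fy) * ((1 - fx) * val(y0, x0) + fx * val(y0, x0 + 1)) +
      fy * ((1 - fx) * val(y0 + 1, x0) + fx * val(y0 + 1, x0 + 1))
    out <- matrix(v, side, side)
  }
  if (shift_x != 0 || shift_y != 0) {
    shifted <- matrix(0, side, side)
    src_r <- seq_len(side) - shift_y
    src_c <- seq_len(side) - shift_x
    ok_r <- src_r >= 1 & src_r <= side
    ok_c <- src_c >= 1 & src_c <= side
    shifted[which(ok_r), which(ok_c)] <- out[src_r[ok_r], src_c[ok_c]]
    out <- shifted
  }
  out
}

#' Training configuration
#'
#' ADAM with initial learning rate `1e-4` and 5 epochs mirrors the full
#' training protocol; scaled-down runs typically raise the rate and lower
#' the epochs.
#'
#' @param learning_rate ADAM learning rate.
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling init and batch order.
#' @param augment Apply the augmentation policy during training?
#' @param policy An [augment_policy()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 5L, batch_size = 64L,
                         seed = 1L, augment = TRUE,
                         policy = augment_policy()) {
  stopifnot(learning_rate > 0, epochs >= 1)
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 augment = augment, policy = policy),
            class = "train_config")
}

#' Multi-target binary cross-entropy with logits
#'
#' Sum over findings of the numerically stable BCE-with-logits
#' \eqn{\max(u,0) - u y + \log(1 + e^{-|u|})}; the loss the multi-target
#' classifier head is trained with.
#'
#' @param logits Numeric vector, one logit per finding.
#' @param labels Binary vector of the same length.
#' @return Non-negative scalar.
#' @examples
#' multi_target_loss(c(0, 0), c(0, 0)) # 2 log 2
#' @export
multi_target_loss <- function(logits, labels) {
  stopifnot(length(logits) == length(labels), all(is.finite(logits)),
            all(labels %in% c(0, 1)))
  sum(pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits))))
}

#' Cross-validation plan with a held-out test set
#'
#' Randomly sets aside `test_n` subjects, then partitions the remainder
#' into `k` folds whose sizes differ by at most one. Each fold's
#' complement trains one model; all `k` models predict the held-out set.
#'
#' @param subject_ids Character vector of subject ids.
#' @param k Number of folds.
#' @param test_n Held-out test-set size (must be < number of subjects).
#' @param seed Integer seed.
#' @return A list of class `cv_plan` with `test_ids` and `folds` (list of
#'   `k` character vectors).
#' @export
make_cv_plan <- function(subject_ids, k = 10L, test_n = 1000L, seed = 1L) {
  n <- length(subject_ids)
  if (test_n >= n) {
    stop("test_n (", test_n, ") must be smaller than the number of subjects (",
         n, ")", call. = FALSE)
  }
  stopifnot(k >= 2, !anyDuplicated(subject_ids))
  withr::with_seed(seed, {
    shuffled <- sample(subject_ids)
    test_ids <- shuffled[seq_len(test_n)]
    rest <- shuffled[-seq_len(test_n)]
    folds <- split(rest, rep_len(seq_len(k), length(rest)))
  })
  structure(list(test_ids = test_ids, folds = unname(folds),
                 k = as.integer(k), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Per-finding binary labels from annotation records
#'
#' Training labels are the merged first-stage screening calls.
#'
#' @param annotations Tibble from [simulate_annotations()] or
#'   [read_annotations()].
#' @return Tibble `subject_id`, `finding`, `label` (0/1).
#' @export
labels_from_annotations <- function(annotations) {
  tibble::tibble(
    subject_id = annotations$subject_id,
    finding    = annotations$finding,
    label      = as.integer(annotations$merged_stage1 == "P")
  )
}

#' Train the cross-validation ensemble and predict the held-out set
#'
#' For each fold of the plan a fresh model is trained on the other
#' `k - 1` folds and predicts logits for every held-out test subject,
#' yielding the `subject x model x finding` prediction grid used by
#' calibration and the model-variability analyses.
#'
#' @param images Named list of grayscale matrices (names = subject ids).
#' @param labels Tibble `subject_id`, `finding`, `label` (see
#'   [labels_from_annotations()]).
#' @param plan A [make_cv_plan()].
#' @param config A [train_config()].
#' @param backend A backend such as [cnn_backend()].
#' @return A list of class `cv_training`: `predictions` (tibble
#'   `subject_id`, `finding`, `model_index`, `logit`), `models` (list of
#'   `k` fitted models) and `findings`.
#' @export
train_and_predict <- function(images, labels, plan, config = train_config(),
                              backend = cnn_backend()) {
  stopifnot(inherits(plan, "cv_plan"), inherits(config, "train_config"))
  findings <- unique(labels$finding)
  lab_wide <- labels |>
    tidyr::pivot_wider(names_from = "finding", values_from = "label") |>
    as.data.frame()
  rownames(lab_wide) <- lab_wide$subject_id
  test_images <- images[plan$test_ids]
  models <- vector("list", plan$k)
  preds <- vector("list", plan$k)
  for (m in seq_len(plan$k)) {
    train_ids <- unlist(plan$folds[-m], use.names = FALSE)
    y <- as.matrix(lab_wide[train_ids, findings, drop = FALSE])
    cfg <- config
    cfg$seed <- config$seed + m  # fresh init per CV model
    model <- tryCatch(
      backend$fit(images[train_ids], y, cfg),
      error = function(e) {
        stop("backend training failed in fold ", m, ": ",
             conditionMessage(e), call. = FALSE)
      }
    )
    models[[m]] <- model
    u <- backend$predict_logits(model, test_images)
    preds[[m]] <- tibble::tibble(
      subject_id  = rep(plan$test_ids, times = length(findings)),
      finding     = rep(findings, each = length(plan$test_ids)),
      model_index = m,
      logit       = as.vector(u)
    )
  }
  structure(list(predictions = dplyr::bind_rows(preds), models = models,
                 findings = findings),
            class = "cv_training")
}

#' Standard binary classification metrics
#'
#' AUC by the Mann-Whitney rank statistic with tie correction, plus F1,
#' precision, recall, specificity and accuracy at a probability/score
#' threshold.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1).
#' @param threshold Decision threshold applied to `scores`.
#' @return One-row tibble with columns `auc`, `f1`, `precision`, `recall`,
#'   `specificity`, `accuracy`.
#' @examples
#' compute_metrics(c(.9, .8, .2, .1), c(1, 1, 0, 0))
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC is undefined: labels contain a single class", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) {
    warning("no positive predictions: precision defined as 0")
    0
  } else tp / (tp + fp)
  recall <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  tibble::tibble(auc = auc, f1 = f1, precision = precision, recall = recall,
                 specificity = specificity, accuracy = (tp + tn) / (n1 + n0))
}

#' Grad-CAM saliency heatmap
#'
#' Channel weights are the spatial means of the gradient of the chosen
#' finding's logit with respect to the last convolutional feature maps;
#' the heatmap is the ReLU of the weighted sum of maps, bilinearly
#' upsampled to the input resolution and max-normalised to 1 (an all-zero
#' map is returned when every weighted sum is negative).
#'
#' @param model A fitted model whose backend exposes
#'   `feature_maps_and_grads` (e.g. from [cnn_backend()]).
#' @param image Input image matrix.
#' @param finding Finding index (column of the logit head).
#' @return A matrix the size of `image` with values in `[0, 1]`.
#' @export
grad_cam <- function(model, image, finding = 1L) {
  backend <- model$backend
  if (is.null(backend$feature_maps_and_grads)) {
    stop("backend does not expose convolutional feature maps; ",
         "Grad-CAM is unsupported", call. = FALSE)
  }
  fg <- backend$feature_maps_and_grads(model, image, finding)
  weights <- apply(fg$grads, 3L, mean)
  cam <- matrix(0, dim(fg$maps)[1L], dim(fg$maps)[2L])
  for (ch in seq_along(weights)) {
    cam <- cam + weights[[ch]] * fg$maps[, , ch]
  }
  cam <- pmax(cam, 0)
  up <- resize_bilinear(cam, nrow(image))
  up <- pmax(up, 0)
  if (max(up) > 0) up <- up / max(up)
  up
}
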