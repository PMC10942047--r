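#' Scale raw classifier logits onto the probability scale
#'
#' The calibrated output is `u* = -lambda * u` and
#' `p* = sigmoid(u*)`: a single positive scale (with a sign flip matching
#' the convention that the raw logit decreases with finding probability)
#' maps raw network logits onto posterior logits.
#'
#' @param logits Tibble with at least `logit` (e.g. a prediction table),
#'   or a bare numeric vector.
#' @param lambda Positive scale.
#' @param sign Either `-1` (default; raw logit decreases with probability)
#'   or `+1` for backends whose positive-class logit already increases
#'   with finding probability.
#' @return The input tibble with columns `u_star` and `p_star` appended
#'   (for a numeric input, a tibble `logit`, `u_star`, `p_star`).
#' @examples
#' scale_outputs(tibble::tibble(logit = c(0, -2.197224)), lambda = 1)
#' @export
scale_outputs <- function(logits, lambda, sign = -1) {
  stopifnot(lambda > 0, sign %in% c(-1, 1))
  if (is.numeric(logits)) logits <- tibble::tibble(logit = logits)
  stopifnot(all(is.finite(logits$logit)))
  logits |>
    dplyr::mutate(u_star = sign * lambda * .data$logit,
                  p_star = sigmoid(.data$u_star))
}

#' Distance configuration for distribution matching
#'
#' The scaled-logit sample is turned into a Gaussian kernel density
#' estimate (Silverman's rule-of-thumb bandwidth) evaluated on a fixed
#' uniform grid, and compared with the analytic posterior logit density.
#' `metric = "l2"` is the Euclidean (L2) distance between the two density
#' curves on the grid; `"cvm"` is the Cramer-von-Mises-style L2 distance
#' between the discretised CDFs.
#'
#' @param grid_min,grid_max Grid end points on the logit scale.
#' @param grid_n Number of grid points (>= 64).
#' @param metric `"l2"` or `"cvm"`.
#' @return A list of class `distance_config`.
#' @export
distance_config <- function(grid_min = -10, grid_max = 10, grid_n = 512L,
                            metric = c("l2", "cvm")) {
  stopifnot(grid_max > grid_min, grid_n >= 64L)
  structure(list(grid_min = grid_min, grid_max = grid_max,
                 grid_n = as.integer(grid_n), metric = match.arg(metric)),
            class = "distance_config")
}

distance_grid <- function(config) {
  seq(config$grid_min, config$grid_max, length.out = config$grid_n)
}

# L2 distance between two curves sampled on a uniform grid.
grid_l2 <- function(f, g, dx) sqrt(sum((f - g)^2) * dx)

#' Distance between scaled logits and a group's posterior logit density
#'
#' Scales the sample by `-lambda`, estimates its density by a Gaussian
#' KDE on the configured grid, and returns the distance to
#' [posterior_logit_density()] of the group.
#'
#' @param logit_sample Numeric vector of raw logits for subjects of the
#'   group (non-empty).
#' @param group Diagnosis group label.
#' @param lambda Positive candidate scale.
#' @param config A [distance_config()].
#' @param sign Logit sign convention, see [scale_outputs()].
#' @return Non-negative scalar distance.
#' @export
distribution_distance <- function(logit_sample, group, lambda,
                                  config = distance_config(), sign = -1) {
  if (length(logit_sample) == 0L) {
    stop("empty logit sample for group ", group, call. = FALSE)
  }
  stopifnot(lambda > 0)
  u_star <- sign * lambda * logit_sample
  grid <- distance_grid(config)
  dx <- grid[2L] - grid[1L]
  kde <- kde_on_grid(u_star, grid)
  target <- posterior_logit_density(group, grid)
  if (config$metric == "l2") {
    grid_l2(kde, target, dx)
  } else {
    grid_l2(cumsum(kde) * dx, cumsum(target) * dx, dx)
  }
}

# Gaussian KDE evaluated on a uniform grid, Silverman bandwidth.
# Large samples go through the FFT-binned estimator; small ones are
# evaluated exactly.
kde_on_grid <- function(x, grid) {
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3
  if (length(x) > 500L) {
    d <- stats::density(x, bw = bw, kernel = "gaussian",
                        from = grid[1L], to = grid[length(grid)],
                        n = length(grid))
    d$y
  } else {
    vapply(grid, function(g) mean(stats::dnorm((g - x) / bw)) / bw,
           numeric(1))
  }
}

#' Fit the logit scale for one finding
#'
#' Groups the evaluated subjects by their diagnosis group, averages each
#' subject's logits across the cross-validation models (default), and
#' finds the `lambda` in `[1e-3, 10]` minimising the unweighted mean of
#' [distribution_distance()] across the available groups (bounded scalar
#' minimisation, tolerance `1e-4`). Groups are weighted equally
#' regardless of size; groups with fewer than `min_members` subjects are
#' dropped, with a warning when fewer than two groups remain usable.
#'
#' @param predictions Tibble `subject_id`, `finding`, `model_index`,
#'   `logit`.
#' @param annotations Tibble with `subject_id`, `finding`, `group`.
#' @param finding Finding name to calibrate.
#' @param config A [distance_config()].
#' @param min_members Minimum group size to enter the objective.
#' @param per_model If `TRUE`, pool all per-model logits instead of
#'   averaging per subject.
#' @param sign Logit sign convention, see [scale_outputs()].
#' @return An object of class `lambda_calibration`: `finding`,
#'   `lambda_hat`, `objective`, `group_distances` (tibble `group`, `n`,
#'   `distance` at the optimum), `config`, `sign`, `per_model`.
#' @export
fit_lambda <- function(predictions, annotations, finding,
                       config = distance_config(), min_members = 10L,
                       per_model = FALSE, sign = -1) {
  stopifnot(inherits(config, "distance_config"))
  pred <- predictions[predictions$finding == finding, ]
  ann <- annotations[annotations$finding == finding, ]
  if (nrow(pred) == 0L) stop("no predictions for finding ", finding)
  if (!per_model) {
    pred <- pred |>
      dplyr::summarise(logit = mean(.data$logit), .by = "subject_id")
  }
  joined <- dplyr::inner_join(pred,
                              ann[, c("subject_id", "group")],
                              by = "subject_id")
  samples <- split(joined$logit, joined$group)
  sizes <- lengths(samples)
  samples <- samples[sizes >= min_members]
  if (length(samples) == 0L) {
    stop("no diagnosis group has at least ", min_members,
         " members for finding ", finding, call. = FALSE)
  }
  if (length(samples) < 2L) {
    warning("only ", length(samples),
            " diagnosis group(s) usable for finding ", finding)
  }
  objective <- function(lambda) {
    mean(vapply(names(samples), function(g) {
      distribution_distance(samples[[g]], g, lambda, config, sign)
    }, numeric(1)))
  }
  opt <- stats::optimize(objective, interval = c(1e-3, 10), tol = 1e-4)
  lambda_hat <- opt$minimum
  dist_tbl <- tibble::tibble(
    group = names(samples),
    n = lengths(samples),
    distance = vapply(names(samples), function(g) {
      distribution_distance(samples[[g]], g, lambda_hat, config, sign)
    }, numeric(1))
  )
  structure(list(finding = finding, lambda_hat = lambda_hat,
                 objective = opt$objective, group_distances = dist_tbl,
                 config = config, sign = sign, per_model = per_model),
            class = "lambda_calibration")
}

#' @export
print.lambda_calibration <- function(x, ...) {
  cat("Logit-scale calibration for finding '", x$finding, "'\n", sep = "")
  cat(sprintf("  lambda_hat = %.4f (mean group distance %.5f, %d groups)\n",
              x$lambda_hat, x$objective, nrow(x$group_distances)))
  invisible(x)
}

#' Tidy a fitted calibration
#'
#' @param x A `lambda_calibration` object.
#' @param ... Unused.
#' @return Tibble of per-group distances at the optimum (`group`, `n`,
#'   `distance`).
#' @export
tidy.lambda_calibration <- function(x, ...) x$group_distances

#' One-row summary of a fitted calibration
#'
#' @param x A `lambda_calibration` object.
#' @param ... Unused.
#' @return One-row tibble: `finding`, `lambda_hat`, `objective`,
#'   `n_groups`, `metric`.
#' @export
glance.lambda_calibration <- function(x, ...) {
  tibble::tibble(finding = x$finding, lambda_hat = x$lambda_hat,
                 objective = x$objective,
                 n_groups = nrow(x$group_distances),
                 metric = x$config$metric)
}

#' @export
autoplot.lambda_calibration <- function(object, ...) {
  ggplot2::ggplot(object$group_distances,
                  ggplot2::aes(x = .data$group, y = .data$distance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("Calibration of '%s': lambda = %.3f",
                      object$finding, object$lambda_hat),
      x = "diagnosis group",
      y = "density distance at optimum"
    ) +
    ggplot2::theme_minimal()
}

#' Generic tidiers
#'
#' `tidy()` returns the per-component table of a fitted object;
#' `glance()` a one-row summary. Methods are provided for
#' `lambda_calibration`.
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
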