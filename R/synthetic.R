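#' Simulation configuration for the synthetic screening cohort
#'
#' Describes the synthetic population the generator draws: per finding, a
#' two-component severity mixture (a large background component with
#' near-zero latent probability and a small affected component whose latent
#' probability spreads over roughly (0.2, 0.95)), a logistic link from
#' severity to the latent reader-positive probability
#' \eqn{p = \sigma(a (s - s_0))}, the true logit scale `lambda_true` used
#' when simulating classifier outputs, and the logit noise sd `sigma`.
#'
#' Default mixture weights are set so the merged first-stage prevalence is
#' about 4.5% for `pleural_thickening` and 1.6% for `scoliosis`, matching
#' the class imbalance typical of these findings in screening cohorts.
#' `latent` switches the latent-probability law: `"mixture"` (default) uses
#' the severity mixture; `"uniform"` draws `p` uniformly on (0, 1), the
#' regime in which annotation groups follow the uniform-prior posterior
#' exactly and calibration is identifiable.
#'
#' @param n_subjects Number of subjects.
#' @param findings Character vector of finding names.
#' @param latent `"mixture"` or `"uniform"`.
#' @param mixture_weight Named (or recycled) affected-component weight per
#'   finding.
#' @param background_meanlog,background_sdlog Lognormal severity parameters
#'   of the background component.
#' @param affected_mean,affected_sd Normal severity parameters of the
#'   affected component.
#' @param link_slope,link_threshold Logistic link parameters `a` and `s0`
#'   per finding.
#' @param sigma Logit noise sd used by [simulate_logits()].
#' @param lambda_true True positive scale per finding used by
#'   [simulate_logits()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1000L,
                       findings = c("pleural_thickening", "scoliosis"),
                       latent = c("mixture", "uniform"),
                       mixture_weight = c(0.0561, 0.0217),
                       background_meanlog = -1.5,
                       background_sdlog = 0.6,
                       affected_mean = c(3.2, 3.4),
                       affected_sd = c(1.0, 1.1),
                       link_slope = c(2.2, 3.5),
                       link_threshold = c(3.0, 3.0),
                       sigma = 0.3,
                       lambda_true = c(0.79, 0.22)) {
  latent <- match.arg(latent)
  k <- length(findings)
  stopifnot(n_subjects >= 0, k >= 1, sigma >= 0, all(lambda_true > 0),
            all(mixture_weight >= 0 & mixture_weight <= 1),
            all(link_slope > 0))
  per <- function(x) stats::setNames(rep_len(x, k), findings)
  structure(list(
    n_subjects         = as.integer(n_subjects),
    findings           = findings,
    latent             = latent,
    mixture_weight     = per(mixture_weight),
    background_meanlog = background_meanlog,
    background_sdlog   = background_sdlog,
    affected_mean      = per(affected_mean),
    affected_sd        = per(affected_sd),
    link_slope         = per(link_slope),
    link_threshold     = per(link_threshold),
    sigma              = sigma,
    lambda_true        = per(lambda_true)
  ), class = "sim_config")
}

#' Draw the synthetic cohort with latent severities and probabilities
#'
#' Severities come from the configured two-component mixture per finding
#' (or, with `latent = "uniform"`, are back-computed from a uniform latent
#' probability through the link); the latent reader-positive probability is
#' `p = sigmoid(a * (s - s0))`. The draw is a pure function of
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `finding`, `affected`
#'   (mixture component indicator), `severity`, `p`.
#' @examples
#' truth <- sample_subjects(sim_config(n_subjects = 100), seed = 1)
#' @export
sample_subjects <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ids <- sprintf("S%06d", seq_len(n))
  out <- withr::with_seed(seed, {
    purrr::map(config$findings, function(f) {
      if (config$latent == "uniform") {
        p <- stats::runif(n)
        s <- config$link_threshold[[f]] + logit(p) / config$link_slope[[f]]
        affected <- rep(TRUE, n)
      } else {
        affected <- stats::runif(n) < config$mixture_weight[[f]]
        s <- numeric(n)
        n_bg <- sum(!affected)
        s[!affected] <- stats::rlnorm(n_bg, config$background_meanlog,
                                      config$background_sdlog)
        s[affected] <- abs(stats::rnorm(sum(affected),
                                        config$affected_mean[[f]],
                                        config$affected_sd[[f]]))
        p <- sigmoid(config$link_slope[[f]] * (s - config$link_threshold[[f]]))
      }
      tibble::tibble(subject_id = ids, finding = f,
                     affected = affected, severity = s, p = p)
    })
  })
  dplyr::bind_rows(out)
}

#' Expected merged first-stage prevalence under a configuration
#'
#' Quadrature over the severity mixture of `1 - (1 - p)^2`, the probability
#' that at least one of the two first-stage readers calls the finding.
#' Serves as the analytic check on the generator's class imbalance.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector, one prevalence per finding.
#' @export
expected_prevalence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vapply(config$findings, function(f) {
    pos <- function(s) {
      p <- sigmoid(config$link_slope[[f]] * (s - config$link_threshold[[f]]))
      1 - (1 - p)^2
    }
    if (config$latent == "uniform") {
      # p ~ U(0,1): E[1-(1-p)^2] = 2/3
      return(2 / 3)
    }
    w <- config$mixture_weight[[f]]
    bg <- stats::integrate(function(s) {
      pos(s) * stats::dlnorm(s, config$background_meanlog,
                             config$background_sdlog)
    }, 0, Inf, rel.tol = 1e-10)$value
    # affected severities are |Normal|, i.e. folded normal
    af <- stats::integrate(function(s) {
      m <- config$affected_mean[[f]]
      sd <- config$affected_sd[[f]]
      pos(s) * (stats::dnorm(s, m, sd) + stats::dnorm(-s, m, sd))
    }, 0, Inf, rel.tol = 1e-10)$value
    (1 - w) * bg + w * af
  }, numeric(1))
}

#' Simulate two-stage reader annotations
#'
#' Four independent Bernoulli(p) reads per subject and finding: two
#' first-stage reads merged by union into the screening call, and two
#' second-stage reads kept individually. The diagnosis group is derived
#' from the calls.
#'
#' @param truth Tibble from [sample_subjects()] (needs `subject_id`,
#'   `finding`, `p`).
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `finding`, `r1_stage1`,
#'   `r2_stage1`, `merged_stage1` (`"P"`/`"N"`), `r1_stage2`, `r2_stage2`,
#'   `group`.
#' @export
simulate_annotations <- function(truth, seed = 1L) {
  stopifnot(all(c("subject_id", "finding", "p") %in% names(truth)),
            all(truth$p >= 0 & truth$p <= 1))
  n <- nrow(truth)
  withr::with_seed(seed, {
    draws <- matrix(stats::rbinom(4L * n, 1L, rep(truth$p, 4L)), ncol = 4L)
    tibble::tibble(
      subject_id    = truth$subject_id,
      finding       = truth$finding,
      r1_stage1     = draws[, 1L],
      r2_stage1     = draws[, 2L],
      merged_stage1 = ifelse(draws[, 1L] | draws[, 2L], "P", "N"),
      r1_stage2     = draws[, 3L],
      r2_stage2     = draws[, 4L]
    ) |>
      dplyr::mutate(group = derive_group(.data$merged_stage1,
                                         .data$r1_stage2, .data$r2_stage2))
  })
}

#' Derive the diagnosis group from reader calls
#'
#' @param merged_stage1 `"P"`/`"N"` merged first-stage call.
#' @param r1_stage2,r2_stage2 Binary second-stage reads (order-free).
#' @return Character vector of group labels such as `"P,PN"`.
#' @export
derive_group <- function(merged_stage1, r1_stage2, r2_stage2) {
  second <- c("NN", "PN", "PP")[r1_stage2 + r2_stage2 + 1L]
  paste(merged_stage1, second, sep = ",")
}

#' Simulate classifier logits consistent with the latent probability
#'
#' Emulates a trained network whose (negated, scaled) output approximates
#' the latent logit: draws `u = -(logit(p) + noise) / lambda_true` with
#' `noise ~ Normal(0, sigma^2)`, so that `-lambda_true * u` recovers
#' `logit(p)` up to the noise. `p` is clamped to `[eps, 1 - eps]`
#' (`eps = 1e-6`) before the logit.
#'
#' @param truth Tibble with `subject_id`, `finding`, `p`.
#' @param lambda_true Positive scale, single value or named per finding.
#' @param sigma Logit noise sd (>= 0).
#' @param seed Integer seed.
#' @param model_index Integer model label(s); one set of logits is drawn
#'   per index, emulating the spread across independently trained
#'   cross-validation models.
#' @return A tibble `subject_id`, `finding`, `model_index`, `logit`.
#' @export
simulate_logits <- function(truth, lambda_true, sigma = 0, seed = 1L,
                            model_index = 1L) {
  stopifnot(all(c("subject_id", "finding", "p") %in% names(truth)),
            sigma >= 0, all(lambda_true > 0))
  eps <- 1e-6
  lam <- if (is.null(names(lambda_true))) {
    stats::setNames(rep_len(lambda_true, length(unique(truth$finding))),
                    unique(truth$finding))
  } else lambda_true
  p <- pmin(pmax(truth$p, eps), 1 - eps)
  base <- logit(p)
  withr::with_seed(seed, {
    purrr::map(as.integer(model_index), function(m) {
      noise <- stats::rnorm(length(base), 0, sigma)
      tibble::tibble(
        subject_id  = truth$subject_id,
        finding     = truth$finding,
        model_index = m,
        logit       = as.numeric(-(base + noise) / lam[truth$finding])
      )
    }) |> dplyr::bind_rows()
  })
}
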