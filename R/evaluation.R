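#' Assign each evaluated subject to its diagnosis group
#'
#' Recomputes the group from the recorded calls (union rule for the first
#' stage, unordered pair for the second), so inconsistent rows cannot slip
#' through.
#'
#' @param annotations Tibble with `subject_id`, `finding`,
#'   `merged_stage1`, `r1_stage2`, `r2_stage2` (missing values are
#'   rejected with the offending subjects named).
#' @return Tibble `subject_id`, `finding`, `group`; each subject appears
#'   in exactly one group per finding.
#' @export
group_assignments <- function(annotations) {
  required <- c("subject_id", "finding", "merged_stage1",
                "r1_stage2", "r2_stage2")
  stopifnot(all(required %in% names(annotations)))
  bad <- annotations[!stats::complete.cases(annotations[required]), ]
  if (nrow(bad) > 0L) {
    stop("records missing stage calls for subject(s): ",
         paste(utils::head(unique(bad$subject_id), 5L), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    subject_id = annotations$subject_id,
    finding    = annotations$finding,
    group      = derive_group(annotations$merged_stage1,
                              annotations$r1_stage2, annotations$r2_stage2)
  )
}

#' Per-group mean and spread of the evaluated output
#'
#' Joins an output table (scaled probabilities by default, raw logits or
#' any per-subject value) with the group assignments and summarises each
#' group. Groups with no members are kept with `n = 0` and `NA`
#' statistics rather than fabricated values.
#'
#' @param outputs Tibble with `subject_id` and the value column.
#' @param groups Tibble from [group_assignments()] (single finding).
#' @param value Name of the value column in `outputs` (default
#'   `"p_star"`).
#' @param sd_type `"sample"` (n-1 denominator, default) or
#'   `"population"`.
#' @return Tibble, one row per diagnosis group in canonical order:
#'   `group`, `n`, `mean`, `sd`, `expected` (the analytic expected
#'   posterior).
#' @export
group_statistics <- function(outputs, groups, value = "p_star",
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(value %in% names(outputs))
  joined <- dplyr::inner_join(
    outputs[, c("subject_id", value)], groups[, c("subject_id", "group")],
    by = "subject_id"
  )
  sd_fun <- if (sd_type == "sample") stats::sd else function(v) {
    sqrt(mean((v - mean(v))^2))
  }
  stats_tbl <- joined |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[value]]),
      sd = if (dplyr::n() > 1L) sd_fun(.data[[value]]) else NA_real_,
      .by = "group"
    )
  posterior_table()[, c("group", "expectation")] |>
    dplyr::rename(expected = "expectation") |>
    dplyr::left_join(stats_tbl, by = "group") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::select("group", "n", "mean", "sd", "expected")
}

#' Correlation between group means and expected posteriors
#'
#' Pearson correlation over the (expected posterior, observed group mean)
#' pairs of the non-empty diagnosis groups — the headline agreement
#' statistic between classifier outputs and the Bayesian reader model.
#'
#' @param stats_tbl Tibble from [group_statistics()].
#' @return Scalar Pearson correlation.
#' @export
posterior_correlation <- function(stats_tbl) {
  ok <- stats_tbl[stats_tbl$n > 0 & !is.na(stats_tbl$mean), ]
  if (nrow(ok) < 3L) {
    stop("need at least 3 non-empty groups for a correlation (have ",
         nrow(ok), ")", call. = FALSE)
  }
  if (stats::sd(ok$mean) == 0 || stats::sd(ok$expected) == 0) {
    stop("correlation undefined: zero variance across groups", call. = FALSE)
  }
  stats::cor(ok$expected, ok$mean)
}

#' Pairwise output correlations across the CV models
#'
#' Pearson correlation of the held-out logits for every pair of
#' cross-validation models (K models give K(K-1)/2 pairs), overall and —
#' when group assignments are supplied — restricted to second-stage
#' outcome strata (`PP`, `PN`, `NN`).
#'
#' @param predictions Tibble `subject_id`, `finding`, `model_index`,
#'   `logit`.
#' @param groups Optional tibble from [group_assignments()]; adds
#'   per-stratum summaries.
#' @return A list with `pairs` (tibble `finding`, `stratum`, `model_a`,
#'   `model_b`, `r`) and `summary` (tibble `finding`, `stratum`,
#'   `n_pairs`, `mean_r`, `sd_r`).
#' @export
cv_output_correlations <- function(predictions, groups = NULL) {
  k <- length(unique(predictions$model_index))
  stopifnot(k >= 2)
  strata <- list(all = NULL)
  if (!is.null(groups)) {
    for (s in c("PP", "PN", "NN")) strata[[s]] <- s
  }
  pairs <- purrr::map(unique(predictions$finding), function(f) {
    pf <- predictions[predictions$finding == f, ]
    purrr::imap(strata, function(second, label) {
      keep <- pf
      if (!is.null(second)) {
        g <- groups[groups$finding == f, ]
        ids <- g$subject_id[endsWith(g$group, second)]
        keep <- pf[pf$subject_id %in% ids, ]
      }
      wide <- keep |>
        tidyr::pivot_wider(names_from = "model_index",
                           values_from = "logit", names_prefix = "m") |>
        dplyr::select(dplyr::starts_with("m"))
      if (nrow(wide) < 3L) return(NULL)
      cm <- stats::cor(as.matrix(wide))
      idx <- which(upper.tri(cm), arr.ind = TRUE)
      tibble::tibble(finding = f, stratum = label,
                     model_a = idx[, 1L], model_b = idx[, 2L],
                     r = cm[idx])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summary <- pairs |>
    dplyr::summarise(n_pairs = dplyr::n(), mean_r = mean(.data$r),
                     sd_r = stats::sd(.data$r),
                     .by = c("finding", "stratum"))
  list(pairs = pairs, summary = summary)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} from
#' a 2x2 contingency table of the two raters' calls.
#'
#' @param table 2x2 matrix of counts: rows = rater 1 (positive first),
#'   columns = rater 2.
#' @return Scalar kappa in `[-1, 1]`.
#' @examples
#' cohens_kappa(matrix(c(40, 10, 10, 40), 2)) # 0.6
#' @export
cohens_kappa <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2L, 2L)),
            all(table >= 0))
  n <- sum(table)
  if (n == 0) stop("empty agreement table", call. = FALSE)
  po <- sum(diag(table)) / n
  pe <- sum(rowSums(table) * colSums(table)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) {
    stop("kappa undefined: degenerate marginals (expected agreement = 1)",
         call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Agreement table between two raters' calls
#'
#' @param rater1,rater2 Binary vectors (0/1) of equal length.
#' @return 2x2 count matrix (positive first on both margins).
#' @export
agreement_table <- function(rater1, rater2) {
  stopifnot(length(rater1) == length(rater2),
            all(rater1 %in% c(0, 1)), all(rater2 %in% c(0, 1)))
  matrix(c(sum(rater1 == 1 & rater2 == 1), sum(rater1 == 1 & rater2 == 0),
           sum(rater1 == 0 & rater2 == 1), sum(rater1 == 0 & rater2 == 0)),
         2L, 2L, byrow = TRUE,
         dimnames = list(rater1 = c("P", "N"), rater2 = c("P", "N")))
}

#' Plot group means against the expected posteriors
#'
#' @param stats_tbl Tibble from [group_statistics()].
#' @param finding Optional finding name for the title.
#' @return A ggplot object: observed group means (with +/- 1 sd bars)
#'   against the analytic expected posterior, with the identity line.
#' @export
plot_group_means <- function(stats_tbl, finding = NULL) {
  ok <- stats_tbl[stats_tbl$n > 0, ]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$expected, y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.02, colour = "grey40", na.rm = TRUE) +
    ggplot2::geom_point(size = 2.5, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$group), vjust = -1,
                       size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(
      title = if (is.null(finding)) "Group means vs expected posterior"
              else paste0("Group means vs expected posterior: ", finding),
      x = "expected posterior probability",
      y = "mean calibrated output"
    ) +
    ggplot2::theme_minimal()
}
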