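#' Diagnosis groups of the two-stage annotation protocol
#'
#' In the screening protocol modelled here, each subject is read twice. In
#' the first stage two physicians read independently and the record is
#' merged to positive (`P`) if either flags the finding; in the second
#' stage two further physicians read blindly and their individual calls are
#' kept, giving `PP`, `PN` (unordered: one positive, one negative) or `NN`.
#' Crossing the merged first-stage call with the second-stage pair yields
#' six diagnosis groups.
#'
#' @return A tibble with columns `group` (label, e.g. `"P,PN"`),
#'   `first_stage` (`"P"`/`"N"`) and `second_stage` (`"PP"`/`"PN"`/`"NN"`),
#'   one row per group, in the conventional order
#'   `(P,PP), (P,PN), (P,NN), (N,PP), (N,PN), (N,NN)`.
#' @examples
#' diagnosis_groups()
#' @export
diagnosis_groups <- function() {
  tibble::tibble(
    first_stage  = rep(c("P", "N"), each = 3L),
    second_stage = rep(c("PP", "PN", "NN"), times = 2L),
    group        = paste(.data$first_stage, .data$second_stage, sep = ",")
  )[, c("group", "first_stage", "second_stage")]
}

group_levels <- function() diagnosis_groups()$group

# Split a "P,PN" label into its two stages, validating both.
parse_group <- function(group) {
  stopifnot(is.character(group), length(group) == 1L)
  if (!group %in% group_levels()) {
    stop("unknown diagnosis group: '", group,
         "' (expected one of ", paste(group_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  parts <- strsplit(group, ",", fixed = TRUE)[[1L]]
  list(first_stage = parts[[1L]], second_stage = parts[[2L]])
}

## ---- exact rational arithmetic (small integers only) -----------------------
## Likelihoods are degree-<=4 polynomials with integer coefficients, so every
## moment is a ratio of small factorials; plain doubles hold these exactly.

frac <- function(num, den) {
  stopifnot(den != 0)
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- frac_gcd(abs(num), den)
  if (g == 0) g <- 1
  list(num = num / g, den = den / g)
}

frac_gcd <- function(a, b) {
  while (b > 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

frac_add <- function(a, b) frac(a$num * b$den + b$num * a$den, a$den * b$den)
frac_mul <- function(a, b) frac(a$num * b$num, a$den * b$den)
frac_div <- function(a, b) {
  stopifnot(b$num != 0)
  frac(a$num * b$den, a$den * b$num)
}
frac_num <- function(a) a$num / a$den
frac_lab <- function(a) {
  if (a$den == 1) as.character(a$num) else paste0(a$num, "/", a$den)
}

## ---- likelihood polynomials -------------------------------------------------
## A stage likelihood is a sum of monomial terms c * x^a * (1-x)^b; products
## of stages stay in this form, and each term integrates exactly over [0,1]
## by the Beta identity  int x^a (1-x)^b dx = a! b! / (a+b+1)!.

stage_terms <- function(stage, outcome) {
  stage <- match.arg(stage, c("first", "second"))
  valid <- if (stage == "first") c("P", "N") else c("PP", "PN", "NN")
  if (!outcome %in% valid) {
    stop("outcome '", outcome, "' is not valid for the ", stage,
         " stage (expected ", paste(valid, collapse = "/"), ")",
         call. = FALSE)
  }
  switch(outcome,
    # merged first stage: union of two Bernoulli(x) reads
    P  = list(list(c = 1, a = 2, b = 0), list(c = 2, a = 1, b = 1)),
    N  = list(list(c = 1, a = 0, b = 2)),
    # second stage: the two reads are kept individually
    PP = list(list(c = 1, a = 2, b = 0)),
    PN = list(list(c = 2, a = 1, b = 1)),
    NN = list(list(c = 1, a = 0, b = 2))
  )
}

terms_product <- function(t1, t2) {
  out <- list()
  for (u in t1) {
    for (v in t2) {
      out[[length(out) + 1L]] <-
        list(c = u$c * v$c, a = u$a + v$a, b = u$b + v$b)
    }
  }
  out
}

group_terms <- function(group) {
  g <- parse_group(group)
  terms_product(stage_terms("first", g$first_stage),
                stage_terms("second", g$second_stage))
}

terms_eval <- function(terms, x) {
  v <- 0
  for (t in terms) v <- v + t$c * x^t$a * (1 - x)^t$b
  v
}

# Exact \int_0^1 x^shift * sum_t c x^a (1-x)^b dx as a reduced fraction.
terms_integral <- function(terms, shift = 0L) {
  acc <- frac(0, 1)
  for (t in terms) {
    a <- t$a + shift
    b <- t$b
    acc <- frac_add(acc, frac(t$c * factorial(a) * factorial(b),
                              factorial(a + b + 1)))
  }
  acc
}

## ---- user-facing operations -------------------------------------------------

#' Likelihood of a stage outcome given the latent reader probability
#'
#' Each physician's read is Bernoulli with the subject's latent positive
#' probability `x`. The merged first-stage call is the union of two reads,
#' so `P` has probability \eqn{x^2 + 2x(1-x)} and `N` has \eqn{(1-x)^2};
#' the second-stage pair keeps both reads, giving \eqn{x^2}, \eqn{2x(1-x)}
#' and \eqn{(1-x)^2} for `PP`, `PN`, `NN`.
#'
#' @param stage `"first"` or `"second"`.
#' @param outcome Stage outcome: `"P"`/`"N"` for the first stage,
#'   `"PP"`/`"PN"`/`"NN"` for the second.
#' @param x Latent probability, vectorised over `[0, 1]`.
#' @return Numeric likelihood values, same length as `x`.
#' @examples
#' stage_likelihood("first", "P", 0.5)   # 0.75
#' stage_likelihood("second", "PN", 0.5) # 0.5
#' @export
stage_likelihood <- function(stage, outcome, x) {
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
  terms_eval(stage_terms(stage, outcome), x)
}

#' Joint likelihood of a diagnosis group given the latent probability
#'
#' Product of the first-stage and second-stage likelihoods, the numerator
#' of the Bayesian posterior under a uniform prior.
#'
#' @param group Diagnosis group label, e.g. `"P,PP"` (see
#'   [diagnosis_groups()]).
#' @param x Latent probability, vectorised over `[0, 1]`.
#' @return Numeric likelihood values.
#' @examples
#' group_likelihood("P,PP", 0.5) # 0.75 * 0.25
#' @export
group_likelihood <- function(group, x) {
  stopifnot(is.numeric(x), all(x >= 0 & x <= 1))
  terms_eval(group_terms(group), x)
}

#' Posterior density of the latent reader probability given a group
#'
#' With a uniform prior on `x`, the posterior density given diagnosis group
#' `D` is the group likelihood normalised by its exact integral over
#' `[0, 1]` (a ratio of factorials, computed in rational arithmetic).
#'
#' @inheritParams group_likelihood
#' @return Numeric density values; the density integrates to 1.
#' @examples
#' posterior_density("N,NN", 0) # 5: density 5 (1-x)^4
#' @export
posterior_density <- function(group, x) {
  terms <- group_terms(group)
  group_likelihood(group, x) / frac_num(terms_integral(terms))
}

#' Posterior density on the logit scale
#'
#' Change of variables `u = logit(x)`: the posterior density of `u` is
#' `posterior_density(group, sigmoid(u)) * sigmoid(u) * (1 - sigmoid(u))`.
#' This is the distribution that scaled classifier logits are matched
#' against during calibration.
#'
#' @param group Diagnosis group label.
#' @param u Logit values (finite), vectorised.
#' @return Numeric density values; integrates to 1 over the real line.
#' @examples
#' posterior_logit_density("P,PP", 0) # 0.15625
#' @export
posterior_logit_density <- function(group, u) {
  stopifnot(is.numeric(u), all(is.finite(u)))
  s <- sigmoid(u)
  posterior_density(group, s) * s * (1 - s)
}

#' Logistic sigmoid and logit
#'
#' `sigmoid(u)` is \eqn{1 / (1 + e^{-u})}; `logit(x)` is its inverse
#' \eqn{\log(x / (1 - x))}.
#'
#' @param u,x Numeric vectors.
#' @return Numeric vector.
#' @export
sigmoid <- function(u) 1 / (1 + exp(-u))

#' @rdname sigmoid
#' @export
logit <- function(x) log(x / (1 - x))

#' Expected posterior probability for a diagnosis group
#'
#' The posterior mean \eqn{E[x \mid D]} under a uniform prior, computed in
#' exact rational arithmetic via the Beta integral identity
#' \eqn{\int_0^1 x^a (1-x)^b dx = a!\,b!/(a+b+1)!}. The six groups give
#' 7/9, 4/7, 3/8, 1/2, 1/3 and 1/6.
#'
#' @param group Diagnosis group label.
#' @param exact If `TRUE`, return a list with integer `num` and `den`
#'   (reduced fraction); otherwise the numeric value.
#' @return Numeric scalar, or a `list(num, den)` when `exact = TRUE`.
#' @examples
#' expected_posterior("P,PP")               # 7/9
#' expected_posterior("N,NN", exact = TRUE) # list(num = 1, den = 6)
#' @export
expected_posterior <- function(group, exact = FALSE) {
  terms <- group_terms(group)
  e <- frac_div(terms_integral(terms, shift = 1L), terms_integral(terms))
  if (exact) e else frac_num(e)
}

#' Posterior summary table for all six diagnosis groups
#'
#' Normalising constants and posterior expectations for every group, as
#' exact reduced fractions and as numerics. The normaliser is the
#' reciprocal of the likelihood's integral over `[0, 1]`, e.g. 10/3 for
#' `(P,PP)`.
#'
#' @return A tibble with one row per group: `group`, `first_stage`,
#'   `second_stage`, `normalizer` / `expectation` (numeric), their integer
#'   `*_num` / `*_den` components, and display fractions
#'   `normalizer_frac` / `expectation_frac`.
#' @examples
#' posterior_table()
#' @export
posterior_table <- function() {
  rows <- purrr::map(group_levels(), function(g) {
    terms <- group_terms(g)
    z <- frac_div(frac(1, 1), terms_integral(terms))
    e <- expected_posterior(g, exact = TRUE)
    tibble::tibble(
      group            = g,
      normalizer       = frac_num(z),
      normalizer_num   = z$num,
      normalizer_den   = z$den,
      normalizer_frac  = frac_lab(z),
      expectation      = frac_num(e),
      expectation_num  = e$num,
      expectation_den  = e$den,
      expectation_frac = frac_lab(e)
    )
  })
  dplyr::left_join(diagnosis_groups(), dplyr::bind_rows(rows), by = "group")
}
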