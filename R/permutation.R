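#' Null-simulation specification for the permutation threshold
#'
#' @param n_target Target population size (pedigree use: 20).
#' @param n_background Background cohort size (pedigree use: 410).
#' @param n_sims Number of simulated scores, default 1000.
#' @param top_fraction Upper tail defining the threshold, default 0.05.
#' @param seed Integer seed; mandatory, there is no wall-clock default.
#' @return A list of class `null_spec`.
#' @export
null_spec <- function(n_target, n_background, n_sims = 1000,
                      top_fraction = 0.05, seed) {
  stopifnot(n_target >= 1, n_background >= 1, n_sims >= 1)
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  structure(
    list(n_target = as.integer(n_target),
         n_background = as.integer(n_background),
         n_sims = as.integer(n_sims),
         top_fraction = top_fraction,
         seed = as.integer(seed)),
    class = "null_spec"
  )
}

#' Simulate the null distribution of fingerprint scores
#'
#' Each simulated score multiplies a term frequency `k / n_target`, with `k`
#' uniform on the integers `{0, ..., n_target}`, by an inverse document
#' frequency at `m` background carriers, with `m` uniform on
#' `{0, ..., n_background}`, drawn independently. This emulates a site with
#' no association between its target and background presence frequencies.
#'
#' @param spec A [null_spec()].
#' @param config A [scoring_config()].
#' @return Numeric vector of `n_sims` simulated scores.
#' @export
simulate_null_scores <- function(spec, config = scoring_config()) {
  stopifnot(inherits(spec, "null_spec"))
  set.seed(spec$seed)
  k <- sample.int(spec$n_target + 1L, spec$n_sims, replace = TRUE) - 1L
  m <- sample.int(spec$n_background + 1L, spec$n_sims, replace = TRUE) - 1L
  term_frequency(k, spec$n_target) *
    inverse_document_frequency(m, spec$n_background, config)
}

#' Empirical upper-tail threshold from a null sample
#'
#' Nearest-rank-from-above rule: the smallest score `s` such that at least
#' `ceiling(top_fraction * n)` scores are `>= s`; equivalently the
#' `ceiling(top_fraction * n)`-th largest score. "Top 5%" of 1000 scores
#' thus means the 50 largest define the boundary.
#'
#' @param scores Non-empty numeric vector of null scores.
#' @param top_fraction Upper-tail fraction in (0, 1).
#' @return The threshold score.
#' @export
threshold_from_null <- function(scores, top_fraction = 0.05) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must lie in (0, 1]", call. = FALSE)
  }
  r <- ceiling(top_fraction * length(scores))
  sort(scores, decreasing = TRUE)[r]
}

#' Permutation-derived fingerprint threshold
#'
#' Composes [simulate_null_scores()] and [threshold_from_null()]; for the
#' pedigree design (20 targets, 410 background, 1000 simulations, top 5%)
#' single realizations scatter around the exact discrete-null quantile with
#' 1000-draw Monte-Carlo noise.
#'
#' @inheritParams simulate_null_scores
#' @return A single threshold score.
#' @export
pedigree_threshold <- function(spec, config = scoring_config()) {
  threshold_from_null(simulate_null_scores(spec, config), spec$top_fraction)
}

#' Exact quantile of the discrete null by exhaustive enumeration
#'
#' Enumerates all `(n_target + 1) x (n_background + 1)` equiprobable `(k, m)`
#' pairs and applies the same nearest-rank rule; the stable reference the
#' Monte-Carlo threshold converges to as `n_sims` grows.
#'
#' @param n_target,n_background Population sizes.
#' @param top_fraction Upper-tail fraction.
#' @param config A [scoring_config()].
#' @return The exact threshold score.
#' @export
exact_null_quantile <- function(n_target, n_background, top_fraction = 0.05,
                                config = scoring_config()) {
  grid <- expand.grid(k = 0:n_target, m = 0:n_background)
  s <- term_frequency(grid$k, n_target) *
    inverse_document_frequency(grid$m, n_background, config)
  threshold_from_null(s, top_fraction)
}
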