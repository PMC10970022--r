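#' Scoring configuration
#'
#' Fixes the TF-IDF formula variant used throughout scoring. The default —
#' base-10 logarithm with add-one smoothing in both numerator and
#' denominator — gives IDF in `[0, log10(n_background + 1)]`, zero for a
#' site present in every background sample.
#'
#' @param log_base Logarithm base for the IDF, `10` (default) or `exp(1)`.
#' @param smoothing One of `"add-one-both"` (default,
#'   `log((n+1)/(df+1))`), `"add-one-denominator"` (`log(n/(df+1))`) or
#'   `"none"` (`log(n/df)`, infinite at `df = 0`).
#' @param background_mode `"disjoint"` (target samples excluded from the
#'   background count; pedigree use) or `"full-cohort"` (every manifest
#'   sample counts toward the background; region use).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(log_base = 10,
                           smoothing = c("add-one-both",
                                         "add-one-denominator", "none"),
                           background_mode = c("disjoint", "full-cohort")) {
  if (!log_base %in% c(10, exp(1))) {
    stop("log_base must be 10 or exp(1)", call. = FALSE)
  }
  structure(
    list(log_base = log_base,
         smoothing = match.arg(smoothing),
         background_mode = match.arg(background_mode)),
    class = "scoring_config"
  )
}

#' Term frequency of a site in the target population
#'
#' The fraction of target samples carrying the site.
#'
#' @param df_target Integer count of target samples with the site
#'   (vectorised).
#' @param n_target Number of target samples; must be >= 1.
#' @return `df_target / n_target`, in `[0, 1]`.
#' @export
term_frequency <- function(df_target, n_target) {
  if (length(n_target) != 1 || is.na(n_target) || n_target < 1) {
    stop("n_target must be a single integer >= 1", call. = FALSE)
  }
  if (any(df_target < 0 | df_target > n_target)) {
    stop("df_target must lie in [0, n_target]", call. = FALSE)
  }
  df_target / n_target
}

#' Inverse document frequency of a site in the background cohort
#'
#' Log-scaled rarity of the site among background samples, non-increasing
#' in `df_background`.
#'
#' @param df_background Integer count of background samples with the site
#'   (vectorised).
#' @param n_background Number of background samples; must be >= 1.
#' @param config A [scoring_config()].
#' @return Non-negative IDF values (infinite only under
#'   `smoothing = "none"` at `df_background = 0`).
#' @export
inverse_document_frequency <- function(df_background, n_background,
                                       config = scoring_config()) {
  if (length(n_background) != 1 || is.na(n_background) || n_background < 1) {
    stop("n_background must be a single integer >= 1", call. = FALSE)
  }
  if (any(df_background < 0 | df_background > n_background)) {
    stop("df_background must lie in [0, n_background]", call. = FALSE)
  }
  ratio <- switch(config$smoothing,
    "add-one-both" = (n_background + 1) / (df_background + 1),
    "add-one-denominator" = n_background / (df_background + 1),
    "none" = n_background / df_background
  )
  log(ratio, base = config$log_base)
}

#' Fingerprint score of every site for a target set against a background
#'
#' For each matrix row, the score is the term frequency in the target
#' samples multiplied by the inverse document frequency in the background.
#' Under `background_mode = "disjoint"` the background is the manifest's
#' `role == "background"` samples; under `"full-cohort"` it is all manifest
#' samples (so a target-only site has `df_background = df_target`).
#'
#' @param matrix A `presence_matrix`.
#' @param manifest data.frame with `sample` and `role` columns.
#' @param config A [scoring_config()].
#' @return data.frame with one row per site: chrom, pos, ref, alt,
#'   df_target, n_target, df_background, n_background, tf, idf, score.
#' @export
score_sites <- function(matrix, manifest, config = scoring_config()) {
  stopifnot(inherits(matrix, "presence_matrix"))
  target <- manifest$sample[manifest$role == "target"]
  background <- switch(config$background_mode,
    "disjoint" = manifest$sample[manifest$role == "background"],
    "full-cohort" = manifest$sample
  )
  if (length(target) == 0) stop("empty target set", call. = FALSE)
  if (length(background) == 0) stop("empty background set", call. = FALSE)
  miss <- setdiff(c(target, background), colnames(matrix$present))
  if (length(miss)) {
    stop("manifest samples absent from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df_t <- rowSums(matrix$present[, target, drop = FALSE])
  df_b <- rowSums(matrix$present[, background, drop = FALSE])
  tf <- term_frequency(df_t, length(target))
  idf <- inverse_document_frequency(df_b, length(background), config)
  data.frame(
    matrix$sites,
    df_target = as.integer(df_t), n_target = length(target),
    df_background = as.integer(df_b), n_background = length(background),
    tf = tf, idf = idf, score = tf * idf,
    stringsAsFactors = FALSE
  )
}

#' Rank scored sites
#'
#' Orders by score descending with (chrom, pos) as the deterministic
#' tie-break.
#'
#' @param results data.frame from [score_sites()].
#' @return The same data.frame, reordered.
#' @export
rank_fingerprints <- function(results) {
  results[order(-results$score, results$chrom, results$pos), , drop = FALSE]
}

#' Select sites at or above a score threshold
#'
#' Boundary-inclusive: a site scoring exactly the threshold is retained.
#' Input order is preserved.
#'
#' @param results data.frame from [score_sites()].
#' @param threshold Finite score threshold.
#' @return Subset of `results` with `score >= threshold`.
#' @export
select_fingerprint_sites <- function(results, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  results[results$score >= threshold, , drop = FALSE]
}
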