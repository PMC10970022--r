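#' Score every site once per region against the full cohort
#'
#' For each region label in the manifest, the term frequency is computed
#' over that region's samples and the inverse document frequency over the
#' whole cohort (full-cohort background). A site fixed in the whole cohort
#' scores 0 in every region under the default smoothing.
#'
#' @param matrix A `presence_matrix`.
#' @param manifest data.frame with `sample` and `region` columns; every
#'   manifest sample counts toward the cohort background, and samples with a
#'   missing/empty region contribute only to the background.
#' @param config A [scoring_config()]; the background mode is forced to
#'   full-cohort.
#' @return A `region_score_table`: list with `sites`, `regions`, `score`
#'   (site x region matrix), `enriched_region`, `max_score`, `tie` (logical,
#'   argmax tied across regions) and `n_background`.
#' @export
score_by_region <- function(matrix, manifest, config = scoring_config()) {
  stopifnot(inherits(matrix, "presence_matrix"))
  if (!"region" %in% names(manifest)) {
    stop("manifest has no 'region' column", call. = FALSE)
  }
  has_region <- !is.na(manifest$region) & nzchar(manifest$region)
  regions <- sort(unique(manifest$region[has_region]))
  if (length(regions) < 2) {
    stop("region scan needs >= 2 non-empty regions", call. = FALSE)
  }
  miss <- setdiff(manifest$sample, colnames(matrix$present))
  if (length(miss)) {
    stop("manifest samples absent from matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n_bg <- nrow(manifest)
  df_b <- rowSums(matrix$present[, manifest$sample, drop = FALSE])
  idf <- inverse_document_frequency(df_b, n_bg, config)
  score <- base::matrix(0, nrow = nrow(matrix$sites), ncol = length(regions),
                        dimnames = list(NULL, regions))
  for (r in regions) {
    ids <- manifest$sample[has_region & manifest$region == r]
    if (length(ids) == 0) {
      stop("region with zero samples: ", r, call. = FALSE)
    }
    tf <- term_frequency(
      rowSums(matrix$present[, ids, drop = FALSE]), length(ids))
    score[, r] <- tf * idf
  }
  tab <- structure(
    list(sites = matrix$sites, regions = regions, score = score,
         n_background = n_bg),
    class = "region_score_table"
  )
  assign_enriched_region(tab)
}

#' Assign each site its enriched region (argmax over region scores)
#'
#' Exact ties are broken lexicographically by region label and flagged.
#'
#' @param table A `region_score_table`.
#' @return The table with `enriched_region`, `max_score` and `tie` filled in.
#' @export
assign_enriched_region <- function(table) {
  stopifnot(inherits(table, "region_score_table"))
  # columns are already in lexicographic region order, so which.max's
  # first-maximum rule is the lexicographic tie-break
  idx <- apply(table$score, 1, which.max)
  idx <- if (length(idx) == 0) integer(0) else as.integer(idx)
  table$max_score <- if (nrow(table$score) == 0) numeric(0) else
    apply(table$score, 1, max)
  table$enriched_region <- table$regions[idx]
  table$tie <- rowSums(table$score == table$max_score) > 1
  table
}

#' @method print region_score_table
#' @export
print.region_score_table <- function(x, ...) {
  cat("region_score_table:", nrow(x$score), "sites x",
      length(x$regions), "regions (", paste(x$regions, collapse = ", "),
      ")\n")
  invisible(x)
}

#' Trim sites of low regional specificity
#'
#' Retains sites whose maximum fingerprint score across regions is at least
#' `min_max_score` (boundary inclusive).
#'
#' @param table A `region_score_table`.
#' @param min_max_score Cutoff, default 0.1.
#' @return The filtered table.
#' @export
trim_low_specificity <- function(table, min_max_score = 0.1) {
  stopifnot(inherits(table, "region_score_table"), min_max_score >= 0)
  keep <- table$max_score >= min_max_score
  if (!any(keep) && nrow(table$score) > 0) {
    warning("cutoff ", min_max_score,
            " exceeds every site's maximum score; empty table",
            call. = FALSE)
  }
  table$sites <- table$sites[keep, , drop = FALSE]
  rownames(table$sites) <- NULL
  table$score <- table$score[keep, , drop = FALSE]
  table$max_score <- table$max_score[keep]
  table$enriched_region <- table$enriched_region[keep]
  table$tie <- table$tie[keep]
  table
}

#' Select region-specific sites at a per-region top fraction
#'
#' For each region independently, selects the sites whose score in that
#' region is at or above the nearest-rank-from-above `(1 - top_fraction)`
#' quantile of that region's score column. Boundary ties are all included,
#' so a region's count can exceed the nominal `ceiling(f * n_sites)`.
#'
#' @param table A `region_score_table`.
#' @param top_fraction Per-region upper tail, default 0.001.
#' @return List with `per_region` (named list of site data.frames with the
#'   region score attached), `counts` (named integer vector) and `union`
#'   (data.frame of distinct selected sites).
#' @export
select_region_specific <- function(table, top_fraction = 0.001) {
  stopifnot(inherits(table, "region_score_table"))
  if (top_fraction <= 0 || top_fraction >= 1) {
    stop("top_fraction must lie in (0, 1)", call. = FALSE)
  }
  per_region <- lapply(table$regions, function(r) {
    col <- table$score[, r]
    thr <- threshold_from_null(col, top_fraction)
    sel <- which(col >= thr)
    out <- table$sites[sel, , drop = FALSE]
    out$score <- col[sel]
    out$region <- r
    rownames(out) <- NULL
    out[order(-out$score, out$chrom, out$pos), , drop = FALSE]
  })
  names(per_region) <- table$regions
  union_idx <- sort(unique(unlist(
    lapply(table$regions, function(r) {
      col <- table$score[, r]
      which(col >= threshold_from_null(col, top_fraction))
    })
  )))
  list(
    per_region = per_region,
    counts = vapply(per_region, nrow, integer(1)),
    union = table$sites[union_idx, , drop = FALSE]
  )
}

#' Compare phenotypic effects between enriched-region groups
#'
#' Resolves a functional-site list (e.g. GWAS hits with signed effects)
#' against a region score table, partitions the resolved sites by their
#' enriched region, and compares two requested groups with a two-sample
#' location test on the effects (and on the scores).
#'
#' @param functional_sites data.frame with columns chrom, pos, ref, alt,
#'   effect.
#' @param table A `region_score_table`.
#' @param pair Character vector of two region labels to test against each
#'   other, or `NULL` to skip the test.
#' @param positive_only If `TRUE`, keep only sites with `effect > 0` before
#'   grouping (an explicit filter, never inferred).
#' @param test `"t"` (Welch t-test, default) or `"wilcoxon"`.
#' @return List with `groups` (per-region n, mean/median effect, mean/median
#'   score), `unresolved` (input rows not found in the table), and — when
#'   `pair` is given — `effect_test` and `score_test` (htest objects).
#' @export
compare_enriched_groups <- function(functional_sites, table, pair = NULL,
                                    positive_only = FALSE,
                                    test = c("t", "wilcoxon")) {
  stopifnot(inherits(table, "region_score_table"))
  test <- match.arg(test)
  req <- c("chrom", "pos", "ref", "alt", "effect")
  if (!all(req %in% names(functional_sites))) {
    stop("functional_sites needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (positive_only) {
    functional_sites <-
      functional_sites[functional_sites$effect > 0, , drop = FALSE]
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  idx <- match(key(functional_sites), key(table$sites))
  unresolved <- functional_sites[is.na(idx), , drop = FALSE]
  resolved <- functional_sites[!is.na(idx), , drop = FALSE]
  ridx <- idx[!is.na(idx)]
  resolved$enriched_region <- table$enriched_region[ridx]
  resolved$score <- table$max_score[ridx]

  groups <- do.call(rbind, lapply(split(resolved, resolved$enriched_region),
    function(g) data.frame(
      region = g$enriched_region[1], n = nrow(g),
      mean_effect = mean(g$effect), median_effect = stats::median(g$effect),
      mean_score = mean(g$score), median_score = stats::median(g$score),
      stringsAsFactors = FALSE)))
  rownames(groups) <- NULL

  out <- list(groups = groups, unresolved = unresolved, sites = resolved)
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2)
    absent <- setdiff(pair, table$regions)
    if (length(absent)) {
      stop("requested region absent from table: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    a <- resolved[resolved$enriched_region == pair[1], , drop = FALSE]
    b <- resolved[resolved$enriched_region == pair[2], , drop = FALSE]
    tfun <- if (test == "t") stats::t.test else stats::wilcox.test
    safe_test <- function(x, y) {
      tryCatch(tfun(x, y), error = function(e) {
        warning("two-sample test degenerate (", conditionMessage(e), ")",
                call. = FALSE)
        NULL
      })
    }
    out$effect_test <- safe_test(a$effect, b$effect)
    out$score_test <- safe_test(a$score, b$score)
  }
  out
}
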