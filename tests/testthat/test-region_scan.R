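region_toy <- function() {
  # 3 regions x 2 samples; site 1 exclusive to region A, site 2 ubiquitous,
  # site 3 absent, site 4 split between B and C
  samples <- c("A1", "A2", "B1", "B2", "C1", "C2")
  present <- rbind(
    c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    rep(TRUE, 6),
    rep(FALSE, 6),
    c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  m <- toy_matrix(present, samples)
  man <- toy_manifest(samples, rep("background", 6),
                      regions = rep(c("A", "B", "C"), each = 2))
  list(m = m, man = man)
}

test_that("region scores are tf(region) x idf(cohort)", {
  tt <- region_toy()
  tab <- score_by_region(tt$m, tt$man)
  expect_equal(tab$regions, c("A", "B", "C"))
  expect_equal(unname(tab$score[1, "A"]), log10(7 / 3))
  expect_equal(unname(tab$score[1, c("B", "C")]), c(0, 0))
  expect_equal(tab$enriched_region[1], "A")
  expect_false(tab$tie[1])
  # ubiquitous and absent sites score 0 everywhere
  expect_true(all(tab$score[2:3, ] == 0))
})

test_that("argmax ties are flagged and broken lexicographically", {
  tt <- region_toy()
  tab <- score_by_region(tt$m, tt$man)
  # site 4: equal presence in B and C
  expect_equal(unname(tab$score[4, "B"]), unname(tab$score[4, "C"]))
  expect_equal(tab$enriched_region[4], "B")
  expect_true(tab$tie[4])
  # all-zero rows tie across every region, label = lexicographic first
  expect_equal(tab$enriched_region[3], "A")
  expect_true(tab$tie[3])
})

test_that("region errors are explicit", {
  tt <- region_toy()
  man <- tt$man
  man$region <- NULL
  expect_error(score_by_region(tt$m, man), "region")
  man1 <- tt$man
  man1$region <- "A"
  expect_error(score_by_region(tt$m, man1), ">= 2")
})

test_that("permuting region labels permutes score columns identically", {
  set.seed(17)
  samples <- sprintf("S%d", 1:30)
  present <- matrix(runif(40 * 30) < 0.3, 40)
  m <- toy_matrix(present, samples)
  regions <- rep(c("N", "S", "W"), each = 10)
  man <- toy_manifest(samples, rep("background", 30), regions = regions)
  relabel <- c(N = "S", S = "W", W = "N")
  man2 <- man
  man2$region <- unname(relabel[man$region])
  t1 <- score_by_region(m, man)
  t2 <- score_by_region(m, man2)
  for (r in t1$regions) {
    expect_equal(t2$score[, unname(relabel[r])], t1$score[, r])
  }
})

test_that("a whole-cohort region reduces to single-population scoring", {
  set.seed(23)
  samples <- sprintf("S%d", 1:12)
  present <- matrix(runif(20 * 12) < 0.4, 20)
  m <- toy_matrix(present, samples)
  # region ALL spans the original cohort; a one-sample region ONE is added
  # only to satisfy the >= 2 regions contract
  man2 <- toy_manifest(c(samples, "X1"), rep("background", 13),
                       regions = c(rep("ALL", 12), "ONE"))
  m2 <- toy_matrix(cbind(present, X1 = FALSE), c(samples, "X1"))
  tab <- score_by_region(m2, man2)
  frac <- rowSums(present) / 12
  idf <- log10(14 / (rowSums(m2$present) + 1))
  expect_equal(unname(tab$score[, "ALL"]), frac * idf)
})

test_that("trim_low_specificity is boundary-inclusive", {
  tt <- region_toy()
  tab <- score_by_region(tt$m, tt$man)
  cut <- tab$max_score[4]
  trimmed <- trim_low_specificity(tab, cut)
  expect_equal(nrow(trimmed$sites), 2) # sites 1 and 4 survive
  expect_equal(nrow(trim_low_specificity(tab, 0)$sites), 4)
  expect_warning(empty <- trim_low_specificity(tab, 99), "empty")
  expect_equal(nrow(empty$sites), 0)
})

test_that("per-region top-fraction selection honours rank arithmetic and ties", {
  set.seed(31)
  samples <- sprintf("S%d", 1:20)
  present <- matrix(runif(1000 * 20) < 0.2, 1000)
  m <- toy_matrix(present, samples)
  man <- toy_manifest(samples, rep("background", 20),
                      regions = rep(c("E", "W"), each = 10))
  tab <- score_by_region(m, man)
  f <- 0.01
  sel <- select_region_specific(tab, f)
  expect_true(all(sel$counts >= ceiling(f * 1000)))
  for (r in tab$regions) {
    thr <- sort(tab$score[, r], decreasing = TRUE)[ceiling(f * 1000)]
    expect_equal(sel$counts[[r]], sum(tab$score[, r] >= thr))
  }
  # identical columns give identical selections
  tab$score[, "W"] <- tab$score[, "E"]
  tab <- assign_enriched_region(tab)
  sel2 <- select_region_specific(tab, f)
  expect_equal(sel2$per_region$E$pos, sel2$per_region$W$pos)
})

test_that("enriched-group comparison partitions, filters and tests", {
  tt <- region_toy()
  set.seed(41)
  samples <- tt$m$samples
  # build a larger toy with clear A- and B-enriched blocks
  present <- rbind(
    matrix(rep(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 3), 3,
           byrow = TRUE),
    matrix(rep(c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE), 3), 3,
           byrow = TRUE)
  )
  m <- toy_matrix(present, samples)
  man <- toy_manifest(samples, rep("background", 6),
                      regions = rep(c("A", "B", "C"), each = 2))
  tab <- score_by_region(m, man)
  fs <- data.frame(m$sites, effect = c(1, 2, 3, 4, 5, 6))
  # within-group scores are constant here, so the score test degenerates
  expect_warning(
    out <- compare_enriched_groups(fs, tab, pair = c("A", "B")),
    "degenerate")
  g <- out$groups
  expect_equal(g$mean_effect[g$region == "A"], 2)
  expect_equal(g$mean_effect[g$region == "B"], 5)
  expect_s3_class(out$effect_test, "htest")

  # unresolved keys are reported, not dropped silently
  fs2 <- rbind(fs, data.frame(chrom = "ZZ", pos = 1L, ref = "A", alt = "G",
                              effect = 9))
  out2 <- compare_enriched_groups(fs2, tab)
  expect_equal(nrow(out2$unresolved), 1)
  expect_equal(out2$unresolved$chrom, "ZZ")

  # positive-effect filter is explicit
  fs3 <- fs
  fs3$effect <- c(-1, 2, 3, -4, 5, 6)
  out3 <- compare_enriched_groups(fs3, tab, positive_only = TRUE)
  expect_equal(sum(out3$groups$n), 4)

  expect_error(compare_enriched_groups(fs, tab, pair = c("A", "Z")),
               "absent.*Z")
})
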