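test_that("genic-context precedence classifies the toy suite exactly", {
  models <- toy_gene_models()
  # gplus (+): span 1001-3000, exons 1001-1500 / 2001-3000, UTR5 1001-1100,
  # UTR3 2901-3000; goverlap (+): exon 1601-1900 inside gplus's intron
  sites <- sites_df("A01", c(1050, 1200, 1502, 1700, 1999, 2500, 2950,
                             500, 3500, 4500))
  ctx <- classify_sites(sites, models)
  expect_equal(as.character(ctx$category),
               c("UTR5",        # 1050: in exon1 and UTR5 span
                 "exonic",      # 1200: exon1 outside UTRs
                 "splicing",    # 1502: 2 bp into the intron
                 "exonic",      # 1700: goverlap exon beats gplus intron
                 "splicing",    # 1999
                 "exonic",      # 2500
                 "UTR3",        # 2950
                 "upstream1kb", # 500
                 "downstream1kb", # 3500
                 "intergenic")) # 4500: > 1 kb from everything
  # multi-gene overlap recorded with both genes
  expect_match(ctx$all_overlaps[4], "goverlap:exonic")
  expect_match(ctx$all_overlaps[4], "gplus:intronic")
  expect_equal(ctx$gene_id[4], "goverlap")
  # a truly intronic gplus site (outside goverlap and splice windows)
  ctx_in <- classify_sites(sites_df("A01", 1950), models)
  expect_equal(as.character(ctx_in$category), "intronic")
})

test_that("flanks are strand-aware on minus-strand genes", {
  models <- toy_gene_models()
  # gminus (-): span 6001-8000; upstream is past the high coordinate
  ctx <- classify_sites(sites_df("A01", c(8100, 5900, 7950, 6050)), models)
  expect_equal(as.character(ctx$category),
               c("upstream1kb", "downstream1kb", "UTR5", "UTR3"))
  # a site on a chromosome absent from the models is intergenic
  ctx2 <- classify_sites(sites_df("D05", 1500), models)
  expect_equal(as.character(ctx2$category), "intergenic")
  expect_true(is.na(ctx2$gene_id))
  expect_false(ctx2$gene_related)
})

test_that("every site gets exactly one category and the partition sums", {
  set.seed(53)
  models <- toy_gene_models()
  sites <- sites_df("A01", sample.int(10000, 300))
  ctx <- classify_sites(sites, models)
  expect_equal(nrow(ctx), 300)
  expect_false(any(is.na(ctx$category)))
  expect_equal(sum(ctx$gene_related) + sum(ctx$category == "intergenic"),
               300)
})

test_that("GFF3 gene models load, validate and classify like the in-code ones", {
  path <- write_toy_gff()
  models <- read_gene_models(path)
  expect_equal(sort(models$genes$gene_id),
               c("gminus", "goverlap", "gplus"))
  sites <- sites_df("A01", c(1050, 1502, 1700, 500, 8100, 4500))
  expect_equal(classify_sites(sites, models)$category,
               classify_sites(sites, toy_gene_models())$category)

  # invalid model: UTR outside the exon union fails at load time
  bad <- toy_gene_models()
  bad$features$start[bad$features$type == "five_prime_UTR" &
                       bad$features$gene_id == "gplus"] <- 900L
  tmp <- write_toy_gff(bad)
  expect_error(read_gene_models(tmp), "UTR outside exon union")
})

test_that("snp_spectrum counts the 12 ordered substitution types", {
  sites <- data.frame(ref = c("G", "G", "C"), alt = c("A", "A", "T"))
  sp <- snp_spectrum(sites)
  expect_length(sp, 12)
  expect_equal(unname(sp["G>A"]), 2L)
  expect_equal(unname(sp["C>T"]), 1L)
  expect_equal(sum(sp), 3L)

  expect_equal(sum(snp_spectrum(data.frame(ref = character(0),
                                           alt = character(0)))), 0L)
  # one of each type -> uniform table of ones
  dna <- c("A", "C", "G", "T")
  all12 <- expand.grid(ref = dna, alt = dna, stringsAsFactors = FALSE)
  all12 <- all12[all12$ref != all12$alt, ]
  expect_true(all(snp_spectrum(all12) == 1L))

  expect_error(snp_spectrum(data.frame(ref = "AT", alt = "A")), "single")
})

test_that("down-sampling counts follow the hypergeometric law", {
  # pool of 10 sites, 4 gene-related, sets of 5
  pool <- c(rep(TRUE, 4), rep(FALSE, 6))
  n_sets <- 20000
  out <- gene_related_downsample_test(rep(TRUE, 2), pool, set_size = 5,
                                      n_sets = n_sets, seed = 77)
  expect_length(out$set_counts, n_sets)
  for (k in 0:4) {
    p_exact <- stats::dhyper(k, 4, 6, 5)
    obs <- mean(out$set_counts == k)
    se <- sqrt(p_exact * (1 - p_exact) / n_sets)
    expect_lt(abs(obs - p_exact), 3 * se + 1e-12)
  }
})

test_that("down-sampling extremes and errors behave as specified", {
  # all-gene-related pool: every set saturates, minimal p
  out <- gene_related_downsample_test(c(TRUE, FALSE), rep(TRUE, 20),
                                      set_size = 5, n_sets = 100, seed = 1)
  expect_true(all(out$set_counts == 5))
  expect_equal(out$p_value, 1 / 101)
  # zero-gene-related pool: p = 1
  out0 <- gene_related_downsample_test(logical(3), rep(FALSE, 20),
                                       set_size = 5, n_sets = 100, seed = 1)
  expect_true(all(out0$set_counts == 0))
  expect_equal(out0$p_value, 1)
  expect_error(
    gene_related_downsample_test(TRUE, rep(TRUE, 3), set_size = 5,
                                 n_sets = 10, seed = 1),
    "smaller than set_size")
  # reproducible under a fixed seed
  a <- gene_related_downsample_test(TRUE, rep(c(TRUE, FALSE), 10),
                                    set_size = 5, n_sets = 50, seed = 9)
  b <- gene_related_downsample_test(TRUE, rep(c(TRUE, FALSE), 10),
                                    set_size = 5, n_sets = 50, seed = 9)
  expect_identical(a$set_counts, b$set_counts)
})
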