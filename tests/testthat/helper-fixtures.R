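# In-code fixtures: toy VCFs, manifests and gene models built at test time.

write_toy_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  # records: data.frame chrom, pos, ref, alt, qual (character to allow "."),
  #          plus one column per sample holding GT strings
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, as.character(r$qual),
            "PASS", ".", "GT", unlist(r[samples])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

toy_manifest <- function(samples, roles, regions = NULL) {
  m <- data.frame(sample = samples, role = roles, stringsAsFactors = FALSE)
  if (!is.null(regions)) m$region <- regions
  m
}

# presence matrix built directly (bypasses VCF parsing)
toy_matrix <- function(present, samples,
                       chrom = rep("A01", nrow(present)),
                       pos = seq_len(nrow(present)) * 10L) {
  colnames(present) <- samples
  rs <- rowSums(present)
  structure(
    list(
      sites = data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", nrow(present)),
                         alt = rep("G", nrow(present)),
                         stringsAsFactors = FALSE),
      samples = samples, present = present,
      n_missing = rep(0L, nrow(present)),
      monomorphic = rs == 0L | rs == ncol(present)
    ),
    class = "presence_matrix"
  )
}

# independent brute-force TF-IDF oracle: per-site loop, no shared code with
# score_sites beyond the arithmetic definition
brute_force_scores <- function(present, target_cols, background_cols) {
  n_t <- length(target_cols)
  n_b <- length(background_cols)
  vapply(seq_len(nrow(present)), function(i) {
    k <- 0
    for (s in target_cols) if (present[i, s]) k <- k + 1
    m <- 0
    for (s in background_cols) if (present[i, s]) m <- m + 1
    (k / n_t) * log10((n_b + 1) / (m + 1))
  }, numeric(1))
}

# toy gene models: + strand gene 1001-3000, exons 1001-1500 / 2001-3000,
# UTR5 1001-1100, UTR3 2901-3000; - strand gene 6001-8000 on the same
# chromosome, exons 6001-6500 / 7001-8000, UTR5 7901-8000 (5' end is the
# high coordinate on -), UTR3 6001-6100; plus a second gene overlapping the
# first gene's intron with an exon, to exercise multi-gene precedence.
toy_gene_models <- function() {
  genes <- data.frame(
    gene_id = c("gplus", "gminus", "goverlap"),
    chrom = c("A01", "A01", "A01"),
    strand = c("+", "-", "+"),
    start = c(1001L, 6001L, 1601L),
    end = c(3000L, 8000L, 1900L),
    stringsAsFactors = FALSE
  )
  features <- data.frame(
    gene_id = c("gplus", "gplus", "gplus", "gplus",
                "gminus", "gminus", "gminus", "gminus",
                "goverlap"),
    type = c("exon", "exon", "five_prime_UTR", "three_prime_UTR",
             "exon", "exon", "five_prime_UTR", "three_prime_UTR",
             "exon"),
    start = c(1001L, 2001L, 1001L, 2901L,
              6001L, 7001L, 7901L, 6001L,
              1601L),
    end = c(1500L, 3000L, 1100L, 3000L,
            6500L, 8000L, 8000L, 6100L,
            1900L),
    stringsAsFactors = FALSE
  )
  structure(list(genes = genes, features = features), class = "gene_models")
}

write_toy_gff <- function(models = toy_gene_models(),
                          path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    f <- models$features[models$features$gene_id == g$gene_id, , drop = FALSE]
    tid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, g$strand, tid, g$gene_id),
      sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom, f$type, f$start, f$end, g$strand, tid))
  }
  writeLines(lines, path)
  path
}

sites_df <- function(chrom, pos, ref = "A", alt = "G") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}
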