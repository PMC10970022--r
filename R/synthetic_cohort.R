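#' Specification of a synthetic cohort
#'
#' Defines a target sub-population (a pedigree) nested alongside a larger
#' background cohort split into geographic regions, with planted
#' pedigree-fingerprint sites (frequent in the target, rare everywhere
#' else) and planted region-specific sites (frequent in one region, rare
#' elsewhere). Presence is simulated directly as site-level Bernoulli draws
#' per sample — the scoring model consumes only presence, so linkage and
#' diploid dosage are deliberately not modelled.
#'
#' @param n_target Number of target (pedigree) samples. Default 20.
#' @param region_sizes Named integer vector of background samples per
#'   region; the background is the union of regions. Default: 410 samples
#'   split near-evenly over USA, YZ, YR, S, N, NW.
#' @param n_sites Number of non-decoy variant sites. Default 10000.
#' @param n_planted_pedigree Planted pedigree-fingerprint sites. Default 20.
#' @param n_planted_per_region Planted region-specific sites per region.
#'   Default 5.
#' @param p_target_present Per-sample presence probability of a planted
#'   site inside its target set/region. Default 0.95.
#' @param p_background_present Per-sample presence probability of a planted
#'   site outside its target set/region. Default 0.002.
#' @param genome Named integer vector of chromosome lengths. Default two
#'   10-Mb chromosomes A01, A02.
#' @param n_genes Genes to simulate for the GFF3. Default 50.
#' @param p_low_qual_decoy Fraction of extra low-QUAL decoy records added
#'   so the QUAL >= 30 ingestion filter is exercised. Default 0.05.
#' @param seed Integer seed; mandatory.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_target = 20,
                        region_sizes = c(USA = 69, YZ = 69, YR = 68,
                                         S = 68, N = 68, NW = 68),
                        n_sites = 10000,
                        n_planted_pedigree = 20,
                        n_planted_per_region = 5,
                        p_target_present = 0.95,
                        p_background_present = 0.002,
                        genome = c(A01 = 1e7, A02 = 1e7),
                        n_genes = 50,
                        p_low_qual_decoy = 0.05,
                        seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  stopifnot(n_target >= 1, all(region_sizes >= 1),
            !is.null(names(region_sizes)), all(nzchar(names(region_sizes))),
            p_target_present >= 0, p_target_present <= 1,
            p_background_present >= 0, p_background_present <= 1)
  n_planted <- n_planted_pedigree +
    n_planted_per_region * length(region_sizes)
  if (n_planted > n_sites) {
    stop("more planted sites than n_sites", call. = FALSE)
  }
  structure(
    list(n_target = as.integer(n_target),
         region_sizes = region_sizes,
         n_sites = as.integer(n_sites),
         n_planted_pedigree = as.integer(n_planted_pedigree),
         n_planted_per_region = as.integer(n_planted_per_region),
         p_target_present = p_target_present,
         p_background_present = p_background_present,
         genome = genome, n_genes = as.integer(n_genes),
         p_low_qual_decoy = p_low_qual_decoy,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a cohort with planted fingerprint sites
#'
#' Unplanted background sites get independent per-sample presence at a
#' per-site probability drawn uniformly on (0.01, 0.99) (applied to every
#' sample, target included, so target and background frequencies are
#' coupled only through that shared probability — the null the permutation
#' threshold is built against). Planted pedigree sites are present at
#' `p_target_present` in target samples and `p_background_present` in
#' background samples; planted region-specific sites at
#' `p_target_present` within their region and `p_background_present`
#' everywhere else. Genotypes are 0/0 vs 0/1; all real records carry
#' QUAL >= 30, decoy records QUAL < 30.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `matrix` (a `presence_matrix`
#'   over the non-decoy sites), `manifest`, `truth` (chrom, pos,
#'   planted_class, planted_region), `genes`/`features` (gene models), and
#'   `vcf_records` (data.frame of all records incl. decoys, for
#'   [write_cohort()]).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)

  target_ids <- sprintf("T%02d", seq_len(spec$n_target))
  bg_ids <- unlist(lapply(names(spec$region_sizes), function(r)
    sprintf("%s_%03d", r, seq_len(spec$region_sizes[[r]]))))
  bg_regions <- rep(names(spec$region_sizes), spec$region_sizes)
  manifest <- data.frame(
    sample = c(target_ids, bg_ids),
    role = c(rep("target", length(target_ids)),
             rep("background", length(bg_ids))),
    region = c(rep(NA_character_, length(target_ids)), bg_regions),
    stringsAsFactors = FALSE
  )
  n_samples <- nrow(manifest)

  n_decoy <- round(spec$p_low_qual_decoy * spec$n_sites)
  n_total <- spec$n_sites + n_decoy
  capacity <- sum(spec$genome)
  if (n_total > capacity) {
    stop("more sites requested than genome positions available",
         call. = FALSE)
  }
  # unique sorted positions across chromosomes, proportional to length
  chrom <- sample(names(spec$genome), n_total, replace = TRUE,
                  prob = spec$genome / capacity)
  pos <- integer(n_total)
  for (ch in names(spec$genome)) {
    sel <- chrom == ch
    pos[sel] <- sample.int(spec$genome[[ch]], sum(sel))
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  dna <- c("A", "C", "G", "T")
  ref <- sample(dna, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(dna, r), 1), character(1))

  is_decoy <- rep(FALSE, n_total)
  if (n_decoy > 0) is_decoy[sample.int(n_total, n_decoy)] <- TRUE
  qual <- numeric(n_total)
  qual[!is_decoy] <- round(stats::runif(sum(!is_decoy), 30, 999), 1)
  qual[is_decoy] <- round(stats::runif(n_decoy, 0, 29.9), 1)

  # plant among the non-decoy sites
  real_idx <- which(!is_decoy)
  regions <- names(spec$region_sizes)
  n_plant_total <- spec$n_planted_pedigree +
    spec$n_planted_per_region * length(regions)
  plant_idx <- sort(sample(real_idx, n_plant_total))
  ped_idx <- plant_idx[seq_len(spec$n_planted_pedigree)]
  reg_idx <- setdiff(plant_idx, ped_idx)
  reg_label <- rep(regions, each = spec$n_planted_per_region)

  planted_class <- rep("none", n_total)
  planted_region <- rep(NA_character_, n_total)
  planted_class[ped_idx] <- "pedigree"
  planted_class[reg_idx] <- "region"
  planted_region[reg_idx] <- reg_label

  is_target <- manifest$role == "target"
  present <- base::matrix(FALSE, n_total, n_samples,
                          dimnames = list(NULL, manifest$sample))
  bg_prob <- stats::runif(n_total, 0.01, 0.99)
  for (i in seq_len(n_total)) {
    if (planted_class[i] == "pedigree") {
      p <- ifelse(is_target, spec$p_target_present,
                  spec$p_background_present)
    } else if (planted_class[i] == "region") {
      in_reg <- !is.na(manifest$region) &
        manifest$region == planted_region[i]
      p <- ifelse(in_reg, spec$p_target_present, spec$p_background_present)
    } else {
      p <- rep(bg_prob[i], n_samples)
    }
    present[i, ] <- stats::runif(n_samples) < p
  }

  gm <- simulate_gene_models(spec$genome, spec$n_genes)

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  real <- !is_decoy
  pm_present <- present[real, , drop = FALSE]
  rs <- rowSums(pm_present)
  pm <- structure(
    list(sites = sites[real, ], samples = manifest$sample,
         present = pm_present,
         n_missing = rep(0L, sum(real)),
         monomorphic = rs == 0L | rs == n_samples),
    class = "presence_matrix"
  )
  rownames(pm$sites) <- NULL

  truth <- data.frame(
    chrom = chrom[real], pos = pos[real],
    planted_class = planted_class[real],
    planted_region = planted_region[real],
    stringsAsFactors = FALSE
  )

  structure(
    list(
      matrix = pm, manifest = manifest, truth = truth,
      gene_models = gm,
      vcf_records = data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
        stringsAsFactors = FALSE),
      vcf_present = present,
      spec = spec
    ),
    class = "synthetic_cohort"
  )
}

# non-overlapping genes with 2-3 exons each, alternating strand; UTRs at
# the transcript ends
simulate_gene_models <- function(genome, n_genes) {
  genes <- list(); feats <- list()
  chroms <- rep(names(genome), length.out = n_genes)
  counter <- 0
  for (i in seq_len(n_genes)) {
    ch <- chroms[i]
    counter <- counter + 1
    gid <- sprintf("gene%03d", counter)
    glen <- sample(3000:8000, 1)
    start <- sample.int(max(1, genome[[ch]] - glen - 2000), 1) + 1000
    end <- start + glen - 1
    n_ex <- sample(2:3, 1)
    cuts <- sort(sample(seq(start + 200, end - 200, by = 50), (n_ex - 1) * 2))
    bounds <- c(start, cuts, end)
    ex_s <- bounds[seq(1, length(bounds), by = 2)]
    ex_e <- bounds[seq(2, length(bounds), by = 2)]
    strand <- if (i %% 2 == 0) "-" else "+"
    genes[[i]] <- data.frame(gene_id = gid, chrom = ch, strand = strand,
                             start = start, end = end,
                             stringsAsFactors = FALSE)
    u_first <- c(ex_s[1], min(ex_s[1] + 99, ex_e[1]))
    u_last <- c(max(ex_e[n_ex] - 99, ex_s[n_ex]), ex_e[n_ex])
    u5 <- if (strand == "+") u_first else u_last
    u3 <- if (strand == "+") u_last else u_first
    feats[[i]] <- data.frame(
      gene_id = gid,
      type = c(rep("exon", n_ex), "five_prime_UTR", "three_prime_UTR"),
      start = c(ex_s, u5[1], u3[1]),
      end = c(ex_e, u5[2], u3[2]),
      stringsAsFactors = FALSE
    )
  }
  structure(list(genes = do.call(rbind, genes),
                 features = do.call(rbind, feats)),
            class = "gene_models")
}

#' Write a synthetic cohort to disk
#'
#' Emits VCF 4.2 (all records, decoys included), manifest TSV, GFF3 gene
#' models and a truth TSV. Byte-stable given the cohort object.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             manifest = file.path(dir, "manifest.tsv"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))

  rec <- cohort$vcf_records
  gt <- ifelse(cohort$vcf_present, "0/1", "0/0")
  contigs <- sprintf("##contig=<ID=%s,length=%d>",
                     names(cohort$spec$genome),
                     as.integer(cohort$spec$genome))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fpfinder-simulate",
    contigs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$manifest$sample), collapse = "\t")
  )
  body <- paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt,
                format(rec$qual, trim = TRUE), "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths["vcf"])

  utils::write.table(cohort$manifest, paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")

  gm <- cohort$gene_models
  gff <- c("##gff-version 3")
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    f <- gm$features[gm$features$gene_id == g$gene_id, , drop = FALSE]
    tid <- paste0(g$gene_id, ".1")
    gff <- c(gff,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, g$start, g$end, g$strand, tid, g$gene_id),
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom, f$type, f$start, f$end, g$strand, tid))
  }
  writeLines(gff, paths["gff"])

  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(paths)
}

#' Precision/recall of planted-site recovery
#'
#' Evaluates a scored result set against the simulator's truth table:
#' which planted sites of `planted_class` exceed the threshold, at what
#' precision, and where the planted sites rank among all sites.
#'
#' @param truth Truth data.frame from [simulate_cohort()].
#' @param results Scored sites from [score_sites()] (columns chrom, pos,
#'   score).
#' @param threshold Selection threshold (boundary inclusive).
#' @param planted_class Truth class counted as positive, default
#'   `"pedigree"`.
#' @return List with `precision`, `recall`, `n_planted`, `n_selected`,
#'   `tp`, and `planted_ranks` (rank of each planted site by descending
#'   score, ties by chrom/pos).
#' @export
recovery_report <- function(truth, results, threshold,
                            planted_class = "pedigree") {
  key <- function(d) paste(d$chrom, d$pos, sep = ":")
  if (nrow(truth) != nrow(results) ||
      !setequal(key(truth), key(results))) {
    stop("truth and results cover different site universes", call. = FALSE)
  }
  idx <- match(key(results), key(truth))
  planted <- truth$planted_class[idx] == planted_class
  selected <- results$score >= threshold
  tp <- sum(planted & selected)
  n_planted <- sum(planted)
  ord <- order(-results$score, results$chrom, results$pos)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  list(
    precision = if (sum(selected) == 0) NA_real_ else tp / sum(selected),
    recall = if (n_planted == 0) NA_real_ else tp / n_planted,
    n_planted = n_planted,
    n_selected = sum(selected),
    tp = tp,
    planted_ranks = sort(rank[planted])
  )
}
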