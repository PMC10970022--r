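#' Load gene models from GFF3
#'
#' Reads gene / mRNA / exon / five_prime_UTR / three_prime_UTR features.
#' Only the first mRNA per gene (by start coordinate, then ID) is used; a
#' warning reports multi-isoform genes. Models are validated at load time:
#' exons must lie within the gene span and not overlap each other, and UTRs
#' must lie within the exon union.
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` object: data.frame of genes (gene_id, chrom,
#'   strand, start, end) plus per-gene exon and UTR interval tables.
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gff$type)
  genes <- gff[typ == "gene"]
  mrnas <- gff[typ == "mRNA"]
  if (length(genes) == 0) stop("no gene features in ", path, call. = FALSE)

  first_parent <- function(x) {
    vapply(as.list(x$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  }
  mrna_gene <- first_parent(mrnas)
  multi <- names(which(table(mrna_gene) > 1))
  if (length(multi)) {
    warning(length(multi), " multi-isoform gene(s); using the first mRNA ",
            "of each: ", paste(utils::head(multi, 5), collapse = ", "),
            call. = FALSE)
  }
  # first mRNA per gene: lowest start, then ID
  ord <- order(mrna_gene, GenomicRanges::start(mrnas),
               as.character(mrnas$ID))
  mrnas <- mrnas[ord]
  mrna_gene <- mrna_gene[ord]
  keep_mrna <- !duplicated(mrna_gene)
  chosen <- as.character(mrnas$ID[keep_mrna])
  names(chosen) <- mrna_gene[keep_mrna]

  sub <- gff[typ %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
  sub_parent <- first_parent(sub)
  sub <- sub[sub_parent %in% chosen]
  sub_parent <- sub_parent[sub_parent %in% chosen]
  # map transcript back to gene
  tx2gene <- stats::setNames(names(chosen), chosen)
  sub_gene <- tx2gene[sub_parent]

  gene_ids <- as.character(genes$ID)
  feat <- data.frame(
    gene_id = sub_gene,
    type = as.character(sub$type),
    start = GenomicRanges::start(sub),
    end = GenomicRanges::end(sub),
    stringsAsFactors = FALSE
  )
  gene_tab <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE
  )
  if (any(!gene_tab$strand %in% c("+", "-"))) {
    stop("gene without +/- strand in ", path, call. = FALSE)
  }
  validate_gene_models(gene_tab, feat)
  structure(list(genes = gene_tab, features = feat), class = "gene_models")
}

validate_gene_models <- function(gene_tab, feat) {
  for (g in unique(feat$gene_id)) {
    f <- feat[feat$gene_id == g, , drop = FALSE]
    gi <- gene_tab[gene_tab$gene_id == g, , drop = FALSE]
    if (nrow(gi) == 0) {
      stop("feature references unknown gene: ", g, call. = FALSE)
    }
    ex <- f[f$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0) stop("gene without exons: ", g, call. = FALSE)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < gi$start) || any(ex$end > gi$end)) {
      stop("exon outside gene span in gene ", g, call. = FALSE)
    }
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      stop("overlapping exons in gene ", g, call. = FALSE)
    }
    utr <- f[f$type != "exon", , drop = FALSE]
    if (nrow(utr)) {
      exon_ir <- IRanges::IRanges(ex$start, ex$end)
      utr_ir <- IRanges::IRanges(utr$start, utr$end)
      cov <- IRanges::intersect(utr_ir, exon_ir)
      if (sum(IRanges::width(cov)) != sum(IRanges::width(
            IRanges::reduce(utr_ir)))) {
        stop("UTR outside exon union in gene ", g, call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# Expand one gene into labelled classification intervals.
# Precedence: splicing > UTR5 > UTR3 > exonic > intronic > upstream1kb >
# downstream1kb; splicing is the 2 bp of intron flanking each junction;
# flanks are strand-aware 1 kb.
gene_intervals <- function(gene, feat, splice_window = 2L,
                           flank = 1000L) {
  f <- feat[feat$gene_id == gene$gene_id, , drop = FALSE]
  ex <- f[f$type == "exon", , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  iv <- list()
  add <- function(start, end, category) {
    ok <- end >= start
    if (any(ok)) {
      iv[[length(iv) + 1]] <<- data.frame(
        start = start[ok], end = end[ok], category = category,
        stringsAsFactors = FALSE)
    }
  }
  # introns and splicing windows
  if (nrow(ex) > 1) {
    int_s <- ex$end[-nrow(ex)] + 1L
    int_e <- ex$start[-1] - 1L
    has_int <- int_e >= int_s
    add(int_s[has_int], int_e[has_int], "intronic")
    w <- pmin(splice_window, int_e[has_int] - int_s[has_int] + 1L)
    add(int_s[has_int], int_s[has_int] + w - 1L, "splicing")
    add(int_e[has_int] - w + 1L, int_e[has_int], "splicing")
  }
  add(ex$start, ex$end, "exonic")
  u5 <- f[f$type == "five_prime_UTR", , drop = FALSE]
  u3 <- f[f$type == "three_prime_UTR", , drop = FALSE]
  if (nrow(u5)) add(u5$start, u5$end, "UTR5")
  if (nrow(u3)) add(u3$start, u3$end, "UTR3")
  if (gene$strand == "+") {
    add(gene$start - flank, gene$start - 1L, "upstream1kb")
    add(gene$end + 1L, gene$end + flank, "downstream1kb")
  } else {
    add(gene$end + 1L, gene$end + flank, "upstream1kb")
    add(gene$start - flank, gene$start - 1L, "downstream1kb")
  }
  out <- do.call(rbind, iv)
  out$start <- pmax(out$start, 1L)
  out
}

#' Genic-context categories in precedence order
#' @export
context_categories <- function() {
  c("splicing", "UTR5", "UTR3", "exonic", "intronic",
    "upstream1kb", "downstream1kb", "intergenic")
}

#' Classify sites by genic context
#'
#' Deterministic single-category assignment with the precedence
#' splicing > UTR5 > UTR3 > exonic > intronic > upstream 1 kb >
#' downstream 1 kb > intergenic. A site inside an exon that lies in a UTR
#' span is labelled UTR5/UTR3, not exonic; splicing is within 2 bp of an
#' exon-intron junction on the intron side; flanks are strand-aware 1 kb.
#' All per-gene overlaps are still recorded.
#'
#' @param sites data.frame with columns chrom, pos (ref/alt carried through
#'   if present).
#' @param models A `gene_models` object from [read_gene_models()].
#' @return data.frame: the input columns plus `category`, `gene_id`
#'   (`NA` for intergenic), `gene_related` and `all_overlaps`
#'   (semicolon-joined `gene:category` pairs).
#' @export
classify_sites <- function(sites, models) {
  stopifnot(inherits(models, "gene_models"))
  cats <- context_categories()
  n <- nrow(sites)
  # one labelled interval table across all genes
  ivs <- do.call(rbind, lapply(seq_len(nrow(models$genes)), function(i) {
    g <- models$genes[i, ]
    iv <- gene_intervals(g, models$features)
    iv$gene_id <- g$gene_id
    iv$chrom <- g$chrom
    iv
  }))
  iv_gr <- GenomicRanges::GRanges(
    ivs$chrom, IRanges::IRanges(ivs$start, ivs$end))
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  # sites on chromosomes absent from the models are legitimately intergenic
  hits <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, iv_gr))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)

  category <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  all_overlaps <- rep("", n)
  if (length(q)) {
    prec <- match(ivs$category[s], cats)
    for (i in unique(q)) {
      sel <- s[q == i]
      pr <- match(ivs$category[sel], cats)
      # per-gene best category, then best across genes
      per_gene <- tapply(pr, ivs$gene_id[sel], min)
      best_gene <- names(per_gene)[order(per_gene, names(per_gene))][1]
      category[i] <- cats[per_gene[[best_gene]]]
      gene_id[i] <- best_gene
      og <- order(per_gene, names(per_gene))
      all_overlaps[i] <- paste(
        paste0(names(per_gene)[og], ":", cats[per_gene[og]]),
        collapse = ";")
    }
  }
  out <- sites
  out$category <- factor(category, levels = cats)
  out$gene_id <- gene_id
  out$gene_related <- category != "intergenic"
  out$all_overlaps <- all_overlaps
  out
}

#' Count the 12 ordered SNP substitution types
#'
#' Ordered ref->alt pairs over {A,C,G,T} (4 x 3 = 12 types); complementary
#' types (e.g. G->A vs C->T) are kept distinct. Counts sum to the number of
#' input sites.
#'
#' @param sites data.frame with single-nucleotide `ref` and `alt` columns,
#'   ref != alt.
#' @return Named integer vector over the 12 types ("A>C", ..., "T>G").
#' @export
snp_spectrum <- function(sites) {
  dna <- c("A", "C", "G", "T")
  types <- unlist(lapply(dna, function(r)
    paste0(r, ">", setdiff(dna, r))))
  if (nrow(sites) == 0) {
    return(stats::setNames(integer(length(types)), types))
  }
  if (!all(sites$ref %in% dna & sites$alt %in% dna) ||
      any(sites$ref == sites$alt)) {
    stop("snp_spectrum requires single-nucleotide sites with ref != alt",
         call. = FALSE)
  }
  obs <- table(factor(paste0(sites$ref, ">", sites$alt), levels = types))
  stats::setNames(as.integer(obs), types)
}

#' Down-sampling test of gene-related enrichment
#'
#' Draws `n_sets` random subsets of `set_size` sites (without replacement,
#' independently per set) from the non-fingerprint pool and counts
#' gene-related sites in each, for comparison with the observed count among
#' the fingerprint sites. The one-sided empirical p-value
#' `(1 + #{sets with count <= observed}) / (n_sets + 1)` asks whether
#' fingerprint sites are depleted of gene-related contexts.
#'
#' @param fingerprint_gene_related Logical vector: gene-related flag per
#'   fingerprint site (e.g. `classify_sites(...)$gene_related`).
#' @param pool_gene_related Logical vector over the non-fingerprint pool.
#' @param set_size Sites per set; defaults to the number of fingerprint
#'   sites.
#' @param n_sets Number of sets, default 1000.
#' @param seed Integer seed.
#' @return List with `observed`, `set_counts` (length `n_sets`),
#'   `p_value`, `set_size`, `n_sets`.
#' @export
gene_related_downsample_test <- function(fingerprint_gene_related,
                                         pool_gene_related,
                                         set_size =
                                           length(fingerprint_gene_related),
                                         n_sets = 1000, seed) {
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  pool <- as.logical(pool_gene_related)
  if (length(pool) < set_size) {
    stop("pool (", length(pool), ") smaller than set_size (", set_size, ")",
         call. = FALSE)
  }
  set.seed(seed)
  counts <- vapply(seq_len(n_sets), function(i)
    sum(pool[sample.int(length(pool), set_size)]), integer(1))
  observed <- sum(as.logical(fingerprint_gene_related))
  list(
    observed = observed,
    set_counts = counts,
    p_value = (1 + sum(counts <= observed)) / (n_sets + 1),
    set_size = set_size,
    n_sets = n_sets
  )
}
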