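#' Read a multi-sample VCF and apply the site quality filter
#'
#' Parses a VCF (plain or bgzipped), keeps biallelic SNP records passing the
#' QUAL filter, and returns the surviving sites with their raw genotype
#' strings. Records with a missing QUAL (".") are dropped and counted, as are
#' multi-allelic and non-SNP records when `biallelic_snps_only = TRUE`.
#'
#' @param path Path to a VCF 4.x file with a GT entry in FORMAT.
#' @param min_qual Minimum variant quality score; records with
#'   `QUAL < min_qual` are trimmed. Default 30.
#' @param biallelic_snps_only Drop multi-allelic records and records whose
#'   REF or ALT is not a single nucleotide. Default `TRUE`.
#' @return A list of class `fp_vcf` with elements:
#'   \describe{
#'     \item{sites}{data.frame with columns chrom, pos, ref, alt, qual,
#'       sorted by (chrom, pos).}
#'     \item{gt}{character matrix of GT strings, sites x samples, rows
#'       aligned with `sites`.}
#'     \item{samples}{sample IDs in VCF header order.}
#'     \item{dropped}{named integer vector with counts for `low_qual`,
#'       `missing_qual`, `multiallelic`, `non_snp`.}
#'   }
#' @export
read_vcf <- function(path, min_qual = 30, biallelic_snps_only = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read VCF: file not found: ", path, call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt_keys <- unique(unlist(strsplit(unname(v@gt[, "FORMAT"]), ":", fixed = TRUE)))
  if (nrow(v@gt) > 0 && !("GT" %in% fmt_keys)) {
    stop("VCF has no GT entry in FORMAT: ", path, call. = FALSE)
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix)) # single-record VCF
  samples <- colnames(v@gt)[-1]
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) {
    gt <- base::matrix(gt, nrow = nrow(fix),
                       dimnames = list(NULL, samples))
  }

  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  dropped <- c(low_qual = 0L, missing_qual = 0L, multiallelic = 0L, non_snp = 0L)
  keep <- rep(TRUE, length(pos))

  miss_q <- is.na(qual)
  dropped["missing_qual"] <- sum(miss_q)
  keep[miss_q] <- FALSE

  low_q <- !miss_q & qual < min_qual
  dropped["low_qual"] <- sum(low_q)
  keep[low_q] <- FALSE

  if (biallelic_snps_only) {
    multi <- keep & grepl(",", alt, fixed = TRUE)
    dropped["multiallelic"] <- sum(multi)
    keep[multi] <- FALSE
    dna <- c("A", "C", "G", "T")
    non_snp <- keep & !(toupper(ref) %in% dna & toupper(alt) %in% dna)
    dropped["non_snp"] <- sum(non_snp)
    keep[non_snp] <- FALSE
  }

  if (!any(keep)) {
    warning("no records survive the filters in ", path,
            " (0 sites retained)", call. = FALSE)
  }

  sites <- data.frame(
    chrom = chrom[keep], pos = pos[keep],
    ref = toupper(ref[keep]), alt = toupper(alt[keep]),
    qual = qual[keep], stringsAsFactors = FALSE
  )
  gt <- gt[keep, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(sites) <- NULL
  rownames(gt) <- NULL
  colnames(gt) <- samples

  structure(
    list(sites = sites, gt = gt, samples = samples, dropped = dropped),
    class = "fp_vcf"
  )
}

#' Convert diploid genotype calls to presence/absence
#'
#' A site is "present" in a sample iff the genotype carries at least one ALT
#' allele (heterozygous or homozygous alternate). Missing calls (`./.` or
#' `.`) are treated as absent under the default policy; callers can count
#' them via the `missing` attribute of the result.
#'
#' @param gt Character vector of GT strings (`0/0`, `0/1`, `1|0`, `./.`,
#'   ...). `NA` is treated like a missing call.
#' @param site Optional site label used in parse-error messages.
#' @return Logical vector of the same length, with an integer attribute
#'   `missing` giving the number of missing calls.
#' @export
genotype_to_presence <- function(gt, site = NULL) {
  gt_chr <- stats::setNames(as.character(gt), names(gt))
  is_missing <- is.na(gt_chr) | gt_chr %in% c(".", "./.", ".|.")
  ok <- is_missing | grepl("^[0-9]+([/|][0-9]+)?$", gt_chr)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    lab <- names(gt_chr)[bad]
    stop("malformed genotype '", gt_chr[bad], "'",
         if (!is.null(lab) && nzchar(lab)) paste0(" for sample ", lab),
         if (!is.null(site)) paste0(" at site ", site),
         call. = FALSE)
  }
  alleles <- strsplit(gt_chr, "[/|]")
  present <- vapply(
    alleles,
    function(a) any(a != "0" & a != "."),
    logical(1)
  )
  present[is_missing] <- FALSE
  structure(present, missing = sum(is_missing))
}

#' Read a sample manifest
#'
#' The manifest is a headered TSV with columns `sample`, `role`
#' (target/background) and optionally `region`.
#'
#' @param path Path to the manifest TSV.
#' @return data.frame with columns sample, role and (if present) region.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample", "role") %in% names(m))) {
    stop("manifest must have 'sample' and 'role' columns: ", path,
         call. = FALSE)
  }
  if (anyDuplicated(m$sample)) {
    stop("duplicate sample IDs in manifest: ",
         paste(unique(m$sample[duplicated(m$sample)]), collapse = ", "),
         call. = FALSE)
  }
  bad_role <- setdiff(unique(m$role), c("target", "background"))
  if (length(bad_role)) {
    stop("manifest roles must be 'target' or 'background'; found: ",
         paste(bad_role, collapse = ", "), call. = FALSE)
  }
  m
}

#' Build the site x sample presence/absence matrix
#'
#' Restricts a parsed VCF to the manifest's samples (in manifest order),
#' resolves every genotype to strict presence/absence, and returns the
#' "variant present|absent table" that the fingerprint score consumes.
#' Monomorphic rows (all-present or all-absent) are retained: they score 0
#' or carry minimal IDF downstream and keeping them makes counts auditable.
#'
#' @param vcf An `fp_vcf` object from [read_vcf()].
#' @param manifest data.frame from [read_manifest()], or any data.frame with
#'   a `sample` column.
#' @param max_missing_frac Optional: drop sites whose fraction of missing
#'   genotypes across manifest samples exceeds this value. Default `NULL`
#'   (keep everything).
#' @return A `presence_matrix`: list with `sites` (chrom, pos, ref, alt),
#'   `samples`, `present` (logical matrix), `n_missing` (per-site missing
#'   call count) and `monomorphic` (per-site flag).
#' @export
build_matrix <- function(vcf, manifest, max_missing_frac = NULL) {
  stopifnot(inherits(vcf, "fp_vcf"))
  missing_ids <- setdiff(manifest$sample, vcf$samples)
  if (length(missing_ids)) {
    stop("manifest samples missing from VCF: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(vcf$samples, manifest$sample)
  if (length(extra)) {
    warning(length(extra), " VCF sample(s) absent from manifest dropped: ",
            paste(utils::head(extra, 5), collapse = ", "),
            if (length(extra) > 5) ", ...", call. = FALSE)
  }
  gt <- vcf$gt[, manifest$sample, drop = FALSE]
  n_sites <- nrow(gt)
  present <- matrix(FALSE, n_sites, ncol(gt),
                    dimnames = list(NULL, manifest$sample))
  n_missing <- integer(n_sites)
  for (i in seq_len(n_sites)) {
    site_lab <- paste0(vcf$sites$chrom[i], ":", vcf$sites$pos[i])
    p <- genotype_to_presence(gt[i, ], site = site_lab)
    present[i, ] <- as.logical(p)
    n_missing[i] <- attr(p, "missing")
  }
  sites <- vcf$sites[, c("chrom", "pos", "ref", "alt")]
  if (!is.null(max_missing_frac) && n_sites > 0) {
    keep <- n_missing / ncol(present) <= max_missing_frac
    sites <- sites[keep, , drop = FALSE]
    present <- present[keep, , drop = FALSE]
    n_missing <- n_missing[keep]
    rownames(sites) <- NULL
  }
  rs <- rowSums(present)
  structure(
    list(sites = sites, samples = manifest$sample, present = present,
         n_missing = n_missing,
         monomorphic = rs == 0L | rs == ncol(present)),
    class = "presence_matrix"
  )
}

#' @method print presence_matrix
#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", nrow(x$present), "sites x",
      length(x$samples), "samples;",
      sum(x$monomorphic), "monomorphic\n")
  invisible(x)
}

#' Write / read a presence matrix as TSV
#'
#' The on-disk form is a headered TSV whose first four columns are chrom,
#' pos, ref, alt followed by one 0/1 column per sample. `read_matrix()` is
#' the exact inverse of `write_matrix()`.
#'
#' @param matrix A `presence_matrix`.
#' @param path Output (or input) file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   `presence_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "presence_matrix"))
  out <- cbind(
    matrix$sites,
    as.data.frame(matrix$present * 1L, check.names = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 4 ||
      !identical(header[1:4], c("chrom", "pos", "ref", "alt"))) {
    stop("malformed presence-matrix header (line 1) in ", path,
         ": expected chrom, pos, ref, alt, <samples...>", call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c("character", "integer",
                                          "character", "character",
                                          rep("integer", length(header) - 4)))
  samples <- header[-(1:4)]
  cells <- as.matrix(tab[, samples, drop = FALSE])
  if (nrow(tab) > 0 && !all(cells %in% c(0L, 1L))) {
    bad_row <- which(rowSums(!(tab[, samples, drop = FALSE] == 0 |
                                 tab[, samples, drop = FALSE] == 1)) > 0)[1]
    stop("malformed presence cell at line ", bad_row + 1, " in ", path,
         ": cells must be 0 or 1", call. = FALSE)
  }
  present <- matrix(as.logical(cells), nrow = nrow(tab),
                    ncol = length(samples),
                    dimnames = list(NULL, samples))
  sites <- tab[, 1:4]
  rs <- rowSums(present)
  structure(
    list(sites = sites, samples = samples, present = present,
         n_missing = rep(NA_integer_, nrow(tab)),
         monomorphic = rs == 0L | rs == length(samples)),
    class = "presence_matrix"
  )
}
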