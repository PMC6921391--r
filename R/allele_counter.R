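#' Build reference/alternative allele count matrices from a BAM file
#'
#' For every SNV, reads overlapping the position are fetched from the BAM,
#' filtered by [qc_read_passes] (mapping quality, flag mask 3844, barcode
#' whitelist), and the read base at the SNV position — obtained by laying
#' the read sequence into reference space through its CIGAR — is compared
#' against the ref and alt alleles. Bases matching neither allele, and
#' reads whose alignment has no base at the position (deletions), count
#' towards neither matrix.
#'
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param snvs SNV table as returned by [read_snv_vcf].
#' @param whitelist barcode whitelist (character vector or path).
#' @param cb_tag BAM tag holding the cell barcode (default `"CB"`, the 10x
#'   convention).
#' @param min_mapq minimum mapping quality (default 10).
#' @return an [allele_counts] object with one row per SNV (`"chrom:pos"`)
#'   and one column per whitelist barcode.
#' @export
build_count_matrices <- function(bam, snvs, whitelist, cb_tag = "CB",
                                 min_mapq = 10L) {
  if (is.character(whitelist) && length(whitelist) == 1 && file.exists(whitelist))
    whitelist <- read_barcodes(whitelist)
  stopifnot(is.character(whitelist), length(whitelist) > 0, nrow(snvs) > 0)

  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing_contig <- !(snvs$chrom %in% names(header))
  if (any(missing_contig))
    warning(sum(missing_contig), " SNV(s) on contigs absent from the BAM ",
            "header were skipped (zero counts): ",
            paste(unique(snvs$chrom[missing_contig]), collapse = ", "))

  n_v <- nrow(snvs)
  n_c <- length(whitelist)
  bc_index <- stats::setNames(seq_len(n_c), whitelist)
  tri <- list(i = integer(), j = integer(), ref = integer(), alt = integer())
  usable <- which(!missing_contig)

  if (length(usable)) {
    gr <- GenomicRanges::GRanges(snvs$chrom[usable],
                                 IRanges::IRanges(snvs$pos[usable], width = 1))
    # flag mask 3844 expressed through scanBamFlag; mapq/barcode applied in R
    param <- Rsamtools::ScanBamParam(
      which = gr,
      what = c("pos", "cigar", "seq", "mapq", "flag"),
      tag = cb_tag,
      flag = Rsamtools::scanBamFlag(
        isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
        isNotPassingQualityControls = FALSE, isDuplicate = FALSE,
        isSupplementaryAlignment = FALSE))
    res <- Rsamtools::scanBam(bam, param = param)

    acc_i <- integer(0); acc_j <- integer(0); acc_r <- integer(0); acc_a <- integer(0)
    for (k in seq_along(usable)) {
      v <- usable[k]
      rd <- res[[k]]
      if (length(rd$pos) == 0) next
      cb <- rd$tag[[cb_tag]]
      if (is.null(cb)) next
      keep <- qc_read_passes(rd$flag, rd$mapq, cb, whitelist,
                             min_mapq = min_mapq)
      if (!any(keep)) next
      layered <- GenomicAlignments::sequenceLayer(
        rd$seq[keep], rd$cigar[keep], from = "query", to = "reference")
      off <- snvs$pos[v] - rd$pos[keep] + 1L
      in_range <- off >= 1L & off <= Biostrings::width(layered)
      if (!any(in_range)) next
      base <- as.character(Biostrings::subseq(
        layered[in_range], start = off[in_range], width = 1L))
      bc_keep <- cb[keep][in_range]
      is_ref <- base == snvs$ref[v]
      is_alt <- base == snvs$alt[v]
      hit <- is_ref | is_alt
      if (!any(hit)) next
      jj <- bc_index[bc_keep[hit]]
      tab <- rowsum(cbind(ref = as.integer(is_ref[hit]),
                          alt = as.integer(is_alt[hit])), group = jj)
      acc_i <- c(acc_i, rep.int(v, nrow(tab)))
      acc_j <- c(acc_j, as.integer(rownames(tab)))
      acc_r <- c(acc_r, tab[, "ref"])
      acc_a <- c(acc_a, tab[, "alt"])
    }
    tri <- list(i = acc_i, j = acc_j, ref = acc_r, alt = acc_a)
  }

  dn <- list(snvs$id, whitelist)
  ref <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = as.double(tri$ref),
                              dims = c(n_v, n_c), dimnames = dn)
  alt <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = as.double(tri$alt),
                              dims = c(n_v, n_c), dimnames = dn)
  allele_counts(Matrix::drop0(ref), Matrix::drop0(alt))
}

#' Filter SNVs by aggregate heterozygous genotype likelihood
#'
#' Pools counts over all cells at each SNV and scores the three diploid
#' genotypes RR, RA, AA under a binomial sequencing-error model: an alt
#' read arises with probability `error_rate` under RR, 0.5 under RA, and
#' `1 - error_rate` under AA. The three log10-likelihoods are normalized to
#' probabilities; an SNV is retained iff the normalized log10 probability
#' of RA is at least `log10(1 - error_rate)` — i.e. the pooled counts look
#' confidently heterozygous in aggregate, which is what makes an SNV
#' informative for splitting donors.
#'
#' @param x an [allele_counts] object.
#' @param error_rate per-read sequencing error rate (default 0.01).
#' @param max_depth cap on the pooled per-SNV depth used in the likelihood;
#'   counts above it are scaled down proportionally for numerical stability
#'   (default 10000).
#' @return the filtered [allele_counts] object (rows removed, labels kept
#'   consistent).
#' @export
het_likelihood_filter <- function(x, error_rate = 0.01, max_depth = 10000) {
  stopifnot(inherits(x, "allele_counts"))
  keep <- .het_keep(Matrix::rowSums(x$alt), Matrix::rowSums(x$ref),
                    error_rate, max_depth)
  if (!any(keep))
    stop("all SNVs removed by the heterozygosity filter; consider ",
         "supplying a common-SNP list to enrich for true polymorphisms")
  x[keep, ]
}

# vectorized three-genotype decision on pooled (alt, ref) counts
.het_keep <- function(A, R, error_rate, max_depth = Inf) {
  depth <- A + R
  over <- depth > max_depth
  if (any(over)) {
    sc <- max_depth / depth[over]
    A[over] <- A[over] * sc
    R[over] <- R[over] * sc
  }
  l_rr <- A * log10(error_rate) + R * log10(1 - error_rate)
  l_ra <- (A + R) * log10(0.5)
  l_aa <- A * log10(1 - error_rate) + R * log10(error_rate)
  m <- pmax(l_rr, l_ra, l_aa)
  norm <- m + log10(10^(l_rr - m) + 10^(l_ra - m) + 10^(l_aa - m))
  (l_ra - norm) >= log10(1 - error_rate)
}
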