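#' Read biallelic SNVs from a VCF, applying variant-quality filters
#'
#' Reads a VCF (optionally gzipped), splits multi-allelic records into
#' biallelic ones, keeps single-nucleotide ref/alt pairs only (indels, MNPs
#' and complex events are dropped), and retains records with QUAL strictly
#' greater than `min_qual`. When a common-SNP VCF is supplied the surviving
#' records are further intersected with it on (chrom, pos, ref, alt) so that
#' only population-polymorphic sites are kept.
#'
#' @param path path to a VCF or VCF.gz file.
#' @param min_qual Phred-scaled variant quality threshold; records must have
#'   `QUAL > min_qual` (strict). Default 30.
#' @param common_snp_path optional path to a common-SNP VCF used to filter
#'   the call set.
#'
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual` and `id` (`"chrom:pos"`), in input order.
#' @export
read_snv_vcf <- function(path, min_qual = 30, common_snp_path = NULL) {
  snvs <- .read_vcf_snv_table(path)
  snvs <- snvs[!is.na(snvs$qual) & snvs$qual > min_qual, , drop = FALSE]
  if (!is.null(common_snp_path)) {
    common <- .read_vcf_snv_table(common_snp_path)
    key <- paste(snvs$chrom, snvs$pos, snvs$ref, snvs$alt)
    common_key <- paste(common$chrom, common$pos, common$ref, common$alt)
    snvs <- snvs[key %in% common_key, , drop = FALSE]
  }
  if (nrow(snvs) == 0)
    stop("no informative variants survive filtering; consider lowering ",
         "'min_qual' or supplying a common-SNP list covering this region")
  rownames(snvs) <- NULL
  snvs
}

# Parse a VCF into a biallelic single-nucleotide table. Multi-allelic
# records are split into one row per ALT allele before filtering.
.read_vcf_snv_table <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  .check_vcf_header(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), id = character(),
                      stringsAsFactors = FALSE))
  alt_split <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  n_alt[n_alt == 0] <- 1L
  alt_split[lengths(alt_split) == 0] <- list(NA_character_)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  out <- data.frame(
    chrom = fix[idx, "CHROM"],
    pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"],
    alt = unlist(alt_split),
    qual = suppressWarnings(as.numeric(fix[idx, "QUAL"])),
    stringsAsFactors = FALSE
  )
  keep <- !is.na(out$ref) & !is.na(out$alt) &
    nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T")
  out <- out[keep, , drop = FALSE]
  out$id <- paste0(out$chrom, ":", out$pos)
  rownames(out) <- NULL
  out
}

.check_vcf_header <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  found <- FALSE
  for (k in seq_len(1000L)) {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (startsWith(line, "#CHROM")) { found <- TRUE; break }
    if (!startsWith(line, "##"))
      stop("malformed VCF at line ", k, " of ", path, ": ", substr(line, 1, 60))
  }
  if (!found) stop("malformed VCF: no #CHROM header line in ", path)
  invisible(TRUE)
}

#' Read a barcode whitelist
#'
#' One barcode per line; blank lines are ignored, duplicates are removed
#' with a warning (first occurrence kept).
#'
#' @param path path to a plain-text barcode list.
#' @return character vector of unique barcodes, in order of first occurrence.
#' @export
read_barcodes <- function(path) {
  bc <- readLines(path)
  bc <- trimws(bc)
  bc <- bc[nzchar(bc)]
  if (length(bc) == 0) stop("barcode whitelist is empty: ", path)
  if (anyDuplicated(bc)) {
    warning(sum(duplicated(bc)), " duplicated barcode(s) removed from whitelist")
    bc <- bc[!duplicated(bc)]
  }
  bc
}

#' Read-level quality control predicate
#'
#' Mirrors `samtools view -q 10 -F 3844` plus a barcode-whitelist check: a
#' read passes iff its mapping quality is at least `min_mapq`, none of the
#' flag bits in `flag_mask` (unmapped, secondary, QC-fail, duplicate,
#' supplementary) are set, and its cell barcode is present in the whitelist
#' (reads without a barcode tag fail).
#'
#' @param flag integer vector of SAM flags.
#' @param mapq integer vector of mapping qualities.
#' @param barcode character vector of cell barcodes (NA when the tag is
#'   absent); optional.
#' @param whitelist character vector of valid barcodes; required when
#'   `barcode` is given.
#' @param min_mapq minimum mapping quality (default 10).
#' @param flag_mask SAM flag exclusion mask (default 3844).
#' @return logical vector, one element per read.
#' @export
qc_read_passes <- function(flag, mapq, barcode = NULL, whitelist = NULL,
                           min_mapq = 10L, flag_mask = 3844L) {
  ok <- !is.na(mapq) & mapq >= min_mapq &
    bitwAnd(as.integer(flag), as.integer(flag_mask)) == 0L
  if (!is.null(barcode)) {
    if (is.null(whitelist)) stop("'whitelist' required when 'barcode' is given")
    ok <- ok & !is.na(barcode) & barcode %in% whitelist
  }
  ok
}

#' Write / read a labelled count matrix as CSV
#'
#' Layout matches the demultiplexing pipeline convention: SNVs in rows
#' (labelled `"chrom:pos"`), barcodes in columns, first header cell empty.
#' Integer counts round-trip losslessly.
#'
#' @param m matrix (dense or sparse) of counts.
#' @param row_ids,col_ids row and column labels; default to the dimnames.
#' @param path output CSV path.
#' @return `write_matrix_csv` returns `path` invisibly; `read_matrix_csv`
#'   returns a sparse [Matrix::dgCMatrix-class] with dimnames.
#' @export
write_matrix_csv <- function(m, path, row_ids = rownames(m), col_ids = colnames(m)) {
  if (is.null(dim(m)) || nrow(m) == 0 || ncol(m) == 0)
    stop("cannot write an empty matrix")
  if (length(row_ids) != nrow(m) || length(col_ids) != ncol(m))
    stop("label lengths do not match matrix dimensions")
  dm <- as.matrix(m)
  lines <- c(
    paste0(",", paste(col_ids, collapse = ",")),
    paste0(row_ids, ",", apply(dm, 1, paste, collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
              "CsparseMatrix")
}

#' Write / read allele count matrix pairs
#'
#' Convenience wrappers writing `ref_filtered.csv` / `alt_filtered.csv`
#' under a directory, the on-disk interface between the counting and
#' modelling stages.
#'
#' @param x an [allele_counts] object.
#' @param dir directory to write into (created if needed).
#' @return `write_allele_counts` returns the two paths invisibly;
#'   `read_allele_counts` returns an [allele_counts] object.
#' @export
write_allele_counts <- function(x, dir) {
  stopifnot(inherits(x, "allele_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rp <- file.path(dir, "ref_filtered.csv")
  ap <- file.path(dir, "alt_filtered.csv")
  write_matrix_csv(x$ref, rp)
  write_matrix_csv(x$alt, ap)
  invisible(c(ref = rp, alt = ap))
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(dir) {
  ref <- read_matrix_csv(file.path(dir, "ref_filtered.csv"))
  alt <- read_matrix_csv(file.path(dir, "alt_filtered.csv"))
  allele_counts(ref, alt)
}
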