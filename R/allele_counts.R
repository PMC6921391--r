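#' Paired reference/alternative allele count matrices
#'
#' The central data structure of the package: two sparse integer matrices of
#' identical shape, SNVs in rows and cell barcodes in columns, holding the
#' number of reads supporting the reference and the alternative allele at
#' each (SNV, barcode) pair.
#'
#' @param ref,alt matrices (dense or sparse) of non-negative counts with
#'   identical dimensions. Coerced to [Matrix::dgCMatrix-class].
#' @param snv_ids character vector of row labels, conventionally
#'   `"chrom:pos"`. Defaults to `rownames(ref)`.
#' @param barcodes character vector of column labels (cell barcodes).
#'   Defaults to `colnames(ref)`.
#'
#' @return An object of class `"allele_counts"`: a list with elements
#'   `ref` and `alt` (sparse matrices) carrying shared dimnames.
#' @export
#' @examples
#' ref <- matrix(c(2, 0, 1, 3), 2, 2, dimnames = list(c("1:10", "1:20"), c("AC", "GT")))
#' alt <- matrix(c(0, 4, 1, 0), 2, 2, dimnames = dimnames(ref))
#' ac <- allele_counts(ref, alt)
#' ac
allele_counts <- function(ref, alt, snv_ids = rownames(ref),
                          barcodes = colnames(ref)) {
  if (is.null(dim(ref)) || is.null(dim(alt)))
    stop("'ref' and 'alt' must be matrices")
  if (!all(dim(ref) == dim(alt)))
    stop("'ref' and 'alt' must have identical dimensions")
  if (is.null(snv_ids)) snv_ids <- paste0("snv", seq_len(nrow(ref)))
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(ncol(ref)))
  if (length(snv_ids) != nrow(ref) || length(barcodes) != ncol(ref))
    stop("label lengths do not match matrix dimensions")
  if (anyDuplicated(snv_ids)) stop("duplicated SNV ids")
  if (anyDuplicated(barcodes)) stop("duplicated barcodes")
  ref <- methods::as(methods::as(Matrix::Matrix(ref, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  alt <- methods::as(methods::as(Matrix::Matrix(alt, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  if (min(ref@x, 0) < 0 || min(alt@x, 0) < 0)
    stop("allele counts must be non-negative")
  dimnames(ref) <- dimnames(alt) <- list(snv_ids, barcodes)
  structure(list(ref = ref, alt = alt), class = "allele_counts")
}

#' @export
dim.allele_counts <- function(x) dim(x$ref)

#' @export
dimnames.allele_counts <- function(x) dimnames(x$ref)

#' @export
print.allele_counts <- function(x, ...) {
  d <- dim(x)
  nz <- length((x$ref + x$alt)@x)
  cat(sprintf(
    "allele_counts: %d SNVs x %d cells (%.1f%% of entries covered)\n",
    d[1], d[2], 100 * nz / max(1, prod(d))))
  cat(sprintf("  total ref reads: %.0f, total alt reads: %.0f\n",
              sum(x$ref), sum(x$alt)))
  invisible(x)
}

#' @export
`[.allele_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$ref))
  if (missing(j)) j <- seq_len(ncol(x$ref))
  allele_counts(x$ref[i, j, drop = FALSE], x$alt[i, j, drop = FALSE])
}

#' Total (ref + alt) coverage matrix
#'
#' @param x an [allele_counts] object.
#' @return sparse matrix of per-(SNV, cell) total allele counts.
#' @export
total_counts <- function(x) {
  stopifnot(inherits(x, "allele_counts"))
  x$ref + x$alt
}
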