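#' Select a dense cell/SNV submatrix for model seeding
#'
#' The full SNV-by-cell matrix is sparse; model seeding needs a dense core.
#' Cells are ranked by how many SNVs have zero total allele count in them,
#' and SNVs by how many cells have zero count at them; each iteration
#' removes `trim_fraction` of the current cells and SNVs, drawn at random
#' from within the worst `low_rank_width` fraction of the ranking (this is
#' the randomness that differentiates restarts). Iteration stops once every
#' remaining cell is non-zero at more than `target_density` of the
#' remaining SNVs and every remaining SNV is non-zero in more than
#' `target_density` of the remaining cells.
#'
#' @param x an [allele_counts] object.
#' @param trim_fraction fraction of cells/SNVs removed per iteration
#'   (default 0.10).
#' @param target_density density both sides must exceed (default 0.90).
#' @param low_rank_width width of the worst-ranked pool the removals are
#'   sampled from, as a fraction (default 0.20). Set equal to
#'   `trim_fraction` for a deterministic worst-first trim.
#' @param min_cells abort if fewer cells than this remain (default 30,
#'   i.e. ten per cluster for a two-donor pool with a doublet cluster).
#' @return list with integer index vectors `cells` and `snvs` into the
#'   columns/rows of `x`, plus `iterations`.
#' @export
select_dense_submatrix <- function(x, trim_fraction = 0.10,
                                   target_density = 0.90,
                                   low_rank_width = 0.20,
                                   min_cells = 30L) {
  stopifnot(inherits(x, "allele_counts"))
  tot <- total_counts(x)
  nz <- tot
  nz@x <- rep(1, length(nz@x))  # sparse 0/1 coverage pattern
  cells <- seq_len(ncol(tot))
  snvs <- seq_len(nrow(tot))
  iter <- 0L
  repeat {
    sub <- nz[snvs, cells, drop = FALSE]
    cell_nnz <- Matrix::colSums(sub)
    snv_nnz <- Matrix::rowSums(sub)
    if (all(cell_nnz > target_density * length(snvs)) &&
        all(snv_nnz > target_density * length(cells))) break
    n_rm_c <- min(max(1L, ceiling(trim_fraction * length(cells))),
                  length(cells) - 1L)
    n_rm_v <- min(max(1L, ceiling(trim_fraction * length(snvs))),
                  length(snvs) - 1L)
    pool_c <- max(n_rm_c, ceiling(low_rank_width * length(cells)))
    pool_v <- max(n_rm_v, ceiling(low_rank_width * length(snvs)))
    # worst = most zeros = smallest non-zero count; ties by original index
    ord_c <- order(cell_nnz, seq_along(cells))
    ord_v <- order(snv_nnz, seq_along(snvs))
    rm_c <- ord_c[seq_len(pool_c)][sample.int(pool_c, n_rm_c)]
    rm_v <- ord_v[seq_len(pool_v)][sample.int(pool_v, n_rm_v)]
    cells <- cells[-rm_c]
    snvs <- snvs[-rm_v]
    iter <- iter + 1L
    if (length(cells) < min_cells)
      stop("dense-submatrix selection collapsed to ", length(cells),
           " cells (< ", min_cells, "); lower 'target_density' or provide ",
           "deeper data")
    if (length(snvs) < 2L)
      stop("dense-submatrix selection exhausted the SNVs; lower ",
           "'target_density'")
  }
  list(cells = cells, snvs = snvs, iterations = iter)
}

#' Seed cell clusters by PCA and K-means on allele fractions
#'
#' Computes per-(cell, SNV) alternative-allele fractions
#' `alt / (alt + ref)` on the dense seed submatrix (zero-coverage entries
#' are treated as 0), reduces cells to `n_pca` principal components, and
#' partitions them into `n_clusters` groups with K-means (10 random
#' starts). If K-means yields an empty cluster the clustering is retried
#' (up to 10 attempts) before erroring.
#'
#' @param x an [allele_counts] object.
#' @param cells,snvs seed indices from [select_dense_submatrix].
#' @param n_clusters number of clusters (donors, plus one if a doublet
#'   cluster is modelled).
#' @param n_pca number of principal components; default
#'   `min(20, n_snvs, n_cells - 1)`.
#' @return integer vector of cluster labels (1..n_clusters) named by the
#'   seed cell barcodes; every cluster non-empty.
#' @export
seed_clusters <- function(x, cells, snvs, n_clusters, n_pca = NULL) {
  stopifnot(inherits(x, "allele_counts"), n_clusters >= 1,
            length(cells) >= n_clusters, length(snvs) >= 1)
  ref <- as.matrix(x$ref[snvs, cells, drop = FALSE])
  alt <- as.matrix(x$alt[snvs, cells, drop = FALSE])
  tot <- ref + alt
  frac <- matrix(0, nrow(tot), ncol(tot))
  nz <- tot > 0
  frac[nz] <- alt[nz] / tot[nz]
  feat <- t(frac)  # cells x snvs
  if (is.null(n_pca)) n_pca <- min(20L, ncol(feat), nrow(feat) - 1L)
  n_pca <- max(1L, min(n_pca, ncol(feat), nrow(feat) - 1L))
  keep_var <- apply(feat, 2, stats::var) > 0
  scores <- if (any(keep_var)) {
    pc <- stats::prcomp(feat[, keep_var, drop = FALSE], center = TRUE,
                        rank. = n_pca)
    pc$x
  } else feat  # degenerate: no variance anywhere, K-means will tie-break
  if (n_clusters == 1L)
    return(stats::setNames(rep(1L, length(cells)), colnames(x$ref)[cells]))
  for (attempt in seq_len(10L)) {
    km <- tryCatch(
      stats::kmeans(scores, centers = n_clusters, nstart = 10L,
                    iter.max = 100L),
      error = function(e) NULL)
    if (!is.null(km) && all(tabulate(km$cluster, n_clusters) > 0))
      return(stats::setNames(as.integer(km$cluster),
                             colnames(x$ref)[cells]))
  }
  stop("K-means produced an empty cluster in 10 attempts; too few ",
       "distinct seed cells for ", n_clusters, " clusters")
}

#' Initialize the allele fraction model from seed labels
#'
#' Per-cluster alternative-allele probabilities are the pseudo-count
#' smoothed alt fractions over the seed cells of each cluster:
#' `P(A_v | S_n) = (sum_c alt + pseudo_a) / (sum_c alt + sum_c ref +
#' pseudo_ar)`, computed at every SNV of `x` (not just the seed SNVs), and
#' cluster weights start uniform, `P(S_n) = 1 / n_clusters`.
#'
#' @param x an [allele_counts] object (full matrix).
#' @param labels named integer cluster labels over seed cells, as from
#'   [seed_clusters].
#' @param pseudo_a pseudo-count added to alt sums (default 1).
#' @param pseudo_ar pseudo-count added to total sums (default 2).
#' @return an `"af_model"` object: list with `P_A` (SNV x cluster matrix,
#'   all entries in (0,1)), `P_S` (cluster weights summing to 1), and the
#'   pseudo-counts.
#' @export
init_model <- function(x, labels, pseudo_a = 1, pseudo_ar = 2) {
  stopifnot(inherits(x, "allele_counts"), length(labels) >= 1)
  k <- max(labels)
  if (!all(tabulate(labels, k) > 0))
    stop("every cluster must have at least one seed cell")
  cells <- match(names(labels), colnames(x$ref))
  if (anyNA(cells)) stop("seed labels name cells absent from the matrix")
  P_A <- matrix(NA_real_, nrow(x$ref), k,
                dimnames = list(rownames(x$ref), paste0("S", seq_len(k))))
  for (n in seq_len(k)) {
    idx <- cells[labels == n]
    a <- Matrix::rowSums(x$alt[, idx, drop = FALSE])
    r <- Matrix::rowSums(x$ref[, idx, drop = FALSE])
    P_A[, n] <- (a + pseudo_a) / (a + r + pseudo_ar)
  }
  af_model(P_A, rep(1 / k, k), pseudo_a, pseudo_ar)
}

#' Construct/validate an allele fraction model
#'
#' @param P_A SNV x cluster matrix of alternative-allele probabilities,
#'   all strictly inside (0, 1).
#' @param P_S cluster weights summing to 1.
#' @param pseudo_a,pseudo_ar pseudo-counts carried for the M-step.
#' @return an `"af_model"` object.
#' @export
af_model <- function(P_A, P_S, pseudo_a = 1, pseudo_ar = 2) {
  P_A <- as.matrix(P_A)
  if (any(P_A <= 0 | P_A >= 1))
    stop("P_A entries must lie strictly in (0, 1)")
  if (length(P_S) != ncol(P_A)) stop("length(P_S) must equal ncol(P_A)")
  if (abs(sum(P_S) - 1) > 1e-9) stop("P_S must sum to 1")
  if (is.null(colnames(P_A))) colnames(P_A) <- paste0("S", seq_len(ncol(P_A)))
  structure(list(P_A = P_A, P_S = as.numeric(P_S),
                 pseudo_a = pseudo_a, pseudo_ar = pseudo_ar),
            class = "af_model")
}

#' @export
print.af_model <- function(x, ...) {
  cat(sprintf("af_model: %d SNVs x %d clusters\n", nrow(x$P_A), ncol(x$P_A)))
  cat("  cluster weights:", paste(sprintf("%.3f", x$P_S), collapse = " "), "\n")
  invisible(x)
}
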