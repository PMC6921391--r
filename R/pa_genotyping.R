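#' Presence/absence genotyping of clusters
#'
#' Pools allele counts over the cells assigned to each singlet cluster and
#' codes each (SNV, cluster) pair: `"P"` when more than `min_count`
#' alternative-allele reads are present, `"A"` when more than `min_count`
#' reference reads are present and no alternative read at all, `"NA"`
#' otherwise. Doublet and unassigned cells never contribute.
#'
#' @param x an [allele_counts] object.
#' @param labels per-cell labels (e.g. from a [poolsplit] fit): cluster
#'   names, `"DBL"`, or `"unassigned"`.
#' @param min_count count threshold (default 10, strict `>`).
#' @return character matrix (SNVs x clusters) with entries `"P"`, `"A"`,
#'   `"NA"`.
#' @export
cluster_pa_matrix <- function(x, labels, min_count = 10) {
  stopifnot(inherits(x, "allele_counts"))
  labels <- labels[colnames(x$ref)]
  clusters <- sort(unique(labels[startsWith(labels, "SNG")]))
  if (!length(clusters)) stop("no singlet clusters in 'labels'")
  pa <- matrix("NA", nrow(x$ref), length(clusters),
               dimnames = list(rownames(x$ref), clusters))
  for (cl in clusters) {
    idx <- which(labels == cl)
    if (!length(idx)) {
      warning("cluster ", cl, " has no assigned cells; all-NA column")
      next
    }
    a <- Matrix::rowSums(x$alt[, idx, drop = FALSE])
    r <- Matrix::rowSums(x$ref[, idx, drop = FALSE])
    pa[a > min_count, cl] <- "P"
    pa[r > min_count & a == 0, cl] <- "A"
  }
  pa
}

#' Presence/absence genotyping of donors from genotype probabilities
#'
#' Builds the donor-side P/A matrix from per-donor GP triplets: `"P"` when
#' the genotype probability of RA or of AA exceeds `gp_threshold`, `"A"`
#' when the probability of RR exceeds it, `"NA"` otherwise. SNVs requested
#' but absent from the donor data give all-NA rows with a warning.
#'
#' @param donors a `donor_genotypes` object (see [synth_donor_genotypes] /
#'   [read_donor_genotypes]).
#' @param snv_subset optional character vector of SNV ids (`"chrom:pos"`)
#'   to restrict/order the rows by.
#' @param gp_threshold genotype-probability threshold (default 0.9).
#' @param r2_filter optional minimum imputation quality; rows whose `r2`
#'   annotation falls below it are set to NA. Skipped when the donor data
#'   carry no `r2` field.
#' @return character matrix (SNVs x donors) with entries `"P"`, `"A"`,
#'   `"NA"`.
#' @export
sample_pa_matrix <- function(donors, snv_subset = NULL, gp_threshold = 0.9,
                             r2_filter = NULL) {
  stopifnot(inherits(donors, "donor_genotypes"))
  gp <- donors$gp  # donors x snvs x 3 (RR, RA, AA)
  n_d <- dim(gp)[1]
  ids <- donors$snvs$id
  pa_all <- matrix("NA", length(ids), n_d,
                   dimnames = list(ids, donors$donor_ids))
  for (d in seq_len(n_d)) {
    p <- matrix(gp[d, , ], ncol = 3)
    is_p <- p[, 2] > gp_threshold | p[, 3] > gp_threshold
    is_a <- p[, 1] > gp_threshold
    pa_all[is_p, d] <- "P"
    pa_all[is_a, d] <- "A"
  }
  if (!is.null(r2_filter) && !is.null(donors$snvs$r2))
    pa_all[donors$snvs$r2 < r2_filter, ] <- "NA"
  if (is.null(snv_subset)) return(pa_all)
  hit <- match(snv_subset, ids)
  if (anyNA(hit))
    warning(sum(is.na(hit)), " requested SNV(s) absent from donor ",
            "genotypes; set to NA")
  out <- matrix("NA", length(snv_subset), n_d,
                dimnames = list(snv_subset, donors$donor_ids))
  ok <- !is.na(hit)
  out[ok, ] <- pa_all[hit[ok], , drop = FALSE]
  out
}

#' Minimal distinguishing-variant set from a P/A matrix
#'
#' Finds a small set of SNVs whose P/A patterns separate every pair of
#' clusters, so that genotyping only those loci suffices to map clusters to
#' donors. Candidate rows are the NA-free rows showing both `"P"` and
#' `"A"` across clusters, deduplicated by pattern. On small instances the
#' returned set is exactly minimum-cardinality (enumeration by increasing
#' subset size); on larger instances rows are selected greedily by
#' Gram-Schmidt orthogonalization (a row is kept when its residual after
#' projection on the span of the already-selected rows exceeds `tol`),
#' followed by pair-repair: any cluster pair still unseparated is fixed by
#' adding an NA-free row that differs between the two.
#'
#' @param pa character matrix (SNVs x clusters), entries `"P"`, `"A"`,
#'   `"NA"`.
#' @param tol Gram-Schmidt residual tolerance for linear independence
#'   (default 1e-6).
#' @param exact_limit maximum number of candidate subsets enumerated by the
#'   exact search before falling back to the greedy path (default 2e5).
#' @return character vector of selected SNV row names; guaranteed to
#'   pairwise-separate all clusters (error otherwise).
#' @export
distinguishing_variants <- function(pa, tol = 1e-6, exact_limit = 2e5) {
  stopifnot(is.matrix(pa), ncol(pa) >= 2)
  k <- ncol(pa)
  na_free <- rowSums(pa == "NA") == 0
  has_both <- rowSums(pa == "P") > 0 & rowSums(pa == "A") > 0
  informative <- which(na_free & has_both)
  pairs <- utils::combn(k, 2)

  .check_separation <- function(rows) {
    # rows: character row names; TRUE iff every cluster pair differs somewhere
    sub <- pa[rows, , drop = FALSE]
    all(vapply(seq_len(ncol(pairs)), function(p)
      any(sub[, pairs[1, p]] != sub[, pairs[2, p]]), logical(1)))
  }
  .uncovered_pairs <- function(rows) {
    sub <- pa[rows, , drop = FALSE]
    which(!vapply(seq_len(ncol(pairs)), function(p)
      nrow(sub) > 0 && any(sub[, pairs[1, p]] != sub[, pairs[2, p]]),
      logical(1)))
  }
  .repair <- function(selected) {
    for (p in .uncovered_pairs(selected)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      cand <- which(na_free & pa[, i] != pa[, j])
      cand <- setdiff(rownames(pa)[cand], selected)
      if (!length(cand))
        stop("clusters ", colnames(pa)[i], " and ", colnames(pa)[j],
             " are indistinguishable on every NA-free SNV")
      selected <- c(selected, cand[1])
    }
    selected
  }

  if (!length(informative)) return(.repair(character(0)))

  patt <- apply(pa[informative, , drop = FALSE], 1, paste, collapse = "")
  uniq <- informative[!duplicated(patt)]
  uniq_names <- rownames(pa)[uniq]
  enc <- (pa[uniq, , drop = FALSE] == "P") * 1  # P=1 / A=0

  # exact minimum set cover over the unique informative patterns
  lower <- max(1L, ceiling(log2(k)))
  n_u <- length(uniq)
  budget <- 0
  for (size in seq.int(min(lower, n_u), n_u)) {
    n_comb <- choose(n_u, size)
    budget <- budget + n_comb
    if (budget > exact_limit) break
    combs <- utils::combn(n_u, size)
    for (ci in seq_len(ncol(combs))) {
      rows <- uniq_names[combs[, ci]]
      if (.check_separation(rows)) return(.repair(rows))
    }
  }

  # greedy Gram-Schmidt on the encoded patterns
  selected <- character(0)
  basis <- NULL
  for (r in seq_len(n_u)) {
    v <- enc[r, ]
    resid <- v
    if (!is.null(basis))
      for (b in seq_len(ncol(basis))) {
        u <- basis[, b]
        resid <- resid - sum(resid * u) * u
      }
    nrm <- sqrt(sum(resid^2))
    if (nrm > tol) {
      basis <- cbind(basis, resid / nrm)
      selected <- c(selected, uniq_names[r])
      if (.check_separation(selected)) return(selected)
    }
  }
  .repair(selected)
}

#' Map clusters to donor samples by P/A matrix agreement
#'
#' Scores every (cluster, donor) pair by the fraction of distinguishing
#' variants at which the two P/A matrices agree (positions where either
#' side is `"NA"` are excluded) and solves the one-to-one assignment
#' maximizing total agreement — exactly, by permutation enumeration, for up
#' to 8 clusters, greedily beyond. A tied optimum returns one mapping with
#' a warning carrying both scores.
#'
#' @param cluster_pa clusters-side P/A matrix (rows = SNV ids).
#' @param sample_pa donor-side P/A matrix (rows = SNV ids).
#' @param variants character vector of distinguishing-variant row ids; the
#'   scoring is restricted to these rows.
#' @return list with `mapping` (named character vector, cluster -> donor),
#'   `match_fraction` (per mapped pair), and `score_matrix`.
#' @export
map_clusters_to_samples <- function(cluster_pa, sample_pa, variants) {
  v1 <- intersect(variants, rownames(cluster_pa))
  v1 <- intersect(v1, rownames(sample_pa))
  if (!length(v1)) stop("no shared distinguishing variants to compare on")
  cpa <- cluster_pa[v1, , drop = FALSE]
  spa <- sample_pa[v1, , drop = FALSE]
  nc <- ncol(cpa); ns <- ncol(spa)
  if (nc > ns) stop("more clusters than donor samples")
  score <- matrix(0, nc, ns, dimnames = list(colnames(cpa), colnames(spa)))
  for (i in seq_len(nc)) for (j in seq_len(ns)) {
    ok <- cpa[, i] != "NA" & spa[, j] != "NA"
    score[i, j] <- if (any(ok)) mean(cpa[ok, i] == spa[ok, j]) else 0
  }
  if (nc <= 8) {
    perms <- .permutations(ns, nc)
    totals <- vapply(seq_len(nrow(perms)), function(p)
      sum(score[cbind(seq_len(nc), perms[p, ])]), numeric(1))
    best <- which.max(totals)
    tied <- which(abs(totals - totals[best]) < 1e-12)
    if (length(tied) > 1)
      warning("ambiguous cluster-to-sample mapping: ", length(tied),
              " assignments tie at total score ",
              format(totals[best], digits = 6))
    assign <- perms[best, ]
  } else {
    assign <- integer(nc)
    taken <- logical(ns)
    sc <- score
    for (step in seq_len(nc)) {
      ix <- which(sc == max(sc), arr.ind = TRUE)[1, ]
      assign[ix[1]] <- ix[2]
      sc[ix[1], ] <- -Inf
      sc[, ix[2]] <- -Inf
      taken[ix[2]] <- TRUE
    }
    warning("more than 8 clusters: greedy (not provably optimal) mapping")
  }
  mapping <- stats::setNames(colnames(spa)[assign], colnames(cpa))
  list(mapping = mapping,
       match_fraction = stats::setNames(score[cbind(seq_len(nc), assign)],
                                        colnames(cpa)),
       score_matrix = score)
}

# all ordered selections of r items from n (n small)
.permutations <- function(n, r) {
  if (r == 1) return(matrix(seq_len(n), ncol = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(n - 1, r - 1)
    rest <- matrix(setdiff(seq_len(n), i)[rest], nrow = nrow(rest))
    out <- rbind(out, cbind(i, rest))
  }
  unname(out)
}

#' Write a P/A matrix as TSV
#'
#' @param pa character P/A matrix.
#' @param path output path.
#' @export
write_pa_matrix <- function(pa, path) {
  lines <- c(paste(c("snv", colnames(pa)), collapse = "\t"),
             paste(rownames(pa),
                   apply(pa, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
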