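#' E-step: cell-by-cluster log-likelihoods and posteriors
#'
#' For each cell and cluster the log-likelihood of the cell's allele counts
#' under the cluster's allele fractions is
#' `log P(C_i | S_n) = sum_v [ alt_iv * log P(A_v|S_n) + ref_iv * log(1 -
#' P(A_v|S_n)) ]` (sums run over non-zero counts only). Posteriors
#' `P(S_n | C_i)` are obtained by Bayes' rule with the current cluster
#' weights as prior, normalized per cell through log-sum-exp. At model
#' initialization the weights are uniform, so the first E-step weighs all
#' clusters equally.
#'
#' @param model an [af_model] object.
#' @param x an [allele_counts] object whose rows match `model$P_A`.
#' @return list with `loglik` (cells x clusters matrix of
#'   `log P(C_i|S_n)`) and `posterior` (cells x clusters, rows sum to 1).
#' @export
e_step <- function(model, x) {
  stopifnot(inherits(model, "af_model"), inherits(x, "allele_counts"))
  if (nrow(x$ref) != nrow(model$P_A))
    stop("matrix rows do not match model SNVs")
  ll <- as.matrix(Matrix::crossprod(x$alt, log(model$P_A)) +
                  Matrix::crossprod(x$ref, log1p(-model$P_A)))
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll), arr.ind = TRUE)[1, ]
    stop("non-finite log-likelihood for cell ", rownames(ll)[bad[1]],
         " in cluster ", bad[2])
  }
  posterior <- .softmax_rows(sweep(ll, 2, log(model$P_S), `+`))
  dimnames(posterior) <- list(colnames(x$ref), colnames(model$P_A))
  dimnames(ll) <- dimnames(posterior)
  list(loglik = ll, posterior = posterior)
}

.softmax_rows <- function(m) {
  mx <- apply(m, 1, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' M-step: update allele fractions and cluster weights
#'
#' Allele fractions are recomputed as posterior-weighted pooled fractions,
#' `P(A_v|S_n) = (sum_i alt_iv * w_in + pseudo_a) / (sum_i (alt_iv +
#' ref_iv) * w_in + pseudo_ar)` where `w_in = P(S_n|C_i)`; cluster weights
#' become the normalized posterior column sums.
#'
#' @param x an [allele_counts] object.
#' @param posterior cells x clusters matrix with rows summing to 1.
#' @param pseudo_a,pseudo_ar pseudo-counts (defaults 1 and 2).
#' @return an updated [af_model].
#' @export
m_step <- function(x, posterior, pseudo_a = 1, pseudo_ar = 2) {
  stopifnot(inherits(x, "allele_counts"))
  posterior <- as.matrix(posterior)
  num <- as.matrix(x$alt %*% posterior) + pseudo_a
  den <- as.matrix((x$alt + x$ref) %*% posterior) + pseudo_ar
  P_A <- num / den
  cs <- colSums(posterior)
  af_model(P_A, cs / sum(cs), pseudo_a, pseudo_ar)
}

#' Overall model log-likelihood
#'
#' `L = sum_i log sum_n P(C_i|S_n) P(S_n)`, evaluated stably in log space.
#'
#' @param model an [af_model].
#' @param x an [allele_counts] object.
#' @param loglik optional precomputed `log P(C_i|S_n)` matrix (from
#'   [e_step]) to avoid recomputation.
#' @return scalar log-likelihood.
#' @export
model_log_likelihood <- function(model, x, loglik = NULL) {
  if (is.null(loglik)) loglik <- e_step(model, x)$loglik
  sum(.logsumexp_rows(sweep(loglik, 2, log(model$P_S), `+`)))
}

#' Run EM to convergence from a given model
#'
#' Alternates [e_step] and [m_step] until the absolute change in the model
#' log-likelihood falls below `tol` or `max_iter` is reached.
#'
#' Because the M-step smooths allele fractions with pseudo-counts, it is a
#' maximum-a-posteriori update (a Beta prior on each allele fraction), and
#' the quantity the iteration provably ascends is the penalized objective
#' `J = L + sum_{v,n} [pseudo_a * log P_A + (pseudo_ar - pseudo_a) *
#' log(1 - P_A)]`, returned as `trace_penalized`; `J` is non-decreasing at
#' every iteration up to floating-point slack. The raw log-likelihood
#' `trace` can dip by a small amount near convergence whenever the prior
#' term and the data term trade off.
#'
#' @param x an [allele_counts] object.
#' @param model initial [af_model] (e.g. from [init_model]).
#' @param tol absolute convergence tolerance on the log-likelihood
#'   (default 1e-4).
#' @param max_iter iteration cap (default 1000); hitting it returns the
#'   current state with `converged = FALSE` and a warning.
#' @return list with `model`, `posterior`, `loglik_mat`, `logLik` (final),
#'   `trace` (per-iteration log-likelihoods), `trace_penalized`
#'   (per-iteration penalized objectives, monotone), `n_iter`, `converged`.
#' @export
run_em <- function(x, model, tol = 1e-4, max_iter = 1000L) {
  penalty <- function(m)
    sum(m$pseudo_a * log(m$P_A) +
        (m$pseudo_ar - m$pseudo_a) * log1p(-m$P_A))
  trace <- tracep <- numeric(0)
  prev <- -Inf
  es <- NULL
  for (it in seq_len(max(1L, max_iter))) {
    es <- e_step(model, x)
    L <- model_log_likelihood(model, x, loglik = es$loglik)
    trace <- c(trace, L)
    tracep <- c(tracep, L + penalty(model))
    if (is.finite(prev) && abs(L - prev) < tol) {
      return(list(model = model, posterior = es$posterior,
                  loglik_mat = es$loglik, logLik = L, trace = trace,
                  trace_penalized = tracep, n_iter = it, converged = TRUE))
    }
    prev <- L
    model <- m_step(x, es$posterior, model$pseudo_a, model$pseudo_ar)
  }
  warning("EM did not converge within ", max_iter, " iterations")
  es <- e_step(model, x)
  L <- model_log_likelihood(model, x, loglik = es$loglik)
  list(model = model, posterior = es$posterior, loglik_mat = es$loglik,
       logLik = L, trace = c(trace, L),
       trace_penalized = c(tracep, L + penalty(model)),
       n_iter = max_iter, converged = FALSE)
}

#' Best-of-restarts EM fit
#'
#' Repeats the whole initialization + EM procedure `n_restarts` times —
#' each restart re-randomizes the dense-submatrix trimming and the K-means
#' seeding — and keeps the restart with the largest model log-likelihood.
#'
#' @param x an [allele_counts] object.
#' @param n_clusters total number of mixture components (donors plus the
#'   doublet cluster, if modelled).
#' @param n_restarts number of random restarts (default 30).
#' @param pseudo_a,pseudo_ar pseudo-counts.
#' @param tol,max_iter EM convergence controls.
#' @param trim_fraction,target_density,low_rank_width,min_cells passed to
#'   [select_dense_submatrix].
#' @param n_pca passed to [seed_clusters].
#' @param verbose print per-restart log-likelihoods.
#' @return the best restart's [run_em] result, augmented with
#'   `restart_logLik` (vector over restarts) and `best_restart`.
#' @export
run_restarts <- function(x, n_clusters, n_restarts = 30L,
                         pseudo_a = 1, pseudo_ar = 2,
                         tol = 1e-4, max_iter = 1000L,
                         trim_fraction = 0.10, target_density = 0.90,
                         low_rank_width = 0.20, min_cells = NULL,
                         n_pca = NULL, verbose = FALSE) {
  stopifnot(n_restarts >= 1)
  if (is.null(min_cells)) min_cells <- 10L * n_clusters
  best <- NULL
  Ls <- rep(NA_real_, n_restarts)
  for (r in seq_len(n_restarts)) {
    fit_r <- tryCatch({
      seed_idx <- select_dense_submatrix(
        x, trim_fraction = trim_fraction, target_density = target_density,
        low_rank_width = low_rank_width, min_cells = min_cells)
      labels <- seed_clusters(x, seed_idx$cells, seed_idx$snvs,
                              n_clusters, n_pca = n_pca)
      model0 <- init_model(x, labels, pseudo_a, pseudo_ar)
      run_em(x, model0, tol = tol, max_iter = max_iter)
    }, error = function(e) e)
    if (inherits(fit_r, "error")) {
      if (r == n_restarts && is.null(best)) stop(fit_r)
      next
    }
    Ls[r] <- fit_r$logLik
    if (verbose)
      message(sprintf("restart %d/%d: logLik %.2f (%d iterations)",
                      r, n_restarts, fit_r$logLik, fit_r$n_iter))
    if (is.null(best) || fit_r$logLik > best$logLik) best <- fit_r
  }
  if (is.null(best)) stop("all restarts failed")
  best$restart_logLik <- Ls
  best$best_restart <- which.max(Ls)
  best
}

#' Identify the doublet cluster by cross-assignment likelihood
#'
#' For each cluster `c`, averages over all cells whose maximum-likelihood
#' cluster is not `c` the log-likelihood of those cells under cluster `c`,
#' plus the cluster weight term: `score(c) = mean_{i not in c} log
#' P(C_i|S_c) + log P(S_c)`. A cluster whose allele fractions are
#' intermediate between the donors — the signature of a doublet component —
#' explains other clusters' cells far better than any true donor cluster
#' does, so the argmax is designated the doublet cluster. The score is
#' normalized per outside cell (a mean, not a raw sum) because the doublet
#' cluster is small: a raw sum runs over many more outside cells for small
#' clusters than for large ones, and that set-size imbalance can override
#' the likelihood signal whenever donors are genetically close (e.g.
#' siblings). Ties are broken towards the lowest index with a warning.
#'
#' @param loglik_mat cells x clusters matrix of `log P(C_i|S_n)`.
#' @param P_S cluster weights.
#' @return integer index of the doublet cluster.
#' @export
identify_doublet_cluster <- function(loglik_mat, P_S) {
  k <- ncol(loglik_mat)
  stopifnot(k >= 2)
  hard <- max.col(loglik_mat, ties.method = "first")
  score <- vapply(seq_len(k), function(cl) {
    out <- hard != cl
    if (!any(out)) return(-Inf)
    mean(loglik_mat[out, cl]) + log(P_S[cl])
  }, numeric(1))
  mx <- max(score)
  tied <- which(score >= mx - 1e-9)
  if (length(tied) > 1)
    warning("doublet-cluster score tie between clusters ",
            paste(tied, collapse = ", "), "; taking the lowest index")
  tied[1]
}

#' Assign cells from posterior probabilities
#'
#' A cell is assigned to its maximum-posterior cluster only when that
#' posterior strictly exceeds `threshold`; otherwise it is `"unassigned"`.
#'
#' @param posterior cells x clusters matrix, rows summing to 1.
#' @param threshold assignment threshold (default 0.99, strict).
#' @param doublet_cluster optional index of the doublet cluster; its
#'   assignments are labelled `"DBL"` and the remaining clusters are
#'   renumbered `"SNG-1"`, `"SNG-2"`, ... in index order.
#' @return character vector of labels named by cell barcode.
#' @export
assign_cells <- function(posterior, threshold = 0.99, doublet_cluster = NULL) {
  posterior <- as.matrix(posterior)
  hard <- max.col(posterior, ties.method = "first")
  pmax_ <- posterior[cbind(seq_len(nrow(posterior)), hard)]
  k <- ncol(posterior)
  name_of <- if (is.null(doublet_cluster)) paste0("SNG-", seq_len(k)) else {
    nm <- character(k)
    nm[doublet_cluster] <- "DBL"
    nm[-doublet_cluster] <- paste0("SNG-", seq_len(k - 1))
    nm
  }
  lab <- ifelse(pmax_ > threshold, name_of[hard], "unassigned")
  stats::setNames(lab, rownames(posterior))
}

#' Top up doublet calls to an expected doublet fraction
#'
#' If fewer cells are labelled `"DBL"` than `round(fraction * n_cells)`,
#' singlet-labelled cells with the largest total read depth are relabelled
#' `"DBL"` until the expectation is met. Existing doublet calls are never
#' demoted; unassigned cells are never promoted.
#'
#' @param labels character labels from [assign_cells].
#' @param x the [allele_counts] object the labels refer to.
#' @param expected_doublet_fraction expected doublet proportion in `[0, 1)`.
#' @return updated label vector.
#' @export
apply_doublet_expectation <- function(labels, x, expected_doublet_fraction) {
  stopifnot(inherits(x, "allele_counts"))
  if (expected_doublet_fraction < 0 || expected_doublet_fraction >= 1)
    stop("'expected_doublet_fraction' must lie in [0, 1)")
  expected <- round(expected_doublet_fraction * length(labels))
  have <- sum(labels == "DBL")
  if (have >= expected) return(labels)
  depth <- Matrix::colSums(total_counts(x))[names(labels)]
  singlet <- which(startsWith(labels, "SNG"))
  promote <- singlet[order(depth[singlet], decreasing = TRUE)]
  promote <- promote[seq_len(min(expected - have, length(promote)))]
  labels[promote] <- "DBL"
  labels
}
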