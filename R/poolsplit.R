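#' Demultiplex a pooled single-cell allele count matrix
#'
#' Fits a finite mixture over donors (plus, by default, one extra doublet
#' component) to SNV-by-cell reference/alternative allele counts by
#' expectation-maximization, with multiple random restarts of the
#' initialization (dense-submatrix selection, PCA, K-means). The restart
#' with the highest model log-likelihood is kept; the doublet cluster is
#' then identified by cross-assignment likelihood, cells are assigned where
#' their posterior exceeds `posterior_threshold`, and doublet calls are
#' topped up to `expected_doublet_fraction` by read depth.
#'
#' @param x an [allele_counts] object (typically after
#'   [het_likelihood_filter]).
#' @param n_samples number of pooled donors (known in advance).
#' @param n_restarts number of random EM restarts (default 30).
#' @param doublet model an extra doublet cluster (default `TRUE`).
#' @param expected_doublet_fraction expected doublet proportion used to top
#'   up doublet calls (default 0.03); ignored when `doublet = FALSE`.
#' @param posterior_threshold minimum posterior for assignment (default
#'   0.99, strict).
#' @param pseudo_a,pseudo_ar pseudo-counts of the allele-fraction prior
#'   (defaults 1 and 2, the mean-1/2 smoothing).
#' @param tol,max_iter EM convergence controls (defaults 1e-4, 1000).
#' @param seed optional integer seed for full reproducibility.
#' @param ... further arguments passed to [run_restarts]
#'   (`trim_fraction`, `target_density`, `low_rank_width`, `n_pca`,
#'   `verbose`).
#'
#' @return An object of class `"poolsplit"`: a list with components
#'   `model` (the converged [af_model]), `posterior` (cells x clusters),
#'   `labels` (`"SNG-k"`, `"DBL"` or `"unassigned"` per barcode),
#'   `doublet_cluster`, `cluster_names`, `logLik`, `restart_logLik`,
#'   `trace`, `converged`, `n_samples`, `counts_dim`, `call`. The usual
#'   methods (`print`, `summary`, `coef`, `logLik`, `predict`, `fitted`,
#'   `residuals`, `plot`, `simulate`) apply.
#' @seealso [assign_cells], [cluster_pa_matrix], [evaluate_demux]
#' @export
poolsplit <- function(x, n_samples, n_restarts = 30L, doublet = TRUE,
                      expected_doublet_fraction = 0.03,
                      posterior_threshold = 0.99,
                      pseudo_a = 1, pseudo_ar = 2,
                      tol = 1e-4, max_iter = 1000L, seed = NULL, ...) {
  stopifnot(inherits(x, "allele_counts"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- n_samples + as.integer(doublet)
  fit <- run_restarts(x, n_clusters = k, n_restarts = n_restarts,
                      pseudo_a = pseudo_a, pseudo_ar = pseudo_ar,
                      tol = tol, max_iter = max_iter, ...)
  doublet_cluster <- if (doublet && k >= 2)
    identify_doublet_cluster(fit$loglik_mat, fit$model$P_S) else NULL
  labels <- assign_cells(fit$posterior, threshold = posterior_threshold,
                         doublet_cluster = doublet_cluster)
  if (doublet)
    labels <- apply_doublet_expectation(labels, x, expected_doublet_fraction)
  cluster_names <- if (is.null(doublet_cluster)) {
    paste0("SNG-", seq_len(k))
  } else {
    nm <- character(k)
    nm[doublet_cluster] <- "DBL"
    nm[-doublet_cluster] <- paste0("SNG-", seq_len(k - 1))
    nm
  }
  colnames(fit$posterior) <- cluster_names
  colnames(fit$model$P_A) <- cluster_names
  structure(list(
    model = fit$model, posterior = fit$posterior, labels = labels,
    doublet_cluster = doublet_cluster, cluster_names = cluster_names,
    logLik = fit$logLik, restart_logLik = fit$restart_logLik,
    best_restart = fit$best_restart, trace = fit$trace,
    trace_penalized = fit$trace_penalized,
    n_iter = fit$n_iter, converged = fit$converged,
    n_samples = n_samples, posterior_threshold = posterior_threshold,
    counts_dim = dim(x), call = match.call()),
    class = "poolsplit")
}

#' @export
print.poolsplit <- function(x, ...) {
  cat("Genotype-free demultiplexing fit (allele-fraction EM mixture)\n")
  cat(sprintf("  %d SNVs x %d cells, %d donors%s\n",
              x$counts_dim[1], x$counts_dim[2], x$n_samples,
              if (!is.null(x$doublet_cluster)) " + doublet cluster" else ""))
  cat(sprintf("  best of %d restarts: logLik %.2f (%s in %d iterations)\n",
              sum(!is.na(x$restart_logLik)), x$logLik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  tab <- table(factor(x$labels, levels = c(sort(unique(
    x$cluster_names[x$cluster_names != "DBL"])), "DBL", "unassigned")))
  cat("  assignments:\n")
  print(tab)
  invisible(x)
}

#' @export
summary.poolsplit <- function(object, ...) {
  post_max <- apply(object$posterior, 1, max)
  s <- list(
    fit = object,
    label_table = table(object$labels),
    posterior_quartiles = stats::quantile(post_max, c(0, .25, .5, .75, 1)),
    prop_unassigned = mean(object$labels == "unassigned"),
    cluster_weights = stats::setNames(object$model$P_S, object$cluster_names),
    restart_spread = range(object$restart_logLik, na.rm = TRUE))
  class(s) <- "summary.poolsplit"
  s
}

#' @export
print.summary.poolsplit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  unassigned: %.2f%%\n", 100 * x$prop_unassigned))
  cat("  max-posterior quartiles:",
      paste(sprintf("%.4f", x$posterior_quartiles), collapse = " "), "\n")
  cat("  cluster weights:",
      paste(sprintf("%s=%.3f", names(x$cluster_weights), x$cluster_weights),
            collapse = " "), "\n")
  cat(sprintf("  restart logLik range: [%.2f, %.2f]\n",
              x$restart_spread[1], x$restart_spread[2]))
  invisible(x)
}

#' @export
coef.poolsplit <- function(object, ...) object$model$P_A

#' @export
logLik.poolsplit <- function(object, ...) {
  k <- ncol(object$model$P_A)
  structure(object$logLik,
            df = nrow(object$model$P_A) * k + (k - 1),
            nobs = object$counts_dim[2], class = "logLik")
}

#' @export
fitted.poolsplit <- function(object, ...) object$posterior

#' Posterior probabilities or labels for (new) cells
#'
#' @param object a fitted `"poolsplit"` object.
#' @param newdata an [allele_counts] object over the same SNVs; when
#'   omitted the training posterior/labels are returned.
#' @param type `"posterior"` (default) or `"labels"`.
#' @param ... unused.
#' @export
predict.poolsplit <- function(object, newdata = NULL,
                              type = c("posterior", "labels"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "posterior") return(object$posterior)
    return(object$labels)
  }
  es <- e_step(object$model, newdata)
  colnames(es$posterior) <- object$cluster_names
  if (type == "posterior") return(es$posterior)
  assign_cells(es$posterior, threshold = object$posterior_threshold,
               doublet_cluster = object$doublet_cluster)
}

#' Per-cell Pearson residuals of the fitted mixture
#'
#' For each cell the alternative-allele count at each covered SNV is
#' compared to its expectation under the cell's maximum-posterior cluster;
#' the per-cell mean Pearson residual is returned. Large values flag cells
#' the model explains poorly (e.g. doublets in a singlet-only fit).
#'
#' @param object a fitted `"poolsplit"` object.
#' @param x the [allele_counts] object the model was fitted to.
#' @param ... unused.
#' @export
residuals.poolsplit <- function(object, x, ...) {
  stopifnot(inherits(x, "allele_counts"))
  hard <- max.col(object$posterior, ties.method = "first")
  tot <- total_counts(x)
  out <- numeric(ncol(tot))
  for (i in seq_len(ncol(tot))) {
    v <- which(tot[, i] > 0)
    if (!length(v)) { out[i] <- NA_real_; next }
    t_i <- tot[v, i]
    a_i <- x$alt[v, i]
    p <- object$model$P_A[v, hard[i]]
    out[i] <- mean((a_i - t_i * p) / sqrt(t_i * p * (1 - p)))
  }
  stats::setNames(out, colnames(tot))
}

#' Diagnostic plots for a demultiplexing fit
#'
#' Two base-graphics panels: the EM log-likelihood trace of the winning
#' restart, and the per-restart final log-likelihoods with the winner
#' highlighted.
#'
#' @param x a fitted `"poolsplit"` object.
#' @param ... passed to [graphics::plot].
#' @export
plot.poolsplit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$trace), x$trace, type = "b", pch = 16,
                 xlab = "EM iteration", ylab = "model log-likelihood",
                 main = "Winning restart", ...)
  Ls <- x$restart_logLik
  cols <- ifelse(seq_along(Ls) == x$best_restart, "firebrick", "grey40")
  graphics::plot(seq_along(Ls), Ls, pch = 16, col = cols,
                 xlab = "restart", ylab = "final log-likelihood",
                 main = "Restarts", ...)
  invisible(x)
}

#' Simulate allele counts from a fitted mixture
#'
#' Draws new cells from the fitted model: each cell picks a cluster with
#' probability `P(S_n)`, receives the total per-SNV coverage of a randomly
#' chosen observed cell (preserving the empirical depth profile), and draws
#' alternative counts binomially from the cluster's allele fractions.
#'
#' @param object a fitted `"poolsplit"` object.
#' @param nsim number of datasets (default 1).
#' @param seed optional seed.
#' @param x the [allele_counts] object supplying the coverage profile.
#' @param n_cells cells per simulated dataset (default: as observed).
#' @param ... unused.
#' @return a list of length `nsim`; each element is a list with `counts`
#'   (an [allele_counts]) and `cluster` (the generating cluster per cell).
#' @export
simulate.poolsplit <- function(object, nsim = 1, seed = NULL, x,
                               n_cells = NULL, ...) {
  stopifnot(inherits(x, "allele_counts"))
  if (!is.null(seed)) set.seed(seed)
  tot <- total_counts(x)
  if (is.null(n_cells)) n_cells <- ncol(tot)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    z <- sample.int(length(object$model$P_S), n_cells, replace = TRUE,
                    prob = object$model$P_S)
    template <- sample.int(ncol(tot), n_cells, replace = TRUE)
    ii <- integer(0); jj <- integer(0); aa <- numeric(0); tt <- numeric(0)
    for (i in seq_len(n_cells)) {
      col <- tot[, template[i]]
      v <- which(col > 0)
      if (!length(v)) next
      a <- stats::rbinom(length(v), size = col[v],
                         prob = object$model$P_A[v, z[i]])
      ii <- c(ii, v); jj <- c(jj, rep.int(i, length(v)))
      aa <- c(aa, a); tt <- c(tt, col[v])
    }
    dn <- list(rownames(tot), sprintf("simcell%05d", seq_len(n_cells)))
    alt <- Matrix::sparseMatrix(ii, jj, x = aa, dims = c(nrow(tot), n_cells),
                                dimnames = dn)
    ref <- Matrix::sparseMatrix(ii, jj, x = tt - aa,
                                dims = c(nrow(tot), n_cells), dimnames = dn)
    out[[s]] <- list(counts = allele_counts(Matrix::drop0(ref),
                                            Matrix::drop0(alt)),
                     cluster = stats::setNames(object$cluster_names[z], dn[[2]]))
  }
  out
}

#' Write the standard result files of a demultiplexing run
#'
#' Emits the result table (barcode, label, max posterior) as TSV, the full
#' posterior matrix and the fitted allele fractions as CSV, each with a
#' provenance header comment.
#'
#' @param object a fitted `"poolsplit"` object.
#' @param dir output directory (created if needed).
#' @param provenance optional named character vector written as `# key=value`
#'   header lines.
#' @return paths of the written files, invisibly.
#' @export
write_demux_results <- function(object, dir, provenance = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- c(sprintf("# poolsplit %s",
                   as.character(utils::packageVersion("poolsplit"))),
           if (!is.null(provenance))
             sprintf("# %s=%s", names(provenance), provenance))
  res_path <- file.path(dir, "result.tsv")
  pmax_ <- apply(object$posterior, 1, max)
  tab <- data.frame(barcode = names(object$labels), label = object$labels,
                    posterior = pmax_[names(object$labels)])
  writeLines(c(hdr, paste(c("barcode", "label", "posterior"), collapse = "\t"),
               sprintf("%s\t%s\t%.6f", tab$barcode, tab$label, tab$posterior)),
             res_path)
  post_path <- file.path(dir, "posterior.csv")
  write_matrix_csv(object$posterior, post_path)
  pa_path <- file.path(dir, "allele_fractions.csv")
  write_matrix_csv(object$model$P_A, pa_path)
  invisible(c(result = res_path, posterior = post_path, model = pa_path))
}
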