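# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementation.

# naive cell x cluster log-likelihood and posterior (Bayes with weights)
oracle_e_step <- function(ref, alt, P_A, P_S) {
  ref <- as.matrix(ref); alt <- as.matrix(alt); P_A <- as.matrix(P_A)
  n_c <- ncol(ref); k <- ncol(P_A)
  ll <- matrix(0, n_c, k)
  for (i in seq_len(n_c)) for (n in seq_len(k)) {
    s <- 0
    for (v in seq_len(nrow(ref)))
      s <- s + alt[v, i] * log(P_A[v, n]) + ref[v, i] * log(1 - P_A[v, n])
    ll[i, n] <- s
  }
  post <- matrix(0, n_c, k)
  for (i in seq_len(n_c)) {
    w <- exp(ll[i, ] - max(ll[i, ])) * P_S
    post[i, ] <- w / sum(w)
  }
  list(loglik = ll, posterior = post)
}

oracle_m_step <- function(ref, alt, posterior, pseudo_a = 1, pseudo_ar = 2) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  k <- ncol(posterior)
  P_A <- matrix(0, nrow(ref), k)
  for (v in seq_len(nrow(ref))) for (n in seq_len(k)) {
    num <- pseudo_a; den <- pseudo_ar
    for (i in seq_len(ncol(ref))) {
      num <- num + alt[v, i] * posterior[i, n]
      den <- den + (alt[v, i] + ref[v, i]) * posterior[i, n]
    }
    P_A[v, n] <- num / den
  }
  ps <- colSums(posterior) / sum(posterior)
  list(P_A = P_A, P_S = ps)
}

oracle_log_likelihood <- function(ref, alt, P_A, P_S) {
  ll <- oracle_e_step(ref, alt, P_A, P_S)$loglik
  tot <- 0
  for (i in seq_len(nrow(ll)))
    tot <- tot + log(sum(exp(ll[i, ]) * P_S))
  tot
}

# normalized three-genotype likelihood decision on pooled counts
oracle_het_keep <- function(A, R, error = 0.01) {
  l <- c(RR = A * log10(error) + R * log10(1 - error),
         RA = (A + R) * log10(0.5),
         AA = A * log10(1 - error) + R * log10(error))
  p <- 10^(l - max(l)); p <- p / sum(p)
  log10(p[["RA"]]) >= log10(1 - error)
}

# smallest subset of NA-free rows whose P/A patterns separate all cluster
# pairs; exhaustive over subset sizes. Returns the minimum size, or Inf.
oracle_min_separating_size <- function(pa) {
  k <- ncol(pa)
  rows <- which(rowSums(pa == "NA") == 0)
  pairs <- utils::combn(k, 2)
  separates <- function(rws) {
    all(apply(pairs, 2, function(p)
      any(pa[rws, p[1]] != pa[rws, p[2]])))
  }
  if (!length(rows) || !separates(rows)) return(Inf)
  for (size in 1:length(rows)) {
    cmb <- utils::combn(rows, size)
    for (ci in seq_len(ncol(cmb)))
      if (separates(cmb[, ci])) return(size)
  }
  Inf
}

# toy allele_counts from dense matrices
toy_counts <- function(ref, alt) {
  dimnames(ref) <- list(paste0("1:", seq_len(nrow(ref)) * 10),
                        paste0("BC", seq_len(ncol(ref))))
  allele_counts(ref, alt, rownames(ref), colnames(ref))
}

# exact generative draw from a mixture model (for parameter recovery)
draw_from_model <- function(P_A, weights, n_cells, depth_per_snv) {
  n_v <- nrow(P_A)
  z <- sample.int(ncol(P_A), n_cells, replace = TRUE, prob = weights)
  tot <- matrix(stats::rpois(n_v * n_cells, depth_per_snv), n_v, n_cells)
  alt <- matrix(stats::rbinom(n_v * n_cells, as.vector(tot),
                              as.vector(P_A[, z])), n_v, n_cells)
  list(counts = toy_counts(tot - alt, alt), z = z)
}
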