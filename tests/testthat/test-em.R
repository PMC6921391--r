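test_that("E-step, M-step and likelihood match the brute-force oracle", {
  # tiny instances, <= 3 cells x 3 SNVs x 2 clusters, tolerance 1e-10
  set.seed(1)
  for (rep in 1:10) {
    n_v <- sample(1:3, 1); n_c <- sample(1:3, 1); k <- sample(1:2, 1)
    ref <- matrix(rpois(n_v * n_c, 2), n_v, n_c)
    alt <- matrix(rpois(n_v * n_c, 2), n_v, n_c)
    P_A <- matrix(runif(n_v * k, 0.05, 0.95), n_v, k)
    w <- runif(k)
    P_S <- w / sum(w)
    x <- toy_counts(ref, alt)
    m <- af_model(P_A, P_S)
    es <- e_step(m, x)
    orc <- oracle_e_step(ref, alt, P_A, P_S)
    expect_equal(unname(es$loglik), orc$loglik, tolerance = 1e-10)
    expect_equal(unname(es$posterior), orc$posterior, tolerance = 1e-10)
    mo <- oracle_m_step(ref, alt, orc$posterior)
    mu <- m_step(x, es$posterior)
    expect_equal(unname(mu$P_A), mo$P_A, tolerance = 1e-10)
    expect_equal(mu$P_S, mo$P_S, tolerance = 1e-10)
    expect_equal(model_log_likelihood(m, x),
                 oracle_log_likelihood(ref, alt, P_A, P_S),
                 tolerance = 1e-10)
  }
})

test_that("degenerate E-step cases behave as the formulas dictate", {
  # single cluster: posterior exactly 1
  x <- toy_counts(matrix(1, 2, 2), matrix(2, 2, 2))
  m1 <- af_model(matrix(0.3, 2, 1), 1)
  expect_equal(unname(e_step(m1, x)$posterior), matrix(1, 2, 1))
  # zero-count cell at uniform weights: uniform posterior (empty product)
  ref <- cbind(c(2, 1), c(0, 0)); alt <- cbind(c(1, 0), c(0, 0))
  x2 <- toy_counts(ref, alt)
  m2 <- af_model(matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2), c(0.5, 0.5))
  expect_equal(unname(e_step(m2, x2)$posterior[2, ]), c(0.5, 0.5))
  # single cell, one cluster, one alt read at P_A = 0.5: L = log(0.5)
  x3 <- toy_counts(matrix(0, 1, 1), matrix(1, 1, 1))
  m3 <- af_model(matrix(0.5, 1, 1), 1)
  expect_equal(model_log_likelihood(m3, x3), log(0.5))
  expect_lte(model_log_likelihood(m3, x3), 0)
})

test_that("M-step with all mass on one cluster reduces to pooled init", {
  sim <- small_sim(seed = 60, n_cells = 10, n_snvs = 15, rpc = 40)
  x <- sim$counts
  post <- cbind(rep(1, 10), rep(0, 10))
  m <- m_step(x, post)
  pooled <- init_model(x, stats::setNames(rep(1L, 10), colnames(x$ref)))
  expect_equal(unname(m$P_A[, 1]), unname(pooled$P_A[, 1]))
  expect_equal(unname(m$P_A[, 2]), rep(0.5, nrow(x$ref)))
  expect_equal(sum(m$P_S), 1)
  # fractional posteriors: hand-weighted Eq.-style arithmetic on 3 cells
  ref <- matrix(c(1, 2, 0), 1, 3); alt <- matrix(c(3, 0, 2), 1, 3)
  x2 <- toy_counts(ref, alt)
  post2 <- rbind(c(0.7, 0.3), c(0.3, 0.7), c(0.5, 0.5))
  m2 <- m_step(x2, post2)
  num1 <- 3 * 0.7 + 0 * 0.3 + 2 * 0.5 + 1
  den1 <- 4 * 0.7 + 2 * 0.3 + 2 * 0.5 + 2
  expect_equal(unname(m2$P_A[1, 1]), num1 / den1)
})

test_that("EM ascends its objective monotonically and converges", {
  for (seed in 1:4) {
    sim <- small_sim(seed = 70 + seed, n_cells = 60, n_snvs = 60, rpc = 80)
    x <- sim$counts
    set.seed(seed)
    n_cells <- ncol(x$ref)
    labels <- stats::setNames(sample(1:3, n_cells, TRUE),
                              colnames(x$ref))
    res <- run_em(x, init_model(x, labels))
    # the pseudo-count M-step ascends the Beta-penalized objective
    expect_true(all(diff(res$trace_penalized) >= -1e-8))
    expect_true(res$converged)
    # posterior rows normalized
    expect_equal(unname(rowSums(res$posterior)),
                 rep(1, n_cells), tolerance = 1e-9)
  }
})

test_that("infinite tolerance stops after a single parameter update", {
  sim <- small_sim(seed = 80, n_cells = 20, n_snvs = 20, rpc = 50)
  x <- sim$counts
  labels <- stats::setNames(rep_len(1:2, ncol(x$ref)), colnames(x$ref))
  m0 <- init_model(x, labels)
  res <- run_em(x, m0, tol = Inf)
  one_update <- m_step(x, e_step(m0, x)$posterior)
  expect_equal(res$model$P_A, one_update$P_A)
})

test_that("cluster relabelling permutes EM output identically", {
  sim <- small_sim(seed = 90, n_cells = 40, n_snvs = 40, rpc = 80)
  x <- sim$counts
  labels <- stats::setNames(sample(1:3, ncol(x$ref), TRUE),
                            colnames(x$ref))
  perm <- c(3L, 1L, 2L)
  r1 <- run_em(x, init_model(x, labels))
  r2 <- run_em(x, init_model(x, stats::setNames(perm[labels],
                                                names(labels))))
  inv <- order(perm)
  expect_equal(unname(r1$model$P_A), unname(r2$model$P_A[, perm]),
               tolerance = 1e-6)
  expect_equal(r1$logLik, r2$logLik, tolerance = 1e-6)
})

test_that("EM recovers generative parameters up to cluster permutation", {
  set.seed(12)
  n_v <- 150
  P_A <- cbind(runif(n_v, 0.02, 0.98), runif(n_v, 0.02, 0.98))
  gen <- draw_from_model(P_A, c(0.5, 0.5), n_cells = 200, depth_per_snv = 2)
  labels <- stats::setNames(sample(1:2, 200, TRUE),
                            colnames(gen$counts$ref))
  set.seed(13)
  res <- run_restarts(gen$counts, 2, n_restarts = 5, min_cells = 10)
  cors <- sapply(list(1:2, 2:1), function(p)
    mean(diag(cor(res$model$P_A, P_A[, p]))))
  expect_gt(max(cors), 0.99)
})

test_that("restart machinery is deterministic and keeps the best run", {
  sim <- small_sim(seed = 95, n_cells = 80, n_snvs = 60, rpc = 80)
  x <- sim$counts
  set.seed(3); a <- run_restarts(x, 3, n_restarts = 2, min_cells = 10)
  set.seed(3); b <- run_restarts(x, 3, n_restarts = 2, min_cells = 10)
  expect_identical(a$model$P_A, b$model$P_A)
  expect_identical(a$restart_logLik, b$restart_logLik)
  expect_equal(a$logLik, max(a$restart_logLik, na.rm = TRUE))
  # best-of-2 is at least as good as the first restart alone
  set.seed(3); one <- run_restarts(x, 3, n_restarts = 1, min_cells = 10)
  expect_gte(a$logLik, one$logLik)
})

test_that("the intermediate-fraction cluster is designated the doublet", {
  # construct a model where cluster 3's fractions average clusters 1 and 2
  set.seed(21)
  n_v <- 100
  p1 <- runif(n_v, 0.02, 0.2); p2 <- runif(n_v, 0.8, 0.98)
  P_A <- cbind(p1, p2, (p1 + p2) / 2)
  gen <- draw_from_model(P_A, c(0.48, 0.48, 0.04), 150, depth_per_snv = 3)
  m <- af_model(P_A, c(0.48, 0.48, 0.04))
  es <- e_step(m, gen$counts)
  expect_equal(identify_doublet_cluster(es$loglik, m$P_S), 3L)
  # symmetric cross-assignment scores tie; lowest index wins with a warning
  ll_sym <- rbind(c(0, -5), c(0, -5), c(-5, 0), c(-5, 0))
  expect_warning(idx <- identify_doublet_cluster(ll_sym, c(0.5, 0.5)),
                 "tie")
  expect_equal(idx, 1L)
})

test_that("posterior threshold assignment is strict", {
  post <- rbind(c(0.995, 0.005), c(0.99, 0.01), c(0.5, 0.5))
  rownames(post) <- paste0("B", 1:3)
  lab <- assign_cells(post, threshold = 0.99)
  expect_equal(unname(lab), c("SNG-1", "unassigned", "unassigned"))
  lab2 <- assign_cells(post, threshold = 0.99, doublet_cluster = 1L)
  expect_equal(unname(lab2[1]), "DBL")
})

test_that("doublet expectation top-up promotes the deepest singlets only", {
  set.seed(31)
  ref <- matrix(rpois(20 * 10, 3), 20, 10)
  alt <- matrix(rpois(20 * 10, 3), 20, 10)
  # make cells 4 and 9 clearly deepest
  ref[, 4] <- ref[, 4] + 50; ref[, 9] <- ref[, 9] + 40
  x <- toy_counts(ref, alt)
  labels <- stats::setNames(c(rep("SNG-1", 5), rep("SNG-2", 4), "DBL"),
                            colnames(x$ref))
  # expectation met: unchanged
  expect_identical(apply_doublet_expectation(labels, x, 0.1), labels)
  expect_identical(apply_doublet_expectation(labels, x, 0), labels)
  # 10 cells, 1 detected, fraction 0.3 -> 2 deepest singlets promoted
  out <- apply_doublet_expectation(labels, x, 0.3)
  expect_equal(sum(out == "DBL"), 3)
  expect_equal(unname(out[c(4, 9)]), c("DBL", "DBL"))
  expect_error(apply_doublet_expectation(labels, x, 1.2), "fraction")
})
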