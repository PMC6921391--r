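test_that("synthetic genotypes follow Hardy-Weinberg at their drawn frequencies", {
  set.seed(1)
  donors <- synth_donor_genotypes(4, 10000)
  expect_equal(dim(donors$genotypes), c(4, 10000))
  expect_true(all(donors$genotypes %in% 0:2))
  expect_true(all(donors$freqs >= 0.05 & donors$freqs <= 0.95))
  # GP triplets sum to 1 and put 0.98 on the true genotype
  expect_equal(apply(donors$gp, c(1, 2), sum)[1, 1:5], rep(1, 5))
  expect_equal(donors$gp[1, 1, donors$genotypes[1, 1] + 1], 0.98)
  # aggregate alt-allele dosage matches 2f within binomial 3-sigma bounds:
  # each donor-SNV genotype is Binomial(2, f)
  s <- sum(donors$genotypes)
  mu <- 4 * sum(2 * donors$freqs)
  sd_ <- sqrt(4 * sum(2 * donors$freqs * (1 - donors$freqs)))
  expect_lt(abs(s - mu) / sd_, 3)
  # heterozygote fraction matches the HW expectation 2f(1-f)
  het_obs <- mean(donors$genotypes == 1)
  het_exp <- mean(2 * donors$freqs * (1 - donors$freqs))
  expect_lt(abs(het_obs - het_exp), 0.01)
  # per-genotype-class counts at near-fixed frequency behave degenerately
  d1 <- synth_donor_genotypes(1, 5)
  expect_equal(dim(d1$genotypes), c(1, 5))
})

test_that("sibling pairs show the closed-form genotype concordance excess", {
  set.seed(2)
  n <- 20000
  sib <- synth_sibling_pair(n)
  # closed-form oracle: enumerate parental genotype pairs under HW(f) and
  # the four transmission patterns to get P(sib1 == sib2 | f) exactly,
  # then compare the empirical concordance against its expectation
  sib_concordance <- function(f) {
    q <- 1 - f
    gpar <- c(q^2, 2 * f * q, f^2)          # parent genotype probs (0,1,2)
    trans <- function(g) switch(g + 1L, c(1, 0), c(0.5, 0.5), c(0, 1))
    p_same <- 0
    for (g1 in 0:2) for (g2 in 0:2) {
      t1 <- trans(g1); t2 <- trans(g2)      # allele probs from each parent
      # offspring genotype distribution given parents
      off <- c(t1[1] * t2[1], t1[1] * t2[2] + t1[2] * t2[1], t1[2] * t2[2])
      p_same <- p_same + gpar[g1 + 1] * gpar[g2 + 1] * sum(off^2)
    }
    p_same
  }
  conc_exp <- mean(vapply(sib$freqs, sib_concordance, numeric(1)))
  conc_obs <- mean(sib$genotypes[1, ] == sib$genotypes[2, ])
  # note: sum(off^2) treats the two sibs as iid draws from the same
  # parental cross, which is exactly the simulator's generative process
  expect_lt(abs(conc_obs - conc_exp), 3 * sqrt(0.25 / n))
  # and sibs share more than unrelated HW donors
  set.seed(3)
  unrel <- synth_donor_genotypes(2, n)
  conc_unrel <- mean(unrel$genotypes[1, ] == unrel$genotypes[2, ])
  expect_gt(conc_obs, conc_unrel + 0.05)
  # parents both homozygous ref force offspring RR: check via forced freq
  sib0 <- synth_sibling_pair(100, maf_range = c(0, 0))
  expect_true(all(sib0$genotypes == 0))
  # empty SNV set is valid
  sib_empty <- synth_sibling_pair(0)
  expect_equal(ncol(sib_empty$genotypes), 0)
})

test_that("alt-read probability follows the dosage rule on GL triplets", {
  # certain RA: P(A) = 0.5; certain AA: P(A) = 1; certain RR: P(A) = 0
  expect_equal(alt_read_probability(matrix(c(0, 1, 0), 1)), 0.5)
  expect_equal(alt_read_probability(matrix(c(0, 0, 1), 1)), 1)
  expect_equal(alt_read_probability(matrix(c(1, 0, 0), 1)), 0)
  # unnormalized triplets are renormalized
  expect_equal(alt_read_probability(matrix(c(2, 2, 0), 1)), 0.25)
})

test_that("simulated counts match the analytic alt fraction in aggregate", {
  set.seed(4)
  # single donor, all SNVs heterozygous with certainty
  donors <- synth_donor_genotypes(1, 50)
  donors$gp[1, , ] <- rep(c(0, 1, 0), each = 50)
  donors$genotypes[] <- 1L
  sim <- simulate_counts(donors, 100, reads_per_cell = 400)
  a <- sum(sim$counts$alt); t <- sum(total_counts(sim$counts))
  z <- (a - 0.5 * t) / sqrt(t * 0.25)
  expect_lt(abs(z), 3)
  # homozygous alt with certainty: every read is alt
  donors$gp[1, , ] <- rep(c(0, 0, 1), each = 50)
  donors$genotypes[] <- 2L
  sim2 <- simulate_counts(donors, 30, reads_per_cell = 200)
  expect_equal(sum(sim2$counts$ref), 0)
  # homozygous ref with certainty: every read is ref
  donors$gp[1, , ] <- rep(c(1, 0, 0), each = 50)
  donors$genotypes[] <- 0L
  sim3 <- simulate_counts(donors, 30, reads_per_cell = 200)
  expect_equal(sum(sim3$counts$alt), 0)
})

test_that("simulated truth assigns every barcode exactly one label", {
  sim <- small_sim(seed = 5, n_cells = 120, n_snvs = 80, rpc = 100)
  asg <- sim$truth$assignments
  expect_equal(nrow(asg), ncol(sim$counts$ref))
  expect_setequal(asg$barcode, colnames(sim$counts$ref))
  expect_false(anyDuplicated(asg$barcode) > 0)
  expect_true(all(asg$label %in% c("donor1", "donor2", "DBL")))
  # doublet pairs are disjoint
  dbl <- sim$truth$doublets
  expect_false(any(dbl$barcode %in% dbl$merged_in))
  expect_false(anyDuplicated(c(dbl$barcode, dbl$merged_in)) > 0)
})

test_that("doublet injection merges columns conservatively", {
  sim0 <- small_sim(seed = 6, n_cells = 100, n_snvs = 60, rpc = 80,
                    doublet_fraction = 0)
  total_before <- sum(total_counts(sim0$counts))
  set.seed(7)
  merged <- inject_doublets(sim0$counts, sim0$truth, 0.03)
  # 100 cells, fraction 0.03: 97 columns remain, 3 marked DBL
  expect_equal(ncol(merged$counts$ref), 97)
  expect_equal(sum(merged$truth$assignments$label == "DBL"), 3)
  expect_equal(sum(total_counts(merged$counts)), total_before)
  # merged column equals the sum of its two source columns
  dbl <- merged$truth$doublets[1, ]
  expect_equal(
    as.numeric(total_counts(merged$counts)[, dbl$barcode]),
    as.numeric(total_counts(sim0$counts)[, dbl$barcode] +
               total_counts(sim0$counts)[, dbl$merged_in]))
  # fraction 0 leaves everything untouched
  same <- inject_doublets(sim0$counts, sim0$truth, 0)
  expect_identical(same$counts, sim0$counts)
  # over-large fraction errors
  expect_error(inject_doublets(sim0$counts, sim0$truth, 0.6), "too large")
})

test_that("donor VCFs round-trip through the VCF reader", {
  set.seed(8)
  donors <- synth_donor_genotypes(3, 25)
  p <- tempfile(fileext = ".vcf")
  write_donor_vcf(donors, p)
  back <- read_donor_genotypes(p)
  expect_equal(back$donor_ids, donors$donor_ids)
  expect_equal(back$genotypes, unname(donors$genotypes))
  expect_equal(back$snvs$id, donors$snvs$id)
  expect_equal(back$gp, donors$gp, tolerance = 1e-3)
})

test_that("truth tables round-trip through TSV", {
  sim <- small_sim(seed = 9, n_cells = 50, n_snvs = 30, rpc = 60)
  p <- tempfile(fileext = ".tsv")
  write_sim_truth(sim$truth, p)
  back <- read_sim_truth(p)
  expect_equal(back$assignments$barcode, sim$truth$assignments$barcode)
  expect_equal(back$assignments$label, sim$truth$assignments$label)
})
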