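make_planted_fixture <- function() {
  # 4 SNVs on chr1, 5 barcodes; plant reads whose base at each SNV is known.
  snvs <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                     ref = c("A", "C", "G", "T"),
                     alt = c("G", "T", "A", "C"), qual = 99,
                     id = paste0("chr1:", c(100, 200, 300, 400)),
                     stringsAsFactors = FALSE)
  wl <- paste0("BC", 1:5)
  base_at <- function(snv_i, allele) {
    if (allele == "ref") snvs$ref[snv_i] else snvs$alt[snv_i]
  }
  reads <- NULL
  truth_ref <- matrix(0L, 4, 5, dimnames = list(snvs$id, wl))
  truth_alt <- truth_ref
  set.seed(5)
  rid <- 0
  for (v in 1:4) for (b in 1:5) {
    n_ref <- sample(0:2, 1); n_alt <- sample(0:2, 1)
    for (allele in c(rep("ref", n_ref), rep("alt", n_alt))) {
      rid <- rid + 1
      start <- snvs$pos[v] - 5L
      seqv <- strrep("A", 11)
      substr(seqv, 6, 6) <- base_at(v, allele)
      reads <- rbind(reads, data.frame(
        qname = paste0("r", rid), flag = 0L, rname = "chr1", pos = start,
        mapq = 60L, cigar = "11M", seq = seqv, cb = wl[b]))
    }
    truth_ref[v, b] <- n_ref
    truth_alt[v, b] <- n_alt
  }
  list(snvs = snvs, wl = wl, reads = reads,
       truth_ref = truth_ref, truth_alt = truth_alt)
}

test_that("counts from a planted BAM equal the planted truth table", {
  fx <- make_planted_fixture()
  bam <- write_test_bam(fx$reads)
  counts <- build_count_matrices(bam, fx$snvs, fx$wl)
  expect_equal(as.matrix(counts$ref), fx$truth_ref + 0)
  expect_equal(as.matrix(counts$alt), fx$truth_alt + 0)
  # conservation: per-barcode column sums equal planted overlaps
  expect_equal(Matrix::colSums(total_counts(counts)),
               colSums(fx$truth_ref + fx$truth_alt))
})

test_that("QC-failing, mismatching and deletion-spanning reads are ignored", {
  snvs <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                     qual = 99, id = "chr1:100", stringsAsFactors = FALSE)
  reads <- data.frame(
    qname = paste0("r", 1:7),
    flag = c(0L, 0L, 0L, 256L, 1024L, 0L, 0L),
    rname = "chr1",
    pos = c(96L, 96L, 96L, 96L, 96L, 96L, 96L),
    mapq = c(60L, 60L, 60L, 60L, 60L, 5L, 60L),
    cigar = c("9M", "9M", "9M", "9M", "9M", "9M", "4M3D5M"),
    # base at offset 5 covers pos 100 for 9M reads
    seq = c("CCCCACCCC",   # ref base -> N_R
            "CCCCGCCCC",   # alt base -> N_A
            "CCCCTCCCC",   # neither allele -> ignored
            "CCCCGCCCC",   # secondary -> ignored
            "CCCCGCCCC",   # duplicate -> ignored
            "CCCCGCCCC",   # mapq 5 -> ignored
            "CCCCCCCCC"),  # 3-bp deletion spans pos 100 -> ignored
    cb = c("BC1", "BC1", "BC1", "BC1", "BC1", "BC1", "BC1"),
    stringsAsFactors = FALSE)
  bam <- write_test_bam(reads)
  counts <- build_count_matrices(bam, snvs, "BC1")
  expect_equal(as.numeric(counts$ref["chr1:100", "BC1"]), 1)
  expect_equal(as.numeric(counts$alt["chr1:100", "BC1"]), 1)
})

test_that("SNVs on contigs missing from the BAM header warn and stay zero", {
  snvs <- data.frame(chrom = c("chr1", "chrMissing"), pos = c(100L, 50L),
                     ref = c("A", "C"), alt = c("G", "T"), qual = 99,
                     id = c("chr1:100", "chrMissing:50"),
                     stringsAsFactors = FALSE)
  reads <- data.frame(qname = "r1", flag = 0L, rname = "chr1", pos = 96L,
                      mapq = 60L, cigar = "9M", seq = "CCCCGCCCC",
                      cb = "BC1", stringsAsFactors = FALSE)
  bam <- write_test_bam(reads)
  expect_warning(counts <- build_count_matrices(bam, snvs, "BC1"),
                 "chrMissing")
  expect_equal(as.numeric(total_counts(counts)["chrMissing:50", ]), 0)
  expect_equal(as.numeric(counts$alt["chr1:100", ]), 1)
})

test_that("heterozygosity filter matches the three-genotype oracle", {
  # balanced counts retained, homozygous-looking removed
  cases <- rbind(c(50, 50), c(100, 0), c(0, 100), c(60, 40), c(85, 15),
                 c(90, 10), c(12, 2), c(5, 5), c(3, 1), c(200, 35))
  # split each SNV's pooled counts across two cells; the filter re-pools
  half <- function(x) cbind(floor(x / 2), ceiling(x / 2))
  ref <- half(cases[, 2])
  alt <- half(cases[, 1])
  x <- toy_counts(ref, alt)
  keep_oracle <- vapply(seq_len(nrow(cases)), function(i)
    oracle_het_keep(cases[i, 1], cases[i, 2]), logical(1))
  expect_true(keep_oracle[1])   # A=50,R=50 retained
  expect_false(keep_oracle[2])  # A=100,R=0 removed
  filtered <- het_likelihood_filter(x)
  expect_equal(rownames(filtered$ref), rownames(x$ref)[keep_oracle])
})

test_that("heterozygosity filter is row-order independent", {
  sim <- small_sim(seed = 8, n_cells = 40, n_snvs = 60, rpc = 100)
  x <- sim$counts
  f1 <- het_likelihood_filter(x)
  perm <- sample(nrow(x$ref))
  f2 <- het_likelihood_filter(x[perm, ])
  expect_setequal(rownames(f1$ref), rownames(f2$ref))
  expect_equal(as.matrix(f2$ref[rownames(f1$ref), ]), as.matrix(f1$ref))
})

test_that("as error_rate tends to 0 only SNVs with both alleles survive", {
  ref <- rbind(c(30, 20), c(50, 0), c(0, 40), c(10, 10))
  alt <- rbind(c(25, 25), c(0, 0), c(45, 5), c(0, 0))
  x <- toy_counts(ref, alt)
  f <- het_likelihood_filter(x, error_rate = 1e-9)
  sums_alt <- Matrix::rowSums(x$alt)
  sums_ref <- Matrix::rowSums(x$ref)
  both <- sums_alt > 0 & sums_ref > 0
  expect_true(all(rownames(f$ref) %in% rownames(x$ref)[both]))
})
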