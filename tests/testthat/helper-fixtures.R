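# Build a small indexed BAM from in-code SAM text (text-only fixtures).
# reads: data.frame with qname, flag, rname, pos, mapq, cigar, seq and
# optionally cb (CB tag; NA = untagged).
write_test_bam <- function(reads, contigs = c(chr1 = 1000L, chr2 = 1000L)) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    line <- paste(r$qname, r$flag, r$rname, r$pos, r$mapq, r$cigar, "*", 0,
                  0, r$seq, strrep("I", nchar(gsub("[^ACGTN]", "", r$seq))),
                  sep = "\t")
    if (!is.null(r$cb) && !is.na(r$cb))
      line <- paste0(line, "\tCB:Z:", r$cb)
    line
  }, character(1))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

# minimal SNV VCF text fixture
write_test_vcf <- function(records, path = tempfile(fileext = ".vcf")) {
  # records: data.frame chrom, pos, ref, alt, qual
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=1000>",
           "##contig=<ID=chr2,length=1000>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t.",
                  records$chrom, records$pos, records$ref, records$alt,
                  as.character(records$qual))
  writeLines(c(hdr, body), path)
  path
}

# quick simulated 2-donor pool at small scale for integration-style tests
small_sim <- function(seed = 1, n_cells = 200, n_snvs = 300, rpc = 300,
                      doublet_fraction = 0.03, siblings = FALSE) {
  set.seed(seed)
  donors <- if (siblings) synth_sibling_pair(n_snvs) else
    synth_donor_genotypes(2, n_snvs)
  sim <- simulate_counts(donors, n_cells, reads_per_cell = rpc)
  sim <- inject_doublets(sim$counts, sim$truth, doublet_fraction)
  c(sim, list(donors = donors))
}

# random P/A matrix generator for the distinguishing-variant property tests
random_pa_matrix <- function(n_snvs, n_clusters, p_na = 0.15) {
  m <- matrix(sample(c("P", "A"), n_snvs * n_clusters, replace = TRUE),
              n_snvs, n_clusters,
              dimnames = list(paste0("1:", seq_len(n_snvs)),
                              paste0("S", seq_len(n_clusters))))
  m[stats::runif(length(m)) < p_na] <- "NA"
  m
}
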