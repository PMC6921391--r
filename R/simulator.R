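#' Synthetic multi-donor diploid genotypes
#'
#' Draws, per SNV, a population alternative-allele frequency from a scaled
#' Beta distribution, then per-donor genotypes under Hardy-Weinberg
#' equilibrium. Genotype-probability (GP) triplets put mass `1 - 2 * gp_error`
#' on the true genotype and `gp_error` on each other genotype, emulating
#' confident external genotyping; GL triplets are their log10.
#'
#' @param n_donors number of donors (>= 1).
#' @param n_snvs number of SNVs.
#' @param maf_shape `c(alpha, beta)` of the Beta allele-frequency
#'   distribution (default `c(2, 2)`).
#' @param maf_range frequencies are rescaled into this interval (default
#'   `c(0.05, 0.95)`).
#' @param gp_error off-genotype GP mass (default 0.01).
#' @return an object of class `"donor_genotypes"`: list with `genotypes`
#'   (donors x SNVs matrix of alt-allele dosages 0/1/2), `gp` (donors x
#'   SNVs x 3 array, RR/RA/AA order), `freqs`, `snvs` (chrom/pos/ref/alt/id
#'   table), `donor_ids`.
#' @export
synth_donor_genotypes <- function(n_donors, n_snvs, maf_shape = c(2, 2),
                                  maf_range = c(0.05, 0.95), gp_error = 0.01) {
  stopifnot(n_donors >= 1, n_snvs >= 0)
  f <- maf_range[1] + stats::rbeta(n_snvs, maf_shape[1], maf_shape[2]) *
    diff(maf_range)
  geno <- matrix(stats::rbinom(n_donors * n_snvs, 2, rep(f, each = n_donors)),
                 nrow = n_donors)
  .donor_genotypes(geno, f, gp_error)
}

#' Synthetic full-sibling genotype pair
#'
#' Simulates two parents under Hardy-Weinberg equilibrium at each SNV and
#' transmits one uniformly chosen allele from each parent, independently, to
#' each of two offspring — full siblings sharing on average half their
#' parental alleles, the hardest realistic case for allele-fraction
#' demultiplexing.
#'
#' @param n_snvs number of SNVs.
#' @inheritParams synth_donor_genotypes
#' @return a `"donor_genotypes"` object with 2 donors (the siblings).
#' @export
synth_sibling_pair <- function(n_snvs, maf_shape = c(2, 2),
                               maf_range = c(0.05, 0.95), gp_error = 0.01) {
  f <- maf_range[1] + stats::rbeta(n_snvs, maf_shape[1], maf_shape[2]) *
    diff(maf_range)
  # parental haplotypes: columns = alleles (0 ref / 1 alt)
  p1 <- cbind(stats::rbinom(n_snvs, 1, f), stats::rbinom(n_snvs, 1, f))
  p2 <- cbind(stats::rbinom(n_snvs, 1, f), stats::rbinom(n_snvs, 1, f))
  transmit <- function() {
    a1 <- p1[cbind(seq_len(n_snvs), sample(1:2, n_snvs, replace = TRUE))]
    a2 <- p2[cbind(seq_len(n_snvs), sample(1:2, n_snvs, replace = TRUE))]
    a1 + a2
  }
  geno <- rbind(transmit(), transmit())
  .donor_genotypes(geno, f, gp_error,
                   donor_ids = c("sibling1", "sibling2"))
}

.donor_genotypes <- function(geno, freqs, gp_error,
                             donor_ids = paste0("donor", seq_len(nrow(geno)))) {
  n_donors <- nrow(geno)
  n_snvs <- ncol(geno)
  gp <- array(gp_error, dim = c(n_donors, n_snvs, 3))
  if (n_snvs > 0)
    for (g in 0:2) {
      hit <- which(geno == g, arr.ind = TRUE)
      if (nrow(hit) > 0)
        gp[cbind(hit, rep(g + 1L, nrow(hit)))] <- 1 - 2 * gp_error
    }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snvs, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  pos <- if (n_snvs > 0) sort(sample.int(n_snvs * 100L, n_snvs)) else integer(0)
  snvs <- data.frame(chrom = rep("1", n_snvs), pos = pos, ref = ref,
                     alt = unname(alt), qual = rep(100, n_snvs),
                     stringsAsFactors = FALSE)
  snvs$id <- if (n_snvs > 0) paste0(snvs$chrom, ":", snvs$pos) else character(0)
  structure(list(genotypes = geno, gp = gp, freqs = freqs, snvs = snvs,
                 donor_ids = donor_ids),
            class = "donor_genotypes")
}

#' @export
print.donor_genotypes <- function(x, ...) {
  cat(sprintf("donor_genotypes: %d donors x %d SNVs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  invisible(x)
}

#' Alternative-allele read probability from genotype likelihoods
#'
#' A read from a cell of a given donor carries the alternative allele with
#' probability `0.5 * L(RA) + L(AA)`, the allele-dosage expectation under
#' the donor's genotype likelihoods. Likelihood triplets are renormalized
#' to sum to 1 when they do not.
#'
#' @param gp matrix (n x 3) of RR/RA/AA likelihoods or probabilities.
#' @return numeric vector of alternative-allele probabilities.
#' @export
alt_read_probability <- function(gp) {
  gp <- matrix(gp, ncol = 3)
  s <- rowSums(gp)
  bad <- abs(s - 1) > 1e-6 & s > 0
  gp[bad, ] <- gp[bad, ] / s[bad]
  0.5 * gp[, 2] + gp[, 3]
}

#' Simulate pooled allele count matrices from donor genotypes
#'
#' Emulates a pooled droplet run without needing a template BAM: barcodes
#' are assigned to donors uniformly at random; each cell's total read count
#' is lognormal around `reads_per_cell` (per-cell depth heterogeneity) and
#' the reads are spread over SNVs proportional to heavy-tailed per-SNV
#' coverage weights (expression heterogeneity); each read at SNV `v` in a
#' cell of donor `d` is alternative with probability
#' [alt_read_probability] of donor `d`'s likelihood triplet at `v`.
#'
#' @param donors a `"donor_genotypes"` object.
#' @param n_cells number of cell barcodes.
#' @param reads_per_cell target mean reads per cell (default 750).
#' @param depth_sdlog lognormal sd (log scale) of per-cell depth
#'   (default 0.5).
#' @param snv_weight_sdlog lognormal sd (log scale) of per-SNV coverage
#'   weights (default 1.5).
#' @return list with `counts` (an [allele_counts]) and `truth` (a
#'   `"sim_truth"` object: per-barcode donor assignment, empty doublet
#'   table, simulation parameters).
#' @export
simulate_counts <- function(donors, n_cells, reads_per_cell = 750,
                            depth_sdlog = 0.5, snv_weight_sdlog = 1.5) {
  stopifnot(inherits(donors, "donor_genotypes"), n_cells >= 1)
  n_snvs <- ncol(donors$genotypes)
  n_donors <- nrow(donors$genotypes)
  barcodes <- sprintf("%s-1", vapply(seq_len(n_cells), function(i)
    paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = ""),
    character(1)))
  while (anyDuplicated(barcodes)) {
    dup <- which(duplicated(barcodes))
    barcodes[dup] <- sprintf("%s-1", vapply(dup, function(i)
      paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE), collapse = ""),
      character(1)))
  }
  assignment <- sample.int(n_donors, n_cells, replace = TRUE)
  # alt-read probability per donor x SNV (Eq.-style dosage expectation)
  p_alt <- matrix(0, n_donors, n_snvs)
  for (d in seq_len(n_donors))
    p_alt[d, ] <- alt_read_probability(matrix(donors$gp[d, , ], ncol = 3))
  depth <- pmax(1L, stats::rpois(n_cells, stats::rlnorm(
    n_cells, meanlog = log(reads_per_cell) - depth_sdlog^2 / 2,
    sdlog = depth_sdlog)))
  w <- stats::rlnorm(n_snvs, 0, snv_weight_sdlog)
  w <- w / sum(w)
  ii <- vector("list", n_cells); aa <- vector("list", n_cells)
  tt <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    hits <- tabulate(sample.int(n_snvs, depth[i], replace = TRUE, prob = w),
                     nbins = n_snvs)
    v <- which(hits > 0)
    a <- stats::rbinom(length(v), hits[v], p_alt[assignment[i], v])
    ii[[i]] <- v; aa[[i]] <- a; tt[[i]] <- hits[v]
  }
  jj <- rep.int(seq_len(n_cells), lengths(ii))
  ii <- unlist(ii); aa <- unlist(aa); tt <- unlist(tt)
  dn <- list(donors$snvs$id, barcodes)
  alt <- Matrix::sparseMatrix(ii, jj, x = as.double(aa),
                              dims = c(n_snvs, n_cells), dimnames = dn)
  ref <- Matrix::sparseMatrix(ii, jj, x = as.double(tt - aa),
                              dims = c(n_snvs, n_cells), dimnames = dn)
  counts <- allele_counts(Matrix::drop0(ref), Matrix::drop0(alt))
  truth <- structure(list(
    assignments = data.frame(barcode = barcodes,
                             donor = donors$donor_ids[assignment],
                             label = donors$donor_ids[assignment],
                             stringsAsFactors = FALSE),
    doublets = data.frame(barcode = character(), merged_in = character(),
                          donor1 = character(), donor2 = character(),
                          same_donor = logical(), stringsAsFactors = FALSE),
    params = list(n_donors = n_donors, n_cells = n_cells, n_snvs = n_snvs,
                  reads_per_cell = reads_per_cell,
                  doublet_fraction = 0)),
    class = "sim_truth")
  list(counts = counts, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d barcodes, %d donors, %d doublets\n",
              nrow(x$assignments), x$params$n_donors, nrow(x$doublets)))
  invisible(x)
}

#' Inject doublets by merging disjoint barcode pairs
#'
#' Chooses `round(doublet_fraction * n_cells)` "keeper" barcodes and an
#' equally sized disjoint set of "merged-in" barcodes; each merged-in
#' column is added into its keeper column and dropped. Keepers become
#' doublets in the truth table (donor pair recorded, flagged when both
#' halves come from the same donor). Total counts are conserved.
#'
#' @param counts an [allele_counts] object.
#' @param truth the matching `"sim_truth"` object.
#' @param doublet_fraction fraction of barcodes converted to doublets
#'   (default 0.03); requires `2 * fraction * n_cells <= n_cells`.
#' @return list with updated `counts` and `truth`.
#' @export
inject_doublets <- function(counts, truth, doublet_fraction = 0.03) {
  stopifnot(inherits(counts, "allele_counts"), inherits(truth, "sim_truth"))
  n <- ncol(counts$ref)
  n_dbl <- round(doublet_fraction * n)
  if (2 * n_dbl > n)
    stop("'doublet_fraction' too large: need 2 * ", n_dbl, " <= ", n,
         " barcodes")
  if (n_dbl == 0) return(list(counts = counts, truth = truth))
  pick <- sample.int(n, 2L * n_dbl)
  keepers <- pick[seq_len(n_dbl)]
  merged <- pick[n_dbl + seq_len(n_dbl)]
  ref <- counts$ref; alt <- counts$alt
  ref[, keepers] <- ref[, keepers] + ref[, merged]
  alt[, keepers] <- alt[, keepers] + alt[, merged]
  keep_cols <- setdiff(seq_len(n), merged)
  bc <- colnames(ref)
  out_counts <- allele_counts(ref[, keep_cols, drop = FALSE],
                              alt[, keep_cols, drop = FALSE])
  asg <- truth$assignments
  rownames(asg) <- asg$barcode
  d1 <- asg[bc[keepers], "donor"]
  d2 <- asg[bc[merged], "donor"]
  dbl <- data.frame(barcode = bc[keepers], merged_in = bc[merged],
                    donor1 = d1, donor2 = d2, same_donor = d1 == d2,
                    stringsAsFactors = FALSE)
  asg <- asg[bc[keep_cols], ]
  asg$label[asg$barcode %in% dbl$barcode] <- "DBL"
  asg$donor[asg$barcode %in% dbl$barcode] <- NA_character_
  rownames(asg) <- NULL
  truth$assignments <- asg
  truth$doublets <- rbind(truth$doublets, dbl)
  truth$params$doublet_fraction <- doublet_fraction
  list(counts = out_counts, truth = truth)
}

#' Write donor genotypes as a minimal VCF with GT:GP:GL fields
#'
#' @param donors a `"donor_genotypes"` object.
#' @param path output path (plain text, VCF 4.2).
#' @export
write_donor_vcf <- function(donors, path) {
  stopifnot(inherits(donors, "donor_genotypes"))
  gt_str <- c("0/0", "0/1", "1/1")
  n_d <- nrow(donors$genotypes)
  n_v <- ncol(donors$genotypes)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=poolsplit-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype ",
           "probabilities RR,RA,AA\">"),
    paste0("##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Log10 ",
           "genotype likelihoods\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donors$donor_ids), collapse = "\t"))
  body <- vapply(seq_len(n_v), function(v) {
    samples <- vapply(seq_len(n_d), function(d) {
      gp <- donors$gp[d, v, ]
      sprintf("%s:%s:%s", gt_str[donors$genotypes[d, v] + 1L],
              paste(formatC(gp, format = "f", digits = 4), collapse = ","),
              paste(formatC(log10(gp), format = "f", digits = 4),
                    collapse = ","))
    }, character(1))
    paste(c(donors$snvs$chrom[v], donors$snvs$pos[v], ".",
            donors$snvs$ref[v], donors$snvs$alt[v], "100", "PASS", ".",
            "GT:GP:GL", samples), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read donor genotypes (GP/GL fields) from a VCF
#'
#' Reads a multi-sample VCF carrying GP (preferred) or GL FORMAT triplets
#' and returns the same `"donor_genotypes"` structure the simulator
#' produces, for use with [sample_pa_matrix] and [simulate_counts].
#'
#' @param path path to the VCF.
#' @return a `"donor_genotypes"` object.
#' @export
read_donor_genotypes <- function(path) {
  .check_vcf_header(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt <- v@gt[, 1]
  use_gp <- all(grepl("GP", fmt))
  field <- if (use_gp) "GP" else "GL"
  tri <- vcfR::extract.gt(v, element = field)
  if (is.null(dim(tri))) tri <- matrix(tri, nrow = 1)
  donor_ids <- colnames(v@gt)[-1]
  n_v <- nrow(tri); n_d <- ncol(tri)
  gp <- array(NA_real_, dim = c(n_d, n_v, 3))
  for (d in seq_len(n_d)) {
    vals <- do.call(rbind, lapply(strsplit(tri[, d], ",", fixed = TRUE),
                                  as.numeric))
    if (!use_gp) vals <- 10^vals
    s <- rowSums(vals)
    gp[d, , ] <- vals / ifelse(s > 0, s, 1)
  }
  geno <- matrix(apply(gp, c(1, 2), which.max) - 1L, nrow = n_d)
  snvs <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                     stringsAsFactors = FALSE)
  snvs$id <- paste0(snvs$chrom, ":", snvs$pos)
  r2 <- vcfR::extract.info(v, element = "R2", as.numeric = TRUE)
  if (!all(is.na(r2))) snvs$r2 <- r2
  structure(list(genotypes = geno, gp = gp,
                 freqs = rep(NA_real_, n_v), snvs = snvs,
                 donor_ids = donor_ids),
            class = "donor_genotypes")
}

#' Write the simulation truth table as TSV
#'
#' @param truth a `"sim_truth"` object.
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  asg <- truth$assignments
  writeLines(c(paste(c("barcode", "donor", "label"), collapse = "\t"),
               sprintf("%s\t%s\t%s", asg$barcode,
                       ifelse(is.na(asg$donor), "NA", asg$donor),
                       asg$label)),
             path)
  invisible(path)
}

#' Read a simulation truth table written by [write_sim_truth]
#'
#' @param path TSV path.
#' @return a `"sim_truth"` object (parameters reconstructed minimally).
#' @export
read_sim_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  df$donor[df$donor == "NA"] <- NA_character_
  structure(list(
    assignments = df,
    doublets = data.frame(barcode = df$barcode[df$label == "DBL"],
                          merged_in = NA_character_, donor1 = NA_character_,
                          donor2 = NA_character_, same_donor = NA,
                          stringsAsFactors = FALSE),
    params = list(n_donors = length(unique(stats::na.omit(df$donor))),
                  n_cells = nrow(df),
                  doublet_fraction = mean(df$label == "DBL"))),
    class = "sim_truth")
}
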