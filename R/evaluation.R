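#' Score demultiplexing predictions against a known truth
#'
#' Builds the confusion matrix of truth classes (donors and `DBL`) against
#' predicted classes (donors, `DBL`, `unassigned`) and derives per-class
#' and aggregate metrics. TPR of a class is the fraction of its true cells
#' predicted into it (unassigned cells count against the denominator); FDR
#' of a class is the fraction of cells assigned to it that do not belong
#' (unassigned cells are not "assigned" and enter neither FDR numerator nor
#' denominator). Singlet metrics are unweighted means over donor classes;
#' Cohen's kappa is computed over assigned cells only.
#'
#' @param labels predicted per-barcode labels (`"SNG-k"`, `"DBL"`,
#'   `"unassigned"`), named by barcode.
#' @param truth a `"sim_truth"` object (or any list with an `assignments`
#'   data frame holding `barcode` and `label`, where `label` is a donor id
#'   or `"DBL"`).
#' @param mapping named character vector mapping predicted cluster names
#'   (`"SNG-k"`) to donor ids, e.g. from [map_clusters_to_samples].
#' @return an object of class `"demux_eval"`: list with `confusion`,
#'   `per_class` (TPR/FDR per class), `singlet_tpr`, `singlet_fdr`,
#'   `doublet_tpr`, `doublet_fdr`, `doublet_tpr_cross` / `doublet_tpr_same`
#'   (cross-donor vs same-donor doublets, when the truth records doublet
#'   pairs; same-donor merges are genetically undetectable in principle and
#'   also excluded from `singlet_fdr_detectable`), `n_same_donor_doublets`,
#'   `avg_tpr`, `avg_fdr`, `kappa`, `n_cells`.
#' @export
evaluate_demux <- function(labels, truth, mapping = NULL) {
  asg <- truth$assignments
  if (is.null(names(labels))) stop("'labels' must be named by barcode")
  common <- intersect(asg$barcode, names(labels))
  if (length(common) < nrow(asg))
    stop("predicted labels missing for ", nrow(asg) - length(common),
         " barcode(s)")
  asg <- asg[match(common, asg$barcode), ]
  pred_raw <- labels[common]

  clusters <- sort(unique(pred_raw[startsWith(pred_raw, "SNG")]))
  if (!is.null(mapping)) {
    miss <- setdiff(clusters, names(mapping))
    if (length(miss))
      stop("mapping is missing cluster(s): ", paste(miss, collapse = ", "))
    pred <- ifelse(pred_raw %in% names(mapping),
                   mapping[pred_raw], pred_raw)
  } else pred <- pred_raw

  donor_classes <- sort(unique(asg$label[asg$label != "DBL"]))
  truth_classes <- c(donor_classes, "DBL")
  pred_classes <- c(donor_classes, "DBL", "unassigned")
  pred[!pred %in% pred_classes] <- "unassigned"
  conf <- table(factor(asg$label, levels = truth_classes),
                factor(pred, levels = pred_classes))
  conf <- unclass(conf)

  tpr <- vapply(truth_classes, function(cl) {
    denom <- sum(conf[cl, ])
    if (denom == 0) NA_real_ else conf[cl, cl] / denom
  }, numeric(1))
  fdr <- vapply(truth_classes, function(cl) {
    assigned <- sum(conf[, cl])
    if (assigned == 0) 0 else (assigned - conf[cl, cl]) / assigned
  }, numeric(1))

  # kappa over assigned cells only
  assigned_cols <- setdiff(pred_classes, "unassigned")
  ca <- conf[, assigned_cols, drop = FALSE]
  n_assigned <- sum(ca)
  kappa <- if (n_assigned == 0) NA_real_ else {
    classes <- union(rownames(ca), colnames(ca))
    sq <- matrix(0, length(classes), length(classes),
                 dimnames = list(classes, classes))
    sq[rownames(ca), colnames(ca)] <- ca
    po <- sum(diag(sq)) / n_assigned
    pe <- sum(rowSums(sq) * colSums(sq)) / n_assigned^2
    if (pe >= 1) 1 else (po - pe) / (1 - pe)
  }

  # same-donor merges are genetically identical to singlets of that donor;
  # they are kept in all strict metrics but additionally reported separately
  # as undetectable-in-principle for an allele-fraction model
  dbl_cross <- dbl_same <- NA_real_
  n_same <- 0L
  fdr_detect <- fdr
  if (nrow(truth$doublets) > 0 && !all(is.na(truth$doublets$same_donor))) {
    cross <- intersect(truth$doublets$barcode[!truth$doublets$same_donor],
                       common)
    same <- intersect(truth$doublets$barcode[truth$doublets$same_donor],
                      common)
    n_same <- length(same)
    if (length(cross))
      dbl_cross <- mean(pred[match(cross, common)] == "DBL")
    if (length(same)) {
      dbl_same <- mean(pred[match(same, common)] == "DBL")
      # detectable FDR: a same-donor doublet predicted into its own donor's
      # cluster is not counted as an error
      own <- stats::setNames(truth$doublets$donor1, truth$doublets$barcode)
      for (cl in donor_classes) {
        excuse <- sum(pred[match(same, common)] == cl & own[same] == cl)
        assigned <- sum(conf[, cl])
        fdr_detect[cl] <- if (assigned == 0) 0 else
          max(0, (assigned - conf[cl, cl] - excuse)) / assigned
      }
    }
  }

  structure(list(
    confusion = conf,
    per_class = data.frame(class = truth_classes, tpr = tpr, fdr = fdr,
                           row.names = NULL),
    singlet_tpr = mean(tpr[donor_classes], na.rm = TRUE),
    singlet_fdr = mean(fdr[donor_classes], na.rm = TRUE),
    doublet_tpr = tpr[["DBL"]],
    doublet_fdr = fdr[["DBL"]],
    doublet_tpr_cross = dbl_cross,
    doublet_tpr_same = dbl_same,
    n_same_donor_doublets = n_same,
    singlet_fdr_detectable = mean(fdr_detect[donor_classes], na.rm = TRUE),
    avg_tpr = mean(tpr, na.rm = TRUE),
    avg_fdr = mean(fdr, na.rm = TRUE),
    kappa = kappa,
    n_cells = length(common)),
    class = "demux_eval")
}

#' @export
print.demux_eval <- function(x, ...) {
  cat("Demultiplexing evaluation against truth\n")
  cat(sprintf("  cells: %d\n", x$n_cells))
  cat(sprintf("  singlet TPR %.4f / FDR %.4g; doublet TPR %.4f / FDR %.4g\n",
              x$singlet_tpr, x$singlet_fdr, x$doublet_tpr, x$doublet_fdr))
  if (!is.na(x$doublet_tpr_cross))
    cat(sprintf("  cross-donor doublet TPR %.4f\n", x$doublet_tpr_cross))
  if (x$n_same_donor_doublets > 0)
    cat(sprintf(paste0("  %d same-donor doublet(s) (undetectable in ",
                       "principle): TPR %.4f; singlet FDR excluding them ",
                       "%.4g\n"),
        x$n_same_donor_doublets, x$doublet_tpr_same,
        x$singlet_fdr_detectable))
  cat(sprintf("  average TPR %.4f / FDR %.4g; Cohen's kappa %.4f\n",
              x$avg_tpr, x$avg_fdr, x$kappa))
  cat("  confusion matrix (rows = truth, cols = predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param x a `"demux_eval"` object.
#' @param path output path.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "demux_eval"))
  metrics <- c(singlet_tpr = x$singlet_tpr, singlet_fdr = x$singlet_fdr,
               doublet_tpr = x$doublet_tpr, doublet_fdr = x$doublet_fdr,
               doublet_tpr_cross = x$doublet_tpr_cross,
               doublet_tpr_same = x$doublet_tpr_same,
               n_same_donor_doublets = x$n_same_donor_doublets,
               singlet_fdr_detectable = x$singlet_fdr_detectable,
               avg_tpr = x$avg_tpr, avg_fdr = x$avg_fdr, kappa = x$kappa,
               n_cells = x$n_cells)
  writeLines(c("metric\tvalue",
               sprintf("%s\t%.8g", names(metrics), metrics)),
             path)
  invisible(path)
}

#' Run the whole demultiplexing pipeline on simulated data
#'
#' Convenience wrapper reproducing the simulation study design: synthesize
#' donor genotypes (unrelated Hardy-Weinberg donors or a full-sibling
#' pair), simulate pooled allele counts with merged-barcode doublets,
#' filter SNVs by aggregate heterozygosity, fit the mixture with restarts,
#' genotype the clusters, map them to donors through distinguishing
#' variants, and score against the simulation truth.
#'
#' @param n_donors number of pooled donors.
#' @param n_cells,n_snvs,reads_per_cell simulation scale.
#' @param doublet_fraction merged-barcode doublet fraction (default 0.03).
#' @param siblings simulate the (two) donors as full siblings
#'   (default `FALSE`; requires `n_donors == 2`).
#' @param n_restarts EM restarts (default 30).
#' @param seed integer seed driving every random step.
#' @param ... passed to [poolsplit].
#' @return list with `fit`, `eval`, `mapping`, `variants`, `truth`,
#'   `counts`.
#' @export
demux_simulation_study <- function(n_donors, n_cells, n_snvs,
                                   reads_per_cell = 750,
                                   doublet_fraction = 0.03,
                                   siblings = FALSE, n_restarts = 30L,
                                   seed = 1L, ...) {
  set.seed(seed)
  donors <- if (siblings) {
    stopifnot(n_donors == 2)
    synth_sibling_pair(n_snvs)
  } else synth_donor_genotypes(n_donors, n_snvs)
  sim <- simulate_counts(donors, n_cells, reads_per_cell = reads_per_cell)
  sim <- inject_doublets(sim$counts, sim$truth, doublet_fraction)
  counts <- het_likelihood_filter(sim$counts)
  fit <- poolsplit(counts, n_samples = n_donors, n_restarts = n_restarts,
                   expected_doublet_fraction = doublet_fraction, ...)
  cpa <- cluster_pa_matrix(counts, fit$labels)
  spa <- sample_pa_matrix(donors, snv_subset = rownames(cpa))
  # deeply sequenced clusters can lack strict absence ("A") calls, leaving
  # no NA-free distinguishing set; fall back to scoring the full P/A matrix
  variants <- tryCatch(distinguishing_variants(cpa), error = function(e) {
    rn <- rownames(cpa)[rowSums(cpa != "NA") > 0]
    attr(rn, "fallback") <- conditionMessage(e)
    rn
  })
  mp <- map_clusters_to_samples(cpa, spa, variants)
  ev <- evaluate_demux(fit$labels, sim$truth, mapping = mp$mapping)
  list(fit = fit, eval = ev, mapping = mp$mapping, variants = variants,
       truth = sim$truth, counts = counts, donors = donors)
}
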