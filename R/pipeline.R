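#' Run the full multi-omics subtyping pipeline on a cohort
#'
#' Chains every stage on a generated (or assembled) cohort: preliminary
#' expression clustering with normal controls and contamination removal;
#' per-omic consensus clustering (mRNA: Pearson/Ward on the 5% most variant
#' genes; miRNA: count filtering and normalization then Pearson/Ward;
#' methylation: Euclidean/unsquared Ward on the 5% most variant CpGs);
#' cluster-of-clusters integration; expression-based 1p/19q co-deletion
#' assignment; MYC-pathway event calling and aggregation with the MYC
#' activity score; mutual-exclusivity tests; and survival comparisons of
#' the aggressive co-deleted subtype, including the radiotherapy-stratified
#' analysis.
#'
#' @param cohort A [generate_cohort()] result, or a list with the same
#'   elements assembled from files.
#' @param k_range K values scanned per omic (default 2:8).
#' @param n_iter Consensus resampling iterations (default 1000).
#' @param feature_fraction Most-variant feature fraction (default 0.05).
#' @param seed Integer seed controlling every resampling stage.
#' @return List with elements `flagged`, `mrna_cc`, `mirna_cc`, `meth_cc`,
#'   `integrated`, `associations`, `codel`, `events`, `exclusivity`,
#'   `score_by_event`, `survival_o1`, `rt`.
#' @export
run_pipeline <- function(cohort, k_range = 2:8, n_iter = 1000,
                         feature_fraction = 0.05, seed = 1) {
  mrna <- cohort$mrna
  annot <- cohort$annot

  ## contamination screen on all mRNA-profiled samples (controls included)
  feats0 <- select_variant_features(mrna, feature_fraction)
  pre <- consensus_cluster(mrna$values[feats0, , drop = FALSE],
                           k_range = k_range, n_iter = n_iter,
                           distance = "pearson", seed = seed)
  flagged <- flag_contamination(pre$partition, annot)
  controls <- annot$sample[annot$is_normal_control]
  keep <- setdiff(colnames(mrna$values), c(flagged, controls))
  mrna_t <- mrna
  mrna_t$values <- mrna$values[, keep, drop = FALSE]

  ## per-omic consensus clustering
  feats <- select_variant_features(mrna_t, feature_fraction)
  mrna_cc <- consensus_cluster(mrna_t$values[feats, , drop = FALSE],
                               k_range = k_range, n_iter = n_iter,
                               distance = "pearson", seed = seed + 1)

  mirna_keep <- intersect(colnames(cohort$mirna_counts), keep)
  # conventional CPM-then-log2 order: the literal log2-then-divide order
  # couples whole profiles to library size (see the methods vignette)
  mirna_norm <- mirna_preprocess(cohort$mirna_counts[, mirna_keep, drop = FALSE],
                                 order = "cpm-first")
  mirna_cc <- consensus_cluster(mirna_norm$values, k_range = k_range,
                                n_iter = n_iter, distance = "pearson",
                                seed = seed + 2)

  meth_keep <- intersect(colnames(cohort$methylation$values), keep)
  meth <- cohort$methylation
  meth$values <- meth$values[, meth_keep, drop = FALSE]
  meth_feats <- select_variant_features(meth, feature_fraction)
  meth_cc <- consensus_cluster(meth$values[meth_feats, , drop = FALSE],
                               k_range = k_range, n_iter = n_iter,
                               distance = "euclidean", linkage = "ward.D",
                               seed = seed + 3)

  ## integration
  indicator <- encode_partitions(list(mrna = mrna_cc$partition,
                                      meth = meth_cc$partition,
                                      mirna = mirna_cc$partition))
  integrated <- cluster_of_clusters(indicator, k_range = k_range,
                                    n_iter = n_iter, seed = seed + 4)
  associations <- list(
    mrna_mirna = crosstab_association(mrna_cc$partition, mirna_cc$partition),
    mrna_meth = crosstab_association(mrna_cc$partition, meth_cc$partition))

  ## co-deletion and MYC-pathway events
  codel <- codel_from_expression(mrna_t)
  myc_gain <- call_gene_event(cohort$gnl, myc_region(), "gain")[keep]
  max_loss <- call_gene_event(cohort$gnl, max_region(), "loss")[keep]
  meth_all <- cohort$methylation
  hypo <- rep(NA, length(keep)); names(hypo) <- keep
  hyper <- hypo
  meth_samples <- intersect(keep, colnames(meth_all$values))
  hypo[meth_samples] <- call_cpg_hypomethylation(meth_all)[meth_samples]
  hyper_call <- call_cpg_hypermethylation(meth_all)
  hyper[meth_samples] <- hyper_call$call[meth_samples]
  score <- myc_activity_score(mrna_t, cohort$myc_targets)
  etable <- aggregate_events(myc_gain, max_loss, hypo, hyper,
                             myc_score = score)

  myc_alt <- ifelse(is.na(etable$myc_gain) & is.na(etable$myc_hypometh), NA,
                    etable$myc_gain %in% TRUE | etable$myc_hypometh %in% TRUE)
  names(myc_alt) <- etable$sample
  exclusivity <- list(
    myc_vs_mir34 = exclusivity_test(myc_alt,
                                    stats::setNames(etable$mir34_hypermeth, etable$sample)),
    myc_vs_max = exclusivity_test(myc_alt,
                                  stats::setNames(etable$max_loss, etable$sample)))
  sbe <- tryCatch(score_by_event(etable), error = function(e) NULL)

  ## survival of the aggressive co-deleted class vs the other co-deleted
  part <- integrated$partition
  surv <- annot[match(names(part), annot$sample), ]
  is_codel <- codel$codel[names(part)]
  cod_samples <- names(part)[is_codel %in% TRUE]
  survival_o1 <- NULL; rt <- NULL
  if (length(cod_samples) >= 4) {
    sc <- surv[match(cod_samples, surv$sample), ]
    cls <- unclass(part)[cod_samples]
    # the integrated class with the highest mean MYC activity among the
    # co-deleted samples is taken as the aggressive (O1-like) class
    cls_score <- tapply(score[cod_samples], cls, mean, na.rm = TRUE)
    o1_class <- names(cls_score)[which.max(cls_score)]
    o1 <- ifelse(cls == o1_class, "O1", "other")
    survival_o1 <- tryCatch(
      logrank(sc$os_time, sc$os_event, o1), error = function(e) NULL)
    rt <- tryCatch(
      rt_stratified(data.frame(os_time = sc$os_time, os_event = sc$os_event,
                               initial_radiotherapy = sc$initial_radiotherapy,
                               subtype = o1)),
      error = function(e) NULL)
  }

  list(flagged = flagged, mrna_cc = mrna_cc, mirna_cc = mirna_cc,
       meth_cc = meth_cc, integrated = integrated,
       associations = associations, codel = codel, events = etable,
       exclusivity = exclusivity, score_by_event = sbe,
       survival_o1 = survival_o1, rt = rt)
}
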