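#' Encode per-omic partitions as binary class indicators
#'
#' Builds the sample x class-variable matrix used by the cluster-of-clusters
#' integration: one binary column per class of each input partition, value 1
#' if the sample is in the class, 0 if it is in another class of the same
#' partition, and NA across a partition's whole block when the sample was
#' not classified at that molecular level. The sample universe is the union
#' over all partitions.
#'
#' @param partitions Named list of [class_partition()] objects (>= 2); names
#'   prefix the column names (e.g. `mrna.1`).
#' @return Numeric matrix, samples x class variables, with NA blocks.
#' @export
encode_partitions <- function(partitions) {
  if (length(partitions) < 2)
    stop("encode_partitions: need at least two partitions")
  if (is.null(names(partitions)))
    names(partitions) <- paste0("omic", seq_along(partitions))
  samples <- Reduce(union, lapply(partitions, names))
  blocks <- lapply(names(partitions), function(nm) {
    p <- partitions[[nm]]
    classes <- sort(unique(stats::na.omit(unclass(p))))
    if (length(classes) < 2)
      stop("encode_partitions: partition '", nm, "' has a single class")
    block <- matrix(NA_real_, length(samples), length(classes),
                    dimnames = list(samples, paste(nm, classes, sep = ".")))
    labelled <- intersect(samples, names(p)[!is.na(unclass(p))])
    for (j in seq_along(classes))
      block[labelled, j] <- as.numeric(unclass(p)[labelled] == classes[j])
    block
  })
  do.call(cbind, blocks)
}

#' Cluster-of-clusters integration
#'
#' Integrates the per-omic partitions by consensus clustering of the binary
#' indicator encoding from [encode_partitions()] (samples as items, class
#' variables as features, Pearson dissimilarity over pairwise-complete
#' columns, Ward linkage). Samples unclassified on every omic are excluded
#' with a warning.
#'
#' @param indicator Matrix from [encode_partitions()].
#' @inheritParams consensus_cluster
#' @return A `consensus_result`; its `$partition` is the integrated
#'   [class_partition()].
#' @export
cluster_of_clusters <- function(indicator, k_range = 2:8, n_iter = 1000,
                                subsample_fraction = 0.8, seed = NULL,
                                delta_threshold = 0.10) {
  all_na <- rowSums(!is.na(indicator)) == 0
  if (any(all_na)) {
    warning("cluster_of_clusters: dropping ", sum(all_na),
            " sample(s) unclassified on every omic")
    indicator <- indicator[!all_na, , drop = FALSE]
  }
  consensus_cluster(t(indicator), k_range = k_range, n_iter = n_iter,
                    subsample_fraction = subsample_fraction,
                    distance = "pearson", linkage = "ward.D2", seed = seed,
                    delta_threshold = delta_threshold)
}

#' Preprocess miRNA read counts for clustering
#'
#' Expression filtering and normalization of small-RNA counts: keep miRNAs
#' with more than `min_reads` reads in at least `min_samples` samples, then
#' (in the default `"log2-first"` order) log2-transform the counts with a
#' pseudocount of 1, divide each sample's column by its total raw read count
#' scaled to per-million, and centre each miRNA on its mean. The
#' conventional counts-per-million-then-log2 order is available via
#' `order = "cpm-first"`.
#'
#' @param counts Non-negative integer matrix, miRNAs x samples.
#' @param min_reads Read threshold (strict, default 10: a sample counts only
#'   with > 10 reads).
#' @param min_samples Minimum number of samples over the threshold
#'   (default 2).
#' @param order `"log2-first"` (log2 then library-size division) or
#'   `"cpm-first"`.
#' @return An [omics_matrix()] of kind `"mirna"`, features centred on zero.
#' @export
mirna_preprocess <- function(counts, min_reads = 10, min_samples = 2,
                             order = c("log2-first", "cpm-first")) {
  order <- match.arg(order)
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE) || any(counts != round(counts), na.rm = TRUE))
    stop("mirna_preprocess: counts must be non-negative integers")
  totals <- colSums(counts, na.rm = TRUE)
  if (any(totals == 0)) {
    warning("mirna_preprocess: excluding ", sum(totals == 0),
            " sample(s) with zero total reads")
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  keep <- rowSums(counts > min_reads, na.rm = TRUE) >= min_samples
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0) stop("mirna_preprocess: no miRNA passes the expression filter")
  if (order == "log2-first") {
    m <- log2(counts + 1)
    m <- sweep(m, 2, totals / 1e6, "/")
  } else {
    m <- sweep(counts, 2, totals / 1e6, "/")
    m <- log2(m + 1)
  }
  m <- m - rowMeans(m, na.rm = TRUE)
  omics_matrix(m, "mirna")
}

#' Association between two partitions
#'
#' Pearson chi-square test on the contingency table of samples labelled in
#' both partitions, as used to compare the per-omic classifications.
#'
#' @param a,b [class_partition()] objects (matched by sample id).
#' @return List with `table`, `statistic`, `df`, `p_value`.
#' @export
crosstab_association <- function(a, b) {
  common <- intersect(names(a), names(b))
  la <- unclass(a)[common]; lb <- unclass(b)[common]
  keep <- !is.na(la) & !is.na(lb)
  tab <- table(la[keep], lb[keep])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2)
    stop("crosstab_association: degenerate contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
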