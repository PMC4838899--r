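#' Call a gene-level copy-number event
#'
#' Conservative "all positions" rule: in segment mode a sample is positive
#' only if the gene region is fully covered by segments and every
#' overlapping segment carries the target sign (gain: +1/+2, loss: -1/-2).
#' In gene mode the gene's own call must match the sign. A region touched by
#' no segment gives an NA call.
#'
#' @param gnl [gnl_table()].
#' @param gene_region For segment mode, a list/vector with `chrom`, `start`,
#'   `end` (1-based inclusive); for gene mode, the gene id.
#' @param direction `"gain"` or `"loss"`.
#' @return Named logical vector over the table's samples (NA = uncovered).
#' @export
call_gene_event <- function(gnl, gene_region, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  sign_ok <- if (direction == "gain") c(1L, 2L) else c(-1L, -2L)
  if (gnl$mode == "gene") {
    gene <- as.character(gene_region)
    if (!gene %in% rownames(gnl$genes))
      stop("call_gene_event: gene '", gene, "' absent from GNL table")
    calls <- gnl$genes[gene, ] %in% sign_ok
    calls[is.na(gnl$genes[gene, ])] <- NA
    return(stats::setNames(calls, colnames(gnl$genes)))
  }
  region <- as.list(gene_region)
  chrom <- as.character(region$chrom)
  rs <- as.numeric(region$start); re <- as.numeric(region$end)
  vapply(gnl$samples, function(s) {
    seg <- gnl$segments[gnl$segments$sample == s & gnl$segments$chrom == chrom &
                          gnl$segments$end >= rs & gnl$segments$start <= re, ,
                        drop = FALSE]
    if (nrow(seg) == 0) return(NA)
    covered <- sum(pmin(seg$end, re) - pmax(seg$start, rs) + 1)
    if (covered < re - rs + 1) return(NA)  # gaps inside the region
    all(seg$gnl %in% sign_ok)
  }, NA)
}

#' Call chromosome-arm copy-number status
#'
#' Aggregates segment calls to an arm-level status in `{-1, 0, +1}`: the arm
#' takes sign `s` when at least `agree_fraction` of its covered length has
#' GNL of that sign, and 0 otherwise. Arms with less than `min_coverage` of
#' their length covered by any segment give NA.
#'
#' @param gnl Segment-mode [gnl_table()].
#' @param arm Arm label (e.g. `"1p"`, `"19q"`) looked up in
#'   [arm_boundaries()].
#' @param agree_fraction Fraction of covered length required (default 0.8).
#' @param min_coverage Minimum covered fraction of the arm (default 0.5).
#' @return Named integer vector over samples with values -1/0/+1 or NA.
#' @export
call_arm_status <- function(gnl, arm, agree_fraction = 0.8, min_coverage = 0.5) {
  if (gnl$mode != "segment")
    stop("call_arm_status: needs a segment-mode GNL table")
  ab <- arm_boundaries()
  row <- ab[ab$arm == arm, ]
  if (nrow(row) != 1) stop("call_arm_status: unknown arm '", arm, "'")
  arm_len <- row$end - row$start + 1
  vapply(gnl$samples, function(s) {
    seg <- gnl$segments[gnl$segments$sample == s & gnl$segments$chrom == row$chrom &
                          gnl$segments$end >= row$start & gnl$segments$start <= row$end, ,
                        drop = FALSE]
    if (nrow(seg) == 0) return(NA_integer_)
    len <- pmin(seg$end, row$end) - pmax(seg$start, row$start) + 1
    if (sum(len) / arm_len < min_coverage) return(NA_integer_)
    gain_len <- sum(len[seg$gnl > 0]); loss_len <- sum(len[seg$gnl < 0])
    if (gain_len / sum(len) >= agree_fraction) return(1L)
    if (loss_len / sum(len) >= agree_fraction) return(-1L)
    0L
  }, NA_integer_)
}

#' Expression-based 1p/19q co-deletion assignment
#'
#' For cohorts lacking copy-number data, co-deletion status is inferred from
#' expression alone: per sample, the mean gene-centred expression of
#' features on 1p (`m1p`) and on 19q (`m19q`) is computed; samples are then
#' split on the averaged score `u = (m1p + m19q) / 2` by the exact
#' one-dimensional two-class partition minimizing total within-class
#' variance. The class with the lower mean score is called co-deleted.
#'
#' @param mrna [omics_matrix()] whose `feature_annot$arm` labels include
#'   `"1p"` and `"19q"` (>= `min_features` each).
#' @param min_features Minimum features per arm (default 5).
#' @param min_class Minimum samples per side at the optimum (default 2);
#'   below it no call is made.
#' @return List with `codel` (named logical), `scores` (data.frame `m1p`,
#'   `m19q`, `u`), `threshold`.
#' @export
codel_from_expression <- function(mrna, min_features = 5, min_class = 2) {
  if (is.null(mrna$feature_annot) || is.null(mrna$feature_annot$arm))
    stop("codel_from_expression: feature_annot with arm labels required")
  m <- mrna$values
  centred <- m - rowMeans(m, na.rm = TRUE)
  arm <- mrna$feature_annot$arm
  i1p <- which(arm == "1p"); i19q <- which(arm == "19q")
  if (length(i1p) < min_features || length(i19q) < min_features)
    stop("codel_from_expression: need >= ", min_features, " features on each of 1p and 19q")
  m1p <- colMeans(centred[i1p, , drop = FALSE], na.rm = TRUE)
  m19q <- colMeans(centred[i19q, , drop = FALSE], na.rm = TRUE)
  u <- (m1p + m19q) / 2
  scores <- data.frame(m1p = m1p, m19q = m19q, u = u)

  ord <- order(u)
  us <- u[ord]
  n <- length(us)
  if (n < 2 * min_class || stats::var(us) == 0) {
    warning("codel_from_expression: degenerate score distribution; no call")
    return(list(codel = stats::setNames(rep(NA, n), names(u)),
                scores = scores, threshold = NA_real_))
  }
  # exact scan over the n-1 ordered splits: within-SS via cumulative sums
  cs <- cumsum(us); cs2 <- cumsum(us^2)
  k <- seq_len(n - 1)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  wss <- ss_left + ss_right
  best <- which.min(wss)
  if (best < min_class || n - best < min_class) {
    warning("codel_from_expression: optimal split leaves < ", min_class,
            " samples on one side; no call")
    return(list(codel = stats::setNames(rep(NA, n), names(u)),
                scores = scores, threshold = NA_real_))
  }
  threshold <- (us[best] + us[best + 1]) / 2
  codel <- u <= us[best]   # lower-score side = co-deleted
  list(codel = codel, scores = scores, threshold = threshold)
}

#' Call hypomethylation at a single CpG
#'
#' Fixed-threshold rule used for the MYC exon 3 site: a sample is
#' hypomethylated when its beta value is strictly below `threshold`.
#'
#' @param methylation Methylation [omics_matrix()].
#' @param cpg_id CpG probe id (default the MYC exon 3 site `cg00163372`).
#' @param threshold Beta threshold, strict inequality (default 0.5).
#' @return Named logical vector (NA beta gives NA call).
#' @export
call_cpg_hypomethylation <- function(methylation, cpg_id = "cg00163372",
                                     threshold = 0.5) {
  m <- methylation$values
  if (!cpg_id %in% rownames(m))
    stop("call_cpg_hypomethylation: CpG '", cpg_id, "' absent from matrix")
  beta <- m[cpg_id, ]
  beta < threshold
}

#' Call hypermethylation at a single CpG (mean + 2 SD rule)
#'
#' Cohort-relative rule used for the mir34b/c promoter site: the threshold
#' is the mean beta plus twice the standard deviation (n-1 denominator) over
#' all non-NA samples of the dataset at the CpG; a sample is hypermethylated
#' when its beta is strictly above it.
#'
#' @param methylation Methylation [omics_matrix()].
#' @param cpg_id CpG probe id (default `cg22879515`; the companion sites
#'   `cg21881253`, `cg13767940`, `cg23211240` at the same locus are
#'   inspectable but do not enter the call).
#' @param min_samples Minimum non-NA samples (default 10).
#' @return List with `call` (named logical) and `threshold`.
#' @export
call_cpg_hypermethylation <- function(methylation, cpg_id = "cg22879515",
                                      min_samples = 10) {
  m <- methylation$values
  if (!cpg_id %in% rownames(m))
    stop("call_cpg_hypermethylation: CpG '", cpg_id, "' absent from matrix")
  beta <- m[cpg_id, ]
  ok <- !is.na(beta)
  if (sum(ok) < min_samples)
    stop("call_cpg_hypermethylation: need >= ", min_samples, " non-NA samples")
  s <- stats::sd(beta[ok])
  if (s == 0) {
    warning("call_cpg_hypermethylation: zero variance at ", cpg_id, "; no sample called")
    return(list(call = stats::setNames(ifelse(ok, FALSE, NA), names(beta)),
                threshold = mean(beta[ok])))
  }
  threshold <- mean(beta[ok]) + 2 * s
  list(call = beta > threshold, threshold = threshold)
}

#' CpG island methylator phenotype (CIMP) status
#'
#' Consensus clustering restricted to CpG-island probes (most-variant
#' selection, Euclidean distance, unsquared-input Ward), cut at K = 2; the
#' class with the higher mean beta over the selected probes is
#' CIMP-positive. Polarity is defined by mean methylation, never by class
#' label, so relabelling cannot flip it.
#'
#' @param methylation Methylation [omics_matrix()] whose
#'   `feature_annot$cpg_island` flags island probes.
#' @param fraction Most-variant island-probe fraction (default 0.05).
#' @param n_iter,subsample_fraction,seed Passed to [consensus_cluster()].
#' @return List with `cimp` (named logical), `partition`, `class_means`.
#' @export
cimp_status <- function(methylation, fraction = 0.05, n_iter = 1000,
                        subsample_fraction = 0.8, seed = NULL) {
  if (is.null(methylation$feature_annot) ||
      is.null(methylation$feature_annot$cpg_island))
    stop("cimp_status: feature_annot with cpg_island flags required")
  island <- which(methylation$feature_annot$cpg_island %in% TRUE)
  if (length(island) == 0) stop("cimp_status: no CpG-island probes")
  sub <- methylation$values[island, , drop = FALSE]
  feats <- select_variant_features(sub, fraction)
  sub <- sub[feats, , drop = FALSE]
  cr <- consensus_cluster(sub, k_range = 2, n_iter = n_iter,
                          subsample_fraction = subsample_fraction,
                          distance = "euclidean", linkage = "ward.D",
                          seed = seed)
  part <- cr$labels[["2"]]
  means <- tapply(colMeans(sub, na.rm = TRUE), unclass(part), mean)
  if (abs(diff(range(means))) < 0.02)
    warning("cimp_status: class mean betas nearly equal; no CIMP structure")
  pos_class <- names(means)[which.max(means)]
  cimp <- unclass(part) == pos_class
  names(cimp) <- names(part)
  list(cimp = cimp, partition = part, class_means = means)
}
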