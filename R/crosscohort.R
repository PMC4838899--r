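#' Per-class expression centroids for a dataset
#'
#' For each class of the partition, the centroid is the per-gene mean
#' expression over class members, computed on the dataset's most variant
#' genes (top `fraction`, default 10%). Class means and gene variances over
#' the full gene universe are retained so that pairwise comparisons can
#' re-select genes on the universe shared with another dataset.
#'
#' @param x [omics_matrix()] or features x samples matrix.
#' @param partition [class_partition()] over the samples (NA samples
#'   ignored; empty classes dropped).
#' @param fraction Most-variant gene fraction (default 0.10).
#' @param dataset Dataset identifier.
#' @return Object of class `centroid_set`: `dataset`, `centroids` (genes x
#'   classes, restricted to the selection), `class_means` (all genes),
#'   `variances`, `genes_used`.
#' @export
compute_centroids <- function(x, partition, fraction = 0.10, dataset = "data") {
  m <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  labs <- unclass(partition)[colnames(m)]
  keep <- !is.na(labs)
  m <- m[, keep, drop = FALSE]; labs <- labs[keep]
  classes <- sort(unique(labs))
  if (length(classes) < 1) stop("compute_centroids: no labelled sample")
  class_means <- vapply(classes, function(cl)
    rowMeans(m[, labs == cl, drop = FALSE], na.rm = TRUE),
    numeric(nrow(m)))
  colnames(class_means) <- classes
  variances <- apply(m, 1, stats::var, na.rm = TRUE)
  sel <- select_variant_features(m, fraction)
  structure(list(dataset = dataset,
                 centroids = class_means[sel, , drop = FALSE],
                 class_means = class_means, variances = variances,
                 genes_used = sel, fraction = fraction),
            class = "centroid_set")
}

# Gene selection for one dataset pair: top-fraction most variant among the
# genes measured in both datasets, taken within each dataset, intersected;
# falls back to the union when the intersection is too small to correlate.
pair_gene_selection <- function(a, b, min_genes = 10) {
  shared <- intersect(names(a$variances), names(b$variances))
  if (length(shared) < min_genes)
    stop("centroid_correlations: fewer than ", min_genes, " shared genes")
  top_of <- function(s) {
    v <- s$variances[shared]
    v <- v[!is.na(v)]
    names(v)[order(-v, names(v))][seq_len(ceiling(s$fraction * length(v)))]
  }
  ta <- top_of(a); tb <- top_of(b)
  genes <- intersect(ta, tb)
  if (length(genes) < min_genes) genes <- union(ta, tb)
  if (length(genes) < min_genes)
    stop("centroid_correlations: pairwise gene selection below ", min_genes, " genes")
  genes
}

#' Correlations between the class centroids of two datasets
#'
#' Pearson correlations between every class centroid of one dataset and
#' every class centroid of another, computed on the pair-specific gene
#' selection (most variant genes among those measured in both datasets).
#'
#' @param a,b [compute_centroids()] results.
#' @param min_genes Minimum usable shared genes (default 10).
#' @return Classes-of-a x classes-of-b correlation matrix, with attribute
#'   `genes` (the selection used).
#' @export
centroid_correlations <- function(a, b, min_genes = 10) {
  genes <- pair_gene_selection(a, b, min_genes)
  r <- stats::cor(a$class_means[genes, , drop = FALSE],
                  b$class_means[genes, , drop = FALSE],
                  use = "pairwise.complete.obs")
  attr(r, "genes") <- genes
  r
}

#' Match classes across datasets into meta-classes
#'
#' Pools the class centroids of two or more datasets and clusters them
#' hierarchically on Pearson correlation distance (1 - r, average linkage
#' by default); cutting at `n_meta` yields the meta-classes that align the
#' per-dataset classifications. Distances between centroids of different
#' datasets use that pair's shared-gene selection, so the combined distance
#' matrix deliberately mixes gene universes.
#'
#' @param sets List of [compute_centroids()] results (>= 2 datasets).
#' @param n_meta Number of meta-classes (default 3).
#' @param linkage hclust linkage for the centroid tree (default
#'   `"average"`).
#' @param min_genes Passed to the pairwise gene selection.
#' @return data.frame (`dataset`, `class`, `meta_class`) with attributes
#'   `distance` (the combined matrix) and `balanced` (TRUE when every
#'   meta-class holds exactly one class from every dataset).
#' @export
match_classes <- function(sets, n_meta = 3, linkage = "average", min_genes = 10) {
  if (length(sets) < 2) stop("match_classes: need >= 2 datasets")
  ids <- unlist(lapply(sets, function(s)
    paste(s$dataset, colnames(s$class_means), sep = ":")))
  n_total <- length(ids)
  if (n_meta > n_total) stop("match_classes: n_meta exceeds the total number of classes")
  owner <- rep(seq_along(sets), vapply(sets, function(s) ncol(s$class_means), 0L))
  classof <- unlist(lapply(sets, function(s) colnames(s$class_means)))

  D <- matrix(0, n_total, n_total, dimnames = list(ids, ids))
  for (i in seq_len(n_total))
    for (j in seq_len(n_total)) {
      if (j <= i) next
      genes <- pair_gene_selection(sets[[owner[i]]], sets[[owner[j]]], min_genes)
      r <- stats::cor(sets[[owner[i]]]$class_means[genes, classof[i]],
                      sets[[owner[j]]]$class_means[genes, classof[j]],
                      use = "pairwise.complete.obs")
      D[i, j] <- D[j, i] <- 1 - r
    }
  h <- stats::hclust(stats::as.dist(D), method = linkage)
  meta <- stats::cutree(h, k = n_meta)
  out <- data.frame(dataset = vapply(sets, `[[`, "", "dataset")[owner],
                    class = classof, meta_class = unname(meta))
  tab <- table(out$dataset, out$meta_class)
  balanced <- all(tab == 1)
  if (!balanced)
    warning("match_classes: some meta-class lacks a member from some dataset")
  attr(out, "distance") <- D
  attr(out, "balanced") <- balanced
  out
}
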