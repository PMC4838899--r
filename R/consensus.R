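#' Select the most variant features
#'
#' Feature filtering used ahead of every clustering stage: the top fraction
#' of features by variance (computed over non-NA entries, on the values as
#' provided, no re-centring). Ties are broken lexicographically by feature
#' id so the selection is deterministic.
#'
#' @param x An [omics_matrix()] or plain features x samples matrix.
#' @param fraction Fraction of features to keep, in `(0, 1]`; the number
#'   kept is `ceiling(fraction * n_features)` (counted before removing
#'   all-NA features).
#' @return Character vector of feature ids, highest variance first.
#' @export
select_variant_features <- function(x, fraction = 0.05) {
  if (fraction <= 0 || fraction > 1)
    stop("select_variant_features: fraction must be in (0, 1]")
  m <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  n_keep <- ceiling(fraction * nrow(m))
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  v <- v[!is.na(v)]  # all-NA or single-value features drop out
  ord <- order(-v, names(v))
  head(names(v)[ord], n_keep)
}

# Sample-by-sample dissimilarity matrix. Pearson dissimilarity (1 - r) uses
# pairwise-complete features; pairs with < 3 shared features give NA, imputed
# as the row maximum so linkage stays total.
sample_dissimilarity <- function(m, distance = c("pearson", "euclidean")) {
  distance <- match.arg(distance)
  if (distance == "pearson") {
    suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
    d <- 1 - r
  } else {
    d <- as.matrix(stats::dist(t(m)))
  }
  diag(d) <- 0
  if (anyNA(d)) {
    for (i in seq_len(nrow(d))) {
      nas <- is.na(d[i, ])
      if (any(nas)) d[i, nas] <- max(d[i, !nas], 1, na.rm = TRUE)
    }
    d <- pmax(d, t(d))  # keep symmetric after imputation
  }
  d
}

#' Resampled consensus clustering
#'
#' The clustering engine shared by every omic and by the integration stage.
#' For each resampling iteration a random subset of samples is drawn, the
#' subset is clustered hierarchically on the chosen dissimilarity, and the
#' partition for every K in `k_range` is recorded. The consensus matrix
#' entry for a sample pair is the fraction of co-samplings in which the pair
#' co-clustered. Per-K labels come from re-clustering `1 - M_K` with the
#' same linkage; K is then selected from the CDF areas of the consensus
#' values (see [select_k()]).
#'
#' @param x [omics_matrix()] or features x samples matrix (items = samples).
#' @param k_range Integer vector of cluster numbers, default `2:8`.
#' @param n_iter Resampling iterations, default 1000.
#' @param subsample_fraction Fraction of samples drawn per iteration
#'   (default 0.8).
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage An `hclust` method; `"ward.D2"` (classic Ward on
#'   distances) by default, `"ward.D"` to reproduce unsquared-input Ward as
#'   used for methylation.
#' @param seed Integer seed fixing the resampling exactly.
#' @param delta_threshold Relative CDF-area increase used by the
#'   `"threshold"` K rule (default 0.10).
#' @param k_method K-selection rule passed to [select_k()] (default
#'   `"plateau"`).
#' @return Object of class `consensus_result`: list with `consensus`
#'   (one sample x sample matrix per K), `areas`, `delta`, `selected_k`,
#'   `labels` (list of [class_partition()] per K), `partition` (labels at
#'   the selected K), `item_consensus`, `weak_structure`, `k_range`.
#' @export
consensus_cluster <- function(x, k_range = 2:8, n_iter = 1000,
                              subsample_fraction = 0.8,
                              distance = c("pearson", "euclidean"),
                              linkage = "ward.D2", seed = NULL,
                              delta_threshold = 0.10,
                              k_method = c("plateau", "threshold")) {
  distance <- match.arg(distance)
  k_method <- match.arg(k_method)
  m <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  n <- ncol(m)
  ids <- colnames(m)
  if (is.null(ids)) stop("consensus_cluster: samples must be named")
  if (n_iter < 1) stop("consensus_cluster: n_iter must be >= 1")
  k_range <- sort(unique(as.integer(k_range)))
  if (!is.null(seed)) set.seed(seed)

  D <- sample_dissimilarity(m, distance)
  n_sub <- max(2, round(subsample_fraction * n))
  conn <- lapply(k_range, function(k) matrix(0, n, n))
  names(conn) <- as.character(k_range)
  pair_count <- matrix(0, n, n)

  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, n_sub))
    h <- stats::hclust(stats::as.dist(D[idx, idx]), method = linkage)
    ks <- pmin(k_range, n_sub)
    labs <- stats::cutree(h, k = ks)
    if (is.null(dim(labs))) labs <- matrix(labs, ncol = 1)
    pair_count[idx, idx] <- pair_count[idx, idx] + 1
    for (j in seq_along(k_range)) {
      l <- labs[, j]
      Z <- matrix(0, n_sub, max(l))
      Z[cbind(seq_len(n_sub), l)] <- 1
      conn[[j]][idx, idx] <- conn[[j]][idx, idx] + tcrossprod(Z)
    }
  }

  never <- pair_count == 0
  diag(never) <- FALSE
  frac_never <- sum(never) / (n * (n - 1))
  if (frac_never > 0.01)
    warning(sprintf("consensus_cluster: %.1f%% of sample pairs never co-sampled; increase n_iter",
                    100 * frac_never))

  consensus <- lapply(conn, function(cm) {
    M <- cm / pair_count
    M[pair_count == 0] <- NA
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    M
  })

  areas <- vapply(consensus, cdf_area, 0)
  sel <- if (length(k_range) == 1)
    list(selected_k = k_range, delta = stats::setNames(NA_real_, k_range),
         weak_structure = FALSE)
  else select_k(areas, k_range, delta_threshold, method = k_method)

  labels <- lapply(seq_along(k_range), function(j) {
    M <- consensus[[j]]
    dM <- 1 - M
    dM[is.na(dM)] <- 1
    h <- stats::hclust(stats::as.dist(dM), method = linkage)
    class_partition(stats::setNames(stats::cutree(h, k = min(k_range[j], n)), ids))
  })
  names(labels) <- as.character(k_range)

  part <- labels[[as.character(sel$selected_k)]]
  Msel <- consensus[[as.character(sel$selected_k)]]
  item_consensus <- vapply(seq_len(n), function(i) {
    mates <- setdiff(which(unclass(part) == part[i]), i)
    if (length(mates) == 0) return(1)
    mean(Msel[i, mates], na.rm = TRUE)
  }, 0)
  names(item_consensus) <- ids

  structure(list(consensus = consensus, areas = areas, delta = sel$delta,
                 selected_k = sel$selected_k, labels = labels,
                 partition = part, item_consensus = item_consensus,
                 weak_structure = sel$weak_structure, k_range = k_range),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: K in {%s}, selected K = %d%s\n",
              paste(x$k_range, collapse = ","), x$selected_k,
              if (x$weak_structure) " (weak structure)" else ""))
  print(round(rbind(area = x$areas, delta = x$delta), 3))
  invisible(x)
}

#' Area under the consensus CDF
#'
#' Exact integral over `[0, 1]` of the empirical cumulative distribution of
#' the off-diagonal consensus entries (NA entries, i.e. never co-sampled
#' pairs, excluded).
#'
#' @param M Consensus matrix with entries in `[0, 1]`.
#' @return The area, a number in `[0, 1]`.
#' @export
cdf_area <- function(M) {
  v <- M[upper.tri(M)]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("cdf_area: no defined off-diagonal entries")
  knots <- sort(unique(c(v, 0, 1)))
  F <- vapply(knots, function(t) mean(v <= t), 0)
  sum(diff(knots) * F[-length(knots)])
}

#' Select the number of clusters from CDF areas
#'
#' Automates the visual reading of the consensus CDF curves from the
#' relative area increase `delta(K) = (A(K) - A(K-1)) / A(K-1)` (with
#' `delta(k_min) = A(k_min)`).
#'
#' Two rules are provided. `"plateau"` (the default) encodes the shape
#' criterion: a K qualifies when its relative increase both exceeds
#' `min_delta` and stands at least `plateau_ratio` times above every later
#' increase in the scanned range, i.e. the curve visibly flattens after it;
#' the largest qualifying K is selected (the top of the K range has no
#' plateau to its right and cannot be elected). `"threshold"` is the plain
#' fixed cut: the largest K with `delta(K) >= delta_threshold`. The fixed
#' cut is scale-blind — for clean balanced clusters the relative increase
#' at the true K shrinks roughly like `1/K^2` and crosses 0.10 near K = 5 —
#' so the plateau rule is preferred for selection while the full delta
#' curve is always returned for manual override.
#'
#' If no K beyond the smallest qualifies, the smallest K is returned
#' flagged as weak structure.
#'
#' @param areas Numeric vector of CDF areas, one per K.
#' @param k_range Matching integer vector of K values.
#' @param delta_threshold Minimum relative area increase for the
#'   `"threshold"` rule (default 0.10).
#' @param method `"plateau"` or `"threshold"`.
#' @param plateau_ratio How far a qualifying increase must stand above the
#'   later ones (default 3).
#' @param min_delta Numerical floor below which an area increase is
#'   considered noise (default 0.02).
#' @return List with `selected_k`, `delta` (named vector) and
#'   `weak_structure` flag.
#' @export
select_k <- function(areas, k_range, delta_threshold = 0.10,
                     method = c("plateau", "threshold"),
                     plateau_ratio = 3, min_delta = 0.02) {
  method <- match.arg(method)
  if (length(areas) < 2) stop("select_k: need at least two K values")
  if (length(areas) != length(k_range)) stop("select_k: length mismatch")
  delta <- c(areas[1], diff(areas) / areas[-length(areas)])
  names(delta) <- as.character(k_range)
  n <- length(delta)
  if (method == "threshold") {
    ok <- which(delta >= delta_threshold)
  } else {
    ok <- which(vapply(seq_len(n - 1), function(i) {
      later <- delta[(i + 1):n]
      delta[i] > min_delta && delta[i] >= plateau_ratio * max(later)
    }, NA))
  }
  weak <- length(setdiff(ok, 1L)) == 0
  selected <- if (length(ok) == 0) k_range[1] else k_range[max(ok)]
  if (weak)
    warning("select_k: weak structure; no K beyond the minimum qualifies")
  list(selected_k = as.integer(selected), delta = delta, weak_structure = weak)
}

#' Flag tumours clustering with normal controls
#'
#' A preliminary clustering that includes non-neoplastic control samples is
#' screened for contamination: any class holding at least `majority` of all
#' control samples is treated as a normal-like class, and every tumour in it
#' is flagged for removal before the main analysis.
#'
#' @param partition [class_partition()] from a clustering that included the
#'   controls.
#' @param annot [sample_annot()] with `is_normal_control`.
#' @param majority Fraction of all controls a class must hold (default 0.5).
#' @return Character vector of flagged tumour sample ids.
#' @export
flag_contamination <- function(partition, annot, majority = 0.5) {
  annot <- sample_annot(annot)
  controls <- annot$sample[annot$is_normal_control]
  controls <- intersect(controls, names(partition))
  if (length(controls) == 0) {
    warning("flag_contamination: no control samples present")
    return(character(0))
  }
  ctrl_classes <- table(unclass(partition)[controls])
  normal_like <- names(ctrl_classes)[ctrl_classes / length(controls) >= majority]
  in_normal <- names(partition)[!is.na(unclass(partition)) &
                                  unclass(partition) %in% normal_like]
  setdiff(in_normal, annot$sample[annot$is_normal_control])
}
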