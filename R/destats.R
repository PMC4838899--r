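#' Moderated t-test (empirical Bayes variance shrinkage)
#'
#' Two-group differential expression with gene-wise variances shrunk toward
#' a common prior. Per feature, the pooled residual variance s^2 (d = n - 2
#' df) is combined with a prior (d0, s0^2) fitted by matching moments of
#' log s^2 to a scaled-F distribution; the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` and the moderated t has `d0 + d` degrees
#' of freedom. With `prior_df = 0` the statistic reduces to the ordinary
#' equal-variance t; with `prior_df = Inf` all features share `prior_var`.
#'
#' @param x [omics_matrix()] or features x samples matrix (log scale).
#' @param group Logical/0-1 vector over samples (TRUE/1 = the class of
#'   interest); named vectors are matched to column names.
#' @param prior_df,prior_var Optional forced prior; both fitted from the
#'   data when NULL.
#' @param adjust Multiple-testing adjustment for the `p_adj` column:
#'   `"none"` (default) or `"BH"`.
#' @return data.frame (one row per feature): `lfc` (class mean minus rest
#'   mean), `t`, `df_total`, `p_value`, `p_adj`, plus attributes `prior_df`
#'   and `prior_var`.
#' @export
moderated_t <- function(x, group, prior_df = NULL, prior_var = NULL,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  if (!is.null(names(group))) group <- group[colnames(m)]
  group <- as.logical(group)
  if (anyNA(group)) stop("moderated_t: group labels do not cover all samples")
  n1 <- sum(group); n2 <- sum(!group)
  if (n1 < 2 || n2 < 2) stop("moderated_t: need >= 2 samples per group")

  m1 <- rowMeans(m[, group, drop = FALSE], na.rm = TRUE)
  m2 <- rowMeans(m[, !group, drop = FALSE], na.rm = TRUE)
  lfc <- m1 - m2
  ss1 <- rowSums((m[, group, drop = FALSE] - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((m[, !group, drop = FALSE] - m2)^2, na.rm = TRUE)
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d

  if (is.null(prior_df)) {
    fit <- fit_f_prior(s2[s2 > 0], d)
    prior_df <- fit$df
    if (is.null(prior_var)) prior_var <- fit$var
  } else if (is.null(prior_var)) {
    prior_var <- if (prior_df == 0) 0 else mean(s2[s2 > 0])
  }

  if (is.infinite(prior_df)) {
    s2_post <- rep(prior_var, length(s2))
    df_total <- rep(Inf, length(s2))
  } else {
    s2_post <- (prior_df * prior_var + d * s2) / (prior_df + d)
    df_total <- rep(prior_df + d, length(s2))
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_stat <- lfc / se
  p <- 2 * stats::pt(abs(t_stat), df_total, lower.tail = FALSE)
  p[s2 == 0 & !is.finite(t_stat)] <- NA  # zero variance in both groups, no shift
  p[se == 0] <- ifelse(lfc[se == 0] == 0, NA, 0)

  out <- data.frame(feature = rownames(m), lfc = lfc, t = t_stat,
                    df_total = df_total, p_value = p,
                    p_adj = if (adjust == "BH") stats::p.adjust(p, "BH") else p,
                    row.names = NULL)
  attr(out, "prior_df") <- prior_df
  attr(out, "prior_var") <- prior_var
  out
}

# Method-of-moments fit of (d0, s0^2) from log sample variances: if
# s^2 ~ s0^2 F(d, d0) then z = log s^2 has
#   E[z]  = log s0^2 + digamma(d/2) - digamma(d0/2) + log(d0/d)
#   Var[z] = trigamma(d/2) + trigamma(d0/2).
fit_f_prior <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(z) - trigamma(d / 2)
  if (is.na(evar) || evar <= 0)
    return(list(df = Inf, var = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(df = d0, var = s0)
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Top up-regulated signature features
#'
#' Among features significantly deregulated at unadjusted `p < alpha` and
#' up-regulated (`lfc > 0`), the `n` with the largest fold change,
#' descending. Used with n = 100 for per-class marker lists and n = 1000
#' for heatmap signatures.
#'
#' @param de Result of [moderated_t()].
#' @param n Number of features requested (default 100).
#' @param alpha Unadjusted p-value cut-off (default 0.05).
#' @return Character vector of feature ids (possibly shorter than `n`, with
#'   attribute `n_available`).
#' @export
signature_top_n <- function(de, n = 100, alpha = 0.05) {
  if (n < 1) stop("signature_top_n: n must be >= 1")
  ok <- !is.na(de$p_value) & de$p_value < alpha & de$lfc > 0
  if (!any(ok)) {
    warning("signature_top_n: no significantly up-regulated feature")
    out <- character(0)
    attr(out, "n_available") <- 0L
    return(out)
  }
  sig <- de[ok, ]
  sig <- sig[order(-sig$lfc, sig$feature), ]
  out <- utils::head(sig$feature, n)
  attr(out, "n_available") <- nrow(sig)
  out
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a signature and a gene set, within a stated universe.
#'
#' @param signature Character vector of feature ids (must lie in
#'   `universe`).
#' @param set A [gene_set()] or character vector; intersected with
#'   `universe`.
#' @param universe Character vector of all testable feature ids.
#' @return List with `p_value`, `overlap`, `set_size`, `signature_size`,
#'   `universe_size`, `expected`.
#' @export
hypergeom_enrich <- function(signature, set, universe) {
  if (inherits(set, "gene_set")) set <- set$members
  universe <- unique(universe)
  if (length(universe) == 0) stop("hypergeom_enrich: empty universe")
  if (!all(signature %in% universe))
    stop("hypergeom_enrich: signature contains features outside the universe")
  set <- intersect(set, universe)
  if (length(set) == 0) stop("hypergeom_enrich: gene set disjoint from universe")
  k <- length(intersect(signature, set))
  K <- length(set); n <- length(unique(signature)); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p_value = p, overlap = k, set_size = K, signature_size = n,
       universe_size = N, expected = n * K / N)
}

#' MYC activity score
#'
#' Per-sample mean expression over a MYC target gene list, after gene-wise
#' centring by default so that the cohort mean score is zero; per-sample
#' centring (subtract each sample's own mean over all genes first) is
#' available via `centre = "sample"`. Targets absent from the matrix are
#' reported, not imputed.
#'
#' @param x [omics_matrix()] or matrix (log-scale expression).
#' @param targets [gene_set()] or character vector of MYC target genes.
#' @param centre `"gene"` (default), `"sample"`, or `"none"`.
#' @return Named numeric vector of scores, with attribute
#'   `missing_targets`.
#' @export
myc_activity_score <- function(x, targets, centre = c("gene", "sample", "none")) {
  centre <- match.arg(centre)
  if (inherits(targets, "gene_set")) targets <- targets$members
  m <- if (inherits(x, "omics_matrix")) x$values else as.matrix(x)
  present <- intersect(targets, rownames(m))
  if (length(present) == 0) stop("myc_activity_score: no target gene present in matrix")
  if (centre == "gene") m <- m - rowMeans(m, na.rm = TRUE)
  if (centre == "sample") m <- sweep(m, 2, colMeans(m, na.rm = TRUE))
  score <- colMeans(m[present, , drop = FALSE], na.rm = TRUE)
  attr(score, "missing_targets") <- setdiff(targets, present)
  score
}
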