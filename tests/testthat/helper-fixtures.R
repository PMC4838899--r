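# Shared fixtures for the suite: small cohort configurations and a plain
# silhouette helper (kept independent of the package internals).

quick_config <- function(...) {
  args <- list(...)
  defaults <- list(
    n_per_subtype = c(A = 25, B = 25, C = 25),
    n_normal_controls = 0, n_contaminated = 0,
    n_genes = 900, signature_size = 100, n_mirnas = 300,
    mirna_signature_size = 30, n_cpgs = 600, meth_signature_size = 50,
    missing_fraction = c(mrna = 0, mirna = 0, methylation = 0))
  do.call(cohort_config, utils::modifyList(defaults, args))
}

# mean silhouette of a labelling on a sample-distance matrix
mean_silhouette <- function(D, labels) {
  n <- nrow(D)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(D[i, labels == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# two well-separated Gaussian point clouds, features x samples
two_clouds <- function(n_per = 30, n_feat = 50, delta = 5, sd = 1, seed = 1) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(n_feat * n_per, 0, sd), n_feat),
             matrix(rnorm(n_feat * n_per, delta, sd), n_feat))
  dimnames(m) <- list(sprintf("f%02d", seq_len(n_feat)),
                      sprintf("s%02d", seq_len(2 * n_per)))
  m
}
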