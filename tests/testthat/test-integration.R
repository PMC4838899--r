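make_parts <- function(n = 60, k = 3, seed = 1, noise = 0, na_frac = 0,
                       n_omics = 3) {
  set.seed(seed)
  truth <- sample(rep(seq_len(k), length.out = n))
  names(truth) <- sprintf("S%03d", seq_len(n))
  parts <- lapply(seq_len(n_omics), function(i) {
    p <- truth
    if (noise > 0) {
      flip <- runif(n) < noise
      p[flip] <- sample(seq_len(k), sum(flip), replace = TRUE)
    }
    if (na_frac > 0) p[runif(n) < na_frac] <- NA
    class_partition(p)
  })
  names(parts) <- paste0("omic", seq_len(n_omics))
  list(truth = truth, parts = parts)
}

test_that("partition encoding produces one column per class with NA blocks", {
  p1 <- class_partition(setNames(c(1:5, 1:5), sprintf("S%02d", 1:10)))
  p2 <- class_partition(setNames(c(rep(1:4, 2), NA, NA), sprintf("S%02d", 1:10)))
  p3 <- class_partition(setNames(rep(1:4, length.out = 8), sprintf("S%02d", 1:8)))
  ind <- encode_partitions(list(mrna = p1, meth = p2, mirna = p3))
  expect_identical(ncol(ind), 13L)  # 5 + 4 + 4 class variables
  expect_identical(nrow(ind), 10L)
  # a sample absent from the miRNA partition has its whole block NA
  expect_true(all(is.na(ind["S09", grepl("^mirna", colnames(ind))])))
  expect_true(all(is.na(ind["S09", grepl("^meth", colnames(ind))])))
  # one-hot within each block: membership in class 2 of 5 reads (0,1,0,0,0)
  expect_identical(unname(ind["S02", grepl("^mrna", colnames(ind))]),
                   c(0, 1, 0, 0, 0))
  expect_true(all(rowSums(ind[, grepl("^mrna", colnames(ind))]) == 1))
  expect_error(encode_partitions(list(p1)), "at least two")
  single <- class_partition(setNames(rep(1, 10), sprintf("S%02d", 1:10)))
  expect_error(encode_partitions(list(a = p1, b = single)), "single class")
})

test_that("identical input partitions are reproduced by the integration", {
  mp <- make_parts(n = 45, k = 3, seed = 2)
  ind <- encode_partitions(mp$parts)
  cc <- cluster_of_clusters(ind, k_range = 2:6, n_iter = 200, seed = 3)
  expect_identical(cc$selected_k, 3L)
  expect_equal(adjusted_rand_index(unclass(cc$partition), mp$truth), 1)
})

test_that("integrating nested partitions recovers the finer one", {
  set.seed(4)
  fine <- sample(rep(1:4, each = 15))
  names(fine) <- sprintf("S%03d", 1:60)
  coarse <- ifelse(fine %in% 1:2, 1, 2)
  names(coarse) <- names(fine)
  ind <- encode_partitions(list(a = class_partition(coarse),
                                b = class_partition(fine)))
  cc <- cluster_of_clusters(ind, k_range = 2:6, n_iter = 200, seed = 5)
  expect_identical(cc$selected_k, 4L)
  expect_equal(adjusted_rand_index(unclass(cc$partition), fine), 1)
})

test_that("integration is invariant to relabelling an input partition", {
  mp <- make_parts(n = 45, k = 3, seed = 6, noise = 0.1, na_frac = 0.1)
  ind1 <- encode_partitions(mp$parts)
  relab <- mp$parts
  # permute the class ids of the first partition: 1->3, 2->1, 3->2
  relab[[1]] <- class_partition(setNames(
    c("3", "1", "2")[as.integer(unclass(mp$parts[[1]]))],
    names(mp$parts[[1]])))
  ind2 <- encode_partitions(relab)
  cc1 <- cluster_of_clusters(ind1, k_range = 3, n_iter = 200, seed = 7)
  cc2 <- cluster_of_clusters(ind2, k_range = 3, n_iter = 200, seed = 7)
  expect_equal(adjusted_rand_index(unclass(cc1$partition),
                                   unclass(cc2$partition)), 1)
})

test_that("an all-NA omic leaves the integration of the others unchanged", {
  mp <- make_parts(n = 40, k = 3, seed = 8, noise = 0.05)
  ind2 <- encode_partitions(mp$parts[1:2])
  na_part <- class_partition(setNames(rep(c(NA, 1, 2), length.out = 40),
                                      names(mp$truth)))
  na_part[] <- NA
  ind3 <- cbind(ind2, matrix(NA_real_, 40, 2,
                             dimnames = list(rownames(ind2), c("x.1", "x.2"))))
  cc2 <- cluster_of_clusters(ind2, k_range = 3, n_iter = 150, seed = 9)
  cc3 <- cluster_of_clusters(ind3, k_range = 3, n_iter = 150, seed = 9)
  expect_identical(unclass(cc2$partition), unclass(cc3$partition))
})

test_that("miRNA preprocessing applies the expression filter literally", {
  counts <- rbind(kept = c(12, 11, 0), dropped = c(12, 9, 9),
                  zero = c(0, 0, 0), high = c(100, 200, 300))
  colnames(counts) <- c("s1", "s2", "s3")
  norm <- mirna_preprocess(counts)
  expect_setequal(rownames(norm$values), c("kept", "high"))
  # every retained miRNA is centred to mean zero (relative to its scale)
  expect_true(all(abs(rowMeans(norm$values)) <
                    1e-10 * apply(abs(norm$values), 1, max)))
  expect_identical(norm$omic_kind, "mirna")
})

test_that("miRNA preprocessing excludes zero-total samples and rejects non-counts", {
  counts <- cbind(s1 = c(20, 30), s2 = c(0, 0), s3 = c(15, 40))
  rownames(counts) <- c("m1", "m2")
  expect_warning(norm <- mirna_preprocess(counts), "zero total")
  expect_identical(colnames(norm$values), c("s1", "s3"))
  expect_error(mirna_preprocess(matrix(c(-1, 2), 1)), "non-negative")
  expect_error(mirna_preprocess(matrix(c(1.5, 2), 1)), "non-negative")
})

test_that("both normalization orders are available and differ", {
  set.seed(10)
  counts <- matrix(rnbinom(200 * 10, mu = 100, size = 5), 200, 10,
                   dimnames = list(sprintf("m%03d", 1:200), sprintf("s%02d", 1:10)))
  a <- mirna_preprocess(counts, order = "log2-first")
  b <- mirna_preprocess(counts, order = "cpm-first")
  expect_identical(dim(a$values), dim(b$values))
  expect_false(isTRUE(all.equal(a$values, b$values)))
  expect_true(all(abs(rowMeans(b$values)) < 1e-12))
})

test_that("partition association reaches its closed-form extremes", {
  # identical balanced 3-class partitions over 30 samples:
  # chi-square equals n * (min(r, c) - 1) = 60
  p <- class_partition(setNames(rep(1:3, each = 10), sprintf("S%02d", 1:30)))
  res <- crosstab_association(p, p)
  expect_equal(res$statistic, 60, tolerance = 1e-12)
  # 2x2 diagonal table [[10, 0], [0, 10]] gives chi-square 20
  a <- class_partition(setNames(rep(1:2, each = 10), sprintf("S%02d", 1:20)))
  expect_equal(crosstab_association(a, a)$statistic, 20, tolerance = 1e-12)
  # degenerate tables are refused
  b <- class_partition(setNames(c(rep(1, 19), 2), sprintf("S%02d", 1:20)))
  c_ <- class_partition(setNames(rep(1:2, 10), sprintf("S%02d", 1:20)))
  expect_error(crosstab_association(
    class_partition(setNames(rep(1, 20), sprintf("S%02d", 1:20))), c_),
    "degenerate")
})

test_that("association p-values are uniform for independent partitions", {
  set.seed(11)
  pvals <- replicate(200, {
    a <- class_partition(setNames(sample(1:3, 200, TRUE), sprintf("S%03d", 1:200)))
    b <- class_partition(setNames(sample(1:3, 200, TRUE), sprintf("S%03d", 1:200)))
    crosstab_association(a, b)$p_value
  })
  expect_gt(median(pvals), 0.35)
  expect_lt(median(pvals), 0.65)
})
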