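test_that("variant-feature selection keeps ceil(fraction * n) by variance", {
  set.seed(1)
  m <- matrix(rnorm(1000 * 10), 1000, 10,
              dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:10)))
  expect_length(select_variant_features(m, 0.05), 50)
  # hand-ranked case: variances (4, 1, 2.25); ceil(0.34 * 3) = 2 kept
  m2 <- rbind(a = c(0, 2, 4), b = c(0, 1, 2), c = c(0, 1.5, 3))
  colnames(m2) <- c("s1", "s2", "s3")
  expect_identical(select_variant_features(m2, 0.34), c("a", "c"))
  # constant matrix: lexicographic ties, count preserved
  m3 <- matrix(1, 5, 4, dimnames = list(c("e", "d", "c", "b", "a"),
                                        paste0("s", 1:4)))
  expect_identical(select_variant_features(m3, 0.5), c("a", "b", "c"))
  # all-NA feature excluded before ranking
  m4 <- rbind(a = c(1, 2, 3), b = c(NA, NA, NA), c = c(0, 0, 0.1))
  colnames(m4) <- paste0("s", 1:3)
  expect_identical(select_variant_features(m4, 1), c("a", "c"))
})

test_that("consensus is near-binary for well-separated clouds", {
  m <- two_clouds(n_per = 30, delta = 5, seed = 2)
  cc <- consensus_cluster(m, k_range = 2, n_iter = 200, distance = "euclidean",
                          seed = 3)
  M <- cc$consensus[["2"]]
  expect_true(isSymmetric(M))
  expect_true(all(M[!is.na(M)] >= 0 & M[!is.na(M)] <= 1))
  truth <- rep(1:2, each = 30)
  within <- M[outer(truth, truth, "==") & upper.tri(M)]
  across <- M[outer(truth, truth, "!=")]
  expect_gt(min(within, na.rm = TRUE), 0.95)
  expect_lt(max(across, na.rm = TRUE), 0.05)
})

test_that("K equal to the number of sampled items gives zero off-diagonal consensus", {
  m <- two_clouds(n_per = 6, delta = 1, seed = 4)   # 12 samples
  cc <- consensus_cluster(m, k_range = 12, n_iter = 50,
                          subsample_fraction = 1, distance = "euclidean", seed = 5)
  M <- cc$consensus[["12"]]
  expect_true(all(M[upper.tri(M)] == 0))
})

test_that("the same seed reproduces the result bit for bit", {
  m <- two_clouds(n_per = 15, delta = 2, seed = 6)
  a <- consensus_cluster(m, k_range = 2:4, n_iter = 100, seed = 7)
  b <- consensus_cluster(m, k_range = 2:4, n_iter = 100, seed = 7)
  expect_identical(a$consensus, b$consensus)
  expect_identical(unclass(a$partition), unclass(b$partition))
  expect_identical(a$areas, b$areas)
})

test_that("one full-sample iteration reduces to plain hierarchical clustering", {
  for (seed in 1:3) {
    m <- two_clouds(n_per = 14, n_feat = 30, delta = 2, seed = seed)  # 28 samples
    cc <- consensus_cluster(m, k_range = 3, n_iter = 1,
                            subsample_fraction = 1, distance = "pearson",
                            linkage = "ward.D2", seed = seed)
    D <- 1 - cor(m)
    ref <- cutree(hclust(as.dist(D), method = "ward.D2"), 3)
    expect_equal(adjusted_rand_index(unclass(cc$partition),
                                     setNames(ref, colnames(m))), 1)
  }
})

test_that("CDF areas computed on hand-built consensus matrices are exact", {
  # block-diagonal binary consensus: 6 samples, clusters of 3 + 3
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- 1; M[4:6, 4:6] <- 1
  # off-diagonal has 6 within-pairs at 1 and 9 across-pairs at 0:
  # empirical CDF is 9/15 on [0, 1) so the area is 0.6
  expect_equal(cdf_area(M), 9 / 15)
  # adding an ambiguous entry at 0.5 moves mass accordingly:
  # F = 8/15 on [0, 0.5) and 9/15 on [0.5, 1)
  M2 <- M; M2[1, 4] <- M2[4, 1] <- 0.5
  expect_equal(cdf_area(M2), (8 / 15) * 0.5 + (9 / 15) * 0.5)
})

test_that("the fixed-threshold K rule reproduces the worked example", {
  sel <- select_k(c(0.2, 0.5, 0.51, 0.512), 2:5, delta_threshold = 0.1,
                  method = "threshold")
  expect_identical(sel$selected_k, 3L)
  expect_equal(unname(sel$delta), c(0.2, 1.5, 0.02, 0.512 / 0.51 - 1),
               tolerance = 1e-12)
  expect_false(sel$weak_structure)
})

test_that("the plateau K rule picks the elbow and flags weak structure", {
  # clear plateau after K = 3
  sel <- select_k(c(0.3, 0.6, 0.61, 0.615, 0.617), 2:6, method = "plateau")
  expect_identical(sel$selected_k, 3L)
  # homogeneous data: smoothly decaying increases, nothing qualifies
  areas <- cumsum(c(0.35, 0.042, 0.030, 0.022, 0.017))
  expect_warning(sel2 <- select_k(areas, 2:6, method = "plateau"),
                 "weak structure")
  expect_identical(sel2$selected_k, 2L)
  expect_true(sel2$weak_structure)
})

test_that("a homogeneous cloud is flagged as weak structure", {
  set.seed(11)
  m <- matrix(rnorm(40 * 40), 40, 40,
              dimnames = list(sprintf("f%02d", 1:40), sprintf("s%02d", 1:40)))
  expect_warning(cc <- consensus_cluster(m, k_range = 2:6, n_iter = 150,
                                         distance = "euclidean", seed = 12),
                 "weak structure")
  expect_true(cc$weak_structure)
  expect_identical(cc$selected_k, 2L)
})

test_that("contamination flagging follows the control-majority rule", {
  # 9 controls in class 2 together with 29 tumours: all 29 flagged
  labs <- c(setNames(rep(2, 9), paste0("N", 1:9)),
            setNames(rep(2, 29), paste0("T", 1:29)),
            setNames(rep(1, 50), paste0("U", 1:50)))
  annot <- data.frame(sample = names(labs),
                      is_normal_control = grepl("^N", names(labs)))
  fl <- flag_contamination(class_partition(labs), annot)
  expect_setequal(fl, paste0("T", 1:29))
  # controls split 5/4: only the class holding 5 triggers
  labs2 <- c(setNames(rep(1, 5), paste0("N", 1:5)),
             setNames(rep(2, 4), paste0("N", 6:9)),
             setNames(c(1, 2), c("T1", "T2")))
  annot2 <- data.frame(sample = names(labs2),
                       is_normal_control = grepl("^N", names(labs2)))
  expect_identical(flag_contamination(class_partition(labs2), annot2), "T1")
  # no controls: empty with warning
  expect_warning(
    fl3 <- flag_contamination(class_partition(c(T1 = 1, T2 = 2)),
                              data.frame(sample = c("T1", "T2"),
                                         is_normal_control = FALSE)),
    "no control")
  expect_length(fl3, 0)
})

test_that("heavily contaminated tumours cluster with controls and get flagged", {
  cf <- quick_config(n_per_subtype = c(A = 25, B = 25, C = 25),
                     n_normal_controls = 8, n_contaminated = 12,
                     contamination_w = 0.8, seed = 13)
  co <- generate_cohort(cf)
  feats <- select_variant_features(co$mrna, 0.1)
  cc <- consensus_cluster(co$mrna$values[feats, ], k_range = 2:6,
                          n_iter = 300, seed = 14)
  fl <- flag_contamination(cc$partition, co$annot)
  cont <- co$truth$sample[co$truth$contamination_w > 0]
  expect_gte(mean(cont %in% fl), 0.9)
})
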