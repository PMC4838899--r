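seg <- function(sample, chrom, start, end, gnl)
  data.frame(sample = sample, chrom = as.character(chrom), start = start,
             end = end, gnl = gnl)

test_that("gene-level events require the target sign at every position", {
  region <- list(chrom = "8", start = 1000, end = 2000)
  g_all <- gnl_table(segments = seg("S1", 8, 500, 2500, 1))
  expect_true(call_gene_event(g_all, region, "gain")[["S1"]])
  # half the region gained, half neutral: fully covered but mixed -> FALSE
  g_half <- gnl_table(segments = rbind(seg("S2", 8, 500, 1500, 1),
                                       seg("S2", 8, 1501, 2500, 0)))
  expect_false(call_gene_event(g_half, region, "gain")[["S2"]])
  # loss direction with amplitude -1 or -2
  g_loss <- gnl_table(segments = seg("S3", 8, 900, 2100, -2))
  expect_true(call_gene_event(g_loss, region, "loss")[["S3"]])
  expect_false(call_gene_event(g_loss, region, "gain")[["S3"]])
  # uncovered region (gap inside) -> NA
  g_gap <- gnl_table(segments = rbind(seg("S4", 8, 500, 1400, 1),
                                      seg("S4", 8, 1600, 2500, 1)))
  expect_true(is.na(call_gene_event(g_gap, region, "gain")[["S4"]]))
  # no overlapping segment at all -> NA
  g_none <- gnl_table(segments = seg("S5", 7, 1, 1e6, 1))
  expect_true(is.na(call_gene_event(g_none, region, "gain")[["S5"]]))
})

test_that("gene-mode GNL calls match the sign directly", {
  g <- gnl_table(genes = matrix(c(1L, -1L, 0L, NA), 2, 2,
                                dimnames = list(c("MYC", "MAX"), c("s1", "s2"))))
  expect_true(call_gene_event(g, "MYC", "gain")[["s1"]])
  expect_true(call_gene_event(g, "MAX", "loss")[["s1"]])
  expect_false(call_gene_event(g, "MYC", "gain")[["s2"]])
  expect_true(is.na(call_gene_event(g, "MAX", "loss")[["s2"]]))
  expect_error(call_gene_event(g, "EGFR", "gain"), "EGFR")
})

test_that("flipping a segment away from the target sign is monotone", {
  region <- list(chrom = "8", start = 1000, end = 2000)
  set.seed(1)
  for (i in 1:20) {
    cuts <- sort(sample(1100:1900, 2))
    segs <- rbind(seg("S1", 8, 500, cuts[1], 1),
                  seg("S1", 8, cuts[1] + 1, cuts[2], 1),
                  seg("S1", 8, cuts[2] + 1, 2500, 1))
    before <- call_gene_event(gnl_table(segments = segs), region, "gain")[["S1"]]
    j <- sample(1:3, 1)
    segs$gnl[j] <- sample(c(-1, 0), 1)
    after <- call_gene_event(gnl_table(segments = segs), region, "gain")[["S1"]]
    expect_true(before)
    expect_false(after)  # true can only turn false, never the reverse
  }
})

test_that("arm status follows the 80% agreement and 50% coverage rules", {
  ab <- arm_boundaries()
  a1p <- ab[ab$arm == "1p", ]
  # whole arm lost
  g <- gnl_table(segments = seg("S1", a1p$chrom, a1p$start, a1p$end, -1))
  expect_identical(call_arm_status(g, "1p")[["S1"]], -1L)
  # 60% lost / 40% neutral: below the 80% rule -> 0
  cut60 <- round(a1p$start + 0.6 * (a1p$end - a1p$start))
  g2 <- gnl_table(segments = rbind(
    seg("S2", a1p$chrom, a1p$start, cut60, -1),
    seg("S2", a1p$chrom, cut60 + 1, a1p$end, 0)))
  expect_identical(call_arm_status(g2, "1p")[["S2"]], 0L)
  # 85% lost -> -1
  cut85 <- round(a1p$start + 0.85 * (a1p$end - a1p$start))
  g3 <- gnl_table(segments = rbind(
    seg("S3", a1p$chrom, a1p$start, cut85, -1),
    seg("S3", a1p$chrom, cut85 + 1, a1p$end, 0)))
  expect_identical(call_arm_status(g3, "1p")[["S3"]], -1L)
  # under 50% of the arm covered -> NA
  cut30 <- round(a1p$start + 0.3 * (a1p$end - a1p$start))
  g4 <- gnl_table(segments = seg("S4", a1p$chrom, a1p$start, cut30, -1))
  expect_true(is.na(call_arm_status(g4, "1p")[["S4"]]))
  expect_error(call_arm_status(g, "1z"), "unknown arm")
})

test_that("the 1-D two-class split lands between the hand-computed groups", {
  # u values (-.4, -.38, -.35, .0, .02, .05): split between -.35 and 0
  u <- c(-0.4, -0.38, -0.35, 0, 0.02, 0.05)
  n <- 30
  m <- sweep(matrix(0, n, 6, dimnames = list(sprintf("g%02d", 1:n),
                                             sprintf("s%d", 1:6))), 2, u, "+")
  annot <- data.frame(arm = rep(c("1p", "19q"), length.out = n))
  res <- codel_from_expression(omics_matrix(m, "mrna", feature_annot = annot),
                               min_class = 2)
  expect_identical(unname(res$codel), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  # scores come out gene-centred, so compare relative to the cohort mean
  expect_equal(unname(res$scores$u), u - mean(u), tolerance = 1e-12)
  expect_gt(res$threshold, -0.35 - mean(u))
  expect_lt(res$threshold, 0 - mean(u))
})

test_that("co-deletion scores are invariant to per-sample constants", {
  co <- generate_cohort(quick_config(seed = 21))
  base <- codel_from_expression(co$mrna)
  shifted <- co$mrna
  shifted$values[, 3] <- shifted$values[, 3] + 5   # constant added to one sample
  res <- suppressWarnings(codel_from_expression(shifted))
  # gene-centring before arm means does NOT absorb per-sample shifts;
  # the arm score of the shifted sample moves by ~ the constant
  expect_gt(abs(res$scores$u[3] - base$scores$u[3]), 1)
  # but a constant added to every sample changes nothing
  all_shift <- co$mrna
  all_shift$values <- all_shift$values + 5
  res2 <- codel_from_expression(all_shift)
  expect_equal(res2$scores$u, base$scores$u, tolerance = 1e-9)
  expect_identical(res2$codel, base$codel)
})

test_that("degenerate score distributions yield no call", {
  m <- matrix(1, 20, 6, dimnames = list(sprintf("g%02d", 1:20),
                                        sprintf("s%d", 1:6)))
  om <- omics_matrix(m, "mrna",
                     feature_annot = data.frame(arm = rep(c("1p", "19q"), 10)))
  expect_warning(res <- codel_from_expression(om), "degenerate")
  expect_true(all(is.na(res$codel)))
})

test_that("co-deletion recovery on generated cohorts is near-perfect", {
  # 50 probes per arm, arm shift -0.3, sigma 0.2, 150 samples
  cf <- cohort_config(n_per_subtype = c(A = 30, B = 30, C = 30, D = 30, E = 30),
                      n_normal_controls = 0, n_contaminated = 0,
                      n_genes = 2900, signature_size = 100, noise_sd = 0.2,
                      codel_shift = -0.3,
                      missing_fraction = c(mrna = 0, mirna = 0, methylation = 0),
                      seed = 22)
  co <- generate_cohort(cf)
  res <- codel_from_expression(co$mrna)
  expect_gte(mean(res$codel[co$truth$sample] == co$truth$codel), 0.99)
})

test_that("hypomethylation at the MYC exon 3 CpG uses a strict threshold", {
  m <- matrix(c(0.49, 0.5, NA), 1, 3,
              dimnames = list("cg00163372", c("s1", "s2", "s3")))
  om <- omics_matrix(m, "methylation")
  call <- call_cpg_hypomethylation(om)
  expect_true(call[["s1"]])    # 0.49 < 0.5
  expect_false(call[["s2"]])   # 0.5 is not < 0.5
  expect_true(is.na(call[["s3"]]))
  expect_error(call_cpg_hypomethylation(om, cpg_id = "cg999"), "cg999")
})

test_that("the mean + 2 SD hypermethylation threshold is exact on fixtures", {
  beta <- c(rep(0.1, 9), 0.9)
  m <- matrix(beta, 1, 10,
              dimnames = list("cg22879515", sprintf("s%02d", 1:10)))
  res <- call_cpg_hypermethylation(omics_matrix(m, "methylation"))
  expect_equal(res$threshold, mean(beta) + 2 * sd(beta), tolerance = 1e-12)
  expect_equal(res$threshold, 0.18 + 2 * 0.2529822, tolerance = 1e-6)
  expect_identical(unname(res$call), c(rep(FALSE, 9), TRUE))
  # constant betas: zero variance, nobody called
  m2 <- matrix(0.3, 1, 12, dimnames = list("cg22879515", sprintf("s%02d", 1:12)))
  expect_warning(res2 <- call_cpg_hypermethylation(omics_matrix(m2, "methylation")),
                 "zero variance")
  expect_true(all(!res2$call))
})

test_that("planted hypermethylation is detected at offset 3 SD", {
  sens <- vapply(1:5, function(s) {
    ep <- matrix(0.02, 4, 2, dimnames = list(
      c("myc_gain", "max_loss", "myc_hypometh", "mir34_hypermeth"), c("A", "B")))
    ep["mir34_hypermeth", ] <- 0.05
    cf <- quick_config(n_per_subtype = c(A = 60, B = 60), event_probs = ep,
                       mir34_offset = 3, seed = s)
    co <- generate_cohort(cf)
    res <- call_cpg_hypermethylation(co$methylation)
    truthy <- co$truth$mir34_hypermeth
    if (sum(truthy) == 0) return(NA_real_)
    mean(res$call[co$truth$sample][truthy])
  }, 0)
  expect_gte(mean(sens, na.rm = TRUE), 0.9)
})

test_that("CIMP status recovers a planted island offset and has fixed polarity", {
  cf <- quick_config(n_per_subtype = c(A = 40, B = 40),
                     cimp_positive = c(A = TRUE, B = FALSE),
                     cimp_beta_shift = 0.3, seed = 23)
  co <- generate_cohort(cf)
  ci <- cimp_status(co$methylation, n_iter = 200, seed = 24)
  truth <- setNames(co$truth$cimp, co$truth$sample)
  expect_gte(adjusted_rand_index(ci$cimp[co$truth$sample], truth), 0.95)
  # polarity is defined by mean beta: the CIMP-positive class is the high one
  expect_gt(ci$class_means[names(which.max(ci$class_means))],
            min(ci$class_means))
  expect_true(all(ci$cimp[co$truth$sample][co$truth$cimp] %in% TRUE))
  expect_error(cimp_status(co$mrna), "cpg_island")
})
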