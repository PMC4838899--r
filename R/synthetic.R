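#' Configuration for the synthetic multi-omics cohort generator
#'
#' Defaults emulate the structure of the discovery cohort the pipeline was
#' designed for: five tumour subtypes (C1..C5) of which three (C1, C4, C5,
#' alias O1, O2, O3) carry the 1p/19q co-deletion, a small set of normal
#' brain controls, a block of tumours contaminated with normal tissue,
#' MYC-pathway event rates concentrated in the OPC-like subtype, and
#' subtype-dependent exponential survival. Every random draw is governed by
#' `seed`.
#'
#' @param n_per_subtype Named integer vector of tumour counts per subtype.
#' @param codel_subtypes Subtype names carrying the 1p/19q co-deletion.
#' @param o1_like The aggressive (OPC-like) co-deleted subtype.
#' @param n_normal_controls Normal brain controls (mRNA only).
#' @param n_contaminated Extra tumours mixed with the mean normal profile.
#' @param contamination_w Mixing weight toward the normal profile in
#'   `[0, 1]`.
#' @param n_genes,n_mirnas,n_cpgs Feature counts per omic.
#' @param signature_size Genes per subtype expression signature.
#' @param signature_effect Log2 mean shift of signature genes (default 2).
#' @param noise_sd Gaussian noise SD on log2 expression (default 1).
#' @param codel_shift Additive expression shift on 1p/19q genes in
#'   co-deleted tumours (default -0.3).
#' @param myc_target_size,myc_target_shift MYC target genes and the shift
#'   they receive in samples carrying at least one MYC event.
#' @param myc_subtype_shift Additional target shift applied to every sample
#'   of the `o1_like` subtype regardless of events (default 0).
#' @param mirna_signature_size,mirna_effect,mirna_dispersion miRNA subtype
#'   signature size, log2 fold change, and negative-binomial size.
#' @param meth_signature_size,meth_effect Methylation subtype signature
#'   size and logit-scale shift.
#' @param methylation_logit_sd Logit-scale noise SD for beta values.
#' @param cimp_positive Named logical: which subtypes are CIMP-positive.
#' @param cimp_beta_shift Beta-scale island hypermethylation in
#'   CIMP-positive samples (default 0.3).
#' @param island_fraction Fraction of CpGs flagged as island probes.
#' @param event_probs 4 x subtypes probability matrix (rows `myc_gain`,
#'   `max_loss`, `myc_hypometh`, `mir34_hypermeth`).
#' @param exclusivity_mode `"independent"` events, or `"exclusive"` (at
#'   most one event per sample).
#' @param arm_events data.frame (`subtype`, `arm`, `sign`, `prob`) of extra
#'   arm-level copy-number events.
#' @param mir34_base_mean,mir34_base_sd,mir34_offset Baseline beta and
#'   event offset (in SD units) at the mir34b/c promoter CpG.
#' @param hazard Named per-subtype exponential hazard (per month).
#' @param censoring_rate Independent exponential censoring hazard.
#' @param rt_probability Probability of initial radiotherapy.
#' @param rt_hazard_multiplier Named per-subtype hazard multiplier under
#'   radiotherapy (default: benefit only in the OPC-like subtype).
#' @param missing_fraction Named per-omic sample drop-out probability.
#' @param seed Integer seed; fully determines the cohort.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_subtype = c(C1 = 47, C2 = 25, C3 = 36, C4 = 17, C5 = 16),
    codel_subtypes = NULL, o1_like = NULL,
    n_normal_controls = 9, n_contaminated = 29, contamination_w = 0.8,
    n_genes = 2000, n_mirnas = 800, n_cpgs = 2000,
    signature_size = 200, signature_effect = 2.0, noise_sd = 1.0,
    codel_shift = -0.3,
    myc_target_size = 50, myc_target_shift = 1.0, myc_subtype_shift = 0,
    mirna_signature_size = 50, mirna_effect = 2.0, mirna_dispersion = 8,
    meth_signature_size = 100, meth_effect = 1.5,
    methylation_logit_sd = 0.5,
    cimp_positive = NULL, cimp_beta_shift = 0.3, island_fraction = 0.4,
    event_probs = NULL,
    exclusivity_mode = c("independent", "exclusive"),
    arm_events = NULL,
    mir34_base_mean = 0.15, mir34_base_sd = 0.03, mir34_offset = 8,
    hazard = NULL, censoring_rate = 0.006, rt_probability = 0.6,
    rt_hazard_multiplier = NULL,
    missing_fraction = c(mrna = 0, mirna = 0.03, methylation = 0.38),
    seed = 1) {
  exclusivity_mode <- match.arg(exclusivity_mode)
  k <- length(n_per_subtype)
  if (k < 1 || any(n_per_subtype < 0)) stop("cohort_config: invalid n_per_subtype")
  if (is.null(names(n_per_subtype)))
    names(n_per_subtype) <- paste0("S", seq_len(k))
  subtypes <- names(n_per_subtype)
  if (is.null(codel_subtypes))
    codel_subtypes <- if (k >= 3) subtypes[c(1, k - 1, k)] else subtypes[1]
  if (!all(codel_subtypes %in% subtypes))
    stop("cohort_config: codel_subtypes not among subtype names")
  if (is.null(o1_like)) o1_like <- codel_subtypes[1]
  if (!o1_like %in% codel_subtypes) stop("cohort_config: o1_like must be co-deleted")

  if (is.null(event_probs)) {
    event_probs <- matrix(0.02, 4, k,
                          dimnames = list(c("myc_gain", "max_loss",
                                            "myc_hypometh", "mir34_hypermeth"),
                                          subtypes))
    event_probs[, o1_like] <- c(0.09, 0.35, 0.20, 0.28)
  }
  if (any(event_probs < 0 | event_probs > 1))
    stop("cohort_config: event_probs outside [0,1]")
  if (exclusivity_mode == "exclusive" && any(colSums(event_probs) > 1))
    stop("cohort_config: exclusive mode needs per-subtype event probs summing to <= 1")

  if (is.null(arm_events)) {
    arm_events <- data.frame(subtype = o1_like,
                             arm = c("9p", "4p", "4q", "18q"),
                             sign = -1L, prob = c(0.35, 0.20, 0.20, 0.25))
    if ("C2" %in% subtypes)
      arm_events <- rbind(arm_events,
                          data.frame(subtype = "C2",
                                     arm = c("7p", "7q", "10p", "10q"),
                                     sign = c(1L, 1L, -1L, -1L),
                                     prob = c(0.75, 0.75, 0.8, 0.8)))
    if ("C3" %in% subtypes)
      arm_events <- rbind(arm_events,
                          data.frame(subtype = "C3",
                                     arm = c("7p", "7q", "11p"),
                                     sign = c(1L, 1L, -1L),
                                     prob = c(0.54, 0.54, 0.41)))
  }
  if (any(arm_events$prob < 0 | arm_events$prob > 1))
    stop("cohort_config: arm_events probs outside [0,1]")
  if (any(arm_events$arm %in% c("8q", "14q")))
    stop("cohort_config: 8q/14q arm events are reserved for the focal MYC/MAX mechanism")

  if (is.null(cimp_positive)) {
    cimp_positive <- stats::setNames(rep(TRUE, k), subtypes)
    if ("C2" %in% subtypes) cimp_positive["C2"] <- FALSE  # IDH-wildtype-like
  }
  if (is.null(hazard)) {
    hazard <- stats::setNames(rep(0.005, k), subtypes)
    hazard[o1_like] <- 0.010
    if ("C2" %in% subtypes) hazard["C2"] <- 0.030
  }
  if (is.null(rt_hazard_multiplier)) {
    rt_hazard_multiplier <- stats::setNames(rep(1, k), subtypes)
    rt_hazard_multiplier[o1_like] <- 0.5
  }
  probs <- c(contamination_w, island_fraction, rt_probability,
             missing_fraction)
  if (any(probs < 0 | probs > 1)) stop("cohort_config: probability outside [0,1]")
  n_special <- k * signature_size + signature_size + myc_target_size
  if (n_special > n_genes)
    stop("cohort_config: n_genes too small for the signature blocks (need >= ",
         n_special, ")")
  if (k * meth_signature_size + 5 > n_cpgs)
    stop("cohort_config: n_cpgs too small for the methylation signature blocks")
  if (k * mirna_signature_size > n_mirnas)
    stop("cohort_config: n_mirnas too small for the miRNA signature blocks")

  structure(list(
    n_per_subtype = n_per_subtype, subtypes = subtypes,
    codel_subtypes = codel_subtypes, o1_like = o1_like,
    n_normal_controls = n_normal_controls, n_contaminated = n_contaminated,
    contamination_w = contamination_w,
    n_genes = n_genes, n_mirnas = n_mirnas, n_cpgs = n_cpgs,
    signature_size = signature_size, signature_effect = signature_effect,
    noise_sd = noise_sd, codel_shift = codel_shift,
    myc_target_size = myc_target_size, myc_target_shift = myc_target_shift,
    myc_subtype_shift = myc_subtype_shift,
    mirna_signature_size = mirna_signature_size, mirna_effect = mirna_effect,
    mirna_dispersion = mirna_dispersion,
    meth_signature_size = meth_signature_size, meth_effect = meth_effect,
    methylation_logit_sd = methylation_logit_sd,
    cimp_positive = cimp_positive, cimp_beta_shift = cimp_beta_shift,
    island_fraction = island_fraction,
    event_probs = event_probs, exclusivity_mode = exclusivity_mode,
    arm_events = arm_events,
    mir34_base_mean = mir34_base_mean, mir34_base_sd = mir34_base_sd,
    mir34_offset = mir34_offset,
    hazard = hazard, censoring_rate = censoring_rate,
    rt_probability = rt_probability,
    rt_hazard_multiplier = rt_hazard_multiplier,
    missing_fraction = missing_fraction, seed = seed),
    class = "cohort_config")
}

# Genomic anchors (GRCh37): MYC on 8q24, MAX on 14q23, the MYC exon 3 CpG,
# and the mir34b/c promoter CpG island on 11q23.
myc_region <- function() list(chrom = "8", start = 128748315, end = 128753680)
max_region <- function() list(chrom = "14", start = 65472819, end = 65569413)

#' Generate a synthetic multi-omics cohort with ground truth
#'
#' Emits matched mRNA expression (log2 scale, Gaussian noise, subtype
#' signature blocks, 1p/19q expression decrement, contamination mixtures
#' with the mean normal profile), miRNA read counts (negative binomial with
#' subtype-specific means and variable library sizes), methylation beta
#' values (logit-normal, CIMP island offset, planted single-CpG events at
#' cg00163372 and cg22879515), arm-level GNL segments consistent with the
#' planted copy-number events, clinical annotation with exponential
#' survival, and the ground-truth table all recovery tests run against.
#'
#' @param config A [cohort_config()].
#' @return List with elements `mrna`, `mirna_counts`, `methylation`, `gnl`,
#'   `annot`, `truth`, `myc_targets`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cf <- config
  if (!inherits(cf, "cohort_config")) stop("generate_cohort: need a cohort_config")
  set.seed(cf$seed)
  k <- length(cf$subtypes)

  ## ---- sample frame -------------------------------------------------
  subtype <- rep(cf$subtypes, cf$n_per_subtype)
  n_clean <- length(subtype)
  cont_sub <- if (cf$n_contaminated > 0)
    cf$subtypes[1 + (seq_len(cf$n_contaminated) - 1) %% k] else character(0)
  subtype <- c(subtype, cont_sub)
  n_tum <- length(subtype)
  tum_ids <- sprintf("S%03d", seq_len(n_tum))
  ctl_ids <- if (cf$n_normal_controls > 0)
    sprintf("N%02d", seq_len(cf$n_normal_controls)) else character(0)
  contaminated <- c(rep(FALSE, n_clean), rep(TRUE, cf$n_contaminated))
  w <- ifelse(contaminated, cf$contamination_w, 0)
  codel <- subtype %in% cf$codel_subtypes

  ## ---- MYC-pathway events ------------------------------------------
  ev_names <- rownames(cf$event_probs)
  events <- matrix(FALSE, n_tum, 4, dimnames = list(tum_ids, ev_names))
  for (i in seq_len(n_tum)) {
    p <- cf$event_probs[, subtype[i]]
    if (cf$exclusivity_mode == "independent") {
      events[i, ] <- stats::runif(4) < p
    } else {
      u <- stats::runif(1)
      cum <- cumsum(p)
      hit <- which(u < cum)[1]
      if (!is.na(hit)) events[i, hit] <- TRUE
    }
  }

  ## ---- gene annotation and expression blocks ------------------------
  ab <- arm_boundaries()
  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))
  sig_idx <- lapply(seq_len(k), function(s)
    ((s - 1) * cf$signature_size + 1):(s * cf$signature_size))
  names(sig_idx) <- cf$subtypes
  normal_idx <- (k * cf$signature_size + 1):((k + 1) * cf$signature_size)
  myc_idx <- ((k + 1) * cf$signature_size + 1):((k + 1) * cf$signature_size + cf$myc_target_size)
  n_special <- (k + 1) * cf$signature_size + cf$myc_target_size

  # arms: special blocks avoid 1p/19q so arm scores stay subtype-neutral
  arms_all <- ab$arm
  arms_no_codel <- setdiff(arms_all, c("1p", "19q"))
  gene_arm <- character(cf$n_genes)
  gene_arm[seq_len(n_special)] <-
    rep_len(arms_no_codel, n_special)
  if (n_special < cf$n_genes)
    gene_arm[(n_special + 1):cf$n_genes] <-
      rep_len(arms_all, cf$n_genes - n_special)
  arm_row <- match(gene_arm, ab$arm)
  gene_pos <- round(ab$start[arm_row] +
                      stats::runif(cf$n_genes) * (ab$end[arm_row] - ab$start[arm_row]))
  gene_annot <- data.frame(chrom = ab$chrom[arm_row], start = gene_pos,
                           end = gene_pos, arm = gene_arm)

  baseline <- stats::rnorm(cf$n_genes, 7, 1)
  n_all <- n_tum + cf$n_normal_controls
  ids <- c(tum_ids, ctl_ids)
  signal <- matrix(baseline, cf$n_genes, n_all, dimnames = list(gene_ids, ids))
  for (s in cf$subtypes) {
    cols <- which(c(subtype, rep(NA, cf$n_normal_controls)) == s)
    signal[sig_idx[[s]], cols] <- signal[sig_idx[[s]], cols] + cf$signature_effect
  }
  codel_genes <- which(gene_arm %in% c("1p", "19q"))
  codel_cols <- which(c(codel, rep(FALSE, cf$n_normal_controls)))
  signal[codel_genes, codel_cols] <- signal[codel_genes, codel_cols] + cf$codel_shift
  any_event <- rowSums(events) > 0
  target_shift <- cf$myc_target_shift * any_event +
    cf$myc_subtype_shift * (subtype == cf$o1_like)
  signal[myc_idx, seq_len(n_tum)] <-
    signal[myc_idx, seq_len(n_tum)] + rep(target_shift, each = length(myc_idx))
  ctl_cols <- n_tum + seq_len(cf$n_normal_controls)
  # normal brain differs from tumour in both directions across its block;
  # a signed offset keeps the contrast visible to correlation distances
  normal_profile <- baseline
  normal_profile[normal_idx] <- normal_profile[normal_idx] +
    stats::rnorm(length(normal_idx), 0, 1.5 * cf$signature_effect)
  if (cf$n_normal_controls > 0) signal[, ctl_cols] <- normal_profile
  cont_cols <- which(c(contaminated, rep(FALSE, cf$n_normal_controls)))
  for (j in cont_cols)
    signal[, j] <- (1 - cf$contamination_w) * signal[, j] +
      cf$contamination_w * normal_profile
  mrna_vals <- signal + matrix(stats::rnorm(length(signal), 0, cf$noise_sd),
                               nrow(signal))
  mrna <- omics_matrix(mrna_vals, "mrna", feature_annot = gene_annot)

  ## ---- miRNA counts -------------------------------------------------
  mir_ids <- sprintf("mir%04d", seq_len(cf$n_mirnas))
  mir_mu <- stats::rlnorm(cf$n_mirnas, log(1000), 1.2)
  lib <- stats::rlnorm(n_tum, 0, 0.3)
  mir_sig <- lapply(seq_len(k), function(s)
    ((s - 1) * cf$mirna_signature_size + 1):(s * cf$mirna_signature_size))
  names(mir_sig) <- cf$subtypes
  lfold <- matrix(0, cf$n_mirnas, n_tum)
  for (s in cf$subtypes)
    lfold[mir_sig[[s]], subtype == s] <- cf$mirna_effect
  mu_mat <- outer(mir_mu, lib) * 2^lfold
  mirna_counts <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                                        size = cf$mirna_dispersion),
                         cf$n_mirnas, n_tum, dimnames = list(mir_ids, tum_ids))

  ## ---- methylation --------------------------------------------------
  special_cpgs <- c("cg00163372", "cg22879515", "cg21881253", "cg13767940",
                    "cg23211240")
  n_sim <- cf$n_cpgs - length(special_cpgs)
  cpg_ids <- c(special_cpgs, sprintf("cgs%05d", seq_len(n_sim)))
  island <- c(FALSE, TRUE, TRUE, TRUE, TRUE,
              stats::runif(n_sim) < cf$island_fraction)
  cpg_arm <- rep_len(arms_all, cf$n_cpgs)
  cpg_arm[1] <- "8q"; cpg_arm[2:5] <- "11q"
  cpg_row <- match(cpg_arm, ab$arm)
  cpg_pos <- round(ab$start[cpg_row] +
                     stats::runif(cf$n_cpgs) * (ab$end[cpg_row] - ab$start[cpg_row]))
  cpg_pos[1] <- 128752988
  cpg_annot <- data.frame(chrom = ab$chrom[cpg_row], start = cpg_pos,
                          end = cpg_pos, arm = cpg_arm, cpg_island = island)

  mu_logit <- stats::rnorm(cf$n_cpgs, 0, 1.5)
  meth_logit <- matrix(mu_logit, cf$n_cpgs, n_tum,
                       dimnames = list(cpg_ids, tum_ids)) +
    matrix(stats::rnorm(cf$n_cpgs * n_tum, 0, cf$methylation_logit_sd), cf$n_cpgs)
  meth_sig <- lapply(seq_len(k), function(s)
    length(special_cpgs) + ((s - 1) * cf$meth_signature_size + 1):(s * cf$meth_signature_size))
  names(meth_sig) <- cf$subtypes
  for (s in cf$subtypes)
    meth_logit[meth_sig[[s]], subtype == s] <-
      meth_logit[meth_sig[[s]], subtype == s] + cf$meth_effect
  beta <- stats::plogis(meth_logit)
  cimp_sample <- cf$cimp_positive[subtype]
  if (any(cimp_sample))
    beta[island, cimp_sample] <- beta[island, cimp_sample] + cf$cimp_beta_shift
  # planted single-CpG events: MYC exon 3 hypomethylation, mir34b/c promoter
  hypo <- events[, "myc_hypometh"]
  beta["cg00163372", ] <- ifelse(hypo, stats::runif(n_tum, 0.10, 0.45),
                                 stats::runif(n_tum, 0.55, 0.95))
  hyper <- events[, "mir34_hypermeth"]
  base34 <- stats::rnorm(n_tum, cf$mir34_base_mean, cf$mir34_base_sd)
  off34 <- cf$mir34_offset * cf$mir34_base_sd
  # hypermethylated islands sit tightly at the methylated level; the
  # unmethylated baseline variance does not carry over
  jit <- stats::rnorm(n_tum, 0, cf$mir34_base_sd / 4)
  for (cg in c("cg22879515", "cg21881253", "cg13767940", "cg23211240"))
    beta[cg, ] <- ifelse(hyper, cf$mir34_base_mean + off34 + jit, base34)
  beta <- pmin(pmax(beta, 1e-3), 1 - 1e-3)
  methylation <- omics_matrix(beta, "methylation", feature_annot = cpg_annot)

  ## ---- GNL segments -------------------------------------------------
  arm_status <- matrix(0L, n_tum, nrow(ab),
                       dimnames = list(tum_ids, ab$arm))
  arm_status[codel, "1p"] <- -1L
  arm_status[codel, "19q"] <- -1L
  for (r in seq_len(nrow(cf$arm_events))) {
    e <- cf$arm_events[r, ]
    hit <- subtype == e$subtype & stats::runif(n_tum) < e$prob
    arm_status[hit, e$arm] <- as.integer(e$sign)
  }
  myc <- myc_region(); mx <- max_region()
  seg_list <- vector("list", n_tum)
  for (i in seq_len(n_tum)) {
    st <- arm_status[i, ]
    segs <- data.frame(sample = tum_ids[i], chrom = ab$chrom, start = ab$start,
                       end = ab$end, gnl = as.integer(st))
    if (events[i, "myc_gain"])
      segs <- split_focal(segs, "8q", ab, myc, 1L)
    if (events[i, "max_loss"])
      segs <- split_focal(segs, "14q", ab, mx, -1L)
    seg_list[[i]] <- segs
  }
  gnl <- gnl_table(segments = do.call(rbind, seg_list))

  ## ---- survival and annotation --------------------------------------
  haz <- cf$hazard[subtype]
  rt <- stats::runif(n_tum) < cf$rt_probability
  haz <- haz * ifelse(rt, cf$rt_hazard_multiplier[subtype], 1)
  t_death <- stats::rexp(n_tum, haz)
  t_cens <- stats::rexp(n_tum, cf$censoring_rate)
  os_time <- pmin(t_death, t_cens)
  os_event <- as.integer(t_death <= t_cens)
  grade <- ifelse(subtype == cf$o1_like,
                  ifelse(stats::runif(n_tum) < 0.9, "III", "II"),
                  ifelse(stats::runif(n_tum) < 0.45, "III", "II"))
  age <- round(stats::rnorm(n_tum, ifelse(subtype == cf$o1_like, 48.7, 44.8), 10), 1)

  annot <- sample_annot(data.frame(
    sample = ids, cohort = "synthetic",
    grade = c(grade, rep(NA, cf$n_normal_controls)),
    histology = c(rep("OT", n_tum), rep("normal brain", cf$n_normal_controls)),
    idh_status = c(ifelse(subtype == "C2", "wt", "mut"),
                   rep(NA, cf$n_normal_controls)),
    codel_status = c(codel, rep(NA, cf$n_normal_controls)),
    age = c(age, rep(NA, cf$n_normal_controls)),
    os_time = c(os_time, rep(NA, cf$n_normal_controls)),
    os_event = c(os_event, rep(NA, cf$n_normal_controls)),
    initial_radiotherapy = c(rt, rep(NA, cf$n_normal_controls)),
    is_normal_control = c(rep(FALSE, n_tum), rep(TRUE, cf$n_normal_controls))))

  ## ---- per-omic availability ----------------------------------------
  avail <- function(p, n) stats::runif(n) >= p
  av_mrna <- avail(cf$missing_fraction[["mrna"]], n_tum)
  av_mirna <- avail(cf$missing_fraction[["mirna"]], n_tum)
  av_meth <- avail(cf$missing_fraction[["methylation"]], n_tum)
  mrna$values <- mrna$values[, c(tum_ids[av_mrna], ctl_ids), drop = FALSE]
  mirna_counts <- mirna_counts[, av_mirna, drop = FALSE]
  methylation$values <- methylation$values[, av_meth, drop = FALSE]

  truth <- data.frame(
    sample = tum_ids, subtype = subtype, codel = codel,
    contamination_w = w,
    myc_gain = events[, "myc_gain"], max_loss = events[, "max_loss"],
    myc_hypometh = events[, "myc_hypometh"],
    mir34_hypermeth = events[, "mir34_hypermeth"],
    any_event = any_event,
    cimp = unname(cf$cimp_positive[subtype]),
    avail_mrna = av_mrna, avail_mirna = av_mirna, avail_methylation = av_meth)

  list(mrna = mrna, mirna_counts = mirna_counts, methylation = methylation,
       gnl = gnl, annot = annot, truth = truth,
       myc_targets = gene_set("myc_targets_synthetic", gene_ids[myc_idx],
                              source = "synthetic plant"),
       config = cf)
}

# Replace the single whole-arm segment with (before, focal, after) pieces so
# a focal gain/loss never overlaps the arm segment.
split_focal <- function(segs, arm, ab, region, gnl_val) {
  row <- which(ab$arm == arm)
  i <- which(segs$start == ab$start[row] & segs$chrom == ab$chrom[row] &
               segs$end == ab$end[row])
  base <- segs$gnl[i]
  pieces <- data.frame(sample = segs$sample[i], chrom = ab$chrom[row],
                       start = c(ab$start[row], region$start, region$end + 1),
                       end = c(region$start - 1, region$end, ab$end[row]),
                       gnl = c(base, gnl_val, base))
  pieces <- pieces[pieces$end >= pieces$start, ]
  rbind(segs[-i, ], pieces)
}

#' Observed frequencies of planted events
#'
#' Tabulates the ground-truth event flags of a generated cohort, overall
#' and per subtype, for comparison against the configured probabilities.
#'
#' @param truth The `truth` component of [generate_cohort()].
#' @return data.frame (`event`, `subtype`, `n`, `n_event`, `rate`), with
#'   subtype `"all"` rows for the overall rates.
#' @export
planted_event_rates <- function(truth) {
  ev <- c("myc_gain", "max_loss", "myc_hypometh", "mir34_hypermeth")
  groups <- c(list(all = rep(TRUE, nrow(truth))),
              lapply(stats::setNames(nm = sort(unique(truth$subtype))),
                     function(s) truth$subtype == s))
  do.call(rbind, lapply(names(groups), function(g) {
    sel <- groups[[g]]
    data.frame(event = ev, subtype = g, n = sum(sel),
               n_event = vapply(ev, function(e) sum(truth[[e]][sel]), 0L),
               rate = vapply(ev, function(e) mean(truth[[e]][sel]), 0),
               row.names = NULL)
  }))
}

#' Write a generated cohort to TSV files
#'
#' Emits the matrices, annotation, GNL segments, ground truth and MYC
#' target list of a [generate_cohort()] result as plain-text files.
#'
#' @param cohort [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_matrix(cohort$mirna_counts, file.path(dir, "mirna_counts.tsv"))
  write_matrix(cohort$methylation, file.path(dir, "methylation.tsv"))
  write_gnl(cohort$gnl, file.path(dir, "gnl_segments.tsv"))
  utils::write.table(cohort$annot, file.path(dir, "sample_annot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  writeLines(paste(c(cohort$myc_targets$name, "synthetic",
                     cohort$myc_targets$members), collapse = "\t"),
             file.path(dir, "myc_targets.gmt"))
  ann <- function(x) data.frame(feature_id = rownames(x$values),
                                x$feature_annot)
  utils::write.table(ann(cohort$mrna), file.path(dir, "mrna_annot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(ann(cohort$methylation), file.path(dir, "methylation_annot.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(dir)
}
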