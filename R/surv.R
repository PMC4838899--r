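#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (via the survival package); at tied times deaths
#' are processed before censorings.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Event indicators (1 = death, 0 = censored).
#' @return data.frame step function: `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("km_estimate: empty input")
  if (any(times < 0)) stop("km_estimate: negative times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank comparison of survival curves, df =
#' number of groups - 1. Empty groups are dropped with a warning.
#'
#' @param times,events Survival data in months / 0-1 indicators.
#' @param group Group labels aligned with `times`.
#' @param strata Optional stratification factor (e.g. cohort).
#' @return List with `statistic`, `df`, `p_value`, `observed`, `expected`.
#' @export
logrank <- function(times, events, group, strata = NULL) {
  keep <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[keep]; events <- events[keep]; group <- group[keep]
  if (!is.null(strata)) strata <- strata[keep]
  tab <- table(group)
  if (any(tab == 0)) {
    warning("logrank: dropping empty group(s)")
    group <- droplevels(factor(group))
  }
  group <- factor(group)
  if (nlevels(group) < 2) stop("logrank: need >= 2 non-empty groups")
  if (sum(events) < 1) stop("logrank: need >= 1 event")
  dat <- data.frame(.t = times, .e = events, .g = group)
  if (is.null(strata)) {
    sd <- survival::survdiff(survival::Surv(.t, .e) ~ .g, data = dat)
  } else {
    dat$.s <- strata
    sd <- survival::survdiff(survival::Surv(.t, .e) ~ .g +
                               survival::strata(.s), data = dat)
  }
  df <- nlevels(group) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Pooled cross-cohort survival comparison
#'
#' Concatenates survival records from several cohorts (times in months
#' throughout) and compares the aggressive subtype against the others
#' (`group_rule`, default O1 vs O2+O3) by log-rank, both unstratified
#' (default) and stratified by cohort.
#'
#' @param cohorts Named list; each element a data.frame with columns
#'   `sample`, `os_time`, `os_event` and a `subtype` column (or supply
#'   partitions via `subtype`).
#' @param group_rule Function mapping the subtype vector to group labels;
#'   default labels `"O1"` vs `"other"`.
#' @param stratify_by_cohort Also report the cohort-stratified test
#'   (default TRUE).
#' @return List with `records` (pooled data.frame with `cohort` tag),
#'   `logrank` and, when requested, `logrank_stratified`.
#' @export
pooled_survival <- function(cohorts,
                            group_rule = function(s) ifelse(s == "O1", "O1", "other"),
                            stratify_by_cohort = TRUE) {
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  recs <- do.call(rbind, lapply(names(cohorts), function(nm) {
    d <- as.data.frame(cohorts[[nm]])
    need <- c("os_time", "os_event", "subtype")
    if (!all(need %in% colnames(d)))
      stop("pooled_survival: cohort '", nm, "' lacks ", paste(setdiff(need, colnames(d)), collapse = ", "))
    if (nrow(d) == 0) return(NULL)
    data.frame(cohort = nm, sample = if (is.null(d$sample)) seq_len(nrow(d)) else d$sample,
               os_time = d$os_time, os_event = d$os_event, subtype = d$subtype)
  }))
  recs <- recs[!is.na(recs$os_time) & !is.na(recs$os_event) & !is.na(recs$subtype), ]
  grp <- group_rule(recs$subtype)
  out <- list(records = recs,
              logrank = logrank(recs$os_time, recs$os_event, grp))
  if (stratify_by_cohort && length(unique(recs$cohort)) > 1)
    out$logrank_stratified <- logrank(recs$os_time, recs$os_event, grp,
                                      strata = recs$cohort)
  out
}

#' Radiotherapy-stratified five-year survival comparison
#'
#' Within each subtype, compares patients who received initial radiotherapy
#' against those who did not. Patients deceased within the first
#' `landmark_months` (default 3) are excluded — they could not have
#' effectively received radiotherapy — and follow-up is administratively
#' censored at `horizon_months` (default 60, i.e. five-year survival).
#'
#' @param records data.frame with `os_time`, `os_event`,
#'   `initial_radiotherapy` (logical) and `subtype`.
#' @param horizon_months Censoring horizon (default 60).
#' @param landmark_months Early-death exclusion window (default 3).
#' @param min_per_arm Minimum patients per RT arm within a stratum
#'   (default 2); below it the stratum reports NA.
#' @return data.frame, one row per subtype: `subtype`, `n_rt`, `n_no_rt`,
#'   `statistic`, `p_value`, `note`.
#' @export
rt_stratified <- function(records, horizon_months = 60, landmark_months = 3,
                          min_per_arm = 2) {
  d <- as.data.frame(records)
  need <- c("os_time", "os_event", "initial_radiotherapy", "subtype")
  if (!all(need %in% colnames(d)))
    stop("rt_stratified: records lack ", paste(setdiff(need, colnames(d)), collapse = ", "))
  d <- d[!is.na(d$os_time) & !is.na(d$os_event) &
           !is.na(d$initial_radiotherapy) & !is.na(d$subtype), ]
  d <- d[!(d$os_event == 1 & d$os_time < landmark_months), ]
  over <- d$os_time > horizon_months
  d$os_event[over] <- 0
  d$os_time[over] <- horizon_months
  do.call(rbind, lapply(sort(unique(d$subtype)), function(st) {
    s <- d[d$subtype == st, ]
    n_rt <- sum(s$initial_radiotherapy); n_no <- sum(!s$initial_radiotherapy)
    if (n_rt < min_per_arm || n_no < min_per_arm || sum(s$os_event) == 0)
      return(data.frame(subtype = st, n_rt = n_rt, n_no_rt = n_no,
                        statistic = NA_real_, p_value = NA_real_,
                        note = "stratum too small or no events"))
    lr <- logrank(s$os_time, s$os_event,
                  ifelse(s$initial_radiotherapy, "RT", "noRT"))
    data.frame(subtype = st, n_rt = n_rt, n_no_rt = n_no,
               statistic = lr$statistic, p_value = lr$p_value, note = "")
  }))
}
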