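#' Aggregate MYC-deregulation events into an event table
#'
#' Combines the four per-sample calls — MYC genomic gain, MAX genomic loss,
#' MYC exon 3 hypomethylation, mir34b/c locus hypermethylation — into one
#' table with an `any_event` column: TRUE if at least one (non-NA) event is
#' present, FALSE if all non-NA events are absent, NA when every call is
#' NA. An optional MYC activity score column is carried along.
#'
#' @param myc_gain,max_loss,myc_hypometh,mir34_hypermeth Named logical
#'   vectors over the same sample universe (NA allowed).
#' @param myc_score Optional named numeric vector of MYC activity scores.
#' @return data.frame of class `event_table`, one row per sample.
#' @export
aggregate_events <- function(myc_gain, max_loss, myc_hypometh,
                             mir34_hypermeth, myc_score = NULL) {
  calls <- list(myc_gain = myc_gain, max_loss = max_loss,
                myc_hypometh = myc_hypometh, mir34_hypermeth = mir34_hypermeth)
  samples <- names(calls[[1]])
  if (is.null(samples)) stop("aggregate_events: calls must be named by sample id")
  for (nm in names(calls))
    if (!setequal(names(calls[[nm]]), samples))
      stop("aggregate_events: sample sets differ ('", nm, "' vs myc_gain)")
  mat <- matrix(unlist(lapply(calls, function(v) as.logical(v[samples]))),
                nrow = length(samples),
                dimnames = list(samples, names(calls)))
  any_event <- apply(mat, 1, function(r) {
    if (all(is.na(r))) NA else any(r, na.rm = TRUE)
  })
  out <- data.frame(sample = samples, mat, any_event = any_event,
                    row.names = NULL)
  if (!is.null(myc_score)) out$myc_score <- unname(myc_score[samples])
  class(out) <- c("event_table", "data.frame")
  out
}

#' One-sided binomial test for mutual exclusivity of two events
#'
#' Under independence, the co-occurrence count among the n samples with
#' both calls defined is Binomial(n, pA * pB) with pA, pB the observed
#' marginal rates. The returned p-value is the lower tail P(X <= k): small
#' values mean the events co-occur less often than independence predicts,
#' i.e. tend to be mutually exclusive.
#'
#' @param a,b Named logical vectors of event calls.
#' @return List with `p_value`, `n`, `observed`, `expected`, `rate_a`,
#'   `rate_b`, and `note` when a marginal rate is zero.
#' @export
exclusivity_test <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("exclusivity_test: no shared samples")
  a <- as.logical(a[common]); b <- as.logical(b[common])
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) stop("exclusivity_test: no sample with both calls defined")
  pA <- mean(a); pB <- mean(b)
  k <- sum(a & b)
  if (pA == 0 || pB == 0)
    return(list(p_value = 1, n = n, observed = k, expected = 0,
                rate_a = pA, rate_b = pB,
                note = "a marginal rate is zero; test has no power"))
  list(p_value = stats::pbinom(k, n, pA * pB), n = n, observed = k,
       expected = n * pA * pB, rate_a = pA, rate_b = pB, note = NULL)
}

#' MYC activity by event status
#'
#' Compares the MYC activity score between samples with and without at
#' least one deregulation event: per-group quartile summaries (box-plot
#' conventions) and a Welch two-sample t-test.
#'
#' @param etable [aggregate_events()] result containing `any_event` and
#'   `myc_score` (or pass `scores`).
#' @param scores Optional named score vector overriding `etable$myc_score`.
#' @return List with `summary` (data.frame: group, n, q1, median, q3, mean)
#'   and `p_value`.
#' @export
score_by_event <- function(etable, scores = NULL) {
  if (is.null(scores)) {
    if (is.null(etable$myc_score)) stop("score_by_event: no scores available")
    scores <- stats::setNames(etable$myc_score, etable$sample)
  }
  s <- scores[etable$sample]
  grp <- etable$any_event
  keep <- !is.na(grp) & !is.na(s)
  s <- s[keep]; grp <- grp[keep]
  if (length(unique(grp)) < 2 || min(table(grp)) < 2)
    stop("score_by_event: need >= 2 samples in each of the event/no-event groups")
  summ <- do.call(rbind, lapply(c(FALSE, TRUE), function(g) {
    q <- stats::quantile(s[grp == g], c(0.25, 0.5, 0.75), type = 7)
    data.frame(group = if (g) "event" else "no_event", n = sum(grp == g),
               q1 = q[[1]], median = q[[2]], q3 = q[[3]], mean = mean(s[grp == g]))
  }))
  tt <- stats::t.test(s[grp], s[!grp])
  list(summary = summ, p_value = tt$p.value)
}
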