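#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate of the survival function, with censored
#' observations handled conventionally (events at a tied time are
#' processed before censorings).
#'
#' @param cohort data.frame with columns `time` (nonnegative), `event`
#'   (1 = event, 0 = censored) and optionally `group`.
#' @param group when given, restrict to that group label.
#' @return data.frame: time, n_risk, n_event, n_censor, survival;
#'   survival starts at 1 and is nonincreasing.
#' @export
km_curve <- function(cohort, group = NULL) {
  .check_cohort(cohort)
  if (!is.null(group)) {
    cohort <- cohort[cohort$group == group, , drop = FALSE]
    if (nrow(cohort) == 0L) stop("empty group '", group, "'")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = cohort)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test
#'
#' @param cohort data.frame with `time`, `event` and a two-level
#'   `group` column; at least one event overall.
#' @return List: statistic (chi-square, 1 df), p.value, observed and
#'   expected event counts per group.
#' @export
logrank <- function(cohort) {
  .check_cohort(cohort)
  if (!"group" %in% names(cohort) || length(unique(cohort$group)) != 2L)
    stop("log-rank test requires exactly two groups")
  if (sum(cohort$event) < 1L) stop("log-rank test requires >= 1 event")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = cohort)
  list(statistic = unname(sd_$chisq),
       p.value = pchisq(sd_$chisq, df = 1L, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

.check_cohort <- function(cohort) {
  stopifnot(all(c("time", "event") %in% names(cohort)))
  if (any(cohort$time < 0)) stop("survival times must be nonnegative")
  if (!all(cohort$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)")
  invisible(TRUE)
}

#' Split samples into groups by score
#'
#' Deterministic high/low (or tertile) labeling.  Samples tied with the
#' cut value are assigned to the lower group.
#'
#' @param scores named numeric vector.
#' @param rule `"median"`, `"tertile"` or `"threshold"`.
#' @param threshold cut value for the `"threshold"` rule.
#' @return Named character vector of labels per sample ("low"/"high",
#'   or "low"/"mid"/"high" for tertiles), in the input order.
#' @export
split_by_score <- function(scores, rule = c("median", "tertile",
                                            "threshold"),
                           threshold = NULL) {
  rule <- match.arg(rule)
  if (length(scores) < 2L) stop("need >= 2 samples to split")
  if (length(unique(scores)) == 1L)
    stop("all scores equal: no split possible")
  lab <- switch(rule,
    median = ifelse(scores <= median(scores), "low", "high"),
    threshold = {
      thr <- .check_number(threshold, "threshold")
      ifelse(scores <= thr, "low", "high")
    },
    tertile = {
      q <- quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
      ifelse(scores <= q[1L], "low", ifelse(scores <= q[2L], "mid", "high"))
    })
  setNames(lab, names(scores))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted P values: monotone, each at least its raw P, capped
#' at 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return Adjusted values in the input order.
#' @export
bh_fdr <- function(p_values) {
  .check_prob(p_values, "p_values", open_left = FALSE)
  p.adjust(p_values, method = "BH")
}
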