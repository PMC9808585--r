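#' @title Retrospective analytics
#' @name analytics
#' @description
#' Retrospective-evaluation computations over an event log and measurement
#' stream: follow-up accounting by category, per-patient follow-up means,
#' intervention-level classification, monthly trend analysis with paired
#' t-tests, and chi-square comparisons of count tables. Percentages are
#' rounded half-up to one decimal and means to two decimals, matching
#' report-style printing.
NULL

#' Percentage share, rounded half-up to one decimal
#'
#' The report-style share convention used throughout the analytics: e.g.
#' 156 of 272 is printed as 57.4 (percent).
#'
#' @param count,total Nonnegative counts (total > 0).
#' @return Numeric percentage with one decimal.
#' @export
pct_share <- function(count, total) {
  stopifnot(total > 0, all(count >= 0))
  round_half_up(100 * count / total, 1)
}

#' Summarize follow-up events by category
#'
#' Counts follow-up events in each of the three categories (regular /
#' abnormal_attention / compliance) with percentage shares, and breaks the
#' abnormal-attention events down by warning type. Shares are invariant
#' under permutation of the event log and sum to 100 up to rounding.
#'
#' @param events Event data.frame with columns event_type, category, detail.
#' @return List of class \code{followup_summary}: \code{by_category}
#'   (category, count, share), \code{warning_breakdown} (type, count,
#'   share within abnormal attention), \code{total}.
#' @export
summarize_followups <- function(events) {
  fu <- events[events$event_type == "followup", , drop = FALSE]
  total <- nrow(fu)
  counts <- vapply(FOLLOWUP_CATEGORIES,
                   function(cat) sum(fu$category == cat), 0L)
  share <- if (total > 0) pct_share(counts, total) else counts * 0
  by_category <- data.frame(category = FOLLOWUP_CATEGORIES,
                            count = as.integer(counts),
                            share = as.numeric(share),
                            stringsAsFactors = FALSE, row.names = NULL)
  abn <- fu[fu$category == "abnormal_attention", , drop = FALSE]
  wcounts <- vapply(WARNING_TYPES,
                    function(ty) sum(abn$detail == ty), 0L)
  wshare <- if (nrow(abn) > 0) pct_share(wcounts, nrow(abn)) else
    wcounts * 0
  warning_breakdown <- data.frame(type = WARNING_TYPES,
                                  count = as.integer(wcounts),
                                  share = as.numeric(wshare),
                                  stringsAsFactors = FALSE, row.names = NULL)
  structure(list(by_category = by_category,
                 warning_breakdown = warning_breakdown,
                 total = total),
            class = "followup_summary")
}

#' @export
print.followup_summary <- function(x, ...) {
  cat("<followup_summary>", x$total, "follow-up events\n")
  print(x$by_category, row.names = FALSE)
  if (sum(x$warning_breakdown$count) > 0) {
    cat("within abnormal attention:\n")
    print(x$warning_breakdown, row.names = FALSE)
  }
  invisible(x)
}

#' Mean follow-ups per patient
#'
#' Mean and standard deviation of follow-up events per patient over a given
#' patient subset; patients with zero events count. The mean is rounded
#' half-up to two decimals. A single patient yields sd 0.
#'
#' @param events Event data.frame (follow-up rows are counted).
#' @param patients Character vector of patient ids (nonempty).
#' @return List: mean, sd, n_patients, n_events.
#' @export
mean_followups_per_patient <- function(events, patients) {
  if (length(patients) == 0) stop("patient subset is empty", call. = FALSE)
  fu <- events[events$event_type == "followup" &
                 events$patient_id %in% patients, , drop = FALSE]
  counts <- vapply(patients, function(p) sum(fu$patient_id == p), 0L)
  s <- if (length(counts) > 1) stats::sd(counts) else 0
  list(mean = round_half_up(mean(counts), 2),
       sd = round_half_up(s, 2),
       n_patients = length(patients), n_events = sum(counts))
}

#' Classify a follow-up count into an intervention level
#'
#' More than 3 follow-up visits is high-intervention, exactly 3 is
#' medium-intervention, fewer than 3 is low-intervention. Total on the
#' nonnegative integers: exactly one label per count.
#'
#' @param count Nonnegative integer vector of follow-up visit counts.
#' @return Character vector "high" / "medium" / "low".
#' @export
classify_intervention_level <- function(count) {
  if (any(is.na(count)) || any(count < 0)) {
    stop("follow-up count must be nonnegative", call. = FALSE)
  }
  ifelse(count > 3, "high", ifelse(count == 3, "medium", "low"))
}

#' Monthly trend of a measurement kind over the management cycle
#'
#' Bins readings into 30-day months from each patient's cycle start (three
#' months partition the 90-day horizon), computes per-patient monthly means
#' and their across-patient average (primary; the pooled per-reading mean is
#' reported alongside), the month-1 minus month-3 delta, and a paired
#' two-tailed t-test of month 1 vs month 3 on patients present in both
#' months.
#'
#' @param measurements Measurement data.frame (needs patient_id, kind,
#'   value and either a \code{day} column, day 1..90, or timestamps).
#' @param kind Measurement kind to analyze (must be present).
#' @param patients Optional patient subset.
#' @param cycle_start Optional named Date vector of per-patient cycle
#'   starts; defaults to each patient's first record.
#' @return List of class \code{monthly_trend}: per-month means, delta
#'   (month1 - month3, positive = decline), t statistic, p value, n_paired.
#' @export
monthly_trend <- function(measurements, kind, patients = NULL,
                          cycle_start = NULL) {
  m <- measurements[measurements$kind == kind, , drop = FALSE]
  if (!is.null(patients)) m <- m[m$patient_id %in% patients, , drop = FALSE]
  if (nrow(m) == 0) stop("no records of kind ", kind, call. = FALSE)
  if (is.null(m$day)) {
    d <- as.Date(as_timestamp(m$timestamp))
    if (is.null(cycle_start)) {
      starts <- tapply(d, m$patient_id, min)
      m$day <- as.integer(d - as.Date(starts[m$patient_id],
                                      origin = "1970-01-01")) + 1L
    } else {
      m$day <- as.integer(d - cycle_start[m$patient_id]) + 1L
    }
  }
  m$month <- pmin(3L, (m$day - 1L) %/% 30L + 1L)
  if (length(unique(m$month)) < 2) {
    stop("need at least two months with data", call. = FALSE)
  }
  pp <- stats::aggregate(value ~ patient_id + month, data = m, FUN = mean)
  months <- data.frame(
    month = 1:3,
    mean_patient = vapply(1:3, function(mo) {
      v <- pp$value[pp$month == mo]
      if (length(v) > 0) mean(v) else NA_real_
    }, 0),
    mean_reading = vapply(1:3, function(mo) {
      v <- m$value[m$month == mo]
      if (length(v) > 0) mean(v) else NA_real_
    }, 0))
  m1 <- pp[pp$month == 1, c("patient_id", "value")]
  m3 <- pp[pp$month == 3, c("patient_id", "value")]
  paired <- merge(m1, m3, by = "patient_id", suffixes = c("_1", "_3"))
  delta <- if (nrow(paired) > 0) mean(paired$value_1 - paired$value_3)
  else NA_real_
  tstat <- NA_real_; pval <- NA_real_
  if (nrow(paired) > 1 && stats::sd(paired$value_1 - paired$value_3) > 0) {
    tt <- stats::t.test(paired$value_1, paired$value_3, paired = TRUE)
    tstat <- unname(tt$statistic); pval <- tt$p.value
  }
  structure(list(kind = kind, months = months, delta = delta,
                 delta_reading = months$mean_reading[1] -
                   months$mean_reading[3],
                 t = tstat, p = pval, n_paired = nrow(paired)),
            class = "monthly_trend")
}

#' @export
print.monthly_trend <- function(x, ...) {
  cat("<monthly_trend>", x$kind, ": per-patient monthly means",
      paste(round(x$months$mean_patient, 2), collapse = " / "),
      "| delta (m1 - m3)", round(x$delta, 2),
      "| paired t p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' Chi-square comparison of a contingency table
#'
#' Standard (uncorrected) chi-square test on a k x m table of nonnegative
#' integer counts; a table with fewer than two rows or columns, or with a
#' zero row/column margin, is malformed.
#'
#' @param table Matrix of nonnegative integer counts.
#' @return List: statistic, df, p_value.
#' @export
compare_counts <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}
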