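# Timing-distribution, fate-table, survival and hypothesis-test layer.
# Cells are classified by their worst misaligned chromosome
# (ensheathed > free > aligned) and followed to one of four fates: normal
# division, micronucleus formation, death, or other defects. P values are
# reported exactly, never binned into significance stars.

FATE_LEVELS <- c("normal", "micronucleus", "death", "other")
CLASS_LEVELS <- c("parental", "control", "aligned", "free", "ensheathed")

#' Build a validated table of per-cell records
#'
#' @param df data.frame with columns cell, class, fate and optional NEB,
#'   metaphase, anaphase times (minutes).
#' @return the validated data.frame, class `cell_records`.
#' @export
cell_records <- function(df) {
  stopifnot(all(c("cell", "class", "fate") %in% names(df)))
  bad <- setdiff(unique(df$class), CLASS_LEVELS)
  if (length(bad)) stopf("unknown class label(s): %s", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$fate), FATE_LEVELS)
  if (length(bad)) stopf("unknown fate label(s): %s", paste(bad, collapse = ", "))
  for (cols in list(c("NEB", "metaphase"), c("metaphase", "anaphase"), c("NEB", "anaphase"))) {
    if (all(cols %in% names(df))) {
      viol <- which(df[[cols[1]]] > df[[cols[2]]])
      if (length(viol)) stopf("record %s: %s > %s", df$cell[viol[1]], cols[1], cols[2])
    }
  }
  class(df) <- c("cell_records", "data.frame")
  df
}

#' Collapse per-chromosome classes to a cell-level class
#'
#' A cell with several misaligned chromosomes takes the highest class
#' (ensheathed > free > aligned).
#' @param classes character vector of chromosome classes in one cell.
#' @export
cell_class <- function(classes) {
  if ("ensheathed" %in% classes) "ensheathed"
  else if ("free" %in% classes) "free"
  else "aligned"
}

#' Cumulative timing distributions per class
#'
#' @param records a [cell_records()] data.frame with the needed timestamps.
#' @param interval "NEB-Meta", "Meta-Ana" or "NEB-Ana".
#' @return list per class: durations, ecdf, median; class `timing_ecdf`.
#' @export
cumulative_timing <- function(records, interval = c("NEB-Meta", "Meta-Ana", "NEB-Ana")) {
  interval <- match.arg(interval)
  cols <- switch(interval, "NEB-Meta" = c("NEB", "metaphase"),
                 "Meta-Ana" = c("metaphase", "anaphase"),
                 "NEB-Ana" = c("NEB", "anaphase"))
  stopifnot(all(cols %in% names(records)))
  keep <- stats::complete.cases(records[, cols])
  rec <- records[keep, , drop = FALSE]
  dur <- rec[[cols[2]]] - rec[[cols[1]]]
  neg <- which(dur < 0)
  if (length(neg)) stopf("record %s: negative %s duration", rec$cell[neg[1]], interval)
  out <- lapply(split(dur, rec$class), function(d)
    list(durations = d, ecdf = stats::ecdf(d), median = stats::median(d), n = length(d)))
  structure(list(by_class = out, interval = interval), class = "timing_ecdf")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Exact p value when both samples have at most 25 observations (and no
#' ties), asymptotic otherwise.
#' @param a,b numeric samples (each >= 2 values).
#' @return list: D, p, n.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stopf("both samples need >= 2 observations")
  exact <- length(a) <= 25 && length(b) <= 25
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = kt$p.value, n = c(length(a), length(b)))
}

#' Fisher's exact test (two-sided, no correction)
#'
#' Two-sided p by summation of hypergeometric probabilities no larger than
#' that of the observed table.
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stopf("need a 2x2 table")
  if (any(table < 0) || any(abs(table - round(table)) > 1e-9)) stopf("counts must be nonnegative integers")
  stats::fisher.test(round(table))$p.value
}

#' Wilcoxon rank-sum test (two-sided, tie-corrected)
#'
#' @param a,b numeric samples (each >= 1 value).
#' @return list: W, p.
#' @export
wilcoxon_rank <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  p <- wt$p.value
  if (is.nan(p)) p <- 1  # fully tied samples: no evidence against the null
  list(W = unname(wt$statistic), p = p)
}

#' Kaplan-Meier estimate of congression times
#'
#' Product-limit estimate for the time from the reference event to
#' congression of the last misaligned chromosome; cells reaching anaphase
#' without congression are censored.
#'
#' @param times event/censoring times (>= 0).
#' @param event_flags 1/TRUE = congression observed, 0/FALSE = censored.
#' @return class `km_curve`: data.frame (time, n_risk, n_event, n_censor,
#'   survival) plus the survfit object.
#' @export
km_congression <- function(times, event_flags) {
  stopifnot(length(times) == length(event_flags), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(event_flags)) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                      n_censor = fit$n.censor, survival = fit$surv)
  structure(list(curve = curve, median = unname(summary(fit)$table["median"]),
                 fit = fit), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median %s\n",
              nrow(x$curve), format(x$median)))
  invisible(x)
}

#' Class-by-fate summary table
#'
#' Counts and row percentages (1 decimal) of mitotic fates per metaphase
#' class, plus an optional rescue summary from a rescued flag.
#'
#' @param records a [cell_records()] data.frame (columns class, fate,
#'   optional rescued).
#' @return list: `counts` (class x fate), `percent`, `n` per class, and
#'   `rescue` (n, rescued, percent) when a rescued column is present.
#' @export
fate_summary <- function(records) {
  records <- cell_records(as.data.frame(records))
  counts <- table(factor(records$class, CLASS_LEVELS),
                  factor(records$fate, FATE_LEVELS))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  pct <- round(100 * prop.table(counts, 1), 1)
  out <- list(counts = unclass(counts), percent = unclass(pct),
              n = rowSums(counts))
  if ("rescued" %in% names(records)) {
    out$rescue <- list(n = nrow(records), rescued = sum(records$rescued),
                       percent = round(100 * mean(records$rescued), 1))
  }
  out
}
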