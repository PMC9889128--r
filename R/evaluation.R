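# Per-pathogen evaluation: contingency counts and precision/recall/F1 with
# micro and macro averaging, at citation-level (pmid, pathogen) granularity.

#' Contingency counts for one pathogen
#'
#' @param tp True positives.
#' @param gold_positives Number of gold-positive (pmid, pathogen) pairs
#'   ("Positives").
#' @param predicted_positives Number of predicted pairs ("FP + TP").
#' @return An `pm_eval_counts` list.
#' @export
eval_counts <- function(tp, gold_positives, predicted_positives) {
  if (any(c(tp, gold_positives, predicted_positives) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (tp > gold_positives || tp > predicted_positives) {
    stop("tp cannot exceed gold or predicted positives", call. = FALSE)
  }
  structure(list(tp = tp, gold_positives = gold_positives,
                 predicted_positives = predicted_positives),
            class = "pm_eval_counts")
}

#' Precision, recall and F1 from contingency counts
#'
#' `precision = tp / predicted_positives`, `recall = tp / gold_positives`,
#' `f1 = 2PR / (P + R)`. Any metric with a zero denominator is 0 by
#' convention. Values are kept at full precision; [round_metrics()] applies
#' the 4-decimal, half-away-from-zero reporting convention.
#'
#' @param counts An [eval_counts()].
#' @return List with `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "pm_eval_counts"))
  p <- if (counts$predicted_positives > 0) counts$tp / counts$predicted_positives else 0
  r <- if (counts$gold_positives > 0) counts$tp / counts$gold_positives else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

#' Round metrics for reporting
#'
#' @param metrics List with `precision`, `recall`, `f1`.
#' @param digits Decimal places (default 4).
#' @return The metrics rounded half-away-from-zero.
#' @export
round_metrics <- function(metrics, digits = 4L) {
  lapply(metrics, round_half_away, digits = digits)
}

#' Micro-averaged metrics
#'
#' Sums contingency counts across pathogens, then computes metrics once: an
#' overall average across all instances, dominated by frequent pathogens.
#'
#' @param counts_list Non-empty list of [eval_counts()].
#' @return Metrics list.
#' @export
micro_average <- function(counts_list) {
  if (!length(counts_list)) stop("empty counts list", call. = FALSE)
  ok <- vapply(counts_list, inherits, logical(1), what = "pm_eval_counts")
  stopifnot(all(ok))
  total <- eval_counts(
    tp = sum(vapply(counts_list, `[[`, numeric(1), "tp")),
    gold_positives = sum(vapply(counts_list, `[[`, numeric(1), "gold_positives")),
    predicted_positives = sum(vapply(counts_list, `[[`, numeric(1),
                                     "predicted_positives")))
  compute_metrics(total)
}

#' Macro-averaged metrics
#'
#' Computes metrics per pathogen, then takes the arithmetic mean of each
#' metric: every pathogen class weighs equally regardless of frequency.
#'
#' @inheritParams micro_average
#' @return Metrics list.
#' @export
macro_average <- function(counts_list) {
  if (!length(counts_list)) stop("empty counts list", call. = FALSE)
  per <- lapply(counts_list, compute_metrics)
  list(precision = mean(vapply(per, `[[`, numeric(1), "precision")),
       recall = mean(vapply(per, `[[`, numeric(1), "recall")),
       f1 = mean(vapply(per, `[[`, numeric(1), "f1")))
}

#' Count predictions against gold for one pathogen
#'
#' Both sets are sets of (pmid, pathogen_id) pairs: a pathogen counts once
#' per citation regardless of how many mentions it has, because the gold
#' labels derive from per-citation MeSH indexing.
#'
#' @param predicted,gold Data frames with columns `pmid` and `pathogen_id`
#'   (duplicates ignored).
#' @param pathogen_id The pathogen to restrict both sets to.
#' @return An [eval_counts()].
#' @export
count_predictions <- function(predicted, gold, pathogen_id) {
  pk <- unique(predicted$pmid[predicted$pathogen_id == pathogen_id])
  gk <- unique(gold$pmid[gold$pathogen_id == pathogen_id])
  eval_counts(tp = length(intersect(pk, gk)),
              gold_positives = length(gk),
              predicted_positives = length(pk))
}

#' Build a per-pathogen evaluation report
#'
#' @param predicted,gold Data frames of (pmid, pathogen_id) pairs.
#' @param pathogen_ids Pathogens to report on; defaults to the union seen in
#'   either set.
#' @return Data frame mirroring the standard report columns — `term`, `tp`,
#'   `positives`, `fp_tp`, `precision`, `recall`, `f1` (rounded to 4
#'   decimals) — with trailing `micro-average` and `macro-average` rows.
#' @export
evaluation_report <- function(predicted, gold, pathogen_ids = NULL) {
  if (is.null(pathogen_ids)) {
    pathogen_ids <- sort(unique(c(predicted$pathogen_id, gold$pathogen_id)))
  }
  if (!length(pathogen_ids)) stop("no pathogens to evaluate", call. = FALSE)
  counts <- lapply(pathogen_ids, function(pid) count_predictions(predicted, gold, pid))
  row_of <- function(term, cts, metrics) {
    m <- round_metrics(metrics)
    data.frame(term = term,
               tp = if (is.null(cts)) NA_real_ else cts$tp,
               positives = if (is.null(cts)) NA_real_ else cts$gold_positives,
               fp_tp = if (is.null(cts)) NA_real_ else cts$predicted_positives,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_along(pathogen_ids), function(i) {
    row_of(pathogen_ids[i], counts[[i]], compute_metrics(counts[[i]]))
  })
  rows <- c(rows,
            list(row_of("micro-average", NULL, micro_average(counts)),
                 row_of("macro-average", NULL, macro_average(counts))))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Write an evaluation report as TSV
#'
#' @param report Data frame from [evaluation_report()].
#' @param path File path.
#' @export
write_evaluation_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
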