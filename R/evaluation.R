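# Detection/ground-truth matching and the published-style metric
# accounting: frame-level TP/FP/TN, follicle-level recall, operator-focus
# correction, and a Table-1-style multi-phase report.
#
# Matching rule: a retained frame is a true positive when it contains at
# least one ground-truth click (half-open containment); a frame holding
# two follicles counts as two found follicles but one TP frame, and a
# follicle found by several frames counts once. True negatives are the
# remaining scanned windows (total - TP - FP).

#' Match retained detections against ground-truth points
#'
#' @param detections Detection tibble (post-NMS; columns `x, y, size`).
#' @param ground_truth Tibble of follicle points in the same frame
#'   (columns `x, y`).
#' @param total_windows Raw number of windows scanned by the detector
#'   (`attr(detections, "n_windows")` when omitted).
#' @return An object of class `match_result`: counts `tp_frames`,
#'   `fp_frames`, `found_follicles`, `real_follicles`, `total_windows`,
#'   `tn_windows`.
#' @export
match_detections <- function(detections, ground_truth,
                             total_windows = attr(detections, "n_windows")) {
  total_windows <- total_windows %||% nrow(detections)
  nd <- nrow(detections); np <- nrow(ground_truth)
  if (nd > 0 && np > 0) {
    contains <- outer(seq_len(nd), seq_len(np), function(i, j) {
      frame_contains(detections$x[i], detections$y[i], detections$size[i],
                     ground_truth$x[j], ground_truth$y[j])
    })
    tp_frames <- sum(rowSums(contains) > 0)
    found <- sum(colSums(contains) > 0)
  } else {
    tp_frames <- 0L
    found <- 0L
  }
  new_match_result(
    tp_frames = tp_frames, fp_frames = nd - tp_frames,
    found_follicles = found, real_follicles = np,
    total_windows = total_windows
  )
}

new_match_result <- function(tp_frames, fp_frames, found_follicles,
                             real_follicles, total_windows) {
  structure(
    list(tp_frames = as.integer(tp_frames),
         fp_frames = as.integer(fp_frames),
         found_follicles = as.integer(found_follicles),
         real_follicles = as.integer(real_follicles),
         total_windows = as.numeric(total_windows),
         tn_windows = as.numeric(total_windows) - tp_frames - fp_frames),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FP %d, TN %s of %s windows; %d/%d follicles found\n",
    x$tp_frames, x$fp_frames, format(x$tn_windows, big.mark = ","),
    format(x$total_windows, big.mark = ","), x$found_follicles,
    x$real_follicles))
  invisible(x)
}

#' Sum several match results into one
#'
#' Used to pool per-section matches into a whole-testing-set result.
#'
#' @param matches List of `match_result` objects.
#' @return One combined `match_result`.
#' @export
combine_match_results <- function(matches) {
  stopifnot(length(matches) > 0)
  new_match_result(
    tp_frames = sum(purrr::map_int(matches, "tp_frames")),
    fp_frames = sum(purrr::map_int(matches, "fp_frames")),
    found_follicles = sum(purrr::map_int(matches, "found_follicles")),
    real_follicles = sum(purrr::map_int(matches, "real_follicles")),
    total_windows = sum(purrr::map_dbl(matches, "total_windows"))
  )
}

#' Recall: correctly detected follicles over real follicles
#'
#' @param found_follicles,real_follicles Counts.
#' @return Exact fraction in `[0, 1]`.
#' @export
compute_recall <- function(found_follicles, real_follicles) {
  if (real_follicles <= 0) abort("recall undefined: no real follicles")
  found_follicles / real_follicles
}

#' Precision: true-positive frames over all positive frames
#'
#' @param tp_frames,fp_frames Counts.
#' @return Exact fraction in `[0, 1]`.
#' @export
compute_precision <- function(tp_frames, fp_frames) {
  if (tp_frames + fp_frames <= 0) {
    abort("precision undefined: no positive frames")
  }
  tp_frames / (tp_frames + fp_frames)
}

#' Evaluation report for one pipeline phase
#'
#' @param match A `match_result`.
#' @param phase One of `"after_training"`, `"after_hnm"`,
#'   `"after_operator_focus"`.
#' @param confirmed_missed Operator-validated false positives that are
#'   real follicles (non-zero only after the operator-focus correction).
#' @return An object of class `eval_report`; recall and precision are
#'   always recomputed from the counts, never stored independently.
#' @export
eval_report <- function(match, phase = c("after_training", "after_hnm",
                                         "after_operator_focus"),
                        confirmed_missed = 0L) {
  phase <- match.arg(phase)
  structure(
    list(phase = phase, match = match,
         confirmed_missed = as.integer(confirmed_missed)),
    class = "eval_report"
  )
}

report_metrics <- function(report) {
  m <- report$match
  list(
    recall = compute_recall(m$found_follicles, m$real_follicles),
    precision = compute_precision(m$tp_frames, m$fp_frames)
  )
}

#' @export
print.eval_report <- function(x, ...) {
  met <- report_metrics(x)
  cat(sprintf("<eval_report phase=%s> recall %.2f%%, precision %.2f%%\n",
              x$phase, as_pct(met$recall), as_pct(met$precision)))
  invisible(x)
}

#' Apply the operator-focus correction
#'
#' After an expert reviews the false positives, those confirmed to be real
#' follicles missed by the manual count move from FP to TP and are added
#' to both the found and the real follicle tallies; recall and precision
#' are then recomputed. The correction can only raise recall (for
#' `found <= real`) and strictly raises precision when `confirmed > 0`.
#'
#' @param report An [eval_report()].
#' @param confirmed_missed Number of reviewed FPs confirmed as real
#'   follicles (`<=` the report's FP count).
#' @return A new `eval_report` with phase `"after_operator_focus"`.
#' @export
apply_operator_correction <- function(report, confirmed_missed) {
  m <- report$match
  if (confirmed_missed < 0 || confirmed_missed > m$fp_frames) {
    abort(sprintf("confirmed_missed (%d) must lie in [0, FP = %d]",
                  confirmed_missed, m$fp_frames))
  }
  corrected <- new_match_result(
    tp_frames = m$tp_frames + confirmed_missed,
    fp_frames = m$fp_frames - confirmed_missed,
    found_follicles = m$found_follicles + confirmed_missed,
    real_follicles = m$real_follicles + confirmed_missed,
    total_windows = m$total_windows
  )
  eval_report(corrected, phase = "after_operator_focus",
              confirmed_missed = confirmed_missed)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  m <- x$match
  met <- report_metrics(x)
  tibble(
    phase = x$phase,
    total_windows = m$total_windows,
    tp_frames = m$tp_frames,
    fp_frames = m$fp_frames,
    tn_windows = m$tn_windows,
    found_follicles = m$found_follicles,
    real_follicles = m$real_follicles,
    confirmed_missed = x$confirmed_missed,
    recall = met$recall,
    precision = met$precision
  )
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  met <- report_metrics(x)
  tibble(phase = x$phase, recall_pct = as_pct(met$recall),
         precision_pct = as_pct(met$precision))
}

#' Multi-phase summary table of the evaluation process
#'
#' One column per phase, with the rows of the published-style accounting:
#' total scanned windows, FP count and rate, TN count and rate, precision,
#' recall, and the detected-follicle count. Percentages are rounded half
#' away from zero to two decimals.
#'
#' @param phases List of [eval_report()] objects (at least one).
#' @return Tibble with a `metric` column and one column per phase.
#' @export
build_table1_report <- function(phases) {
  stopifnot(length(phases) >= 1)
  cols <- purrr::map(phases, function(rep) {
    m <- rep$match
    pos <- m$tp_frames + m$fp_frames
    c(
      total_windows = m$total_windows,
      fp_frames = m$fp_frames,
      fp_pct = as_pct(m$fp_frames / m$total_windows),
      tn_windows = m$tn_windows,
      tn_pct = as_pct(m$tn_windows / m$total_windows),
      precision_pct = if (pos > 0) as_pct(compute_precision(m$tp_frames, m$fp_frames)) else NA_real_,
      recall_pct = if (m$real_follicles > 0) as_pct(compute_recall(m$found_follicles, m$real_follicles)) else NA_real_,
      found_follicles = m$found_follicles
    )
  })
  out <- tibble(metric = c("total_windows", "fp_frames", "fp_pct",
                           "tn_windows", "tn_pct", "precision_pct",
                           "recall_pct", "found_follicles"))
  for (i in seq_along(phases)) {
    out[[phases[[i]]$phase]] <- unname(cols[[i]])
  }
  out
}

#' Write the phase table as CSV and aligned text
#'
#' @param table1 Tibble from [build_table1_report()].
#' @param csv_path,txt_path Output paths (either may be `NULL`).
#' @return `table1`, invisibly.
#' @export
write_table1_report <- function(table1, csv_path = NULL, txt_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(table1, csv_path)
  if (!is.null(txt_path)) {
    txt <- utils::capture.output(print(as.data.frame(table1),
                                       row.names = FALSE))
    writeLines(txt, txt_path)
  }
  invisible(table1)
}
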