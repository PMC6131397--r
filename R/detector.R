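# Sliding-window detection: enumerate half-overlapping windows, score each
# with the patch classifier, threshold, and keep one frame per follicle by
# greedy non-maximum suppression.

#' Detection parameters
#'
#' @param window Square window side, px (the patch classifier's input
#'   size).
#' @param overlap_fraction Fraction of the window shared by successive
#'   windows; 0.5 means stride = window / 2, guaranteeing that no follicle
#'   is missed by falling across a window boundary.
#' @param threshold Probability cut in `[0, 1]`; kept deliberately low so
#'   recall stays high at the price of false positives, which the
#'   hard-negative-mining round then removes.
#' @param adjacency `"any_overlap"` (frames sharing at least one pixel are
#'   adjacent) or `"iou"` with `iou_threshold`.
#' @param iou_threshold IoU above which frames count as adjacent (only for
#'   `adjacency = "iou"`).
#' @param chunk_size Scoring batch size; has no effect on the results.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(window = 64, overlap_fraction = 0.5,
                             threshold = 0.15,
                             adjacency = c("any_overlap", "iou"),
                             iou_threshold = 0.1, chunk_size = 256) {
  adjacency <- match.arg(adjacency)
  assert_scalar_number(overlap_fraction, "overlap_fraction", 1e-9, 1 - 1e-9)
  assert_scalar_number(threshold, "threshold", 0, 1)
  stride <- max(1L, as.integer(round(window * (1 - overlap_fraction))))
  structure(
    list(window = as.integer(window), overlap_fraction = overlap_fraction,
         stride = stride, threshold = threshold, adjacency = adjacency,
         iou_threshold = iou_threshold, chunk_size = chunk_size),
    class = "detection_params"
  )
}

#' Enumerate sliding-window frames
#'
#' Row-major grid of window top-lefts at the configured stride; when the
#' grid does not reach the right or bottom edge, a final column/row is
#' added flush with that edge so every pixel is covered by at least one
#' window.
#'
#' @param width,height Image size, px.
#' @param params A [detection_params()].
#' @return Tibble `x, y, size` (0-based top-lefts, half-open frames).
#' @export
enumerate_windows <- function(width, height, params = detection_params()) {
  win <- params$window
  if (win > width || win > height) {
    abort(sprintf("window %d exceeds the %d x %d image", win, width, height))
  }
  starts <- function(extent) {
    s <- seq(0L, extent - win, by = params$stride)
    if (s[length(s)] != extent - win) s <- c(s, extent - win)
    as.integer(s)
  }
  xs <- starts(width); ys <- starts(height)
  tibble(x = rep(xs, times = length(ys)),
         y = rep(ys, each = length(xs)),
         size = win)
}

#' Score frames with the patch classifier
#'
#' @param model A `follicle_classifier`.
#' @param section A [section_image].
#' @param frames Tibble `x, y, size` from [enumerate_windows()].
#' @return Detection tibble: the frames plus a `probability` column, order
#'   preserved.
#' @export
score_windows <- function(model, section, frames) {
  px <- section$pixels
  if (nrow(frames) == 0) {
    return(tibble(x = integer(), y = integer(), size = integer(),
                  probability = numeric()))
  }
  crops <- purrr::map2(frames$x, frames$y, function(x, y) {
    px[(y + 1):(y + frames$size[1]), (x + 1):(x + frames$size[1]),
       drop = FALSE]
  })
  out <- frames
  out$probability <- predict_proba(model, crops)
  out
}

#' Threshold detections
#'
#' Keeps detections with `probability >= threshold`, order preserved.
#'
#' @param detections Detection tibble.
#' @param threshold Probability cut.
#' @return Filtered detection tibble.
#' @export
apply_threshold <- function(detections, threshold) {
  detections[detections$probability >= threshold, , drop = FALSE]
}

#' Greedy non-maximum suppression
#'
#' Half-overlapping windows produce several positive frames per follicle;
#' NMS repeatedly emits the highest-probability remaining detection and
#' discards every remaining detection adjacent to it, so only the frame
#' with the maximal follicle probability survives within each cluster of
#' adjacent positives. Ties are broken by (y, x) lexicographic order.
#'
#' @param detections Detection tibble (already thresholded).
#' @param params A [detection_params()] supplying the adjacency rule.
#' @return Detection tibble sorted by descending probability.
#' @export
non_max_suppression <- function(detections, params = detection_params()) {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  ord <- order(-detections$probability, detections$y, detections$x)
  d <- detections[ord, ]
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) == 0) break
    adj <- if (params$adjacency == "any_overlap") {
      frames_overlap(d$x[i], d$y[i], d$size[i],
                     d$x[cand], d$y[cand], d$size[cand])
    } else {
      frame_iou(d$x[i], d$y[i], d$size[i],
                d$x[cand], d$y[cand], d$size[cand]) > params$iou_threshold
    }
    alive[cand[adj]] <- FALSE
  }
  d[keep, , drop = FALSE]
}

#' Detect follicles in a section
#'
#' Composition of the full detection stage: enumerate half-overlapping
#' windows, score them with the classifier (in chunks, which cannot change
#' the results), threshold, and apply non-maximum suppression.
#'
#' @param model A trained `follicle_classifier`.
#' @param section A [section_image].
#' @param params A [detection_params()].
#' @return Detection tibble of retained frames (class
#'   `follicle_detections`), sorted by descending probability, with
#'   attributes `n_windows` (raw enumerated count) and `n_above_threshold`.
#' @export
detect_follicles <- function(model, section, params = detection_params()) {
  frames <- enumerate_windows(ncol(section$pixels), nrow(section$pixels),
                              params)
  scored_chunks <- purrr::map(
    split(seq_len(nrow(frames)),
          ceiling(seq_len(nrow(frames)) / params$chunk_size)),
    function(idx) score_windows(model, section, frames[idx, ]))
  scored <- dplyr::bind_rows(scored_chunks)
  kept <- non_max_suppression(apply_threshold(scored, params$threshold),
                              params)
  kept$slide_id <- rep(section$slide_id, nrow(kept))
  kept$section_id <- rep(section$section_id, nrow(kept))
  kept <- kept[, c("slide_id", "section_id", "x", "y", "size", "probability")]
  structure(kept,
            class = c("follicle_detections", class(kept)),
            n_windows = nrow(frames),
            n_above_threshold = sum(scored$probability >= params$threshold))
}

#' Plot detections over a section
#'
#' @param section A [section_image].
#' @param detections Detection tibble.
#' @param truth Optional annotation tibble in section coordinates.
#' @return A ggplot: section raster, detection squares, truth points.
#' @export
plot_detections <- function(section, detections, truth = NULL) {
  px <- section$pixels
  df <- tibble(
    x = rep(seq_len(ncol(px)) - 1, each = nrow(px)),
    y = rep(seq_len(nrow(px)) - 1, times = ncol(px)),
    value = as.numeric(px)
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(detections) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(detections),
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$size,
                   ymin = .data$y, ymax = .data$y + .data$size),
      colour = "red", fill = NA, linewidth = 0.4)
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = truth, ggplot2::aes(.data$x, .data$y),
      colour = "cyan", shape = 3, size = 1.5)
  }
  p
}
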