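# Section isolation: binarize the slide, find outer contours on a
# low-resolution mask, crop each ovarian section into its own image.

#' Binarize a grayscale slide
#'
#' Produces a tissue mask (tissue = 1 where the image is darker than the
#' threshold, background = 0). The default threshold is Otsu's, computed on
#' the image histogram; a fixed threshold may be supplied instead.
#'
#' @param slide A [slide_image] or a numeric pixel matrix in `[0, 1]`.
#' @param method `"otsu"` (parameter-free) or `"fixed"`.
#' @param fixed_threshold Intensity in `[0, 1]`, required for `"fixed"`.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
binarize <- function(slide, method = c("otsu", "fixed"),
                     fixed_threshold = NULL) {
  method <- match.arg(method)
  px <- if (inherits(slide, "slide_image")) slide$pixels else slide
  stopifnot(is.matrix(px))
  thr <- switch(method,
    otsu = EBImage::otsu(EBImage::Image(px), range = c(0, 1)),
    fixed = {
      if (is.null(fixed_threshold)) {
        abort("method = \"fixed\" requires `fixed_threshold`.")
      }
      assert_scalar_number(fixed_threshold, "fixed_threshold", 0, 1)
      fixed_threshold
    }
  )
  mask <- matrix(0L, nrow(px), ncol(px))
  mask[px < thr] <- 1L
  mask
}

#' Find bounding boxes of tissue sections in a binary mask
#'
#' Labels the connected tissue components of the mask (border-following
#' contour extraction and connected-component labelling are equivalent for
#' outer bounding boxes), drops components below `min_area`, expands each
#' box by `margin` pixels on every side (clamped to the mask bounds), and
#' merges boxes that overlap after expansion so a section is never split or
#' double-counted.
#'
#' @param mask Integer 0/1 matrix (tissue = 1).
#' @param min_area Minimum component area in pixels^2.
#' @param margin Expansion margin in pixels.
#' @return Tibble `x, y, w, h, area` (0-based top-left, half-open extent),
#'   sorted top-to-bottom then left-to-right.
#' @export
find_section_boxes <- function(mask, min_area = 0, margin = 0) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) return(tibble(x = integer(), y = integer(),
                                    w = integer(), h = integer(),
                                    area = integer()))
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  ids <- which(lab > 0)
  comp <- lab[ids]
  rows <- (ids - 1) %% nrow(lab) + 1
  cols <- (ids - 1) %/% nrow(lab) + 1
  area <- tabulate(comp)
  keep <- which(area >= min_area)
  if (length(keep) == 0) return(tibble(x = integer(), y = integer(),
                                       w = integer(), h = integer(),
                                       area = integer()))
  boxes <- lapply(keep, function(k) {
    sel <- comp == k
    r <- range(rows[sel]); c <- range(cols[sel])
    x0 <- max(0, c[1] - 1 - margin)
    y0 <- max(0, r[1] - 1 - margin)
    x1 <- min(ncol(mask), c[2] + margin)   # exclusive
    y1 <- min(nrow(mask), r[2] + margin)
    c(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
  })
  boxes <- do.call(rbind, boxes)
  boxes <- merge_overlapping_boxes(boxes)
  out <- as_tibble(as.data.frame(boxes))
  out$area <- out$w * out$h
  out <- out[order(out$y, out$x), ]
  out[] <- lapply(out, as.integer)
  out
}

# Merge boxes (matrix with columns x, y, w, h) that overlap into their
# union box; repeat until a fixed point.
merge_overlapping_boxes <- function(boxes) {
  repeat {
    n <- nrow(boxes)
    if (n <= 1) return(boxes)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        bi <- boxes[i, ]; bj <- boxes[j, ]
        if (bi["x"] < bj["x"] + bj["w"] && bj["x"] < bi["x"] + bi["w"] &&
            bi["y"] < bj["y"] + bj["h"] && bj["y"] < bi["y"] + bi["h"]) {
          x0 <- min(bi["x"], bj["x"]); y0 <- min(bi["y"], bj["y"])
          x1 <- max(bi["x"] + bi["w"], bj["x"] + bj["w"])
          y1 <- max(bi["y"] + bi["h"], bj["y"] + bj["h"])
          boxes[i, ] <- c(x0, y0, x1 - x0, y1 - y0)
          boxes <- boxes[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(boxes)
  }
}

#' Crop section boxes out of a slide
#'
#' @param slide A [slide_image].
#' @param boxes Tibble from [find_section_boxes()] (working-resolution frame).
#' @return List of [section_image]; `section_id` is the box rank.
#' @export
crop_sections <- function(slide, boxes) {
  px <- slide$pixels
  h <- nrow(px); w <- ncol(px)
  purrr::map(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    if (b$x < 0 || b$y < 0 || b$x + b$w > w || b$y + b$h > h) {
      abort(sprintf("section box %d exceeds slide bounds", i))
    }
    section_image(
      pixels = px[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w), drop = FALSE],
      offset_x = b$x, offset_y = b$y,
      section_id = i, slide_id = slide$slide_id
    )
  })
}

#' Map a full-resolution annotation into a section crop's frame
#'
#' Applies the slide's working scale factor to the click coordinates and
#' subtracts the crop offset. Returns the sentinel `"outside"` when the
#' rescaled point does not fall inside the crop.
#'
#' @param annotation One-row annotation tibble (or list with
#'   `slide_id, x, y`).
#' @param section A [section_image].
#' @param scale_factor Working/full resolution ratio of the slide the
#'   section was cropped from.
#' @return Named numeric vector `c(x, y)` in the section frame, or the
#'   character sentinel `"outside"`.
#' @export
to_section_coords <- function(annotation, section, scale_factor = 1) {
  if (!identical(as.character(annotation$slide_id), section$slide_id)) {
    abort(sprintf("annotation slide '%s' does not match section slide '%s'",
                  annotation$slide_id, section$slide_id))
  }
  sx <- round(annotation$x * scale_factor) - section$offset_x
  sy <- round(annotation$y * scale_factor) - section$offset_y
  if (sx < 0 || sy < 0 || sx >= ncol(section$pixels) ||
      sy >= nrow(section$pixels)) {
    return("outside")
  }
  c(x = sx, y = sy)
}

# Vectorised variant: all of a slide's annotations into one section's frame.
# Returns the in-crop subset with section-frame columns x, y.
annotations_in_section <- function(annotations, section, scale_factor = 1) {
  ann <- annotations[as.character(annotations$slide_id) == section$slide_id, ]
  if (nrow(ann) == 0) return(ann)
  sx <- round(ann$x * scale_factor) - section$offset_x
  sy <- round(ann$y * scale_factor) - section$offset_y
  inside <- sx >= 0 & sy >= 0 & sx < ncol(section$pixels) &
    sy < nrow(section$pixels)
  ann <- ann[inside, ]
  ann$x <- sx[inside]
  ann$y <- sy[inside]
  ann
}

#' Isolate ovarian sections from a slide
#'
#' End-to-end section isolation: binarize, contour the mask at a further
#' downsampled resolution for robustness and speed, rescale the boxes to
#' the working resolution, crop, and verify that no annotated follicle was
#' cropped out (a warning lists any orphan annotation).
#'
#' @param slide A [slide_image].
#' @param annotations Annotation tibble in the full-resolution frame
#'   (optional, used for the section-loss check).
#' @param extra_downsample Additional integer factor for contour detection.
#' @param min_area_frac Minimum section area as a fraction of slide area.
#' @param margin_frac Margin as a fraction of the box diagonal.
#' @param binarize_method Passed to [binarize()].
#' @param fixed_threshold Passed to [binarize()].
#' @return List of [section_image].
#' @export
isolate_sections <- function(slide, annotations = NULL, extra_downsample = 4,
                             min_area_frac = 0.005, margin_frac = 0.02,
                             binarize_method = "otsu",
                             fixed_threshold = NULL) {
  low <- block_downsample(slide$pixels, extra_downsample)
  mask <- binarize(low, method = binarize_method,
                   fixed_threshold = fixed_threshold)
  min_area <- min_area_frac * length(low)
  boxes <- find_section_boxes(mask, min_area = min_area, margin = 0)
  if (nrow(boxes) > 0) {
    # rescale to working resolution, then add the margin there
    boxes$x <- boxes$x * extra_downsample
    boxes$y <- boxes$y * extra_downsample
    boxes$w <- boxes$w * extra_downsample
    boxes$h <- boxes$h * extra_downsample
    margin <- ceiling(margin_frac * sqrt(boxes$w^2 + boxes$h^2))
    x1 <- pmin(ncol(slide$pixels), boxes$x + boxes$w + margin)
    y1 <- pmin(nrow(slide$pixels), boxes$y + boxes$h + margin)
    boxes$x <- pmax(0, boxes$x - margin)
    boxes$y <- pmax(0, boxes$y - margin)
    boxes$w <- x1 - boxes$x
    boxes$h <- y1 - boxes$y
    m <- merge_overlapping_boxes(as.matrix(boxes[, c("x", "y", "w", "h")]))
    boxes <- as_tibble(as.data.frame(m))
    boxes <- boxes[order(boxes$y, boxes$x), ]
  }
  sections <- crop_sections(slide, boxes)
  if (!is.null(annotations)) {
    ann <- annotations[as.character(annotations$slide_id) == slide$slide_id, ]
    if (nrow(ann) > 0) {
      covered <- rep(FALSE, nrow(ann))
      for (sec in sections) {
        sx <- round(ann$x * slide$scale_factor) - sec$offset_x
        sy <- round(ann$y * slide$scale_factor) - sec$offset_y
        covered <- covered | (sx >= 0 & sy >= 0 & sx < ncol(sec$pixels) &
                                sy < nrow(sec$pixels))
      }
      if (any(!covered)) {
        orphans <- ann[!covered, ]
        warn(sprintf(
          "section isolation cropped out %d annotation(s) on slide '%s': %s",
          nrow(orphans), slide$slide_id,
          paste(sprintf("(%g,%g)", orphans$x, orphans$y), collapse = " ")))
      }
    }
  }
  sections
}
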