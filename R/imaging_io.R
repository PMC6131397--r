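# Slide/annotation I/O: TIFF slides in, CSV point annotations in,
# PNG crops + overview images and CSV detection tables out.

FOLLICLE_CLASSES <- c("primordial", "primary", "secondary", "antral")

#' Slide image record
#'
#' Light container for a grayscale slide: a pixel matrix in `[0, 1]`
#' (row = y, column = x), the physical resolution, and the downsampling
#' state relative to the native scan.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param microns_per_pixel Physical size of one pixel side, in microns.
#' @param slide_id Character identifier of the slide.
#' @param scale_factor Ratio of current to full resolution (1 = native).
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, microns_per_pixel = 1, slide_id = "slide",
                        scale_factor = 1) {
  stopifnot(is.matrix(pixels))
  assert_scalar_number(microns_per_pixel, "microns_per_pixel", min = 1e-12)
  assert_scalar_number(scale_factor, "scale_factor", min = 1e-12, max = 1)
  structure(
    list(pixels = pixels, microns_per_pixel = microns_per_pixel,
         slide_id = as.character(slide_id), scale_factor = scale_factor),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image '%s'> %d x %d px, %.4g um/px, scale %.3g\n",
              x$slide_id, ncol(x$pixels), nrow(x$pixels),
              x$microns_per_pixel, x$scale_factor))
  invisible(x)
}

#' Section image record
#'
#' A crop of one ovarian section out of a slide, remembering where the crop
#' sits in the (working-resolution) slide frame.
#'
#' @param pixels Numeric matrix in `[0, 1]`.
#' @param offset_x,offset_y 0-based top-left position of the crop in the
#'   slide frame, in working-resolution pixels.
#' @param section_id Integer rank of the section within the slide.
#' @param slide_id Character identifier of the parent slide.
#' @return An object of class `section_image`.
#' @export
section_image <- function(pixels, offset_x = 0, offset_y = 0, section_id = 1L,
                          slide_id = "slide") {
  stopifnot(is.matrix(pixels), offset_x >= 0, offset_y >= 0)
  structure(
    list(pixels = pixels, offset_x = as.integer(offset_x),
         offset_y = as.integer(offset_y), section_id = as.integer(section_id),
         slide_id = as.character(slide_id)),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image '%s' #%d> %d x %d px at (%d, %d)\n",
              x$slide_id, x$section_id, ncol(x$pixels), nrow(x$pixels),
              x$offset_x, x$offset_y))
  invisible(x)
}

#' Read a slide image from TIFF
#'
#' Reads a single-plane TIFF (LZW-compressed or not), converts RGB to
#' grayscale with Rec. 601 luminance weights (0.299, 0.587, 0.114), and
#' optionally block-averages it down by an integer factor. The returned
#' `microns_per_pixel` and `scale_factor` account for the downsampling.
#'
#' @param path Path to a TIFF file.
#' @param downsample_factor Positive integer; 1 keeps the native grid.
#' @param microns_per_pixel Native resolution of the scan (microns/pixel).
#' @param slide_id Identifier; defaults to the file name without extension.
#' @param color_removal Convert RGB input to grayscale (default `TRUE`).
#' @return A [slide_image].
#' @export
read_slide <- function(path, downsample_factor = 1, microns_per_pixel = 1,
                       slide_id = NULL, color_removal = TRUE) {
  if (!file.exists(path)) abort(sprintf("slide file not found: %s", path))
  if (downsample_factor < 1 || downsample_factor != round(downsample_factor)) {
    abort("`downsample_factor` must be a positive integer.")
  }
  img <- tryCatch(
    tiff::readTIFF(path),
    error = function(e) abort(sprintf(
      "cannot decode TIFF '%s' (unsupported format or codec): %s",
      path, conditionMessage(e)))
  )
  if (length(dim(img)) == 3) {
    if (!color_removal) abort("RGB slide read with color_removal = FALSE")
    nc <- dim(img)[3]
    if (nc >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img <- block_downsample(img, downsample_factor)
  slide_image(
    pixels = img,
    microns_per_pixel = microns_per_pixel * downsample_factor,
    slide_id = slide_id %||% sub("\\.[^.]+$", "", basename(path)),
    scale_factor = 1 / downsample_factor
  )
}

#' Write a slide image to TIFF
#'
#' @param slide A [slide_image].
#' @param path Output path.
#' @param compression `"none"` or `"LZW"`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, compression = c("none", "LZW")) {
  compression <- match.arg(compression)
  tiff::writeTIFF(pmin(pmax(slide$pixels, 0), 1), path,
                  bits.per.sample = 8L, compression = compression)
  invisible(path)
}

#' Read point annotations from CSV
#'
#' Annotations are manual follicle clicks: one row per follicle with its
#' slide, its 0-based full-resolution pixel coordinates (x = column
#' rightward, y = row downward) and its Pedersen class.
#'
#' @param path CSV file with header `slide_id,x,y,follicle_class`.
#' @return A tibble with those four columns, row order preserved.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  ann <- readr::read_csv(path, col_types = readr::cols(
    slide_id = readr::col_character(),
    x = readr::col_double(),
    y = readr::col_double(),
    follicle_class = readr::col_character()
  ), progress = FALSE)
  prob <- readr::problems(ann)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed annotation row at line %d of %s: %s",
                  prob$row[1] + 1L, path, prob$expected[1]))
  }
  missing_cols <- setdiff(c("slide_id", "x", "y", "follicle_class"), names(ann))
  if (length(missing_cols) > 0) {
    abort(sprintf("annotation file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_annotations(ann, context = path)
  ann
}

validate_annotations <- function(ann, context = "annotations") {
  bad_class <- which(!ann$follicle_class %in% FOLLICLE_CLASSES)
  if (length(bad_class) > 0) {
    abort(sprintf(
      "unknown follicle class '%s' at line %d of %s (expected one of %s)",
      ann$follicle_class[bad_class[1]], bad_class[1] + 1L, context,
      paste(FOLLICLE_CLASSES, collapse = ", ")))
  }
  bad_xy <- which(ann$x < 0 | ann$y < 0 | !is.finite(ann$x) | !is.finite(ann$y))
  if (length(bad_xy) > 0) {
    abort(sprintf("negative or non-finite coordinate at line %d of %s",
                  bad_xy[1] + 1L, context))
  }
  invisible(ann)
}

#' Write point annotations to CSV
#'
#' @param annotations Tibble with columns `slide_id, x, y, follicle_class`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  readr::write_csv(annotations[, c("slide_id", "x", "y", "follicle_class")],
                   path)
  invisible(path)
}

#' Save detection crops and an annotated overview image
#'
#' Writes one PNG crop per retained detection plus one overview PNG of the
#' whole section with a square outline drawn around every detection — the
#' artefacts an operator reviews when auditing false positives.
#'
#' @param detections Detection tibble (columns `x, y, size, probability`).
#' @param section A [section_image].
#' @param out_dir Output directory (created if needed).
#' @param save_crops Write per-detection crops (default `TRUE`).
#' @return A list with `detections`, `crops_written`, `overview_written`,
#'   and `overview_path`.
#' @export
write_detection_report <- function(detections, section, out_dir,
                                   save_crops = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  px <- section$pixels
  h <- nrow(px); w <- ncol(px)
  crops_written <- 0L
  if (save_crops && nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      d <- detections[i, ]
      # clamp the crop window to the image bounds
      x0 <- max(0, min(d$x, w - d$size))
      y0 <- max(0, min(d$y, h - d$size))
      crop <- px[(y0 + 1):(y0 + d$size), (x0 + 1):(x0 + d$size), drop = FALSE]
      png::writePNG(crop, file.path(out_dir, sprintf(
        "crop_%s_s%02d_%05d.png", section$slide_id, section$section_id, i)))
      crops_written <- crops_written + 1L
    }
  }
  overview <- px
  if (nrow(detections) > 0) {
    for (i in seq_len(nrow(detections))) {
      d <- detections[i, ]
      r0 <- max(1, d$y + 1); r1 <- min(h, d$y + d$size)
      c0 <- max(1, d$x + 1); c1 <- min(w, d$x + d$size)
      overview[r0, c0:c1] <- 0
      overview[r1, c0:c1] <- 0
      overview[r0:r1, c0] <- 0
      overview[r0:r1, c1] <- 0
    }
  }
  overview_path <- file.path(out_dir, sprintf(
    "overview_%s_s%02d.png", section$slide_id, section$section_id))
  png::writePNG(overview, overview_path)
  list(detections = detections, crops_written = crops_written,
       overview_written = TRUE, overview_path = overview_path)
}

#' Write a detection table to CSV
#'
#' @param detections Detection tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections, path)
  invisible(path)
}
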