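# Balanced, augmented binary patch training set: positives centred on
# primordial-follicle clicks, negatives sampled away from any follicle.
#
# A patch set is a tibble with one row per patch:
#   pixels (list of frame_size x frame_size matrices), label
#   ("follicle"/"background"), slide_id, section_id, x, y (0-based centre
#   in the section frame), augmentation_tag.

new_patch_tibble <- function(pixels = list(), label = character(),
                             slide_id = character(), section_id = integer(),
                             x = numeric(), y = numeric(),
                             augmentation_tag = character()) {
  tibble(pixels = pixels, label = label, slide_id = slide_id,
         section_id = section_id, x = x, y = y,
         augmentation_tag = augmentation_tag)
}

#' Extract positive patches around follicle clicks
#'
#' One square patch per in-section annotation of a selected class, centred
#' on the click (top-left = click − frame_size/2). Patches reaching past
#' the section border are padded with the section's median intensity so
#' every frame keeps a constant size.
#'
#' @param section A [section_image].
#' @param annotations Annotation tibble already mapped to section
#'   coordinates (columns `x, y, follicle_class`; see
#'   [to_section_coords()]).
#' @param frame_size Even patch side length, px.
#' @param classes Follicle classes treated as positives.
#' @return Patch tibble (label `"follicle"`).
#' @export
extract_positive_patches <- function(section, annotations, frame_size = 64,
                                     classes = "primordial") {
  check_frame_size(frame_size, section)
  px <- section$pixels
  pad <- median(px)
  half <- frame_size / 2
  ann <- annotations[annotations$follicle_class %in% classes, , drop = FALSE]
  if (nrow(ann) == 0) return(new_patch_tibble())
  new_patch_tibble(
    pixels = purrr::map2(ann$x, ann$y, function(cx, cy) {
      crop_padded(px, cx - half, cy - half, frame_size, pad)
    }),
    label = rep("follicle", nrow(ann)),
    slide_id = rep(section$slide_id, nrow(ann)),
    section_id = rep(section$section_id, nrow(ann)),
    x = ann$x, y = ann$y,
    augmentation_tag = rep("original", nrow(ann))
  )
}

check_frame_size <- function(frame_size, section = NULL) {
  if (frame_size < 2 || frame_size %% 2 != 0) {
    abort("`frame_size` must be an even integer >= 2.")
  }
  if (!is.null(section) &&
      (frame_size > nrow(section$pixels) || frame_size > ncol(section$pixels))) {
    abort(sprintf("frame_size %d exceeds the %d x %d section", frame_size,
                  ncol(section$pixels), nrow(section$pixels)))
  }
  invisible(frame_size)
}

#' Sample negative background patches
#'
#' Draws `n` fully-in-section patches whose centres lie at least
#' `min_dist` pixels (Euclidean) from every annotation of any follicle
#' class. Sampling is rejection-based and deterministic for a fixed seed.
#'
#' @param section A [section_image].
#' @param annotations Annotations in section coordinates (any class).
#' @param frame_size Even patch side, px.
#' @param n Number of negatives to draw.
#' @param min_dist Minimum centre distance to any annotation, px.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget (default `60 * n`).
#' @return Patch tibble (label `"background"`).
#' @export
sample_negative_patches <- function(section, annotations, frame_size = 64,
                                    n = 10, min_dist = frame_size, seed = 1,
                                    max_tries = 60 * n) {
  check_frame_size(frame_size, section)
  stopifnot(n >= 0)
  if (n == 0) return(new_patch_tibble())
  px <- section$pixels
  h <- nrow(px); w <- ncol(px)
  half <- frame_size / 2
  ax <- annotations$x; ay <- annotations$y
  withr::with_seed(seed, {
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0
    while (length(xs) < n && tries < max_tries) {
      tries <- tries + 1
      cx <- floor(runif(1, half, w - half + 1))
      cy <- floor(runif(1, half, h - half + 1))
      if (length(ax) > 0 && min((ax - cx)^2 + (ay - cy)^2) < min_dist^2) next
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
    if (length(xs) < n) {
      abort(sprintf(
        "negative sampling exhausted: %d of %d patches placed after %d tries",
        length(xs), n, tries))
    }
    new_patch_tibble(
      pixels = purrr::map2(xs, ys, function(cx, cy) {
        px[(cy - half + 1):(cy + half), (cx - half + 1):(cx + half),
           drop = FALSE]
      }),
      label = rep("background", n),
      slide_id = rep(section$slide_id, n),
      section_id = rep(section$section_id, n),
      x = xs, y = ys,
      augmentation_tag = rep("original", n)
    )
  })
}

# --- geometric augmentation ----------------------------------------------

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_h <- function(m) m[, ncol(m):1, drop = FALSE]
flip_v <- function(m) m[nrow(m):1, , drop = FALSE]

#' Apply one geometric augmentation to a patch
#'
#' The op families mirror what makes sense for histology frames: right-angle
#' rotations, horizontal/vertical reversals, and small translations. A
#' translation re-crops the shifted frame from the parent section when one
#' is supplied, and otherwise pads with the patch median.
#'
#' @param patch One-row patch tibble.
#' @param op One of `"rot90"`, `"rot180"`, `"rot270"`, `"flip_h"`,
#'   `"flip_v"`, `"translate"`.
#' @param dx,dy Translation shift in px (for `op = "translate"`).
#' @param section Optional parent [section_image] for translation re-crops.
#' @param max_shift Maximum allowed `|dx|`, `|dy|`.
#' @return One-row patch tibble with the op recorded in `augmentation_tag`.
#' @export
augment_patch <- function(patch, op, dx = 0, dy = 0, section = NULL,
                          max_shift = round(0.1 * ncol(patch$pixels[[1]]))) {
  stopifnot(nrow(patch) == 1)
  m <- patch$pixels[[1]]
  size <- ncol(m)
  out <- patch
  if (op == "translate") {
    if (abs(dx) > max_shift || abs(dy) > max_shift) {
      abort(sprintf("translation (%d, %d) exceeds max_shift %d", dx, dy,
                    max_shift))
    }
    half <- size / 2
    if (!is.null(section)) {
      out$pixels[[1]] <- crop_padded(section$pixels,
                                     patch$x + dx - half, patch$y + dy - half,
                                     size, median(section$pixels))
    } else {
      shifted <- matrix(median(m), size, size)
      src_r <- (1:size) + dy
      src_c <- (1:size) + dx
      rin <- src_r >= 1 & src_r <= size
      cin <- src_c >= 1 & src_c <= size
      shifted[rin, cin] <- m[src_r[rin], src_c[cin], drop = FALSE]
      out$pixels[[1]] <- shifted
    }
    out$augmentation_tag <- sprintf("translate(%d,%d)", dx, dy)
  } else {
    out$pixels[[1]] <- switch(op,
      rot90 = rot90_cw(m),
      rot180 = rot90_cw(rot90_cw(m)),
      rot270 = rot90_cw(rot90_cw(rot90_cw(m))),
      flip_h = flip_h(m),
      flip_v = flip_v(m),
      abort(sprintf("unknown augmentation op '%s'", op))
    )
    out$augmentation_tag <- op
  }
  out
}

#' Augment a patch set with the default recipe
#'
#' Each input patch yields the original, its 7 non-identity dihedral
#' variants (rot90/180/270, both flips, and the two flipped rotations),
#' and two seeded random translations of at most a quarter of the frame.
#' The translation range is tied to the detector geometry: with
#' half-overlapping windows a follicle centre can sit up to stride/2 =
#' frame/4 away from the nearest window centre, and the classifier must
#' accept follicles across that whole offset range.
#'
#' @param patches Patch tibble.
#' @param section Optional parent [section_image] (translation re-crops).
#' @param seed Integer seed for the translation draws.
#' @param max_shift Maximum translation in px (default a quarter of the
#'   frame side).
#' @return Augmented patch tibble (10 rows per input row).
#' @export
augment_patches <- function(patches, section = NULL, seed = 1,
                            max_shift = NULL) {
  if (nrow(patches) == 0) return(patches)
  size <- ncol(patches$pixels[[1]])
  max_shift <- max_shift %||% round(0.25 * size)
  withr::with_seed(seed, {
    out <- purrr::map(seq_len(nrow(patches)), function(i) {
      p <- patches[i, ]
      shifted <- function() {
        augment_patch(p, "translate",
                      dx = sample(-max_shift:max_shift, 1),
                      dy = sample(-max_shift:max_shift, 1),
                      section = section, max_shift = max_shift)
      }
      # each dihedral variant acts on a freshly shifted re-crop, so the
      # set spans orientation x position jointly
      dihedral <- purrr::map(
        c("rot90", "rot180", "rot270", "flip_h", "flip_v"),
        function(op) {
          s <- shifted()
          out <- augment_patch(s, op)
          out$augmentation_tag <- paste0(op, "+", s$augmentation_tag)
          out
        })
      # the two remaining dihedral elements: transpose and anti-transpose
      tr <- shifted()
      tr2 <- augment_patch(augment_patch(tr, "rot90"), "flip_h")
      tr2$augmentation_tag <- paste0("rot90+flip_h+", tr$augmentation_tag)
      atr <- shifted()
      atr2 <- augment_patch(augment_patch(atr, "rot270"), "flip_h")
      atr2$augmentation_tag <- paste0("rot270+flip_h+", atr$augmentation_tag)
      shifts <- purrr::map(1:2, function(k) shifted())
      dplyr::bind_rows(c(list(p), dihedral, list(tr2, atr2), shifts))
    })
    dplyr::bind_rows(out)
  })
}

#' Balance negatives and split a patch set by ovary
#'
#' Splitting is by whole ovary, never by patch: the test set receives
#' every patch whose ovary is in `holdout_ovary_ids`; training negatives
#' are subsampled (seeded) to `ceiling(neg_pos_ratio * positives)`.
#'
#' @param positives,negatives Patch tibbles.
#' @param neg_pos_ratio Target negatives per positive in the training set.
#' @param holdout_ovary_ids Ovary ids held out for testing (may be empty).
#' @param seed Integer seed for the negative subsample.
#' @param ovary_of Named character vector mapping slide_id to ovary id;
#'   by default each slide is its own ovary.
#' @return List of two `patch_dataset` objects, `train` and `test`, each
#'   carrying `patches`, `positives`, `negatives`, `seed`.
#' @export
balance_and_split <- function(positives, negatives, neg_pos_ratio = 1,
                              holdout_ovary_ids = character(), seed = 1,
                              ovary_of = NULL) {
  all_slides <- unique(c(positives$slide_id, negatives$slide_id))
  if (is.null(ovary_of)) ovary_of <- setNames(all_slides, all_slides)
  unmapped <- setdiff(all_slides, names(ovary_of))
  if (length(unmapped) > 0) {
    abort(sprintf("slide(s) without an ovary mapping: %s",
                  paste(unmapped, collapse = ", ")))
  }
  missing_holdout <- setdiff(holdout_ovary_ids, unname(ovary_of))
  if (length(missing_holdout) > 0) {
    abort(sprintf("holdout ovary id(s) absent from the data: %s",
                  paste(missing_holdout, collapse = ", ")))
  }
  in_holdout <- function(p) unname(ovary_of[p$slide_id]) %in% holdout_ovary_ids
  test_pos <- positives[in_holdout(positives), ]
  test_neg <- negatives[in_holdout(negatives), ]
  train_pos <- positives[!in_holdout(positives), ]
  train_neg <- negatives[!in_holdout(negatives), ]
  if (nrow(train_pos) == 0) {
    abort("empty training set: every ovary with positives is held out")
  }
  n_keep <- min(nrow(train_neg), ceiling(neg_pos_ratio * nrow(train_pos)))
  train_neg <- withr::with_seed(seed,
    train_neg[sample(nrow(train_neg), n_keep), ])
  list(
    train = patch_dataset(dplyr::bind_rows(train_pos, train_neg), seed),
    test = patch_dataset(dplyr::bind_rows(test_pos, test_neg), seed)
  )
}

#' Patch dataset container
#'
#' @param patches Patch tibble.
#' @param seed Seed recorded for provenance.
#' @return Object of class `patch_dataset` with fields `patches`,
#'   `positives`, `negatives`, `seed`.
#' @export
patch_dataset <- function(patches, seed = NA_integer_) {
  structure(
    list(patches = patches,
         positives = sum(patches$label == "follicle"),
         negatives = sum(patches$label == "background"),
         seed = seed),
    class = "patch_dataset"
  )
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches (%d follicle, %d background)\n",
              nrow(x$patches), x$positives, x$negatives))
  invisible(x)
}
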