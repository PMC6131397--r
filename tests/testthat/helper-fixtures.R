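# Shared fixtures, built in code at test time.

# Small synthetic slide spec used across tests: fast to render, still has
# several follicles and distractors per section.
small_spec <- function(seed = 42, ...) {
  args <- list(slide_w = 512, slide_h = 512, n_sections = 2,
               follicles_per_section = c(3, 6),
               follicle_diameter = c(14, 22),
               distractors_per_section = c(5, 10),
               noise_sd = 6, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

# A trivially separable toy patch set: dark squares are "follicles",
# bright squares background (objects are darker than field, as on slides).
toy_separable_patches <- function(n_per_class = 10, size = 16, seed = 1) {
  withr::with_seed(seed, {
    dark <- purrr::map(seq_len(n_per_class), function(i) {
      matrix(runif(size * size, 0, 0.2), size, size)
    })
    bright <- purrr::map(seq_len(n_per_class), function(i) {
      matrix(runif(size * size, 0.8, 1), size, size)
    })
  })
  tibble::tibble(
    pixels = c(dark, bright),
    label = rep(c("follicle", "background"), each = n_per_class),
    slide_id = "toy", section_id = 1L,
    x = size / 2, y = size / 2, augmentation_tag = "original"
  )
}

# Tiny architecture on 16 px inputs: fast enough for training loops in tests.
toy_arch <- function(size = 16) {
  architecture_config(
    input_size = size,
    blocks = list(list(n_conv = 1, kernel = 3, filters = 4)),
    pool = 4, fc_units = 8, dropout_rate = 0, n_classes = 2
  )
}

# Seeded training run on the separable toy set, cached per session.
toy_env <- new.env(parent = emptyenv())
trained_toy_model <- function() {
  if (is.null(toy_env$model)) {
    m <- build_classifier(toy_arch(), seed = 7)
    toy_env$model <- train_classifier(
      m, toy_separable_patches(),
      training_config(batch_size = 5, epochs = 30, seed = 11))
  }
  toy_env$model
}

# One small rendered slide with sections and per-section truth, cached.
small_slide_env <- new.env(parent = emptyenv())
small_slide_fixture <- function() {
  if (is.null(small_slide_env$fix)) {
    gen <- generate_slide(small_spec(), "fix1")
    secs <- isolate_sections(gen$slide, gen$annotations)
    truth <- purrr::map(secs, function(sec) {
      follidetect:::annotations_in_section(gen$annotations, sec, 1)
    })
    small_slide_env$fix <- list(gen = gen, sections = secs, truth = truth)
  }
  small_slide_env$fix
}

# Uniform background section for negative-control tests.
blank_section <- function(size = 160, value = 230 / 255) {
  section_image(matrix(value, size, size), 0, 0, 1L, "blank")
}

# Construct a match_result directly from counts (e.g. published tallies).
new_match_result_for_test <- function(tp, fp, found, real, total) {
  follidetect:::new_match_result(
    tp_frames = tp, fp_frames = fp, found_follicles = found,
    real_follicles = real, total_windows = total)
}

# Independent BFS connected-component labelling (4-connectivity), used as
# the oracle for contour-box detection.
bfs_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (mask[i, j] == 1 && lab[i, j] == 0) {
        cur <- cur + 1L
        queue <- matrix(c(i, j), ncol = 2)
        lab[i, j] <- cur
        while (nrow(queue) > 0) {
          p <- queue[1, , drop = FALSE]
          queue <- queue[-1, , drop = FALSE]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            ni <- p[1] + d[1]; nj <- p[2] + d[2]
            if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
                mask[ni, nj] == 1 && lab[ni, nj] == 0) {
              lab[ni, nj] <- cur
              queue <- rbind(queue, c(ni, nj))
            }
          }
        }
      }
    }
  }
  lab
}

# Independent exhaustive greedy NMS oracle: rescan the remaining set at
# every step rather than using a precomputed order.
nms_oracle <- function(detections, window_overlap = TRUE, iou_t = 0.1) {
  remaining <- detections
  kept <- detections[0, ]
  while (nrow(remaining) > 0) {
    best <- NULL
    for (i in seq_len(nrow(remaining))) {
      if (is.null(best)) { best <- i; next }
      bi <- remaining[i, ]; bb <- remaining[best, ]
      if (bi$probability > bb$probability ||
          (bi$probability == bb$probability &&
           (bi$y < bb$y || (bi$y == bb$y && bi$x < bb$x)))) {
        best <- i
      }
    }
    b <- remaining[best, ]
    kept <- rbind(kept, b)
    keep_mask <- rep(TRUE, nrow(remaining))
    for (i in seq_len(nrow(remaining))) {
      bi <- remaining[i, ]
      adjacent <- if (window_overlap) {
        abs(bi$x - b$x) < b$size && abs(bi$y - b$y) < b$size
      } else {
        follidetect:::frame_iou(bi$x, bi$y, bi$size, b$x, b$y, b$size) > iou_t
      }
      if (adjacent) keep_mask[i] <- FALSE
    }
    remaining <- remaining[keep_mask, , drop = FALSE]
  }
  kept
}
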