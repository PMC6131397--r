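# Window enumeration, thresholding, greedy NMS and the composed detector.

test_that("window enumeration follows the half-overlap stride with edge flush", {
  p <- detection_params(window = 128, overlap_fraction = 0.5)
  w9 <- enumerate_windows(256, 256, p)
  expect_identical(nrow(w9), 9L)
  expect_identical(sort(unique(w9$x)), c(0L, 64L, 128L))
  expect_identical(sort(unique(w9$y)), c(0L, 64L, 128L))
  # row-major: y varies slowest
  expect_identical(w9$y, rep(c(0L, 64L, 128L), each = 3))

  one <- enumerate_windows(128, 128, p)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$x, one$y), c(0L, 0L))

  flush <- enumerate_windows(300, 128, p)
  expect_identical(sort(unique(flush$x)), c(0L, 64L, 128L, 172L))
  expect_identical(unique(flush$y), 0L)

  expect_error(enumerate_windows(100, 100, p), "exceeds")
})

test_that("enumerated windows cover the image; interior pixels fall in >= 4", {
  p <- detection_params(window = 64, overlap_fraction = 0.5)
  for (dims in list(c(256, 256), c(300, 200), c(131, 97))) {
    w <- dims[1]; h <- dims[2]
    fr <- enumerate_windows(w, h, p)
    cover <- matrix(0L, h, w)
    for (i in seq_len(nrow(fr))) {
      cover[(fr$y[i] + 1):(fr$y[i] + 64), (fr$x[i] + 1):(fr$x[i] + 64)] <-
        cover[(fr$y[i] + 1):(fr$y[i] + 64), (fr$x[i] + 1):(fr$x[i] + 64)] + 1L
    }
    expect_true(all(cover >= 1))
    interior <- cover[65:(h - 64), 65:(w - 64)]
    expect_true(all(interior >= 4))
  }
})

test_that("thresholding keeps order and is monotone", {
  withr::with_seed(5, det <- tibble::tibble(
    x = sample(0:200, 30), y = sample(0:200, 30), size = 32,
    probability = runif(30)))
  expect_identical(apply_threshold(det, 0), det)
  kept1 <- apply_threshold(det, 1.0)
  expect_identical(nrow(kept1), sum(det$probability == 1))
  n_prev <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    n <- nrow(apply_threshold(det, t))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # detections at a higher threshold are a subset of a lower one
  lo <- apply_threshold(det, 0.3); hi <- apply_threshold(det, 0.6)
  expect_true(all(paste(hi$x, hi$y) %in% paste(lo$x, lo$y)))
})

test_that("three mutually adjacent frames keep only the middle maximum", {
  det <- tibble::tibble(x = c(0, 32, 64), y = 0, size = 64,
                        probability = c(0.4, 0.9, 0.6))
  kept <- non_max_suppression(det, detection_params(window = 64))
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$x, 32)
  expect_identical(kept$probability, 0.9)
})

test_that("greedy NMS equals the exhaustive rescanning oracle", {
  p_any <- detection_params(window = 32)
  p_iou <- detection_params(window = 32, adjacency = "iou",
                            iou_threshold = 0.2)
  withr::with_seed(101, {
    for (case in 1:120) {
      n <- sample(0:12, 1)
      det <- tibble::tibble(
        x = sample(0:96, n, replace = TRUE),
        y = sample(0:96, n, replace = TRUE),
        size = 32,
        probability = round(runif(n), 2))   # rounding forces ties
      for (params in list(p_any, p_iou)) {
        mine <- non_max_suppression(det, params)
        oracle <- nms_oracle(det, params$adjacency == "any_overlap",
                             params$iou_threshold)
        expect_identical(as.data.frame(mine), as.data.frame(oracle))
        # idempotence
        expect_identical(as.data.frame(non_max_suppression(mine, params)),
                         as.data.frame(mine))
        # independence: no two kept frames adjacent; every suppressed frame
        # is adjacent to a kept one of >= probability
        if (nrow(mine) > 1) {
          for (i in seq_len(nrow(mine) - 1)) for (j in (i + 1):nrow(mine)) {
            adj <- if (params$adjacency == "any_overlap") {
              follidetect:::frames_overlap(mine$x[i], mine$y[i], 32,
                                           mine$x[j], mine$y[j], 32)
            } else {
              follidetect:::frame_iou(mine$x[i], mine$y[i], 32,
                                      mine$x[j], mine$y[j], 32) >
                params$iou_threshold
            }
            expect_false(adj)
          }
        }
        dropped <- dplyr::anti_join(det, as.data.frame(mine),
                                    by = c("x", "y", "size", "probability"))
        if (nrow(dropped) > 0 && nrow(mine) > 0) {
          for (i in seq_len(nrow(dropped))) {
            adj <- if (params$adjacency == "any_overlap") {
              follidetect:::frames_overlap(dropped$x[i], dropped$y[i], 32,
                                           mine$x, mine$y, 32)
            } else {
              follidetect:::frame_iou(dropped$x[i], dropped$y[i], 32,
                                      mine$x, mine$y, 32) > params$iou_threshold
            }
            expect_true(any(adj & mine$probability >= dropped$probability[i]))
          }
        }
      }
    }
  })
})

test_that("score_windows preserves order and count", {
  m <- trained_toy_model()
  sec <- blank_section(48)
  fr <- enumerate_windows(48, 48, detection_params(window = 16))
  det <- score_windows(m, sec, fr)
  expect_identical(nrow(det), nrow(fr))
  expect_identical(det$x, fr$x)
  dup <- score_windows(m, sec, fr[c(1, 1), ])
  expect_identical(dup$probability[1], dup$probability[2])
  empty <- score_windows(m, sec, fr[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("detect_follicles composes the stages and reports window bookkeeping", {
  m <- trained_toy_model()
  # blank bright section: a model trained on bright-negative patches stays
  # silent
  det0 <- detect_follicles(m, blank_section(64, value = 0.9),
                           detection_params(window = 16, threshold = 0.5))
  expect_identical(nrow(det0), 0L)
  expect_identical(attr(det0, "n_windows"),
                   nrow(enumerate_windows(64, 64,
                                          detection_params(window = 16))))

  # one dark 'object' on the bright field is found exactly once after NMS
  px <- matrix(0.9, 64, 64)
  px[25:40, 25:40] <- 0.05
  sec <- section_image(px, 0, 0, 1L, "toy")
  det1 <- detect_follicles(m, sec,
                           detection_params(window = 16, threshold = 0.5))
  expect_identical(nrow(det1), 1L)
  expect_true(det1$x < 40 && det1$x + 16 > 25)

  # chunking cannot change the result
  det_chunked <- detect_follicles(
    m, sec, detection_params(window = 16, threshold = 0.5, chunk_size = 7))
  expect_identical(as.data.frame(det1), as.data.frame(det_chunked))
})
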