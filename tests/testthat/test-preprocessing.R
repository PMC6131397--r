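# Binarization, contour boxes, cropping, and coordinate mapping.

test_that("otsu binarization matches an exhaustive between-class-variance search", {
  withr::with_seed(3, {
    img <- matrix(runif(80 * 80, 0.75, 0.95), 80, 80)   # bright field
    disc_r <- 18
    for (i in 1:80) for (j in 1:80) {
      if ((i - 40)^2 + (j - 40)^2 <= disc_r^2) img[i, j] <- runif(1, 0.2, 0.4)
    }
  })
  mask <- binarize(img, method = "otsu")

  # oracle: exhaustive search over 256 candidate thresholds maximising
  # between-class variance
  counts <- tabulate(findInterval(img, seq(0, 1, length.out = 257),
                                  rightmost.closed = TRUE), 256)
  p <- counts / sum(counts)
  mids <- (seq_len(256) - 0.5) / 256
  best_t <- NA; best_v <- -1
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- k / 256 }
  }
  oracle_mask <- matrix(as.integer(img < best_t), 80, 80)
  # agreement within a 1-px boundary band: allow a small count of
  # disagreeing pixels relative to the disc circumference
  expect_lt(sum(mask != oracle_mask), 2 * pi * disc_r)
  inside <- sum(mask[(40 - 10):(40 + 10), (40 - 10):(40 + 10)])
  expect_identical(inside, 441L)          # the disc interior is tissue
  expect_identical(sum(mask[1:10, 1:10]), 0L)
})

test_that("uniform, inverted and fixed-threshold cases behave by definition", {
  bright <- matrix(0.9, 20, 20)
  expect_identical(sum(binarize(bright, "fixed", fixed_threshold = 0.5)), 0L)
  img <- matrix(0.9, 20, 20); img[5:10, 5:10] <- 0.1
  m1 <- binarize(img, "fixed", fixed_threshold = 0.5)
  m2 <- binarize(1 - img, "fixed", fixed_threshold = 0.5)
  expect_identical(m1 + m2, matrix(1L, 20, 20))  # complement masks
  expect_error(binarize(img, "fixed"), "fixed_threshold")
})

test_that("find_section_boxes agrees with a BFS component-labelling oracle", {
  withr::with_seed(9, {
    mask <- matrix(0L, 120, 160)
    centers <- list(c(30, 30), c(30, 120), c(90, 70))
    radii <- c(14, 11, 17)
    for (k in 1:3) {
      for (i in 1:120) for (j in 1:160) {
        if ((i - centers[[k]][1])^2 + (j - centers[[k]][2])^2 <= radii[k]^2) {
          mask[i, j] <- 1L
        }
      }
    }
  })
  boxes <- find_section_boxes(mask, min_area = 50)
  lab <- bfs_label(mask)
  expect_identical(nrow(boxes), max(lab))
  for (k in seq_len(max(lab))) {
    ids <- which(lab == k, arr.ind = TRUE)
    ox <- range(ids[, 2]); oy <- range(ids[, 1])
    hit <- which(boxes$x == ox[1] - 1 & boxes$y == oy[1] - 1 &
                   boxes$w == diff(ox) + 1 & boxes$h == diff(oy) + 1)
    expect_length(hit, 1)
  }
  # sorted top-to-bottom then left-to-right
  expect_true(!is.unsorted(boxes$y))

  # filter rule and empty input
  expect_identical(nrow(find_section_boxes(mask, min_area = 1e6)), 0L)
  expect_identical(nrow(find_section_boxes(matrix(0L, 10, 10))), 0L)
})

test_that("overlapping boxes after margin expansion merge into their union", {
  mask <- matrix(0L, 40, 40)
  mask[5:15, 5:15] <- 1L
  mask[5:15, 18:28] <- 1L    # 2 px apart: margin 3 makes them overlap
  merged <- find_section_boxes(mask, min_area = 10, margin = 3)
  expect_identical(nrow(merged), 1L)
  expect_gte(merged$w, 24)
  separate <- find_section_boxes(mask, min_area = 10, margin = 0)
  expect_identical(nrow(separate), 2L)
})

test_that("crop_sections preserves pixels, offsets and degenerate boxes", {
  withr::with_seed(2, px <- matrix(runif(50 * 60), 50, 60))
  slide <- slide_image(px, slide_id = "s")
  whole <- crop_sections(slide, tibble::tibble(x = 0, y = 0, w = 60, h = 50))
  expect_identical(whole[[1]]$pixels, px)
  expect_identical(c(whole[[1]]$offset_x, whole[[1]]$offset_y), c(0L, 0L))

  boxes <- tibble::tibble(x = c(5, 30), y = c(10, 0), w = c(10, 20),
                          h = c(15, 25))
  crops <- crop_sections(slide, boxes)
  expect_equal(sum(crops[[1]]$pixels), sum(px[11:25, 6:15]))
  expect_equal(sum(crops[[2]]$pixels), sum(px[1:25, 31:50]))

  one <- crop_sections(slide, tibble::tibble(x = 3, y = 4, w = 1, h = 1))
  expect_identical(dim(one[[1]]$pixels), c(1L, 1L))
  expect_error(
    crop_sections(slide, tibble::tibble(x = 55, y = 0, w = 10, h = 10)),
    "bounds")
})

test_that("to_section_coords maps clicks and flags outsiders", {
  sec <- section_image(matrix(0, 50, 50), offset_x = 10, offset_y = 10,
                       section_id = 1, slide_id = "s1")
  corner <- to_section_coords(list(slide_id = "s1", x = 10, y = 10), sec, 1)
  expect_equal(corner, c(x = 0, y = 0))
  expect_identical(
    to_section_coords(list(slide_id = "s1", x = 500, y = 2), sec, 1),
    "outside")
  half <- to_section_coords(list(slide_id = "s1", x = 100, y = 40), sec, 0.5)
  expect_equal(half, c(x = 40, y = 10))
  expect_error(
    to_section_coords(list(slide_id = "other", x = 1, y = 1), sec, 1),
    "does not match")
})

test_that("section isolation keeps every annotated follicle and warns on loss", {
  fix <- small_slide_fixture()
  expect_identical(sum(purrr::map_int(fix$truth, nrow)),
                   nrow(fix$gen$annotations))
  # a fake annotation in empty background space is reported as cropped out
  bad <- dplyr::bind_rows(
    fix$gen$annotations,
    tibble::tibble(slide_id = "fix1", x = 2, y = 2,
                   follicle_class = "primordial"))
  expect_warning(isolate_sections(fix$gen$slide, bad), "cropped out 1")
})
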