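# Patch extraction, negative sampling, augmentation group properties,
# balancing and the by-ovary split.

make_section <- function(size = 100, seed = 4) {
  withr::with_seed(seed, {
    section_image(matrix(runif(size * size, 0.5, 0.7), size, size),
                  0, 0, 1L, "s1")
  })
}

test_that("positive patches are centred on clicks and padded at borders", {
  sec <- make_section(100)
  ann <- tibble::tibble(x = c(50, 5, 70), y = c(50, 50, 20),
                        follicle_class = c("primordial", "primordial",
                                           "secondary"))
  pos <- extract_positive_patches(sec, ann, frame_size = 64,
                                  classes = "primordial")
  expect_identical(nrow(pos), 2L)     # the secondary follicle is excluded
  expect_true(all(pos$label == "follicle"))
  # centre patch reproduces the section sub-grid exactly
  expect_identical(pos$pixels[[1]], sec$pixels[19:82, 19:82])
  # border patch is padded on the left with the section median, full size
  expect_identical(dim(pos$pixels[[2]]), c(64L, 64L))
  expect_identical(unique(as.numeric(pos$pixels[[2]][, 1:27])),
                   median(sec$pixels))
  # every positive contains its generating click
  expect_identical(pos$pixels[[2]][, 28:64], sec$pixels[19:82, 1:37])

  expect_error(extract_positive_patches(sec, ann, frame_size = 128),
               "exceeds")
  expect_error(extract_positive_patches(sec, ann, frame_size = 63), "even")
})

test_that("negative sampling respects min_dist, the seed and the feasibility contract", {
  sec <- make_section(120)
  ann <- tibble::tibble(x = 60, y = 60, follicle_class = "primary")
  expect_identical(nrow(sample_negative_patches(sec, ann, 32, n = 0)), 0L)

  n1 <- sample_negative_patches(sec, ann, 32, n = 15, min_dist = 40, seed = 9)
  n2 <- sample_negative_patches(sec, ann, 32, n = 15, min_dist = 40, seed = 9)
  expect_identical(n1$x, n2$x)
  expect_identical(n1$y, n2$y)
  expect_true(all(sqrt((n1$x - 60)^2 + (n1$y - 60)^2) >= 40))
  expect_true(all(n1$label == "background"))
  # all patches fully inside the section (no padding for negatives)
  expect_true(all(n1$x - 16 >= 0 & n1$x + 16 <= 120))

  n3 <- sample_negative_patches(sec, ann, 32, n = 15, min_dist = 40, seed = 5)
  expect_false(identical(n1$x, n3$x))

  # annotations covering every valid centre make sampling impossible
  expect_error(
    sample_negative_patches(sec, ann, 32, n = 5, min_dist = 400, seed = 1),
    "0 of 5")
})

test_that("dihedral augmentations form the expected group actions", {
  sec <- make_section(80)
  p <- extract_positive_patches(
    sec, tibble::tibble(x = 40, y = 40, follicle_class = "primordial"), 32)

  rot180_twice <- augment_patch(augment_patch(p, "rot180"), "rot180")
  expect_identical(rot180_twice$pixels[[1]], p$pixels[[1]])
  fh_twice <- augment_patch(augment_patch(p, "flip_h"), "flip_h")
  expect_identical(fh_twice$pixels[[1]], p$pixels[[1]])
  fv_twice <- augment_patch(augment_patch(p, "flip_v"), "flip_v")
  expect_identical(fv_twice$pixels[[1]], p$pixels[[1]])
  r4 <- p
  for (k in 1:4) r4 <- augment_patch(r4, "rot90")
  expect_identical(r4$pixels[[1]], p$pixels[[1]])
  # rot90 composed twice equals rot180
  r2 <- augment_patch(augment_patch(p, "rot90"), "rot90")
  expect_identical(r2$pixels[[1]],
                   augment_patch(p, "rot180")$pixels[[1]])
  # label and size never change
  aug <- augment_patches(p, section = sec, seed = 2)
  expect_identical(nrow(aug), 10L)
  expect_true(all(aug$label == "follicle"))
  expect_true(all(purrr::map_int(aug$pixels, nrow) == 32L))
  expect_identical(dplyr::n_distinct(aug$augmentation_tag), 10L)
})

test_that("translation re-crops from the parent section and validates max_shift", {
  sec <- make_section(80)
  p <- extract_positive_patches(
    sec, tibble::tibble(x = 40, y = 40, follicle_class = "primordial"), 32)
  tr <- augment_patch(p, "translate", dx = 3, dy = -2, section = sec)
  # shifting the window by (3, -2) means top-left moves to (27, 22)
  expect_identical(tr$pixels[[1]], sec$pixels[23:54, 28:59])
  expect_identical(tr$augmentation_tag, "translate(3,-2)")
  expect_error(augment_patch(p, "translate", dx = 10, dy = 0, section = sec),
               "max_shift")
})

test_that("augmented datasets rebuild bit-identically for a fixed seed", {
  fix <- small_slide_fixture()
  sec <- fix$sections[[1]]
  ann <- fix$truth[[1]]
  pos <- extract_positive_patches(sec, ann, 48)
  a1 <- augment_patches(pos, sec, seed = 33)
  a2 <- augment_patches(pos, sec, seed = 33)
  expect_identical(a1$pixels, a2$pixels)
})

test_that("balance_and_split balances negatives and splits by ovary", {
  mk <- function(n, label, slide) tibble::tibble(
    pixels = purrr::map(seq_len(n), ~matrix(0, 4, 4)),
    label = label, slide_id = slide, section_id = 1L,
    x = seq_len(n), y = seq_len(n), augmentation_tag = "original")
  pos <- dplyr::bind_rows(mk(60, "follicle", "a1"), mk(40, "follicle", "b1"))
  neg <- dplyr::bind_rows(mk(600, "background", "a1"),
                          mk(400, "background", "b1"))
  ovary_of <- c(a1 = "A", b1 = "B")

  # ratio 1, no holdout: train keeps all 100 positives + 100 negatives
  sp <- balance_and_split(pos, neg, neg_pos_ratio = 1, seed = 3,
                          ovary_of = ovary_of)
  expect_identical(sp$train$positives, 100L)
  expect_identical(sp$train$negatives, 100L)
  expect_identical(nrow(sp$test$patches), 0L)

  # holdout ovary B: its patches all land in test, none in train
  sp2 <- balance_and_split(pos, neg, neg_pos_ratio = 1,
                           holdout_ovary_ids = "B", seed = 3,
                           ovary_of = ovary_of)
  expect_identical(sort(unique(sp2$test$patches$slide_id)), "b1")
  expect_identical(sp2$test$positives, 40L)
  expect_identical(unique(sp2$train$patches$slide_id), "a1")
  expect_identical(sp2$train$negatives, 60L)

  # determinism of the seeded subsample
  sp3 <- balance_and_split(pos, neg, neg_pos_ratio = 1, seed = 3,
                           ovary_of = ovary_of)
  expect_identical(sp$train$patches$x, sp3$train$patches$x)

  expect_error(
    balance_and_split(pos, neg, holdout_ovary_ids = c("A", "B"),
                      ovary_of = ovary_of),
    "empty training set")
  expect_error(
    balance_and_split(pos, neg, holdout_ovary_ids = "Z", ovary_of = ovary_of),
    "absent")
})
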