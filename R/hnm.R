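# Hard negative mining: run the detector over a dedicated mining slide
# set, harvest retained frames that contain no ground-truth follicle as
# forced negatives, rebalance, and continue training.

#' Mine hard negatives from a mining slide set
#'
#' Runs the detector on every mining section; each retained detection
#' whose frame contains no annotation point of any follicle class becomes
#' a background patch tagged `"hnm"`.
#'
#' @param model A trained `follicle_classifier`.
#' @param mining_sections List of `list(section = section_image,
#'   annotations = tibble)` pairs with annotations already in section
#'   coordinates; must be disjoint from the test ovaries.
#' @param params A [detection_params()].
#' @return An object of class `mining_result`: `mined_patches` (patch
#'   tibble), `source_counts` (tibble `slide_id, n_fp`), `rounds`.
#' @export
mine_hard_negatives <- function(model, mining_sections,
                                params = detection_params()) {
  if (length(mining_sections) == 0) {
    abort("mining set is empty: supply at least one section")
  }
  mined <- list()
  counts <- list()
  for (item in mining_sections) {
    section <- item$section
    ann <- item$annotations
    det <- detect_follicles(model, section, params)
    if (nrow(det) > 0) {
      is_fp <- purrr::map_lgl(seq_len(nrow(det)), function(i) {
        !any(frame_contains(det$x[i], det$y[i], det$size[i], ann$x, ann$y))
      })
      fp <- det[is_fp, , drop = FALSE]
    } else {
      fp <- det
    }
    counts[[length(counts) + 1]] <- tibble(slide_id = section$slide_id,
                                           section_id = section$section_id,
                                           n_fp = nrow(fp))
    if (nrow(fp) > 0) {
      px <- section$pixels
      mined[[length(mined) + 1]] <- new_patch_tibble(
        pixels = purrr::map2(fp$x, fp$y, function(x, y) {
          px[(y + 1):(y + fp$size[1]), (x + 1):(x + fp$size[1]),
             drop = FALSE]
        }),
        label = rep("background", nrow(fp)),
        slide_id = rep(section$slide_id, nrow(fp)),
        section_id = rep(section$section_id, nrow(fp)),
        x = fp$x + fp$size / 2, y = fp$y + fp$size / 2,
        augmentation_tag = rep("hnm", nrow(fp))
      )
    }
  }
  structure(
    list(
      mined_patches = if (length(mined)) dplyr::bind_rows(mined)
                      else new_patch_tibble(),
      source_counts = dplyr::bind_rows(counts),
      rounds = 1L
    ),
    class = "mining_result"
  )
}

#' @export
print.mining_result <- function(x, ...) {
  cat(sprintf("<mining_result> %d hard negatives from %d section(s)\n",
              nrow(x$mined_patches), nrow(x$source_counts)))
  invisible(x)
}

#' Retrain with mined hard negatives
#'
#' Builds the retraining set as all positives, all mined negatives, and a
#' seeded subsample of the original negatives filling the balance budget
#' `ceiling(neg_pos_ratio * positives)` (mined negatives are kept in full;
#' if they alone exceed the budget a warning is raised and every original
#' negative is dropped). Training then continues from the input model's
#' weights.
#'
#' @param model The phase-I `follicle_classifier`.
#' @param base_data The original `patch_dataset` (or patch tibble).
#' @param mined A `mining_result`.
#' @param cfg A [training_config()] for the continuation epochs.
#' @param neg_pos_ratio Negatives-per-positive budget.
#' @return The retrained `follicle_classifier`.
#' @export
retrain_with_hard_negatives <- function(model, base_data, mined,
                                        cfg = training_config(),
                                        neg_pos_ratio = 1) {
  patches <- patches_of(base_data)
  pos <- patches[patches$label == "follicle", ]
  neg <- patches[patches$label == "background", ]
  if (nrow(pos) == 0) abort("base dataset has no positives")
  budget <- ceiling(neg_pos_ratio * nrow(pos))
  n_mined <- nrow(mined$mined_patches)
  if (n_mined > budget) {
    warn(sprintf(
      "%d mined negatives exceed the balance budget of %d; keeping all mined patches and dropping every original negative",
      n_mined, budget))
    n_orig <- 0L
  } else {
    n_orig <- min(nrow(neg), budget - n_mined)
  }
  neg_keep <- withr::with_seed(cfg$seed, neg[sample(nrow(neg), n_orig), ])
  data2 <- patch_dataset(
    dplyr::bind_rows(pos, mined$mined_patches, neg_keep), cfg$seed)
  train_classifier(model, data2, cfg)
}
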