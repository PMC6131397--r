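# End-to-end orchestration: synthesize (or load) a slide corpus,
# preprocess, build the patch dataset, train, mine hard negatives and
# retrain, detect on the held-out test slides, and report Table-1-style
# metrics. One master seed fans out deterministically to per-stage seeds.

#' Default pipeline configuration
#'
#' Nested list of every stage's tunables; [run_pipeline()] merges a user
#' configuration over these defaults and rejects unknown keys.
#'
#' @return Named nested list.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = NULL,
    synthesize = TRUE,
    corpus = list(
      n_train_slides = 4, n_mine_slides = 1, n_test_slides = 2,
      slide_w = 1024, slide_h = 1024, n_sections = 4,
      follicles_per_section = c(5, 15), follicle_diameter = c(18, 30),
      distractors_per_section = c(10, 30), noise_sd = 8,
      allow_pairs = FALSE,
      dir = NULL, annotations = NULL,
      train_slides = NULL, mine_slides = NULL, test_slides = NULL
    ),
    preprocess = list(
      downsample = 1,
      contour = list(extra_downsample = 4, min_area_frac = 0.005,
                     margin_frac = 0.02),
      binarize = list(method = "otsu", fixed_threshold = NULL)
    ),
    dataset = list(frame_size = 64, neg_pos_ratio = 1, min_dist = NULL,
                   raw_neg_per_positive = 12),
    model = list(preset = "tiny"),
    train = list(batch_size = 32, epochs = 6),
    detect = list(window = NULL, overlap_fraction = 0.5, threshold = 0.15,
                  adjacency = "iou", iou_threshold = 0.25),
    hnm = list(rounds = 1, epochs = 4),
    report = list(save_crops = FALSE, operator_confirmed = 0)
  )
}

config_abort <- function(msg) abort(msg, class = "follidetect_config_error")
data_abort <- function(msg) abort(msg, class = "follidetect_data_error")

# Merge `user` over `defaults`, keeping the default tree shape and
# rejecting keys the defaults do not know.
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    config_abort(sprintf("unknown configuration key(s): %s",
                         paste(c(path, unknown[1]), collapse = ".")))
  }
  for (nm in names(user)) {
    defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
  }
  defaults
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [default_pipeline_config()] key tree.
#' @return Merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_abort(sprintf("config file not found: %s", path))
  merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "follidetect_config_error") ||
        inherits(e, "follidetect_data_error")) stop(e)
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
          class = "follidetect_stage_error")
  })
}

# Negative sampling with a shrinking fallback: crowded sections can have a
# very small feasible region, in which case fewer negatives are accepted
# rather than failing the whole stage.
sample_negatives_robust <- function(section, ann, frame_size, n, min_dist,
                                    seed) {
  while (n > 0) {
    got <- tryCatch(
      sample_negative_patches(section, ann, frame_size = frame_size, n = n,
                              min_dist = min_dist, seed = seed),
      error = function(e) NULL)
    if (!is.null(got)) return(got)
    n <- n %/% 2
  }
  new_patch_tibble()
}

#' Run the full detection pipeline
#'
#' Executes synthesize (optional) -> preprocess -> build-dataset -> train
#' -> (mine -> retrain) x rounds -> detect on the test slides -> evaluate,
#' and writes a run manifest, the per-phase metric table, and the final
#' detections under `config$out_dir`.
#'
#' @param config Nested configuration list (see
#'   [default_pipeline_config()]); unknown keys are rejected.
#' @return Invisibly, a list with `reports` (one [eval_report()] per
#'   phase), `table1`, `model`, `manifest_path`, and the resolved
#'   `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$out_dir)) config_abort("config requires `out_dir`")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- cfg$seed
  frame <- cfg$dataset$frame_size
  min_dist <- cfg$dataset$min_dist %||% frame
  window <- cfg$detect$window %||% frame
  dparams <- detection_params(
    window = window, overlap_fraction = cfg$detect$overlap_fraction,
    threshold = cfg$detect$threshold, adjacency = cfg$detect$adjacency,
    iou_threshold = cfg$detect$iou_threshold)

  # --- corpus ------------------------------------------------------------
  corpus <- run_stage("synthesize", {
    cc <- cfg$corpus
    if (isTRUE(cfg$synthesize)) {
      n_total <- cc$n_train_slides + cc$n_mine_slides + cc$n_test_slides
      spec <- synthetic_spec(
        slide_w = cc$slide_w, slide_h = cc$slide_h,
        n_sections = cc$n_sections,
        follicles_per_section = unlist(cc$follicles_per_section),
        follicle_diameter = unlist(cc$follicle_diameter),
        distractors_per_section = unlist(cc$distractors_per_section),
        noise_sd = cc$noise_sd, seed = derive_seed(master, "corpus"),
        allow_pairs = isTRUE(cc$allow_pairs))
      dir <- file.path(cfg$out_dir, "corpus")
      manifest <- generate_corpus(spec, n_total, dir)
      manifest$role <- rep(c("train", "mine", "test"),
                           c(cc$n_train_slides, cc$n_mine_slides,
                             cc$n_test_slides))
      list(slides = manifest,
           annotations = read_annotations(file.path(dir, "annotations.csv")))
    } else {
      paths <- c(cc$train_slides, cc$mine_slides, cc$test_slides)
      if (is.null(cc$annotations) || length(paths) == 0) {
        config_abort("synthesize = FALSE requires corpus$train_slides/mine_slides/test_slides and corpus$annotations")
      }
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0) {
        data_abort(sprintf("missing slide file(s): %s",
                           paste(missing, collapse = ", ")))
      }
      slides <- tibble(
        slide_id = sub("\\.[^.]+$", "", basename(paths)), path = paths,
        role = rep(c("train", "mine", "test"),
                   c(length(cc$train_slides), length(cc$mine_slides),
                     length(cc$test_slides))))
      list(slides = slides, annotations = read_annotations(cc$annotations))
    }
  })
  message(sprintf("[synthesize] %d slides, %d annotated follicles",
                  nrow(corpus$slides), nrow(corpus$annotations)))

  # --- preprocess --------------------------------------------------------
  sections_by_slide <- run_stage("preprocess", {
    pp <- cfg$preprocess
    out <- list()
    for (i in seq_len(nrow(corpus$slides))) {
      row <- corpus$slides[i, ]
      slide <- read_slide(row$path, downsample_factor = pp$downsample,
                          slide_id = row$slide_id)
      secs <- isolate_sections(
        slide, annotations = corpus$annotations,
        extra_downsample = pp$contour$extra_downsample,
        min_area_frac = pp$contour$min_area_frac,
        margin_frac = pp$contour$margin_frac,
        binarize_method = pp$binarize$method,
        fixed_threshold = pp$binarize$fixed_threshold)
      out[[row$slide_id]] <- list(slide = slide, sections = secs, role = row$role)
    }
    out
  })
  message(sprintf("[preprocess] %d sections isolated",
                  sum(purrr::map_int(sections_by_slide,
                                     ~ length(.x$sections)))))

  section_truth <- function(entry, sec) {
    annotations_in_section(corpus$annotations, sec, entry$slide$scale_factor)
  }

  # --- build-dataset -----------------------------------------------------
  base_data <- run_stage("build-dataset", {
    pos_all <- list(); neg_all <- list()
    for (sid in names(sections_by_slide)) {
      entry <- sections_by_slide[[sid]]
      if (entry$role != "train") next
      for (sec in entry$sections) {
        ann <- section_truth(entry, sec)
        pos <- extract_positive_patches(sec, ann, frame_size = frame,
                                        classes = "primordial")
        if (nrow(pos) > 0) {
          pos <- augment_patches(pos, section = sec,
                                 seed = derive_seed(master, paste0("aug_", sid, "_", sec$section_id)))
        }
        n_raw <- cfg$dataset$raw_neg_per_positive *
          max(1, sum(ann$follicle_class == "primordial"))
        neg <- sample_negatives_robust(
          sec, ann, frame_size = frame, n = n_raw, min_dist = min_dist,
          seed = derive_seed(master, paste0("neg_", sid, "_", sec$section_id)))
        pos_all[[length(pos_all) + 1]] <- pos
        neg_all[[length(neg_all) + 1]] <- neg
      }
    }
    pos_all <- dplyr::bind_rows(pos_all)
    neg_all <- dplyr::bind_rows(neg_all)
    if (nrow(pos_all) == 0) data_abort("no positive patches on the training slides")
    split <- balance_and_split(pos_all, neg_all,
                               neg_pos_ratio = cfg$dataset$neg_pos_ratio,
                               holdout_ovary_ids = character(),
                               seed = derive_seed(master, "balance"))
    split$train
  })
  message(sprintf("[build-dataset] %d positives + %d negatives",
                  base_data$positives, base_data$negatives))

  # --- train -------------------------------------------------------------
  model <- run_stage("train", {
    m <- build_classifier(cfg$model$preset,
                          seed = derive_seed(master, "init"),
                          input_size = frame)
    train_classifier(m, base_data, training_config(
      batch_size = cfg$train$batch_size, epochs = cfg$train$epochs,
      seed = derive_seed(master, "train")))
  })
  message(sprintf("[train] %d epochs, final loss %.4f",
                  nrow(model$history), tail(model$history$loss, 1)))

  evaluate_phase <- function(mod, phase) {
    matches <- list(); dets <- list()
    for (sid in names(sections_by_slide)) {
      entry <- sections_by_slide[[sid]]
      if (entry$role != "test") next
      for (sec in entry$sections) {
        det <- detect_follicles(mod, sec, dparams)
        truth <- section_truth(entry, sec)
        matches[[length(matches) + 1]] <- match_detections(det, truth)
        dets[[length(dets) + 1]] <- as_tibble(det)
      }
    }
    list(report = eval_report(combine_match_results(matches), phase = phase),
         detections = dplyr::bind_rows(dets))
  }

  # --- detect + evaluate, phase I ---------------------------------------
  phase1 <- run_stage("evaluate", evaluate_phase(model, "after_training"))
  reports <- list(phase1$report)
  detections <- phase1$detections
  met1 <- report_metrics(phase1$report)
  message(sprintf("[evaluate] phase I recall %.2f%%, precision %.2f%%",
                  as_pct(met1$recall), as_pct(met1$precision)))

  # --- hard negative mining rounds --------------------------------------
  for (round in seq_len(cfg$hnm$rounds)) {
    mined <- run_stage("mine", {
      mining_sections <- list()
      for (sid in names(sections_by_slide)) {
        entry <- sections_by_slide[[sid]]
        if (entry$role != "mine") next
        for (sec in entry$sections) {
          mining_sections[[length(mining_sections) + 1]] <-
            list(section = sec, annotations = section_truth(entry, sec))
        }
      }
      mine_hard_negatives(model, mining_sections, dparams)
    })
    message(sprintf("[mine] round %d: %d hard negatives", round,
                    nrow(mined$mined_patches)))
    model <- run_stage("retrain", {
      retrain_with_hard_negatives(
        model, base_data, mined,
        training_config(batch_size = cfg$train$batch_size,
                        epochs = cfg$hnm$epochs,
                        seed = derive_seed(master, paste0("hnm", round))),
        neg_pos_ratio = cfg$dataset$neg_pos_ratio)
    })
    phase2 <- run_stage("evaluate", evaluate_phase(model, "after_hnm"))
    reports[[length(reports) + 1]] <- phase2$report
    detections <- phase2$detections
    met2 <- report_metrics(phase2$report)
    message(sprintf("[evaluate] after HNM round %d: recall %.2f%%, precision %.2f%%",
                    round, as_pct(met2$recall), as_pct(met2$precision)))
  }

  # --- operator-focus correction ----------------------------------------
  if (cfg$report$operator_confirmed > 0) {
    reports[[length(reports) + 1]] <- apply_operator_correction(
      reports[[length(reports)]], cfg$report$operator_confirmed)
  }

  # --- report ------------------------------------------------------------
  result <- run_stage("report", {
    report_dir <- file.path(cfg$out_dir, "report")
    dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
    table1 <- build_table1_report(reports)
    write_table1_report(table1, file.path(report_dir, "table1.csv"),
                        file.path(report_dir, "table1.txt"))
    write_detections(detections, file.path(report_dir, "detections.csv"))
    metrics <- purrr::map(reports, function(r) {
      met <- report_metrics(r)
      m <- r$match
      list(phase = r$phase, recall_pct = as_pct(met$recall),
           precision_pct = as_pct(met$precision),
           tp_frames = m$tp_frames, fp_frames = m$fp_frames,
           found_follicles = m$found_follicles,
           real_follicles = m$real_follicles,
           total_windows = m$total_windows)
    })
    jsonlite::write_json(metrics, file.path(report_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    model_path <- file.path(cfg$out_dir, "model.rds")
    save_classifier(model, model_path)
    if (isTRUE(cfg$report$save_crops)) {
      for (sid in names(sections_by_slide)) {
        entry <- sections_by_slide[[sid]]
        if (entry$role != "test") next
        for (sec in entry$sections) {
          sel <- detections[detections$slide_id == sid &
                              detections$section_id == sec$section_id, ]
          write_detection_report(sel, sec, file.path(report_dir, "crops"))
        }
      }
    }
    manifest <- list(
      seed = master,
      config = cfg[setdiff(names(cfg), "out_dir")],
      slides = corpus$slides[, c("slide_id", "role")],
      dataset = list(positives = base_data$positives,
                     negatives = base_data$negatives),
      metrics = metrics,
      artifacts = list(table1 = "report/table1.csv",
                       detections = "report/detections.csv",
                       metrics = "report/metrics.json",
                       model = "model.rds")
    )
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(reports = reports, table1 = table1, model = model,
         detections = detections, manifest_path = manifest_path,
         config = cfg)
  })
  invisible(result)
}
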