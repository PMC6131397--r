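# Public classifier API: VGG-style architecture presets, seeded
# construction, mini-batch Adadelta training, dropout, inference.

#' Architecture configuration
#'
#' Describes a VGG-style stack: blocks of 3x3 'same' convolutions (each
#' followed by ReLU) ending in a max-pool, then flatten, optional dropout,
#' a hidden fully-connected layer with ReLU, and a final dense layer read
#' out through softmax.
#'
#' @param input_size Square input side, px.
#' @param blocks List of `(n_conv, kernel, filters)` triples (as lists).
#' @param pool Pooling window per block (recycled if scalar).
#' @param fc_units Hidden fully-connected width.
#' @param dropout_rate Dropout fraction in `[0, 1)` before the FC layer.
#' @param n_classes Number of softmax outputs (2: background, follicle).
#' @return An object of class `architecture_config`.
#' @export
architecture_config <- function(input_size = 64,
                                blocks = list(list(n_conv = 2, kernel = 3,
                                                   filters = 32)),
                                pool = 2, fc_units = 128, dropout_rate = 0.5,
                                n_classes = 2) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must be in [0, 1).")
  }
  if (n_classes < 2) abort("`n_classes` must be at least 2.")
  pool <- rep(as.list(pool), length.out = length(blocks))
  structure(
    list(input_size = input_size, blocks = blocks, pool = pool,
         fc_units = fc_units, dropout_rate = dropout_rate,
         n_classes = n_classes),
    class = "architecture_config"
  )
}

#' Architecture presets
#'
#' `"tiny"` (one 8-filter block, 4x4 pool, 32-unit FC, no dropout) trains
#' in minutes on a CPU and is the default for the synthetic benchmark;
#' `"vgg-small"` (three 3x3 blocks of 32/64/128 filters, 2x2 pools,
#' 128-unit FC, dropout 0.5) is a scaled-down VGG-style stack for real
#' data.
#'
#' @param preset `"tiny"` or `"vgg-small"`.
#' @param input_size Square input side, px.
#' @return An [architecture_config].
#' @export
classifier_preset <- function(preset = c("tiny", "vgg-small"),
                              input_size = 64) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = architecture_config(
      input_size = input_size,
      blocks = list(list(n_conv = 1, kernel = 3, filters = 8)),
      pool = 4, fc_units = 32, dropout_rate = 0, n_classes = 2),
    `vgg-small` = architecture_config(
      input_size = input_size,
      blocks = list(list(n_conv = 2, kernel = 3, filters = 32),
                    list(n_conv = 2, kernel = 3, filters = 64),
                    list(n_conv = 2, kernel = 3, filters = 128)),
      pool = 2, fc_units = 128, dropout_rate = 0.5, n_classes = 2)
  )
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param epochs Number of passes over the training set (>= 0).
#' @param rho,epsilon Adadelta decay and stabiliser.
#' @param seed Integer seed (shuffling, dropout).
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 32, epochs = 10, rho = 0.95,
                            epsilon = 1e-6, seed = 1) {
  stopifnot(batch_size >= 1, epochs >= 0, rho > 0, rho < 1, epsilon > 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), rho = rho, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "training_config")
}

CLASS_LEVELS <- c("background", "follicle")

#' Build an untrained patch classifier
#'
#' @param arch An [architecture_config] or preset name.
#' @param seed Integer seed for the weight initialisation.
#' @param input_size Used when `arch` is a preset name.
#' @return An object of class `follicle_classifier`.
#' @export
build_classifier <- function(arch = "tiny", seed = 1, input_size = 64) {
  if (is.character(arch)) arch <- classifier_preset(arch, input_size)
  stopifnot(inherits(arch, "architecture_config"))
  built <- withr::with_seed(seed, build_layers(arch))
  structure(
    list(arch = arch, layers = built$layers, n_params = built$n_params,
         opt_state = NULL, seed = seed,
         history = tibble(epoch = integer(), loss = numeric(),
                          accuracy = numeric())),
    class = "follicle_classifier"
  )
}

#' @export
print.follicle_classifier <- function(x, ...) {
  cat(sprintf(
    "<follicle_classifier> input %dx%d, %d blocks, %s parameters, %d epochs trained\n",
    x$arch$input_size, x$arch$input_size, length(x$arch$blocks),
    format(x$n_params, big.mark = ","), nrow(x$history)))
  invisible(x)
}

patches_of <- function(data) {
  if (inherits(data, "patch_dataset")) data$patches else data
}

#' Train the classifier with mini-batch Adadelta
#'
#' Seeded mini-batch gradient descent on the categorical cross-entropy of
#' the two softmax outputs, with dropout active during training. The
#' per-epoch mean loss and argmax accuracy of the training forward passes
#' are appended to the model's history. `epochs = 0` returns the model
#' unchanged. Training resumes from the model's current weights and
#' optimizer state, which is what a hard-negative-mining round relies on.
#'
#' @param model A [build_classifier()] model.
#' @param data A `patch_dataset` or patch tibble with labels.
#' @param cfg A [training_config()].
#' @return The trained `follicle_classifier`.
#' @export
train_classifier <- function(model, data, cfg = training_config()) {
  stopifnot(inherits(model, "follicle_classifier"),
            inherits(cfg, "training_config"))
  patches <- patches_of(data)
  if (cfg$epochs == 0) return(model)
  if (nrow(patches) == 0) abort("cannot train on an empty dataset")
  size <- model$arch$input_size
  bad <- purrr::map_lgl(patches$pixels, function(m) {
    nrow(m) != size || ncol(m) != size
  })
  if (any(bad)) {
    abort(sprintf("patch %d is not %dx%d", which(bad)[1], size, size))
  }
  labels <- match(patches$label, CLASS_LEVELS)
  if (anyNA(labels)) abort("labels must be 'background' or 'follicle'")
  layers <- model$layers
  state <- model$opt_state %||% adadelta_init(layers)
  history <- model$history
  n <- nrow(patches)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        grads_sum <- NULL
        for (s in idx) {
          fw <- nn_forward(layers, patches$pixels[[s]], training = TRUE)
          le <- softmax_xent(fw$scores, labels[s])
          ep_loss <- ep_loss + le$loss
          ep_correct <- ep_correct + (which.max(le$probs) == labels[s])
          g <- nn_backward(layers, fw$cache, le$dscores)
          if (is.null(grads_sum)) {
            grads_sum <- g
          } else {
            for (i in seq_along(g)) {
              if (is.null(g[[i]])) next
              grads_sum[[i]]$W <- grads_sum[[i]]$W + g[[i]]$W
              grads_sum[[i]]$b <- grads_sum[[i]]$b + g[[i]]$b
            }
          }
        }
        for (i in seq_along(grads_sum)) {
          if (is.null(grads_sum[[i]])) next
          grads_sum[[i]]$W <- grads_sum[[i]]$W / length(idx)
          grads_sum[[i]]$b <- grads_sum[[i]]$b / length(idx)
        }
        upd <- adadelta_step(layers, state, grads_sum, cfg$rho, cfg$epsilon)
        layers <- upd$layers
        state <- upd$state
      }
      history <- dplyr::bind_rows(history, tibble(
        epoch = nrow(history) + 1L, loss = ep_loss / n,
        accuracy = ep_correct / n))
    }
  })
  model$layers <- layers
  model$opt_state <- state
  model$history <- history
  model
}

#' Predict follicle probabilities for patches
#'
#' Deterministic inference (dropout disabled): one softmax follicle-class
#' probability per patch.
#'
#' @param model A trained `follicle_classifier`.
#' @param patches List of pixel matrices, a patch tibble, or a
#'   `patch_dataset`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, patches) {
  stopifnot(inherits(model, "follicle_classifier"))
  if (inherits(patches, "patch_dataset") || is.data.frame(patches)) {
    patches <- patches_of(patches)$pixels
  }
  if (is.matrix(patches)) patches <- list(patches)
  size <- model$arch$input_size
  fol <- match("follicle", CLASS_LEVELS)
  purrr::map_dbl(patches, function(m) {
    if (nrow(m) != size || ncol(m) != size) {
      abort(sprintf("patch is %dx%d but the model expects %dx%d",
                    nrow(m), ncol(m), size, size))
    }
    softmax(nn_forward(model$layers, m, training = FALSE)$scores)[fol]
  })
}

#' Save / load a classifier checkpoint
#'
#' A checkpoint is a single file embedding the architecture, weights,
#' optimizer state, seed and history.
#'
#' @param model A `follicle_classifier`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored model (load).
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "follicle_classifier"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "follicle_classifier")) {
    abort(sprintf("%s is not a classifier checkpoint", path))
  }
  model
}

#' @method tidy follicle_classifier
#' @export
tidy.follicle_classifier <- function(x, ...) x$history

#' @method glance follicle_classifier
#' @export
glance.follicle_classifier <- function(x, ...) {
  tibble(
    n_params = x$n_params,
    n_blocks = length(x$arch$blocks),
    input_size = x$arch$input_size,
    dropout_rate = x$arch$dropout_rate,
    epochs_trained = nrow(x$history),
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
    final_accuracy = if (nrow(x$history)) x$history$accuracy[nrow(x$history)] else NA_real_
  )
}

#' Training-history curve
#'
#' @param object A `follicle_classifier`.
#' @param ... Unused.
#' @return A ggplot of per-epoch loss and training accuracy.
#' @export
autoplot.follicle_classifier <- function(object, ...) {
  hist <- tidyr_pivot(object$history)
  ggplot2::ggplot(hist, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Patch classifier training history") +
    ggplot2::theme_minimal()
}

# long-format history without importing tidyr
tidyr_pivot <- function(history) {
  dplyr::bind_rows(
    tibble(epoch = history$epoch, metric = "loss", value = history$loss),
    tibble(epoch = history$epoch, metric = "accuracy",
           value = history$accuracy)
  )
}
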