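# Classifier stack: reference equations, seeded construction, gradient
# correctness, training behaviour, inference contracts.

test_that("neuron_response implements sigma(w.x - b) for both activations", {
  expect_identical(neuron_response(c(1, 1), c(1, 1), 2, "relu"), 0)
  expect_identical(neuron_response(numeric(0), numeric(0), 0, "sigmoid"), 0.5)
  expect_identical(neuron_response(3, 2, 1, "relu"), 5)
  expect_error(neuron_response(c(1, 2), 1), "length")

  # brute-force loop oracle on random vectors
  withr::with_seed(12, {
    for (case in 1:50) {
      n <- sample(1:8, 1)
      x <- runif(n, -3, 3); w <- runif(n, -3, 3); b <- runif(1, -2, 2)
      acc <- 0
      for (i in seq_len(n)) acc <- acc + w[i] * x[i]
      expect_equal(neuron_response(x, w, b, "relu"), max(0, acc - b))
      expect_equal(neuron_response(x, w, b, "sigmoid"),
                   1 / (1 + exp(-(acc - b))))
    }
  })
})

test_that("softmax is a shift-invariant, overflow-safe simplex map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(7, 7, 7)), rep(1 / 3, 3))
  expect_equal(softmax(c(2, 0)), c(0.880797, 0.119203), tolerance = 1e-6)
  withr::with_seed(4, {
    for (case in 1:25) {
      z <- runif(sample(2:6, 1), -5, 5)
      p <- softmax(z)
      expect_true(all(p >= 0))
      expect_equal(sum(p), 1)
      expect_equal(softmax(z + 123.4), p)
    }
  })
  extreme <- softmax(c(1e4, -1e4, 0))
  expect_true(all(is.finite(extreme)))
  expect_equal(sum(extreme), 1)
  expect_error(softmax(numeric(0)), "empty")
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("build_classifier is seeded, presets are valid, dropout bounds enforced", {
  m1 <- build_classifier("tiny", seed = 5, input_size = 64)
  m2 <- build_classifier("tiny", seed = 5, input_size = 64)
  w1 <- purrr::keep(m1$layers, ~!is.null(.x$W))
  w2 <- purrr::keep(m2$layers, ~!is.null(.x$W))
  expect_identical(purrr::map(w1, "W"), purrr::map(w2, "W"))
  m3 <- build_classifier("tiny", seed = 6, input_size = 64)
  expect_false(identical(
    purrr::map(purrr::keep(m3$layers, ~!is.null(.x$W)), "W"),
    purrr::map(w1, "W")))

  # an untrained model still outputs a 2-class probability for a patch
  p <- predict_proba(m1, matrix(0.5, 64, 64))
  expect_true(p >= 0 && p <= 1)

  expect_s3_class(classifier_preset("vgg-small"), "architecture_config")
  expect_no_error(architecture_config(dropout_rate = 0.99))
  expect_error(architecture_config(dropout_rate = 1), "dropout_rate")
  expect_error(architecture_config(n_classes = 1), "n_classes")
  # pooling must divide the feature map
  expect_error(
    build_classifier(architecture_config(input_size = 30, pool = 4), 1),
    "pool")
})

test_that("backpropagated gradients match finite differences", {
  ns <- asNamespace("follidetect")
  arch <- architecture_config(
    input_size = 8, blocks = list(list(n_conv = 2, kernel = 3, filters = 3)),
    pool = 2, fc_units = 5, dropout_rate = 0, n_classes = 2)
  m <- build_classifier(arch, seed = 3)
  withr::with_seed(7, x <- matrix(runif(64), 8, 8))
  label <- 2L
  fw <- ns$nn_forward(m$layers, x, training = FALSE)
  le <- ns$softmax_xent(fw$scores, label)
  gr <- ns$nn_backward(m$layers, fw$cache, le$dscores)
  loss_of <- function(layers) {
    f <- ns$nn_forward(layers, x, training = FALSE)
    ns$softmax_xent(f$scores, label)$loss
  }
  eps <- 1e-6
  withr::with_seed(9, {
    for (i in seq_along(m$layers)) {
      if (is.null(gr[[i]])) next
      for (rep in 1:6) {
        j <- sample(length(m$layers[[i]]$W), 1)
        lp <- m$layers; lp[[i]]$W[j] <- lp[[i]]$W[j] + eps
        lm <- m$layers; lm[[i]]$W[j] <- lm[[i]]$W[j] - eps
        num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
        expect_equal(gr[[i]]$W[j], num, tolerance = 1e-4)
      }
      jb <- sample(length(m$layers[[i]]$b), 1)
      lp <- m$layers; lp[[i]]$b[jb] <- lp[[i]]$b[jb] + eps
      lm <- m$layers; lm[[i]]$b[jb] <- lm[[i]]$b[jb] - eps
      num <- (loss_of(lp) - loss_of(lm)) / (2 * eps)
      expect_equal(gr[[i]]$b[jb], num, tolerance = 1e-4)
    }
  })
})

test_that("training is an identity at 0 epochs and learns the separable toy set", {
  data <- toy_separable_patches()
  m0 <- build_classifier(toy_arch(), seed = 7)
  same <- train_classifier(m0, data, training_config(epochs = 0, seed = 1))
  expect_identical(purrr::map(same$layers, "W"), purrr::map(m0$layers, "W"))
  expect_error(
    train_classifier(m0, tibble::tibble(pixels = list(), label = character()),
                     training_config(epochs = 1)),
    "empty")

  m <- trained_toy_model()
  hist <- tidy(m)
  expect_identical(nrow(hist), 30L)
  expect_identical(hist$accuracy[30], 1)
  # loss is non-increasing over the last 10 epochs
  expect_true(all(diff(hist$loss[21:30]) <= 1e-12))
  # perfect separation on the training patches
  probs <- predict_proba(m, data)
  expect_true(all(probs[data$label == "follicle"] > 0.5))
  expect_true(all(probs[data$label == "background"] < 0.5))

  g <- glance(m)
  expect_identical(g$epochs_trained, 30L)
  expect_identical(g$final_accuracy, 1)
})

test_that("training with one seed is reproducible and inference is deterministic", {
  data <- toy_separable_patches()
  cfg <- training_config(batch_size = 5, epochs = 3, seed = 19)
  ma <- train_classifier(build_classifier(toy_arch(), seed = 2), data, cfg)
  mb <- train_classifier(build_classifier(toy_arch(), seed = 2), data, cfg)
  expect_identical(purrr::map(ma$layers, "W"), purrr::map(mb$layers, "W"))
  expect_identical(ma$history, mb$history)

  expect_identical(predict_proba(ma, data$pixels),
                   predict_proba(ma, data$pixels))
  expect_identical(predict_proba(ma, list()), numeric(0))
  dup <- predict_proba(ma, list(data$pixels[[1]], data$pixels[[1]]))
  expect_identical(dup[1], dup[2])
  expect_error(predict_proba(ma, matrix(0, 5, 5)), "expects")
})

test_that("dropout regularises training but never perturbs inference", {
  arch <- architecture_config(
    input_size = 16, blocks = list(list(n_conv = 1, kernel = 3, filters = 4)),
    pool = 4, fc_units = 8, dropout_rate = 0.5, n_classes = 2)
  data <- toy_separable_patches(n_per_class = 6)
  cfg <- training_config(batch_size = 4, epochs = 2, seed = 3)
  ma <- train_classifier(build_classifier(arch, seed = 4), data, cfg)
  mb <- train_classifier(build_classifier(arch, seed = 4), data, cfg)
  # dropout draws are seeded: training is still reproducible
  expect_identical(purrr::map(ma$layers, "W"), purrr::map(mb$layers, "W"))
  expect_true(all(is.finite(ma$history$loss)))
  # inference is deterministic (dropout disabled)
  p1 <- predict_proba(ma, data)
  p2 <- predict_proba(ma, data)
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip through a single file", {
  m <- trained_toy_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(m, path)
  back <- load_classifier(path)
  expect_identical(purrr::map(back$layers, "W"), purrr::map(m$layers, "W"))
  expect_identical(back$history, m$history)
  data <- toy_separable_patches()
  expect_identical(predict_proba(back, data), predict_proba(m, data))
})
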