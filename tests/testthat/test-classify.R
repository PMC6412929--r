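test_that("simple CNN feature maps follow the 28 -> 14 -> 7 shape chain", {
  model <- build_simple_cnn(5, seed = 1)
  x <- array(runif(28 * 28 * 3), dim = c(28, 28, 3))
  fwd <- ecgscalo:::cnn_forward(model, x)
  expect_equal(dim(fwd$cache$c1$out), c(28L * 28L, 8L))   # conv1: 28x28x8
  expect_equal(dim(fwd$cache$p1$out), NULL)               # pooled vector
  expect_length(fwd$cache$p1$out, 14 * 14 * 8)            # pool1: 14x14x8
  expect_equal(dim(fwd$cache$c2$out), c(14L * 14L, 16L))  # conv2: 14x14x16
  expect_length(fwd$cache$p2$out, 7 * 7 * 16)             # pool2: 7x7x16
  expect_equal(dim(fwd$cache$c3$out), c(7L * 7L, 32L))    # conv3: 7x7x32
  expect_length(fwd$scores, 5L)
  expect_error(build_simple_cnn(1), ">= 2")
  # identical seed -> identical initialization
  expect_identical(build_simple_cnn(4, seed = 7)$params,
                   build_simple_cnn(4, seed = 7)$params)
})

test_that("backprop gradients match central differences", {
  set.seed(10)
  model <- build_simple_cnn(3, seed = 2)
  x <- array(runif(28 * 28 * 3), dim = c(28, 28, 3))
  y <- 2L
  loss_at <- function(m) {
    pr <- ecgscalo:::softmax_rows(ecgscalo:::cnn_forward(m, x, keep_cache = FALSE)$scores)
    -log(pr[1, y])
  }
  fwd <- ecgscalo:::cnn_forward(model, x)
  pr <- drop(ecgscalo:::softmax_rows(fwd$scores))
  d <- pr; d[y] <- d[y] - 1
  grads <- ecgscalo:::cnn_backward(model, fwd, d)
  eps <- 1e-5
  for (nm in names(model$params)) {
    idx <- sample(length(model$params[[nm]]), min(3, length(model$params[[nm]])))
    for (i in idx) {
      up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
      dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("stratified split respects ratio, determinism and small classes", {
  data <- tibble::tibble(
    image = as.list(seq_len(300)),
    label = rep(c("a", "b", "c"), each = 100)
  )
  sp <- split_train_validation(data, c(90, 10), seed = 3)
  expect_equal(nrow(sp$train), 270L)
  expect_equal(nrow(sp$validation), 30L)
  expect_equal(unname(table(sp$train$label)), rep(90L, 3), ignore_attr = TRUE)
  # disjoint union equals input
  expect_setequal(c(sp$train$image, sp$validation$image), data$image)
  sp2 <- split_train_validation(data, c(90, 10), seed = 3)
  expect_identical(sp$train$image, sp2$train$image)
  # 3 items per class at 50:50 -> parts differ by at most one
  small <- tibble::tibble(image = as.list(1:6), label = rep(c("a", "b"), each = 3))
  sp3 <- split_train_validation(small, c(50, 50), seed = 1)
  per_class <- table(sp3$train$label)
  expect_true(all(abs(per_class - table(sp3$validation$label)) <= 1))
  expect_error(split_train_validation(
    tibble::tibble(image = list(1), label = "a"), c(50, 50), 1), "at least 2")
})

test_that("training is seeded, reproducible and identity at zero epochs", {
  data <- separable_image_data(10)
  model <- build_simple_cnn(2, seed = 5)
  cfg0 <- train_config("adam", epochs = 0, seed = 1)
  fit0 <- train_cnn(model, data, cfg0)
  expect_identical(fit0$model$params, model$params)
  expect_equal(nrow(fit0$metrics), 0L)
  cfg <- train_config("adam", epochs = 2, minibatch = 4, seed = 11)
  f1 <- train_cnn(model, data, cfg)
  f2 <- train_cnn(model, data, cfg)
  expect_identical(f1$metrics$loss, f2$metrics$loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("all three optimizers reduce the loss on a separable task", {
  data <- separable_image_data(10)
  model <- build_simple_cnn(2, seed = 5)
  for (m in c("sgdm", "rmsprop", "adam")) {
    cfg <- train_config(m, epochs = 2, minibatch = 4, seed = 2)
    fit <- train_cnn(model, data, cfg)
    expect_true(all(is.finite(fit$metrics$loss)))
    expect_lt(fit$metrics$loss[2], fit$metrics$loss[1])
  }
})

test_that("Adam at lr 1e-4 separates dark from bright images", {
  data <- separable_image_data(100)
  sp <- split_train_validation(data, c(80, 20), seed = 7)
  model <- build_simple_cnn(2, seed = 1)
  cfg <- train_config("adam", initial_lr = 1e-4, minibatch = 4, epochs = 5,
                      seed = 1)
  fit <- train_cnn(model, sp$train, cfg, validation = sp$validation)
  m <- tidy(fit)
  expect_gte(m$train_accuracy[nrow(m)], 0.95)
  # held-out accuracy on the same separable task
  preds <- predict(fit, sp$validation)
  expect_gte(mean(preds$.pred_class == sp$validation$label), 0.95)
  # training loss non-increasing after 3-epoch smoothing
  sm <- stats::filter(m$loss, rep(1 / 3, 3), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) <= 1e-8))
  # glance summarises the run
  g <- glance(fit)
  expect_equal(g$epochs, 5L)
  expect_equal(g$method, "adam")
})

test_that("softmax rows sum to one and tie-break picks the lowest index", {
  data <- separable_image_data(5)
  model <- build_simple_cnn(2, seed = 2)
  fit <- train_cnn(model, data, train_config(epochs = 0, seed = 1))
  preds <- predict(fit, data)
  probs <- as.matrix(preds[, c(".pred_bright", ".pred_dark")])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(data)), tolerance = 1e-6)
  # duplicated input row -> identical scores
  dup <- data[c(1, 1), ]
  pd <- predict(fit, dup)
  expect_identical(pd[1, ], pd[2, ])
})

test_that("zero last-layer learning-rate multiplier freezes the final layer", {
  data <- separable_image_data(8)
  model <- build_simple_cnn(2, seed = 3)
  cfg <- train_config("adam", epochs = 2, minibatch = 4,
                      last_layer_lr_multiplier = 0, seed = 4)
  fit <- train_cnn(model, data, cfg)
  expect_identical(fit$model$params$Wfc, model$params$Wfc)
  expect_identical(fit$model$params$bfc, model$params$bfc)
  # other layers did move
  expect_false(identical(fit$model$params$W1, model$params$W1))
})

test_that("backbone registry resolves names and transfers weights", {
  expect_error(load_backbone("no_such_net", 3), "unknown backbone")
  # adapter matches the direct build path at a fixed seed
  m1 <- load_backbone("simple_cnn", n_classes = 4, seed = 9)
  m2 <- build_simple_cnn(4, seed = 9)
  expect_identical(m1$params, m2$params)
  # weight transfer copies matching parameter groups
  data <- separable_image_data(5)
  fit <- train_cnn(build_simple_cnn(2, seed = 1), data,
                   train_config(epochs = 1, minibatch = 4, seed = 1))
  m3 <- load_backbone("simple_cnn", n_classes = 2, weights = fit, seed = 0)
  expect_identical(m3$params$W1, fit$model$params$W1)
  # restricted transfer range leaves other groups at fresh initialization
  m4 <- load_backbone("simple_cnn", n_classes = 2, weights = fit,
                      transfer_range = 1:2, seed = 0)
  expect_identical(m4$params$W1, fit$model$params$W1)
  expect_false(identical(m4$params$W3, fit$model$params$W3))
  # custom registration
  register_backbone("tiny_test_net", function(n_classes, seed) {
    build_simple_cnn(n_classes, seed)
  })
  expect_s3_class(load_backbone("tiny_test_net", 2), "simple_cnn")
})
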