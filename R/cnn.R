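# ---- small CNN: layers, initialization, forward/backward -------------------
#
# The network is small enough (about 20k parameters at 5 classes) that a
# vectorised pure-R implementation trains in seconds on desk-scale cohorts.
# Convolutions use im2col: each 3x3xC patch becomes one row of a matrix, so a
# convolution is a single matrix product and its backward pass is a
# scatter-add through the same index map.

# index map for 3x3, pad-1, stride-1 convolution on an H x W x C input
conv_index <- function(H, W, C) {
  oi <- rep(seq_len(H), times = W)
  oj <- rep(seq_len(W), each = H)
  ki <- rep(1:3, times = 3L * C)
  kj <- rep(rep(1:3, each = 3L), times = C)
  cc <- rep(seq_len(C), each = 9L)
  A <- outer(oi, ki - 1L, "+")               # padded row coords
  B <- outer(oj, kj - 1L, "+")               # padded col coords
  Cm <- matrix(cc, nrow = H * W, ncol = 9L * C, byrow = TRUE)
  A + (B - 1L) * (H + 2L) + (Cm - 1L) * ((H + 2L) * (W + 2L))
}

# index map for 2x2, stride-2 max pooling on an H x W x C input (H, W even)
pool_index <- function(H, W, C) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  oi <- rep(seq_len(Ho), times = Wo * C)
  oj <- rep(rep(seq_len(Wo), each = Ho), times = C)
  cc <- rep(seq_len(C), each = Ho * Wo)
  base <- (2L * oi - 1L) + (2L * oj - 2L) * H + (cc - 1L) * (H * W)
  cbind(base, base + 1L, base + H, base + H + 1L)
}

glorot_mat <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Build the small scalogram-classification CNN
#'
#' Constructs the fixed architecture used for desk-scale subject
#' identification from 28 x 28 x 3 scalogram images: three 3x3 pad-1
#' convolutions with 8, 16 and 32 filters (each followed by ReLU), 2x2
#' stride-2 max pooling after the first two convolutions, then a single
#' fully-connected softmax layer. Feature maps run 28x28x8 -> 14x14x8 ->
#' 14x14x16 -> 7x7x16 -> 7x7x32 -> `n_classes`.
#'
#' Weights are Glorot-uniform initialized, deterministically given `seed`.
#'
#' @param n_classes Number of output classes (>= 2).
#' @param seed Integer seed for weight initialization (default 0).
#' @return An object of class `simple_cnn`: architecture spec, parameter
#'   arrays and cached convolution/pooling index maps.
#' @export
build_simple_cnn <- function(n_classes, seed = 0L) {
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) {
    stop("`n_classes` must be an integer >= 2", call. = FALSE)
  }
  params <- withr::with_seed(as.integer(seed), list(
    W1 = glorot_mat(9 * 3, 9 * 8, c(3, 3, 3, 8)), b1 = numeric(8),
    W2 = glorot_mat(9 * 8, 9 * 16, c(3, 3, 8, 16)), b2 = numeric(16),
    W3 = glorot_mat(9 * 16, 9 * 32, c(3, 3, 16, 32)), b3 = numeric(32),
    Wfc = glorot_mat(7 * 7 * 32, n_classes, c(7 * 7 * 32, n_classes)),
    bfc = numeric(n_classes)
  ))
  structure(
    list(
      spec = list(
        input = c(28L, 28L, 3L),
        layers = c("conv 3x3x8 pad 1 + relu", "maxpool 2 stride 2",
                   "conv 3x3x16 pad 1 + relu", "maxpool 2 stride 2",
                   "conv 3x3x32 pad 1 + relu",
                   sprintf("fully-connected %d", n_classes), "softmax")
      ),
      n_classes = n_classes,
      params = params,
      idx = list(
        c1 = conv_index(28L, 28L, 3L), p1 = pool_index(28L, 28L, 8L),
        c2 = conv_index(14L, 14L, 8L), p2 = pool_index(14L, 14L, 16L),
        c3 = conv_index(7L, 7L, 16L)
      )
    ),
    class = "simple_cnn"
  )
}

#' @export
print.simple_cnn <- function(x, ...) {
  cat("<simple_cnn> input", paste(x$spec$input, collapse = "x"), "\n")
  for (l in x$spec$layers) cat("  -", l, "\n")
  cat(sprintf("  %d parameters\n", sum(lengths(x$params))))
  invisible(x)
}

# pad an H x W x C array by one pixel of zeros on each side
pad1 <- function(x) {
  d <- dim(x)
  p <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  p[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  p
}

conv_fwd <- function(x, Warr, b, idx) {
  d <- dim(Warr)
  cols <- matrix(pad1(x)[idx], nrow = nrow(idx))
  out <- cols %*% matrix(Warr, nrow = d[1] * d[2] * d[3])
  out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
  list(out = out, cols = cols)              # out: (H*W) x F
}

conv_bwd <- function(dout, cols, Warr, idx, in_dim) {
  d <- dim(Warr)
  Wmat <- matrix(Warr, nrow = d[1] * d[2] * d[3])
  dW <- array(crossprod(cols, dout), dim = d)
  db <- colSums(dout)
  dcols <- dout %*% t(Wmat)
  agg <- rowsum(as.vector(dcols), group = as.vector(idx))
  dpad <- numeric((in_dim[1] + 2L) * (in_dim[2] + 2L) * in_dim[3])
  dpad[as.integer(rownames(agg))] <- agg
  dpad <- array(dpad, dim = c(in_dim[1] + 2L, in_dim[2] + 2L, in_dim[3]))
  dx <- dpad[2:(in_dim[1] + 1L), 2:(in_dim[2] + 1L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

pool_fwd <- function(x, pidx) {
  vals <- matrix(x[pidx], nrow = nrow(pidx))
  win <- max.col(vals, ties.method = "first")
  list(out = vals[cbind(seq_len(nrow(vals)), win)],
       win_idx = pidx[cbind(seq_len(nrow(vals)), win)])
}

# forward pass for one image; keeps the caches needed for backprop
cnn_forward <- function(model, x, keep_cache = TRUE) {
  p <- model$params; ix <- model$idx
  c1 <- conv_fwd(x, p$W1, p$b1, ix$c1)
  a1 <- pmax(c1$out, 0)
  h1 <- array(a1, dim = c(28, 28, 8))
  p1 <- pool_fwd(h1, ix$p1)
  h2in <- array(p1$out, dim = c(14, 14, 8))
  c2 <- conv_fwd(h2in, p$W2, p$b2, ix$c2)
  a2 <- pmax(c2$out, 0)
  h2 <- array(a2, dim = c(14, 14, 16))
  p2 <- pool_fwd(h2, ix$p2)
  h3in <- array(p2$out, dim = c(7, 7, 16))
  c3 <- conv_fwd(h3in, p$W3, p$b3, ix$c3)
  a3 <- pmax(c3$out, 0)
  feat <- as.vector(a3)                         # 7*7*32 = 1568
  scores <- drop(feat %*% p$Wfc) + p$bfc
  res <- list(scores = scores, feat = feat)
  if (keep_cache) {
    res$cache <- list(c1 = c1, a1 = a1, p1 = p1, h2in_dim = c(14L, 14L, 8L),
                      c2 = c2, a2 = a2, p2 = p2, h3in_dim = c(7L, 7L, 16L),
                      c3 = c3, a3 = a3)
  }
  res
}

# backward pass for one image given dscores; returns per-parameter gradients
cnn_backward <- function(model, fwd, dscores) {
  p <- model$params; ix <- model$idx; ca <- fwd$cache
  dWfc <- fwd$feat %o% dscores
  dbfc <- dscores
  dfeat <- drop(p$Wfc %*% dscores)
  da3 <- matrix(dfeat, nrow = 49, ncol = 32)
  da3 <- da3 * (ca$c3$out > 0)
  b3 <- conv_bwd(da3, ca$c3$cols, p$W3, ix$c3, ca$h3in_dim)
  # un-pool into the 14x14x16 map
  dh2 <- numeric(14 * 14 * 16)
  dh2[ca$p2$win_idx] <- as.vector(b3$dx)
  da2 <- matrix(dh2, nrow = 196, ncol = 16)
  da2 <- da2 * (ca$c2$out > 0)
  b2 <- conv_bwd(da2, ca$c2$cols, p$W2, ix$c2, ca$h2in_dim)
  dh1 <- numeric(28 * 28 * 8)
  dh1[ca$p1$win_idx] <- as.vector(b2$dx)
  da1 <- matrix(dh1, nrow = 784, ncol = 8)
  da1 <- da1 * (ca$c1$out > 0)
  b1 <- conv_bwd(da1, ca$c1$cols, p$W1, ix$c1, c(28L, 28L, 3L))
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
       W3 = b3$dW, b3 = b3$db, Wfc = dWfc, bfc = dbfc)
}

softmax_rows <- function(s) {
  if (is.null(dim(s))) s <- matrix(s, nrow = 1)
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# ---- training configuration and optimizers ---------------------------------

#' Training configuration for the CNN
#'
#' @param method Optimizer: `"sgdm"`, `"rmsprop"` or `"adam"`.
#' @param initial_lr Initial learning rate (> 0, default 1e-4).
#' @param minibatch Minibatch size (>= 1, default 16).
#' @param epochs Number of passes over the training set (>= 0, default 10).
#' @param last_layer_lr_multiplier Learning-rate multiplier applied to the
#'   weight and bias of the final fully-connected layer (default 1; 0 freezes
#'   that layer bitwise).
#' @param train_val_ratio Two positive numbers summing to 100, e.g.
#'   `c(90, 10)`, used by [split_train_validation()].
#' @param seed Integer seed controlling shuffling (and, by convention, model
#'   initialization in the pipeline wrappers).
#' @return An object of class `train_config`.
#' @export
train_config <- function(method = c("adam", "sgdm", "rmsprop"),
                         initial_lr = 1e-4, minibatch = 16L, epochs = 10L,
                         last_layer_lr_multiplier = 1,
                         train_val_ratio = c(90, 10), seed = 1L) {
  method <- match.arg(method)
  if (initial_lr <= 0) stop("`initial_lr` must be > 0", call. = FALSE)
  minibatch <- as.integer(minibatch)
  if (is.na(minibatch) || minibatch < 1L) stop("`minibatch` must be >= 1", call. = FALSE)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 0L) stop("`epochs` must be >= 0", call. = FALSE)
  if (last_layer_lr_multiplier < 0) {
    stop("`last_layer_lr_multiplier` must be >= 0", call. = FALSE)
  }
  if (length(train_val_ratio) != 2L || any(train_val_ratio <= 0) ||
      abs(sum(train_val_ratio) - 100) > 1e-9) {
    stop("`train_val_ratio` must be two positive parts summing to 100", call. = FALSE)
  }
  structure(
    list(method = method, initial_lr = initial_lr, minibatch = minibatch,
         epochs = epochs, last_layer_lr_multiplier = last_layer_lr_multiplier,
         train_val_ratio = train_val_ratio, seed = as.integer(seed)),
    class = "train_config"
  )
}

make_optimizer <- function(method, params) {
  zeros <- lapply(params, function(p) p * 0)   # preserves each shape
  state <- switch(method,
    sgdm = list(v = zeros),
    rmsprop = list(cache = zeros),
    adam = list(m = zeros, v = zeros, t = 0)
  )
  list(method = method, state = state)
}

optimizer_step <- function(opt, params, grads, lr_each) {
  s <- opt$state
  eps <- 1e-8
  if (opt$method == "adam") s$t <- s$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    lr <- lr_each[[nm]]
    if (opt$method == "sgdm") {
      s$v[[nm]] <- 0.9 * s$v[[nm]] - lr * g
      params[[nm]] <- params[[nm]] + s$v[[nm]]
    } else if (opt$method == "rmsprop") {
      s$cache[[nm]] <- 0.9 * s$cache[[nm]] + 0.1 * g^2
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(s$cache[[nm]]) + eps)
    } else {
      s$m[[nm]] <- 0.9 * s$m[[nm]] + 0.1 * g
      s$v[[nm]] <- 0.999 * s$v[[nm]] + 0.001 * g^2
      mhat <- s$m[[nm]] / (1 - 0.9^s$t)
      vhat <- s$v[[nm]] / (1 - 0.999^s$t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  opt$state <- s
  list(opt = opt, params = params)
}

# ---- dataset helpers --------------------------------------------------------

check_image_data <- function(data, input_dim = c(28L, 28L, 3L)) {
  if (!is.data.frame(data) || !all(c("image", "label") %in% names(data))) {
    stop("`data` must be a data frame with `image` and `label` columns", call. = FALSE)
  }
  if (nrow(data) == 0L) stop("`data` must be non-empty", call. = FALSE)
  ok <- vapply(data$image, function(im) {
    is.numeric(im) && length(dim(im)) == 3L && all(dim(im) == input_dim)
  }, logical(1))
  if (!all(ok)) {
    stop(sprintf("all images must be %s arrays",
                 paste(input_dim, collapse = "x")), call. = FALSE)
  }
  invisible(data)
}

#' Stratified train/validation split
#'
#' Splits a labeled image table per class at the given ratio using a
#' floor-then-remainder rule: each class contributes
#' `floor(n * ratio[1]/100)` training items and the rest goes to validation.
#' Deterministic given `seed`; the two parts are disjoint and their union is
#' the input.
#'
#' @param data Data frame with a `label` column (any other columns ride along).
#' @param ratio Two positive parts summing to 100 (default `c(90, 10)`).
#' @param seed Integer seed.
#' @return Named list with tibbles `train` and `validation`.
#' @export
split_train_validation <- function(data, ratio = c(90, 10), seed = 1L) {
  if (!is.data.frame(data) || !"label" %in% names(data)) {
    stop("`data` must be a data frame with a `label` column", call. = FALSE)
  }
  if (length(ratio) != 2L || any(ratio <= 0) || abs(sum(ratio) - 100) > 1e-9) {
    stop("`ratio` must be two positive parts summing to 100", call. = FALSE)
  }
  counts <- table(data$label)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 items to split", call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  idx_tr <- integer(0)
  withr::with_seed(as.integer(seed), {
    for (cl in names(counts)) {
      rows <- which(data$label == cl)
      n_tr <- floor(length(rows) * ratio[1] / 100)
      n_tr <- max(1L, min(length(rows) - 1L, n_tr))  # both parts non-empty
      idx_tr <- c(idx_tr, sample(rows, n_tr))
    }
  })
  idx_tr <- sort(idx_tr)
  list(train = data[idx_tr, ], validation = data[-idx_tr, ])
}

# ---- training loop ----------------------------------------------------------

#' Train the CNN on labeled scalogram images
#'
#' Runs exactly `config$epochs` passes of minibatch updates with the chosen
#' optimizer (SGDM with momentum 0.9, RMSProp with squared-gradient decay
#' 0.9, or Adam with beta 0.9/0.999) at the configured initial learning rate;
#' the loss is categorical cross-entropy on the softmax outputs. The final
#' fully-connected layer's learning rate is scaled by
#' `last_layer_lr_multiplier`. Shuffling is seeded, so a run is reproducible
#' on one thread.
#'
#' @param model A [build_simple_cnn()] model (or a backbone from
#'   [load_backbone()]).
#' @param data Training data: data frame with `image` (list of 28x28x3
#'   arrays in `[0,1]`) and `label` columns.
#' @param config A [train_config()].
#' @param validation Optional validation data frame of the same shape.
#' @return An object of class `cnn_fit`: trained `model`, `metrics` tibble
#'   (epoch, loss, train_accuracy, val_accuracy), `classes` and `config`.
#' @export
train_cnn <- function(model, data, config = train_config(), validation = NULL) {
  stopifnot(inherits(model, "simple_cnn"), inherits(config, "train_config"))
  check_image_data(data, model$spec$input)
  classes <- sort(unique(as.character(data$label)))
  if (length(classes) > model$n_classes) {
    stop("more classes in `data` than model outputs", call. = FALSE)
  }
  y <- match(as.character(data$label), classes)
  n <- nrow(data)
  opt <- make_optimizer(config$method, model$params)
  lr_each <- lapply(stats::setNames(nm = names(model$params)), function(nm) {
    if (nm %in% c("Wfc", "bfc")) config$initial_lr * config$last_layer_lr_multiplier
    else config$initial_lr
  })
  metrics <- vector("list", config$epochs)
  if (config$epochs > 0L) {
    withr::with_seed(config$seed, {
      for (ep in seq_len(config$epochs)) {
        ord <- sample.int(n)
        total_loss <- 0; total_correct <- 0L
        for (start in seq(1L, n, by = config$minibatch)) {
          batch <- ord[start:min(start + config$minibatch - 1L, n)]
          B <- length(batch)
          fwds <- vector("list", B)
          scores <- matrix(0, B, model$n_classes)
          for (b in seq_len(B)) {
            fwds[[b]] <- cnn_forward(model, data$image[[batch[b]]])
            scores[b, ] <- fwds[[b]]$scores
          }
          probs <- softmax_rows(scores)
          yb <- y[batch]
          total_loss <- total_loss - sum(log(pmax(probs[cbind(seq_len(B), yb)], 1e-300)))
          total_correct <- total_correct + sum(max.col(probs, ties.method = "first") == yb)
          dscores <- probs
          dscores[cbind(seq_len(B), yb)] <- dscores[cbind(seq_len(B), yb)] - 1
          dscores <- dscores / B
          grads <- NULL
          for (b in seq_len(B)) {
            g <- cnn_backward(model, fwds[[b]], dscores[b, ])
            grads <- if (is.null(grads)) g else
              stats::setNames(lapply(names(g), function(nm) grads[[nm]] + g[[nm]]), names(g))
          }
          step <- optimizer_step(opt, model$params, grads, lr_each)
          opt <- step$opt
          model$params <- step$params
        }
        val_acc <- NA_real_
        if (!is.null(validation) && nrow(validation) > 0L) {
          val_pred <- predict_scores(model, validation$image)
          val_y <- match(as.character(validation$label), classes)
          val_acc <- mean(max.col(val_pred, ties.method = "first") == val_y)
        }
        metrics[[ep]] <- tibble::tibble(
          epoch = ep, loss = total_loss / n,
          train_accuracy = total_correct / n, val_accuracy = val_acc
        )
      }
    })
  }
  structure(
    list(
      model = model,
      metrics = dplyr::bind_rows(metrics),
      classes = classes,
      config = config
    ),
    class = "cnn_fit"
  )
}

# score matrix (n x K) for a list of images
predict_scores <- function(model, images) {
  out <- matrix(0, length(images), model$n_classes)
  for (i in seq_along(images)) {
    out[i, ] <- cnn_forward(model, images[[i]], keep_cache = FALSE)$scores
  }
  softmax_rows(out)
}

#' Predict class probabilities and labels
#'
#' Softmax scores for new images; each score row sums to one, and the
#' predicted label is the argmax with lowest-index tie-break.
#'
#' @param object A `cnn_fit` from [train_cnn()].
#' @param new_data Data frame with an `image` list-column (a bare list of
#'   images is also accepted).
#' @param ... Unused.
#' @return A tibble with one `.pred_<class>` probability column per class and
#'   a `.pred_class` column.
#' @export
predict.cnn_fit <- function(object, new_data, ...) {
  images <- if (is.data.frame(new_data)) new_data$image else new_data
  check_image_data(tibble::tibble(image = images, label = NA), object$model$spec$input)
  probs <- predict_scores(object$model, images)
  classes <- object$classes
  out <- tibble::as_tibble(as.data.frame(probs))
  names(out) <- paste0(".pred_", classes)
  out$.pred_class <- classes[max.col(probs, ties.method = "first")]
  out
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit> %d classes, %d epochs (%s, lr %g)\n",
              length(x$classes), nrow(x$metrics), x$config$method,
              x$config$initial_lr))
  if (nrow(x$metrics) > 0) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final loss %.4f, train acc %.3f, val acc %s\n",
                last$loss, last$train_accuracy,
                ifelse(is.na(last$val_accuracy), "-", sprintf("%.3f", last$val_accuracy))))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training metrics of a fitted CNN
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `loss`, `train_accuracy`,
#'   `val_accuracy`.
#' @export
tidy.cnn_fit <- function(x, ...) x$metrics

#' One-row summary of a fitted CNN
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return One-row tibble: `epochs`, `final_loss`, `final_train_accuracy`,
#'   `final_val_accuracy`, `n_parameters`, `method`.
#' @export
glance.cnn_fit <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    epochs = nrow(m),
    final_loss = if (nrow(m)) m$loss[nrow(m)] else NA_real_,
    final_train_accuracy = if (nrow(m)) m$train_accuracy[nrow(m)] else NA_real_,
    final_val_accuracy = if (nrow(m)) m$val_accuracy[nrow(m)] else NA_real_,
    n_parameters = sum(lengths(x$model$params)),
    method = x$config$method
  )
}

#' Training-curve plot for a fitted CNN
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and accuracies against epoch.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  m <- object$metrics
  if (nrow(m) == 0) stop("no epochs were run", call. = FALSE)
  long <- tibble::tibble(
    epoch = rep(m$epoch, 3),
    metric = rep(c("loss", "train_accuracy", "val_accuracy"), each = nrow(m)),
    value = c(m$loss, m$train_accuracy, m$val_accuracy)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

# ---- backbone plug-in registry ---------------------------------------------

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone constructor
#'
#' Adapters make externally defined architectures (for example pretrained
#' deep models) available to the training harness as opaque plug-ins. A
#' constructor takes `(n_classes, seed)` and returns a model object the
#' training loop understands.
#'
#' @param name Backbone identifier.
#' @param constructor Function of `(n_classes, seed)`.
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, constructor) {
  stopifnot(is.character(name), length(name) == 1L, is.function(constructor))
  assign(name, constructor, envir = .backbone_registry)
  invisible(name)
}

#' Load a classification backbone by name
#'
#' Looks up a registered adapter and builds a model with its final
#' classification layer sized to `n_classes`. With `weights = NULL` the model
#' is randomly initialized (training from scratch); when a previously saved
#' model state is supplied, its parameters are copied in, optionally only for
#' the unit (parameter-group) range `transfer_range`.
#'
#' @param name Registered backbone name; `"simple_cnn"` is built in.
#' @param n_classes Number of output classes.
#' @param weights Optional model object (or `cnn_fit`) to transfer parameters
#'   from.
#' @param transfer_range Optional integer range of parameter-group indices to
#'   transfer (in `names(model$params)` order); `NULL` transfers all but the
#'   final layer when sizes differ.
#' @param seed Seed for the randomly initialized parts.
#' @return A model object compatible with [train_cnn()].
#' @export
load_backbone <- function(name, n_classes, weights = NULL,
                          transfer_range = NULL, seed = 0L) {
  if (!exists(name, envir = .backbone_registry, inherits = FALSE)) {
    stop(sprintf("unknown backbone '%s'; registered: %s", name,
                 paste(ls(.backbone_registry), collapse = ", ")),
         call. = FALSE)
  }
  ctor <- get(name, envir = .backbone_registry)
  model <- ctor(n_classes, seed)
  if (!is.null(weights)) {
    src <- if (inherits(weights, "cnn_fit")) weights$model else weights
    if (is.null(src$params)) stop("`weights` does not carry parameters", call. = FALSE)
    nms <- names(model$params)
    take <- if (is.null(transfer_range)) seq_along(nms) else as.integer(transfer_range)
    if (any(take < 1L | take > length(nms))) {
      stop("`transfer_range` outside parameter groups", call. = FALSE)
    }
    for (i in take) {
      nm <- nms[i]
      if (!nm %in% names(src$params)) next
      if (identical(dim(src$params[[nm]]), dim(model$params[[nm]])) &&
          length(src$params[[nm]]) == length(model$params[[nm]])) {
        model$params[[nm]] <- src$params[[nm]]
      }
    }
  }
  model
}

# built-in adapter: the small CNN itself
register_backbone("simple_cnn", function(n_classes, seed) {
  build_simple_cnn(n_classes, seed)
})
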