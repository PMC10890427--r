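## Image-level binary classification (with vs without microfracture): the
## pre-screen stage of the dual-method design. A compact 15-processing-layer
## convolutional network — 4 x (3x3 convolution, batch normalization, ReLU)
## with 2x2 max pooling after the first three blocks — followed by a global
## max pool, dense layer and softmax head, trained with stochastic gradient
## descent with momentum (SGDM).

#' Classifier configuration
#'
#' Presets follow the source acquisition geometry (480x854, 960x960, 480x480);
#' the 128x128 preset keeps training at desk scale. Arbitrary-resolution
#' inputs are rescaled to the configured size inside training and inference.
#'
#' @param input_height,input_width Network input size (multiples of 8).
#' @param n_channels Input channels (3; grayscale is replicated).
#' @param channels Feature channels of the four convolution blocks.
#' @param learning_rate,momentum,weight_decay SGDM hyperparameters. The
#'   learning rate default (0.003) is the largest value stable under
#'   batch-normalized minibatches of 16 on this architecture; weight decay is
#'   the usual L2 penalty on convolution and dense weights.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param balance `"class_weights"` (default: inverse-frequency loss weights,
#'   used because augmentation-equalized retraining proved unsatisfactory in
#'   the source workflow) or `"none"`.
#' @param seed Integer seed controlling initialization and shuffling.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(input_height = 128L, input_width = 128L,
                              n_channels = 3L,
                              channels = c(8L, 16L, 32L, 32L),
                              learning_rate = 0.003, momentum = 0.9,
                              weight_decay = 1e-4,
                              epochs = 12L, batch_size = 16L,
                              balance = c("class_weights", "none"),
                              seed = 1L) {
  balance <- match.arg(balance)
  stopifnot(input_height %% 8 == 0, input_width %% 8 == 0,
            length(channels) == 4L, epochs >= 1, batch_size >= 2)
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 n_channels = as.integer(n_channels),
                 channels = as.integer(channels),
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 balance = balance, seed = as.integer(seed)),
            class = "classifier_config")
}

class_levels <- c("with_microfracture", "without_microfracture")

# image (matrix or H x W x 3 array), any size -> flat-layout (h*w x 3) float
# matrix in roughly [-0.5, 0.5]
prep_image <- function(img, h, w) {
  if (length(dim(img)) == 3L) img <- rec601_luminance(img[, , 1], img[, , 2], img[, , 3])
  if (!all(dim(img) == c(h, w))) {
    img <- as.matrix(EBImage::resize(EBImage::Image(img), w = h, h = w))
  }
  v <- as.vector(img) / 255 - 0.5
  matrix(v, h * w, 3L)
}

random_augment <- function(img, background) {
  choice <- sample.int(4L, 1L)
  im <- EBImage::Image(img)
  out <- switch(choice,
    EBImage::flip(im),                                   # vertical flip
    EBImage::flop(im),                                   # horizontal flip
    EBImage::rotate(im, stats::runif(1, -15, 15),
                    output.dim = dim(img), bg.col = background),
    {
      sh <- round(stats::runif(2, -0.05, 0.05) * dim(img))
      EBImage::translate(im, c(sh[2], sh[1]), bg.col = background)
    })
  as.matrix(out)
}

#' Augment a labeled image set
#'
#' Adds flipped/rotated (+-15 degrees)/translated (+-5%) copies of existing
#' images until each requested class reaches `target_per_class`; originals are
#' retained and labels never change. Deterministic under `seed`. A class
#' already at or above the target is returned unchanged.
#'
#' @param ds A `labeled_image_set`.
#' @param target_per_class Desired images per class.
#' @param seed Integer seed.
#' @param classes Which classes to augment (default: all).
#' @return A `labeled_image_set`; augmented entries have
#'   `provenance = "augmented"` and an `aug_source` attribute on each image
#'   giving the source index.
#' @export
augment_dataset <- function(ds, target_per_class, seed = 1L,
                            classes = class_levels) {
  stopifnot(inherits(ds, "labeled_image_set"), length(ds$images) > 0)
  set.seed(seed)
  images <- ds$images; labels <- as.character(ds$labels)
  prov <- ds$provenance
  for (cl in classes) {
    src <- which(labels == cl)
    n_have <- length(src)
    if (n_have == 0L || n_have >= target_per_class) next
    need <- target_per_class - n_have
    for (i in seq_len(need)) {
      s <- src[(i - 1L) %% n_have + 1L]
      img <- random_augment(ds$images[[s]], background = 20)
      attr(img, "aug_source") <- s
      images[[length(images) + 1L]] <- img
      labels[length(labels) + 1L] <- cl
      prov[length(prov) + 1L] <- "augmented"
    }
  }
  structure(list(images = images,
                 labels = factor(labels, levels = class_levels),
                 provenance = prov),
            class = "labeled_image_set")
}

#' Train the convolutional microfracture classifier
#'
#' Trains the 15-processing-layer network with SGDM. Inputs of any resolution
#' are rescaled to the configured input size. The training log records the
#' per-epoch mean loss and training accuracy (plus validation accuracy when a
#' validation set is given). Reproducible under `cfg$seed`.
#'
#' @param train A `labeled_image_set` containing both classes.
#' @param cfg A [classifier_config()].
#' @param validation Optional held-out `labeled_image_set` scored per epoch.
#' @return An object of class `microfract_cnn`: the fitted network, `cfg`,
#'   and a `log` tibble (`epoch`, `loss`, `train_accuracy`,
#'   `val_accuracy`).
#' @export
train_classifier <- function(train, cfg = classifier_config(),
                             validation = NULL) {
  stopifnot(inherits(train, "labeled_image_set"))
  y <- as.integer(train$labels) # 1 = with, 2 = without
  if (length(unique(y)) < 2L) stop("training set must contain both classes")
  h <- cfg$input_height; w <- cfg$input_width
  n <- length(train$images)

  xs <- lapply(train$images, prep_image, h = h, w = w)
  cw <- c(1, 1)
  if (cfg$balance == "class_weights") {
    freq <- tabulate(y, nbins = 2L)
    cw <- (n / 2) / pmax(freq, 1L)
  }

  net <- cnn_new(h, w, channels = cfg$channels,
                 n_input_channels = cfg$n_channels, seed = cfg$seed)
  log_rows <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c(); correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      ids <- ord[start:min(start + cfg$batch_size - 1L, n)]
      if (length(ids) < 2L) next # batch norm needs > 1 sample
      B <- length(ids)
      xb <- matrix(0, h * w * B, cfg$n_channels)
      for (b in seq_len(B)) {
        xb[((b - 1L) * h * w + 1L):(b * h * w), ] <- xs[[ids[b]]]
      }
      yb <- y[ids]
      fwd <- cnn_forward(net, xb, B, training = TRUE)
      net <- fwd$net
      p <- fwd$probs
      wts <- cw[yb]
      loss <- -sum(wts * log(pmax(p[cbind(seq_len(B), yb)], 1e-12))) / sum(wts)
      onehot <- matrix(0, B, 2L); onehot[cbind(seq_len(B), yb)] <- 1
      dlogits <- (p - onehot) * wts / sum(wts)
      grads <- cnn_backward(net, fwd, dlogits)
      net <- sgdm_step(net, grads, cfg$learning_rate, cfg$momentum,
                       cfg$weight_decay)
      losses <- c(losses, loss)
      correct <- correct + sum(max.col(p) == yb)
    }
    val_acc <- NA_real_
    if (!is.null(validation)) {
      val_acc <- evaluate_accuracy(
        structure(list(net = net, cfg = cfg), class = "microfract_cnn"),
        validation)$accuracy
    }
    log_rows[[ep]] <- tibble::tibble(epoch = ep, loss = mean(losses),
                                     train_accuracy = correct / n,
                                     val_accuracy = val_acc)
  }
  structure(list(net = net, cfg = cfg, log = dplyr::bind_rows(log_rows)),
            class = "microfract_cnn")
}

predict_probs <- function(model, images, chunk = 32L) {
  h <- model$cfg$input_height; w <- model$cfg$input_width
  n <- length(images)
  probs <- matrix(0, n, 2L)
  for (start in seq(1L, n, by = chunk)) {
    ids <- start:min(start + chunk - 1L, n)
    B <- length(ids)
    xb <- matrix(0, h * w * B, model$cfg$n_channels)
    for (b in seq_len(B)) {
      xb[((b - 1L) * h * w + 1L):(b * h * w), ] <- prep_image(images[[ids[b]]], h, w)
    }
    fwd <- cnn_forward(model$net, xb, B, training = FALSE)
    probs[ids, ] <- fwd$probs
  }
  colnames(probs) <- class_levels
  probs
}

#' Classify one image
#'
#' @param model A fitted `microfract_cnn`.
#' @param image Grayscale matrix (or RGB array) of any resolution.
#' @return List with `label` (factor level) and `score` (probability of the
#'   predicted class; the two class scores sum to 1).
#' @export
classify_image <- function(model, image) {
  stopifnot(inherits(model, "microfract_cnn"))
  p <- predict_probs(model, list(image))
  k <- which.max(p[1, ])
  list(label = factor(class_levels[k], levels = class_levels),
       score = unname(p[1, k]))
}

#' Evaluate classification accuracy on a labeled set
#'
#' @param model A fitted `microfract_cnn`.
#' @param test A nonempty `labeled_image_set`.
#' @return List with `accuracy` (fraction correct), `confusion` (2x2 table,
#'   truth in rows), and `predictions` (factor).
#' @export
evaluate_accuracy <- function(model, test) {
  stopifnot(inherits(model, "microfract_cnn"), length(test$images) > 0)
  p <- predict_probs(model, test$images)
  pred <- factor(class_levels[max.col(p, ties.method = "first")],
                 levels = class_levels)
  truth <- factor(as.character(test$labels), levels = class_levels)
  list(accuracy = mean(pred == truth),
       confusion = table(truth = truth, predicted = pred),
       predictions = pred)
}

#' @export
print.microfract_cnn <- function(x, ...) {
  cat(sprintf(paste0("<microfract_cnn> %dx%dx%d input, channels %s\n",
                     "  trained %d epochs; final loss %.4f, train accuracy %.3f\n"),
              x$cfg$input_height, x$cfg$input_width, x$cfg$n_channels,
              paste(x$cfg$channels, collapse = "-"),
              nrow(x$log), x$log$loss[nrow(x$log)],
              x$log$train_accuracy[nrow(x$log)]))
  invisible(x)
}

#' Save / load a classifier checkpoint
#'
#' Single-file JSON checkpoint with a versioned header; weights are stored as
#' flat numeric vectors, so checkpoints are plain text and portable.
#'
#' @param model A `microfract_cnn`.
#' @param path Output file.
#' @return `save_classifier`: invisibly, `path`. `load_classifier`: the model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "microfract_cnn"))
  ser <- list(format = "microfract_cnn", version = 1L,
              cfg = unclass(model$cfg), log = model$log,
              net = serialize_net(model$net))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "microfract_cnn")) stop("not a classifier checkpoint")
  cfg <- structure(j$cfg, class = "classifier_config")
  net <- cnn_new(cfg$input_height, cfg$input_width, channels = cfg$channels,
                 n_input_channels = cfg$n_channels, seed = cfg$seed)
  net <- deserialize_net(net, j$net)
  structure(list(net = net, cfg = cfg, log = tibble::as_tibble(j$log)),
            class = "microfract_cnn")
}

serialize_net <- function(net) {
  out <- list()
  for (k in 1:4) {
    cv <- net$blocks[[k]]$conv; bn <- net$blocks[[k]]$bn
    out[[paste0("block", k)]] <- list(
      W = as.vector(cv$W), b = cv$b, gamma = bn$gamma, beta = bn$beta,
      run_mean = bn$run_mean, run_var = bn$run_var)
  }
  out$dense <- list(W = as.vector(net$dense$W), b = net$dense$b)
  out
}

deserialize_net <- function(net, ser) {
  for (k in 1:4) {
    s <- ser[[paste0("block", k)]]
    cv <- net$blocks[[k]]$conv
    cv$W <- matrix(s$W, nrow(cv$W), ncol(cv$W))
    cv$b <- s$b
    net$blocks[[k]]$conv <- cv
    bn <- net$blocks[[k]]$bn
    bn$gamma <- s$gamma; bn$beta <- s$beta
    bn$run_mean <- s$run_mean; bn$run_var <- s$run_var
    net$blocks[[k]]$bn <- bn
  }
  net$dense$W <- matrix(ser$dense$W, 2L)
  net$dense$b <- ser$dense$b
  net
}
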