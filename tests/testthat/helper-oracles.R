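# Independent brute-force oracles used to check the package's fast paths,
# plus small fixture builders shared across test files.

# breadth-first connected-component count/labels for a 2D mask
bf_label_2d <- function(mask, connectivity = 8L) {
  nb <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  lbl <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (start in which(mask)) {
    if (lbl[start] != 0L) next
    k <- k + 1L
    queue <- start
    lbl[start] <- k
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nrow(mask) + 1L
      c <- (cur - 1L) %/% nrow(mask) + 1L
      for (i in seq_len(nrow(nb))) {
        rr <- r + nb[i, 1]; cc <- c + nb[i, 2]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
          lin <- rr + (cc - 1L) * nrow(mask)
          if (mask[lin] && lbl[lin] == 0L) {
            lbl[lin] <- k
            queue <- c(queue, lin)
          }
        }
      }
    }
  }
  lbl
}

# plain union-find 3D component count over a logical volume
bf_components_3d <- function(vol, connectivity = 26L) {
  dm <- dim(vol)
  fg <- which(vol)
  if (!length(fg)) return(0L)
  parent <- seq_along(fg)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  id <- integer(prod(dm)); id[fg] <- seq_along(fg)
  ind <- arrayInd(fg, dm)
  offs <- expand.grid(dr = -1:1, dc = -1:1, dz = -1:1)
  offs <- offs[rowSums(offs != 0) > 0, ]
  deg <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = deg == 1, "18" = deg <= 2, deg <= 3), ]
  for (v in seq_along(fg)) {
    for (k in seq_len(nrow(offs))) {
      rr <- ind[v, 1] + offs[k, 1]; cc <- ind[v, 2] + offs[k, 2]
      zz <- ind[v, 3] + offs[k, 3]
      if (rr >= 1 && rr <= dm[1] && cc >= 1 && cc <= dm[2] &&
          zz >= 1 && zz <= dm[3]) {
        lin <- rr + (cc - 1L) * dm[1] + (zz - 1L) * dm[1] * dm[2]
        if (vol[lin]) {
          a <- find(v); b <- find(id[lin])
          if (a != b) parent[a] <- b
        }
      }
    }
  }
  length(unique(vapply(seq_along(fg), find, 1L)))
}

# enclosed background count via explicit border flood fill
bf_enclosed_background <- function(mask) {
  bg <- !mask
  reach <- matrix(FALSE, nrow(mask), ncol(mask))
  queue <- which(bg & (row(mask) %in% c(1, nrow(mask)) |
                       col(mask) %in% c(1, ncol(mask))))
  reach[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    r <- (cur - 1L) %% nrow(mask) + 1L
    c <- (cur - 1L) %/% nrow(mask) + 1L
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask)) {
        lin <- rr + (cc - 1L) * nrow(mask)
        if (bg[lin] && !reach[lin]) { reach[lin] <- TRUE; queue <- c(queue, lin) }
      }
    }
  }
  sum(bg & !reach)
}

# random blobby mask for property tests
random_mask <- function(n = 64, p = 0.2, seed = 1) {
  set.seed(seed)
  matrix(runif(n * n) < p, n, n)
}

# tiny separable image set: bright blob vs blank, both noisy
toy_labeled_set <- function(n_per_class = 20, size = 32, seed = 1) {
  set.seed(seed)
  mk <- function(blob) {
    m <- matrix(20, size, size)
    if (blob) {
      r <- sample(8:(size - 8), 1); c <- sample(8:(size - 8), 1)
      m[(r - 3):(r + 3), (c - 3):(c + 3)] <- 200
    }
    m + matrix(rnorm(size * size, 0, 4), size, size)
  }
  structure(list(
    images = c(lapply(seq_len(n_per_class), function(i) mk(TRUE)),
               lapply(seq_len(n_per_class), function(i) mk(FALSE))),
    labels = factor(rep(c("with_microfracture", "without_microfracture"),
                        each = n_per_class),
                    levels = c("with_microfracture", "without_microfracture")),
    provenance = rep("synthetic", 2 * n_per_class)),
    class = "labeled_image_set")
}

# memoized heavy objects shared between test files (trained once per run)
.shared <- new.env(parent = emptyenv())

shared_t5 <- function() {
  if (is.null(.shared$t5)) {
    spec <- synth_spec(height = 128L, width = 128L)
    train <- generate_labeled_dataset(spec, 400, 400, seed = 2)
    test <- generate_labeled_dataset(spec, 200, 200, seed = 20002)
    model <- train_classifier(train, classifier_config(seed = 2))
    .shared$t5 <- list(model = model, test = test,
                       eval = evaluate_accuracy(model, test))
  }
  .shared$t5
}
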