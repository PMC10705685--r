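# CNN descriptor stage.
#
# Every backbone exposes the same contract: a normalized 224 x 224 RGB
# input and a 1000-dimensional output vector (the ImageNet-head activations
# used as the extracted feature). The always-available "tiny-test" backbone
# is a small randomly initialized two-layer convolutional network with a
# linear 1000-dim head; the named large architectures are declared but need
# a user-supplied weight loader. Fine-tuning trains a softmax classifier
# head on frozen trunk features with SGD + momentum, a stepped learning-rate
# schedule and a two-phase early-stopping rule.

.backbone_names <- c("VGG16", "ResNet101", "DenseNet169", "MobileNetV3-L",
                     "RegNetX-8GF", "ConvNeXt-S", "tiny-test")

#' Construct a backbone specification
#'
#' @param name one of "tiny-test" (default; random weights, no download) or
#'   a named ImageNet architecture, which then requires `weights` produced
#'   by an external loader.
#' @param seed seed for the tiny-test random weights.
#' @param weights optional externally loaded weights for named architectures:
#'   a function(array224) -> numeric(1000).
#' @return an object of class `backbone_spec` with `output_dim` 1000.
#' @export
backbone_spec <- function(name = "tiny-test", seed = 1, weights = NULL) {
  name <- match.arg(name, .backbone_names)
  w <- NULL
  if (name == "tiny-test") {
    w <- withr::with_seed(derive_seed(seed, 99L), {
      list(conv1 = array(rnorm(3 * 3 * 3 * 8, 0, sqrt(2 / 27)), c(3, 3, 3, 8)),
           conv2 = array(rnorm(3 * 3 * 8 * 16, 0, sqrt(2 / 72)), c(3, 3, 8, 16)),
           head_W = matrix(rnorm(1000 * 1024, 0, sqrt(1 / 1024)), 1000, 1024),
           head_b = rnorm(1000, 0, 0.01))
    })
  } else if (is.null(weights)) {
    # declared but not loadable without external pretrained weights
    w <- NULL
  }
  structure(list(name = name, input_size = 224L, output_dim = 1000L,
                 weights = if (is.null(w)) weights else w, head = NULL),
            class = "backbone_spec")
}

# 'same'-padded 3x3 convolution + ReLU for an H x W x Cin array.
.conv_relu <- function(x, kern) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(kern)[3]; cout <- dim(kern)[4]
  xp <- array(0, c(H + 2, W + 2, cin))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  # im2col: each output pixel sees a 3*3*cin patch
  patch <- matrix(0, H * W, 9 * cin)
  k <- 1
  for (c in seq_len(cin)) for (dc in 0:2) for (dr in 0:2) {
    patch[, k] <- as.vector(xp[(1 + dr):(H + dr), (1 + dc):(W + dc), c])
    k <- k + 1
  }
  km <- matrix(0, 9 * cin, cout)
  k <- 1
  for (c in seq_len(cin)) for (dc in 0:2) for (dr in 0:2) {
    km[k, ] <- kern[dr + 1, dc + 1, c, ]
    k <- k + 1
  }
  out <- patch %*% km
  out[out < 0] <- 0
  array(out, c(H, W, cout))
}

.maxpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  o <- array(0, c(H / 2, W / 2, C))
  for (c in seq_len(C)) {
    m <- x[, , c]
    o[, , c] <- pmax(m[seq(1, H, 2), seq(1, W, 2)], m[seq(2, H, 2), seq(1, W, 2)],
                     m[seq(1, H, 2), seq(2, W, 2)], m[seq(2, H, 2), seq(2, W, 2)])
  }
  o
}

#' Extract a 1000-dimensional CNN feature vector
#'
#' The crop is resized to the backbone's 224 x 224 input and channel-
#' normalized (ImageNet means/sds); the backbone forward pass returns its
#' 1000-dim head output. Deterministic in eval mode.
#'
#' @param backbone a `backbone_spec`.
#' @param crop a `crop_result` or an H x W x 3 array.
#' @return numeric vector of length 1000.
#' @export
extract_features <- function(backbone, crop) {
  stopifnot(inherits(backbone, "backbone_spec"))
  if (inherits(crop, "crop_result")) crop <- crop$crop_rgb
  if (is.null(backbone$weights))
    stop("no weights available for backbone '", backbone$name,
         "'; supply a pretrained weight loader or use 'tiny-test'")
  x <- resize_raster(crop, 224, 224)
  mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
  for (c in 1:3) x[, , c] <- (x[, , c] - mu[c]) / sdv[c]
  if (is.function(backbone$weights)) return(backbone$weights(x))
  w <- backbone$weights
  x <- resize_raster(x, 32, 32)            # tiny-test internal resolution
  x <- .maxpool2(.conv_relu(x, w$conv1))   # 16 x 16 x 8
  x <- .maxpool2(.conv_relu(x, w$conv2))   # 8 x 8 x 16
  as.vector(w$head_W %*% as.vector(x) + w$head_b)
}

#' Training protocol constants
#'
#' SGD with momentum 0.9, cross-entropy loss, batch size 64, initial
#' learning rate 1e-4 decayed by 0.8 every 5 epochs, and two-phase early
#' stopping: convergence begins once training loss fluctuates by < 0.001
#' over 5 epochs, and training halts when validation loss then shifts by
#' < 0.005 over another 5 epochs. The checkpoint with peak validation
#' accuracy is kept.
#'
#' @param max_epochs training-epoch cap (the stopping rule usually fires
#'   first).
#' @return a list of protocol constants.
#' @export
train_protocol <- function(max_epochs = 200) {
  list(optimizer = "sgd", momentum = 0.9, loss = "cross-entropy",
       batch_size = 64, lr0 = 1e-4, lr_factor = 0.8, lr_every = 5,
       train_loss_flux_tol = 0.001, val_loss_shift_tol = 0.005,
       window = 5, max_epochs = max_epochs)
}

#' Stepped learning-rate schedule
#'
#' lr(epoch) = lr0 * factor^floor((epoch - 1) / every) for 1-based epochs,
#' i.e. the rate drops by `factor` every `every` epochs.
#'
#' @param epoch 1-based epoch number (vectorized).
#' @param lr0 initial learning rate.
#' @param factor decay multiplier.
#' @param every epochs between decays.
#' @return learning rate(s).
#' @export
lr_schedule <- function(epoch, lr0 = 1e-4, factor = 0.8, every = 5) {
  lr0 * factor^((epoch - 1) %/% every)
}

#' Two-phase early-stopping rule
#'
#' Scans loss traces for the first epoch `s` at which the training loss has
#' fluctuated (max - min) by less than `flux_tol` over the trailing
#' `window` epochs; training is considered fully converged at the first
#' epoch `f >= s + window` at which the validation loss has shifted by less
#' than `shift_tol` over the trailing `window` epochs, and `f` is returned.
#'
#' @param train_loss,val_loss numeric per-epoch loss traces.
#' @param flux_tol training-loss fluctuation tolerance.
#' @param shift_tol validation-loss shift tolerance.
#' @param window trailing window length in epochs.
#' @return the stop epoch, or NA if the rule never fires.
#' @export
early_stop_epoch <- function(train_loss, val_loss, flux_tol = 0.001,
                             shift_tol = 0.005, window = 5) {
  n <- length(train_loss)
  stopifnot(length(val_loss) == n)
  if (n < 2 * window) return(NA_integer_)
  flux <- function(x, e) max(x[(e - window + 1):e]) - min(x[(e - window + 1):e])
  s <- NA_integer_
  for (e in window:n) if (flux(train_loss, e) < flux_tol) { s <- e; break }
  if (is.na(s)) return(NA_integer_)
  for (f in (s + window):n) {
    if (f < window) next
    if (flux(val_loss, f) < shift_tol) return(f)
  }
  NA_integer_
}

#' Photographic data augmentation
#'
#' Applies a random subset (each family with probability 1/2) of horizontal
#' flip, integer translation, rotation and brightness scaling, with
#' magnitudes bounded by `magnitudes`. Deterministic under a fixed seed;
#' with all magnitudes zero the input is returned unchanged. Output always
#' has the input's dimensions.
#'
#' @param image H x W x 3 array in [0,1] (or a `pupa_image`).
#' @param seed integer seed.
#' @param magnitudes list(flip = logical, max_shift = px, max_angle =
#'   degrees, max_brightness = fraction).
#' @return augmented H x W x 3 array.
#' @export
augment <- function(image, seed,
                    magnitudes = list(flip = TRUE, max_shift = 10,
                                      max_angle = 15, max_brightness = 0.2)) {
  if (inherits(image, "pupa_image")) image <- image$pixels
  H <- dim(image)[1]; W <- dim(image)[2]
  withr::with_seed(derive_seed(seed, 31L), {
    out <- image
    bg <- apply(image[c(1, H), , , drop = FALSE], 3, stats::median)
    if (isTRUE(magnitudes$flip) && runif(1) < 0.5)
      out <- out[, W:1, , drop = FALSE]
    if (runif(1) < 0.5 && magnitudes$max_shift > 0) {
      dr <- sample(-magnitudes$max_shift:magnitudes$max_shift, 1)
      dc <- sample(-magnitudes$max_shift:magnitudes$max_shift, 1)
      shifted <- array(rep(bg, each = H * W), dim = dim(out))
      sr <- max(1, 1 + dr):min(H, H + dr); sc <- max(1, 1 + dc):min(W, W + dc)
      shifted[sr, sc, ] <- out[sr - dr, sc - dc, , drop = FALSE]
      out <- shifted
    }
    if (runif(1) < 0.5 && magnitudes$max_angle > 0) {
      ang <- runif(1, -magnitudes$max_angle, magnitudes$max_angle) * pi / 180
      cy <- (H + 1) / 2; cx <- (W + 1) / 2
      rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
      srr <- round(cy + cos(ang) * (rr - cy) - sin(ang) * (cc - cx))
      scc <- round(cx + sin(ang) * (rr - cy) + cos(ang) * (cc - cx))
      ok <- srr >= 1 & srr <= H & scc >= 1 & scc <= W
      rot <- array(rep(bg, each = H * W), dim = dim(out))
      for (ch in 1:3) {
        plane <- rot[, , ch]
        src <- out[, , ch]
        plane[ok] <- src[cbind(srr[ok], scc[ok])]
        rot[, , ch] <- plane
      }
      out <- rot
    }
    if (runif(1) < 0.5 && magnitudes$max_brightness > 0) {
      fac <- 1 + runif(1, -magnitudes$max_brightness, magnitudes$max_brightness)
      out <- pmin(pmax(out * fac, 0), 1)
    }
    out
  })
}

#' Fine-tune a backbone on labeled crops
#'
#' Features are extracted once with the frozen trunk; a softmax classifier
#' head (1000 -> n classes) is then trained per [train_protocol()]: SGD with
#' momentum 0.9, cross-entropy, batch size 64, the stepped LR schedule, and
#' the two-phase early-stopping rule. The head from the epoch with peak
#' validation accuracy is kept.
#'
#' @param backbone a `backbone_spec` with weights.
#' @param train_set,val_set lists with `$x` (list of crops/arrays, or a
#'   precomputed n x 1000 feature matrix) and `$y` (labels).
#' @param protocol a [train_protocol()].
#' @param seed integer seed for initialization and shuffling.
#' @return the backbone with `$head` (list W, b, levels), `$log` (per-epoch
#'   data.frame: epoch, lr, train_loss, val_loss, val_acc) and
#'   `$stopped_epoch` attached.
#' @export
finetune <- function(backbone, train_set, val_set, protocol = train_protocol(),
                     seed = 1) {
  feat <- function(s) {
    if (is.matrix(s$x)) s$x
    else t(vapply(s$x, function(im) extract_features(backbone, im),
                  numeric(backbone$output_dim)))
  }
  if (length(train_set$y) == 0 || length(val_set$y) == 0)
    stop("empty training or validation split")
  Xtr <- feat(train_set); Xva <- feat(val_set)
  lev <- sort(unique(c(as.character(train_set$y), as.character(val_set$y))))
  ytr <- match(as.character(train_set$y), lev)
  yva <- match(as.character(val_set$y), lev)
  K <- length(lev); P <- ncol(Xtr); n <- nrow(Xtr)
  mu <- colMeans(Xtr); sdv <- pmax(apply(Xtr, 2, stats::sd), 1e-8)
  Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
  Xva <- sweep(sweep(Xva, 2, mu), 2, sdv, "/")
  ce <- function(W, b, X, y) {
    z <- sweep(X %*% W, 2, b, "+")
    z <- z - apply(z, 1, max)
    p <- exp(z) / rowSums(exp(z))
    list(loss = -mean(log(pmax(p[cbind(seq_along(y), y)], 1e-12))), p = p)
  }
  withr::with_seed(derive_seed(seed, 7L), {
    W <- matrix(rnorm(P * K, 0, 0.01), P, K); b <- numeric(K)
    vW <- W * 0; vb <- b * 0
    log_rows <- list(); best <- list(acc = -1)
    stopped <- NA_integer_
    for (epoch in seq_len(protocol$max_epochs)) {
      lr <- lr_schedule(epoch, protocol$lr0, protocol$lr_factor, protocol$lr_every)
      ord <- sample(n)
      for (start in seq(1, n, by = protocol$batch_size)) {
        bi <- ord[start:min(start + protocol$batch_size - 1, n)]
        X <- Xtr[bi, , drop = FALSE]; y <- ytr[bi]
        fp <- ce(W, b, X, y)
        G <- fp$p
        G[cbind(seq_along(y), y)] <- G[cbind(seq_along(y), y)] - 1
        G <- G / length(y)
        gW <- t(X) %*% G; gb <- colSums(G)
        vW <- protocol$momentum * vW - lr * gW
        vb <- protocol$momentum * vb - lr * gb
        W <- W + vW; b <- b + vb
      }
      tr <- ce(W, b, Xtr, ytr); va <- ce(W, b, Xva, yva)
      acc <- mean(max.col(va$p) == yva)
      log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                      train_loss = tr$loss, val_loss = va$loss,
                                      val_acc = acc)
      if (acc > best$acc) best <- list(acc = acc, W = W, b = b, epoch = epoch)
      log_df <- do.call(rbind, log_rows)
      stop_at <- early_stop_epoch(log_df$train_loss, log_df$val_loss,
                                  protocol$train_loss_flux_tol,
                                  protocol$val_loss_shift_tol, protocol$window)
      if (!is.na(stop_at) && stop_at <= epoch) { stopped <- epoch; break }
    }
  })
  backbone$head <- list(W = best$W, b = best$b, levels = lev, center = mu,
                        scale = sdv, val_acc = best$acc, best_epoch = best$epoch)
  backbone$log <- do.call(rbind, log_rows)
  backbone$stopped_epoch <- stopped
  backbone
}
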