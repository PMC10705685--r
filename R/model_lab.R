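# Dataset partitioning, descriptor fusion and grid-searched classifiers.
#
# Partitioning follows the study design: pupa weight differs systematically
# by species and sex, so within every (species, sex) class the pupae are
# ordered by weight and assigned to splits systematically (every 5th pupa to
# test for 8:2; every 10th to calibration and to test for 8:1:1), which
# matches the weight distributions across splits. All three posture images
# of a pupa always land in the same split, preventing identity leakage.

#' Weight-stratified systematic dataset split
#'
#' @param manifest data.frame with columns pupa_id, species, sex, posture,
#'   weight (one row per image), e.g. `generate_dataset()$manifest`.
#' @param ratios c(8, 2) for train/test or c(8, 1, 1) for
#'   train/calibration/test.
#' @param seed reserved for tie-breaking pupae with identical weight.
#' @return the manifest with an added `split` column
#'   ("train"/"calibration"/"test").
#' @export
split_dataset <- function(manifest, ratios = c(8, 2), seed = 1) {
  stopifnot(all(c("pupa_id", "species", "sex", "weight") %in% names(manifest)))
  if (!identical(unname(ratios), c(8, 2)) && !identical(unname(ratios), c(8, 1, 1)))
    stop("supported split ratios are 8:2 and 8:1:1")
  cls <- paste(manifest$species, manifest$sex, sep = "_")
  pupae <- unique(data.frame(pupa_id = manifest$pupa_id, class = cls,
                             weight = manifest$weight, stringsAsFactors = FALSE))
  assign <- character(0); names(assign) <- character(0)
  for (cl in unique(pupae$class)) {
    pc <- pupae[pupae$class == cl, ]
    if (nrow(pc) < 5) stop("class ", cl, " has fewer than 5 pupae; cannot split")
    o <- withr::with_seed(derive_seed(seed, 3L),
                          order(pc$weight, stats::runif(nrow(pc))))
    pc <- pc[o, ]
    rank <- seq_len(nrow(pc))
    # systematic mid-stratum picks along the weight order: every 5th pupa
    # (offset 3) to test for 8:2; every 10th to calibration (offset 3) and
    # test (offset 8) for 8:1:1, keeping split weight distributions matched
    sp <- if (identical(unname(ratios), c(8, 2))) {
      ifelse(rank %% 5 == 3, "test", "train")
    } else {
      ifelse(rank %% 10 == 8, "test",
             ifelse(rank %% 10 == 3, "calibration", "train"))
    }
    assign[pc$pupa_id] <- sp
  }
  manifest$split <- unname(assign[manifest$pupa_id])
  manifest
}

#' Fit a feature-fusion reducer on training data
#'
#' Each descriptor block is z-scored with training statistics; blocks wider
#' than `target_dim` are then compressed to exactly `target_dim` columns by
#' a variance-maximizing linear projection (principal-component loadings,
#' completed to an orthonormal basis of the requested width when the
#' training sample supports fewer components); narrower blocks pass through
#' unchanged. Fit on the training split only; apply everywhere with
#' [apply_fusion()].
#'
#' @param train_features named list of numeric matrices (rows = training
#'   samples, shared row order) keyed by descriptor name.
#' @param target_dim compression target, default 500.
#' @return an object of class `fusion_fit`.
#' @export
fit_fusion <- function(train_features, target_dim = 500) {
  stopifnot(is.list(train_features), length(train_features) >= 1)
  members <- lapply(names(train_features), function(nm) {
    x <- as.matrix(train_features[[nm]])
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl < 1e-12] <- 1
    xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    proj <- NULL
    if (ncol(x) > target_dim) {
      pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
      R <- pc$rotation[, seq_len(min(ncol(pc$rotation), target_dim)), drop = FALSE]
      if (ncol(R) < target_dim) {
        # complete to an orthonormal target_dim-frame (deterministic QR)
        base <- diag(ncol(x))[, seq_len(target_dim), drop = FALSE]
        Q <- qr.Q(qr(cbind(R, base)))[, seq_len(target_dim), drop = FALSE]
        Q[, seq_len(ncol(R))] <- R
        R <- Q
      }
      proj <- R
    }
    list(name = nm, center = ctr, scale = scl, proj = proj,
         in_dim = ncol(x), out_dim = if (is.null(proj)) ncol(x) else target_dim)
  })
  names(members) <- names(train_features)
  structure(list(members = members, order = names(train_features),
                 target_dim = target_dim), class = "fusion_fit")
}

#' Apply a fitted fusion to feature blocks
#'
#' Standardizes and projects each descriptor block with the train-fitted
#' parameters (no refit) and concatenates the blocks in the fitted order.
#'
#' @param fit a `fusion_fit`.
#' @param features named list of matrices with the same descriptors (and
#'   column counts) used at fit time; rows are samples.
#' @return numeric matrix n x sum(out_dims).
#' @export
apply_fusion <- function(fit, features) {
  stopifnot(inherits(fit, "fusion_fit"))
  missing <- setdiff(fit$order, names(features))
  if (length(missing))
    stop("missing descriptor block(s): ", paste(missing, collapse = ", "))
  blocks <- lapply(fit$order, function(nm) {
    m <- fit$members[[nm]]
    x <- as.matrix(features[[nm]])
    if (ncol(x) != m$in_dim)
      stop("descriptor '", nm, "' has ", ncol(x), " columns; expected ", m$in_dim)
    bad <- rownames(x)[!stats::complete.cases(x)]
    if (length(bad))
      stop("descriptor '", nm, "' has missing values for sample(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
    xs <- sweep(sweep(x, 2, m$center), 2, m$scale, "/")
    if (is.null(m$proj)) xs else xs %*% m$proj
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(features[[fit$order[1]]])
  out
}

#' Classifier specification with its hyperparameter grid
#'
#' Fixed settings and search grids mirror the study protocol: MLP with ReLU
#' activation and an L-BFGS solver (hidden sizes 25..150 and the two-layer
#' variants (25,25)..(100,100), alpha 1e-1..1e-6); one-vs-rest RBF SVM
#' (C in 2^-5..2^5, gamma in 2^-15, 2^-13, ..., 2^5); random forest with
#' Gini impurity (200..800 trees in steps of 10). `variant = "deep"` selects
#' the fixed settings used with CNN features (MLP hidden 120 / alpha 1e-5,
#' linear SVM with C = 1, RF with 500 trees). Random state is fixed at 9.
#'
#' @param kind "mlp", "svm" or "rf".
#' @param variant "traditional" (grid search) or "deep" (fixed parameters).
#' @param grid optional data.frame overriding the default grid.
#' @param random_state integer seed used for CV folds and model fits.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("mlp", "svm", "rf"),
                            variant = c("traditional", "deep"),
                            grid = NULL, random_state = 9) {
  kind <- match.arg(kind); variant <- match.arg(variant)
  if (is.null(grid)) {
    grid <- if (variant == "deep") {
      switch(kind,
             mlp = data.frame(hidden = I(list(120)), alpha = 1e-5),
             svm = data.frame(kernel = "linear", C = 1, gamma = NA_real_),
             rf = data.frame(ntree = 500))
    } else {
      switch(kind,
             mlp = {
               hid <- c(as.list(seq(25, 150, by = 25)),
                        list(c(25, 25), c(50, 50), c(75, 75), c(100, 100)))
               g <- expand.grid(h = seq_along(hid), alpha = 10^-(1:6))
               data.frame(hidden = I(hid[g$h]), alpha = g$alpha)
             },
             svm = {
               g <- expand.grid(C = 2^(-5:5), gamma = 2^seq(-15, 5, by = 2))
               data.frame(kernel = "radial", C = g$C, gamma = g$gamma)
             },
             rf = data.frame(ntree = seq(200, 800, by = 10)))
    }
  }
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  structure(list(kind = kind, variant = variant, grid = grid,
                 random_state = random_state), class = "classifier_spec")
}

# ---- internal classifier fits ------------------------------------------

# Multilayer perceptron: ReLU hidden layers, softmax output, cross-entropy
# + (alpha/2n) L2 penalty, optimized with L-BFGS-B on analytic gradients.
.fit_mlp <- function(x, y, hidden, alpha, seed, maxit = 400) {
  lev <- levels(y)
  K <- length(lev); P <- ncol(x); n <- nrow(x)
  yi <- as.integer(y)
  sizes <- c(P, hidden, K)
  nw <- sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  unpack <- function(theta) {
    Ws <- list(); bs <- list(); p <- 1
    for (l in seq_len(length(sizes) - 1)) {
      nin <- sizes[l]; nout <- sizes[l + 1]
      Ws[[l]] <- matrix(theta[p:(p + nin * nout - 1)], nin, nout); p <- p + nin * nout
      bs[[l]] <- theta[p:(p + nout - 1)]; p <- p + nout
    }
    list(W = Ws, b = bs)
  }
  fwd <- function(pars) {
    acts <- list(x)
    a <- x
    L <- length(pars$W)
    for (l in seq_len(L)) {
      z <- sweep(a %*% pars$W[[l]], 2, pars$b[[l]], "+")
      a <- if (l < L) pmax(z, 0) else z
      acts[[l + 1]] <- a
    }
    zs <- a - apply(a, 1, max)
    probs <- exp(zs) / rowSums(exp(zs))
    list(acts = acts, probs = probs)
  }
  fn <- function(theta) {
    pars <- unpack(theta)
    f <- fwd(pars)
    ce <- -mean(log(pmax(f$probs[cbind(seq_len(n), yi)], 1e-12)))
    ce + alpha / (2 * n) * sum(vapply(pars$W, function(w) sum(w^2), 0))
  }
  gr <- function(theta) {
    pars <- unpack(theta)
    f <- fwd(pars)
    L <- length(pars$W)
    delta <- f$probs
    delta[cbind(seq_len(n), yi)] <- delta[cbind(seq_len(n), yi)] - 1
    delta <- delta / n
    gW <- vector("list", L); gb <- vector("list", L)
    for (l in L:1) {
      gW[[l]] <- t(f$acts[[l]]) %*% delta + alpha / n * pars$W[[l]]
      gb[[l]] <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(pars$W[[l]])) * (f$acts[[l]] > 0)
    }
    unlist(c(mapply(function(w, b) c(as.vector(w), b), gW, gb, SIMPLIFY = FALSE)))
  }
  theta0 <- withr::with_seed(seed, {
    unlist(lapply(seq_len(length(sizes) - 1), function(l) {
      c(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])), numeric(sizes[l + 1]))
    }))
  })
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(pars = unpack(opt$par), levels = lev, sizes = sizes)
}

.predict_mlp <- function(fit, x) {
  a <- as.matrix(x)
  L <- length(fit$pars$W)
  for (l in seq_len(L)) {
    z <- sweep(a %*% fit$pars$W[[l]], 2, fit$pars$b[[l]], "+")
    a <- if (l < L) pmax(z, 0) else z
  }
  z <- a - apply(a, 1, max)
  p <- exp(z) / rowSums(exp(z))
  colnames(p) <- fit$levels
  p
}

# Support vector machine via libsvm (e1071). Multiclass training is
# libsvm's pairwise decomposition — the same engine and semantics as
# sklearn's SVC, whose "one-vs-rest" decision-function shape reshapes the
# pairwise outputs into per-class scores. Per-class probability scores
# (Platt-calibrated, rows summing to 1) are fitted on the final model only.
.fit_svm <- function(x, y, kernel, C, gamma, seed, probability = FALSE) {
  withr::with_seed(seed, {
    if (kernel == "linear")
      e1071::svm(x, y, kernel = "linear", cost = C, scale = FALSE,
                 probability = probability)
    else
      e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma,
                 scale = FALSE, probability = probability)
  })
}

.predict_svm_scores <- function(fit, x) {
  p <- attr(predict(fit, as.matrix(x), probability = TRUE), "probabilities")
  if (is.null(p))
    stop("svm model was fitted without probability scores")
  p / rowSums(p)
}

.fit_rf <- function(x, y, ntree, seed) {
  withr::with_seed(seed,
    randomForest::randomForest(x, y, ntree = ntree, nodesize = 1))
}

.fit_one <- function(x, y, spec, params, final = FALSE) {
  switch(spec$kind,
         mlp = .fit_mlp(x, y, unlist(params$hidden), params$alpha,
                        spec$random_state),
         svm = .fit_svm(x, y, as.character(params$kernel), params$C,
                        params$gamma, spec$random_state, probability = final),
         rf = .fit_rf(x, y, params$ntree, spec$random_state))
}

# Hard labels only (used for CV scoring; cheap for every classifier).
.predict_labels <- function(kind, fit, x) {
  switch(kind,
         mlp = {
           p <- .predict_mlp(fit, x)
           colnames(p)[max.col(p, ties.method = "first")]
         },
         svm = as.character(predict(fit, as.matrix(x))),
         rf = as.character(predict(fit, as.matrix(x))))
}

.predict_scores <- function(kind, fit, x) {
  switch(kind,
         mlp = .predict_mlp(fit, x),
         svm = .predict_svm_scores(fit, x),
         rf = {
           p <- predict(fit, as.matrix(x), type = "prob")
           p / rowSums(p)
         })
}

# Stratified k-fold assignment, seeded.
.stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grid-search a classifier with 5-fold cross-validation
#'
#' Exhaustively evaluates the spec's hyperparameter grid by stratified
#' k-fold CV accuracy on the training data, refits the best point (ties:
#' first grid row) on the full training set, and records the CV table.
#'
#' @param x numeric feature matrix (training split).
#' @param y labels (factor or coercible).
#' @param spec a [classifier_spec()].
#' @param folds number of CV folds, default 5.
#' @return an object of class `pupa_model` with elements kind, fit,
#'   best_params, cv_table, levels, feature_dim.
#' @export
grid_search_train <- function(x, y, spec, folds = 5) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  x <- sweep(sweep(x, 2, center), 2, scale, "/")
  y <- droplevels(as.factor(y))
  if (min(table(y)) < folds)
    stop("need at least ", folds, " samples per class for ", folds, "-fold CV")
  grid <- spec$grid
  cv_acc <- numeric(nrow(grid))
  if (nrow(grid) == 1) {
    cv_acc <- NA_real_
  } else {
    fold <- .stratified_folds(y, folds, spec$random_state)
    for (gi in seq_len(nrow(grid))) {
      correct <- 0L
      for (f in seq_len(folds)) {
        tr <- fold != f
        fit <- .fit_one(x[tr, , drop = FALSE], droplevels(y[tr]), spec,
                        grid[gi, , drop = FALSE])
        pred <- .predict_labels(spec$kind, fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == as.character(y[!tr]))
      }
      cv_acc[gi] <- correct / length(y)
    }
  }
  best_i <- if (all(is.na(cv_acc))) 1L else which.max(cv_acc)
  fit <- .fit_one(x, y, spec, grid[best_i, , drop = FALSE], final = TRUE)
  cv_table <- cbind(grid, cv_accuracy = cv_acc)
  cv_table$hidden <- NULL
  if (spec$kind == "mlp")
    cv_table <- cbind(hidden = vapply(grid$hidden, function(h)
      paste(unlist(h), collapse = "x"), ""), cv_table)
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 best_params = grid[best_i, , drop = FALSE], best_cv_accuracy = cv_acc[best_i],
                 cv_table = cv_table, levels = levels(y), feature_dim = ncol(x),
                 center = center, scale = scale),
            class = "pupa_model")
}

#' Predict labels and per-class scores
#'
#' @param object a `pupa_model` from [grid_search_train()].
#' @param newdata feature matrix with the training feature dimension.
#' @param ... unused.
#' @return list(class = factor of hard labels, scores = n x K matrix of
#'   per-class scores with rows summing to 1). Hard labels are the argmax of
#'   the score rows (ties: first class).
#' @export
predict.pupa_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$feature_dim)
    stop("feature dimension ", ncol(newdata), " does not match the ",
         object$feature_dim, " used in training")
  newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  sc <- .predict_scores(object$kind, object$fit, newdata)
  sc <- sc[, object$levels, drop = FALSE]
  lab <- factor(object$levels[max.col(sc, ties.method = "first")],
                levels = object$levels)
  list(class = lab, scores = sc)
}

#' @export
print.pupa_model <- function(x, ...) {
  cat(sprintf("pupa_model: %s over %d classes (%d features); best CV accuracy %s\n",
              toupper(x$kind), length(x$levels), x$feature_dim,
              ifelse(is.na(x$best_cv_accuracy), "n/a (single grid point)",
                     sprintf("%.4f", x$best_cv_accuracy))))
  invisible(x)
}
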