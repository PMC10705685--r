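make_manifest <- function(pupae_per_class = 20, seed = 1) {
  generate_dataset(default_species_profiles("realistic"), pupae_per_class,
                   seed = seed, render = FALSE)$manifest
}

test_that("weight-stratified 8:2 split gives the expected per-class counts", {
  m <- split_dataset(make_manifest(120), ratios = c(8, 2))
  per <- table(m$class, m$split) / 3          # pupae, not images
  expect_true(all(per[, "train"] == 96))
  expect_true(all(per[, "test"] == 24))
  m2 <- split_dataset(make_manifest(120), ratios = c(8, 1, 1))
  per2 <- table(m2$class, m2$split) / 3
  expect_true(all(per2[, "train"] == 96))
  expect_true(all(per2[, "calibration"] == 12))
  expect_true(all(per2[, "test"] == 12))
})

test_that("splits are grouped by pupa and balanced in weight", {
  m <- split_dataset(make_manifest(20), ratios = c(8, 2))
  # all three postures of a pupa share one split
  expect_true(all(tapply(m$split, m$pupa_id,
                         function(s) length(unique(s))) == 1))
  # systematic weight-ordered assignment keeps split means close
  for (cl in unique(m$class)) {
    cw <- m[m$class == cl, ]
    expect_lt(abs(mean(cw$weight[cw$split == "test"]) - mean(cw$weight)) /
                mean(cw$weight), 0.05)
    expect_lt(abs(mean(cw$weight[cw$split == "train"]) - mean(cw$weight)) /
                mean(cw$weight), 0.05)
  }
  expect_error(split_dataset(make_manifest(4)), "fewer than 5")
  expect_error(split_dataset(make_manifest(20), ratios = c(7, 3)), "8:2")
})

test_that("fusion compresses wide blocks to exactly 500 and passes narrow ones", {
  set.seed(3)
  n <- 60
  feats <- list(hog = matrix(rnorm(n * 1296), n, 1296,
                             dimnames = list(sprintf("s%02d", 1:n), NULL)),
                sdpsf = matrix(rnorm(n * 37), n, 37,
                               dimnames = list(sprintf("s%02d", 1:n), NULL)))
  fit <- fit_fusion(feats, target_dim = 500)
  out <- apply_fusion(fit, feats)
  expect_equal(ncol(out), 500 + 37)
  expect_equal(fit$members$hog$out_dim, 500L)
  expect_equal(fit$members$sdpsf$out_dim, 37L)
  # projection columns are orthonormal even when PCA rank < 500
  P <- fit$members$hog$proj
  expect_equal(dim(P), c(1296, 500))
  expect_equal(crossprod(P[, 1:10]), diag(10), tolerance = 1e-8)
})

test_that("fusion applies the train-fitted projection to test data without refit", {
  set.seed(4)
  tr <- list(x = matrix(rnorm(200 * 600), 200, 600))
  te <- list(x = matrix(rnorm(50 * 600), 50, 600))
  fit <- fit_fusion(tr, target_dim = 500)
  P_before <- fit$members$x$proj
  out_te <- apply_fusion(fit, te)
  expect_identical(fit$members$x$proj, P_before)
  manual <- sweep(sweep(te$x, 2, fit$members$x$center), 2,
                  fit$members$x$scale, "/") %*% P_before
  expect_equal(unname(out_te), unname(manual))
  expect_error(apply_fusion(fit, list(y = te$x)), "missing descriptor")
  expect_error(apply_fusion(fit, list(x = te$x[, 1:10])), "expected 600")
})

test_that("classifier grids match the search protocol", {
  expect_equal(nrow(classifier_spec("rf")$grid), 61)       # 200..800 step 10
  expect_equal(nrow(classifier_spec("svm")$grid), 121)     # 11 C x 11 gamma
  mlp <- classifier_spec("mlp")$grid
  expect_equal(nrow(mlp), 60)                              # 10 sizes x 6 alphas
  expect_true(list(c(100, 100)) %in% mlp$hidden)
  deep <- classifier_spec("mlp", variant = "deep")
  expect_equal(nrow(deep$grid), 1)
  expect_equal(deep$grid$alpha, 1e-5)
  expect_equal(classifier_spec("svm", variant = "deep")$grid$C, 1)
  expect_equal(classifier_spec("rf", variant = "deep")$grid$ntree, 500)
  expect_error(classifier_spec("svm", grid = data.frame()), "empty")
})

separable_xy <- function(n_per = 20, k = 4, seed = 5) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(cl)
    matrix(rnorm(n_per * 10, mean = 4 * cl), n_per, 10)))
  list(x = x, y = factor(rep(letters[1:k], each = n_per)))
}

test_that("SVM reaches perfect CV accuracy on separable data", {
  d <- separable_xy()
  spec <- classifier_spec("svm",
                          grid = data.frame(kernel = "radial",
                                            C = c(1, 8), gamma = c(0.01, 0.1)))
  m <- grid_search_train(d$x, d$y, spec)
  expect_equal(m$best_cv_accuracy, 1.0)
  expect_equal(nrow(m$cv_table), 2)
  pr <- predict(m, d$x)
  expect_equal(as.character(pr$class), as.character(d$y))
})

test_that("a single grid point is a direct fit for each classifier kind", {
  d <- separable_xy(n_per = 12, k = 3)
  for (kind in c("mlp", "svm", "rf")) {
    spec <- classifier_spec(kind, variant = "deep")
    m <- grid_search_train(d$x, d$y, spec)
    expect_true(is.na(m$best_cv_accuracy))
    pr <- predict(m, d$x)
    expect_equal(as.character(pr$class), as.character(d$y))
  }
})

test_that("predictions expose normalized scores consistent with labels", {
  d <- separable_xy(n_per = 15, k = 3)
  for (kind in c("mlp", "svm", "rf")) {
    m <- grid_search_train(d$x, d$y, classifier_spec(kind, variant = "deep"))
    pr <- predict(m, d$x)
    expect_equal(unname(rowSums(pr$scores)), rep(1, nrow(d$x)),
                 tolerance = 1e-9)
    expect_equal(as.character(pr$class),
                 colnames(pr$scores)[max.col(pr$scores, ties.method = "first")])
    expect_equal(colnames(pr$scores), levels(d$y))
  }
  m <- grid_search_train(d$x, d$y, classifier_spec("rf", variant = "deep"))
  expect_error(predict(m, d$x[, 1:3]), "dimension")
})

test_that("grid search is deterministic given the spec's random state", {
  d <- separable_xy(n_per = 10, k = 3, seed = 9)
  spec <- classifier_spec("rf", grid = data.frame(ntree = c(50, 100)))
  m1 <- grid_search_train(d$x, d$y, spec)
  m2 <- grid_search_train(d$x, d$y, spec)
  expect_equal(m1$cv_table$cv_accuracy, m2$cv_table$cv_accuracy)
  expect_identical(predict(m1, d$x)$class, predict(m2, d$x)$class)
})
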