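ols_fit <- function(X, Y) {
  Xd <- cbind(1, X)
  B <- solve(crossprod(Xd), crossprod(Xd, Y))
  function(Xn) cbind(1, Xn) %*% B
}

test_that("PLS reproduces an exact affine colour map and equals OLS at full rank", {
  set.seed(21)
  X <- matrix(runif(300), 100, 3)
  A <- matrix(c(-0.2, 0.3, 0.1, 0.4, -0.1, 0.2, 0.05, 0.15, -0.3), 3, 3)
  Y <- sweep(X %*% A, 2, c(0.5, 0.4, 0.6), "+")
  mm <- multimodal_image(array(X, c(10, 10, 3)))
  he <- array(Y, c(10, 10, 3))
  cm <- fit_color_model(mm, he, 3)
  expect_lt(cm$rmse, 1e-6)
  pred <- predict_color(cm, mm)
  expect_lt(sqrt(mean((pred - he)^2)), 1e-6)

  ## full-rank PLS equals the normal-equations oracle
  set.seed(22)
  Yn <- Y + matrix(rnorm(300, sd = 0.05), 100, 3)
  cm3 <- fit_color_model(mm, array(Yn, c(10, 10, 3)), 3)
  oracle <- ols_fit(X, Yn)
  fitted <- sweep(sweep(X, 2, cm3$x_mean) %*% cm3$coef, 2, cm3$y_mean, "+")
  expect_lt(sqrt(mean((fitted - oracle(X))^2)), 1e-8)

  ## fewer components cannot beat OLS on the training data
  cm1 <- fit_color_model(mm, array(Yn, c(10, 10, 3)), 1)
  rmse_ols <- sqrt(mean((oracle(X) - Yn)^2))
  expect_gte(cm1$rmse, rmse_ols - 1e-12)
})

test_that("PLS predictions agree with an independent PLS implementation", {
  set.seed(31)
  X <- matrix(runif(150), 50, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  Y <- sweep(X %*% matrix(rnorm(9), 3, 3), 2, c(0.3, 0.2, 0.1), "+") +
    matrix(rnorm(150, sd = 0.1), 50, 3)
  colnames(Y) <- c("r", "g", "b")
  mm <- multimodal_image(array(X, c(10, 5, 3)))
  for (nc in 1:2) {
    cm <- fit_color_model(mm, array(Y, c(10, 5, 3)), nc)
    ref <- mixOmics::pls(X, Y, ncomp = nc, mode = "regression",
                         scale = FALSE)
    prd <- predict(ref, X)$predict[, , nc]
    fitted <- sweep(sweep(X, 2, cm$x_mean) %*% cm$coef, 2, cm$y_mean, "+")
    expect_lt(sqrt(mean((fitted - prd)^2)), 1e-6)
  }
})

test_that("colour prediction handles degenerate inputs sensibly", {
  set.seed(23)
  X <- matrix(runif(300), 100, 3)
  Y <- X %*% diag(3) * 0.5 + 0.2
  mm <- multimodal_image(array(X, c(10, 10, 3)))
  cm <- fit_color_model(mm, array(Y, c(10, 10, 3)), 3)
  zero <- multimodal_image(array(0, c(4, 4, 3)))
  pz <- predict_color(cm, zero)
  expected <- pmin(pmax(cm$y_mean - drop(crossprod(cm$coef, cm$x_mean)), 0), 1)
  for (ch in 1:3)
    expect_equal(pz[1, 1, ch], unname(expected[ch]), tolerance = 1e-12)

  expect_error(predict_color(list(), mm), "trained")
  he_bad <- array(0.5, c(9, 9, 3))
  expect_error(fit_color_model(mm, he_bad), "registered")

  ## rank-deficient input: third channel duplicates the first
  Xr <- X; Xr[, 3] <- Xr[, 1]
  mmr <- multimodal_image(array(Xr, c(10, 10, 3)))
  expect_warning(cmr <- fit_color_model(mmr, array(Y, c(10, 10, 3)), 3),
                 "rank-deficient")
  expect_true(all(is.finite(cmr$coef)))
})

test_that("LDA nuclei model separates well-separated classes and matches the affine oracle", {
  set.seed(31)
  n <- 400
  S <- diag(c(0.02, 0.02, 0.02))
  x0 <- matrix(rnorm(3 * n, sd = sqrt(0.02)), n, 3) +
    matrix(c(0.6, 0.6, 0.4), n, 3, byrow = TRUE)
  ## Mahalanobis distance 6 between means
  shift <- 6 * sqrt(0.02)
  x1 <- matrix(rnorm(3 * n, sd = sqrt(0.02)), n, 3) +
    matrix(c(0.6 - shift, 0.6, 0.4), n, 3, byrow = TRUE)
  px <- rbind(x0, x1); lab <- rep(c(FALSE, TRUE), each = n)
  nm <- fit_nuclei_model(px, lab)
  acc <- mean((nuclei_posterior(nm, px) >= 0.5) == lab)
  expect_gte(acc, 0.99)

  ## decision equals sign of the explicit discriminant from means/covariance
  post <- nuclei_posterior(nm, px)
  affine <- drop(px %*% nm$w) + nm$b
  expect_equal(post >= 0.5, affine >= 0)

  ## and agrees with an independent LDA implementation
  fit <- MASS::lda(px, grouping = factor(lab))
  ref_post <- predict(fit, px)$posterior[, "TRUE"]
  expect_equal(post, unname(ref_post), tolerance = 1e-8)
})

test_that("LDA degrades to the prior without signal and guards singular covariance", {
  set.seed(32)
  px <- matrix(rnorm(900, mean = 0.5, sd = 0.1), 300, 3)
  lab <- rep(c(TRUE, FALSE), c(100, 200))
  nm <- fit_nuclei_model(px, lab)
  acc <- mean((nuclei_posterior(nm, px) >= 0.5) == lab)
  expect_lt(abs(acc - 2 / 3), 0.05 + 1e-9)

  pxs <- cbind(px[, 1], px[, 1], px[, 1])   # rank-1 covariance
  expect_warning(nms <- fit_nuclei_model(pxs, lab), "singular|ridge")
  expect_true(all(is.finite(nms$w)))

  expect_error(fit_nuclei_model(px[1:15, ], rep(c(TRUE, FALSE), c(5, 10))),
               "at least 10")
})

test_that("nuclei mask prediction recovers generated nuclei and honors thresholds", {
  sc <- generate_multimodal_pair(image_scene_params(seed = 13))
  ev <- evaluate_pseudo_he_scene(sc, seed = 1)
  expect_gte(ev$metrics$nuclei_iou, 0.7)

  pp <- ev$preprocessed
  empty <- predict_nuclei_mask(ev$nuclei_model, pp, threshold = 1.0)
  expect_false(any(empty))
  huge <- predict_nuclei_mask(ev$nuclei_model, pp, min_area = 1e6)
  expect_false(any(huge))
})

test_that("background weighting picks the darkest class and respects radii", {
  set.seed(41)
  bright <- matrix(c(0.9, 0.8, 0.7), 60, 3, byrow = TRUE) +
    matrix(rnorm(180, sd = 0.01), 60, 3)
  dark <- matrix(c(0.02, 0.01, 0.02), 40, 3, byrow = TRUE) +
    matrix(rnorm(120, sd = 0.005), 40, 3)
  px <- abs(rbind(bright, dark))
  img <- multimodal_image(array(px, c(10, 10, 3)))
  bw <- estimate_background_weight(img, k = 2, median_radius = 0,
                                   close_radius = 0, open_radius = 0,
                                   mean_radius = 0, seed = 1)
  expect_equal(sum(rowSums(bw$centers^2) < 1), 1L)
  dark_idx <- matrix(FALSE, 10, 10); dark_idx[61:100] <- TRUE
  expect_equal(bw$weight == 1, dark_idx)
  expect_true(all(bw$weight %in% c(0, 1)))   # mean_radius = 0 keeps it binary
})

test_that("background selection is invariant to channel permutation", {
  img <- random_mm(12, 12, seed = 5)
  img$channels[, , 1] <- img$channels[, , 1] * 0.1   # make a dark structure
  bw1 <- estimate_background_weight(img, k = 3, median_radius = 0,
                                    close_radius = 0, open_radius = 0,
                                    mean_radius = 0, seed = 7)
  perm <- img
  perm$channels <- img$channels[, , c(2, 3, 1)]
  bw2 <- estimate_background_weight(perm, k = 3, median_radius = 0,
                                    close_radius = 0, open_radius = 0,
                                    mean_radius = 0, seed = 7)
  expect_equal(bw1$weight, bw2$weight)
})

test_that("background weight recovers the scene background region", {
  sc <- generate_multimodal_pair(image_scene_params(seed = 17))
  ev <- evaluate_pseudo_he_scene(sc, seed = 2)
  expect_gte(ev$metrics$background_iou, 0.9)
})

test_that("compositing blends white, nuclei colour and predicted colour convexly", {
  col <- array(0.5, c(6, 6, 3))
  nuc <- matrix(FALSE, 6, 6)
  white <- compose_pseudo_he(col, nuc, matrix(1, 6, 6))
  expect_true(all(white == 1))
  plain <- compose_pseudo_he(col, nuc, matrix(0, 6, 6))
  expect_equal(unclass(plain), col, ignore_attr = TRUE)

  col0 <- array(0, c(2, 2, 3))
  half <- compose_pseudo_he(col0, matrix(FALSE, 2, 2), matrix(0.5, 2, 2))
  expect_true(all(half == 0.5))

  nuc[2, 2] <- TRUE
  out <- compose_pseudo_he(col, nuc, matrix(0, 6, 6),
                           nuclei_color = c(0.29, 0.13, 0.37))
  expect_equal(out[2, 2, ], c(0.29, 0.13, 0.37))
  expect_error(compose_pseudo_he(col, matrix(FALSE, 5, 5), matrix(0, 6, 6)),
               "shape")
})

test_that("pseudo-HE model JSON persistence round-trips", {
  set.seed(51)
  X <- matrix(runif(300), 100, 3)
  Y <- sweep(X %*% diag(c(0.5, 0.4, 0.3)), 2, 0.2, "+")
  mm <- multimodal_image(array(X, c(10, 10, 3)))
  cm <- fit_color_model(mm, array(Y, c(10, 10, 3)))
  nm <- fit_nuclei_model(X, X[, 1] < 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  save_pseudo_he_model(cm, nm, path)
  back <- load_pseudo_he_model(path)
  expect_equal(back$color_model$coef, unname(cm$coef), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$nuclei_model$w, unname(nm$w), tolerance = 1e-12,
               ignore_attr = TRUE)
  p1 <- predict_color(cm, mm); p2 <- predict_color(back$color_model, mm)
  expect_equal(p1, p2, tolerance = 1e-12)
})
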