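test_that("median denoising matches a brute-force sliding median", {
  m <- matrix(runif(256, min = 0), 16, 16)
  img <- multimodal_image(array(rep(m, 3), c(16, 16, 3)))
  out <- median_denoise(img, 1)
  expect_equal(out$channels[, , 2], brute_median(m, 1), tolerance = 0)

  const <- multimodal_image(array(0.4, c(8, 8, 3)))
  expect_equal(median_denoise(const, 2)$channels, const$channels)

  spike <- matrix(0.2, 9, 9); spike[5, 5] <- 1
  si <- multimodal_image(array(rep(spike, 3), c(9, 9, 3)))
  expect_equal(median_denoise(si, 1)$channels[5, 5, 1], 0.2)

  expect_error(median_denoise(img, 0), ">= 1")
})

test_that("block-mean downsampling averages exactly and preserves the mean", {
  x <- array(0, c(4, 4, 3))
  x[, , 1] <- matrix(0:15, 4, 4) / 15
  x[, , 2] <- 0.3; x[, , 3] <- 0.7
  d <- downsample(multimodal_image(x), 4)
  expect_equal(dim(d$channels)[1:2], c(1L, 1L))
  expect_equal(d$channels[1, 1, 1], mean(0:15) / 15)

  img <- random_mm(32, 32, seed = 4)
  d2 <- downsample(img, 4)
  expect_equal(mean(d2$channels[, , 1]), mean(img$channels[, , 1]),
               tolerance = 1e-9)
  expect_identical(downsample(img, 1), img)
  expect_error(downsample(img, 0), "positive")
  expect_message(downsample(random_mm(10, 10), 4), "cropping")
})

test_that("illumination correction is identity on flat mosaics", {
  flat <- multimodal_image(array(0.5, c(64, 64, 3)),
                           tile_shape = c(32L, 32L))
  for (method in c("mosaic", "tile")) {
    out <- correct_tile_illumination(flat, method = method)
    expect_equal(out$channels, flat$channels, tolerance = 1e-6)
  }
})

test_that("tiles with identical content but different gains correct to equality", {
  set.seed(8)
  content <- 0.3 + 0.4 * matrix(runif(32 * 32), 32, 32)
  x <- array(0, c(32, 64, 3))
  for (ch in 1:3) x[, , ch] <- cbind(content, 0.5 * content)
  img <- multimodal_image(x, tile_shape = c(32L, 32L))
  out <- correct_tile_illumination(img, method = "mosaic")
  t1 <- out$channels[, 1:32, 1]; t2 <- out$channels[, 33:64, 1]
  expect_lt(max(abs(t1 - t2) / pmax(t1, 1e-6)), 0.02)
})

test_that("correction removes at least half the within-tile vignetting spread", {
  ## flat content under a 0.4-deep radial vignette: the per-tile
  ## mean-normalised coefficient of variation must drop by >= 50 %
  tr <- 32L
  rr <- (seq_len(tr) - (tr + 1) / 2) / (tr / 2)
  vign <- 1 - 0.4 * outer(rr^2, rr^2, "+") / 2
  x <- array(0, c(64, 64, 3))
  for (ch in 1:3) for (i in 0:1) for (j in 0:1)
    x[i * tr + seq_len(tr), j * tr + seq_len(tr), ch] <- 0.6 * vign
  img <- multimodal_image(x, tile_shape = c(tr, tr))
  cv_tile <- function(im) {
    v <- numeric(0)
    for (i in 0:1) for (j in 0:1) {
      t <- im$channels[i * tr + seq_len(tr), j * tr + seq_len(tr), 1]
      v <- c(v, sd(t / mean(t)))
    }
    mean(v)
  }
  out <- correct_tile_illumination(img, method = "mosaic")
  expect_lt(cv_tile(out), 0.5 * cv_tile(img))
})

test_that("contrast adjustment clips at the requested quantiles", {
  ramp <- matrix(seq(0, 999) / 999, 100, 10)
  img <- multimodal_image(array(rep(ramp, 3), c(100, 10, 3)))
  lim <- contrast_limits(cars = c(0.05, 0.05), tpef = c(0.05, 0.05),
                         shg = c(0.05, 0.05))
  out <- adjust_contrast(img, lim)$channels[, , 1]
  v <- as.vector(ramp)
  q <- quantile(v, c(0.05, 0.95), names = FALSE)
  expect_true(all(out[ramp <= q[1]] == 0))
  expect_true(all(out[ramp >= q[2]] == 1))
  mid <- which.min(abs(v - mean(q)))
  expect_equal(as.vector(out)[mid], 0.5, tolerance = 2e-3)

  span <- multimodal_image(array(rep(seq(0, 1, length.out = 100), 3),
                                 c(10, 10, 3)))
  id <- adjust_contrast(span, contrast_limits(c(0, 0), c(0, 0), c(0, 0)))
  expect_equal(id$channels, span$channels, tolerance = 1e-12)

  const <- multimodal_image(array(0.5, c(8, 8, 3)))
  w <- capture_warnings(z <- adjust_contrast(const))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(z$channels == 0))
})

test_that("contrast limit validation rejects impossible tails", {
  expect_error(contrast_limits(cars = c(0.6, 0.5)), "sum < 1")
  expect_error(contrast_limits(tpef = c(-0.1, 0)), "\\[0, 1\\)")
})

test_that("the composed preprocessing chain is deterministic and bounded", {
  sc <- generate_multimodal_pair(small_scene_params(seed = 6))
  p1 <- preprocess_multimodal(sc$multimodal, factor = 2L)
  p2 <- preprocess_multimodal(sc$multimodal, factor = 2L)
  expect_identical(p1$channels, p2$channels)
  expect_true(all(p1$channels >= 0 & p1$channels <= 1))
  expect_true(all(is.finite(p1$channels)))
})
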