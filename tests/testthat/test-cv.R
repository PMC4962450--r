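table1 <- function() {
  m <- rbind(adenoma = c(4, 1, 0), carcinoma = c(3, 5, 0),
             normal = c(0, 0, 16))
  colnames(m) <- rownames(m)
  m
}

test_that("confusion statistics reproduce the printed region-level rates", {
  st <- confusion_stats(table1())
  expect_equal(st$per_class$sensitivity, c(80, 62.5, 100))
  expect_equal(round(st$per_class$specificity, 1), c(87.5, 95.2, 100))
  expect_equal(st$mean_sensitivity, mean(c(80, 62.5, 100)))

  mg <- merge_confusion(table1())
  expect_equal(unname(mg), rbind(c(13, 0), c(0, 16)))
  expect_equal(confusion_stats(mg)$mean_sensitivity, 100)
  expect_equal(sum(mg), sum(table1()))
})

test_that("confusion statistics handle edge cases", {
  id <- diag(c(5, 7)); rownames(id) <- colnames(id) <- c("a", "b")
  st <- confusion_stats(id)
  expect_true(all(st$per_class$sensitivity == 100))
  expect_true(all(st$per_class$specificity == 100))

  z <- rbind(a = c(0, 0), b = c(2, 3)); colnames(z) <- c("a", "b")
  stz <- confusion_stats(z)
  expect_true(is.na(stz$per_class$sensitivity[1]))
  expect_equal(stz$mean_sensitivity, 60)   # only class b contributes

  expect_error(confusion_stats(matrix(1, 2, 3)), "square")
  expect_error(confusion_stats(matrix(-1, 2, 2)), "non-negative")
})

test_that("IO-CV partitions individuals exactly once and scores separated data perfectly", {
  set.seed(101)
  n_per <- 30
  mk <- function(center, cls, ind) {
    list(f = matrix(rnorm(2 * n_per, sd = 0.05), n_per, 2) +
           matrix(center, n_per, 2, byrow = TRUE),
         cls = rep(cls, n_per), ind = rep(ind, n_per))
  }
  parts <- list(
    mk(c(0, 0), "normal", "i1"), mk(c(5, 0), "adenoma", "i1"),
    mk(c(0, 5), "carcinoma", "i1"),
    mk(c(0.2, 0.1), "normal", "i2"), mk(c(5.1, 0.2), "adenoma", "i2"),
    mk(c(0.1, 5.2), "carcinoma", "i2"),
    mk(c(-0.1, 0.2), "normal", "i3"), mk(c(4.9, -0.2), "adenoma", "i3"),
    mk(c(-0.2, 4.8), "carcinoma", "i3"))
  ds <- structure(list(
    features = do.call(rbind, lapply(parts, `[[`, "f")),
    class = factor(unlist(lapply(parts, `[[`, "cls")),
                   levels = c("adenoma", "carcinoma", "normal")),
    individual = unlist(lapply(parts, `[[`, "ind")),
    scan = unlist(lapply(parts, `[[`, "ind")),
    region = paste(unlist(lapply(parts, `[[`, "ind")),
                   unlist(lapply(parts, `[[`, "cls")), sep = ":"),
    counts = list()), class = "shp_dataset")
  cv <- individual_out_cv(ds)
  expect_equal(cv$stats$mean_sensitivity, 100)
  expect_equal(cv$merged_stats$mean_sensitivity, 100)
  expect_equal(sum(cv$confusion), 9)          # 3 individuals x 3 regions
  expect_setequal(names(cv$folds), c("i1", "i2", "i3"))
  expect_false(anyNA(cv$predictions$predicted))

  g <- glance(cv)
  expect_equal(g$mean_sensitivity, 100)
  expect_equal(nrow(tidy(cv)), 3)
})

test_that("IO-CV does not beat resubstitution when individual effects exist", {
  co <- generate_raman_cohort(small_cohort_params(seed = 31,
                                                  individual_effect_sd = 0.2,
                                                  noise_sd = 0.3))
  ds <- truth_dataset(co)
  cv <- individual_out_cv(ds, level = "spectrum")
  ## resubstitution: 1-NN self-prediction excluding self
  X <- ds$features
  D <- as.matrix(dist(X)); diag(D) <- Inf
  resub <- ds$class[apply(D, 1, which.min)]
  resub_cm <- table(ds$class, factor(resub, levels = levels(ds$class)))
  resub_sens <- confusion_stats(unclass(as.matrix(resub_cm)))$mean_sensitivity
  expect_lte(cv$stats$mean_sensitivity, resub_sens + 1e-9)
})

test_that("IO-CV sensitivity rises monotonically with class separation", {
  sens <- vapply(c(0.25, 1, 4), function(scale) {
    amp <- default_band_amplitudes()
    dcls <- c("normal", "adenoma", "carcinoma")
    ctr <- matrix(colMeans(amp[dcls, ]), 3, ncol(amp), byrow = TRUE)
    amp[dcls, ] <- (amp[dcls, ] - ctr) * scale + ctr
    amp <- pmax(amp, 0)
    co <- generate_raman_cohort(small_cohort_params(
      seed = 32, class_band_amplitudes = amp, noise_sd = 0.3))
    individual_out_cv(truth_dataset(co),
                      level = "spectrum")$stats$mean_sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], sens[1])
})

test_that("fold records report classes missing from training", {
  set.seed(103)
  ds <- structure(list(
    features = matrix(rnorm(80), 40, 2),
    class = factor(c(rep("normal", 20), rep("carcinoma", 20)),
                   levels = c("carcinoma", "normal")),
    individual = rep(c("i1", "i2"), each = 20),
    scan = rep(c("s1", "s2"), each = 20),
    region = rep(c("s1:normal", "s2:carcinoma"), each = 20),
    counts = list()), class = "shp_dataset")
  cv <- individual_out_cv(ds, level = "spectrum")
  expect_equal(cv$folds$i1$missing_in_training, "normal")
  expect_equal(cv$folds$i2$missing_in_training, "carcinoma")
})

test_that("Wilcoxon screening is exact for small samples and calibrated", {
  scores <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  g <- rep(c("a", "b"), each = 3)
  p <- wilcoxon_screen(scores, g, components = 1)$p_value
  ## oracle: enumerate all choose(6, 3) = 20 assignments of ranks
  rks <- 1:6
  sums <- combn(rks, 3, sum)
  obs <- sum(1:3)
  p_exact <- mean(abs(sums - mean(sums)) >= abs(obs - mean(sums)))
  expect_equal(p_exact, 0.1)
  expect_equal(p, p_exact)

  same <- matrix(rep(c(5, 6, 7), 2), ncol = 1)
  p_same <- wilcoxon_screen(same, g, components = 1)$p_value
  expect_gte(p_same, 0.99)

  expect_error(wilcoxon_screen(scores, rep("a", 6), 1), "two groups")
  expect_error(wilcoxon_screen(scores, g, components = 5), "exceeds")
})

test_that("Wilcoxon detects a 2-SD shift at n = 50 almost always", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    x <- rnorm(50); y <- rnorm(50, mean = 2)
    wilcoxon_screen(matrix(c(x, y), ncol = 1),
                    rep(c("a", "b"), each = 50), 1)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("region-label shuffling keeps structure but destroys signal", {
  co <- generate_raman_cohort(small_cohort_params(seed = 33))
  ds <- truth_dataset(co)
  dsh <- shuffle_region_labels(ds, seed = 4)
  expect_identical(dsh$region, ds$region)
  expect_identical(sort(as.character(unique(dsh$class))),
                   sort(as.character(unique(ds$class))))
  for (r in unique(dsh$region))
    expect_length(unique(dsh$class[dsh$region == r]), 1L)
})
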