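test_that("per-scan clustering recovers separated blobs and validates k", {
  expect_equal(cluster_scan(matrix(rnorm(20), 10, 2), k = 1), rep(1L, 10))
  set.seed(91)
  blobs <- rbind(matrix(rnorm(60, mean = 0, sd = 0.1), 30, 2),
                 matrix(rnorm(60, mean = 5, sd = 0.1), 30, 2))
  cl <- cluster_scan(blobs, k = 2, seed = 3)
  truth <- rep(1:2, each = 30)
  agree <- max(mean(cl == truth), mean(cl == 3 - truth))
  expect_equal(agree, 1)
  expect_error(cluster_scan(blobs, k = 100), "exceeds")
  ## a 1360-spectrum scan accepts the default k = 9
  set.seed(92)
  big <- matrix(rnorm(1360 * 3), 1360, 3)
  expect_length(cluster_scan(big, k = 9, seed = 1), 1360L)
})

test_that("annotation transfer propagates cluster classes and flags exclusions", {
  cl <- c(1L, 1L, 2L, 3L, 2L)
  all_norm <- transfer_annotation(cl, c("1" = "normal", "2" = "normal",
                                        "3" = "normal"))
  expect_true(all(all_norm$class == "normal"))
  expect_false(any(all_norm$excluded))

  mixed <- transfer_annotation(cl, c("1" = "carcinoma", "2" = "background",
                                     "3" = "normal"))
  expect_equal(which(mixed$excluded), which(cl == 2L))
  expect_error(transfer_annotation(cl, c("1" = "normal")), "unmapped.*2, 3")
})

test_that("the simulated pathologist transfers truth labels accurately", {
  co <- generate_raman_cohort(small_cohort_params(seed = 15))
  pp <- preprocess_map(co$maps[[1]])
  pca <- fit_pca(pp$spectra, 10)
  sc <- project_pca(pca, pp$spectra)
  cl <- cluster_scan(sc, k = 9, seed = 2)
  mapping <- majority_truth_mapping(cl, pp$pixel_labels)
  ann <- transfer_annotation(cl, mapping)
  expect_gte(mean(ann$class == pp$pixel_labels), 0.9)
})

test_that("dataset assembly conserves counts and enforces cohort structure", {
  co <- generate_raman_cohort(raman_cohort_params(
    n_individuals = 6L, scans_per_individual = 2L, grid_shape = c(8L, 10L),
    seed = 16))
  ds <- truth_dataset(co)
  expect_setequal(unique(ds$individual), paste0("ind", 1:6))
  expect_equal(ds$counts$retained + ds$counts$excluded, ds$counts$total)
  expect_true(all(levels(ds$class) %in% c("adenoma", "carcinoma", "normal")))

  ## all spectra excluded -> empty dataset error
  pp <- lapply(co$maps, preprocess_map)
  sc <- lapply(pp, function(m) matrix(0, nrow(m$spectra), 2))
  ann_all_bg <- lapply(pp, function(m)
    data.frame(class = "background", excluded = TRUE))
  expect_error(assemble_shp_dataset(sc, ann_all_bg, pp), "empty dataset")
})

test_that("weighted kNN matches a brute-force oracle at k = 1", {
  one <- kknn_fit(matrix(c(0, 0), 1, 2), "a")
  expect_true(all(kknn_predict(one, matrix(rnorm(10), 5, 2))$labels == "a"))

  set.seed(93)
  tr <- matrix(runif(40), 20, 2)
  lab <- factor(sample(c("x", "y", "z"), 20, replace = TRUE))
  qu <- matrix(runif(10), 5, 2)
  model <- kknn_fit(tr, lab, k = 1)
  got <- kknn_predict(model, qu)$labels
  D <- as.matrix(dist(rbind(qu, tr)))[1:5, 6:25]
  expect_equal(as.character(got), as.character(lab[apply(D, 1, which.min)]))
})

test_that("kNN ties break to the earlier training row and vote weights sum sensibly", {
  tr <- rbind(c(1, 0), c(-1, 0))
  model <- kknn_fit(tr, c("first_row", "second_row"), k = 1)
  got <- kknn_predict(model, matrix(c(0, 0), 1, 2))
  expect_equal(as.character(got$labels), "first_row")   # row 1 wins the tie

  set.seed(94)
  tr2 <- matrix(rnorm(40), 20, 2)
  lab2 <- factor(rep(c("a", "b"), 10))
  m3 <- kknn_fit(tr2, lab2, k = 3)
  out <- kknn_predict(m3, matrix(rnorm(12), 6, 2))
  expect_true(all(rowSums(out$weights) > 0))
  expect_equal(as.character(out$labels),
               colnames(out$weights)[max.col(out$weights, "first")])
  expect_error(kknn_predict(m3, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("with k = 1 every kernel reduces to plain nearest neighbour", {
  set.seed(95)
  tr <- matrix(rnorm(60), 30, 2)
  lab <- factor(sample(c("p", "q"), 30, replace = TRUE))
  qu <- matrix(rnorm(20), 10, 2)
  opt <- kknn_predict(kknn_fit(tr, lab, k = 1, kernel = "optimal"), qu)
  rect <- kknn_predict(kknn_fit(tr, lab, k = 1, kernel = "rectangular"), qu)
  expect_identical(opt$labels, rect$labels)
})

test_that("Minkowski orders other than 2 change the metric as expected", {
  ## from the origin, A = (2.2, 0) is L1-nearer (2.2 vs 2.6) while
  ## B = (1.3, 1.3) is L2-nearer (1.84 vs 2.2)
  tr <- rbind(c(2.2, 0), c(1.3, 1.3))
  lab <- c("A", "B")
  got1 <- kknn_predict(kknn_fit(tr, lab, k = 1, p = 1), rbind(c(0, 0)))
  got2 <- kknn_predict(kknn_fit(tr, lab, k = 1, p = 2), rbind(c(0, 0)))
  expect_equal(as.character(got1$labels), "A")
  expect_equal(as.character(got2$labels), "B")
})
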