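test_that("nuclei counts match ground truth on dissociated-cell tissue", {
  cfg <- fx_config()
  rt <- fx_signet()
  truth_n <- max(rt$truth$nuclei_mask)
  expect_gt(truth_n, 100)
  nrm <- normalize_stains(rt$image, cfg$stain$reference)
  det <- detect_nuclei(nrm, cfg)
  expect_lt(abs(nrow(det$table) - truth_n) / truth_n, 0.15)
  # blank stroma: nothing to find
  rt0 <- render_tissue(tissue_phenotype("negative", 0, 1, 0, 0, 7, seed = 3),
                       size_px = c(256, 256))
  expect_equal(nrow(detect_nuclei(rt0$image, cfg)$table), 0)
})

test_that("ROI formation covers dense tiles and drops sparse ones", {
  cfg <- fx_config()
  expect_equal(nrow(form_rois(data.frame(row = numeric(0), col = numeric(0),
                                         area_um2 = numeric(0),
                                         eccentricity = numeric(0),
                                         mean_h = numeric(0)),
                              c(1024, 1024), 0.92)), 0)
  # uniform 400-nucleus field on 1024^2 with 256-px ROIs -> all 16 tiles kept
  set.seed(4)
  nuc <- data.frame(row = stats::runif(400, 1, 1024),
                    col = stats::runif(400, 1, 1024),
                    area_um2 = 40, eccentricity = 0.5, mean_h = 0.8)
  rois <- form_rois(nuc, c(1024, 1024), 0.92, roi_size_px = 256,
                    min_nuclei = 10)
  expect_equal(nrow(rois), 16)
  expect_true(all(rois$nuclei_count >= 10))
  # sparse corner tile is dropped
  nuc2 <- rbind(nuc, data.frame(row = 1, col = 1, area_um2 = 40,
                                eccentricity = 0.5, mean_h = 0.8))
  rois2 <- form_rois(nuc2[nuc2$row < 512 | seq_len(nrow(nuc2)) <= 100, ],
                     c(2048, 2048), 0.92, roi_size_px = 256, min_nuclei = 10)
  expect_true(all(rois2$nuclei_count >= 10))
  expect_error(form_rois(nuc, c(1024, 1024), 0.92, roi_size_px = 32), ">= 64")
})

test_that("top-3 mean-square aggregation matches direct arithmetic", {
  expect_equal(aggregate_top3(c(1, 1, 1, 0.2)), 1.0)
  expect_equal(aggregate_top3(c(0.9, 0.8, 0.7, 0.1)), 0.646667,
               tolerance = 1e-6)
  expect_equal(aggregate_top3(0.6), 0.12)  # zero-padding below 3 scores
  expect_equal(aggregate_top3(numeric(0)), 0)
})

test_that("the aggregate matches a brute-force oracle and is monotone", {
  oracle <- function(s) mean(c(sort(s, decreasing = TRUE), 0, 0, 0)[1:3]^2)
  set.seed(7)
  for (i in 1:200) {
    s <- stats::runif(sample(0:8, 1))
    expect_equal(aggregate_top3(s), oracle(s))
    if (length(s) > 0) {
      j <- sample(length(s), 1)
      s2 <- s; s2[j] <- min(1, s2[j] + stats::runif(1, 0, 1 - s2[j]))
      expect_gte(aggregate_top3(s2), aggregate_top3(s))
    }
  }
})

test_that("MIL training recovers bag labels from a shifted instance population", {
  mk_bags <- function(n_pos, n_neg, seed) {
    set.seed(seed)
    bags <- list(); y <- numeric(0)
    for (i in seq_len(n_pos)) {
      n <- sample(6:12, 1)
      X <- matrix(stats::rnorm(n * 8), n, 8)
      k <- sample(3:5, 1)  # at least 3 atypical instances
      X[seq_len(k), 1:3] <- X[seq_len(k), 1:3] + 2
      bags <- c(bags, list(X)); y <- c(y, 1)
    }
    for (i in seq_len(n_neg)) {
      n <- sample(6:12, 1)
      bags <- c(bags, list(matrix(stats::rnorm(n * 8), n, 8)))
      y <- c(y, 0)
    }
    list(bags = bags, y = y)
  }
  tr <- mk_bags(20, 20, 101)
  model <- train_mil(tr$bags, tr$y, seed = 42)
  te <- mk_bags(20, 20, 202)
  s <- vapply(te$bags, function(b) score_bag(model, b), numeric(1))
  auc <- mean(outer(s[te$y == 1], s[te$y == 0], ">") +
                0.5 * outer(s[te$y == 1], s[te$y == 0], "=="))
  expect_gte(auc, 0.9)
  # determinism: identical weights on retrain
  model2 <- train_mil(tr$bags, tr$y, seed = 42)
  expect_identical(model$W1, model2$W1)
  expect_identical(model$w2, model2$w2)
})

test_that("MIL on identical instances with mixed labels stays near chance", {
  set.seed(9)
  bags <- replicate(30, matrix(1, 5, 8), simplify = FALSE)
  y <- rep(c(0, 1), 15)
  model <- train_mil(bags, y, seed = 42)
  s <- vapply(bags, function(b) score_bag(model, b), numeric(1))
  auc <- mean(outer(s[y == 1], s[y == 0], ">") +
                0.5 * outer(s[y == 1], s[y == 0], "=="))
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
  expect_error(train_mil(bags, rep(1, 30), seed = 1), "single-class")
})

test_that("instance scoring is bounded, pure, and shape-checked", {
  tr <- list(bags = list(matrix(stats::rnorm(40), 5, 8),
                         matrix(stats::rnorm(40) + 1, 5, 8)),
             y = c(0, 1))
  model <- train_mil(tr$bags, tr$y, epochs = 50, seed = 1)
  set.seed(11)
  X <- matrix(stats::rnorm(1000 * 8, 0, 3), 1000, 8)
  s <- score_rois(model, X)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(score_rois(model, X[c(1, 1), ])[1],
               score_rois(model, X[c(1, 1), ])[2])
  expect_equal(length(score_rois(model, X[0, , drop = FALSE])), 0)
  expect_error(score_rois(model, X[, 1:5]), "mismatch")
})

test_that("MIL models survive JSON serialization", {
  model <- default_mil_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_mil_model(model, path)
  back <- read_mil_model(path)
  set.seed(3)
  X <- matrix(stats::rnorm(80), 10, 8)
  expect_equal(score_rois(back, X), score_rois(model, X), tolerance = 1e-12)
})

test_that("the cytological decision respects its boundary convention", {
  expect_equal(classify_cyto(0, 0.5), "low")
  expect_equal(classify_cyto(1, 0.5), "high")
  expect_equal(classify_cyto(0.5, 0.5), "high")  # boundary favours sensitivity
  expect_error(classify_cyto(0.5, 0), "threshold")
})
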