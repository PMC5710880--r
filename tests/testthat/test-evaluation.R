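test_that("confusion matrices tally correctly", {
  cm0 <- build_matrix(character(0), character(0))
  expect_equal(cm0$n_all, 0)
  expect_true(all(cm0$counts == 0))
  cm <- build_matrix(c("Group5", "Group3"), c("P", "A"))
  expect_equal(cm$counts["Group5", "P"], 1L)
  expect_equal(cm$counts["Group3", "A"], 1L)
  expect_equal(cm$n_all, 2)
  expect_error(build_matrix("Group5", c("P", "A")), "equal length")
  expect_error(build_matrix("GroupZ", "P"), "unknown truth")
  expect_error(build_matrix("Group5", "Q"), "unknown prediction")
  # long-form prediction names are accepted
  cm2 <- build_matrix("Group3", "Adenoma")
  expect_equal(cm2$counts["Group3", "A"], 1L)
})

test_that("the packaged hospital fixtures carry the published totals", {
  tokyo <- hospital_confusion("tokyo")
  expect_equal(tokyo$n_all, 1077)
  expect_equal(unname(colSums(tokyo$counts)), c(474L, 416L, 180L, 7L))
  east <- hospital_confusion("east")
  expect_equal(east$n_all, 251)
  expect_equal(unname(colSums(east$counts)), c(150L, 65L, 36L, 0L))
})

test_that("screening indices reproduce the published two-hospital values", {
  tokyo <- hospital_confusion("tokyo")
  expect_equal(undetected_rate_carcinoma(tokyo), 0.0)
  expect_equal(undetected_rate_adenoma(tokyo), 9.9)
  expect_equal(over_detected_proportion(tokyo), 36.1)
  east <- hospital_confusion("east")
  expect_equal(undetected_rate_carcinoma(east), 9.3)
  expect_equal(undetected_rate_adenoma(east), 0.0)
  expect_equal(over_detected_proportion(east), 27.1)
})

test_that("index arithmetic and denominators behave", {
  # n(N|G3)=1, n(G3)=8 -> 12.5
  cm <- build_matrix(rep("Group3", 8), c(rep("A", 7), "N"))
  expect_equal(undetected_rate_adenoma(cm), 12.5)
  # diagonal-perfect matrix -> all zero
  cmd <- build_matrix(c("Group5", "Group3", "Group1"), c("P", "A", "N"))
  expect_equal(undetected_rate_carcinoma(cmd), 0)
  expect_equal(over_detected_proportion(cmd), 0)
  # all-Negative predictions on all-Group1 truth -> no over-detection
  cmn <- build_matrix(rep("Group1", 5), rep("N", 5))
  expect_equal(over_detected_proportion(cmn), 0)
  # zero denominators error strictly and report NA otherwise
  expect_error(undetected_rate_carcinoma(cmn), "zero denominator")
  expect_true(is.na(undetected_rate_carcinoma(cmn, strict = FALSE)))
})

test_that("indices equal the brute-force pair-list oracle on random cohorts", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    truth <- sample(truth_groups(), n, replace = TRUE,
                    prob = c(0.2, 0.03, 0.02, 0.05, 0.3, 0.05, 0.3, 0.05))
    pred <- sample(prediction_classes(), n, replace = TRUE)
    cm <- build_matrix(truth, pred)
    got <- unname(screening_indices(cm))
    expect_equal(got, oracle_indices(truth, pred))
    # permutation invariance
    p <- sample(n)
    expect_equal(unname(screening_indices(build_matrix(truth[p], pred[p]))),
                 got)
  }
})

test_that("evaluate_run joins, tallies, writes and flags undefined indices", {
  dir <- withr::local_tempdir()
  truth <- data.frame(tissue_id = sprintf("t%02d", 1:6),
                      group = c("Group5", "Group5", "Group3", "Group3",
                                "Group1", "Group1"))
  pred <- data.frame(tissue_id = sprintf("t%02d", 6:1),
                     final_class = c("Negative", "Positive", "Adenoma",
                                     "Adenoma", "Positive", "Positive"))
  out <- evaluate_run(truth, pred,
                      matrix_csv = file.path(dir, "cm.csv"),
                      report_json = file.path(dir, "idx.json"))
  expect_equal(unname(out$indices["undetected_carcinoma_pct"]), 0)
  expect_equal(unname(out$indices["over_detected_pct"]),
               round(100 / 6, 1))
  back <- read_confusion_csv(file.path(dir, "cm.csv"))
  expect_identical(back$counts, out$confusion$counts)
  # no Group3 rows -> adenoma index undefined, not zero
  t2 <- truth[truth$group != "Group3", ]
  p2 <- pred[pred$tissue_id %in% t2$tissue_id, ]
  out2 <- evaluate_run(t2, p2)
  expect_true(is.na(out2$indices["undetected_adenoma_pct"]))
  expect_error(evaluate_run(truth[1:5, ], pred), "mismatch")
})

test_that("CSV fixtures round-trip through the confusion-matrix reader", {
  cm <- hospital_confusion("tokyo")
  path <- withr::local_tempfile(fileext = ".csv")
  write_confusion_csv(cm, path)
  expect_identical(read_confusion_csv(path)$counts, cm$counts)
})
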