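test_that("the combination rule matches its table on all 18 cases", {
  expected <- list(
    # structural, cyto, quality -> final
    c("low", "low", "ok", "Negative"),
    c("low", "low", "partial_degraded", "Negative"),
    c("low", "low", "unusable", "Unclassifiable"),
    c("low", "high", "ok", "Positive"),
    c("low", "high", "partial_degraded", "Positive"),
    c("low", "high", "unusable", "Unclassifiable"),
    c("middle", "low", "ok", "Adenoma"),
    c("middle", "low", "partial_degraded", "Adenoma"),
    c("middle", "low", "unusable", "Unclassifiable"),
    c("middle", "high", "ok", "Positive"),
    c("middle", "high", "partial_degraded", "Positive"),
    c("middle", "high", "unusable", "Unclassifiable"),
    c("high", "low", "ok", "Positive"),
    c("high", "low", "partial_degraded", "Positive"),
    c("high", "low", "unusable", "Unclassifiable"),
    c("high", "high", "ok", "Positive"),
    c("high", "high", "partial_degraded", "Positive"),
    c("high", "high", "unusable", "Unclassifiable"))
  for (case in expected) {
    out <- combine_results(case[1], case[2], case[3])
    expect_equal(out$final_class, case[4],
                 label = paste(case[1:3], collapse = "/"))
    expect_gt(length(out$explanation), 0)
  }
  # the open corner: structural unclassifiable
  expect_equal(combine_results("unclassifiable", "low", "ok")$final_class,
               "Unclassifiable")
  expect_equal(combine_results("unclassifiable", "high", "ok")$final_class,
               "Positive")
  expect_error(combine_results("none", "low", "ok"), "unknown structural")
  expect_error(combine_results("low", "mid", "ok"), "unknown cyto")
})

test_that("raising either atypia level never demotes the final class", {
  ord <- c(Negative = 1, Adenoma = 2, Positive = 3)
  s_levels <- c("low", "middle", "high")
  c_levels <- c("low", "high")
  for (q in c("ok", "partial_degraded")) {
    for (si in 1:2) for (ci in seq_along(c_levels)) {
      base <- combine_results(s_levels[si], c_levels[ci], q)$final_class
      up_s <- combine_results(s_levels[si + 1], c_levels[ci], q)$final_class
      expect_gte(ord[up_s], ord[base])
    }
    for (si in seq_along(s_levels)) {
      base <- combine_results(s_levels[si], "low", q)$final_class
      up_c <- combine_results(s_levels[si], "high", q)$final_class
      expect_gte(ord[up_c], ord[base])
    }
  }
})

test_that("diagnosis labels map onto the system vocabulary", {
  expect_equal(map_diagnosis(c("Group1", "Group2", "Group3", "Group4",
                               "Group5", "GroupX")),
               c("N", "N", "A", "P", "P", "X"))
  expect_equal(map_diagnosis(c("lymphoma", "carcinoid")), c("P", "P"))
  expect_error(map_diagnosis("Group9"), "unknown diagnosis")
})

test_that("end-to-end classification handles the canonical phenotypes", {
  cfg <- fx_config()
  model <- default_mil_model()
  # artifact-free negative tissue
  tc_neg <- classify_tissue(fx_negative()$image, model, cfg)
  expect_equal(tc_neg$final_class, "Negative")
  # overall blur short-circuits: atypia stages never run
  bl <- apply_artifacts(fx_negative()$image, artifact_spec(3, 1, seed = 41))
  tc_bl <- classify_tissue(bl$image, model, cfg)
  expect_equal(tc_bl$final_class, "Unclassifiable")
  expect_null(tc_bl$structural)
  expect_null(tc_bl$cyto)
  # dissociated-cell carcinoma is caught by the cytological route
  tc_sig <- classify_tissue(fx_signet()$image, model, cfg)
  expect_equal(tc_sig$final_class, "Positive")
  expect_equal(tc_sig$cyto_level, "high")
})

test_that("per-tissue reports serialize to JSON", {
  cfg <- fx_config()
  tc <- classify_tissue(fx_negative()$image, default_mil_model(), cfg,
                        tissue_id = "t1")
  path <- withr::local_tempfile(fileext = ".json")
  write_tissue_report(tc, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$tissue_id, "t1")
  expect_equal(rep$final_class, "Negative")
  expect_equal(rep$quality$status, "ok")
})
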