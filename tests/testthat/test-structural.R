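test_that("the tissue mask matches ground truth and resists brightness shifts", {
  rt <- fx_adenoma()
  nrm <- fx_adenoma_norm()
  m <- make_mask(nrm)
  truth <- rt$truth$tissue_mask & !rt$truth$lumen_mask
  dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
  expect_gt(dice, 0.9)
  expect_error(make_mask(tissue_image(array(1, c(256, 256, 3)), 1)), "empty")
  shifted <- tissue_image(pmin(nrm$pixels + 5 / 255, 1), nrm$um_per_px)
  m2 <- make_mask(shifted)
  expect_gt(2 * sum(m & m2) / (sum(m) + sum(m2)), 0.95)
})

test_that("glandular components are recovered one per gland", {
  cfg <- fx_config()
  rt <- render_tissue(tissue_phenotype("adenoma", 6, 2.2, 0.2, 0, 7.5,
                                       seed = 54), size_px = c(1024, 1024))
  nrm <- normalize_stains(rt$image, cfg$stain$reference)
  comps <- extract_glandular_nuclei_lowmag(nrm, make_mask(nrm), cfg)
  expect_gte(length(comps), 5)
  expect_lte(length(comps), 7)
  # nothing gland-like in a tissue with no glands and no cells
  rt0 <- render_tissue(tissue_phenotype("negative", 0, 1, 0, 0, 7, seed = 2),
                       size_px = c(256, 256))
  nrm0 <- tryCatch(normalize_stains(rt0$image, cfg$stain$reference),
                   error = function(e) rt0$image)
  expect_length(extract_glandular_nuclei_lowmag(nrm0, make_mask(nrm0), cfg), 0)
})

test_that("component count is stable under eosin-scale perturbation", {
  cfg <- fx_config()
  ph <- tissue_phenotype("adenoma", 5, 2.3, 0.2, 0, 7.5, seed = 55)
  n_comp <- function(stain) {
    rt <- render_tissue(ph, stain, size_px = c(512, 512))
    nrm <- normalize_stains(rt$image, cfg$stain$reference)
    length(extract_glandular_nuclei_lowmag(nrm, make_mask(nrm), cfg))
  }
  expect_equal(n_comp(default_stain_profile()),
               n_comp(stain_profile(intensity_scale = 1.2)))
})

test_that("thickness follows analytic ribbon geometry", {
  bar <- matrix(FALSE, 40, 80); bar[15:24, 10:70] <- TRUE
  expect_equal(quantify_thickness(bar, 1), 10, tolerance = 0.1)
  line <- matrix(FALSE, 40, 80); line[20, 10:70] <- TRUE
  expect_equal(quantify_thickness(line, 1), 2)
  expect_error(quantify_thickness(matrix(FALSE, 10, 10), 1), "empty")
})

test_that("rim thickness of rendered glands matches the phenotype", {
  cfg <- fx_config()
  rt <- render_tissue(tissue_phenotype("carcinoma", 4, 3, 0, 0, 7, seed = 53),
                      size_px = c(512, 512))
  nrm <- normalize_stains(rt$image, cfg$stain$reference)
  comps <- extract_glandular_nuclei_lowmag(nrm, make_mask(nrm), cfg)
  th <- vapply(comps, quantify_thickness, numeric(1), um_per_px = 0.92)
  # 3 nuclear widths x 7 um
  expect_true(all(abs(th - 21) <= 5))
})

test_that("gland levels bin and clip as configured", {
  expect_equal(assign_gland_levels(4), 1L)    # below range clips to 1
  expect_equal(assign_gland_levels(56), 10L)  # above range clips to 10
  expect_equal(assign_gland_levels(c(7, 14, 22, 33, 52)),
               c(1L, 2L, 4L, 6L, 10L))
  # monotone property over random thickness lists
  set.seed(1)
  for (i in 1:50) {
    t <- sort(stats::runif(20, 0, 70))
    expect_true(all(diff(assign_gland_levels(t)) >= 0))
  }
})

test_that("level overlays use the fixed palette and touch only components", {
  cfg <- fx_config()
  nrm <- fx_adenoma_norm()
  comps <- extract_glandular_nuclei_lowmag(nrm, make_mask(nrm), cfg)
  comps <- lapply(comps, function(cp) {
    cp$thickness_um <- quantify_thickness(cp, nrm$um_per_px); cp
  })
  comps[[1]]$thickness_um <- 4    # force coolest
  comps[[2]]$thickness_um <- 60   # force warmest
  comps <- assign_gland_levels(comps)
  ov <- render_levels(nrm, comps)
  pal <- grDevices::col2rgb(gland_level_palette()) / 255
  i1 <- comps[[1]]$mask_idx[1]
  expect_equal(c(ov[, , 1][i1], ov[, , 2][i1], ov[, , 3][i1]),
               unname(pal[, 1]))
  i10 <- comps[[2]]$mask_idx[1]
  expect_equal(c(ov[, , 1][i10], ov[, , 2][i10], ov[, , 3][i10]),
               unname(pal[, 10]))
  # untouched outside components and the legend strip
  untouched <- ov != nrm$pixels
  comp_px <- unique(unlist(lapply(comps, function(cp) cp$mask_idx)))
  h <- dim(ov)[1]
  changed <- which(untouched[, , 1] | untouched[, , 2] | untouched[, , 3])
  legend <- changed[(changed - 1) %% h + 1 > h - 12]
  expect_true(all(setdiff(changed, legend) %in% comp_px))
})

test_that("arrangement scores track generator stratification", {
  cfg <- fx_config()
  score_of <- function(strat, rim, seed) {
    cl <- if (rim >= 3) "carcinoma" else if (rim > 1.5) "adenoma" else "negative"
    rt <- render_tissue(tissue_phenotype(cl, 4, rim, strat, 0, 8, seed = seed),
                        size_px = c(512, 512))
    nrm <- normalize_stains(rt$image, cfg$stain$reference)
    comps <- extract_glandular_nuclei_lowmag(nrm, make_mask(nrm), cfg)
    segs <- lapply(comps, function(cp)
      segment_gland_cells_highmag(nrm, cp, cfg))
    expect_true(all(vapply(segs, function(s)
      sum(s$nuclei_mask & s$cytoplasm_mask), numeric(1)) == 0))
    mean(vapply(segs, function(s) s$arrangement_score, numeric(1)))
  }
  # polarized single-layer glands
  expect_lte(score_of(0, 1.2, 21), 0.2)
  expect_lte(score_of(0, 1.2, 24), 0.2)
  # fully stratified glands
  expect_gte(score_of(1, 2.5, 21), 0.6)
  expect_gte(score_of(1, 2.5, 22), 0.6)
})

test_that("the structural decision rule applies the documented cutpoints", {
  cfg <- fx_config()
  mk <- function(lvl) structure(list(component_id = 1L, mask_idx = 1L,
                                     dim = c(10L, 10L), n_px = 1L,
                                     centroid = c(1, 1), thickness_um = 1,
                                     gland_level = as.integer(lvl)),
                                class = "gland_component")
  seg <- function(a) structure(list(component_id = 1L, arrangement_score = a),
                               class = "gland_segmentation")
  expect_equal(classify_structural(list(mk(2)), list(), cfg)$level, "low")
  expect_equal(classify_structural(list(mk(6)), list(seg(0.3)), cfg)$level,
               "middle")
  expect_equal(classify_structural(list(mk(9)), list(), cfg)$level, "high")
  expect_equal(classify_structural(list(mk(6)), list(seg(0.6)), cfg)$level,
               "high")
  expect_equal(classify_structural(list(), list(), cfg,
                                   expect_glands = TRUE)$level,
               "unclassifiable")
  expect_equal(classify_structural(list(), list(), cfg,
                                   expect_glands = FALSE)$level, "low")
})

test_that("high-magnification segmentation runs only above the trigger level", {
  cfg <- fx_config()
  res_neg <- analyze_structural(normalize_stains(fx_negative()$image,
                                                 cfg$stain$reference), cfg)
  expect_equal(attr(res_neg, "highmag_calls"), 0L)
  expect_equal(res_neg$level, "low")
  rt <- render_tissue(tissue_phenotype("carcinoma", 4, 4.5, 0.8, 0, 9,
                                       seed = 26), size_px = c(512, 512))
  res_carc <- analyze_structural(normalize_stains(rt$image,
                                                  cfg$stain$reference), cfg)
  expect_gt(attr(res_carc, "highmag_calls"), 0L)
  expect_equal(res_carc$level, "high")
})

test_that("median max gland level increases strictly with rim thickness", {
  cfg <- fx_config()
  med_level <- vapply(c(1, 3, 5), function(rim) {
    lv <- vapply(1:3, function(s) {
      cl <- if (rim >= 3) "carcinoma" else if (rim >= 2) "adenoma" else "negative"
      strat <- if (cl == "carcinoma") 0.6 else if (cl == "adenoma") 0.2 else 0
      rt <- render_tissue(tissue_phenotype(cl, 5, rim, strat, 0, 7,
                                           seed = 100 + s),
                          size_px = c(512, 512))
      nrm <- normalize_stains(rt$image, cfg$stain$reference)
      comps <- extract_glandular_nuclei_lowmag(nrm, make_mask(nrm), cfg)
      comps <- lapply(comps, function(cp) {
        cp$thickness_um <- quantify_thickness(cp, nrm$um_per_px); cp
      })
      comps <- assign_gland_levels(comps)
      max(vapply(comps, function(cp) cp$gland_level, integer(1)))
    }, integer(1))
    stats::median(lv)
  }, numeric(1))
  expect_true(all(diff(med_level) > 0))
})
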