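test_that("rendering is a pure function of the phenotype seed", {
  ph <- tissue_phenotype("adenoma", 4, 2.2, 0.2, 0, 7.5, seed = 11)
  a <- render_tissue(ph, size_px = c(256, 256))
  b <- render_tissue(ph, size_px = c(256, 256))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$nuclei_mask, b$truth$nuclei_mask)
})

test_that("an empty phenotype renders no nuclei and bad inputs are rejected", {
  ph <- tissue_phenotype("negative", 0, 1, 0, 0, 7, seed = 2)
  rt <- render_tissue(ph, size_px = c(256, 256))
  expect_equal(max(rt$truth$nuclei_mask), 0)
  expect_error(render_tissue(ph, size_px = c(128, 128)), "256")
  expect_error(render_tissue(ph, um_per_px = -1), "positive")
  expect_error(tissue_phenotype("negative", 4, rim_thickness_nuclei = 2),
               "negative phenotype")
  expect_error(tissue_phenotype("carcinoma", 4, rim_thickness_nuclei = 1),
               "carcinoma phenotype")
})

test_that("rim thickness in the phenotype scales the measured rim width", {
  # brute-force oracle: mean width of the (closed) nuclear band is
  # 4 x the mean distance-transform value over the band
  width_of <- function(rim, seed) {
    cl <- if (rim >= 3) "carcinoma" else "negative"
    ph <- tissue_phenotype(cl, 5, rim, 0, 0, 7, seed = seed)
    rt <- render_tissue(ph, size_px = c(512, 512))
    m <- rt$truth$nuclei_mask > 0
    mc <- EBImage::closing(m * 1, EBImage::makeBrush(9, "disc")) > 0
    4 * mean(EBImage::distmap(mc * 1)[mc])
  }
  for (s in c(51, 52)) {
    ratio <- width_of(4, s) / width_of(1, s)
    expect_gt(ratio, 3)
    expect_lt(ratio, 5)
  }
})

test_that("ground-truth masks are mutually consistent", {
  for (rt in list(fx_adenoma(), fx_signet())) {
    truth <- rt$truth
    expect_identical(dim(truth$nuclei_mask), dim(rt$image$pixels)[1:2])
    # lumen disjoint from nuclei
    expect_equal(sum(truth$lumen_mask & truth$nuclei_mask > 0), 0)
    # every nucleus pixel carries more hematoxylin than the stromal median
    od <- -log(pmax(rt$image$pixels, 1 / 255))
    hproj <- od[, , 1] * 0.644 + od[, , 2] * 0.717 + od[, , 3] * 0.267
    stroma <- truth$tissue_mask & truth$nuclei_mask == 0 &
      truth$gland_mask == 0 & truth$cytoplasm_mask == 0
    nuc <- truth$nuclei_mask > 0
    expect_gt(stats::quantile(hproj[nuc], 0.05), stats::median(hproj[stroma]))
  }
})

test_that("batch re-rendering under the identity profile is a near no-op", {
  img <- fx_adenoma()$image
  out <- apply_batch_effect(img, default_stain_profile())
  for (k in 1:3)
    expect_lt(mean(abs(out$pixels[, , k] - img$pixels[, , k])) * 255, 1)
})

test_that("contrast compression reduces per-channel spread and distinct shifts differ", {
  img <- fx_adenoma()$image
  lo <- apply_batch_effect(img, stain_profile(contrast_scale = 0.4))
  tissue <- fx_adenoma()$truth$tissue_mask
  for (k in 1:3)
    expect_lt(stats::sd(lo$pixels[, , k][tissue]),
              stats::sd(img$pixels[, , k][tissue]))
  a <- apply_batch_effect(img, stain_profile(hematoxylin = c(0.7, 0.65, 0.29),
                                             intensity_scale = 1.15))
  b <- apply_batch_effect(img, stain_profile(eosin = c(0.05, 0.93, 0.36),
                                             intensity_scale = 0.8))
  expect_gt(mean(abs(a$pixels - b$pixels)) * 255, 3)
})

test_that("artifact application honours its spec", {
  img <- fx_adenoma()$image
  # no-op spec
  out <- apply_artifacts(img, artifact_spec(seed = 41))
  expect_identical(out$image$pixels, img$pixels)
  expect_equal(sum(out$truth$artifact_mask), 0)
  # full-coverage blur marks every pixel
  out <- apply_artifacts(img, artifact_spec(3, 1, seed = 41))
  expect_true(all(out$truth$artifact_mask))
  # pen ink is more saturated than the tissue median
  out <- apply_artifacts(img, artifact_spec(pen_mark = TRUE, seed = 43))
  expect_gt(sum(out$truth$artifact_mask), 0)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(out$image$pixels[, , 1]),
                                  as.vector(out$image$pixels[, , 2]),
                                  as.vector(out$image$pixels[, , 3])),
                            maxColorValue = 1)
  sat <- matrix(hsv[2, ], nrow(out$truth$artifact_mask))
  expect_gt(stats::median(sat[out$truth$artifact_mask]),
            stats::median(sat[!out$truth$artifact_mask]))
  # coverage/sigma coupling enforced
  expect_error(artifact_spec(blur_sigma = 0, blur_coverage = 0.5), "iff|exactly")
})

test_that("cohort generation is reproducible and artifact flags are binomial", {
  co1 <- generate_cohort(list(negative = 5), seed = 5, size_px = c(256, 256),
                         keep_images = FALSE)
  expect_equal(nrow(co1$manifest), 5)
  expect_true(all(co1$manifest$class == "negative"))
  co2 <- generate_cohort(list(negative = 5), seed = 5, size_px = c(256, 256),
                         keep_images = FALSE)
  expect_identical(co1$manifest, co2$manifest)
  # Monte-Carlo over master seeds: flag count ~ Binomial(30, 0.1)
  counts <- vapply(1:40, function(s) {
    co <- generate_cohort(list(carcinoma = 10, adenoma = 10, negative = 10),
                          artifact_rate = 0.1, seed = s, render = FALSE)
    sum(co$manifest$blur_sigma > 0 | co$manifest$pen_mark |
          co$manifest$shadow)
  }, numeric(1))
  expect_gt(mean(counts), 3 - 3 * sqrt(30 * 0.1 * 0.9 / 40))
  expect_lt(mean(counts), 3 + 3 * sqrt(30 * 0.1 * 0.9 / 40))
})

test_that("cohort files round-trip through disk", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(list(negative = 2), seed = 6, dir = dir,
                        size_px = c(256, 256), keep_images = TRUE)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- read_tissue_png(file.path(dir, "t0001.png"), co$um_per_px)
  expect_equal(img$pixels, co$images[[1]]$pixels, tolerance = 1 / 254)
  m <- read_label_mask(file.path(dir, "t0001_nuclei.tif"))
  expect_identical(m, co$truths[[1]]$nuclei_mask)
})
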