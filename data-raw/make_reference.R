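# Regenerates the frozen defaults in R/config.R:
#   - the normalization reference stain estimate (.reference_stain_estimate)
#     from the fixed-seed reference render below (print and paste), and
#   - the focus-score calibration behind quality$blur_threshold: per-tile
#     variance-of-Laplacian ranges on sharp vs sigma-3 blurred renders
#     across classes and seeds; the threshold sits in the wide gap between
#     the two distributions (sharp minimum ~25, blurred maximum ~4).
# Run from the package root with the package loaded (devtools::load_all()).

ph <- tissue_phenotype("adenoma", 6, 2.2, 0.25, 0, 7.5, seed = 20240101)
rt <- render_tissue(ph, size_px = c(512, 512))
est <- estimate_stains(rt$image)
print(lapply(unclass(est), round, 6))

for (s in 1:4) for (cl in c("negative", "adenoma", "carcinoma")) {
  r <- render_tissue(sample_phenotype(cl, s), size_px = c(512, 512))
  s1 <- sharpness_map(r$image, 64)
  b <- apply_artifacts(r$image, artifact_spec(3, 1, seed = s))
  s2 <- sharpness_map(b$image, 64)
  cat(sprintf("%s seed=%d sharp_min=%.1f blur_max=%.2f\n", cl, s,
              min(s1$scores[s1$foreground]), max(s2$scores[s2$foreground])))
}
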