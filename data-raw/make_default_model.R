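# Trains the packaged default MIL model (inst/extdata/default_mil_model.json)
# on a fixed-seed synthetic cohort: 20 tissues per class at 512 px, bags of
# per-ROI nuclear-morphometry features, bag label = carcinoma. The model is
# synthetic-data-trained; it has never seen real histology.
# Run from the package root with the package loaded (devtools::load_all()).

cfg <- default_config()
co <- generate_cohort(list(negative = 20, adenoma = 20, carcinoma = 20),
                      seed = 777, keep_images = TRUE)
bags <- lapply(seq_len(nrow(co$manifest)), function(i) {
  img <- cohort_tissue(co, i)
  nrm <- tryCatch(normalize_stains(img, cfg$stain$reference),
                  error = function(e) img)
  nuc <- detect_nuclei(nrm, cfg)
  rois <- form_rois(nuc$table, dim(nrm$pixels)[1:2], nrm$um_per_px,
                    cfg$cyto$roi_size_px, cfg$cyto$min_nuclei)
  if (nrow(rois) > 0) as.matrix(rois[, roi_feature_names()]) else
    matrix(0, 1, length(roi_feature_names()),
           dimnames = list(NULL, roi_feature_names()))
})
model <- train_mil(bags, as.numeric(co$manifest$class == "carcinoma"),
                   hidden = cfg$cyto$mil$hidden, pool = cfg$cyto$mil$pool,
                   pool_r = cfg$cyto$mil$pool_r, epochs = cfg$cyto$mil$epochs,
                   lr = cfg$cyto$mil$lr, l2 = cfg$cyto$mil$l2,
                   seed = cfg$cyto$mil$seed)
write_mil_model(model, file.path("inst", "extdata", "default_mil_model.json"))

# The frozen default cyto$threshold in R/config.R follows the calibration
# rule on the fixed-seed validation cohort below (midpoint between the
# highest benign and the lowest poorly-differentiated carcinoma aggregate).
va <- generate_cohort(list(negative = 20, adenoma = 20, carcinoma = 20),
                      seed = 888, keep_images = TRUE)
agg <- vapply(seq_len(nrow(va$manifest)), function(i) {
  img <- cohort_tissue(va, i)
  nrm <- tryCatch(normalize_stains(img, cfg$stain$reference),
                  error = function(e) img)
  analyze_cyto(nrm, model, cfg)$aggregate
}, numeric(1))
cls <- va$manifest$class
poorly <- cls == "carcinoma" & va$manifest$dissociated_density > 0
cat("min poorly-diff aggregate:", min(agg[poorly]), "\n")
cat("max benign aggregate:", max(agg[cls != "carcinoma"]), "\n")
cat("calibrated threshold:",
    min(0.95 * min(agg[poorly]),
        0.5 * (max(agg[cls != "carcinoma"]) + min(agg[poorly]))), "\n")
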