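#' Default pipeline configuration
#'
#' All tunable thresholds and parameters of the pipeline, with documented
#' defaults. Tuning lives here, not in code: [calibrate_thresholds()]
#' returns an updated copy.
#'
#' \describe{
#'   \item{quality}{`tile_size_px` (64); `blur_threshold`, the
#'     variance-of-Laplacian focus cutoff on the 0-255 luminance scale,
#'     calibrated once on generator output; `max_blur` (0.5), `max_pen`
#'     (0.2), `max_shadow` (0.3): unusable-fraction cutoffs; `partial`
#'     (0.05): any fraction above it degrades the tissue.}
#'   \item{stain}{`reference`: the normalization target stain estimate
#'     (derived from a fixed-seed generator image, see `data-raw/`);
#'     `nuclei_h_threshold` (0.5): absolute hematoxylin-concentration
#'     cutoff for nuclear pixels.}
#'   \item{structural}{`nuclear_width_um` (7): closing radius for linking
#'     rim nuclei; `min_nuclei_per_component` (5); `binning`: ten 5-um
#'     levels spanning 5-55 um; `trigger_level` (5): minimum level for the
#'     high-magnification pass; `low_max` (3) / `high_min` (8): level
#'     cutpoints; `arrangement_cut` (0.5): arrangement score at or above
#'     which the tissue is high; `basal_cut` (0.6) and `n_sectors` (24):
#'     the polarity measure; `cyto_e_threshold` (0.26): eosin cutoff for
#'     gland cytoplasm.}
#'   \item{cyto}{`roi_size_px` (128), `min_nuclei` (10) per kept ROI,
#'     `threshold` for the top-3 mean-square aggregate, and the `mil`
#'     training settings.}
#' }
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    quality = list(tile_size_px = 64L,
                   blur_threshold = 10,
                   max_blur = 0.5, max_pen = 0.2, max_shadow = 0.3,
                   partial = 0.05),
    stain = list(
      reference = .reference_stain_estimate(),
      nuclei_h_threshold = 0.5),
    structural = list(
      nuclear_width_um = 7,
      min_nuclei_per_component = 5,
      binning = list(min_um = 5, max_um = 55, n_levels = 10L),
      trigger_level = 5L, low_max = 3L, high_min = 8L,
      arrangement_cut = 0.5, basal_cut = 0.6, n_sectors = 24L,
      cyto_e_threshold = 0.30),
    cyto = list(roi_size_px = 128L, min_nuclei = 10L, threshold = 0.6,
                mil = list(hidden = 8L, pool = "lse", pool_r = 4,
                           epochs = 400L, lr = 0.01, l2 = 1e-4, seed = 42L))
  )
}

# Normalization target: stain estimate of the fixed-seed reference render
# (regenerated by data-raw/make_reference.R; values frozen here so the
# default config needs no computation).
.reference_stain_estimate <- function() {
  structure(list(
    h_vector = c(0.600651, 0.749047, 0.279587),
    e_vector = c(0.146997, 0.937946, 0.314098),
    h_scale_percentiles = c(0.046893, 1.110303),
    e_scale_percentiles = c(0.189716, 0.449753),
    white_point = c(248.0, 247.0, 249.0)),
    class = "stain_estimate")
}

# Recursively check that cfg introduces no keys absent from the reference.
check_config_keys <- function(cfg, ref, path = "") {
  bad <- setdiff(names(cfg), names(ref))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !inherits(ref[[k]], "stain_estimate") &&
        is.list(cfg[[k]]))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "$"))
  }
  invisible(TRUE)
}

# Deep-merge overrides into base (lists merged recursively).
merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !inherits(base[[k]], "stain_estimate")) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load / save a pipeline configuration as YAML
#'
#' Loaded values override the defaults; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return the merged configuration list.
#' @export
load_config <- function(path) {
  override <- yaml::read_yaml(path)
  base <- default_config()
  if (is.null(override)) return(base)
  check_config_keys(override, base)
  cfg <- merge_config(base, override)
  if (!inherits(cfg$stain$reference, "stain_estimate"))
    cfg$stain$reference <- structure(cfg$stain$reference,
                                     class = "stain_estimate")
  cfg
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  config$stain$reference <- unclass(config$stain$reference)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Calibrate decision thresholds on a validation cohort
#'
#' Mirrors the screening priority: the cytological threshold is set first,
#' just below the smallest aggregate observed on poorly differentiated
#' (dissociated-cell) carcinomas, so none is missed on the validation set;
#' then the structural low/middle cutpoint is set below the 5th percentile
#' of adenoma maximum gland levels (adenoma sensitivity); finally the
#' high-magnification trigger is placed at or below the 10th percentile of
#' glandular-carcinoma levels so their arrangement is actually examined.
#' Over-detection is reported, not optimized.
#'
#' @param results [classify_cohort()] output on the validation cohort.
#' @param manifest the validation cohort manifest.
#' @param config configuration to update.
#' @return list with the updated `config` and the validation `indices`.
#' @export
calibrate_thresholds <- function(results, manifest, config = default_config()) {
  m <- merge(results, manifest[, c("tissue_id", "dissociated_density")],
             by = "tissue_id")
  usable <- m$quality_status != "unusable"
  poorly <- m$class == "carcinoma" & m$dissociated_density > 0 & usable
  carc_gl <- m$class == "carcinoma" & m$dissociated_density == 0 & usable
  aden <- m$class == "adenoma" & usable
  if (any(poorly)) {
    min_poorly <- min(m$cyto_aggregate[poorly], na.rm = TRUE)
    noncarc <- usable & m$class != "carcinoma"
    max_benign <- if (any(noncarc)) max(m$cyto_aggregate[noncarc], na.rm = TRUE) else 0
    # midway between the highest benign aggregate and the lowest
    # poorly-differentiated carcinoma aggregate, but never above the point
    # that would miss a validation carcinoma (sensitivity first)
    thr <- min(0.95 * min_poorly, 0.5 * (max_benign + min_poorly))
    config$cyto$threshold <- clamp(thr, 0.05, 0.9)
  }
  if (any(aden)) {
    q <- stats::quantile(m$max_level[aden], 0.05, type = 1, na.rm = TRUE)
    config$structural$low_max <- max(1L, as.integer(q) - 1L)
  }
  if (any(carc_gl)) {
    q <- stats::quantile(m$max_level[carc_gl], 0.1, type = 1, na.rm = TRUE)
    config$structural$trigger_level <-
      as.integer(clamp(q, config$structural$low_max + 1L,
                       config$structural$high_min))
  }
  # validation indices under the new thresholds
  group <- c(negative = "Group1", adenoma = "Group3",
             carcinoma = "Group5")[m$class]
  final <- reapply_thresholds(m, config)
  cmv <- build_matrix(group, final)
  list(config = config, indices = screening_indices(cmv))
}

# Re-derive final classes from recorded stage quantities under a (new)
# config, without re-running image analysis. Arrangement-driven "high"
# calls are kept as recorded.
reapply_thresholds <- function(results, config) {
  st <- config$structural
  vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    if (r$quality_status == "unusable") return("Unclassifiable")
    structural <- if (is.na(r$max_level)) {
      if (r$structural_level == "unclassifiable") "unclassifiable" else "low"
    } else if (r$max_level >= st$high_min ||
               (!is.na(r$max_arrangement) &&
                r$max_arrangement >= st$arrangement_cut &&
                r$max_level >= st$trigger_level)) {
      "high"
    } else if (r$max_level <= st$low_max) "low" else "middle"
    cyto <- if (!is.na(r$cyto_aggregate) &&
                r$cyto_aggregate >= config$cyto$threshold) "high" else "low"
    combine_results(structural, cyto, r$quality_status)$final_class
  }, character(1))
}
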