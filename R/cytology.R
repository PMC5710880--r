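#' Detect nuclei and per-nucleus morphometry
#'
#' Thresholds the hematoxylin concentration map at the configured absolute
#' cutoff, cleans speckle, splits touching nuclei by watershed on the
#' distance transform, and returns centroids with morphometric features.
#' The absolute (not image-adaptive) cutoff is deliberate: on low-contrast
#' batches the nuclear and background colour distributions overlap and
#' detection collapses unless the image was colour-normalized first.
#'
#' @param tissue a (normalized) [tissue_image()].
#' @param config pipeline configuration.
#' @param exclude optional logical matrix; nuclei whose centroid falls in
#'   it are dropped (degraded-tile masking).
#' @return list with `table` (data.frame: `row`, `col`, `area_um2`,
#'   `eccentricity`, `mean_h`) and `labels` (integer label matrix).
#' @export
detect_nuclei <- function(tissue, config = default_config(), exclude = NULL) {
  stopifnot(inherits(tissue, "tissue_image"))
  ref <- config$stain$reference
  ch <- h_concentration(tissue, ref$h_vector, ref$e_vector, ref$white_point)
  mask <- ch > config$stain$nuclei_h_threshold
  empty <- list(table = data.frame(row = numeric(0), col = numeric(0),
                                   area_um2 = numeric(0),
                                   eccentricity = numeric(0),
                                   mean_h = numeric(0)),
                labels = matrix(0L, nrow(ch), ncol(ch)))
  if (!any(mask)) return(empty)
  mask <- EBImage::opening(mask * 1, EBImage::makeBrush(3, "disc")) > 0
  min_px <- max(3, round(10 / tissue$um_per_px^2))  # 10 um^2
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(mask * 1)
  lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  n <- max(lab)
  if (n == 0) return(empty)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- sizes >= min_px
  sum_r <- rowsum(as.numeric((seq_along(lab) - 1L) %% nrow(lab) + 1L)[lab > 0],
                  lab[lab > 0])
  sum_c <- rowsum(as.numeric((seq_along(lab) - 1L) %/% nrow(lab) + 1L)[lab > 0],
                  lab[lab > 0])
  sum_h <- rowsum(ch[lab > 0], lab[lab > 0])
  ids <- as.integer(rownames(sum_r))
  cx <- as.vector(sum_r) / sizes[ids]
  cy <- as.vector(sum_c) / sizes[ids]
  mh <- as.vector(sum_h) / sizes[ids]
  # eccentricity from second moments
  ecc <- numeric(length(ids))
  rr_all <- (which(lab > 0) - 1L) %% nrow(lab) + 1L
  cc_all <- (which(lab > 0) - 1L) %/% nrow(lab) + 1L
  lv <- lab[lab > 0]
  ord <- order(lv)
  lv <- lv[ord]; rr_all <- rr_all[ord]; cc_all <- cc_all[ord]
  starts <- c(1, which(diff(lv) > 0) + 1, length(lv) + 1)
  for (i in seq_along(ids)) {
    sel <- starts[i]:(starts[i + 1] - 1)
    r <- rr_all[sel] - cx[i]; c <- cc_all[sel] - cy[i]
    mrr <- mean(r^2); mcc <- mean(c^2); mrc <- mean(r * c)
    tr <- mrr + mcc
    det <- mrr * mcc - mrc^2
    l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
    l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
    ecc[i] <- if (l1 <= 0) 0 else sqrt(1 - clamp(l2 / l1))
  }
  df <- data.frame(row = cx, col = cy,
                   area_um2 = sizes[ids] * tissue$um_per_px^2,
                   eccentricity = ecc, mean_h = mh)
  ok <- keep[ids]
  if (!is.null(exclude))
    ok <- ok & !exclude[cbind(pmin(pmax(round(df$row), 1), nrow(ch)),
                              pmin(pmax(round(df$col), 1), ncol(ch)))]
  df <- df[ok, , drop = FALSE]
  rownames(df) <- NULL
  lab[!(lab %in% ids[ok])] <- 0L
  list(table = df, labels = lab)
}

# Fixed-length ROI feature vector (order is part of a model's contract).
roi_feature_names <- function() {
  c("density_per_mm2", "mean_area_um2", "sd_area_um2", "mean_ecc",
    "mean_h", "sd_h", "mean_nn_um", "frac_large")
}

roi_features <- function(nuc, roi_area_um2, um_per_px) {
  n <- nrow(nuc)
  nn <- if (n >= 2) {
    d2 <- as.matrix(stats::dist(nuc[, c("row", "col")]))
    diag(d2) <- Inf
    mean(apply(d2, 1, min)) * um_per_px
  } else 0
  c(density_per_mm2 = n / roi_area_um2 * 1e6,
    mean_area_um2 = mean(nuc$area_um2),
    sd_area_um2 = if (n > 1) stats::sd(nuc$area_um2) else 0,
    mean_ecc = mean(nuc$eccentricity),
    mean_h = mean(nuc$mean_h),
    sd_h = if (n > 1) stats::sd(nuc$mean_h) else 0,
    mean_nn_um = nn,
    frac_large = mean(nuc$area_um2 > 55))
}

#' Form nuclei-density regions of interest over a tissue
#'
#' Lays a regular grid of `roi_size_px` tiles over the image and keeps
#' every tile containing at least `min_nuclei` detected nuclei, so the
#' kept ROIs cover the cellular part of the tissue; sparse tiles are
#' dropped. Each ROI carries the fixed-length nuclear-morphometry feature
#' vector used by the MIL classifier.
#'
#' @param nuclei result of [detect_nuclei()] (its `table`), or the
#'   data.frame directly.
#' @param dim_hw image dimensions `c(rows, cols)`.
#' @param um_per_px pixel spacing.
#' @param roi_size_px ROI edge length, >= 64.
#' @param min_nuclei minimum nuclei per kept ROI (default 10).
#' @return data.frame of ROIs: bbox columns (`row0,col0,row1,col1`,
#'   half-open), `nuclei_count`, and one column per feature.
#' @export
form_rois <- function(nuclei, dim_hw, um_per_px,
                      roi_size_px = 256L, min_nuclei = 10L) {
  if (is.list(nuclei) && !is.data.frame(nuclei)) nuclei <- nuclei$table
  if (roi_size_px < 64) stop("roi_size_px must be >= 64")
  empty <- cbind(data.frame(row0 = integer(0), col0 = integer(0),
                            row1 = integer(0), col1 = integer(0),
                            nuclei_count = integer(0)),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0,
                                                      length(roi_feature_names()))),
                                 roi_feature_names()))
  if (nrow(nuclei) == 0) return(empty)
  nr <- ceiling(dim_hw[1] / roi_size_px)
  nc <- ceiling(dim_hw[2] / roi_size_px)
  ti <- pmin(floor((nuclei$row - 1) / roi_size_px), nr - 1)
  tj <- pmin(floor((nuclei$col - 1) / roi_size_px), nc - 1)
  key <- ti * nc + tj
  rows <- list()
  for (k in sort(unique(key))) {
    sel <- key == k
    if (sum(sel) < min_nuclei) next
    i <- k %/% nc; j <- k %% nc
    r0 <- i * roi_size_px; c0 <- j * roi_size_px
    r1 <- min(r0 + roi_size_px, dim_hw[1])
    c1 <- min(c0 + roi_size_px, dim_hw[2])
    area_um2 <- (r1 - r0) * (c1 - c0) * um_per_px^2
    f <- roi_features(nuclei[sel, , drop = FALSE], area_um2, um_per_px)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(row0 = r0, col0 = c0, row1 = r1, col1 = c1,
                 nuclei_count = sum(sel)),
      as.data.frame(as.list(f)))
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mean square of the top three ROI scores
#'
#' The tissue-level cytological aggregate: the mean of the squares of the
#' three largest per-ROI scores. Fewer than three scores are zero-padded;
#' an empty list aggregates to 0. Monotone in every coordinate and bounded
#' in `[0,1]`.
#'
#' @param scores numeric vector of per-ROI scores in `[0,1]`.
#' @return aggregate in `[0,1]`.
#' @export
aggregate_top3 <- function(scores) {
  s <- sort(scores, decreasing = TRUE)
  top <- c(s, 0, 0, 0)[1:3]
  mean(top^2)
}

#' Two-level cytological decision
#'
#' `high` iff `aggregate >= threshold`; the boundary maps to `high` so that
#' carcinoma sensitivity is favoured.
#'
#' @param aggregate result of [aggregate_top3()].
#' @param threshold decision threshold in `(0,1)`.
#' @return `"high"` or `"low"`.
#' @export
classify_cyto <- function(aggregate, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  if (aggregate >= threshold) "high" else "low"
}

#' Full cytological atypia analysis for one tissue
#'
#' Nuclei detection, ROI formation, MIL scoring, top-3 aggregation and
#' thresholding.
#'
#' @param tissue a normalized [tissue_image()].
#' @param model a [train_mil()] model.
#' @param config pipeline configuration.
#' @param exclude optional degraded-pixel mask.
#' @return object of class `cyto_result`: `roi_scores`, `aggregate`,
#'   `level`, `threshold_used`, `rois`, `n_nuclei`.
#' @export
analyze_cyto <- function(tissue, model, config = default_config(),
                         exclude = NULL) {
  nuc <- detect_nuclei(tissue, config, exclude)
  rois <- form_rois(nuc$table, dim(tissue$pixels)[1:2], tissue$um_per_px,
                    config$cyto$roi_size_px, config$cyto$min_nuclei)
  scores <- if (nrow(rois) > 0) {
    score_rois(model, as.matrix(rois[, roi_feature_names(), drop = FALSE]))
  } else numeric(0)
  agg <- aggregate_top3(scores)
  structure(list(roi_scores = scores, aggregate = agg,
                 level = classify_cyto(agg, config$cyto$threshold),
                 threshold_used = config$cyto$threshold,
                 rois = rois, n_nuclei = nrow(nuc$table)),
            class = "cyto_result")
}
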