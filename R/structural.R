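#' Tissue-foreground mask (pre-processing for structural analysis)
#'
#' Pixels whose optical-density magnitude exceeds `od_threshold` are tissue;
#' background and gland lumina (near-white) are excluded, so lumina remain
#' holes. A small opening removes speckle.
#'
#' @param tissue a (normalized) [tissue_image()].
#' @param od_threshold OD magnitude cutoff (default 0.15).
#' @return logical matrix.
#' @export
make_mask <- function(tissue, od_threshold = 0.15) {
  stopifnot(inherits(tissue, "tissue_image"))
  od <- rgb_to_od(tissue$pixels, rep(250, 3))
  odn <- sqrt(od[, , 1]^2 + od[, , 2]^2 + od[, , 3]^2)
  m <- odn > od_threshold
  if (!any(m)) stop("empty tissue foreground")
  m <- EBImage::opening(m * 1, EBImage::makeBrush(3, "disc")) > 0
  if (!any(m)) stop("empty tissue foreground")
  m
}

#' Extract glandular nuclear components at low magnification
#'
#' Thresholds the hematoxylin concentration map to nuclear pixels, then
#' links the nuclei of one gland rim into connected components by
#' morphological closing with a radius of one nuclear width. Components
#' containing fewer than `min_nuclei` nucleus-equivalents of area are
#' discarded (isolated or dissociated cells are not glandular components).
#'
#' @param tissue a normalized [tissue_image()] at low magnification.
#' @param mask tissue-foreground mask from [make_mask()].
#' @param config pipeline configuration.
#' @return list of `gland_component` objects: `component_id`, `mask_idx`
#'   (linear pixel indices), `dim`, `n_px`, `centroid`; thickness and level
#'   are filled in by [quantify_thickness()] / [assign_gland_levels()].
#' @export
extract_glandular_nuclei_lowmag <- function(tissue, mask,
                                            config = default_config()) {
  st <- config$structural
  ch <- h_concentration(tissue, config$stain$reference$h_vector,
                        config$stain$reference$e_vector,
                        config$stain$reference$white_point)
  nuc <- ch > config$stain$nuclei_h_threshold & mask
  if (!any(nuc)) return(list())
  r_px <- max(2L, round(st$nuclear_width_um / tissue$um_per_px))
  closed <- EBImage::closing(nuc * 1, EBImage::makeBrush(2 * r_px + 1, "disc")) > 0
  lab <- EBImage::bwlabel(closed * 1)
  n <- max(lab)
  if (n == 0) return(list())
  nuc_area_px <- pi * (st$nuclear_width_um / 2 / tissue$um_per_px)^2
  out <- list()
  sizes <- tabulate(lab[lab > 0], nbins = n)
  for (k in seq_len(n)) {
    if (sizes[k] / nuc_area_px < st$min_nuclei_per_component) next
    idx <- which(lab == k)
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    out[[length(out) + 1]] <- structure(
      list(component_id = length(out) + 1L, mask_idx = idx,
           dim = dim(lab), n_px = sizes[k],
           centroid = c(mean(rr), mean(cc)),
           thickness_um = NA_real_, gland_level = NA_integer_),
      class = "gland_component")
  }
  out
}

# Rebuild a component's binary mask (cropped to its padded bbox).
component_mask <- function(component, pad = 2L) {
  idx <- component$mask_idx
  h <- component$dim[1]
  rr <- (idx - 1L) %% h + 1L
  cc <- (idx - 1L) %/% h + 1L
  r0 <- max(1L, min(rr) - pad); c0 <- max(1L, min(cc) - pad)
  m <- matrix(FALSE, max(rr) - r0 + 1L + pad, max(cc) - c0 + 1L + pad)
  m[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- TRUE
  list(mask = m, r0 = r0, c0 = c0)
}

#' Median rim thickness of a glandular nuclear component
#'
#' Thickness = 2 x median of the Euclidean distance transform sampled on
#' the component's skeleton (medial axis), converted to micrometres. Robust
#' to branch points, unlike a mean or maximum.
#'
#' @param component a `gland_component` (or a logical mask matrix).
#' @param um_per_px pixel spacing.
#' @return thickness in micrometres.
#' @export
quantify_thickness <- function(component, um_per_px) {
  m <- if (inherits(component, "gland_component"))
    component_mask(component)$mask else component != 0
  if (!any(m)) stop("empty component mask")
  dm <- EBImage::distmap(m * 1)
  sk <- skeletonize(m)
  if (!any(sk)) sk <- dm == max(dm)
  2 * stats::median(dm[sk]) * um_per_px
}

#' Map rim thickness to the 1-10 gland level
#'
#' Fixed equal-width thickness bins (default ten 5-um bins spanning
#' 5-55 um, clipped at both ends) shared across images, so levels compare
#' across tissues.
#'
#' @param components list of `gland_component`s with `thickness_um` set, or
#'   a numeric vector of thicknesses.
#' @param binning list with `min_um`, `max_um`, `n_levels`.
#' @return components with `gland_level` filled (or an integer vector).
#' @export
assign_gland_levels <- function(components,
                                binning = default_config()$structural$binning) {
  lvl <- function(t) {
    w <- (binning$max_um - binning$min_um) / binning$n_levels
    as.integer(clamp(floor((t - binning$min_um) / w) + 1, 1, binning$n_levels))
  }
  if (is.numeric(components)) return(lvl(components))
  lapply(components, function(cp) { cp$gland_level <- lvl(cp$thickness_um); cp })
}

#' Ten-colour cool-to-warm gland-level palette
#' @return character vector of 10 hex colours (level 1 = coolest).
#' @export
gland_level_palette <- function() {
  c("#313695", "#4575B4", "#74ADD1", "#ABD9E9", "#E0F3F8",
    "#FEE090", "#FDAE61", "#F46D43", "#D73027", "#A50026")
}

#' Paint components with their gland-level colours
#'
#' Each component is painted with the fixed cool-to-warm palette entry of
#' its level; a small legend strip is embedded bottom-left.
#'
#' @param tissue a [tissue_image()].
#' @param components levelled `gland_component`s.
#' @return RGB array of the overlay.
#' @export
render_levels <- function(tissue, components) {
  px <- tissue$pixels
  pal <- gland_level_palette()
  for (cp in components) {
    if (is.na(cp$gland_level)) next
    rgbv <- grDevices::col2rgb(pal[cp$gland_level])[, 1] / 255
    for (k in 1:3) {
      chn <- px[, , k]
      chn[cp$mask_idx] <- rgbv[k]
      px[, , k] <- chn
    }
  }
  # legend: 10 swatches, 8 px squares, bottom-left
  h <- dim(px)[1]; sw <- 8
  for (l in 1:10) {
    rgbv <- grDevices::col2rgb(pal[l])[, 1] / 255
    rows <- (h - sw - 2):(h - 2)
    cols <- (2 + (l - 1) * (sw + 2)):(2 + (l - 1) * (sw + 2) + sw)
    for (k in 1:3) px[rows, cols, k] <- rgbv[k]
  }
  px
}

#' Segment gland nuclei and cytoplasm and score nuclear arrangement
#'
#' Within the dilated component, nuclei are high-hematoxylin pixels
#' (watershed-split) and cytoplasm the remaining eosin-dominant gland
#' pixels. The component's epithelial band is swept in angular sectors
#' around the lumen; a sector violates basal polarity when the radial
#' centroid of its nuclear pixels lies luminal of `basal_cut` of the band
#' extent. The arrangement score is the violated fraction of sectors
#' (0 = perfect polarity, 1 = fully stratified).
#'
#' @param tissue_highmag [tissue_image()] covering the component (the
#'   finest available magnification).
#' @param component a `gland_component` (mask indices must refer to the
#'   same grid as `tissue_highmag`; pass `scale` if they do not).
#' @param config pipeline configuration.
#' @param scale factor from component-grid to image-grid coordinates.
#' @return object of class `gland_segmentation`: `nuclei_mask`,
#'   `cytoplasm_mask` (logical, disjoint), `component_id`,
#'   `arrangement_score`.
#' @export
segment_gland_cells_highmag <- function(tissue_highmag, component,
                                        config = default_config(),
                                        scale = 1) {
  st <- config$structural
  d <- dim(tissue_highmag$pixels)[1:2]
  idx <- component$mask_idx
  h0 <- component$dim[1]
  rr <- round(((idx - 1L) %% h0 + 1L) * scale)
  cc <- round(((idx - 1L) %/% h0 + 1L) * scale)
  keep <- rr >= 1 & rr <= d[1] & cc >= 1 & cc <= d[2]
  if (!any(keep)) stop("component lies outside the high-magnification crop")
  rr <- rr[keep]; cc <- cc[keep]
  comp <- matrix(FALSE, d[1], d[2])
  comp[cbind(rr, cc)] <- TRUE
  if (scale != 1)
    comp <- EBImage::dilate(comp * 1,
                            EBImage::makeBrush(2 * ceiling(scale) + 1, "disc")) > 0
  dil_r <- max(2L, round(st$nuclear_width_um / tissue_highmag$um_per_px))
  region <- EBImage::dilate(comp * 1,
                            EBImage::makeBrush(2 * dil_r + 1, "disc")) > 0
  ref <- config$stain$reference
  od <- rgb_to_od(tissue_highmag$pixels, ref$white_point)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  C <- stain_pinv(cbind(ref$h_vector, ref$e_vector)) %*% odm
  chm <- matrix(pmax(C[1, ], 0), d[1], d[2])
  cem <- matrix(pmax(C[2, ], 0), d[1], d[2])
  nuclei <- chm > config$stain$nuclei_h_threshold & region
  cyto <- region & !nuclei & cem > st$cyto_e_threshold
  # lumen centre: largest hole of the filled component, else its centroid
  filled <- EBImage::fillHull(comp * 1) > 0
  hole <- filled & !comp
  centre <- if (any(hole)) {
    hl <- EBImage::bwlabel(hole * 1)
    big <- which.max(tabulate(hl[hl > 0]))
    w <- which(hl == big, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  } else {
    w <- which(comp, arr.ind = TRUE)
    c(mean(w[, 1]), mean(w[, 2]))
  }
  band <- nuclei | cyto
  wb <- which(band, arr.ind = TRUE)
  ang <- atan2(wb[, 1] - centre[1], wb[, 2] - centre[2])
  rad <- sqrt((wb[, 1] - centre[1])^2 + (wb[, 2] - centre[2])^2)
  isnuc <- nuclei[band]
  nsec <- st$n_sectors
  sec <- pmin(floor((ang + pi) / (2 * pi) * nsec) + 1, nsec)
  min_px <- 5
  violated <- 0L; counted <- 0L
  for (s in unique(sec)) {
    i <- sec == s
    # a sector is assessable only when both compartments are visible
    if (sum(isnuc[i]) < min_px || sum(!isnuc[i]) < min_px) next
    r <- rad[i]
    inner <- stats::quantile(r, 0.05, names = FALSE)
    outer <- stats::quantile(r, 0.95, names = FALSE)
    if (outer - inner < 1e-6) next
    rc <- stats::median(r[isnuc[i]])
    pos <- (rc - inner) / (outer - inner)
    counted <- counted + 1L
    if (pos < st$basal_cut) violated <- violated + 1L
  }
  score <- if (counted == 0) 0 else violated / counted
  structure(list(component_id = component$component_id,
                 nuclei_mask = nuclei, cytoplasm_mask = cyto,
                 arrangement_score = score),
            class = "gland_segmentation")
}

#' Four-way structural atypia decision
#'
#' Pure rule over component levels and arrangement scores: no measurable
#' component -> `unclassifiable` when `expect_glands` and no nuclear signal
#' was seen, else `low`; max level <= `low_max` -> `low`; max level >=
#' `high_min` or any arrangement score >= `arrangement_cut` -> `high`;
#' otherwise `middle`.
#'
#' @param components levelled `gland_component`s.
#' @param segmentations list of `gland_segmentation`s (possibly empty).
#' @param config pipeline configuration.
#' @param expect_glands was epithelium present but unmeasurable?
#' @return object of class `structural_result`: `level`, `components`,
#'   `segmentations`, `max_level`, `max_arrangement`.
#' @export
classify_structural <- function(components, segmentations = list(),
                                config = default_config(),
                                expect_glands = FALSE) {
  st <- config$structural
  arr <- vapply(segmentations, function(s) s$arrangement_score, numeric(1))
  if (length(components) == 0) {
    level <- if (expect_glands) "unclassifiable" else "low"
    return(structure(list(level = level, components = components,
                          segmentations = segmentations,
                          max_level = NA_integer_,
                          max_arrangement = if (length(arr)) max(arr) else NA_real_),
                     class = "structural_result"))
  }
  lv <- vapply(components, function(cp) cp$gland_level, integer(1))
  maxl <- max(lv)
  level <- if (maxl >= st$high_min ||
               (length(arr) > 0 && max(arr) >= st$arrangement_cut)) {
    "high"
  } else if (maxl <= st$low_max) "low" else "middle"
  structure(list(level = level, components = components,
                 segmentations = segmentations, max_level = maxl,
                 max_arrangement = if (length(arr)) max(arr) else NA_real_),
            class = "structural_result")
}

#' Run the full two-pass structural atypia analysis
#'
#' Low-magnification pass: foreground mask, glandular nuclear component
#' extraction, thickness quantification and level assignment. Components
#' reaching `trigger_level` are segmented at high magnification (the
#' provided `highmag` image, or the input image when none is available) and
#' scored for nuclear arrangement; the two-pass design avoids the costly
#' segmentation on clearly thin-glanded tissues.
#'
#' @param tissue normalized low-magnification [tissue_image()].
#' @param config pipeline configuration.
#' @param highmag optional finer-magnification [tissue_image()] of the same
#'   region.
#' @return a `structural_result`; attribute `highmag_calls` counts
#'   segmentation invocations.
#' @export
analyze_structural <- function(tissue, config = default_config(),
                               highmag = NULL) {
  mask <- make_mask(tissue)
  comps <- extract_glandular_nuclei_lowmag(tissue, mask, config)
  comps <- lapply(comps, function(cp) {
    cp$thickness_um <- quantify_thickness(cp, tissue$um_per_px)
    cp
  })
  comps <- assign_gland_levels(comps, config$structural$binning)
  st <- config$structural
  segs <- list()
  calls <- 0L
  hm <- if (is.null(highmag)) tissue else highmag
  hm_scale <- if (is.null(highmag)) 1 else tissue$um_per_px / highmag$um_per_px
  for (cp in comps) {
    if (cp$gland_level >= st$trigger_level) {
      calls <- calls + 1L
      segs[[length(segs) + 1]] <-
        segment_gland_cells_highmag(hm, cp, config, scale = hm_scale)
    }
  }
  ch <- h_concentration(tissue, config$stain$reference$h_vector,
                        config$stain$reference$e_vector,
                        config$stain$reference$white_point)
  nuc_frac <- mean(ch > config$stain$nuclei_h_threshold & mask)
  expect <- length(comps) == 0 && nuc_frac < 0.005
  res <- classify_structural(comps, segs, config, expect_glands = expect)
  attr(res, "highmag_calls") <- calls
  res
}
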