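#' Write / read a tissue image as 8-bit RGB PNG
#' @param image a [tissue_image()].
#' @param path output file.
#' @export
write_tissue_png <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' @rdname write_tissue_png
#' @param um_per_px pixel spacing to attach on read (PNG carries none).
#' @param region_id region id to attach.
#' @export
read_tissue_png <- function(path, um_per_px, region_id = 1L) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3]
  tissue_image(px, um_per_px, region_id, provenance = path)
}

#' Write / read an integer label mask as 16-bit single-channel TIFF
#' @param mask integer (or logical) matrix of labels; max label 65535.
#' @param path output file.
#' @export
write_label_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask)) / 65535
  if (max(m) > 1) stop("label mask exceeds 16-bit range")
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_mask
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Load a slide image as a resolution pyramid
#'
#' Plain and pyramidal TIFF and PNG (single level) are supported. Pixel
#' spacing is taken from `um_per_px` (spacing of the finest level); levels
#' are ordered coarse to fine and spacings of coarser levels are derived
#' from their size ratio to the base level.
#'
#' @param path TIFF or PNG file.
#' @param um_per_px pixel spacing of the base (finest) level; required
#'   because these container formats carry no reliable spacing metadata.
#' @return object of class `slide_pyramid`: `levels` (list of
#'   `list(pixels, um_per_px)`, coarse to fine) and `base_um_per_px`.
#' @export
load_slide <- function(path, um_per_px = NULL) {
  if (!file.exists(path)) stop("cannot read slide: ", path)
  if (is.null(um_per_px))
    stop("missing pixel-size metadata: supply um_per_px")
  ext <- tolower(tools::file_ext(path))
  pages <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path, all = TRUE)
  } else if (ext == "png") {
    list(png::readPNG(path))
  } else stop("unsupported slide format: ", ext)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 2) p <- array(rep(p, 3), c(dim(p), 3))
    if (dim(p)[3] == 4) p <- p[, , 1:3]
    p
  })
  widths <- vapply(pages, function(p) dim(p)[2], numeric(1))
  base_w <- max(widths)
  ord <- order(widths)  # coarse (small) first
  levels <- lapply(ord, function(i) {
    list(pixels = pages[[i]], um_per_px = um_per_px * base_w / widths[i])
  })
  structure(list(levels = levels, base_um_per_px = um_per_px, path = path),
            class = "slide_pyramid")
}

#' Write a pyramidal TIFF slide
#'
#' Builds `n_levels` levels by repeated 2x downsampling and writes a
#' multi-page TIFF (finest page first).
#'
#' @param pixels H x W x 3 array in `[0,1]` (base level).
#' @param path output file.
#' @param n_levels number of pyramid levels.
#' @export
write_slide_tiff <- function(pixels, path, n_levels = 3) {
  pages <- list(pixels)
  cur <- pixels
  for (l in seq_len(n_levels - 1)) {
    cur <- EBImage::resize(cur, w = ceiling(dim(cur)[1] / 2),
                           h = ceiling(dim(cur)[2] / 2))
    cur <- clamp(cur)
    pages[[l + 1]] <- cur
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Detect individual tissue regions on a low-resolution overview
#'
#' Background is removed by thresholding: pixels are foreground when their
#' saturation exceeds an Otsu threshold and their luminance is below the
#' bright-background level. Nearby fragments are merged by morphological
#' closing (radius `close_um`), holes are filled, and connected components
#' smaller than `min_area_mm2` are discarded. Regions are returned in
#' reading order (top-to-bottom rows, then left-to-right).
#'
#' @param overview H x W x 3 RGB array or [tissue_image()].
#' @param um_per_px pixel spacing of the overview.
#' @param min_area_mm2 minimum region area (default 0.05, filters dust).
#' @param close_um closing radius in micrometres (merges fragments closer
#'   than roughly this distance).
#' @return list of `tissue_region` objects: `region_id`, `bbox`
#'   `(row0, col0, row1, col1)` half-open at the overview scale, `mask`,
#'   `area_mm2`, `centroid`.
#' @export
detect_tissues <- function(overview, um_per_px, min_area_mm2 = 0.05,
                           close_um = 250) {
  px <- if (inherits(overview, "tissue_image")) overview$pixels else overview
  hsv <- rgb_to_hsv_mats(px)
  lum <- luminance(px)
  sat_thr <- tryCatch(EBImage::otsu(hsv$s, range = c(0, 1)),
                      error = function(e) 0.08)
  bright <- stats::quantile(lum, 0.92, names = FALSE)
  fg <- (hsv$s > pmax(sat_thr, 0.04) | lum < 0.8 * bright) & lum < 0.985
  r_px <- max(1, round(close_um / um_per_px / 2))
  kern <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  fg <- EBImage::closing(fg * 1, kern)
  fg <- EBImage::fillHull(fg)
  lab <- EBImage::bwlabel(fg)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  regions <- list()
  for (k in seq_len(nlab)) {
    m <- lab == k
    area_mm2 <- sum(m) * (um_per_px / 1000)^2
    if (area_mm2 < min_area_mm2) next
    w <- which(m, arr.ind = TRUE)
    regions[[length(regions) + 1]] <- structure(
      list(region_id = NA_integer_,
           bbox = c(row0 = min(w[, 1]) - 1L, col0 = min(w[, 2]) - 1L,
                    row1 = max(w[, 1]), col1 = max(w[, 2])),
           mask = m, area_mm2 = area_mm2,
           centroid = c(mean(w[, 1]), mean(w[, 2]))),
      class = "tissue_region")
  }
  if (length(regions) == 0) return(list())
  # reading order: group rows whose centroids are within a typical height
  cr <- vapply(regions, function(r) r$centroid[1], numeric(1))
  cc <- vapply(regions, function(r) r$centroid[2], numeric(1))
  hgt <- stats::median(vapply(regions, function(r)
    r$bbox["row1"] - r$bbox["row0"], numeric(1)))
  ord <- order(cr)
  group <- integer(length(ord)); g <- 1L; group[ord[1]] <- g
  if (length(ord) > 1) for (i in 2:length(ord)) {
    if (cr[ord[i]] - cr[ord[i - 1]] > 0.6 * hgt) g <- g + 1L
    group[ord[i]] <- g
  }
  ord2 <- order(group, cc)
  regions <- regions[ord2]
  for (i in seq_along(regions)) regions[[i]]$region_id <- i
  regions
}

#' Crop one tissue region from a slide pyramid
#'
#' Maps the region's base-level bounding box to the pyramid level whose
#' pixel spacing is closest to `target_um_per_px` (no resampling is done)
#' and crops with half-open bounds.
#'
#' @param slide a [load_slide()] pyramid.
#' @param region a `tissue_region` with bbox in base-level pixels, or a
#'   length-4 `c(row0, col0, row1, col1)` half-open bbox.
#' @param target_um_per_px requested spacing; must be >= the base spacing.
#' @return a [tissue_image()] at the chosen level's spacing.
#' @export
crop_tissue <- function(slide, region, target_um_per_px = NULL) {
  stopifnot(inherits(slide, "slide_pyramid"))
  bbox <- if (inherits(region, "tissue_region")) region$bbox else region
  if (is.null(target_um_per_px)) target_um_per_px <- slide$base_um_per_px
  if (target_um_per_px < slide$base_um_per_px * 0.999)
    stop("target spacing finer than the base level")
  ums <- vapply(slide$levels, function(l) l$um_per_px, numeric(1))
  li <- which.min(abs(log(ums / target_um_per_px)))
  lev <- slide$levels[[li]]
  s <- slide$base_um_per_px / lev$um_per_px
  r0 <- floor(bbox[1] * s); c0 <- floor(bbox[2] * s)
  r1 <- ceiling(bbox[3] * s); c1 <- ceiling(bbox[4] * s)
  d <- dim(lev$pixels)
  if (r0 < 0 || c0 < 0 || r1 > d[1] || c1 > d[2] || r1 <= r0 || c1 <= c0)
    stop("bbox exceeds slide bounds at the selected level")
  px <- lev$pixels[(r0 + 1):r1, (c0 + 1):c1, , drop = FALSE]
  rid <- if (inherits(region, "tissue_region")) region$region_id else 1L
  tissue_image(px, lev$um_per_px, rid,
               provenance = sprintf("%s[%d:%d,%d:%d]@%.3f", slide$path,
                                    r0, r1, c0, c1, lev$um_per_px))
}

#' Write detected regions as CSV (+ optional per-region crops)
#' @param regions list from [detect_tissues()].
#' @param path CSV path (`region_id,row0,col0,row1,col1,area_mm2`).
#' @export
write_regions_csv <- function(regions, path) {
  df <- do.call(rbind, lapply(regions, function(r)
    data.frame(region_id = r$region_id, row0 = r$bbox[1], col0 = r$bbox[2],
               row1 = r$bbox[3], col1 = r$bbox[4], area_mm2 = r$area_mm2)))
  if (is.null(df)) df <- data.frame(region_id = integer(), row0 = integer(),
                                    col0 = integer(), row1 = integer(),
                                    col1 = integer(), area_mm2 = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
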