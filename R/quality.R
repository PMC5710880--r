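#' Per-tile focus (sharpness) map
#'
#' Focus score per tile = variance of the Laplacian of the luminance channel
#' (luminance on a 0-255 scale), computed over foreground tiles only.
#' Background tiles (mostly near-white pixels) are flagged and excluded
#' from downstream fractions.
#'
#' @param tissue a [tissue_image()].
#' @param tile_size_px tile edge in pixels, >= 32.
#' @return object of class `sharpness_map`: `scores` and logical
#'   `foreground` grids plus `tile_size_px`.
#' @export
sharpness_map <- function(tissue, tile_size_px = 64L) {
  stopifnot(inherits(tissue, "tissue_image"))
  if (tile_size_px < 32) stop("tile_size_px must be >= 32")
  d <- dim(tissue$pixels)
  if (any(d[1:2] < tile_size_px)) stop("tissue smaller than one tile")
  lum <- luminance(tissue$pixels) * 255
  lap_kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- EBImage::filter2(lum, lap_kern)
  scores <- tile_apply(lap, tile_size_px, function(b) stats::var(as.vector(b)))
  dark <- (255 - lum) > 20  # stained (non-background) pixels
  fg <- tile_apply(dark * 1, tile_size_px, mean) > 0.25
  structure(list(tile_size_px = as.integer(tile_size_px),
                 scores = scores, foreground = fg),
            class = "sharpness_map")
}

#' Detect pen (marker) ink
#'
#' Marks pixels whose saturation is high and whose hue lies in the marker
#' band (green through blue, far from both hematoxylin purple and eosin
#' pink), or that are near-black; components smaller than `min_area_mm2`
#' are dropped.
#'
#' @param tissue a [tissue_image()].
#' @param min_area_mm2 minimum ink component area (default 0.01).
#' @return logical matrix, `TRUE` on ink.
#' @export
detect_pen_marks <- function(tissue, min_area_mm2 = 0.01) {
  stopifnot(inherits(tissue, "tissue_image"))
  hsv <- rgb_to_hsv_mats(tissue$pixels)
  ink <- (hsv$s > 0.55 & hsv$h >= 70 & hsv$h <= 235 & hsv$v > 0.12) |
    hsv$v < 0.2
  if (!any(ink)) return(ink)
  lab <- EBImage::bwlabel(ink * 1)
  min_px <- min_area_mm2 * 1e6 / tissue$um_per_px^2
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_px)
  matrix(lab %in% keep, nrow(ink), ncol(ink))
}

#' Detect shadows next to tissue
#'
#' Estimates the low-frequency illumination field by heavy smoothing of the
#' luminance channel; pixels where the field drops more than 20% below the
#' background white point, outside the stained tissue foreground, are
#' flagged as shadow.
#'
#' @param tissue a [tissue_image()].
#' @return logical matrix, `TRUE` on shadow.
#' @export
detect_shadow <- function(tissue) {
  stopifnot(inherits(tissue, "tissue_image"))
  lum <- luminance(tissue$pixels)
  white <- stats::quantile(lum, 0.99, names = FALSE)
  hsv <- rgb_to_hsv_mats(tissue$pixels)
  # stained tissue is saturated; shadowed background stays grey
  fg <- hsv$s > 0.12
  # illumination field from background pixels only (normalized convolution,
  # so tissue darkness cannot bleed into the estimate)
  f <- max(32, round(nrow(lum) / 8)) / nrow(lum)
  bg_s <- EBImage::resize((!fg) * 1, w = round(nrow(lum) * f))
  lum_s <- EBImage::resize(lum * !fg, w = round(nrow(lum) * f))
  num <- EBImage::gblur(lum_s, sigma = 2.5)
  den <- EBImage::gblur(bg_s, sigma = 2.5)
  field_s <- num / pmax(den, 0.05)
  field <- EBImage::resize(field_s, w = nrow(lum), h = ncol(lum))
  field < 0.8 * white & !fg
}

#' Combine artifact evidence into a per-tissue quality verdict
#'
#' A tile is blurred when its focus score falls below
#' `thresholds$blur_threshold`. Fractions are computed over foreground
#' tiles. Defaults: `unusable` when the blurred fraction is >= 0.5 or the
#' pen fraction >= 0.2 or the shadow fraction >= 0.3; `partial_degraded`
#' when any fraction exceeds 0.05; `ok` otherwise.
#'
#' @param sharpness a [sharpness_map()].
#' @param pen,shadow logical masks from [detect_pen_marks()] /
#'   [detect_shadow()] (or `NULL`).
#' @param thresholds list with `blur_threshold`, `max_blur`, `max_pen`,
#'   `max_shadow`, `partial` (see [default_config()]`$quality`).
#' @return object of class `quality_verdict`: `status` (one of `ok`,
#'   `partial_degraded`, `unusable`), the three fractions, and a logical
#'   `degraded_tiles` grid.
#' @export
assess_quality <- function(sharpness, pen = NULL, shadow = NULL,
                           thresholds = default_config()$quality) {
  stopifnot(inherits(sharpness, "sharpness_map"))
  fg <- sharpness$foreground
  n_fg <- max(sum(fg), 1L)
  blurred <- sharpness$scores < thresholds$blur_threshold & fg
  blurred_fraction <- sum(blurred) / n_fg
  ts <- sharpness$tile_size_px
  tile_frac <- function(mask) {
    if (is.null(mask) || !any(mask)) return(list(f = 0, tiles = fg & FALSE))
    cov <- tile_apply(mask * 1, ts, mean)
    hit <- cov > 0.1 & fg
    list(f = sum(hit) / n_fg, tiles = hit)
  }
  pm <- tile_frac(pen)
  sh <- tile_frac(shadow)
  status <- if (blurred_fraction >= thresholds$max_blur ||
                pm$f >= thresholds$max_pen || sh$f >= thresholds$max_shadow) {
    "unusable"
  } else if (blurred_fraction > thresholds$partial ||
             pm$f > thresholds$partial || sh$f > thresholds$partial) {
    "partial_degraded"
  } else "ok"
  structure(list(status = status,
                 blurred_fraction = blurred_fraction,
                 pen_mark_fraction = pm$f,
                 shadow_fraction = sh$f,
                 degraded_tiles = blurred | pm$tiles | sh$tiles,
                 tile_size_px = ts),
            class = "quality_verdict")
}

#' Full quality-control pass for one tissue
#' @param tissue a [tissue_image()].
#' @param config pipeline configuration (see [default_config()]).
#' @return a `quality_verdict`.
#' @export
check_quality <- function(tissue, config = default_config()) {
  sm <- sharpness_map(tissue, config$quality$tile_size_px)
  pen <- detect_pen_marks(tissue)
  shadow <- detect_shadow(tissue)
  assess_quality(sm, pen, shadow, config$quality)
}
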