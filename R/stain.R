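#' Stain profile for Beer-Lambert rendering and batch-effect simulation
#'
#' A stain profile holds the optical-density (OD) directions of hematoxylin
#' and eosin, the brightfield white point, and two scalars describing a
#' staining/scanning batch: `intensity_scale` multiplies all stain
#' concentrations (overall stain uptake) and `contrast_scale` compresses
#' concentrations towards their faint (stromal) baseline, emulating
#' washed-out, low-contrast slides in which nuclear and background colour
#' distributions overlap.
#'
#' @param hematoxylin,eosin length-3 non-negative OD vectors; normalized to
#'   unit Euclidean norm.
#' @param background_rgb brightfield white point, components in `[200, 255]`.
#' @param intensity_scale positive scalar multiplying stain concentrations.
#' @param contrast_scale scalar in `(0, 1.5]`; values below 1 reduce the
#'   separation between strongly and weakly stained pixels.
#' @return object of class `stain_profile`.
#' @export
stain_profile <- function(hematoxylin = c(0.644, 0.717, 0.267),
                          eosin = c(0.093, 0.954, 0.283),
                          background_rgb = c(245, 244, 246),
                          intensity_scale = 1,
                          contrast_scale = 1) {
  stopifnot(length(hematoxylin) == 3, length(eosin) == 3,
            all(hematoxylin >= 0), all(eosin >= 0),
            length(background_rgb) == 3, all(background_rgb >= 200),
            all(background_rgb <= 255),
            intensity_scale > 0,
            contrast_scale > 0, contrast_scale <= 1.5)
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  e <- eosin / sqrt(sum(eosin^2))
  structure(list(hematoxylin = h, eosin = e,
                 background_rgb = as.numeric(background_rgb),
                 intensity_scale = intensity_scale,
                 contrast_scale = contrast_scale),
            class = "stain_profile")
}

#' Default H&E stain profile
#'
#' Standard Ruifrok-style hematoxylin and eosin OD directions with a neutral
#' white point; the generator's rendering basis and the deconvolution default.
#'
#' @return a [stain_profile()].
#' @export
default_stain_profile <- function() stain_profile()

# 3 x 2 stain matrix (columns H, E) of a profile.
stain_matrix <- function(profile) cbind(profile$hematoxylin, profile$eosin)

# Moore-Penrose pseudo-inverse of a 3 x 2 stain matrix.
stain_pinv <- function(M) solve(crossprod(M), t(M))

# RGB array [0,1] -> per-channel OD relative to a white point (length 3,
# 0-255 scale). Pixels brighter than white clip to OD 0.
rgb_to_od <- function(pixels, white_rgb) {
  d <- dim(pixels)
  od <- array(0, d)
  for (k in 1:3) {
    w <- white_rgb[k] / 255
    od[, , k] <- -log(pmax(pixels[, , k], 1 / 255) / w)
  }
  od[od < 0] <- 0
  od
}

# H x W x 3 OD array -> RGB in [0,1] under a white point.
od_to_rgb <- function(od, white_rgb) {
  d <- dim(od)
  out <- array(0, d)
  for (k in 1:3) out[, , k] <- (white_rgb[k] / 255) * exp(-od[, , k])
  clamp(out)
}

# Per-pixel stain concentrations: OD array -> list(h = matrix, e = matrix),
# least-squares projection onto the profile's stain plane, clipped at 0.
od_to_concentrations <- function(od, profile) {
  d <- dim(od)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  C <- stain_pinv(stain_matrix(profile)) %*% odm
  C[C < 0] <- 0
  list(h = matrix(C[1, ], d[1], d[2]), e = matrix(C[2, ], d[1], d[2]))
}

# Concentrations -> RGB under a profile (applies intensity and contrast).
concentrations_to_rgb <- function(ch, ce, profile) {
  cs <- profile$contrast_scale
  if (cs != 1) {
    fg <- ch + ce > 0.05
    if (any(fg)) {
      bh <- stats::quantile(ch[fg], 0.25, names = FALSE)
      be <- stats::quantile(ce[fg], 0.25, names = FALSE)
      ch <- pmax(bh + cs * (ch - bh), 0)
      ce <- pmax(be + cs * (ce - be), 0)
    }
  }
  is <- profile$intensity_scale
  h <- profile$hematoxylin; e <- profile$eosin
  d <- c(dim(ch), 3)
  od <- array(0, d)
  for (k in 1:3) od[, , k] <- is * (ch * h[k] + ce * e[k])
  od_to_rgb(od, profile$background_rgb)
}

# Angle in degrees between two vectors.
vec_angle <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(clamp(ca, -1, 1)) * 180 / pi
}
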