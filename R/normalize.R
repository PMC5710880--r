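#' Estimate stain vectors and concentration scales from a tissue image
#'
#' SVD-plane ("Macenko-style") stain estimation: the white point is the
#' 99th-percentile intensity per channel, optical densities of foreground
#' pixels are projected onto their top-2 singular plane, and the stain
#' vectors are taken at the 1st/99th percentile of the angular distribution
#' in that plane. Concentration percentiles (p50, p99) are recorded per
#' stain for percentile-matched normalization.
#'
#' @param tissue a [tissue_image()].
#' @param min_fg minimum number of foreground pixels (default 1e4).
#' @param max_px subsample cap for the SVD (deterministic striding).
#' @return object of class `stain_estimate`: unit OD vectors `h_vector`,
#'   `e_vector`, `h_scale_percentiles`, `e_scale_percentiles` (p50, p99),
#'   and `white_point` (RGB, 0-255).
#' @export
estimate_stains <- function(tissue, min_fg = 1e4, max_px = 5e4) {
  stopifnot(inherits(tissue, "tissue_image"))
  px <- tissue$pixels
  white <- vapply(1:3, function(k)
    stats::quantile(px[, , k], 0.99, names = FALSE) * 255, numeric(1))
  white <- pmax(white, 200)
  od <- rgb_to_od(px, white)
  odm <- cbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  odn <- sqrt(rowSums(odm^2))
  fg <- which(odn > 0.12)
  if (length(fg) < min_fg)
    stop("too few foreground pixels for stain estimation (",
         length(fg), " < ", min_fg, ")")
  if (length(fg) > max_px)
    fg <- fg[seq(1, length(fg), length.out = max_px)]
  X <- odm[fg, , drop = FALSE]
  sv <- svd(X, nu = 0, nv = 2)
  # a genuinely two-stain image spreads OD across a plane; when nearly all
  # variance lies on one axis the second vector would be fitted to noise
  if (sv$d[2] / sv$d[1] < 0.1)
    stop("degenerate single-stain image: optical densities span a single direction")
  V <- sv$v  # 3 x 2 basis of the stain plane
  # orient so that projections are mostly positive on the first axis
  P <- X %*% V
  if (sum(P[, 1]) < 0) { V[, 1] <- -V[, 1]; P[, 1] <- -P[, 1] }
  phi <- atan2(P[, 2], P[, 1])
  qs <- stats::quantile(phi, c(0.01, 0.99), names = FALSE)
  mk <- function(a) {
    v <- V %*% c(cos(a), sin(a))
    v <- pmax(as.vector(v), 0)
    v / sqrt(sum(v^2))
  }
  v1 <- mk(qs[1]); v2 <- mk(qs[2])
  ref_h <- c(0.644, 0.717, 0.267)
  if (vec_angle(v1, ref_h) <= vec_angle(v2, ref_h)) {
    h <- v1; e <- v2
  } else {
    h <- v2; e <- v1
  }
  if (vec_angle(h, e) <= 10)
    stop("degenerate single-stain image: stain vectors separated by <= 10 degrees")
  M <- cbind(h, e)
  C <- stain_pinv(M) %*% t(odm[fg, , drop = FALSE])
  C[C < 0] <- 0
  structure(list(h_vector = h, e_vector = e,
                 h_scale_percentiles = stats::quantile(C[1, ], c(0.5, 0.99),
                                                       names = FALSE),
                 e_scale_percentiles = stats::quantile(C[2, ], c(0.5, 0.99),
                                                       names = FALSE),
                 white_point = white),
            class = "stain_estimate")
}

#' Normalize a tissue image to a target stain estimate
#'
#' Estimates the source image's stain vectors, projects every pixel onto
#' per-stain concentrations, rescales them so the 99th-percentile
#' concentration of each stain matches the target's, and re-renders with
#' the target stain vectors and white point. Removes batch effects of
#' colour tone, intensity and contrast before analysis.
#'
#' @param tissue a [tissue_image()].
#' @param target a [stain_estimate()] (the normalization reference; the
#'   default configuration ships one derived from a fixed-seed generator
#'   image).
#' @param source optional pre-computed source [estimate_stains()] result.
#' @return a normalized [tissue_image()].
#' @export
normalize_stains <- function(tissue, target, source = NULL) {
  stopifnot(inherits(tissue, "tissue_image"), inherits(target, "stain_estimate"))
  if (is.null(source)) source <- estimate_stains(tissue)
  od <- rgb_to_od(tissue$pixels, source$white_point)
  d <- dim(od)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  Ms <- cbind(source$h_vector, source$e_vector)
  C <- stain_pinv(Ms) %*% odm
  C[C < 0] <- 0
  # cap the rescaling factor: a stain that is essentially absent from the
  # source must not have its noise amplified to the target's range
  sh <- min(target$h_scale_percentiles[2] /
              max(source$h_scale_percentiles[2], 1e-6), 4)
  se <- min(target$e_scale_percentiles[2] /
              max(source$e_scale_percentiles[2], 1e-6), 4)
  C[1, ] <- C[1, ] * sh
  C[2, ] <- C[2, ] * se
  Mt <- cbind(target$h_vector, target$e_vector)
  odn <- Mt %*% C
  out <- array(0, d)
  for (k in 1:3) {
    out[, , k] <- (target$white_point[k] / 255) *
      exp(-matrix(odn[k, ], d[1], d[2]))
  }
  tissue_image(quantize8(out), tissue$um_per_px, tissue$region_id,
               paste0(tissue$provenance, "+norm"))
}

#' Serialize / restore a stain estimate as JSON
#' @param estimate a `stain_estimate`.
#' @param path JSON file.
#' @export
write_stain_estimate <- function(estimate, path) {
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stain_estimate
#' @export
read_stain_estimate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "stain_estimate")
}

# Per-pixel hematoxylin concentration map under given stain vectors.
h_concentration <- function(tissue, h_vector, e_vector, white) {
  od <- rgb_to_od(tissue$pixels, white)
  d <- dim(od)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]),
               as.vector(od[, , 3]))
  C <- stain_pinv(cbind(h_vector, e_vector)) %*% odm
  matrix(pmax(C[1, ], 0), d[1], d[2])
}
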