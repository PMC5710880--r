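#' Tissue image container
#'
#' Minimal container for one cropped tissue region: an RGB pixel array in
#' `[0,1]` (8-bit quantized), its pixel spacing, and provenance.
#'
#' @param pixels H x W x 3 array in `[0,1]`.
#' @param um_per_px pixel spacing in micrometres.
#' @param region_id integer id of the tissue on its slide.
#' @param provenance free-text origin (slide path and bbox, or "synthetic").
#' @return object of class `tissue_image`.
#' @export
tissue_image <- function(pixels, um_per_px, region_id = 1L,
                         provenance = "synthetic") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            um_per_px > 0, all(dim(pixels)[1:2] > 0))
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 region_id = as.integer(region_id), provenance = provenance),
            class = "tissue_image")
}

#' @export
print.tissue_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("tissue_image %dx%d px, %.3f um/px (%s)\n",
              d[1], d[2], x$um_per_px, x$provenance))
  invisible(x)
}

#' Tissue phenotype for the synthetic generator
#'
#' Describes one synthetic colonic tissue along the negative -> adenoma ->
#' carcinoma morphological spectrum: how many tubular glands, how thick and
#' how disordered (stratified) their nuclear rims are, and the density of
#' dissociated high-atypia cells (the poorly differentiated / signet-ring
#' pattern, which forms no glands).
#'
#' @param class_label one of `"negative"`, `"adenoma"`, `"carcinoma"`.
#' @param gland_count number of tubular glands to draw.
#' @param rim_thickness_nuclei nuclear rim thickness in nuclear widths;
#'   `<= 1.5` for negative tissue.
#' @param stratification in `[0,1]`: probability that a nucleus leaves the
#'   basal layer and scatters through the epithelial band (loss of polarity).
#' @param dissociated_cell_density dissociated atypical cells per 1000 um^2
#'   of tissue; 0 for negative tissue.
#' @param nuclear_size_um nuclear diameter in micrometres.
#' @param seed integer; all randomness in rendering derives from it.
#' @return object of class `tissue_phenotype`.
#' @export
tissue_phenotype <- function(class_label,
                             gland_count = 6L,
                             rim_thickness_nuclei = 1.2,
                             stratification = 0,
                             dissociated_cell_density = 0,
                             nuclear_size_um = 7,
                             seed = 1L) {
  class_label <- match.arg(class_label, c("negative", "adenoma", "carcinoma"))
  stopifnot(gland_count >= 0, rim_thickness_nuclei > 0,
            stratification >= 0, stratification <= 1,
            dissociated_cell_density >= 0, nuclear_size_um > 0)
  if (class_label == "negative" &&
      (rim_thickness_nuclei > 1.5 || dissociated_cell_density > 0))
    stop("negative phenotype requires rim_thickness_nuclei <= 1.5 and no dissociated cells")
  if (class_label == "carcinoma" &&
      rim_thickness_nuclei < 3 && dissociated_cell_density <= 0)
    stop("carcinoma phenotype requires rim_thickness_nuclei >= 3 or dissociated cells")
  structure(list(class_label = class_label,
                 gland_count = as.integer(gland_count),
                 rim_thickness_nuclei = rim_thickness_nuclei,
                 stratification = stratification,
                 dissociated_cell_density = dissociated_cell_density,
                 nuclear_size_um = nuclear_size_um,
                 seed = as.integer(seed)),
            class = "tissue_phenotype")
}

#' Acquisition-artifact specification
#'
#' @param blur_sigma Gaussian blur sigma in pixels (0 = no blur).
#' @param blur_coverage fraction of the image area blurred, in `[0,1]`;
#'   must be 0 iff `blur_sigma` is 0.
#' @param pen_mark draw an opaque marker stroke?
#' @param pen_color `"blue"`, `"green"` or `"black"`.
#' @param shadow apply a multiplicative darkening gradient from one edge?
#' @param seed integer seed for artifact geometry.
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(blur_sigma = 0, blur_coverage = 0,
                          pen_mark = FALSE, pen_color = "blue",
                          shadow = FALSE, seed = 1L) {
  stopifnot(blur_sigma >= 0, blur_coverage >= 0, blur_coverage <= 1)
  if ((blur_coverage == 0) != (blur_sigma == 0))
    stop("blur_coverage must be 0 exactly when blur_sigma is 0")
  pen_color <- match.arg(pen_color, c("blue", "green", "black"))
  structure(list(blur_sigma = blur_sigma, blur_coverage = blur_coverage,
                 pen_mark = isTRUE(pen_mark), pen_color = pen_color,
                 shadow = isTRUE(shadow), seed = as.integer(seed)),
            class = "artifact_spec")
}

# Smooth unit-variance noise field.
smooth_noise <- function(h, w, sigma) {
  n <- matrix(stats::rnorm(h * w), h, w)
  s <- EBImage::gblur(n, sigma = sigma)
  s / max(stats::sd(s), 1e-9)
}

#' Render a synthetic H&E tissue image with per-pixel ground truth
#'
#' Composites tubular glands (an elliptical lumen, an apical cytoplasm band,
#' and a nuclear rim whose thickness is `rim_thickness_nuclei` nuclear
#' widths) and dissociated atypical cells onto a stromal blob, then converts
#' per-pixel hematoxylin/eosin concentrations to RGB through the
#' Beer-Lambert relation `I = background * exp(-OD)`. Deterministic for a
#' fixed phenotype seed.
#'
#' @param phenotype a [tissue_phenotype()].
#' @param stain a [stain_profile()] used for rendering.
#' @param size_px canvas size `c(rows, cols)`, at least 256 x 256.
#' @param um_per_px pixel spacing (default 0.92, a low-magnification scale).
#' @return list with elements `image` (a [tissue_image()]) and `truth`
#'   (class `ground_truth`: `nuclei_mask`, `cytoplasm_mask`, `gland_mask`
#'   label matrices, `lumen_mask`, `tissue_mask`, `artifact_mask` logical
#'   matrices, and the `phenotype`).
#' @export
render_tissue <- function(phenotype, stain = default_stain_profile(),
                          size_px = c(1024, 1024), um_per_px = 0.92) {
  stopifnot(inherits(phenotype, "tissue_phenotype"),
            inherits(stain, "stain_profile"))
  if (length(size_px) == 1) size_px <- rep(size_px, 2)
  if (any(size_px < 256)) stop("size_px must be at least 256 x 256")
  if (um_per_px <= 0) stop("um_per_px must be positive")
  H <- as.integer(size_px[1]); W <- as.integer(size_px[2])
  with_op_seed(phenotype$seed, "render_tissue", {
    dimhw <- c(H, W)
    rows <- matrix(seq_len(H), H, W)
    cols <- matrix(seq_len(W), H, W, byrow = TRUE)
    cy <- H / 2 + stats::runif(1, -H * 0.03, H * 0.03)
    cx <- W / 2 + stats::runif(1, -W * 0.03, W * 0.03)
    ay <- H * 0.46; ax <- W * 0.46

    # wavy tissue blob
    th <- atan2(rows - cy, cols - cx)
    ph <- stats::runif(3, 0, 2 * pi)
    wob <- 0.05 * sin(2 * th + ph[1]) + 0.035 * sin(3 * th + ph[2]) +
      0.025 * sin(5 * th + ph[3])
    rad <- sqrt(((rows - cy) / ay)^2 + ((cols - cx) / ax)^2)
    tissue <- rad <= 1 + wob

    # stromal staining fields
    ce <- 0.18 + 0.05 * smooth_noise(H, W, 18)
    ch <- 0.045 + 0.012 * smooth_noise(H, W, 24)
    ce <- pmax(ce, 0.05); ch <- pmax(ch, 0.01)

    nuclei_lab <- matrix(0L, H, W)
    gland_lab <- matrix(0L, H, W)
    cyto_lab <- matrix(0L, H, W)
    lumen <- matrix(FALSE, H, W)
    nuc_d_px <- phenotype$nuclear_size_um / um_per_px
    nuc_r_px <- nuc_d_px / 2

    # gland placement by rejection sampling
    centers <- NULL
    glands <- list()
    if (phenotype$gland_count > 0) {
      for (g in seq_len(phenotype$gland_count)) {
        r_lum <- stats::runif(1, 8, 14) / um_per_px
        c_band <- stats::runif(1, 4, 7) / um_per_px
        t_band <- max(phenotype$rim_thickness_nuclei * nuc_d_px, nuc_d_px)
        r_out <- r_lum + c_band + t_band
        placed <- FALSE
        for (try in 1:250) {
          pr <- stats::runif(1, cy - ay, cy + ay)
          pc <- stats::runif(1, cx - ax, cx + ax)
          if (sqrt(((pr - cy) / ay)^2 + ((pc - cx) / ax)^2) >
              0.92 - r_out / min(ay, ax)) next
          if (!is.null(centers)) {
            dd <- sqrt((centers[, 1] - pr)^2 + (centers[, 2] - pc)^2)
            # keep a lamina-propria gap wide enough that closing at one
            # nuclear width never merges neighbouring glands
            if (any(dd < centers[, 3] + r_out + 18 / um_per_px)) next
          }
          placed <- TRUE
          break
        }
        if (!placed) next
        centers <- rbind(centers, c(pr, pc, r_out))
        glands[[length(glands) + 1]] <- list(
          pr = pr, pc = pc, r_lum = r_lum, c_band = c_band,
          t_band = t_band, r_out = r_out,
          q = stats::runif(1, 0.78, 1), theta = stats::runif(1, 0, pi))
      }
    }

    nuc_id <- 0L
    for (gi in seq_along(glands)) {
      g <- glands[[gi]]
      # local elliptical radius over the gland's bounding box
      rpad <- ceiling(g$r_out / min(g$q, 1)) + 2
      r0 <- max(1, floor(g$pr - rpad)); r1 <- min(H, ceiling(g$pr + rpad))
      c0 <- max(1, floor(g$pc - rpad)); c1 <- min(W, ceiling(g$pc + rpad))
      rr <- r0:r1; cc <- c0:c1
      dr <- outer(rr - g$pr, rep(1, length(cc)))
      dc <- outer(rep(1, length(rr)), cc - g$pc)
      u <- cos(g$theta) * dr + sin(g$theta) * dc
      v <- -sin(g$theta) * dr + cos(g$theta) * dc
      rho <- sqrt(u^2 + (v / g$q)^2)
      lin <- function(sel) {
        idx <- which(sel)
        ((cc[(idx - 1L) %/% length(rr) + 1L] - 1L) * H) +
          rr[(idx - 1L) %% length(rr) + 1L]
      }
      in_gl <- lin(rho <= g$r_out)
      in_gl <- in_gl[tissue[in_gl]]
      gland_lab[in_gl] <- gi
      lum_idx <- lin(rho < g$r_lum); lum_idx <- lum_idx[tissue[lum_idx]]
      cy_idx <- lin(rho >= g$r_lum & rho < g$r_lum + g$c_band)
      cy_idx <- cy_idx[tissue[cy_idx]]
      band_idx <- lin(rho >= g$r_lum + g$c_band & rho <= g$r_out)
      band_idx <- band_idx[tissue[band_idx]]
      lumen[lum_idx] <- TRUE
      ch[lum_idx] <- 0.01; ce[lum_idx] <- 0.015
      cyto_lab[cy_idx] <- gi
      ce[cy_idx] <- 0.40 + 0.04 * stats::runif(length(cy_idx))
      ch[cy_idx] <- 0.06
      # epithelial cytoplasm between rim nuclei
      ce[band_idx] <- 0.33 + 0.04 * stats::runif(length(band_idx))
      ch[band_idx] <- 0.07
      cyto_lab[band_idx] <- gi

      # nuclei in layered rings over the basal band
      n_layers <- max(1L, round(phenotype$rim_thickness_nuclei))
      basal0 <- g$r_lum + g$c_band
      for (l in seq_len(n_layers)) {
        r_l <- basal0 + (l - 0.5) * g$t_band / n_layers
        n_l <- max(4L, round(2 * pi * r_l * (1 + g$q) / 2 / (nuc_d_px * 1.06)))
        phis <- 2 * pi * (seq_len(n_l) - 1 + stats::runif(n_l, -0.25, 0.25)) / n_l
        for (k in seq_len(n_l)) {
          rho_k <- r_l + stats::runif(1, -0.15, 0.15) * nuc_d_px
          if (stats::runif(1) < phenotype$stratification) {
            # polarity loss: nucleus scatters anywhere in the epithelial band
            rho_k <- stats::runif(1, g$r_lum + nuc_r_px * 1.1,
                                  max(g$r_lum + nuc_r_px * 1.1,
                                      g$r_out - nuc_r_px * 0.6))
          }
          uu <- rho_k * cos(phis[k]); vv <- rho_k * g$q * sin(phis[k])
          prk <- g$pr + cos(g$theta) * uu - sin(g$theta) * vv
          pck <- g$pc + sin(g$theta) * uu + cos(g$theta) * vv
          a <- nuc_r_px * stats::runif(1, 0.85, 1.05)
          b <- nuc_r_px * stats::runif(1, 0.68, 0.9)
          idx <- ellipse_indices(dimhw, prk, pck, a, b,
                                 stats::runif(1, 0, pi))
          idx <- idx[!lumen[idx] & tissue[idx]]
          if (length(idx) < 3) next
          nuc_id <- nuc_id + 1L
          nuclei_lab[idx] <- nuc_id
          ch[idx] <- clamp(0.95 * stats::runif(1, 0.88, 1.1), 0.6, 1.2)
          ce[idx] <- 0.12
        }
      }
    }

    # dissociated high-atypia cells (poorly differentiated / signet-ring)
    if (phenotype$dissociated_cell_density > 0) {
      area_um2 <- sum(tissue) * um_per_px^2
      n_cells <- round(phenotype$dissociated_cell_density * area_um2 / 1000)
      cell_r <- nuc_r_px * 1.6
      placed <- matrix(numeric(0), ncol = 2)
      tries <- 0
      while (nrow(placed) < n_cells && tries < n_cells * 40) {
        tries <- tries + 1
        pr <- stats::runif(1, 1, H); pc <- stats::runif(1, 1, W)
        ii <- (round(pc) - 1L) * H + round(pr)
        if (ii < 1 || ii > H * W || !tissue[ii] || gland_lab[ii] > 0) next
        if (nrow(placed) > 0 &&
            min((placed[, 1] - pr)^2 + (placed[, 2] - pc)^2) <
            (2.2 * cell_r)^2) next
        placed <- rbind(placed, c(pr, pc))
        body <- ellipse_indices(dimhw, pr, pc, cell_r,
                                cell_r * stats::runif(1, 0.8, 1),
                                stats::runif(1, 0, pi))
        body <- body[tissue[body] & gland_lab[body] == 0L]
        ce[body] <- 0.28; ch[body] <- 0.05
        cyto_lab[body] <- 10000L + nrow(placed)
        ang <- stats::runif(1, 0, 2 * pi)
        off <- 0.4 * cell_r
        idx <- ellipse_indices(dimhw, pr + off * sin(ang), pc + off * cos(ang),
                               nuc_r_px * 0.95, nuc_r_px * 0.62, ang)
        idx <- idx[tissue[idx] & gland_lab[idx] == 0L & !lumen[idx]]
        if (length(idx) >= 3) {
          nuc_id <- nuc_id + 1L
          nuclei_lab[idx] <- nuc_id
          ch[idx] <- clamp(1.0 * stats::runif(1, 0.9, 1.1), 0.6, 1.25)
          ce[idx] <- 0.1
        }
      }
    }

    ch[!tissue] <- 0; ce[!tissue] <- 0
    rgb <- concentrations_to_rgb(ch, ce, stain)
    noise <- array(stats::rnorm(H * W * 3, 0, 0.006), c(H, W, 3))
    img <- tissue_image(quantize8(rgb + noise), um_per_px,
                        provenance = sprintf("synthetic(seed=%d,class=%s)",
                                             phenotype$seed,
                                             phenotype$class_label))
    truth <- structure(list(nuclei_mask = nuclei_lab,
                            cytoplasm_mask = cyto_lab,
                            gland_mask = gland_lab,
                            lumen_mask = lumen,
                            tissue_mask = tissue,
                            artifact_mask = matrix(FALSE, H, W),
                            phenotype = phenotype),
                       class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Re-render a tissue image under a shifted stain profile (batch effect)
#'
#' Estimates per-pixel stain concentrations from the image under the
#' `source` profile's stain basis and re-renders them under `stain_shift`,
#' reproducing inter-laboratory differences in stain colour, intensity and
#' contrast. `contrast_scale < 1` compresses concentrations towards their
#' stromal baseline, the low-contrast failure mode in which nuclear and
#' background colour distributions overlap.
#'
#' @param image a [tissue_image()].
#' @param stain_shift target [stain_profile()].
#' @param source profile the image was rendered/scanned under.
#' @return a [tissue_image()].
#' @export
apply_batch_effect <- function(image, stain_shift,
                               source = default_stain_profile()) {
  stopifnot(inherits(image, "tissue_image"), inherits(stain_shift, "stain_profile"))
  od <- rgb_to_od(image$pixels, source$background_rgb)
  conc <- od_to_concentrations(od, source)
  rel <- stain_shift
  rel$intensity_scale <- stain_shift$intensity_scale / source$intensity_scale
  out <- concentrations_to_rgb(conc$h, conc$e, rel)
  # carry the non-stain-plane OD residual (noise, quantization) through
  # unchanged: batch effects act on stain concentrations only
  Ms <- stain_matrix(source)
  for (k in 1:3) {
    resid <- od[, , k] - (conc$h * Ms[k, 1] + conc$e * Ms[k, 2])
    out[, , k] <- clamp(out[, , k] * exp(-resid))
  }
  tissue_image(quantize8(out), image$um_per_px, image$region_id,
               paste0(image$provenance, "+batch"))
}

#' Apply acquisition artifacts (blur, pen mark, shadow) to a tissue image
#'
#' @param image a [tissue_image()].
#' @param spec an [artifact_spec()].
#' @param truth optional `ground_truth` whose `artifact_mask` is updated.
#' @return list `image` (degraded [tissue_image()]) and `truth` (with
#'   `artifact_mask` marking every affected pixel).
#' @export
apply_artifacts <- function(image, spec, truth = NULL) {
  stopifnot(inherits(image, "tissue_image"), inherits(spec, "artifact_spec"))
  px <- image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  amask <- matrix(FALSE, H, W)
  with_op_seed(spec$seed, "apply_artifacts", {
    if (spec$blur_sigma > 0) {
      if (spec$blur_coverage >= 1) {
        region <- matrix(TRUE, H, W)
      } else {
        # focal out-of-focus patch: wobbly disc of the requested area
        rc <- stats::runif(1, 0.25 * H, 0.75 * H)
        cc <- stats::runif(1, 0.25 * W, 0.75 * W)
        rows <- matrix(seq_len(H), H, W)
        cols <- matrix(seq_len(W), H, W, byrow = TRUE)
        g <- sqrt((rows - rc)^2 + (cols - cc)^2) +
          0.06 * min(H, W) * smooth_noise(H, W, 40)
        region <- g <= stats::quantile(g, spec$blur_coverage, names = FALSE)
      }
      bl <- px
      for (k in 1:3) bl[, , k] <- EBImage::gblur(px[, , k], sigma = spec$blur_sigma)
      for (k in 1:3) {
        ch <- px[, , k]; ch[region] <- bl[, , k][region]; px[, , k] <- ch
      }
      amask <- amask | region
    }
    if (spec$shadow) {
      side <- sample(1:4, 1)
      rows <- matrix(seq_len(H), H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      dist <- switch(side, rows - 1, H - rows, cols - 1, W - cols)
      depth <- stats::runif(1, 0.35, 0.5)
      len <- stats::runif(1, 0.18, 0.28) * min(H, W)
      factor <- 1 - depth * exp(-dist / len)
      for (k in 1:3) px[, , k] <- px[, , k] * factor
      amask <- amask | (factor < 0.85)
    }
    if (spec$pen_mark) {
      col_rgb <- switch(spec$pen_color,
                        blue = c(30, 90, 230) / 255,
                        green = c(30, 160, 60) / 255,
                        black = c(25, 25, 28) / 255)
      npts <- sample(3:4, 1)
      pts_r <- stats::runif(npts, 0.15 * H, 0.85 * H)
      pts_c <- stats::runif(npts, 0.15 * W, 0.85 * W)
      rad <- max(4, 55 / image$um_per_px)  # marker lines are ~0.1 mm wide
      pen <- matrix(FALSE, H, W)
      for (s in seq_len(npts - 1)) {
        n_step <- ceiling(max(abs(pts_r[s + 1] - pts_r[s]),
                              abs(pts_c[s + 1] - pts_c[s])))
        tfrac <- seq(0, 1, length.out = max(n_step, 2))
        for (t in tfrac) {
          pen[disc_indices(c(H, W),
                           pts_r[s] + t * (pts_r[s + 1] - pts_r[s]),
                           pts_c[s] + t * (pts_c[s + 1] - pts_c[s]), rad)] <- TRUE
        }
      }
      for (k in 1:3) {
        chl <- px[, , k]
        chl[pen] <- 0.9 * col_rgb[k] + 0.1 * chl[pen]
        px[, , k] <- chl
      }
      amask <- amask | pen
    }
  })
  out_img <- tissue_image(quantize8(px), image$um_per_px, image$region_id,
                          paste0(image$provenance, "+artifacts"))
  if (is.null(truth)) {
    truth <- structure(list(nuclei_mask = matrix(0L, H, W),
                            cytoplasm_mask = matrix(0L, H, W),
                            gland_mask = matrix(0L, H, W),
                            lumen_mask = matrix(FALSE, H, W),
                            tissue_mask = matrix(TRUE, H, W),
                            artifact_mask = amask,
                            phenotype = NULL),
                       class = "ground_truth")
  } else {
    truth$artifact_mask <- truth$artifact_mask | amask
  }
  list(image = out_img, truth = truth)
}

#' Sample a class-typical phenotype
#'
#' Draws generator parameters for one tissue of the given diagnostic class:
#' negative mucosa (thin single-layered rims, no dissociated cells), adenoma
#' (moderately thickened, mildly stratified rims, modest nuclear
#' enlargement) or carcinoma (either markedly thickened, strongly stratified
#' glands, or the gland-free poorly differentiated / signet-ring pattern
#' with dissociated large cells).
#'
#' @param class_label `"negative"`, `"adenoma"` or `"carcinoma"`.
#' @param seed integer seed.
#' @param gland_count_range integer range for the number of glands.
#' @return a [tissue_phenotype()].
#' @export
sample_phenotype <- function(class_label, seed, gland_count_range = NULL) {
  class_label <- match.arg(class_label, c("negative", "adenoma", "carcinoma"))
  with_op_seed(seed, "sample_phenotype", {
    if (class_label == "negative") {
      gl <- if (is.null(gland_count_range)) 5:8 else gland_count_range
      tissue_phenotype("negative",
                       gland_count = sample(gl, 1),
                       rim_thickness_nuclei = stats::runif(1, 1.0, 1.3),
                       stratification = stats::runif(1, 0, 0.08),
                       dissociated_cell_density = 0,
                       nuclear_size_um = stats::runif(1, 6, 7),
                       seed = seed)
    } else if (class_label == "adenoma") {
      gl <- if (is.null(gland_count_range)) 4:7 else gland_count_range
      tissue_phenotype("adenoma",
                       gland_count = sample(gl, 1),
                       rim_thickness_nuclei = stats::runif(1, 2.0, 2.8),
                       stratification = stats::runif(1, 0.15, 0.45),
                       dissociated_cell_density = 0,
                       nuclear_size_um = stats::runif(1, 7, 8.2),
                       seed = seed)
    } else {
      if (stats::runif(1) < 0.7) {
        gl <- if (is.null(gland_count_range)) 3:5 else gland_count_range
        tissue_phenotype("carcinoma",
                         gland_count = sample(gl, 1),
                         rim_thickness_nuclei = stats::runif(1, 3.4, 5.0),
                         stratification = stats::runif(1, 0.55, 1),
                         dissociated_cell_density = 0,
                         nuclear_size_um = stats::runif(1, 8.5, 10),
                         seed = seed)
      } else {
        tissue_phenotype("carcinoma",
                         gland_count = 0L,
                         rim_thickness_nuclei = 1,
                         stratification = 0,
                         dissociated_cell_density = stats::runif(1, 1.5, 3.5),
                         nuclear_size_um = stats::runif(1, 9, 11),
                         seed = seed)
      }
    }
  })
}

#' Generate a labelled synthetic cohort
#'
#' Renders `n_per_class` tissues per diagnostic class under one stain
#' profile, optionally degrades a fraction with acquisition artifacts, and
#' (if `dir` is given) writes 8-bit RGB PNG images, 16-bit TIFF label masks
#' and a `manifest.csv`. Fully reproducible from `seed`.
#'
#' @param n_per_class named integer vector/list with names among
#'   `negative`, `adenoma`, `carcinoma`.
#' @param stain rendering [stain_profile()].
#' @param artifact_rate probability a tissue receives an artifact (full
#'   blur, pen mark or shadow, equally likely).
#' @param seed integer master seed.
#' @param dir output directory (created), or `NULL` to keep results in memory.
#' @param size_px canvas size per tissue.
#' @param um_per_px pixel spacing.
#' @param keep_images keep rendered images/truths in the returned object.
#' @param render render images at all; `FALSE` produces the manifest and
#'   phenotypes only (tissues can be rendered later with
#'   [cohort_tissue()]).
#' @return list with `manifest` (data.frame with columns
#'   `tissue_id,class,gland_count,rim_thickness,stratification,
#'   dissociated_density,blur_sigma,pen_mark,shadow,seed`), `phenotypes`,
#'   `dir`, and (if kept) `images` and `truths`.
#' @export
generate_cohort <- function(n_per_class, stain = default_stain_profile(),
                            artifact_rate = 0, seed = 1L, dir = NULL,
                            size_px = c(512, 512), um_per_px = 0.92,
                            keep_images = is.null(dir), render = TRUE) {
  stopifnot(all(names(n_per_class) %in% c("negative", "adenoma", "carcinoma")))
  classes <- rep(names(n_per_class), times = unlist(n_per_class))
  n <- length(classes)
  flags <- with_op_seed(seed, "generate_cohort", {
    data.frame(artifact = stats::runif(n) < artifact_rate,
               type = sample(c("blur", "pen", "shadow"), n, replace = TRUE))
  })
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phenos <- vector("list", n)
  images <- if (keep_images) vector("list", n) else NULL
  truths <- if (keep_images) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tseed <- derive_seed(seed, paste0("cohort_tissue_", i))
    ph <- sample_phenotype(classes[i], tseed)
    phenos[[i]] <- ph
    blur_sigma <- 0; pen <- FALSE; shad <- FALSE
    if (flags$artifact[i]) {
      blur_sigma <- if (flags$type[i] == "blur") 3 else 0
      pen <- flags$type[i] == "pen"
      shad <- flags$type[i] == "shadow"
    }
    if (render) {
      rt <- render_tissue(ph, stain, size_px, um_per_px)
      if (flags$artifact[i]) {
        sp <- artifact_spec(blur_sigma = blur_sigma,
                            blur_coverage = if (blur_sigma > 0) 1 else 0,
                            pen_mark = pen, shadow = shad, seed = tseed)
        rt <- apply_artifacts(rt$image, sp, rt$truth)
      }
    }
    tid <- sprintf("t%04d", i)
    if (!is.null(dir) && render) {
      write_tissue_png(rt$image, file.path(dir, paste0(tid, ".png")))
      write_label_mask(rt$truth$nuclei_mask,
                       file.path(dir, paste0(tid, "_nuclei.tif")))
      write_label_mask(rt$truth$gland_mask,
                       file.path(dir, paste0(tid, "_glands.tif")))
    }
    if (keep_images && render) {
      images[[i]] <- rt$image
      truths[[i]] <- rt$truth
    }
    rows[[i]] <- data.frame(tissue_id = tid, class = classes[i],
                            gland_count = ph$gland_count,
                            rim_thickness = ph$rim_thickness_nuclei,
                            stratification = ph$stratification,
                            dissociated_density = ph$dissociated_cell_density,
                            blur_sigma = blur_sigma, pen_mark = pen,
                            shadow = shad, seed = tseed)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(manifest = manifest, phenotypes = phenos, dir = dir,
       images = images, truths = truths, stain = stain,
       size_px = size_px, um_per_px = um_per_px, seed = seed)
}

#' Load one cohort tissue (from disk if written, else re-rendered)
#' @param cohort result of [generate_cohort()].
#' @param i tissue index (row of the manifest).
#' @return a [tissue_image()].
#' @export
cohort_tissue <- function(cohort, i) {
  if (!is.null(cohort$images)) return(cohort$images[[i]])
  if (!is.null(cohort$dir)) {
    f <- file.path(cohort$dir, paste0(cohort$manifest$tissue_id[i], ".png"))
    if (file.exists(f)) return(read_tissue_png(f, cohort$um_per_px))
  }
  m <- cohort$manifest[i, ]
  rt <- render_tissue(cohort$phenotypes[[i]], cohort$stain,
                      cohort$size_px, cohort$um_per_px)
  if (m$blur_sigma > 0 || m$pen_mark || m$shadow) {
    sp <- artifact_spec(blur_sigma = m$blur_sigma,
                        blur_coverage = if (m$blur_sigma > 0) 1 else 0,
                        pen_mark = m$pen_mark, shadow = m$shadow,
                        seed = m$seed)
    rt <- apply_artifacts(rt$image, sp, rt$truth)
  }
  rt$image
}
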