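# Deterministic per-operation seed derivation: every stochastic operation
# draws from a stream keyed by (seed, operation name) so that adding or
# reordering calls elsewhere never perturbs an operation's output.
derive_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(op) * (seq_len(nchar(op)) %% 31L + 1L))
  s <- (abs(seed) %% 2147483647)
  as.integer((s * 69069 + h * 9973 + 12345) %% 2147483647)
}

# Evaluate expr with a local RNG state seeded from (seed, op); restores the
# caller's RNG stream afterwards.
with_op_seed <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, op))
  expr
}

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# Quantize to the 8-bit grid in [0,1]; rendering always ends here so that
# determinism contracts can be asserted bit-for-bit.
quantize8 <- function(x) round(clamp(x) * 255) / 255

# Round half away from zero (printed tables use conventional rounding,
# while base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Rec.709 luma of an H x W x 3 array in [0,1].
luminance <- function(pixels) {
  0.2126 * pixels[, , 1] + 0.7152 * pixels[, , 2] + 0.0722 * pixels[, , 3]
}

# HSV channels of an RGB array; returns list of H (degrees), S, V matrices.
rgb_to_hsv_mats <- function(pixels) {
  d <- dim(pixels)
  m <- rbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  list(h = matrix(hsv[1, ] * 360, d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# Integer (dr, dc) offsets of a filled disc of radius r (pixels).
disc_offsets <- function(r) {
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# Paint value into mat at disc(center, r); returns linear indices painted.
disc_indices <- function(dim_hw, row, col, r) {
  off <- disc_offsets(r)
  rr <- round(row) + off$dr
  cc <- round(col) + off$dc
  ok <- rr >= 1 & rr <= dim_hw[1] & cc >= 1 & cc <= dim_hw[2]
  (cc[ok] - 1L) * dim_hw[1] + rr[ok]
}

# Indices of a filled ellipse: center (row,col), semi-axes a,b (px), angle th.
ellipse_indices <- function(dim_hw, row, col, a, b, theta = 0) {
  rmax <- ceiling(max(a, b))
  r0 <- max(1L, floor(row - rmax)); r1 <- min(dim_hw[1], ceiling(row + rmax))
  c0 <- max(1L, floor(col - rmax)); c1 <- min(dim_hw[2], ceiling(col + rmax))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  u <-  cos(theta) * dr + sin(theta) * dc
  v <- -sin(theta) * dr + cos(theta) * dc
  sel <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(sel)
  ((cc[(idx - 1L) %/% length(rr) + 1L] - 1L) * dim_hw[1]) +
    rr[(idx - 1L) %% length(rr) + 1L]
}

# Shift a matrix by (dr, dc) with zero fill (used by the thinning pass).
mat_shift <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Topological skeleton of a binary mask
#'
#' Zhang-Suen thinning, implemented with vectorized neighbour shifts. Used to
#' measure rim thickness as twice the median distance-transform value along
#' the medial axis.
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter safety cap on thinning sweeps.
#' @return logical matrix of the same size, `TRUE` on the skeleton.
#' @export
skeletonize <- function(mask, max_iter = 200L) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  # neighbour order P2..P9 clockwise from north
  shifts <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 0:1) {
      p <- lapply(shifts, function(s) mat_shift(m, s[1], s[2]))
      b <- Reduce(`+`, p)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8) 1 else i + 1
        a <- a + (p[[i]] == 0L & p[[j]] == 1L)
      }
      if (step == 0) {
        c1 <- p[[1]] * p[[3]] * p[[5]]
        c2 <- p[[3]] * p[[5]] * p[[7]]
      } else {
        c1 <- p[[1]] * p[[3]] * p[[7]]
        c2 <- p[[1]] * p[[5]] * p[[7]]
      }
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# Tile a matrix into a grid of tile x tile blocks and apply f to each block.
# Returns a matrix of results indexed by (tile_row, tile_col). Partial edge
# tiles are included.
tile_apply <- function(m, tile, f) {
  nr <- ceiling(nrow(m) / tile)
  nc <- ceiling(ncol(m) / tile)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rs <- ((i - 1) * tile + 1):min(i * tile, nrow(m))
    for (j in seq_len(nc)) {
      cs <- ((j - 1) * tile + 1):min(j * tile, ncol(m))
      out[i, j] <- f(m[rs, cs, drop = FALSE])
    }
  }
  out
}
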