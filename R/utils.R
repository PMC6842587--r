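# Internal numeric helpers shared across modules.
#
# Image convention (used everywhere): a micrograph is an nx x ny matrix M with
# M[i, j] the pixel at x index i (lattice a axis), y index j (lattice c axis).
# The origin is at the lower-left corner; pixel centres sit at continuous
# pixel coordinates (i, j), i.e. the centre of pixel M[1, 1] is (1, 1) and an
# Angstrom position x maps to pixel coordinate x / pixel_size + 0.5.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
ang_to_px <- function(x, pixel_size) x / pixel_size + 0.5

#' @noRd
px_to_ang <- function(p, pixel_size) (p - 0.5) * pixel_size

# Wrapped FFT frequency index (cycles per pixel) for an n-point axis.
#' @noRd
fft_freqs <- function(n) {
  k <- c(seq(0L, floor(n / 2) - 1L), seq(-ceiling(n / 2), -1L))
  k / n
}

# Centre the zero-frequency component of a 2D FFT output.
#' @noRd
fftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- floor(nx / 2); sy <- floor(ny / 2)
  m[c((sx + 1):nx, 1:sx), c((sy + 1):ny, 1:sy)]
}

#' @noRd
ifftshift2 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  sx <- ceiling(nx / 2); sy <- ceiling(ny / 2)
  m[c((sx + 1):nx, 1:sx), c((sy + 1):ny, 1:sy)]
}

#' @noRd
fft2 <- function(m) stats::fft(m)

#' @noRd
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Bilinear sampling of matrix M at continuous pixel coordinates (xp, yp)
# (centre-of-pixel convention above).  Out-of-range samples are filled with
# `fill`; the number of such samples is returned in attr "n_outside".
#' @noRd
bilinear_sample <- function(M, xp, yp, fill = mean(M)) {
  nx <- nrow(M); ny <- ncol(M)
  x0 <- floor(xp); y0 <- floor(yp)
  outside <- xp < 1 | yp < 1 | xp > nx | yp > ny
  x0c <- pmin(pmax(x0, 1L), nx - 1L)
  y0c <- pmin(pmax(y0, 1L), ny - 1L)
  fx <- xp - x0c; fy <- yp - y0c
  i00 <- cbind(x0c, y0c)
  v <- (1 - fx) * (1 - fy) * M[i00] +
    fx * (1 - fy) * M[cbind(x0c + 1L, y0c)] +
    (1 - fx) * fy * M[cbind(x0c, y0c + 1L)] +
    fx * fy * M[cbind(x0c + 1L, y0c + 1L)]
  v[outside] <- fill
  attr(v, "n_outside") <- sum(outside)
  v
}

# Catmull-Rom bicubic sampling (a = -0.5).  Bilinear interpolation
# attenuates frequencies near Nyquist (up to ~25% at half-pixel shifts at
# the 1.5 Angstrom reflection), which matters when resampling is meant to
# *restore* high-resolution signal; the cubic kernel keeps that loss to a
# few percent.  Edge taps are clamped; fully outside samples get `fill`.
#' @noRd
bicubic_sample <- function(M, xp, yp, fill = mean(M)) {
  nx <- nrow(M); ny <- ncol(M)
  x0 <- floor(xp); y0 <- floor(yp)
  outside <- xp < 1 | yp < 1 | xp > nx | yp > ny
  fx <- xp - x0; fy <- yp - y0
  ck <- function(t) {
    at <- abs(t)
    ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
           ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
  }
  v <- numeric(length(xp))
  for (i in -1:2) {
    wx <- ck(fx - i)
    xi <- pmin(pmax(x0 + i, 1L), nx)
    for (j in -1:2) {
      wy <- ck(fy - j)
      yj <- pmin(pmax(y0 + j, 1L), ny)
      v <- v + wx * wy * M[cbind(xi, yj)]
    }
  }
  v[outside] <- fill
  attr(v, "n_outside") <- sum(outside)
  v
}

# Deposit weights w at continuous pixel coordinates (xp, yp) into an nx x ny
# accumulator with bilinear (area-weighted) splatting.  Total weight is
# conserved for points at least one pixel inside the field.
#' @noRd
bilinear_deposit <- function(xp, yp, w, nx, ny) {
  x0 <- floor(xp); y0 <- floor(yp)
  fx <- xp - x0; fy <- yp - y0
  ii <- c(x0, x0 + 1, x0, x0 + 1)
  jj <- c(y0, y0, y0 + 1, y0 + 1)
  ww <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
          w * (1 - fx) * fy, w * fx * fy)
  keep <- ii >= 1 & ii <= nx & jj >= 1 & jj <= ny & ww != 0
  as.matrix(Matrix::sparseMatrix(i = ii[keep], j = jj[keep], x = ww[keep],
                                 dims = c(nx, ny)))
}

# Periodic (wrap-around) isotropic Gaussian kernel, peak 1, as an FFT-ready
# nx x ny matrix with the peak at index (1, 1).
#' @noRd
gaussian_kernel_fft <- function(nx, ny, sigma_px) {
  dx <- pmin(0:(nx - 1), nx - (0:(nx - 1)))
  dy <- pmin(0:(ny - 1), ny - (0:(ny - 1)))
  outer(dx^2, dy^2, function(a, b) exp(-(a + b) / (2 * sigma_px^2)))
}

# Dihedral angle (degrees, signed, in (-180, 180]) of four points given as
# rows of 3-vectors.
#' @noRd
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  # IUPAC sign convention (agrees with standard structure tools)
  rad2deg(atan2(-sum(m1 * n2), sum(n1 * n2)))
}

# Smallest absolute angular difference in degrees.
#' @noRd
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
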