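# The micrograph container and the synthetic projection renderer with
# lattice distortion and additive noise.

#' Construct a micrograph
#'
#' A micrograph is a real-valued nx x ny pixel matrix with a physical pixel
#' size.  `M[i, j]` is the pixel at x index i (lattice a axis) and y index j
#' (c axis); the origin is the lower-left corner and pixel centres lie at
#' continuous pixel coordinates `(i, j)`.
#'
#' @param pixels Numeric matrix of densities.
#' @param pixel_size Pixel size in Angstrom per pixel.
#' @return A `micrograph` object.
#' @export
micrograph <- function(pixels, pixel_size) {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  if (!all(is.finite(pixels))) stop("micrograph pixels must be finite")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px at %.3f A/px (%.0f x %.0f A)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              nrow(x$pixels) * x$pixel_size, ncol(x$pixels) * x$pixel_size))
  invisible(x)
}

#' Render the b-axis projection of an atom model
#'
#' Projects atoms along z onto the image plane as isotropic 2D Gaussians of
#' fixed width sigma = 0.8 Angstrom, each with amplitude proportional to the
#' atomic number Z.  Atoms superposed in a column (same x, y) add linearly,
#' so a 3-atom bromine column is three times as bright as a single Br.
#'
#' @param model An `atom_model`.
#' @param pixel_size Angstrom per pixel; should be at most 0.7 for the
#'   1.5 Angstrom lattice reflections to stay below Nyquist.
#' @param box_shape Integer length-2 `(nx, ny)` image dimensions in pixels.
#' @param origin Length-2 `(x, y)` of the image's lower-left corner in model
#'   coordinates (Angstrom).  Default centres the model in the box.
#' @param sigma Gaussian width in Angstrom (default 0.8).
#' @param clip If `TRUE`, atoms outside the box are silently dropped (used
#'   when rendering a lattice larger than the field of view); if `FALSE`
#'   (default) such atoms raise an error naming the required box size.
#' @return A [micrograph()].
#' @export
render_projection <- function(model, pixel_size = 0.5,
                              box_shape = c(256L, 256L), origin = NULL,
                              sigma = 0.8, clip = FALSE) {
  stopifnot(inherits(model, "atom_model"), nrow(model) >= 1,
            pixel_size > 0, length(box_shape) == 2)
  nx <- as.integer(box_shape[1]); ny <- as.integer(box_shape[2])
  if (is.null(origin)) {
    origin <- c(mean(range(model$x)) - nx * pixel_size / 2,
                mean(range(model$y)) - ny * pixel_size / 2)
  }
  xp <- ang_to_px(model$x - origin[1], pixel_size)
  yp <- ang_to_px(model$y - origin[2], pixel_size)
  inside <- xp >= 0.5 & xp <= nx + 0.5 & yp >= 0.5 & yp <= ny + 0.5
  if (!clip && !all(inside)) {
    need_x <- ceiling(diff(range(model$x)) / pixel_size) + 2
    need_y <- ceiling(diff(range(model$y)) / pixel_size) + 2
    stop(sprintf(paste0("model footprint exceeds the box: need at least ",
                        "%d x %d px at %.3f A/px"), need_x, need_y,
                 pixel_size))
  }
  z <- atomic_number(model$element)
  W <- bilinear_deposit(xp[inside], yp[inside], z[inside], nx, ny)
  K <- gaussian_kernel_fft(nx, ny, sigma / pixel_size)
  img <- Re(ifft2(fft2(W) * fft2(K)))
  m <- micrograph(img, pixel_size)
  m$origin_A <- origin
  m
}

#' Parametric smooth distortion field
#'
#' Describes the smooth in-plane displacement fields that bend 2D crystal
#' images: dislocations aside, stress and optics produce slowly varying
#' displacements well modelled by constants, long-period sinusoids or
#' low-order polynomials.
#'
#' @param type `"constant"`, `"sinusoid"` or `"polynomial"`.
#' @param amplitude Length-2 `(ax, ay)` displacement amplitude in pixels
#'   (constant and sinusoid types).
#' @param period Length-2 `(Tx, Ty)` in pixels: the x displacement varies
#'   sinusoidally with y (period `Ty`) and the y displacement with x
#'   (period `Tx`).
#' @param phase Length-2 phase offsets in radians.
#' @param coef_x,coef_y Coefficient vectors for the polynomial type, in the
#'   column order of `poly_terms(x, y, degree)` (1, x, y, x^2, xy, y^2, ...).
#' @param degree Polynomial degree.
#' @return A `distortion_field` object; evaluate with [field_displacement()].
#' @export
distortion_field <- function(type = c("constant", "sinusoid", "polynomial"),
                             amplitude = c(0, 0), period = c(200, 200),
                             phase = c(0, 0), coef_x = NULL, coef_y = NULL,
                             degree = 3L) {
  type <- match.arg(type)
  structure(list(type = type, amplitude = amplitude, period = period,
                 phase = phase, coef_x = coef_x, coef_y = coef_y,
                 degree = as.integer(degree)),
            class = "distortion_field")
}

# Raw polynomial design matrix in x and y up to total degree `degree`.
#' @noRd
poly_terms <- function(x, y, degree) {
  cols <- list(rep(1, length(x)))
  for (d in seq_len(degree)) {
    for (i in 0:d) cols[[length(cols) + 1L]] <- x^(d - i) * y^i
  }
  do.call(cbind, cols)
}

#' Evaluate a distortion field
#'
#' @param field A [distortion_field()].
#' @param x,y Pixel coordinates.
#' @return List with numeric `dx`, `dy` displacements in pixels.
#' @export
field_displacement <- function(field, x, y) {
  switch(field$type,
    constant = list(dx = rep(field$amplitude[1], length(x)),
                    dy = rep(field$amplitude[2], length(x))),
    sinusoid = list(
      dx = field$amplitude[1] * sin(2 * pi * y / field$period[2] +
                                      field$phase[1]),
      dy = field$amplitude[2] * sin(2 * pi * x / field$period[1] +
                                      field$phase[2])),
    polynomial = {
      P <- poly_terms(x, y, field$degree)
      list(dx = as.numeric(P %*% field$coef_x),
           dy = as.numeric(P %*% field$coef_y))
    })
}

#' Apply a smooth distortion to a micrograph
#'
#' Resamples the image at displaced coordinates:
#' `out(p) = in(p + field(p))` with bilinear interpolation.  A zero field is
#' the identity.  Samples falling outside the image are filled with the
#' image mean and counted in attr `n_outside`.
#'
#' @param m A [micrograph()].
#' @param field A [distortion_field()].
#' @param interp `"bilinear"` (default) or `"bicubic"` resampling; the
#'   cubic kernel preserves near-Nyquist amplitudes much better and is
#'   what [unbend_image()] uses.
#' @return The distorted [micrograph()].
#' @export
apply_distortion <- function(m, field, interp = c("bilinear", "bicubic")) {
  stopifnot(inherits(m, "micrograph"), inherits(field, "distortion_field"))
  interp <- match.arg(interp)
  nx <- nrow(m$pixels); ny <- ncol(m$pixels)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  d <- field_displacement(field, g$x, g$y)
  sampler <- if (interp == "bicubic") bicubic_sample else bilinear_sample
  v <- sampler(m$pixels, g$x + d$dx, g$y + d$dy,
               fill = mean(m$pixels))
  out <- micrograph(matrix(v, nx, ny), m$pixel_size)
  out$n_outside <- attr(v, "n_outside")
  out
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise with variance `var(signal) / snr`, the
#' additive-noise proxy for low-dose imaging used throughout the synthetic
#' pipeline.
#'
#' @param m A [micrograph()].
#' @param snr Target SNR (signal variance over noise variance), > 0.
#' @param seed Integer seed; recorded in the output for provenance.  The
#'   caller's RNG state is left untouched.
#' @return The noisy [micrograph()] (field `noise_seed` records the seed).
#' @export
add_noise <- function(m, snr, seed = 1L) {
  stopifnot(inherits(m, "micrograph"), snr > 0)
  s <- sqrt(stats::var(as.numeric(m$pixels)) / snr)
  noise <- with_seed(seed, stats::rnorm(length(m$pixels), 0, s))
  out <- micrograph(m$pixels + matrix(noise, nrow(m$pixels)), m$pixel_size)
  out$noise_seed <- seed
  out$snr <- snr
  out
}
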