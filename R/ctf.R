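# Contrast transfer function: model, application, estimation and
# phase-flip / multi-defocus correction.

#' CTF parameters
#'
#' Weak-phase contrast transfer function parameters.  Defaults are typical
#' of a 300 kV field-emission instrument (Cs 2.7 mm, 7% amplitude
#' contrast); the electron wavelength is derived relativistically from the
#' accelerating voltage.
#'
#' @param defocus Defocus in Angstrom, positive = underfocus.
#' @param voltage Accelerating voltage, kV.
#' @param cs Spherical aberration, mm.
#' @param amp_contrast Amplitude contrast fraction in `[0, 1)`.
#' @param pixel_size Angstrom per pixel of the images the CTF is applied to.
#' @return A `ctf_params` object (with derived `lambda` in Angstrom).
#' @export
ctf_params <- function(defocus, voltage = 300, cs = 2.7,
                       amp_contrast = 0.07, pixel_size = 0.5) {
  stopifnot(voltage > 0, amp_contrast >= 0, amp_contrast < 1, pixel_size > 0)
  structure(list(defocus = defocus, voltage = voltage, cs = cs,
                 amp_contrast = amp_contrast, pixel_size = pixel_size,
                 lambda = electron_wavelength(voltage)),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(paste0("<ctf_params> defocus %.0f A, %g kV ",
                     "(lambda %.4f A), Cs %g mm, A %.2f\n"),
              x$defocus, x$voltage, x$lambda, x$cs, x$amp_contrast))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv Accelerating voltage in kV.
#' @return Wavelength in Angstrom (0.0197 at 300 kV).
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2643 / sqrt(v * (1 + 0.978476e-6 * v))
}

#' Evaluate the CTF at spatial frequency q
#'
#' `CTF(q) = -(sqrt(1 - A^2) sin(chi) + A cos(chi))` with phase error
#' `chi(q) = pi lambda df q^2 - (pi/2) Cs lambda^3 q^4`.  At q = 0 the value
#' is exactly `-A`.
#'
#' @param q Spatial frequency in 1/Angstrom (>= 0).
#' @param p A [ctf_params()].
#' @return Numeric contrast factor in `[-1, 1]`.
#' @export
ctf_value <- function(q, p) {
  stopifnot(inherits(p, "ctf_params"))
  cs_A <- p$cs * 1e7
  chi <- pi * p$lambda * p$defocus * q^2 -
    (pi / 2) * cs_A * p$lambda^3 * q^4
  -(sqrt(1 - p$amp_contrast^2) * sin(chi) + p$amp_contrast * cos(chi))
}

# 2D |q| grid (1/Angstrom) in FFT (unshifted) layout for an nx x ny image.
#' @noRd
q_grid <- function(nx, ny, pixel_size) {
  fx <- fft_freqs(nx) / pixel_size
  fy <- fft_freqs(ny) / pixel_size
  sqrt(outer(fx^2, fy^2, "+"))
}

#' Apply a CTF to a micrograph
#'
#' Multiplies the Fourier transform by the radially symmetric CTF.
#'
#' @param m A [micrograph()].
#' @param p A [ctf_params()].
#' @return The modulated [micrograph()].
#' @export
apply_ctf <- function(m, p) {
  stopifnot(inherits(m, "micrograph"))
  q <- q_grid(nrow(m$pixels), ncol(m$pixels), m$pixel_size)
  micrograph(Re(ifft2(fft2(m$pixels) * ctf_value(q, p))), m$pixel_size)
}

#' Phase-flip CTF correction
#'
#' Multiplies Fourier amplitudes by the sign of the CTF, restoring the
#' phases inverted by the oscillating transfer function while leaving the
#' power spectrum untouched.  Applying it twice returns the original image.
#'
#' @inheritParams apply_ctf
#' @return The phase-corrected [micrograph()].
#' @export
phase_flip <- function(m, p) {
  stopifnot(inherits(m, "micrograph"))
  q <- q_grid(nrow(m$pixels), ncol(m$pixels), m$pixel_size)
  s <- ifelse(ctf_value(q, p) < 0, -1, 1)
  micrograph(Re(ifft2(fft2(m$pixels) * s)), m$pixel_size)
}

#' Merge micrographs taken at different defocus values
#'
#' Fourier-space CTF compensation from a defocus series: each image is
#' phase-flipped and the spectra are averaged with weights `|CTF_i(q)|`,
#' normalised by `max(sum_i |CTF_i(q)|, floor)`.  Frequencies lost in one
#' image's CTF zero are filled from the others.
#'
#' @param images List of aligned [micrograph()]s (same shape).
#' @param params List of matching [ctf_params()].
#' @param floor Weight-sum floor (default 0.01) guarding against division
#'   by near-zero total weight.
#' @return The merged [micrograph()].
#' @export
multi_defocus_merge <- function(images, params, floor = 0.01) {
  stopifnot(length(images) >= 2, length(images) == length(params))
  dims <- lapply(images, function(m) dim(m$pixels))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("images must all have the same shape")
  nx <- dims[[1]][1]; ny <- dims[[1]][2]
  ps <- images[[1]]$pixel_size
  q <- q_grid(nx, ny, ps)
  num <- matrix(0 + 0i, nx, ny)
  den <- matrix(0, nx, ny)
  for (i in seq_along(images)) {
    ci <- ctf_value(q, params[[i]])
    num <- num + ci * fft2(images[[i]]$pixels)  # |C| * sign(C) * F
    den <- den + abs(ci)
  }
  micrograph(Re(ifft2(num / pmax(den, floor))), ps)
}

#' Estimate defocus from Thon rings
#'
#' Fits the rotationally averaged power spectrum against `|CTF|^2` over a
#' defocus grid (background removed from both by a running-median
#' subtraction), refines the best defocus parabolically, and reports the
#' Thon-ring detection limit: the highest frequency band (between
#' consecutive CTF zeros) where the measured rings still correlate with the
#' model.
#'
#' @param m A [micrograph()] containing CTF-modulated signal or noise.
#' @param defocus_range Length-2 search interval in Angstrom.
#' @param p0 Optional [ctf_params()] supplying voltage / Cs / amplitude
#'   contrast (defocus ignored); instrument defaults otherwise.
#' @param fit_band Frequency band (1/Angstrom) used for the defocus fit;
#'   default 0.02 to the smaller of 0.25 and 0.8 x Nyquist, where the
#'   radial binning still resolves the rings.
#' @param ring_threshold Correlation threshold for a band to count as
#'   detected rings (default 0.5).
#' @return List with `params` (fitted [ctf_params()]), `defocus`,
#'   `thon_limit_A` (resolution of the last detected ring band), `fit_cor`
#'   and `reliable` (FALSE when no defocus correlates, e.g. a flat
#'   spectrum).
#' @export
estimate_defocus <- function(m, defocus_range = c(5000, 40000), p0 = NULL,
                             fit_band = NULL, ring_threshold = 0.5) {
  stopifnot(inherits(m, "micrograph"))
  if (is.null(p0)) p0 <- ctf_params(1e4, pixel_size = m$pixel_size)
  nx <- nrow(m$pixels); ny <- ncol(m$pixels)
  q <- q_grid(nx, ny, m$pixel_size)
  P <- Mod(fft2(m$pixels))^2
  nyq <- 0.5 / m$pixel_size
  dq <- 1 / (max(nx, ny) * m$pixel_size)
  qb <- seq(0, nyq, by = dq)
  bin <- findInterval(q, qb)
  prof_all <- tapply(as.numeric(P), bin, mean)
  qc_all <- (qb[-length(qb)] + qb[-1]) / 2
  prof <- prof_all[as.character(seq_along(qc_all))]
  ok <- !is.na(prof)
  qc <- qc_all[ok]; prof <- as.numeric(prof[ok])
  if (is.null(fit_band)) fit_band <- c(0.02, min(0.25, 0.8 * nyq))
  debg <- function(v) {
    k <- min(31, 2 * floor(length(v) / 4) + 1)
    v - stats::runmed(v, k)
  }
  sel <- qc >= fit_band[1] & qc <= fit_band[2]
  obs <- debg(prof)[sel]
  model_at <- function(df) {
    p <- ctf_params(df, p0$voltage, p0$cs, p0$amp_contrast, m$pixel_size)
    debg(ctf_value(qc, p)^2)[sel]
  }
  grid <- seq(defocus_range[1], defocus_range[2], by = 250)
  cors <- vapply(grid, function(df) {
    mo <- model_at(df)
    if (stats::sd(mo) == 0 || stats::sd(obs) == 0) return(-1)
    stats::cor(obs, mo)
  }, numeric(1))
  i <- which.max(cors)
  best <- grid[i]
  # parabolic refinement on the correlation curve
  if (i > 1 && i < length(grid)) {
    y1 <- cors[i - 1]; y2 <- cors[i]; y3 <- cors[i + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) best <- grid[i] - 250 * (y3 - y1) / (2 * den)
  }
  # fine local search
  fine <- seq(best - 300, best + 300, by = 20)
  fine <- fine[fine >= defocus_range[1] & fine <= defocus_range[2]]
  fcors <- vapply(fine, function(df) stats::cor(obs, model_at(df)),
                  numeric(1))
  best <- fine[which.max(fcors)]
  fit_cor <- max(fcors)
  reliable <- is.finite(fit_cor) && fit_cor > 0.6
  if (!reliable)
    warning("flat or ringless power spectrum: defocus estimate unreliable")
  pbest <- ctf_params(best, p0$voltage, p0$cs, p0$amp_contrast, m$pixel_size)
  thon <- thon_limit(qc, debg(prof), pbest, nyq, ring_threshold)
  list(params = pbest, defocus = best, thon_limit_A = thon,
       fit_cor = fit_cor, reliable = reliable)
}

# Highest-resolution band between consecutive CTF zeros whose measured
# radial profile still correlates with |CTF|^2 above the threshold.
#' @noRd
thon_limit <- function(qc, prof_bs, p, nyq, threshold) {
  cv <- ctf_value(qc, p)
  zc <- which(diff(sign(cv)) != 0)
  edges <- c(0, qc[zc], nyq)
  best_q <- NA_real_
  model <- cv^2
  for (b in seq_len(length(edges) - 1)) {
    sel <- qc > edges[b] & qc <= edges[b + 1]
    if (sum(sel) < 4) next
    if (stats::sd(model[sel]) == 0 || stats::sd(prof_bs[sel]) == 0) next
    if (stats::cor(prof_bs[sel], model[sel]) > threshold)
      best_q <- edges[b + 1]
  }
  if (is.na(best_q) || best_q <= 0) NA_real_ else 1 / best_q
}
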