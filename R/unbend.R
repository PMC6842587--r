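# Crystal unbending: correlation-based unit-cell tracking against a
# Fourier-filtered reference, smooth displacement-field fitting and
# resampling.  Recovers high-frequency diffraction signal smeared by
# dislocations, stress and optical distortion.

# Real-space lattice vectors (columns, px) from a reciprocal lattice.
#' @noRd
real_cell_vectors <- function(lat) {
  G <- rbind(lat$g_a * lat$pixel_size, lat$g_c * lat$pixel_size)  # cycles/px
  solve(G)  # columns v_a, v_c in px, v_i . g_j = delta_ij
}

#' Build an unbending reference patch
#'
#' Fourier-filters the micrograph, retaining only DC and +/-1 pixel around
#' every indexed reflection (and its Hermitian mate), then crops one unit
#' cell around the strongest motif in the filtered image.  The result
#' approximates the ideal repeating motif with the background and noise
#' suppressed.
#'
#' @param m A [micrograph()].
#' @param lat A `reciprocal_lattice` from [find_lattice()].
#' @param pad Half-width in pixels of the retained square around each
#'   reflection (default 2, covering the truncation sidelobes of the
#'   finite field of view).
#' @return A matrix patch of one unit cell; attrs `filtered` (the full
#'   filtered image) and `peak_power_fraction` (non-DC power retained on
#'   the indexed reflections).
#' @export
make_reference <- function(m, lat, pad = 2L) {
  stopifnot(inherits(m, "micrograph"), inherits(lat, "reciprocal_lattice"))
  nx <- nrow(m$pixels); ny <- ncol(m$pixels)
  F <- fft2(m$pixels)
  mask <- matrix(FALSE, nx, ny)
  mask[1, 1] <- TRUE  # DC
  add_peak <- function(qx, qy) {
    # unshifted FFT indices of +q and -q
    for (s in c(1, -1)) {
      i <- round(s * qx * m$pixel_size * nx) %% nx + 1
      j <- round(s * qy * m$pixel_size * ny) %% ny + 1
      ii <- ((i - 1 + (-pad):pad) %% nx) + 1
      jj <- ((j - 1 + (-pad):pad) %% ny) + 1
      mask[ii, jj] <<- TRUE
    }
  }
  for (r in seq_len(nrow(lat$peaks)))
    add_peak(lat$peaks$qx[r], lat$peaks$qy[r])
  P <- Mod(F)^2
  nondc <- sum(P) - P[1, 1]
  frac <- if (nondc > 0) (sum(P[mask]) - P[1, 1]) / nondc else NA_real_
  filt <- Re(ifft2(F * mask))
  V <- real_cell_vectors(lat)
  bx <- max(3L, round(sqrt(sum(V[, 1]^2))))
  by <- max(3L, round(sqrt(sum(V[, 2]^2))))
  # crop around the strongest filtered pixel, fully interior
  ctr <- which(filt == max(filt), arr.ind = TRUE)[1, ]
  cx <- min(max(ctr[1], ceiling(bx / 2) + 1), nx - ceiling(bx / 2) - 1)
  cy <- min(max(ctr[2], ceiling(by / 2) + 1), ny - ceiling(by / 2) - 1)
  x0 <- cx - floor(bx / 2); y0 <- cy - floor(by / 2)
  patch <- filt[x0:(x0 + bx - 1), y0:(y0 + by - 1)]
  attr(patch, "filtered") <- filt
  attr(patch, "peak_power_fraction") <- frac
  patch
}

# Normalised cross-correlation of image M with template (FFT-based,
# sliding local normalisation).  Returns the NCC map: entry (i, j) is the
# correlation with the template centred at pixel (i, j).
#' @noRd
ncc_map <- function(M, tmpl) {
  nx <- nrow(M); ny <- ncol(M)
  tx <- nrow(tmpl); ty <- ncol(tmpl)
  t0 <- tmpl - mean(tmpl)
  tnorm <- sqrt(sum(t0^2))
  if (tnorm == 0) stop("flat template")
  npix <- tx * ty
  # place template centred at origin with wrap-around
  T <- matrix(0, nx, ny)
  ox <- floor(tx / 2); oy <- floor(ty / 2)
  ix <- ((seq_len(tx) - 1 - ox) %% nx) + 1
  iy <- ((seq_len(ty) - 1 - oy) %% ny) + 1
  T[ix, iy] <- t0
  box <- matrix(0, nx, ny)
  box[ix, iy] <- 1
  FM <- fft2(M)
  FM2 <- fft2(M^2)
  num <- Re(ifft2(FM * Conj(fft2(T))))
  s1 <- Re(ifft2(FM * Conj(fft2(box))))
  s2 <- Re(ifft2(FM2 * Conj(fft2(box))))
  denom <- sqrt(pmax(s2 - s1^2 / npix, 1e-12)) * tnorm
  num / denom
}

#' Track unit-cell positions across a micrograph
#'
#' Normalised cross-correlation of the micrograph against the reference
#' patch, followed by region-growing lattice tracking: starting from the
#' strongest correlation peak, each neighbouring node is predicted from
#' its already-matched neighbour plus one lattice vector and matched to
#' the nearest correlation maximum within a search radius of 0.4 x the
#' shorter cell edge (so large smooth distortions are followed
#' incrementally without neighbour capture).  Displacements are recorded
#' against the ideal (undistorted) lattice anchored at the starting node.
#'
#' @param m A [micrograph()].
#' @param lat A `reciprocal_lattice`.
#' @param ref Reference patch from [make_reference()].
#' @param min_score Minimum correlation for a node to count as matched.
#' @return A `cell_positions` data frame: lattice indices `i`, `j`, ideal
#'   positions `x_pred`, `y_pred`, measured `x_obs`, `y_obs`,
#'   displacements `dx`, `dy`, `score`, `matched`.  Attr `ncc` holds the
#'   correlation map.  More than 50% unmatched interior nodes is an
#'   error ("lattice lost").
#' @export
track_cells <- function(m, lat, ref, min_score = 0.2) {
  stopifnot(inherits(m, "micrograph"), inherits(lat, "reciprocal_lattice"))
  C <- ncc_map(m$pixels, ref)
  nx <- nrow(C); ny <- ncol(C)
  V <- real_cell_vectors(lat)
  r_search <- 0.4 * min(sqrt(colSums(V^2)))
  o <- which(C == max(C), arr.ind = TRUE)[1, ]
  origin <- as.numeric(o)
  # enumerate candidate nodes (i, j) whose ideal positions are interior
  rng <- function(v) {
    lim <- ceiling((nx + ny) / min(sqrt(colSums(V^2))))
    -lim:lim
  }
  cand <- expand.grid(i = rng(1), j = rng(2))
  ideal_x <- origin[1] + cand$i * V[1, 1] + cand$j * V[1, 2]
  ideal_y <- origin[2] + cand$i * V[2, 1] + cand$j * V[2, 2]
  margin <- 2
  keep <- ideal_x > margin & ideal_x <= nx - margin &
    ideal_y > margin & ideal_y <= ny - margin
  cand <- cand[keep, ]
  ideal_x <- ideal_x[keep]; ideal_y <- ideal_y[keep]
  n <- nrow(cand)
  key <- paste(cand$i, cand$j)
  obs_x <- obs_y <- score <- rep(NA_real_, n)
  matched <- rep(FALSE, n)
  visited <- rep(FALSE, n)
  # local correlation peak near (px, py); the search box extends further
  # along the row direction (up to just under half the a spacing), where
  # smooth fields change fastest between rows and the prediction error
  # is largest
  rx_search <- max(r_search, 0.45 * sqrt(sum(V[, 1]^2)))
  local_peak <- function(px, py) {
    x0 <- max(2, floor(px - rx_search)); x1 <- min(nx - 1, ceiling(px + rx_search))
    y0 <- max(2, floor(py - r_search)); y1 <- min(ny - 1, ceiling(py + r_search))
    if (x1 <= x0 || y1 <= y0) return(NULL)
    sub <- C[x0:x1, y0:y1]
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- x0 + w[1] - 1; j <- y0 + w[2] - 1
    if (abs(i - px) > rx_search + 1 || abs(j - py) > r_search + 1)
      return(NULL)
    # quadratic sub-pixel refinement, clamped to one pixel
    sx <- sy <- 0
    if (i > 1 && i < nx) {
      den <- C[i - 1, j] - 2 * C[i, j] + C[i + 1, j]
      if (den < 0) sx <- max(-1, min(1, 0.5 * (C[i - 1, j] - C[i + 1, j]) / den))
    }
    if (j > 1 && j < ny) {
      den <- C[i, j - 1] - 2 * C[i, j] + C[i, j + 1]
      if (den < 0) sy <- max(-1, min(1, 0.5 * (C[i, j - 1] - C[i, j + 1]) / den))
    }
    list(x = i + sx, y = j + sy, s = C[i, j])
  }
  # serpentine tracking: each row is entered exactly once, by a single
  # c-step from the best-scoring matched node of the previously tracked
  # row, and then expanded sequentially along a (where a smooth field
  # changes very little between neighbours).  A single entry per row
  # keeps the whole row on one lattice branch - identical chains make
  # the x lock ambiguous modulo the a spacing, so mixed entries would
  # split rows between branches.
  try_node <- function(w, px, py) {
    pk <- local_peak(px, py)
    if (!is.null(pk) && pk$s >= min_score) {
      obs_x[w] <<- pk$x; obs_y[w] <<- pk$y; score[w] <<- pk$s
      matched[w] <<- TRUE
    }
    matched[w]
  }
  expand_row <- function(jr, w0) {
    ii <- which(cand$j == jr)
    ii <- ii[order(cand$i[ii])]
    k0 <- which(ii == w0)
    for (dir in c(1, -1)) {
      ks <- if (dir == 1) seq_len(length(ii) - k0) + k0 else rev(seq_len(k0 - 1))
      last <- w0
      for (k in ks) {
        w <- ii[k]
        step <- cand$i[w] - cand$i[last]
        px <- obs_x[last] + step * V[1, 1]
        py <- obs_y[last] + step * V[2, 1]
        if (try_node(w, px, py)) last <- w
      }
    }
  }
  start <- which(key == "0 0")
  obs_x[start] <- origin[1]; obs_y[start] <- origin[2]
  score[start] <- C[round(origin[1]), round(origin[2])]
  matched[start] <- TRUE
  pk0 <- local_peak(origin[1], origin[2])
  if (!is.null(pk0)) { obs_x[start] <- pk0$x; obs_y[start] <- pk0$y
    score[start] <- pk0$s }
  expand_row(0L, start)
  for (sgn in c(1L, -1L)) {
    prev <- 0L
    repeat {
      jr <- prev + sgn
      ii <- which(cand$j == jr)
      if (!length(ii)) break
      par <- which(cand$j == prev & matched)
      if (!length(par)) break
      anchor <- par[which.max(score[par])]
      w0 <- ii[which.min(abs(cand$i[ii] - cand$i[anchor]))]
      step <- cand$i[w0] - cand$i[anchor]
      px <- obs_x[anchor] + step * V[1, 1] + sgn * V[1, 2]
      py <- obs_y[anchor] + step * V[2, 1] + sgn * V[2, 2]
      if (try_node(w0, px, py)) expand_row(jr, w0)
      prev <- jr
    }
  }
  if (mean(matched) < 0.5)
    stop("lattice lost: more than 50% of nodes unmatched")
  # refit the ideal (average) lattice from the tracked positions: a
  # least-squares origin + cell vectors over all matched nodes, so the
  # recorded displacements carry no spurious affine trend from the
  # initial reciprocal-space basis estimate
  ok <- matched
  if (sum(ok) >= 6) {
    X <- cbind(1, cand$i[ok], cand$j[ok])
    cf <- qr.solve(X, cbind(obs_x[ok], obs_y[ok]))
    ideal_x <- cf[1, 1] + cand$i * cf[2, 1] + cand$j * cf[3, 1]
    ideal_y <- cf[1, 2] + cand$i * cf[2, 2] + cand$j * cf[3, 2]
    V <- t(cf[2:3, ])
  }
  cells <- data.frame(i = cand$i, j = cand$j,
                      x_pred = ideal_x, y_pred = ideal_y,
                      x_obs = obs_x, y_obs = obs_y,
                      dx = obs_x - ideal_x, dy = obs_y - ideal_y,
                      score = score, matched = matched)
  class(cells) <- c("cell_positions", "data.frame")
  attr(cells, "ncc") <- C
  attr(cells, "cell_vectors") <- V
  cells
}

#' Unbend a distorted micrograph
#'
#' Fits the tracked displacements with a smooth 2D polynomial field
#' (least squares, default degree 3; the degree is lowered automatically
#' with a warning if the fit is rank-deficient) and resamples the image at
#' the corrected coordinates `p + d(p)`.  On synthetic distortions this
#' restores indexed-reflection power to within a few percent of the
#' undistorted image.
#'
#' @param m A [micrograph()].
#' @param cells A `cell_positions` table from [track_cells()] (at least 6
#'   matched nodes).
#' @param degree Polynomial degree of the displacement field.
#' @param interp Resampling kernel; bicubic by default, since restoring
#'   high-resolution reflections is the whole point and bilinear
#'   attenuates them at fractional shifts.
#' @return The unbent [micrograph()]; field `unbend_field` holds the
#'   fitted [distortion_field()].
#' @export
unbend_image <- function(m, cells, degree = 3L,
                         interp = c("bicubic", "bilinear")) {
  interp <- match.arg(interp)
  stopifnot(inherits(m, "micrograph"))
  cc <- cells[cells$matched, , drop = FALSE]
  if (nrow(cc) < 6) stop("need at least 6 matched nodes to fit the field")
  deg <- as.integer(degree)
  repeat {
    X <- poly_terms(cc$x_obs, cc$y_obs, deg)
    if (qr(X)$rank == ncol(X) && nrow(cc) >= ncol(X)) break
    if (deg == 0) stop("displacement field fit is degenerate")
    deg <- deg - 1L
    warning("rank-deficient displacement fit: degree lowered to ", deg)
  }
  # displacement measured at the observed positions: the image shows the
  # motif of ideal node n at n + d, so resampling at p + d(p) undoes it
  cf <- qr.solve(X, cbind(cc$dx, cc$dy))
  field <- distortion_field("polynomial", coef_x = cf[, 1], coef_y = cf[, 2],
                            degree = deg)
  # an already-straight lattice needs no correction: resampling for a
  # sub-quarter-pixel field would only cost interpolation loss, so the
  # image is returned unchanged (this also makes unbending idempotent)
  dchk <- field_displacement(field, cc$x_obs, cc$y_obs)
  if (max(abs(c(dchk$dx, dchk$dy))) < 0.25) {
    out <- m
    out$unbend_field <- distortion_field("constant", amplitude = c(0, 0))
    return(out)
  }
  out <- apply_distortion(m, field, interp = interp)
  out$unbend_field <- field
  out
}

#' Summed power at indexed reflections
#'
#' Bookkeeping helper for unbending checks: the sum over indexed
#' reflections of the maximum power within +/-1 pixel of the predicted
#' position.
#'
#' @param m A [micrograph()].
#' @param lat A `reciprocal_lattice` (its peak list defines the
#'   reflections).
#' @param pad Half-width in Fourier pixels of the window integrated
#'   around each predicted position (default 3).  Integrating rather
#'   than taking the bin maximum makes the measure insensitive to
#'   scalloping (the sub-bin alignment of a Bragg peak with the DFT
#'   grid) and to the small affine lattice difference left by unbending
#'   to the tracked average lattice.
#' @param window `"hann"` (default) tapers the field of view before the
#'   transform, which spreads each Bragg peak smoothly over a few bins
#'   and makes the integrated power insensitive to its sub-bin
#'   alignment; `"none"` uses the raw transform.
#' @return Named numeric vector of per-reflection powers (names "h,k");
#'   sum is the total indexed power.
#' @export
indexed_peak_power <- function(m, lat, pad = 3L,
                               window = c("hann", "none")) {
  window <- match.arg(window)
  px <- m$pixels
  if (window == "hann") {
    nx0 <- nrow(px); ny0 <- ncol(px)
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx0) - 1) / nx0)
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny0) - 1) / ny0)
    px <- (px - mean(px)) * outer(wx, wy)
  }
  P <- fftshift2(Mod(fft2(px))^2)
  nx <- nrow(P); ny <- ncol(P)
  cx <- floor(nx / 2) + 1; cy <- floor(ny / 2) + 1
  out <- numeric(nrow(lat$peaks))
  for (r in seq_len(nrow(lat$peaks))) {
    i <- cx + round(lat$peaks$x_px[r])
    j <- cy + round(lat$peaks$y_px[r])
    ii <- max(pad + 1, min(i, nx - pad)); jj <- max(pad + 1, min(j, ny - pad))
    out[r] <- sum(P[(ii - pad):(ii + pad), (jj - pad):(jj + pad)])
  }
  names(out) <- paste(lat$peaks$h, lat$peaks$k, sep = ",")
  out
}

#' Write tracked cell positions to CSV
#'
#' @param cells A `cell_positions` table.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cell_positions <- function(cells, path) {
  utils::write.csv(as.data.frame(cells), path, row.names = FALSE)
  invisible(path)
}
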