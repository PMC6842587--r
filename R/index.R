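# Reciprocal-lattice indexing: power spectra, peak picking, basis
# refinement and spacing measurement.

#' Power spectrum of a micrograph
#'
#' `|FFT|^2`, DC-centred, with the frequency axes calibrated by the pixel
#' size.
#'
#' @param m A [micrograph()].
#' @param window `"none"` (default; power is exactly conserved) or
#'   `"hann"`.  The Hann taper suppresses the truncation sidelobes of the
#'   rectangular field of view, which otherwise bias sub-pixel peak
#'   centres; [find_lattice()] uses it for peak localisation.
#' @return A `power_spectrum` object: `power` matrix (DC at
#'   `(floor(nx/2)+1, floor(ny/2)+1)`), frequency axes `fx`, `fy` in
#'   1/Angstrom, and the source `pixel_size`.
#' @export
power_spectrum <- function(m, window = c("none", "hann")) {
  stopifnot(inherits(m, "micrograph"))
  window <- match.arg(window)
  px <- m$pixels
  if (window == "hann") {
    nx <- nrow(px); ny <- ncol(px)
    wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nx) - 1) / nx)
    wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ny) - 1) / ny)
    px <- (px - mean(px)) * outer(wx, wy)
  }
  P <- fftshift2(Mod(fft2(px))^2)
  nx <- nrow(P); ny <- ncol(P)
  structure(list(power = P,
                 fx = sort(fft_freqs(nx)) / m$pixel_size,
                 fy = sort(fft_freqs(ny)) / m$pixel_size,
                 pixel_size = m$pixel_size, nx = nx, ny = ny),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d x %d, Nyquist %.3f 1/A\n",
              x$nx, x$ny, 0.5 / x$pixel_size))
  invisible(x)
}

# Pick local maxima above mean + nsigma * sd within resolution annuli.
# Returns peak positions in DC-relative Fourier-pixel units with 3x3
# centre-of-mass sub-pixel refinement, de-duplicated to the Hermitian
# half-plane.
#' @noRd
pick_peaks <- function(ps, min_d, max_d, nsigma = 5, n_annuli = 24) {
  P <- ps$power
  nx <- ps$nx; ny <- ps$ny
  cx <- floor(nx / 2) + 1; cy <- floor(ny / 2) + 1
  qx <- outer(ps$fx, rep(1, ny))
  qy <- outer(rep(1, nx), ps$fy)
  qr <- sqrt(qx^2 + qy^2)
  qlo <- 1 / max_d; qhi <- 1 / min_d
  in_band <- qr >= qlo & qr <= qhi
  # annular thresholds
  br <- seq(qlo, qhi, length.out = n_annuli + 1)
  ann <- findInterval(qr, br, rightmost.closed = TRUE)
  thr <- matrix(Inf, nx, ny)
  for (b in seq_len(n_annuli)) {
    sel <- in_band & ann == b
    if (sum(sel) < 10) next
    v <- P[sel]
    thr[sel] <- mean(v) + nsigma * stats::sd(v)
  }
  # strict 3x3 local maxima
  cand <- which(in_band & P > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nx &
                 cand[, 2] > 1 & cand[, 2] < ny, , drop = FALSE]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- P[(i - 1):(i + 1), (j - 1):(j + 1)]
    keep[k] <- P[i, j] >= max(nb) && sum(nb == max(nb)) == 1
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(u = numeric(0), v = numeric(0), height = numeric(0)))
  # 3x3 centre-of-mass sub-pixel refinement
  u <- v <- h <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    nb <- P[(i - 1):(i + 1), (j - 1):(j + 1)]
    w <- nb - min(nb)
    sw <- sum(w)
    du <- sum(w * matrix(-1:1, 3, 3)) / sw
    dv <- sum(w * matrix(-1:1, 3, 3, byrow = TRUE)) / sw
    u[k] <- i - cx + du
    v[k] <- j - cy + dv
    h[k] <- P[i, j]
  }
  pk <- data.frame(u = u, v = v, height = h)
  # Hermitian half-plane: keep v > 0, or v == 0 & u > 0
  pk <- pk[pk$v > 1e-9 | (abs(pk$v) <= 1e-9 & pk$u > 0), , drop = FALSE]
  pk[order(-pk$height), , drop = FALSE]
}

# Gauss lattice reduction of a 2x2 reciprocal basis (rows g1, g2) to the
# two shortest lattice vectors.  A reflection may be structure-factor
# suppressed (e.g. (1,0) when apex and tip columns cancel), in which case
# the shortest *observed* non-collinear peak gives an oblique primitive
# basis; reduction recovers the conventional rectangular setting.
#' @noRd
gauss_reduce <- function(G) {
  g1 <- G[1, ]; g2 <- G[2, ]
  if (sum(g1^2) > sum(g2^2)) { tmp <- g1; g1 <- g2; g2 <- tmp }
  repeat {
    r <- round(sum(g1 * g2) / sum(g1^2))
    g2 <- g2 - r * g1
    if (sum(g2^2) >= sum(g1^2)) break
    tmp <- g1; g1 <- g2; g2 <- tmp
  }
  rbind(g1, g2)
}

# Drop peaks below a relative height floor and absorb residual sidelobes:
# any peak within `merge_px` of a stronger accepted peak is discarded.
#' @noRd
vet_peaks <- function(pk, min_rel_height = 1e-3, merge_px = 4) {
  if (nrow(pk) == 0) return(pk)
  pk <- pk[pk$height >= min_rel_height * max(pk$height), , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (k in seq_len(nrow(pk))[-1]) {
    acc <- which(keep[seq_len(k - 1)])
    d2 <- (pk$u[acc] - pk$u[k])^2 + (pk$v[acc] - pk$v[k])^2
    if (any(d2 < merge_px^2)) keep[k] <- FALSE
  }
  pk[keep, , drop = FALSE]
}

#' Detect and refine the reciprocal lattice in a power spectrum
#'
#' Picks reflections (local maxima above mean + 5 sigma within resolution
#' annuli, 3x3 centre-of-mass sub-pixel centres), selects the two shortest
#' non-collinear peaks as the basis, indexes every peak and refines the
#' basis vectors by least squares against all indexed reflections.
#'
#' @param ps A [power_spectrum()] (or a [micrograph()], transformed
#'   internally).
#' @param min_d,max_d Resolution band searched, in Angstrom.  The default
#'   `max_d = 30` keeps the search below supercell fundamentals: sheets
#'   with alternating (antiparallel) rows double the crystallographic
#'   repeat along c, and the conventional c spacing is the adjacent-row
#'   spacing.
#' @param nsigma Peak threshold in annulus standard deviations.
#' @param min_rel_height Reflections below this fraction of the strongest
#'   reflection are treated as noise.
#' @return A `reciprocal_lattice`: basis vectors `g_a`, `g_c` (1/Angstrom,
#'   `g_a` the longer reciprocal vector = shorter real spacing), a `peaks`
#'   data frame (h, k, qx, qy, x_px, y_px, height, d_A) and `n_unindexed`.
#' @export
find_lattice <- function(ps, min_d = 1.2, max_d = 30, nsigma = 5,
                         min_rel_height = 1e-3) {
  if (inherits(ps, "micrograph")) ps <- power_spectrum(ps, window = "hann")
  stopifnot(inherits(ps, "power_spectrum"))
  dqx <- 1 / (ps$nx * ps$pixel_size)
  dqy <- 1 / (ps$ny * ps$pixel_size)
  pk <- vet_peaks(pick_peaks(ps, min_d, max_d, nsigma),
                  min_rel_height = min_rel_height)
  if (nrow(pk) < 2) stop("unindexable: fewer than 2 reflections found")
  # peak q vectors in 1/A
  Q <- cbind(pk$u * dqx, pk$v * dqy)
  qn <- sqrt(rowSums(Q^2))
  o <- order(qn)
  # candidate bases: the shortest peaks paired with the shortest
  # non-collinear partners; the pair that indexes the most peak weight
  # (residual < 0.75 px) wins.  This keeps a weak but genuine second
  # axis from losing to a spurious short vector.
  sine_with <- function(g, i) {
    abs(g[1] * Q[i, 2] - g[2] * Q[i, 1]) / (sqrt(sum(g^2)) * qn[i])
  }
  index_score <- function(G) {
    hk <- t(solve(t(G), t(Q)))
    pred <- round(hk) %*% G
    res <- sqrt(((Q[, 1] - pred[, 1]) / dqx)^2 +
                  ((Q[, 2] - pred[, 2]) / dqy)^2)
    sum(pk$height[res < 0.75 & rowSums(abs(round(hk))) > 0])
  }
  oh <- order(-pk$height)
  g1_cand <- unique(c(o[seq_len(min(3, length(o)))],
                      oh[seq_len(min(3, length(oh)))]))
  best <- NULL; best_score <- -Inf
  for (i1 in g1_cand) {
    noncol <- vapply(seq_len(nrow(Q)), function(i) i != i1 &&
                       sine_with(Q[i1, ], i) > 0.2, logical(1))
    partners <- unique(c(utils::head(o[noncol[o]], 5),
                         utils::head(oh[noncol[oh]], 5)))
    for (i2 in partners) {
      G <- rbind(Q[i1, ], Q[i2, ])
      sc <- tryCatch(index_score(G), error = function(e) -Inf)
      if (sc > best_score) { best_score <- sc; best <- G }
    }
  }
  g2 <- NULL
  if (!is.null(best)) { g1 <- best[1, ]; g2 <- best[2, ] }
  else g1 <- Q[o[1], ]
  if (is.null(g2)) {
    warning("collinear reflections only: 1D lattice, g_c undefined")
    lat <- structure(list(g_a = g1, g_c = c(NA_real_, NA_real_),
                          peaks = data.frame(), n_unindexed = 0L,
                          pixel_size = ps$pixel_size,
                          nx = ps$nx, ny = ps$ny),
                     class = "reciprocal_lattice")
    return(lat)
  }
  G <- rbind(g1, g2)
  # two rounds: index + least-squares refinement of the basis
  for (round in 1:2) {
    hk <- t(solve(t(G), t(Q)))       # Q = hk %*% G
    hk_i <- round(hk)
    pred <- hk_i %*% G
    res_px <- sqrt(((Q[, 1] - pred[, 1]) / dqx)^2 +
                     ((Q[, 2] - pred[, 2]) / dqy)^2)
    ok <- res_px < (if (round == 1) 1.5 else 0.75) &
      rowSums(abs(hk_i)) > 0
    if (sum(ok) < 3) break
    M <- hk_i[ok, , drop = FALSE]
    G <- solve(t(M) %*% M, t(M) %*% Q[ok, , drop = FALSE])
    G <- gauss_reduce(G)
  }
  hk <- t(solve(t(G), t(Q)))
  hk_i <- round(hk)
  pred <- hk_i %*% G
  res_px <- sqrt(((Q[, 1] - pred[, 1]) / dqx)^2 +
                   ((Q[, 2] - pred[, 2]) / dqy)^2)
  ok <- res_px < 0.75 & rowSums(abs(hk_i)) > 0
  # a genuine lattice indexes most of the reflection weight; random peak
  # fields do not
  if (sum(ok) < 4 || sum(pk$height[ok]) < 0.4 * sum(pk$height))
    stop("unindexable: no basis accounts for the detected reflections")
  g_a <- G[1, ]; g_c <- G[2, ]
  # g_a = larger |g| (shorter real-space spacing); ties broken by the
  # vector closer to the +x axis
  na_ <- sqrt(sum(g_a^2)); nc_ <- sqrt(sum(g_c^2))
  swap <- if (abs(na_ - nc_) / max(na_, nc_) < 1e-3) {
    abs(atan2(g_a[2], g_a[1])) > abs(atan2(g_c[2], g_c[1]))
  } else na_ < nc_
  if (swap) { tmp <- g_a; g_a <- g_c; g_c <- tmp; hk_i <- hk_i[, 2:1] }
  peaks <- data.frame(h = hk_i[ok, 1], k = hk_i[ok, 2],
                      qx = Q[ok, 1], qy = Q[ok, 2],
                      x_px = Q[ok, 1] / dqx, y_px = Q[ok, 2] / dqy,
                      height = pk$height[ok],
                      d_A = 1 / sqrt(rowSums(Q[ok, , drop = FALSE]^2)))
  structure(list(g_a = unname(g_a), g_c = unname(g_c), peaks = peaks,
                 n_unindexed = sum(!ok),
                 pixel_size = ps$pixel_size, nx = ps$nx, ny = ps$ny),
            class = "reciprocal_lattice")
}

#' @export
print.reciprocal_lattice <- function(x, ...) {
  sp <- measure_spacings(x)
  cat(sprintf(paste0("<reciprocal_lattice> a = %.1f A, c = %.1f A, ",
                     "%d indexed peak(s), %d unindexed\n"),
              sp["a"], sp["c"], nrow(x$peaks), x$n_unindexed))
  invisible(x)
}

#' Measure lattice spacings
#'
#' Real-space spacings from the refined reciprocal basis: `a = 1/|g_a|`
#' (the shorter spacing, the chain-to-chain distance within a row) and
#' `c = 1/|g_c|` (the adjacent-row spacing), reported to 0.1 Angstrom.
#'
#' @param lat A `reciprocal_lattice` from [find_lattice()].
#' @return Named numeric `c(a = , c = )` in Angstrom, rounded to 0.1;
#'   attr `"raw"` holds the unrounded values.
#' @export
measure_spacings <- function(lat) {
  stopifnot(inherits(lat, "reciprocal_lattice"))
  a <- 1 / sqrt(sum(lat$g_a^2))
  cc <- if (anyNA(lat$g_c)) NA_real_ else 1 / sqrt(sum(lat$g_c^2))
  out <- c(a = round(a, 1), c = round(cc, 1))
  attr(out, "raw") <- c(a = a, c = cc)
  out
}

#' Predict powder-pattern peak positions
#'
#' Axial d-spacings of the rectangular sheet lattice for wide-angle
#' scattering comparison: `d(00l) = c / l` and `d(h00) = a / h` up to
#' `max_order`, each rounded to 0.1 Angstrom, with the scattering-vector
#' magnitude `q = 2 pi / d`.
#'
#' @param a,c Lattice spacings in Angstrom.
#' @param max_order Highest order reported.
#' @return Data frame with `hkl`, `d_A` (rounded to 0.1) and `q_invA`.
#' @export
predict_powder_peaks <- function(a, c, max_order = 3L) {
  stopifnot(a > 0, c > 0, max_order >= 1)
  ord <- seq_len(max_order)
  d <- c(c / ord, a / ord)
  lab <- c(sprintf("(00%d)", ord), sprintf("(%d00)", ord))
  data.frame(hkl = lab, d_A = round(d, 1), q_invA = 2 * pi / d)
}

#' JSON peak table for an indexed lattice
#'
#' @param lat A `reciprocal_lattice`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_peak_table <- function(lat, path) {
  stopifnot(inherits(lat, "reciprocal_lattice"))
  jsonlite::write_json(
    lat$peaks[, c("h", "k", "x_px", "y_px", "height", "d_A")],
    path, digits = NA)
  invisible(path)
}
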