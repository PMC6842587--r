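# Geometric observables from class averages: the projected V dihedral and
# heavy-atom column positions.

#' Fit the projected V geometry of a class average
#'
#' The apex is the global intensity maximum (3x3 centre-of-mass refined).
#' Boxes are lattice-registered, so the backbone row runs through the
#' apex: its direction is found from the near-maximal backbone columns
#' (the apex and its lattice neighbours) when the box contains them, and
#' is taken along +x for an isolated motif.  The image is de-rotated so
#' the row lies along x, and each arm is then traced row by row: for
#' every image row at least `band_exclude_A` from the apex row, the arm
#' crossing is the intensity-weighted circular centroid of the
#' (median-subtracted) row - circular in x with the box period, so arms
#' wrapping across the one-cell-wide box stay on a single line.  A
#' robust (weighted Theil-Sen) fit of the unwrapped crossing position
#' against y gives each arm's slope, hence direction; the V dihedral is
#' the angle
#' between the +c and -c arm directions, reported to 1 degree.  Collinear
#' arms give ~180 degrees and are flagged degenerate.
#'
#' @param avg Class-average image (matrix, or a single-class
#'   [class_average()] element, or a [micrograph()]).
#' @param pixel_size Angstrom per pixel.
#' @param threshold Rows whose residual arm amplitude falls below this
#'   fraction of the strongest row are left out of the fit (default 0.5).
#' @param band_exclude_A Half-width of the apex-row band excluded from
#'   the arm fit (the apex blob is isotropic and carries no direction,
#'   and its skirt drags near-apex crossings).  The band shrinks
#'   automatically (to no less than 2 Angstrom) when the box is too
#'   short to leave enough rows.
#' @param min_rows Minimum number of usable rows per arm.
#' @param a_px Lattice a period in pixels.  The per-row crossing centroid
#'   is circular with this period, so boxes wider than one cell (whose
#'   rows hold several phase-locked crossings) stay coherent; defaults to
#'   the box width (a one-cell box).
#' @return A `v_geometry`: `apex_A` (x, y in Angstrom from the box
#'   lower-left), `arm1` (+c arm), `arm2` (-c arm) unit vectors in the
#'   original frame, `ridge` (backbone row direction), `dihedral_deg`
#'   (1-degree precision), `dihedral_raw`, `degenerate` flag (TRUE within
#'   4 degrees of a straight line).
#' @export
fit_v_shape <- function(avg, pixel_size = 0.5, threshold = 0.5,
                        band_exclude_A = 2.5, min_rows = 4,
                        a_px = NULL) {
  M <- if (inherits(avg, "micrograph")) avg$pixels else as.matrix(avg)
  nx <- nrow(M); ny <- ncol(M)
  # boxes are lattice-registered with the backbone column at the centre;
  # take the local maximum near the centre (the global maximum may be a
  # brighter heavy-atom tip) and refine by 3x3 centre of mass
  ric <- 2.5 / pixel_size
  ci <- (nx + 1) / 2; cj <- (ny + 1) / 2
  near <- which((((seq_len(nx * ny) - 1) %% nx + 1) - ci)^2 +
                  (((seq_len(nx * ny) - 1) %/% nx + 1) - cj)^2 <= ric^2)
  imax <- near[which.max(M[near])]
  ai <- (imax - 1) %% nx + 1
  aj <- (imax - 1) %/% nx + 1
  ii <- max(2, min(ai, nx - 1)); jj <- max(2, min(aj, ny - 1))
  nb <- M[(ii - 1):(ii + 1), (jj - 1):(jj + 1)]
  w <- nb - min(nb)
  apex <- c(ii + sum(w * matrix(-1:1, 3, 3)) / sum(w),
            jj + sum(w * matrix(-1:1, 3, 3, byrow = TRUE)) / sum(w))

  # backbone row direction from the near-maximal backbone columns; +x
  # for an isolated motif (no off-apex columns)
  ridge_deg <- 0
  gx <- (seq_len(nx * ny) - 1) %% nx + 1 - apex[1]
  gy <- (seq_len(nx * ny) - 1) %/% nx + 1 - apex[2]
  r2 <- gx^2 + gy^2
  # restrict to the nearest-neighbour range of the backbone row (the a
  # spacing): heavy tip columns lie further out, at the arm length
  strong <- as.numeric(M) >= 0.8 * max(M) & r2 > (1.8 / pixel_size)^2 &
    r2 < (6 / pixel_size)^2
  if (any(strong)) {
    # principal axis of the strong columns about the apex; accepted as
    # the row direction only if their mass is balanced on both sides
    W0 <- as.numeric(M)[strong]
    sx <- gx[strong]; sy <- gy[strong]
    S <- matrix(c(sum(W0 * sx^2), sum(W0 * sx * sy),
                  sum(W0 * sx * sy), sum(W0 * sy^2)), 2, 2)
    ev <- eigen(S, symmetric = TRUE)
    u <- ev$vectors[, 1]
    al <- u[1] * sx + u[2] * sy
    s2 <- c(sum(W0[al > 0]), sum(W0[al < 0]))
    anis <- ev$values[1] / max(sum(ev$values), 1e-12)
    if (min(s2) / max(max(s2), 1e-12) > 0.3 && anis > 0.8)
      ridge_deg <- (rad2deg(atan2(u[2], u[1]))) %% 180
  }
  rot <- min(ridge_deg, 180 - ridge_deg) > 0.5
  W <- M
  if (rot) {
    # de-rotate about the apex so the row lies along x
    th <- deg2rad(-ridge_deg)
    xs <- rep(seq_len(nx), ny) - apex[1]
    ys <- rep(seq_len(ny), each = nx) - apex[2]
    xr <- apex[1] + cos(th) * xs + sin(th) * ys
    yr <- apex[2] - sin(th) * xs + cos(th) * ys
    W <- matrix(bicubic_sample(M, xr, yr, fill = stats::median(M)), nx, ny)
  }

  # subtract the isotropic (angular-median) radial profile about the
  # apex: the apex blob's skirt otherwise drags near-apex crossings
  # toward the apex column and biases the arm slope
  r_apex <- sqrt((rep(seq_len(nx), ny) - apex[1])^2 +
                   (rep(seq_len(ny), each = nx) - apex[2])^2)
  rim <- pmin(floor(r_apex), 200L)
  med <- tapply(as.numeric(W), rim, stats::median)
  W <- W - matrix(med[as.character(rim)], nx, ny)

  # per-row circular centroid of the arm crossing, circular with the
  # lattice period so several phase-locked crossings per row add
  # coherently
  if (is.null(a_px)) a_px <- nx
  band <- band_exclude_A / pixel_size
  phase_rows <- function(js) {
    amp <- wz <- ph <- yy <- numeric(0)
    for (j in js) {
      cols <- seq_len(nx)
      if (a_px < nx) {
        # use a whole number of lattice periods centred on the apex (a
        # partial crossing at the row end would bias the centroid); a
        # de-rotated image is only valid inside the inscribed disc
        half_w <- if (rot) {
          sqrt(max((min(nx, ny) / 2 - 2)^2 - (j - apex[2])^2, 0))
        } else {
          min(apex[1] - 1, nx - apex[1])
        }
        n_per <- floor(half_w / a_px)
        if (n_per < 1) next
        cols <- round(apex[1]) + seq(-n_per * a_px, n_per * a_px - 1)
        cols <- cols[cols >= 1 & cols <= nx]
      }
      v <- W[cols, j] - stats::median(W[cols, j])
      v[v < 0] <- 0
      if (sum(v) <= 0) next
      z <- sum(v * exp(2i * pi * (cols - 1) / a_px))
      if (Mod(z) / sum(v) < 0.1) next  # no localised crossing
      amp <- c(amp, max(v)); wz <- c(wz, Mod(z))
      ph <- c(ph, Arg(z)); yy <- c(yy, j)
    }
    list(amp = amp, wz = wz, ph = ph, y = yy)
  }
  arm_fit <- function(js, sign_y) {
    pr <- phase_rows(js)
    if (length(pr$amp) == 0)
      stop("arm not resolved: no usable rows on the ",
           if (sign_y > 0) "+c" else "-c", " side")
    # walk away from the apex; the arm ends where the row amplitude
    # drops below `threshold` x the median non-empty amplitude, and the
    # rows within a couple of blur lengths of that end are dropped as
    # well (the crossing centroid there is dragged back along the arm -
    # end effect)
    o <- order(if (sign_y > 0) pr$y else -pr$y)
    ph <- pr$ph[o]; yy <- pr$y[o]; am <- pr$amp[o]; wz <- pr$wz[o]
    nonempty <- am > 0.05 * max(am)
    sig <- nonempty & am >= threshold * stats::median(am[nonempty])
    if (!any(sig))
      stop("arm not resolved: no significant rows on the ",
           if (sign_y > 0) "+c" else "-c", " side")
    trim <- ceiling(2.2 / pixel_size)
    last_sig <- max(which(sig))
    # a bright heavy-atom tip near the arm end marks it more reliably
    # than the amplitude cutoff (the tip's blur tail keeps rows beyond
    # it "significant")
    idx_max <- which.max(am)
    if (am[idx_max] > 2 * stats::median(am[nonempty]) &&
        idx_max > 0.6 * last_sig)
      last_sig <- min(last_sig, idx_max)
    last <- last_sig - trim
    use_r <- sig & seq_along(am) <= last
    if (sum(use_r) < min_rows)
      stop("arm not resolved: fewer than ", min_rows,
           " usable rows on the ", if (sign_y > 0) "+c" else "-c", " side")
    ph <- ph[use_r]; yy <- yy[use_r]; wz <- wz[use_r]
    for (k in seq_along(ph)[-1]) {
      d <- ph[k] - ph[k - 1]
      ph[k] <- ph[k] - 2 * pi * round(d / (2 * pi))
    }
    # weighted median of pairwise slopes (Theil-Sen) with one round of
    # residual rejection: rows still carrying the end-effect lag deviate
    # from the line and are dropped before the final estimate
    theil_sen <- function(ph, yy, wz) {
      n_r <- length(ph)
      ij <- which(upper.tri(matrix(0, n_r, n_r)), arr.ind = TRUE)
      sl <- (ph[ij[, 2]] - ph[ij[, 1]]) / (yy[ij[, 2]] - yy[ij[, 1]])
      wp <- wz[ij[, 1]] * wz[ij[, 2]]
      o2 <- order(sl)
      cw <- cumsum(wp[o2]) / sum(wp)
      sl[o2][which(cw >= 0.5)[1]]
    }
    slope <- theil_sen(ph, yy, wz)
    resid <- ph - slope * yy
    resid <- resid - stats::median(resid)
    tol <- max(3 * stats::mad(resid), 0.03)
    keep2 <- abs(resid) <= tol
    if (sum(keep2) >= min_rows && any(!keep2))
      slope <- theil_sen(ph[keep2], yy[keep2], wz[keep2])
    m_px <- slope * a_px / (2 * pi)  # dx/dy in px/px
    u <- c(m_px * sign_y, sign_y)
    u / sqrt(sum(u^2))
  }
  arm_fit_adaptive <- function(sign_y) {
    bands <- unique(pmax(c(band_exclude_A, 2.5, 2.0), 2.0))
    bands <- bands[bands <= band_exclude_A + 1e-9]
    err <- NULL
    for (b in sort(bands, decreasing = TRUE)) {
      js <- if (sign_y > 0) {
        seq_len(ny)[seq_len(ny) > apex[2] + b / pixel_size]
      } else {
        seq_len(ny)[seq_len(ny) < apex[2] - b / pixel_size]
      }
      out <- tryCatch(arm_fit(js, sign_y), error = function(e) e)
      if (!inherits(out, "error")) return(out)
      err <- out
    }
    stop(err)
  }
  u1 <- tryCatch(arm_fit_adaptive(1), error = function(e) e)
  u2 <- tryCatch(arm_fit_adaptive(-1), error = function(e) e)
  if (inherits(u1, "error") || inherits(u2, "error")) {
    # collinear (straight-line) motifs: the whole structure is absorbed
    # into the detected ridge and no arms remain off it
    if (rot) {
      Wp <- W - stats::median(W)
      Wp[Wp < 0] <- 0
      wy <- rep(seq_len(ny), each = nx)
      frac <- sum(Wp[abs(wy - apex[2]) < 3]) / max(sum(Wp), 1e-12)
      ridge <- c(cos(deg2rad(ridge_deg)), sin(deg2rad(ridge_deg)))
      if (frac > 0.6)
        return(structure(list(apex_A = px_to_ang(apex, pixel_size),
                              arm1 = ridge, arm2 = -ridge, ridge = ridge,
                              dihedral_deg = 180, dihedral_raw = 180,
                              degenerate = TRUE),
                         class = "v_geometry"))
    }
    stop(if (inherits(u1, "error")) u1 else u2)
  }
  if (rot) {
    th <- deg2rad(ridge_deg)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    u1 <- as.numeric(R %*% u1)
    u2 <- as.numeric(R %*% u2)
  }
  ang <- rad2deg(acos(pmin(pmax(sum(u1 * u2), -1), 1)))
  ridge <- c(cos(deg2rad(ridge_deg)), sin(deg2rad(ridge_deg)))
  structure(list(apex_A = px_to_ang(apex, pixel_size),
                 arm1 = u1, arm2 = u2, ridge = ridge,
                 dihedral_deg = round(ang),
                 dihedral_raw = ang,
                 degenerate = ang > 176),
            class = "v_geometry")
}

#' @export
print.v_geometry <- function(x, ...) {
  cat(sprintf("<v_geometry> dihedral %d deg%s, apex (%.2f, %.2f) A\n",
              x$dihedral_deg, if (x$degenerate) " [degenerate]" else "",
              x$apex_A[1], x$apex_A[2]))
  invisible(x)
}

#' Locate heavy-atom column peaks in a class average
#'
#' Finds local maxima at or above `threshold` x max, excluding the
#' backbone apex ridges.  Averages are boxed with a backbone row at the
#' box centre, so ridge lines lie at the centre y (plus multiples of the
#' row spacing when `c_spacing` is given); pixels within
#' `ridge_exclude_A` of a ridge line are not peak candidates.  For sheets
#' with heavy para substituents the surviving maxima are the
#' superposed-atom columns at the side-chain tips; averages without heavy
#' tips return an empty result with `found = FALSE`.
#'
#' With `c_spacing`, each peak is assigned to the inter-row interface it
#' lies in, and the tip-to-tip distance across the c interface is the
#' minimum distance between a lower-row tip and an upper-row tip within
#' the same interface (requires a patch spanning at least two rows).
#'
#' @param avg Class-average image (matrix or [micrograph()]).
#' @param pixel_size Angstrom per pixel.
#' @param threshold Peak threshold as a fraction of the image maximum
#'   (default 0.7).
#' @param c_spacing Optional row spacing in Angstrom.
#' @param backbone_y_A y position (Angstrom) of a backbone row; default
#'   the box centre.
#' @param ridge_exclude_A Half-width of the excluded apex ridges.
#' @return A `heavy_atom_peaks`: `peaks` data frame (x_A, y_A, height,
#'   interface, side), `tip_to_tip_A` (NA without `c_spacing` or without
#'   cross-row pairs), `found`.
#' @export
locate_heavy_columns <- function(avg, pixel_size = 0.5, threshold = 0.7,
                                 c_spacing = NULL, backbone_y_A = NULL,
                                 ridge_exclude_A = 1.0) {
  M <- if (inherits(avg, "micrograph")) avg$pixels else as.matrix(avg)
  nx <- nrow(M); ny <- ncol(M)
  if (is.null(backbone_y_A)) backbone_y_A <- ny * pixel_size / 2
  thr <- threshold * max(M)
  # local maxima with out-of-image neighbours treated as -Inf
  Mp <- matrix(-Inf, nx + 2, ny + 2)
  Mp[2:(nx + 1), 2:(ny + 1)] <- M
  xs <- ys <- hs <- numeric(0)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      v <- M[i, j]
      if (v < thr) next
      nb <- Mp[i:(i + 2), j:(j + 2)]
      if (v < max(nb)) next
      if (sum(nb == v) > 1 && !(v > max(nb[nb != v]))) next
      # 3x3 centre-of-mass sub-pixel position (interior peaks)
      si <- i; sj <- j
      if (i > 1 && i < nx && j > 1 && j < ny) {
        w9 <- M[(i - 1):(i + 1), (j - 1):(j + 1)]
        w9 <- w9 - min(w9)
        if (sum(w9) > 0) {
          si <- i + sum(w9 * matrix(-1:1, 3, 3)) / sum(w9)
          sj <- j + sum(w9 * matrix(-1:1, 3, 3, byrow = TRUE)) / sum(w9)
        }
      }
      xs <- c(xs, si); ys <- c(ys, sj); hs <- c(hs, v)
    }
  }
  # merge duplicate maxima (plateau ties straddling a pixel boundary)
  if (length(xs) > 1) {
    o <- order(-hs)
    xs <- xs[o]; ys <- ys[o]; hs <- hs[o]
    keep <- rep(TRUE, length(xs))
    for (k in seq_along(xs)[-1]) {
      acc <- which(keep[seq_len(k - 1)])
      if (any((xs[acc] - xs[k])^2 + (ys[acc] - ys[k])^2 < 2^2))
        keep[k] <- FALSE
    }
    xs <- xs[keep]; ys <- ys[keep]; hs <- hs[keep]
  }
  y_A <- px_to_ang(ys, pixel_size)
  dy <- y_A - backbone_y_A
  ridge_dist <- if (is.null(c_spacing)) abs(dy) else {
    off <- dy %% c_spacing
    pmin(off, c_spacing - off)
  }
  keep <- ridge_dist > ridge_exclude_A
  xs <- xs[keep]; hs <- hs[keep]; y_A <- y_A[keep]; dy <- dy[keep]
  if (length(xs) == 0) {
    return(structure(list(peaks = data.frame(x_A = numeric(0),
                                             y_A = numeric(0),
                                             height = numeric(0),
                                             interface = integer(0),
                                             side = character(0)),
                          tip_to_tip_A = NA_real_, found = FALSE),
                     class = "heavy_atom_peaks"))
  }
  pk <- data.frame(x_A = px_to_ang(xs, pixel_size), y_A = y_A, height = hs)
  t2t <- NA_real_
  if (!is.null(c_spacing)) {
    pk$interface <- as.integer(floor(dy / c_spacing))
    pk$side <- ifelse(dy %% c_spacing < c_spacing / 2, "lower", "upper")
    for (iface in unique(pk$interface)) {
      lo <- pk[pk$interface == iface & pk$side == "lower", ]
      hi <- pk[pk$interface == iface & pk$side == "upper", ]
      if (nrow(lo) && nrow(hi)) {
        d <- sqrt(outer(lo$x_A, hi$x_A, "-")^2 +
                    outer(lo$y_A, hi$y_A, "-")^2)
        t2t <- min(t2t, min(d), na.rm = TRUE)
      }
    }
  } else {
    pk$interface <- ifelse(dy >= 0, 0L, -1L)
    pk$side <- ifelse(dy >= 0, "lower", "upper")
  }
  structure(list(peaks = pk, tip_to_tip_A = t2t, found = TRUE),
            class = "heavy_atom_peaks")
}

#' @export
print.heavy_atom_peaks <- function(x, ...) {
  cat(sprintf("<heavy_atom_peaks> %d peak(s)%s\n", nrow(x$peaks),
              if (is.na(x$tip_to_tip_A)) ""
              else sprintf(", tip-to-tip %.2f A", x$tip_to_tip_A)))
  invisible(x)
}
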