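# Shared test fixtures and independent oracles, all built in code.

# Independent internal-to-Cartesian chain builder used as the oracle for
# build_chain: the new atom is first placed cis to A in the A-B-C plane
# at the requested bond angle, then rotated about the B-C axis by the
# torsion (Rodrigues rotation) - a different formulation from the
# package's local-frame NeRF.
oracle_place_atom <- function(p1, p2, p3, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- (p3 - p2); bc <- bc / sqrt(sum(bc^2))
  ab <- p1 - p2
  ap <- ab - sum(ab * bc) * bc
  ap <- ap / sqrt(sum(ap^2))
  d0 <- -cos(ang) * bc + sin(ang) * ap
  rodrigues <- function(v, k, th) {
    v * cos(th) + pracma_cross(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
  }
  p3 + bond * rodrigues(d0, bc, tor)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Oracle backbone for a chain_spec: N/CA/C coordinates by sequential
# placement with the same internal coordinates the package documents.
oracle_backbone <- function(spec) {
  bl <- c(n_ca = 1.46, ca_c = 1.52, c_n = 1.33)
  ba <- c(n_ca_c = 111, ca_c_n = 114, c_n_ca = 123)
  n <- length(spec$monomers)
  out <- matrix(NA_real_, 3 * n, 3)
  out[1, ] <- c(0, 0, 0)
  out[2, ] <- c(bl["n_ca"], 0, 0)
  th <- ba["n_ca_c"] * pi / 180
  out[3, ] <- out[2, ] + bl["ca_c"] * c(-cos(th), sin(th), 0)
  if (n > 1) {
    for (i in 2:n) {
      r <- 3 * (i - 1)
      out[r + 1, ] <- oracle_place_atom(out[r - 2, ], out[r - 1, ], out[r, ],
                                        bl["c_n"], ba["ca_c_n"],
                                        spec$psi[i - 1])
      out[r + 2, ] <- oracle_place_atom(out[r - 1, ], out[r, ], out[r + 1, ],
                                        bl["n_ca"], ba["c_n_ca"], 0)
      out[r + 3, ] <- oracle_place_atom(out[r, ], out[r + 1, ], out[r + 2, ],
                                        bl["ca_c"], ba["n_ca_c"],
                                        spec$phi[i])
    }
  }
  out
}

# Rotate a micrograph matrix by `deg` about its centre (bilinear, mean
# fill): used for rotation-equivariance checks.
rotate_image <- function(M, deg) {
  nx <- nrow(M); ny <- ncol(M)
  th <- -deg * pi / 180
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- rep(seq_len(nx), ny) - cx
  ys <- rep(seq_len(ny), each = nx) - cy
  xr <- cx + cos(th) * xs - sin(th) * ys
  yr <- cy + sin(th) * xs + cos(th) * ys
  x0 <- floor(xr); y0 <- floor(yr)
  x0c <- pmin(pmax(x0, 1L), nx - 1L); y0c <- pmin(pmax(y0, 1L), ny - 1L)
  fx <- xr - x0c; fy <- yr - y0c
  v <- (1 - fx) * (1 - fy) * M[cbind(x0c, y0c)] +
    fx * (1 - fy) * M[cbind(x0c + 1L, y0c)] +
    (1 - fx) * fy * M[cbind(x0c, y0c + 1L)] +
    fx * fy * M[cbind(x0c + 1L, y0c + 1L)]
  out <- x0 < 1 | y0 < 1 | x0 >= nx | y0 >= ny
  v[out] <- mean(M)
  matrix(v, nx, ny)
}

# Stack of noisy copies of one clean box, normalised like extract_boxes.
noisy_box_stack <- function(clean, n, snr, seed) {
  set.seed(seed)
  p <- length(clean)
  sdn <- sqrt(stats::var(as.numeric(clean)) / snr)
  B <- matrix(NA_real_, n, p)
  for (k in seq_len(n)) {
    b <- as.numeric(clean) + rnorm(p, 0, sdn)
    B[k, ] <- (b - mean(b)) / sd(b)
  }
  B
}

# Small cached fixtures (built once per test run)
.fixtures <- new.env()
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

sheet1_noiseless_512 <- function() fixture("s1n512", function()
  simulate_micrograph(1, n_px = 512, snr = Inf, seed = 1))

sheet4_noiseless_512 <- function() fixture("s4n512", function()
  simulate_micrograph(4, n_px = 512, snr = Inf, seed = 1))

# small FFT helpers shared by tests
fft2p <- function(m) stats::fft(m)
ifft2p <- function(m) stats::fft(m, inverse = TRUE) / length(m)
gauss_kernel256 <- function() {
  d <- pmin(0:255, 256 - 0:255)
  outer(d^2, d^2, function(a, b) exp(-(a + b) / (2 * 1.6^2)))
}
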