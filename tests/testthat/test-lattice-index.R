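# Power spectra, peak picking, basis refinement and spacing measurement.

test_that("a pure cosine gives exactly two symmetric reflections", {
  n <- 576L  # period 9 divides the field exactly
  img <- matrix(cos(2 * pi * (0:(n - 1)) / 9), n, n)
  ps <- power_spectrum(micrograph(img, 1))
  P <- ps$power
  cx <- floor(n / 2) + 1
  ord <- order(-P)
  top <- ord[1:2]  # the cosine has zero mean, so there is no DC term
  ij <- cbind((top - 1) %% n + 1, (top - 1) %/% n + 1)
  expect_setequal(ij[, 2], rep(cx, 2))
  expect_setequal(ij[, 1] - cx, c(n / 9, -n / 9))
  expect_gt(P[top[1]] / max(P[ord[3]], 1e-300), 1e6)
  # real input: centrosymmetric spectrum
  m <- sheet1_noiseless_512()
  P2 <- power_spectrum(m)$power[2:512, 2:512]
  flip <- P2[rev(seq_len(511)), rev(seq_len(511))]
  expect_lt(max(abs(P2 - flip)) / max(P2), 1e-9)
})

test_that("synthetic rectangular lattices are indexed to better than 1%", {
  m <- simulate_micrograph(4, n_px = 512, snr = 0.5, seed = 1)
  lat <- find_lattice(m)
  raw <- attr(measure_spacings(lat), "raw")
  expect_lt(abs(raw["a"] - 4.5) / 4.5, 0.01)
  expect_lt(abs(raw["c"] - 18.2) / 18.2, 0.01)
  # indexed peaks land within half a pixel of their predictions
  dqx <- 1 / (lat$nx * lat$pixel_size); dqy <- 1 / (lat$ny * lat$pixel_size)
  pred <- as.matrix(lat$peaks[, c("h", "k")]) %*% rbind(lat$g_a, lat$g_c)
  res <- sqrt(((lat$peaks$qx - pred[, 1]) / dqx)^2 +
                ((lat$peaks$qy - pred[, 2]) / dqy)^2)
  expect_true(all(res < 0.75))
})

test_that("pure noise is unindexable", {
  set.seed(3)
  m <- micrograph(matrix(rnorm(256^2), 256, 256), 0.5)
  expect_error(find_lattice(m), "unindexable")
})

test_that("a square lattice reports equal spacings with a stable tie-break", {
  # delta lattice with a = c = 8 Angstrom
  img <- matrix(0, 256, 256)
  at <- seq(8, 248, by = 16)  # 8 A at 0.5 A/px
  img[at, at] <- 1
  img <- Re(ifft2p(fft2p(img) *
                     fft2p(gauss_kernel256())))
  lat <- find_lattice(micrograph(img, 0.5))
  sp <- measure_spacings(lat)
  expect_equal(unname(sp["a"]), unname(sp["c"]))
  # a assigned to the basis vector closer to the +x axis
  expect_lt(abs(atan2(lat$g_a[2], lat$g_a[1])),
            abs(atan2(lat$g_c[2], lat$g_c[1])) + 1e-9)
})

test_that("measured spacings are pixel-size invariant", {
  p <- sheet_preset(1)
  m1 <- simulate_micrograph(p, n_px = 512, pixel_size = 0.5, snr = Inf,
                            seed = 1)
  m2 <- simulate_micrograph(p, n_px = 512, pixel_size = 0.7, snr = Inf,
                            seed = 1)
  r1 <- attr(measure_spacings(find_lattice(m1)), "raw")
  r2 <- attr(measure_spacings(find_lattice(m2)), "raw")
  expect_equal(unname(r1["c"]), unname(r2["c"]), tolerance = 0.005)
  expect_equal(unname(r1["a"]), unname(r2["a"]), tolerance = 0.005)
})

test_that("powder peak arithmetic follows d = c/l and d = a/h", {
  pk <- predict_powder_peaks(4.5, 18.4, max_order = 3)
  expect_equal(pk$d_A[pk$hkl == "(001)"], 18.4)
  expect_equal(pk$d_A[pk$hkl == "(002)"], 9.2)
  expect_equal(pk$d_A[pk$hkl == "(003)"], 6.1)
  expect_equal(pk$d_A[pk$hkl == "(300)"], 1.5)
  expect_equal(pk$q_invA, 2 * pi / c(18.4 / 1:3, 4.5 / 1:3),
               tolerance = 1e-9)
})

test_that("random rectangular lattices are recovered within 1%", {
  set.seed(17)
  ok <- 0L; n_trials <- 12L
  for (t in seq_len(n_trials)) {
    a <- runif(1, 4, 5); cc <- runif(1, 15, 20)
    p <- custom_sheet(a = a, c = cc)
    m <- simulate_micrograph(p, n_px = 512, snr = 0.5, seed = t)
    raw <- tryCatch(attr(measure_spacings(find_lattice(m)), "raw"),
                    error = function(e) c(a = NA, c = NA))
    if (!anyNA(raw) && abs(raw["a"] - a) / a < 0.01 &&
        abs(raw["c"] - cc) / cc < 0.01)
      ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.95)
})

test_that("rotating the micrograph rotates the basis, not the spacings", {
  m <- sheet1_noiseless_512()
  lat0 <- find_lattice(m)
  mr <- micrograph(rotate_image(m$pixels, 20), m$pixel_size)
  latr <- find_lattice(mr)
  r0 <- attr(measure_spacings(lat0), "raw")
  rr <- attr(measure_spacings(latr), "raw")
  expect_lt(abs(rr["a"] - r0["a"]) / r0["a"], 0.005)
  expect_lt(abs(rr["c"] - r0["c"]) / r0["c"], 0.005)
  ang <- function(g) atan2(g[2], g[1]) * 180 / pi
  dth <- (ang(latr$g_c) - ang(lat0$g_c)) %% 90
  expect_lt(min(dth, 90 - dth, abs(dth - 20), abs(dth - 70)), 1.5)
})
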