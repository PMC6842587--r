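# Projection rendering, lattice distortion, noise and MRC I/O.

test_that("a single atom renders as a centred Gaussian with Z-scaled mass", {
  m1 <- render_projection(atom_model("C", 0, 0, 0), pixel_size = 0.5,
                          box_shape = c(64, 64))
  w <- which(m1$pixels == max(m1$pixels), arr.ind = TRUE)
  expect_equal(as.numeric(w), c(32, 32), tolerance = 1.01)
  m2 <- render_projection(atom_model("O", 0, 0, 0), pixel_size = 0.5,
                          box_shape = c(64, 64))
  expect_equal(sum(m2$pixels) / sum(m1$pixels), 8 / 6, tolerance = 1e-6)
})

test_that("superposed heavy-atom columns add linearly", {
  br1 <- render_projection(atom_model("Br", 0, 0, 0), 0.5, c(64, 64))
  br3 <- render_projection(atom_model(rep("Br", 3), rep(0, 3), rep(0, 3),
                                      c(-3, 0, 3)), 0.5, c(64, 64))
  expect_equal(max(br3$pixels) / max(br1$pixels), 3, tolerance = 1e-6)
  c1 <- render_projection(atom_model("C", 0, 0, 0), 0.5, c(64, 64))
  expect_equal(max(br3$pixels) / max(c1$pixels), 3 * 35 / 6,
               tolerance = 1e-6)
})

test_that("rendering is linear in the model", {
  a <- atom_model(c("C", "N"), c(-3, 2), c(1, -2), c(0, 0))
  b <- atom_model(c("Br", "O"), c(4, -1), c(-4, 3), c(0, 0))
  ab <- atom_model(c(a$element, b$element), c(a$x, b$x), c(a$y, b$y),
                   c(a$z, b$z))
  org <- c(-16, -16)
  r <- function(m) render_projection(m, 0.5, c(64, 64), origin = org)$pixels
  expect_equal(r(ab), r(a) + r(b), tolerance = 1e-9)
})

test_that("a model larger than the box is rejected with the needed size", {
  m <- atom_model(c("C", "C"), c(0, 100), c(0, 0), c(0, 0))
  expect_error(render_projection(m, 0.5, c(32, 32)), "at least")
  expect_silent(render_projection(m, 0.5, c(32, 32), origin = c(-8, -8),
                                  clip = TRUE))
})

test_that("the brightest columns of a Br sheet sit at the para tips", {
  m <- sheet4_noiseless_512()
  tips <- attr(v_motif_model(tip_elements = c("Br", "Br")),
               "provenance")$tips
  w <- which(m$pixels == max(m$pixels), arr.ind = TRUE)[1, ]
  prov <- m$provenance
  # distance from the global maximum to the nearest generator tip site
  pos_A <- (as.numeric(w) - 0.5) * 0.5
  p4 <- sheet_preset(4)
  g <- (180 - p4$v_dihedral) / 2 * pi / 180
  L <- (p4$c - 2 * vdw_radius("Br")) / (2 * cos(g))
  tip_x <- outer(prov$node_x_A, c(-1, 1) * L * sin(g), "+")
  tip_y <- outer(prov$node_y_A, c(-1, 1) * L * cos(g), "+")
  dx <- min(abs(outer(as.numeric(tip_x), pos_A[1], "-")))
  dy <- min(abs(outer(as.numeric(tip_y), pos_A[2], "-")))
  expect_lt(dx, 1); expect_lt(dy, 1)
})

test_that("a zero-amplitude distortion is the identity", {
  m <- sheet1_noiseless_512()
  out <- apply_distortion(m, distortion_field("constant",
                                              amplitude = c(0, 0)))
  expect_equal(out$pixels, m$pixels, tolerance = 1e-12)
})

test_that("a uniform shift translates the image", {
  m <- sheet1_noiseless_512()
  out <- apply_distortion(m, distortion_field("constant",
                                              amplitude = c(3, 0)))
  # out(p) = in(p + (3,0)): interior pixels shifted by -3 along x
  expect_equal(out$pixels[10:200, 10:200], m$pixels[13:203, 10:200],
               tolerance = 1e-9)
  # cross-correlation peak of out against in sits at -3 along x
  X <- fft2p(out$pixels); Y <- fft2p(m$pixels)
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE))
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- as.numeric(w) - 1
  sh <- ifelse(sh > dim(cc) / 2, sh - dim(cc), sh)
  expect_equal(sh, c(-3, 0))
})

test_that("sinusoidal bending depresses the lattice reflections", {
  m <- sheet1_noiseless_512()
  lat <- find_lattice(m)
  fld <- distortion_field("sinusoid", amplitude = c(2, 0),
                          period = c(200, 200))
  md <- apply_distortion(m, fld)
  expect_gt(md$n_outside, 0)
  p0 <- indexed_peak_power(m, lat, pad = 1)
  p1 <- indexed_peak_power(md, lat, pad = 1)
  a_star <- abs(lat$peaks$h) >= 1
  expect_lt(sum(p1[a_star]), sum(p0[a_star]))
})

test_that("noise honours the target SNR, the seed and the noiseless limit", {
  m <- micrograph(matrix(sin(outer(1:256, 1:256, "+") / 5), 256, 256), 0.5)
  n1 <- add_noise(m, snr = 0.5, seed = 7)
  n2 <- add_noise(m, snr = 0.5, seed = 7)
  expect_identical(n1$pixels, n2$pixels)
  v_target <- stats::var(as.numeric(m$pixels)) / 0.5
  v_obs <- stats::var(as.numeric(n1$pixels - m$pixels))
  expect_lt(abs(v_obs - v_target) / v_target, 0.05)
  n_inf <- add_noise(m, snr = 1e12, seed = 1)
  expect_lt(max(abs(n_inf$pixels - m$pixels)),
            1e-3 * diff(range(m$pixels)))
})

test_that("the transform conserves total power", {
  m <- sheet1_noiseless_512()$pixels[1:128, 1:128]
  F <- stats::fft(m)
  back <- Re(stats::fft(F, inverse = TRUE)) / length(m)
  expect_lt(max(abs(back - m)) / max(abs(m)), 1e-6)
  expect_equal(sum(Mod(F)^2) / length(m), sum(m^2), tolerance = 1e-6)
})

test_that("MRC files round-trip bit-exactly at float precision", {
  m <- micrograph(matrix(0, 64, 64), 0.5)
  path <- tempfile(fileext = ".mrc")
  write_mrc(m, path)
  back <- read_mrc(path)
  expect_identical(back$pixels, m$pixels)
  expect_equal(back$pixel_size, 0.5)

  m2 <- sheet1_noiseless_512()
  m2$pixels <- m2$pixels[1:128, 1:96]
  write_mrc(m2, path)
  back2 <- read_mrc(path)
  expect_equal(back2$pixels, m2$pixels,
               tolerance = 1e-6 * max(abs(m2$pixels)))
  expect_equal(back2$pixel_size, m2$pixel_size, tolerance = 1e-6)
})

test_that("int16 reads convert with a warning; unknown modes error", {
  path <- tempfile(fileext = ".mrc")
  m <- micrograph(matrix(seq_len(64 * 64) %% 100, 64, 64), 1)
  write_mrc(m, path)
  # rewrite the mode word and payload as int16
  con <- file(path, "r+b")
  seek(con, 12, rw = "write")
  writeBin(1L, con, size = 4, endian = "little")
  seek(con, 1024, rw = "write")
  writeBin(as.integer(m$pixels), con, size = 2, endian = "little")
  close(con)
  expect_warning(b <- read_mrc(path), "mode 1")
  expect_equal(b$pixels, m$pixels)
  con <- file(path, "r+b")
  seek(con, 12, rw = "write")
  writeBin(4L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(path), "mode 4")
})
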