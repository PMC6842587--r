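# Crystal unbending: reference construction, lattice tracking,
# displacement-field fitting and resampling.

# the smooth distortion used across these tests: a degree-2 polynomial
# field with several-pixel displacements, inside the fitted model class
test_field <- function(scale = 1) {
  distortion_field("polynomial", degree = 2L,
                   coef_x = scale * c(-2, 0.004, 0.018, 0.5e-5, -1.2e-5, -3.2e-5),
                   coef_y = scale * c(1.5, -0.012, 0.006, 1.2e-5, 0.8e-5, -0.8e-5))
}

test_that("the Fourier-filtered reference matches a true unit cell", {
  m <- sheet1_noiseless_512()
  lat <- find_lattice(m, min_rel_height = 1e-6)
  ref <- make_reference(m, lat)
  expect_gte(attr(ref, "peak_power_fraction"), 0.9)
  # correlate against direct crops at lattice nodes of the raw image
  prov <- m$provenance
  bx <- dim(ref)
  cors <- c()
  for (k in 5:8) {
    x0 <- round(prov$node_x_A[40] / 0.5 + 0.5)
    y0 <- round(prov$node_y_A[k] / 0.5 + 0.5)
    if (y0 < 40 || y0 > 470) next
    crop <- m$pixels[(x0 - floor(bx[1] / 2)) + seq_len(bx[1]) - 1,
                     (y0 - floor(bx[2] / 2)) + seq_len(bx[2]) - 1]
    # best circular alignment of crop vs reference
    cc <- Re(stats::fft(stats::fft(crop - mean(crop)) *
                          Conj(stats::fft(ref - mean(ref))),
                        inverse = TRUE))
    cors <- c(cors, max(cc) / (length(crop) * sd(crop) * sd(ref)) *
                length(crop) / (length(crop) - 1))
  }
  expect_gt(max(cors), 0.99)
})

test_that("a DC-only filter yields a constant patch", {
  m <- sheet1_noiseless_512()
  lat <- find_lattice(m)
  lat$peaks <- lat$peaks[0, ]
  ref <- make_reference(m, lat)
  expect_lt(diff(range(ref)) / max(abs(ref)), 1e-6)
})

test_that("tracking a perfect lattice reports sub-half-pixel displacements", {
  m <- sheet1_noiseless_512()
  lat <- find_lattice(m)
  cells <- track_cells(m, lat, make_reference(m, lat))
  cc <- cells[cells$matched, ]
  expect_gt(mean(cells$matched), 0.95)
  expect_true(all(abs(c(cc$dx, cc$dy)) < 0.5))
})

test_that("tracked displacements reproduce a smooth synthetic field", {
  m <- sheet1_noiseless_512()
  fld <- distortion_field("sinusoid", amplitude = c(4, 0),
                          period = c(300, 300))
  md <- apply_distortion(m, fld, interp = "bicubic")
  lat <- find_lattice(md)
  cells <- track_cells(md, lat, make_reference(md, lat))
  cc <- cells[cells$matched, ]
  d <- field_displacement(fld, cc$x_pred, cc$y_pred)
  # displacements follow -field up to the affine part absorbed by the
  # average-lattice refit
  res <- stats::lm(cbind(cc$dx + d$dx, cc$dy + d$dy) ~ cc$x_pred + cc$y_pred)
  expect_lt(sqrt(mean(stats::residuals(res)^2)), 0.5)
})

test_that("unbending with a zero displacement table is the exact identity", {
  m <- sheet1_noiseless_512()
  cells <- data.frame(i = rep(1:4, 4), j = rep(1:4, each = 4),
                      x_pred = rep(c(50, 150, 250, 350), 4),
                      y_pred = rep(c(80, 200, 320, 440), each = 4))
  cells$x_obs <- cells$x_pred; cells$y_obs <- cells$y_pred
  cells$dx <- 0; cells$dy <- 0; cells$score <- 1; cells$matched <- TRUE
  out <- unbend_image(m, cells)
  expect_equal(out$pixels, m$pixels, tolerance = 1e-12)
})

test_that("unbending restores distorted reflections", {
  m <- sheet1_noiseless_512()
  lat_c <- find_lattice(m)
  own_power <- function(mm) {
    l <- find_lattice(mm)
    p <- indexed_peak_power(mm, l, pad = 1)
    c(total = sum(p), hires = sum(p[l$peaks$d_A < 4]))
  }
  pc <- own_power(m)
  md <- apply_distortion(m, test_field(2.2), interp = "bicubic")
  lat_d <- find_lattice(md)
  cells <- track_cells(md, lat_d, make_reference(md, lat_d))
  mu <- unbend_image(md, cells)
  pd <- own_power(md); pu <- own_power(mu)
  expect_lt(pd["hires"] / pc["hires"], 0.95)   # the distortion really hurt
  expect_gte(pu["hires"] / pc["hires"], 0.9)   # and unbending restored it
  expect_gt(pu["hires"], pd["hires"])
  # measured spacings recover the generator values
  sp <- measure_spacings(find_lattice(mu))
  expect_equal(unname(sp["a"]), 4.5, tolerance = 0.100001)
  expect_equal(unname(sp["c"]), 16.2, tolerance = 0.100001)
})

test_that("unbending never degrades the indexed power and is idempotent", {
  m <- sheet4_noiseless_512()
  for (sc in c(0, 1.5)) {
    md <- if (sc == 0) m else
      apply_distortion(m, test_field(sc), interp = "bicubic")
    lat_d <- find_lattice(md)
    cells <- track_cells(md, lat_d, make_reference(md, lat_d))
    mu <- unbend_image(md, cells)
    p_before <- indexed_peak_power(md, lat_d, pad = 1)
    lat_u <- find_lattice(mu)
    p_after <- indexed_peak_power(mu, lat_u, pad = 1)
    expect_gte(sum(p_after), 0.95 * sum(p_before))
    # second pass changes the indexed power by less than 2%
    cells2 <- track_cells(mu, lat_u, make_reference(mu, lat_u))
    mu2 <- unbend_image(mu, cells2)
    p_again <- indexed_peak_power(mu2, find_lattice(mu2), pad = 1)
    expect_lt(abs(sum(p_again) - sum(p_after)) / sum(p_after), 0.02)
  }
})

test_that("losing the lattice is reported, not silently tolerated", {
  set.seed(9)
  m <- micrograph(matrix(rnorm(256^2), 256, 256), 0.5)
  lat <- find_lattice(sheet1_noiseless_512())
  ref <- matrix(rnorm(9 * 32), 9, 32)
  expect_error(track_cells(m, lat, ref, min_score = 0.9), "lattice lost")
})
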