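# V-dihedral fitting and heavy-atom column location on class averages.

test_that("the drawn V dihedral is recovered from clean cell averages", {
  for (id in c(1, 4, 7, 9)) {
    v <- fit_v_shape(reference_motif(id))
    expect_lt(abs(v$dihedral_raw - 104), 2.5)
    expect_false(v$degenerate)
  }
})

test_that("a straight line is reported as a degenerate 180-degree V", {
  mot <- atom_model(rep("C", 41), rep(0, 41), seq(-10, 10, by = 0.5),
                    rep(0, 41))
  img <- render_projection(mot, 0.5, c(56, 56))
  v <- fit_v_shape(img$pixels)
  expect_true(v$degenerate)
  expect_gt(v$dihedral_raw, 176)
})

test_that("random V angles are recovered within 3 degrees after averaging", {
  set.seed(41)
  angles <- runif(10, 60, 150)
  errs <- vapply(angles, function(vd) {
    g <- (180 - vd) / 2 * pi / 180
    mot <- v_motif_model(v_dihedral = vd,
                         arm_length = max(6.5, 13 / cos(g)),
                         arm_sites = 18L)
    img <- render_projection(mot, 0.5, c(128, 128),
                             origin = c(-32, -32), clip = TRUE)
    B <- noisy_box_stack(img$pixels, 100, snr = 1,
                         seed = round(vd * 10))
    avg <- matrix(colMeans(B), 128, 128)
    abs(fit_v_shape(avg)$dihedral_raw - vd)
  }, numeric(1))
  expect_lt(max(errs), 3)
})

test_that("the fitted V is rotation-equivariant", {
  # the same in-lattice row rendered at a 30-degree lattice orientation
  mot <- peptoidsheet:::preset_motif(sheet_preset(1))
  d <- do.call(rbind, lapply(-3:3, function(k) {
    a <- as.data.frame(mot); a$x <- a$x + k * 4.5; a
  }))
  img <- render_projection(atom_model(d$element, d$x, d$y, d$z), 0.5,
                           c(72, 72), origin = c(-18, -18),
                           clip = TRUE)$pixels
  v0 <- fit_v_shape(img, a_px = 9)
  th <- 30 * pi / 180
  xr <- cos(th) * d$x - sin(th) * d$y
  yr <- sin(th) * d$x + cos(th) * d$y
  imgr <- render_projection(atom_model(d$element, xr, yr, d$z), 0.5,
                            c(72, 72), origin = c(-18, -18),
                            clip = TRUE)$pixels
  vr <- fit_v_shape(imgr, a_px = 9)
  # one internal resampling (the de-rotation) costs up to ~2 degrees
  expect_lt(abs(vr$dihedral_raw - v0$dihedral_raw), 2)
  ang <- function(u) atan2(u[2], u[1]) * 180 / pi
  # arm vectors rotate with the lattice (modulo up/down arm pairing)
  rot_errs <- abs(((c(ang(vr$arm1) - ang(v0$arm1),
                      ang(vr$arm2) - ang(v0$arm2)) - 30 + 180) %% 360) - 180)
  expect_lt(min(rot_errs), 3)
})

test_that("heavy-atom tips are located only where heavy tips exist", {
  h4 <- locate_heavy_columns(reference_motif(4))
  expect_true(h4$found)
  expect_equal(nrow(h4$peaks), 2L)  # both arms Br-tipped
  h9 <- locate_heavy_columns(reference_motif(9))
  expect_equal(nrow(h9$peaks), 1L)  # one Br-bearing arm per chain
  h1 <- locate_heavy_columns(reference_motif(1))
  expect_false(h1$found)
  expect_equal(nrow(h1$peaks), 0L)
})

test_that("tip-to-tip contact across the c interface measures 2 r_vdw(Br)", {
  p4 <- sheet_preset(4)
  mot <- peptoidsheet:::preset_motif(sheet_preset(4))
  g <- (180 - p4$v_dihedral) / 2 * pi / 180
  L <- attr(mot, "provenance")$arm_length
  delta <- (2 * L * sin(g)) %% p4$a
  up <- do.call(rbind, lapply(-3:3, function(k) {
    a <- as.data.frame(mot); a$x <- a$x + k * p4$a; a
  }))
  dn <- do.call(rbind, lapply(-3:3, function(k) {
    a <- as.data.frame(transform_model(mot, angle_deg = 180))
    a$x <- a$x + k * p4$a + delta; a$y <- a$y + p4$c; a
  }))
  d <- rbind(up, dn)
  mdl <- atom_model(d$element, d$x, d$y, rep(0, nrow(d)))
  bx <- c(40, 2 * round(p4$c / 0.5))
  img <- render_projection(mdl, 0.5, bx,
                           origin = c(-bx[1] * 0.25, -bx[2] * 0.25),
                           clip = TRUE)
  hp <- locate_heavy_columns(img$pixels, 0.5, c_spacing = p4$c)
  expect_equal(hp$tip_to_tip_A, 2 * vdw_radius("Br"), tolerance = 0.5)
})

test_that("tip peak height scales with the number of superposed atoms", {
  # a 3-atom and a 1-atom Br column in one frame, off the apex ridge
  mdl <- atom_model(rep("Br", 4), c(-6, -6, -6, 6), c(5, 5, 5, 5),
                    c(-3, 0, 3, 0))
  img <- render_projection(mdl, 0.5, c(64, 64), origin = c(-16, -16))
  h <- locate_heavy_columns(img$pixels, threshold = 0.2)
  expect_equal(nrow(h$peaks), 2L)
  hs <- h$peaks$height[order(h$peaks$x_A)]
  expect_equal(hs[1] / hs[2], 3, tolerance = 0.02)
})
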