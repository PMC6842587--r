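# Unit-cell boxing, correlation k-means classification, class averages,
# packing fractions and distribution maps.

test_that("boxing keeps one normalised box per interior matched node", {
  m <- sheet1_noiseless_512()
  lat <- find_lattice(m)
  cells <- track_cells(m, lat, make_reference(m, lat))
  st <- extract_boxes(m, cells, c(9, 32))
  expect_equal(nrow(st$boxes) + st$n_dropped, sum(cells$matched))
  expect_lt(max(abs(rowMeans(st$boxes))), 1e-9)
  vars <- apply(st$boxes, 1, stats::var)
  expect_true(all(abs(vars - 1) < 1e-6))

  # a box at an integer-centred node equals the direct crop, normalised
  cells_one <- cells[cells$matched, ][1, ]
  cells_one$x_obs <- round(cells_one$x_obs)
  cells_one$y_obs <- round(cells_one$y_obs)
  st1 <- extract_boxes(m, cells_one, c(9, 31))
  crop <- m$pixels[cells_one$x_obs + (-4:4), cells_one$y_obs + (-15:15)]
  crop <- (crop - mean(crop)) / stats::sd(crop)
  expect_equal(matrix(st1$boxes[1, ], 9, 31), crop, tolerance = 1e-9)
})

test_that("stacks of a single motif classify as one fully parallel class", {
  st <- simulate_cell_stack(1, n_rows = 10, n_cols = 10, snr = 2, seed = 4)
  cen <- classify_motifs(st, k = 2, seed = 1,
                         reference = reference_motif(1))
  expect_equal(unname(cen$fractions["parallel"]), 100)
  expect_equal(sum(cen$class_counts > 0), 2L)  # reseeded class keeps 1 box
  expect_true(all(cen$opening == cen$opening[1]))
})

test_that("class averages beat single boxes by roughly sqrt(n) in SNR", {
  clean <- reference_motif(1)
  B <- noisy_box_stack(clean, 100, snr = 1, seed = 8)
  avg <- colMeans(B)
  expect_gt(stats::cor(avg, as.numeric(clean)), 0.99)
  cl_n <- (as.numeric(clean) - mean(clean)) / stats::sd(clean)
  snr_of <- function(v) {
    beta <- sum(v * cl_n) / sum(cl_n^2)
    stats::var(beta * cl_n) / stats::var(v - beta * cl_n)
  }
  gain <- snr_of(avg) / snr_of(B[1, ])
  expect_gt(gain, 100 / 2)
  expect_lt(gain, 100 * 2)
})

test_that("two distinct motifs separate into self-matching averages", {
  up <- reference_motif(1)
  dn <- matrix(rev(as.numeric(up)), nrow(up), ncol(up))  # 180-deg rotation
  B <- rbind(noisy_box_stack(up, 40, 1, seed = 21),
             noisy_box_stack(dn, 40, 1, seed = 22))
  st <- structure(list(boxes = B, box_shape = dim(up),
                       pos = data.frame(i = rep(1:8, 10),
                                        j = rep(1:10, each = 8)),
                       pixel_size = 0.5),
                  class = "unitcell_stack")
  avg <- class_average(st, rep(1:2, each = 40))
  expect_gt(stats::cor(as.numeric(avg$class_1), as.numeric(up)),
            stats::cor(as.numeric(avg$class_1), as.numeric(dn)))
  expect_gt(stats::cor(as.numeric(avg$class_2), as.numeric(dn)),
            stats::cor(as.numeric(avg$class_2), as.numeric(up)))
  expect_equal(attr(avg, "n"), c(40L, 40L))
  one <- class_average(st, c(1L, rep(2L, 79)))
  expect_equal(as.numeric(one$class_1), B[1, ], tolerance = 1e-12)
})

test_that("mixture fractions are recovered and are label-permutation safe", {
  st <- simulate_cell_stack(7, n_rows = 26, n_cols = 10, snr = 1, seed = 5)
  cen <- classify_motifs(st, k = 4, seed = 1,
                         reference = reference_motif(7))
  expect_equal(unname(cen$fractions["antiparallel"]), 60, tolerance = 3)
  # fractions come from openings + positions, not class indices
  cen2 <- cen
  perm <- c(3L, 1L, 4L, 2L)
  cen2$class <- perm[cen$class]
  expect_equal(motif_fractions(cen2), cen$fractions)
})

test_that("fractions are stable across classification seeds", {
  st <- simulate_cell_stack(7, n_rows = 16, n_cols = 8, snr = 1, seed = 2)
  fr <- vapply(1:10, function(s)
    classify_motifs(st, k = 4, seed = s,
                    reference = reference_motif(7))$fractions["antiparallel"],
    numeric(1))
  expect_true(all(fr == fr[1]))
})

test_that("k-means matches the exhaustive best partition on small stacks", {
  up <- reference_motif(1)
  dn <- matrix(rev(as.numeric(up)), nrow(up), ncol(up))
  set.seed(33)
  n_ok <- 0L; n_trials <- 40L
  for (t in seq_len(n_trials)) {
    n_up <- sample(2:6, 1)
    B <- rbind(noisy_box_stack(up, n_up, 1, seed = 100 + t),
               noisy_box_stack(dn, 8 - n_up, 1, seed = 200 + t))
    st <- structure(list(boxes = B, box_shape = dim(up),
                         pos = data.frame(i = 1:8, j = rep(1, 8)),
                         pixel_size = 0.5),
                    class = "unitcell_stack")
    cen <- classify_motifs(st, k = 2, seed = t, reference = up)
    # exhaustive: best 2-partition by summed member-to-mean correlation
    best_obj <- -Inf; best_assign <- NULL
    for (mask in 1:(2^7 - 1)) {
      lab <- c(1L, as.integer(intToBits(mask))[1:7] + 1L)
      if (length(unique(lab)) < 2) next
      obj <- 0
      for (cl in 1:2) {
        mu <- colMeans(B[lab == cl, , drop = FALSE])
        obj <- obj + sum(stats::cor(t(B[lab == cl, , drop = FALSE]), mu))
      }
      if (obj > best_obj) { best_obj <- obj; best_assign <- lab }
    }
    same <- identical(cen$class, best_assign) ||
      identical(cen$class, 3L - best_assign)
    if (same) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_trials, 0.95)
})

test_that("distribution maps report directional flip statistics", {
  # all parallel: uniform map, zero flip fractions
  st <- simulate_cell_stack(1, n_rows = 8, n_cols = 8, snr = 2, seed = 6)
  cen <- classify_motifs(st, k = 2, seed = 1,
                         reference = reference_motif(1))
  dm <- distribution_map(cen)
  expect_equal(dm$flip_frac_c, 0)
  expect_equal(dm$flip_frac_a, 0)

  # random 50/50 labels: both flip fractions near one half
  set.seed(12)
  n <- 30
  cen_r <- cen
  cen_r$pos <- expand.grid(i = 1:n, j = 1:n)
  cen_r$opening <- sample(c("up", "down"), n^2, replace = TRUE)
  cen_r$junk <- rep(FALSE, n^2)
  dm_r <- distribution_map(cen_r)
  expect_lt(abs(dm_r$flip_frac_c - 0.5), 0.05)
  expect_lt(abs(dm_r$flip_frac_a - 0.5), 0.05)

  # whole-row flips only: heterogeneity concentrated along c
  st7 <- simulate_cell_stack(7, n_rows = 16, n_cols = 12, snr = 1,
                             seed = 9, mode = "row")
  cen7 <- classify_motifs(st7, k = 4, seed = 1,
                          reference = reference_motif(7))
  dm7 <- distribution_map(cen7)
  expect_gt(dm7$flip_frac_c, dm7$flip_frac_a)
  expect_equal(dm7$flip_frac_a, 0, tolerance = 0.02)
})
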