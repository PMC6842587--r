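# Unit-cell boxing, correlation k-means motif classification, class
# averaging, packing fractions and distribution maps.

#' Extract unit-cell boxes from a micrograph
#'
#' Cuts one box per matched lattice node, recentred to sub-pixel node
#' positions by bilinear interpolation, and normalises every box to zero
#' mean and unit variance.  Boxes overlapping the image edge are dropped
#' (count in `n_dropped`).
#'
#' @param m A [micrograph()] (normally unbent).
#' @param cells A `cell_positions` table from [track_cells()].
#' @param box_shape Integer `(nx, ny)` box dimensions in pixels.
#' @return A `unitcell_stack`: `boxes` (n x npixel matrix, one row per
#'   box), `box_shape`, `pos` (lattice indices i = a column, j = c row),
#'   `pixel_size`, `n_dropped`.
#' @export
extract_boxes <- function(m, cells, box_shape) {
  stopifnot(inherits(m, "micrograph"))
  cells <- cells[cells$matched, , drop = FALSE]
  if (nrow(cells) == 0) stop("no matched cells to box")
  bx <- as.integer(box_shape[1]); by <- as.integer(box_shape[2])
  nx <- nrow(m$pixels); ny <- ncol(m$pixels)
  offx <- seq_len(bx) - (bx + 1) / 2
  offy <- seq_len(by) - (by + 1) / 2
  gx <- rep(offx, by); gy <- rep(offy, each = bx)
  keep <- logical(nrow(cells))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    xs <- cells$x_obs[k] + gx
    ys <- cells$y_obs[k] + gy
    if (min(xs) < 1 || max(xs) > nx || min(ys) < 1 || max(ys) > ny) next
    v <- bilinear_sample(m$pixels, xs, ys)
    s <- stats::sd(v)
    if (s == 0) next
    rows[[k]] <- (v - mean(v)) / s
    keep[k] <- TRUE
  }
  structure(list(boxes = do.call(rbind, rows[keep]),
                 box_shape = c(bx, by),
                 pos = data.frame(i = cells$i[keep], j = cells$j[keep]),
                 pixel_size = m$pixel_size,
                 n_dropped = sum(!keep),
                 cell_rows = which(keep)),
            class = "unitcell_stack")
}

#' @export
print.unitcell_stack <- function(x, ...) {
  cat(sprintf("<unitcell_stack> %d boxes of %d x %d px\n",
              nrow(x$boxes), x$box_shape[1], x$box_shape[2]))
  invisible(x)
}

# Mirror a box (given as a vector + shape) across the a axis.
#' @noRd
mirror_box <- function(v, box_shape) {
  as.numeric(matrix(v, box_shape[1], box_shape[2])[, rev(seq_len(box_shape[2]))])
}

# 180-degree in-plane rotation of a box: the appearance of a chain in an
# antiparallel row (rotated about the sheet normal), which both flips the
# V opening along c and reverses the arm tilt along a.
#' @noRd
rot180_box <- function(v, box_shape) {
  as.numeric(matrix(v, box_shape[1],
                    box_shape[2])[rev(seq_len(box_shape[1])),
                                  rev(seq_len(box_shape[2]))])
}

# Row-wise Pearson correlation of box matrix B against columns of M.
#' @noRd
cor_to <- function(B, M) {
  stats::cor(t(B), M)
}

#' Classify unit-cell motifs by correlation k-means
#'
#' Groups boxed unit cells into `k` classes by iterated
#' maximum-Pearson-correlation assignment and arithmetic class-mean
#' updates (seeded random boxes as initial means; empty classes reseeded
#' from the worst-fitting box; at most `max_iter` sweeps).  Each class
#' average is then assigned a V opening direction by whichever of the
#' reference motif and its antiparallel counterpart (the reference
#' rotated 180 degrees in plane, the appearance of a chain in a flipped
#' row) it correlates with more strongly, and every member inherits its
#' class's opening.  Boxes
#' whose best class correlation falls below `junk_threshold` are excluded
#' from orientation counting.
#'
#' Packing labels follow from the openings: a cell packs parallel when the
#' c-adjacent cell in the next row opens the same way, antiparallel when
#' it opens the opposite way (Table-style parallel/antiparallel V
#' percentages are fractions of c-adjacent pairs).
#'
#' @param stack A `unitcell_stack`.
#' @param k Number of classes (default 4: two orientations plus margin for
#'   junk classes).
#' @param seed Integer seed for initial class means.
#' @param reference Reference motif box (matrix or vector) defining the
#'   "up" opening; e.g. [reference_motif()].
#' @param nstart Number of seeded restarts; the run with the highest mean
#'   within-class correlation wins.
#' @param max_iter Maximum assignment sweeps per restart.
#' @param junk_threshold Minimum best-class correlation for a box to count
#'   toward orientation fractions.
#' @return A `motif_census`: per-box `class`, `opening`, `best_cor`,
#'   `junk`; `class_averages` (list of matrices); `class_openings`;
#'   `fractions` (% parallel / % antiparallel over labelled c-adjacent
#'   pairs); `converged`.
#' @export
classify_motifs <- function(stack, k = 4L, seed = 1L, reference,
                            nstart = 5L, max_iter = 50L,
                            junk_threshold = 0.2) {
  stopifnot(inherits(stack, "unitcell_stack"))
  B <- stack$boxes
  n <- nrow(B)
  if (n < k) stop("need at least k boxes (", k, "), got ", n)
  ref <- as.numeric(reference)
  if (length(ref) != ncol(B))
    stop("reference shape does not match box shape")
  ref_m <- rot180_box(ref, stack$box_shape)

  run_once <- function(seed_i) {
    means <- t(B[with_seed(seed_i, sample.int(n, k)), , drop = FALSE])
    labels <- integer(n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      cc <- cor_to(B, means)
      new_labels <- max.col(cc, ties.method = "first")
      best <- cc[cbind(seq_len(n), new_labels)]
      # reseed empty classes from the worst-fitting box
      for (cl in seq_len(k)) {
        if (!any(new_labels == cl)) {
          w <- which.min(best)
          new_labels[w] <- cl
          best[w] <- 1
        }
      }
      if (identical(new_labels, labels)) { converged <- TRUE; break }
      labels <- new_labels
      for (cl in seq_len(k))
        means[, cl] <- colMeans(B[labels == cl, , drop = FALSE])
    }
    cc <- cor_to(B, means)
    best <- cc[cbind(seq_len(n), labels)]
    list(labels = labels, means = means, best = best,
         obj = mean(best), converged = converged)
  }
  runs <- lapply(seq_len(nstart), function(r) run_once(seed + (r - 1L)))
  res <- runs[[which.max(vapply(runs, `[[`, numeric(1), "obj"))]]
  if (!res$converged)
    warning("motif classification did not converge in ", max_iter,
            " iterations")

  class_openings <- vapply(seq_len(k), function(cl) {
    mu <- res$means[, cl]
    if (stats::cor(mu, ref) >= stats::cor(mu, ref_m)) "up" else "down"
  }, character(1))
  opening <- class_openings[res$labels]
  junk <- res$best < junk_threshold
  averages <- lapply(seq_len(k), function(cl)
    matrix(res$means[, cl], stack$box_shape[1], stack$box_shape[2]))
  census <- structure(
    list(class = res$labels, opening = opening, best_cor = res$best,
         junk = junk, class_averages = averages,
         class_openings = class_openings,
         class_counts = tabulate(res$labels, k),
         pos = stack$pos, box_shape = stack$box_shape,
         converged = res$converged),
    class = "motif_census")
  census$fractions <- motif_fractions(census)
  census
}

#' @export
print.motif_census <- function(x, ...) {
  f <- x$fractions
  cat(sprintf(paste0("<motif_census> %d boxes in %d classes ",
                     "(%d junk); %.1f%% parallel / %.1f%% antiparallel\n"),
              length(x$class), length(x$class_counts), sum(x$junk),
              f["parallel"], f["antiparallel"]))
  invisible(x)
}

#' Parallel / antiparallel packing fractions
#'
#' Fractions of c-adjacent unit-cell pairs whose V motifs open the same way
#' (parallel) or opposite ways (antiparallel), over pairs of non-junk
#' cells.  When the census carries no lattice positions the fractions fall
#' back to the opening split itself (degenerate single-row stacks).
#'
#' @param census A `motif_census`.
#' @return Named numeric `c(parallel = , antiparallel = )` in percent,
#'   summing to 100 over labelled pairs.
#' @export
motif_fractions <- function(census) {
  stopifnot(inherits(census, "motif_census"))
  ok <- !census$junk
  pos <- census$pos
  if (!is.null(pos) && length(unique(pos$j)) > 1) {
    key <- paste(pos$i, pos$j)
    idx <- seq_along(census$opening)
    nb <- match(paste(pos$i, pos$j + 1), key)
    have <- !is.na(nb) & ok & ok[ifelse(is.na(nb), 1L, nb)]
    same <- census$opening[idx[have]] == census$opening[nb[have]]
    n_pair <- sum(have)
    if (n_pair == 0) return(c(parallel = NA_real_, antiparallel = NA_real_))
    c(parallel = 100 * sum(same) / n_pair,
      antiparallel = 100 * sum(!same) / n_pair)
  } else {
    n <- sum(ok)
    if (n == 0) return(c(parallel = NA_real_, antiparallel = NA_real_))
    up <- sum(census$opening[ok] == "up")
    maj <- max(up, n - up)
    c(parallel = 100 * maj / n, antiparallel = 100 * (n - maj) / n)
  }
}

#' Class averages of a box stack
#'
#' Arithmetic mean of the member boxes of each label; averaging n noisy
#' copies improves the signal-to-noise ratio by about a factor n in
#' variance (sqrt(n) in amplitude).
#'
#' @param stack A `unitcell_stack`.
#' @param labels Integer class label per box.
#' @return Named list of average matrices (`class_1`, ...), with member
#'   counts in attr `"n"`.
#' @export
class_average <- function(stack, labels) {
  stopifnot(inherits(stack, "unitcell_stack"),
            length(labels) == nrow(stack$boxes))
  cls <- sort(unique(labels))
  out <- lapply(cls, function(cl)
    matrix(colMeans(stack$boxes[labels == cl, , drop = FALSE]),
           stack$box_shape[1], stack$box_shape[2]))
  names(out) <- paste0("class_", cls)
  attr(out, "n") <- as.integer(table(factor(labels, cls)))
  out
}

#' Spatial distribution map of motif orientations
#'
#' Rasterises per-cell opening labels on the lattice-index grid and
#' reports directional flip statistics: the fraction of c-adjacent and of
#' a-adjacent cell pairs whose labels differ.  Chain flips concentrated
#' between rows (the observed mode of packing heterogeneity) give a larger
#' c-direction than a-direction flip fraction.
#'
#' @param census A `motif_census` (with lattice positions).
#' @return A `distribution_map`: `grid` (character matrix of openings, NA
#'   where unlabelled), `flip_frac_c`, `flip_frac_a`.
#' @export
distribution_map <- function(census) {
  stopifnot(inherits(census, "motif_census"))
  pos <- census$pos
  if (is.null(pos)) stop("census has no lattice positions")
  io <- pos$i - min(pos$i) + 1L
  jo <- pos$j - min(pos$j) + 1L
  grid <- matrix(NA_character_, max(io), max(jo))
  lab <- census$opening
  lab[census$junk] <- NA
  grid[cbind(io, jo)] <- lab
  flip_frac <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  }
  ni <- nrow(grid); nj <- ncol(grid)
  fc <- if (nj > 1) flip_frac(grid[, -nj], grid[, -1]) else NA_real_
  fa <- if (ni > 1) flip_frac(grid[-ni, ], grid[-1, ]) else NA_real_
  structure(list(grid = grid, flip_frac_c = fc, flip_frac_a = fa),
            class = "distribution_map")
}

#' @export
print.distribution_map <- function(x, ...) {
  cat(sprintf(paste0("<distribution_map> %d x %d cells; flip fraction ",
                     "c: %.3f, a: %.3f\n"),
              nrow(x$grid), ncol(x$grid), x$flip_frac_c, x$flip_frac_a))
  invisible(x)
}

#' Plot a distribution map
#'
#' @param x A `distribution_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.distribution_map <- function(x, ...) {
  z <- matrix(NA_real_, nrow(x$grid), ncol(x$grid))
  z[x$grid == "up"] <- 1
  z[x$grid == "down"] <- 2
  graphics::image(z = z, col = c("#2166ac", "#b2182b"), axes = FALSE,
                  xlab = "a index", ylab = "c index", ...)
  invisible(x)
}

#' Write census and distribution-map artifacts
#'
#' CSV of the per-box census and (optionally) a PNG of the distribution
#' map (non-authoritative visual aid).
#'
#' @param census A `motif_census`.
#' @param csv_path Census CSV path.
#' @param png_path Optional distribution-map PNG path.
#' @return Invisibly, `csv_path`.
#' @export
write_census <- function(census, csv_path, png_path = NULL) {
  df <- data.frame(i = census$pos$i, j = census$pos$j,
                   class = census$class, opening = census$opening,
                   best_cor = round(census$best_cor, 6),
                   junk = census$junk)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 600, height = 600)
    plot(distribution_map(census))
    grDevices::dev.off()
  }
  invisible(csv_path)
}
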