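# Sheet presets encoding the four characterised nanosheet lattices, plus
# the synthetic micrograph and unit-cell-stack generators built from them.

.PRESETS <- list(
  `1` = list(id = 1L, name = "Nte4-Npe6", a = 4.5, c = 16.2,
             v_dihedral = 104, tip_elements = c("H", "H"),
             frac_antiparallel = 0, chirality_pattern = "uniform",
             hydrophobic_monomers = rep("Npe", 6L)),
  `4` = list(id = 4L, name = "Nte4-N4Brpe6", a = 4.5, c = 18.2,
             v_dihedral = 104, tip_elements = c("Br", "Br"),
             frac_antiparallel = 1, chirality_pattern = "uniform",
             hydrophobic_monomers = rep("N4Brpe", 6L)),
  `7` = list(id = 7L, name = "Nte4-N4mpe6", a = 4.5, c = 18.2,
             v_dihedral = 104, tip_elements = c("C", "C"),
             frac_antiparallel = 0.6, chirality_pattern = "uniform",
             hydrophobic_monomers = rep("N4mpe", 6L)),
  `9` = list(id = 9L, name = "Nte4-(N4BrpeNpe)3", a = 4.5, c = 17.2,
             v_dihedral = 104, tip_elements = c("Br", "H"),
             frac_antiparallel = 0, chirality_pattern = "alternating",
             hydrophobic_monomers = rep(c("N4Brpe", "Npe"), 3L))
)

#' Sheet preset
#'
#' Lattice geometry and packing pattern of the four nanosheets
#' characterised at atomic resolution: the parent phenylethyl sheet 1
#' (c 16.2 Angstrom, all-parallel V packing), the para-bromo sheet 4
#' (c 18.2, all-antiparallel, Br tip columns), the para-methyl sheet 7
#' (c 18.2, mixed 60% antiparallel) and the alternating Br/H-armed sheet 9
#' (c 17.2, all-parallel, racemic row pairing).  All share a = 4.5 Angstrom
#' and a projected V dihedral of ~104 degrees.
#'
#' @param id Sheet number: 1, 4, 7 or 9.
#' @return A list of class `sheet_preset`.
#' @export
sheet_preset <- function(id) {
  p <- .PRESETS[[as.character(id)]]
  if (is.null(p)) stop("unknown sheet preset: ", id,
                       " (available: 1, 4, 7, 9)")
  class(p) <- "sheet_preset"
  p
}

#' Custom sheet geometry
#'
#' A [sheet_preset()]-compatible object with arbitrary lattice
#' parameters, for simulations outside the four characterised sheets
#' (e.g. recovery sweeps over random spacings).
#'
#' @param a,c Lattice spacings, Angstrom (`c > a`).
#' @param v_dihedral Projected V dihedral, degrees.
#' @param tip_elements Length-2 para terminal atoms (+c arm, -c arm).
#' @param frac_antiparallel Fraction of antiparallel row transitions.
#' @param chirality_pattern `"uniform"` or `"alternating"`.
#' @return A `sheet_preset`.
#' @export
custom_sheet <- function(a = 4.5, c = 16.2, v_dihedral = 104,
                         tip_elements = c("H", "H"),
                         frac_antiparallel = 0,
                         chirality_pattern = "uniform") {
  stopifnot(a > 0, c > a, v_dihedral > 0, v_dihedral < 180)
  structure(list(id = NA_integer_, name = "custom", a = a, c = c,
                 v_dihedral = v_dihedral, tip_elements = tip_elements,
                 frac_antiparallel = frac_antiparallel,
                 chirality_pattern = chirality_pattern,
                 hydrophobic_monomers = rep("Npe", 6L)),
            class = "sheet_preset")
}

#' @export
print.sheet_preset <- function(x, ...) {
  cat(sprintf(paste0("<sheet_preset %d> %s: a %.1f A, c %.1f A, ",
                     "%.0f%% antiparallel, tips %s/%s\n"),
              x$id, x$name, x$a, x$c, 100 * x$frac_antiparallel,
              x$tip_elements[1], x$tip_elements[2]))
  invisible(x)
}

# Preset motif: the arm length is set so that para tips of c-adjacent rows
# sit in van der Waals contact (tip-to-tip packing across the row
# interface), the packing the spacings encode.
#' @noRd
preset_motif <- function(preset) {
  g <- deg2rad((180 - preset$v_dihedral) / 2)
  contact <- sum(vdw_radius(preset$tip_elements))
  arm_length <- (preset$c - contact) / (2 * cos(g))
  v_motif_model(v_dihedral = preset$v_dihedral, arm_length = arm_length,
                tip_elements = preset$tip_elements)
}

#' @noRd
preset_chain_spec <- function(preset) {
  chain_spec(preset$hydrophobic_monomers)
}

# Row opening pattern ("up"/"down") with an exact number of antiparallel
# row-to-row transitions: round(frac * (n_rows - 1)) flips placed uniformly
# at random.  "up" means the V opens toward +c.
#' @noRd
row_openings <- function(n_rows, frac_antiparallel, seed = NULL) {
  n_tr <- n_rows - 1L
  n_flip <- round(frac_antiparallel * n_tr)
  flips <- with_seed(seed, {
    f <- rep(FALSE, n_tr)
    if (n_flip > 0) f[sample.int(n_tr, n_flip)] <- TRUE
    f
  })
  op <- cumsum(c(0L, as.integer(flips))) %% 2L
  ifelse(op == 0L, "up", "down")
}

#' Simulate a nanosheet micrograph
#'
#' Renders a full synthetic micrograph of a sheet preset: the V motif is
#' tiled over a rectangular lattice covering the field of view, rows are
#' flipped (180 degrees about the sheet normal through their own nodes)
#' according to the preset's antiparallel transition fraction, and the
#' projection is optionally distorted, CTF-modulated and degraded with
#' Gaussian noise.
#'
#' @param preset A [sheet_preset()] (or a sheet id).
#' @param n_px Image side in pixels (square image).
#' @param pixel_size Angstrom per pixel.
#' @param snr Target signal-to-noise ratio; `Inf` for a noiseless render.
#' @param seed Integer seed controlling the row pattern and the noise.
#' @param distortion Optional [distortion_field()] applied to the clean
#'   projection.
#' @param ctf Optional [ctf_params()] applied after distortion.
#' @return A [micrograph()] whose `provenance` field records the preset,
#'   the lattice node grid (Angstrom), the per-row openings and the seed.
#' @export
simulate_micrograph <- function(preset, n_px = 1024L, pixel_size = 0.5,
                                snr = 0.5, seed = 1L, distortion = NULL,
                                ctf = NULL) {
  if (!inherits(preset, "sheet_preset")) preset <- sheet_preset(preset)
  field_A <- n_px * pixel_size
  motif <- preset_motif(preset)
  # node grid with one-cell margin beyond every edge
  xs <- seq(-preset$a, field_A + preset$a, by = preset$a)
  ys <- seq(-preset$c, field_A + preset$c, by = preset$c)
  openings <- row_openings(length(ys), preset$frac_antiparallel, seed)
  up <- as.data.frame(motif)
  down <- as.data.frame(transform_model(motif, angle_deg = 180))
  per_row <- function(j) {
    tmpl <- if (openings[j] == "up") up else down
    n_at <- nrow(tmpl)
    data.frame(element = rep(tmpl$element, length(xs)),
               x = rep(tmpl$x, length(xs)) + rep(xs, each = n_at),
               y = tmpl$y + ys[j])
  }
  allat <- do.call(rbind, lapply(seq_along(ys), per_row))
  model <- atom_model(allat$element, allat$x, allat$y,
                      z = numeric(nrow(allat)))
  m <- render_projection(model, pixel_size = pixel_size,
                         box_shape = c(n_px, n_px), origin = c(0, 0),
                         clip = TRUE)
  if (!is.null(distortion)) m <- apply_distortion(m, distortion)
  if (!is.null(ctf)) m <- apply_ctf(m, ctf)
  if (is.finite(snr)) m <- add_noise(m, snr, seed = seed + 1L)
  m$provenance <- list(preset = unclass(preset), seed = seed,
                       node_x_A = xs, node_y_A = ys, openings = openings,
                       snr = snr)
  m
}

#' Clean reference motif image
#'
#' Noiseless render of one unit cell of a preset's parallel ("up"-opening)
#' V motif, used as the orientation reference in motif classification.
#'
#' @param preset A [sheet_preset()] (or sheet id).
#' @param pixel_size Angstrom per pixel.
#' @param box_shape Box dimensions in pixels; default one unit cell
#'   `(a, c) / pixel_size`.
#' @param neighbours If `TRUE` (default), include enough a-adjacent chains
#'   of the same row that the box content matches an in-lattice cell.
#' @return A matrix (box) with the apex at the box centre.
#' @export
reference_motif <- function(preset, pixel_size = 0.5, box_shape = NULL,
                            neighbours = TRUE) {
  if (!inherits(preset, "sheet_preset")) preset <- sheet_preset(preset)
  if (is.null(box_shape))
    box_shape <- c(round(preset$a / pixel_size),
                   round(preset$c / pixel_size))
  motif <- preset_motif(preset)
  d <- as.data.frame(motif)
  if (neighbours) {
    half_w <- box_shape[1] * pixel_size / 2
    reach <- max(abs(d$x)) + 2
    n_nb <- ceiling((half_w + reach) / preset$a)
    for (s in setdiff(-n_nb:n_nb, 0)) {
      nb <- as.data.frame(motif)
      nb$x <- nb$x + s * preset$a
      d <- rbind(d, nb)
    }
  }
  model <- atom_model(d$element, d$x, d$y, d$z)
  ctr <- c(box_shape[1] * pixel_size / 2, box_shape[2] * pixel_size / 2)
  m <- render_projection(model, pixel_size = pixel_size,
                         box_shape = box_shape,
                         origin = c(-ctr[1], -ctr[2]), clip = TRUE)
  m$pixels
}

#' Simulate a stack of unit-cell boxes
#'
#' Generates boxed unit cells directly (bypassing the micrograph path) on a
#' lattice-index grid: each cell is the clean V motif opening up or down,
#' with openings following row-wise (whole rows flip between c-neighbours;
#' the observed flip mode) or cell-wise patterns with an exact fraction of
#' antiparallel c-transitions, plus per-box Gaussian noise at the target
#' SNR.  Boxes are normalised to zero mean and unit variance.
#'
#' @param preset A [sheet_preset()] (or sheet id).
#' @param n_rows,n_cols Grid dimensions (c and a directions).
#' @param snr Per-box signal-to-noise ratio; `Inf` for clean boxes.
#' @param seed Integer seed (openings and noise).
#' @param frac_antiparallel Fraction of antiparallel c-transitions; default
#'   the preset's value.
#' @param mode `"row"` (whole-row openings) or `"cell"` (independent
#'   per-column transition patterns).
#' @param pixel_size Angstrom per pixel.
#' @return A `unitcell_stack` (see [extract_boxes()]) whose `provenance`
#'   records the true openings.
#' @export
simulate_cell_stack <- function(preset, n_rows = 10L, n_cols = 20L,
                                snr = 1, seed = 1L,
                                frac_antiparallel = NULL, mode = "row",
                                pixel_size = 0.5) {
  if (!inherits(preset, "sheet_preset")) preset <- sheet_preset(preset)
  if (is.null(frac_antiparallel)) frac_antiparallel <- preset$frac_antiparallel
  ref_up <- reference_motif(preset, pixel_size)
  ref_down <- ref_up[rev(seq_len(nrow(ref_up))), rev(seq_len(ncol(ref_up)))]
  box_px <- dim(ref_up)
  if (mode == "row") {
    row_op <- row_openings(n_rows, frac_antiparallel, seed)
    openings <- matrix(rep(row_op, n_cols), n_rows, n_cols)
  } else {
    openings <- with_seed(seed, {
      vapply(seq_len(n_cols), function(j)
        row_openings(n_rows, frac_antiparallel, seed = NULL),
        character(n_rows))
    })
  }
  n <- n_rows * n_cols
  p <- prod(box_px)
  sd_noise <- if (is.finite(snr))
    sqrt(stats::var(as.numeric(ref_up)) / snr) else 0
  boxes <- with_seed(seed + 1L, {
    B <- matrix(NA_real_, n, p)
    for (k in seq_len(n)) {
      r <- (k - 1) %% n_rows + 1; cl <- (k - 1) %/% n_rows + 1
      base <- if (openings[r, cl] == "up") ref_up else ref_down
      b <- as.numeric(base)
      if (sd_noise > 0) b <- b + stats::rnorm(p, 0, sd_noise)
      B[k, ] <- (b - mean(b)) / stats::sd(b)
    }
    B
  })
  pos <- data.frame(i = rep(seq_len(n_cols), each = n_rows),
                    j = rep(seq_len(n_rows), n_cols))
  structure(list(boxes = boxes, box_shape = box_px, pos = pos,
                 pixel_size = pixel_size,
                 provenance = list(preset = unclass(preset), seed = seed,
                                   openings = as.vector(openings),
                                   frac_antiparallel = frac_antiparallel,
                                   mode = mode)),
            class = "unitcell_stack")
}
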