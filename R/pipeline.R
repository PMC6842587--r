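# End-to-end orchestration: build -> simulate -> process -> report, as
# plain R functions over run-configuration lists.  Every stochastic step
# carries an explicit seed and the configuration is echoed verbatim into
# the output directory, so a run is reproducible from its artifacts.

#' Run configuration for the nanosheet pipeline
#'
#' @param preset Sheet preset id (1, 4, 7, 9) or a [sheet_preset()].
#' @param n_px Simulated micrograph side in pixels.
#' @param pixel_size Angstrom per pixel.
#' @param snr Signal-to-noise ratio of the simulation (`Inf` = noiseless).
#' @param seed Integer master seed.
#' @param defocus Optional numeric vector of defocus values (Angstrom);
#'   when given, `nanosheet_simulate` writes one CTF-modulated micrograph
#'   per defocus and `nanosheet_process` merges them after phase
#'   flipping.
#' @param distortion Optional [distortion_field()].
#' @param k Number of classes for motif classification.
#' @param box_shape Unit-cell box `(nx, ny)` in pixels; default one cell.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(preset = 1, n_px = 1024L, pixel_size = 0.5,
                       snr = 0.5, seed = 1L, defocus = NULL,
                       distortion = NULL, k = 4L, box_shape = NULL,
                       out_dir = tempfile("nanosheet_run_")) {
  if (!inherits(preset, "sheet_preset")) preset <- sheet_preset(preset)
  structure(list(preset = preset, n_px = as.integer(n_px),
                 pixel_size = pixel_size, snr = snr, seed = as.integer(seed),
                 defocus = defocus, distortion = distortion,
                 k = as.integer(k), box_shape = box_shape,
                 out_dir = out_dir),
            class = "run_config")
}

# Circular-shift registration of a (unit-cell periodic) box against the
# apex-centred reference; returns the (dx, dy) pixel shift to add to the
# cell centres.
#' @noRd
box_register <- function(box, reference, box_shape) {
  A <- matrix(as.numeric(box), box_shape[1], box_shape[2])
  R <- matrix(as.numeric(reference), box_shape[1], box_shape[2])
  A <- A - mean(A); R <- R - mean(R)
  cc <- Re(ifft2(fft2(A) * Conj(fft2(R))))
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  sh <- w - 1L
  sh <- ifelse(sh > box_shape / 2, sh - box_shape, sh)
  as.numeric(sh)
}

#' @noRd
echo_config <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  cfg$preset <- unclass(cfg$preset)
  cfg$distortion <- if (is.null(cfg$distortion)) NULL else unclass(cfg$distortion)
  jsonlite::write_json(cfg, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(config$out_dir)
}

#' Build the pseudo-atomic sheet model of a preset
#'
#' Builds the hydrophobic-block chain from its torsion recipe, tiles a
#' 12 x 2 block (12 chains stacked parallel along a; the second row
#' parallel or antiparallel following the preset) and writes a PDB plus
#' a JSON provenance sidecar.
#'
#' @param config A [run_config()].
#' @return Invisibly, the PDB path; the sheet `atom_model` in attr
#'   `"model"`.
#' @export
nanosheet_build <- function(config) {
  echo_config(config)
  preset <- config$preset
  chain <- build_chain(preset_chain_spec(preset))
  lattice <- sheet_lattice(
    a_spacing = preset$a, c_spacing = preset$c, n_a = 12L, n_c = 2L,
    row_orientations = c("parallel",
                         if (preset$frac_antiparallel >= 0.5)
                           "antiparallel" else "parallel"),
    v_dihedral = preset$v_dihedral,
    chirality_pattern = preset$chirality_pattern)
  sheet <- suppressWarnings(build_sheet(chain, lattice))
  path <- file.path(config$out_dir, sprintf("sheet%d_model.pdb", preset$id))
  write_pdb(sheet, path)
  out <- invisible(path)
  attr(out, "model") <- sheet
  out
}

#' Simulate micrographs for a run
#'
#' One synthetic micrograph per defocus value (or a single CTF-free
#' micrograph when the config has none), written as MRC2014.
#'
#' @param config A [run_config()].
#' @return Character vector of MRC paths (attr `"micrographs"` holds the
#'   in-memory list).
#' @export
nanosheet_simulate <- function(config) {
  echo_config(config)
  defoci <- config$defocus
  paths <- character(0)
  mics <- list()
  if (is.null(defoci)) {
    m <- simulate_micrograph(config$preset, n_px = config$n_px,
                             pixel_size = config$pixel_size,
                             snr = config$snr, seed = config$seed,
                             distortion = config$distortion)
    p <- file.path(config$out_dir,
                   sprintf("sheet%d_seed%d.mrc", config$preset$id,
                           config$seed))
    write_mrc(m, p)
    paths <- p; mics <- list(m)
  } else {
    for (i in seq_along(defoci)) {
      ctf <- ctf_params(defoci[i], pixel_size = config$pixel_size)
      m <- simulate_micrograph(config$preset, n_px = config$n_px,
                               pixel_size = config$pixel_size,
                               snr = config$snr,
                               seed = config$seed + (i - 1L) * 101L,
                               distortion = config$distortion, ctf = ctf)
      p <- file.path(config$out_dir,
                     sprintf("sheet%d_seed%d_df%d.mrc", config$preset$id,
                             config$seed, round(defoci[i])))
      write_mrc(m, p)
      paths <- c(paths, p); mics <- c(mics, list(m))
    }
  }
  attr(paths, "micrographs") <- mics
  paths
}

#' Process micrographs into structural observables
#'
#' The full 2D crystallography pipeline: optional CTF phase-flip and
#' multi-defocus merge, power-spectrum indexing, crystal unbending,
#' unit-cell boxing, correlation k-means classification, class
#' averaging, V-dihedral and heavy-atom measurements, and packing
#' fractions.  Artifacts (census CSV, class-average MRC stack,
#' measurement JSON, distribution-map PNG) are written to the run
#' directory.
#'
#' @param micrographs A [micrograph()], list of micrographs, or paths to
#'   MRC files (a defocus series is merged).
#' @param config A [run_config()].
#' @return A `nanosheet_report` list: `a_A`, `c_A`, `dihedral_deg`,
#'   `pct_parallel`, `pct_antiparallel`, `tip_peaks`, `n_cells`,
#'   `flip_frac_c`, `flip_frac_a`, plus the `census` and lattice.
#' @export
nanosheet_process <- function(micrographs, config) {
  echo_config(config)
  if (inherits(micrographs, "micrograph")) micrographs <- list(micrographs)
  if (is.character(micrographs)) micrographs <- lapply(micrographs, read_mrc)
  if (!is.null(config$defocus) && length(micrographs) > 1) {
    params <- lapply(config$defocus,
                     function(df) ctf_params(df, pixel_size = config$pixel_size))
    m <- multi_defocus_merge(micrographs, params)
  } else {
    m <- micrographs[[1]]
    if (!is.null(config$defocus))
      m <- phase_flip(m, ctf_params(config$defocus[1],
                                    pixel_size = config$pixel_size))
  }
  lat <- find_lattice(m)
  ref <- make_reference(m, lat)
  cells <- track_cells(m, lat, ref)
  m_unb <- unbend_image(m, cells)
  lat2 <- find_lattice(m_unb)
  ref2 <- make_reference(m_unb, lat2)
  cells2 <- track_cells(m_unb, lat2, ref2)
  sp <- measure_spacings(lat2)
  box_shape <- config$box_shape %||%
    c(round(config$preset$a / m$pixel_size),
      round(config$preset$c / m$pixel_size))
  stack <- extract_boxes(m_unb, cells2, box_shape)
  refm <- reference_motif(config$preset, pixel_size = m$pixel_size,
                          box_shape = box_shape)
  census <- classify_motifs(stack, k = config$k, seed = config$seed,
                            reference = refm)
  fr <- census$fractions
  # V geometry from the dominant class, recentred on the backbone row:
  # correlation tracking against the Fourier-filtered reference can lock
  # onto the inter-row interface (whose tip pairs can outshine the apex
  # in heavy-tip sheets), so the class average is registered against the
  # apex-centred reference (or its antiparallel counterpart) by circular
  # cross-correlation and those boxes re-extracted at shifted centres
  cls_sizes <- tabulate(census$class[!census$junk], config$k)
  cls_star <- which.max(cls_sizes)
  avg0 <- census$class_averages[[cls_star]]
  ref_dn <- matrix(rot180_box(as.numeric(refm), box_shape),
                   box_shape[1], box_shape[2])
  cand <- unique(rbind(c(0, 0),
                       box_register(avg0, refm, box_shape),
                       box_register(avg0, ref_dn, box_shape),
                       c(0, round(box_shape[2] / 2)),
                       c(0, -round(box_shape[2] / 2))))
  sel <- stack$cell_rows[census$class == cls_star & !census$junk]
  cm0 <- cells2[cells2$matched, , drop = FALSE][sel, , drop = FALSE]
  best <- NULL; best_cor <- -Inf
  for (ci in seq_len(nrow(cand))) {
    cm <- cm0
    cm$x_obs <- cm$x_obs + cand[ci, 1]
    cm$y_obs <- cm$y_obs + cand[ci, 2]
    st <- tryCatch(extract_boxes(m_unb, cm, box_shape),
                   error = function(e) NULL)
    if (is.null(st) || nrow(st$boxes) < 10) next
    av <- matrix(colMeans(st$boxes), box_shape[1], box_shape[2])
    sc <- max(stats::cor(as.numeric(av), as.numeric(refm)),
              stats::cor(as.numeric(av), as.numeric(ref_dn)))
    if (sc > best_cor) { best_cor <- sc; best <- av }
  }
  avg <- best %||% avg0
  vfit <- tryCatch(fit_v_shape(avg, pixel_size = m$pixel_size),
                   error = function(e) NULL)
  tips <- locate_heavy_columns(avg, pixel_size = m$pixel_size)
  dmap <- distribution_map(census)
  report <- list(preset_id = config$preset$id,
                 a_A = unname(sp["a"]), c_A = unname(sp["c"]),
                 dihedral_deg = if (is.null(vfit)) NA_integer_
                 else vfit$dihedral_deg,
                 pct_parallel = unname(fr["parallel"]),
                 pct_antiparallel = unname(fr["antiparallel"]),
                 tip_peaks = nrow(tips$peaks),
                 n_cells = nrow(stack$boxes),
                 flip_frac_c = dmap$flip_frac_c,
                 flip_frac_a = dmap$flip_frac_a,
                 seed = config$seed)
  class(report) <- "nanosheet_report"
  # artifacts
  write_census(census, file.path(config$out_dir, "census.csv"),
               file.path(config$out_dir, "distribution_map.png"))
  avg_stack <- class_average(stack, census$class)
  for (nm in names(avg_stack))
    write_mrc(micrograph(avg_stack[[nm]], m$pixel_size),
              file.path(config$out_dir, paste0(nm, "_avg.mrc")))
  jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                       file.path(config$out_dir, "measurements.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  report$census <- census
  report$lattice <- lat2
  report
}

#' @export
print.nanosheet_report <- function(x, ...) {
  cat(sprintf(paste0("<nanosheet_report> sheet %s: a = %.1f A, c = %.1f A, ",
                     "V = %s deg, %.0f%% parallel / %.0f%% antiparallel ",
                     "(%d cells)\n"),
              x$preset_id, x$a_A, x$c_A,
              ifelse(is.na(x$dihedral_deg), "NA", x$dihedral_deg),
              x$pct_parallel, x$pct_antiparallel, x$n_cells))
  invisible(x)
}

#' Compare a processed run against its preset ground truth
#'
#' @param report A `nanosheet_report` from [nanosheet_process()].
#' @param config The [run_config()] of the run.
#' @return Data frame with measured values, preset values and
#'   differences; also written to `report.json` in the run directory.
#' @export
nanosheet_report <- function(report, config) {
  preset <- config$preset
  truth <- c(a_A = preset$a, c_A = preset$c,
             dihedral_deg = preset$v_dihedral,
             pct_antiparallel = 100 * preset$frac_antiparallel)
  measured <- c(a_A = report$a_A, c_A = report$c_A,
                dihedral_deg = as.numeric(report$dihedral_deg),
                pct_antiparallel = report$pct_antiparallel)
  df <- data.frame(quantity = names(truth), preset = unname(truth),
                   measured = unname(measured),
                   difference = unname(measured - truth))
  jsonlite::write_json(df, file.path(config$out_dir, "report.json"),
                       digits = NA)
  df
}
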