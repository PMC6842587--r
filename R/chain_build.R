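# Pseudo-atomic chain construction from internal coordinates and tiling of
# chains into sheet lattices.

# Backbone internal coordinates (standard peptide values; only the torsions
# are sequence-specific).
.BB <- list(
  b_n_ca = 1.46,  # N-CA bond
  b_ca_c = 1.52,  # CA-C bond
  b_c_n  = 1.33,  # C-N (amide) bond
  a_n_ca_c = 111, # N-CA-C angle
  a_ca_c_n = 114, # CA-C-N angle
  a_c_n_ca = 123  # C-N-CA angle
)

# Coarse 3-site side-chain template measured along the ring axis from the
# amide nitrogen: CB (the first methylene), a ring-centroid proxy carbon and
# the para terminal atom.
.SC <- list(d_cb = 1.47, d_ring = 3.95, d_para = 6.35)

# Natural-extension-reference-frame placement: position atom D given the
# three preceding atoms A-B-C, the C-D bond length, the B-C-D angle (deg)
# and the A-B-C-D torsion (deg).
#' @noRd
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle); phi <- deg2rad(torsion)
  # the sign of the out-of-plane component fixes the handedness so that
  # the A-B-C-D dihedral measured from the coordinates equals `torsion`
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(phi),
          bond * sin(th) * sin(phi))
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a peptoid chain from a torsion recipe
#'
#' Constructs backbone coordinates (N, CA, C per residue) by sequential
#' internal-to-Cartesian placement with all amides cis and (phi, psi)
#' alternating between the two mirror torsion states, then attaches the
#' coarse 3-site side-chain template (CB, ring-centroid proxy, para terminal
#' atom) along the free valence direction of each amide nitrogen.
#' Hydrophilic Nte monomers, amorphous in the sheets, get no side-chain
#' sites.
#'
#' @param spec A [chain_spec()].
#' @return An `atom_model` with one chain; backbone torsions recomputed from
#'   the coordinates match the spec to well under a degree.
#' @export
build_chain <- function(spec) {
  if (!inherits(spec, "chain_spec")) stop("spec must be a chain_spec")
  validate_torsions(spec)
  n <- length(spec$monomers)
  bb <- .BB
  # rows: per-residue N, CA, C
  N <- CA <- C <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bb$b_n_ca, 0, 0)
  th <- deg2rad(bb$a_n_ca_c)
  C[1, ] <- CA[1, ] + bb$b_ca_c * c(-cos(th), sin(th), 0)
  if (n > 1) {
    for (i in 2:n) {
      # psi(i-1): N(i-1)-CA(i-1)-C(i-1)-N(i)
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           bb$b_c_n, bb$a_ca_c_n, spec$psi[i - 1])
      # omega(i): CA(i-1)-C(i-1)-N(i)-CA(i), cis = 0
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            bb$b_n_ca, bb$a_c_n_ca, spec$omega[i])
      # phi(i): C(i-1)-N(i)-CA(i)-C(i)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           bb$b_ca_c, bb$a_n_ca_c, spec$phi[i])
    }
  }
  el <- character(0); xs <- ys <- zs <- numeric(0)
  resno <- integer(0); nm <- character(0)
  para <- monomer_para_atom(spec$monomers)
  sc <- .SC
  for (i in seq_len(n)) {
    el <- c(el, "N", "C", "C"); nm <- c(nm, "N", "CA", "C")
    xs <- c(xs, N[i, 1], CA[i, 1], C[i, 1])
    ys <- c(ys, N[i, 2], CA[i, 2], C[i, 2])
    zs <- c(zs, N[i, 3], CA[i, 3], C[i, 3])
    resno <- c(resno, rep(i, 3L))
    if (!is.na(para[i])) {
      # free valence of the amide N: away from the mean of its bonded heavies
      u <- N[i, ] - CA[i, ]
      if (i > 1) u <- u / sqrt(sum(u^2)) +
          (N[i, ] - C[i - 1, ]) / sqrt(sum((N[i, ] - C[i - 1, ])^2))
      u <- u / sqrt(sum(u^2))
      sites <- rbind(N[i, ] + sc$d_cb * u,
                     N[i, ] + sc$d_ring * u,
                     N[i, ] + sc$d_para * u)
      el <- c(el, "C", "C", para[i]); nm <- c(nm, "CB", "CG", "PA")
      xs <- c(xs, sites[, 1]); ys <- c(ys, sites[, 2]); zs <- c(zs, sites[, 3])
      resno <- c(resno, rep(i, 3L))
    }
  }
  atom_model(el, xs, ys, zs, chain = "A", resno = resno, name = nm,
             provenance = list(chain_spec = spec), check_clash = TRUE)
}

#' Measure backbone torsions from chain coordinates
#'
#' Recomputes phi (residues 2..n), psi (residues 1..n-1) and omega
#' (residues 2..n) from the N/CA/C coordinates of a built chain.
#'
#' @param model An `atom_model` holding a single chain built by
#'   [build_chain()].
#' @return List with numeric vectors `phi`, `psi`, `omega` (degrees, NA
#'   where undefined).
#' @export
measure_torsions <- function(model) {
  bb <- model[model$name %in% c("N", "CA", "C"), , drop = FALSE]
  n <- max(bb$resno)
  get <- function(i, nm) {
    r <- bb[bb$resno == i & bb$name == nm, ]
    c(r$x, r$y, r$z)
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral4(get(i - 1, "C"), get(i, "N"), get(i, "CA"),
                          get(i, "C"))
      omega[i] <- dihedral4(get(i - 1, "CA"), get(i - 1, "C"), get(i, "N"),
                            get(i, "CA"))
    }
    if (i < n)
      psi[i] <- dihedral4(get(i, "N"), get(i, "CA"), get(i, "C"),
                          get(i + 1, "N"))
  }
  list(phi = phi, psi = psi, omega = omega)
}

#' Tile a chain into a sheet lattice
#'
#' Replicates a chain over an `n_a` x `n_c` rectangular lattice: copies
#' within a row are translated by `a_spacing` along x, rows by `c_spacing`
#' along y.  A row labelled antiparallel is rotated 180 degrees about the
#' sheet normal through its own lattice node before translation.  With an
#' alternating chirality pattern, alternate rows are mirrored in z
#' (equivalent to flipping the sign of every phi/psi).
#'
#' @param chain An `atom_model` of one chain, positioned with its reference
#'   node at the origin.
#' @param lattice A [sheet_lattice()].
#' @param align If `TRUE` (default for chains built by [build_chain()]),
#'   first rotate the chain so its end-to-end backbone axis lies along the
#'   sheet normal +z, the orientation of chains in the nanosheet.
#' @param check_clash If `TRUE` and the sheet holds at most 300 chains,
#'   warn (with a count) when interchain atom pairs fall within 1.5 Angstrom.
#' @return An `atom_model` with `n_a * n_c` chains, ids `R<row>C<col>`.
#' @export
build_sheet <- function(chain, lattice, align = NULL, check_clash = TRUE) {
  stopifnot(inherits(chain, "atom_model"), inherits(lattice, "sheet_lattice"))
  if (is.null(align))
    align <- !identical(attr(chain, "provenance")$frame, "sheet")
  if (align) chain <- align_chain_axis(chain)
  rows <- vector("list", lattice$n_c * lattice$n_a)
  idx <- 1L
  for (j in seq_len(lattice$n_c)) {
    base <- chain
    if (lattice$chirality_pattern == "alternating" && j %% 2 == 0)
      base$z <- -base$z
    flip <- lattice$row_orientations[j] == "antiparallel"
    for (i in seq_len(lattice$n_a)) {
      m <- base
      if (flip) m <- transform_model(m, angle_deg = 180, pivot = c(0, 0))
      m <- transform_model(m, translate = c((i - 1) * lattice$a_spacing,
                                            (j - 1) * lattice$c_spacing, 0))
      m$chain <- sprintf("R%dC%d", j, i)
      rows[[idx]] <- m
      idx <- idx + 1L
    }
  }
  sheet <- do.call(bind_models, rows)
  attr(sheet, "provenance") <- list(lattice = lattice,
                                    chain_provenance = attr(chain, "provenance"))
  if (check_clash && lattice$n_a * lattice$n_c <= 300) {
    n_clash <- count_interchain_clashes(sheet, 1.5)
    if (n_clash > 0)
      warning(sprintf("%d interchain atom pair(s) closer than 1.5 Angstrom",
                      n_clash))
  }
  sheet
}

# Rotate a chain so its backbone end-to-end vector lies along +z.
#' @noRd
align_chain_axis <- function(chain) {
  bb <- chain[chain$name %in% c("N", "CA", "C"), ]
  if (nrow(bb) < 2) return(chain)
  v <- c(bb$x[nrow(bb)] - bb$x[1], bb$y[nrow(bb)] - bb$y[1],
         bb$z[nrow(bb)] - bb$z[1])
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  ax <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
          v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(ax^2)); cth <- sum(v * z)
  xyz <- cbind(chain$x, chain$y, chain$z)
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2, ctr)
  if (s > 1e-12) {
    ax <- ax / s
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
    R <- diag(3) + sin(acos(pmin(pmax(cth, -1), 1))) * K + (1 - cth) * K %*% K
    xyz <- xyz %*% t(R)
  } else if (cth < 0) {
    xyz[, c(1, 3)] <- -xyz[, c(1, 3)]
  }
  chain$x <- xyz[, 1]; chain$y <- xyz[, 2]; chain$z <- xyz[, 3]
  chain
}

# Count interchain atom pairs closer than `cutoff`, comparing only chains
# whose bounding boxes come within `cutoff`.
#' @noRd
count_interchain_clashes <- function(model, cutoff = 1.5) {
  ids <- unique(model$chain)
  sp <- split(seq_len(nrow(model)), model$chain)[ids]
  boxes <- t(vapply(sp, function(ix)
    c(min(model$x[ix]), max(model$x[ix]), min(model$y[ix]), max(model$y[ix])),
    numeric(4)))
  n_clash <- 0L
  for (p in seq_along(ids)) {
    for (q in seq_len(p - 1L)) {
      if (boxes[p, 1] > boxes[q, 2] + cutoff ||
          boxes[q, 1] > boxes[p, 2] + cutoff ||
          boxes[p, 3] > boxes[q, 4] + cutoff ||
          boxes[q, 3] > boxes[p, 4] + cutoff) next
      a <- model[sp[[p]], ]; b <- model[sp[[q]], ]
      d2 <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
        outer(a$z, b$z, "-")^2
      n_clash <- n_clash + sum(d2 < cutoff^2)
    }
  }
  n_clash
}

#' Minimal non-clashing row spacing
#'
#' Smallest c spacing at which a two-row sheet of the given chain has no
#' van der Waals overlap between rows (every interchain atom pair at least
#' the sum of the two vdW radii apart).  Replacing para H by Br on both
#' interface faces raises this by about twice the radius difference
#' (2 x (1.85 - 1.2) = 1.3 Angstrom), the arithmetic behind the measured
#' c-spacing trend.
#'
#' @param chain An `atom_model` with its node at the origin (sheet frame).
#' @param orientation `"antiparallel"` (default) or `"parallel"` second row.
#' @param n_a Chains per row used in the scan.
#' @param c_range Search interval for c, Angstrom.
#' @param tol Bisection tolerance, Angstrom.
#' @return Minimal contact c spacing in Angstrom.
#' @export
min_contact_c <- function(chain, orientation = "antiparallel", n_a = 3L,
                          c_range = c(2, 40), tol = 0.01) {
  r <- vdw_radius(chain$element)
  xyz <- cbind(chain$x, chain$y, chain$z)
  offs <- (seq_len(n_a) - (n_a + 1) / 2) * 4.5
  clash_at <- function(cc) {
    for (o in offs) {
      b <- xyz
      if (orientation == "antiparallel") b[, 1:2] <- -b[, 1:2]
      b[, 1] <- b[, 1] + o
      b[, 2] <- b[, 2] + cc
      d <- sqrt(outer(xyz[, 1], b[, 1], "-")^2 +
                  outer(xyz[, 2], b[, 2], "-")^2 +
                  outer(xyz[, 3], b[, 3], "-")^2)
      if (any(d < outer(r, r, "+"))) return(TRUE)
    }
    FALSE
  }
  lo <- c_range[1]; hi <- c_range[2]
  if (clash_at(hi)) stop("still clashing at c_range upper bound")
  if (!clash_at(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (clash_at(mid)) lo <- mid else hi <- mid
  }
  hi
}

#' Write an atom model to a PDB file
#'
#' One PDB chain record per peptoid chain.  Files round-trip through
#' standard PDB readers with coordinates preserved to 1e-3 Angstrom (PDB
#' fixed-format precision).
#'
#' @param model An `atom_model`.
#' @param path Output file path.
#' @param provenance_json If `TRUE` (default), also write a JSON sidecar
#'   `<path>.json` recording the generating parameters.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path, provenance_json = TRUE) {
  stopifnot(inherits(model, "atom_model"), nrow(model) >= 1)
  if (nrow(model) > 99999L)
    stop("more than 99,999 atoms: split the model (e.g. one file per row ",
         "of chains) before writing PDB")
  chain_ids <- unique(model$chain)
  pdb_chain <- c(LETTERS, letters, as.character(0:9))
  if (length(chain_ids) > length(pdb_chain))
    pdb_chain <- rep(pdb_chain, length.out = length(chain_ids))
  ch <- pdb_chain[match(model$chain, chain_ids)]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(cbind(model$x, model$y, model$z))),
                   type = rep("ATOM", nrow(model)),
                   resno = model$resno,
                   resid = rep("PTD", nrow(model)),
                   eleno = seq_len(nrow(model)),
                   elety = model$name,
                   chain = ch,
                   elesy = toupper(model$element))
  if (provenance_json) {
    prov <- attr(model, "provenance")
    jsonlite::write_json(serialize_provenance(prov),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

# Strip S3 classes recursively so provenance lists serialise plainly.
#' @noRd
serialize_provenance <- function(prov) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.function(x)) NULL
    else unclass(x)
  }
  strip(prov %||% list())
}

#' Read a PDB file into an atom model
#'
#' Thin wrapper over `bio3d::read.pdb` mapping records back to the
#' `atom_model` columns.
#'
#' @param path PDB file path.
#' @return An `atom_model`.
#' @export
read_pdb_model <- function(path) {
  p <- bio3d::read.pdb(path)
  a <- p$atom
  el <- a$elesy
  el[is.na(el) | el == ""] <- a$elety[is.na(el) | el == ""]
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  atom_model(el, a$x, a$y, a$z, chain = a$chain, resno = a$resno,
             name = a$elety)
}
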