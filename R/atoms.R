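# Element properties and the atom_model container.

# Atomic numbers for the elements that occur in the coarse models.
.Z_TABLE <- c(H = 1, C = 6, N = 7, O = 8, F = 9, Cl = 17, Br = 35, I = 53)

# Van der Waals radii (Angstrom).  Br 1.85 and H 1.2 set the c-spacing
# arithmetic for the para-substituted sheets.
.VDW_TABLE <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.52, F = 1.47,
                Cl = 1.75, Br = 1.85, I = 1.98)

#' Atomic number of an element symbol
#'
#' @param element Character vector of element symbols (`"H"`, `"C"`, `"Br"`, ...).
#' @return Integer vector of atomic numbers.
#' @export
atomic_number <- function(element) {
  z <- .Z_TABLE[element]
  if (anyNA(z)) stop("unknown element symbol: ",
                     paste(unique(element[is.na(z)]), collapse = ", "))
  unname(z)
}

#' Van der Waals radius of an element symbol
#'
#' @inheritParams atomic_number
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  r <- .VDW_TABLE[element]
  if (anyNA(r)) stop("unknown element symbol: ",
                     paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Construct an atom model
#'
#' An `atom_model` is a data frame of element-tagged 3D coordinates, the
#' common currency between the chain builder, the sheet tiler and the
#' projection renderer.  Coordinates are in Angstrom in the sheet frame:
#' the lattice a axis along +x, the c axis along +y and the sheet normal
#' b (the projection axis) along +z.
#'
#' @param element Character vector of element symbols.
#' @param x,y,z Numeric coordinate vectors (Angstrom).
#' @param chain Chain identifiers (one peptoid chain per id).
#' @param resno Residue index within the chain.
#' @param name Atom names (PDB-style); defaults to the element symbol.
#' @param provenance Optional list recording the generating parameters.
#' @param check_clash If `TRUE`, error when two atoms lie within 0.5 Angstrom
#'   (generated single-chain models only; tiled sheets use a softer
#'   interchain warning in [build_sheet()]).
#' @return A data frame of class `atom_model`.
#' @export
atom_model <- function(element, x, y, z, chain = "A", resno = 1L,
                       name = element, provenance = NULL,
                       check_clash = FALSE) {
  atomic_number(element)  # validates symbols
  stopifnot(length(x) == length(element), length(y) == length(element),
            length(z) == length(element))
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("atom coordinates must be finite")
  m <- data.frame(element = element, x = x, y = y, z = z,
                  chain = rep_len(as.character(chain), length(element)),
                  resno = rep_len(as.integer(resno), length(element)),
                  name = rep_len(name, length(element)),
                  stringsAsFactors = FALSE)
  if (check_clash && nrow(m) > 1) {
    d <- stats::dist(cbind(m$x, m$y, m$z))
    if (any(d < 0.5)) stop("atom clash: pair closer than 0.5 Angstrom")
  }
  attr(m, "provenance") <- provenance
  class(m) <- c("atom_model", "data.frame")
  m
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model> %d atoms, %d chain(s), elements: %s\n",
              nrow(x), length(unique(x$chain)),
              paste(names(sort(table(x$element), decreasing = TRUE)),
                    collapse = " ")))
  invisible(x)
}

# rbind that keeps the atom_model class and drops provenance.
#' @noRd
bind_models <- function(...) {
  m <- do.call(rbind, lapply(list(...), as.data.frame))
  class(m) <- c("atom_model", "data.frame")
  m
}

#' Rigid transform of an atom model
#'
#' Rotates the model about the z (sheet-normal) axis through a given pivot
#' and then translates it.  Used by the sheet tiler to generate antiparallel
#' rows (180 degree rotation about b).
#'
#' @param model An `atom_model`.
#' @param angle_deg Rotation angle about +z, degrees.
#' @param pivot Length-2 (x, y) rotation pivot, Angstrom.
#' @param translate Length-3 translation applied after the rotation.
#' @return The transformed `atom_model`.
#' @export
transform_model <- function(model, angle_deg = 0, pivot = c(0, 0),
                            translate = c(0, 0, 0)) {
  th <- deg2rad(angle_deg)
  xr <- pivot[1] + cos(th) * (model$x - pivot[1]) - sin(th) * (model$y - pivot[2])
  yr <- pivot[2] + sin(th) * (model$x - pivot[1]) + cos(th) * (model$y - pivot[2])
  model$x <- xr + translate[1]
  model$y <- yr + translate[2]
  model$z <- model$z + translate[3]
  model
}
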