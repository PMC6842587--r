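# Monomer codes, chain specifications and sheet lattice geometry.

.MONOMER_TABLE <- data.frame(
  code = c("Npe", "N4Fpe", "N4Clpe", "N4Brpe", "N4Ipe", "N4mpe",
           "N4OMepe", "Nte"),
  para_atom = c("H", "F", "Cl", "Br", "I", "C", "O", NA),
  stringsAsFactors = FALSE
)

#' Monomer code table
#'
#' The N-substituted glycine monomers used in the nanosheet-forming diblock
#' sequences.  `para_atom` is the terminal heavy atom of the para substituent
#' of the phenylethyl side chain (`H` for unsubstituted Npe, `C` for the
#' methyl of N4mpe, `O` for the methoxy of N4OMepe); `Nte` is the hydrophilic
#' triethylene-glycol monomer, which is amorphous in the sheets and carries
#' no aromatic para atom.
#'
#' @return Data frame with columns `code`, `para_atom`, `vdw_radius`.
#' @export
monomer_table <- function() {
  t <- .MONOMER_TABLE
  t$vdw_radius <- ifelse(is.na(t$para_atom), NA_real_,
                         vdw_radius(ifelse(is.na(t$para_atom), "H",
                                           t$para_atom)))
  t
}

#' @noRd
monomer_para_atom <- function(code) {
  i <- match(code, .MONOMER_TABLE$code)
  if (anyNA(i)) stop("unknown monomer code: ",
                     paste(unique(code[is.na(i)]), collapse = ", "))
  .MONOMER_TABLE$para_atom[i]
}

#' Specify a peptoid chain
#'
#' A chain specification holds the monomer sequence and the backbone torsion
#' recipe.  All amides are cis (omega = 0) and the (phi, psi) pair strictly
#' alternates between the two mirror-image torsion states
#' (+90, +150) and (-90, -150), the two backbone chirality states of the
#' cis 2-residue repeat.
#'
#' @param monomers Character vector of monomer codes (see [monomer_table()]).
#' @param chirality_state Which torsion state residue 1 starts in: `"plus"`
#'   for (+90, +150) or `"minus"` for (-90, -150).
#' @param phi_psi Length-2 numeric, the magnitude of the (phi, psi) pair;
#'   default `c(90, 150)`.
#' @param omega Amide torsion in degrees; must be 0 (cis) for lattice models.
#' @return A list of class `chain_spec` with per-residue `phi`, `psi`,
#'   `omega` vectors.
#' @export
chain_spec <- function(monomers, chirality_state = c("plus", "minus"),
                       phi_psi = c(90, 150), omega = 0) {
  chirality_state <- match.arg(chirality_state)
  monomer_para_atom(monomers)  # validates codes
  if (!isTRUE(all.equal(omega, 0)))
    stop("omega must be 0 degrees: lattice chains are all cis-amide")
  n <- length(monomers)
  s0 <- if (chirality_state == "plus") 1 else -1
  sgn <- s0 * (-1)^(seq_len(n) - 1)
  spec <- list(monomers = monomers,
               phi = sgn * phi_psi[1],
               psi = sgn * phi_psi[2],
               omega = rep(0, n),
               chirality_state = chirality_state)
  class(spec) <- "chain_spec"
  spec
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> %d residues [%s], start state %s, cis-amide\n",
              length(x$monomers), paste(x$monomers, collapse = "-"),
              x$chirality_state))
  invisible(x)
}

# Validate an explicit torsion table: strict alternation between the two
# states, cis amides.
#' @noRd
validate_torsions <- function(spec) {
  n <- length(spec$monomers)
  if (n > 1) {
    flips <- sign(spec$phi[-1]) == sign(spec$phi[-n])
    if (any(flips)) stop("phi/psi pattern must strictly alternate between ",
                         "the (+90,+150) and (-90,-150) states")
  }
  if (any(abs(spec$omega) > 1e-9)) stop("non-cis omega in chain_spec")
  invisible(spec)
}

#' Specify a sheet lattice
#'
#' Geometry of a rectangular nanosheet lattice: chains at spacing `a` along
#' the a axis within a row, rows at spacing `c` along the c axis.  Rows
#' labelled `"antiparallel"` are rotated 180 degrees about the sheet normal
#' relative to row 1, which flips the opening direction of the projected
#' V motif along c.
#'
#' @param a_spacing Chain-to-chain spacing along a, Angstrom (~4.5).
#' @param c_spacing Row-to-row spacing along c, Angstrom (16-19, side-chain
#'   size dependent); must exceed `a_spacing`.
#' @param n_a Chains per row.
#' @param n_c Number of rows.
#' @param row_orientations Character vector of length `n_c`, each
#'   `"parallel"` or `"antiparallel"` (relative to row 1).
#' @param v_dihedral Projected V opening angle in degrees, in (0, 180).
#' @param chirality_pattern `"uniform"` or `"alternating"` backbone
#'   chirality by row (the racemic row pairing of the alternating
#'   Br/H-armed sheet).
#' @return A list of class `sheet_lattice`.
#' @export
sheet_lattice <- function(a_spacing = 4.5, c_spacing = 16.2,
                          n_a = 12L, n_c = 2L,
                          row_orientations = rep("parallel", n_c),
                          v_dihedral = 104,
                          chirality_pattern = c("uniform", "alternating")) {
  chirality_pattern <- match.arg(chirality_pattern)
  stopifnot(a_spacing > 0, c_spacing > a_spacing,
            n_a >= 1, n_c >= 1,
            v_dihedral > 0, v_dihedral < 180)
  row_orientations <- match.arg(row_orientations,
                                c("parallel", "antiparallel"),
                                several.ok = TRUE)
  if (length(row_orientations) != n_c)
    stop("row_orientations must have length n_c")
  structure(list(a_spacing = a_spacing, c_spacing = c_spacing,
                 n_a = as.integer(n_a), n_c = as.integer(n_c),
                 row_orientations = row_orientations,
                 v_dihedral = v_dihedral,
                 chirality_pattern = chirality_pattern),
            class = "sheet_lattice")
}

#' @export
print.sheet_lattice <- function(x, ...) {
  cat(sprintf(paste0("<sheet_lattice> a = %.2f A, c = %.2f A, %d x %d chains, ",
                     "%d antiparallel row(s), V = %.0f deg\n"),
              x$a_spacing, x$c_spacing, x$n_a, x$n_c,
              sum(x$row_orientations == "antiparallel"), x$v_dihedral))
  invisible(x)
}
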