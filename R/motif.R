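# Direct V-motif templates: the projected appearance of one peptoid chain
# viewed along the sheet normal, parameterised by the observables the
# imaging pipeline recovers (V dihedral, tip chemistry) rather than by
# backbone torsions.

#' Build a projected V-motif model of one chain
#'
#' In projection along b each chain is a V: a bright apex (the superposed
#' backbone column, one dot in the backbone row line) with two side-chain
#' arms extending from either side of the row line, one toward +c and one
#' toward -c, both tilted the same way along a.  With tilt gamma from the
#' c axis the arm directions are `(sin g, +/-cos g)` and the angle between
#' them - the projected V dihedral - is exactly `180 - 2 g` degrees.
#' Within a row all chains tilt identically, so arms of a-adjacent chains
#' are parallel and never cross; an antiparallel row (the chain rotated
#' 180 degrees about the sheet normal) tilts the opposite way, giving the
#' herringbone contrast between packing motifs.
#'
#' Each arm is a rod of ring-carbon columns (3 side chains superposed per
#' face of a 6-mer hydrophobic block) ending in a column of
#' `tips_per_arm` para terminal atoms.
#'
#' @param v_dihedral V opening angle between the two arms, degrees in
#'   (0, 180).
#' @param arm_length Apex-to-tip distance in Angstrom (default 6.5, a
#'   phenylethyl-like reach; sheet presets derive it from the row spacing
#'   so that tips of c-adjacent rows sit in van der Waals contact).
#' @param tip_elements Length-2 character: para terminal atom of the +c
#'   and -c arm (`"H"`, `"Br"`, `"C"` for methyl, ...).
#' @param tips_per_arm Number of superposed para atoms per tip column.
#' @param arm_sites Number of rod sites per arm (columns of 3 superposed
#'   ring carbons).
#' @return An `atom_model` with the apex at the origin; provenance records
#'   the parameters and tip positions, and `frame = "sheet"` marks it as
#'   already lying in the sheet frame.
#' @export
v_motif_model <- function(v_dihedral = 104, arm_length = 6.5,
                          tip_elements = c("H", "H"),
                          tips_per_arm = 3L, arm_sites = 12L) {
  stopifnot(v_dihedral > 0, v_dihedral < 180, length(tip_elements) == 2,
            arm_length > 0)
  g <- deg2rad((180 - v_dihedral) / 2)  # arm tilt from the c axis
  u_up <- c(sin(g), cos(g))
  u_dn <- c(sin(g), -cos(g))

  # apex: 6-residue backbone column (N, CA, C, O per residue) projected
  # into a tight cluster around the origin
  n_res <- 6L
  ang <- seq(0, 2 * pi, length.out = 4 * n_res + 1)[-(4 * n_res + 1)]
  apex_r <- 0.6
  apex <- data.frame(element = rep(c("N", "C", "C", "O"), n_res),
                     x = apex_r * cos(ang), y = apex_r * sin(ang),
                     z = rep(seq(-4, 4, length.out = n_res), each = 4))
  tfrac <- seq(0.2, 0.95, length.out = arm_sites)
  arm_pts <- function(u) {
    s <- arm_length * outer(tfrac, u)
    data.frame(element = rep("C", 3 * arm_sites),
               x = rep(s[, 1], each = 3), y = rep(s[, 2], each = 3),
               z = rep(c(-2.5, 0, 2.5), arm_sites))
  }
  tip_pts <- function(u, elem) {
    p <- arm_length * u
    data.frame(element = rep(elem, tips_per_arm),
               x = rep(p[1], tips_per_arm), y = rep(p[2], tips_per_arm),
               z = seq(-3, 3, length.out = tips_per_arm))
  }
  d <- rbind(apex, arm_pts(u_up), arm_pts(u_dn),
             tip_pts(u_up, tip_elements[1]), tip_pts(u_dn, tip_elements[2]))
  tips <- data.frame(x = arm_length * c(u_up[1], u_dn[1]),
                     y = arm_length * c(u_up[2], u_dn[2]),
                     element = tip_elements, stringsAsFactors = FALSE)
  atom_model(d$element, d$x, d$y, d$z, chain = "A",
             resno = 1L, name = d$element,
             provenance = list(frame = "sheet", v_dihedral = v_dihedral,
                               arm_length = arm_length,
                               tip_elements = tip_elements,
                               tips = tips))
}
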