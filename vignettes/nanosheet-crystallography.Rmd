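---
title: "2D crystallography of polypeptoid nanosheets: models, simulation and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{2D crystallography of polypeptoid nanosheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(peptoidsheet)
```

This vignette is the package's account of the science it implements: the
lattice model, what the synthetic data emulate (and do not), and the
numerical choices inside each processing stage.  Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The lattice model

The crystalline core of an amphiphilic diblock polypeptoid nanosheet is a
rectangular 2D lattice.  Chains stand perpendicular to the sheet plane
(along *b*, the projection axis of top-view imaging), spaced
*a* = 4.5 Å within a row; rows repeat at *c* = 16–19 Å depending on the
*para* substituent of the phenylethyl side chains.  The backbone is all
cis-amide (ω = 0°) with (Φ, Ψ) alternating between the two mirror torsion
states (+90°, +150°) and (−90°, −150°), giving a 2-residue repeat.
`build_chain()` constructs this backbone by sequential
internal-to-Cartesian placement with standard peptide internal
coordinates (N–Cα 1.46 Å, Cα–C 1.52 Å, C–N 1.33 Å; angles
111°/114°/123°) — only the torsions are specific to the system — and
attaches a coarse 3-site side-chain template (Cβ, ring-centroid proxy,
*para* terminal atom) along the amide nitrogen's free valence.  The
imaging pipeline only needs projected mass at the arm and tip positions,
so all-atom rings are deliberately out of scope.  `build_sheet()` tiles
chains into `n_a × n_c` blocks; an antiparallel row is the chain rotated
180° about the sheet normal through its own lattice node, and a racemic
(alternating-chirality) row pattern mirrors alternate rows in *z*,
equivalent to flipping every Φ/Ψ sign.

In projection each chain is a **V**: the backbone atoms superpose into a
bright apex column on the row line, and the side chains of the two faces
form two arms, one toward +*c* and one toward −*c*, both tilted the same
way along *a*.  With tilt γ from the *c* axis the arm directions are
(±: sin γ, ±cos γ) and the angle between them — the projected V
dihedral — is 180° − 2γ; the ~104° dihedral corresponds to γ = 38°.
Within a row all arms are parallel and never cross; an antiparallel row
tilts the other way, which is what distinguishes the two packings in an
image.  `v_motif_model()` builds this projected motif directly from the
observables (dihedral, tip chemistry): an apex column representing the
6-residue backbone, two rods of ring-carbon columns (3 side chains
superposed per face), and a tip column of 3 *para* atoms.  Sheet presets
(`sheet_preset(1, 4, 7, 9)`) set the arm length so that tips of
*c*-adjacent rows sit in van der Waals contact, the packing that the
measured *c* trend encodes: replacing *para* H (1.2 Å) by Br (1.85 Å) on
both interface faces adds 2 × 0.65 = 1.3 Å of contact distance, matching
the 16.2 → 18.2 Å step between the parent and the brominated sheet.

A consequence of alternating (antiparallel) rows is that the
crystallographic repeat along *c* doubles, with weak superlattice
reflections at odd multiples of 1/(2c).  The conventional *c* reported
for these sheets is the **adjacent-row spacing**, and the indexing
default (`max_d = 30 Å`) deliberately stays below the ~36 Å supercell
fundamental so the row lattice is indexed directly.

## What the synthetic data emulate

`simulate_micrograph()` renders a preset lattice over the field of view
(default 1024² px at 0.5 Å/px), with the row pattern drawn so that an
exact fraction of row-to-row transitions is antiparallel (sheet 1: 0%,
sheet 4: 100%, sheet 7: 60%, sheet 9: 0% with alternating Br/H arms),
then optionally applies a smooth distortion field, a CTF, and additive
Gaussian noise with variance `var(signal)/SNR`.  Rendering sums
isotropic 2D Gaussians of fixed σ = 0.8 Å with amplitude proportional to
atomic number; atoms superposed in a column add linearly, so a 3-atom
bromine column is 3 × as bright as one Br and (3·35)/6 × a single
carbon.  This Z-weighted Gaussian model reproduces the contrast ordering
that matters — Br tip column > backbone column > arm — without tabulated
electron scattering factors.

What the generator does **not** emulate: multislice image physics, beam
induced motion, detector response, dose fractionation and Poisson
counting, grain boundaries and dislocations, and the amorphous
hydrophilic faces (omitted from projections).  Passing tests therefore
demonstrate that the *processing* recovers what the *generator* encodes
under CTF, smooth bending and heavy noise — they do not validate the
image formation model against real micrographs.

Unit-cell stacks for classification experiments can also be generated
directly (`simulate_cell_stack()`), bypassing the micrograph: boxed
cells on a lattice-index grid whose openings follow whole-row flips (the
observed mode of packing heterogeneity) with an exact antiparallel
transition fraction.  The mixed sheet's census uses a 26 × 20 grid so
that exactly 15 of the 25 row transitions (60%) are antiparallel.

## Processing stages and numerical choices

**Indexing.**  `find_lattice()` picks reflections in the DC-centred
power spectrum as local maxima above mean + 5σ within resolution annuli,
with sub-pixel centres from a 3 × 3 centre of mass.  Peak localisation
uses a Hann-tapered transform: the rectangular field of view otherwise
leaves sinc sidelobes that bias sub-pixel centres by ~0.1 Å at the
measured spacings.  Reflections below 10⁻³ of the strongest are treated
as noise, and candidate bases (shortest and strongest peaks paired with
shortest/strongest non-collinear partners) are scored by how much
reflection weight they index to < 0.75 px; the winner is refined by
least squares against all indexed reflections and reduced (Gauss
reduction) to the conventional shortest basis — necessary because a
reflection such as (100) can be structure-factor suppressed when apex
and tip columns nearly cancel, leaving the shortest *observed* peaks an
oblique primitive basis.  Spacings are reported to 0.1 Å, matching the
measurement precision of the field.  An image whose detected peaks
cannot be indexed (fewer than 4 reflections or under 40% of the peak
weight) is declared unindexable rather than fitted.

**CTF.**  Defaults are instrument-typical for a 300 kV field-emission
microscope: Cs 2.7 mm, 7% amplitude contrast; the wavelength is derived
relativistically.  `estimate_defocus()` fits the rotationally averaged
power spectrum against |CTF|² over a defocus grid after running-median
background removal, restricted to 0.02–0.25 Å⁻¹ where the radial binning
still resolves the rings at the defoci of interest; the Thon limit is
the highest inter-zero band whose measured profile still correlates with
the model.  Correction is phase flipping plus an amplitude-weighted
multi-defocus merge with weight floor ε = 0.01 — not a full Wiener
filter with spectral SNR, which the available information does not
support.

**Unbending.**  The reference is the image Fourier-filtered to ±2 px
around every indexed reflection, cropped to one unit cell.  Tracking is
serpentine: each row of cells is entered exactly once by a *c*-step from
the best-scoring node of the previous row and then expanded sequentially
along *a*.  Identical chains make the *x* lock of a row ambiguous modulo
*a*, so multiple entries per row could split a row between lattice
branches; the single-entry rule plus a search box extended along the row
direction (0.45 *a*, where smooth fields change fastest between rows)
keeps whole rows on one branch.  The tracked average lattice (origin and
cell vectors) is refit from the matched nodes so displacements carry no
affine trend, and the displacement field is fit with a least-squares 2D
polynomial (degree 3, lowered automatically if rank-deficient).  This
global smooth-field model handles fields whose change between adjacent
rows stays below about half the *a* spacing — at 0.5 Å/px and
*c* ≈ 16 Å that means bending with characteristic periods ≳ 300 px; the
tracker itself reproduces such sinusoids with RMS residuals well under
half a pixel.  Resampling uses a Catmull–Rom bicubic kernel: bilinear
interpolation attenuates the 1.5 Å reflection by up to ~25% at
half-pixel shifts, which would defeat the purpose of restoring
high-resolution signal.  A fitted field below a quarter pixel is treated
as no correction (the image is returned unchanged), which also makes
unbending idempotent.  Reflection bookkeeping (`indexed_peak_power()`)
integrates a small window of the Hann-windowed spectrum rather than
reading single-bin heights, since single bins suffer scalloping of up to
~40% under sub-bin peak shifts — measurement noise, not signal.

**Classification.**  Boxes (one unit cell, sub-pixel recentred,
normalised to zero mean and unit variance) are clustered by correlation
k-means: seeded random boxes initialise k = 4 class means (two
orientations plus margin for junk), assignment is by maximum Pearson
correlation, means are arithmetic, empty classes are reseeded from the
worst-fitting box, and the best of 5 seeded restarts (by mean
within-class correlation) is kept.  Each class average is assigned an
opening direction by correlating against the clean reference motif and
its **180° in-plane rotation** — the appearance of a chain in an
antiparallel row; a mirror across *a* would only be equivalent for
motifs with left-right symmetric projections, which the tilted-arm V is
not.  Boxes whose best class correlation falls below 0.2 are excluded
from orientation counts as junk.  The parallel/antiparallel percentages
are fractions of *c*-adjacent cell pairs whose openings agree/differ:
this is the packing relation the per-sheet census describes (an
all-alternating sheet is 100% antiparallel even though half its cells
open each way).  `distribution_map()` rasterises openings on the lattice
grid and reports directional flip fractions; whole-row flipping shows up
as a *c*-direction flip fraction far above the *a*-direction one.

**V dihedral.**  `fit_v_shape()` assumes a lattice-registered box with
the backbone column at the centre (the brightest pixel can be a heavier
tip column).  If near-maximal columns flank the apex within the
nearest-neighbour range, their principal axis defines the backbone row
and the image is de-rotated (one bicubic resampling) so rows lie along
*x*; the isotropic radial profile about the apex is then subtracted
(removing the apex skirt, which otherwise drags near-apex crossings),
and each arm is traced row by row: the crossing position is the
intensity-weighted circular centroid of the row with the lattice period
(so several phase-locked crossings per row add coherently and arms
wrapping across the one-cell box stay on one line), and the arm slope is
a weighted Theil–Sen fit of unwrapped crossing position against *y* with
one round of residual rejection.  Rows within 2.5 Å of the apex and
within ~2 Å of the arm end are excluded — the apex blob is directionless
and the blur's end effect drags the last crossings back along the arm.
On clean preset averages this recovers the 104° dihedral to within
about 2°, and on a 60–150° sweep after 100-box averaging at SNR 1 to
within 3°; rotation equivariance holds to about 2°, limited by the one
internal resampling.  These tolerances are honest measurement limits of
the estimator at 0.5 Å/px with a 0.8 Å rendering blur.

**Heavy-atom columns.**  `locate_heavy_columns()` reports local maxima
at ≥ 70% of the image maximum, outside the backbone ridge lines
(anchored at the box centre, repeating at the row spacing when given).
With a row spacing, peaks are assigned to inter-row interfaces and the
tip-to-tip distance is the minimum lower-tip-to-upper-tip distance
within an interface; when the generator places tips in van der Waals
contact this measures 2 × r(Br) = 3.7 Å.  A sheet without heavy tips
(hydrogen, Z = 1) correctly yields an empty result.

## Problem sizes

The tests and the acceptance script use the study conditions where they
are stated — 1024² px at 0.5 Å/px and SNR 0.5 for spacing recovery,
10-seed censuses of 520-cell stacks at SNR 0.5 for the mixed sheet,
200-cell stacks at SNR 1 for the homogeneous sheets, 100-box averages
for the dihedral — and 512² simulations for the unbending, tracking and
pipeline properties, where the lattice already spans ~30 rows × 110
chains and the statistics are set by the number of cells rather than the
field of view.

## Known limitations

* The side-chain representation is a coarse template; all-atom ring
  geometry, force fields and energetics are out of scope.
* The additive-Gaussian noise model has no dose or detector physics; SNR
  values are not electron doses.
* Unbending assumes a single crystal grain with a smooth (degree ≤ 3
  polynomial) distortion field; dislocations and grain boundaries are
  not segmented, and fields bending faster than about half an *a*
  spacing per row exceed the tracker's branch-resolution envelope.
* The V dihedral is a projected, 2D quantity; no 3D reconstruction is
  attempted.
* Rotational CTF averaging assumes no astigmatism.
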