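# peptoidsheet

Atomic-level analysis of crystalline polypeptoid nanosheet lattices from
synthetic cryo-TEM-style projection images.

## The problem

Amphiphilic diblock polypeptoids with a hydrophilic oligo-ether block and
an aromatic (2-phenylethyl glycine based) hydrophobic block self-assemble
into free-floating 2D nanosheets.  The hydrophobic cores are rectangular
2D crystals: chains stand perpendicular to the sheet plane (the *b*
projection axis), packed at a universal spacing *a* ≈ 4.5 Å within rows
and at a row-to-row spacing *c* ≈ 16–19 Å that tracks the size of the
*para* substituent on the aromatic ring (H, CH₃, Br, ...).  Viewed along
*b*, each chain projects as a **V**: a bright backbone column at the apex
with two side-chain arms extending to the +*c* and −*c* faces, both
tilted the same way along *a* and meeting at a dihedral of ~104°.
Adjacent rows pack either **parallel** (all V's tilt the same way) or
**antiparallel** (alternate rows rotated 180° about the sheet normal),
and sheets with heavy *para* atoms show superposed bromine columns at the
side-chain tips in tip-to-tip contact across the row interface.

No raw micrographs of these crystals are publicly deposited, so the
package pairs a fully parameterised synthetic generator with the complete
2D electron crystallography pipeline needed to measure such images:

* **Model building** — pseudo-atomic chains from the cis-amide backbone
  torsion recipe (Φ/Ψ alternating between (+90°, +150°) and
  (−90°, −150°)), tiled into sheet lattices, written as PDB.
* **Simulation** — Z-weighted Gaussian projection rendering (σ = 0.8 Å),
  smooth lattice distortion, weak-phase CTF
  (CTF(q) = −[√(1−A²)·sin χ + A·cos χ], χ = πλΔf q² − (π/2)Cs λ³q⁴),
  additive Gaussian noise at a target SNR, MRC2014 I/O.
* **Processing** — power-spectrum indexing with least-squares lattice
  refinement, Thon-ring defocus estimation, phase-flip and multi-defocus
  CTF compensation, correlation-based crystal unbending, unit-cell
  boxing, correlation k-means classification with class averaging,
  parallel/antiparallel packing census and distribution maps, projected
  V-dihedral fitting and heavy-atom column location.

The observables the pipeline reports — *a*, *c*, the V dihedral, the
percent parallel/antiparallel packing, heavy-atom tip positions, and the
higher-order powder spacings d(00l) = c/l — are the quantities that
characterise these lattices.

## Worked example

Simulate the para-bromo sheet (preset 4: c = 18.2 Å, all-antiparallel
packing, Br tip columns) and run the full pipeline:

```r
library(peptoidsheet)

cfg   <- run_config(preset = 4, n_px = 512, snr = 0.5, seed = 1,
                    out_dir = "run4")
paths <- nanosheet_simulate(cfg)      # writes MRC micrograph(s)
rep   <- nanosheet_process(paths, cfg)
rep
#> <nanosheet_report> sheet 4: a = 4.5 A, c = 18.2 A, V = 102 deg,
#>   0% parallel / 100% antiparallel (728 cells)
nanosheet_report(rep, cfg)
#>           quantity preset measured difference
#> 1              a_A    4.5      4.5          0
#> 2              c_A   18.2     18.2          0
#> 3     dihedral_deg  104.0    102.0         -2
#> 4 pct_antiparallel  100.0    100.0          0
```

The report reads: the chain-to-chain spacing along *a* and the
row-to-row spacing along *c* are recovered exactly at the 0.1 Å
reporting precision; every one of the 728 boxed unit cells classifies
into the antiparallel packing that the preset encodes; and the V opening
angle fitted from the class average is within 2° of the generator's
104°.  Higher-order powder positions follow from the spacings:

```r
predict_powder_peaks(4.5, 18.4, max_order = 3)
#>     hkl  d_A    q_invA
#> 1 (001) 18.4 0.3414775
#> 2 (002)  9.2 0.6829549
#> 3 (003)  6.1 1.0244324
#> 4 (100)  4.5 1.3962634
#> 5 (200)  2.2 2.7925268
#> 6 (300)  1.5 4.1887902
```

(For the para-bromo sheet the first-order (001) reflection is obscured
in wide-angle scattering, but its second and third orders at 9.2 and
6.1 Å remain visible — pure arithmetic once *c* is known.)

Lower-level entry points (`build_chain`, `simulate_micrograph`,
`find_lattice`, `track_cells`, `unbend_image`, `classify_motifs`,
`fit_v_shape`, ...) expose each stage separately; see the vignette
`vignettes/nanosheet-crystallography.Rmd` for the methods.

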