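# Chain construction from torsion recipes and sheet tiling.

test_that("single-residue chain reproduces the template internal coordinates", {
  m <- build_chain(chain_spec("Npe"))
  expect_equal(sum(m$name %in% c("N", "CA", "C")), 3L)
  get <- function(nm) unlist(m[m$name == nm, c("x", "y", "z")])
  expect_equal(sqrt(sum((get("N") - get("CA"))^2)), 1.46, tolerance = 1e-9)
  expect_equal(sqrt(sum((get("CA") - get("C"))^2)), 1.52, tolerance = 1e-9)
  # side-chain sites lie along one axis from N at template distances
  expect_equal(sqrt(sum((get("N") - get("CB"))^2)), 1.47, tolerance = 1e-9)
  expect_equal(sqrt(sum((get("N") - get("PA"))^2)), 6.35, tolerance = 1e-9)
})

test_that("backbone torsions recomputed from coordinates match the recipe", {
  spec <- chain_spec(rep("Npe", 6))
  m <- build_chain(spec)
  tor <- measure_torsions(m)
  expect_true(all(abs(tor$phi[-1] - spec$phi[-1]) < 1))
  expect_true(all(abs(tor$psi[-6] - spec$psi[-6]) < 1))
  expect_true(all(abs(tor$omega[-1]) < 1))
  # cross-check phi against an independent dihedral implementation
  bb <- m[m$name %in% c("N", "CA", "C"), ]
  xyz <- as.numeric(t(as.matrix(bb[, c("x", "y", "z")])))
  tor_b3d <- bio3d::torsion.xyz(xyz, atm.inc = 1)
  # torsion.xyz over the N-CA-C chain: element k holds the dihedral of
  # the window starting at atom k-1; phi(i) = C(i-1)-N(i)-CA(i)-C(i)
  # starts at atom 3(i-1), so it sits at position 3i - 2
  phi_idx <- 3 * (2:6) - 2
  expect_true(all(abs(tor_b3d[phi_idx] - spec$phi[2:6]) < 1))
})

test_that("the displacement NeRF agrees with a rotation-matrix frame oracle", {
  spec <- chain_spec(rep("Npe", 10), chirality_state = "minus")
  m <- build_chain(spec)
  bb <- as.matrix(m[m$name %in% c("N", "CA", "C"), c("x", "y", "z")])
  oracle <- oracle_backbone(spec)
  expect_lt(sqrt(mean((bb - oracle)^2)), 1e-6)
  # rise per 2-residue repeat is the same in both constructions
  rise_pkg <- sqrt(sum((bb[7, ] - bb[1, ])^2))
  rise_orc <- sqrt(sum((oracle[7, ] - oracle[1, ])^2))
  expect_equal(rise_pkg, rise_orc, tolerance = 1e-9)
})

test_that("flipping every residue's chirality state mirrors the chain", {
  a <- build_chain(chain_spec(rep("Npe", 8), "plus"))
  b <- build_chain(chain_spec(rep("Npe", 8), "minus"))
  # construction starts in the xy plane, so the mirror is z -> -z exactly
  expect_lt(sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z + b$z)^2)), 1e-6)
})

test_that("non-alternating torsion patterns and unknown monomers are rejected", {
  expect_error(chain_spec(c("Npe", "Nxx")), "unknown monomer")
  spec <- chain_spec(rep("Npe", 4))
  spec$phi[2] <- spec$phi[1]  # break alternation by hand
  expect_error(build_chain(spec), "alternate")
  expect_error(chain_spec("Npe", omega = 180), "cis")
})

test_that("sheet tiling conserves atoms and applies the row transforms", {
  chain <- v_motif_model()
  lat <- sheet_lattice(a_spacing = 4.5, c_spacing = 16.2, n_a = 3, n_c = 3,
                       row_orientations = rep("parallel", 3))
  sheet <- build_sheet(chain, lat)
  expect_equal(nrow(sheet), 9L * nrow(chain))
  # centroid spacing between adjacent rows equals c
  cy <- tapply(sheet$y, sub("C.*", "", sheet$chain), mean)
  expect_equal(as.numeric(diff(sort(cy))), rep(16.2, 2), tolerance = 1e-9)

  # identity tiling
  one <- build_sheet(chain, sheet_lattice(n_a = 1, n_c = 1,
                                          row_orientations = "parallel"))
  expect_equal(one$x, chain$x, tolerance = 1e-12)
  expect_equal(one$y, chain$y, tolerance = 1e-12)

  # antiparallel row = 180-degree rotation about b, then translation by c
  lat2 <- sheet_lattice(n_a = 2, n_c = 2, c_spacing = 18.2,
                        row_orientations = c("parallel", "antiparallel"))
  sh2 <- build_sheet(chain, lat2, check_clash = FALSE)
  r0 <- sh2[sh2$chain == "R1C1", ]
  r1 <- sh2[sh2$chain == "R2C1", ]
  rot <- transform_model(r0, angle_deg = 180, translate = c(0, 18.2, 0))
  expect_equal(r1$x, rot$x, tolerance = 1e-9)
  expect_equal(r1$y, rot$y, tolerance = 1e-9)
})

test_that("interchain contacts below 1.5 Angstrom raise a counted warning", {
  chain <- v_motif_model()
  lat <- sheet_lattice(a_spacing = 0.8, c_spacing = 2, n_a = 2, n_c = 1,
                       row_orientations = "parallel")
  expect_warning(build_sheet(chain, lat), "closer than 1.5")
})

test_that("substituting Br for H at the para tips widens the contact c by 1.3", {
  # a chain whose para tips face the c interface head-on, so the contact
  # is purely along c and the substitution arithmetic is exact
  rod <- function(tip) {
    atom_model(c(rep("C", 9), tip, tip),
               rep(0, 11), c(seq(-4, 4, by = 1), -5.5, 5.5), rep(0, 11),
               provenance = list(frame = "sheet"))
  }
  c_h <- min_contact_c(rod("H"))
  c_br <- min_contact_c(rod("Br"))
  # the increase is twice the vdW radius difference, 2 x (1.85 - 1.2)
  expect_equal(c_br - c_h, 1.3, tolerance = 0.05)
  # and the printed spacing trend is consistent with that arithmetic
  expect_lt(abs((16.2 + (c_br - c_h)) - 18.2), 1)
})

test_that("PDB files round-trip through a third-party reader", {
  # the coarse-template chain packs tightly at the printed spacings;
  # the contact warning is informative, not an error
  sheet <- suppressWarnings(
    build_sheet(build_chain(chain_spec(rep("N4Brpe", 6))),
                sheet_lattice(n_a = 12, n_c = 2, c_spacing = 18.2,
                              row_orientations = c("parallel",
                                                   "antiparallel"))))
  path <- tempfile(fileext = ".pdb")
  write_pdb(sheet, path)
  back <- read_pdb_model(path)
  expect_equal(nrow(back), nrow(sheet))
  expect_equal(back$x, sheet$x, tolerance = 1e-3)
  expect_equal(back$y, sheet$y, tolerance = 1e-3)
  expect_equal(back$z, sheet$z, tolerance = 1e-3)
  expect_true(file.exists(paste0(path, ".json")))
  # element symbol column (77-78) right-justified for Br
  lines <- readLines(path)
  br_lines <- lines[grepl("^ATOM", lines) &
                      toupper(substr(lines, 77, 78)) == "BR"]
  expect_gt(length(br_lines), 0)
})

test_that("single-atom models produce one well-formed ATOM record", {
  m <- atom_model("C", 1.234, 5.678, -9.1, name = "CA")
  path <- tempfile(fileext = ".pdb")
  write_pdb(m, path, provenance_json = FALSE)
  lines <- readLines(path)
  atom <- lines[grepl("^ATOM", lines)]
  expect_length(atom, 1L)
  expect_equal(as.numeric(substr(atom, 31, 38)), 1.234)
  expect_equal(as.numeric(substr(atom, 39, 46)), 5.678)
  expect_equal(as.numeric(substr(atom, 47, 54)), -9.1)
})

test_that("models beyond the PDB atom limit are rejected with guidance", {
  n <- 100000L
  m <- atom_model(rep("C", n), seq_len(n) * 1000, rep(0, n), rep(0, n))
  expect_error(write_pdb(m, tempfile()), "99,999")
})
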