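test_that("lattice validation rejects degenerate and out-of-range cells", {
  expect_error(lattice_parameters(-1, 2, 2), "positive")
  expect_error(lattice_parameters(2, 2, 2, alpha = 0), "angles")
  expect_error(lattice_parameters(2, 2, 2, alpha = 190), "angles")
  # angle triple violating the triangle-like volume condition
  expect_error(lattice_parameters(2, 2, 2, 30, 150, 90), "degenerate")
})

test_that("reciprocal basis is dual to the direct basis and volumes agree", {
  for (lat in list(lattice_parameters(2, 2, 2),
                   reference_lattice("rubrene"),
                   reference_lattice("tips_pentacene"),
                   lattice_parameters(3.1, 5.2, 7.3, 101, 83, 67))) {
    rb <- reciprocal_basis(lat)
    expect_lt(max(abs(rb$direct %*% t(rb$recip) - diag(3))), 1e-12)
    # closed-form triclinic volume vs Cartesian triple product
    expect_equal(cell_volume(lat), rb$volume, tolerance = 1e-10)
    expect_gt(rb$volume, 0)
  }
})

test_that("reciprocal vector magnitudes reproduce simple and printed values", {
  rb_cub <- reciprocal_basis(lattice_parameters(2, 2, 2))
  expect_equal(sqrt(sum(g_vector(rb_cub, 1, 0, 0)^2)), 0.5)
  expect_equal(rb_cub$volume, 8)
  expect_equal(sqrt(sum(g_vector(rb_cub, 0, 0, 0)^2)), 0)

  rb_rub <- reciprocal_basis(reference_lattice("rubrene"))
  expect_equal(sqrt(sum(g_vector(rb_rub, 0, 1, 0)^2)), 1 / 7.170, tolerance = 1e-12)
  expect_equal(rb_rub$volume, 26.789 * 7.170 * 14.211, tolerance = 1e-12)

  # triclinic a*: 10|g_100| is quoted as ~1.4 1/A for TIPS pentacene
  rb_tips <- reciprocal_basis(reference_lattice("tips_pentacene"))
  a_star <- sqrt(sum(g_vector(rb_tips, 1, 0, 0)^2))
  expect_equal(10 * a_star, 1.4, tolerance = 0.05)
})

test_that("triclinic g magnitudes match the metric-tensor oracle", {
  lat <- reference_lattice("tips_pentacene")
  rb <- reciprocal_basis(lat)
  Gstar <- solve(rb$direct %*% t(rb$direct))  # reciprocal metric = G^-1
  set.seed(42)
  for (i in 1:20) {
    hkl <- sample(-5:5, 3, replace = TRUE)
    g <- g_vector(rb, hkl[1], hkl[2], hkl[3])
    expect_equal(sum(g^2), drop(t(hkl) %*% Gstar %*% hkl), tolerance = 1e-12)
  }
  # closed form a* = b c sin(alpha) / Omega
  a_star_cf <- lat$b * lat$c * sin(lat$alpha * pi / 180) / cell_volume(lat)
  expect_equal(sqrt(sum(g_vector(rb, 1, 0, 0)^2)), a_star_cf, tolerance = 1e-12)
})

test_that("ZOLZ magnitudes are inversion symmetric", {
  rb <- reciprocal_basis(reference_lattice("tips_pentacene"))
  for (hk in list(c(3, 1), c(-2, 5), c(7, -4))) {
    expect_equal(sqrt(sum(g_vector(rb, hk[1], hk[2], 0)^2)),
                 sqrt(sum(g_vector(rb, -hk[1], -hk[2], 0)^2)))
  }
})

test_that("toy crystals are deterministic and validate their atoms", {
  expect_equal(nrow(toy_crystal("monatomic_cubic")$atoms), 1)
  expect_error(toy_crystal("nonsense"), "unknown toy crystal kind")
  r1 <- toy_crystal("random_light_organic", seed = 1)
  r2 <- toy_crystal("random_light_organic", seed = 1)
  expect_identical(r1$atoms, r2$atoms)
  r3 <- toy_crystal("random_light_organic", seed = 2)
  expect_false(identical(r1$atoms, r3$atoms))
  expect_true(all(r1$atoms$element %in% c("H", "C", "N", "O", "Si")))
  expect_error(crystal_structure(lattice_parameters(4, 4, 4),
                                 data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "unsupported element")
})

test_that("fractional coordinates are reduced mod 1 on ingest", {
  cry <- crystal_structure(lattice_parameters(4, 4, 4),
                           data.frame(element = "C", x = 1.25, y = -0.3, z = 2))
  expect_equal(cry$atoms$x, 0.25)
  expect_equal(cry$atoms$y, 0.7)
  expect_equal(cry$atoms$z, 0)
})

test_that("CIF round trip preserves the structure", {
  cry <- toy_crystal("random_light_organic", seed = 7, n_atoms = 12,
                     lattice = lattice_parameters(5, 6, 7, 95, 90, 88))
  path <- tempfile(fileext = ".cif")
  write_cif(cry, path)
  back <- read_cif(path)
  expect_equal(back$lattice$a, cry$lattice$a, tolerance = 1e-6)
  expect_equal(back$lattice$gamma, cry$lattice$gamma, tolerance = 1e-6)
  expect_equal(back$atoms$element, cry$atoms$element)
  expect_equal(back$atoms$x, cry$atoms$x, tolerance = 1e-6)
  expect_equal(back$atoms$occupancy, cry$atoms$occupancy, tolerance = 1e-6)
})

test_that("CIF symmetry expansion doubles a general position under P-1", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell_length_a 6.0", "_cell_length_b 6.0", "_cell_length_c 6.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "'-x, -y, -z'",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.1 0.2 0.3",
    "O1 O 0.0 0.0 0.0"), path)
  cry <- read_cif(path)
  # general position doubled, special position (origin) kept once
  expect_equal(sum(cry$atoms$element == "C"), 2)
  expect_equal(sum(cry$atoms$element == "O"), 1)
  # and the expanded structure is centrosymmetric: real structure factors
  expect_lt(abs(Im(structure_factor(cry, c(2, 1, 3)))), 1e-12)
})

test_that("CIF reader reports parse errors", {
  p1 <- tempfile(); writeLines(c("data_x", "loop_", "_atom_site_fract_x", "0.1"), p1)
  expect_error(read_cif(p1), "cell")
  p2 <- tempfile(); writeLines(c("data_x", "_cell_length_a 4", "_cell_length_b 4",
                                 "_cell_length_c 4"), p2)
  expect_error(read_cif(p2), "atom_site")
  expect_error(read_cif(tempfile()), "not found")
})

test_that("a one-atom hand-written CIF reads as expected", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_min",
    "_cell_length_a 4.0", "_cell_length_b 4.0", "_cell_length_c 4.0",
    "loop_",
    "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.0 0.0 0.0"), path)
  cry <- read_cif(path)
  expect_equal(nrow(cry$atoms), 1)
  expect_equal(cry$lattice$alpha, 90)   # missing angles default to 90
  expect_equal(cry$atoms$occupancy, 1)
})
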