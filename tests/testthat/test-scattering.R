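test_that("relativistic wavelength has the expected values and limits", {
  rw <- relativistic_wavelength(200e3)
  expect_equal(rw$lambda, 0.02508, tolerance = 1e-3)
  expect_equal(rw$gamma_rel, 1 + 200e3 * 1.602176634e-19 /
                 (9.1093837015e-31 * 299792458^2), tolerance = 1e-12)
  expect_gt(relativistic_wavelength(100e3)$lambda, rw$lambda)
  expect_gt(relativistic_wavelength(1)$lambda, 10)  # V -> 0: lambda diverges
  expect_error(relativistic_wavelength(0))
})

test_that("scattering factors decay, stay positive, and match the table at q = 0", {
  tab <- scattering_factor_table()
  expect_true(all(c("H", "C", "N", "O", "Si") %in% rownames(tab)))
  for (el in c("H", "C", "Si")) {
    q <- seq(0, 2, by = 0.01)
    f <- scattering_factor(el, q)
    expect_true(all(f > 0))
    expect_true(all(diff(f) <= 0))  # non-increasing on [0, 2]
    # f(el, 0) equals the parameter-sum from the table
    expect_equal(scattering_factor(el, 0),
                 sum(as.numeric(tab[el, seq(1, 9, 2)])), tolerance = 1e-12)
  }
  expect_lt(scattering_factor("C", 10), 0.05 * scattering_factor("C", 0))
  expect_error(scattering_factor("Uub", 0.1), "unsupported element")
})

test_that("structure factors have unit phase at origin and Friedel symmetry", {
  cry <- cubic_c()
  F0 <- structure_factor(cry, c(1, 1, 0))
  expect_equal(Im(F0), 0, tolerance = 1e-14)
  expect_equal(Re(F0), scattering_factor("C", sqrt(2) / 4), tolerance = 1e-12)

  pair <- toy_crystal("centrosymmetric_pair")
  for (hkl in list(c(1, 0, 0), c(2, 3, 1), c(-1, 4, 2))) {
    expect_lt(abs(Im(structure_factor(pair, hkl))), 1e-12)
  }

  rnd <- toy_crystal("random_light_organic", seed = 3)
  for (hkl in list(c(1, 2, 0), c(3, -1, 2))) {
    expect_equal(structure_factor(rnd, -hkl),
                 Conj(structure_factor(rnd, hkl)), tolerance = 1e-12)
  }
})

test_that("U_g follows the quadrature oracle and scales with volume/occupancy", {
  cry <- cubic_c(4)
  for (hkl in list(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0))) {
    u <- fourier_potential_coefficient(cry, hkl, phys200)
    u_oracle <- ug_quadrature_oracle(cry, hkl, phys200, n_grid = 48)
    expect_equal(Mod(u), Mod(u_oracle), tolerance = 0.01)
  }
  # doubling the cell volume at (nearly) fixed F halves |U|
  big <- toy_crystal("monatomic_cubic", a = 4 * 2^(1/3))
  ratio <- Mod(fourier_potential_coefficient(big, c(0, 0, 0), phys200)) /
    Mod(fourier_potential_coefficient(cry, c(0, 0, 0), phys200))
  expect_equal(ratio, 0.5, tolerance = 1e-10)
  # occupancy alpha multiplies |F| by alpha and divides xi by alpha
  half <- crystal_structure(cry$lattice,
                            data.frame(element = "C", x = 0, y = 0, z = 0,
                                       occupancy = 0.5))
  expect_equal(Mod(structure_factor(half, c(1, 0, 0))),
               0.5 * Mod(structure_factor(cry, c(1, 0, 0))), tolerance = 1e-12)
  expect_equal(extinction_distance(half, c(1, 0, 0), phys200) /
                 extinction_distance(cry, c(1, 0, 0), phys200),
               2, tolerance = 1e-3)  # K shifts slightly with mean inner potential
})

test_that("corrected wavevector exceeds k0 by a small mean-inner-potential shift", {
  cry <- toy_crystal("random_light_organic", seed = 5, n_atoms = 30,
                     lattice = lattice_parameters(8, 8, 8))
  K <- corrected_wavevector(cry, phys200)
  expect_gt(K, phys200$k0)
  expect_lt((K - phys200$k0) / phys200$k0, 1e-3)
  # adding atoms increases K
  more <- crystal_structure(cry$lattice,
                            rbind(cry$atoms,
                                  data.frame(element = "Si", x = 0.5, y = 0.5,
                                             z = 0.5, occupancy = 1)))
  expect_gt(corrected_wavevector(more, phys200), K)
})

test_that("extinction distance behaves as K/|U_g|", {
  cry <- cubic_c()
  xi <- extinction_distance(cry, c(1, 0, 0), phys200)
  u <- Mod(fourier_potential_coefficient(cry, c(1, 0, 0), phys200))
  expect_equal(xi, corrected_wavevector(cry, phys200) / u, tolerance = 1e-12)
  # lighter element at identical geometry has larger xi
  cry_si <- toy_crystal("monatomic_cubic", element = "Si")
  expect_gt(extinction_distance(toy_crystal("monatomic_cubic", element = "H"),
                                c(1, 0, 0), phys200),
            extinction_distance(cry_si, c(1, 0, 0), phys200))
  # F_g = 0 is undefined: an empty-potential stub via zero occupancy is
  # rejected upstream, so use a reflection with exact cancellation
  cancel <- crystal_structure(cry$lattice,
                              data.frame(element = c("C", "C"),
                                         x = c(0, 0.5), y = 0, z = 0))
  expect_error(extinction_distance(cancel, c(1, 0, 0), phys200),
               "undefined extinction")
})

test_that("two-beam pendellosung at exact Bragg peaks first at xi/2", {
  cry <- cubic_c()
  basis <- reciprocal_basis(cry$lattice)
  xi <- extinction_distance(cry, c(1, 0, 0), phys200)
  A <- direct_structure_matrix(cry, basis, rbind(c(0, 0), c(1, 0)), phys200)
  A[1, 1] <- 0; A[2, 2] <- 0  # exact Bragg: both beams on the sphere
  z <- seq(0, 1.2 * xi, length.out = 2000)
  res <- propagate_bloch(bloch_decompose(A), z)
  z_peak <- z[which.max(res$intensity[, 2])]
  expect_equal(z_peak, xi / 2, tolerance = 2e-3)
})

test_that("Hermitian pairing U_{-g} = Conj(U_g) holds for every fixture", {
  for (cry in list(cubic_c(), toy_crystal("rocksalt_like"),
                   toy_crystal("random_light_organic", seed = 9))) {
    for (hkl in list(c(1, 0, 0), c(2, -1, 3))) {
      expect_lt(Mod(fourier_potential_coefficient(cry, -hkl, phys200) -
                      Conj(fourier_potential_coefficient(cry, hkl, phys200))),
                1e-12)
    }
  }
})
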