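# Shared fixtures and independent oracles for the test suite.

phys200 <- beam_physics(200e3)

cubic_c <- function(a = 4) toy_crystal("monatomic_cubic", a = a, element = "C")

# five-beam cross (000, +/-100, +/-010) on a cubic cell
five_beam_set <- function(basis) {
  beam_set(basis, rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
}

# independent matrix exponential: Taylor series with scaling and squaring
# (no eigen-decomposition anywhere)
expm_taylor <- function(M, terms = 30) {
  nrm <- max(rowSums(abs(M)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 4L)
  Ms <- M / 2^s
  E <- diag(1 + 0i, nrow(M))
  term <- E
  for (j in seq_len(terms)) {
    term <- term %*% Ms / j
    E <- E + term
  }
  for (j in seq_len(s)) E <- E %*% E
  E
}

# closed-form two-beam diffracted intensity at excitation error s
two_beam_intensity <- function(z, s, xi) {
  seff <- sqrt(s^2 + 1 / xi^2)
  sin(pi * z * seff)^2 / (1 + (s * xi)^2)
}

# assemble a structure matrix directly from first principles (no cluster
# machinery): dense couplings over an explicit beam list at normal incidence
direct_structure_matrix <- function(structure, basis, hk, physics,
                                    tilt_polar = 0, azimuth = 0) {
  bs <- beam_set(basis, hk)
  K <- corrected_wavevector(structure, physics)
  geom <- incident_wavevector(basis, K, tilt_polar, azimuth)
  s <- deviation_parameters(geom, bs)
  n <- nrow(bs)
  A <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { A[i, j] <- s[i]; next }
    dh <- bs$h[i] - bs$h[j]; dk <- bs$k[i] - bs$k[j]
    A[i, j] <- fourier_potential_coefficient(structure, c(dh, dk, 0),
                                             physics, basis) / (2 * geom$K_n)
  }
  attr(A, "beams") <- bs
  attr(A, "i000") <- attr(bs, "i000")
  attr(A, "K_n") <- geom$K_n
  A
}

# real-space quadrature oracle for U_g on a monatomic cell: the atomic
# potential is the analytic inverse Fourier transform of the Gaussian
# scattering-factor parametrization, superposed over periodic images, and
# U_g is its Fourier coefficient computed by Riemann sum
ug_quadrature_oracle <- function(structure, hkl, physics, n_grid = 32,
                                 n_images = 1) {
  stopifnot(nrow(structure$atoms) == 1, structure$atoms$x == 0)
  lat <- structure$lattice
  stopifnot(lat$alpha == 90, lat$beta == 90, lat$gamma == 90)
  p <- as.numeric(scattering_factor_table()[structure$atoms$element[1], ])
  cs <- p[seq(1, 9, 2)]; ds <- p[seq(2, 10, 2)]
  # v(r) = sum_i c_i (pi/d_i)^(3/2) exp(-pi^2 r^2 / d_i)  (3D inverse FT)
  v_atom <- function(r2) {
    out <- 0
    for (i in 1:5) out <- out + cs[i] * (pi / ds[i])^1.5 * exp(-pi^2 * r2 / ds[i])
    out
  }
  a <- lat$a; b <- lat$b; cc <- lat$c
  gx <- seq(0, a, length.out = n_grid + 1)[1:n_grid]
  gy <- seq(0, b, length.out = n_grid + 1)[1:n_grid]
  gz <- seq(0, cc, length.out = n_grid + 1)[1:n_grid]
  grid <- expand.grid(x = gx, y = gy, z = gz)
  pot <- 0
  for (ix in -n_images:n_images) for (iy in -n_images:n_images)
    for (iz in -n_images:n_images) {
      r2 <- (grid$x - ix * a)^2 + (grid$y - iy * b)^2 + (grid$z - iz * cc)^2
      pot <- pot + v_atom(r2)
    }
  g <- c(hkl[1] / a, hkl[2] / b, hkl[3] / cc)
  phase <- exp(-2i * pi * (grid$x * g[1] + grid$y * g[2] + grid$z * g[3]))
  omega <- a * b * cc
  dv <- omega / n_grid^3
  # Fourier coefficient of the periodic potential, scaled as U_g
  physics$gamma_rel / (pi * omega) * sum(pot * phase) * dv
}
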