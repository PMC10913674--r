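# Electron atomic scattering factors, structure factors, Fourier potential
# coefficients, extinction distances and beam kinematics.

# CODATA 2018 constants
.planck_h <- 6.62607015e-34      # J s
.m0 <- 9.1093837015e-31          # kg
.e_charge <- 1.602176634e-19     # C
.c_light <- 299792458            # m/s

the_sf_cache <- new.env(parent = emptyenv())

#' Electron scattering-factor parameter table
#'
#' Loads (and caches) the shipped five-Gaussian electron scattering-factor
#' parametrization \eqn{f_e(q) = \sum_i c_i \exp(-d_i q^2)} with
#' \eqn{q = |g| = 1/d} in 1/Angstrom and \eqn{f_e} in Angstrom.  See the
#' header of `inst/extdata/electron_scattering_factors.txt` for provenance.
#'
#' @return A data frame, one row per element (row names are element
#'   symbols), columns `c1,d1,...,c5,d5`.
#' @export
scattering_factor_table <- function() {
  if (!is.null(the_sf_cache$table)) return(the_sf_cache$table)
  path <- system.file("extdata", "electron_scattering_factors.txt",
                      package = "dynED", mustWork = TRUE)
  raw <- read.table(path, comment.char = "#", stringsAsFactors = FALSE)
  names(raw) <- c("element", paste0(c("c", "d"), rep(1:5, each = 2)))
  rownames(raw) <- raw$element
  the_sf_cache$table <- raw[, -1]
  the_sf_cache$table
}

#' Relativistic electron wavelength
#'
#' \eqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / 2 m_0 c^2)}} and the
#' relativistic mass factor \eqn{\gamma = 1 + eV / m_0 c^2}.
#'
#' @param voltage Accelerating voltage in volts (> 0).
#' @return List with `lambda` (Angstrom) and `gamma_rel`.
#' @examples
#' relativistic_wavelength(200e3)$lambda  # ~0.02508 A
#' @export
relativistic_wavelength <- function(voltage) {
  stopifnot(voltage > 0)
  lam <- .planck_h / sqrt(2 * .m0 * .e_charge * voltage *
                            (1 + .e_charge * voltage / (2 * .m0 * .c_light^2)))
  list(lambda = lam * 1e10,
       gamma_rel = 1 + .e_charge * voltage / (.m0 * .c_light^2))
}

#' Beam physics for a given accelerating voltage
#'
#' @param voltage Accelerating voltage in volts.
#' @return Object of class `"beam_physics"`: `voltage`, `lambda` (Angstrom),
#'   `gamma_rel`, `k0` = 1/lambda (1/Angstrom).
#' @export
beam_physics <- function(voltage) {
  rw <- relativistic_wavelength(voltage)
  structure(list(voltage = voltage, lambda = rw$lambda,
                 gamma_rel = rw$gamma_rel, k0 = 1 / rw$lambda),
            class = "beam_physics")
}

#' @export
print.beam_physics <- function(x, ...) {
  cat(sprintf("<beam_physics> %.0f kV: lambda = %.6f A, gamma = %.4f, k0 = %.3f 1/A\n",
              x$voltage / 1e3, x$lambda, x$gamma_rel, x$k0))
  invisible(x)
}

#' Electron atomic scattering factor
#'
#' @param element Element symbol (vectorized over `q`, scalar element).
#' @param q Scattering-vector magnitude \eqn{|g| = 1/d} in 1/Angstrom (>= 0).
#' @return f(q) in Angstrom.
#' @export
scattering_factor <- function(element, q) {
  stopifnot(all(q >= 0))
  el <- normalize_element(element)
  p <- as.numeric(scattering_factor_table()[el, ])
  cs <- p[seq(1, 9, 2)]; ds <- p[seq(2, 10, 2)]
  vapply(q, function(qq) sum(cs * exp(-ds * qq^2)), numeric(1))
}

#' Structure factor F_g
#'
#' \eqn{F_g = \sum_j occ_j f_j(|g|) \exp(-2\pi i\, g\cdot r_j)} with
#' \eqn{g \cdot r_j = h x_j + k y_j + l z_j} summed over all atoms in the
#' unit cell.
#'
#' @param structure A [crystal_structure()] object.
#' @param hkl Integer 3-vector, or n x 3 matrix of Miller indices.
#' @param basis Optional precomputed [reciprocal_basis()] (avoids rebuilding).
#' @return Complex F_g in Angstrom (vector for matrix `hkl`).
#' @export
structure_factor <- function(structure, hkl, basis = NULL) {
  if (is.null(basis)) basis <- reciprocal_basis(structure$lattice)
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  g <- hkl %*% basis$recip
  q <- sqrt(rowSums(g^2))
  at <- structure$atoms
  f_el <- lapply(unique(at$element), function(el) scattering_factor(el, q))
  names(f_el) <- unique(at$element)
  out <- complex(length(q))
  phase_arg <- hkl %*% t(as.matrix(at[, c("x", "y", "z")]))  # n_hkl x n_atom
  for (j in seq_len(nrow(at))) {
    out <- out + at$occupancy[j] * f_el[[at$element[j]]] *
      exp(-2i * pi * phase_arg[, j])
  }
  if (length(out) == 1L) out[[1]] else out
}

#' Fourier coefficient of the (relativistically corrected) crystal potential
#'
#' \eqn{U_g = \gamma_{rel} F_g / (\pi \Omega)} in 1/Angstrom^2; the
#' relativistic mass correction enters once, here.
#'
#' @inheritParams structure_factor
#' @param physics A [beam_physics()] object.
#' @return Complex U_g in 1/Angstrom^2.
#' @export
fourier_potential_coefficient <- function(structure, hkl, physics, basis = NULL) {
  omega <- cell_volume(structure$lattice)
  physics$gamma_rel * structure_factor(structure, hkl, basis) / (pi * omega)
}

#' Mean-inner-potential-corrected wavevector magnitude K
#'
#' \eqn{K = \sqrt{k_0^2 + U_0}} with
#' \eqn{U_0 = \gamma_{rel} F_{000} / (\pi \Omega)},
#' \eqn{F_{000} = \sum_j occ_j f_j(0)}.
#'
#' @inheritParams fourier_potential_coefficient
#' @return K in 1/Angstrom (>= k0).
#' @export
corrected_wavevector <- function(structure, physics) {
  u0 <- Re(fourier_potential_coefficient(structure, c(0, 0, 0), physics))
  sqrt(physics$k0^2 + u0)
}

#' Extinction distance
#'
#' \eqn{\xi_g = K / |U_g|}: the depth period of the two-beam thickness
#' oscillation at the exact Bragg condition.
#'
#' @inheritParams fourier_potential_coefficient
#' @return xi_g in Angstrom.
#' @export
extinction_distance <- function(structure, hkl, physics, basis = NULL) {
  ug <- fourier_potential_coefficient(structure, hkl, physics, basis)
  if (any(abs(ug) < 1e-14))
    stop("undefined extinction distance: F_g = 0", call. = FALSE)
  corrected_wavevector(structure, physics) / abs(ug)
}
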