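# Bloch-wave reference solver: Hermitian eigen-decomposition of the
# structure matrix and exact depth propagation phi(z) = exp(2 pi i A z) phi(0).

#' Bloch-wave eigen-decomposition of the structure matrix
#'
#' @param A Hermitian structure matrix from [assemble_structure_matrix()].
#' @param tol Relative Hermiticity tolerance for the input guard.
#' @return Object of class `"bloch_decomposition"`: list with real
#'   eigenvalues `gamma` (descending), unitary eigenvector matrix `C`
#'   (columns are Bloch-wave Fourier coefficients, phase-fixed so the
#'   largest-magnitude component of each column is real positive), and the
#'   matrix attributes (`beams`, `i000`).
#' @export
bloch_decompose <- function(A, tol = 1e-8) {
  scale <- max(abs(A), 1e-300)
  if (hermitian_check(A) > tol * scale)
    stop("structure matrix is not Hermitian within tolerance (elastic-only scope)",
         call. = FALSE)
  es <- eigen((A + Conj(t(A))) / 2, symmetric = TRUE)
  C <- es$vectors
  # deterministic phase: largest-magnitude component of each column real positive
  for (j in seq_len(ncol(C))) {
    i <- which.max(abs(C[, j]))
    ph <- C[i, j] / abs(C[i, j])
    C[, j] <- C[, j] / ph
  }
  structure(list(gamma = es$values, C = C,
                 beams = attr(A, "beams"), i000 = attr(A, "i000")),
            class = "bloch_decomposition")
}

#' Exact depth propagation of the diffracted-beam amplitudes
#'
#' \eqn{\phi(z) = C \,\mathrm{diag}(e^{2\pi i \gamma^{(j)} z})\, C^\dagger
#' \phi(0)}; the default initial state is the unscattered beam,
#' \eqn{\phi_g(0) = \delta_{g,0}}.
#'
#' @param decomp A [bloch_decompose()] object.
#' @param depths Non-negative depths z in Angstrom.
#' @param initial Optional complex initial amplitudes over the active beams.
#' @return A `"pendellosung"` result (see [pendellosung_result()]).
#' @export
propagate_bloch <- function(decomp, depths, initial = NULL) {
  if (any(depths < 0)) stop("depths must be non-negative", call. = FALSE)
  nb <- length(decomp$gamma)
  if (is.null(initial)) {
    initial <- complex(nb); initial[decomp$i000] <- 1 + 0i
  }
  proj <- Conj(t(decomp$C)) %*% initial           # C^H phi0
  I <- matrix(0, length(depths), nb)
  amps <- matrix(0 + 0i, length(depths), nb)
  for (iz in seq_along(depths)) {
    phi <- decomp$C %*% (exp(2i * pi * decomp$gamma * depths[iz]) * proj)
    amps[iz, ] <- phi
    I[iz, ] <- Mod(phi)^2
  }
  pendellosung_result(depths, I, decomp$beams,
                      meta = list(solver = "bloch"), amplitudes = amps)
}

#' Pendellösung result container
#'
#' Beam intensities I_g(z) on a depth grid for one orientation (or a
#' precession average).
#'
#' @param z Depth grid in Angstrom.
#' @param intensity Matrix `length(z)` x `n_beams` of |phi_g|^2.
#' @param beams Data frame of beam labels (columns `h`, `k`, ...).
#' @param meta List of run metadata (solver, voltage, g_max, s_max, dz, ...).
#' @param amplitudes Optional complex amplitude matrix (same shape).
#' @return Object of class `"pendellosung"`.
#' @export
pendellosung_result <- function(z, intensity, beams, meta = list(),
                                amplitudes = NULL) {
  stopifnot(length(z) == nrow(intensity), nrow(beams) == ncol(intensity))
  structure(list(z = z, intensity = intensity,
                 beams = as.data.frame(beams)[, c("h", "k")],
                 meta = meta, amplitudes = amplitudes),
            class = "pendellosung")
}

#' @export
print.pendellosung <- function(x, ...) {
  cat(sprintf("<pendellosung> %s: %d beams, %d depths (%.0f..%.0f A)\n",
              if (is.null(x$meta$solver)) "?" else x$meta$solver,
              ncol(x$intensity), length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Total intensity at each depth
#'
#' For an elastic Bloch calculation this is conserved (unitarity); for the
#' forward-Euler scattering cluster algorithm it drifts with slice
#' thickness and depth.
#'
#' @param result A `"pendellosung"` object.
#' @return Numeric vector, one value per depth.
#' @export
total_intensity <- function(result) {
  rowSums(result$intensity)
}

#' Extract one beam's intensity profile
#'
#' @param result A `"pendellosung"` object.
#' @param h,k Miller indices of the beam.
#' @return Numeric vector I_hk(z).
#' @export
beam_intensity <- function(result, h, k) {
  i <- which(result$beams$h == h & result$beams$k == k)
  if (length(i) != 1L) stop("beam (", h, ",", k, ") not in result", call. = FALSE)
  result$intensity[, i]
}

#' Minimal pendellösung plot
#'
#' @param x A `"pendellosung"` object.
#' @param beams Data frame or matrix of (h, k) rows to plot; default 000.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.pendellosung <- function(x, beams = data.frame(h = 0, k = 0), ...) {
  beams <- as.data.frame(beams)
  Y <- sapply(seq_len(nrow(beams)),
              function(i) beam_intensity(x, beams[i, 1], beams[i, 2]))
  graphics::matplot(x$z, Y, type = "l", xlab = "depth z (A)",
                    ylab = "beam intensity", ...)
  invisible(x)
}
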