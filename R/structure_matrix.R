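# Cluster-truncated structure-matrix terms and assembly of the Hermitian
# structure matrix A: diagonal A_gg = s_g, off-diagonal A_gh = U_{g-h}/(2 K_n)
# for |g - h| <= g_max, zero outside the cluster.

#' Cluster potential: the unique non-diagonal couplings
#'
#' Evaluates the Fourier potential coefficients U_Delta for every ZOLZ
#' difference vector Delta with |Delta| <= g_max.  Because the crystal
#' potential is real, U_{-Delta} = Conj(U_Delta); only one member of each
#' +/-Delta pair is computed from the structure, the mate is filled by
#' conjugation.  The stored values are geometry-free: the 1/(2 K_n) factor
#' is applied at assembly time, so one cluster potential serves every
#' incident-beam orientation of a tilt or precession series.
#'
#' @param structure A [crystal_structure()] object.
#' @param basis A [reciprocal_basis()] for the same lattice.
#' @param g_max Cluster radius in 1/Angstrom (`Inf` allowed only with
#'   `members` supplied).
#' @param physics A [beam_physics()] object.
#' @param members Optional precomputed [cluster_members()] data frame.
#' @return Object of class `"cluster_potential"`: data frame with columns
#'   `dh`, `dk`, `gmag`, `U` (complex, 1/Angstrom^2); attributes `g_max`
#'   and `n_unique` (couplings actually evaluated from the structure).
#' @export
compute_cluster_potential <- function(structure, basis, g_max, physics,
                                      members = NULL) {
  if (is.null(members)) members <- cluster_members(basis, g_max)
  n <- nrow(members)
  U <- complex(n)
  done <- rep(FALSE, n)
  key <- paste(members$dh, members$dk)
  mate <- match(paste(-members$dh, -members$dk), key)
  n_unique <- 0L
  for (i in seq_len(n)) {
    if (done[i]) next
    U[i] <- fourier_potential_coefficient(
      structure, c(members$dh[i], members$dk[i], 0), physics, basis)
    done[i] <- TRUE
    n_unique <- n_unique + 1L
    j <- mate[i]
    if (!is.na(j) && !done[j]) { U[j] <- Conj(U[i]); done[j] <- TRUE }
  }
  out <- members
  out$U <- U
  structure(out, g_max = g_max, n_unique = n_unique,
            class = c("cluster_potential", "data.frame"))
}

#' Assemble the structure matrix for one incident-beam orientation
#'
#' @param beams A [beam_grid()]/[beam_set()] object.
#' @param cluster A [compute_cluster_potential()] object.
#' @param s Deviation parameters for every beam of `beams` (1/Angstrom).
#' @param K_n Surface-normal component of the incident wavevector
#'   (1/Angstrom).
#' @param active Logical mask of active beams (default: all); the matrix is
#'   restricted to active beams.
#' @return Complex Hermitian matrix over the active beams, with attributes
#'   `beams` (active-beam data frame), `active`, `i000` (index of 000 among
#'   active beams), `K_n`.
#' @export
assemble_structure_matrix <- function(beams, cluster, s, K_n,
                                      active = rep(TRUE, nrow(beams))) {
  if (length(s) != nrow(beams))
    stop("dimension mismatch: deviation parameters vs beam set", call. = FALSE)
  if (length(active) != nrow(beams))
    stop("dimension mismatch: active mask vs beam set", call. = FALSE)
  idx <- which(active)
  nb <- length(idx)
  h <- beams$h[idx]; k <- beams$k[idx]
  A <- matrix(0 + 0i, nb, nb)
  # off-diagonals: look up U_{g-h} by integer index difference
  dh <- outer(h, h, "-"); dk <- outer(k, k, "-")
  pos <- match(dh * 1e6 + dk, cluster$dh * 1e6 + cluster$dk)
  hit <- !is.na(pos)
  A[hit] <- cluster$U[pos[hit]] / (2 * K_n)
  diag(A) <- s[idx]
  i000_all <- attr(beams, "i000")
  structure(A, beams = beams[idx, , drop = FALSE], active = active,
            i000 = match(i000_all, idx), K_n = K_n)
}

#' Hermiticity guard
#'
#' @param A Complex square matrix.
#' @return max |A_gh - Conj(A_hg)|.
#' @export
hermitian_check <- function(A) {
  max(abs(A - Conj(t(A))))
}
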