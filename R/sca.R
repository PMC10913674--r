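# Scattering cluster algorithm: slice-by-slice integration of
# d(phi)/dz = 2 pi i A phi with the cluster-truncated, s_max-filtered
# structure matrix.

#' SCA configuration
#'
#' The three input parameters of the scattering cluster algorithm, plus the
#' depth bookkeeping.
#'
#' @param g_max Cluster radius in 1/Angstrom (`Inf` retains every
#'   coupling of the beam set).
#' @param dz Slice thickness in Angstrom (> 0).
#' @param s_max Maximum deviation parameter in 1/Angstrom, `"auto"` for the
#'   [smax_default()] rule, or `Inf` to disable the filter.
#' @param thickness Total specimen thickness in Angstrom.
#' @param record_z Approximate depth spacing of stored samples in Angstrom
#'   (the stride is `max(1, round(record_z / dz))` slices).
#' @param method Integration scheme: `"euler"` (default, the algorithm as
#'   described) or `"rk4"`.
#' @return Object of class `"sca_config"`.
#' @export
sca_config <- function(g_max, dz, s_max = "auto", thickness = 1000,
                       record_z = 10, method = c("euler", "rk4")) {
  stopifnot(dz > 0, thickness >= dz)
  method <- match.arg(method)
  structure(list(g_max = g_max, dz = dz, s_max = s_max, thickness = thickness,
                 record_z = record_z, method = method),
            class = "sca_config")
}

#' One SCA slice step
#'
#' Forward-Euler update `phi + 2 pi i dz (A phi)`: a single matrix-vector
#' product.
#'
#' @param A Structure matrix over the active beams.
#' @param phi Complex amplitudes of the active beams.
#' @param dz Slice thickness in Angstrom.
#' @return Updated amplitudes.
#' @export
sca_step <- function(A, phi, dz) {
  if (length(phi) != nrow(A))
    stop("dimension mismatch: amplitudes vs structure matrix", call. = FALSE)
  phi + (2i * pi * dz) * drop(A %*% phi)
}

#' Integrate the SCA through the specimen depth
#'
#' Repeats [sca_step()] (or the RK4 variant) for
#' `round(thickness / dz)` slices, recording intensities every stride.
#'
#' @param A Structure matrix over the active beams (from
#'   [assemble_structure_matrix()]).
#' @param config An [sca_config()].
#' @param initial Optional complex initial amplitudes; default is the
#'   unscattered beam, `phi_g(0) = delta_g0`.
#' @return A `"pendellosung"` result over the active beams.
#' @export
sca_propagate <- function(A, config, initial = NULL) {
  nb <- nrow(A)
  if (is.null(initial)) {
    initial <- complex(nb); initial[attr(A, "i000")] <- 1 + 0i
  }
  nsteps <- round(config$thickness / config$dz)
  stride <- max(1L, as.integer(round(config$record_z / config$dz)))
  out <- sca_propagate_cpp(unclass(A), initial, config$dz, as.integer(nsteps),
                           stride, if (config$method == "euler") 0L else 1L)
  pendellosung_result(drop(out$z), out$intensity, attr(A, "beams"),
                      meta = list(solver = "sca", dz = config$dz,
                                  method = config$method,
                                  g_max = config$g_max))
}

resolve_smax <- function(s_max, physics, g_max) {
  if (identical(s_max, "auto")) {
    if (!is.finite(g_max))
      stop("s_max = 'auto' needs a finite g_max", call. = FALSE)
    smax_default(physics$lambda, g_max)
  } else s_max
}

#' Run a full simulation for one incident-beam orientation
#'
#' Orchestrates the pipeline: cluster potential -> deviation parameters ->
#' s_max filter -> structure-matrix assembly -> depth integration, with
#' either solver.  Beams excluded by the s_max filter are reported with
#' zero intensity.
#'
#' @param structure A [crystal_structure()] object.
#' @param beams A [beam_grid()]/[beam_set()] over the structure's lattice.
#' @param physics A [beam_physics()] object.
#' @param config An [sca_config()]; for the Bloch solver `dz`/`method` are
#'   ignored and `g_max`/`s_max` may be `Inf`.
#' @param solver `"sca"` or `"bloch"`.
#' @param tilt_polar,azimuth Incident-beam tilt in degrees (0 = zone-axis
#'   incidence).
#' @param cluster Optional precomputed [compute_cluster_potential()] (reused
#'   across orientations of a tilt/precession series).
#' @return A `"pendellosung"` result over the *full* beam set (inactive
#'   beams zero), with counts and configuration in `meta`.
#' @export
run_simulation <- function(structure, beams, physics, config,
                           solver = c("sca", "bloch"),
                           tilt_polar = 0, azimuth = 0, cluster = NULL) {
  solver <- match.arg(solver)
  basis <- attr(beams, "basis")
  if (is.null(cluster)) {
    cluster <- if (is.finite(config$g_max))
      compute_cluster_potential(structure, basis, config$g_max, physics)
    else
      compute_cluster_potential(structure, basis, Inf, physics,
                                members = all_pair_differences(beams, basis))
  }
  Kmag <- corrected_wavevector(structure, physics)
  geom <- incident_wavevector(basis, Kmag, tilt_polar, azimuth)
  s <- deviation_parameters(geom, beams)
  s_max <- resolve_smax(config$s_max, physics, config$g_max)
  active <- filter_beams(s, s_max, attr(beams, "i000"))
  A <- assemble_structure_matrix(beams, cluster, s, geom$K_n, active)
  res <- if (solver == "sca") {
    sca_propagate(A, config)
  } else {
    depths <- unique(c(seq(0, config$thickness, by = config$record_z),
                       config$thickness))
    propagate_bloch(bloch_decompose(A), depths)
  }
  # re-embed into the full beam set with zeros for filtered-out beams
  I_full <- matrix(0, length(res$z), nrow(beams))
  I_full[, which(active)] <- res$intensity
  pendellosung_result(res$z, I_full, beams,
                      meta = list(solver = solver, voltage = physics$voltage,
                                  g_max = config$g_max, s_max = s_max,
                                  dz = if (solver == "sca") config$dz else NA,
                                  method = if (solver == "sca") config$method else "eigen",
                                  tilt_polar = tilt_polar, azimuth = azimuth,
                                  n_beams = nrow(beams),
                                  n_active = sum(active),
                                  n_cluster = nrow(cluster),
                                  n_unique_couplings = attr(cluster, "n_unique")))
}

# every distinct nonzero (dh, dk) difference realisable within a beam set
# (used for g_max = Inf: the untruncated dense structure matrix)
all_pair_differences <- function(beams, basis) {
  nh <- max(abs(beams$h)); nk <- max(abs(beams$k))
  hk <- expand.grid(dk = -(2 * nk):(2 * nk), dh = -(2 * nh):(2 * nh))[, c("dh", "dk")]
  hk <- hk[!(hk$dh == 0 & hk$dk == 0), ]
  g <- as.matrix(hk) %*% basis$recip[1:2, ]
  out <- data.frame(dh = hk$dh, dk = hk$dk, gmag = sqrt(rowSums(g^2)))
  rownames(out) <- NULL
  out
}
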