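# ZOLZ beam sets, incident wavevectors (normal and precessed), deviation
# parameters, the s_max filter and cluster membership.

#' ZOLZ beam set on a rectangular index grid
#'
#' All reflections (h, k, 0) with |h| <= N_h and |k| <= N_k in row-major
#' order, for a crystal oriented on the [001] zone axis.  The (hk0) plane is
#' perpendicular to the direct-lattice c axis, which is taken as the
#' specimen surface normal.
#'
#' @param basis A [reciprocal_basis()] object.
#' @param N_h,N_k Non-negative grid half-extents.
#' @param zone Zone axis; only `c(0, 0, 1)` is supported.
#' @return Object of class `"beam_set"`: data frame with columns `h`, `k`,
#'   `gx`, `gy`, `gz`, `gmag`; attributes `i000` (row index of the 000
#'   beam) and `basis`.
#' @examples
#' bs <- beam_grid(reciprocal_basis(reference_lattice("tips_pentacene")), 10, 10)
#' nrow(bs)  # 441
#' @export
beam_grid <- function(basis, N_h, N_k, zone = c(0, 0, 1)) {
  stopifnot(N_h >= 0, N_k >= 0)
  if (!identical(as.numeric(zone), c(0, 0, 1)))
    stop("only the [001] zone axis is supported", call. = FALSE)
  hk <- expand.grid(k = -N_k:N_k, h = -N_h:N_h)[, c("h", "k")]
  beam_set(basis, as.matrix(hk))
}

#' Beam set from an explicit (h, k) index list
#'
#' @param basis A [reciprocal_basis()] object.
#' @param hk Integer matrix with two columns (h, k); must contain (0, 0).
#' @return A `"beam_set"` (see [beam_grid()]).
#' @export
beam_set <- function(basis, hk) {
  hk <- matrix(as.integer(hk), ncol = 2)
  i000 <- which(hk[, 1] == 0L & hk[, 2] == 0L)
  if (length(i000) != 1L)
    stop("beam set must contain the 000 beam exactly once", call. = FALSE)
  g <- cbind(hk, 0) %*% basis$recip
  df <- data.frame(h = hk[, 1], k = hk[, 2], gx = g[, 1], gy = g[, 2],
                   gz = g[, 3], gmag = sqrt(rowSums(g^2)))
  structure(df, i000 = i000, basis = basis, class = c("beam_set", "data.frame"))
}

#' Incident-beam geometry
#'
#' The specimen surface normal n is the unit vector along the direct c axis
#' (flat, untilted foil on the [001] zone).  The incident wavevector has the
#' mean-inner-potential-corrected magnitude `K_mag` and makes the polar
#' angle `tilt_polar` with n; the azimuth is measured about n from the a*
#' direction.
#'
#' @param basis A [reciprocal_basis()] object.
#' @param K_mag Corrected wavevector magnitude in 1/Angstrom
#'   (from [corrected_wavevector()]).
#' @param tilt_polar Polar tilt from the zone axis in degrees, in [0, 90).
#' @param azimuth Azimuthal angle in degrees.
#' @return Object of class `"incident_geometry"`: list with unit normal `n`,
#'   Cartesian wavevector `K` (1/Angstrom), `K_mag`, `K_n` = K . n,
#'   `tilt_polar`, `azimuth`.
#' @export
incident_wavevector <- function(basis, K_mag, tilt_polar = 0, azimuth = 0) {
  stopifnot(tilt_polar >= 0, tilt_polar < 90, K_mag > 0)
  n <- basis$direct["c", ]; n <- n / sqrt(sum(n^2))
  e1 <- basis$recip["a*", ]; e1 <- e1 - sum(e1 * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  tp <- tilt_polar * pi / 180; az <- azimuth * pi / 180
  Kvec <- K_mag * (cos(tp) * n + sin(tp) * (cos(az) * e1 + sin(az) * e2))
  structure(list(n = n, K = Kvec, K_mag = K_mag, K_n = K_mag * cos(tp),
                 tilt_polar = tilt_polar, azimuth = azimuth),
            class = "incident_geometry")
}

#' Deviation parameters (excitation errors)
#'
#' \eqn{s_g = -(|g|^2 + 2 K\cdot g) / (2 K_n)}: positive when g lies inside
#' the Ewald sphere, zero exactly on it.
#'
#' @param geometry An [incident_wavevector()] object.
#' @param beams A [beam_grid()]/[beam_set()] object (or an n x 3 matrix of
#'   Cartesian g vectors).
#' @return Numeric vector s_g in 1/Angstrom.
#' @export
deviation_parameters <- function(geometry, beams) {
  g <- if (inherits(beams, "beam_set")) as.matrix(beams[, c("gx", "gy", "gz")])
       else as.matrix(beams)
  unname(-(rowSums(g^2) + 2 * drop(g %*% geometry$K)) / (2 * geometry$K_n))
}

#' Default maximum deviation parameter
#'
#' The rule \eqn{s_{max} = (\lambda/2)(g_{max}/2)^2}: the excitation-error
#' magnitude at half the cluster radius for normal beam incidence.
#'
#' @param lambda Electron wavelength in Angstrom.
#' @param g_max Cluster radius in 1/Angstrom.
#' @return s_max in 1/Angstrom.
#' @export
smax_default <- function(lambda, g_max) {
  stopifnot(lambda > 0, g_max > 0)
  (lambda / 2) * (g_max / 2)^2
}

#' Beam activity mask from the s_max filter
#'
#' Beams with |s_g| > s_max are excluded from the propagation state and
#' reported with zero intensity; the 000 beam is always active.
#'
#' @param s Deviation parameters (1/Angstrom).
#' @param s_max Threshold in 1/Angstrom (`Inf` disables the filter).
#' @param i000 Index of the 000 beam.
#' @return Logical mask of active beams.
#' @export
filter_beams <- function(s, s_max, i000) {
  stopifnot(s_max >= 0)
  active <- abs(s) <= s_max
  active[i000] <- TRUE
  active
}

# relative tolerance used to keep lattice points lying exactly on the
# cluster/filter radius inside the closed ball despite floating-point
# rounding of |g|
.radius_tol <- 1e-9

#' Scattering-cluster membership
#'
#' All nonzero ZOLZ lattice vectors with |g| <= g_max (closed ball; a 1e-9
#' relative tolerance keeps points exactly on the boundary inside).  The
#' list is closed under g -> -g.
#'
#' @param basis A [reciprocal_basis()] object.
#' @param g_max Cluster radius in 1/Angstrom.  Symbolic multiples of a
#'   reciprocal basis vector can be formed with e.g.
#'   `5 * sqrt(sum(basis$recip["a*", ]^2))`.
#' @param zone Zone axis; only `c(0, 0, 1)` is supported.
#' @return Data frame with columns `dh`, `dk`, `gmag`, ordered row-major in
#'   (dh, dk).
#' @examples
#' rb <- reciprocal_basis(reference_lattice("rubrene"))
#' b_star <- sqrt(sum(rb$recip["b*", ]^2))
#' nrow(cluster_members(rb, 8 * b_star))  # 734
#' @export
cluster_members <- function(basis, g_max, zone = c(0, 0, 1)) {
  stopifnot(g_max > 0)
  if (!identical(as.numeric(zone), c(0, 0, 1)))
    stop("only the [001] zone axis is supported", call. = FALSE)
  astar <- basis$recip["a*", ]; bstar <- basis$recip["b*", ]
  # conservative index bounds from the in-plane cell geometry
  amag <- sqrt(sum(astar^2)); bmag <- sqrt(sum(bstar^2))
  cosab <- sum(astar * bstar) / (amag * bmag)
  sinab <- sqrt(max(1 - cosab^2, 1e-12))
  nh <- ceiling(g_max / (amag * sinab)) + 1L
  nk <- ceiling(g_max / (bmag * sinab)) + 1L
  hk <- expand.grid(dk = -nk:nk, dh = -nh:nh)[, c("dh", "dk")]
  hk <- hk[!(hk$dh == 0 & hk$dk == 0), ]
  g <- as.matrix(hk) %*% rbind(astar, bstar)
  gmag <- sqrt(rowSums(g^2))
  keep <- gmag <= g_max * (1 + .radius_tol)
  out <- data.frame(dh = hk$dh[keep], dk = hk$dk[keep], gmag = gmag[keep])
  rownames(out) <- NULL
  out
}

#' Two-beam first rocking-curve minimum thickness
#'
#' In two-beam dynamical theory the rocking pattern of a reflection with
#' excitation error s and extinction distance xi has its first thickness
#' minimum at \eqn{t = 1/\sqrt{s^2 + \xi^{-2}}}.  For light-element organic
#' crystals xi is large, so \eqn{t \approx 1/s}.
#'
#' @param s Excitation error in 1/Angstrom.
#' @param xi Extinction distance in Angstrom (`Inf` for the light-element
#'   limit).
#' @return Thickness in Angstrom.
#' @export
two_beam_first_minimum_thickness <- function(s, xi = Inf) {
  if (s == 0 && !is.finite(xi))
    stop("undefined: s = 0 with infinite extinction distance", call. = FALSE)
  1 / sqrt(s^2 + 1 / xi^2)
}
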