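# Convergence metrics: the L1 intensity R factor and depth profiles.

#' Intensity R factor
#'
#' \eqn{R = \sum_g |I_{test,g} - I_{ref,g}| / \sum_g I_{ref,g}}, summed over
#' beams with `I_ref >= floor * max(I_ref)`.  The floor exists because the
#' dynamic range of diffracted intensities spans many orders of magnitude
#' and the weakest beams can dominate an unfloored R; the default (0)
#' includes every beam.
#'
#' @param I_test,I_ref Per-beam intensities on matching beam labels.
#' @param floor Relative inclusion threshold in [0, 1].
#' @return Dimensionless R >= 0.
#' @export
r_factor <- function(I_test, I_ref, floor = 0) {
  if (length(I_test) != length(I_ref))
    stop("intensity vectors must match beam-for-beam", call. = FALSE)
  keep <- I_ref >= floor * max(I_ref)
  denom <- sum(I_ref[keep])
  if (denom == 0) stop("undefined R factor: reference intensities sum to zero",
                       call. = FALSE)
  sum(abs(I_test[keep] - I_ref[keep])) / denom
}

#' R factor as a function of depth
#'
#' @param result_test,result_ref `"pendellosung"` results on identical depth
#'   grids and beam sets.
#' @param floor Relative inclusion threshold (see [r_factor()]).
#' @return Data frame with columns `z` and `R`.
#' @export
r_profile <- function(result_test, result_ref, floor = 0) {
  if (length(result_test$z) != length(result_ref$z) ||
      max(abs(result_test$z - result_ref$z)) > 1e-9)
    stop("depth grids do not match (interpolation refused)", call. = FALSE)
  if (!identical(result_test$beams, result_ref$beams))
    stop("beam sets do not match", call. = FALSE)
  R <- vapply(seq_along(result_test$z), function(i)
    r_factor(result_test$intensity[i, ], result_ref$intensity[i, ], floor),
    numeric(1))
  data.frame(z = result_test$z, R = R)
}
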