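# Result and configuration serialization: tidy CSV for pendellösung data,
# YAML for run configurations.

#' Write a pendellösung result as tidy CSV
#'
#' Columns `z`, `h`, `k`, `intensity`, one row per (depth, beam).
#'
#' @param result A `"pendellosung"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pendellosung <- function(result, path) {
  nb <- nrow(result$beams)
  df <- data.frame(
    z = rep(result$z, times = nb),
    h = rep(result$beams$h, each = length(result$z)),
    k = rep(result$beams$k, each = length(result$z)),
    intensity = as.vector(result$intensity))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy pendellösung CSV back into a result object
#'
#' @param path File written by [write_pendellosung()].
#' @return A `"pendellosung"` object (without metadata).
#' @export
read_pendellosung <- function(path) {
  df <- read.csv(path)
  z <- sort(unique(df$z))
  beams <- unique(df[, c("h", "k")])
  rownames(beams) <- NULL
  ord <- order(match(paste(df$h, df$k), paste(beams$h, beams$k)), df$z)
  I <- matrix(df$intensity[ord], nrow = length(z))
  pendellosung_result(z, I, beams)
}

run_config_keys <- c("structure", "seed", "voltage", "N_h", "N_k", "solver",
                     "g_max", "s_max", "dz", "thickness", "record_z",
                     "method", "phi_p", "n_azimuths")

#' Read a run configuration from YAML
#'
#' Known keys (units: volts, Angstrom, 1/Angstrom, degrees):
#' `structure` (CIF path or toy-fixture name), `seed`, `voltage`, `N_h`,
#' `N_k`, `solver` ("bloch"/"sca"), `g_max`, `s_max` (number, "auto" or
#' `.inf`), `dz`, `thickness`, `record_z`, `method`, `phi_p`, `n_azimuths`.
#' `g_max` and `s_max` may also be symbolic multiples of an in-plane
#' reciprocal vector, e.g. `"10g100"` or `"8g010"`, resolved against the
#' structure's lattice.
#'
#' @param path YAML file.
#' @return Named list of class `"run_config"` with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in c("structure", "voltage")) {
    if (is.null(cfg[[key]]))
      stop("missing required configuration key: ", key, call. = FALSE)
  }
  defaults <- list(seed = 1, N_h = 10, N_k = 10, solver = "bloch",
                   g_max = Inf, s_max = Inf, dz = 0.2, thickness = 1000,
                   record_z = 10, method = "euler", phi_p = 0, n_azimuths = 1)
  for (key in names(defaults)) if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#'
#' @param config Named list (e.g. from [read_run_config()], possibly with
#'   symbolic values resolved to literals).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Resolve a symbolic reciprocal-space quantity
#'
#' Accepts a number, `"auto"`, `"inf"`, or a string like `"10g100"` /
#' `"8g010"` meaning that multiple of the in-plane reciprocal-vector
#' magnitude |g_100| or |g_010| of the given lattice.
#'
#' @param x Value to resolve.
#' @param basis A [reciprocal_basis()] object.
#' @return Numeric value in 1/Angstrom (or the string `"auto"`, passed
#'   through for downstream resolution).
#' @export
resolve_symbolic_g <- function(x, basis) {
  if (is.numeric(x)) return(x)
  if (identical(x, "auto")) return("auto")
  if (tolower(x) %in% c("inf", ".inf")) return(Inf)
  m <- regmatches(x, regexec("^([0-9.]+)g(100|010)$", x))[[1]]
  if (length(m) == 3) {
    vec <- if (m[3] == "100") basis$recip["a*", ] else basis$recip["b*", ]
    return(as.numeric(m[2]) * sqrt(sum(vec^2)))
  }
  stop("cannot resolve symbolic value: ", x, call. = FALSE)
}
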