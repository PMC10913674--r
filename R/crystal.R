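# Crystal structures: lattices, reciprocal bases, CIF input, toy fixtures.

#' Lattice parameters
#'
#' Construct a validated set of unit-cell parameters.
#'
#' @param a,b,c Cell edge lengths in Angstrom (> 0).
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class `"lattice"`: a list with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`.
#' @examples
#' lattice_parameters(7.565, 7.750, 16.835, 89.15, 78.42, 83.63)
#' @export
lattice_parameters <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0))
    stop("invalid lattice: cell lengths must be positive", call. = FALSE)
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("invalid lattice: cell angles must lie in (0, 180) degrees", call. = FALSE)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0)
    stop("invalid lattice: degenerate cell (volume discriminant <= 0)", call. = FALSE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma),
            class = "lattice")
}

#' @export
print.lattice <- function(x, ...) {
  cat(sprintf("<lattice> a=%.4f b=%.4f c=%.4f A  alpha=%.3f beta=%.3f gamma=%.3f deg\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' Triclinic closed form
#' \eqn{\Omega = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'   +2\cos\alpha\cos\beta\cos\gamma}}.
#'
#' @param lattice A [lattice_parameters()] object.
#' @return Volume in cubic Angstrom.
#' @export
cell_volume <- function(lattice) {
  ca <- cos(lattice$alpha * pi / 180); cb <- cos(lattice$beta * pi / 180)
  cg <- cos(lattice$gamma * pi / 180)
  lattice$a * lattice$b * lattice$c *
    sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
}

#' Direct and reciprocal Cartesian bases
#'
#' Builds the Cartesian direct basis (a along x, b in the x-y plane, c
#' completing a right-handed set) and its crystallographic reciprocal
#' (without the factor 2*pi), satisfying a_i . a*_j = delta_ij.
#'
#' @param lattice A [lattice_parameters()] object.
#' @return Object of class `"recip_basis"`: list with `direct` (3x3 matrix,
#'   rows a, b, c in Angstrom), `recip` (3x3 matrix, rows a*, b*, c* in
#'   1/Angstrom), `volume` (cubic Angstrom) and the source `lattice`.
#' @examples
#' rb <- reciprocal_basis(lattice_parameters(2, 2, 2))
#' rb$volume                 # 8
#' sqrt(sum(rb$recip[1, ]^2)) # |a*| = 0.5
#' @export
reciprocal_basis <- function(lattice) {
  if (!inherits(lattice, "lattice")) lattice <- do.call(lattice_parameters, as.list(lattice))
  al <- lattice$alpha * pi / 180; be <- lattice$beta * pi / 180; ga <- lattice$gamma * pi / 180
  ca <- cos(al); cb <- cos(be); cg <- cos(ga); sg <- sin(ga)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  av <- c(lattice$a, 0, 0)
  bv <- c(lattice$b * cg, lattice$b * sg, 0)
  cv <- c(lattice$c * cb, lattice$c * (ca - cb * cg) / sg, lattice$c * sqrt(disc) / sg)
  direct <- rbind(a = av, b = bv, c = cv)
  recip <- t(solve(direct))
  rownames(recip) <- c("a*", "b*", "c*")
  structure(list(direct = direct, recip = recip,
                 volume = det(direct), lattice = lattice),
            class = "recip_basis")
}

#' Reciprocal-lattice vector g(hkl)
#'
#' @param basis A [reciprocal_basis()] object.
#' @param h,k,l Miller indices (vectors of equal length are accepted).
#' @return For scalar indices a Cartesian 3-vector in 1/Angstrom; for vector
#'   input an n x 3 matrix.
#' @export
g_vector <- function(basis, h, k, l = 0) {
  hkl <- cbind(h, k, l)
  g <- hkl %*% basis$recip
  colnames(g) <- c("gx", "gy", "gz")
  if (nrow(g) == 1L) drop(g) else g
}

known_elements <- function() {
  rownames(scattering_factor_table())
}

normalize_element <- function(element) {
  el <- paste0(toupper(substr(element, 1, 1)), tolower(substring(element, 2)))
  bad <- !(el %in% known_elements())
  if (any(bad))
    stop("unsupported element symbol(s): ", paste(unique(element[bad]), collapse = ", "),
         call. = FALSE)
  el
}

#' Crystal structure
#'
#' A lattice plus an ordered atom list.  Fractional coordinates are reduced
#' into `[0, 1)`; occupancies multiply scattering factors.
#'
#' @param lattice A [lattice_parameters()] object.
#' @param atoms A data frame with columns `element`, `x`, `y`, `z` and
#'   optionally `occupancy` (default 1).
#' @param label Free-text label.
#' @return Object of class `"crystal"`.
#' @export
crystal_structure <- function(lattice, atoms, label = "") {
  stopifnot(inherits(lattice, "lattice"), is.data.frame(atoms))
  if (nrow(atoms) < 1L) stop("crystal structure needs at least one atom", call. = FALSE)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (any(atoms$occupancy <= 0 | atoms$occupancy > 1))
    stop("occupancies must lie in (0, 1]", call. = FALSE)
  atoms$element <- normalize_element(atoms$element)
  for (cc in c("x", "y", "z")) atoms[[cc]] <- atoms[[cc]] %% 1
  atoms <- atoms[, c("element", "x", "y", "z", "occupancy")]
  rownames(atoms) <- NULL
  structure(list(lattice = lattice, atoms = atoms, label = label),
            class = "crystal")
}

#' @export
print.crystal <- function(x, ...) {
  cat(sprintf("<crystal> %s: %d atoms (%s), Omega = %.2f A^3\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$atoms),
              paste(names(table(x$atoms$element)), collapse = ","),
              cell_volume(x$lattice)))
  print(x$lattice)
  invisible(x)
}

# ---- CIF input/output (minimal, small-molecule dialect) --------------------

strip_su <- function(s) as.numeric(sub("\\(.*\\)", "", s))

cif_tokens <- function(line) {
  # CIF values are whitespace-separated; quoted strings may contain spaces
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

parse_symop <- function(op) {
  # e.g. "-x, y+1/2, 1/2-z" -> function(xyz) xyz'
  parts <- strsplit(tolower(op), ",")[[1]]
  if (length(parts) != 3L) stop("CIF parse error: bad symmetry operation '", op, "'",
                                call. = FALSE)
  exprs <- lapply(parts, function(p) {
    p <- gsub("\\s", "", p)
    if (!grepl("^[xyz0-9+/*.-]+$", p))
      stop("CIF parse error: bad symmetry operation '", op, "'", call. = FALSE)
    parse(text = p)[[1]]
  })
  function(xyz) {
    env <- list2env(list(x = xyz[1], y = xyz[2], z = xyz[3]))
    vapply(exprs, eval, numeric(1), envir = env)
  }
}

#' Read a crystal structure from a CIF file
#'
#' Minimal CIF reader: extracts cell parameters and the `atom_site` loop,
#' and expands symmetry operations (from `_symmetry_equiv_pos_as_xyz` or
#' `_space_group_symop_operation_xyz`) so the atom list covers the full unit
#' cell.  Atoms generated by symmetry that fall within 1e-3 fractional
#' distance of an existing atom are de-duplicated (special positions).
#'
#' @param path Path to a CIF file.
#' @return A [crystal_structure()] object.
#' @export
read_cif <- function(path) {
  if (!file.exists(path)) stop("CIF parse error: file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]

  get_scalar <- function(tag) {
    hit <- grep(paste0("^\\s*", tag, "\\b"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_real_)
    strip_su(cif_tokens(hit[1])[2])
  }
  cell <- c(a = get_scalar("_cell_length_a"), b = get_scalar("_cell_length_b"),
            c = get_scalar("_cell_length_c"), alpha = get_scalar("_cell_angle_alpha"),
            beta = get_scalar("_cell_angle_beta"), gamma = get_scalar("_cell_angle_gamma"))
  if (any(is.na(cell[1:3])))
    stop("CIF parse error: missing _cell_length_* block", call. = FALSE)
  cell[4:6][is.na(cell[4:6])] <- 90
  lattice <- lattice_parameters(cell[["a"]], cell[["b"]], cell[["c"]],
                                cell[["alpha"]], cell[["beta"]], cell[["gamma"]])

  # collect loops: list(tags = character, rows = list of token vectors)
  loops <- list(); i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      tags <- character(0); i <- i + 1L
      while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, cif_tokens(lines[i])[1]); i <- i + 1L
      }
      rows <- list()
      while (i <= length(lines) && !grepl("^\\s*(loop_|_|data_)", lines[i]) &&
             !grepl("^\\s*$", lines[i])) {
        rows[[length(rows) + 1L]] <- cif_tokens(lines[i]); i <- i + 1L
      }
      loops[[length(loops) + 1L]] <- list(tags = tags, rows = rows)
    } else i <- i + 1L
  }

  find_loop <- function(tag_re) {
    for (lp in loops) if (any(grepl(tag_re, lp$tags))) return(lp)
    NULL
  }

  symops <- list(function(xyz) xyz)
  sym_loop <- find_loop("_(symmetry_equiv_pos_as_xyz|space_group_symop_operation_xyz)$")
  if (!is.null(sym_loop)) {
    col <- grep("_(symmetry_equiv_pos_as_xyz|space_group_symop_operation_xyz)$",
                sym_loop$tags)[1]
    symops <- lapply(sym_loop$rows, function(r) parse_symop(r[col]))
  }

  site_loop <- find_loop("^_atom_site_fract_x$")
  if (is.null(site_loop))
    stop("CIF parse error: missing atom_site loop", call. = FALSE)
  tg <- site_loop$tags
  ix <- match("_atom_site_fract_x", tg); iy <- match("_atom_site_fract_y", tg)
  iz <- match("_atom_site_fract_z", tg)
  itype <- match("_atom_site_type_symbol", tg)
  ilab <- match("_atom_site_label", tg)
  iocc <- match("_atom_site_occupancy", tg)
  atoms <- do.call(rbind, lapply(site_loop$rows, function(r) {
    el <- if (!is.na(itype)) r[itype] else gsub("[0-9'()*]+.*$", "", r[ilab])
    data.frame(element = el, x = strip_su(r[ix]), y = strip_su(r[iy]),
               z = strip_su(r[iz]),
               occupancy = if (!is.na(iocc)) strip_su(r[iocc]) else 1)
  }))

  # expand symmetry, reduce mod 1, de-duplicate special positions
  expanded <- do.call(rbind, lapply(seq_len(nrow(atoms)), function(j) {
    xyz0 <- as.numeric(atoms[j, c("x", "y", "z")])
    pos <- t(vapply(symops, function(op) op(xyz0) %% 1, numeric(3)))
    keep <- rep(TRUE, nrow(pos))
    for (p in seq_len(nrow(pos))) {
      if (!keep[p]) next
      if (p < nrow(pos)) for (q in seq((p + 1L), nrow(pos))) {
        d <- abs(pos[q, ] - pos[p, ]); d <- pmin(d, 1 - d)
        if (sqrt(sum(d^2)) < 1e-3) keep[q] <- FALSE
      }
    }
    data.frame(element = atoms$element[j], x = pos[keep, 1], y = pos[keep, 2],
               z = pos[keep, 3], occupancy = atoms$occupancy[j])
  }))
  crystal_structure(lattice, expanded, label = basename(path))
}

#' Write a minimal CIF file (P1, fixture use)
#'
#' @param structure A [crystal_structure()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path) {
  lt <- structure$lattice
  lines <- c(
    "data_dynED",
    sprintf("_cell_length_a %.6f", lt$a),
    sprintf("_cell_length_b %.6f", lt$b),
    sprintf("_cell_length_c %.6f", lt$c),
    sprintf("_cell_angle_alpha %.6f", lt$alpha),
    sprintf("_cell_angle_beta %.6f", lt$beta),
    sprintf("_cell_angle_gamma %.6f", lt$gamma),
    "loop_",
    "_symmetry_equiv_pos_as_xyz",
    "'x, y, z'",
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    sprintf("%s%d %s %.8f %.8f %.8f %.4f",
            structure$atoms$element, seq_len(nrow(structure$atoms)),
            structure$atoms$element, structure$atoms$x, structure$atoms$y,
            structure$atoms$z, structure$atoms$occupancy))
  writeLines(lines, path)
  invisible(path)
}

# ---- Toy fixtures ----------------------------------------------------------

#' Toy crystal fixtures
#'
#' Deterministic light-element structures used in tests and examples.
#'
#' Kinds:
#' \describe{
#'   \item{`monatomic_cubic`}{One atom of `element` at the origin of a cubic
#'     cell of edge `a`.}
#'   \item{`rocksalt_like`}{Two interpenetrating cubic sublattices (C at
#'     (0,0,0)-type sites, O at (1/2,1/2,1/2)-type sites) in a cubic cell.}
#'   \item{`centrosymmetric_pair`}{Two like atoms at \eqn{\pm r}, giving an
#'     inversion-symmetric structure with real structure factors.}
#'   \item{`random_light_organic`}{`n_atoms` atoms drawn from H/C/N/O/Si at
#'     uniform random fractional positions; reproducible for a given `seed`.}
#' }
#'
#' @param kind One of `"monatomic_cubic"`, `"rocksalt_like"`,
#'   `"centrosymmetric_pair"`, `"random_light_organic"`.
#' @param a Cubic cell edge in Angstrom (ignored if `lattice` given).
#' @param element Element symbol for the monatomic/pair kinds.
#' @param lattice Optional [lattice_parameters()] overriding the cubic cell.
#' @param n_atoms Atom count for `random_light_organic`.
#' @param seed Integer seed for `random_light_organic`.
#' @param elements Sampling pool for `random_light_organic`.
#' @return A [crystal_structure()] object.
#' @examples
#' toy_crystal("monatomic_cubic", a = 4, element = "C")
#' @export
toy_crystal <- function(kind, a = 4, element = "C", lattice = NULL,
                        n_atoms = 20, seed = 1,
                        elements = c("H", "C", "N", "O", "Si")) {
  if (is.null(lattice)) lattice <- lattice_parameters(a, a, a)
  switch(kind,
    monatomic_cubic = crystal_structure(
      lattice, data.frame(element = element, x = 0, y = 0, z = 0),
      label = "monatomic_cubic"),
    rocksalt_like = crystal_structure(
      lattice,
      data.frame(
        element = rep(c("C", "O"), each = 4),
        x = c(0, 0.5, 0.5, 0, 0.5, 0, 0, 0.5),
        y = c(0, 0.5, 0, 0.5, 0.5, 0, 0.5, 0),
        z = c(0, 0, 0.5, 0.5, 0.5, 0.5, 0, 0)),
      label = "rocksalt_like"),
    centrosymmetric_pair = crystal_structure(
      lattice,
      data.frame(element = element, x = c(0.15, -0.15), y = c(0.23, -0.23),
                 z = c(0.31, -0.31)),
      label = "centrosymmetric_pair"),
    random_light_organic = {
      stopifnot(n_atoms >= 1)
      u <- seeded_uniforms(seed, 4L * n_atoms)
      crystal_structure(
        lattice,
        data.frame(element = elements[floor(u[1:n_atoms] * length(elements)) + 1L],
                   x = u[n_atoms + 1:n_atoms], y = u[2L * n_atoms + 1:n_atoms],
                   z = u[3L * n_atoms + 1:n_atoms]),
        label = sprintf("random_light_organic(seed=%d)", seed))
    },
    stop("unknown toy crystal kind: ", kind, call. = FALSE))
}

# seeded uniform draws that do not disturb the caller's RNG state
seeded_uniforms <- function(seed, n) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(state)) assign(".Random.seed", state, envir = globalenv()))
  set.seed(seed)
  runif(n)
}

#' Synthetic rubrene-like crystal (fixture)
#'
#' The published rubrene lattice (orthorhombic, a = 26.789, b = 7.170,
#' c = 14.211 Angstrom) filled with the rubrene unit-cell composition
#' (168 C + 112 H for Z = 4 molecules of C42H28) at seeded random fractional
#' positions.  This is a synthetic stand-in: the lattice and stoichiometry
#' are real, the atomic coordinates are not (the genuine coordinates live in
#' an external CIF).  Useful for exercising solver behaviour at the real
#' beam-set geometry and a realistic total scattering power.
#'
#' @param seed Integer seed.
#' @return A [crystal_structure()] object.
#' @export
synthetic_rubrene_like <- function(seed = 1) {
  lt <- lattice_parameters(26.789, 7.170, 14.211)
  n_c <- 168L; n_h <- 112L; n <- n_c + n_h
  u <- seeded_uniforms(seed, 3L * n)
  crystal_structure(
    lt,
    data.frame(element = c(rep("C", n_c), rep("H", n_h)),
               x = u[1:n], y = u[n + 1:n], z = u[2L * n + 1:n]),
    label = sprintf("synthetic_rubrene_like(seed=%d)", seed))
}

#' Lattices of the two reference organic semiconductors
#'
#' Published unit-cell parameters for TIPS pentacene (triclinic) and rubrene
#' (orthorhombic), used throughout the examples: these determine reciprocal
#' geometry, beam sets and cluster membership without needing atomic
#' coordinates.
#'
#' @param material `"tips_pentacene"` or `"rubrene"`.
#' @return A [lattice_parameters()] object.
#' @export
reference_lattice <- function(material = c("tips_pentacene", "rubrene")) {
  material <- match.arg(material)
  switch(material,
    tips_pentacene = lattice_parameters(7.565, 7.750, 16.835, 89.15, 78.42, 83.63),
    rubrene = lattice_parameters(26.789, 7.170, 14.211))
}
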