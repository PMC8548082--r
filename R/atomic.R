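# Atomic models: coordinate-file readers (via bio3d) and a deterministic
# phantom-particle generator so the test suite and experiments need no
# external downloads.

# Atomic numbers for element symbols accepted in atomic models
element_z <- c(
  H = 1, C = 6, N = 7, O = 8, F = 9, NA_ = 11, MG = 12, P = 15, S = 16,
  CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27, NI = 28, CU = 29,
  ZN = 30, SE = 34, BR = 35, MO = 42, I = 53, W = 74, AU = 79
)

lookup_z <- function(element) {
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA_"
  z <- element_z[key]
  if (anyNA(z)) {
    bad <- unique(element[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  }
  unname(z)
}

new_atomic_model <- function(element, x, y, z, occupancy = 1) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z))) {
    stop("atomic model coordinates must be finite")
  }
  lookup_z(element) # validates symbols
  occupancy <- rep_len(occupancy, length(x))
  structure(
    data.frame(element = as.character(element), x = x, y = y, z = z,
               occupancy = occupancy, stringsAsFactors = FALSE),
    class = c("atomic_model", "data.frame")
  )
}

#' Read an atomic model from a PDB or mmCIF file
#'
#' Parses ATOM/HETATM records into one atom per record with its occupancy.
#' Alternate locations are all retained; their fractional occupancies weight
#' the deposited potential, so an atom split over two conformers contributes
#' its full potential once in total. The atom count is reported with a
#' message.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file.
#' @return An `atomic_model` data.frame with columns `element`, `x`, `y`,
#'   `z`, `occupancy` (coordinates in Angstroms).
#' @export
read_atomic_model <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) {
      stop("failed to parse coordinate file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == "")) {
    # fall back to the first character of the atom name
    element <- substr(trimws(at$elety), 1, 1)
  }
  occ <- at$o
  occ[is.na(occ)] <- 1
  model <- new_atomic_model(element, at$x, at$y, at$z, occ)
  message(nrow(model), " atoms read from ", basename(path))
  model
}

# Run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a deterministic phantom particle
#'
#' Produces a globular pseudo-protein: `n_atoms` atoms with protein-like
#' element composition (C/N/O/S) at uniform random positions in a ball of
#' the given radius. Atoms are re-centred on their centroid, so the particle
#' centre of mass is exactly the origin, and rescaled if recentring pushed
#' any atom outside the radius. A random cloud of this kind has no point
#' symmetry, so orientation recovery is testable.
#'
#' @param seed Integer seed; the same seed always returns the same model.
#' @param n_atoms Number of atoms (>= 1).
#' @param radius Maximum atom distance from the centre, Angstroms.
#' @return An `atomic_model`.
#' @export
make_phantom_particle <- function(seed, n_atoms, radius) {
  stopifnot(n_atoms >= 1, radius > 0)
  with_seed(seed, {
    # uniform in ball: direction * radius * U^(1/3)
    u <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- radius * 0.98 * stats::runif(n_atoms)^(1 / 3)
    xyz <- u * r
    xyz <- sweep(xyz, 2, colMeans(xyz)) # centroid exactly at origin
    mx <- sqrt(max(rowSums(xyz^2)))
    if (mx > radius) xyz <- xyz * (0.999 * radius / mx)
    elements <- sample(c("C", "N", "O", "S"), n_atoms, replace = TRUE,
                       prob = c(0.63, 0.17, 0.19, 0.01))
    new_atomic_model(elements, xyz[, 1], xyz[, 2], xyz[, 3])
  })
}
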