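# Crystal and beam models for still shots.
#
# A crystal is an orthonormal orientation matrix U plus a symmetry-
# constrained unit cell; the reciprocal orthogonalization matrix B (upper
# triangular, Busing-Levy convention, no 2*pi) is recomputed whenever the
# cell changes, and reciprocal-lattice points are rlp = U B h (1/Angstrom).

#' Reciprocal orthogonalization matrix from unit-cell parameters
#'
#' Upper-triangular Busing-Levy B matrix; `U %*% B %*% h` gives the
#' reciprocal-lattice vector of Miller index h in 1/Angstrom (no 2*pi).
#'
#' @param cell numeric length-6: a, b, c (Angstrom), alpha, beta, gamma
#'   (degrees).
#' @return 3x3 upper-triangular matrix.
#' @export
cell_to_B <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  V <- a * b * cc * sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
                           2 * cos(al) * cos(be) * cos(ga))
  as <- b * cc * sin(al) / V
  bs <- a * cc * sin(be) / V
  cs <- a * b * sin(ga) / V
  cos_als <- (cos(be) * cos(ga) - cos(al)) / (sin(be) * sin(ga))
  cos_bes <- (cos(al) * cos(ga) - cos(be)) / (sin(al) * sin(ga))
  cos_gas <- (cos(al) * cos(be) - cos(ga)) / (sin(al) * sin(be))
  sin_bes <- sqrt(max(0, 1 - cos_bes^2))
  sin_gas <- sqrt(max(0, 1 - cos_gas^2))
  matrix(c(as, 0, 0,
           bs * cos_gas, bs * sin_gas, 0,
           cs * cos_bes, -cs * sin_bes * cos(al), 1 / cc),
         nrow = 3)
}

# Canonical cell for a constraint tag given its free lengths.
constrained_cell <- function(tag, lengths) {
  switch(tag,
    hexagonal    = c(lengths[1], lengths[1], lengths[2], 90, 90, 120),
    orthorhombic = c(lengths[1], lengths[2], lengths[3], 90, 90, 90),
    triclinic    = lengths,   # all six parameters free
    stop("unknown constraint tag: ", tag))
}

#' Free cell-parameter count for a symmetry constraint
#'
#' @param tag `"hexagonal"` (free a, c), `"orthorhombic"` (free a, b, c) or
#'   `"triclinic"` (all six).
#' @return integer count of free cell parameters.
#' @export
n_free_cell_params <- function(tag) {
  switch(tag, hexagonal = 2L, orthorhombic = 3L, triclinic = 6L,
         stop("unknown constraint tag: ", tag))
}

#' Construct a crystal model
#'
#' @param U 3x3 orthonormal orientation matrix.
#' @param tag symmetry constraint tag (see [n_free_cell_params()]).
#' @param lengths free cell parameters: `c(a, c)` for hexagonal,
#'   `c(a, b, c)` for orthorhombic, all six for triclinic.
#' @return an object of class `"crystal_model"` with fields `U`, `cell`,
#'   `tag`, `lengths` and the derived `B`.
#' @export
crystal_model <- function(U, tag, lengths) {
  if (max(abs(crossprod(U) - diag(3))) > 1e-9)
    stop("crystal orientation U is not orthonormal")
  cell <- constrained_cell(tag, lengths)
  structure(list(U = U, cell = cell, tag = tag, lengths = as.numeric(lengths),
                 B = cell_to_B(cell)),
            class = "crystal_model")
}

#' Update the free cell lengths of a crystal (B is recomputed)
#'
#' @param crystal a [crystal_model()].
#' @param lengths new free cell parameters.
#' @return the updated crystal.
#' @export
set_cell_lengths <- function(crystal, lengths) {
  crystal_model(crystal$U, crystal$tag, lengths)
}

#' Apply small orientation rotations to a crystal
#'
#' The three refinable orientation parameters are sequential right-handed
#' rotations about the fixed laboratory axes x, y, z (radians), composed
#' onto the current U.  During refinement the reference U is reset at the
#' start of each macro-step so the parameters stay near zero.
#'
#' @param crystal a [crystal_model()].
#' @param angles numeric length-3, radians.
#' @return the updated crystal.
#' @export
rotate_crystal <- function(crystal, angles) {
  U <- crystal$U
  if (angles[1] != 0) U <- rotation_about_axis(c(1, 0, 0), angles[1]) %*% U
  if (angles[2] != 0) U <- rotation_about_axis(c(0, 1, 0), angles[2]) %*% U
  if (angles[3] != 0) U <- rotation_about_axis(c(0, 0, 1), angles[3]) %*% U
  crystal$U <- U
  crystal
}

#' Construct a beam model
#'
#' @param wavelength wavelength in Angstrom (> 0); stills experiments carry
#'   one per shot because each pulse has a slightly different mean energy.
#' @param direction unit vector pointing from the crystal toward the
#'   detector; the default beam travels along -z.
#' @return an object of class `"beam_model"`; `s0` is `direction /
#'   wavelength` (1/Angstrom).
#' @export
beam_model <- function(wavelength, direction = c(0, 0, -1)) {
  stopifnot(wavelength > 0)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) stop("beam direction must be a unit vector")
  structure(list(direction = as.numeric(direction), wavelength = wavelength,
                 s0 = as.numeric(direction) / wavelength),
            class = "beam_model")
}

#' Real-space cell axis vectors of a crystal
#'
#' Laboratory-frame a, b, c axis vectors (columns), from the inverse of the
#' reciprocal setting matrix `U B`.
#'
#' @param crystal a [crystal_model()].
#' @return 3x3 matrix with columns a, b, c (Angstrom).
#' @export
real_space_axes <- function(crystal) {
  # rows of (U B)^-1 transposed: direct axes are columns of t(solve(U %*% B))
  t(solve(crystal$U %*% crystal$B))
}

# Random orientation, uniform over rotations (normalized quaternion method).
random_orientation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3)
}
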