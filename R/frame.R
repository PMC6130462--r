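# Frame algebra for hierarchical detector models.
#
# A frame holds an origin vector d0 (mm, in the parent frame) and two
# orthonormal unit vectors dx (fast readout direction) and dy (slow readout
# direction).  The normal dn = dx x dy is always derived, never stored.

#' Construct a coordinate frame
#'
#' A frame is the basic building block of the hierarchical detector model:
#' an origin `d0` expressed in the parent frame plus orthonormal fast/slow
#' direction vectors `dx`, `dy`.  The plane normal `dn = dx x dy` is derived
#' on access and never stored independently.
#'
#' @param d0 numeric length-3 translation (mm) from the parent origin.
#' @param dx numeric length-3 unit vector, fast direction.
#' @param dy numeric length-3 unit vector, slow direction (orthogonal to `dx`).
#' @return An object of class `"frame"`.
#' @examples
#' f <- frame(c(0, 0, -100), c(1, 0, 0), c(0, 1, 0))
#' frame_dn(f)
#' @export
frame <- function(d0 = c(0, 0, 0), dx = c(1, 0, 0), dy = c(0, 1, 0)) {
  d0 <- as.numeric(d0); dx <- as.numeric(dx); dy <- as.numeric(dy)
  stopifnot(length(d0) == 3L, length(dx) == 3L, length(dy) == 3L)
  f <- structure(list(d0 = d0, dx = dx, dy = dy), class = "frame")
  validate_frame(f)
  f
}

#' @export
print.frame <- function(x, ...) {
  cat("frame: d0 = (", paste(signif(x$d0, 6), collapse = ", "),
      ")  dx = (", paste(signif(x$dx, 6), collapse = ", "),
      ")  dy = (", paste(signif(x$dy, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Validate frame orthonormality
#'
#' Checks `|dx| = |dy| = 1` and `dx . dy = 0` to within `tol`.
#'
#' @param f a [frame()].
#' @param tol orthonormality tolerance (default `1e-9`).
#' @return `f`, invisibly; signals an error for a non-orthonormal frame.
#' @export
validate_frame <- function(f, tol = 1e-9) {
  if (abs(sqrt(sum(f$dx^2)) - 1) > tol)
    stop("frame validation: |dx| != 1 (", sqrt(sum(f$dx^2)), ")")
  if (abs(sqrt(sum(f$dy^2)) - 1) > tol)
    stop("frame validation: |dy| != 1 (", sqrt(sum(f$dy^2)), ")")
  if (abs(sum(f$dx * f$dy)) > tol)
    stop("frame validation: dx . dy != 0 (", sum(f$dx * f$dy), ")")
  invisible(f)
}

# 3x3 determinant (avoids masking issues where `det` names a detector).
det3 <- function(m) {
  m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
  m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
  m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Frame normal vector
#'
#' @param f a [frame()].
#' @return `dx x dy`, the unit plane normal.
#' @export
frame_dn <- function(f) cross3(f$dx, f$dy)

#' Homogeneous 4x4 transform of a frame
#'
#' Columns 1-3 of the rotation block are `dx`, `dy`, `dn`; column 4 is `d0`;
#' the last row is (0, 0, 0, 1).  Applied to a homogeneous point it rotates
#' into the parent basis and then translates.
#'
#' @param f a [frame()].
#' @return a 4x4 numeric matrix.
#' @export
frame_to_matrix <- function(f) {
  validate_frame(f)
  m <- diag(4)
  m[1:3, 1] <- f$dx
  m[1:3, 2] <- f$dy
  m[1:3, 3] <- frame_dn(f)
  m[1:3, 4] <- f$d0
  m
}

#' Build a frame back from a homogeneous matrix
#'
#' Inverse of [frame_to_matrix()]; the dn column is discarded (re-derived).
#'
#' @param m a 4x4 homogeneous transform with orthonormal rotation block.
#' @return a [frame()].
#' @export
matrix_to_frame <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  frame(d0 = m[1:3, 4], dx = m[1:3, 1], dy = m[1:3, 2])
}

#' Compose two frames
#'
#' Returns the frame whose homogeneous matrix equals
#' `frame_to_matrix(parent) %*% frame_to_matrix(child)`; composition is
#' associative, so chaining down a detector hierarchy is order-independent
#' in the usual sense.
#'
#' @param parent,child [frame()] objects.
#' @return the composed [frame()].
#' @export
compose_frames <- function(parent, child) {
  matrix_to_frame(frame_to_matrix(parent) %*% frame_to_matrix(child))
}

# Rotation matrix about arbitrary unit axis (Rodrigues), radians.
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  ca <- cos(angle); sa <- sin(angle)
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  K <- matrix(c(0, z, -y, -z, 0, x, y, -x, 0), 3, 3)
  diag(3) * ca + sa * K + (1 - ca) * outer(axis, axis)
}

# Apply a 3x3 rotation (about the parent-frame origin) to a frame.
rotate_frame <- function(f, R, about = c(0, 0, 0)) {
  frame(d0 = as.numeric(R %*% (f$d0 - about)) + about,
        dx = as.numeric(R %*% f$dx),
        dy = as.numeric(R %*% f$dy))
}
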