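# Still-shot spot prediction.
#
# For a still exposure a reciprocal-lattice point (rlp) is generally not in
# the exact Bragg condition.  delta-psi is the smallest crystal rotation,
# about the axis e = rlp x s0 / |rlp x s0|, that places the rlp exactly on
# the Ewald sphere: |s0 + R(e, psi) rlp| = |s0|.  The rotated diffracted ray
# s1 = s0 + R(e, psi) rlp, projected from the crystal origin onto a panel
# plane, gives the predicted centroid (x_calc, y_calc); psi itself enters
# the refinement target as a restraint.

# Vectorized delta-psi: rlp is m x 3, s0 length 3 (1/Angstrom).
# Closed form: with e fixed, R(e,psi) rlp = rlp cos(psi) + (e x rlp) sin(psi)
# (e is orthogonal to rlp), and the Ewald condition |s0 + R rlp| = |s0|
# reduces to P cos(psi) + Q sin(psi) = -|rlp|^2 with P = 2 s0.rlp and
# Q = 2 |rlp x s0| >= 0.  Writing the left side as rho cos(psi - phi),
# rho = (P^2 + Q^2)^(1/2), phi = atan2(Q, P), the two roots are
# psi = phi +/- acos(-|rlp|^2 / rho); the smaller-magnitude root is taken.
delta_psi_vec <- function(rlp, s0) {
  rx <- rlp[, 1]; ry <- rlp[, 2]; rz <- rlp[, 3]
  r2 <- rx * rx + ry * ry + rz * rz
  P <- 2 * (rx * s0[1] + ry * s0[2] + rz * s0[3])
  cx <- ry * s0[3] - rz * s0[2]
  cy <- rz * s0[1] - rx * s0[3]
  cz <- rx * s0[2] - ry * s0[1]
  cn <- sqrt(cx * cx + cy * cy + cz * cz)
  Q <- 2 * cn
  rho <- sqrt(P * P + Q * Q)
  ratio <- -r2 / rho
  valid <- is.finite(ratio) & abs(ratio) <= 1 & cn > 1e-12 & r2 > 0
  ratio[!valid] <- 0
  phi <- atan2(Q, P)
  am <- acos(ratio)
  psi1 <- phi - am
  psi2 <- phi + am
  # wrap to (-pi, pi]
  wrap <- function(x) x - 2 * pi * round(x / (2 * pi))
  psi1 <- wrap(psi1); psi2 <- wrap(psi2)
  psi <- ifelse(abs(psi1) <= abs(psi2), psi1, psi2)
  psi[!valid] <- NA_real_
  # unit rotation axis and rotated rlp
  ex <- cx / cn; ey <- cy / cn; ez <- cz / cn
  # e x rlp
  px <- ey * rz - ez * ry
  py <- ez * rx - ex * rz
  pz <- ex * ry - ey * rx
  cp <- cos(psi); sp <- sin(psi)
  s1x <- s0[1] + rx * cp + px * sp
  s1y <- s0[2] + ry * cp + py * sp
  s1z <- s0[3] + rz * cp + pz * sp
  list(psi = psi, s1 = cbind(s1x, s1y, s1z), e = cbind(ex, ey, ez),
       valid = valid)
}

#' Smallest rotation bringing a reciprocal-lattice point to the Bragg condition
#'
#' Returns the signed, smallest-magnitude rotation angle psi about the axis
#' `e = rlp x s0 / |rlp x s0|` such that `|s0 + R(e, psi) rlp| = |s0|`
#' (`s0 = direction / wavelength`).  Positive psi follows the right-hand
#' rule about `e`; negating the beam-transverse component of the rlp flips
#' the sign.
#'
#' @param rlp reciprocal-lattice vector (1/Angstrom), nonzero.
#' @param beam a [beam_model()].
#' @return list with `psi` (radians), `s1` (diffracted ray, 1/Angstrom) and
#'   the rotation axis `e`.
#' @export
delta_psi <- function(rlp, beam) {
  rlp <- as.numeric(rlp)
  if (sqrt(sum(rlp^2)) == 0) stop("delta_psi: rlp must be nonzero")
  cr <- cross3(rlp, beam$s0)
  if (sqrt(sum(cr^2)) <= 1e-12 * sqrt(sum(rlp^2)) * sqrt(sum(beam$s0^2)))
    stop("delta_psi: rlp parallel to the beam, rotation axis degenerate")
  out <- delta_psi_vec(matrix(rlp, 1), beam$s0)
  if (!out$valid[1]) stop("delta_psi: rlp cannot be rotated onto the Ewald sphere")
  list(psi = out$psi[1], s1 = as.numeric(out$s1[1, ]), e = as.numeric(out$e[1, ]))
}

# Panel table columns as a plain numeric matrix (hot-path representation).
ptab_matrix <- function(ptab) {
  as.matrix(ptab[, c("d0x", "d0y", "d0z", "dxx", "dxy", "dxz",
                     "dyx", "dyy", "dyz", "dnx", "dny", "dnz",
                     "n_fast", "n_slow", "psz_f", "psz_s")])
}

# Intersect rays s1 (m x 3, from the origin) with the planes of panels pan
# (1-based rows of ptm); returns in-plane mm coordinates and on-panel flags.
project_to_panels <- function(s1, pan, ptm) {
  Pm <- ptm[pan, , drop = FALSE]
  den <- s1[, 1] * Pm[, 10] + s1[, 2] * Pm[, 11] + s1[, 3] * Pm[, 12]
  num <- Pm[, 1] * Pm[, 10] + Pm[, 2] * Pm[, 11] + Pm[, 3] * Pm[, 12]
  tt <- num / den
  vx <- tt * s1[, 1] - Pm[, 1]
  vy <- tt * s1[, 2] - Pm[, 2]
  vz <- tt * s1[, 3] - Pm[, 3]
  fast <- vx * Pm[, 4] + vy * Pm[, 5] + vz * Pm[, 6]
  slow <- vx * Pm[, 7] + vy * Pm[, 8] + vz * Pm[, 9]
  ok <- is.finite(tt) & tt > 0 &
    fast >= 0 & fast <= Pm[, 13] * Pm[, 15] &
    slow >= 0 & slow <= Pm[, 14] * Pm[, 16]
  list(fast = fast, slow = slow, on_panel = ok)
}

# Candidate Miller indices with |B h| <= 1/d_min (orientation-independent).
hkl_candidates <- function(B, d_min, margin = 1.05) {
  rmax <- margin / d_min
  # conservative per-index bounds from the direct cell lengths
  Binv <- solve(B)
  lim <- ceiling(rmax * sqrt(rowSums(Binv^2)))
  H <- as.matrix(expand.grid(h = -lim[1]:lim[1], k = -lim[2]:lim[2],
                             l = -lim[3]:lim[3]))
  q <- H %*% t(B)
  keep <- rowSums(q^2) <= rmax^2 & rowSums(abs(H)) > 0
  H[keep, , drop = FALSE]
}

#' Predict Bragg spots for a still shot
#'
#' Enumerates Miller indices to the resolution limit, keeps those whose
#' delta-psi magnitude falls within the acceptance window (the stand-in for
#' an explicit mosaicity model), and projects the rotated diffracted rays
#' onto the detector panels, keeping on-panel intersections.  Output is
#' deterministic (sorted by h, k, l).
#'
#' @param crystal a [crystal_model()].
#' @param beam a [beam_model()].
#' @param det a [detector()].
#' @param d_min resolution limit, Angstrom.
#' @param psi_window delta-psi acceptance half-window, radians.
#' @param hkl optional precomputed candidate index matrix (3 columns).
#' @param ptab optional precomputed [panel_table()].
#' @return data.frame with columns `panel`, `h`, `k`, `l`, `x_calc`,
#'   `y_calc` (mm, in-panel), `psi` (radians).
#' @export
predict_still <- function(crystal, beam, det, d_min = 2.5,
                          psi_window = 0.05 * pi / 180,
                          hkl = NULL, ptab = NULL) {
  if (d_min <= 0) stop("d_min must be positive")
  if (is.null(hkl)) hkl <- hkl_candidates(crystal$B, d_min)
  if (is.null(ptab)) ptab <- panel_table(det)
  ptm <- ptab_matrix(ptab)
  UB <- crystal$U %*% crystal$B
  rlp <- hkl %*% t(UB)
  s0 <- beam$s0
  # strict resolution cut (candidate sets may carry a safety margin)
  rr <- sqrt(rowSums(rlp^2))
  inres <- rr <= 1 / d_min
  hkl <- hkl[inres, , drop = FALSE]
  rlp <- rlp[inres, , drop = FALSE]
  rr <- rr[inres]
  # cheap Ewald-distance prefilter: |psi| <= w implies the radial distance
  # to the sphere is at most ~ |rlp| * w (arc length); 2x safety factor.
  dist_sphere <- abs(sqrt((rlp[, 1] + s0[1])^2 + (rlp[, 2] + s0[2])^2 +
                            (rlp[, 3] + s0[3])^2) - 1 / beam$wavelength)
  pre <- dist_sphere <= 2 * rr * psi_window + 1e-12
  hkl <- hkl[pre, , drop = FALSE]
  rlp <- rlp[pre, , drop = FALSE]
  if (nrow(hkl) == 0L)
    return(data.frame(panel = integer(), h = integer(), k = integer(),
                      l = integer(), x_calc = numeric(), y_calc = numeric(),
                      psi = numeric()))
  dp <- delta_psi_vec(rlp, s0)
  keep <- dp$valid & !is.na(dp$psi) & abs(dp$psi) <= psi_window
  hkl <- hkl[keep, , drop = FALSE]
  s1 <- dp$s1[keep, , drop = FALSE]
  psi <- dp$psi[keep]
  if (nrow(hkl) == 0L)
    return(data.frame(panel = integer(), h = integer(), k = integer(),
                      l = integer(), x_calc = numeric(), y_calc = numeric(),
                      psi = numeric()))
  # try every panel; keep on-panel intersections
  out <- vector("list", nrow(ptm))
  for (p in seq_len(nrow(ptm))) {
    pr <- project_to_panels(s1, rep.int(p, nrow(s1)), ptm)
    if (any(pr$on_panel)) {
      i <- which(pr$on_panel)
      out[[p]] <- data.frame(panel = p, h = hkl[i, 1], k = hkl[i, 2],
                             l = hkl[i, 3], x_calc = pr$fast[i],
                             y_calc = pr$slow[i], psi = psi[i])
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    return(data.frame(panel = integer(), h = integer(), k = integer(),
                      l = integer(), x_calc = numeric(), y_calc = numeric(),
                      psi = numeric()))
  res <- res[order(res$h, res$k, res$l, res$panel), ]
  rownames(res) <- NULL
  res
}

#' Assign Miller indices to observed centroids
#'
#' Back-projects each observed centroid to reciprocal space by scaling the
#' panel point's unit ray to the Ewald sphere (`q = s1 - s0`), forms
#' fractional Miller indices `(U B)^-1 q`, then corrects the candidate by
#' rotating q back through the candidate's own minimal delta-psi angle so
#' that an exactly generated centroid recovers its integer index to
#' numerical precision.  A centroid is assigned when all three fractional
#' distances to the nearest integer are strictly below `cutoff`.
#'
#' @param obs data.frame with columns `panel`, `x_obs`, `y_obs` (mm).
#' @param crystal a [crystal_model()].
#' @param beam a [beam_model()].
#' @param det a [detector()].
#' @param cutoff fractional-index acceptance cutoff (default 0.3).
#' @param ptab optional precomputed [panel_table()].
#' @return `obs` with added columns `h`, `k`, `l` (NA when unassigned) and
#'   `frac_resid` (max fractional distance).
#' @export
assign_indices <- function(obs, crystal, beam, det, cutoff = 0.3, ptab = NULL) {
  if (is.null(ptab)) ptab <- panel_table(det)
  ptm <- ptab_matrix(ptab)
  UB <- crystal$U %*% crystal$B
  if (abs(det3(UB)) < 1e-12) stop("assign_indices: singular U %*% B")
  UBinv <- solve(UB)
  Pm <- ptm[obs$panel, , drop = FALSE]
  lab <- cbind(Pm[, 1] + obs$x_obs * Pm[, 4] + obs$y_obs * Pm[, 7],
               Pm[, 2] + obs$x_obs * Pm[, 5] + obs$y_obs * Pm[, 8],
               Pm[, 3] + obs$x_obs * Pm[, 6] + obs$y_obs * Pm[, 9])
  nrm <- sqrt(rowSums(lab^2))
  s1 <- lab / (nrm * beam$wavelength)
  q <- sweep(s1, 2, beam$s0)
  frac0 <- q %*% t(UBinv)
  h0 <- round(frac0)
  # candidate correction: rotate q back through the candidate rlp's own
  # minimal delta-psi about its axis, then re-evaluate the fraction
  rlp0 <- h0 %*% t(UB)
  dp <- delta_psi_vec(rlp0, beam$s0)
  psi0 <- dp$psi; psi0[is.na(psi0)] <- 0
  ex <- dp$e[, 1]; ey <- dp$e[, 2]; ez <- dp$e[, 3]
  cp <- cos(-psi0); sp <- sin(-psi0)
  # Rodrigues rotation of q about e by -psi0
  dotqe <- q[, 1] * ex + q[, 2] * ey + q[, 3] * ez
  crx <- ey * q[, 3] - ez * q[, 2]
  cry <- ez * q[, 1] - ex * q[, 3]
  crz <- ex * q[, 2] - ey * q[, 1]
  qp <- cbind(q[, 1] * cp + crx * sp + ex * dotqe * (1 - cp),
              q[, 2] * cp + cry * sp + ey * dotqe * (1 - cp),
              q[, 3] * cp + crz * sp + ez * dotqe * (1 - cp))
  frac <- qp %*% t(UBinv)
  hh <- round(frac)
  dev <- abs(frac - hh)
  resid <- pmax(dev[, 1], dev[, 2], dev[, 3])
  ok <- resid < cutoff & rowSums(abs(hh)) > 0
  obs$h <- ifelse(ok, hh[, 1], NA_integer_)
  obs$k <- ifelse(ok, hh[, 2], NA_integer_)
  obs$l <- ifelse(ok, hh[, 3], NA_integer_)
  obs$frac_resid <- resid
  obs
}

# Set the sample-to-detector distance by translating the root along its
# normal so that the plane offset |d0 . dn| equals `dist`.
set_detector_distance <- function(det, dist) {
  f <- det$root$frame
  dn <- frame_dn(f)
  cur <- sum(f$d0 * dn)
  move_node(det, det$root$name, distance = (sign(cur) * dist) - cur)
}

#' Detector distance of the root frame
#'
#' @param det a [detector()].
#' @return `|d0 . dn|` of the root frame, mm.
#' @export
detector_distance <- function(det) {
  f <- det$root$frame
  abs(sum(f$d0 * frame_dn(f)))
}

#' Scan the detector distance by indexing success
#'
#' Reassigns indices at each grid distance and returns the distance that
#' maximizes the number of images with at least `min_assigned` indexed
#' observations; ties are broken toward the smaller distance.
#'
#' @param obs data.frame with `image_id`, `panel`, `x_obs`, `y_obs`.
#' @param crystals list of [crystal_model()] indexed by image.
#' @param beams list of [beam_model()] indexed by image.
#' @param det a [detector()] (its distance is scanned).
#' @param grid numeric vector of candidate distances, mm.
#' @param cutoff fractional-index cutoff for [assign_indices()].
#' @param min_assigned minimum indexed observations for an image to count.
#' @return list with `distance` (best grid value) and `counts` (indexed
#'   image count per grid distance).
#' @export
scan_distance <- function(obs, crystals, beams, det, grid, cutoff = 0.3,
                          min_assigned = 10L) {
  if (length(grid) == 0L) stop("scan_distance: empty grid")
  grid <- sort(grid)
  counts <- integer(length(grid))
  for (gi in seq_along(grid)) {
    det_g <- set_detector_distance(det, grid[gi])
    ptab <- panel_table(det_g)
    n_ok <- 0L
    for (im in unique(obs$image_id)) {
      oi <- obs[obs$image_id == im, ]
      ai <- assign_indices(oi, crystals[[im]], beams[[im]], det_g,
                           cutoff = cutoff, ptab = ptab)
      if (sum(!is.na(ai$h)) >= min_assigned) n_ok <- n_ok + 1L
    }
    counts[gi] <- n_ok
  }
  if (max(counts) == 0L)
    warning("scan_distance: no images indexed at any grid distance")
  list(distance = grid[which.max(counts)], counts = counts)
}
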