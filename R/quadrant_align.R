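# Quadrant alignment by rotational autocorrelation of virtual powder
# patterns.
#
# A correctly placed quadrant produces powder rings that correlate with a
# copy of themselves rotated about the beam centre; a misplaced quadrant
# does not.  Scanning a grid of integer-pixel translations of the
# quadrant and recording the correlation of the translated pattern with
# its rotation yields a heat map whose maximum is the positional
# correction for that quadrant.  The scan uses the sensor closest to the
# beam centre and correlates against the quadrant's own pixels (both
# sides of the correlation carry the candidate translation, so the
# maximum is exact for noiseless rings regardless of the other
# quadrants).

# Bilinear sampling of matrix M at fractional indices (fi, fj); NA outside
# or where any participating neighbour is NA.
bilinear_sample <- function(M, fi, fj) {
  nx <- nrow(M); ny <- ncol(M)
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  ok <- i0 >= 1 & i0 <= nx - 1 & j0 >= 1 & j0 <= ny - 1
  out <- rep(NA_real_, length(fi))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; wi <- wi[ok]; wj <- wj[ok]
  v00 <- M[cbind(i0, j0)]
  v10 <- M[cbind(i0 + 1L, j0)]
  v01 <- M[cbind(i0, j0 + 1L)]
  v11 <- M[cbind(i0 + 1L, j0 + 1L)]
  out[ok] <- v00 * (1 - wi) * (1 - wj) + v10 * wi * (1 - wj) +
             v01 * (1 - wi) * wj + v11 * wi * wj
  out
}

# The quadrant's sensor closest to the beam centre (by cumulative-frame
# centre distance in the detector plane); ties broken lexicographically.
near_beam_sensor <- function(det, quadrant_path) {
  sens <- nodes_at_level(det, "sensor")
  qp <- paste(quadrant_path, collapse = "/")
  sens <- Filter(function(p)
    startsWith(paste(p, collapse = "/"), paste0(qp, "/")), sens)
  pt <- panel_table(det)
  dist <- vapply(sens, function(p) {
    pp <- paste(p, collapse = "/")
    rows <- pt[startsWith(pt$path, paste0(pp, "/")) | pt$path == pp, ]
    cx <- mean(rows$d0x + (rows$n_fast * rows$psz_f / 2) * rows$dxx +
                 (rows$n_slow * rows$psz_s / 2) * rows$dyx)
    cy <- mean(rows$d0y + (rows$n_fast * rows$psz_f / 2) * rows$dxy +
                 (rows$n_slow * rows$psz_s / 2) * rows$dyy)
    sqrt(cx^2 + cy^2)
  }, 0)
  keys <- vapply(sens, paste, "", collapse = "/")
  sens[[order(dist, keys)[1]]]
}

# Raster indices and values of the pixels of all panels under `path`.
panel_raster_pixels <- function(powder, det, path) {
  pt <- panel_table(det)
  pp <- paste(path, collapse = "/")
  rows <- which(startsWith(pt$path, paste0(pp, "/")) | pt$path == pp)
  ix <- integer(0); iy <- integer(0)
  for (p in rows) {
    r <- pt[p, ]
    f <- (seq_len(r$n_fast) - 0.5) * r$psz_f
    s <- (seq_len(r$n_slow) - 0.5) * r$psz_s
    ff <- rep(f, times = r$n_slow); ss <- rep(s, each = r$n_fast)
    wx <- r$d0x + ff * r$dxx + ss * r$dyx
    wy <- r$d0y + ff * r$dxy + ss * r$dyy
    ix <- c(ix, floor((wx - powder$x0) / powder$pitch) + 1L)
    iy <- c(iy, floor((wy - powder$y0) / powder$pitch) + 1L)
  }
  ok <- ix >= 1L & ix <= nrow(powder$raster) &
        iy >= 1L & iy <= ncol(powder$raster)
  list(ix = ix[ok], iy = iy[ok])
}

#' Rotational-autocorrelation heat map for one quadrant
#'
#' For every integer pixel offset (dx, dy) in the square search window,
#' translates the quadrant by that offset, rotates the translated pattern
#' by `angle` about the beam centre (bilinear resampling) and computes the
#' sample correlation coefficient between the near-beam sensor's pixel
#' values and the rotated pattern over the overlapping unmasked pixels of
#' the quadrant.  The argmax offset is the correction to apply to the
#' quadrant.  Ties break toward the smallest offset magnitude, then
#' lexicographically; offsets with overlap below `min_overlap` are set to
#' `-Inf` and excluded from the argmax.
#'
#' @param powder a `"powder_image"` from [render_powder()] (or a
#'   compatible list with `raster`, `x0`, `y0`, `pitch`, `owner`).
#' @param det the working [detector()] the raster was assembled with.
#' @param quadrant quadrant index (1-based, tree order).
#' @param beam_center_mm beam centre in the detector plane (mm).
#' @param search_radius half-width of the offset grid, pixels.
#' @param angle rotation angle, degrees (default 45).
#' @param min_overlap minimum overlapping pixels per offset.
#' @return object of class `"heat_map"`: `cc` matrix ((2r+1) x (2r+1)),
#'   `offsets` (grid vector, pixels), `argmax` (c(dx, dy) correction),
#'   `cc_max`, `angle`.
#' @export
autocorrelation_map <- function(powder, det, quadrant,
                                beam_center_mm = c(0, 0),
                                search_radius = 25L, angle = 45,
                                min_overlap = 200L) {
  quads <- nodes_at_level(det, "quadrant")
  stopifnot(quadrant >= 1L, quadrant <= length(quads))
  qpath <- quads[[quadrant]]
  spath <- near_beam_sensor(det, qpath)
  # quadrant-own raster layer (robust to bins overwritten by other,
  # mis-set quadrants in the combined assembly); fall back to the
  # owner-masked combined raster for externally supplied powder objects
  nx <- nrow(powder$raster); ny <- ncol(powder$raster)
  if (!is.null(powder$quad_px) && length(powder$quad_px) >= quadrant &&
      !is.null(powder$quad_px[[quadrant]])) {
    Q <- matrix(NA_real_, nx, ny)
    Q[powder$quad_px[[quadrant]]$idx] <- powder$quad_px[[quadrant]]$vals
  } else {
    Q <- powder$raster
    Q[powder$owner != quadrant] <- NA_real_
  }
  px <- panel_raster_pixels(powder, det, spath)
  vals <- Q[cbind(px$ix, px$iy)]
  keep <- is.finite(vals)
  vals <- vals[keep]
  # sensor pixel positions, mm (bin centres)
  sx <- powder$x0 + (px$ix[keep] - 0.5) * powder$pitch
  sy <- powder$y0 + (px$iy[keep] - 0.5) * powder$pitch
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  cx <- beam_center_mm[1]; cy <- beam_center_mm[2]
  # rotated base positions: c + R (p - c); a candidate offset t adds (R-I) t
  bx <- cx + R[1, 1] * (sx - cx) + R[1, 2] * (sy - cy)
  by <- cy + R[2, 1] * (sx - cx) + R[2, 2] * (sy - cy)
  offs <- (-search_radius):search_radius
  cc <- matrix(-Inf, length(offs), length(offs))
  for (oi in seq_along(offs)) for (oj in seq_along(offs)) {
    tx <- offs[oi] * powder$pitch; ty <- offs[oj] * powder$pitch
    ax <- bx + (R[1, 1] - 1) * tx + R[1, 2] * ty
    ay <- by + R[2, 1] * tx + (R[2, 2] - 1) * ty
    fi <- (ax - powder$x0) / powder$pitch + 0.5
    fj <- (ay - powder$y0) / powder$pitch + 0.5
    s <- bilinear_sample(Q, fi, fj)
    ok <- is.finite(s)
    if (sum(ok) >= min_overlap && stats::sd(vals[ok]) > 0 &&
        stats::sd(s[ok]) > 0)
      cc[oi, oj] <- stats::cor(vals[ok], s[ok])
  }
  best <- which(is.finite(cc) & cc == max(cc[is.finite(cc)]), arr.ind = TRUE)
  if (nrow(best) > 1) {
    mag <- offs[best[, 1]]^2 + offs[best[, 2]]^2
    best <- best[order(mag, best[, 1], best[, 2]), , drop = FALSE]
  }
  structure(list(cc = cc, offsets = offs,
                 argmax = c(offs[best[1, 1]], offs[best[1, 2]]),
                 cc_max = cc[best[1, 1], best[1, 2]], angle = angle),
            class = "heat_map")
}

#' Multi-angle autocorrelation heat map
#'
#' Repeats the rotational-autocorrelation scan at several angles and keeps,
#' for each offset, the maximum CC over the angle list (21 angles for the
#' default 20-70 degrees in 2.5-degree increments).  This suppresses the
#' beat pattern of local maxima seen in single-angle maps on weak data.
#'
#' @inheritParams autocorrelation_map
#' @param angles rotation angles, degrees.
#' @return a `"heat_map"`; `angle` is the vector of angles used.
#' @export
multi_angle_map <- function(powder, det, quadrant, beam_center_mm = c(0, 0),
                            search_radius = 25L,
                            angles = seq(20, 70, by = 2.5),
                            min_overlap = 200L) {
  cc <- NULL
  for (a in angles) {
    hm <- autocorrelation_map(powder, det, quadrant, beam_center_mm,
                              search_radius, a, min_overlap)
    cc <- if (is.null(cc)) hm$cc else pmax(cc, hm$cc)
  }
  offs <- (-search_radius):search_radius
  best <- which(is.finite(cc) & cc == max(cc[is.finite(cc)]), arr.ind = TRUE)
  if (nrow(best) > 1) {
    mag <- offs[best[, 1]]^2 + offs[best[, 2]]^2
    best <- best[order(mag, best[, 1], best[, 2]), , drop = FALSE]
  }
  structure(list(cc = cc, offsets = offs,
                 argmax = c(offs[best[1, 1]], offs[best[1, 2]]),
                 cc_max = cc[best[1, 1], best[1, 2]], angle = angles),
            class = "heat_map")
}

#' Apply in-plane pixel offsets to detector quadrants
#'
#' Shifts each quadrant frame by the given laboratory-frame (x, y) offset
#' times the pixel size -- the correction returned by the heat-map argmax.
#' Offsets compose additively over repeated applications.
#'
#' @param det a [detector()].
#' @param offsets_px matrix (n_quadrants x 2) or list of length-2 vectors;
#'   row i is the (dx, dy) pixel offset for quadrant i (zero rows allowed).
#' @return the updated [detector()].
#' @export
apply_quadrant_offsets <- function(det, offsets_px) {
  if (is.list(offsets_px)) offsets_px <- do.call(rbind, offsets_px)
  quads <- nodes_at_level(det, "quadrant")
  stopifnot(nrow(offsets_px) == length(quads))
  pt <- panel_table(det)
  pitch <- pt$psz_f[1]
  for (qi in seq_along(quads)) {
    off <- offsets_px[qi, ]
    if (all(off == 0)) next
    lab <- c(off[1] * pitch, off[2] * pitch, 0)
    f <- cumulative_frame(det, quads[[qi]])
    det <- move_node(det, quads[[qi]],
                     shift1 = sum(lab * f$dx), shift2 = sum(lab * f$dy))
  }
  det
}

#' Align all quadrants from a virtual powder pattern
#'
#' Runs the (single- or multi-angle) rotational-autocorrelation scan for
#' every quadrant and applies the recovered corrections.
#'
#' @inheritParams autocorrelation_map
#' @param multi_angle use [multi_angle_map()].
#' @param ... passed to the map function.
#' @return list with `det` (corrected detector), `offsets_px` (per
#'   quadrant) and `cc` (per-quadrant maximum CC).
#' @export
align_quadrants <- function(powder, det, beam_center_mm = c(0, 0),
                            search_radius = 25L, multi_angle = FALSE, ...) {
  quads <- nodes_at_level(det, "quadrant")
  offs <- matrix(0, length(quads), 2)
  ccs <- numeric(length(quads))
  for (qi in seq_along(quads)) {
    hm <- if (multi_angle)
      multi_angle_map(powder, det, qi, beam_center_mm, search_radius, ...)
    else
      autocorrelation_map(powder, det, qi, beam_center_mm, search_radius, ...)
    offs[qi, ] <- hm$argmax
    ccs[qi] <- hm$cc_max
  }
  list(det = apply_quadrant_offsets(det, offs), offsets_px = offs, cc = ccs)
}
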