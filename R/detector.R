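# Hierarchical multi-panel detector model.
#
# A detector is a tree of named nodes, each carrying a local frame relative
# to its parent.  Leaves (and only leaves) carry a pixel-array panel payload.
# The laboratory frame has the crystal at the origin and the beam travelling
# along -z toward the detector, which nominally sits in the plane
# z = -distance.

new_detector_node <- function(name, level, frame, children = list(), panel = NULL) {
  structure(list(name = name, level = level, frame = frame,
                 children = children, panel = panel),
            class = "detector_node")
}

#' Construct a detector from a node tree
#'
#' @param root a detector node (see [cspad_detector()] for the standard
#'   builder); the root's frame is expressed in the laboratory frame.
#' @return an object of class `"detector"`.
#' @export
detector <- function(root) {
  det <- structure(list(root = root), class = "detector")
  validate_detector(det)
  det
}

#' Validate detector invariants
#'
#' Checks that every frame is orthonormal, that leaves and only leaves carry
#' panel payloads, and that panel payloads have positive pixel counts and
#' sizes.
#'
#' @param det a [detector()].
#' @return `det`, invisibly; errors name the offending node.
#' @export
validate_detector <- function(det) {
  walk <- function(node) {
    validate_frame(node$frame)
    if (length(node$children) == 0L) {
      if (is.null(node$panel))
        stop("detector validation: leaf node '", node$name, "' has no panel payload")
      p <- node$panel
      if (!all(c(p$n_fast, p$n_slow) >= 1L) ||
          !all(c(p$pixel_size_fast, p$pixel_size_slow) > 0))
        stop("detector validation: invalid panel payload on '", node$name, "'")
    } else {
      if (!is.null(node$panel))
        stop("detector validation: non-leaf node '", node$name, "' carries a panel payload")
      for (ch in node$children) walk(ch)
    }
  }
  walk(det$root)
  invisible(det)
}

# --- node addressing ---------------------------------------------------------

# A node path is a character vector of names from the root down, e.g.
# c("detector", "q1", "s3").  find_node returns the node; stop on break.
find_node <- function(det, path) {
  node <- det$root
  if (path[1] != node$name) stop("broken node path: root is '", node$name, "'")
  for (nm in path[-1]) {
    idx <- match(nm, vapply(node$children, `[[`, "", "name"))
    if (is.na(idx)) stop("broken node path: no child '", nm, "' under '", node$name, "'")
    node <- node$children[[idx]]
  }
  node
}

replace_node <- function(det, path, new_node) {
  rec <- function(node, rest) {
    if (length(rest) == 0L) return(new_node)
    idx <- match(rest[1], vapply(node$children, `[[`, "", "name"))
    if (is.na(idx)) stop("broken node path: no child '", rest[1], "'")
    node$children[[idx]] <- rec(node$children[[idx]], rest[-1])
    node
  }
  if (path[1] != det$root$name) stop("broken node path")
  det$root <- rec(det$root, path[-1])
  det
}

#' All node paths at a hierarchy level
#'
#' @param det a [detector()].
#' @param level level name to collect (`"detector"`, `"quadrant"`,
#'   `"sensor"`, `"asic"`, ...).
#' @return list of character-vector node paths, in tree order.
#' @export
nodes_at_level <- function(det, level) {
  out <- list()
  walk <- function(node, path) {
    if (identical(node$level, level)) out[[length(out) + 1L]] <<- path
    for (ch in node$children) walk(ch, c(path, ch$name))
  }
  walk(det$root, det$root$name)
  out
}

#' Cumulative frame of a node
#'
#' Composes the local frames along a root-to-node path into a single frame
#' expressed in the laboratory frame.  The cumulative d-vectors follow from
#' the homogeneous chain product: `d0 = F (0,0,0,1)` (dropping the last
#' element), `dx = F (1,0,0,1) - d0`, `dy = F (0,1,0,1) - d0`.
#'
#' @param det a [detector()].
#' @param path character node path from the root (see [nodes_at_level()]).
#' @return a [frame()] in laboratory coordinates.
#' @export
cumulative_frame <- function(det, path) {
  node <- det$root
  if (path[1] != node$name) stop("broken node path")
  acc <- node$frame
  for (nm in path[-1]) {
    idx <- match(nm, vapply(node$children, `[[`, "", "name"))
    if (is.na(idx)) stop("broken node path: no child '", nm, "'")
    node <- node$children[[idx]]
    acc <- compose_frames(acc, node$frame)
  }
  acc
}

#' Cumulative d-vectors of a node
#'
#' @inheritParams cumulative_frame
#' @return list with `d0`, `dx`, `dy` (laboratory frame, mm / unit vectors).
#' @export
cumulative_d_vectors <- function(det, path) {
  f <- cumulative_frame(det, path)
  list(d0 = f$d0, dx = f$dx, dy = f$dy)
}

# --- panel table -------------------------------------------------------------

#' Flatten a detector into a panel table
#'
#' Computes, for every leaf panel, the cumulative laboratory-frame origin and
#' axis vectors plus the panel payload.  This is the working representation
#' used by prediction and refinement; callers in hot loops should compute it
#' once per detector state and reuse it.
#'
#' @param det a [detector()].
#' @return a data.frame with one row per panel: `panel` (1-based id in tree
#'   order), `path` ("/"-joined node path), origin `d0x,d0y,d0z`, axes
#'   `dxx,...,dnz`, and `n_fast`, `n_slow`, `psz_f`, `psz_s`.
#' @export
panel_table <- function(det) {
  rows <- list()
  paths <- character()
  # lean accumulation of R (lab rotation) and t (lab origin) down the tree;
  # equivalent to chained compose_frames but without per-node validation
  walk <- function(node, R, t, path) {
    f <- node$frame
    Rl <- cbind(f$dx, f$dy, cross3(f$dx, f$dy))
    Rn <- R %*% Rl
    tn <- t + as.numeric(R %*% f$d0)
    if (length(node$children) == 0L) {
      rows[[length(rows) + 1L]] <<- c(tn, Rn[, 1], Rn[, 2], Rn[, 3],
                                      node$panel$n_fast, node$panel$n_slow,
                                      node$panel$pixel_size_fast,
                                      node$panel$pixel_size_slow)
      paths[[length(paths) + 1L]] <<- paste(path, collapse = "/")
    } else {
      for (ch in node$children) walk(ch, Rn, tn, c(path, ch$name))
    }
  }
  walk(det$root, diag(3), c(0, 0, 0), det$root$name)
  m <- do.call(rbind, rows)
  colnames(m) <- c("d0x", "d0y", "d0z", "dxx", "dxy", "dxz",
                   "dyx", "dyy", "dyz", "dnx", "dny", "dnz",
                   "n_fast", "n_slow", "psz_f", "psz_s")
  out <- as.data.frame(m)
  out$path <- paths
  out$panel <- seq_len(nrow(out))
  out
}

#' Panel-to-laboratory coordinate mapping
#'
#' `lab_from_panel()` maps in-plane millimetre coordinates on a panel to a
#' laboratory-frame point: `p = d0 + fast * dx + slow * dy` using the leaf's
#' cumulative frame.  `panel_from_lab()` inverts the mapping for a point on
#' (or projected onto) the panel plane.  The pixel convention is 0-based with
#' the panel origin at the outer corner of pixel (0,0), so pixel `(f, s)` has
#' its centre at `((f + 0.5) * pitch_fast, (s + 0.5) * pitch_slow)` mm.
#'
#' @param det a [detector()] (or a precomputed [panel_table()] via `ptab`).
#' @param panel 1-based panel id (tree order).
#' @param fast_mm,slow_mm in-plane coordinates, mm.
#' @param ptab optional precomputed panel table.
#' @return `lab_from_panel`: numeric length-3 laboratory point (mm).
#' @export
lab_from_panel <- function(det, panel, fast_mm, slow_mm, ptab = NULL) {
  pt <- if (is.null(ptab)) panel_table(det) else ptab
  if (panel < 1 || panel > nrow(pt)) stop("no such panel: ", panel)
  r <- pt[panel, ]
  c(r$d0x, r$d0y, r$d0z) + fast_mm * c(r$dxx, r$dxy, r$dxz) +
    slow_mm * c(r$dyx, r$dyy, r$dyz)
}

#' @rdname lab_from_panel
#' @param p laboratory-frame point (mm), assumed to lie on the panel plane
#'   (points off the plane are orthogonally projected).
#' @return `panel_from_lab`: list with `fast_mm`, `slow_mm`, and logical
#'   `on_panel` (off-panel results are flagged, never clamped).
#' @export
panel_from_lab <- function(det, p, panel, ptab = NULL) {
  pt <- if (is.null(ptab)) panel_table(det) else ptab
  if (panel < 1 || panel > nrow(pt)) stop("no such panel: ", panel)
  r <- pt[panel, ]
  v <- p - c(r$d0x, r$d0y, r$d0z)
  fast <- sum(v * c(r$dxx, r$dxy, r$dxz))
  slow <- sum(v * c(r$dyx, r$dyy, r$dyz))
  list(fast_mm = fast, slow_mm = slow,
       on_panel = fast >= 0 && fast <= r$n_fast * r$psz_f &&
                  slow >= 0 && slow <= r$n_slow * r$psz_s)
}

# --- rigid-body moves --------------------------------------------------------

#' Move a hierarchy node rigidly
#'
#' Applies the standard six refinable degrees of freedom of a panel group:
#' `distance` translates along the node's current normal `dn`, `shift1` and
#' `shift2` along `dx` and `dy`, and `tau1`, `tau2`, `tau3` rotate (radians,
#' right-handed) about `dn`, `dx` and `dy` respectively, in that order, about
#' the node's pre-move axes through the node origin.  All descendants move
#' rigidly because their frames are expressed relative to the node.
#'
#' @param det a [detector()].
#' @param path node path.
#' @param distance,shift1,shift2 translations, mm.
#' @param tau1,tau2,tau3 rotations, radians.
#' @return the updated [detector()].
#' @export
move_node <- function(det, path, distance = 0, shift1 = 0, shift2 = 0,
                      tau1 = 0, tau2 = 0, tau3 = 0) {
  node <- find_node(det, path)
  f <- node$frame
  dn <- frame_dn(f)
  d0 <- f$d0 + distance * dn + shift1 * f$dx + shift2 * f$dy
  if (tau1 != 0 || tau2 != 0 || tau3 != 0) {
    R <- rotation_about_axis(f$dy, tau3) %*%
         rotation_about_axis(f$dx, tau2) %*%
         rotation_about_axis(dn, tau1)
    dx <- as.numeric(R %*% f$dx)
    dy <- as.numeric(R %*% f$dy)
  } else {
    dx <- f$dx; dy <- f$dy
  }
  node$frame <- frame(d0 = d0, dx = dx, dy = dy)
  replace_node(det, path, node)
}

# --- CSPAD-like builder ------------------------------------------------------

#' Build a CSPAD-like hierarchical detector
#'
#' Constructs the default four-level hierarchy: one detector frame, four
#' quadrants rotated 90 degrees from one another about the beam axis
#' (pinwheel layout), eight sensors per quadrant, and two ASICs per sensor
#' separated by a fixed inter-ASIC gap (three pixel widths by default; the
#' gap is part of the sensor construction and is never refined).
#'
#' Sensors within a quadrant are laid out on a 2 x 4 grid and numbered such
#' that their radial distances from the beam centre increase in the order
#' 1, 0, 7, 3, 2, 6, 4, 5 -- the admission order used by the expanding
#' refinement protocol.
#'
#' @param distance sample-to-detector distance, mm (detector plane at
#'   `z = -distance`).
#' @param asic_fast,asic_slow ASIC pixel counts (defaults 194 x 185).
#' @param pixel pixel size, mm (default 0.110).
#' @param gap_px inter-ASIC gap in pixel widths (default 3).
#' @param asic_dy_flip if `TRUE`, ASIC leaves use a flipped slow axis
#'   (readout-order convention seen on some assembled devices); the covered
#'   area is unchanged.
#' @return a [detector()] with 64 panels.
#' @examples
#' det <- cspad_detector(distance = 130)
#' nrow(panel_table(det))
#' @export
cspad_detector <- function(distance = 130, asic_fast = 194L, asic_slow = 185L,
                           pixel = 0.110, gap_px = 3, asic_dy_flip = FALSE) {
  w <- (2 * asic_fast + gap_px) * pixel     # sensor fast extent, mm
  h <- asic_slow * pixel                    # sensor slow extent, mm
  m0 <- 2 * pixel                           # margin from the beam axes
  g2 <- 2 * pixel                           # inter-sensor gap
  # slot (col,row) -> lower-left corner in quadrant coordinates
  slot_origin <- function(col, row) c(m0 + col * (w + g2), m0 + row * (h + g2), 0)
  # sensor index -> slot, ordered by increasing slot radius (see Details)
  slots <- list(`1` = c(0, 0), `0` = c(0, 1), `7` = c(0, 2), `3` = c(1, 0),
                `2` = c(1, 1), `6` = c(0, 3), `4` = c(1, 2), `5` = c(1, 3))
  make_asic <- function(name, fast_off_mm) {
    if (asic_dy_flip) {
      fr <- frame(d0 = c(fast_off_mm, h, 0), dx = c(1, 0, 0), dy = c(0, -1, 0))
    } else {
      fr <- frame(d0 = c(fast_off_mm, 0, 0), dx = c(1, 0, 0), dy = c(0, 1, 0))
    }
    new_detector_node(name, "asic", fr,
                      panel = list(n_fast = asic_fast, n_slow = asic_slow,
                                   pixel_size_fast = pixel, pixel_size_slow = pixel))
  }
  make_sensor <- function(si) {
    sl <- slots[[as.character(si)]]
    fr <- frame(d0 = slot_origin(sl[1], sl[2]), dx = c(1, 0, 0), dy = c(0, 1, 0))
    new_detector_node(paste0("s", si), "sensor", fr,
                      children = list(make_asic("a0", 0),
                                      make_asic("a1", (asic_fast + gap_px) * pixel)))
  }
  make_quadrant <- function(qi) {
    R <- rotation_about_axis(c(0, 0, 1), qi * pi / 2)
    fr <- frame(d0 = c(0, 0, 0), dx = as.numeric(R %*% c(1, 0, 0)),
                dy = as.numeric(R %*% c(0, 1, 0)))
    new_detector_node(paste0("q", qi), "quadrant", fr,
                      children = lapply(0:7, make_sensor))
  }
  root <- new_detector_node("detector", "detector",
                            frame(d0 = c(0, 0, -distance)),
                            children = lapply(0:3, make_quadrant))
  detector(root)
}

# Hot-path variant of panel_table: numeric matrix only, no data.frame.
# Column layout matches ptab_matrix().
panel_matrix <- function(det) {
  rows <- vector("list", 64)
  nr <- 0L
  walk <- function(node, R, t) {
    f <- node$frame
    Rl <- cbind(f$dx, f$dy, cross3(f$dx, f$dy))
    Rn <- R %*% Rl
    tn <- t + as.numeric(R %*% f$d0)
    if (length(node$children) == 0L) {
      nr <<- nr + 1L
      rows[[nr]] <<- c(tn, Rn[, 1], Rn[, 2], Rn[, 3],
                       node$panel$n_fast, node$panel$n_slow,
                       node$panel$pixel_size_fast, node$panel$pixel_size_slow)
    } else {
      for (ch in node$children) walk(ch, Rn, tn)
    }
  }
  walk(det$root, diag(3), c(0, 0, 0))
  matrix(unlist(rows[seq_len(nr)], use.names = FALSE), nrow = nr, byrow = TRUE)
}

# Apply several node moves in one traversal.  `moves` is a named list:
# "/"-joined node path -> numeric c(distance, shift1, shift2, tau1, tau2,
# tau3).  Semantics identical to repeated move_node() calls (the moved
# nodes must not be nested).
apply_moves <- function(det, moves) {
  rec <- function(node, path) {
    key <- paste(path, collapse = "/")
    mv <- moves[[key]]
    if (!is.null(mv) && any(mv != 0)) {
      f <- node$frame
      dn <- cross3(f$dx, f$dy)
      d0 <- f$d0 + mv[1] * dn + mv[2] * f$dx + mv[3] * f$dy
      if (mv[4] != 0 || mv[5] != 0 || mv[6] != 0) {
        R <- NULL
        if (mv[4] != 0) R <- rotation_about_axis(dn, mv[4])
        if (mv[5] != 0) {
          R2 <- rotation_about_axis(f$dx, mv[5])
          R <- if (is.null(R)) R2 else R2 %*% R
        }
        if (mv[6] != 0) {
          R3 <- rotation_about_axis(f$dy, mv[6])
          R <- if (is.null(R)) R3 else R3 %*% R
        }
        # rotation of an orthonormal frame stays orthonormal; skip the
        # validating constructor on this hot path
        node$frame <- structure(list(d0 = d0, dx = as.numeric(R %*% f$dx),
                                     dy = as.numeric(R %*% f$dy)),
                                class = "frame")
      } else {
        node$frame$d0 <- d0
      }
    } else if (length(node$children)) {
      node$children <- lapply(seq_along(node$children), function(i)
        rec(node$children[[i]], c(path, node$children[[i]]$name)))
    }
    node
  }
  det$root <- rec(det$root, det$root$name)
  det
}

#' Expanding-protocol sensor admission order
#'
#' Sensors within each quadrant ordered by increasing radial distance from
#' the detector centre, as used by the expanding refinement protocol.
#'
#' @return integer vector of sensor indices.
#' @export
sensor_admission_order <- function() c(1L, 0L, 7L, 3L, 2L, 6L, 4L, 5L)
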