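# Joint refinement core: the least-squares target over one detector model
# and many crystal models.
#
# The target is L = sum_i [ w_x (x_calc - x_obs)^2 + w_y (y_calc - y_obs)^2
# + w_psi psi_calc^2 ], with statistical weights w_x, w_y equal to the
# inverse centroid variance and a constant psi weight (default 1e6, which
# puts the psi term on the same scale as the positional terms and prevents
# crystal orientations from drifting about axes perpendicular to the beam).
# There are m matched reflections but 3m residuals.  Residual rows are
# stacked [x-block; y-block; psi-block].
#
# Free parameters are owned either by a detector hierarchy node (distance /
# shift1 / shift2 / tau1 / tau2 / tau3, applied as rigid moves about the
# node's step-start axes) or by one crystal (three orientation angles about
# fixed laboratory axes plus the symmetry-free cell lengths).  Distinct
# crystals share no residuals, and distinct same-level detector nodes share
# no residuals, which is what makes the normal equations sparse and lets
# central finite differences perturb whole parameter classes at once.

#' Describe one refinement step
#'
#' @param level detector hierarchy level whose nodes are refined
#'   (`"detector"`, `"quadrant"`, `"sensor"`).
#' @param dofs character subset of `c("distance", "shift1", "shift2",
#'   "tau1", "tau2", "tau3")`.
#' @param nodes optional explicit list of node paths (defaults to all nodes
#'   at `level`); used by the expanding protocol to admit sensor subsets.
#' @param coplanar if `TRUE`, the distance dof is a single parameter shared
#'   by every node at the level (the coplanarity constraint).
#' @param fix_first_tau1 fix tau1 of the first node in the group (only
#'   N - 1 of the N rotations about the common normal are independent).
#' @param crystals_free co-refine all crystal parameters (orientations and
#'   free cell lengths) with the detector dofs.
#' @return a `"refine_step"` list.
#' @export
refine_step <- function(level, dofs, nodes = NULL, coplanar = TRUE,
                        fix_first_tau1 = TRUE, crystals_free = TRUE) {
  bad <- setdiff(dofs, c("distance", "shift1", "shift2", "tau1", "tau2", "tau3"))
  if (length(bad)) stop("unknown dofs: ", paste(bad, collapse = ", "))
  structure(list(level = level, dofs = dofs, nodes = nodes,
                 coplanar = coplanar, fix_first_tau1 = fix_first_tau1,
                 crystals_free = crystals_free),
            class = "refine_step")
}

#' Build the flattened free-parameter set for a refinement step
#'
#' Lays out one column per free parameter: detector dofs per refined node
#' (with the coplanarity constraint collapsing all distance dofs into one
#' shared column, and the first tau1 optionally fixed), followed by the
#' per-crystal orientation angles and free cell lengths.  Crystals with
#' fewer than `min_refl` matched reflections are held fixed for the step.
#'
#' @param det a [detector()] (the step-start snapshot).
#' @param crystals list of [crystal_model()] indexed by image id.
#' @param refl matched reflection table (`image_id`, `panel`, `h`, `k`,
#'   `l`, ...); `NULL` treats every crystal as refinable with full support
#'   (used for parameter counting).
#' @param step a [refine_step()].
#' @param min_refl minimum reflections for a crystal to be refined.
#' @return a `"parameter_set"` list; element `n` is the free-parameter
#'   count and `par` the per-column ownership table.
#' @export
build_parameter_set <- function(det, crystals, refl, step, min_refl = 6L) {
  nodes <- if (is.null(step$nodes)) nodes_at_level(det, step$level) else step$nodes
  if (length(nodes) == 0L) stop("no nodes at level '", step$level, "'")
  par <- list()
  add <- function(type, owner, dof)
    par[[length(par) + 1L]] <<- data.frame(type = type, owner = owner, dof = dof)
  if ("distance" %in% step$dofs) {
    if (step$coplanar) add("det", 0L, "distance")       # owner 0 = shared
    else for (j in seq_along(nodes)) add("det", j, "distance")
  }
  for (dof in intersect(c("shift1", "shift2"), step$dofs))
    for (j in seq_along(nodes)) add("det", j, dof)
  for (dof in intersect(c("tau1", "tau2", "tau3"), step$dofs)) {
    first <- dof == "tau1" && step$fix_first_tau1
    for (j in seq_along(nodes)) if (!(first && j == 1L)) add("det", j, dof)
  }
  free_images <- integer(0)
  if (step$crystals_free) {
    if (is.null(refl)) {
      free_images <- seq_along(crystals)
    } else {
      tb <- table(refl$image_id)
      free_images <- as.integer(names(tb))[tb >= min_refl]
    }
    for (i in free_images) {
      for (dof in c("rot1", "rot2", "rot3")) add("cry", i, dof)
      for (ci in seq_len(n_free_cell_params(crystals[[i]]$tag)))
        add("cry", i, paste0("len", ci))
    }
  }
  par <- do.call(rbind, par)
  par$col <- seq_len(nrow(par))
  # fast lookup tables for the hot apply path
  dof_names <- c("distance", "shift1", "shift2", "tau1", "tau2", "tau3")
  det_idx <- matrix(0L, length(nodes), 6,
                    dimnames = list(NULL, dof_names))
  shared_col <- 0L
  pd <- par[par$type == "det", , drop = FALSE]
  for (ri in seq_len(nrow(pd))) {
    if (pd$owner[ri] == 0L) shared_col <- pd$col[ri]
    else det_idx[pd$owner[ri], pd$dof[ri]] <- pd$col[ri]
  }
  cry_idx <- list()
  pc <- par[par$type == "cry", , drop = FALSE]
  if (nrow(pc)) {
    sp <- split(pc, pc$owner)
    for (nm in names(sp)) {
      s <- sp[[nm]]
      cry_idx[[nm]] <- list(
        rot = s$col[match(c("rot1", "rot2", "rot3"), s$dof)],
        len = s$col[grepl("^len", s$dof)])
    }
  }
  structure(list(det0 = det, crystals0 = crystals, step = step,
                 nodes = nodes, par = par, n = nrow(par),
                 free_images = free_images, det_idx = det_idx,
                 shared_col = shared_col, cry_idx = cry_idx),
            class = "parameter_set")
}

# Detector with the step's detector parameters applied to the snapshot.
# Builds a per-node delta list and applies all moves in one tree traversal.
apply_theta_det <- function(pset, theta) {
  if (all(pset$det_idx == 0L) && pset$shared_col == 0L) return(pset$det0)
  d_shared <- if (pset$shared_col > 0L) theta[pset$shared_col] else 0
  th0 <- c(0, theta)            # index 0 -> delta 0
  moves <- list()
  for (j in seq_along(pset$nodes)) {
    v <- th0[pset$det_idx[j, ] + 1L]
    v[1] <- v[1] + d_shared
    moves[[paste(pset$nodes[[j]], collapse = "/")]] <- v
  }
  # shared distance moves every node at the level, refined subset or not,
  # preserving a coplanar detector
  if (d_shared != 0) {
    for (p in nodes_at_level(pset$det0, pset$step$level)) {
      key <- paste(p, collapse = "/")
      if (is.null(moves[[key]])) moves[[key]] <- c(d_shared, 0, 0, 0, 0, 0)
    }
  }
  apply_moves(pset$det0, moves)
}

# Crystals with the step's crystal parameters applied to the snapshot.
apply_theta_crystals <- function(pset, theta) {
  crystals <- pset$crystals0
  if (length(pset$cry_idx) == 0L) return(crystals)
  for (i in pset$free_images) {
    ix <- pset$cry_idx[[as.character(i)]]
    ang <- theta[ix$rot]
    dl <- theta[ix$len]
    if (all(ang == 0) && all(dl == 0)) next
    cry <- crystals[[i]]
    if (any(ang != 0)) cry <- rotate_crystal(cry, ang)
    if (any(dl != 0)) cry <- set_cell_lengths(cry, cry$lengths + dl)
    crystals[[i]] <- cry
  }
  crystals
}

# UB (3x3, column-major as length-9 rows) and s0 rows for the image set.
ub_matrix <- function(crystals, imgs) {
  t(vapply(imgs, function(i) as.numeric(crystals[[i]]$U %*% crystals[[i]]$B),
           numeric(9)))
}
s0_matrix <- function(beams, imgs) {
  t(vapply(imgs, function(i) beams[[i]]$s0, numeric(3)))
}

# Vectorized calculated positions for matched reflections.
# ubm/s0m rows follow `imgs`; refl$.img indexes those rows.
calc_positions <- function(ubm, s0m, ptm, refl) {
  A <- ubm[refl$.img, , drop = FALSE]
  h <- refl$h; k <- refl$k; l <- refl$l
  rlp <- cbind(A[, 1] * h + A[, 4] * k + A[, 7] * l,
               A[, 2] * h + A[, 5] * k + A[, 8] * l,
               A[, 3] * h + A[, 6] * k + A[, 9] * l)
  s0 <- s0m[refl$.img, , drop = FALSE]
  rx <- rlp[, 1]; ry <- rlp[, 2]; rz <- rlp[, 3]
  r2 <- rx * rx + ry * ry + rz * rz
  P <- 2 * (rx * s0[, 1] + ry * s0[, 2] + rz * s0[, 3])
  cx <- ry * s0[, 3] - rz * s0[, 2]
  cy <- rz * s0[, 1] - rx * s0[, 3]
  cz <- rx * s0[, 2] - ry * s0[, 1]
  cn <- sqrt(cx * cx + cy * cy + cz * cz)
  Q <- 2 * cn
  rho <- sqrt(P * P + Q * Q)
  ratio <- pmin(pmax(-r2 / rho, -1), 1)
  phi <- atan2(Q, P)
  am <- acos(ratio)
  psi1 <- phi - am; psi2 <- phi + am
  psi1 <- psi1 - 2 * pi * round(psi1 / (2 * pi))
  psi2 <- psi2 - 2 * pi * round(psi2 / (2 * pi))
  psi <- ifelse(abs(psi1) <= abs(psi2), psi1, psi2)
  px <- (cy * rz - cz * ry) / cn
  py <- (cz * rx - cx * rz) / cn
  pz <- (cx * ry - cy * rx) / cn
  cp <- cos(psi); sp <- sin(psi)
  s1 <- cbind(s0[, 1] + rx * cp + px * sp,
              s0[, 2] + ry * cp + py * sp,
              s0[, 3] + rz * cp + pz * sp)
  pr <- project_to_panels(s1, refl$panel, ptm)
  list(x = pr$fast, y = pr$slow, psi = psi)
}

# Panel-plane projection for a pre-expanded per-reflection panel matrix
# (columns as ptab_matrix rows, one row per reflection).
project_expanded <- function(s1, Pm) {
  den <- s1[, 1] * Pm[, 10] + s1[, 2] * Pm[, 11] + s1[, 3] * Pm[, 12]
  num <- Pm[, 1] * Pm[, 10] + Pm[, 2] * Pm[, 11] + Pm[, 3] * Pm[, 12]
  tt <- num / den
  vx <- tt * s1[, 1] - Pm[, 1]
  vy <- tt * s1[, 2] - Pm[, 2]
  vz <- tt * s1[, 3] - Pm[, 3]
  list(fast = vx * Pm[, 4] + vy * Pm[, 5] + vz * Pm[, 6],
       slow = vx * Pm[, 7] + vy * Pm[, 8] + vz * Pm[, 9])
}

#' Build a residual system from matched observations and predictions
#'
#' Matches observations to predictions by (image, hkl), forms the residual
#' vector (x, y and psi blocks), the inverse-variance weights (psi weight
#' constant), the target value L and the positional r.m.s.d.
#'
#' @param obs observation table with `image_id`, `h`, `k`, `l`, `x_obs`,
#'   `y_obs` and variances `var_x`, `var_y`.
#' @param pred prediction table with `image_id`, `h`, `k`, `l`, `x_calc`,
#'   `y_calc`, `psi`.
#' @param w_psi constant psi weight (default 1e6).
#' @param var_fallback variance used where the table has none (default
#'   pixel^2/12 for a 0.110 mm pixel; pass explicitly for other pixels).
#' @return list with `r` (length 3m), `w` (weights, same layout), `L`,
#'   `rmsd_um` (positional only, micrometres) and the matched table.
#' @export
build_residuals <- function(obs, pred, w_psi = 1e6,
                            var_fallback = 0.110^2 / 12) {
  key_o <- paste(obs$image_id, obs$h, obs$k, obs$l)
  key_p <- paste(pred$image_id, pred$h, pred$k, pred$l)
  idx <- match(key_o, key_p)
  keep <- !is.na(idx)
  o <- obs[keep, ]; p <- pred[idx[keep], ]
  vx <- o$var_x; vy <- o$var_y
  vx[!is.finite(vx) | vx <= 0] <- var_fallback
  vy[!is.finite(vy) | vy <= 0] <- var_fallback
  rx <- p$x_calc - o$x_obs
  ry <- p$y_calc - o$y_obs
  r <- c(rx, ry, p$psi)
  w <- c(1 / vx, 1 / vy, rep(w_psi, nrow(o)))
  list(r = r, w = w, L = sum(w * r^2),
       rmsd_um = 1000 * sqrt(mean(rx^2 + ry^2)), matched = cbind(o, p[, c("x_calc", "y_calc", "psi")]))
}

#' Create the refinement system for one step
#'
#' Precomputes weights, ownership maps and finite-difference perturbation
#' groups, and returns closures evaluating the residual vector, target,
#' Jacobian and r.m.s.d. as functions of the flat parameter vector.  The
#' Jacobian uses central differences with step `1e-6`; because distinct
#' crystals (and distinct same-level detector nodes) have disjoint residual
#' support, each parameter class is perturbed for all owners at once.
#'
#' @param det,crystals,beams current models (step-start snapshot).
#' @param refl matched reflections (`image_id`, `panel`, `h`, `k`, `l`,
#'   `x_obs`, `y_obs`, `var_x`, `var_y`).
#' @param step a [refine_step()].
#' @param w_psi constant psi weight.
#' @param min_refl minimum reflections for a crystal to refine.
#' @return a `"refine_system"` list; key elements: `n`, `m`, `pset`,
#'   `residuals(theta)`, `L(theta)`, `jacobian(theta)`, `rmsd_um(theta)`,
#'   `sw` (sqrt-weight vector).
#' @export
make_refine_system <- function(det, crystals, beams, refl, step,
                               w_psi = 1e6, min_refl = 6L) {
  stopifnot(nrow(refl) > 0)
  pset <- build_parameter_set(det, crystals, refl, step, min_refl = min_refl)
  m <- nrow(refl)
  imgs <- sort(unique(refl$image_id))
  refl$.img <- match(refl$image_id, imgs)
  ptab0 <- panel_table(det)
  pxf <- ptab0$psz_f[refl$panel]
  vx <- refl$var_x; vy <- refl$var_y
  vx[!is.finite(vx) | vx <= 0] <- pxf[!is.finite(vx) | vx <= 0]^2 / 12
  vy[!is.finite(vy) | vy <= 0] <- pxf[!is.finite(vy) | vy <= 0]^2 / 12
  sw <- sqrt(c(1 / vx, 1 / vy, rep(w_psi, m)))
  obs_vec <- c(refl$x_obs, refl$y_obs, rep(0, m))
  s0m <- s0_matrix(beams, imgs)

  # ownership: panel -> refined-node index (NA if under none)
  node_str <- vapply(pset$nodes, paste, "", collapse = "/")
  panel_node <- rep(NA_integer_, nrow(ptab0))
  for (j in seq_along(node_str)) {
    hit <- startsWith(ptab0$path, paste0(node_str[j], "/")) |
      ptab0$path == node_str[j]
    panel_node[hit] <- j
  }
  refl_node <- panel_node[refl$panel]
  rows_by_node <- split(seq_len(m), factor(refl_node, seq_along(pset$nodes)))
  rows_by_img <- split(seq_len(m), factor(refl$image_id, imgs))

  # support rows (reflection-level) per column
  col_rows <- vector("list", pset$n)
  pd <- pset$par
  for (ci in seq_len(nrow(pd))) {
    col_rows[[pd$col[ci]]] <-
      if (pd$type[ci] == "det") {
        if (pd$owner[ci] == 0L) seq_len(m) else rows_by_node[[pd$owner[ci]]]
      } else rows_by_img[[match(pd$owner[ci], imgs)]]
  }

  # finite-difference groups: columns with pairwise-disjoint support that
  # can be perturbed simultaneously
  groups <- list()
  det_mask <- pd$type == "det"
  for (dof in unique(pd$dof[det_mask & pd$owner != 0L]))
    groups[[length(groups) + 1L]] <-
      list(kind = "det", cols = pd$col[det_mask & pd$dof == dof & pd$owner != 0L])
  if (any(det_mask & pd$owner == 0L))
    groups[[length(groups) + 1L]] <-
      list(kind = "det", cols = pd$col[det_mask & pd$owner == 0L])
  cry_mask <- pd$type == "cry"
  for (dof in unique(pd$dof[cry_mask]))
    groups[[length(groups) + 1L]] <-
      list(kind = "cry", cols = pd$col[cry_mask & pd$dof == dof])

  # staged evaluation: rlp(ubm) -> (psi, s1) -> panel projection
  hklm <- cbind(refl$h, refl$k, refl$l)
  iimg <- refl$.img
  pan <- refl$panel
  rlp_of <- function(ubm) {
    A <- ubm[iimg, , drop = FALSE]
    cbind(A[, 1] * hklm[, 1] + A[, 4] * hklm[, 2] + A[, 7] * hklm[, 3],
          A[, 2] * hklm[, 1] + A[, 5] * hklm[, 2] + A[, 8] * hklm[, 3],
          A[, 3] * hklm[, 1] + A[, 6] * hklm[, 2] + A[, 9] * hklm[, 3])
  }
  s0r <- s0m[iimg, , drop = FALSE]
  psi_s1_of <- function(rlp) {
    rx <- rlp[, 1]; ry <- rlp[, 2]; rz <- rlp[, 3]
    r2 <- rx * rx + ry * ry + rz * rz
    P <- 2 * (rx * s0r[, 1] + ry * s0r[, 2] + rz * s0r[, 3])
    cx <- ry * s0r[, 3] - rz * s0r[, 2]
    cy <- rz * s0r[, 1] - rx * s0r[, 3]
    cz <- rx * s0r[, 2] - ry * s0r[, 1]
    cn <- sqrt(cx * cx + cy * cy + cz * cz)
    rho <- sqrt(P * P + 4 * cn * cn)
    ratio <- pmin(pmax(-r2 / rho, -1), 1)
    phi <- atan2(2 * cn, P)
    am <- acos(ratio)
    psi1 <- phi - am; psi2 <- phi + am
    psi1 <- psi1 - 2 * pi * round(psi1 / (2 * pi))
    psi2 <- psi2 - 2 * pi * round(psi2 / (2 * pi))
    psi <- ifelse(abs(psi1) <= abs(psi2), psi1, psi2)
    px <- (cy * rz - cz * ry) / cn
    py <- (cz * rx - cx * rz) / cn
    pz <- (cx * ry - cy * rx) / cn
    cp <- cos(psi); sp <- sin(psi)
    list(psi = psi,
         s1 = cbind(s0r[, 1] + rx * cp + px * sp,
                    s0r[, 2] + ry * cp + py * sp,
                    s0r[, 3] + rz * cp + pz * sp))
  }
  eval_models <- function(theta) {
    list(ptm = panel_matrix(apply_theta_det(pset, theta)),
         ubm = ub_matrix(apply_theta_crystals(pset, theta), imgs))
  }
  resid_from <- function(ptm, ubm) {
    ps <- psi_s1_of(rlp_of(ubm))
    pr <- project_expanded(ps$s1, ptm[pan, , drop = FALSE])
    c(pr$fast, pr$slow, ps$psi) - obs_vec
  }
  residuals <- function(theta) {
    mdl <- eval_models(theta)
    resid_from(mdl$ptm, mdl$ubm)
  }
  Lfun <- function(theta) {
    r <- residuals(theta)
    sum((sw * r)^2)
  }
  rmsd_um <- function(theta) {
    r <- residuals(theta)
    1000 * sqrt(mean(r[1:m]^2 + r[(m + 1):(2 * m)]^2))
  }

  # --- detector node geometry at the step-start snapshot (for the chain
  # Jacobian): per node at the step level, its panel rows in the panel
  # matrix and its cumulative origin/axes
  lvl_nodes <- nodes_at_level(det, step$level)
  lvl_info <- lapply(lvl_nodes, function(p) {
    pp <- paste(p, collapse = "/")
    f <- cumulative_frame(det, p)
    list(panels = which(startsWith(ptab0$path, paste0(pp, "/")) |
                          ptab0$path == pp),
         o0 = f$d0, dx0 = f$dx, dy0 = f$dy, dn0 = frame_dn(f))
  })
  refined_lvl <- match(vapply(pset$nodes, paste, "", collapse = "/"),
                       vapply(lvl_nodes, paste, "", collapse = "/"))
  # whether the cheap chain rules apply (no tilt dofs, homogeneous cell tag)
  tags <- unique(vapply(pset$free_images, function(i) crystals[[i]]$tag, ""))
  chain_ok <- !any(c("tau2", "tau3") %in% step$dofs) && length(tags) <= 1L

  jacobian_fd <- function(theta, h = 1e-6) {
    mdl0 <- eval_models(theta)
    tri <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      tp <- theta; tp[g$cols] <- tp[g$cols] + h
      tm <- theta; tm[g$cols] <- tm[g$cols] - h
      if (g$kind == "det") {
        rp <- resid_from(panel_matrix(apply_theta_det(pset, tp)), mdl0$ubm)
        rm <- resid_from(panel_matrix(apply_theta_det(pset, tm)), mdl0$ubm)
      } else {
        rp <- resid_from(mdl0$ptm, ub_matrix(apply_theta_crystals(pset, tp), imgs))
        rm <- resid_from(mdl0$ptm, ub_matrix(apply_theta_crystals(pset, tm), imgs))
      }
      d <- (rp - rm) / (2 * h)
      if (any(!is.finite(d)))
        stop("non-finite derivative in a '", g$kind, "' parameter group")
      rws <- col_rows[g$cols]
      lens <- lengths(rws)
      r1 <- unlist(rws, use.names = FALSE)
      rows3 <- c(r1, r1 + m, r1 + 2 * m)
      cols1 <- rep.int(g$cols, lens)
      tri[[gi]] <- list(i = rows3, j = c(cols1, cols1, cols1), x = d[rows3])
    }
    Matrix::sparseMatrix(i = unlist(lapply(tri, `[[`, "i"), use.names = FALSE),
                         j = unlist(lapply(tri, `[[`, "j"), use.names = FALSE),
                         x = unlist(lapply(tri, `[[`, "x"), use.names = FALSE),
                         dims = c(3 * m, pset$n))
  }

  skew <- function(a) matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3)
  # chain-rule Jacobian: rlp-space central differences give the sensitivity
  # of (x, y, psi) to the reciprocal-lattice vector once per call; crystal
  # parameter directions d rlp / d p are analytic; detector columns come
  # from rigid perturbations applied directly to the panel matrix (psi does
  # not depend on the detector)
  jacobian_chain <- function(theta, h = 1e-6, hr = 1e-7) {
    det_th <- apply_theta_det(pset, theta)
    ptm <- panel_matrix(det_th)
    crys <- apply_theta_crystals(pset, theta)
    ubm <- ub_matrix(crys, imgs)
    rlp <- rlp_of(ubm)
    Pmb <- ptm[pan, , drop = FALSE]
    Dx <- Dy <- Dp <- matrix(0, m, 3)
    for (i in 1:3) {
      rp <- rlp; rp[, i] <- rp[, i] + hr
      pp <- psi_s1_of(rp); qp <- project_expanded(pp$s1, Pmb)
      rm_ <- rlp; rm_[, i] <- rm_[, i] - hr
      pm <- psi_s1_of(rm_); qm <- project_expanded(pm$s1, Pmb)
      Dx[, i] <- (qp$fast - qm$fast) / (2 * hr)
      Dy[, i] <- (qp$slow - qm$slow) / (2 * hr)
      Dp[, i] <- (pp$psi - pm$psi) / (2 * hr)
    }
    tri_i <- list(); tri_j <- list(); tri_x <- list()
    emit <- function(rows, cols, vx, vy, vp = NULL) {
      tri_i[[length(tri_i) + 1L]] <<-
        if (is.null(vp)) c(rows, rows + m) else c(rows, rows + m, rows + 2 * m)
      tri_j[[length(tri_j) + 1L]] <<-
        if (is.null(vp)) c(cols, cols) else c(cols, cols, cols)
      tri_x[[length(tri_x) + 1L]] <<-
        if (is.null(vp)) c(vx, vy) else c(vx, vy, vp)
    }
    # crystal columns -----------------------------------------------------
    if (length(pset$free_images)) {
      n_img <- length(imgs)
      nlen <- n_free_cell_params(crystals[[pset$free_images[1]]]$tag)
      Mrot <- list(matrix(0, n_img, 9), matrix(0, n_img, 9), matrix(0, n_img, 9))
      Mlen <- lapply(seq_len(nlen), function(...) matrix(0, n_img, 9))
      colmap_rot <- matrix(NA_integer_, n_img, 3)
      colmap_len <- matrix(NA_integer_, n_img, nlen)
      Sx <- skew(c(1, 0, 0)); Sy <- skew(c(0, 1, 0)); Sz <- skew(c(0, 0, 1))
      for (gi_im in pset$free_images) {
        ri <- match(gi_im, imgs)
        if (is.na(ri)) next
        ix <- pset$cry_idx[[as.character(gi_im)]]
        ang <- theta[ix$rot]
        Rz <- rotation_about_axis(c(0, 0, 1), ang[3])
        Ry <- rotation_about_axis(c(0, 1, 0), ang[2])
        # d rlp / d phi_k = M_k rlp for U = Rz Ry Rx U0
        Mrot[[1]][ri, ] <- as.numeric(Rz %*% Ry %*% Sx %*% t(Ry) %*% t(Rz))
        Mrot[[2]][ri, ] <- as.numeric(Rz %*% Sy %*% t(Rz))
        Mrot[[3]][ri, ] <- as.numeric(Sz)
        colmap_rot[ri, ] <- ix$rot
        cry <- crys[[gi_im]]
        for (li in seq_len(nlen)) {
          lp <- cry$lengths; lp[li] <- lp[li] + h
          lm <- cry$lengths; lm[li] <- lm[li] - h
          dB <- (cell_to_B(constrained_cell(cry$tag, lp)) -
                   cell_to_B(constrained_cell(cry$tag, lm))) / (2 * h)
          Mlen[[li]][ri, ] <- as.numeric(cry$U %*% dB)
          colmap_len[ri, li] <- ix$len[li]
        }
      }
      apply9 <- function(Mm, v) {
        A <- Mm[iimg, , drop = FALSE]
        cbind(A[, 1] * v[, 1] + A[, 4] * v[, 2] + A[, 7] * v[, 3],
              A[, 2] * v[, 1] + A[, 5] * v[, 2] + A[, 8] * v[, 3],
              A[, 3] * v[, 1] + A[, 6] * v[, 2] + A[, 9] * v[, 3])
      }
      for (k in 1:3) {
        v <- apply9(Mrot[[k]], rlp)
        cols <- colmap_rot[iimg, k]
        sel <- which(!is.na(cols))
        emit(sel, cols[sel],
             rowSums(Dx[sel, , drop = FALSE] * v[sel, , drop = FALSE]),
             rowSums(Dy[sel, , drop = FALSE] * v[sel, , drop = FALSE]),
             rowSums(Dp[sel, , drop = FALSE] * v[sel, , drop = FALSE]))
      }
      for (li in seq_len(nlen)) {
        v <- apply9(Mlen[[li]], hklm)
        cols <- colmap_len[iimg, li]
        sel <- which(!is.na(cols))
        emit(sel, cols[sel],
             rowSums(Dx[sel, , drop = FALSE] * v[sel, , drop = FALSE]),
             rowSums(Dy[sel, , drop = FALSE] * v[sel, , drop = FALSE]),
             rowSums(Dp[sel, , drop = FALSE] * v[sel, , drop = FALSE]))
      }
    }
    # detector columns (perturb the expanded per-reflection panel rows) ---
    s1b <- psi_s1_of(rlp)$s1
    proj_d <- function(Pm2) project_expanded(s1b, Pm2)
    refl_rows_lvl <- lapply(lvl_info, function(info)
      which(pan %in% info$panels))
    perturb_trans <- function(nodes_idx, axis_name, hh) {
      p2 <- Pmb
      for (jj in nodes_idx) {
        info <- lvl_info[[jj]]
        rows <- refl_rows_lvl[[jj]]
        if (!length(rows)) next
        a <- switch(axis_name, dn = info$dn0, dx = info$dx0, dy = info$dy0)
        p2[rows, 1:3] <- p2[rows, 1:3] + rep(hh * a, each = length(rows))
      }
      p2
    }
    theta0 <- c(0, theta)
    node_origin <- function(jj_lvl, j_ref) {
      info <- lvl_info[[jj_lvl]]
      o <- info$o0
      if (!is.na(j_ref) && j_ref > 0) {
        d_sh <- if (pset$shared_col > 0L) theta[pset$shared_col] else 0
        v <- theta0[pset$det_idx[j_ref, ] + 1L]
        o <- o + (v[1] + d_sh) * info$dn0 + v[2] * info$dx0 + v[3] * info$dy0
      } else if (pset$shared_col > 0L) {
        o <- o + theta[pset$shared_col] * info$dn0
      }
      o
    }
    perturb_tau1 <- function(hh) {
      p2 <- Pmb
      for (j in seq_along(pset$nodes)) {
        if (pset$det_idx[j, "tau1"] == 0L) next
        jj <- refined_lvl[j]
        info <- lvl_info[[jj]]
        rows <- refl_rows_lvl[[jj]]
        if (!length(rows)) next
        R <- rotation_about_axis(info$dn0, hh)
        o <- node_origin(jj, j)
        p2[rows, 1:3] <- sweep(sweep(p2[rows, 1:3, drop = FALSE], 2, o) %*%
                                 t(R), 2, o, `+`)
        p2[rows, 4:6] <- p2[rows, 4:6, drop = FALSE] %*% t(R)
        p2[rows, 7:9] <- p2[rows, 7:9, drop = FALSE] %*% t(R)
        p2[rows, 10:12] <- p2[rows, 10:12, drop = FALSE] %*% t(R)
      }
      p2
    }
    det_emit <- function(dof, qp, qm) {
      dx_ <- (qp$fast - qm$fast) / (2 * h)
      dy_ <- (qp$slow - qm$slow) / (2 * h)
      for (j in seq_along(pset$nodes)) {
        cc <- pset$det_idx[j, dof]
        if (cc == 0L) next
        rows <- rows_by_node[[j]]
        emit(rows, rep.int(cc, length(rows)), dx_[rows], dy_[rows])
      }
    }
    dofs <- step$dofs
    if ("shift1" %in% dofs) {
      ref <- refined_lvl[pset$det_idx[, "shift1"] > 0L]
      det_emit("shift1", proj_d(perturb_trans(ref, "dx", h)),
               proj_d(perturb_trans(ref, "dx", -h)))
    }
    if ("shift2" %in% dofs) {
      ref <- refined_lvl[pset$det_idx[, "shift2"] > 0L]
      det_emit("shift2", proj_d(perturb_trans(ref, "dy", h)),
               proj_d(perturb_trans(ref, "dy", -h)))
    }
    if ("distance" %in% dofs && !step$coplanar) {
      ref <- refined_lvl[pset$det_idx[, "distance"] > 0L]
      det_emit("distance", proj_d(perturb_trans(ref, "dn", h)),
               proj_d(perturb_trans(ref, "dn", -h)))
    }
    if (pset$shared_col > 0L) {
      qp <- proj_d(perturb_trans(seq_along(lvl_info), "dn", h))
      qm <- proj_d(perturb_trans(seq_along(lvl_info), "dn", -h))
      rows <- seq_len(m)
      emit(rows, rep.int(pset$shared_col, m),
           (qp$fast - qm$fast) / (2 * h), (qp$slow - qm$slow) / (2 * h))
    }
    if ("tau1" %in% dofs) {
      det_emit("tau1", proj_d(perturb_tau1(h)), proj_d(perturb_tau1(-h)))
    }
    J <- Matrix::sparseMatrix(i = unlist(tri_i, use.names = FALSE),
                              j = unlist(tri_j, use.names = FALSE),
                              x = unlist(tri_x, use.names = FALSE),
                              dims = c(3 * m, pset$n))
    if (any(!is.finite(J@x))) stop("non-finite derivative in chain Jacobian")
    J
  }

  jacobian <- function(theta, h = 1e-6, mode = if (chain_ok) "chain" else "fd") {
    if (mode == "chain") jacobian_chain(theta, h) else jacobian_fd(theta, h)
  }
  structure(list(n = pset$n, m = m, pset = pset, sw = sw,
                 residuals = residuals, L = Lfun, jacobian = jacobian,
                 rmsd_um = rmsd_um, col_rows = col_rows, imgs = imgs),
            class = "refine_system")
}

#' Gauss-Newton curvature approximation
#'
#' Diagonal of the approximate Hessian, `2 * sum_i w_i (dr_i/dp)^2`; exact
#' when the residuals are linear in the parameters, and increasingly
#' accurate as refinement approaches convergence.  Always non-negative.
#'
#' @param J Jacobian (3m x n, sparse or dense).
#' @param w residual weights (length 3m).
#' @return numeric length-n curvature vector.
#' @export
curvature_diag <- function(J, w) {
  Jw <- Matrix::Diagonal(x = sqrt(w)) %*% J
  2 * as.numeric(Matrix::colSums(Jw^2))
}

#' Structural sparsity pattern of the normal matrix
#'
#' Computed from parameter ownership and reflection co-occurrence alone,
#' before any numeric work: entry (i, j) is structurally nonzero iff the
#' two parameters share at least one residual.  Cross-terms between two
#' distinct crystals, or between parameters sharing no reflection, are
#' structural zeros.
#'
#' @param system a [make_refine_system()] result.
#' @return a sparse logical (pattern) matrix of dimension n x n.
#' @export
sparsity_structure <- function(system) {
  m <- system$m
  ii <- integer(0); jj <- integer(0)
  for (cc in seq_along(system$col_rows)) {
    rws <- system$col_rows[[cc]]
    ii <- c(ii, rws); jj <- c(jj, rep.int(cc, length(rws)))
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(m, system$n))
  Matrix::crossprod(P) > 0
}
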