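# Refinement engines.
#
# Four interchangeable minimizers of the joint least-squares target:
# LBFGS, LBFGS seeded with Gauss-Newton curvatures, dense
# Levenberg-Marquardt and sparse Levenberg-Marquardt.  All work on the
# pre-whitened system (residuals scaled by sqrt(weight)), so the normal
# matrix is A = Jw' Jw and the gradient 2 Jw' rw -- identical algebra to
# the weighted normal equations, with better conditioning.
#
# LevMar builds the normal equations A delta = b (b = -Jw' rw), damps A by
# lambda * diag(A) (Marquardt scaling), solves by Cholesky decomposition --
# dense, or sparse with a fill-reducing permutation -- and accepts the step
# iff the target decreases.  The damping schedule is lambda0 = 1e-3, x2 on
# reject, /3 on accept.  Convergence: relative decrease of L below `ltol`
# on two consecutive accepted steps, or gradient infinity-norm below
# `gtol`, or the step cap.

#' @importFrom methods as
NULL

new_refine_result <- function(engine, theta, L_traj, steps, rmsd_um,
                              converged, n, nnz_A = NA_real_,
                              nnz_chol = NA_real_, delta_history = NULL) {
  structure(list(engine = engine, theta = theta, L = L_traj[length(L_traj)],
                 L_trajectory = L_traj, steps = steps, rmsd_um = rmsd_um,
                 converged = converged, n = n, nnz_A = nnz_A,
                 nnz_chol = nnz_chol, delta_history = delta_history),
            class = "refine_result")
}

#' @export
print.refine_result <- function(x, ...) {
  cat(sprintf("refine_result [%s]: n = %d, steps = %d, L = %.6g, r.m.s.d. = %.3f um%s\n",
              x$engine, x$n, x$steps, x$L, x$rmsd_um,
              if (x$converged) "" else " (step cap reached)"))
  invisible(x)
}

levmar_impl <- function(system, sparse, max_steps = 100, lambda0 = 1e-3,
                        ltol = 1e-6, gtol = 1e-10, record_deltas = FALSE,
                        max_retries = 30L) {
  sw <- system$sw
  theta <- numeric(system$n)
  r <- system$residuals(theta)
  L <- sum((sw * r)^2)
  L_traj <- L
  lambda <- lambda0
  n_small <- 0L
  steps <- 0L
  converged <- FALSE
  nnz_A <- nnz_chol <- NA_real_
  deltas <- if (record_deltas) list() else NULL
  for (it in seq_len(max_steps)) {
    J <- system$jacobian(theta)
    Jw <- Matrix::Diagonal(x = sw) %*% J
    rw <- sw * r
    b <- -as.numeric(Matrix::crossprod(Jw, rw))
    if (max(abs(b)) * 2 < gtol) { converged <- TRUE; break }
    A <- Matrix::forceSymmetric(Matrix::crossprod(Jw))
    dA <- pmax(Matrix::diag(A), 1e-12)
    # Jacobi column scaling: solve in units where diag(A) = 1, which keeps
    # the mm/radian parameter mix well conditioned; Marquardt damping
    # lambda * diag(A) becomes lambda * I in the scaled space
    cs <- sqrt(dA)
    Dinv <- Matrix::Diagonal(x = 1 / cs)
    Ah <- Matrix::forceSymmetric(Dinv %*% A %*% Dinv)
    bh <- b / cs
    accepted <- FALSE
    for (tr in seq_len(max_retries)) {
      Ad <- Ah + lambda * Matrix::Diagonal(n = length(bh))
      delta_alt <- NULL
      delta <- tryCatch({
        if (sparse) {
          ch <- Matrix::Cholesky(Ad, LDL = FALSE, perm = TRUE)
          if (is.na(nnz_chol)) {
            nnz_A <- Matrix::nnzero(A)
            nnz_chol <- Matrix::nnzero(as(ch, "sparseMatrix"))
          }
          as.numeric(Matrix::solve(ch, bh)) / cs
        } else {
          R <- chol(as.matrix(Ad))
          backsolve(R, backsolve(R, bh, transpose = TRUE)) / cs
        }
      }, error = function(e) NULL)
      if (!is.null(delta) && record_deltas) {
        # companion solve of the same damped system with the other
        # factorization, for the per-iteration sparse/dense cross-check
        delta_alt <- tryCatch({
          if (sparse) {
            R <- chol(as.matrix(Ad))
            backsolve(R, backsolve(R, bh, transpose = TRUE)) / cs
          } else {
            ch <- Matrix::Cholesky(Ad, LDL = FALSE, perm = TRUE)
            as.numeric(Matrix::solve(ch, bh)) / cs
          }
        }, error = function(e) NULL)
      }
      if (is.null(delta)) { lambda <- lambda * 10; next }   # indefinite
      theta_try <- theta + delta
      r_try <- system$residuals(theta_try)
      L_try <- sum((sw * r_try)^2)
      if (is.finite(L_try) && L_try < L) {
        rel <- (L - L_try) / max(L, .Machine$double.eps)
        theta <- theta_try; r <- r_try; L <- L_try
        lambda <- lambda / 3
        steps <- steps + 1L
        L_traj <- c(L_traj, L)
        if (record_deltas)
          deltas[[length(deltas) + 1L]] <- list(delta = delta, alt = delta_alt)
        n_small <- if (rel < ltol) n_small + 1L else 0L
        accepted <- TRUE
        break
      }
      lambda <- lambda * 2
    }
    if (!accepted) { converged <- TRUE; break }   # no downhill step exists
    if (n_small >= 2L) { converged <- TRUE; break }
  }
  m <- system$m
  rmsd <- 1000 * sqrt(mean(r[1:m]^2 + r[(m + 1):(2 * m)]^2))
  new_refine_result(if (sparse) "sparse_levmar" else "levmar", theta, L_traj,
                    steps, rmsd, converged, system$n, nnz_A, nnz_chol, deltas)
}

#' Levenberg-Marquardt engines
#'
#' `engine_levmar_dense()` solves the damped normal equations by dense
#' Cholesky decomposition; `engine_levmar_sparse()` uses a sparse Cholesky
#' factorization with a fill-reducing ordering and records the nonzero
#' counts of the normal matrix and of its Cholesky factor.  Both produce
#' identical step vectors (to solver round-off) under the same damping
#' schedule.
#'
#' @param system a [make_refine_system()] result.
#' @param max_steps accepted-step cap.
#' @param lambda0 initial Marquardt damping.
#' @param ltol relative-decrease convergence tolerance (two consecutive
#'   accepted steps).
#' @param gtol gradient infinity-norm tolerance.
#' @param record_deltas keep the per-iteration step vectors; each history
#'   entry also carries `alt`, the same damped system solved with the other
#'   (dense vs sparse) factorization, for the per-iteration equivalence
#'   check.
#' @return a `"refine_result"`.
#' @export
engine_levmar_dense <- function(system, max_steps = 100, lambda0 = 1e-3,
                                ltol = 1e-6, gtol = 1e-10,
                                record_deltas = FALSE) {
  levmar_impl(system, sparse = FALSE, max_steps = max_steps,
              lambda0 = lambda0, ltol = ltol, gtol = gtol,
              record_deltas = record_deltas)
}

#' @rdname engine_levmar_dense
#' @export
engine_levmar_sparse <- function(system, max_steps = 100, lambda0 = 1e-3,
                                 ltol = 1e-6, gtol = 1e-10,
                                 record_deltas = FALSE) {
  levmar_impl(system, sparse = TRUE, max_steps = max_steps,
              lambda0 = lambda0, ltol = ltol, gtol = gtol,
              record_deltas = record_deltas)
}

lbfgs_impl <- function(system, curvatures, max_steps = 10000, history = 10L,
                       ltol = 1e-10, gtol = 1e-8, c1 = 1e-4, c2 = 0.9) {
  sw <- system$sw
  # unit scaling: engines work in variables where rotations are expressed
  # in milliradians, so all parameter classes have comparable magnitudes
  ps <- par_unit_scale(system$pset)
  resid_z <- function(z) system$residuals(z * ps)
  n <- system$n
  z <- numeric(n)
  r <- resid_z(z)
  L <- sum((sw * r)^2)
  L_traj <- L
  Svec <- list(); Yvec <- list(); rho <- numeric(0)
  gamma <- 1
  steps <- 0L
  converged <- FALSE
  g_old <- NULL
  for (it in seq_len(max_steps)) {
    J <- system$jacobian(z * ps)
    Jw <- Matrix::Diagonal(x = sw) %*% J
    g <- 2 * as.numeric(Matrix::crossprod(Jw, sw * r)) * ps
    if (max(abs(g)) < gtol) { converged <- TRUE; break }
    if (!is.null(g_old) && !is.null(attr(g_old, "step"))) {
      y <- g - g_old
      s_ <- attr(g_old, "step")
      sy <- sum(s_ * y)
      if (sy > 1e-12) {
        Svec[[length(Svec) + 1L]] <- s_
        Yvec[[length(Yvec) + 1L]] <- y
        rho <- c(rho, 1 / sy)
        gamma <- sy / sum(y * y)
        if (length(Svec) > history) {
          Svec <- Svec[-1]; Yvec <- Yvec[-1]; rho <- rho[-1]
        }
      }
    }
    # two-loop recursion; H0 is the scalar gamma (plain) or the inverse
    # Gauss-Newton curvature diagonal (curvature seeding)
    q <- g
    k <- length(Svec)
    al <- numeric(k)
    if (k > 0) for (j in k:1) {
      al[j] <- rho[j] * sum(Svec[[j]] * q)
      q <- q - al[j] * Yvec[[j]]
    }
    if (curvatures) {
      cv <- pmax(curvature_diag(J, sw^2) * ps^2, 1e-10)
      q <- q / cv
    } else if (k == 0) {
      q <- q / max(abs(g))        # first step: conservative scale
    } else {
      q <- gamma * q
    }
    if (k > 0) for (j in 1:k) {
      beta <- rho[j] * sum(Yvec[[j]] * q)
      q <- q + (al[j] - beta) * Svec[[j]]
    }
    dirn <- -q
    gd <- sum(g * dirn)
    if (gd >= 0) {                 # restart from steepest descent
      Svec <- list(); Yvec <- list(); rho <- numeric(0)
      dirn <- -g / max(abs(g))
      gd <- sum(g * dirn)
    }
    ls <- wolfe_search(function(tt) {
      r_t <- resid_z(z + tt * dirn)
      list(L = sum((sw * r_t)^2), r = r_t)
    }, L, gd, c1 = c1, c2 = c2)
    if (is.null(ls)) {
      # terminal fallback: plain backtracking along steepest descent; stop
      # only when that cannot decrease L either
      Svec <- list(); Yvec <- list(); rho <- numeric(0)
      dirn <- -g / max(abs(g))
      gd <- sum(g * dirn)
      tt <- 1
      for (bb in 1:50) {
        r_t <- resid_z(z + tt * dirn)
        L_t <- sum((sw * r_t)^2)
        if (is.finite(L_t) && L_t < L + c1 * tt * gd) {
          ls <- list(t = tt, L = L_t, r = r_t)
          break
        }
        tt <- tt / 2
      }
      if (is.null(ls)) { converged <- TRUE; break }
    }
    s_ <- ls$t * dirn
    g_old <- g; attr(g_old, "step") <- s_
    rel <- (L - ls$L) / max(L, .Machine$double.eps)
    z <- z + s_
    r <- ls$r
    L <- ls$L
    steps <- steps + 1L
    L_traj <- c(L_traj, L)
    if (rel < ltol && it > 2) { converged <- TRUE; break }
  }
  m <- system$m
  rmsd <- 1000 * sqrt(mean(r[1:m]^2 + r[(m + 1):(2 * m)]^2))
  new_refine_result(if (curvatures) "lbfgs_curv" else "lbfgs", z * ps, L_traj,
                    steps, rmsd, converged, system$n)
}

# milliradian unit scale per parameter column
par_unit_scale <- function(pset) {
  rotdofs <- c("tau1", "tau2", "tau3", "rot1", "rot2", "rot3")
  ifelse(pset$par$dof %in% rotdofs, 1e-3, 1)
}

# Strong-Wolfe line search on phi(t) = L(theta + t * dirn).
# `fn(t)` returns list(L, r); L0 and gd0 are phi(0) and phi'(0) < 0.
# Returns list(t, L, r) or NULL on failure.
wolfe_search <- function(fn, L0, gd0, c1 = 1e-4, c2 = 0.9,
                         t0 = 1, max_bracket = 12L, max_zoom = 25L) {
  eps_t <- 1e-7
  dphi <- function(tt) (fn(tt + eps_t * tt)$L - fn(tt - eps_t * tt)$L) /
    (2 * eps_t * tt)
  t_prev <- 0; L_prev <- L0
  tt <- t0
  lo <- hi <- NA; L_lo <- NA
  for (i in seq_len(max_bracket)) {
    ev <- fn(tt)
    if (!is.finite(ev$L)) { tt <- tt / 4; next }
    if (ev$L > L0 + c1 * tt * gd0 || (i > 1L && ev$L >= L_prev)) {
      lo <- t_prev; hi <- tt; L_lo <- L_prev; break
    }
    gt <- dphi(tt)
    if (abs(gt) <= -c2 * gd0) return(list(t = tt, L = ev$L, r = ev$r))
    if (gt >= 0) { lo <- tt; hi <- t_prev; L_lo <- ev$L; break }
    t_prev <- tt; L_prev <- ev$L
    tt <- tt * 2
  }
  if (is.na(lo)) return(NULL)
  best <- NULL
  for (i in seq_len(max_zoom)) {
    tt <- (lo + hi) / 2
    ev <- fn(tt)
    if (!is.finite(ev$L) || ev$L > L0 + c1 * tt * gd0 || ev$L >= L_lo) {
      hi <- tt
    } else {
      best <- list(t = tt, L = ev$L, r = ev$r)
      gt <- dphi(tt)
      if (abs(gt) <= -c2 * gd0) return(best)
      if (gt * (hi - lo) >= 0) hi <- lo
      lo <- tt; L_lo <- ev$L
    }
  }
  if (!is.null(best) && best$L < L0) return(best)
  NULL
}

#' LBFGS engines
#'
#' Limited-memory BFGS on the same pre-whitened target, with Armijo
#' backtracking.  `engine_lbfgs_curv()` seeds the inverse-Hessian
#' approximation with the Gauss-Newton curvature diagonal
#' ([curvature_diag()]), which typically reduces the number of steps to
#' convergence by an order of magnitude.
#'
#' @param system a [make_refine_system()] result.
#' @param max_steps step cap (exhaustion is reported via `converged =
#'   FALSE`, not raised).
#' @param history number of correction pairs retained.
#' @param ltol relative-decrease stopping tolerance.
#' @param gtol gradient infinity-norm tolerance.
#' @return a `"refine_result"`.
#' @export
engine_lbfgs <- function(system, max_steps = 10000, history = 10L,
                         ltol = 1e-10, gtol = 1e-8) {
  lbfgs_impl(system, curvatures = FALSE, max_steps = max_steps,
             history = history, ltol = ltol, gtol = gtol)
}

#' @rdname engine_lbfgs
#' @export
engine_lbfgs_curv <- function(system, max_steps = 10000, history = 10L,
                              ltol = 1e-10, gtol = 1e-8) {
  lbfgs_impl(system, curvatures = TRUE, max_steps = max_steps,
             history = history, ltol = ltol, gtol = gtol)
}

#' Run a named engine
#'
#' @param system a [make_refine_system()] result.
#' @param engine one of `"lbfgs"`, `"lbfgs_curv"`, `"levmar"`,
#'   `"sparse_levmar"`.
#' @param ... passed to the engine.
#' @return a `"refine_result"`.
#' @export
run_engine <- function(system, engine = c("sparse_levmar", "levmar",
                                          "lbfgs", "lbfgs_curv"), ...) {
  engine <- match.arg(engine)
  switch(engine,
         sparse_levmar = engine_levmar_sparse(system, ...),
         levmar = engine_levmar_dense(system, ...),
         lbfgs = engine_lbfgs(system, ...),
         lbfgs_curv = engine_lbfgs_curv(system, ...))
}
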