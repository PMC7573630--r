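# Backward-Euler direct collocation: the optimal control problem becomes a
# sparse NLP in z = (x_0..x_{N-1}, u_0..u_{N-1}, T_sim). Dynamics enter as
# N defect blocks f(x_k, (x_k - x_{k-1})/h, u_k) = 0, the last of which
# wraps through the periodicity image of the first node, so the cycle is
# closed without duplicating variables. The solver is an augmented
# Lagrangian with projected limited-memory quasi-Newton inner iterations
# and a Gauss-Newton feasibility polish on the defect system.

#' Central angle of one gait cycle on a circle
#'
#' `theta = 2 asin(v T / (2 r))`: the angle subtended at the circle centre
#' by the chord a cycle of curved running covers at norm horizontal speed
#' `v` in duration `T`.
#'
#' @param v_norm norm horizontal speed (m/s)
#' @param T_sim cycle duration (s)
#' @param r circle radius (m)
#' @return list with `theta` (rad) and `dtheta_dT` (rad/s)
#' @export
central_angle <- function(v_norm, T_sim, r) {
  ratio <- v_norm * T_sim / (2 * r)
  if (ratio > 1)
    stop("infeasible: chord v*T = ", v_norm * T_sim,
         " exceeds the circle diameter ", 2 * r)
  list(theta = 2 * asin(ratio),
       dtheta_dT = if (ratio < 1) v_norm / (r * sqrt(1 - ratio^2)) else Inf)
}

#' Periodicity residual
#'
#' `x_end - (R_per x_0 + t_per)` stacked with `u_end - u_0`. For straight
#' running the map is a pure horizontal translation by `(v_x T, 0, v_z T)`;
#' for curved running it rotates the pelvis horizontal position and global
#' velocity about the vertical axis by the central angle and adds the angle
#' to the heading coordinate.
#'
#' @param model a `runopt_model`
#' @param task a `runopt_task`
#' @param x0,x_end states at the cycle start and end
#' @param u0,u_end controls at the cycle start and end
#' @param T_sim cycle duration (s)
#' @return residual vector of length `n_x + n_u`
#' @export
periodicity_residual <- function(model, task, x0, x_end, u0, u_end, T_sim) {
  c(x_end - periodic_image_r(model, task, x0, T_sim), u_end - u0)
}

task_vec <- function(task) {
  kind <- match(task$kind, c("standing", "straight", "curved")) - 1
  c(kind, task$v_x %||% 0, task$v_z %||% 0, task$v_norm %||% 0,
    task$radius %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast triplet -> column-compressed sparse matrix (duplicates sum)
sparse_from_triplets <- function(i0, j0, x, dims) {
  methods::as(methods::new(methods::getClassDef("dgTMatrix",
                                                package = "Matrix"),
                           i = as.integer(i0), j = as.integer(j0),
                           x = as.numeric(x), Dim = as.integer(dims)),
              "CsparseMatrix")
}

#' Assemble the collocation NLP
#'
#' Builds the sparse nonlinear program for a task: decision variables
#' `(x_0..x_{N-1}, u_0..u_{N-1}, T_sim)`, dynamics defects at every node
#' (with the wrap defect through the periodicity image), variable bounds
#' from the model file, and first-node pelvis anchors fixed via equal
#' bounds. The standing problem is the single-node special case with
#' `xdot = 0` and no periodicity.
#'
#' @param model a validated `runopt_model`
#' @param task a `runopt_task`, see [task_spec()]
#' @param ref a `runopt_reference` (required when the task tracks signals)
#' @return an `runopt_nlp` list with `n_var`, `lb`, `ub`, `n_con`,
#'   objective/constraint callbacks, and index helpers
#' @export
assemble_nlp <- function(model, task, ref = NULL) {
  bad <- validate_model(model)
  if (length(bad)) stop("invalid model: ", paste(bad, collapse = "; "))
  lay <- state_control_layout(model)
  N <- task$N
  standing <- task$kind == "standing"
  if (!standing && is.null(ref))
    stop("a tracking reference is required for running tasks")
  track <- if (!is.null(ref) && task$weights$W_track > 0)
    prepare_tracking(model, task, ref)
  cd <- .cdata(model)
  tvec <- task_vec(task)
  nx <- lay$n_x; nu <- lay$n_u
  n_var <- N * (nx + nu) + 1
  ix <- function(k) (k - 1) * nx + seq_len(nx)          # state node k (1-based)
  iu <- function(k) N * nx + (k - 1) * nu + seq_len(nu)
  iT <- n_var
  b <- model$bounds
  lb <- c(rep(b$x_lb, N), rep(b$u_lb, N),
          if (standing) 1 else task$T_bounds[1])
  ub <- c(rep(b$x_ub, N), rep(b$u_ub, N),
          if (standing) 1 else task$T_bounds[2])
  for (a in task$anchors) {
    j <- ix(1)[match(a$dof, model$dof_index)]
    lb[j] <- ub[j] <- a$value
  }
  split_z <- function(z) {
    list(X = matrix(z[seq_len(N * nx)], nx, N),
         U = matrix(z[N * nx + seq_len(N * nu)], nu, N),
         T_sim = z[iT])
  }
  # simulated-GRF evaluations (values + node Jacobians) are shared between
  # the objective gradient and its Gauss-Newton Hessian at the same point
  grf_memo <- new.env(parent = emptyenv())
  grf_fn <- function(X, want_jac) {
    if (!is.null(grf_memo$X) && identical(grf_memo$X, X) &&
        (!want_jac || !is.null(grf_memo$val$jac)))
      return(grf_memo$val)
    val <- cpp_traj_grf(cd, X, want_jac)
    if (want_jac) {
      grf_memo$X <- X
      grf_memo$val <- val
    }
    val
  }
  obj <- function(z, want_grad = TRUE) {
    s <- split_z(z)
    o <- traj_objective(model, task, track, s$X, s$U, s$T_sim, want_grad,
                        grf_fn = grf_fn)
    if (want_grad)
      o$grad <- c(as.numeric(o$gX), as.numeric(o$gU), o$gT)
    o
  }
  con <- function(z) {
    s <- split_z(z)
    as.numeric(cpp_traj_constraints(cd, s$X, s$U, s$T_sim, tvec))
  }
  con_gradmul <- function(z, w) {
    s <- split_z(z)
    as.numeric(cpp_traj_gradmul(cd, s$X, s$U, s$T_sim, tvec, w))
  }
  con_jac <- function(z) {
    s <- split_z(z)
    tr <- cpp_traj_jacobian(cd, s$X, s$U, s$T_sim, tvec)
    sparse_from_triplets(tr$i, tr$j, tr$v, c(tr$nrow, tr$ncol))
  }
  # Gauss-Newton curvature of the objective (sparse triplets): diagonal
  # tracking/effort/torque blocks, dense per-node GRF-tracking blocks, and
  # the periodic second-difference operator of the regularization term
  obj_hess <- function(z) {
    s <- split_z(z)
    W <- task$weights
    acc_i <- list(); acc_j <- list(); acc_v <- list()
    n_acc <- 0
    add <- function(i, j, v) {
      keep <- v != 0
      n_acc <<- n_acc + 1
      acc_i[[n_acc]] <<- i[keep]
      acc_j[[n_acc]] <<- j[keep]
      acc_v[[n_acc]] <<- v[keep]
    }
    if (!is.null(track)) {
      na <- length(track$ang_rows)
      dcoef <- 2 * W$W_track / N
      for (i in seq_len(na)) {
        idx <- (seq_len(N) - 1) * nx + track$ang_rows[i]
        add(idx, idx, dcoef * track$w[i] / track$var[, i])
      }
      if (length(track$grf_idx) > 0) {
        grf <- grf_fn(s$X, TRUE)
        nqd <- 2 * lay$n_dof
        for (k in seq_len(N)) {
          Jg <- matrix(grf$jac[track$grf_idx, , k], ncol = nqd)
          D <- dcoef * track$w[na + seq_along(track$grf_idx)] /
            track$var[k, na + seq_along(track$grf_idx)]
          Hk <- crossprod(Jg * sqrt(D))
          rows <- rep((k - 1) * nx + seq_len(nqd), times = nqd)
          cols <- rep((k - 1) * nx + seq_len(nqd), each = nqd)
          add(rows, cols, as.numeric(Hk))
        }
      }
    }
    ne_idx <- N * nx + as.numeric(outer(lay$ine, (seq_len(N) - 1) * nu, `+`))
    ne_val <- pmax(as.numeric(s$U[lay$ine, , drop = FALSE]), 0)
    add(ne_idx, ne_idx,
        W$W_mus * 6 * rep(task$vol_frac, N) * ne_val /
          (lay$n_mus * task$effort_div * N))
    if (lay$n_tor > 0) {
      mi <- N * nx + as.numeric(outer(lay$im, (seq_len(N) - 1) * nu, `+`))
      add(mi, mi, rep(W$W_tor * 2 / (lay$n_tor * N), length(mi)))
    }
    if (task$kind != "standing" && W$W_reg > 0) {
      c2 <- 2 * N * W$W_reg / (s$T_sim^2 * (nx + nu))
      for (blk in list(list(n = nx, off = 0, per = nx),
                       list(n = nu, off = N * nx, per = nu))) {
        for (k in seq_len(N)) {
          idx <- blk$off + (k - 1) * blk$per + seq_len(blk$n)
          nxt <- blk$off + (k %% N) * blk$per + seq_len(blk$n)
          add(idx, idx, rep(2 * c2, blk$n))
          add(idx, nxt, rep(-c2, blk$n))
          add(nxt, idx, rep(-c2, blk$n))
        }
      }
    }
    # duplicate (i, j) triplets sum on conversion to column storage
    sparse_from_triplets(unlist(acc_i) - 1L, unlist(acc_j) - 1L,
                         unlist(acc_v), c(n_var, n_var))
  }
  structure(list(model = model, task = task, track = track,
                 n_var = n_var, lb = lb, ub = ub,
                 n_con = if (standing) nx else N * nx,
                 N = N, nx = nx, nu = nu, ix = ix, iu = iu, iT = iT,
                 split_z = split_z, obj = obj, con = con,
                 con_gradmul = con_gradmul, con_jac = con_jac,
                 obj_hess = obj_hess),
            class = "runopt_nlp")
}

#' Default solver settings
#'
#' @param tol optimality tolerance on the augmented-Lagrangian inner solve
#' @param con_tol feasibility tolerance on the max constraint violation
#' @param max_outer maximum augmented-Lagrangian (multiplier) updates
#' @param max_inner maximum inner projected-Newton iterations per outer
#'   iteration
#' @param rho0 initial penalty parameter
#' @param rho_mult penalty growth factor when feasibility stalls
#' @param polish_iter maximum Gauss-Newton feasibility polish steps
#' @return settings list
#' @export
solver_settings <- function(tol = 1e-5, con_tol = 1e-3, max_outer = 12,
                            max_inner = 50, rho0 = 1e4, rho_mult = 10,
                            polish_iter = 20) {
  list(tol = tol, con_tol = con_tol, max_outer = max_outer,
       max_inner = max_inner, rho0 = rho0, rho_mult = rho_mult,
       polish_iter = polish_iter)
}

#' Solve a collocation NLP
#'
#' Augmented-Lagrangian method: bound constraints are handled by the
#' projected quasi-Newton inner solver (L-BFGS-B), equality constraints
#' (dynamics defects) by multiplier and penalty updates, followed by a
#' Gauss-Newton feasibility polish that solves the defect normal equations
#' with a sparse Cholesky factorization. A failed solve is returned flagged
#' as unconverged, never silently accepted.
#'
#' @param nlp an `runopt_nlp` from [assemble_nlp()]
#' @param z0 initial guess (clipped to bounds if outside, with a log note)
#' @param settings see [solver_settings()]
#' @param quiet suppress per-iteration output
#' @return a `runopt_solution` list: trajectories `X`, `U`, `T_sim`,
#'   objective value and term breakdown, `max_violation`, `converged`,
#'   iteration log
#' @export
solve_nlp <- function(nlp, z0, settings = solver_settings(), quiet = TRUE) {
  stopifnot(length(z0) == nlp$n_var)
  if (any(nlp$lb > nlp$ub)) stop("infeasible bounds: lower > upper")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  if (any(z0 < nlp$lb - 1e-12) || any(z0 > nlp$ub + 1e-12))
    note("initial guess clipped to bounds (%d entries)",
         sum(z0 < nlp$lb | z0 > nlp$ub))
  z <- pmin(pmax(z0, nlp$lb), nlp$ub)
  lambda <- rep(0, nlp$n_con)
  rho <- settings$rho0
  cache <- new.env(parent = emptyenv())
  al_value <- function(z) {
    cv <- nlp$con(z)
    nlp$obj(z, want_grad = FALSE)$value + sum(lambda * cv) +
      0.5 * rho * sum(cv^2)
  }
  # inner solver: projected Newton on the augmented Lagrangian with a
  # Gauss-Newton Hessian (objective curvature + rho J'J), sparse Cholesky,
  # Levenberg-Marquardt damping and an active set at the bounds
  inner_newton <- function(z, max_it) {
    sigma <- 1e-2
    n_fact <- 0
    last_alpha <- NA
    stall <- 0
    phi_prev <- Inf
    it <- 0
    for (it in seq_len(max_it)) {
      cv <- nlp$con(z)
      J <- nlp$con_jac(z)
      o <- nlp$obj(z, want_grad = TRUE)
      g <- o$grad + as.numeric(Matrix::crossprod(J, lambda + rho * cv))
      phi <- o$value + sum(lambda * cv) + 0.5 * rho * sum(cv^2)
      at_lb <- z <= nlp$lb + 1e-12 & g > 0
      at_ub <- z >= nlp$ub - 1e-12 & g < 0
      fixed <- (nlp$ub - nlp$lb < 1e-14) | at_lb | at_ub
      gp <- g
      gp[fixed] <- 0
      if (max(abs(gp)) < settings$tol * max(1, abs(phi))) break
      # stop early once the subproblem stagnates; the outer loop's
      # multiplier update is then more productive than further iterations
      stall <- if (phi_prev - phi < 1e-5 * max(1, abs(phi))) stall + 1 else 0
      phi_prev <- phi
      if (stall >= 4) break
      Hobj <- if (is.null(nlp$obj_hess)) {
        Matrix::Diagonal(nlp$n_var, 0)
      } else {
        nlp$obj_hess(z)
      }
      H <- Hobj + rho * Matrix::crossprod(J)
      free <- which(!fixed)
      Hf <- H[free, free, drop = FALSE]
      gf <- g[free]
      success <- FALSE
      for (try in 1:8) {
        step_f <- tryCatch({
          F <- Matrix::Cholesky(Matrix::forceSymmetric(Hf) +
                                  Matrix::Diagonal(length(free), sigma),
                                LDL = FALSE, perm = TRUE)
          n_fact <- n_fact + 1
          -as.numeric(Matrix::solve(F, gf, system = "A"))
        }, error = function(e) NULL)
        if (is.null(step_f)) {
          sigma <- sigma * 10
          next
        }
        step <- numeric(nlp$n_var)
        step[free] <- step_f
        alpha <- min(1, 4 / max(1e-12, max(abs(step))))
        for (ls in 1:8) {
          z_new <- pmin(pmax(z + alpha * step, nlp$lb), nlp$ub)
          if (al_value(z_new) < phi - 1e-12 * abs(phi)) {
            success <- TRUE
            break
          }
          alpha <- alpha / 3
        }
        if (success) {
          z <- z_new
          last_alpha <- alpha
          # Levenberg-Marquardt damping tracks the useful step length: a
          # nearly full step relaxes the damping, a heavily backtracked
          # one tightens it so the next model stays in its trust region
          sigma <- if (alpha >= 0.5) {
            max(sigma / 3, 1e-8)
          } else if (alpha >= 0.05) {
            sigma
          } else {
            sigma * 5
          }
          break
        }
        sigma <- sigma * 10
      }
      if (it %% 10 == 0 && !quiet)
        note("    inner %3d: phi = %.6g, max|c| = %.3g, sigma = %.2g, %s",
             it, phi, max(abs(cv)), sigma,
             paste0("alpha = ", signif(last_alpha, 2)))
      if (!success) break
    }
    list(z = z, iters = it, nfact = n_fact)
  }
  # damped Gauss-Newton restoration on the defect system: minimum-norm
  # steps from the normal equations, accepted only when the violation
  # drops (Levenberg-Marquardt damping otherwise). The T_sim column
  # couples every defect block, so it is split off and handled by a
  # Sherman-Morrison update to keep the normal matrix banded.
  restore <- function(z, target, max_it) {
    nu <- 1e-6
    for (it in seq_len(max_it)) {
      cv <- nlp$con(z)
      viol <- max(abs(cv))
      if (viol <= target) break
      J <- nlp$con_jac(z)
      # freeze fixed variables and anything sitting on a bound: restoration
      # works in the interior so the Gauss-Newton subspace stays stable
      fixed <- which(nlp$ub - nlp$lb < 1e-14 | z <= nlp$lb + 1e-10 |
                       z >= nlp$ub - 1e-10)
      if (length(fixed)) J[, fixed] <- 0
      tcol <- as.numeric(J[, nlp$iT])
      B <- J
      B[, nlp$iT] <- 0
      BBt <- Matrix::forceSymmetric(Matrix::tcrossprod(B))
      improved <- FALSE
      for (try in 1:6) {
        y <- tryCatch({
          S <- BBt + Matrix::Diagonal(nrow(J), nu * max(1, viol))
          F <- Matrix::Cholesky(S, LDL = FALSE, perm = TRUE)
          y0 <- as.numeric(Matrix::solve(F, cv, system = "A"))
          if (any(tcol != 0)) {
            u <- as.numeric(Matrix::solve(F, tcol, system = "A"))
            y0 - u * sum(tcol * y0) / (1 + sum(tcol * u))
          } else y0
        }, error = function(e) NULL)
        if (is.null(y)) {
          nu <- nu * 100
          next
        }
        step <- -as.numeric(Matrix::crossprod(J, y))
        # Gauss-Newton's natural merit is the 2-norm of the defects; the
        # max-norm may rise transiently on an accepted step. A trust
        # radius caps near-singular steps.
        nrm2 <- sum(cv^2)
        alpha <- min(1, 1 / max(1e-12, max(abs(step))))
        for (ls in 1:6) {
          z_new <- pmin(pmax(z + alpha * step, nlp$lb), nlp$ub)
          if (sum(nlp$con(z_new)^2) < nrm2 * (1 - 1e-4 * alpha)) {
            improved <- TRUE
            break
          }
          alpha <- alpha / 4
        }
        if (improved) {
          z <- z_new
          nu <- max(nu / 10, 1e-8)
          break
        }
        nu <- nu * 100
      }
      if (!improved) break
    }
    z
  }
  converged <- FALSE
  prev_viol <- Inf
  for (outer in seq_len(settings$max_outer)) {
    res <- inner_newton(z, settings$max_inner)
    z <- res$z
    cv <- nlp$con(z)
    viol <- max(abs(cv))
    if (viol > settings$con_tol) {
      # feasibility restoration between multiplier updates
      z <- restore(z, settings$con_tol / 2, 5)
      cv <- nlp$con(z)
      viol <- max(abs(cv))
    }
    o <- nlp$obj(z, want_grad = FALSE)
    note("outer %2d: J = %.6g, max|c| = %.3g, rho = %.1g, newton = %d",
         outer, o$value, viol, rho, res$iters)
    # update the multipliers while feasibility makes any progress; raise
    # the penalty (moderately capped -- very large rho only degrades the
    # conditioning) when it genuinely stalls
    if (viol <= settings$con_tol || viol < 0.97 * prev_viol) {
      lambda <- lambda + rho * cv
    } else if (rho < 1e6) {
      rho <- rho * settings$rho_mult
      lambda <- lambda + rho * cv
    }
    if (viol <= settings$con_tol &&
        abs(o$value - (cache$last_obj %||% Inf)) <
          settings$tol * max(1, abs(o$value))) {
      converged <- TRUE
      break
    }
    cache$last_obj <- o$value
    prev_viol <- min(prev_viol, viol)
  }
  # final feasibility polish
  z <- restore(z, settings$con_tol / 10, settings$polish_iter)
  cv <- nlp$con(z)
  viol <- max(abs(cv))
  o <- nlp$obj(z, want_grad = FALSE)
  converged <- viol <= settings$con_tol
  if (!converged)
    note("NOT converged: max|c| = %.3g > %.3g", viol, settings$con_tol)
  s <- nlp$split_z(z)
  structure(list(X = s$X, U = s$U, T_sim = s$T_sim, z = z,
                 objective = o$value, terms = o$terms,
                 max_violation = viol, converged = converged,
                 task = nlp$task, log = log_lines),
            class = "runopt_solution")
}

#' @export
print.runopt_solution <- function(x, ...) {
  cat(sprintf("<runopt_solution> task '%s': J = %.5g, T_sim = %.3f s\n",
              x$task$kind, x$objective, x$T_sim))
  cat(sprintf("  max constraint violation %.3g (%s)\n", x$max_violation,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Derivative check for an assembled NLP
#'
#' Compares the objective gradient and the constraint Jacobian against
#' central finite differences on a random subset of directions and reports
#' the worst relative error and its location.
#'
#' @param nlp an `runopt_nlp`
#' @param z evaluation point (within bounds)
#' @param n_dirs number of coordinate directions to probe
#' @param seed RNG seed for the direction sample
#' @param h finite-difference step
#' @return list with `max_rel_error_grad`, `max_rel_error_jac` and the
#'   offending indices
#' @export
check_derivatives <- function(nlp, z, n_dirs = 30, seed = 1, h = 1e-6) {
  set.seed(seed)
  dirs <- sample.int(nlp$n_var, min(n_dirs, nlp$n_var))
  g <- nlp$obj(z, want_grad = TRUE)$grad
  J <- nlp$con_jac(z)
  worst_g <- c(err = 0, idx = NA)
  worst_j <- c(err = 0, col = NA, row = NA)
  scale_g <- max(1, max(abs(g)))
  for (j in dirs) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
    fd_g <- (nlp$obj(zp, FALSE)$value - nlp$obj(zm, FALSE)$value) / (2 * h)
    eg <- abs(fd_g - g[j]) / scale_g
    if (eg > worst_g["err"]) worst_g <- c(err = eg, idx = j)
    fd_c <- (nlp$con(zp) - nlp$con(zm)) / (2 * h)
    jc <- as.numeric(J[, j])
    ej <- max(abs(fd_c - jc)) / max(1, max(abs(jc)))
    if (ej > worst_j["err"])
      worst_j <- c(err = ej, col = j, row = which.max(abs(fd_c - jc)))
  }
  list(max_rel_error_grad = unname(worst_g["err"]),
       grad_index = unname(worst_g["idx"]),
       max_rel_error_jac = unname(worst_j["err"]),
       jac_col = unname(worst_j["col"]), jac_row = unname(worst_j["row"]))
}
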