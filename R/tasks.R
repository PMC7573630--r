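# The three simulations: standing prediction (single node, multistart),
# straight-running tracking, and curved-running prediction, chained by warm
# starts (standing -> straight -> curved).

#' Construct a task specification
#'
#' Fills in the task-kind defaults: objective weights, tracked-signal
#' selector, first-node anchors, node count and effort-speed normalization.
#' Standing uses a single collocation node, `W_mus = W_tor = 1`, no
#' tracking and no periodicity. Straight running tracks all joint angles,
#' the pelvis global orientation and all GRF components with `W_Track = 1`,
#' `W_mus = 1e3`, `W_tor = 1`, and anchors the first-node pelvis at the
#' origin. Curved running tracks joint angles and vertical GRFs only,
#' raises `W_mus` and `W_tor` tenfold, and anchors the first node at
#' `(-r, 0)` so the model runs counterclockwise (left leg inside) around
#' the vertical axis through the origin.
#'
#' @param model a `runopt_model`
#' @param kind one of "standing", "straight", "curved"
#' @param v_x,v_z straight-running speeds (m/s)
#' @param v_norm,radius curved-running norm speed (m/s) and radius (m)
#' @param N number of collocation nodes
#' @param weights optional list overriding any of `W_track`, `W_mus`,
#'   `W_tor`, `W_reg`, `W_ang`, `W_grf`
#' @param n_starts,seed multistart count and RNG seed (standing)
#' @return a `runopt_task`
#' @export
task_spec <- function(model, kind = c("standing", "straight", "curved"),
                      v_x = 4.0, v_z = 0.0, v_norm = 2.7, radius = 3.7,
                      N = NULL, weights = list(), n_starts = 50, seed = 1) {
  kind <- match.arg(kind)
  nd <- model$dof_index
  internal_angles <- nd[-(1:6)]
  pelvis_orient <- nd[4:6]
  grf_all <- c("grf_r_x", "grf_r_y", "grf_r_z",
               "grf_l_x", "grf_l_y", "grf_l_z")
  w <- switch(kind,
    standing = list(W_track = 0, W_mus = 1, W_tor = 1, W_reg = 0,
                    W_ang = 1, W_grf = 5),
    straight = list(W_track = 1, W_mus = 1e3, W_tor = 1, W_reg = 1e-3,
                    W_ang = 1, W_grf = 5),
    curved = list(W_track = 1, W_mus = 1e4, W_tor = 10, W_reg = 1e-3,
                  W_ang = 1, W_grf = 5))
  w[names(weights)] <- weights
  tracked <- switch(kind,
    standing = list(angles = character(0), grfs = character(0)),
    straight = list(angles = c(pelvis_orient, internal_angles),
                    grfs = grf_all),
    curved = list(angles = internal_angles,
                  grfs = c("grf_r_y", "grf_l_y")))
  anchors <- switch(kind,
    standing = list(),
    straight = list(list(dof = "pelvis_tx", value = 0),
                    list(dof = "pelvis_tz", value = 0)),
    curved = list(list(dof = "pelvis_tx", value = -radius),
                  list(dof = "pelvis_tz", value = 0)))
  v_eff <- switch(kind, standing = c(0, 0), straight = c(v_x, v_z),
                  curved = c(v_norm, 0))
  vnorm_eff <- sqrt(sum(v_eff^2))
  vol <- vapply(model$muscles, function(m) m$F_ISO * m$l_CE_opt, numeric(1))
  structure(list(kind = kind, v_x = v_x, v_z = v_z, v_norm = v_norm,
                 radius = radius,
                 N = if (is.null(N)) (if (kind == "standing") 1L else 50L)
                     else as.integer(N),
                 weights = setNames(w, c("W_track", "W_mus", "W_tor",
                                         "W_reg", "W_ang", "W_grf")),
                 tracked = tracked, anchors = anchors,
                 var_floor_frac = 0.1,
                 vol_frac = vol / sum(vol),
                 effort_div = if (vnorm_eff > 0) vnorm_eff^3 else 1,
                 T_bounds = c(0.3, 1.5),
                 n_starts = n_starts, seed = seed),
            class = "runopt_task")
}

# Contact-stiffness continuation: running solves start on a softened
# ground (k_n scaled down) and tighten in stages, warm-starting each stage
# from the previous solution. The final stage uses the model's true
# stiffness, so the returned solution satisfies the unmodified dynamics.
scale_contact <- function(model, fac) {
  m2 <- model
  attr(m2, "cdata_env") <- NULL
  m2$contact_par$k_n <- model$contact_par$k_n * fac
  m2
}

# periodic linear resampling of a reference or node trajectory to a new
# grid (used by the coarse-to-fine warm-start cascade)
resample_reference <- function(ref, N) {
  if (nrow(ref$mean) == N) return(ref)
  resamp <- function(M) {
    ph_old <- (seq_len(nrow(M)) - 1) / nrow(M)
    ph_new <- (seq_len(N) - 1) / N
    apply(M, 2, function(y)
      approx(c(ph_old, 1), c(y, y[1]), xout = ph_new)$y)
  }
  ref$mean <- resamp(ref$mean)
  ref$sd <- resamp(ref$sd)
  ref
}

resample_nodes <- function(M, N, wrap = M[, 1]) {
  if (ncol(M) == N) return(M)
  ph_old <- (seq_len(ncol(M)) - 1) / ncol(M)
  ph_new <- (seq_len(N) - 1) / N
  out <- matrix(0, nrow(M), N)
  for (i in seq_len(nrow(M))) {
    out[i, ] <- approx(c(ph_old, 1), c(M[i, ], wrap[i]),
                       xout = ph_new)$y
  }
  out
}

# Warm-start cascade for the running solves: a coarse-grid solve on a
# softened ground finds the basin cheaply; the solution is interpolated to
# the full grid and the ground stiffness tightened in stages. The final
# stage solves the unmodified problem at the task's node count.
solve_running_staged <- function(model, task, ref, z0, settings, quiet,
                                 plan = NULL) {
  lay <- state_control_layout(model)
  N_final <- task$N
  if (is.null(plan)) {
    # per-stage outer-iteration budgets: generous on the cheap coarse
    # grids, bridging on the intermediate stiffness rungs, the full
    # budget on the final unmodified problem
    plan <- list(list(N = 10, fac = 1e-3, outer = 8),
                 list(N = 25, fac = 1e-3, outer = 5),
                 list(N = N_final, fac = 1e-3,
                      outer = max(2, settings$max_outer %/% 2)),
                 list(N = N_final, fac = 1e-1,
                      outer = max(2, settings$max_outer %/% 2)),
                 list(N = N_final, fac = 1, outer = settings$max_outer))
  }
  nx <- lay$n_x; nu <- lay$n_u
  N0 <- (length(z0) - 1) / (nx + nu)
  X <- matrix(z0[seq_len(nx * N0)], nx, N0)
  U <- matrix(z0[nx * N0 + seq_len(nu * N0)], nu, N0)
  T_sim <- z0[length(z0)]
  sol <- NULL
  for (si in seq_along(plan)) {
    st_N <- plan[[si]]$N
    fac <- plan[[si]]$fac
    m_s <- if (fac == 1) model else scale_contact(model, fac)
    task_s <- task
    task_s$N <- as.integer(st_N)
    ref_s <- resample_reference(ref, st_N)
    nlp_s <- assemble_nlp(m_s, task_s, ref_s)
    # states wrap through the periodicity image (pelvis progression is not
    # plain-periodic); controls wrap to themselves
    x_wrap <- periodic_image_r(model, task, X[, 1], T_sim)
    X <- resample_nodes(X, st_N, wrap = x_wrap)
    U <- resample_nodes(U, st_N)
    z <- pmin(pmax(c(as.numeric(X), as.numeric(U), T_sim), nlp_s$lb),
              nlp_s$ub)
    st <- if (!is.null(plan[[si]]$outer)) {
      modifyList(settings, list(max_outer = plan[[si]]$outer))
    } else {
      settings
    }
    sol <- solve_nlp(nlp_s, z, st, quiet = quiet)
    if (!quiet)
      message(sprintf("stage %d (N = %d, contact x%g): max|c| = %.3g",
                      si, st_N, fac, sol$max_violation))
    X <- sol$X
    U <- sol$U
    T_sim <- sol$T_sim
  }
  sol
}

# align a tracking reference with a task's tracked-signal selector
prepare_tracking <- function(model, task, ref) {
  sel <- c(task$tracked$angles, task$tracked$grfs)
  if (length(sel) == 0) return(NULL)
  miss <- setdiff(sel, ref$names)
  if (length(miss))
    stop("tracking reference lacks signals: ", paste(miss, collapse = ", "))
  if (nrow(ref$mean) != task$N)
    stop("reference has ", nrow(ref$mean), " samples but the task uses N = ",
         task$N, " nodes")
  cols <- match(sel, ref$names)
  mu <- ref$mean[, cols, drop = FALSE]
  vr <- apply(ref$sd[, cols, drop = FALSE], 2, adjust_variance,
              floor_frac = task$var_floor_frac)
  n_ang <- length(task$tracked$angles)
  n_grf <- length(task$tracked$grfs)
  sw <- signal_weights(n_ang, n_grf, task$weights$W_ang, task$weights$W_grf)
  grf_pos <- c(grf_r_x = 1, grf_r_y = 2, grf_r_z = 3,
               grf_l_x = 4, grf_l_y = 5, grf_l_z = 6)
  list(ang_rows = match(task$tracked$angles, model$dof_index),
       grf_idx = unname(grf_pos[task$tracked$grfs]),
       mu = mu, var = vr,
       w = c(rep(sw$angle, n_ang), rep(sw$grf, n_grf)),
       names = sel)
}

#' Predict static standing
#'
#' Single-node problem with `xdot = 0` and no periodicity: find a pose,
#' muscle states and controls in static equilibrium minimizing
#' `W_mus J_mus + W_tor J_tor`. Solved `n_starts` times from random initial
#' guesses drawn uniformly within the variable bounds (pelvis translations
#' within a standing-sized box); the converged solution with the lowest
#' objective wins.
#'
#' @param model a `runopt_model`
#' @param n_starts number of random restarts
#' @param seed RNG seed for the initial guesses
#' @param settings solver settings, see [solver_settings()]
#' @param quiet suppress solver output
#' @return the best `runopt_solution`; `$multistart` holds the per-start
#'   objective and convergence list
#' @export
standing_task <- function(model, n_starts = 50, seed = 1,
                          settings = solver_settings(),
                          quiet = TRUE) {
  stopifnot(n_starts >= 1)
  task <- task_spec(model, "standing", n_starts = n_starts, seed = seed)
  nlp <- assemble_nlp(model, task)
  lay <- state_control_layout(model)
  set.seed(seed)
  best <- NULL
  per_start <- data.frame(start = seq_len(n_starts), objective = NA_real_,
                          max_violation = NA_real_, converged = FALSE)
  for (i in seq_len(n_starts)) {
    lb <- nlp$lb; ub <- nlp$ub
    z0 <- runif(nlp$n_var, lb, ub)
    # pelvis translations inside a standing-sized box; rates near zero so
    # every random pose is a static candidate
    z0[1] <- runif(1, -0.5, 0.5)
    z0[2] <- runif(1, 0.8, 1.2)
    z0[3] <- runif(1, -0.5, 0.5)
    z0[lay$iqd] <- runif(lay$n_dof, -0.2, 0.2)
    z0[nlp$iT] <- 1
    sol <- solve_nlp(nlp, z0, settings, quiet = quiet)
    per_start$objective[i] <- sol$objective
    per_start$max_violation[i] <- sol$max_violation
    per_start$converged[i] <- sol$converged
    if (sol$converged &&
        (is.null(best) || sol$objective < best$objective)) best <- sol
  }
  if (is.null(best))
    stop("no standing start converged (", n_starts, " attempts)")
  best$multistart <- per_start
  best
}

#' Track straight running
#'
#' Tracks all joint angles, pelvis global orientation and both feet's GRFs
#' against the reference, with the study weights, periodicity through
#' a pure horizontal translation `(v_x T, 0, v_z T)`, and the pelvis
#' anchored at the origin at the first node. Warm-started from a standing
#' solution tiled over the cycle with the prescribed forward progression.
#'
#' @param model a `runopt_model`
#' @param ref a `runopt_reference` covering all tracked signals
#' @param v_x,v_z prescribed average horizontal speeds (m/s)
#' @param init a standing `runopt_solution` used as initial guess
#' @param N node count
#' @param settings solver settings
#' @param quiet suppress solver output
#' @return a `runopt_solution` (flagged unconverged on failure)
#' @export
straight_running_task <- function(model, ref, v_x = 4.0, v_z = 0.0, init,
                                  N = 50,
                                  settings = solver_settings(),
                                  quiet = TRUE) {
  task <- task_spec(model, "straight", v_x = v_x, v_z = v_z, N = N)
  ref <- resample_reference(ref, N)
  T0 <- ref$cadence %||% 0.7
  # the free cycle duration stays in a window around the reference cadence
  task$T_bounds <- T0 * c(0.75, 1.3)
  nlp <- assemble_nlp(model, task, ref)
  lay <- state_control_layout(model)
  tk <- (seq_len(N) - 1) / N * T0
  # initial trajectory: standing states tiled over the cycle with the
  # prescribed forward progression, joint angles bent toward the tracked
  # reference means, rates by periodic differences, and tendon-consistent
  # contraction states
  X0 <- matrix(init$X[, 1], lay$n_x, N)
  X0[1, ] <- v_x * tk
  X0[3, ] <- v_z * tk
  ang_rows <- match(task$tracked$angles, model$dof_index)
  X0[ang_rows, ] <- t(ref$mean[, match(task$tracked$angles, ref$names)])
  h <- T0 / N
  X0[lay$iqd, ] <- (X0[lay$iq, c(2:N, 1), drop = FALSE] -
                      X0[lay$iq, c(N, 1:(N - 1)), drop = FALSE]) / (2 * h)
  X0[lay$iqd[1], ] <- v_x
  X0[lay$iqd[3], ] <- v_z
  # pelvis vertical/fore-aft arcs consistent with the reference GRFs: the
  # whole-body momentum balance integrated over the cycle (the generator's
  # impulse balance makes the integrals periodic)
  fy <- rowSums(ref$mean[, match(c("grf_r_y", "grf_l_y"), ref$names)])
  fx <- rowSums(ref$mean[, match(c("grf_r_x", "grf_l_x"), ref$names)])
  acc_y <- fy / model$subject_mass - 9.81
  vy <- cumsum(acc_y * h)
  vy <- vy - mean(vy)
  y <- cumsum(vy * h)
  y <- y - mean(y) + init$X[2, 1] - 0.02
  vx_dev <- cumsum((fx / model$subject_mass) * h)
  vx_dev <- vx_dev - mean(vx_dev)
  X0[2, ] <- y
  X0[lay$iqd[2], ] <- vy
  X0[1, ] <- c(0, cumsum((v_x + vx_dev)[-N] * h))
  X0[lay$iqd[1], ] <- v_x + vx_dev
  # calibrate the pelvis height so the deepest contact-point excursion of
  # the initial kinematics is a centimetre of penetration
  min_h <- Inf
  for (k in seq_len(N)) {
    fk <- forward_kinematics(model, X0[lay$iq, k])
    min_h <- min(min_h, min(fk$contact_points$pos[, 2]))
  }
  X0[2, ] <- X0[2, ] - (min_h + 0.010)
  cd <- .cdata(model)
  for (k in seq_len(N)) {
    geo <- cpp_mus_geometry(cd, X0[lay$iq, k])
    lmtu <- geo[seq_len(lay$n_mus)]
    for (im in seq_len(lay$n_mus)) {
      mu <- model$muscles[[im]]
      X0[lay$is[im], k] <- min(max(lmtu[im] - mu$l_slack, 1e-3), 0.6)
    }
  }
  # uniform interior activations/controls: the standing optimum's muscle
  # pattern reflects its own (sometimes passive-dominated) pose and is a
  # poor and irreproducible seed for running
  X0[lay$ia, ] <- 0.1
  U0 <- matrix(0, lay$n_u, N)
  U0[lay$ine, ] <- 0.1
  z0 <- pmin(pmax(c(as.numeric(X0), as.numeric(U0), T0), nlp$lb), nlp$ub)
  sol <- solve_running_staged(model, task, ref, z0, settings, quiet)
  sol$ref <- ref
  sol
}

#' Predict curved running
#'
#' Tracks the straight-running joint angles and vertical GRFs only, with
#' `W_mus` and `W_tor` raised tenfold, and closes the cycle through the
#' rotational periodicity map: the pelvis horizontal position and global
#' velocity rotate by the central angle `theta = 2 asin(v T / 2r)` and the
#' heading gains `theta`. The first-node pelvis is anchored at `(-r, 0)`;
#' the motion is counterclockwise about the vertical axis with the left
#' leg inside. Warm-started from the straight-running solution rotated
#' onto the circle.
#'
#' @param model a `runopt_model`
#' @param straight_ref the straight-running `runopt_reference` (the curved
#'   prediction tracks straight data)
#' @param v_norm norm horizontal speed (m/s)
#' @param r circle radius (m)
#' @param init the straight-running `runopt_solution`
#' @param N node count
#' @param settings solver settings
#' @param quiet suppress solver output
#' @return a `runopt_solution`
#' @export
curved_running_task <- function(model, straight_ref, v_norm = 2.7, r = 3.7,
                                init, N = NULL,
                                settings = solver_settings(),
                                quiet = TRUE) {
  if (is.null(N)) N <- ncol(init$X)
  task <- task_spec(model, "curved", v_norm = v_norm, radius = r, N = N)
  straight_ref <- resample_reference(straight_ref, N)
  # cadence window for the slower curved speed
  T_exp <- 1.4 / sqrt(v_norm)
  task$T_bounds <- T_exp * c(0.75, 1.3)
  nlp <- assemble_nlp(model, task, straight_ref)
  lay <- state_control_layout(model)
  T0 <- min(max(init$T_sim, task$T_bounds[1]), task$T_bounds[2])
  th <- central_angle(v_norm, T0, r)$theta
  X0 <- init$X
  rot2 <- function(a, b, ang) {
    cs <- cos(ang); sn <- sin(ang)
    rbind(cs * a + sn * b, -sn * a + cs * b)
  }
  v_straight <- init$task$v_x %||% 4.0
  for (k in seq_len(N)) {
    frac <- (k - 1) / N
    phi <- -pi / 2 + th * frac  # tangent heading at this point of the circle
    x <- X0[, k]
    # deviation of the straight solution from uniform forward progression,
    # re-expressed in the rotating frame and attached to the circle point
    d <- c(x[1] - v_straight * T0 * frac, x[3])
    cxz <- rot2(-r, 0, th * frac)  # pelvis reference point on the circle
    dxz <- rot2(d[1], d[2], phi)
    vxz <- rot2(x[lay$iqd[1]], x[lay$iqd[3]], phi)
    x[1] <- cxz[1] + dxz[1]
    x[3] <- cxz[2] + dxz[2]
    x[4] <- x[4] + phi
    x[lay$iqd[1]] <- vxz[1]
    x[lay$iqd[3]] <- vxz[2]
    X0[, k] <- x
  }
  # anchor exactly
  X0[1, 1] <- -r
  X0[3, 1] <- 0
  z0 <- pmin(pmax(c(as.numeric(X0), as.numeric(init$U), T0), nlp$lb),
             nlp$ub)
  # warm-started from a solution of the stiff-ground straight problem:
  # a shorter continuation suffices
  sol <- solve_running_staged(model, task, straight_ref, z0, settings,
                              quiet,
                              plan = list(list(N = N, fac = 1e-1),
                                          list(N = N, fac = 1)))
  sol$ref <- straight_ref
  sol
}

#' Simulated GRFs of a solution
#'
#' @param model a `runopt_model`
#' @param sol a `runopt_solution`
#' @return 6 x N matrix (rows: right x/y/z then left x/y/z, N)
#' @export
solution_grf <- function(model, sol) {
  g <- cpp_traj_grf(.cdata(model), sol$X, FALSE)$grf
  rownames(g) <- c("grf_r_x", "grf_r_y", "grf_r_z",
                   "grf_l_x", "grf_l_y", "grf_l_z")
  g
}
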