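# The four objective terms: variance-normalized tracking, volume-weighted
# cubed muscular effort, squared torque controls, and a regularization term
# on state and control derivatives. Integrals use the same backward-Euler
# rectangle rule as the dynamics (uniform h = T_sim / N), so the 1/T_sim
# normalization cancels into 1/N; T_sim still enters through the
# derivatives in the regularization term.

#' Variance flooring for tracking
#'
#' Squared reference SDs are floored at a fraction (default 10 percent) of
#' the signal's mean variance to avoid division by near-zero variances, as
#' happens for GRF variance during the swing phase.
#'
#' @param sd_traj nonnegative SD trajectory of one signal
#' @param floor_frac variance floor as a fraction of the mean variance
#' @return adjusted variance trajectory (strictly positive)
#' @export
adjust_variance <- function(sd_traj, floor_frac = 0.1) {
  stopifnot(length(sd_traj) > 0, all(sd_traj >= 0))
  v <- sd_traj^2
  if (all(v == 0))
    stop("all-zero SD for a tracked signal: variance normalization impossible")
  pmax(v, floor_frac * mean(v))
}

#' Per-signal tracking weights
#'
#' Weighted arithmetic mean balancing joint-angle and GRF tracking
#' independently of the signal counts:
#' `W_i = W_ang / (N_Ang W_ang + N_GRF W_GRF)` for angle signals and
#' `W_GRF / (...)` for GRF signals; the weights sum to one.
#'
#' @param n_ang,n_grf numbers of tracked angle and GRF signals
#' @param w_ang,w_grf group weights (study defaults 1 and 5)
#' @return list with `angle` and `grf` per-signal weights
#' @export
signal_weights <- function(n_ang, n_grf, w_ang = 1, w_grf = 5) {
  stopifnot(n_ang >= 0, n_grf >= 0)
  den <- n_ang * w_ang + n_grf * w_grf
  if (den <= 0) stop("no tracked signals: zero weight denominator")
  list(angle = w_ang / den, grf = w_grf / den)
}

#' Tracking cost
#'
#' Variance-normalized squared deviation from the reference mean,
#' backward-Euler quadrature over the node grid:
#' `J = (1/N) sum_k sum_i W_i (y_ki - mu_ki)^2 / var_ki`.
#'
#' @param y_sim simulated signals, N x n_signals matrix
#' @param ref_mean,ref_var reference mean and adjusted variance, same shape
#' @param weights per-signal weight vector (length n_signals)
#' @return dimensionless nonnegative cost
#' @export
tracking_cost <- function(y_sim, ref_mean, ref_var, weights) {
  if (!all(dim(y_sim) == dim(ref_mean)))
    stop("grid mismatch between simulated signals and reference")
  dev2 <- (y_sim - ref_mean)^2 / ref_var
  mean(dev2 %*% weights)
}

#' Muscular effort cost
#'
#' Volume-weighted cubed neural excitation, normalized by the cubed norm of
#' the horizontal translation speed to compensate for different running
#' speeds: `J = (1/(N_mus ||v||^3)) mean_k sum_i vol_i n_e^3`. For the
#' standing task (`v = 0`) the speed divisor is taken as one.
#'
#' @param n_e excitation trajectories, N x n_mus matrix in `[0, 1]`
#' @param muscles list of muscle parameter lists (for `F_ISO`, `l_CE_opt`)
#' @param v_ref horizontal speed 2-vector `(v_x, v_z)` (m/s)
#' @return dimensionless nonnegative cost
#' @export
effort_cost <- function(n_e, muscles, v_ref = c(0, 0)) {
  vol <- vapply(muscles, function(m) m$F_ISO * m$l_CE_opt, numeric(1))
  vol <- vol / sum(vol)
  vnorm <- sqrt(sum(v_ref^2))
  div <- if (vnorm > 0) vnorm^3 else 1
  mean((n_e^3) %*% vol) / (length(muscles) * div)
}

#' Torque cost
#'
#' Mean squared normalized torque controls: `J = (1/N_tor) mean_k sum_i
#' m_i^2`; zero when the model has no torque actuators.
#'
#' @param m_traj torque control trajectories, N x n_tor matrix
#' @return dimensionless nonnegative cost
#' @export
torque_cost <- function(m_traj) {
  if (is.null(m_traj) || ncol(m_traj) == 0) return(0)
  mean(m_traj^2 %*% rep(1, ncol(m_traj))) / ncol(m_traj)
}

#' Regularization cost
#'
#' Mean squared backward-difference derivative of all states and controls,
#' `J = (1/(N_states + N_controls)) mean_k (sum xdot^2 + sum udot^2)`; the
#' wrap interval uses the periodicity image of the first node.
#'
#' @param X states, n_x x N matrix (nodes in columns)
#' @param U controls, n_u x N matrix
#' @param T_sim cycle duration (s)
#' @param x_wrap state at `T_sim` (periodicity image of column 1); defaults
#'   to column 1 itself (plain periodic wrap)
#' @return dimensionless nonnegative cost
#' @export
regularization_cost <- function(X, U, T_sim, x_wrap = X[, 1]) {
  N <- ncol(X)
  stopifnot(N >= 2 || !is.null(x_wrap))
  dX <- cbind(X[, -1, drop = FALSE] - X[, -N, drop = FALSE],
              x_wrap - X[, N])
  dU <- cbind(U[, -1, drop = FALSE] - U[, -N, drop = FALSE],
              U[, 1] - U[, N])
  h <- T_sim / N
  (sum(dX^2) + sum(dU^2)) / (h^2 * N * (nrow(X) + nrow(U)))
}

# ---------------------------------------------------------------------------
# periodicity image of the first node and its derivatives (R mirror of the
# C++ map used inside the wrap defect)
# ---------------------------------------------------------------------------
periodic_image_r <- function(model, task, x0, T_sim) {
  lay <- state_control_layout(model)
  xN <- x0
  if (task$kind == "straight") {
    xN[1] <- xN[1] + task$v_x * T_sim
    xN[3] <- xN[3] + task$v_z * T_sim
  } else if (task$kind == "curved") {
    th <- central_angle(task$v_norm, T_sim, task$radius)$theta
    cs <- cos(th); sn <- sin(th)
    xN[1] <- cs * x0[1] + sn * x0[3]
    xN[3] <- -sn * x0[1] + cs * x0[3]
    xN[4] <- x0[4] + th
    iv <- lay$n_dof + c(1, 3)
    xN[iv[1]] <- cs * x0[iv[1]] + sn * x0[iv[2]]
    xN[iv[2]] <- -sn * x0[iv[1]] + cs * x0[iv[2]]
  }
  xN
}

# transpose-Jacobian product t(dP/dx0) %*% v and the derivative dP/dT
periodic_image_derivs <- function(model, task, x0, T_sim, v) {
  lay <- state_control_layout(model)
  jtv <- v
  dT <- numeric(length(x0))
  if (task$kind == "straight") {
    dT[1] <- task$v_x
    dT[3] <- task$v_z
  } else if (task$kind == "curved") {
    ca <- central_angle(task$v_norm, T_sim, task$radius)
    th <- ca$theta
    cs <- cos(th); sn <- sin(th)
    rotT <- function(a, b) c(cs * a - sn * b, sn * a + cs * b)
    jtv[c(1, 3)] <- rotT(v[1], v[3])
    iv <- lay$n_dof + c(1, 3)
    jtv[iv] <- rotT(v[iv[1]], v[iv[2]])
    # dP/dtheta * dtheta/dT
    dth <- numeric(length(x0))
    dth[1] <- -sn * x0[1] + cs * x0[3]
    dth[3] <- -cs * x0[1] - sn * x0[3]
    dth[4] <- 1
    dth[iv[1]] <- -sn * x0[iv[1]] + cs * x0[iv[2]]
    dth[iv[2]] <- -cs * x0[iv[1]] - sn * x0[iv[2]]
    dT <- dth * ca$dtheta_dT
  }
  list(jtv = jtv, dT = dT)
}

# ---------------------------------------------------------------------------
# full objective over a trajectory, with analytic gradient; used by the
# solver and by total_objective()
# ---------------------------------------------------------------------------
traj_objective <- function(model, task, track, X, U, T_sim,
                           want_grad = TRUE, grf_fn = NULL) {
  lay <- state_control_layout(model)
  N <- ncol(X)
  W <- task$weights
  gX <- if (want_grad) matrix(0, nrow(X), N)
  gU <- if (want_grad) matrix(0, nrow(U), N)
  gT <- 0

  # tracking
  J_track <- 0
  if (!is.null(track) && W$W_track > 0) {
    ys_ang <- t(X[track$ang_rows, , drop = FALSE])      # N x n_ang
    grf <- if (is.null(grf_fn)) {
      cpp_traj_grf(.cdata(model), X, want_grad)
    } else {
      grf_fn(X, want_grad)
    }
    ys_grf <- t(grf$grf[track$grf_idx, , drop = FALSE]) # N x n_grf
    y <- cbind(ys_ang, ys_grf)
    dev <- (y - track$mu) / track$var
    J_track <- mean(((y - track$mu) * dev) %*% track$w)
    if (want_grad) {
      dJdy <- sweep(2 * dev / N, 2, track$w, `*`)       # N x n_sig
      na <- length(track$ang_rows)
      if (na > 0)
        gX[track$ang_rows, ] <- gX[track$ang_rows, ] +
          W$W_track * t(dJdy[, seq_len(na), drop = FALSE])
      if (length(track$grf_idx) > 0) {
        for (k in seq_len(N)) {
          Jg <- grf$jac[track$grf_idx, , k, drop = FALSE] # n_grf x 2 n_dof
          gk <- colSums(Jg * dJdy[k, na + seq_along(track$grf_idx)])
          gX[seq_len(2 * lay$n_dof), k] <-
            gX[seq_len(2 * lay$n_dof), k] + W$W_track * gk
        }
      }
    }
  }

  # effort
  vol <- task$vol_frac
  ne <- U[lay$ine, , drop = FALSE]
  div <- task$effort_div
  J_mus <- mean(colSums(vol * ne^3)) / (lay$n_mus * div)
  if (want_grad)
    gU[lay$ine, ] <- gU[lay$ine, ] +
      W$W_mus * 3 * vol * ne^2 / (lay$n_mus * div * N)

  # torque
  J_tor <- 0
  if (lay$n_tor > 0) {
    mm <- U[lay$im, , drop = FALSE]
    J_tor <- mean(colSums(mm^2)) / lay$n_tor
    if (want_grad)
      gU[lay$im, ] <- gU[lay$im, ] + W$W_tor * 2 * mm / (lay$n_tor * N)
  }

  # regularization (skipped for the single-node standing problem)
  J_reg <- 0
  if (task$kind != "standing" && W$W_reg > 0) {
    x_wrap <- periodic_image_r(model, task, X[, 1], T_sim)
    dX <- cbind(X[, -1, drop = FALSE] - X[, -N, drop = FALSE],
                x_wrap - X[, N])
    dU <- cbind(U[, -1, drop = FALSE] - U[, -N, drop = FALSE],
                U[, 1] - U[, N])
    cden <- N / (T_sim^2 * (lay$n_x + lay$n_u))
    S <- sum(dX^2) + sum(dU^2)
    J_reg <- cden * S
    if (want_grad) {
      # each X[, j] enters dX[, j] with a minus sign and dX[, j-1] with a
      # plus sign; the wrap column depends on X[, 1] through the map P
      c2 <- 2 * cden * W$W_reg
      gX <- gX - c2 * dX
      gX[, -1] <- gX[, -1] + c2 * dX[, -N, drop = FALSE]
      pd <- periodic_image_derivs(model, task, X[, 1], T_sim, dX[, N])
      gX[, 1] <- gX[, 1] + c2 * pd$jtv
      gU <- gU - c2 * dU
      gU[, -1] <- gU[, -1] + c2 * dU[, -N, drop = FALSE]
      gU[, 1] <- gU[, 1] + c2 * dU[, N]
      gT <- gT + W$W_reg * (-2 * J_reg / T_sim) +
        c2 * sum(dX[, N] * pd$dT)
    }
  }

  J <- W$W_track * J_track + W$W_mus * J_mus + W$W_tor * J_tor +
    W$W_reg * J_reg
  out <- list(value = J,
              terms = c(track = J_track, mus = J_mus, tor = J_tor,
                        reg = J_reg))
  if (want_grad) out[c("gX", "gU", "gT")] <- list(gX, gU, gT)
  out
}

#' Total objective with gradient
#'
#' Weighted sum `J = W_Track J_track + W_mus J_mus + W_tor J_tor +
#' W_reg J_reg` over a node trajectory, with the analytic gradient with
#' respect to all decision variables (states, controls and cycle duration).
#'
#' @param model a `runopt_model`
#' @param task a `runopt_task` (see [task_spec()])
#' @param ref a `runopt_reference` or `NULL` when nothing is tracked
#' @param X states, n_x x N matrix
#' @param U controls, n_u x N matrix
#' @param T_sim cycle duration (s)
#' @return list with `value`, per-term breakdown `terms`, and gradients
#'   `gX`, `gU`, `gT`
#' @export
total_objective <- function(model, task, ref, X, U, T_sim) {
  track <- if (!is.null(ref)) prepare_tracking(model, task, ref)
  traj_objective(model, task, track, X, U, T_sim, want_grad = TRUE)
}
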