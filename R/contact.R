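# Penetration-based ground contact: cubic normal stiffness with velocity
# damping and smoothed Coulomb friction. All outputs are C1 so the model can
# sit inside a gradient-based trajectory optimizer.

#' Ground contact force at a point
#'
#' Smoothed penetration `p = 0.5 (sqrt(y^2 + eps_p^2) - y)` drives a cubic
#' normal force `F_y = k_n p^3 (1 - c_n ydot)`, softly clamped nonnegative;
#' the tangential force is smoothed Coulomb friction
#' `F_t = -mu F_y v_t / sqrt(||v_t||^2 + v_c^2)`.
#'
#' @param pos world position of the contact point (3-vector, m); the ground
#'   plane is `y = 0`
#' @param vel world velocity of the contact point (3-vector, m/s)
#' @param cp contact parameter list, see [contact_defaults()]
#' @return force 3-vector (N)
#' @export
contact_force <- function(pos, vel, cp = contact_defaults()) {
  y <- pos[2]; yd <- vel[2]
  pen <- 0.5 * (sqrt(y^2 + cp$eps_p^2) - y)
  f_raw <- cp$k_n * pen^3 * (1 - cp$c_n * yd)
  f_y <- 0.5 * (sqrt(f_raw^2 + cp$f_eps^2) + f_raw)
  den <- sqrt(vel[1]^2 + vel[3]^2 + cp$v_c^2)
  c(-cp$mu * f_y * vel[1] / den, f_y, -cp$mu * f_y * vel[3] / den)
}

#' Contact generalized forces and per-foot ground reaction forces
#'
#' Maps the point contact forces into generalized forces through the point
#' Jacobians (virtual work) and sums each foot's point forces into the
#' simulated ground reaction force signal.
#'
#' @param model a `runopt_model`
#' @param q,qd generalized coordinates and velocities
#' @return list with `tau` (generalized force vector, length `n_dof`),
#'   `grf_right`, `grf_left` (3-vectors, N) and `point_forces` (matrix, one
#'   row per contact point)
#' @export
contact_generalized_forces <- function(model, q, qd) {
  nd <- length(model$dof_index)
  stopifnot(length(q) == nd, length(qd) == nd)
  cd <- .cdata(model)
  res <- cpp_contact_gen(cd, as.numeric(q), as.numeric(qd))
  list(tau = as.numeric(res$tau), grf_right = res$grf[1:3],
       grf_left = res$grf[4:6], point_forces = res$point_forces)
}
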