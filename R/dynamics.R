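# Implicit full-body dynamics: forward kinematics, multibody residual via
# recursive Newton-Euler, the stacked residual f(x, xdot, u) = 0 and its
# Jacobians. The numeric core lives in src/dynamics.cpp; Jacobians come from
# complex-step differentiation of the same templated code path.

#' Forward kinematics
#'
#' Computes world-frame pose (rotation, origin), centre-of-mass position and
#' velocity for every segment, and world position/velocity of every contact
#' point, by traversing the joint tree.
#'
#' @param model a `runopt_model`
#' @param q generalized coordinates (length `n_dof`)
#' @param qd generalized velocities (length `n_dof`)
#' @return list with `segments` (named list of `rot` 3x3, `origin`, `com`,
#'   `com_vel` per segment) and `contact_points` (matrix columns `pos`/`vel`)
#' @export
forward_kinematics <- function(model, q, qd = rep(0, length(q))) {
  nd <- length(model$dof_index)
  stopifnot(length(q) == nd, length(qd) == nd)
  if (anyNA(q)) {
    stop("NaN in q at DOF ", paste(model$dof_index[is.na(q)], collapse = ", "))
  }
  cd <- .cdata(model)
  res <- cpp_fk(cd, as.numeric(q), as.numeric(qd))
  # elementary body index of each segment = last body of its joint
  body_of <- segment_body_map(model)
  segs <- lapply(body_of, function(b) {
    i <- b + 1L
    list(rot = matrix(res$rot[i, ], 3, 3, byrow = TRUE),
         origin = res$origin[i, ], com = res$com[i, ],
         com_vel = res$com_vel[i, ])
  })
  list(segments = segs,
       contact_points = list(pos = res$cp_pos, vel = res$cp_vel))
}

segment_body_map <- function(model) {
  b <- -1L
  out <- integer(0)
  for (j in model$joints) {
    b <- b + joint_ndof(j$type)
    out[j$child] <- b
  }
  out
}

#' Multibody dynamics residual
#'
#' Evaluates `M(q) qdd + bias(q, qd) - tau_gen` by recursive Newton-Euler
#' inverse dynamics (gravity included); the residual is zero iff
#' `(qdd, tau_gen)` satisfy the skeletal equations of motion.
#'
#' @param model a `runopt_model`
#' @param q,qd,qdd coordinates, velocities, accelerations (length `n_dof`)
#' @param tau_gen generalized forces (length `n_dof`), default zero
#' @return residual vector in natural units (N or N m per row)
#' @export
multibody_residual <- function(model, q, qd, qdd,
                               tau_gen = rep(0, length(q))) {
  nd <- length(model$dof_index)
  stopifnot(length(q) == nd, length(qd) == nd, length(qdd) == nd,
            length(tau_gen) == nd)
  cd <- .cdata(model)
  as.numeric(cpp_rne(cd, as.numeric(q), as.numeric(qd),
                     as.numeric(qdd))) - tau_gen
}

#' Full implicit dynamics residual
#'
#' Stacks (a) the kinematic identity rows, (b) the multibody rows with
#' muscle, torque-actuator and ground-contact generalized forces, (c) the
#' per-muscle Hill contraction residuals and (d) the per-muscle activation
#' residuals into the implicit system `f(x, xdot, u) = 0`. Rows are
#' nondimensionalized (multibody by subject weight, contraction by
#' `F_ISO`, activation by `T_act`) so a single feasibility tolerance is
#' meaningful across the whole vector.
#'
#' @param model a `runopt_model`
#' @param x state vector `(q, qdot, s, a)`
#' @param xd state derivative vector
#' @param u control vector `(n_e, m)`
#' @return list with `f` (length `n_x` residual) and `grf` (6-vector: right
#'   then left foot ground reaction force, N)
#' @export
full_dynamics_residual <- function(model, x, xd, u) {
  lay <- state_control_layout(model)
  if (length(x) != lay$n_x || length(xd) != lay$n_x || length(u) != lay$n_u)
    stop("layout error: expected n_x = ", lay$n_x, ", n_u = ", lay$n_u)
  cd <- .cdata(model)
  res <- cpp_node_residual(cd, as.numeric(x), as.numeric(xd), as.numeric(u))
  list(f = as.numeric(res$f), grf = as.numeric(res$grf))
}

#' Jacobians of the implicit dynamics residual
#'
#' Returns the three sparse Jacobians of [full_dynamics_residual()] with a
#' fixed sparsity pattern (the union of the structural nonzeros observed at
#' reference evaluation points, cached per model).
#'
#' @inheritParams full_dynamics_residual
#' @return list of sparse matrices `Jx` (`n_x` x `n_x`), `Jxd` (`n_x` x
#'   `n_x`), `Ju` (`n_x` x `n_u`)
#' @export
residual_jacobians <- function(model, x, xd, u) {
  lay <- state_control_layout(model)
  if (length(x) != lay$n_x || length(xd) != lay$n_x || length(u) != lay$n_u)
    stop("layout error: expected n_x = ", lay$n_x, ", n_u = ", lay$n_u)
  cd <- .cdata(model)
  J <- cpp_node_jacobians(cd, as.numeric(x), as.numeric(xd), as.numeric(u))
  pat <- jacobian_pattern(model)
  list(Jx = Matrix::Matrix(J$Jx * pat$Jx, sparse = TRUE),
       Jxd = Matrix::Matrix(J$Jxd * pat$Jxd, sparse = TRUE),
       Ju = Matrix::Matrix(J$Ju * pat$Ju, sparse = TRUE))
}

# structural sparsity pattern derived from the model topology: which rows
# of the stacked residual can ever depend on which inputs. The multibody
# block is taken dense in (q, qd, qdd) -- the kinematic tree couples every
# DOF through the root -- while muscle rows follow the path polynomials.
jacobian_pattern <- function(model) {
  env <- attr(model, "cdata_env")
  if (!is.null(env) && !is.null(env$jac_pattern)) return(env$jac_pattern)
  lay <- state_control_layout(model)
  nd <- lay$n_dof; nm <- lay$n_mus
  Jx <- matrix(0, lay$n_x, lay$n_x)
  Jxd <- matrix(0, lay$n_x, lay$n_x)
  Ju <- matrix(0, lay$n_x, lay$n_u)
  # kinematic identity rows: d/d(xdot_q) = I, d/d(qdot) = -I
  Jxd[cbind(lay$iq, lay$iq)] <- 1
  Jx[cbind(lay$iq, lay$iqd)] <- 1
  # multibody rows: dense in q, qd (bias, contact, muscle geometry) and qdd
  Jx[lay$iqd, c(lay$iq, lay$iqd)] <- 1
  Jxd[lay$iqd, lay$iqd] <- 1
  spans <- lapply(model$muscles,
                  function(mu) match(mu$path$dof_names, model$dof_index))
  for (i in seq_len(nm)) {
    # tendon force enters the spanned DOFs' force balance
    Jx[lay$iqd[spans[[i]]], lay$is[i]] <- 1
    # contraction row: spanned angles, own s / sdot / a
    Jx[lay$is[i], lay$iq[spans[[i]]]] <- 1
    Jx[lay$is[i], lay$is[i]] <- 1
    Jx[lay$is[i], lay$ia[i]] <- 1
    Jxd[lay$is[i], lay$is[i]] <- 1
    # activation row: own a / adot / n_e
    Jx[lay$ia[i], lay$ia[i]] <- 1
    Jxd[lay$ia[i], lay$ia[i]] <- 1
    Ju[lay$ia[i], lay$ine[i]] <- 1
  }
  for (t in seq_along(model$torque_actuators)) {
    d <- match(model$torque_actuators[[t]]$dof, model$dof_index)
    Ju[lay$iqd[d], lay$im[t]] <- 1
  }
  pat <- list(Jx = Jx, Jxd = Jxd, Ju = Ju)
  if (!is.null(env)) env$jac_pattern <- pat
  pat
}

# total mechanical energy of the passive skeleton (for consistency checks)
mechanical_energy <- function(model, q, qd) {
  cd <- .cdata(model)
  nd <- length(q)
  # kinetic energy via unit-velocity RNE columns: T = 0.5 qd' M qd with
  # M from inverse dynamics at zero gravity/velocity
  cd0 <- cd
  cd0$gravity <- c(0, 0, 0)
  Mqd <- cpp_rne(cd0, q, rep(0, nd), qd)
  kin <- 0.5 * sum(qd * Mqd)
  fk <- cpp_fk(cd, q, rep(0, nd))
  pot <- -sum(cd$mass * (fk$com %*% model$gravity))
  kin + pot
}
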