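#' @useDynLib runopt3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as new
#' @importFrom stats optim rnorm runif sd approx median setNames
#' @importFrom utils modifyList
NULL

# ---------------------------------------------------------------------------
# Model structure: segments, joints, muscles, torque actuators, contact
# points, bounds, and the flat state/control layout.
#
# Coordinate convention: x forward, y vertical up, z to the subject's right.
# Rotations about y define heading; the pelvis rotation order puts heading
# outermost so a whole-body rotation about the vertical axis adds to the
# single coordinate `pelvis_rot`.
# ---------------------------------------------------------------------------

#' Default Hill-type muscle parameters
#'
#' Three-element Hill muscle with Gaussian active force-length curve,
#' hyperbolic force-velocity curve saturating eccentrically, quadratic series
#' elastic element (SEE) and quadratic parallel elastic element (PEE)
#' engaging at optimal contractile element (CE) length. The CE contraction
#' state is the projection `s` of the CE length onto the line of action,
#' with a constant-height pennation model.
#'
#' @return named list of default parameters: `W` force-length width
#'   (dimensionless), `v_max` maximum shortening velocity (optimal CE
#'   lengths per second), `A_hill` force-velocity curvature, `f_ecc`
#'   eccentric plateau, `phi_opt` pennation at optimal length (rad),
#'   `T_act`/`T_deact` activation and deactivation time constants (s),
#'   `eps0_SEE` SEE strain at maximum isometric force, `k_PEE` PEE
#'   quadratic stiffness (units of `F_ISO / l_CE_opt^2`), `d_CE` CE damping
#'   (units of `F_ISO` per `l_CE_opt`/s).
#' @export
muscle_defaults <- function() {
  list(W = 0.56, v_max = 10, A_hill = 0.25, f_ecc = 1.5, phi_opt = 0.1,
       T_act = 0.01, T_deact = 0.04, eps0_SEE = 0.04,
       k_PEE = 1 / 0.56^2, d_CE = 0.01)
}

#' Default penetration ground-contact parameters
#'
#' Cubic normal stiffness with velocity-dependent damping and smoothed
#' Coulomb friction; all outputs are C1 so the contact model can sit inside
#' a gradient-based optimizer.
#'
#' @return named list: `k_n` normal stiffness (N/m^3), `c_n` damping
#'   coefficient (s/m), `mu` friction coefficient, `v_c` friction velocity
#'   smoothing (m/s), `eps_p` penetration smoothing (m), `f_eps` normal
#'   force smoothing (N).
#' @export
contact_defaults <- function() {
  list(k_n = 2.5e8, c_n = 1.0, mu = 1.0, v_c = 0.01, eps_p = 1e-3,
       f_eps = 1e-3)
}

new_segment <- function(name, mass, inertia, com_offset,
                        contact_points = list()) {
  list(name = name, mass = mass, inertia = inertia, com_offset = com_offset,
       contact_points = contact_points)
}

new_joint <- function(name, parent, child, type, translation,
                      axis = NULL, rotation_order = NULL, dof_names = NULL,
                      dof_bounds = NULL) {
  list(name = name, parent = parent, child = child, type = type,
       translation = translation, axis = axis,
       rotation_order = rotation_order, dof_names = dof_names,
       dof_bounds = dof_bounds)
}

axis_vec <- function(label) {
  switch(label,
         x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
         stop("unknown axis label: ", label))
}

joint_ndof <- function(type) switch(type, free6 = 6L, ball3 = 3L,
                                    revolute1 = 1L)

#' Build the reduced 3D runner model
#'
#' Constructs a desk-scale 3D musculoskeletal runner: a pelvis root with six
#' degrees of freedom (three translations, three rotations with heading
#' about the vertical axis outermost), a torso on a 3-DOF ball joint driven
#' by three torque actuators (normalized by 10 N m), and per leg a 3-DOF ball
#' hip, revolute knee, revolute ankle and revolute subtalar joint -- 21 DOFs
#' in total. Each leg carries 9 Hill-type muscle-tendon units whose
#' muscle-tendon lengths are polynomials in the spanned joint angles, and
#' each foot has two ground contact points (heel and toe). Segment masses
#' and lengths are scaled by standard anthropometric fractions of the
#' subject's mass and height; the segment masses sum exactly to
#' `subject_mass`.
#'
#' @param subject_mass subject body mass in kg
#' @param subject_height subject stature in m
#' @return a `runopt_model` list with elements `segments`, `joints`,
#'   `dof_index`, `muscles`, `torque_actuators`, `contact_par`, `gravity`,
#'   `subject_mass`, `subject_height`, `bounds`
#' @export
build_reduced_runner <- function(subject_mass = 92, subject_height = 1.95) {
  if (!is.numeric(subject_mass) || subject_mass <= 0 ||
      !is.numeric(subject_height) || subject_height <= 0) {
    stop("subject mass and height must be positive")
  }
  m <- subject_mass
  H <- subject_height

  # mass fractions: legs and pelvis fixed, torso(+head+arms) is the remainder
  # so that the total is exactly the subject mass
  f_thigh <- 0.100; f_shank <- 0.0465; f_talus <- 0.0008; f_foot <- 0.0129
  f_pelvis <- 0.142
  f_leg <- f_thigh + f_shank + f_talus + f_foot
  f_torso <- 1 - f_pelvis - 2 * f_leg

  l_thigh <- 0.245 * H
  l_shank <- 0.246 * H
  l_foot <- 0.152 * H
  h_ankle <- 0.039 * H      # ankle height above sole
  w_hip <- 0.045 * H        # pelvis origin to hip centre, lateral
  h_hip <- 0.035 * H        # pelvis origin to hip centre, downward

  box_inertia <- function(mass, lx, ly, lz) {
    diag(mass / 12 * c(ly^2 + lz^2, lx^2 + lz^2, lx^2 + ly^2))
  }
  rod_inertia_y <- function(mass, len, rad) {
    diag(c(mass * (3 * rad^2 + len^2) / 12, mass * rad^2 / 2,
           mass * (3 * rad^2 + len^2) / 12))
  }

  segs <- list()
  segs$pelvis <- new_segment("pelvis", f_pelvis * m,
                             box_inertia(f_pelvis * m, 0.18, 0.12, 0.28),
                             c(0, 0, 0))
  segs$torso <- new_segment("torso", f_torso * m,
                            box_inertia(f_torso * m, 0.22, 0.55, 0.30),
                            c(0, 0.28, 0))
  leg_side <- function(side) {
    sgn <- if (side == "r") 1 else -1
    th <- new_segment(paste0("thigh_", side), f_thigh * m,
                      rod_inertia_y(f_thigh * m, l_thigh, 0.055),
                      c(0, -l_thigh / 2, 0))
    sh <- new_segment(paste0("shank_", side), f_shank * m,
                      rod_inertia_y(f_shank * m, l_shank, 0.04),
                      c(0, -l_shank / 2, 0))
    ta <- new_segment(paste0("talus_", side), f_talus * m,
                      diag(1e-4, 3), c(0, 0, 0))
    ft <- new_segment(paste0("foot_", side), f_foot * m,
                      box_inertia(f_foot * m, l_foot, 0.06, 0.08),
                      c(0.045, -h_ankle / 2, 0),
                      contact_points = list(
                        heel = c(-0.045, -h_ankle, 0),
                        toe = c(0.75 * l_foot, -h_ankle, sgn * 0.01)))
    list(thigh = th, shank = sh, talus = ta, foot = ft)
  }
  rl <- leg_side("r"); ll <- leg_side("l")
  segs[paste0(c("thigh_", "shank_", "talus_", "foot_"), "r")] <- rl
  segs[paste0(c("thigh_", "shank_", "talus_", "foot_"), "l")] <- ll

  pelvis_rot_bounds <- list(pelvis_rot = c(-7, 7),
                            pelvis_list = c(-0.8, 0.8),
                            pelvis_tilt = c(-0.8, 0.8))
  joints <- list(
    new_joint("ground_pelvis", "ground", "pelvis", "free6",
              translation = c(0, 0, 0), rotation_order = c("y", "x", "z"),
              dof_names = c("pelvis_tx", "pelvis_ty", "pelvis_tz",
                            "pelvis_rot", "pelvis_list", "pelvis_tilt"),
              dof_bounds = c(list(pelvis_tx = c(-20, 20),
                                  pelvis_ty = c(0.4, 1.5),
                                  pelvis_tz = c(-20, 20)),
                             pelvis_rot_bounds)),
    new_joint("pelvis_torso", "pelvis", "torso", "ball3",
              translation = c(0, 0.08, 0), rotation_order = c("z", "x", "y"),
              dof_names = c("torso_tilt", "torso_list", "torso_rot"),
              dof_bounds = list(torso_tilt = c(-0.8, 0.8),
                                torso_list = c(-0.8, 0.8),
                                torso_rot = c(-0.9, 0.9)))
  )
  leg_joints <- function(side) {
    sgn <- if (side == "r") 1 else -1
    list(
      new_joint(paste0("hip_", side), "pelvis", paste0("thigh_", side),
                "ball3", translation = c(0, -h_hip, sgn * w_hip),
                rotation_order = c("z", "x", "y"),
                dof_names = paste0(c("hip_flexion_", "hip_adduction_",
                                     "hip_rotation_"), side),
                dof_bounds = setNames(list(c(-0.8, 2.1), c(-0.9, 0.9),
                                           c(-0.9, 0.9)),
                                      paste0(c("hip_flexion_",
                                               "hip_adduction_",
                                               "hip_rotation_"), side))),
      # axis -z so that a positive coordinate is anatomical knee flexion
      # (shank swinging backward)
      new_joint(paste0("knee_", side), paste0("thigh_", side),
                paste0("shank_", side), "revolute1",
                translation = c(0, -l_thigh, 0), axis = c(0, 0, -1),
                dof_names = paste0("knee_flexion_", side),
                dof_bounds = setNames(list(c(-0.1, 2.4)),
                                      paste0("knee_flexion_", side))),
      new_joint(paste0("ankle_", side), paste0("shank_", side),
                paste0("talus_", side), "revolute1",
                translation = c(0, -l_shank, 0), axis = c(0, 0, 1),
                dof_names = paste0("ankle_dorsiflexion_", side),
                dof_bounds = setNames(list(c(-0.9, 0.9)),
                                      paste0("ankle_dorsiflexion_", side))),
      new_joint(paste0("subtalar_", side), paste0("talus_", side),
                paste0("foot_", side), "revolute1",
                translation = c(0, 0, 0), axis = c(1, 0, 0),
                dof_names = paste0("subtalar_", side),
                dof_bounds = setNames(list(c(-0.6, 0.6)),
                                      paste0("subtalar_", side)))
    )
  }
  joints <- c(joints, leg_joints("r"), leg_joints("l"))
  dof_index <- unlist(lapply(joints, `[[`, "dof_names"))

  muscles <- c(leg_muscles("r"), leg_muscles("l"))

  model <- structure(list(
    segments = segs,
    joints = joints,
    dof_index = dof_index,
    muscles = muscles,
    torque_actuators = list(
      list(dof = "torso_tilt", scale = 10),
      list(dof = "torso_list", scale = 10),
      list(dof = "torso_rot", scale = 10)),
    contact_par = contact_defaults(),
    # small passive viscous damping at the internal joints (N m s/rad),
    # standing in for unmodeled passive structures
    joint_damping = c(rep(0, 6), rep(0.3, 15)),
    gravity = c(0, -9.81, 0),
    subject_mass = m,
    subject_height = H
  ), class = "runopt_model")
  model$bounds <- default_bounds(model)
  model
}

# 9 muscle-tendon units per leg; paths are polynomials in the spanned joint
# angles with moment arm = -dl/dq (virtual work convention). Constant terms
# put l_MTU at (l_CE_opt + l_slack) in the neutral pose so standing sits near
# optimal CE length.
leg_muscles <- function(side) {
  d <- muscle_defaults()
  hf <- paste0("hip_flexion_", side)
  ha <- paste0("hip_adduction_", side)
  hr <- paste0("hip_rotation_", side)
  kn <- paste0("knee_flexion_", side)
  an <- paste0("ankle_dorsiflexion_", side)
  st <- paste0("subtalar_", side)
  lin <- function(l0, ...) {
    arms <- list(...)
    terms <- list(list(coef = l0, powers = integer(0), dofs = character(0)))
    for (dn in names(arms)) {
      terms <- c(terms, list(list(coef = arms[[dn]], powers = 1L, dofs = dn)))
    }
    terms
  }
  mk <- function(name, fiso, lopt, lslack, arms) {
    terms <- do.call(lin, c(list(l0 = lopt + lslack), arms))
    c(list(name = paste0(name, "_", side), F_ISO = fiso, l_CE_opt = lopt,
           l_slack = lslack,
           path = list(dof_names = unique(unlist(lapply(terms, `[[`,
                                                        "dofs"))),
                       terms = terms)), d)
  }
  ms <- list(
    mk("iliopsoas", 2500, 0.10, 0.12, setNames(list(-0.050), hf)),
    mk("glutei", 4500, 0.11, 0.13, setNames(list(0.060, 0.030), c(hf, hr))),
    mk("hip_abductor", 2500, 0.09, 0.10, setNames(list(0.040), ha)),
    mk("hip_adductor", 1800, 0.10, 0.11,
       setNames(list(-0.040, -0.030), c(ha, hr))),
    mk("hamstrings", 5000, 0.10, 0.30,
       setNames(list(0.060, -0.025), c(hf, kn))),
    mk("rectus_femoris", 1600, 0.08, 0.30,
       setNames(list(-0.045, 0.040), c(hf, kn))),
    mk("vasti", 9000, 0.09, 0.20, setNames(list(0.045), kn)),
    mk("triceps_surae", 9000, 0.06, 0.36,
       setNames(list(-0.020, 0.050, 0.020), c(kn, an, st))),
    mk("tibialis_anterior", 1500, 0.07, 0.22,
       setNames(list(-0.040, -0.025), c(an, st)))
  )
  ms
}

default_bounds <- function(model) {
  q_lb <- q_ub <- numeric(0)
  for (j in model$joints) {
    for (dn in j$dof_names) {
      b <- j$dof_bounds[[dn]]
      q_lb <- c(q_lb, b[1]); q_ub <- c(q_ub, b[2])
    }
  }
  nd <- length(model$dof_index)
  nm <- length(model$muscles)
  ntor <- length(model$torque_actuators)
  qd_lim <- ifelse(grepl("_t[xyz]$", model$dof_index), 15, 40)
  # activations and excitations are bounded away from zero (0.01): the
  # exact-zero corner is degenerate (flat cubed-excitation gradient and a
  # bound that idle muscles ride exactly)
  list(x_lb = c(q_lb, -qd_lim, rep(1e-3, nm), rep(0.01, nm)),
       x_ub = c(q_ub, qd_lim, rep(0.6, nm), rep(1, nm)),
       u_lb = c(rep(0.01, nm), rep(-5, ntor)),
       u_ub = c(rep(1, nm), rep(5, ntor)))
}

#' State and control vector layout
#'
#' The state vector is `x = (q, qdot, s, a)` and the control vector is
#' `u = (n_e, m)`: generalized coordinates and their rates, the projected CE
#' length and activation of every muscle, neural excitations, and the
#' normalized torso actuator torques.
#'
#' @param model a `runopt_model`
#' @return list with counts `n_dof`, `n_mus`, `n_tor`, `n_x`, `n_u` and
#'   index vectors `iq`, `iqd`, `is`, `ia` into `x` and `ine`, `im` into `u`
#' @export
state_control_layout <- function(model) {
  nd <- length(model$dof_index)
  nm <- length(model$muscles)
  nt <- length(model$torque_actuators)
  list(n_dof = nd, n_mus = nm, n_tor = nt,
       n_x = 2 * nd + 2 * nm, n_u = nm + nt,
       iq = seq_len(nd), iqd = nd + seq_len(nd),
       is = 2 * nd + seq_len(nm), ia = 2 * nd + nm + seq_len(nm),
       ine = seq_len(nm), im = nm + seq_len(nt))
}

#' Pack and unpack state/control vectors
#'
#' @param model a `runopt_model`
#' @param q,qd,s,a components of the state vector
#' @return `pack_state` returns the flat state vector; `unpack_state` the
#'   named component list.
#' @export
pack_state <- function(model, q, qd, s, a) {
  lay <- state_control_layout(model)
  stopifnot(length(q) == lay$n_dof, length(qd) == lay$n_dof,
            length(s) == lay$n_mus, length(a) == lay$n_mus)
  c(q, qd, s, a)
}

#' @rdname pack_state
#' @param x flat state vector
#' @export
unpack_state <- function(model, x) {
  lay <- state_control_layout(model)
  stopifnot(length(x) == lay$n_x)
  list(q = x[lay$iq], qd = x[lay$iqd], s = x[lay$is], a = x[lay$ia])
}

#' @rdname pack_state
#' @param n_e neural excitations
#' @param m normalized actuator torques
#' @export
pack_control <- function(model, n_e, m) {
  lay <- state_control_layout(model)
  stopifnot(length(n_e) == lay$n_mus, length(m) == lay$n_tor)
  c(n_e, m)
}

#' @rdname pack_state
#' @param u flat control vector
#' @export
unpack_control <- function(model, u) {
  lay <- state_control_layout(model)
  stopifnot(length(u) == lay$n_u)
  list(n_e = u[lay$ine], m = u[lay$im])
}

#' Validate a model definition
#'
#' Checks every structural invariant of the model definition -- positive
#' masses, symmetric positive semi-definite inertia tensors, unique segment
#' names, tree-structured joints, ordered bounds, unit revolute axes, and
#' that torque actuators and muscle paths reference existing DOFs. Reports
#' violations instead of throwing.
#'
#' @param model a `runopt_model`
#' @return character vector of violation messages; empty if the model is
#'   usable
#' @export
validate_model <- function(model) {
  bad <- character(0)
  segnames <- vapply(model$segments, `[[`, "", "name")
  if (anyDuplicated(segnames))
    bad <- c(bad, "duplicate segment names")
  for (s in model$segments) {
    if (!is.numeric(s$mass) || s$mass <= 0)
      bad <- c(bad, sprintf("segment '%s': mass must be positive", s$name))
    I <- s$inertia
    if (!isTRUE(all.equal(I, t(I), tolerance = 1e-8))) {
      bad <- c(bad, sprintf("segment '%s': inertia not symmetric", s$name))
    } else if (min(eigen(I, symmetric = TRUE,
                         only.values = TRUE)$values) < -1e-10) {
      bad <- c(bad, sprintf("segment '%s': inertia not positive semi-definite",
                            s$name))
    }
  }
  children <- vapply(model$joints, `[[`, "", "child")
  if (anyDuplicated(children))
    bad <- c(bad, "a segment has more than one parent joint")
  roots <- sum(vapply(model$joints, function(j) j$parent == "ground",
                      logical(1)))
  if (roots != 1)
    bad <- c(bad, sprintf("expected exactly one root joint, found %d", roots))
  for (j in model$joints) {
    if (j$parent != "ground" && !(j$parent %in% segnames))
      bad <- c(bad, sprintf("joint '%s': unknown parent segment '%s'",
                            j$name, j$parent))
    if (!(j$child %in% segnames))
      bad <- c(bad, sprintf("joint '%s': unknown child segment '%s'",
                            j$name, j$child))
    if (j$type == "revolute1" &&
        abs(sqrt(sum(j$axis^2)) - 1) > 1e-8)
      bad <- c(bad, sprintf("joint '%s': revolute axis not unit norm",
                            j$name))
    for (dn in j$dof_names) {
      b <- j$dof_bounds[[dn]]
      if (is.null(b) || b[1] > b[2])
        bad <- c(bad, sprintf("DOF '%s': missing or unordered bounds", dn))
    }
  }
  ndof_sum <- sum(vapply(model$joints, function(j) joint_ndof(j$type),
                         integer(1)))
  if (ndof_sum != length(model$dof_index))
    bad <- c(bad, "dof_index length does not match the joint DOF count")
  for (ta in model$torque_actuators) {
    if (!(ta$dof %in% model$dof_index))
      bad <- c(bad, sprintf("torque actuator references unknown DOF '%s'",
                            ta$dof))
  }
  for (mus in model$muscles) {
    unknown <- setdiff(mus$path$dof_names, model$dof_index)
    for (d in unknown)
      bad <- c(bad, sprintf("muscle '%s' references unknown DOF '%s'",
                            mus$name, d))
    pos <- c(mus$F_ISO, mus$l_CE_opt, mus$l_slack, mus$W, mus$v_max,
             mus$A_hill, mus$T_act, mus$T_deact, mus$eps0_SEE, mus$k_PEE)
    if (any(!is.finite(pos)) || any(pos <= 0))
      bad <- c(bad, sprintf("muscle '%s': non-positive parameter", mus$name))
    if (mus$T_act > mus$T_deact)
      bad <- c(bad, sprintf("muscle '%s': T_act exceeds T_deact", mus$name))
  }
  bad
}

# ---------------------------------------------------------------------------
# Compilation of the model definition into the flat elementary-joint chain
# consumed by the C++ dynamics core. free6 expands into 3 prismatic + 3
# revolute elementary bodies, ball3 into 3 revolutes (intrinsic rotations);
# segment mass properties sit on the last elementary body of each joint.
# ---------------------------------------------------------------------------
compile_model <- function(model) {
  cache <- attr(model, "cdata_env")
  if (!is.null(cache) && !is.null(cache$cdata)) return(cache$cdata)
  seg_by_name <- setNames(model$segments,
                          vapply(model$segments, `[[`, "", "name"))
  parent <- integer(0); jtype <- integer(0)
  axis <- numeric(0); offset <- numeric(0)
  mass <- numeric(0); com <- numeric(0); inertia <- numeric(0)
  body_of_seg <- c(ground = -1L)
  add_body <- function(p, type, ax, off, seg = NULL) {
    parent[length(parent) + 1L] <<- p
    jtype[length(jtype) + 1L] <<- type
    axis <<- c(axis, ax)
    offset <<- c(offset, off)
    if (is.null(seg)) {
      mass <<- c(mass, 0); com <<- c(com, c(0, 0, 0))
      inertia <<- c(inertia, rep(0, 9))
    } else {
      mass <<- c(mass, seg$mass); com <<- c(com, seg$com_offset)
      inertia <<- c(inertia, as.numeric(t(seg$inertia)))
    }
    length(parent) - 1L
  }
  for (j in model$joints) {
    p <- body_of_seg[[j$parent]]
    seg <- seg_by_name[[j$child]]
    if (j$type == "free6") {
      for (k in 1:3) {
        p <- add_body(p, 0L, axis_vec(c("x", "y", "z")[k]),
                      if (k == 1) j$translation else c(0, 0, 0))
      }
      ro <- j$rotation_order
      for (k in 1:3) {
        p <- add_body(p, 1L, axis_vec(ro[k]), c(0, 0, 0),
                      seg = if (k == 3) seg)
      }
    } else if (j$type == "ball3") {
      ro <- j$rotation_order
      for (k in 1:3) {
        p <- add_body(p, 1L, axis_vec(ro[k]),
                      if (k == 1) j$translation else c(0, 0, 0),
                      seg = if (k == 3) seg)
      }
    } else {
      p <- add_body(p, 1L, j$axis / sqrt(sum(j$axis^2)), j$translation,
                    seg = seg)
    }
    body_of_seg[[j$child]] <- p
  }
  # contact points
  cp_body <- integer(0); cp_foot <- integer(0); cp_local <- numeric(0)
  for (s in model$segments) {
    if (length(s$contact_points) == 0) next
    b <- body_of_seg[[s$name]]
    side <- if (grepl("_l$", s$name)) 1L else 0L
    for (cp in s$contact_points) {
      cp_body <- c(cp_body, b); cp_foot <- c(cp_foot, side)
      cp_local <- c(cp_local, cp)
    }
  }
  # muscles
  dof_pos <- setNames(seq_along(model$dof_index) - 1L, model$dof_index)
  mus_par <- matrix(0, length(model$muscles), 13)
  term_mus <- integer(0); term_coef <- numeric(0); term_nd <- integer(0)
  term_dof <- integer(0); term_pow <- integer(0)
  for (i in seq_along(model$muscles)) {
    mu <- model$muscles[[i]]
    mus_par[i, ] <- c(mu$F_ISO, mu$l_CE_opt, mu$l_slack, mu$W, mu$v_max,
                      mu$A_hill, mu$f_ecc, mu$phi_opt, mu$T_act, mu$T_deact,
                      mu$eps0_SEE, mu$k_PEE, mu$d_CE)
    for (tm in mu$path$terms) {
      term_mus <- c(term_mus, i - 1L)
      term_coef <- c(term_coef, tm$coef)
      term_nd <- c(term_nd, length(tm$dofs))
      if (length(tm$dofs) > 0) {
        term_dof <- c(term_dof, dof_pos[tm$dofs])
        term_pow <- c(term_pow, as.integer(tm$powers))
      }
    }
  }
  tor_dof <- vapply(model$torque_actuators,
                    function(ta) dof_pos[[ta$dof]], integer(1))
  cpar <- model$contact_par
  cdata <- list(parent = parent, jtype = jtype, axis = axis, offset = offset,
                mass = mass, com = com, inertia = inertia,
                cp_body = cp_body, cp_foot = cp_foot, cp_local = cp_local,
                mus_par = mus_par, term_mus = term_mus,
                term_coef = term_coef, term_nd = term_nd,
                term_dof = term_dof, term_pow = term_pow,
                tor_dof = tor_dof,
                tor_scale = if (length(model$torque_actuators))
                  model$torque_actuators[[1]]$scale else 10,
                dof_damp = if (is.null(model$joint_damping))
                  rep(0, length(model$dof_index)) else
                    as.numeric(model$joint_damping),
                gravity = model$gravity,
                mb_scale = model$subject_mass * 9.81,
                act_scale = 0.01,
                contact_par = c(cpar$k_n, cpar$c_n, cpar$mu, cpar$v_c,
                                cpar$eps_p, cpar$f_eps),
                pelvis_idx = c(0L, 1L, 2L, 3L))
  env <- new.env(parent = emptyenv())
  env$cdata <- cdata
  attr(model, "cdata_env") <- env
  cdata
}

# compiled data with per-session caching keyed on the model object
.cdata <- local({
  memo <- new.env(parent = emptyenv())
  function(model) {
    key <- attr(model, "cdata_key")
    if (is.null(key)) {
      return(compile_model(model))
    }
    if (is.null(memo[[key]])) memo[[key]] <- compile_model(model)
    memo[[key]]
  }
})

#' Write and read a model definition file
#'
#' Serializes the full model definition (segments, joints, muscles, torque
#' actuators, contact parameters, bounds) as a structured YAML document, and
#' reads it back. Inertia tensors are stored row-wise.
#'
#' @param model a `runopt_model`
#' @param path file path
#' @return `read_model_yaml` returns the restored `runopt_model`
#' @export
write_model_yaml <- function(model, path) {
  ser <- unclass(model)
  ser$segments <- lapply(ser$segments, function(s) {
    s$inertia <- as.numeric(t(s$inertia))
    s
  })
  yaml::write_yaml(ser, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  ser <- yaml::read_yaml(path)
  ser$segments <- lapply(ser$segments, function(s) {
    s$inertia <- matrix(as.numeric(s$inertia), 3, 3, byrow = TRUE)
    s$com_offset <- as.numeric(s$com_offset)
    s$contact_points <- lapply(s$contact_points, as.numeric)
    s
  })
  ser$joints <- lapply(ser$joints, function(j) {
    j$translation <- as.numeric(j$translation)
    if (!is.null(j$axis)) j$axis <- as.numeric(j$axis)
    j$dof_bounds <- lapply(j$dof_bounds, as.numeric)
    j
  })
  ser$gravity <- as.numeric(ser$gravity)
  ser$bounds <- lapply(ser$bounds, as.numeric)
  structure(ser, class = "runopt_model")
}

#' @export
print.runopt_model <- function(x, ...) {
  lay <- state_control_layout(x)
  cat(sprintf(paste0("<runopt_model> %d segments, %d DOFs, %d muscles, ",
                     "%d torque actuators\n"),
              length(x$segments), lay$n_dof, lay$n_mus, lay$n_tor))
  cat(sprintf("  subject: %.1f kg, %.2f m; n_x = %d, n_u = %d\n",
              x$subject_mass, x$subject_height, lay$n_x, lay$n_u))
  invisible(x)
}
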