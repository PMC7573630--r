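# shared fixtures: tiny oracle models and one cached reduced runner

runner_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_reduced_runner(92, 1.95)
    m
  }
})

# uniform rod of length L pinned at one end, swinging about z; the angle is
# measured from the downward vertical, so qdd = -(3 g / 2 L) sin(q)
pendulum_model <- function(L = 1, mass = 1) {
  m <- list(
    segments = list(rod = list(
      name = "rod", mass = mass,
      inertia = diag(c(mass * L^2 / 12, 1e-10, mass * L^2 / 12)),
      com_offset = c(0, -L / 2, 0), contact_points = list())),
    joints = list(list(
      name = "pin", parent = "ground", child = "rod", type = "revolute1",
      translation = c(0, 0, 0), axis = c(0, 0, 1), dof_names = "pin_angle",
      dof_bounds = list(pin_angle = c(-10, 10)))),
    dof_index = "pin_angle", muscles = list(), torque_actuators = list(),
    contact_par = contact_defaults(), gravity = c(0, -9.81, 0),
    subject_mass = mass, subject_height = L)
  class(m) <- "runopt_model"
  m$bounds <- runopt3d:::default_bounds(m)
  m
}

# passive double pendulum (two rods, revolute z joints), for energy checks
double_pendulum_model <- function() {
  rod_seg <- function(name, mass, L) {
    list(name = name, mass = mass,
         inertia = diag(c(mass * L^2 / 12, 1e-10, mass * L^2 / 12)),
         com_offset = c(0, -L / 2, 0), contact_points = list())
  }
  m <- list(
    segments = list(upper = rod_seg("upper", 1.2, 0.8),
                    lower = rod_seg("lower", 0.7, 0.6)),
    joints = list(
      list(name = "shoulder", parent = "ground", child = "upper",
           type = "revolute1", translation = c(0, 0, 0), axis = c(0, 0, 1),
           dof_names = "q1", dof_bounds = list(q1 = c(-10, 10))),
      list(name = "elbow", parent = "upper", child = "lower",
           type = "revolute1", translation = c(0, -0.8, 0), axis = c(0, 0, 1),
           dof_names = "q2", dof_bounds = list(q2 = c(-10, 10)))),
    dof_index = c("q1", "q2"), muscles = list(), torque_actuators = list(),
    contact_par = contact_defaults(), gravity = c(0, -9.81, 0),
    subject_mass = 1.9, subject_height = 1.4)
  class(m) <- "runopt_model"
  m$bounds <- runopt3d:::default_bounds(m)
  m
}

# a random feasible-ish state/control for the runner
random_runner_point <- function(model, seed = 1, airborne = FALSE) {
  lay <- state_control_layout(model)
  set.seed(seed)
  x <- runif(lay$n_x, -0.2, 0.2)
  x[2] <- if (airborne) 5 else 1.0
  x[lay$is] <- runif(lay$n_mus, 0.05, 0.15)
  x[lay$ia] <- runif(lay$n_mus, 0.1, 0.9)
  xd <- runif(lay$n_x, -0.3, 0.3)
  u <- runif(lay$n_u)
  u[lay$im] <- runif(lay$n_tor, -1, 1)
  list(x = x, xd = xd, u = u, lay = lay)
}
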