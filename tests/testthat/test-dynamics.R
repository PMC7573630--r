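test_that("forward kinematics: neutral pose, translation and heading", {
  m <- runner_model()
  nd <- length(m$dof_index)
  q0 <- rep(0, nd)
  fk <- forward_kinematics(m, q0)
  # neutral pose: every segment frame axis-aligned
  for (s in fk$segments) expect_equal(s$rot, diag(3), tolerance = 1e-12)
  # heel point: chain of fixed translations only
  hip_y <- -0.035 * 1.95
  heel_y <- hip_y - (0.245 + 0.246) * 1.95 - 0.039 * 1.95
  expect_equal(fk$contact_points$pos[1, 2], heel_y, tolerance = 1e-9)

  # translating the pelvis shifts every point rigidly
  q1 <- q0; q1[1] <- 1
  fk1 <- forward_kinematics(m, q1)
  expect_equal(fk1$contact_points$pos,
               fk$contact_points$pos + rep(c(1, 0, 0), each = 4),
               tolerance = 1e-12)

  # heading pi/2 about +y maps +x offsets to -z
  q2 <- q0; q2[4] <- pi / 2
  fk2 <- forward_kinematics(m, q2)
  toe_r0 <- fk$contact_points$pos[2, ]
  toe_r2 <- fk2$contact_points$pos[2, ]
  expect_equal(toe_r2[1], toe_r0[3], tolerance = 1e-9)
  expect_equal(toe_r2[3], -toe_r0[1], tolerance = 1e-9)
  expect_equal(toe_r2[2], toe_r0[2], tolerance = 1e-12)
})

test_that("point velocities match finite differences of positions", {
  m <- runner_model()
  nd <- length(m$dof_index)
  set.seed(11)
  q <- runif(nd, -0.3, 0.3); q[2] <- 1
  qd <- runif(nd, -1, 1)
  h <- 1e-7
  fkp <- forward_kinematics(m, q + h * qd)
  fkm <- forward_kinematics(m, q - h * qd)
  fk <- forward_kinematics(m, q, qd)
  fd <- (fkp$contact_points$pos - fkm$contact_points$pos) / (2 * h)
  expect_equal(fk$contact_points$vel, fd, tolerance = 1e-6)
})

test_that("forward kinematics rejects NaN coordinates by name", {
  m <- runner_model()
  q <- rep(0, 21); q[13] <- NaN
  expect_error(forward_kinematics(m, q), "knee_flexion_r")
})

test_that("rod pendulum closed form is reproduced to 1e-10", {
  pend <- pendulum_model(L = 1, mass = 1)
  g <- 9.81
  for (q in seq(-3, 3, length.out = 13)) {
    qdd <- -(3 * g / 2) * sin(q)
    expect_lt(abs(multibody_residual(pend, q, 0, qdd)), 1e-10)
  }
  # with a generalized torque: M qdd = tau at qdd = 0, q = pi/2
  tau_hold <- 1 * g * 0.5  # m g L/2 holds the rod horizontal
  expect_lt(abs(multibody_residual(pend, pi / 2, 0, 0, tau_hold)), 1e-10)
})

test_that("free fall: gravity on root translations, zero elsewhere", {
  m <- runner_model()
  nd <- 21
  q <- rep(0, nd); q[2] <- 5  # airborne
  qdd <- rep(0, nd); qdd[2] <- -9.81
  res <- multibody_residual(m, q, rep(0, nd), qdd)
  expect_lt(max(abs(res)), 1e-9)
})

test_that("multibody residual is affine in qdd", {
  m <- runner_model()
  set.seed(5)
  q <- runif(21, -0.3, 0.3); qd <- runif(21, -1, 1)
  qdd1 <- runif(21); qdd2 <- runif(21)
  r <- function(qdd) multibody_residual(m, q, qd, qdd)
  expect_equal(r(qdd1 + qdd2) - r(qdd1) - r(qdd2) + r(rep(0, 21)),
               rep(0, 21), tolerance = 1e-8)
})

test_that("passive mechanical energy is conserved along the dynamics", {
  m <- double_pendulum_model()
  set.seed(21)
  for (rep in 1:3) {
    q <- runif(2, -1.5, 1.5)
    qd <- runif(2, -2, 2)
    # solve qdd from residual = 0 via the affine structure
    r0 <- multibody_residual(m, q, qd, c(0, 0))
    M <- cbind(multibody_residual(m, q, qd, c(1, 0)) - r0,
               multibody_residual(m, q, qd, c(0, 1)) - r0)
    qdd <- solve(M, -r0)
    h <- 1e-6
    ep <- runopt3d:::mechanical_energy(m, q + h * qd, qd + h * qdd)
    em <- runopt3d:::mechanical_energy(m, q - h * qd, qd - h * qdd)
    dE <- (ep - em) / (2 * h)
    expect_lt(abs(dE), 1e-5 * max(1, abs(ep)))
  }
})

test_that("stacked residual: steady activation and layout errors", {
  m <- runner_model()
  p <- random_runner_point(m, seed = 9)
  lay <- p$lay
  # a = n_e, adot = 0 makes the activation rows vanish
  x <- p$x; xd <- p$xd; u <- p$u
  u[lay$ine] <- x[lay$ia]
  xd[lay$ia] <- 0
  f <- full_dynamics_residual(m, x, xd, u)$f
  expect_equal(f[lay$ia], rep(0, lay$n_mus), tolerance = 1e-12)
  expect_error(full_dynamics_residual(m, x[-1], xd, u), "layout")
})

test_that("residual Jacobians match central finite differences", {
  m <- runner_model()
  set.seed(123)
  worst <- 0
  for (rep in 1:3) {
    p <- random_runner_point(m, seed = 100 + rep)
    J <- residual_jacobians(m, p$x, p$xd, p$u)
    h <- 1e-6
    cols_x <- sample(p$lay$n_x, 15)
    for (j in cols_x) {
      xp <- p$x; xm <- p$x
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      fd <- (full_dynamics_residual(m, xp, p$xd, p$u)$f -
               full_dynamics_residual(m, xm, p$xd, p$u)$f) / (2 * h)
      worst <- max(worst, max(abs(fd - J$Jx[, j]) /
                                pmax(1, abs(J$Jx[, j]))))
    }
    for (j in sample(p$lay$n_x, 10)) {
      xp <- p$xd; xm <- p$xd
      xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
      fd <- (full_dynamics_residual(m, p$x, xp, p$u)$f -
               full_dynamics_residual(m, p$x, xm, p$u)$f) / (2 * h)
      worst <- max(worst, max(abs(fd - J$Jxd[, j]) /
                                pmax(1, abs(J$Jxd[, j]))))
    }
    for (j in sample(p$lay$n_u, 8)) {
      up <- p$u; um <- p$u
      up[j] <- up[j] + h; um[j] <- um[j] - h
      fd <- (full_dynamics_residual(m, p$x, p$xd, up)$f -
               full_dynamics_residual(m, p$x, p$xd, um)$f) / (2 * h)
      worst <- max(worst, max(abs(fd - J$Ju[, j]) /
                                pmax(1, abs(J$Ju[, j]))))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("Jacobian structure: identity blocks and fixed sparsity", {
  m <- runner_model()
  lay <- state_control_layout(m)
  pat <- runopt3d:::jacobian_pattern(m)
  for (rep in 1:10) {
    p <- random_runner_point(m, seed = 200 + rep)
    J <- residual_jacobians(m, p$x, p$xd, p$u)
    # kinematic identity rows of df/dxdot
    expect_equal(as.matrix(J$Jxd[lay$iq, lay$iq]), diag(lay$n_dof),
                 tolerance = 1e-12)
    # activation rows of df/du: nonzero diagonal in n_e
    dact <- diag(as.matrix(J$Ju[lay$ia, lay$ine]))
    expect_true(all(dact != 0))
    # every nonzero lies inside the fixed structural pattern
    expect_true(all(as.matrix(J$Jx != 0) <= (pat$Jx > 0)))
    expect_true(all(as.matrix(J$Jxd != 0) <= (pat$Jxd > 0)))
    expect_true(all(as.matrix(J$Ju != 0) <= (pat$Ju > 0)))
  }
})
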