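test_that("central angle: endpoints, worked value, monotonicity", {
  expect_equal(central_angle(0, 0.7, 3.7)$theta, 0)
  expect_equal(central_angle(2, 3.7, 3.7)$theta, pi)  # chord = diameter
  expect_equal(central_angle(2.7, 0.74, 3.7)$theta,
               2 * asin(2.7 * 0.74 / (2 * 3.7)), tolerance = 1e-12)
  expect_equal(central_angle(2.7, 0.74, 3.7)$theta, 0.5468, tolerance = 1e-3)
  expect_error(central_angle(3, 3, 3.7), "infeasible")
  # monotone increasing in T; small-T limit theta ~ v T / r
  ths <- vapply(seq(0.1, 1, 0.1),
                function(T) central_angle(2.7, T, 3.7)$theta, numeric(1))
  expect_true(all(diff(ths) > 0))
  Tsmall <- 1e-3
  expect_equal(central_angle(2.7, Tsmall, 3.7)$theta, 2.7 * Tsmall / 3.7,
               tolerance = 1e-6)
  # analytic derivative vs finite difference
  h <- 1e-7
  fd <- (central_angle(2.7, 0.74 + h, 3.7)$theta -
           central_angle(2.7, 0.74 - h, 3.7)$theta) / (2 * h)
  expect_equal(central_angle(2.7, 0.74, 3.7)$dtheta_dT, fd,
               tolerance = 1e-6)
})

test_that("periodicity residual: straight translation and curved rotation", {
  m <- runner_model()
  lay <- state_control_layout(m)
  set.seed(55)
  x0 <- runif(lay$n_x)
  u0 <- runif(lay$n_u)
  T_sim <- 0.7

  # straight: pure translation of the pelvis position
  task_s <- task_spec(m, "straight", v_x = 4, v_z = 0.5)
  x_end <- x0
  x_end[1] <- x_end[1] + 4 * T_sim
  x_end[3] <- x_end[3] + 0.5 * T_sim
  r <- periodicity_residual(m, task_s, x0, x_end, u0, u0, T_sim)
  expect_equal(max(abs(r)), 0, tolerance = 1e-12)

  # identity: theta = 0 with zero translation
  task_0 <- task_spec(m, "straight", v_x = 0, v_z = 0)
  expect_equal(periodicity_residual(m, task_0, x0, x0, u0, u0, T_sim),
               rep(0, lay$n_x + lay$n_u))

  # curved quarter circle: start (-3.7, 0.95, 0) heading 0 maps to
  # (0, 0.95, 3.7) heading pi/2
  r_c <- 3.7
  task_c <- task_spec(m, "curved", v_norm = 2.7, radius = r_c)
  T_quarter <- 2 * r_c * sin(pi / 4) / 2.7  # theta = pi/2 by Eq. geometry
  expect_equal(central_angle(2.7, T_quarter, r_c)$theta, pi / 2,
               tolerance = 1e-12)
  x0q <- x0
  x0q[1] <- -3.7; x0q[2] <- 0.95; x0q[3] <- 0; x0q[4] <- 0
  img <- runopt3d:::periodic_image_r(m, task_c, x0q, T_quarter)
  expect_equal(img[1:4], c(0, 0.95, 3.7, pi / 2), tolerance = 1e-9)
  # pelvis global velocity pair rotates with the map
  iv <- lay$n_dof + c(1, 3)
  expect_equal(img[iv],
               c(x0q[iv[1]] * cos(pi / 2) + x0q[iv[2]] * sin(pi / 2),
                 -x0q[iv[1]] * sin(pi / 2) + x0q[iv[2]] * cos(pi / 2)),
               tolerance = 1e-9)
  # C++ and R images agree
  img_c <- runopt3d:::cpp_periodic_image(runopt3d:::.cdata(m), x0q,
                                         T_quarter,
                                         runopt3d:::task_vec(task_c))
  expect_equal(as.numeric(img_c), img, tolerance = 1e-12)
})

test_that("solver recovers a convex QP and flags bad bounds", {
  # min (z1-1)^2 + (z2-2)^2 + z3^2  s.t.  z1 + z2 + z3 = 2
  # optimum: z = (1,2,0) - lambda/2 * (1,1,1) with lambda = 2/3
  nlp <- list(n_var = 3, lb = rep(-10, 3), ub = rep(10, 3), n_con = 1,
              iT = 3,
              obj = function(z, want_grad = TRUE) {
                v <- (z[1] - 1)^2 + (z[2] - 2)^2 + z[3]^2
                out <- list(value = v)
                if (want_grad)
                  out$grad <- c(2 * (z[1] - 1), 2 * (z[2] - 2), 2 * z[3])
                out
              },
              con = function(z) sum(z) - 2,
              con_gradmul = function(z, w) rep(w, 3),
              con_jac = function(z)
                Matrix::Matrix(1, 1, 3, sparse = TRUE),
              obj_hess = function(z) Matrix::Diagonal(3, 2),
              split_z = function(z)
                list(X = matrix(z[1], 1, 1), U = matrix(z[2], 1, 1),
                     T_sim = z[3]),
              task = list(kind = "qp"))
  class(nlp) <- "runopt_nlp"
  sol <- solve_nlp(nlp, c(5, -3, 2),
                   settings = solver_settings(max_outer = 25, tol = 1e-10))
  z_star <- c(1, 2, 0) - (1 / 3) * c(1, 1, 1)
  expect_true(sol$converged)
  expect_equal(sol$z, z_star, tolerance = 1e-6, ignore_attr = TRUE)

  nlp_bad <- nlp
  nlp_bad$lb <- c(5, 5, 5); nlp_bad$ub <- c(-5, -5, -5)
  expect_error(solve_nlp(nlp_bad, c(0, 0, 0)), "infeasible bounds")
})

test_that("backward-Euler defect: scalar ODE step solves x1 = x0/(1+h)", {
  # xdot = lambda x with lambda = -1, h = 0.1: the implicit step satisfies
  # x1 - x0 = h * lambda * x1  =>  x1 = x0 / 1.1
  lam <- -1; h <- 0.1; x0 <- 1
  defect <- function(x1) (x1 - x0) / h - lam * x1
  x1 <- uniroot(defect, c(0, 2), tol = 1e-12)$root
  expect_equal(x1, 1 / 1.1, tolerance = 1e-10)
  # the same relation through the solver on a 2-variable NLP
  nlp <- list(n_var = 2, lb = c(1, -10), ub = c(1, 10), n_con = 1, iT = 2,
              obj = function(z, want_grad = TRUE) {
                out <- list(value = 0)
                if (want_grad) out$grad <- c(0, 0)
                out
              },
              con = function(z) (z[2] - z[1]) / h - lam * z[2],
              con_gradmul = function(z, w)
                w * c(-1 / h, 1 / h - lam),
              con_jac = function(z)
                Matrix::Matrix(c(-1 / h, 1 / h - lam), 1, 2, sparse = TRUE),
              split_z = function(z)
                list(X = matrix(z, 2, 1), U = matrix(0, 0, 1), T_sim = NA),
              task = list(kind = "ode"))
  class(nlp) <- "runopt_nlp"
  sol <- solve_nlp(nlp, c(1, 1))
  expect_equal(sol$z[2], 1 / 1.1, tolerance = 1e-6)
})

test_that("assembled NLP: structure, defect consistency, derivatives", {
  m <- runner_model()
  N <- 3
  task <- task_spec(m, "straight", v_x = 4, N = N)
  cyc <- synth_reference(m, speed = 4, n_cycles = 3, seed = 2)
  ref <- cycles_to_reference(cyc, N = N)
  nlp <- assemble_nlp(m, task, ref)
  lay <- state_control_layout(m)
  expect_equal(nlp$n_var, N * (lay$n_x + lay$n_u) + 1)
  expect_equal(nlp$n_con, N * lay$n_x)
  # anchors: first-node pelvis tx/tz fixed at zero
  expect_equal(nlp$lb[1], 0)
  expect_equal(nlp$ub[1], 0)
  expect_equal(nlp$lb[3], 0)
  expect_equal(nlp$ub[3], 0)

  # defect rows equal the node residual with backward-difference rates
  set.seed(66)
  X <- matrix(runif(lay$n_x * N, -0.1, 0.1), lay$n_x, N)
  X[2, ] <- 1
  X[lay$is, ] <- runif(lay$n_mus * N, 0.05, 0.2)
  X[lay$ia, ] <- runif(lay$n_mus * N, 0.1, 0.9)
  U <- matrix(runif(lay$n_u * N), lay$n_u, N)
  T_sim <- 0.6
  z <- c(as.numeric(X), as.numeric(U), T_sim)
  cv <- nlp$con(z)
  h <- T_sim / N
  # first defect block couples nodes 1 and 2 with the controls of node 2
  f2 <- full_dynamics_residual(m, X[, 2], (X[, 2] - X[, 1]) / h, U[, 2])$f
  expect_equal(cv[seq_len(lay$n_x)], f2, tolerance = 1e-12)
  # wrap block uses the periodicity image of node 1 and controls of node 1
  x_wrap <- runopt3d:::periodic_image_r(m, task, X[, 1], T_sim)
  f_wrap <- full_dynamics_residual(m, x_wrap, (x_wrap - X[, N]) / h,
                                   U[, 1])$f
  expect_equal(cv[(N - 1) * lay$n_x + seq_len(lay$n_x)], f_wrap,
               tolerance = 1e-12)

  # constraint Jacobian against finite differences (random columns)
  J <- nlp$con_jac(z)
  set.seed(10)
  worst <- 0
  for (j in sample(nlp$n_var, 25)) {
    hd <- 1e-6
    zp <- z; zm <- z
    zp[j] <- zp[j] + hd; zm[j] <- zm[j] - hd
    fd <- (nlp$con(zp) - nlp$con(zm)) / (2 * hd)
    worst <- max(worst, max(abs(fd - J[, j])) / max(1, max(abs(J[, j]))))
  }
  expect_lt(worst, 1e-5)

  # standing problem: a single node with xdot = 0 and no periodicity rows
  task_st <- task_spec(m, "standing")
  nlp_st <- assemble_nlp(m, task_st)
  expect_equal(nlp_st$n_con, lay$n_x)
  z_st <- c(X[, 1], U[, 1], 1)
  expect_equal(nlp_st$con(z_st),
               full_dynamics_residual(m, X[, 1], rep(0, lay$n_x), U[, 1])$f,
               tolerance = 1e-12)

  # a running task without a reference is rejected
  expect_error(assemble_nlp(m, task, ref = NULL), "reference")
})

test_that("check_derivatives reports clean gradients and flags corruption", {
  m <- runner_model()
  N <- 4  # smallest grid on which every GRF signal keeps nonzero variance
  task <- task_spec(m, "straight", v_x = 4, N = N)
  ref <- cycles_to_reference(synth_reference(m, n_cycles = 3, seed = 4),
                             N = N)
  nlp <- assemble_nlp(m, task, ref)
  lay <- state_control_layout(m)
  set.seed(77)
  X <- matrix(runif(lay$n_x * N, -0.1, 0.1), lay$n_x, N)
  X[1, 1] <- 0; X[3, 1] <- 0; X[2, ] <- 1
  X[lay$is, ] <- runif(lay$n_mus * N, 0.05, 0.2)
  X[lay$ia, ] <- runif(lay$n_mus * N, 0.1, 0.9)
  U <- matrix(runif(lay$n_u * N), lay$n_u, N)
  z <- c(as.numeric(X), as.numeric(U), 0.7)
  rep <- check_derivatives(nlp, z, n_dirs = 20, seed = 5)
  expect_lt(rep$max_rel_error_grad, 1e-5)
  expect_lt(rep$max_rel_error_jac, 1e-5)

  # fault injection: a corrupted gradient is flagged at the right index
  nlp_bad <- nlp
  true_obj <- nlp$obj
  bad_idx <- 5
  bump <- 100 * max(abs(nlp$obj(z, TRUE)$grad), 1)
  nlp_bad$obj <- function(z, want_grad = TRUE) {
    o <- true_obj(z, want_grad)
    if (want_grad) o$grad[bad_idx] <- o$grad[bad_idx] + bump
    o
  }
  rep_bad <- check_derivatives(nlp_bad, z, n_dirs = nlp$n_var, seed = 5)
  expect_gt(rep_bad$max_rel_error_grad, 1e-2)
  expect_equal(rep_bad$grad_index, bad_idx)
})
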