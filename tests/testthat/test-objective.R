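test_that("variance flooring at 10 percent of the mean variance", {
  expect_equal(adjust_variance(sqrt(c(0, 1, 2))), c(0.1, 1, 2))
  expect_equal(adjust_variance(c(1, 1, 1)), c(1, 1, 1))
  expect_error(adjust_variance(c(0, 0, 0)), "all-zero")
  # swing-phase-like profile: min adjusted variance = 10% of mean variance
  sd_prof <- c(rep(0, 30), seq(50, 250, length.out = 20))
  v <- adjust_variance(sd_prof)
  expect_equal(min(v), 0.1 * mean(sd_prof^2))
})

test_that("signal weights balance angle and GRF groups and sum to one", {
  w <- signal_weights(10, 6, 1, 5)
  expect_equal(w$angle, 1 / 40)
  expect_equal(w$grf, 5 / 40)
  expect_equal(10 * w$angle + 6 * w$grf, 1)
  w0 <- signal_weights(8, 0, 1, 5)
  expect_equal(w0$angle, 1 / 8)
  we <- signal_weights(4, 4, 2, 2)
  expect_equal(we$angle, we$grf)
  expect_equal(we$angle, 1 / 8)
  expect_error(signal_weights(0, 0), "zero")
})

test_that("tracking cost: zero at the mean, one at one SD, linear in w", {
  N <- 50
  mu <- matrix(sin(2 * pi * (1:N) / N), N, 3)
  sdm <- matrix(c(0.5, 1, 2), N, 3, byrow = TRUE)
  varm <- apply(sdm, 2, adjust_variance)
  w <- c(0.2, 0.3, 0.5)
  expect_equal(tracking_cost(mu, mu, varm, w), 0)
  expect_equal(tracking_cost(mu + sdm, mu, varm, w), 1)
  expect_equal(tracking_cost(mu + sdm, mu, varm, 2 * w), 2)
  expect_error(tracking_cost(mu[1:10, ], mu, varm, w), "mismatch")
})

test_that("effort cost: worked value, zero input, volume invariance", {
  musc <- list(list(F_ISO = 1000, l_CE_opt = 0.1),
               list(F_ISO = 500, l_CE_opt = 0.2))
  ne <- matrix(0.5, 10, 2)
  expect_equal(effort_cost(ne, musc, v_ref = c(2, 0)), 0.125 / (2 * 8))
  expect_equal(effort_cost(matrix(0, 10, 2), musc, c(2, 0)), 0)
  musc10 <- lapply(musc, function(m) {
    m$F_ISO <- 10 * m$F_ISO
    m
  })
  expect_equal(effort_cost(ne, musc10, c(2, 0)),
               effort_cost(ne, musc, c(2, 0)))
  # standing: zero speed uses divisor one
  expect_equal(effort_cost(ne, musc, c(0, 0)), 0.125 / 2)
})

test_that("torque cost: worked value and symmetry", {
  mt <- matrix(0.5, 20, 3)
  expect_equal(torque_cost(mt), 0.25)
  expect_equal(torque_cost(-mt), 0.25)
  expect_equal(torque_cost(matrix(0, 20, 3)), 0)
  expect_equal(torque_cost(matrix(numeric(0), 20, 0)), 0)
})

test_that("regularization cost: backward differences with periodic wrap", {
  N <- 50; T_sim <- 1
  xk <- sin(2 * pi * (0:(N - 1)) / N)
  X <- rbind(xk, matrix(1, 3, N))  # one moving state, three constant
  U <- matrix(0.5, 2, N)
  J <- regularization_cost(X, U, T_sim)
  dif <- diff(c(xk, xk[1]))
  expect_equal(J, sum(dif^2) * N / T_sim^2 / (nrow(X) + nrow(U)))
  expect_equal(regularization_cost(matrix(1, 4, N), U, T_sim), 0)
  # halving T quadruples the derivative penalty
  expect_equal(regularization_cost(X, U, T_sim / 2), 4 * J)
})

test_that("total objective decomposes and matches finite differences", {
  m <- runner_model()
  task <- task_spec(m, "straight", v_x = 4, N = 8)
  cyc <- synth_reference(m, speed = 4, n_cycles = 4, seed = 3)
  ref <- cycles_to_reference(cyc, N = 8)
  lay <- state_control_layout(m)
  set.seed(44)
  X <- matrix(runif(lay$n_x * 8, -0.2, 0.2), lay$n_x, 8)
  X[2, ] <- 1.15  # light foot-ground contact keeps the cost well-scaled
  X[lay$is, ] <- runif(lay$n_mus * 8, 0.05, 0.2)
  X[lay$ia, ] <- runif(lay$n_mus * 8, 0.1, 0.9)
  U <- matrix(runif(lay$n_u * 8), lay$n_u, 8)
  T_sim <- 0.7
  o <- total_objective(m, task, ref, X, U, T_sim)
  expect_true(all(o$terms >= 0))
  W <- task$weights
  expect_equal(o$value, W$W_track * o$terms["track"] +
                 W$W_mus * o$terms["mus"] + W$W_tor * o$terms["tor"] +
                 W$W_reg * o$terms["reg"], ignore_attr = TRUE)

  # with only the tracking weight the value reduces to tracking_cost
  task_tr <- task_spec(m, "straight", v_x = 4, N = 8,
                       weights = list(W_mus = 0, W_tor = 0, W_reg = 0))
  tr <- runopt3d:::prepare_tracking(m, task_tr, ref)
  y <- cbind(t(X[tr$ang_rows, ]), t(solution_grf(m, list(X = X))[tr$grf_idx, ]))
  o_tr <- total_objective(m, task_tr, ref, X, U, T_sim)
  expect_equal(o_tr$value, tracking_cost(y, tr$mu, tr$var, tr$w))

  # gradient vs central differences on a random subset
  h <- 1e-6
  worst <- 0
  set.seed(9)
  for (j in sample(lay$n_x * 8, 12)) {
    Xp <- X; Xm <- X
    Xp[j] <- Xp[j] + h; Xm[j] <- Xm[j] - h
    fd <- (total_objective(m, task, ref, Xp, U, T_sim)$value -
             total_objective(m, task, ref, Xm, U, T_sim)$value) / (2 * h)
    worst <- max(worst, abs(fd - o$gX[j]) / max(1, abs(fd)))
  }
  for (j in sample(lay$n_u * 8, 8)) {
    Up <- U; Um <- U
    Up[j] <- Up[j] + h; Um[j] <- Um[j] - h
    fd <- (total_objective(m, task, ref, X, Up, T_sim)$value -
             total_objective(m, task, ref, X, Um, T_sim)$value) / (2 * h)
    worst <- max(worst, abs(fd - o$gU[j]) / max(1, abs(fd)))
  }
  fdT <- (total_objective(m, task, ref, X, U, T_sim + h)$value -
            total_objective(m, task, ref, X, U, T_sim - h)$value) / (2 * h)
  worst <- max(worst, abs(fdT - o$gT) / max(1, abs(fdT)))
  expect_lt(worst, 1e-5)

  # zero weights give a zero objective and gradient
  task0 <- task_spec(m, "straight", N = 8,
                     weights = list(W_track = 0, W_mus = 0, W_tor = 0,
                                    W_reg = 0))
  o0 <- total_objective(m, task0, ref, X, U, T_sim)
  expect_equal(o0$value, 0)
  expect_equal(max(abs(o0$gX)), 0)
})

test_that("tracking cost is invariant to signal reordering", {
  N <- 20
  set.seed(8)
  y <- matrix(rnorm(N * 4), N, 4)
  mu <- matrix(rnorm(N * 4), N, 4)
  varm <- matrix(runif(N * 4, 0.5, 2), N, 4)
  w <- c(0.1, 0.2, 0.3, 0.4)
  perm <- c(3, 1, 4, 2)
  expect_equal(tracking_cost(y[, perm], mu[, perm], varm[, perm], w[perm]),
               tracking_cost(y, mu, varm, w))
})

test_that("quadrature consistency: N = 50 vs N = 200 differ by O(1/N)", {
  f <- function(N) {
    tk <- (0:(N - 1)) / N
    y <- matrix(sin(2 * pi * tk), N, 1)
    mu <- matrix(0, N, 1)
    varm <- matrix(1, N, 1)
    tracking_cost(y, mu, varm, 1)
  }
  # exact integral of sin^2 over one period is 1/2
  expect_lt(abs(f(50) - 0.5), 1 / 50)
  expect_lt(abs(f(200) - 0.5), 1 / 200)
  expect_lt(abs(f(200) - 0.5), abs(f(50) - 0.5) + 1e-12)
})
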