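mus_par <- function(...) {
  modifyList(c(list(F_ISO = 1000, l_CE_opt = 0.1, l_slack = 0.2),
               muscle_defaults()),
             list(...))
}

test_that("path polynomial geometry: lengths and moment arms", {
  p1 <- path_polynomial("q_knee", list(
    list(coef = 0.4, dofs = character(0), powers = integer(0)),
    list(coef = -0.05, dofs = "q_knee", powers = 1L)))
  g <- mtu_geometry(p1, c(q_knee = 0))
  expect_equal(g$l_mtu, 0.4)
  expect_equal(unname(g$moment_arms), 0.05)

  pconst <- path_polynomial("q", list(
    list(coef = 0.3, dofs = character(0), powers = integer(0))))
  g2 <- mtu_geometry(pconst, c(q = 1.3))
  expect_equal(g2$l_mtu, 0.3)
  expect_equal(unname(g2$moment_arms), 0)

  pq <- path_polynomial("q", list(
    list(coef = 0.4, dofs = character(0), powers = integer(0)),
    list(coef = -0.05, dofs = "q", powers = 1L),
    list(coef = 0.01, dofs = "q", powers = 2L)))
  g3 <- mtu_geometry(pq, c(q = 0.5))
  expect_equal(g3$l_mtu, 0.4 - 0.05 * 0.5 + 0.01 * 0.25)
  expect_equal(unname(g3$moment_arms), -(-0.05 + 0.02 * 0.5))
})

test_that("moment arms equal -dl/dq by central differences", {
  m <- runner_model()
  cd <- runopt3d:::.cdata(m)
  set.seed(31)
  q <- runif(21, -0.5, 0.5)
  out <- runopt3d:::cpp_mus_geometry(cd, q)
  nm <- 18
  arms <- matrix(out[-(1:nm)], nrow = 21)
  h <- 1e-6
  for (im in seq_len(nm)) {
    for (j in 1:21) {
      qp <- q; qm <- q
      qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      lp <- runopt3d:::cpp_mus_geometry(cd, qp)[im]
      lm <- runopt3d:::cpp_mus_geometry(cd, qm)[im]
      expect_equal(arms[j, im], -(lp - lm) / (2 * h), tolerance = 1e-6)
    }
  }
})

test_that("path fitting recovers polynomial coefficients exactly", {
  qs <- seq(-1, 1, length.out = 15)
  samples <- lapply(qs, function(q)
    list(q = c(kq = q), l_mtu = 0.4 - 0.05 * q))
  fit <- fit_path_polynomial(samples, "kq", max_degree = 2)
  g <- mtu_geometry(fit, c(kq = 0.3))
  expect_equal(g$l_mtu, 0.4 - 0.05 * 0.3, tolerance = 1e-8)
  expect_lt(attr(fit, "rms_residual"), 1e-10)

  # degree-3 over two DOFs
  f3 <- function(a, b) 0.35 + 0.02 * a - 0.04 * b + 0.01 * a * b^2
  grid <- expand.grid(a = seq(-1, 1, 0.25), b = seq(-1, 1, 0.25))
  samples3 <- lapply(seq_len(nrow(grid)), function(i)
    list(q = c(a = grid$a[i], b = grid$b[i]),
         l_mtu = f3(grid$a[i], grid$b[i])))
  fit3 <- fit_path_polynomial(samples3, c("a", "b"), max_degree = 3)
  for (pt in list(c(0.5, -0.7), c(-0.2, 0.9))) {
    expect_equal(mtu_geometry(fit3, c(a = pt[1], b = pt[2]))$l_mtu,
                 f3(pt[1], pt[2]), tolerance = 1e-8)
  }

  expect_error(fit_path_polynomial(samples3[1:2], c("a", "b"),
                                   max_degree = 2),
               "samples")
})

test_that("isometric Hill equilibrium at optimal length gives F_ISO", {
  p <- mus_par(phi_opt = 0)
  l_mtu <- p$l_CE_opt + p$l_slack * (1 + p$eps0_SEE)
  r <- contraction_residual(p, a = 1, s = p$l_CE_opt, sd = 0, l_mtu = l_mtu)
  expect_equal(r$F_SEE, p$F_ISO, tolerance = 1e-10)
  expect_equal(r$residual, 0, tolerance = 1e-8)
})

test_that("slack tendon at rest gives zero residual", {
  p <- mus_par(phi_opt = 0)
  r <- contraction_residual(p, a = 0, s = 0.9 * p$l_CE_opt, sd = 0,
                            l_mtu = 0.9 * p$l_CE_opt + 0.9 * p$l_slack)
  expect_equal(r$residual, 0, tolerance = 1e-12)
  expect_equal(r$F_SEE, 0)
})

test_that("force-velocity endpoints: f_V(-v_max) = 0, f_V(0) = 1", {
  p <- mus_par(phi_opt = 0)
  l_mtu <- p$l_CE_opt + p$l_slack * (1 + p$eps0_SEE)
  # shortening at v_max: active force vanishes, residual = F_SEE - damping
  sd_vmax <- -p$v_max * p$l_CE_opt
  r <- contraction_residual(p, a = 1, s = p$l_CE_opt, sd = sd_vmax,
                            l_mtu = l_mtu)
  f_damp <- p$d_CE * p$F_ISO * (-p$v_max)
  expect_equal(r$residual, r$F_SEE - f_damp, tolerance = 1e-8)
})

test_that("contraction residual is monotone in sdot and singularity-free", {
  p <- mus_par(phi_opt = 1.4)  # extreme pennation geometry
  l_mtu <- p$l_CE_opt + p$l_slack * 1.02
  sds <- seq(-1.5, 1.5, length.out = 41)
  res <- vapply(sds, function(sd)
    contraction_residual(p, 0.5, 0.05, sd, l_mtu)$residual, numeric(1))
  expect_true(all(is.finite(res)))
  expect_true(all(diff(res) < 0))  # strictly decreasing in sdot
  # finite for tiny s (pennation angle near pi/2)
  r2 <- contraction_residual(p, 0.5, 1e-6, 0.3, l_mtu)
  expect_true(is.finite(r2$residual))
  expect_error(contraction_residual(p, 0.5, -0.01, 0, l_mtu), "positive")
})

test_that("activation residual steady states and pure rates", {
  p <- mus_par()
  expect_equal(activation_residual(p, a = 0.3, ad = 0, n_e = 0.3), 0)
  expect_equal(activation_residual(p, a = 0, ad = 1 / p$T_act, n_e = 1), 0)
  expect_equal(activation_residual(p, a = 1, ad = -1 / p$T_deact, n_e = 0),
               0)
})

test_that("R and C++ muscle paths agree inside the stacked residual", {
  m <- runner_model()
  p <- random_runner_point(m, seed = 77)
  lay <- p$lay
  f <- full_dynamics_residual(m, p$x, p$xd, p$u)$f
  for (im in c(1, 5, 9, 12, 18)) {
    mus <- m$muscles[[im]]
    qn <- setNames(p$x[lay$iq], m$dof_index)
    lm <- mtu_geometry(mus$path, qn)$l_mtu
    r <- contraction_residual(mus, p$x[lay$ia[im]], p$x[lay$is[im]],
                              p$xd[lay$is[im]], lm)
    expect_equal(f[lay$is[im]], r$residual / mus$F_ISO, tolerance = 1e-10)
    ar <- activation_residual(mus, p$x[lay$ia[im]], p$xd[lay$ia[im]],
                              p$u[lay$ine[im]])
    expect_equal(f[lay$ia[im]], ar * 0.01, tolerance = 1e-10)
  }
})
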