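test_that("synthetic reference is deterministic and noise-controlled", {
  m <- runner_model()
  a <- synth_reference(m, speed = 4, n_cycles = 4, seed = 9)
  b <- synth_reference(m, speed = 4, n_cycles = 4, seed = 9)
  expect_identical(a, b)
  cc <- synth_reference(m, speed = 4, n_cycles = 4, seed = 10)
  expect_false(identical(a, cc))
  # zero noise: every cycle follows the template; after resampling the
  # cycles of different lengths, only interpolation error remains in the SD
  z <- synth_reference(m, speed = 4, n_cycles = 3, seed = 1,
                       noise_sd_angle = 0, noise_grf_frac = 0)
  ref <- cycles_to_reference(z, N = 40)
  expect_lt(max(ref$sd[, ref$kinds == "angle"]), 1e-3)
  expect_error(synth_reference(m, n_cycles = 1), "2 cycles")
})

test_that("vertical impulse balance: mean total vertical GRF = weight", {
  m <- runner_model()  # 92 kg -> 902.5 N
  cyc <- synth_reference(m, speed = 4, n_cycles = 12, seed = 1)
  ref <- cycles_to_reference(cyc, N = 50)
  fy <- ref$mean[, ref$names %in% c("grf_r_y", "grf_l_y")]
  total <- mean(rowSums(fy))
  expect_equal(total, 92 * 9.81, tolerance = 0.01 * 92 * 9.81)
})

test_that("cycle averaging: sample SD definition and resampling rule", {
  cyc <- structure(list(
    cycles = list(list(sig = rep(1, 100)), list(sig = rep(3, 60))),
    names = "sig", kinds = "angle", cadence = 0.7),
    class = "runopt_cycles")
  ref <- cycles_to_reference(cyc, N = 50)
  expect_equal(nrow(ref$mean), 50)
  expect_equal(unname(ref$mean[, 1]), rep(2, 50))
  expect_equal(unname(ref$sd[, 1]), rep(sqrt(2), 50))
  expect_error(cycles_to_reference(structure(list(cycles = list()),
                                             class = "runopt_cycles")),
               "empty")
})

test_that("cycle averaging commutes with signal reordering", {
  m <- runner_model()
  cyc <- synth_reference(m, speed = 4, n_cycles = 3, seed = 5)
  ref <- cycles_to_reference(cyc, N = 20)
  perm <- rev(seq_along(cyc$names))
  cyc2 <- cyc
  cyc2$names <- cyc$names[perm]
  cyc2$kinds <- cyc$kinds[perm]
  ref2 <- cycles_to_reference(cyc2, N = 20)
  expect_equal(ref2$mean[, match(cyc$names, cyc2$names)], ref$mean,
               ignore_attr = TRUE)
})

test_that("synthetic reference is periodic within the noise level", {
  m <- runner_model()
  cyc <- synth_reference(m, speed = 4, n_cycles = 12, seed = 2)
  ref <- cycles_to_reference(cyc, N = 50)
  ang <- which(ref$kinds == "angle")
  gap <- abs(ref$mean[1, ang] - ref$mean[50, ang])
  # first and last sample of the resampled mean nearly close the cycle
  expect_lt(max(gap), 0.12)
})

test_that("motion files round-trip and convert degrees", {
  m <- runner_model()
  N <- 50
  tk <- seq(0, 0.98, length.out = N)
  df <- data.frame(time = tk,
                   hip_flexion_r = sin(tk),
                   grf_r_y = 800 * abs(sin(10 * tk)))
  path <- tempfile(fileext = ".sto")
  write_motion(df, path, name = "testmotion")
  back <- read_motion(path)
  expect_equal(attr(back, "motion_name"), "testmotion")
  expect_lt(max(abs(as.matrix(back) - as.matrix(df))), 1e-10)

  # inDegrees=yes: angles convert to radians on read, forces do not
  path2 <- tempfile(fileext = ".mot")
  write_motion(df, path2, in_degrees = TRUE)
  back2 <- read_motion(path2)
  expect_equal(back2$hip_flexion_r, df$hip_flexion_r, tolerance = 1e-10)
  expect_equal(back2$grf_r_y, df$grf_r_y, tolerance = 1e-10)

  # malformed header: missing endheader reported with position
  path3 <- tempfile()
  writeLines(c("name", "nRows=2", "time\tx", "0\t1", "1\t2"), path3)
  expect_error(read_motion(path3), "endheader")

  # time must increase; duplicate names rejected
  expect_error(write_motion(data.frame(time = c(0, 0), x = 1:2),
                            tempfile()),
               "increasing")
  unlink(c(path, path2, path3))
})

test_that("solution motion export uses the node grid", {
  m <- runner_model()
  lay <- state_control_layout(m)
  sol <- structure(list(X = matrix(0.1, lay$n_x, 10),
                        U = matrix(0, lay$n_u, 10), T_sim = 0.8,
                        task = list(kind = "straight")),
                   class = "runopt_solution")
  sol$X[1, ] <- seq(0, 3.6, length.out = 10)
  path <- tempfile(fileext = ".sto")
  write_solution_motion(m, sol, path)
  back <- read_motion(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$time, (0:9) / 10 * 0.8, tolerance = 1e-10)
  expect_equal(back$pelvis_tx, sol$X[1, ], tolerance = 1e-10)
  unlink(path)
})
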