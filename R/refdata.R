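# Synthetic tracking references with gait-like structure, cycle averaging
# (mean and SD of repeated cycles resampled to the collocation grid), and a
# columnar motion-storage file dialect (.sto/.mot compatible).

# periodic gait templates for the reduced runner; phase in [0, 1), right
# heel strike at phase 0, left leg shifted by half a cycle. Joint-angle
# curves are periodic splines through running-typical keypoints so that
# the stance foot is near the ground over the stance window and the swing
# foot clears it.
periodic_template <- function(phases, values) {
  force(phases); force(values)
  function(p) {
    spline(c(phases, phases[1] + 1), c(values, values[1]),
           method = "periodic", xout = p %% 1)$y
  }
}

gait_templates <- function(duty = 0.35) {
  ang <- list(
    hip_flexion = periodic_template(
      c(0, 0.18, 0.35, 0.55, 0.75, 0.9),
      c(0.52, 0.15, -0.17, 0.30, 0.79, 0.66)),
    hip_adduction = function(p) 0.06 * cos(2 * pi * p) + 0.02,
    hip_rotation = function(p) 0.04 * sin(2 * pi * p + 1),
    knee_flexion = periodic_template(
      c(0, 0.12, 0.25, 0.35, 0.5, 0.65, 0.8, 0.92),
      c(0.35, 0.75, 0.55, 0.45, 1.10, 1.60, 0.80, 0.40)),
    ankle_dorsiflexion = periodic_template(
      c(0, 0.1, 0.25, 0.35, 0.5, 0.7, 0.85),
      c(0.00, 0.22, 0.12, -0.25, 0.05, 0.12, 0.05)),
    subtalar = function(p) 0.06 * sin(2 * pi * p + 0.5)
  )
  trunk <- list(
    pelvis_rot = function(p) 0.05 * sin(2 * pi * p),
    pelvis_list = function(p) 0.04 * sin(2 * pi * p + 2),
    pelvis_tilt = function(p) 0.10 + 0.02 * sin(4 * pi * p),
    torso_tilt = function(p) 0.08 + 0.03 * sin(4 * pi * p),
    torso_list = function(p) 0.03 * sin(2 * pi * p),
    torso_rot = function(p) 0.06 * cos(2 * pi * p)
  )
  # vertical GRF: smooth single hump over the stance window, scaled so the
  # cycle-average vertical force of each leg is half body weight
  grf <- function(p, bw, side_sign) {
    stance <- p < duty
    ps <- ifelse(stance, p / duty, 0)
    fy <- ifelse(stance, (bw / duty) * sin(pi * ps)^2, 0)
    fx <- ifelse(stance, -0.2 * (bw / duty) * sin(2 * pi * ps), 0)
    fz <- side_sign * 0.05 * fy
    cbind(fx, fy, fz)
  }
  list(ang = ang, trunk = trunk, grf = grf, duty = duty)
}

# smooth unit-variance periodic noise from a few random harmonics
smooth_noise <- function(phase, n_harm = 3) {
  w <- rnorm(2 * n_harm)
  y <- 0
  for (h in seq_len(n_harm)) {
    y <- y + w[2 * h - 1] * cos(2 * pi * h * phase) +
      w[2 * h] * sin(2 * pi * h * phase)
  }
  y / sqrt(n_harm)
}

#' Generate a synthetic gait-cycle set
#'
#' Emulates the structure of cycle-extracted running data: `n_cycles`
#' noisy realizations of periodic joint-angle and GRF templates, right heel
#' strike at phase zero, left leg phase-shifted by half a cycle, stance
#' duty factor ~35 percent, vertical GRF scaled so the two legs' cycle
#' average vertical force equals body weight, biphasic
#' braking/propulsion fore-aft GRFs, and seeded smooth cycle-to-cycle
#' variation (about 2 degrees SD on angles, 5 percent on GRF amplitude).
#' Cycle lengths vary slightly to exercise resampling.
#'
#' @param model a `runopt_model` (for body weight and DOF names)
#' @param speed forward running speed (m/s), sets the cadence
#' @param n_cycles number of gait cycles (>= 2; the reference is their
#'   mean and SD)
#' @param seed RNG seed; the output is byte-identical for equal seeds
#' @param noise_sd_angle cycle-to-cycle SD of joint angles (rad)
#' @param noise_grf_frac relative SD of the GRF amplitude per cycle
#' @param duty stance duty factor
#' @param cadence optional cycle duration (s); default `1.4 / sqrt(speed)`
#' @return a `runopt_cycles` list: `cycles` (per cycle: named list of
#'   signal trajectories), `names`, `kinds`, `cadence`
#' @export
synth_reference <- function(model, speed = 4.0, n_cycles = 12, seed = 1,
                            noise_sd_angle = 2 * pi / 180,
                            noise_grf_frac = 0.05, duty = 0.35,
                            cadence = NULL) {
  if (n_cycles < 2) stop("need at least 2 cycles to define an SD")
  set.seed(seed)
  if (is.null(cadence)) cadence <- 1.4 / sqrt(speed)
  bw <- model$subject_mass * 9.81
  tpl <- gait_templates(duty)
  sig_names <- c(names(tpl$trunk),
                 paste0(rep(names(tpl$ang), each = 2), c("_r", "_l")),
                 c("grf_r_x", "grf_r_y", "grf_r_z",
                   "grf_l_x", "grf_l_y", "grf_l_z"))
  kinds <- ifelse(grepl("^grf_", sig_names), "GRF", "angle")
  cycles <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    M <- 90 + (cyc * 7) %% 21  # deterministic slight length variation
    p <- (seq_len(M) - 1) / M
    sig <- list()
    for (nm in names(tpl$trunk)) {
      sig[[nm]] <- tpl$trunk[[nm]](p) + noise_sd_angle * smooth_noise(p)
    }
    for (nm in names(tpl$ang)) {
      sig[[paste0(nm, "_r")]] <- tpl$ang[[nm]](p) +
        noise_sd_angle * smooth_noise(p)
      sig[[paste0(nm, "_l")]] <- tpl$ang[[nm]]((p + 0.5) %% 1) +
        noise_sd_angle * smooth_noise(p)
    }
    amp_r <- 1 + noise_grf_frac * rnorm(1)
    amp_l <- 1 + noise_grf_frac * rnorm(1)
    gr <- tpl$grf(p, bw, +1) * amp_r
    gl <- tpl$grf((p + 0.5) %% 1, bw, -1) * amp_l
    sig$grf_r_x <- gr[, 1]; sig$grf_r_y <- gr[, 2]; sig$grf_r_z <- gr[, 3]
    sig$grf_l_x <- gl[, 1]; sig$grf_l_y <- gl[, 2]; sig$grf_l_z <- gl[, 3]
    cycles[[cyc]] <- sig
  }
  structure(list(cycles = cycles, names = sig_names, kinds = kinds,
                 cadence = cadence),
            class = "runopt_cycles")
}

#' Average gait cycles into a tracking reference
#'
#' Linearly resamples every cycle of every signal to `N` samples (phases
#' `0, 1/N, ..., (N-1)/N` of the cycle) and computes the per-sample mean
#' and standard deviation (n-1 denominator) across cycles.
#'
#' @param cycles a `runopt_cycles` set
#' @param N number of samples (the collocation node count)
#' @return a `runopt_reference`: `names`, `kinds`, `mean` and `sd`
#'   (N x n_signals matrices), `cadence`
#' @export
cycles_to_reference <- function(cycles, N = 50) {
  if (length(cycles$cycles) == 0) stop("empty gait-cycle set")
  stopifnot(N >= 2)
  ph <- (seq_len(N) - 1) / N
  ns <- length(cycles$names)
  arr <- array(NA_real_, c(N, ns, length(cycles$cycles)))
  for (ci in seq_along(cycles$cycles)) {
    cyc <- cycles$cycles[[ci]]
    for (si in seq_len(ns)) {
      y <- cyc[[cycles$names[si]]]
      M <- length(y)
      # periodic padding so phases up to (N-1)/N interpolate cleanly
      py <- c(y, y[1])
      px <- c((seq_len(M) - 1) / M, 1)
      arr[, si, ci] <- approx(px, py, xout = ph)$y
    }
  }
  structure(list(names = cycles$names, kinds = cycles$kinds,
                 mean = apply(arr, c(1, 2), mean),
                 sd = apply(arr, c(1, 2), sd),
                 cadence = cycles$cadence),
            class = "runopt_reference")
}

#' Write a columnar motion-storage file
#'
#' Header lines (`name`, `nRows`, `nColumns`, `inDegrees`, `endheader`)
#' followed by a tab-separated numeric table whose first column is time in
#' seconds; compatible with the common motion-storage dialect.
#'
#' @param data data frame with a strictly increasing `time` column
#' @param path output path
#' @param name motion name written in the header
#' @param in_degrees write (and flag) angle columns in degrees
#' @return the path, invisibly
#' @export
write_motion <- function(data, path, name = "motion", in_degrees = FALSE) {
  stopifnot(is.data.frame(data), "time" %in% names(data))
  if (any(diff(data$time) <= 0)) stop("time must be strictly increasing")
  if (anyDuplicated(names(data))) stop("column names must be unique")
  out <- data
  if (in_degrees) {
    ang <- angle_columns(names(out))
    out[ang] <- out[ang] * 180 / pi
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name,
               sprintf("nRows=%d", nrow(out)),
               sprintf("nColumns=%d", ncol(out)),
               sprintf("inDegrees=%s", if (in_degrees) "yes" else "no"),
               "endheader",
               paste(names(out), collapse = "\t")), con)
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# angle columns: everything that is neither time, a force/GRF signal, nor
# a translation coordinate
angle_columns <- function(nms) {
  setdiff(nms,
          c("time", grep("^grf_|force|_f[xyz]$|_t[xyz]$", nms, value = TRUE)))
}

#' Read a columnar motion-storage file
#'
#' Parses the header and table written by [write_motion()] (and compatible
#' files); if the header flags `inDegrees=yes`, angle columns are converted
#' to radians on read.
#'
#' @param path file path
#' @return data frame with attribute `motion_name`
#' @export
read_motion <- function(path) {
  lines <- readLines(path)
  end <- match("endheader", trimws(lines))
  if (is.na(end))
    stop("malformed motion file: no 'endheader' line found in the first ",
         length(lines), " lines of ", path)
  hdr <- lines[seq_len(end - 1)]
  in_deg <- any(grepl("^\\s*inDegrees\\s*=\\s*yes", hdr, ignore.case = TRUE))
  cols <- strsplit(trimws(lines[end + 1]), "\t")[[1]]
  if (length(cols) < 1 || cols[1] != "time")
    stop("malformed motion file: expected a 'time' column at line ", end + 1)
  body <- lines[-(seq_len(end + 1))]
  body <- body[nzchar(trimws(body))]
  dat <- utils::read.table(text = body, sep = "\t", col.names = cols,
                           check.names = FALSE)
  if (in_deg) {
    ang <- angle_columns(cols)
    dat[ang] <- dat[ang] * pi / 180
  }
  nm <- if (end >= 2) trimws(lines[1]) else "motion"
  attr(dat, "motion_name") <- nm
  dat
}

#' Write a solution's coordinate trajectories as a motion file
#'
#' @param model a `runopt_model`
#' @param sol a `runopt_solution`
#' @param path output path
#' @param in_degrees write angles in degrees
#' @return the path, invisibly
#' @export
write_solution_motion <- function(model, sol, path, in_degrees = FALSE) {
  lay <- state_control_layout(model)
  N <- ncol(sol$X)
  tk <- (seq_len(N) - 1) / N * sol$T_sim
  q <- t(sol$X[lay$iq, , drop = FALSE])
  colnames(q) <- model$dof_index
  df <- data.frame(time = tk, q, check.names = FALSE)
  write_motion(df, path, name = paste0(sol$task$kind, "_solution"),
               in_degrees = in_degrees)
}
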