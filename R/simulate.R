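# Raw-stream generators for the synthetic cohort.
#
# Generators are parameterised directly in feature space where possible
# (choice probabilities, watch fractions, questionnaire endorsement); the
# signal-level motor generator is driven through Monte-Carlo-fitted inverse
# maps (see profiles.R). Low-frequency "wander" noise is built from
# sinusoids at harmonics of the trial window so its displacement power is
# (nearly) deterministic per trial and stays out of the 0.2-5 Hz analysis
# band.

#' Simulation configuration
#'
#' @param n_per_group named integer vector of group sizes (default the
#'   40/48/43 three-group field cohort).
#' @param seed master seed; split deterministically per (child, task) so that
#'   adding a task never perturbs the other streams.
#' @param battery a [start_config()].
#' @param sex_f_prop per-group probability of sex `"F"` (defaults matching
#'   the field cohort's 19:21 / 12:36 / 9:34 ratios).
#' @return list of class `start_sim_config`.
#' @export
sim_config <- function(n_per_group = c(TD = 40, AS = 48, ID = 43), seed = 1L,
                       battery = start_config(),
                       sex_f_prop = c(TD = 19 / 40, AS = 12 / 48, ID = 9 / 43)) {
  stopifnot(all(GROUP_LEVELS %in% names(n_per_group)), all(n_per_group >= 2))
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 battery = battery, sex_f_prop = sex_f_prop),
            class = "start_sim_config")
}

#' Simulate a preferential-looking gaze stream
#'
#' Frame labels are drawn independently with the requested marginal
#' probabilities: a frame is `undetected` with probability `p_undetected`,
#' otherwise `off_tablet` with probability `p_offscreen`, otherwise
#' `elsewhere_on_tablet` with probability `p_elsewhere`, otherwise on one of
#' the two stimuli (`social_side` with probability `p_social`). The social
#' fraction among on-stimulus frames converges to `p_social`.
#'
#' @param p_social probability of the social side among on-stimulus frames.
#' @param duration_s stream duration in seconds.
#' @param fps frame rate (Hz).
#' @param p_offscreen,p_undetected,p_elsewhere marginal probabilities.
#' @param seed integer seed.
#' @return A gaze-frame data frame (`t_ms`, `eye_detected`, `gaze`).
#' @export
simulate_gaze_stream <- function(p_social, duration_s, fps = 20,
                                 p_offscreen = 0.05, p_undetected = 0.1,
                                 p_elsewhere = 0.05, seed = 1L) {
  stopifnot(all(c(p_social, p_offscreen, p_undetected, p_elsewhere) >= 0),
            all(c(p_social, p_offscreen, p_undetected, p_elsewhere) <= 1))
  n <- max(1L, round(duration_s * fps))
  with_seed(seed, function() {
    u_det <- stats::runif(n) >= p_undetected
    u_on <- stats::runif(n) >= p_offscreen
    u_stim <- stats::runif(n) >= p_elsewhere
    u_soc <- stats::runif(n) < p_social
    gaze <- rep("undetected", n)
    gaze[u_det & !u_on] <- "off_tablet"
    gaze[u_det & u_on & !u_stim] <- "elsewhere_on_tablet"
    gaze[u_det & u_on & u_stim] <- ifelse(u_soc[u_det & u_on & u_stim],
                                          "social_side", "nonsocial_side")
    data.frame(t_ms = as.integer(round((seq_len(n) - 1) * 1000 / fps)),
               eye_detected = u_det, gaze = gaze, stringsAsFactors = FALSE)
  })
}

#' Generate a butterfly target trajectory
#'
#' A piecewise-smooth path sweeping across the screen with variable speed:
#' the speed profile interpolates random control speeds inside
#' `velocity_range` plus a bounded in-band speed oscillation, and the heading
#' combines a slow vertical meander with a faint in-band ripple. With a
#' degenerate range (`vmin == vmax`) the path is a straight horizontal line
#' of length speed x duration. Speed knots are lowered uniformly when needed
#' so the sweep fits the screen width.
#'
#' @param duration_s trial duration (s).
#' @param velocity_range c(vmin, vmax) speed bounds in px/s.
#' @param seed integer seed.
#' @param direction +1 left-to-right, -1 right-to-left.
#' @param config battery configuration (screen size, frame rate).
#' @return Data frame `t_ms`, `x_px`, `y_px`.
#' @export
generate_butterfly_trajectory <- function(duration_s = 30,
                                          velocity_range = c(45, 105),
                                          seed = 1L, direction = 1,
                                          config = start_config()) {
  vmin <- velocity_range[1]; vmax <- velocity_range[2]
  if (vmin < 0 || vmax < vmin) stopf("degenerate velocity range")
  vr <- vmax - vmin
  fps <- config$fps
  W <- config$screen_px[1]; H <- config$screen_px[2]
  n <- round(duration_s * fps) + 1
  t <- (seq_len(n) - 1) / fps
  with_seed(seed, function() {
    nk <- 7
    knots <- stats::runif(nk, vmin + 0.3 * vr, vmax - 0.3 * vr)
    kt <- seq(0, duration_s, length.out = nk)
    # cosine interpolation keeps the profile within the knot hull
    base <- stats::approx(kt, knots, xout = t, method = "linear")$y
    seg <- findInterval(t, kt, all.inside = TRUE)
    frac <- (t - kt[seg]) / diff(kt)[1]
    cw <- (1 - cos(pi * frac)) / 2
    base <- knots[seg] * (1 - cw) + knots[seg + 1] * cw
    aw <- 0.10 * vr
    f_s <- 0.33   # fixed in-band speed-modulation frequency
    speed <- base + aw * sin(2 * pi * f_s * t + stats::runif(1, 0, 2 * pi))
    th_slow <- if (vr > 0) 0.05 else 0
    th_band <- if (vr > 0) 0.018 else 0
    f_slow <- 1 / duration_s   # window-harmonic: spectrally out of band
    f_band <- 0.26   # fixed: keeps the in-band reference content stable
    theta <- th_slow * sin(2 * pi * f_slow * t + stats::runif(1, 0, 2 * pi)) +
      th_band * sin(2 * pi * f_band * t + stats::runif(1, 0, 2 * pi))
    # shrink speeds uniformly (never below the range) if the sweep overflows
    margin <- 80
    extent <- sum(speed * cos(theta)) / fps
    avail <- W - 2 * margin
    if (extent > avail) {
      delta <- (extent - avail) / duration_s
      speed <- pmax(speed - delta, vmin)
    }
    vx <- direction * speed * cos(theta)
    vy <- speed * sin(theta)
    x0 <- if (direction > 0) margin else W - margin
    x <- x0 + c(0, cumsum(vx[-n])) / fps
    y <- H / 2 + c(0, cumsum(vy[-n])) / fps
    data.frame(t_ms = as.integer(round(t * 1000)),
               x_px = clamp(x, 0, W), y_px = clamp(y, 0, H))
  })
}

# Path-compression factor of the motor deviation model: the fraction of the
# target path the child actually covers at deviation scale s.
motor_gamma <- function(s) 1 - pmin(7e-4 * s, 0.85)

# Slow tracking deviation for one axis: zero-phase sinusoids at harmonics
# m/T (m = 1..3) of the trial window with random signs, plus an optional
# constant offset. Window-periodic harmonics and constants are (with the
# endpoint detrend and periodic Hann window of the spectral analysis)
# invisible inside the 0.2-5 Hz band, vanish at the trial ends (where the
# target sits near the screen edges), have near-deterministic displacement
# power, and negligible third differences - so the deviation scale drives
# RMSE without touching the frequency gains or jerk.
deviation_component <- function(t_s, dc, a1, a23, T_s) {
  out <- rep(dc * sample(c(-1, 1), 1), length(t_s)) +
    a1 * sample(c(-1, 1), 1) * sin(2 * pi * t_s / T_s)
  for (m in 2:3) {
    out <- out + a23 * sample(c(-1, 1), 1) * sin(2 * pi * m * t_s / T_s)
  }
  out
}

#' Simulate one motor-following touch trial
#'
#' The touch stream is the target delayed by `lag_ms` plus a temporally
#' smooth tracking deviation of overall scale `noise_sd_px`, composed of a
#' trailing delay (the finger following the same path seconds behind the
#' target), a sustained vertical offset, and slow screen-bounded sinusoidal
#' wander below the 0.2 Hz analysis band. Optional in-band tremor sinusoids,
#' a high-frequency (above-band) micro-tremor and white jitter can be added
#' on top. Expected RMSE increases monotonically with both lag and
#' `noise_sd_px`.
#'
#' @param target a target trajectory (see
#'   [generate_butterfly_trajectory()]).
#' @param lag_ms tracking delay (ms, >= 0).
#' @param noise_sd_px deviation scale (px, >= 0).
#' @param seed integer seed.
#' @param tremor_x,tremor_y `c(amplitude_px, frequency_hz)` in-band tremor.
#' @param hf_tremor `c(amplitude_px, frequency_hz)` micro-tremor above the
#'   analysis band (drives jerk without touching the band).
#' @param jitter_sd white per-sample jitter sd (px).
#' @param config battery configuration.
#' @return A motor trial: `list(target, touch)`.
#' @export
simulate_motor_trial <- function(target, lag_ms = 0, noise_sd_px = 0, seed = 1L,
                                 tremor_x = c(0, 0.45), tremor_y = c(0, 0.26),
                                 hf_tremor = c(0, 7), jitter_sd = 0,
                                 config = start_config()) {
  if (lag_ms < 0 || noise_sd_px < 0) stopf("lag and noise must be non-negative")
  W <- config$screen_px[1]; H <- config$screen_px[2]
  t_ms <- target$t_ms
  t_s <- t_ms / 1000
  T_s <- max(t_s) - min(t_s)
  s <- noise_sd_px
  with_seed(seed, function() {
    # incomplete tracking: the finger follows a gamma-scaled copy of the
    # path (compressed towards the start point / vertical centre). Spatial
    # scaling multiplies every spectral magnitude by gamma exactly, so it
    # carries arbitrarily large RMSE with no in-band spectral footprint,
    # no added jerk, and no screen clipping.
    gam <- motor_gamma(s)
    lx <- stats::approx(t_ms, target$x_px, xout = t_ms - lag_ms, rule = 2)$y
    ly <- stats::approx(t_ms, target$y_px, xout = t_ms - lag_ms, rule = 2)$y
    bx <- W / 2 + gam * (lx - W / 2)
    by <- H / 2 + gam * (ly - H / 2)
    # constant anchor offset in x, bounded by the margin the compression
    # frees up (constants are spectrally invisible after detrending)
    dc_x <- min(0.45 * s,
                max(0, (1 - gam) * (W / 2 - 80) - min(0.30 * s, 420) - 60))
    x <- bx + deviation_component(t_s, dc_x, min(0.30 * s, 420), min(0.06 * s, 40), T_s) +
      tremor_x[1] * sin(2 * pi * tremor_x[2] * t_s + stats::runif(1, 0, 2 * pi))
    y <- by + deviation_component(t_s, min(0.35 * s, 380), min(0.22 * s, 170),
                                  min(0.06 * s, 40), T_s) +
      tremor_y[1] * sin(2 * pi * tremor_y[2] * t_s + stats::runif(1, 0, 2 * pi))
    if (hf_tremor[1] > 0) {
      ph <- stats::runif(2, 0, 2 * pi)
      x <- x + hf_tremor[1] * sin(2 * pi * hf_tremor[2] * t_s + ph[1])
      y <- y + hf_tremor[1] * sin(2 * pi * hf_tremor[2] * t_s + ph[2])
    }
    if (jitter_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, jitter_sd)
      y <- y + stats::rnorm(length(y), 0, jitter_sd)
    }
    touch <- data.frame(t_ms = t_ms, x_px = clamp(x, 0, W), y_px = clamp(y, 0, H),
                        pressure = clamp(stats::rnorm(length(x), 0.3, 0.05), 0, 1))
    list(target = target, touch = touch)
  })
}

# ---- colouring construction -------------------------------------------------

colouring_polygon <- function(config) {
  W <- config$screen_px[1]; H <- config$screen_px[2]
  r <- 0.28 * H
  ang <- seq(0, 2 * pi, length.out = 17)[-17]
  cbind(W / 2 + r * cos(ang), H / 2 + r * sin(ang))
}

ring_stroke <- function(cx, cy, radius, step_px = 30, t0 = 0) {
  npts <- max(8, ceiling(2 * pi * radius / step_px))
  ang <- seq(0, 2 * pi, length.out = npts)
  data.frame(t_ms = as.integer(t0 + (seq_len(npts) - 1) * 30),
             x_px = cx + radius * cos(ang), y_px = cy + radius * sin(ang),
             pressure = 0.12)
}

# A stroke oscillating across the outline exactly `k` times.
wiggle_stroke <- function(cx, cy, r, k, t0 = 0, phi0 = 0) {
  if (k <= 0) {
    return(data.frame(t_ms = as.integer(t0 + c(0, 30)),
                      x_px = cx + c(r - 60, r - 62), y_px = cy + c(0, 2),
                      pressure = 0.12))
  }
  # point j alternates radius r-28 (strictly inside, below the apothem of the
  # 16-gon) and r+28 (strictly outside); k sign changes
  rad <- r + 28 * rep_len(c(-1, 1), k + 1)
  ang <- phi0 + (seq_len(k + 1) - 1) * 0.05
  data.frame(t_ms = as.integer(t0 + (seq_len(k + 1) - 1) * 30),
             x_px = cx + rad * cos(ang), y_px = cy + rad * sin(ang),
             pressure = 0.12)
}

raster_strokes <- function(x0, x1, H, area_px, spacing = 70, step_px = 25, t0 = 0) {
  if (area_px <= 0 || x1 <= x0) return(list())
  len <- x1 - x0
  n_lines <- min(floor((H - 120) / spacing), max(1, ceiling(area_px / (len * spacing))))
  strokes <- vector("list", n_lines)
  for (j in seq_len(n_lines)) {
    yy <- 60 + j * spacing
    xs <- seq(x0, x1, by = step_px)
    if (j %% 2 == 0) xs <- rev(xs)
    strokes[[j]] <- data.frame(
      t_ms = as.integer(t0 + (seq_along(xs) - 1) * 25),
      x_px = xs, y_px = yy, pressure = 0.12)
  }
  strokes
}

# Two colouring sessions with exactly `crossings` outline crossings in total
# and approximately `coverage` painted screen fraction.
simulate_colouring <- function(crossings, coverage, config) {
  W <- config$screen_px[1]; H <- config$screen_px[2]
  poly <- colouring_polygon(config)
  cx <- W / 2; cy <- H / 2
  r <- 0.28 * H
  k1 <- floor(crossings / 2); k2 <- crossings - k1
  scribble_max_r <- if (coverage >= config$coverage_threshold) r - 70 else 0.45 * r
  rings <- lapply(seq(60, scribble_max_r, by = 60), function(rr) ring_stroke(cx, cy, rr))
  area_scribble <- pi * (scribble_max_r + config$brush_radius_px)^2
  area_needed <- max(0, coverage * W * H - area_scribble)
  gap <- r + 130
  left <- raster_strokes(60, cx - gap, H, area_needed / 2)
  right <- raster_strokes(cx + gap, W - 60, H, area_needed / 2)
  s1 <- list(figure_outline = poly, screen_px = config$screen_px,
             brush_radius_px = config$brush_radius_px,
             strokes = c(rings, list(wiggle_stroke(cx, cy, r, k1, phi0 = 0.8))))
  s2 <- list(figure_outline = poly, screen_px = config$screen_px,
             brush_radius_px = config$brush_radius_px,
             strokes = c(list(wiggle_stroke(cx, cy, r, k2, phi0 = 3.9)), left, right))
  list(s1, s2)
}

# ---- per-child simulation ---------------------------------------------------

#' Simulate one child's full session record
#'
#' Generates all eight raw task sub-records so that the extracted features
#' follow the group profile's target mean/SD (attrition is applied
#' separately, see [apply_attrition()]). The seed is split deterministically
#' per task.
#'
#' @param group `"TD"`, `"AS"` or `"ID"`.
#' @param profiles a [default_profiles()] object.
#' @param config battery configuration (must match `profiles$config`).
#' @param seed integer seed for this child.
#' @param child_id identifier.
#' @param age_years,sex demographics (drawn from the config range when `NULL`).
#' @return A `start_child` record with all eight tasks.
#' @export
simulate_child <- function(group, profiles, config = profiles$config, seed = 1L,
                           child_id = "C001", age_years = NULL, sex = NULL) {
  pf <- profiles$groups[[group]]
  if (is.null(pf)) stopf("no profile for group '%s'", group)
  maps <- profiles$motor_maps
  demo <- with_seed(mix_seed(seed, 0), function() {
    list(age = stats::runif(1, config$age_range[1], config$age_range[2]),
         sex = if (stats::runif(1) < profiles$sex_f_prop[[group]]) "F" else "M")
  })
  tasks <- list()

  # 1. preferential looking
  tasks$preferential <- with_seed(mix_seed(seed, 1), function() {
    p_soc <- rbeta_target(1, pf$pref$beta)
    pd <- stats::runif(1, 0.80, 0.95)
    poff <- stats::runif(1, 0.02, 0.08)
    lapply(seq_len(config$preferential_trials), function(i) {
      list(social_on_left = i %% 2 == 1,
           frames = simulate_gaze_stream(p_soc, config$preferential_trial_s,
                                         config$fps, poff, 1 - pd, 0.05,
                                         seed = mix_seed(seed, 1, i)))
    })
  })

  # 2. button choices
  tasks$button <- with_seed(mix_seed(seed, 2), function() {
    p_choice <- rbeta_target(1, pf$button$choice_beta)
    comp <- stats::runif(config$button_trials) < pf$button$completion_p
    choice <- ifelse(comp,
                     ifelse(stats::runif(config$button_trials) < p_choice,
                            "social", "nonsocial"),
                     "none")
    data.frame(completed = comp, choice = choice, stringsAsFactors = FALSE)
  })

  # 3. wheel
  tasks$wheel <- with_seed(mix_seed(seed, 3), function() {
    w <- rbeta_target(1, pf$wheel$looking_beta)
    detect <- if (stats::runif(1) < pf$wheel$face_fail_p) {
      stats::runif(1, 0.05, 0.18)
    } else {
      stats::runif(1, 0.50, 0.90)
    }
    dmin <- rtnorm_target(1, pf$wheel$dmin)
    dgap <- rtnorm_target(1, pf$wheel$dgap)
    lapply(seq_len(config$wheel_trials), function(i) {
      completed <- stats::runif(1) < pf$wheel$completion_p
      if (!completed) {
        return(list(completed = FALSE, play_duration_s = 0,
                    max_duration_s = config$wheel_trial_s,
                    face_frames = data.frame(t_ms = integer(0),
                                             face_detected = logical(0),
                                             distance_mm = numeric(0),
                                             gaze_on_wheel = logical(0))))
      }
      n <- round(config$wheel_trial_s * config$fps)
      det <- stats::runif(n) < detect
      d <- ifelse(det, stats::runif(n, dmin, dmin + dgap), NA_real_)
      list(completed = TRUE, play_duration_s = config$wheel_trial_s,
           max_duration_s = config$wheel_trial_s,
           face_frames = data.frame(
             t_ms = as.integer(round((seq_len(n) - 1) * 1000 / config$fps)),
             face_detected = det, distance_mm = d,
             gaze_on_wheel = stats::runif(n) < w))
    })
  })

  # 4. motor following (inverse-map calibrated)
  tasks$motor <- motor_generate(pf$motor, maps, config, seed)

  # 5. bubble popping
  tasks$bubble <- with_seed(mix_seed(seed, 5), function() {
    W <- config$screen_px[1]; H <- config$screen_px[2]
    nb <- sum(seq_len(config$bubble_trials))
    f <- rbeta_target(1, pf$bubble$force_beta)
    dx <- rtnorm_target(1, pf$bubble$distx)
    dy <- rtnorm_target(1, pf$bubble$disty)
    bx <- stats::runif(nb, 400, W - 400)
    by <- stats::runif(nb, 300, H - 300)
    ox <- stats::rnorm(nb, 0, dx * sqrt(pi / 2))
    oy <- stats::rnorm(nb, 0, dy * sqrt(pi / 2))
    data.frame(bubble_x = bx, bubble_y = by,
               touch_x = clamp(bx + ox, 0, W), touch_y = clamp(by + oy, 0, H),
               pressure = clamp(stats::rnorm(nb, f, pf$bubble$pressure_sd), 0, 1),
               popped = stats::runif(nb) < pf$bubble$pop_p)
  })

  # 6. colouring
  tasks$colouring <- with_seed(mix_seed(seed, 6), function() {
    k <- max(0L, round(rtnorm_target(1, pf$colouring$crossings)))
    pass <- stats::runif(1) < pf$colouring$pass_p
    cov <- if (pass) stats::runif(1, 0.33, 0.55) else stats::runif(1, 0.06, 0.17)
    simulate_colouring(k, cov, config)
  })

  # 7. questionnaire
  tasks$questionnaire <- with_seed(mix_seed(seed, 7), function() {
    q <- pf$questionnaire
    theta <- stats::rnorm(1, q$mu, q$tau)
    red_flag <- stats::runif(14) < stats::plogis(q$delta + theta)
    rev <- seq_len(14) %in% q$reverse_items
    items <- ifelse(rev, ifelse(red_flag, "no", "yes"),
                    ifelse(red_flag, "yes", "no"))
    list(items = items, reverse_coded = q$reverse_items)
  })

  # 8. caregiver-child interaction codes
  tasks$pci <- with_seed(mix_seed(seed, 8), function() {
    init <- rbeta_target(1, pf$pci$init_beta)
    sync <- rbeta_target(1, pf$pci$sync_beta)
    ncod <- if (stats::runif(1) < pf$pci$multi_p) 3L else 1L
    # coder scores drawn from a Beta around the child's latent value: stays
    # in [0,1] without clamping, so no variance is eaten at the boundaries
    coder_draw <- function(latent, noise_sd) {
      lim <- 0.9 * sqrt(clamp(latent, 0.01, 0.99) * (1 - clamp(latent, 0.01, 0.99)))
      rbeta_target(1, beta_solve(latent, min(noise_sd, lim)))
    }
    lapply(seq_len(ncod), function(j) list(
      coder_id = sprintf("coder%d", j),
      child_initiation_prop = coder_draw(init, pf$pci$init_coder_sd),
      caregiver_sync_prop = coder_draw(sync, pf$pci$sync_coder_sd),
      child_opportunities = 10L + stats::rpois(1, 20),
      caregiver_opportunities = 10L + stats::rpois(1, 20)))
  })

  child_record(child_id, group, demo$age, demo$sex, tasks)
}

# Draw one child's motor latents (RMSE, frequency gains, jerk) and generate
# the four motor trials through the calibrated inverse maps. Shared by
# simulate_child() and the profile self-calibration stage so both follow the
# identical code path.
motor_generate <- function(pfm, maps, config, seed) {
  with_seed(mix_seed(seed, 4), function() {
    r_t <- draw_latent(1, pfm$rmse)
    gx <- draw_latent(1, pfm$gx)
    gy <- draw_latent(1, pfm$gy)
    # the zero-tremor gain baseline shifts with the child's own deviation
    # scale (it equals the path-compression factor); correct the inversion
    # target accordingly, with a short fixed point since the deviation scale
    # in turn depends on the tremor amplitudes
    a_x <- 0; a_y <- 0; dev_s <- 0
    for (it in 1:2) {
      base <- sqrt(max(maps$rmse0^2, r_t^2 - (a_x^2 + a_y^2) / 2))
      dev_s <- maps$inv_rmse(base)
      dg <- motor_gamma(dev_s) - motor_gamma(maps$s_ref)
      a_x <- maps$inv_gain_x(gx - dg)
      a_y <- maps$inv_gain_y(gy - dg)
    }
    t_jerk <- sqrt(maps$jerk_base(dev_s)^2 + (maps$jerk_slope_y * a_y)^2 +
                     (maps$jerk_slope_x * a_x)^2)
    mx <- pfm$jerk_mix
    excess <- if (stats::runif(1) < mx$pi) min(stats::rexp(1, 1 / mx$scale), 4) else 0
    J <- max(t_jerk, excess)
    hf_amp <- maps$inv_jerk_hf(sqrt(max(J^2 - t_jerk^2, 0)))
    fx <- stats::runif(1, 0.24, 0.32)
    fy <- stats::runif(1, 0.22, 0.26)
    fhf <- stats::runif(1, 6, 9)
    valid <- stats::runif(config$motor_trials) < pfm$valid_p
    lapply(seq_len(config$motor_trials), function(i) {
      dir <- if (i %% 2 == 1) 1 else -1
      tg <- generate_butterfly_trajectory(config$motor_trial_s,
                                          config$motor_velocity_range,
                                          seed = mix_seed(seed, 4, i), dir, config)
      tr <- simulate_motor_trial(tg, config$motor_lag_ms, dev_s,
                                 seed = mix_seed(seed, 4, 100 + i),
                                 tremor_x = c(a_x, fx), tremor_y = c(a_y, fy),
                                 hf_tremor = c(hf_amp, fhf), config = config)
      if (!valid[i]) {
        keep <- seq_len(max(2, floor(nrow(tr$touch) * stats::runif(1, 0.05, 0.40))))
        tr$touch <- tr$touch[keep, , drop = FALSE]
      }
      tr
    })
  })
}

#' Apply per-task attrition to a cohort
#'
#' Each task sub-record is removed independently per child with its group's
#' dropout probability (child refusal, app malfunction). Removal only:
#' surviving sub-records are untouched.
#'
#' @param cohort a `start_cohort`.
#' @param profiles a [default_profiles()] object carrying per-group dropout
#'   probabilities.
#' @param seed integer seed.
#' @return The thinned cohort.
#' @export
apply_attrition <- function(cohort, profiles, seed = 1L) {
  for (i in seq_along(cohort)) {
    drop_p <- profiles$groups[[cohort[[i]]$group]]$dropout
    for (k in seq_along(TASK_NAMES)) {
      task <- TASK_NAMES[k]
      p <- drop_p[[task]] %||% 0
      if (p > 0 && with_seed(mix_seed(seed, i, 500 + k), function() stats::runif(1)) < p) {
        cohort[[i]]$tasks[[task]] <- NULL
      }
    }
  }
  cohort
}

#' Simulate a full three-group cohort
#'
#' Group sizes, demographics, all eight raw task streams and per-task
#' attrition, with every stream seeded deterministically from the master
#' seed.
#'
#' @param config a [sim_config()].
#' @param profiles group profiles; defaults to
#'   [default_profiles()] for `config$battery`.
#' @return A validated `start_cohort`.
#' @export
simulate_cohort <- function(config = sim_config(), profiles = NULL) {
  if (is.null(profiles)) profiles <- default_profiles(config$battery)
  profiles$sex_f_prop <- config$sex_f_prop
  battery <- config$battery
  cohort <- list()
  idx <- 0L
  for (g in GROUP_LEVELS) {
    for (j in seq_len(config$n_per_group[[g]])) {
      idx <- idx + 1L
      cohort[[idx]] <- simulate_child(
        g, profiles, battery, seed = mix_seed(config$seed, idx),
        child_id = sprintf("%s%03d", g, j))
    }
  }
  cohort <- apply_attrition(cohort, profiles, seed = mix_seed(config$seed, 999983))
  validate_cohort(cohort, battery)
  structure(cohort, class = "start_cohort")
}
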