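# Per-task filters and dependent-variable computations, with independent
# oracles for the signal-level metrics.

test_that("social preference counts frames and applies the 50% filters", {
  tr <- gaze_trial(c(rep("social_side", 60), rep("nonsocial_side", 40)))
  r <- social_preference(list(tr))
  expect_true(r$outcome$included)
  expect_equal(unname(r$value["social_preference"]), 0.6)
  # 49% eye detection -> excluded
  tr2 <- gaze_trial(c(rep("social_side", 49), rep("undetected", 51)))
  r2 <- social_preference(list(tr2))
  expect_false(r2$outcome$included)
  expect_equal(r2$outcome$reason, "eye_detection_below_half")
  expect_true(is.na(r2$value["social_preference"]))
  # exactly 50% detection counts as included ("at least 50%")
  tr3 <- gaze_trial(c(rep("social_side", 50), rep("undetected", 50)))
  expect_true(social_preference(list(tr3))$outcome$included)
  # gaze off the tablet fails the second filter
  tr4 <- gaze_trial(c(rep("social_side", 40), rep("off_tablet", 60)))
  expect_equal(social_preference(list(tr4))$outcome$reason,
               "gaze_on_tablet_below_half")
  # social frames only -> 1.0
  expect_equal(unname(social_preference(list(gaze_trial(rep("social_side", 10))))$value[1]), 1)
  # on-tablet but never on a stimulus -> degenerate, recorded
  tr5 <- gaze_trial(rep("elsewhere_on_tablet", 100))
  expect_equal(social_preference(list(tr5))$outcome$reason, "degenerate")
  expect_equal(social_preference(NULL)$outcome$reason, "missing_task")
})

test_that("button choice uses completed trials with an inclusive 50% rule", {
  bt <- function(comp, choice) data.frame(completed = comp, choice = choice,
                                          stringsAsFactors = FALSE)
  full <- bt(rep(TRUE, 8), rep(c("social", "nonsocial"), 4))
  expect_equal(unname(button_social_choice(full, 8)$value[1]), 0.5)
  # 3 of 8 completed -> excluded
  part <- bt(c(rep(TRUE, 3), rep(FALSE, 5)),
             c(rep("social", 3), rep("none", 5)))
  expect_equal(button_social_choice(part, 8)$outcome$reason, "fewer_than_half_trials")
  # exactly 4 of 8 counts as included; 4 social -> 1.0
  half <- bt(c(rep(TRUE, 4), rep(FALSE, 4)),
             c(rep("social", 4), rep("none", 4)))
  r <- button_social_choice(half, 8)
  expect_true(r$outcome$included)
  expect_equal(unname(r$value[1]), 1)
})

wheel_trial <- function(completed = TRUE, look_s = 10, trial_s = 15,
                        detect = TRUE, dist = 300) {
  n <- trial_s * 20
  on <- seq_len(n) <= look_s * 20
  list(completed = completed, play_duration_s = trial_s, max_duration_s = 15,
       face_frames = data.frame(
         t_ms = as.integer((seq_len(n) - 1) * 50),
         face_detected = rep(detect, n),
         distance_mm = ifelse(rep(detect, n), dist, NA_real_),
         gaze_on_wheel = on))
}

test_that("wheel looking time is summed over completed trials", {
  r <- wheel_looking(list(wheel_trial(look_s = 10), wheel_trial(look_s = 10),
                          wheel_trial(completed = FALSE, look_s = 0)))
  expect_true(r$outcome$included)
  expect_equal(unname(r$value[1]), 20 / 30, tolerance = 0.01)
  # fewer than two completed trials
  r2 <- wheel_looking(list(wheel_trial(), wheel_trial(completed = FALSE)))
  expect_equal(r2$outcome$reason, "fewer_than_two_trials")
  # face detected on exactly 25% of frames is excluded ("25% or fewer")
  tr <- wheel_trial()
  tr$face_frames$face_detected <- rep(c(TRUE, FALSE, FALSE, FALSE), 75)
  tr$face_frames$distance_mm <- ifelse(tr$face_frames$face_detected, 300, NA)
  r3 <- wheel_looking(list(tr, tr))
  expect_equal(r3$outcome$reason, "face_detection_at_or_below_quarter")
  # just above 25% is included
  tr$face_frames$face_detected[2] <- TRUE
  tr$face_frames$distance_mm[2] <- 300
  expect_true(wheel_looking(list(tr, tr))$outcome$included)
})

test_that("wheel face distance returns the detected-frame range", {
  r <- wheel_face_distance(list(wheel_trial(dist = 300), wheel_trial(dist = 300)))
  expect_equal(unname(r$value), c(300, 300))
  t1 <- wheel_trial()
  t1$face_frames$distance_mm[t1$face_frames$face_detected] <-
    rep(c(250, 400, 310), length.out = sum(t1$face_frames$face_detected))
  r2 <- wheel_face_distance(list(t1, wheel_trial(dist = 300)))
  expect_equal(unname(r2$value), c(250, 400))
  # all frames undetected -> excluded by the face filter
  und <- wheel_trial(detect = FALSE)
  expect_false(wheel_face_distance(list(und, und))$outcome$included)
})

test_that("motor RMSE matches hand values and a brute-force oracle", {
  expect_equal(motor_rmse(shifted_trial(0, 0)), 0)
  expect_equal(motor_rmse(shifted_trial(3, 4)), 5)
  # random 20-point trial with offset touch timestamps vs direct recomputation
  set.seed(31)
  t <- as.integer(seq(0, 950, by = 50))
  target <- data.frame(t_ms = t, x_px = cumsum(runif(20, 10, 40)) + 300,
                       y_px = cumsum(rnorm(20, 0, 15)) + 800)
  tt <- as.integer(seq(25, 925, by = 50))
  touch <- data.frame(t_ms = tt, x_px = runif(19, 300, 1200),
                      y_px = runif(19, 400, 1200), pressure = 0.3)
  trial <- list(target = target, touch = touch)
  # oracle: manual interpolation of touch onto target timestamps in overlap
  lo <- max(min(t), min(tt)); hi <- min(max(t), max(tt))
  grid <- t[t >= lo & t <= hi]
  manual_interp <- function(tq, ts, vs) {
    i <- findInterval(tq, ts)
    w <- (tq - ts[i]) / (ts[i + 1] - ts[i])
    vs[i] * (1 - w) + vs[i + 1] * w
  }
  dx <- manual_interp(grid, tt, touch$x_px) -
    target$x_px[match(grid, t)]
  dy <- manual_interp(grid, tt, touch$y_px) -
    target$y_px[match(grid, t)]
  expect_equal(motor_rmse(trial), sqrt(mean(dx^2 + dy^2)), tolerance = 1e-10)
  # invalid trials: empty touch, or touch covering under half the support
  expect_true(is.na(motor_rmse(list(target = target,
                                    touch = touch[0, , drop = FALSE]))))
  expect_true(is.na(motor_rmse(list(target = target,
                                    touch = touch[1:6, , drop = FALSE]))))
})

test_that("frequency gain is 1 for perfect tracking and matches a direct DFT oracle", {
  n <- 64
  t <- as.integer((seq_len(n) - 1) * 50)
  base <- 500 + 3 * seq_len(n) + 40 * sin(2 * pi * 1.2 * t / 1000)
  target <- data.frame(t_ms = t, x_px = base, y_px = base / 2)
  same <- list(target = target,
               touch = data.frame(t_ms = t, x_px = base, y_px = base / 2,
                                  pressure = 0.3))
  expect_equal(motor_frequency_gain(same, "x"), 1, tolerance = 1e-9)
  expect_equal(motor_frequency_gain(same, "y"), 1, tolerance = 1e-9)
  # adding an in-band sinusoid raises the gain above 1
  plus <- same
  plus$touch$x_px <- plus$touch$x_px + 25 * sin(2 * pi * 2.5 * t / 1000)
  expect_gt(motor_frequency_gain(plus, "x"), 1)
  # direct discrete-transform oracle computed from the definition
  set.seed(8)
  noisy <- same
  noisy$touch$x_px <- noisy$touch$x_px + rnorm(n, 0, 12)
  oracle_spec <- function(v, dt = 0.05) {
    m <- length(v)
    i <- seq_len(m) - 1
    v <- v - (v[1] + (v[m] - v[1]) * i / (m - 1))
    v <- v - mean(v)
    w <- 0.5 - 0.5 * cos(2 * pi * i / m)
    vw <- v * w
    k <- 0:(m - 1)
    mag <- vapply(k, function(kk) {
      Mod(sum(vw * exp(-2i * pi * kk * i / m)))
    }, numeric(1))
    f <- k / (m * dt)
    keep <- f <= 1 / (2 * dt)
    list(f = f[keep], mag = mag[keep])
  }
  # the analysis window drops the duplicated endpoint sample
  resample <- function(v) v[seq_len(n - 1)]
  st <- oracle_spec(resample(noisy$target$x_px))
  sc <- oracle_spec(resample(noisy$touch$x_px))
  inb <- st$f >= 0.2 & st$f <= 5
  expect_equal(motor_frequency_gain(noisy, "x"),
               sum(sc$f[inb] * sc$mag[inb]) / sum(st$f[inb] * st$mag[inb]),
               tolerance = 1e-8)
  # all-zero target spectrum in the band -> missing
  flat <- list(target = data.frame(t_ms = t, x_px = seq_len(n), y_px = rep(1, n)),
               touch = data.frame(t_ms = t, x_px = seq_len(n), y_px = rep(1, n),
                                  pressure = 0.3))
  expect_true(is.na(motor_frequency_gain(flat, "y")))
})

test_that("jerk vanishes on straight lines and matches the cubic closed form", {
  expect_equal(motor_jerk(shifted_trial(0, 0)), 0)
  # cubic path x = t^3 (t in seconds): constant third difference 6*dt^3,
  # so the normalised jerk is exactly 6 / screen diagonal
  n <- 40
  ts <- (seq_len(n) - 1) * 0.05
  trial <- list(target = shifted_trial()$target,
                touch = data.frame(t_ms = as.integer(ts * 1000),
                                   x_px = ts^3, y_px = 0, pressure = 0.3))
  diag_px <- sqrt(2560^2 + 1600^2)
  expect_equal(motor_jerk(trial, c(2560, 1600)), 6 / diag_px, tolerance = 1e-9)
  # a direction reversal is jerkier than a straight line
  rev_trial <- shifted_trial()
  m <- nrow(rev_trial$touch)
  rev_trial$touch$x_px <- c(seq(100, 500, length.out = ceiling(m / 2)),
                            seq(500, 100, length.out = m - ceiling(m / 2)))
  expect_gt(motor_jerk(rev_trial), motor_jerk(shifted_trial(0, 0)))
  # fewer than 4 samples -> missing
  short <- shifted_trial()
  short$touch <- short$touch[1:3, ]
  expect_true(is.na(motor_jerk(short)))
})

test_that("bubble features average popped touches only", {
  one <- data.frame(bubble_x = 500, bubble_y = 500, touch_x = 500,
                    touch_y = 500, pressure = 0.07, popped = TRUE)
  r <- bubble_features(one)
  expect_equal(unname(r$value), c(0.07, 0, 0))
  two <- data.frame(bubble_x = c(500, 900), bubble_y = c(500, 700),
                    touch_x = c(510, 870), touch_y = c(490, 710),
                    pressure = c(0.05, 0.09), popped = c(TRUE, TRUE))
  r2 <- bubble_features(two)
  expect_equal(unname(r2$value), c(0.07, 20, 10))
  # unpopped touches are ignored; zero pops -> excluded
  two$popped <- c(FALSE, FALSE)
  expect_equal(bubble_features(two)$outcome$reason, "no_bubbles_popped")
})

test_that("colouring crossings count classification changes within strokes", {
  poly <- square_polygon()   # [500,1000] x [500,1000]
  sess <- function(strokes) list(figure_outline = poly, screen_px = c(2560, 1600),
                                 brush_radius_px = 40, strokes = strokes)
  stroke <- function(x, y) data.frame(t_ms = as.integer(seq_along(x)) * 30L,
                                      x_px = x, y_px = y, pressure = 0.1)
  inside <- stroke(c(600, 700, 800), c(700, 750, 800))
  expect_equal(colouring_crossings(sess(list(inside))), 0)
  # enter once and leave once -> 2
  through <- stroke(c(400, 750, 1200), c(750, 750, 750))
  expect_equal(colouring_crossings(sess(list(through))), 2)
  # stroke boundaries generate no crossings
  half1 <- stroke(c(400, 750), c(750, 750))
  half2 <- stroke(c(760, 1200), c(750, 750))
  expect_equal(colouring_crossings(sess(list(half1, half2))), 2)
  # random 200-sample walk vs a per-sample classification oracle
  set.seed(99)
  x <- cumsum(rnorm(200, 0, 80)) + 750
  y <- cumsum(rnorm(200, 0, 80)) + 750
  x <- pmin(pmax(x, 10), 2550); y <- pmin(pmax(y, 10), 1590)
  walk <- stroke(x, y)
  inside_sq <- x >= 500 & x <= 1000 & y >= 500 & y <= 1000
  expect_equal(colouring_crossings(sess(list(walk))),
               sum(inside_sq[-1] != inside_sq[-200]))
  # rigid translation of polygon and strokes leaves the count unchanged
  sess2 <- sess(list(walk))
  sess2$figure_outline <- poly + 120
  sess2$strokes[[1]]$x_px <- x + 120
  sess2$strokes[[1]]$y_px <- y + 120
  expect_equal(colouring_crossings(sess2), colouring_crossings(sess(list(walk))))
})

test_that("coverage approximates painted area on the pixel grid", {
  sess <- function(strokes, r = 40) list(figure_outline = square_polygon(),
                                         screen_px = c(2560, 1600),
                                         brush_radius_px = r, strokes = strokes)
  empty <- sess(list(data.frame(t_ms = integer(0), x_px = numeric(0),
                                y_px = numeric(0), pressure = numeric(0))))
  expect_equal(colouring_coverage(empty, 4), 0)
  # single disc: pi r^2 / (W H) within 5%
  dot <- sess(list(data.frame(t_ms = 0L, x_px = 1280, y_px = 800, pressure = 0.1)))
  expect_equal(colouring_coverage(dot, 1), pi * 40^2 / (2560 * 1600),
               tolerance = 0.05)
  # strokes tiling the whole screen -> coverage ~ 1
  lines <- lapply(seq(20, 1595, by = 50), function(yy) {
    data.frame(t_ms = as.integer(seq(0, 2550, by = 25)),
               x_px = seq(5, 2555, by = 25), y_px = yy, pressure = 0.1)
  })
  expect_gt(colouring_coverage(sess(lines), 4), 0.97)
})

test_that("questionnaire scoring reverses the marked items", {
  expect_equal(questionnaire_score(quest(rep("no", 14))), 8)
  expect_equal(questionnaire_score(quest(rep("yes", 14))), 6)
  rev_set <- c(2L, 4L, 6L, 8L, 10L, 12L, 13L, 14L)
  items <- ifelse(seq_len(14) %in% rev_set, "no", "yes")
  expect_equal(questionnaire_score(quest(items)), 14)
  expect_error(questionnaire_score(quest(rep("no", 13))), "14")
})

test_that("interaction coder selection is reproducible", {
  one <- list(list(coder_id = "A", child_initiation_prop = 0.48,
                   caregiver_sync_prop = 0.33, child_opportunities = 10L,
                   caregiver_opportunities = 10L))
  expect_equal(unname(pci_features(one)$value), c(0.48, 0.33))
  two <- c(one, list(list(coder_id = "B", child_initiation_prop = 0.60,
                          caregiver_sync_prop = 0.20, child_opportunities = 10L,
                          caregiver_opportunities = 10L)))
  r1 <- pci_features(two, seed = 5)
  r2 <- pci_features(two, seed = 5)
  expect_identical(r1$value, r2$value)
  expect_equal(pci_features(NULL)$outcome$reason, "missing_task")
})

test_that("extract_features covers all tasks and preserves missingness", {
  rec <- make_child("E1")
  ex <- extract_features(rec, test_config(), seed = 2)
  expect_named(ex$features, FEATURE_SLOTS)
  expect_equal(nrow(ex$outcomes), 8)
  expect_setequal(ex$outcomes$task, c("preferential", "button", "wheel", "motor",
                                      "bubble", "colouring", "questionnaire", "pci"))
  # absent wheel task -> wheel slots missing, others untouched
  rec2 <- rec
  rec2$tasks$wheel <- NULL
  ex2 <- extract_features(rec2, test_config(), seed = 2)
  expect_true(all(is.na(ex2$features[c("wheel_looking", "wheel_dist_min",
                                       "wheel_dist_max")])))
  expect_equal(ex2$features["social_preference"], ex$features["social_preference"])
  expect_equal(ex2$outcomes$reason[ex2$outcomes$task == "wheel"], "missing_task")
  # extraction is idempotent under a fixed seed
  ex3 <- extract_features(rec, test_config(), seed = 2)
  expect_identical(ex3$features, ex$features)
})

test_that("feature invariances: translation, pressure scaling, bounds", {
  # translation invariance of RMSE
  tr <- shifted_trial(3, 4)
  tr2 <- tr
  tr2$target$x_px <- tr2$target$x_px + 111
  tr2$touch$x_px <- tr2$touch$x_px + 111
  expect_equal(motor_rmse(tr2), motor_rmse(tr))
  # pressure scaling scales force linearly below the clip
  bb <- data.frame(bubble_x = runif(5, 400, 2000), bubble_y = runif(5, 300, 1300),
                   touch_x = runif(5, 400, 2000), touch_y = runif(5, 300, 1300),
                   pressure = runif(5, 0.05, 0.2), popped = TRUE)
  f1 <- bubble_features(bb)$value["pop_force"]
  bb$pressure <- bb$pressure * 3
  expect_equal(unname(bubble_features(bb)$value["pop_force"]), unname(3 * f1))
  # bounded features stay in range on simulated records
  feats <- test_features131()$features
  for (s in c("social_preference", "social_choice", "wheel_looking",
              "pop_force", "pci_child_init", "pci_caregiver_sync")) {
    v <- feats[[s]]
    expect_true(all(is.na(v) | (v >= 0 & v <= 1)), info = s)
  }
  for (s in c("motor_rmse", "jerk", "pop_dist_x", "pop_dist_y",
              "colour_crossings", "fft_gain_x", "fft_gain_y")) {
    expect_true(all(is.na(feats[[s]]) | feats[[s]] >= 0), info = s)
  }
  expect_true(all(is.na(feats$questionnaire_score) |
                    feats$questionnaire_score %in% 0:14))
})
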