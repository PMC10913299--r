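# Shared fixtures: one battery configuration (coarser coverage grid for
# speed; the coverage threshold itself is untouched), lazily-built profiles
# and a lazily-built default cohort.

.fixture_env <- new.env(parent = emptyenv())

test_config <- function() start_config(coverage_grid_step = 8)

test_profiles <- function() {
  if (is.null(.fixture_env$profiles)) {
    .fixture_env$profiles <- default_profiles(test_config())
  }
  .fixture_env$profiles
}

# the default 131-child cohort (seed 7) and its feature table
test_cohort131 <- function() {
  if (is.null(.fixture_env$c131)) {
    sc <- sim_config(seed = 7, battery = test_config())
    .fixture_env$c131 <- simulate_cohort(sc, test_profiles())
  }
  .fixture_env$c131
}

test_features131 <- function() {
  if (is.null(.fixture_env$f131)) {
    .fixture_env$f131 <- extract_cohort(test_cohort131(), test_config(), seed = 7)
  }
  .fixture_env$f131
}

# A minimal hand-built child record touching every task type.
make_child <- function(id = "C001", group = "TD", age = 4.5, sex = "F") {
  frames <- data.frame(
    t_ms = as.integer(seq(0, 450, by = 50)),
    eye_detected = rep(TRUE, 10),
    gaze = c(rep("social_side", 6), rep("nonsocial_side", 3), "elsewhere_on_tablet"),
    stringsAsFactors = FALSE)
  wheel_ff <- data.frame(
    t_ms = as.integer(seq(0, 950, by = 50)),
    face_detected = rep(c(TRUE, FALSE), 10),
    distance_mm = ifelse(rep(c(TRUE, FALSE), 10), 300, NA_real_),
    gaze_on_wheel = rep(c(TRUE, TRUE, FALSE, FALSE), 5))
  target <- data.frame(t_ms = as.integer(seq(0, 1000, by = 50)),
                       x_px = seq(100, 600, length.out = 21),
                       y_px = rep(800, 21))
  touch <- data.frame(target, pressure = 0.3)
  names(touch) <- c("t_ms", "x_px", "y_px", "pressure")
  stroke <- data.frame(t_ms = as.integer(seq(0, 90, by = 30)),
                       x_px = c(1200, 1250, 1300, 1350),
                       y_px = rep(800, 4), pressure = 0.1)
  child_record(id, group, age, sex, tasks = list(
    preferential = list(list(social_on_left = TRUE, frames = frames)),
    button = data.frame(completed = c(TRUE, TRUE, FALSE),
                        choice = c("social", "nonsocial", "none"),
                        stringsAsFactors = FALSE),
    wheel = list(
      list(completed = TRUE, play_duration_s = 15, max_duration_s = 15,
           face_frames = wheel_ff),
      list(completed = TRUE, play_duration_s = 15, max_duration_s = 15,
           face_frames = wheel_ff)),
    motor = list(list(target = target, touch = touch),
                 list(target = target, touch = touch)),
    bubble = data.frame(bubble_x = c(500, 700), bubble_y = c(400, 600),
                        touch_x = c(510, 690), touch_y = c(395, 610),
                        pressure = c(0.07, 0.09), popped = c(TRUE, TRUE)),
    colouring = list(list(
      figure_outline = square_polygon(),
      screen_px = c(2560, 1600), brush_radius_px = 40,
      strokes = list(stroke))),
    questionnaire = list(items = rep(c("yes", "no"), 7),
                         reverse_coded = c(2L, 4L, 6L, 8L, 10L, 12L, 13L, 14L)),
    pci = list(list(coder_id = "A", child_initiation_prop = 0.48,
                    caregiver_sync_prop = 0.33, child_opportunities = 20L,
                    caregiver_opportunities = 25L))))
}

square_polygon <- function(x0 = 500, y0 = 500, side = 500) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

# straight-line motor trial: touch = target shifted by (dx, dy)
shifted_trial <- function(dx = 0, dy = 0, n = 21, dt = 50) {
  t <- as.integer((seq_len(n) - 1) * dt)
  target <- data.frame(t_ms = t, x_px = seq(100, 900, length.out = n),
                       y_px = seq(200, 600, length.out = n))
  touch <- data.frame(t_ms = t, x_px = target$x_px + dx,
                      y_px = target$y_px + dy, pressure = 0.3)
  list(target = target, touch = touch)
}

# gaze trial wrapper
gaze_trial <- function(gaze, social_on_left = TRUE) {
  n <- length(gaze)
  list(social_on_left = social_on_left,
       frames = data.frame(t_ms = as.integer((seq_len(n) - 1) * 50),
                           eye_detected = gaze != "undetected",
                           gaze = gaze, stringsAsFactors = FALSE))
}

quest <- function(items, reverse = c(2L, 4L, 6L, 8L, 10L, 12L, 13L, 14L)) {
  list(items = items, reverse_coded = reverse)
}
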