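# Generators: determinism, stated limit cases, monotone responses,
# attrition semantics and cohort structure.

test_that("butterfly trajectories respect the speed range and direction", {
  cfg <- test_config()
  tg1 <- generate_butterfly_trajectory(30, c(45, 105), seed = 3, 1, cfg)
  tg2 <- generate_butterfly_trajectory(30, c(45, 105), seed = 3, 1, cfg)
  expect_identical(tg1, tg2)
  # degenerate velocity range: straight horizontal path of length v * T
  flat <- generate_butterfly_trajectory(20, c(60, 60), seed = 1, 1, cfg)
  expect_true(all(abs(diff(flat$y_px)) < 1e-9))
  expect_equal(max(flat$x_px) - min(flat$x_px), 60 * 20, tolerance = 0.01)
  # sampled speeds lie inside the configured range (property over seeds)
  for (s in 1:40) {
    tg <- generate_butterfly_trajectory(30, c(45, 105), seed = s,
                                        direction = if (s %% 2) 1 else -1, cfg)
    v <- sqrt(diff(tg$x_px)^2 + diff(tg$y_px)^2) / diff(tg$t_ms) * 1000
    expect_true(all(v >= 44 & v <= 106), info = paste("seed", s))
    expect_true(all(tg$x_px >= 0 & tg$x_px <= 2560))
    expect_true(all(tg$y_px >= 0 & tg$y_px <= 1600))
  }
  # direction reverses the sweep
  lr <- generate_butterfly_trajectory(30, c(45, 105), seed = 9, 1, cfg)
  rl <- generate_butterfly_trajectory(30, c(45, 105), seed = 9, -1, cfg)
  expect_gt(lr$x_px[601] - lr$x_px[1], 1000)
  expect_lt(rl$x_px[601] - rl$x_px[1], -1000)
})

test_that("motor trials: zero noise tracks exactly; RMSE responds monotonically", {
  cfg <- test_config()
  tg <- generate_butterfly_trajectory(30, c(45, 105), seed = 5, 1, cfg)
  perfect <- simulate_motor_trial(tg, lag_ms = 0, noise_sd_px = 0, seed = 1,
                                  config = cfg)
  expect_equal(motor_rmse(perfect), 0, tolerance = 1e-9)
  # monotone in noise scale over seeds
  mean_rmse <- function(s) {
    mean(vapply(1:12, function(j) {
      motor_rmse(simulate_motor_trial(tg, 120, s, seed = j, config = cfg))
    }, numeric(1)))
  }
  r <- vapply(c(50, 250, 700), mean_rmse, numeric(1))
  expect_true(all(diff(r) > 0))
  # monotone in lag at zero noise
  lagged <- vapply(c(0, 200, 600), function(l) {
    motor_rmse(simulate_motor_trial(tg, l, 0, seed = 2, config = cfg))
  }, numeric(1))
  expect_true(all(diff(lagged) > 0))
  # small-sample mean within 3 SE of a 10x Monte-Carlo oracle
  few <- vapply(1:8, function(j) {
    motor_rmse(simulate_motor_trial(tg, 0, 300, seed = j, config = cfg))
  }, numeric(1))
  many <- vapply(1:80, function(j) {
    motor_rmse(simulate_motor_trial(tg, 0, 300, seed = 1000 + j, config = cfg))
  }, numeric(1))
  expect_lt(abs(mean(few) - mean(many)), 3 * sd(many) / sqrt(8))
})

test_that("gaze streams reproduce their marginal probabilities", {
  pure <- simulate_gaze_stream(1, 5, 20, 0, 0, 0, seed = 4)
  r <- social_preference(list(list(social_on_left = TRUE, frames = pure)))
  expect_equal(unname(r$value[1]), 1)
  # law of large numbers at 1e5 frames
  big <- simulate_gaze_stream(0.5, 5000, 20, 0.05, 0.1, 0.05, seed = 11)
  soc <- sum(big$gaze == "social_side")
  non <- sum(big$gaze == "nonsocial_side")
  expect_equal(soc / (soc + non), 0.5, tolerance = 0.01)
  # undetected everywhere fails the eye-detection filter
  blind <- simulate_gaze_stream(0.5, 5, 20, 0, 1, 0, seed = 2)
  rr <- social_preference(list(list(social_on_left = TRUE, frames = blind)))
  expect_equal(rr$outcome$reason, "eye_detection_below_half")
})

test_that("simulate_child is deterministic and valid", {
  pf <- test_profiles()
  a <- simulate_child("TD", pf, test_config(), seed = 77, child_id = "T1")
  b <- simulate_child("TD", pf, test_config(), seed = 77, child_id = "T1")
  expect_identical(a, b)
  expect_silent(validate_child_record(a, test_config()))
  expect_setequal(names(a$tasks), c("preferential", "button", "wheel", "motor",
                                    "bubble", "colouring", "questionnaire", "pci"))
})

test_that("attrition removes whole sub-records and nothing else", {
  pf <- test_profiles()
  cohort <- lapply(1:6, function(i) {
    simulate_child(c("TD", "AS", "ID")[(i - 1) %% 3 + 1], pf, test_config(),
                   seed = 100 + i, child_id = sprintf("K%02d", i))
  })
  # zero dropout leaves the cohort untouched
  pf0 <- pf
  for (g in names(pf0$groups)) pf0$groups[[g]]$dropout[] <- 0
  expect_identical(apply_attrition(cohort, pf0, seed = 1), cohort)
  # dropout 1 for one task removes that task everywhere
  pf1 <- pf0
  for (g in names(pf1$groups)) pf1$groups[[g]]$dropout["wheel"] <- 1
  thinned <- apply_attrition(cohort, pf1, seed = 1)
  expect_true(all(vapply(thinned, function(r) is.null(r$tasks$wheel), logical(1))))
  # surviving sub-records are bit-identical (removal only)
  for (i in seq_along(thinned)) {
    kept <- names(thinned[[i]]$tasks)
    expect_identical(thinned[[i]]$tasks[kept], cohort[[i]]$tasks[kept])
  }
})

test_that("simulated cohorts have the configured structure", {
  cohort <- test_cohort131()
  expect_length(cohort, 131)
  grp <- vapply(cohort, function(r) r$group, character(1))
  expect_equal(as.vector(table(factor(grp, c("TD", "AS", "ID")))), c(40L, 48L, 43L))
  ids <- vapply(cohort, function(r) r$child_id, character(1))
  expect_false(any(duplicated(ids)))
  ages <- vapply(cohort, function(r) r$age_years, numeric(1))
  expect_true(all(ages >= 2 & ages <= 7.99))
  # same seed, same cohort
  again <- simulate_cohort(sim_config(seed = 7, battery = test_config()),
                           test_profiles())
  expect_identical(again, cohort)
  # different seed differs
  other <- simulate_cohort(sim_config(n_per_group = c(TD = 2, AS = 2, ID = 2),
                                      seed = 8, battery = test_config()),
                           test_profiles())
  expect_false(identical(other[[1]], cohort[[1]]))
})

test_that("sex draws follow the configured group ratios in expectation", {
  pf <- test_profiles()
  # pool demographic draws over many per-child seeds (streams untouched)
  n <- 400
  sexes <- vapply(seq_len(n), function(i) {
    simulate_child("AS", pf, test_config(), seed = 9000 + i, child_id = "s")$sex
  }, character(1))
  p <- mean(sexes == "F")
  expect_lt(abs(p - 12 / 48), 4 * sqrt(0.25 * 0.75 / n) + 0.02)
})

test_that("default profiles encode the printed targets and attrition", {
  pf <- test_profiles()
  tg <- pf$groups$TD$targets
  expect_equal(tg$mean[tg$slot == "social_preference"], 0.59)
  expect_equal(tg$sd[tg$slot == "social_preference"], 0.09)
  tgA <- pf$groups$AS$targets
  expect_equal(tgA$mean[tgA$slot == "motor_rmse"], 591.27)
  expect_equal(tgA$sd[tgA$slot == "motor_rmse"], 283.63)
  tgI <- pf$groups$ID$targets
  expect_equal(tgI$mean[tgI$slot == "questionnaire_score"], 3.09)
  expect_equal(tgI$sd[tgI$slot == "questionnaire_score"], 2.32)
  # expected interaction-task availability ~ 100 of 131
  drop <- vapply(pf$groups, function(g) g$dropout[["pci"]], numeric(1))
  expect_equal(unname(40 * (1 - drop["TD"]) + 48 * (1 - drop["AS"]) +
                        43 * (1 - drop["ID"])), 100, tolerance = 0.5)
})

test_that("simulating a harder motor deficit raises extracted RMSE", {
  pf <- test_profiles()
  cfg <- test_config()
  easy <- pf$groups$TD$motor
  hard <- easy
  hard$rmse <- gamma_solve <- startpheno:::gamma_solve(500, 100, floor = 60, cap = 1100)
  r_easy <- mean(vapply(1:10, function(i) {
    motor_features(startpheno:::motor_generate(easy, pf$motor_maps, cfg, 300 + i),
                   cfg)$value["motor_rmse"]
  }, numeric(1)), na.rm = TRUE)
  r_hard <- mean(vapply(1:10, function(i) {
    motor_features(startpheno:::motor_generate(hard, pf$motor_maps, cfg, 300 + i),
                   cfg)$value["motor_rmse"]
  }, numeric(1)), na.rm = TRUE)
  expect_gt(r_hard, r_easy)
})
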