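test_that("correction factors follow the standardization walks", {
  std <- data.frame(true_m = c(5, 5, 10, 10),
                    d_response = c(5, 5, 10, 10))
  cf <- correction_factors(std)
  expect_equal(cf$cf5, 1)
  expect_equal(cf$cf10, 1)

  std2 <- data.frame(true_m = c(5, 5, 10, 10),
                     d_response = c(4, 4, 12.5, 12.5))
  cf2 <- correction_factors(std2)
  expect_equal(cf2$cf5, 1.25)
  expect_equal(cf2$cf10, 0.8)

  std3 <- data.frame(true_m = c(5, 5, 10, 10),
                     d_response = c(0, 0, 10, 10))
  expect_error(correction_factors(std3), "positive")
})

test_that("distance correction switches factors at 7.5 m", {
  expect_equal(correct_distance(6, 1.2, 1.0), 7.2)
  expect_equal(correct_distance(8, 1.2, 0.9), 7.2)
  # boundary belongs to the 5 m branch
  expect_equal(correct_distance(7.5, 1.1, 2.0), 8.25)
  expect_error(correct_distance(-1, 1, 1), "positive")
})

test_that("presumed start is stop plus the reported displacement", {
  expect_equal(presumed_start(c(0, 0), 5, 90)[1, ], c(x = 0, y = 5),
               tolerance = 1e-12)
  expect_equal(presumed_start(c(3, 4), 0, 123)[1, ], c(x = 3, y = 4))
  expect_equal(presumed_start(c(1, 1), 2, 0)[1, ], c(x = 3, y = 1))
})

test_that("segment errors match the plane-geometry oracle", {
  # start (0,0); stop1 (5,0) reported (4 m, 180 deg) -> presumed (1,0),
  # error 1; stop2 (5,5) reported (7 m, 225 deg) -> presumed
  # (5 - 7/sqrt(2), 5 - 7/sqrt(2)) ~ (0.0503, 0.0503), error vs (1,0)
  tr <- data.frame(path_id = 1, stop_index = c(1, 2),
                   start_x = 0, start_y = 0,
                   stop_x = c(5, 5), stop_y = c(0, 5),
                   true_distance_m = c(5, sqrt(50)),
                   true_orientation_deg = c(180, 225),
                   d_response = c(4, 7),
                   ori_response_deg = c(180, 225))
  errs <- segment_errors(tr, list(cf5 = 1, cf10 = 1))
  p2 <- c(5 - 7 / sqrt(2), 5 - 7 / sqrt(2))
  oracle2 <- sqrt(sum((p2 - c(1, 0))^2))
  expect_equal(errs[1], 1, tolerance = 1e-12)
  expect_equal(errs[2], oracle2, tolerance = 1e-12)
  expect_equal(oracle2, 0.951077, tolerance = 1e-5)

  # perfect reports give zero error at both stops
  perfect <- tr
  perfect$d_response <- perfect$true_distance_m
  perfect$ori_response_deg <- perfect$true_orientation_deg
  expect_equal(segment_errors(perfect, list(cf5 = 1, cf10 = 1)),
               c(0, 0), tolerance = 1e-10)

  tr$d_response[2] <- NA
  expect_error(segment_errors(tr, list(cf5 = 1, cf10 = 1)), "missing")
})

test_that("performance is the reciprocal mean error", {
  expect_equal(pi_performance(0.5)$performance, 2)
  expect_equal(pi_performance(c(1, 3))$performance, 0.5)
  p0 <- pi_performance(c(0, 0))
  expect_true(p0$perfect)
  expect_equal(p0$performance, Inf)
  expect_error(pi_performance(numeric(0)), "no errors")
})

test_that("the synthetic path fixture matches the task structure", {
  paths <- pi_session_paths()
  expect_equal(length(unique(paths$traversal)), 16)
  expect_equal(nrow(paths), 32)           # two stops per traversal
  expect_true(all(paths$true_distance_m >= 4 &
                    paths$true_distance_m <= 14))
  court <- pi_court()
  expect_true(all(paths$stop_x >= 0 & paths$stop_x <= court$width_m))
  expect_true(all(paths$stop_y >= 0 & paths$stop_y <= court$length_m))
  # orientation consistent with coordinates
  ori <- (atan2(paths$start_y - paths$stop_y,
                paths$start_x - paths$stop_x) * 180 / pi) %% 360
  expect_equal(paths$true_orientation_deg, ori)
})

test_that("a shared multiplicative bias cancels exactly", {
  paths <- pi_session_paths()
  resp <- simulate_pi_responses(
    paths, pi_behavior_model(distance_gain = 0.8, distance_cv = 0,
                             angular_sd_deg = 0), seed = 4)
  cfs <- correction_factors(resp$standardization)
  expect_equal(correct_distance(resp$responses$d_response, cfs$cf5,
                                cfs$cf10),
               paths$true_distance_m, tolerance = 1e-9)
  sc <- score_pi(resp)
  expect_true(sc$performance == Inf || sc$mean_error < 1e-9)
  # determinism
  expect_identical(resp, simulate_pi_responses(
    paths, pi_behavior_model(0.8, 0, 0), seed = 4))
})

test_that("mean error grows with angular noise", {
  paths <- pi_session_paths()
  lv <- c(5, 15, 30)
  means <- vapply(seq_along(lv), function(i) {
    mean(vapply(1:200, function(r) {
      resp <- simulate_pi_responses(
        paths, pi_behavior_model(0.9, 0.05, lv[i]),
        seed = 10000 * i + r)
      score_pi(resp)$mean_error
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("scores are invariant to a rigid motion of the court frame", {
  paths <- pi_session_paths()
  resp <- simulate_pi_responses(paths, pi_behavior_model(), seed = 6)
  base <- score_pi(resp)

  ang <- 37 * pi / 180
  Rm <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  shift <- c(3.2, -1.7)
  rot <- resp
  xy <- as.matrix(resp$responses[, c("stop_x", "stop_y")]) %*% t(Rm)
  st <- as.matrix(resp$responses[, c("start_x", "start_y")]) %*% t(Rm)
  rot$responses$stop_x <- xy[, 1] + shift[1]
  rot$responses$stop_y <- xy[, 2] + shift[2]
  rot$responses$start_x <- st[, 1] + shift[1]
  rot$responses$start_y <- st[, 2] + shift[2]
  rot$responses$ori_response_deg <-
    (rot$responses$ori_response_deg + 37) %% 360
  rot$responses$true_orientation_deg <-
    (rot$responses$true_orientation_deg + 37) %% 360
  moved <- score_pi(rot)
  expect_equal(moved$mean_error, base$mean_error, tolerance = 1e-9)
  expect_equal(moved$performance, base$performance, tolerance = 1e-9)
})
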