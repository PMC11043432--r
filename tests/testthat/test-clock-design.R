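test_that("clock positions, circular distances and chord directions", {
  expect_equal(number_position(12)[1, ], c(x = 0, y = 1))
  expect_equal(number_position(3)[1, ], c(x = 1, y = 0))
  expect_equal(number_position(7)[1, ],
               c(x = cospi(240 / 180), y = sinpi(240 / 180)))
  expect_error(number_position(0), "1..12")

  expect_identical(circular_distance(9, 12), 3L)
  expect_identical(circular_distance(1, 2), 1L)
  expect_identical(circular_distance(2, 8), 6L)
  expect_error(circular_distance(5, 5))

  expect_equal(path_direction(9, 12), 45)
  expect_equal(path_direction(12, 9), 225)
  expect_error(path_direction(4, 4))
  # reversal adds 180 for every admissible pair
  dp <- directed_paths()
  expect_equal(path_direction(dp$end, dp$start),
               (dp$direction_deg + 180) %% 360)
})

test_that("path enumeration matches the 36-path stimulus set", {
  u <- enumerate_valid_paths()
  expect_equal(nrow(u), 36)
  expect_true(all(u$circ_dist %in% 3:5))
  # adjacent pairs and diameters excluded
  expect_false(any(u$start == 1 & u$end == 2))
  expect_false(any(u$circ_dist %in% c(1, 2, 6)))
  expect_equal(as.vector(table(u$length_class)[c("short", "medium",
                                                 "long")]),
               c(12, 12, 12))

  # directed closure: 72 paths over 24 direction bins; multiples of 30
  # degrees are served by the two medium chords, odd multiples of 15 by
  # two short plus two long chords
  dp <- directed_paths()
  expect_equal(nrow(dp), 72)
  expect_equal(sort(unique(dp$direction_deg)), seq(0, 345, by = 15))
  for (b in seq(0, 345, by = 15)) {
    sub <- dp[dp$direction_deg == b, ]
    if (b %% 30 == 0) {
      expect_equal(sort(sub$circ_dist), c(4, 4))
    } else {
      expect_equal(sort(sub$circ_dist), c(3, 3, 5, 5))
    }
  }
})

test_that("left/right judgment agrees with the rotation oracle", {
  expect_equal(judge_side(9, 12, 3), "right")
  expect_equal(judge_side(9, 12, 11), "left")
  expect_error(judge_side(9, 12, 9), "target")

  dp <- directed_paths()
  for (i in seq_len(nrow(dp))) {
    s <- dp$start[i]
    e <- dp$end[i]
    for (tg in setdiff(1:12, c(s, e))) {
      oracle <- rotation_oracle_side(s, e, tg)
      if (is.na(oracle)) {
        expect_error(judge_side(s, e, tg))
      } else {
        expect_identical(judge_side(s, e, tg), oracle)
      }
    }
  }
})

test_that("admissible targets always exist on both sides", {
  dp <- directed_paths()
  for (i in seq_len(nrow(dp))) {
    adm <- gridclock:::admissible_targets(dp$start[i], dp$end[i])
    sides <- vapply(adm, function(tg) {
      judge_side(dp$start[i], dp$end[i], tg)
    }, character(1))
    expect_true(all(c("left", "right") %in% sides))
  }
})

test_that("generated runs satisfy every run invariant across seeds", {
  for (sd in 1:100) {
    run <- build_run("forward", run_index = 1L, seed = sd)
    expect_true(validate_run(run))
  }
  # determinism
  expect_identical(build_run("forward", seed = 5),
                   build_run("forward", seed = 5))
})

test_that("sessions are counterbalanced across their eight runs", {
  s <- fix_session()
  expect_identical(build_session(seed = 1), s)
  expect_length(s$runs, 8)
  expect_equal(sum(vapply(s$runs, function(r) nrow(r$trials), 1)), 192)
  expect_equal(vapply(s$runs, `[[`, "", "polarity"),
               rep(c("forward", "backward"), 4))
  for (r in s$runs) expect_true(validate_run(r))

  # backward runs traverse the forward chords in the opposite direction
  for (k in 1:4) {
    f <- sort(s$runs[[2 * k - 1]]$trials$direction_deg)
    b <- sort((s$runs[[2 * k]]$trials$direction_deg + 180) %% 360)
    expect_equal(f, b)
  }

  # every directed trajectory meets a left target in exactly half of
  # the four runs presenting it
  tr <- do.call(rbind, lapply(s$runs, function(r) {
    r$trials[, c("start", "end", "correct_side")]
  }))
  tab <- aggregate(I(correct_side == "left") ~ start + end, data = tr,
                   FUN = sum)
  expect_equal(nrow(tab), 48)
  expect_true(all(tab[[3]] == 2))
})

test_that("events tables round-trip through TSV", {
  s <- fix_session()
  d <- withr::local_tempdir()
  files <- write_events(s, d)
  evs <- read_events(d)
  expect_length(evs, 8)
  for (i in seq_along(evs)) {
    ref <- run_events(s$runs[[i]])
    expect_equal(evs[[i]], ref, ignore_attr = TRUE)
    expect_equal(sum(evs[[i]]$trial_type == "imagination"), 24)
    ang <- evs[[i]]$angle_deg[evs[[i]]$trial_type == "imagination"]
    expect_true(all(ang %% 15 == 0))
  }
})
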