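#' Court geometry for the path-integration task
#'
#' Half of a tennis court, 10.97 m wide and 11.88 m long, with the
#' origin at one corner and axes along the court lines.
#'
#' @param width_m,length_m Court dimensions in metres.
#' @return An object of class `pi_court`.
#' @export
pi_court <- function(width_m = 10.97, length_m = 11.88) {
  structure(list(width_m = width_m, length_m = length_m),
            class = "pi_court")
}

#' Synthetic path-integration path set
#'
#' Eight synthetic linear paths laid out along court grid lines within
#' the half-court, each with a start point and two stopping points whose
#' straight-line distances from the start fall in the 4--14 m range of
#' the task.  Presented twice per session (16 traversals).  These are a
#' synthetic stand-in with the same structure as the experimental paths,
#' not a reproduction of them.
#'
#' @param court A [pi_court()].
#' @param repetitions Number of presentations of each path (default 2).
#' @return Data frame with one row per (traversal, stop):
#'   `traversal`, `path_id`, `stop_index`, `start_x`, `start_y`,
#'   `stop_x`, `stop_y`, `true_distance_m`, `true_orientation_deg`
#'   (direction from the stop back to the start, math convention).
#' @export
pi_session_paths <- function(court = pi_court(), repetitions = 2L) {
  w <- court$width_m
  l <- court$length_m
  # start (x, y), stop1 (x, y), stop2 (x, y); along-line segments
  raw <- list(
    c(0.5, 0.5,    0.5, 6.0,   6.0, 6.0),
    c(10.5, 0.5,   5.0, 0.5,   5.0, 8.0),
    c(0.5, 11.0,   6.5, 11.0,  6.5, 3.0),
    c(10.5, 11.0,  10.5, 4.0,  2.5, 4.0),
    c(5.5, 0.5,    5.5, 9.0,   1.0, 9.0),
    c(0.5, 5.5,    8.0, 5.5,   8.0, 11.0),
    c(10.0, 6.0,   3.0, 6.0,   3.0, 0.5),
    c(2.0, 0.5,    2.0, 7.5,   9.5, 7.5))
  rows <- list()
  for (p in seq_along(raw)) {
    v <- raw[[p]]
    start <- v[1:2]
    stops <- list(v[3:4], v[5:6])
    for (s in 1:2) {
      st <- stops[[s]]
      stopifnot(st[1] >= 0, st[1] <= w, st[2] >= 0, st[2] <= l)
      d <- sqrt(sum((start - st)^2))
      ori <- (atan2(start[2] - st[2], start[1] - st[1]) * 180 / pi) %% 360
      rows[[length(rows) + 1]] <- data.frame(
        path_id = p, stop_index = s, start_x = start[1],
        start_y = start[2], stop_x = st[1], stop_y = st[2],
        true_distance_m = d, true_orientation_deg = ori)
    }
  }
  one <- do.call(rbind, rows)
  stopifnot(all(one$true_distance_m >= 4 - 1e-9),
            all(one$true_distance_m <= 14 + 1e-9))
  out <- do.call(rbind, lapply(seq_len(repetitions), function(rep) {
    o <- one
    o$traversal <- (rep - 1L) * 8L + o$path_id
    o
  }))
  rownames(out) <- NULL
  out[, c("traversal", "path_id", "stop_index", "start_x", "start_y",
          "stop_x", "stop_y", "true_distance_m", "true_orientation_deg")]
}

#' Behavioural model for path-integration responses
#'
#' Reported distances are `distance_gain * true * (1 + eps)` with
#' `eps ~ N(0, distance_cv)`; reported orientations are the true
#' stop-to-start direction plus Gaussian angular noise.
#'
#' @param distance_gain Multiplicative distance bias (> 0; < 1 means
#'   underestimation).
#' @param distance_cv Coefficient of variation of reported distance.
#' @param angular_sd_deg SD of orientation error in degrees.
#' @return An object of class `pi_behavior_model`.
#' @export
pi_behavior_model <- function(distance_gain = 0.9, distance_cv = 0.15,
                              angular_sd_deg = 15) {
  stopifnot(distance_gain > 0, distance_cv >= 0, angular_sd_deg >= 0)
  structure(list(distance_gain = distance_gain,
                 distance_cv = distance_cv,
                 angular_sd_deg = angular_sd_deg),
            class = "pi_behavior_model")
}

#' Simulate path-integration responses
#'
#' Generates distance and orientation reports for every stop of every
#' traversal, plus the 5 m and 10 m standardization-walk reports
#' (administered at session start and end), all under the same
#' multiplicative distance bias so that the correction-factor procedure
#' can recover true distances.
#'
#' @param paths A [pi_session_paths()] table.
#' @param model A [pi_behavior_model()].
#' @param seed Integer seed.
#' @return List with `responses` (the `paths` table plus `d_response`
#'   and `ori_response_deg`) and `standardization` (data frame with
#'   `true_m`, `administration`, `d_response`).
#' @export
simulate_pi_responses <- function(paths, model = pi_behavior_model(),
                                  seed = 1L) {
  with_seed(seed, {
    n <- nrow(paths)
    resp <- paths
    resp$d_response <- model$distance_gain * paths$true_distance_m *
      (1 + stats::rnorm(n, 0, model$distance_cv))
    resp$d_response <- pmax(resp$d_response, 0.1)
    resp$ori_response_deg <- (paths$true_orientation_deg +
                                stats::rnorm(n, 0,
                                             model$angular_sd_deg)) %% 360
    std <- expand.grid(true_m = c(5, 10), administration = c(1L, 2L))
    std$d_response <- pmax(
      model$distance_gain * std$true_m *
        (1 + stats::rnorm(nrow(std), 0, model$distance_cv)), 0.1)
    list(responses = resp, standardization = std)
  })
}

#' Distance correction factors from the standardization walks
#'
#' Responses to each standardization distance are averaged over the two
#' administrations, and the correction factor is the true distance
#' divided by the averaged response.
#'
#' @param standardization Data frame with columns `true_m` (5 or 10)
#'   and `d_response` (two rows per distance), or a list holding it.
#' @return List with `cf5` and `cf10`.
#' @export
correction_factors <- function(standardization) {
  if (is.list(standardization) && !is.data.frame(standardization) &&
      !is.null(standardization$standardization)) {
    standardization <- standardization$standardization
  }
  avg <- function(d) mean(standardization$d_response[
    standardization$true_m == d])
  a5 <- avg(5)
  a10 <- avg(10)
  if (!is.finite(a5) || !is.finite(a10) || a5 <= 0 || a10 <= 0) {
    stop("standardization responses must be positive")
  }
  list(cf5 = 5 / a5, cf10 = 10 / a10)
}

#' Correct a reported distance
#'
#' Reported distances up to 7.5 m are scaled by the 5 m correction
#' factor and larger ones by the 10 m factor (the sub-4 m tail, possible
#' in synthetic data, also uses the 5 m factor).
#'
#' @param d_response Reported distance in metres (> 0, vectorised).
#' @param cf5,cf10 Correction factors from [correction_factors()].
#' @return Corrected distance(s) in metres.
#' @export
correct_distance <- function(d_response, cf5, cf10) {
  if (any(d_response <= 0)) stop("reported distances must be positive")
  ifelse(d_response <= 7.5, d_response * cf5, d_response * cf10)
}

#' Presumed starting position implied by one report
#'
#' From a stop at `stop_xy`, walking the corrected distance in the
#' reported direction lands on the presumed start:
#' `stop + d * (cos(ori), sin(ori))`.
#'
#' @param stop_xy Numeric length-2 (or n x 2 matrix) stop coordinates.
#' @param d_corrected Corrected distance(s) in metres.
#' @param ori_deg Reported orientation(s) in degrees, court frame.
#' @return Matrix with columns `x`, `y`.
#' @export
presumed_start <- function(stop_xy, d_corrected, ori_deg) {
  if (is.vector(stop_xy)) stop_xy <- matrix(stop_xy, ncol = 2)
  a <- ori_deg * pi / 180
  cbind(x = stop_xy[, 1] + d_corrected * cos(a),
        y = stop_xy[, 2] + d_corrected * sin(a))
}

#' Per-stop path-integration errors for one traversal
#'
#' The error at each stop is the Euclidean distance between the
#' presumed start estimated there and the presumed start estimated at
#' the previous stop (the true start for the first stop), scoring each
#' path segment independently of cumulative drift.  A perfect
#' integrator scores zero at every stop.
#'
#' @param traversal Data frame with the two stops of one traversal
#'   (columns as in [pi_session_paths()] plus `d_response`,
#'   `ori_response_deg`).
#' @param cfs Correction factors list (`cf5`, `cf10`).
#' @return Numeric vector of per-stop errors in metres (stop order).
#' @export
segment_errors <- function(traversal, cfs) {
  traversal <- traversal[order(traversal$stop_index), , drop = FALSE]
  if (any(is.na(traversal$d_response)) ||
      any(is.na(traversal$ori_response_deg))) {
    stop("missing response")
  }
  d <- correct_distance(traversal$d_response, cfs$cf5, cfs$cf10)
  ps <- presumed_start(cbind(traversal$stop_x, traversal$stop_y), d,
                       traversal$ori_response_deg)
  prev <- rbind(c(traversal$start_x[1], traversal$start_y[1]),
                ps[-nrow(ps), , drop = FALSE])
  sqrt(rowSums((ps - prev)^2))
}

#' Path-integration performance
#'
#' Errors are averaged across stopping points and traversals; the
#' performance score is the reciprocal of the mean error.
#'
#' @param errors Numeric vector of per-stop errors (nonempty).
#' @return List with `mean_error`, `performance` (and `perfect = TRUE`
#'   with infinite performance when the mean error is zero).
#' @export
pi_performance <- function(errors) {
  if (length(errors) == 0) stop("no errors supplied")
  m <- mean(errors)
  if (m == 0) {
    return(list(mean_error = 0, performance = Inf, perfect = TRUE))
  }
  list(mean_error = m, performance = 1 / m, perfect = FALSE)
}

#' Score a full path-integration session
#'
#' Applies the standardization correction, computes presumed starts and
#' per-stop errors for every traversal, and summarises performance.
#'
#' @param responses Output of [simulate_pi_responses()] (or a list with
#'   the same `responses` / `standardization` fields from real data).
#' @return An object of class `pi_scorecard`: `cf5`, `cf10`, `errors`
#'   (per-stop table), `mean_error`, `performance`.
#' @export
score_pi <- function(responses) {
  cfs <- correction_factors(responses$standardization)
  tab <- responses$responses
  errs <- do.call(rbind, lapply(split(tab, tab$traversal), function(tr) {
    data.frame(traversal = tr$traversal[order(tr$stop_index)],
               stop_index = sort(tr$stop_index),
               error_m = segment_errors(tr, cfs))
  }))
  rownames(errs) <- NULL
  perf <- pi_performance(errs$error_m)
  structure(list(cf5 = cfs$cf5, cf10 = cfs$cf10, errors = errs,
                 mean_error = perf$mean_error,
                 performance = perf$performance),
            class = "pi_scorecard")
}

#' @export
print.pi_scorecard <- function(x, ...) {
  cat(sprintf(
    "<pi_scorecard> Cf5 = %.3f, Cf10 = %.3f, mean error = %.3f m, performance = %.3f\n",
    x$cf5, x$cf10, x$mean_error, x$performance))
  invisible(x)
}
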