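#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators do not
#' perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  code
}

#' Choose a balanced 24-path combination
#'
#' Selects one directed path per 15-degree direction bin (24 bins), with
#' six short, twelve medium and six long paths, such that every clock
#' number serves as a start or end point exactly four times.  Directions
#' that are multiples of 30 degrees are only reachable by medium
#' (distance-4) chords, so the medium quota is spent there; odd multiples
#' of 15 choose between short and long chords.  A randomised backtracking
#' search over the candidate chords satisfies the endpoint balance.
#'
#' @param space A [clock_space()].
#' @param max_nodes,max_restarts Search budget before declaring the
#'   design unsatisfiable.
#' @return A data frame of 24 directed paths (columns as in
#'   [directed_paths()]), in unspecified order.
#' @export
choose_path_set <- function(space = clock_space(), max_nodes = 50000,
                            max_restarts = 20) {
  dp <- directed_paths(space)
  bins <- sort(unique(dp$direction_deg))   # 0, 15, ..., 345 -> 24 bins
  lc_idx <- match(dp$length_class, c("short", "medium", "long"))
  chord_id <- pmin(dp$start, dp$end) * 16L + pmax(dp$start, dp$end)
  cand <- lapply(bins, function(b) which(dp$direction_deg == b))

  for (restart in seq_len(max_restarts)) {
    order_bins <- sample(length(bins))
    counts <- integer(12)          # endpoint usage per clock number
    quota <- c(6L, 12L, 6L)        # short / medium / long
    used <- integer(0)             # unordered chords already taken
    chosen <- integer(length(bins))
    nodes <- 0L

    search <- function(i) {
      if (i > length(order_bins)) return(TRUE)
      nodes <<- nodes + 1L
      if (nodes > max_nodes) return(NA)
      b <- order_bins[i]
      cc <- cand[[b]]
      for (j in sample(length(cc))) {
        k <- cc[j]
        lc <- lc_idx[k]
        s <- dp$start[k]
        e <- dp$end[k]
        if (quota[lc] == 0L || chord_id[k] %in% used) next
        if (counts[s] >= 4L || counts[e] >= 4L) next
        counts[c(s, e)] <<- counts[c(s, e)] + 1L
        quota[lc] <<- quota[lc] - 1L
        used <<- c(used, chord_id[k])
        chosen[b] <<- k
        res <- search(i + 1L)
        if (isTRUE(res)) return(TRUE)
        counts[c(s, e)] <<- counts[c(s, e)] - 1L
        quota[lc] <<- quota[lc] + 1L
        used <<- used[-length(used)]
        chosen[b] <<- 0L
        if (is.na(res)) return(NA)
      }
      FALSE
    }
    res <- search(1L)
    if (isTRUE(res)) {
      out <- dp[chosen, ]
      rownames(out) <- NULL
      return(out)
    }
  }
  stop("unsatisfiable design: path-set search exhausted its budget")
}

# Order 24 directed paths to maximise end->start chaining (greedy with
# random restarts); returns row indices plus a jump flag per position.
order_for_chaining <- function(paths, n_restarts = 40) {
  best <- NULL
  best_jumps <- Inf
  n <- nrow(paths)
  for (r in seq_len(n_restarts)) {
    remaining <- seq_len(n)
    ord <- integer(n)
    jump <- logical(n)
    cur_end <- NA_integer_
    for (k in seq_len(n)) {
      nxt <- remaining[which(paths$start[remaining] == cur_end)]
      if (length(nxt) == 0L) {
        nxt <- remaining
        jump[k] <- k > 1L      # first trial starts fresh, no jump cue
      }
      pick <- if (length(nxt) == 1L) nxt else sample(nxt, 1L)
      ord[k] <- pick
      cur_end <- paths$end[pick]
      remaining <- setdiff(remaining, pick)
    }
    nj <- sum(jump)
    if (nj < best_jumps) {
      best <- list(order = ord, jump = jump)
      best_jumps <- nj
      if (nj == 0L) break
    }
  }
  best
}

#' Build one counterbalanced run
#'
#' Assembles 24 trials covering all 24 direction bins exactly once with
#' the 6/12/6 short/medium/long mix, endpoint balance (each number used
#' as start or end four times), maximal end-to-start chaining with jump
#' cues where chaining breaks, jittered imagination durations, and
#' left/right-balanced target numbers.
#'
#' Trial timing: start cue 0.5 s, 0.5 s gap, end cue 0.5 s, imagination
#' for 4--6 s (0.5 s steps), target cue 0.5 s, 2 s response window,
#' 0.5 s inter-trial gap; a jump cue adds 0.5 s instruction plus 4 s
#' reorientation before the trial.
#'
#' @param polarity `"forward"` or `"backward"`.
#' @param run_index Integer 1..8.
#' @param seed Optional integer seed (the run is deterministic given it).
#' @param paths Optional 24-row directed path set (forward orientation is
#'   used as-is; pass the already-reversed set for backward runs).  When
#'   `NULL` a fresh set is chosen.
#' @param sides Optional character vector of required target sides
#'   aligned with the rows of `paths`; must contain 12 `"left"` and 12
#'   `"right"`.  When `NULL` a balanced assignment is drawn.
#' @param space A [clock_space()].
#' @return An object of class `run_design`: a list with `trials` (data
#'   frame), `polarity`, `run_index`, `duration_s`.
#' @export
build_run <- function(polarity = c("forward", "backward"), run_index = 1L,
                      seed = NULL, paths = NULL, sides = NULL,
                      space = clock_space()) {
  polarity <- match.arg(polarity)
  with_seed(seed, {
    if (is.null(paths)) {
      paths <- choose_path_set(space)
      if (polarity == "backward") {
        paths <- reverse_path_set(paths, space)
      }
    }
    stopifnot(nrow(paths) == 24)
    if (is.null(sides)) {
      sides <- sample(rep(c("left", "right"), each = 12))
    }
    stopifnot(sum(sides == "left") == 12)

    ordn <- order_for_chaining(paths)
    trials <- paths[ordn$order, , drop = FALSE]
    trials$jump_flag <- ordn$jump
    req_side <- sides[ordn$order]

    # target numbers: admissible and on the required side
    trials$target <- NA_integer_
    trials$correct_side <- req_side
    for (k in seq_len(24)) {
      adm <- admissible_targets(trials$start[k], trials$end[k], space)
      sd <- judge_side(rep(trials$start[k], length(adm)),
                       rep(trials$end[k], length(adm)), adm, space)
      ok <- adm[sd == req_side[k]]
      if (length(ok) == 0L) {
        stop("unsatisfiable design: no admissible target on required side")
      }
      trials$target[k] <- if (length(ok) == 1L) ok else sample(ok, 1L)
    }

    # timing
    dur_choices <- seq(4, 6, by = 0.5)
    t <- 2.0
    n <- nrow(trials)
    trials$jump_onset_s <- NA_real_
    trials$start_cue_s <- NA_real_
    for (k in seq_len(n)) {
      if (trials$jump_flag[k]) {
        trials$jump_onset_s[k] <- t
        t <- t + 0.5 + 4.0
      }
      trials$start_cue_s[k] <- t
      t <- t + 1.0
      trials$end_cue_s[k] <- t
      trials$imagination_onset_s[k] <- t + 1.0
      d <- sample(dur_choices, 1L)
      trials$imagination_duration_s[k] <- d
      trials$target_onset_s[k] <- trials$imagination_onset_s[k] + d
      trials$response_window_s[k] <- 2.0
      t <- trials$target_onset_s[k] + 0.5 + 2.0 + 0.5
    }
    rownames(trials) <- NULL
    structure(list(trials = trials, polarity = polarity,
                   run_index = as.integer(run_index),
                   duration_s = ceiling(t + 8)),
              class = "run_design")
  })
}

# swap start/end of a path set and recompute directions
reverse_path_set <- function(paths, space = clock_space()) {
  rev <- data.frame(start = paths$end, end = paths$start,
                    circ_dist = paths$circ_dist,
                    length_class = paths$length_class)
  rev$direction_deg <- path_direction(rev$start, rev$end, space)
  rev[, c("start", "end", "direction_deg", "circ_dist", "length_class")]
}

#' @export
print.run_design <- function(x, ...) {
  cat(sprintf("<run_design> run %d (%s), 24 trials, %d jump(s), %.0f s\n",
              x$run_index, x$polarity, sum(x$trials$jump_flag),
              x$duration_s))
  invisible(x)
}

#' Build a full 8-run session
#'
#' One 24-path combination is chosen and presented in its standard
#' orientation in the four forward runs and reversed in the four backward
#' runs, interleaved (F B F B F B F B).  Target sides are counterbalanced
#' so that each trajectory's target lies on the left in exactly two of
#' the four runs presenting it and on the right in the other two, while
#' every run individually holds a 12/12 left/right balance.
#'
#' @param seed Integer seed; the session is deterministic given it.
#' @param space A [clock_space()].
#' @param path_set Optional 24-row directed path set to present (e.g.
#'   to hold the chosen combination fixed across participants while
#'   randomising trial order, jitter and targets); a fresh one is
#'   chosen when `NULL`.
#' @return An object of class `session_design`: `runs` (list of eight
#'   [build_run()] results), `path_set`, `seed`.
#' @export
build_session <- function(seed = 1L, space = clock_space(),
                          path_set = NULL) {
  with_seed(seed, {
    fwd <- if (is.null(path_set)) choose_path_set(space) else path_set
    bwd <- reverse_path_set(fwd, space)

    # per-trajectory side patterns: the six 2-subsets of the four runs of
    # a polarity, each used by four trajectories -> every run sums to 12
    side_matrix <- function() {
      subs <- utils::combn(4, 2, simplify = FALSE)
      pat <- sample(rep(seq_along(subs), each = 4))   # one per trajectory
      m <- matrix("right", nrow = 24, ncol = 4)
      for (i in seq_len(24)) m[i, subs[[pat[i]]]] <- "left"
      m
    }
    sides_f <- side_matrix()
    sides_b <- side_matrix()

    runs <- vector("list", 8)
    for (r in 1:8) {
      fwd_run <- r %% 2 == 1L               # interleaved, forward first
      pos <- ceiling(r / 2)                 # polarity-local run position
      runs[[r]] <- build_run(
        polarity = if (fwd_run) "forward" else "backward",
        run_index = r, seed = NULL,
        paths = if (fwd_run) fwd else bwd,
        sides = if (fwd_run) sides_f[, pos] else sides_b[, pos],
        space = space)
    }
    structure(list(runs = runs, path_set = fwd, seed = seed),
              class = "session_design")
  })
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design> 8 runs x 24 trials (seed %d)\n", x$seed))
  invisible(x)
}

#' Event table for one run
#'
#' BIDS-style long-format events: one row per start cue, end cue,
#' imagination period, jump cue, target cue and response window, with
#' onset and duration in seconds from run start.
#'
#' @param run A `run_design`.
#' @return A data frame with columns `onset`, `duration`, `trial_type`,
#'   `trial`, `angle_deg`, `target_number`, `correct_side`.
#' @export
run_events <- function(run) {
  tr <- run$trials
  n <- nrow(tr)
  mk <- function(type, onset, duration, trial, angle = NA_real_,
                 target = NA_integer_, side = NA_character_) {
    data.frame(onset = onset, duration = duration, trial_type = type,
               trial = trial, angle_deg = angle, target_number = target,
               correct_side = side)
  }
  ev <- rbind(
    mk("start_cue", tr$start_cue_s, 0.5, seq_len(n)),
    mk("end_cue", tr$end_cue_s, 0.5, seq_len(n)),
    mk("imagination", tr$imagination_onset_s, tr$imagination_duration_s,
       seq_len(n), angle = tr$direction_deg),
    mk("target", tr$target_onset_s, 0.5, seq_len(n),
       target = tr$target, side = tr$correct_side),
    mk("response", tr$target_onset_s + 0.5, tr$response_window_s,
       seq_len(n)))
  jumps <- which(tr$jump_flag)
  if (length(jumps)) {
    ev <- rbind(ev, mk("jump", tr$jump_onset_s[jumps], 4.5, jumps))
  }
  ev <- ev[order(ev$onset, ev$trial_type), ]
  rownames(ev) <- NULL
  ev
}

#' Write per-run events TSV files
#'
#' One tab-separated events file per run (`run-01_events.tsv`, ...), BIDS
#' conventions: dot decimal, seconds from run start, `n/a` for missing.
#'
#' @param session A `session_design`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_events <- function(session, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(session$runs))
  for (i in seq_along(session$runs)) {
    ev <- run_events(session$runs[[i]])
    for (cl in names(ev)) ev[[cl]][is.na(ev[[cl]])] <- NA  # keep NA typed
    f <- file.path(dir, sprintf("run-%02d_events.tsv", i))
    utils::write.table(ev, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "n/a")
    paths[i] <- f
  }
  invisible(paths)
}

#' Read per-run events TSV files
#'
#' @param files Character vector of events-TSV paths (or a directory
#'   containing `run-*_events.tsv` files).
#' @return A list of event data frames, one per run.
#' @export
read_events <- function(files) {
  if (length(files) == 1 && dir.exists(files)) {
    files <- sort(list.files(files, pattern = "run-.*_events\\.tsv$",
                             full.names = TRUE))
  }
  lapply(files, function(f) {
    ev <- utils::read.delim(f, na.strings = "n/a",
                            stringsAsFactors = FALSE)
    ev
  })
}

#' Check run-design invariants
#'
#' Validates direction coverage (all 24 bins once), endpoint balance
#' (each number start-or-end four times), length mix (6/12/6), target
#' side balance (12/12), target admissibility and end-to-start chaining
#' of non-jump trials.
#'
#' @param run A `run_design`.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
validate_run <- function(run) {
  tr <- run$trials
  stopifnot(nrow(tr) == 24)
  if (!setequal(tr$direction_deg %% 360, seq(0, 345, by = 15)) ||
      anyDuplicated(tr$direction_deg)) {
    stop("direction bins not covered exactly once")
  }
  cnt <- table(factor(c(tr$start, tr$end), levels = 1:12))
  if (any(cnt != 4)) stop("endpoint counts differ from 4")
  mix <- table(factor(tr$length_class,
                      levels = c("short", "medium", "long")))
  if (!all(mix == c(6, 12, 6))) stop("length mix is not 6/12/6")
  if (sum(tr$correct_side == "left") != 12) stop("side balance violated")
  for (k in seq_len(24)) {
    adm <- admissible_targets(tr$start[k], tr$end[k])
    if (!(tr$target[k] %in% adm)) stop("inadmissible target")
    if (judge_side(tr$start[k], tr$end[k], tr$target[k]) !=
        tr$correct_side[k]) {
      stop("recorded side disagrees with geometry")
    }
  }
  chain_ok <- tr$jump_flag[-1] | (tr$start[-1] == tr$end[-24])
  if (!all(chain_ok)) stop("non-jump trial breaks the chain")
  invisible(TRUE)
}
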