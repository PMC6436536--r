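#' The 12 ratio levels of the dot-comparison task
#'
#' Difficulty levels are ordered from easiest (index 0, ratio 1:3) to hardest
#' (index 11, ratio 11:12).  Each level has a fixed pair of dot counts chosen
#' to keep the total as close to 20 as possible.  Level 0 is used only in the
#' practice phase; test sessions start at, and never drop below, level 1
#' (ratio 1:2).
#'
#' @return A data frame with columns `index` (0..11), `ratio_label`,
#'   `n_small`, `n_large`.
#' @export
level_table <- function() {
  data.frame(
    index = 0:11,
    ratio_label = c("1:3", "1:2", "2:3", "3:4", "4:5", "5:6", "6:7",
                    "7:8", "8:9", "9:10", "10:11", "11:12"),
    n_small = c(5, 7, 8, 9, 8, 10, 12, 7, 8, 9, 10, 11),
    n_large = c(15, 14, 12, 12, 10, 12, 14, 8, 9, 10, 11, 12),
    stringsAsFactors = FALSE
  )
}

TEST_FLOOR <- 1L   # 1:2 — errors at this level do not demote further
TEST_CEIL  <- 11L  # 11:12 — promotions clamp here

#' Two-up/one-down level transition
#'
#' One wrong answer demotes a level (with a floor at the 1:2 ratio); two
#' consecutive correct answers at the same level promote (with a ceiling at
#' the hardest 11:12 ratio).  The consecutive-correct counter is managed by
#' the caller and resets on every level change and every wrong answer.
#'
#' @param current_index Current level index, 1..11 (test sessions never visit
#'   level 0).
#' @param outcome `"correct"` or `"wrong"`.
#' @param consecutive_correct_at_level Number of immediately preceding
#'   consecutive correct answers at this level (0 or more).
#' @return The next level index.
#' @export
next_level <- function(current_index, outcome = c("correct", "wrong"),
                       consecutive_correct_at_level = 0L) {
  outcome <- match.arg(outcome)
  if (!is.numeric(current_index) || length(current_index) != 1L ||
      current_index < TEST_FLOOR || current_index > TEST_CEIL)
    stop("`current_index` must be in 1..11", call. = FALSE)
  current_index <- as.integer(current_index)
  if (outcome == "wrong") return(max(current_index - 1L, TEST_FLOOR))
  if (consecutive_correct_at_level >= 1L)
    return(min(current_index + 1L, TEST_CEIL))
  current_index
}

#' Build a shuffled 8-trial deck for one level
#'
#' Each level has eight stimulus versions: four where red is the more
#' numerous (correct) colour and four where black is.  Decks are drawn
#' without replacement during a session and reshuffled when exhausted.
#'
#' @param level One row of [level_table()] (or its `index`).
#' @param rng_seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A data frame of 8 rows: `version` (1..8) and `correct_color`.
#' @export
build_trial_deck <- function(level, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  deck <- data.frame(
    version = 1:8,
    correct_color = rep(c("red", "black"), each = 4),
    stringsAsFactors = FALSE
  )
  deck[sample.int(8L), , drop = FALSE]
}

#' Simulate one 30-trial staircase session
#'
#' Responses are drawn from the Gaussian ANS model at the given Weber
#' fraction, the level sequence follows the two-up/one-down rule starting at
#' the 1:2 ratio, and trial stimuli are dealt from per-level 8-trial decks
#' (reshuffled when exhausted).  The whole record is replayable from `seed`.
#'
#' @param w True Weber fraction of the simulated responder.
#' @param task `"cards"` or `"computer"`.
#' @param participant_id Identifier stored on every trial.
#' @param seed Integer seed; the session is a pure function of it.
#' @param n_trials Number of test trials (default 30).
#' @param lapse Lapse rate of the simulated responder (default 0).
#' @return An object of class `session_record`: list with `participant_id`,
#'   `task`, `seed`, and `trials`, a data frame of one row per trial
#'   (`trial_index`, `level_index`, `ratio_label`, `n_small`, `n_large`,
#'   `n_red`, `n_black`, `correct_color`, `response_color`, `is_correct`,
#'   `deck_version`).
#' @export
simulate_session <- function(w, task = c("cards", "computer"),
                             participant_id = "sim", seed = 1L,
                             n_trials = 30L, lapse = 0) {
  task <- match.arg(task)
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("`w` must be a single positive number", call. = FALSE)
  set.seed(seed)
  lt <- level_table()

  # per-level deck state: shuffled version order + pointer
  deck_order <- vector("list", 12L)
  deck_pos <- integer(12L)
  deal <- function(idx) {
    k <- idx + 1L
    if (is.null(deck_order[[k]]) || deck_pos[k] >= 8L) {
      deck_order[[k]] <<- sample.int(8L)
      deck_pos[k] <<- 0L
    }
    deck_pos[k] <<- deck_pos[k] + 1L
    deck_order[[k]][deck_pos[k]]
  }

  current <- TEST_FLOOR
  streak <- 0L
  rows <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    lev <- lt[current + 1L, ]
    version <- deal(current)
    correct_color <- if (version <= 4L) "red" else "black"
    p <- p_correct(lev$n_small, lev$n_large, w)
    p_eff <- (1 - lapse) * p + lapse * 0.5
    ok <- stats::runif(1) < p_eff
    rows[[i]] <- data.frame(
      participant_id = participant_id, task = task, trial_index = i,
      level_index = lev$index, ratio_label = lev$ratio_label,
      n_small = lev$n_small, n_large = lev$n_large,
      n_red = if (correct_color == "red") lev$n_large else lev$n_small,
      n_black = if (correct_color == "black") lev$n_large else lev$n_small,
      correct_color = correct_color,
      response_color = if (ok) correct_color else setdiff(c("red", "black"), correct_color),
      is_correct = ok, deck_version = version,
      stringsAsFactors = FALSE
    )
    nxt <- next_level(current, if (ok) "correct" else "wrong", streak)
    # counter resets on any wrong answer and whenever the two-in-a-row rule
    # fires (even when clamped at the hardest level)
    streak <- if (ok && streak < 1L) 1L else 0L
    current <- nxt
  }
  structure(list(participant_id = participant_id, task = task, seed = seed,
                 trials = do.call(rbind, rows)),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("Staircase session: %s / %s, %d trials, %.0f%% correct (seed %d)\n",
              x$participant_id, x$task, nrow(x$trials),
              100 * mean(x$trials$is_correct), x$seed))
  invisible(x)
}

#' Replay-validate a session's level sequence
#'
#' Re-derives the level trajectory from the outcome sequence via
#' [next_level()] and checks it matches the recorded `level_index` column,
#' that trials start at the 1:2 level with consecutive `trial_index`, and
#' that per-level deck versions repeat only after all 8 are used.
#'
#' @param session A `session_record` or its trials data frame.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_session <- function(session) {
  tr <- if (inherits(session, "session_record")) session$trials else session
  stopifnot(is.data.frame(tr), nrow(tr) >= 1)
  if (tr$level_index[1] != TEST_FLOOR)
    stop("session must start at the 1:2 level", call. = FALSE)
  if (!identical(as.integer(tr$trial_index), seq_len(nrow(tr))))
    stop("trial_index must be consecutive from 1", call. = FALSE)
  current <- TEST_FLOOR; streak <- 0L
  for (i in seq_len(nrow(tr))) {
    if (tr$level_index[i] != current)
      stop(sprintf("trial %d: level %d does not follow the staircase rule (expected %d)",
                   i, tr$level_index[i], current), call. = FALSE)
    ok <- tr$is_correct[i]
    nxt <- next_level(current, if (ok) "correct" else "wrong", streak)
    streak <- if (ok && streak < 1L) 1L else 0L
    current <- nxt
  }
  if ("deck_version" %in% names(tr)) {
    for (lev in unique(tr$level_index)) {
      v <- tr$deck_version[tr$level_index == lev]
      for (start in seq(1, length(v), by = 8)) {
        blk <- v[start:min(start + 7, length(v))]
        if (anyDuplicated(blk))
          stop(sprintf("level %d: deck version repeated before deck exhausted", lev),
               call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Run the practice phase for a simulated responder
#'
#' Practice is eight trials at the easiest (1:3, 5 vs 15) ratio; an attempt
#' passes only with zero errors, and a responder gets at most three attempts.
#'
#' @param w True Weber fraction.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param lapse Lapse rate.
#' @return List of class `practice_result`: `passed`, `attempts_used`,
#'   `per_attempt_errors`.
#' @export
run_practice <- function(w, seed = NULL, lapse = 0) {
  if (!is.null(seed)) set.seed(seed)
  lt <- level_table()
  p <- p_correct(lt$n_small[1], lt$n_large[1], w)
  p_eff <- (1 - lapse) * p + lapse * 0.5
  errors <- integer(0)
  passed <- FALSE
  for (attempt in 1:3) {
    e <- sum(stats::runif(8) >= p_eff)
    errors <- c(errors, e)
    if (e == 0L) { passed <- TRUE; break }
  }
  structure(list(passed = passed, attempts_used = length(errors),
                 per_attempt_errors = errors),
            class = "practice_result")
}
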