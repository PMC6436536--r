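TRIALS_COLS <- c("participant_id", "task", "trial_index", "level_index",
                 "ratio_label", "n_red", "n_black", "correct_color",
                 "response_color")
COHORT_COLS <- c("participant_id", "education_years", "age_years", "gender",
                 "computer_first", "logw_cards", "logw_computer")

#' Write trial records to a trials CSV
#'
#' The trials file is a plain RFC-4180 CSV with header
#' `participant_id, task, trial_index, level_index, ratio_label, n_red,
#' n_black, correct_color, response_color`.
#'
#' @param records A `session_record`, a list of them, or a trials data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  if (inherits(records, "session_record")) records <- list(records)
  tr <- if (is.data.frame(records)) records
        else do.call(rbind, lapply(records, function(s) s$trials))
  miss <- setdiff(TRIALS_COLS, names(tr))
  if (length(miss))
    stop("trials lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(tr[, TRIALS_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a trials CSV
#'
#' Parses a trials file (see [write_trials()] for the dialect), validates
#' every row against the level table (counts must be exactly the level's
#' fixed pair, labels must match, tasks and colours must be known), and
#' derives `n_small`, `n_large` and `is_correct`.  Malformed rows are
#' reported with their file line number.
#'
#' @param path Path to a trials CSV.
#' @return A list of `session_record` objects, one per participant-task
#'   session, trials ordered by `trial_index`.  A header-only file gives an
#'   empty list.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIALS_COLS, names(tr))
  if (length(miss))
    stop("trials file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(tr) == 0L) return(list())

  line <- seq_len(nrow(tr)) + 1L  # header is line 1
  bad <- function(cond, what) {
    if (any(cond))
      stop(sprintf("%s (line %s)", what,
                   paste(line[cond][seq_len(min(5, sum(cond)))], collapse = ", ")),
           call. = FALSE)
  }
  bad(!tr$task %in% c("cards", "computer"), "unknown task label")
  bad(!tr$correct_color %in% c("red", "black"), "unknown correct_color")
  bad(!tr$response_color %in% c("red", "black"), "unknown response_color")
  suppressWarnings({
    n_red <- as.numeric(tr$n_red); n_black <- as.numeric(tr$n_black)
  })
  bad(is.na(n_red) | is.na(n_black) | n_red %% 1 != 0 | n_black %% 1 != 0,
      "dot counts must be integers")

  lt <- level_table()
  idx <- match(tr$level_index, lt$index)
  bad(is.na(idx), "unknown level_index")
  ns <- pmin(n_red, n_black); nl <- pmax(n_red, n_black)
  bad(ns != lt$n_small[idx] | nl != lt$n_large[idx],
      "dot counts do not match the level's fixed pair")
  bad(tr$ratio_label != lt$ratio_label[idx],
      "ratio_label does not match level_index")

  tr$n_red <- as.integer(n_red); tr$n_black <- as.integer(n_black)
  tr$n_small <- as.integer(ns); tr$n_large <- as.integer(nl)
  tr$is_correct <- tr$response_color == tr$correct_color

  key <- paste(tr$participant_id, tr$task, sep = "\r")
  lapply(split(tr, factor(key, levels = unique(key))), function(d) {
    d <- d[order(d$trial_index), ]
    rownames(d) <- NULL
    structure(list(participant_id = d$participant_id[1], task = d$task[1],
                   seed = NA_integer_, trials = d),
              class = "session_record")
  })
}

#' Write / read a cohort CSV
#'
#' One row per participant: `participant_id, education_years, age_years,
#' gender, computer_first, logw_cards, logw_computer`.
#'
#' @param cohort Wide cohort data frame (or `ans_cohort`).
#' @param path File path.
#' @return `write_cohort`: `path` invisibly; `read_cohort`: the validated
#'   data frame.
#' @export
write_cohort <- function(cohort, path) {
  if (inherits(cohort, "ans_cohort")) cohort <- cohort$cohort
  miss <- setdiff(COHORT_COLS, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(cohort[, COHORT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLS, names(d))
  if (length(miss))
    stop("cohort file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d)) {
    if (anyDuplicated(d$participant_id))
      stop("duplicate participant_id in cohort file", call. = FALSE)
    if (any(d$education_years %% 1 != 0 | d$education_years < 0 |
              d$education_years > 16, na.rm = TRUE))
      stop("education_years must be whole numbers in 0..16", call. = FALSE)
    d$computer_first <- as.logical(d$computer_first)
  }
  d
}
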