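# Build a trials table by hand from level indices and an outcome vector.
# Red is always the correct colour (irrelevant to the likelihood).
make_trials <- function(level_index, is_correct, task = "cards",
                        participant_id = "fix") {
  lt <- level_table()
  li <- lt[match(level_index, lt$index), ]
  n <- length(level_index)
  data.frame(
    participant_id = rep(participant_id, n), task = rep(task, n),
    trial_index = seq_len(n),
    level_index = li$index, ratio_label = li$ratio_label,
    n_small = li$n_small, n_large = li$n_large,
    n_red = li$n_large, n_black = li$n_small,
    correct_color = rep("red", n),
    response_color = ifelse(is_correct, "red", "black"),
    is_correct = is_correct,
    stringsAsFactors = FALSE
  )
}

# A maximally uninformative session: at every test level, exactly half the
# responses correct.
chance_trials <- function(per_level = 4L) {
  idx <- rep(1:11, each = 2L * per_level)
  ok <- rep(rep(c(TRUE, FALSE), each = per_level), times = 11L)
  make_trials(idx, ok)
}

# A single zero-signal placeholder trial (equal counts) for likelihood tests.
equal_counts_trial <- function() {
  data.frame(n_small = 7L, n_large = 7L, is_correct = TRUE)
}
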