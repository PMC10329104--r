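# Shared fixtures: all test data is built in code.

default_cfg <- task_config()

# Build a schema-complete trial table from compact per-trial descriptions.
# rows: list of lists with fields pair, stake, left, right, choice (NA for
# missed), reward_red, reward_purple. Planet/treasure/points are derived.
make_trials <- function(rows, config = default_cfg, subject_id = "t01") {
  build <- function(i) {
    r <- rows[[i]]
    missed <- is.na(r$choice)
    planet <- if (missed) NA_character_ else transition(r$choice, config)
    treasure <- if (missed) NA_integer_ else
      as.integer(round(if (planet == "red") r$reward_red else r$reward_purple))
    data.frame(subject_id = subject_id, trial = i, pair = r$pair,
               stake = as.integer(r$stake), option_left = r$left,
               option_right = r$right,
               choice = if (missed) NA_character_ else r$choice,
               planet = planet, treasure = treasure,
               points = if (missed) NA_integer_ else
                 as.integer(treasure * r$stake),
               missed = missed, reward_red = r$reward_red,
               reward_purple = r$reward_purple, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(rows), build))
  rownames(out) <- NULL
  out
}

tr <- function(pair, stake, left, right, choice, reward_red, reward_purple)
  list(pair = pair, stake = stake, left = left, right = right,
       choice = choice, reward_red = reward_red, reward_purple = reward_purple)
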