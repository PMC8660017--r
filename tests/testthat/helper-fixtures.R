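# Shared fixtures: small configs and hand-built trial/spike tables.

small_config <- function(...) {
  generative_config(n_sessions = 2, trials_per_session = 96, rng_seed = 42L,
                    ...)
}

# A minimal hand-built trial table: `specs` is a list of lists with
# elements colors (named by location), target, outcome, response.
make_trials <- function(specs, session_id = 1L) {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    colors <- rep(NA_character_, 6)
    colors[as.integer(names(s$colors))] <- unname(unlist(s$colors))
    df <- data.frame(trial_id = i, session_id = session_id,
                     t(colors), stringsAsFactors = FALSE)
    names(df)[3:8] <- paste0("color_", 1:6)
    df$n_left <- sum(!is.na(colors[1:3]))
    df$n_right <- sum(!is.na(colors[4:6]))
    df$target_location <- s$target
    df$response_location <- if (!is.null(s$response)) s$response else s$target
    df$outcome <- if (!is.null(s$outcome)) s$outcome else "correct"
    df
  })
  do.call(rbind, rows)
}

# Spike table from a list of per-(neuron, trial) timestamp vectors.
make_spikes <- function(entries) {
  rows <- lapply(entries, function(e) {
    if (length(e$times) == 0) return(NULL)
    data.frame(neuron_id = e$neuron, trial_id = e$trial, time = e$times)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(neuron_id = integer(), trial_id = integer(),
                      time = numeric())
  }
  out
}

# Balanced load-1 trials for one location with alternating colors, plus
# spikes for one neuron whose rate depends on the color.
tuned_neuron_fixture <- function(location = 4L, n_per_color = 20,
                                 rate_A = 20, rate_B = 5, seed = 7L) {
  specs <- list()
  for (i in seq_len(2 * n_per_color)) {
    col <- if (i %% 2 == 0) "A" else "B"
    colors <- stats::setNames(list(col), as.character(location))
    # one left item keeps the total array size at two
    colors[["1"]] <- "A"
    specs[[i]] <- list(colors = colors, target = location)
  }
  trials <- make_trials(specs)
  set.seed(seed)
  entries <- lapply(seq_len(nrow(trials)), function(i) {
    rate <- if (trials[[paste0("color_", location)]][i] == "A") rate_A else
      rate_B
    n <- stats::rpois(1, rate * 1.8)
    list(neuron = 1L, trial = trials$trial_id[i],
         times = sort(stats::runif(n, 0, 1.8)))
  })
  list(trials = trials, spikes = make_spikes(entries))
}
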