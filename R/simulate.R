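#' Valid hemifield load combinations
#'
#' All `(n_left, n_right)` pairs with one to three items per hemifield and
#' a total array size of two to five.  The (3, 3) combination (total six)
#' is excluded by the task design.
#'
#' @return A data.frame with columns `n_left`, `n_right`.
#' @export
load_combinations <- function() {
  combos <- expand.grid(n_left = 1:3, n_right = 1:3)
  combos <- combos[combos$n_left + combos$n_right <= 5, , drop = FALSE]
  rownames(combos) <- NULL
  combos
}

#' Generate trials of the delayed change-localization task
#'
#' Produces one row per trial with the displayed color (A/B) at each of the
#' six locations, hemifield loads, and the target (change) location.  Load
#' combinations are balanced exactly up to rounding within each session;
#' displayed locations, colors, and the target are drawn uniformly.
#' Outcomes are not assigned here (see [gen_behavior()]).
#'
#' @param config A [generative_config()].
#' @param n Total number of trials; defaults to
#'   `n_sessions * trials_per_session`.
#' @param seed Integer seed; identical `(config, n, seed)` yield identical
#'   trial tables.
#' @return A data.frame with columns `trial_id`, `session_id`,
#'   `color_1` .. `color_6` (`"A"`, `"B"`, or `NA` for absent), `n_left`,
#'   `n_right`, `target_location`, `response_location`, `outcome`.
#' @export
gen_trials <- function(config, n = config$n_sessions * config$trials_per_session,
                       seed = config$rng_seed) {
  stopifnot(inherits(config, "generative_config"), .is_count(n))
  combos <- load_combinations()
  per_session <- rep(n %/% config$n_sessions, config$n_sessions)
  extra <- n %% config$n_sessions
  if (extra > 0) per_session[seq_len(extra)] <- per_session[seq_len(extra)] + 1L
  per_session <- per_session[per_session > 0]

  .with_seed(derive_seed(seed, "trials"), {
    rows <- vector("list", length(per_session))
    for (s in seq_along(per_session)) {
      ns <- per_session[s]
      combo_idx <- sample(rep(seq_len(nrow(combos)), length.out = ns))
      nl <- combos$n_left[combo_idx]
      nr <- combos$n_right[combo_idx]
      colors <- matrix(NA_character_, nrow = ns, ncol = 6)
      target <- integer(ns)
      for (i in seq_len(ns)) {
        shown <- c(sample(.LEFT_LOCATIONS, nl[i]),
                   sample(.RIGHT_LOCATIONS, nr[i]))
        colors[i, shown] <- sample(c("A", "B"), length(shown), replace = TRUE)
        target[i] <- if (length(shown) == 1L) shown else sample(shown, 1L)
      }
      df <- data.frame(
        session_id = s,
        colors,
        n_left = nl,
        n_right = nr,
        target_location = target,
        response_location = NA_integer_,
        outcome = NA_character_,
        stringsAsFactors = FALSE
      )
      names(df)[2:7] <- .color_col(1:6)
      rows[[s]] <- df
    }
    out <- do.call(rbind, rows)
    out <- cbind(trial_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

# Probability of a correct response for given hemifield loads.
.p_correct <- function(config, ipsi, contra) {
  if (is.function(config$p_correct)) {
    p <- mapply(config$p_correct, ipsi, contra)
  } else {
    p <- config$p_correct[ipsi] +
      config$interaction * (ipsi - 1) * (contra - 1)
  }
  pmin(pmax(p, 0), 1)
}

#' Assign behavioral outcomes to trials
#'
#' Each trial is correct with a probability that depends on the ipsilateral
#' (change-side) hemifield load, optionally modulated by an ipsi-by-contra
#' interaction term.  Errors are distributed uniformly over the displayed
#' non-target locations.
#'
#' @param trials Output of [gen_trials()] with no outcomes yet.
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @return `trials` with `response_location` and `outcome`
#'   (`"correct"`/`"error"`) filled in.
#' @export
gen_behavior <- function(trials, config, seed = config$rng_seed) {
  stopifnot(inherits(config, "generative_config"))
  if (!all(is.na(trials$outcome))) {
    stop("trials already carry outcomes", call. = FALSE)
  }
  target_side_left <- trials$target_location <= 3L
  ipsi <- ifelse(target_side_left, trials$n_left, trials$n_right)
  contra <- ifelse(target_side_left, trials$n_right, trials$n_left)
  p <- .p_correct(config, ipsi, contra)

  color_cols <- as.matrix(trials[, .color_col(1:6)])
  .with_seed(derive_seed(seed, "behavior"), {
    correct <- stats::runif(nrow(trials)) < p
    resp <- trials$target_location
    for (i in which(!correct)) {
      shown <- which(!is.na(color_cols[i, ]))
      alt <- setdiff(shown, trials$target_location[i])
      resp[i] <- if (length(alt) == 1L) alt else sample(alt, 1L)
    }
    trials$response_location <- resp
    trials$outcome <- ifelse(correct, "correct", "error")
    trials
  })
}

# Normalized display rate for one neuron on one trial in one phase.
# Items in the neuron's favorite hemifield enter a weighted mean of their
# single-item rates; contralateral items never enter (hemifield
# independence).  An empty favorite hemifield yields the baseline rate.
.display_rate <- function(neuron, colors_row, phase, baseline) {
  fav <- neuron$favorite_location
  side_locs <- if (fav <= 3L) .LEFT_LOCATIONS else .RIGHT_LOCATIONS
  shown <- side_locs[!is.na(colors_row[side_locs])]
  if (length(shown) == 0L) return(baseline)
  ref_color <- if (fav %in% shown) colors_row[fav] else NA_character_
  rate_a <- neuron[[paste0("rate_A_", phase)]]
  rate_b <- neuron[[paste0("rate_B_", phase)]]
  rates <- numeric(length(shown))
  weights <- numeric(length(shown))
  for (k in seq_along(shown)) {
    loc <- shown[k]
    if (loc == fav) {
      rates[k] <- if (colors_row[loc] == "A") rate_a else rate_b
      weights[k] <- neuron$w_ref
    } else {
      rates[k] <- neuron$probe_rate
      wm <- neuron$w_probe_match
      if (!is.na(wm) && !is.na(ref_color)) {
        weights[k] <- if (colors_row[loc] == ref_color) wm else
          neuron$w_probe_nonmatch
      } else {
        weights[k] <- neuron$w_probe
      }
    }
  }
  if (sum(weights) <= 0) return(baseline)
  sum(weights * rates) / sum(weights)
}

#' Generate Poisson spike trains for a neuron population
#'
#' Spikes are drawn as a homogeneous Poisson process per epoch: baseline
#' rate during fixation, and the weighted-normalized display rate (see
#' [generative_config()]) during the sample and delay epochs.  Timestamps
#' are in seconds relative to sample onset; fixation spikes are negative.
#'
#' @param trials Trial table with colors assigned.
#' @param neurons Data.frame from [neuron_population()].
#' @param config A [generative_config()].
#' @param seed Master seed; per-neuron streams are derived from it so
#'   results do not depend on neuron order.
#' @return A data.frame with columns `neuron_id`, `trial_id`, `time`,
#'   sorted by neuron, trial, time.
#' @export
gen_spikes <- function(trials, neurons, config, seed = config$rng_seed) {
  stopifnot(inherits(config, "generative_config"))
  color_cols <- as.matrix(trials[, .color_col(1:6)])
  n_trials <- nrow(trials)
  epochs <- list(
    fixation = c(-config$fixation, 0),
    sample = c(0, config$sample),
    delay = c(config$sample, config$sample + config$delay)
  )
  out <- vector("list", nrow(neurons))
  for (j in seq_len(nrow(neurons))) {
    neuron <- neurons[j, ]
    rate_sample <- numeric(n_trials)
    rate_delay <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      rate_sample[i] <- .display_rate(neuron, color_cols[i, ], "sample",
                                      neuron$baseline)
      rate_delay[i] <- .display_rate(neuron, color_cols[i, ], "delay",
                                     neuron$baseline)
    }
    out[[j]] <- .with_seed(derive_seed(seed, "spikes", neuron$neuron_id), {
      pieces <- lapply(names(epochs), function(ep) {
        lim <- epochs[[ep]]
        dur <- lim[2] - lim[1]
        rate <- switch(ep,
                       fixation = rep(neuron$baseline, n_trials),
                       sample = rate_sample,
                       delay = rate_delay)
        counts <- stats::rpois(n_trials, rate * dur)
        if (sum(counts) == 0L) return(NULL)
        data.frame(
          neuron_id = neuron$neuron_id,
          trial_id = rep(trials$trial_id, counts),
          time = lim[1] + stats::runif(sum(counts)) * dur
        )
      })
      do.call(rbind, pieces)
    })
  }
  spikes <- do.call(rbind, out)
  if (is.null(spikes)) {
    spikes <- data.frame(neuron_id = integer(), trial_id = integer(),
                         time = numeric())
  }
  spikes <- spikes[order(spikes$neuron_id, spikes$trial_id, spikes$time), ]
  rownames(spikes) <- NULL
  spikes
}

#' Simulate SE/SI index pairs under weighted divisive normalization
#'
#' Builds a population of synthetic neurons with known single-condition
#' rates, sets every pair-condition rate to the weighted mean
#' `(w_ref * REF + w_probe * PROBE) / (w_ref + w_probe)`, and returns the
#' full set of eight selectivity/interaction index pairs per neuron.  With
#' `noise = "none"` the indices satisfy the algebraic identity
#' `SI = (w_probe / (w_ref + w_probe)) * SE` exactly; with
#' `noise = "poisson"` condition means are estimated from Poisson spike
#' counts before the indices are formed.
#'
#' @param n_neurons Number of neurons.
#' @param w_ref,w_probe Normalization weights.
#' @param noise `"none"` for noiseless rates, `"poisson"` for estimated
#'   condition means.
#' @param trials_per_condition Trials per condition when `noise = "poisson"`.
#' @param duration Phase duration in seconds over which counts accumulate.
#' @param rate_range Range (Hz) for the uniform single-condition rates.
#' @param seed Integer seed.
#' @return A data.frame of index pairs as returned by [build_index_set()],
#'   pooled over neurons.
#' @export
simulate_index_population <- function(n_neurons = 200,
                                      w_ref = 1,
                                      w_probe = 1,
                                      noise = c("none", "poisson"),
                                      trials_per_condition = 30,
                                      duration = 0.8,
                                      rate_range = c(2, 20),
                                      seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(.is_count(n_neurons), w_ref >= 0, w_probe >= 0,
            w_ref + w_probe > 0)
  wsum <- w_ref + w_probe
  .with_seed(derive_seed(seed, "index-pop"), {
    res <- vector("list", n_neurons)
    for (j in seq_len(n_neurons)) {
      # single-item rates: 2 reference colors, 2 probe locations x 2 colors
      ref <- stats::runif(2, rate_range[1], rate_range[2])
      names(ref) <- c("A", "B")
      probe <- matrix(stats::runif(4, rate_range[1], rate_range[2]), 2, 2,
                      dimnames = list(c("p1", "p2"), c("A", "B")))
      pair <- array(NA_real_, dim = c(2, 2, 2),
                    dimnames = list(c("A", "B"), c("p1", "p2"), c("A", "B")))
      for (i in c("A", "B")) {
        for (l in c("p1", "p2")) {
          for (cc in c("A", "B")) {
            pair[i, l, cc] <- (w_ref * ref[i] + w_probe * probe[l, cc]) / wsum
          }
        }
      }
      est <- function(rate) {
        if (noise == "none") return(rate)
        mean(stats::rpois(trials_per_condition, rate * duration)) / duration
      }
      ref_hat <- vapply(ref, est, numeric(1))
      probe_hat <- apply(probe, c(1, 2), est)
      pair_hat <- apply(pair, c(1, 2, 3), est)
      mx <- max(ref_hat, probe_hat, pair_hat)
      if (mx <= 0) next
      rows <- expand.grid(ref_color = c("A", "B"), probe_location = c("p1", "p2"),
                          probe_color = c("A", "B"), stringsAsFactors = FALSE)
      rows$neuron_id <- j
      rows$se <- NA_real_
      rows$si <- NA_real_
      for (r in seq_len(nrow(rows))) {
        i <- rows$ref_color[r]; l <- rows$probe_location[r]
        cc <- rows$probe_color[r]
        rows$se[r] <- se_index(ref_hat[i] / mx, probe_hat[l, cc] / mx)
        rows$si[r] <- si_index(ref_hat[i] / mx, pair_hat[i, l, cc] / mx)
      }
      res[[j]] <- rows
    }
    out <- do.call(rbind, res)
    out[, c("neuron_id", "ref_color", "probe_location", "probe_color",
            "se", "si")]
  })
}

#' Simulate null neuron-bins for permutation-test calibration
#'
#' Generates spike-count samples whose Poisson rate is identical for both
#' color labels, runs the label-permutation information test on each, and
#' returns the p-values.
#'
#' @param n_bins Number of simulated neuron-bins.
#' @param rate Poisson rate in Hz.
#' @param bin_width Bin width in seconds.
#' @param trials_per_color Trials per color label.
#' @param n_perm Permutations per test.
#' @param seed Integer seed.
#' @return Numeric vector of `n_bins` permutation p-values.
#' @export
simulate_null_pev_pvalues <- function(n_bins = 500,
                                      rate = 15,
                                      bin_width = 0.2,
                                      trials_per_color = 30,
                                      n_perm = 1000,
                                      seed = 1L) {
  stopifnot(.is_count(n_bins), rate >= 0)
  groups <- rep(c("A", "B"), each = trials_per_color)
  vapply(seq_len(n_bins), function(b) {
    counts <- .with_seed(derive_seed(seed, "null-bin", b), {
      stats::rpois(2 * trials_per_color, rate * bin_width)
    })
    permutation_pev_test(counts, groups, n_perm = n_perm,
                         seed = derive_seed(seed, "null-perm", b))$p.value
  }, numeric(1))
}
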