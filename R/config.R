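#' Configuration for the synthetic task and spiking generator
#'
#' Bundles every parameter of the generative model: task structure (six
#' locations, two colors per location, array sizes two to five), epoch
#' timing (160 ms fixation, 800 ms sample, 1000 ms memory delay), Poisson
#' firing rates, divisive-normalization weights, and per-ipsilateral-load
#' behavioral accuracy.
#'
#' The rate rule for a neuron viewing a multi-item display is a weighted
#' normalized mean of the single-item rates of all items in its favorite
#' hemifield: `r = sum(w_j * r_j) / sum(w_j)`, with weight `w_ref` on the
#' item at the favorite location and `w_probe` on every other ipsilateral
#' item.  Equal weights reproduce the arithmetic-mean normalization that
#' yields an SE/SI regression slope of 0.5; reference-biased weights yield
#' a slope of `w_probe / (w_ref + w_probe)`.
#'
#' @param n_sessions Number of recording sessions to simulate.
#' @param trials_per_session Trials per session.
#' @param baseline_rate Baseline Poisson rate (Hz) outside tuned epochs.
#' @param tuning_gain Rate difference (Hz) between color A and color B at a
#'   tuned neuron's favorite location.
#' @param probe_rate Single-item rate (Hz) for items at non-favorite
#'   locations.
#' @param w_ref,w_probe Nonnegative normalization weights for the
#'   favorite-location item and the other ipsilateral items.
#' @param p_correct Either a numeric vector of length 3 giving the
#'   probability of a correct response at ipsilateral (change-side) loads
#'   1-3, or a function `f(ipsi, contra)` returning that probability.
#' @param interaction Optional ipsi-by-contra interaction coefficient added
#'   to the correct probability as `interaction * (ipsi - 1) * (contra - 1)`
#'   (ignored when `p_correct` is a function).
#' @param fixation,sample,delay Epoch durations in seconds.
#' @param bin_width Analysis bin width in seconds; must divide the sample
#'   and delay durations.
#' @param rng_seed Default master seed.
#' @return An object of class `generative_config`.
#' @examples
#' cfg <- generative_config(n_sessions = 2, trials_per_session = 48)
#' cfg$sample / cfg$bin_width # 4 sample bins
#' @export
generative_config <- function(n_sessions = 10,
                              trials_per_session = 480,
                              baseline_rate = 10,
                              tuning_gain = 10,
                              probe_rate = 5,
                              w_ref = 1,
                              w_probe = 1,
                              p_correct = c(0.9588, 0.7831, 0.5821),
                              interaction = 0,
                              fixation = 0.16,
                              sample = 0.8,
                              delay = 1.0,
                              bin_width = 0.2,
                              rng_seed = 1L) {
  if (!.is_count(n_sessions) || !.is_count(trials_per_session)) {
    stop("n_sessions and trials_per_session must be positive integers",
         call. = FALSE)
  }
  if (any(c(baseline_rate, tuning_gain, probe_rate) < 0)) {
    stop("all rates must be >= 0", call. = FALSE)
  }
  if (w_ref < 0 || w_probe < 0 || (w_ref + w_probe) <= 0) {
    stop("normalization weights must be nonnegative with w_ref + w_probe > 0",
         call. = FALSE)
  }
  if (any(c(fixation, sample, delay, bin_width) <= 0)) {
    stop("epoch durations and bin width must be strictly positive",
         call. = FALSE)
  }
  if (!.divides(bin_width, sample) || !.divides(bin_width, delay)) {
    stop("bin_width must divide the sample and delay durations",
         call. = FALSE)
  }
  if (is.numeric(p_correct)) {
    if (length(p_correct) != 3L || any(p_correct < 0) || any(p_correct > 1)) {
      stop("numeric p_correct must have length 3 with values in [0, 1]",
           call. = FALSE)
    }
  } else if (!is.function(p_correct)) {
    stop("p_correct must be a numeric vector of length 3 or a function",
         call. = FALSE)
  }
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      trials_per_session = as.integer(trials_per_session),
      locations = .LOCATIONS,
      baseline_rate = baseline_rate,
      tuning_gain = tuning_gain,
      probe_rate = probe_rate,
      w_ref = w_ref,
      w_probe = w_probe,
      p_correct = p_correct,
      interaction = interaction,
      fixation = fixation,
      sample = sample,
      delay = delay,
      bin_width = bin_width,
      rng_seed = as.integer(rng_seed)
    ),
    class = "generative_config"
  )
}

#' @export
print.generative_config <- function(x, ...) {
  cat("Generative config for the change-localization task\n")
  cat(sprintf("  sessions: %d x %d trials\n", x$n_sessions,
              x$trials_per_session))
  cat(sprintf("  epochs (s): fixation %.2f | sample %.2f | delay %.2f\n",
              x$fixation, x$sample, x$delay))
  cat(sprintf("  rates (Hz): baseline %.1f, tuning gain %.1f, probe %.1f\n",
              x$baseline_rate, x$tuning_gain, x$probe_rate))
  cat(sprintf("  normalization weights: w_ref %.2f, w_probe %.2f\n",
              x$w_ref, x$w_probe))
  if (is.numeric(x$p_correct)) {
    cat(sprintf("  p(correct) by ipsi load: %s\n",
                paste(sprintf("%.4f", x$p_correct), collapse = ", ")))
  } else {
    cat("  p(correct): user function of (ipsi, contra) load\n")
  }
  invisible(x)
}

#' Build a synthetic neuron population
#'
#' Draws per-neuron tuning parameters.  Neuron types emulate the response
#' classes seen in associative working-memory areas: neurons color-tuned in
#' the sample phase only, the delay only, both phases, neurons that gain
#' color differentiation only at load 2 ("gaining": equal single-color rates
#' but color-dependent pair weights), and untuned neurons.
#'
#' @param n Number of neurons.
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @param proportions Named numeric vector over types
#'   `c(sample, delay, both, gaining, none)`; normalized to sum to 1.
#' @param favorite_candidates Locations eligible as favorite locations
#'   (default 4:6, the hemifield contralateral to a left-hemisphere
#'   implant).
#' @return A data.frame with one row per neuron: favorite location,
#'   per-phase color rates (Hz), probe rate, normalization weights, and the
#'   optional color-matched probe weights used by gaining neurons.
#' @export
neuron_population <- function(n, config,
                              seed = config$rng_seed,
                              proportions = c(sample = 0.30, delay = 0.10,
                                              both = 0.10, gaining = 0.20,
                                              none = 0.30),
                              favorite_candidates = .RIGHT_LOCATIONS) {
  stopifnot(.is_count(n), inherits(config, "generative_config"))
  proportions <- proportions / sum(proportions)
  .with_seed(derive_seed(seed, "neurons"), {
    type <- sample(names(proportions), n, replace = TRUE, prob = proportions)
    fav <- sample(favorite_candidates, n, replace = TRUE)
    b <- config$baseline_rate
    g <- config$tuning_gain
    sample_tuned <- type %in% c("sample", "both")
    delay_tuned <- type %in% c("delay", "both")
    gaining <- type == "gaining"
    data.frame(
      neuron_id = seq_len(n),
      type = type,
      favorite_location = fav,
      baseline = b,
      rate_A_sample = b + ifelse(sample_tuned, g, ifelse(gaining, g / 2, 0)),
      rate_B_sample = b + ifelse(gaining, g / 2, 0),
      rate_A_delay = b + ifelse(delay_tuned, g, ifelse(gaining, g / 2, 0)),
      rate_B_delay = b + ifelse(gaining, g / 2, 0),
      probe_rate = config$probe_rate,
      w_ref = config$w_ref,
      w_probe = config$w_probe,
      # gaining neurons: probe weight depends on whether the probe color
      # label matches the reference color label, creating load-2-only
      # differentiation
      w_probe_match = ifelse(gaining, 4 * config$w_probe, NA_real_),
      w_probe_nonmatch = ifelse(gaining, 0.25 * config$w_probe, NA_real_),
      stringsAsFactors = FALSE
    )
  })
}
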