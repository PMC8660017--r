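#' Condition firing rates for the normalization analysis
#'
#' Mean firing rates over an entire phase (sample 800 ms or delay 1000 ms)
#' for the conditions entering the SE/SI indices: each reference color
#' alone at the favorite location (ipsilateral load 1), each probe color
#' alone at the two other ipsilateral locations (load 1), and every
#' reference-probe pair shown together (ipsilateral load 2, exactly the
#' reference and probe items in the hemifield; contralateral items are
#' ignored).  All condition means are then divided by the neuron-phase
#' maximum, which bounds the derived indices in [-1, 1].
#'
#' @param spikes Spike table.
#' @param trials Trial table with outcomes (correct trials are used).
#' @param neuron_id Neuron to analyze.
#' @param favorite The neuron's favorite location.
#' @param phase `"sample"` or `"delay"`.
#' @param sample_dur,delay_dur Epoch durations in seconds.
#' @return An object of class `condition_rates`: list with `neuron_id`,
#'   `phase`, `favorite`, `probe_locations`, `raw` and `normalized` (named
#'   rate vectors, `NA` for conditions without trials), `n_trials`,
#'   `excluded` (TRUE when all rates are zero).
#' @export
condition_rates <- function(spikes, trials, neuron_id, favorite,
                            phase = c("sample", "delay"),
                            sample_dur = 0.8, delay_dur = 1.0) {
  phase <- match.arg(phase)
  window <- if (phase == "sample") c(0, sample_dur) else
    c(sample_dur, sample_dur + delay_dur)
  dur <- window[2] - window[1]
  side_locs <- if (favorite <= 3L) .LEFT_LOCATIONS else .RIGHT_LOCATIONS
  probes <- setdiff(side_locs, favorite)
  sp <- spikes[spikes$neuron_id == neuron_id, , drop = FALSE]
  correct <- trials[trials$outcome == "correct", , drop = FALSE]
  ipsi_load <- .hemifield_load(correct, favorite)
  fav_col <- correct[[.color_col(favorite)]]

  mean_rate <- function(sub) {
    if (nrow(sub) == 0) return(c(NA_real_, 0))
    counts <- .count_matrix(sp, sub$trial_id, window, dur)
    c(mean(counts[, 1]) / dur, nrow(sub))
  }

  raw <- c()
  n_trials <- c()
  for (i in c("A", "B")) {
    sub <- correct[ipsi_load == 1L & !is.na(fav_col) & fav_col == i, ,
                   drop = FALSE]
    mr <- mean_rate(sub)
    raw[paste0("REF_", i)] <- mr[1]
    n_trials[paste0("REF_", i)] <- mr[2]
  }
  for (l in probes) {
    lc <- correct[[.color_col(l)]]
    for (cc in c("A", "B")) {
      sub <- correct[ipsi_load == 1L & !is.na(lc) & lc == cc, , drop = FALSE]
      mr <- mean_rate(sub)
      raw[paste0("PROBE_", l, "_", cc)] <- mr[1]
      n_trials[paste0("PROBE_", l, "_", cc)] <- mr[2]
    }
  }
  for (i in c("A", "B")) {
    for (l in probes) {
      lc <- correct[[.color_col(l)]]
      for (cc in c("A", "B")) {
        sub <- correct[ipsi_load == 2L & !is.na(fav_col) & fav_col == i &
                         !is.na(lc) & lc == cc, , drop = FALSE]
        mr <- mean_rate(sub)
        raw[paste0("PAIR_", i, "_", l, "_", cc)] <- mr[1]
        n_trials[paste0("PAIR_", i, "_", l, "_", cc)] <- mr[2]
      }
    }
  }
  mx <- suppressWarnings(max(raw, na.rm = TRUE))
  excluded <- !is.finite(mx) || mx <= 0
  normalized <- if (excluded) raw * NA_real_ else raw / mx
  structure(
    list(neuron_id = neuron_id, phase = phase, favorite = favorite,
         probe_locations = probes, raw = raw, normalized = normalized,
         n_trials = n_trials, excluded = excluded),
    class = "condition_rates"
  )
}

#' @export
print.condition_rates <- function(x, ...) {
  cat(sprintf("condition rates: neuron %s, %s phase, favorite location %d\n",
              x$neuron_id, x$phase, x$favorite))
  if (x$excluded) {
    cat("  excluded: all condition rates are zero or missing\n")
  } else {
    cat(sprintf("  %d conditions, max raw rate %.2f Hz\n",
                sum(!is.na(x$raw)), max(x$raw, na.rm = TRUE)))
  }
  invisible(x)
}

#' Color selectivity index
#'
#' `SE = PROBE - REF` on normalized rates: -1 means completely selective
#' for the reference color, +1 completely selective for the probe color.
#'
#' @param ref Normalized reference-alone rate in [0, 1].
#' @param probe Normalized probe-alone rate in [0, 1].
#' @return SE in [-1, 1].
#' @examples
#' se_index(1, 0) # -1
#' @export
se_index <- function(ref, probe) {
  if (any(ref < 0 | ref > 1 | probe < 0 | probe > 1, na.rm = TRUE)) {
    stop("normalized rates must lie in [0, 1]", call. = FALSE)
  }
  probe - ref
}

#' Sensory interaction index
#'
#' `SI = PAIR - REF` on normalized rates: -1 means full suppression of the
#' reference response by the probe, +1 full enhancement.
#'
#' @param ref Normalized reference-alone rate in [0, 1].
#' @param pair Normalized pair (simultaneous display) rate in [0, 1].
#' @return SI in [-1, 1].
#' @examples
#' si_index(1, 0) # -1
#' @export
si_index <- function(ref, pair) {
  if (any(ref < 0 | ref > 1 | pair < 0 | pair > 1, na.rm = TRUE)) {
    stop("normalized rates must lie in [0, 1]", call. = FALSE)
  }
  pair - ref
}

#' Build the SE/SI index set for one neuron-phase
#'
#' Forms all selectivity/interaction pairs from the condition rates: two
#' reference colors times two probe locations times two probe colors gives
#' exactly eight pairs under a complete design.  Pairs whose reference,
#' probe, or pair condition lacks trials are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param cr A [condition_rates()] object.
#' @return Data.frame with columns `neuron_id`, `phase`, `ref_color`,
#'   `probe_location`, `probe_color`, `se`, `si`.
#' @export
build_index_set <- function(cr) {
  stopifnot(inherits(cr, "condition_rates"))
  if (cr$excluded) {
    stop("neuron excluded: all condition rates are zero or missing",
         call. = FALSE)
  }
  norm <- cr$normalized
  rows <- list()
  skipped <- 0L
  for (i in c("A", "B")) {
    ref <- norm[paste0("REF_", i)]
    for (l in cr$probe_locations) {
      for (cc in c("A", "B")) {
        probe <- norm[paste0("PROBE_", l, "_", cc)]
        pair <- norm[paste0("PAIR_", i, "_", l, "_", cc)]
        if (any(is.na(c(ref, probe, pair)))) {
          skipped <- skipped + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = cr$neuron_id, phase = cr$phase, ref_color = i,
          probe_location = l, probe_color = cc,
          se = unname(se_index(ref, probe)),
          si = unname(si_index(ref, pair)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(neuron_id = integer(), phase = character(),
               ref_color = character(), probe_location = integer(),
               probe_color = character(), se = numeric(), si = numeric())
  attr(out, "skipped") <- skipped
  out
}

#' Pooled SI-on-SE regression
#'
#' Ordinary least squares of the sensory interaction index on the
#' selectivity index over all index pairs of a neuron group.  A slope near
#' 0.5 indicates equal influence of reference and probe (even-weight
#' divisive normalization); the slope equals
#' `w_probe / (w_ref + w_probe)` for noiseless weighted-mean
#' normalization.  Decisions against 0.5 and 0 use 95% confidence-interval
#' inclusion.
#'
#' @param pairs Data.frame of index pairs with columns `se`, `si`
#'   (e.g. from [build_index_set()] rows pooled over neurons).
#' @return An object of class `slope_fit`: list with `slope`, `intercept`,
#'   `ci` (95% for the slope), `adj_r_squared`, `F`, `df`, `p.value`,
#'   `n`, `differs_from_half`, `differs_from_zero`.
#' @export
fit_se_si_regression <- function(pairs) {
  stopifnot(all(c("se", "si") %in% names(pairs)))
  d <- pairs[!is.na(pairs$se) & !is.na(pairs$si), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least three index pairs", call. = FALSE)
  if (stats::sd(d$se) == 0) {
    stop("zero variance in SE: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(si ~ se, data = d)
  sm <- summary(fit)
  ci <- stats::confint(fit, "se", level = 0.95)
  fstat <- sm$fstatistic
  structure(
    list(
      slope = unname(stats::coef(fit)["se"]),
      intercept = unname(stats::coef(fit)["(Intercept)"]),
      ci = c(ci[1], ci[2]),
      adj_r_squared = sm$adj.r.squared,
      F = unname(fstat["value"]),
      df = unname(fstat[c("numdf", "dendf")]),
      p.value = stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                          lower.tail = FALSE),
      n = nrow(d),
      differs_from_half = !(0.5 >= ci[1] && 0.5 <= ci[2]),
      differs_from_zero = !(0 >= ci[1] && 0 <= ci[2])
    ),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("SI ~ SE: slope %.3f (95%% CI [%.3f, %.3f]), n = %d pairs\n",
              x$slope, x$ci[1], x$ci[2], x$n))
  cat(sprintf("  adj R^2 %.3f, F(%d, %d) = %.2f, p = %.3g\n",
              x$adj_r_squared, x$df[1], x$df[2], x$F, x$p.value))
  cat(sprintf("  differs from 0.5: %s; differs from 0: %s\n",
              x$differs_from_half, x$differs_from_zero))
  invisible(x)
}

#' Neuron groups for the divisive-normalization analysis
#'
#' Assigns each neuron, per phase, to one of three disjoint groups based on
#' whole-phase significance: information-carrying (significant at load 1),
#' information-gaining (not at load 1 but at load 2), non-informative
#' (neither).
#'
#' @param classifications Data.frame with columns `neuron_id`, `phase`,
#'   `sig_load1`, `sig_load2` (whole-phase, single-bin significance).
#' @return The input with an added `dnr_group` column.
#' @export
group_neurons_for_dnr <- function(classifications) {
  stopifnot(all(c("neuron_id", "phase", "sig_load1", "sig_load2") %in%
                  names(classifications)))
  s1 <- classifications$sig_load1
  s2 <- classifications$sig_load2
  grp <- ifelse(is.na(s1) | is.na(s2), NA_character_,
                ifelse(s1, "information-carrying",
                       ifelse(s2, "information-gaining", "non-informative")))
  classifications$dnr_group <- grp
  classifications
}

#' Divisive-normalization analysis over a recorded population
#'
#' Orchestrates the SE/SI analysis for one phase: whole-phase permutation
#' significance at loads 1 and 2 per neuron, grouping into
#' information-carrying / information-gaining / non-informative neurons,
#' per-neuron index sets, and the pooled SI-on-SE regression per group.
#'
#' @param spikes Spike table.
#' @param trials Trial table with outcomes.
#' @param favorites Data.frame with columns `neuron_id`,
#'   `favorite_location`.
#' @param phase `"sample"` or `"delay"`.
#' @param n_perm Permutations for the whole-phase tests.
#' @param seed Integer seed.
#' @return List with `groups` (per-neuron data.frame), `pairs` (all index
#'   pairs with `dnr_group`), and `fits` (named list of `slope_fit` per
#'   group with at least three pairs).
#' @export
dnr_analysis <- function(spikes, trials, favorites,
                         phase = c("sample", "delay"),
                         n_perm = 1000, seed = 1L) {
  phase <- match.arg(phase)
  rows <- list()
  pair_rows <- list()
  for (r in seq_len(nrow(favorites))) {
    nid <- favorites$neuron_id[r]
    loc <- favorites$favorite_location[r]
    p1 <- phase_significance(spikes, trials, nid, loc, phase, load = 1L,
                             n_perm = n_perm, seed = seed)
    p2 <- phase_significance(spikes, trials, nid, loc, phase, load = 2L,
                             n_perm = n_perm, seed = seed)
    if (is.null(p1) || is.null(p2)) next
    rows[[length(rows) + 1L]] <- data.frame(
      neuron_id = nid, phase = phase,
      sig_load1 = p1$significant, sig_load2 = p2$significant,
      stringsAsFactors = FALSE
    )
    cr <- condition_rates(spikes, trials, nid, loc, phase)
    if (!cr$excluded) {
      pair_rows[[length(pair_rows) + 1L]] <- build_index_set(cr)
    }
  }
  if (length(rows) == 0) stop("no neuron has usable trials", call. = FALSE)
  groups <- group_neurons_for_dnr(do.call(rbind, rows))
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else
    data.frame()
  if (nrow(pairs) > 0) {
    pairs$dnr_group <- groups$dnr_group[match(pairs$neuron_id,
                                              groups$neuron_id)]
  }
  fits <- list()
  for (g in c("information-carrying", "information-gaining",
              "non-informative")) {
    sub <- pairs[!is.na(pairs$dnr_group) & pairs$dnr_group == g, ,
                 drop = FALSE]
    if (nrow(sub) >= 3 && stats::sd(sub$se) > 0) {
      fits[[g]] <- fit_se_si_regression(sub)
    }
  }
  list(groups = groups, pairs = pairs, fits = fits)
}
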