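#' Bin spike timestamps into fixed-width counts
#'
#' Counts spikes per (neuron, trial, bin) on a half-open grid `[a, b)`
#' spanning `window`, for every neuron in `spikes` and every trial in
#' `trials` (trials without spikes contribute zero counts).
#'
#' @param spikes Spike table (`neuron_id`, `trial_id`, `time`).
#' @param trials Trial table (defines the trial set).
#' @param bin_width Bin width in seconds; must divide the window length.
#' @param window Length-2 numeric, seconds relative to sample onset.
#' @return Data.frame with columns `neuron_id`, `trial_id`, `bin`,
#'   `bin_start`, `bin_end`, `count`.
#' @export
bin_spikes <- function(spikes, trials, bin_width = 0.2, window = c(0, 1.8)) {
  if (!.divides(bin_width, window[2] - window[1])) {
    stop("bin_width must divide the window length (no partial bins)",
         call. = FALSE)
  }
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
  edges <- window[1] + bin_width * (0:n_bins)
  neurons <- sort(unique(spikes$neuron_id))
  trial_ids <- trials$trial_id
  grid <- expand.grid(bin = seq_len(n_bins), trial_id = trial_ids,
                      neuron_id = neurons)
  grid <- grid[, c("neuron_id", "trial_id", "bin")]
  grid$bin_start <- edges[grid$bin]
  grid$bin_end <- edges[grid$bin + 1L]
  grid$count <- integer(nrow(grid))
  inwin <- spikes$time >= window[1] & spikes$time < window[2]
  sp <- spikes[inwin & spikes$trial_id %in% trial_ids, , drop = FALSE]
  if (nrow(sp) > 0) {
    bin <- floor((sp$time - window[1]) / bin_width) + 1L
    bin[bin > n_bins] <- n_bins # guard exact upper edge under fp error
    key <- paste(sp$neuron_id, sp$trial_id, bin)
    tab <- table(key)
    gkey <- paste(grid$neuron_id, grid$trial_id, grid$bin)
    hit <- match(names(tab), gkey)
    grid$count[hit] <- as.integer(tab)
  }
  grid
}

# Counts matrix (trials x bins) for one neuron over a trial subset.
.count_matrix <- function(spikes, trial_ids, window, bin_width) {
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
  m <- matrix(0L, nrow = length(trial_ids), ncol = n_bins)
  sp <- spikes[spikes$trial_id %in% trial_ids &
                 spikes$time >= window[1] & spikes$time < window[2], ,
               drop = FALSE]
  if (nrow(sp) > 0) {
    row <- match(sp$trial_id, trial_ids)
    bin <- floor((sp$time - window[1]) / bin_width) + 1L
    bin[bin > n_bins] <- n_bins
    for (k in seq_along(row)) m[row[k], bin[k]] <- m[row[k], bin[k]] + 1L
  }
  m
}

#' One-way omega-squared (PEV) decomposition
#'
#' Percent explained variance of spike counts by a grouping factor (color
#' identity), as the bias-corrected effect size
#' `omega^2 = (SS_effect - df_effect * MS_error) / (SS_total + MS_error)`
#' from the one-way sums of squares.  Negative values are preserved; for
#' constant data (zero total variance) the decomposition is undefined and
#' `omega_squared` is `NA` with `degenerate = TRUE`.
#'
#' @param values Numeric spike counts.
#' @param groups Grouping labels, at least two groups with two observations
#'   each.
#' @return An object of class `anova_decomposition`: list with `ss_effect`,
#'   `ss_within`, `ss_total`, `ms_error`, `df_effect`, `omega_squared`,
#'   `group_sizes`, `degenerate`.
#' @examples
#' omega_squared(c(2, 4, 8, 10), c("A", "A", "B", "B"))$omega_squared # 34/42
#' @export
omega_squared <- function(values, groups) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  if (any(sizes < 2L)) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  n <- length(values)
  k <- length(sizes)
  grand <- mean(values)
  group_means <- tapply(values, groups, mean)
  ss_effect <- sum(sizes * (group_means - grand)^2)
  ss_total <- sum((values - grand)^2)
  ss_within <- ss_total - ss_effect
  df_effect <- k - 1L
  ms_error <- ss_within / (n - k)
  degenerate <- ss_total <= 0
  omega <- if (degenerate) {
    NA_real_
  } else {
    (ss_effect - df_effect * ms_error) / (ss_total + ms_error)
  }
  structure(
    list(ss_effect = ss_effect, ss_within = ss_within, ss_total = ss_total,
         ms_error = ms_error, df_effect = df_effect, omega_squared = omega,
         group_sizes = as.integer(sizes), degenerate = degenerate),
    class = "anova_decomposition"
  )
}

#' @export
print.anova_decomposition <- function(x, ...) {
  cat(sprintf(
    "one-way decomposition: SS_effect %.4g, SS_total %.4g, MS_error %.4g\n",
    x$ss_effect, x$ss_total, x$ms_error))
  cat(sprintf("  df_effect %d, omega^2 = %s\n", x$df_effect,
              if (is.na(x$omega_squared)) "NA (constant data)" else
                sprintf("%.4f", x$omega_squared)))
  invisible(x)
}

#' Label-permutation test of the omega-squared information statistic
#'
#' Permutes the color-identity labels `n_perm` times and estimates the
#' probability of a permuted omega-squared at least as large as the
#' observed one, using the add-one estimator
#' `p = (1 + #permuted >= observed) / (n_perm + 1)` (ties count against
#' significance).  A bin is significant when `p < 0.05`.
#'
#' Permutations are compared on `SS_effect`, a strictly increasing function
#' of omega-squared when the data (hence `SS_total`) are fixed, so the
#' p-value is identical to comparing omega-squared directly.
#'
#' @param values Numeric spike counts.
#' @param groups Grouping labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return List with `omega_squared`, `p.value`, `significant`, `n_perm`.
#' @export
permutation_pev_test <- function(values, groups, n_perm = 1000, seed = NULL) {
  if (!.is_count(n_perm)) stop("n_perm must be >= 1", call. = FALSE)
  obs <- omega_squared(values, groups)
  if (obs$degenerate) {
    # every permutation ties with the observed (constant) data
    return(list(omega_squared = obs$omega_squared, p.value = 1,
                significant = FALSE, n_perm = n_perm))
  }
  v <- as.numeric(values)
  g <- as.character(groups)
  n <- length(v)
  sizes <- table(g)
  # indicator matrix (groups x observations) for fast group sums
  G <- outer(names(sizes), g, "==") * 1
  total <- sum(v)
  correction <- total^2 / n
  exceed <- .with_seed(seed, {
    perm <- matrix(0, nrow = n, ncol = n_perm)
    for (j in seq_len(n_perm)) perm[, j] <- v[sample.int(n)]
    S <- G %*% perm # group sums per permutation
    ss_eff_perm <- colSums(S^2 / as.numeric(sizes)) - correction
    sum(ss_eff_perm >= obs$ss_effect - 1e-12)
  })
  p <- (1 + exceed) / (n_perm + 1)
  list(omega_squared = obs$omega_squared, p.value = p,
       significant = p < 0.05, n_perm = n_perm)
}

#' Determine a neuron's favorite location
#'
#' The favorite location is the candidate location (by default the three
#' locations contralateral to the recorded hemisphere) with the highest
#' cumulative omega-squared PEV for color identity over the four
#' non-overlapping 200-ms sample bins, computed from correct load-1 trials
#' (the candidate alone in its hemifield).  Exact ties resolve to the
#' lowest location index.
#'
#' @param spikes Spike table.
#' @param trials Trial table with outcomes.
#' @param neuron_id Neuron to analyze.
#' @param candidates Candidate locations (default 4:6).
#' @param sample_dur Sample duration in seconds.
#' @param bin_width Bin width in seconds.
#' @return Integer location, with attribute `cumulative_pev` (named vector
#'   over candidates, `NA` for excluded candidates).
#' @export
favorite_location <- function(spikes, trials, neuron_id,
                              candidates = .RIGHT_LOCATIONS,
                              sample_dur = 0.8, bin_width = 0.2) {
  sp <- spikes[spikes$neuron_id == neuron_id, , drop = FALSE]
  cum <- stats::setNames(rep(NA_real_, length(candidates)),
                         as.character(candidates))
  for (loc in candidates) {
    colcol <- .color_col(loc)
    sel <- trials$outcome == "correct" &
      !is.na(trials[[colcol]]) &
      .hemifield_load(trials, loc) == 1L
    sub <- trials[sel, , drop = FALSE]
    if (nrow(sub) == 0) next
    if (any(table(sub[[colcol]]) < 2L) || length(unique(sub[[colcol]])) < 2L) {
      next # candidate excluded: cannot form the decomposition
    }
    counts <- .count_matrix(sp, sub$trial_id, c(0, sample_dur), bin_width)
    pev <- apply(counts, 2, function(x) {
      om <- omega_squared(x, sub[[colcol]])$omega_squared
      if (is.na(om)) 0 else om
    })
    cum[as.character(loc)] <- sum(pev)
  }
  if (all(is.na(cum))) {
    stop("no candidate location has usable load-1 trials for neuron ",
         neuron_id, call. = FALSE)
  }
  best <- candidates[which.max(replace(cum, is.na(cum), -Inf))]
  structure(as.integer(best), cumulative_pev = cum)
}

#' Load-resolved PEV timecourse for one neuron
#'
#' Omega-squared information about color identity at `location`, per
#' 200-ms bin across the sample and delay, separately for each load
#' condition.  For `side = "ipsi"` the load is the item count in the
#' hemifield of `location`; for `side = "contra"` the opposite-hemifield
#' load varies while the ipsilateral load is held at `contra_fixed`.
#' Each bin carries a label-permutation p-value.
#'
#' @param spikes Spike table.
#' @param trials Trial table with outcomes (correct trials are used).
#' @param neuron_id Neuron to analyze.
#' @param location The neuron's favorite location.
#' @param loads Load conditions (default 1:3).
#' @param side `"ipsi"` or `"contra"`.
#' @param contra_fixed Ipsilateral load held fixed for contralateral
#'   timecourses (default 1).
#' @param sample_dur,delay_dur Epoch durations in seconds.
#' @param bin_width Bin width in seconds.
#' @param n_perm Permutations per bin.
#' @param seed Master seed; per-(load, bin) permutation streams are derived
#'   from it.
#' @return Data.frame with columns `neuron_id`, `side`, `load`, `bin`,
#'   `bin_start`, `bin_end`, `phase`, `n_trials`, `omega2`, `p`,
#'   `significant`.
#' @export
pev_timecourse <- function(spikes, trials, neuron_id, location,
                           loads = 1:3, side = c("ipsi", "contra"),
                           contra_fixed = 1L,
                           sample_dur = 0.8, delay_dur = 1.0,
                           bin_width = 0.2, n_perm = 1000, seed = 1L) {
  side <- match.arg(side)
  sp <- spikes[spikes$neuron_id == neuron_id, , drop = FALSE]
  colcol <- .color_col(location)
  window <- c(0, sample_dur + delay_dur)
  n_bins <- as.integer(round((window[2] - window[1]) / bin_width))
  edges <- window[1] + bin_width * (0:n_bins)
  out <- vector("list", length(loads))
  for (li in seq_along(loads)) {
    load <- loads[li]
    sel <- trials$outcome == "correct" & !is.na(trials[[colcol]])
    if (side == "ipsi") {
      sel <- sel & .hemifield_load(trials, location) == load
    } else {
      sel <- sel & .opposite_load(trials, location) == load &
        .hemifield_load(trials, location) == contra_fixed
    }
    sub <- trials[sel, , drop = FALSE]
    res <- data.frame(
      neuron_id = neuron_id, side = side, load = load, bin = seq_len(n_bins),
      bin_start = edges[-length(edges)], bin_end = edges[-1],
      phase = ifelse(edges[-length(edges)] < sample_dur, "sample", "delay"),
      n_trials = nrow(sub), omega2 = NA_real_, p = NA_real_,
      significant = NA
    )
    usable <- nrow(sub) >= 4 && length(unique(sub[[colcol]])) == 2L &&
      all(table(sub[[colcol]]) >= 2L)
    if (usable) {
      counts <- .count_matrix(sp, sub$trial_id, window, bin_width)
      for (b in seq_len(n_bins)) {
        pt <- permutation_pev_test(
          counts[, b], sub[[colcol]], n_perm = n_perm,
          seed = derive_seed(seed, neuron_id, load, b,
                             if (side == "ipsi") 0L else 1L))
        res$omega2[b] <- pt$omega_squared
        res$p[b] <- pt$p.value
        res$significant[b] <- pt$significant
      }
    }
    out[[li]] <- res
  }
  do.call(rbind, out)
}

# Phase-level significance flag from per-bin flags.
.phase_flag <- function(flags, strict) {
  flags <- flags[!is.na(flags)]
  if (length(flags) == 0) return(NA)
  if (!strict) return(any(flags))
  if (length(flags) < 2) return(FALSE)
  any(flags[-length(flags)] & flags[-1])
}

# Table of the seven significance groups: rows are (load1, load2, load3)
# significance triples.
.GROUP_TABLE <- data.frame(
  load1 = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
  load2 = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE),
  load3 = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
  group = c("I", "II", "III", "IV", "V", "VI", "VII"),
  stringsAsFactors = FALSE
)

#' Group label for a load-significance triple
#'
#' Maps the (load 1, load 2, load 3) significance booleans to the group
#' labels I-VII; the all-false triple has no group (`NA`).
#'
#' @param load1,load2,load3 Logical significance flags.
#' @return Character group label or `NA`.
#' @export
significance_group <- function(load1, load2, load3) {
  key <- paste(load1, load2, load3)
  tab_key <- paste(.GROUP_TABLE$load1, .GROUP_TABLE$load2, .GROUP_TABLE$load3)
  .GROUP_TABLE$group[match(key, tab_key)]
}

#' Classify neurons by phase- and load-resolved significance
#'
#' For each neuron and phase (sample, delay), a load condition counts as
#' significant when at least one bin in that phase is significant
#' (default), or when two consecutive bins are significant under the
#' stricter criterion.  The three flags map to groups I-VII; pooled group g
#' contains the neurons significant at load g.
#'
#' @param pev Long PEV table from [pev_timecourse()] (ipsilateral side),
#'   possibly covering many neurons.
#' @param strict Require two consecutive significant bins.
#' @return Data.frame with one row per neuron x phase: significance flags
#'   per load, `group`, and pooled-group membership columns
#'   `pooled1`..`pooled3`.
#' @export
classify_neurons <- function(pev, strict = FALSE) {
  pev <- pev[pev$side == "ipsi", , drop = FALSE]
  neurons <- sort(unique(pev$neuron_id))
  rows <- list()
  for (nid in neurons) {
    for (ph in c("sample", "delay")) {
      flags <- vapply(1:3, function(l) {
        sub <- pev[pev$neuron_id == nid & pev$phase == ph & pev$load == l, ,
                   drop = FALSE]
        sub <- sub[order(sub$bin), , drop = FALSE]
        .phase_flag(sub$significant, strict)
      }, logical(1))
      known <- !is.na(flags)
      grp <- if (all(known)) {
        significance_group(flags[1], flags[2], flags[3])
      } else {
        NA_character_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = nid, phase = ph,
        sig_load1 = flags[1], sig_load2 = flags[2], sig_load3 = flags[3],
        group = grp,
        pooled1 = isTRUE(flags[1]), pooled2 = isTRUE(flags[2]),
        pooled3 = isTRUE(flags[3]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact binomial test of a proportion of significant neurons
#'
#' Upper-tail probability of observing at least `k` significant neurons out
#' of `n` when each is significant with probability `p0` by chance.
#'
#' @param k Number of significant neurons.
#' @param n Total neurons.
#' @param p0 Chance significance probability (default 0.05).
#' @return Upper-tail probability `P(X >= k)`.
#' @examples
#' binomial_proportion_test(1, 1) # 0.05
#' @export
binomial_proportion_test <- function(k, n, p0 = 0.05) {
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)", call. = FALSE)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

#' Whole-phase permutation significance for one neuron
#'
#' Runs the label-permutation information test on spike counts pooled over
#' an entire phase (sample 800 ms or delay 1000 ms as one bin) for a given
#' ipsilateral load, as used to define the neuron groups entering the
#' divisive-normalization analysis.
#'
#' @param spikes Spike table.
#' @param trials Trial table with outcomes.
#' @param neuron_id Neuron to analyze.
#' @param location The neuron's favorite location.
#' @param phase `"sample"` or `"delay"`.
#' @param load Ipsilateral load condition.
#' @param sample_dur,delay_dur Epoch durations in seconds.
#' @param n_perm Permutations.
#' @param seed Integer seed.
#' @return List as from [permutation_pev_test()], or `NULL` when the load
#'   condition lacks usable trials.
#' @export
phase_significance <- function(spikes, trials, neuron_id, location,
                               phase = c("sample", "delay"), load,
                               sample_dur = 0.8, delay_dur = 1.0,
                               n_perm = 1000, seed = 1L) {
  phase <- match.arg(phase)
  window <- if (phase == "sample") c(0, sample_dur) else
    c(sample_dur, sample_dur + delay_dur)
  colcol <- .color_col(location)
  sel <- trials$outcome == "correct" & !is.na(trials[[colcol]]) &
    .hemifield_load(trials, location) == load
  sub <- trials[sel, , drop = FALSE]
  if (nrow(sub) < 4 || length(unique(sub[[colcol]])) < 2L ||
      any(table(sub[[colcol]]) < 2L)) {
    return(NULL)
  }
  sp <- spikes[spikes$neuron_id == neuron_id, , drop = FALSE]
  counts <- .count_matrix(sp, sub$trial_id, window, window[2] - window[1])
  permutation_pev_test(counts[, 1], sub[[colcol]], n_perm = n_perm,
                       seed = derive_seed(seed, "phase", neuron_id, load,
                                          if (phase == "sample") 0L else 1L))
}
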