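#' Window-pooled PEV per neuron, window, and load
#'
#' Computes one omega-squared value per (neuron, window, load) from spike
#' counts pooled over each analysis window: early/late sample (first and
#' second 400 ms) and early/late delay (first and second 500 ms).
#'
#' @param spikes Spike table.
#' @param trials Trial table with outcomes.
#' @param favorites Data.frame with columns `neuron_id`,
#'   `favorite_location`.
#' @param loads Load conditions (default 1:3).
#' @param windows Named list of `[start, end)` windows in seconds relative
#'   to sample onset; every window must lie inside a single epoch and the
#'   windows must tile the sample (0-0.8 s) and delay (0.8-1.8 s) exactly.
#' @param sample_dur,delay_dur Epoch durations in seconds.
#' @return Data.frame with columns `neuron_id`, `window`, `load`,
#'   `n_trials`, `omega2`.
#' @export
window_pev <- function(spikes, trials, favorites, loads = 1:3,
                       windows = list(early_sample = c(0, 0.4),
                                      late_sample = c(0.4, 0.8),
                                      early_delay = c(0.8, 1.3),
                                      late_delay = c(1.3, 1.8)),
                       sample_dur = 0.8, delay_dur = 1.0) {
  total <- sample_dur + delay_dur
  for (w in windows) {
    inside_sample <- w[1] >= 0 && w[2] <= sample_dur
    inside_delay <- w[1] >= sample_dur && w[2] <= total
    if (w[1] >= w[2] || !(inside_sample || inside_delay)) {
      stop("windows must lie within a single epoch (sample or delay)",
           call. = FALSE)
    }
  }
  covered <- sum(vapply(windows, function(w) w[2] - w[1], numeric(1)))
  if (!isTRUE(all.equal(covered, total))) {
    stop("windows must tile the sample and delay epochs", call. = FALSE)
  }
  rows <- list()
  for (r in seq_len(nrow(favorites))) {
    nid <- favorites$neuron_id[r]
    loc <- favorites$favorite_location[r]
    colcol <- .color_col(loc)
    sp <- spikes[spikes$neuron_id == nid, , drop = FALSE]
    for (load in loads) {
      sel <- trials$outcome == "correct" & !is.na(trials[[colcol]]) &
        .hemifield_load(trials, loc) == load
      sub <- trials[sel, , drop = FALSE]
      usable <- nrow(sub) >= 4 && length(unique(sub[[colcol]])) == 2L &&
        all(table(sub[[colcol]]) >= 2L)
      for (wn in names(windows)) {
        w <- windows[[wn]]
        om <- NA_real_
        if (usable) {
          counts <- .count_matrix(sp, sub$trial_id, w, w[2] - w[1])
          om <- omega_squared(counts[, 1], sub[[colcol]])$omega_squared
        }
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = nid, window = wn, load = load,
          n_trials = nrow(sub), omega2 = om, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way load-effect ANOVA on window PEV values
#'
#' Tests whether per-neuron window PEV differs across load conditions:
#' one-way F test, omega-squared effect size from the same decomposition,
#' and Bonferroni-corrected pairwise pooled-variance t-tests (m = number of
#' load pairs).
#'
#' @param window_table Output of [window_pev()].
#' @param window Window name to test.
#' @return List with `F`, `df` (length 2), `p.value`, `omega_squared`,
#'   `pairwise` (data.frame with raw and Bonferroni-corrected p-values),
#'   `n_per_load`.
#' @export
load_effect_anova <- function(window_table, window) {
  d <- window_table[window_table$window == window & !is.na(window_table$omega2),
                    , drop = FALSE]
  counts <- table(d$load)
  keep <- names(counts)[counts >= 2]
  if (length(keep) < length(counts)) {
    warning("excluding load(s) with fewer than 2 neurons: ",
            paste(setdiff(names(counts), keep), collapse = ", "))
  }
  d <- d[d$load %in% as.integer(keep), , drop = FALSE]
  if (length(unique(d$load)) < 2L) {
    stop("need at least two loads with two or more neurons", call. = FALSE)
  }
  dec <- omega_squared(d$omega2, d$load)
  n <- nrow(d)
  k <- length(unique(d$load))
  df1 <- k - 1L
  df2 <- n - k
  ms_effect <- dec$ss_effect / df1
  f <- if (dec$ms_error > 0) ms_effect / dec$ms_error else
    ifelse(ms_effect > 0, Inf, 0)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  loads <- sort(unique(d$load))
  pairs <- utils::combn(loads, 2)
  m <- ncol(pairs)
  pw <- data.frame(load_a = pairs[1, ], load_b = pairs[2, ],
                   p_raw = NA_real_, p_bonferroni = NA_real_)
  for (j in seq_len(m)) {
    xa <- d$omega2[d$load == pairs[1, j]]
    xb <- d$omega2[d$load == pairs[2, j]]
    if (stats::sd(c(xa, xb)) == 0) {
      pw$p_raw[j] <- 1
    } else {
      pw$p_raw[j] <- tryCatch(
        stats::t.test(xa, xb, var.equal = TRUE)$p.value,
        error = function(e) NA_real_)
    }
    pw$p_bonferroni[j] <- min(1, pw$p_raw[j] * m)
  }
  list(F = f, df = c(df1, df2), p.value = p,
       omega_squared = dec$omega_squared, pairwise = pw,
       n_per_load = counts[keep])
}

#' One-sample t-test of PEV values against zero
#'
#' @param values Numeric vector (per-neuron window PEV), length >= 2.
#' @return List with `t`, `df`, `p.value`, `mean`, and `degenerate`
#'   (TRUE when the values have zero variance, in which case `t` is 0 for
#'   all-zero data and signed infinity otherwise).
#' @export
above_zero_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (stats::sd(values) == 0) {
    m <- mean(values)
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, df = length(values) - 1L,
                p.value = if (m == 0) 1 else 0,
                mean = m, degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean = mean(values), degenerate = FALSE)
}

#' Average omega-squared over subsamples matched to a target size
#'
#' Repeatedly draws, without replacement and per color group, as many
#' correct trials as there are error trials, computes omega-squared on each
#' draw, and averages.  When the target counts equal the available counts
#' there is a single possible draw and the full-sample value is returned
#' exactly.
#'
#' @param values Numeric spike counts (correct trials).
#' @param groups Color labels for `values`.
#' @param target_counts Named vector: draws per group (e.g. error-trial
#'   counts per color).
#' @param n_rep Number of subsample repetitions (default 1000).
#' @param seed Integer seed.
#' @return List with `mean_omega2`, `n_rep_used`, `full_draw` (TRUE when
#'   target equals available counts).
#' @export
subsampled_omega2 <- function(values, groups, target_counts, n_rep = 1000,
                              seed = NULL) {
  groups <- as.character(groups)
  avail <- table(groups)
  gnames <- names(target_counts)
  if (is.null(gnames) || !all(gnames %in% names(avail))) {
    stop("target_counts must be named by group", call. = FALSE)
  }
  if (any(target_counts < 2)) {
    stop("need at least two trials per group in the target", call. = FALSE)
  }
  if (any(target_counts > avail[gnames])) {
    stop("target_counts exceed available trials", call. = FALSE)
  }
  full_draw <- all(target_counts == avail[gnames]) &&
    length(gnames) == length(avail)
  if (full_draw) {
    om <- omega_squared(values, groups)$omega_squared
    return(list(mean_omega2 = om, n_rep_used = 1L, full_draw = TRUE))
  }
  idx_by_group <- split(seq_along(values), groups)
  oms <- .with_seed(seed, {
    vapply(seq_len(n_rep), function(r) {
      take <- unlist(lapply(gnames, function(g) {
        sample(idx_by_group[[g]], target_counts[[g]])
      }))
      omega_squared(values[take], groups[take])$omega_squared
    }, numeric(1))
  })
  list(mean_omega2 = mean(oms, na.rm = TRUE),
       n_rep_used = sum(!is.na(oms)), full_draw = FALSE)
}

#' Correct-versus-error information comparison with trial-count matching
#'
#' For each neuron, the correct-trial PEV is re-estimated by subsampling
#' correct trials down to the error-trial counts (per color, `n_rep`
#' times, averaged), then compared against the error-trial PEV across
#' neurons with a dependent t-test and Cohen's d.  Neurons with fewer than
#' two error trials for any color are excluded.
#'
#' @param neuron_tables A list; each element describes one neuron as a list
#'   with `correct_values`, `correct_groups`, `error_values`,
#'   `error_groups`.
#' @param n_rep Subsample repetitions per neuron.
#' @param seed Integer seed.
#' @return List with per-neuron data.frame `per_neuron` (subsampled correct
#'   and error omega-squared), `t`, `df`, `p.value`, `cohens_d`,
#'   `n_excluded`.
#' @export
error_correct_comparison <- function(neuron_tables, n_rep = 1000, seed = 1L) {
  rows <- list()
  excluded <- 0L
  for (i in seq_along(neuron_tables)) {
    nt <- neuron_tables[[i]]
    err_counts <- table(as.character(nt$error_groups))
    ok <- length(err_counts) >= 2 && all(err_counts >= 2) &&
      all(names(err_counts) %in% names(table(as.character(nt$correct_groups))))
    corr_counts <- table(as.character(nt$correct_groups))
    ok <- ok && all(err_counts <= corr_counts[names(err_counts)])
    if (!ok) {
      excluded <- excluded + 1L
      next
    }
    sub <- subsampled_omega2(nt$correct_values, nt$correct_groups,
                             stats::setNames(as.integer(err_counts),
                                             names(err_counts)),
                             n_rep = n_rep, seed = derive_seed(seed, "sub", i))
    err_om <- omega_squared(nt$error_values, nt$error_groups)$omega_squared
    rows[[length(rows) + 1L]] <- data.frame(
      neuron = i, correct_omega2 = sub$mean_omega2, error_omega2 = err_om
    )
  }
  if (length(rows) < 2) {
    stop("need at least two neurons with usable error trials", call. = FALSE)
  }
  per_neuron <- do.call(rbind, rows)
  diffs <- per_neuron$correct_omega2 - per_neuron$error_omega2
  tt <- stats::t.test(per_neuron$correct_omega2, per_neuron$error_omega2,
                      paired = TRUE)
  list(per_neuron = per_neuron,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       cohens_d = mean(diffs) / stats::sd(diffs),
       n_excluded = excluded)
}

#' Hierarchical clustering of PEV timecourses
#'
#' Agglomerative clustering of per-neuron load-1 PEV traces with a
#' (1 - Pearson correlation) distance and average (UPGMA) linkage.  Traces
#' are z-normalized per neuron (inert under the correlation distance);
#' constant traces are excluded with a warning.  Within-cluster
#' sum-of-squares is reported for k = 1..`k_max` so the elbow can be
#' inspected; the returned labels use `k` clusters (default 7).  Clusters
#' are numbered in dendrogram leaf order, which minimizes the average
#' inter-cluster distance along the ordering.
#'
#' @param traces Numeric matrix, one row per neuron, one column per bin.
#' @param k Number of clusters for the returned labels.
#' @param k_max Largest k for the within-cluster sum-of-squares curve.
#' @return An object of class `cluster_result`: list with `labels` (named
#'   by row), `hclust`, `wss` (length `k_max`), `k`, `order` (cluster ids
#'   in leaf order), `traces` (the z-normalized matrix), `excluded` (rows
#'   dropped as constant).
#' @export
cluster_timecourses <- function(traces, k = 7, k_max = 10) {
  traces <- as.matrix(traces)
  if (is.null(rownames(traces))) rownames(traces) <- seq_len(nrow(traces))
  sds <- apply(traces, 1, stats::sd)
  excluded <- rownames(traces)[is.na(sds) | sds == 0]
  if (length(excluded) > 0) {
    warning("excluding ", length(excluded),
            " constant trace(s): correlation undefined")
    traces <- traces[!(rownames(traces) %in% excluded), , drop = FALSE]
  }
  if (nrow(traces) < k) {
    stop("need at least k traces after exclusions", call. = FALSE)
  }
  z <- t(scale(t(traces)))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  hc <- stats::hclust(d, method = "average")
  k_max <- min(k_max, nrow(z))
  wss <- vapply(seq_len(k_max), function(kk) {
    lab <- stats::cutree(hc, kk)
    sum(vapply(split(seq_len(nrow(z)), lab), function(idx) {
      center <- colMeans(z[idx, , drop = FALSE])
      sum(sweep(z[idx, , drop = FALSE], 2, center)^2)
    }, numeric(1)))
  }, numeric(1))
  raw_labels <- stats::cutree(hc, k)
  # renumber clusters by first appearance along the dendrogram leaf order
  leaf_first <- raw_labels[hc$order]
  cluster_order <- unique(leaf_first)
  labels <- match(raw_labels, cluster_order)
  names(labels) <- rownames(z)
  structure(
    list(labels = labels, hclust = hc, wss = wss, k = k,
         order = seq_along(cluster_order), traces = z,
         excluded = excluded),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("hierarchical clustering of %d traces into %d clusters\n",
              length(x$labels), x$k))
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  cat(sprintf("  within-cluster SS at k = %d: %.3f\n", x$k, x$wss[x$k]))
  invisible(x)
}
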