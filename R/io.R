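#' Write / read trial tables as CSV
#'
#' Trial tables are plain UTF-8 CSV with a header row: `trial_id`,
#' `session_id`, `color_1`..`color_6` (`A`, `B`, or empty for absent),
#' `n_left`, `n_right`, `target_location`, `response_location`, `outcome`.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns a
#'   validated trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  need <- c("trial_id", "session_id", .color_col(1:6), "n_left", "n_right",
            "target_location", "response_location", "outcome")
  header <- names(utils::read.csv(path, nrows = 0))
  missing <- setdiff(need, header)
  if (length(missing) > 0) {
    stop("trial file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = stats::setNames(
                          rep("character", 6), .color_col(1:6)))
  for (cc in .color_col(1:6)) df[[cc]][df[[cc]] == ""] <- NA_character_
  df$outcome[!is.na(df$outcome) & df$outcome == ""] <- NA_character_
  .validate_trials(df)
  df
}

# Structural validation with row numbers in error messages.
.validate_trials <- function(df) {
  bad_load <- which(df$n_left < 1 | df$n_left > 3 |
                      df$n_right < 1 | df$n_right > 3 |
                      df$n_left + df$n_right < 2 |
                      df$n_left + df$n_right > 5)
  if (length(bad_load) > 0) {
    stop("hemifield loads out of range (1-3 per side, total 2-5) in row(s): ",
         paste(utils::head(bad_load, 5), collapse = ", "), call. = FALSE)
  }
  shown <- !is.na(as.matrix(df[, .color_col(1:6)]))
  n_shown_left <- rowSums(shown[, 1:3, drop = FALSE])
  n_shown_right <- rowSums(shown[, 4:6, drop = FALSE])
  bad_count <- which(n_shown_left != df$n_left | n_shown_right != df$n_right)
  if (length(bad_count) > 0) {
    stop("displayed colors inconsistent with hemifield loads in row(s): ",
         paste(utils::head(bad_count, 5), collapse = ", "), call. = FALSE)
  }
  tgt_color <- shown[cbind(seq_len(nrow(df)), df$target_location)]
  bad_tgt <- which(!tgt_color)
  if (length(bad_tgt) > 0) {
    stop("target location has no displayed color in row(s): ",
         paste(utils::head(bad_tgt, 5), collapse = ", "), call. = FALSE)
  }
  ok_out <- is.na(df$outcome) |
    df$outcome %in% c("correct", "error", "aborted", "no_response")
  if (!all(ok_out)) {
    stop("unknown outcome value in row(s): ",
         paste(utils::head(which(!ok_out), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Write / read spike tables as CSV
#'
#' Spike tables are plain CSV with columns `neuron_id`, `trial_id`, `time`
#' (seconds relative to sample onset; negative during fixation).  On read,
#' unsorted timestamps are sorted per (neuron, trial) with a warning, and
#' spikes referencing unknown trials raise an error when a trial table is
#' supplied.
#'
#' @param spikes Spike table.
#' @param path File path.
#' @param trials Optional trial table for referential checking.
#' @return `write_spikes` returns `path` invisibly; `read_spikes` returns
#'   the spike table sorted by neuron, trial, time.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path, trials = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "trial_id", "time")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("spike file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(trials)) {
    unknown <- setdiff(unique(df$trial_id), trials$trial_id)
    if (length(unknown) > 0) {
      stop("spikes reference unknown trial id(s): ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  ord <- order(df$neuron_id, df$trial_id, df$time)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("spike timestamps were not sorted; sorting per (neuron, trial)")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Run manifest for a pipeline execution
#'
#' Records the configuration snapshot, master seed, derived per-stage
#' seeds, package version, and timestamp, so a rerun with an equal manifest
#' reproduces equal outputs.
#'
#' @param config A [generative_config()].
#' @param seed Master seed.
#' @param stages Character vector of stage names.
#' @return A list (class `run_manifest`).
#' @export
run_manifest <- function(config, seed, stages = c("trials", "behavior",
                                                  "spikes", "information",
                                                  "population",
                                                  "normalization")) {
  cfg <- unclass(config)
  cfg$p_correct <- if (is.function(cfg$p_correct)) "<function>" else
    cfg$p_correct
  structure(
    list(
      package_version = as.character(utils::packageVersion("wmload")),
      master_seed = as.integer(seed),
      stage_seeds = stats::setNames(
        lapply(stages, function(s) derive_seed(seed, s)), stages),
      config = cfg,
      created = format(Sys.time(), tz = "UTC", usetz = TRUE)
    ),
    class = "run_manifest"
  )
}

#' Run the full synthetic-data analysis pipeline
#'
#' Generates trials, outcomes, and spikes from a [generative_config()],
#' then runs every analysis stage: behavioral report (per-load medians,
#' performance matrix, Cowan's K, Friedman test, load model), favorite
#' locations, PEV timecourses and classification, population window
#' statistics, hierarchical clustering of load-1 traces, and the
#' divisive-normalization regression.  All tables are written as CSV and
#' reports as JSON next to a manifest.
#'
#' @param config A [generative_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param n_neurons Number of synthetic neurons.
#' @param n_perm Permutations per significance test.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir, seed = config$rng_seed,
                         n_neurons = 40, n_perm = 200) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- run_manifest(config, seed)
  trials <- gen_trials(config, seed = derive_seed(seed, "trials"))
  trials <- gen_behavior(trials, config, seed = derive_seed(seed, "behavior"))
  neurons <- neuron_population(n_neurons, config,
                               seed = derive_seed(seed, "neurons"))
  spikes <- gen_spikes(trials, neurons, config,
                       seed = derive_seed(seed, "spikes"))
  write_trials(trials, file.path(out_dir, "trials.csv"))
  write_spikes(spikes, file.path(out_dir, "spikes.csv"))

  perf <- performance_by_load(trials)
  behavior_report <- list(
    medians = as.list(stats::setNames(perf$medians, paste0("load", 1:3))),
    performance_matrix = performance_matrix(trials),
    capacity = capacity_by_size(trials),
    friedman = tryCatch(
      friedman_load_test(
        perf$per_session[stats::complete.cases(perf$per_session), ,
                         drop = FALSE]),
      error = function(e) list(statistic = NA_real_, df = NA_integer_,
                               p.value = NA_real_,
                               note = conditionMessage(e))),
    glm = tryCatch(
      fit_load_glm(session_load_table(trials)),
      error = function(e) list(note = conditionMessage(e)))
  )

  favorites <- data.frame(
    neuron_id = neurons$neuron_id,
    favorite_location = vapply(neurons$neuron_id, function(nid) {
      as.integer(favorite_location(spikes, trials, nid))
    }, integer(1))
  )
  pev <- do.call(rbind, lapply(seq_len(nrow(favorites)), function(r) {
    pev_timecourse(spikes, trials, favorites$neuron_id[r],
                   favorites$favorite_location[r], n_perm = n_perm,
                   seed = seed)
  }))
  classes <- classify_neurons(pev)
  wtab <- window_pev(spikes, trials, favorites)

  load1 <- pev[pev$load == 1L, , drop = FALSE]
  traces <- do.call(rbind, lapply(split(load1, load1$neuron_id), function(d) {
    d$omega2[order(d$bin)]
  }))
  k <- min(7L, max(2L, nrow(traces) - 1L))
  clusters <- tryCatch(cluster_timecourses(traces, k = k),
                       error = function(e) NULL)
  dnr <- lapply(c(sample = "sample", delay = "delay"), function(ph) {
    dnr_analysis(spikes, trials, favorites, phase = ph, n_perm = n_perm,
                 seed = seed)
  })

  utils::write.csv(pev, file.path(out_dir, "pev.csv"), row.names = FALSE)
  utils::write.csv(classes, file.path(out_dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(wtab, file.path(out_dir, "window_pev.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(manifest = unclass(manifest),
         behavior = lapply(behavior_report, function(x) {
           if (is.matrix(x)) as.data.frame(x) else x
         })),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, trials = trials, neurons = neurons,
                 spikes = spikes, behavior = behavior_report,
                 favorites = favorites, pev = pev, classes = classes,
                 window_pev = wtab, clusters = clusters, dnr = dnr))
}
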