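test_that("selectivity and interaction indices hit their boundaries", {
  expect_equal(se_index(1.0, 0.0), -1) # fully reference-selective
  expect_equal(se_index(0.5, 0.5), 0)
  expect_equal(se_index(0.2, 0.6), 0.4)
  expect_equal(si_index(1.0, 0.0), -1) # full suppression by the probe
  expect_equal(si_index(0.4, 0.4), 0)
  expect_equal(si_index(0.4, 0.7), 0.3, tolerance = 1e-12)
  expect_error(se_index(1.2, 0.5), "\\[0, 1\\]")
  expect_error(si_index(0.5, -0.1), "\\[0, 1\\]")
})

test_that("condition rates normalize by the neuron-phase maximum", {
  # one neuron, favorite 4, probe locations 5 and 6; constant-rate spikes
  specs <- list()
  id <- 0
  add <- function(colors) {
    id <<- id + 1
    specs[[id]] <<- list(colors = colors, target = 4)
  }
  for (r in 1:3) {
    for (cc in c("A", "B")) {
      add(stats::setNames(list(cc, "A"), c("4", "1")))   # REF_cc
      add(stats::setNames(list(cc, "A"), c("5", "1")))   # PROBE_5_cc
      add(stats::setNames(list(cc, "A"), c("6", "1")))   # PROBE_6_cc
      for (c2 in c("A", "B")) {
        add(stats::setNames(list(cc, c2, "A"), c("4", "5", "1"))) # PAIR 5
        add(stats::setNames(list(cc, c2, "A"), c("4", "6", "1"))) # PAIR 6
      }
    }
  }
  trials <- make_trials(specs)
  trials$target_location <- 4L
  trials$target_location[trials$n_right == 1 & is.na(trials$color_4)] <- 1L
  # deterministic spiking: REF_A trials 8 spikes, everything else 4
  entries <- lapply(seq_len(nrow(trials)), function(i) {
    is_ref_a <- !is.na(trials$color_4[i]) & trials$color_4[i] == "A" &
      trials$n_right[i] == 1
    n <- if (isTRUE(is_ref_a)) 8 else 4
    list(neuron = 1, trial = trials$trial_id[i],
         times = seq(0.05, 0.75, length.out = n))
  })
  cr <- condition_rates(make_spikes(entries), trials, 1L, 4L, "sample")
  expect_false(cr$excluded)
  expect_equal(unname(cr$normalized["REF_A"]), 1.0)
  expect_equal(unname(cr$normalized["REF_B"]), 0.5)
  expect_true(all(abs(cr$normalized[grepl("PROBE", names(cr$normalized))] -
                        0.5) < 1e-12))
  idx <- build_index_set(cr)
  expect_equal(nrow(idx), 8L) # complete design: exactly 8 pairs
  # with equal rates everywhere the normalized maximum is 1 for all
  entries_eq <- lapply(entries, function(e) {
    e$times <- seq(0.05, 0.75, length.out = 4)
    e
  })
  cr_eq <- condition_rates(make_spikes(entries_eq), trials, 1L, 4L, "sample")
  expect_true(all(abs(cr_eq$normalized - 1) < 1e-12))
})

test_that("missing conditions shrink the index set and are recorded", {
  cr <- structure(
    list(neuron_id = 1L, phase = "sample", favorite = 4L,
         probe_locations = c(5L, 6L),
         raw = c(REF_A = 10, REF_B = 5,
                 PROBE_5_A = 4, PROBE_5_B = 6,
                 PROBE_6_A = NA, PROBE_6_B = NA,
                 PAIR_A_5_A = 7, PAIR_A_5_B = 8,
                 PAIR_B_5_A = 4.5, PAIR_B_5_B = 5.5,
                 PAIR_A_6_A = 7, PAIR_A_6_B = 8,
                 PAIR_B_6_A = 4.5, PAIR_B_6_B = 5.5),
         n_trials = NULL, excluded = FALSE),
    class = "condition_rates")
  cr$normalized <- cr$raw / max(cr$raw, na.rm = TRUE)
  idx <- build_index_set(cr)
  expect_equal(nrow(idx), 4L) # one probe location missing: half the pairs
  expect_equal(attr(idx, "skipped"), 4L)
  cr$excluded <- TRUE
  expect_error(build_index_set(cr), "excluded")
})

test_that("noiseless weighted normalization gives the exact slope identity", {
  # equal weights: SI = SE / 2, slope exactly 0.5, perfect fit
  p_eq <- simulate_index_population(120, w_ref = 1, w_probe = 1,
                                    noise = "none", seed = 30L)
  expect_equal(p_eq$si, p_eq$se / 2, tolerance = 1e-12)
  f_eq <- suppressWarnings(fit_se_si_regression(p_eq))
  expect_equal(f_eq$slope, 0.5, tolerance = 1e-12)
  expect_equal(f_eq$adj_r_squared, 1, tolerance = 1e-10)
  # reference-biased weights (0.8, 0.2): slope w_probe/(w_ref+w_probe) = 0.2
  p_rb <- simulate_index_population(120, w_ref = 0.8, w_probe = 0.2,
                                    noise = "none", seed = 31L)
  f_rb <- suppressWarnings(fit_se_si_regression(p_rb))
  expect_equal(f_rb$slope, 0.2, tolerance = 1e-12)
  # full reference weighting: PAIR = REF, SI identically zero, slope 0
  p_full <- simulate_index_population(120, w_ref = 1, w_probe = 0,
                                      noise = "none", seed = 32L)
  expect_true(all(abs(p_full$si) < 1e-12))
  f_full <- suppressWarnings(fit_se_si_regression(p_full))
  expect_equal(f_full$slope, 0, tolerance = 1e-12)
})

test_that("index pairs stay inside [-1, 1] and slopes are recovered under noise", {
  covered <- 0L
  for (s in 1:6) {
    p <- simulate_index_population(150, w_ref = 1, w_probe = 1,
                                   noise = "poisson",
                                   trials_per_condition = 40, seed = s)
    expect_true(all(p$se >= -1 & p$se <= 1))
    expect_true(all(p$si >= -1 & p$si <= 1))
    f <- fit_se_si_regression(p)
    covered <- covered + (f$ci[1] <= 0.5 && f$ci[2] >= 0.5)
  }
  # the 95% CI should cover the true equal-weight slope in most replicates
  expect_gte(covered, 4L)
  expect_error(fit_se_si_regression(data.frame(se = rep(0.2, 5),
                                               si = stats::runif(5))),
               "zero variance")
  expect_error(fit_se_si_regression(data.frame(se = 1:2 / 2, si = 1:2 / 2)),
               "three index pairs")
})

test_that("DNR grouping is disjoint and follows the load-1/load-2 rule", {
  cls <- data.frame(neuron_id = 1:4, phase = "sample",
                    sig_load1 = c(TRUE, FALSE, FALSE, TRUE),
                    sig_load2 = c(FALSE, TRUE, FALSE, TRUE))
  g <- group_neurons_for_dnr(cls)
  expect_equal(g$dnr_group,
               c("information-carrying", "information-gaining",
                 "non-informative", "information-carrying"))
  expect_true(all(table(g$neuron_id) == 1)) # one group per neuron-phase
})

test_that("color relabeling leaves the pooled regression invariant", {
  cfg <- generative_config(n_sessions = 1, trials_per_session = 800,
                           p_correct = c(1, 1, 1), rng_seed = 40L)
  tr <- gen_behavior(gen_trials(cfg), cfg)
  neurons <- neuron_population(3, cfg, seed = 41L)
  neurons$type <- "sample"
  neurons$favorite_location <- 4L
  neurons$rate_A_sample <- c(24, 18, 15)
  neurons$rate_B_sample <- c(6, 9, 12)
  neurons$w_probe_match <- NA_real_
  sp <- gen_spikes(tr, neurons, cfg, seed = 42L)
  pairs1 <- do.call(rbind, lapply(1:3, function(n) {
    build_index_set(condition_rates(sp, tr, n, 4L, "sample"))
  }))
  # swap every A/B label; the spikes are untouched, so the index multiset
  # and the fitted slope must not change
  tr2 <- tr
  for (cc in paste0("color_", 1:6)) {
    tr2[[cc]] <- c(A = "B", B = "A")[tr[[cc]]]
  }
  pairs2 <- do.call(rbind, lapply(1:3, function(n) {
    build_index_set(condition_rates(sp, tr2, n, 4L, "sample"))
  }))
  expect_equal(sort(round(pairs1$se, 10)), sort(round(pairs2$se, 10)))
  expect_equal(sort(round(pairs1$si, 10)), sort(round(pairs2$si, 10)))
  expect_equal(fit_se_si_regression(pairs1)$slope,
               fit_se_si_regression(pairs2)$slope, tolerance = 1e-10)
})

test_that("the generated equal-weight population shows DNR end to end", {
  cfg <- generative_config(n_sessions = 1, trials_per_session = 1600,
                           p_correct = c(1, 1, 1), rng_seed = 50L)
  tr <- gen_behavior(gen_trials(cfg), cfg)
  neurons <- neuron_population(8, cfg, seed = 51L)
  neurons$type <- "sample"
  neurons$favorite_location <- 4L
  neurons$rate_A_sample <- 20; neurons$rate_B_sample <- 8
  neurons$w_probe_match <- NA_real_
  sp <- gen_spikes(tr, neurons, cfg, seed = 52L)
  fav <- data.frame(neuron_id = neurons$neuron_id, favorite_location = 4L)
  res <- dnr_analysis(sp, tr, fav, phase = "sample", n_perm = 300,
                      seed = 53L)
  expect_true(all(res$groups$dnr_group == "information-carrying"))
  fit <- res$fits[["information-carrying"]]
  expect_equal(nrow(res$pairs), 8 * 8)
  expect_equal(fit$slope, 0.5, tolerance = 0.15)
})
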