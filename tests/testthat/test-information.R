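test_that("omega-squared matches hand-computed decompositions", {
  o <- omega_squared(c(2, 4, 8, 10), c("A", "A", "B", "B"))
  expect_equal(o$ss_effect, 36)
  expect_equal(o$ss_total, 40)
  expect_equal(o$ms_error, 2)
  expect_equal(o$df_effect, 1L)
  expect_equal(o$omega_squared, 34 / 42)
  # zero effect with residual noise: negative omega-squared preserved
  o2 <- omega_squared(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(o2$omega_squared, -0.2)
  # degenerate and invalid inputs
  expect_true(is.na(omega_squared(rep(2, 6),
                                  rep(c("A", "B"), 3))$omega_squared))
  expect_error(omega_squared(1:4, rep("A", 4)), "two groups")
  expect_error(omega_squared(1:3, c("A", "A", "B")), "two observations")
})

test_that("omega-squared agrees with an aov-based oracle on random data", {
  set.seed(101)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    sizes <- sample(2:6, k, replace = TRUE)
    g <- rep(letters[1:k], sizes)
    v <- stats::rpois(sum(sizes), 5) + stats::runif(sum(sizes), 0, 0.01)
    tab <- stats::anova(stats::aov(v ~ factor(g)))
    oracle <- (tab$`Sum Sq`[1] - tab$Df[1] * tab$`Mean Sq`[2]) /
      (sum(tab$`Sum Sq`) + tab$`Mean Sq`[2])
    expect_equal(omega_squared(v, g)$omega_squared, oracle,
                 tolerance = 1e-12)
  }
})

test_that("binning uses half-open bins and conserves spike counts", {
  tr <- make_trials(list(list(colors = list(`4` = "A", `1` = "B"),
                              target = 4)))
  # empty spike train: all-zero counts
  b0 <- bin_spikes(make_spikes(list(list(neuron = 1, trial = 1,
                                         times = numeric(0)))), tr)
  expect_equal(nrow(b0), 0L) # no neurons present at all
  sp <- make_spikes(list(list(neuron = 1, trial = 1, times = 0.35)))
  b <- bin_spikes(sp, tr)
  expect_equal(nrow(b), 9L)
  expect_equal(b$count[b$bin_start == 0.2], 1L)
  expect_equal(sum(b$count), 1L)
  # spike exactly on an edge belongs to the right-hand bin
  b2 <- bin_spikes(make_spikes(list(list(neuron = 1, trial = 1,
                                         times = c(0.2, 0.1999)))), tr)
  expect_equal(b2$count[b2$bin_start == 0.2], 1L)
  expect_equal(b2$count[b2$bin_start == 0.0], 1L)
  expect_error(bin_spikes(sp, tr, bin_width = 0.7), "divide")
  # Poisson rate recovery: 10 Hz, 0.2 s bins, mean count ~ 2
  set.seed(5)
  n <- 2000
  tr_many <- do.call(rbind, lapply(1:n, function(i) {
    t1 <- make_trials(list(list(colors = list(`4` = "A", `1` = "B"),
                                target = 4)))
    t1$trial_id <- i
    t1
  }))
  times <- lapply(1:n, function(i) sort(stats::runif(stats::rpois(1, 18),
                                                     0, 1.8)))
  spm <- make_spikes(lapply(1:n, function(i) list(neuron = 1, trial = i,
                                                  times = times[[i]])))
  bm <- bin_spikes(spm, tr_many)
  expect_equal(mean(bm$count), 2, tolerance = 0.05)
})

test_that("permutation p-values use the add-one rule and count ties", {
  # observed separation unattainable by chance: p = 1/(n_perm + 1)
  v <- c(100 + (1:10) / 10, (1:12) / 10)
  g <- rep(c("A", "B"), c(10, 12))
  pt <- permutation_pev_test(v, g, n_perm = 1000, seed = 1L)
  expect_equal(pt$p.value, 1 / 1001)
  expect_true(pt$significant)
  # constant data: every permutation ties, p = 1
  pt0 <- permutation_pev_test(rep(3, 8), rep(c("A", "B"), 4), n_perm = 100)
  expect_equal(pt0$p.value, 1)
  expect_false(pt0$significant)
  # determinism under a fixed seed
  v2 <- stats::rpois(40, 4)
  g2 <- rep(c("A", "B"), 20)
  expect_equal(permutation_pev_test(v2, g2, n_perm = 300, seed = 9L)$p.value,
               permutation_pev_test(v2, g2, n_perm = 300, seed = 9L)$p.value)
  expect_error(permutation_pev_test(v2, g2, n_perm = 0), "n_perm")
})

test_that("permutation p-values are superuniform under the null", {
  pv <- simulate_null_pev_pvalues(n_bins = 300, n_perm = 500, seed = 13L)
  # empirical CDF at alpha within Monte Carlo error of alpha or below
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(pv <= alpha), alpha + 3 * sqrt(alpha / 300))
  }
  expect_gte(mean(pv <= 0.25), 0.25 - 3 * sqrt(0.25 / 300))
})

test_that("favorite location is recovered, ties break to the lowest index", {
  fx <- tuned_neuron_fixture(location = 5L, n_per_color = 30)
  loc <- favorite_location(fx$spikes, fx$trials, 1L)
  expect_equal(as.integer(loc), 5L)
  cum <- attr(loc, "cumulative_pev")
  expect_equal(names(which.max(cum)), "5")
  # neuron with no spikes at all: all candidates tie at zero, lowest wins
  fx2 <- tuned_neuron_fixture(location = 5L)
  silent <- fx2$spikes[0, ]
  tr_all <- do.call(rbind, lapply(4:6, function(l) {
    t <- tuned_neuron_fixture(location = l, n_per_color = 3)$trials
    t$trial_id <- t$trial_id + 100 * l
    t
  }))
  no_spikes <- make_spikes(list())
  expect_equal(as.integer(favorite_location(no_spikes, tr_all, 1L)), 4L)
  expect_error(favorite_location(silent, fx2$trials[0, ], 1L),
               "no candidate")
})

test_that("timecourses flag information where the generator put it", {
  cfg <- generative_config(n_sessions = 1, trials_per_session = 600,
                           p_correct = c(1, 1, 1), rng_seed = 2L)
  tr <- gen_behavior(gen_trials(cfg), cfg)
  neurons <- neuron_population(1, cfg, seed = 3L)
  neurons$type <- "sample"
  neurons$favorite_location <- 4L
  neurons$rate_A_sample <- 25; neurons$rate_B_sample <- 5
  neurons$rate_A_delay <- neurons$baseline
  neurons$rate_B_delay <- neurons$baseline
  neurons$w_probe_match <- NA_real_
  sp <- gen_spikes(tr, neurons, cfg, seed = 4L)
  pev <- pev_timecourse(sp, tr, 1L, 4L, n_perm = 300, seed = 5L)
  expect_equal(nrow(pev), 27L) # 3 loads x 9 bins
  expect_equal(unique(pev$phase[pev$bin <= 4]), "sample")
  expect_equal(unique(pev$phase[pev$bin >= 5]), "delay")
  s1 <- pev[pev$load == 1 & pev$phase == "sample", ]
  expect_true(all(s1$significant))
  expect_true(mean(s1$omega2) >
                mean(pev$omega2[pev$load == 2 & pev$phase == "sample"]))
  # deterministic given the seed
  pev2 <- pev_timecourse(sp, tr, 1L, 4L, n_perm = 300, seed = 5L)
  expect_identical(pev, pev2)
})

test_that("the significance truth table is a bijection onto groups I-VII", {
  triples <- expand.grid(l1 = c(TRUE, FALSE), l2 = c(TRUE, FALSE),
                         l3 = c(TRUE, FALSE))
  labels <- significance_group(triples$l1, triples$l2, triples$l3)
  expect_equal(sum(is.na(labels)), 1L) # only the all-false triple
  expect_setequal(labels[!is.na(labels)],
                  c("I", "II", "III", "IV", "V", "VI", "VII"))
  expect_equal(significance_group(TRUE, FALSE, FALSE), "I")
  expect_equal(significance_group(FALSE, TRUE, FALSE), "II")
  expect_equal(significance_group(TRUE, TRUE, TRUE), "VII")
})

test_that("classification flags, groups, and pooled membership line up", {
  # synthetic PEV table: load 1 significant in sample bin 2 only,
  # load 2 significant in delay bins 6 and 7, load 3 never
  pev <- expand.grid(bin = 1:9, load = 1:3)
  pev$neuron_id <- 1L
  pev$side <- "ipsi"
  pev$phase <- ifelse(pev$bin <= 4, "sample", "delay")
  pev$significant <- FALSE
  pev$significant[pev$load == 1 & pev$bin == 2] <- TRUE
  pev$significant[pev$load == 2 & pev$bin %in% 6:7] <- TRUE
  cl <- classify_neurons(pev)
  s <- cl[cl$phase == "sample", ]
  d <- cl[cl$phase == "delay", ]
  expect_equal(s$group, "I")
  expect_true(s$pooled1 && !s$pooled2 && !s$pooled3)
  expect_equal(d$group, "II")
  expect_true(!d$pooled1 && d$pooled2 && !d$pooled3)
  # strict criterion requires two consecutive significant bins
  cls <- classify_neurons(pev, strict = TRUE)
  expect_false(cls$sig_load1[cls$phase == "sample"])
  expect_true(cls$sig_load2[cls$phase == "delay"])
  # no significant bins anywhere: no group, no pooled membership
  pev$significant <- FALSE
  cl0 <- classify_neurons(pev)
  expect_true(all(is.na(cl0$group)))
  expect_false(any(cl0$pooled1 | cl0$pooled2 | cl0$pooled3))
})

test_that("binomial proportion test gives exact upper tails", {
  expect_equal(binomial_proportion_test(0, 100), 1)
  expect_equal(binomial_proportion_test(1, 1), 0.05)
  # oracle: explicit tail sum
  expect_equal(binomial_proportion_test(34, 362),
               sum(stats::dbinom(34:362, 362, 0.05)), tolerance = 1e-12)
  expect_lt(binomial_proportion_test(34, 362), 0.001)
  expect_error(binomial_proportion_test(5, 4), "k must")
  expect_error(binomial_proportion_test(1, 4, p0 = 1), "p0")
})
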