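#' Per-session performance by ipsilateral load
#'
#' Proportion of correct responses per session and ipsilateral (change-side)
#' hemifield load, with the across-session median per load.  Aborted and
#' no-response trials are excluded; a (session, load) cell with no completed
#' trials is `NA`, never 0.
#'
#' @param trials Trial table with outcomes.
#' @return A list with `per_session` (sessions x loads matrix of proportions)
#'   and `medians` (length-3 vector of across-session medians).
#' @export
performance_by_load <- function(trials) {
  done <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  sessions <- sort(unique(trials$session_id))
  per_session <- matrix(NA_real_, nrow = length(sessions), ncol = 3,
                        dimnames = list(session = sessions, load = 1:3))
  if (nrow(done) > 0) {
    left <- done$target_location <= 3L
    ipsi <- ifelse(left, done$n_left, done$n_right)
    for (s in seq_along(sessions)) {
      for (l in 1:3) {
        sel <- done$session_id == sessions[s] & ipsi == l
        if (any(sel)) {
          per_session[s, l] <- mean(done$outcome[sel] == "correct")
        }
      }
    }
  }
  medians <- apply(per_session, 2, stats::median, na.rm = TRUE)
  medians[is.nan(medians)] <- NA_real_
  list(per_session = per_session, medians = medians)
}

#' Mean performance matrix over ipsi- and contralateral load combinations
#'
#' Mean of session-level proportions correct per (ipsilateral load,
#' contralateral load) cell.  The (3, 3) cell is absent by task design
#' (array sizes two to five) and stays `NA`.
#'
#' @param trials Trial table with outcomes.
#' @return A 3 x 3 matrix, rows = ipsilateral load, columns = contralateral
#'   load.
#' @export
performance_matrix <- function(trials) {
  done <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  out <- matrix(NA_real_, 3, 3,
                dimnames = list(ipsi = 1:3, contra = 1:3))
  if (nrow(done) == 0) return(out)
  left <- done$target_location <= 3L
  done$ipsi <- ifelse(left, done$n_left, done$n_right)
  done$contra <- ifelse(left, done$n_right, done$n_left)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i + j > 5) next
      sel <- done[done$ipsi == i & done$contra == j, , drop = FALSE]
      if (nrow(sel) == 0) next
      by_sess <- tapply(sel$outcome == "correct", sel$session_id, mean)
      out[i, j] <- mean(by_sess)
    }
  }
  out
}

#' Cowan's K capacity estimate
#'
#' `K = n * p` for array size `n` and proportion correct `p`: the expected
#' number of items held in working memory under a single-probe change
#' detection design.
#'
#' @param n Array size(s), items in working memory.
#' @param p Proportion(s) correct in `[0, 1]`.
#' @return A data.frame with columns `n`, `p`, `K`.
#' @examples
#' cowan_k(2, 0.7831) # K = 1.5662
#' @export
cowan_k <- function(n, p) {
  if (any(n < 1) || any(n != round(n))) {
    stop("n must be a positive integer array size", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  data.frame(n = n, p = p, K = n * p)
}

#' Capacity estimates per total array size
#'
#' Overall proportion correct at each full array size (two to five items)
#' converted to Cowan's K.
#'
#' @param trials Trial table with outcomes.
#' @return A data.frame with columns `n`, `p`, `K` for n = 2..5 (rows with
#'   no completed trials are dropped).
#' @export
capacity_by_size <- function(trials) {
  done <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  total <- done$n_left + done$n_right
  sizes <- sort(unique(total))
  sizes <- sizes[sizes >= 2 & sizes <= 5]
  p <- vapply(sizes, function(nn) mean(done$outcome[total == nn] == "correct"),
              numeric(1))
  cowan_k(sizes, p)
}

#' Friedman test of the ipsilateral load effect on performance
#'
#' Nonparametric test of a load effect with sessions as blocks and the
#' three ipsilateral loads as treatments.
#'
#' @param perf Sessions x loads matrix of proportions correct (e.g.
#'   `performance_by_load(trials)$per_session`).
#' @return A list with `statistic` (chi-squared), `df`, and `p.value`.
#' @export
friedman_load_test <- function(perf) {
  perf <- as.matrix(perf)
  if (nrow(perf) < 2) {
    stop("need at least two complete sessions (blocks)", call. = FALSE)
  }
  if (any(is.na(perf))) {
    stop("incomplete blocks: remove sessions with missing load cells ",
         "(listwise) before the Friedman test", call. = FALSE)
  }
  ft <- stats::friedman.test(perf)
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) {
    # complete ties: no rank variation at all, so no load effect
    stat <- 0
    p <- 1
  }
  list(statistic = stat,
       df = unname(ft$parameter),
       p.value = p)
}

# Extract the coefficient table and fit summaries from an lm fit.
.glm_fit_summary <- function(fit) {
  sm <- summary(fit)
  coefs <- stats::coef(sm)
  fstat <- sm$fstatistic
  list(
    coefficients = coefs[, "Estimate"],
    t = coefs[, "t value"],
    p = coefs[, "Pr(>|t|)"],
    df_residual = fit$df.residual,
    adj_r_squared = sm$adj.r.squared,
    f = if (is.null(fstat)) NA_real_ else unname(fstat["value"]),
    f_df = if (is.null(fstat)) c(NA, NA) else unname(fstat[c("numdf", "dendf")]),
    log_lik = as.numeric(stats::logLik(fit))
  )
}

#' Linear model of performance on ipsi- and contralateral load
#'
#' Fits session-level proportion correct on ipsilateral load, contralateral
#' load, and their interaction (Gaussian errors, identity link), plus a
#' reduced model that omits the contralateral main effect but keeps the
#' interaction, and reports the absolute log-likelihood difference between
#' the two.
#'
#' @param rows Data.frame with columns `performance`, `ipsi`, `contra`
#'   (one row per session x load-combination cell).
#' @param center Center the load predictors before fitting (default FALSE,
#'   raw 1-3 scale).
#' @return A list with `full`, `reduced` (coefficient tables, t, p,
#'   adjusted R-squared, F, log-likelihood) and `delta_llr`.
#' @export
fit_load_glm <- function(rows, center = FALSE) {
  stopifnot(all(c("performance", "ipsi", "contra") %in% names(rows)))
  if (nrow(rows) < 10) {
    stop("need at least 10 session-level rows", call. = FALSE)
  }
  if (!all(rows$ipsi %in% 1:3) || !all(rows$contra %in% 1:3)) {
    stop("loads must be in {1, 2, 3}", call. = FALSE)
  }
  d <- data.frame(performance = rows$performance,
                  ipsi = as.numeric(rows$ipsi),
                  contra = as.numeric(rows$contra))
  if (center) {
    d$ipsi <- d$ipsi - mean(d$ipsi)
    d$contra <- d$contra - mean(d$contra)
  }
  mm <- stats::model.matrix(~ ipsi + contra + ipsi:contra, data = d)
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    bad <- colnames(mm)[qr(mm)$pivot[(qr_rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- stats::lm(performance ~ ipsi + contra + ipsi:contra, data = d)
  reduced <- stats::lm(performance ~ ipsi + ipsi:contra, data = d)
  list(
    full = .glm_fit_summary(full),
    reduced = .glm_fit_summary(reduced),
    delta_llr = abs(as.numeric(stats::logLik(full)) -
                      as.numeric(stats::logLik(reduced)))
  )
}

#' Session-level rows for the load model
#'
#' Aggregates trials into one row per (session, ipsi load, contra load)
#' cell with its proportion correct, the unit of analysis for
#' [fit_load_glm()].
#'
#' @param trials Trial table with outcomes.
#' @return Data.frame with columns `session_id`, `ipsi`, `contra`,
#'   `n_trials`, `performance`.
#' @export
session_load_table <- function(trials) {
  done <- trials[trials$outcome %in% c("correct", "error"), , drop = FALSE]
  left <- done$target_location <= 3L
  done$ipsi <- ifelse(left, done$n_left, done$n_right)
  done$contra <- ifelse(left, done$n_right, done$n_left)
  agg <- stats::aggregate(list(performance = done$outcome == "correct"),
                          by = list(session_id = done$session_id,
                                    ipsi = done$ipsi, contra = done$contra),
                          FUN = mean)
  counts <- stats::aggregate(list(n_trials = done$outcome),
                             by = list(session_id = done$session_id,
                                       ipsi = done$ipsi, contra = done$contra),
                             FUN = length)
  out <- merge(agg, counts)
  out[order(out$session_id, out$ipsi, out$contra), , drop = FALSE]
}
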