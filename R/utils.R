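# Internal helpers shared across modules.

# Screen layout: six fixed stimulus locations, 1-3 in the left hemifield,
# 4-6 in the right hemifield.
.LOCATIONS <- 1:6
.LEFT_LOCATIONS <- 1:3
.RIGHT_LOCATIONS <- 4:6

#' Hemifield of a screen location
#'
#' Locations 1-3 lie in the left visual hemifield, 4-6 in the right.
#'
#' @param location Integer location id(s) in 1..6.
#' @return Character vector, `"left"` or `"right"`.
#' @export
hemifield <- function(location) {
  stopifnot(all(location %in% .LOCATIONS))
  ifelse(location <= 3L, "left", "right")
}

# Item count in the hemifield of `location`, per trial.
.hemifield_load <- function(trials, location) {
  if (hemifield(location) == "left") trials$n_left else trials$n_right
}

# Item count in the hemifield opposite to `location`, per trial.
.opposite_load <- function(trials, location) {
  if (hemifield(location) == "left") trials$n_right else trials$n_left
}

.color_col <- function(location) paste0("color_", location)

#' Derive a reproducible integer seed from a master seed and stream ids
#'
#' All randomness in the package flows from explicit seeds.  Sub-streams
#' (per neuron, per load, per bin) use seeds derived deterministically from
#' the master seed so results do not depend on evaluation order.
#'
#' @param master Integer master seed.
#' @param ... Integer or character stream identifiers.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  ids <- list(...)
  m <- 2147483647 # 2^31 - 1, keeps seeds inside R's integer range
  s <- as.double(master) %% m
  for (id in ids) {
    v <- if (is.character(id)) {
      codes <- utf8ToInt(id)
      sum(codes * seq_along(codes))
    } else {
      as.double(id)
    }
    s <- (s * 48271 + abs(v) + 1) %% m
  }
  as.integer(s)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == round(x)
}

# Nearly-integer check for duration/bin divisibility.
.divides <- function(width, duration, tol = 1e-8) {
  ratio <- duration / width
  abs(ratio - round(ratio)) < tol
}
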