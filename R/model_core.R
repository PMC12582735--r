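# Four-state Markov engine: transition profiles, structural variants,
# cohort trace propagation, and the complete-response effect measure.

#' The four health states of the seizure model
#'
#' The model admits exactly four mutually exclusive states: seizure-free
#' (complete response), partial response (at least 50\% reduction in seizure
#' frequency), non-response, and discontinuation of treatment for any reason.
#'
#' @return Character vector of the four state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("seizure_free", "partial_response", "non_response", "discontinued")
}

# canonical order used by every matrix/vector in the package
.states <- c("seizure_free", "partial_response", "non_response", "discontinued")

#' Structural variants of the transition structure
#'
#' @description
#' The per-cycle outcome probabilities are constant over the horizon; the
#' variants differ in which states terminate further transitions:
#' \describe{
#'   \item{`absorbing_sf_disc`}{seizure-free and discontinued are absorbing;
#'     partial and non-responders re-draw their outcome each cycle (default).}
#'   \item{`absorbing_disc_only`}{only discontinued is absorbing; seizure-free
#'     patients re-draw along with partial and non-responders.}
#'   \item{`redraw_all`}{no absorbing state; every patient re-draws each
#'     cycle (memoryless repeated multinomial).}
#' }
#' @return Character vector of the three variant names.
#' @export
structural_variants <- function() {
  c("absorbing_sf_disc", "absorbing_disc_only", "redraw_all")
}

#' Construct a per-cycle transition profile for one treatment
#'
#' A transition profile holds a treatment's probabilities of landing in each
#' of the four health states over one 3-month cycle, together with their
#' standard errors (used by the probabilistic sensitivity analysis to
#' moment-match beta distributions). Probabilities must lie on the unit
#' simplex: small printing slack (up to `tol`) is renormalized silently,
#' larger deviations are an error naming the treatment.
#'
#' @param treatment Treatment label (e.g. `"BRV"`).
#' @param p Numeric vector of 4 probabilities in canonical state order
#'   (seizure-free, partial response, non-response, discontinued).
#' @param se Numeric vector of 4 nonnegative standard errors (default all 0).
#'   Each must satisfy `se^2 < p * (1 - p)` when `p` is interior, the
#'   feasibility bound for a beta distribution with those moments.
#' @param tol Simplex tolerance on input (default 1e-6).
#'
#' @return An object of class `transition_profile`: a list with elements
#'   `treatment`, `p` (named, renormalized to sum exactly 1) and `se`.
#' @export
#' @examples
#' transition_profile("BRV", c(0.065, 0.355, 0.370, 0.210),
#'                    c(0.003, 0.018, 0.011, 0.011))
transition_profile <- function(treatment, p, se = rep(0, 4), tol = 1e-6) {
  if (!is.character(treatment) || length(treatment) != 1L) {
    stop_foscea("`treatment` must be a single label", "foscea_validation_error")
  }
  if (length(p) != 4L || !is.numeric(p) || anyNA(p)) {
    stop_foscea(sprintf("transition profile for %s needs 4 probabilities",
                        treatment), "foscea_validation_error")
  }
  if (length(se) != 4L || !is.numeric(se) || anyNA(se)) {
    stop_foscea(sprintf("transition profile for %s needs 4 standard errors",
                        treatment), "foscea_validation_error")
  }
  if (any(p < -tol) || any(p > 1 + tol)) {
    stop_foscea(sprintf("probabilities for %s outside [0, 1]", treatment),
                "foscea_simplex_error")
  }
  s <- sum(p)
  if (abs(s - 1) > tol) {
    stop_foscea(
      sprintf("probabilities for %s sum to %.8f, not 1 (tolerance %g)",
              treatment, s, tol),
      "foscea_simplex_error")
  }
  p <- pmin(pmax(p, 0), 1)
  p <- p / sum(p)
  if (any(se < 0)) {
    stop_foscea(sprintf("negative standard error for %s", treatment),
                "foscea_validation_error")
  }
  interior <- p > 0 & p < 1
  bad <- interior & se > 0 & se^2 >= p * (1 - p)
  if (any(bad)) {
    stop_foscea(
      sprintf("standard error for %s state '%s' violates se^2 < p(1-p)",
              treatment, .states[which(bad)[1]]),
      "foscea_infeasible_moments_error")
  }
  structure(
    list(treatment = treatment,
         p = setNames(as.numeric(p), .states),
         se = setNames(as.numeric(se), .states)),
    class = "transition_profile")
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf("<transition_profile> %s\n", x$treatment))
  print(round(rbind(p = x$p, se = x$se), 4))
  invisible(x)
}

#' Build the 4x4 per-cycle transition matrix for a structural variant
#'
#' Rows index the current state, columns the next state; every row is a
#' probability vector. Absorbing states receive identity rows; re-drawing
#' states receive the profile's outcome probabilities.
#'
#' @param profile A [transition_profile()].
#' @param variant One of [structural_variants()].
#' @return A 4x4 row-stochastic matrix with state dimnames.
#' @export
#' @examples
#' brv <- transition_profile("BRV", c(0.065, 0.355, 0.370, 0.210))
#' build_transition_matrix(brv, "redraw_all")
build_transition_matrix <- function(profile,
                                    variant = structural_variants()) {
  variant <- match.arg(variant)
  stopifnot(inherits(profile, "transition_profile"))
  p <- profile$p
  m <- matrix(rep(p, each = 4L), nrow = 4L, dimnames = list(.states, .states))
  absorbing <- switch(variant,
    absorbing_sf_disc   = c("seizure_free", "discontinued"),
    absorbing_disc_only = "discontinued",
    redraw_all          = character(0))
  for (s in absorbing) {
    m[s, ] <- 0
    m[s, s] <- 1
  }
  m
}

#' Model run settings: cycles, horizon and structural variant
#'
#' @param n_cycles Number of 3-month cycles (default 8, the 2-year horizon).
#' @param cycle_length_days Days per cycle (default 90).
#' @param variant Structural variant, see [structural_variants()].
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(n_cycles = 8L, cycle_length_days = 90,
                       variant = structural_variants()) {
  variant <- match.arg(variant)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop_foscea("`n_cycles` must be a whole number >= 1",
                "foscea_config_error")
  }
  assert_scalar_number(cycle_length_days, "cycle_length_days", lower = 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 cycle_length_days = cycle_length_days,
                 variant = variant),
            class = "model_spec")
}

#' Propagate a cohort through the Markov model
#'
#' The whole cohort starts treatment-naive and realizes its first-cycle
#' multinomial outcome at cycle 1 (the first occupancy row equals the
#' profile's probabilities); each later row is the previous row propagated
#' through the variant's transition matrix. State occupancy is evaluated at
#' cycle end with no half-cycle correction. Alongside occupancy, the trace
#' accumulates `ever_sf`, the cumulative proportion of the cohort that has
#' entered the seizure-free state by each cycle — the model's
#' complete-response outcome. Under variants where seizure-free is absorbing,
#' `ever_sf` coincides with seizure-free occupancy.
#'
#' @param spec A [model_spec()].
#' @param profile A [transition_profile()].
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   (`n_cycles` x 4 matrix of proportions, rows summing to 1), `ever_sf`
#'   (length `n_cycles`, non-decreasing), `treatment`, and `spec`.
#' @export
#' @examples
#' brv <- transition_profile("BRV", c(0.065, 0.355, 0.370, 0.210))
#' tr <- run_cohort(model_spec(), brv)
#' tr$ever_sf[8]  # cumulative complete response at 2 years
run_cohort <- function(spec, profile) {
  stopifnot(inherits(spec, "model_spec"), inherits(profile, "transition_profile"))
  n <- spec$n_cycles
  m <- build_transition_matrix(profile, spec$variant)
  occ <- matrix(NA_real_, nrow = n, ncol = 4L,
                dimnames = list(NULL, .states))
  occ[1L, ] <- profile$p

  # ever_sf: mass that has ever visited seizure_free. Track the complement:
  # the never-SF mass by current state; each cycle its inflow into
  # seizure_free moves permanently into the "ever" bucket.
  ever <- numeric(n)
  ever[1L] <- profile$p[["seizure_free"]]
  never <- profile$p
  never[["seizure_free"]] <- 0

  if (n > 1L) {
    for (t in 2:n) {
      occ[t, ] <- occ[t - 1L, , drop = TRUE] %*% m
      never <- drop(never %*% m)
      ever[t] <- ever[t - 1L] + never[["seizure_free"]]
      never[["seizure_free"]] <- 0
    }
  }
  structure(list(occupancy = occ, ever_sf = ever,
                 treatment = profile$treatment, spec = spec),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %s, %d cycles, variant %s\n",
              x$treatment, x$spec$n_cycles, x$spec$variant))
  print(round(cbind(x$occupancy, ever_sf = x$ever_sf), 4))
  invisible(x)
}

#' The effectiveness outcome: proportion achieving complete response
#'
#' @param trace A [run_cohort()] trace.
#' @param definition How complete response is read off the trace:
#'   `"ever_sf"` (default) — cumulative proportion ever seizure-free by the
#'   final cycle; `"mean_sf_occupancy"` — cycle-average seizure-free
#'   occupancy; `"terminal_sf"` — final-cycle seizure-free occupancy.
#' @return A proportion in \[0, 1\].
#' @export
effect_measure <- function(trace,
                           definition = c("ever_sf", "mean_sf_occupancy",
                                          "terminal_sf")) {
  stopifnot(inherits(trace, "cohort_trace"))
  definition <- match.arg(definition)
  n <- nrow(trace$occupancy)
  unname(switch(definition,
    ever_sf = trace$ever_sf[n],
    mean_sf_occupancy = mean(trace$occupancy[, "seizure_free"]),
    terminal_sf = trace$occupancy[n, "seizure_free"]))
}

#' Cohort trace as a long data frame
#'
#' @param trace A [run_cohort()] trace.
#' @return Data frame with columns `cycle`, `state`, `proportion`, `ever_sf`.
#' @export
trace_as_df <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  n <- nrow(trace$occupancy)
  data.frame(
    cycle = rep(seq_len(n), times = 4L),
    state = rep(.states, each = n),
    proportion = as.vector(trace$occupancy),
    ever_sf = rep(trace$ever_sf, times = 4L),
    stringsAsFactors = FALSE)
}
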