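# Second-order Monte Carlo probabilistic sensitivity analysis: parameter
# sampling, the iteration engine, ICER-plane quadrant summaries and the
# cost-effectiveness acceptability curve.

#' Draw one transition profile from its beta uncertainty distributions
#'
#' The seizure-free, partial-response and discontinuation probabilities are
#' drawn from beta distributions moment-matched to their means and standard
#' errors; the non-response probability is the residual `1 - sum`, mirroring
#' how the model inputs define it. Draws with a negative residual are
#' rejected and redrawn (cap `max_attempts`), so every returned profile lies
#' on the simplex. With all standard errors zero, the input profile is
#' returned unchanged.
#'
#' @param profile A [transition_profile()] with standard errors.
#' @param max_attempts Rejection cap (default 1000).
#' @return A [transition_profile()] with the drawn probabilities (standard
#'   errors carried over unchanged).
#' @export
sample_transition_profile <- function(profile, max_attempts = 1000L) {
  stopifnot(inherits(profile, "transition_profile"))
  p <- profile$p; se <- profile$se
  if (all(se == 0)) return(profile)
  direct <- c("seizure_free", "partial_response", "discontinued")
  for (attempt in seq_len(max_attempts)) {
    draw <- vapply(direct, function(s) rbeta_mean_se(1L, p[[s]], se[[s]]),
                   numeric(1))
    p_nr <- 1 - sum(draw)
    if (p_nr >= 0) {
      newp <- setNames(c(draw[["seizure_free"]], draw[["partial_response"]],
                         p_nr, draw[["discontinued"]]), health_states())
      return(structure(list(treatment = profile$treatment, p = newp,
                            se = se), class = "transition_profile"))
    }
  }
  stop_foscea(
    sprintf("transition sampling for %s: residual non-response < 0 in %d consecutive draws",
            profile$treatment, max_attempts),
    "foscea_sampling_infeasible_error")
}

#' Run the probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: each iteration simultaneously redraws every
#' uncertain parameter from its distribution — transition probabilities
#' (beta, residual non-response), per-mg drug and adverse-event-drug costs
#' (gamma from mean/SE), healthcare service costs (gamma, SE from the stated
#' +/-25\% variation), annual adverse-event probabilities (beta, SE from the
#' same +/-25\% convention), and the annual discount rate (beta rescaled to
#' its stated 0-5\% range) — then runs the deterministic pipeline and records
#' each treatment's (cost, effect). Dose schedules are fixed (no uncertainty
#' is reported for them). Results are reproducible given the seed.
#'
#' @param cfg A `foscea_config`.
#' @param n_iterations Number of iterations; default from `cfg$psa`.
#' @param seed RNG seed; default from `cfg$psa`.
#' @return An object of class `psa_result`: list with `cost` and `effect`
#'   (`n_iterations` x treatments matrices), `treatments`, `reference`,
#'   `n_iterations`, `seed`, and `summary` (per-treatment iteration means).
#' @export
#' @examples
#' cfg <- default_config()
#' psa <- run_psa(cfg, n_iterations = 50, seed = 1)
#' psa$summary
run_psa <- function(cfg, n_iterations = NULL, seed = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(n_iterations)) n_iterations <- cfg$psa$n_iterations
  if (is.null(seed)) seed <- cfg$psa$seed
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop_foscea("`n_iterations` must be >= 1", "foscea_config_error")
  }
  n_iterations <- as.integer(n_iterations)
  set.seed(seed)

  trts <- names(cfg$treatments)
  spec <- model_spec(cfg$model$n_cycles, cfg$model$cycle_length_days,
                     cfg$model$variant)
  base_profiles <- lapply(trts, function(trt)
    transition_profile(trt, cfg$treatments[[trt]]$transition$p,
                       cfg$treatments[[trt]]$transition$se))
  names(base_profiles) <- trts
  svc_mean <- unlist(cfg$services)[.services]
  svc_se <- if (cfg$cost_variation_pct > 0)
    vapply(svc_mean, se_from_pct_range, numeric(1),
           pct = cfg$cost_variation_pct) else setNames(rep(0, 5), .services)
  ae_pct <- cfg$ae_prob_variation_pct
  disc <- cfg$discount

  cost <- matrix(NA_real_, n_iterations, length(trts),
                 dimnames = list(NULL, trts))
  effect <- cost
  rates <- numeric(n_iterations)

  for (it in seq_len(n_iterations)) {
    res <- tryCatch({
      rate <- rbeta_scaled(1L, disc$annual_rate, disc$psa_se,
                           disc$psa_low, disc$psa_high)
      svc <- setNames(mapply(function(m, s) rgamma_mean_se(1L, m, s),
                             svc_mean, svc_se), .services)
      ae_drug <- vapply(cfg$ae_drug_cost_per_mg, function(d)
        rgamma_mean_se(1L, d$mean, d$se), numeric(1))
      per_trt <- lapply(trts, function(trt) {
        t <- cfg$treatments[[trt]]
        prof <- sample_transition_profile(base_profiles[[trt]])
        cpm <- rgamma_mean_se(1L, t$drug_cost_per_mg$mean,
                              t$drug_cost_per_mg$se %||% 0)
        ae_ann <- vapply(t$ae_annual, function(p) {
          se <- if (ae_pct > 0 && p > 0) ae_pct * p / 1.96 else 0
          rbeta_mean_se(1L, p, se)
        }, numeric(1))
        t$drug_cost_per_mg <- list(mean = cpm)
        t$ae_annual <- ae_ann
        evaluate_treatment(trt, t, svc, ae_drug, cfg$state_bundles,
                           cfg$ae_management, cfg$ae_accrual, spec, rate,
                           cfg$model$effect, profile = prof)
      })
      list(rate = rate,
           cost = vapply(per_trt, `[[`, numeric(1), "cost"),
           effect = vapply(per_trt, `[[`, numeric(1), "effect"))
    }, foscea_error = function(e) {
      stop_foscea(sprintf("PSA iteration %d failed: %s", it,
                          conditionMessage(e)),
                  "foscea_psa_iteration_error", iteration = it)
    })
    rates[it] <- res$rate
    cost[it, ] <- res$cost
    effect[it, ] <- res$effect
  }

  summary <- data.frame(
    treatment = trts,
    mean_cost = colMeans(cost),
    mean_effect = colMeans(effect),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(cost = cost, effect = effect, treatments = trts,
                 reference = cfg$reference, n_iterations = n_iterations,
                 seed = seed, discount_rates = rates, summary = summary),
            class = "psa_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations, seed %s, reference %s\n",
              x$n_iterations, format(x$seed), x$reference))
  df <- x$summary
  df$mean_cost <- round(df$mean_cost, 2)
  df$mean_effect_pct <- round(100 * df$mean_effect, 2)
  print(df[, c("treatment", "mean_cost", "mean_effect_pct")],
        row.names = FALSE)
  invisible(x)
}

#' PSA iterations as a long data frame
#'
#' @param psa A [run_psa()] result.
#' @return Data frame with columns `iteration`, `treatment`, `cost`,
#'   `effect`.
#' @export
psa_as_df <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  data.frame(
    iteration = rep(seq_len(psa$n_iterations), times = length(psa$treatments)),
    treatment = rep(psa$treatments, each = psa$n_iterations),
    cost = as.vector(psa$cost),
    effect = as.vector(psa$effect),
    stringsAsFactors = FALSE)
}

#' Incremental summary of a PSA (iteration-mean costs and effects)
#'
#' Pairwise incremental analysis of the reference treatment against each
#' comparator, computed on the arithmetic means of the PSA iterations
#' (the probabilistic analogue of the deterministic base case).
#'
#' @param psa A [run_psa()] result.
#' @return Data frame `intervention`, `comparator`, `delta_cost`,
#'   `delta_effect`, `icer`, `dominance`.
#' @export
psa_incremental <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  s <- psa$summary
  ref <- psa$reference
  ri <- which(s$treatment == ref)
  comps <- setdiff(s$treatment, ref)
  do.call(rbind, lapply(comps, function(cmp) {
    ci <- which(s$treatment == cmp)
    r <- icer(ce_result(ref, s$mean_cost[ri], s$mean_effect[ri]),
              ce_result(cmp, s$mean_cost[ci], s$mean_effect[ci]))
    data.frame(intervention = ref, comparator = cmp,
               delta_cost = r$delta_cost, delta_effect = r$delta_effect,
               icer = r$icer, dominance = r$dominance,
               stringsAsFactors = FALSE)
  }))
}

#' Quadrant fractions on the incremental cost-effectiveness plane
#'
#' Classifies each PSA iteration's (delta effect, delta cost) point into the
#' four plane quadrants: NE (more effective, more costly — trade-off), SE
#' (more effective, less costly — cost-saving), NW (less effective, more
#' costly — dominated), SW (less effective, less costly). Boundary points
#' are assigned by a documented tie rule: a zero cost difference counts
#' toward the cost-saving side and a zero effect difference toward the
#' non-effective side (both configurable).
#'
#' @param psa A [run_psa()] result.
#' @param comparator Comparator treatment label.
#' @param intervention Intervention label (default: the PSA reference).
#' @param ties_cost `"saving"` (default) or `"tradeoff"`: side that
#'   receives points with `delta_cost == 0`.
#' @param ties_effect `"noneffective"` (default) or `"effective"`: side that
#'   receives points with `delta_effect == 0`.
#' @return Named numeric vector `c(NE, SE, NW, SW)` of fractions summing
#'   to 1, with iteration counts in attribute `"counts"`.
#' @export
icer_plane_quadrants <- function(psa, comparator,
                                 intervention = psa$reference,
                                 ties_cost = c("saving", "tradeoff"),
                                 ties_effect = c("noneffective", "effective")) {
  stopifnot(inherits(psa, "psa_result"))
  ties_cost <- match.arg(ties_cost)
  ties_effect <- match.arg(ties_effect)
  for (t in c(intervention, comparator)) {
    if (!t %in% psa$treatments) {
      stop_foscea(sprintf("treatment '%s' not in PSA result", t),
                  "foscea_validation_error")
    }
  }
  de <- psa$effect[, intervention] - psa$effect[, comparator]
  dc <- psa$cost[, intervention] - psa$cost[, comparator]
  eff_pos <- if (ties_effect == "effective") de >= 0 else de > 0
  cost_pos <- if (ties_cost == "tradeoff") dc >= 0 else dc > 0
  counts <- c(NE = sum(eff_pos & cost_pos),
              SE = sum(eff_pos & !cost_pos),
              NW = sum(!eff_pos & cost_pos),
              SW = sum(!eff_pos & !cost_pos))
  structure(counts / length(de), counts = counts)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value and each comparator, the fraction of
#' PSA iterations in which the intervention's net monetary benefit exceeds
#' the comparator's, i.e. `wtp * delta_effect - delta_cost > 0`. Effects are
#' on the complete-response proportion scale, so the threshold applies to
#' the same ICER scale reported by [icer()].
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Nonnegative willingness-to-pay values (JOD per unit CR).
#' @param comparators Comparator labels (default: all non-reference
#'   treatments).
#' @param intervention Intervention label (default: the PSA reference).
#' @return Data frame with columns `wtp`, `comparator`, `probability`.
#' @export
#' @examples
#' cfg <- default_config()
#' psa <- run_psa(cfg, n_iterations = 50, seed = 1)
#' head(ceac(psa, c(0, 3000, 9000)))
ceac <- function(psa, wtp_grid,
                 comparators = setdiff(psa$treatments, intervention),
                 intervention = psa$reference) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0L || any(wtp_grid < 0) || anyNA(wtp_grid)) {
    stop_foscea("`wtp_grid` must be nonempty and nonnegative",
                "foscea_validation_error")
  }
  rows <- lapply(comparators, function(cmp) {
    de <- psa$effect[, intervention] - psa$effect[, cmp]
    dc <- psa$cost[, intervention] - psa$cost[, cmp]
    prob <- vapply(wtp_grid, function(w) mean(w * de - dc > 0), numeric(1))
    data.frame(wtp = wtp_grid, comparator = cmp, probability = prob,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
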