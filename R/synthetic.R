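# Synthetic model instances with known structure, the individual-level
# microsimulation oracle used to validate the cohort expectation engine,
# and the degenerate known-answer fixtures shared across the test suite.

#' Specification for a synthetic model instance
#'
#' Describes the statistical shape of a generated configuration: transition
#' profiles drawn from a symmetric Dirichlet (higher `concentration` keeps
#' profiles away from the simplex boundary, so residual non-response
#' probabilities stay positive in PSA with high probability), standard
#' errors as a fraction of the binomial bound, positively skewed drug costs
#' drawn log-uniformly, and uniform annual adverse-event probabilities.
#'
#' @param n_treatments Number of treatments (>= 2 so an incremental analysis
#'   exists; default 4).
#' @param concentration Symmetric Dirichlet concentration for transition
#'   profiles (default 8).
#' @param se_scale Standard errors are `se_scale * sqrt(p (1 - p))`;
#'   must be in \[0, 1) for beta feasibility (default 0.05).
#' @param drug_cost_range Per-mg cost range, JOD (log-uniform; default
#'   0.004-0.8, the span of the study drugs).
#' @param dose_range Daily-dose range, mg/day (default 50-800).
#' @param service_cost_range Unit-cost range for healthcare services
#'   (default 5-150 JOD).
#' @param ae_range Annual adverse-event probability range (default
#'   0.01-0.25).
#' @param seed Mandatory RNG seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_treatments = 4L, concentration = 8,
                           se_scale = 0.05, drug_cost_range = c(0.004, 0.8),
                           dose_range = c(50, 800),
                           service_cost_range = c(5, 150),
                           ae_range = c(0.01, 0.25), seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop_foscea("`seed` is mandatory for a synthetic spec",
                "foscea_validation_error")
  }
  if (n_treatments < 2) {
    stop_foscea("`n_treatments` must be >= 2", "foscea_validation_error")
  }
  assert_scalar_number(concentration, "concentration",
                       lower = .Machine$double.eps)
  assert_scalar_number(se_scale, "se_scale", lower = 0, upper = 1 - 1e-9)
  for (rg in list(drug_cost_range, dose_range, service_cost_range,
                  ae_range)) {
    if (length(rg) != 2L || rg[1] > rg[2] || any(rg < 0)) {
      stop_foscea("ranges must be nondecreasing nonnegative pairs",
                  "foscea_validation_error")
    }
  }
  structure(list(n_treatments = as.integer(n_treatments),
                 concentration = concentration, se_scale = se_scale,
                 drug_cost_range = drug_cost_range, dose_range = dose_range,
                 service_cost_range = service_cost_range,
                 ae_range = ae_range, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a fully valid synthetic model configuration
#'
#' @param spec A [synthetic_spec()].
#' @return A validated `foscea_config`, reproducible from `spec$seed`.
#' @export
#' @examples
#' cfg <- generate_model(synthetic_spec(seed = 42))
#' run_deterministic(cfg)$results
generate_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  runif_rng <- function(n, rg) runif(n, rg[1], rg[2])
  log_runif <- function(n, rg) exp(runif(n, log(rg[1]), log(rg[2])))
  trts <- sprintf("T%02d", seq_len(spec$n_treatments))
  treatments <- lapply(trts, function(trt) {
    g <- rgamma(4L, shape = spec$concentration)
    p <- g / sum(g)
    se <- spec$se_scale * sqrt(p * (1 - p))
    maint <- round(runif_rng(1L, spec$dose_range))
    tit <- round(maint * runif(1L, 0.4, 1))
    cpm <- log_runif(1L, spec$drug_cost_range)
    list(
      transition = list(p = setNames(p, health_states()),
                        se = setNames(se, health_states())),
      ae_annual = setNames(runif_rng(5L, spec$ae_range), .adverse_events),
      dose = list(titration = max(tit, 1), maintenance = maint),
      drug_cost_per_mg = list(mean = cpm,
                              se = se_from_pct_range(cpm, 0.25)))
  })
  names(treatments) <- trts
  services <- as.list(setNames(round(runif_rng(5L, spec$service_cost_range), 2),
                               .services))
  cfg <- default_config()
  cfg <- unclass(cfg)
  cfg$treatments <- treatments
  cfg$reference <- trts[1L]
  cfg$services <- services
  cfg$psa$seed <- spec$seed
  validate_config(cfg)
}

#' Individual-level microsimulation oracle for the cohort engine
#'
#' Simulates `n_agents` independent patients through the configured
#' structural variant: each agent draws a first-cycle multinomial outcome,
#' then re-draws each later cycle unless in an absorbing state. Returns the
#' empirical analogue of [run_cohort()]'s trace, with binomial standard
#' errors, for validating the cohort expectation engine.
#'
#' @param profile A [transition_profile()].
#' @param spec A [model_spec()].
#' @param n_agents Number of simulated patients (>= 1).
#' @param seed RNG seed.
#' @return List of class `microsim_trace`: `occupancy` and `occupancy_se`
#'   (cycle x state matrices), `ever_sf` and `ever_sf_se` (per cycle),
#'   `n_agents`, `treatment`, `spec`. Empirical occupancy rows sum to 1
#'   exactly (they are counts over `n_agents`).
#' @export
#' @examples
#' brv <- transition_profile("BRV", c(0.065, 0.355, 0.370, 0.210))
#' ms <- microsim_oracle(brv, model_spec(), n_agents = 1e4, seed = 7)
#' ms$ever_sf[8]
microsim_oracle <- function(profile, spec, n_agents, seed) {
  stopifnot(inherits(profile, "transition_profile"),
            inherits(spec, "model_spec"))
  if (!is.numeric(n_agents) || n_agents < 1) {
    stop_foscea("`n_agents` must be >= 1", "foscea_validation_error")
  }
  n_agents <- as.integer(n_agents)
  set.seed(seed)
  n <- spec$n_cycles
  p <- profile$p
  redraw <- switch(spec$variant,
    absorbing_sf_disc   = c(2L, 3L),
    absorbing_disc_only = c(1L, 2L, 3L),
    redraw_all          = 1:4)
  occ <- matrix(NA_real_, n, 4L, dimnames = list(NULL, health_states()))
  ever_sf <- numeric(n)
  states <- sample.int(4L, n_agents, replace = TRUE, prob = p)
  ever <- states == 1L
  occ[1L, ] <- tabulate(states, 4L) / n_agents
  ever_sf[1L] <- mean(ever)
  if (n > 1L) {
    for (t in 2:n) {
      idx <- which(states %in% redraw)
      if (length(idx)) {
        states[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = p)
      }
      ever <- ever | states == 1L
      occ[t, ] <- tabulate(states, 4L) / n_agents
      ever_sf[t] <- mean(ever)
    }
  }
  structure(list(
    occupancy = occ,
    occupancy_se = sqrt(occ * (1 - occ) / n_agents),
    ever_sf = ever_sf,
    ever_sf_se = sqrt(ever_sf * (1 - ever_sf) / n_agents),
    n_agents = n_agents, treatment = profile$treatment, spec = spec),
    class = "microsim_trace")
}

#' Degenerate known-answer fixtures used across the modules
#'
#' @description
#' A fixed set of constructions with analytically known behaviour:
#' \describe{
#'   \item{`table3`}{the published deterministic cost/effect pairs for the
#'     four study drugs, as [ce_result()]s — a worked-example fixture for
#'     the incremental analysis (BRV 3925/57.71\%, ESL 4139/28.70\%,
#'     LCM 3078/26.83\%, PER 5541/31.27\%).}
#'   \item{`certain_response` / `certain_discontinuation`}{degenerate
#'     transition profiles (1,0,0,0) and (0,0,0,1).}
#'   \item{`zero_cost_config`}{the packaged config with every unit cost 0.}
#'   \item{`zero_se_config`}{the packaged config with every uncertainty
#'     parameter 0, so a PSA on it is exactly the deterministic model.}
#'   \item{`symmetric_cloud`}{a deterministic `psa_result` whose incremental
#'     cloud is a centred circle: exactly one quarter of the points in each
#'     plane quadrant, none on a boundary.}
#' }
#' @return Named list of fixtures.
#' @export
known_answer_cases <- function() {
  cfg0 <- default_config()

  zero_cost <- unclass(cfg0)
  zero_cost$services <- as.list(setNames(rep(0, 5), .services))
  for (trt in names(zero_cost$treatments)) {
    zero_cost$treatments[[trt]]$drug_cost_per_mg$mean <- 0
  }
  for (d in names(zero_cost$ae_drug_cost_per_mg)) {
    zero_cost$ae_drug_cost_per_mg[[d]]$mean <- 0
  }
  zero_cost <- validate_config(zero_cost)

  zero_se <- unclass(cfg0)
  for (trt in names(zero_se$treatments)) {
    zero_se$treatments[[trt]]$transition$se[] <- 0
    zero_se$treatments[[trt]]$drug_cost_per_mg$se <- 0
  }
  for (d in names(zero_se$ae_drug_cost_per_mg)) {
    zero_se$ae_drug_cost_per_mg[[d]]$se <- 0
  }
  zero_se$cost_variation_pct <- 0
  zero_se$ae_prob_variation_pct <- 0
  zero_se$discount$psa_se <- 0
  zero_se <- validate_config(zero_se)

  n <- 400L
  ang <- (seq_len(n) - 0.5) / n * 2 * pi
  de <- 0.1 * cos(ang)
  dc <- 500 * sin(ang)
  cloud <- structure(list(
    cost = cbind(A = 2000 + dc, B = rep(2000, n)),
    effect = cbind(A = 0.5 + de, B = rep(0.5, n)),
    treatments = c("A", "B"), reference = "A", n_iterations = n,
    seed = NA_integer_, discount_rates = rep(0.035, n),
    summary = data.frame(treatment = c("A", "B"),
                         mean_cost = c(2000, 2000),
                         mean_effect = c(0.5, 0.5),
                         stringsAsFactors = FALSE)),
    class = "psa_result")

  list(
    table3 = list(
      BRV = ce_result("BRV", 3925, 0.5771),
      ESL = ce_result("ESL", 4139, 0.2870),
      LCM = ce_result("LCM", 3078, 0.2683),
      PER = ce_result("PER", 5541, 0.3127)),
    certain_response = transition_profile("certain_response", c(1, 0, 0, 0)),
    certain_discontinuation =
      transition_profile("certain_discontinuation", c(0, 0, 0, 1)),
    zero_cost_config = zero_cost,
    zero_se_config = zero_se,
    symmetric_cloud = cloud)
}
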