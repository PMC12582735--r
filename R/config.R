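# Model configuration: construction, YAML round-trip, schema validation.
# A config is a plain nested list of class "foscea_config" so it survives
# YAML serialization unchanged.

.services <- c("inpatient_night", "emergency_visit", "neurologist_visit",
               "gp_visit", "eeg")
.adverse_events <- c("ataxia", "dizziness", "fatigue", "nausea", "somnolence")

#' The packaged Jordanian focal-onset seizure model configuration
#'
#' All transition probabilities (per 3-month cycle, with standard errors),
#' annual adverse-event probabilities, per-mg drug acquisition costs, and
#' healthcare service unit costs are the published model inputs for the
#' four adjunctive antiseizure medications (brivaracetam BRV, eslicarbazepine
#' ESL, lacosamide LCM, perampanel PER) in Jordan, in JOD.
#'
#' Dose schedules are NOT published with the model inputs (they live in an
#' inaccessible supplement); the defaults here are synthetic label-range
#' median doses (titration then maintenance, mg/day) and should be replaced
#' with study-specific values for any substantive reanalysis: BRV 50/100,
#' ESL 400/800, LCM 100/400, PER 2/8.
#'
#' @return A validated object of class `foscea_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$treatments$BRV$transition$p
default_config <- function() {
  tp <- function(p, se) list(p = setNames(p, health_states()),
                             se = setNames(se, health_states()))
  ae <- function(x) setNames(x, .adverse_events)
  cfg <- list(
    treatments = list(
      BRV = list(
        transition = tp(c(0.065, 0.355, 0.370, 0.210),
                        c(0.003, 0.018, 0.011, 0.011)),
        ae_annual = ae(c(0.030, 0.130, 0.110, 0.050, 0.140)),
        dose = list(titration = 50, maintenance = 100),   # synthetic default
        drug_cost_per_mg = list(mean = 0.042, se = 0.016)),
      ESL = list(
        transition = tp(c(0.032, 0.330, 0.469, 0.169),
                        c(0.002, 0.017, 0.009, 0.009)),
        ae_annual = ae(c(0.060, 0.230, 0.060, 0.120, 0.120)),
        dose = list(titration = 400, maintenance = 800),  # synthetic default
        drug_cost_per_mg = list(mean = 0.004, se = 0.004)),
      LCM = list(
        transition = tp(c(0.030, 0.308, 0.448, 0.214),
                        c(0.002, 0.016, 0.011, 0.011)),
        ae_annual = ae(c(0.080, 0.240, 0.060, 0.110, 0.100)),
        dose = list(titration = 100, maintenance = 400),  # synthetic default
        drug_cost_per_mg = list(mean = 0.013, se = 0.003)),
      PER = list(
        transition = tp(c(0.035, 0.296, 0.493, 0.176),
                        c(0.002, 0.015, 0.009, 0.009)),
        ae_annual = ae(c(0.040, 0.230, 0.070, 0.010, 0.140)),
        dose = list(titration = 2, maintenance = 8),      # synthetic default
        drug_cost_per_mg = list(mean = 0.804, se = 0.267))),
    reference = "BRV",
    services = list(inpatient_night = 100, emergency_visit = 30,
                    neurologist_visit = 14, gp_visit = 8, eeg = 100),
    ae_drug_cost_per_mg = list(
      acetazolamide = list(mean = 0.001, se = 0.001),
      cinnarizine   = list(mean = 0.001, se = 0.001)),
    ae_management = default_ae_management(),
    state_bundles = default_state_bundles(),
    model = list(n_cycles = 8L, cycle_length_days = 90,
                 variant = "absorbing_sf_disc", effect = "ever_sf"),
    discount = list(annual_rate = 0.035, psa_low = 0, psa_high = 0.05,
                    psa_se = 0.00625),
    cost_variation_pct = 0.25,
    ae_prob_variation_pct = 0.25,
    ae_accrual = "all_cycles",
    psa = list(n_iterations = 2000L, seed = 20250101L),
    wtp = 9000,
    wtp_grid = seq(0, 18000, by = 500))
  validate_config(cfg)
}

# Coerce YAML-parsed nested lists back into the canonical in-memory shapes
# (named numeric vectors where the constructors expect them).
normalize_config <- function(cfg) {
  num <- function(x) {
    if (is.list(x)) setNames(vapply(x, as.numeric, numeric(1)), names(x))
    else x
  }
  for (trt in names(cfg$treatments)) {
    cfg$treatments[[trt]]$transition$p <- num(cfg$treatments[[trt]]$transition$p)
    cfg$treatments[[trt]]$transition$se <- num(cfg$treatments[[trt]]$transition$se)
    cfg$treatments[[trt]]$ae_annual <- num(cfg$treatments[[trt]]$ae_annual)
  }
  cfg$state_bundles <- lapply(cfg$state_bundles, num)
  if (!is.null(cfg$wtp_grid)) cfg$wtp_grid <- as.numeric(unlist(cfg$wtp_grid))
  cfg$model$n_cycles <- as.integer(cfg$model$n_cycles)
  cfg$psa$n_iterations <- as.integer(cfg$psa$n_iterations)
  if (!is.null(cfg$psa$seed)) cfg$psa$seed <- as.integer(cfg$psa$seed)
  cfg
}

#' Validate a model configuration
#'
#' Checks the full schema: every treatment carries a simplex-valid transition
#' profile with feasible standard errors, annual adverse-event probabilities
#' for the five tracked events, a dose schedule, and a nonnegative per-mg
#' cost; unit costs cover every service referenced by the state bundles;
#' the reference treatment resolves; model, discount, PSA and WTP settings
#' are in range. Errors name the offending field.
#'
#' @param cfg A configuration list.
#' @return The (normalized) config, invisibly classed `foscea_config`.
#' @export
validate_config <- function(cfg) {
  cfg <- normalize_config(cfg)
  req <- function(cond, field, what = "is missing or invalid") {
    if (!isTRUE(cond)) {
      stop_foscea(sprintf("config field `%s` %s", field, what),
                  "foscea_config_error")
    }
  }
  req(is.list(cfg$treatments) && length(cfg$treatments) >= 1, "treatments",
      "must list at least one treatment")
  for (trt in names(cfg$treatments)) {
    t <- cfg$treatments[[trt]]
    pfx <- paste0("treatments$", trt)
    req(!is.null(t$transition$p), paste0(pfx, "$transition$p"))
    # constructor enforces simplex + SE feasibility, naming the treatment
    transition_profile(trt, t$transition$p,
                       if (is.null(t$transition$se)) rep(0, 4) else
                         t$transition$se)
    req(!is.null(t$dose), paste0(pfx, "$dose"))
    req(is.numeric(t$dose$titration) && t$dose$titration > 0,
        paste0(pfx, "$dose$titration"), "must be a positive daily dose")
    req(is.numeric(t$dose$maintenance) && t$dose$maintenance > 0,
        paste0(pfx, "$dose$maintenance"), "must be a positive daily dose")
    req(!is.null(t$drug_cost_per_mg$mean) && t$drug_cost_per_mg$mean >= 0,
        paste0(pfx, "$drug_cost_per_mg$mean"), "must be >= 0")
    req(all(.adverse_events %in% names(t$ae_annual)),
        paste0(pfx, "$ae_annual"), "must cover all five adverse events")
    req(all(t$ae_annual >= 0 & t$ae_annual <= 1),
        paste0(pfx, "$ae_annual"), "probabilities must lie in [0, 1]")
  }
  req(is.character(cfg$reference) && cfg$reference %in% names(cfg$treatments),
      "reference", "must name one of the configured treatments")
  req(all(.services %in% names(cfg$services)), "services",
      "must price all five healthcare services")
  req(all(unlist(cfg$services) >= 0), "services", "costs must be >= 0")
  req(cfg$model$variant %in% structural_variants(), "model$variant",
      "must be a known structural variant")
  req(cfg$model$n_cycles >= 1, "model$n_cycles", "must be >= 1")
  req(cfg$model$effect %in% c("ever_sf", "mean_sf_occupancy", "terminal_sf"),
      "model$effect", "must be a known effect definition")
  req(is.numeric(cfg$discount$annual_rate) && cfg$discount$annual_rate >= 0,
      "discount$annual_rate", "must be >= 0")
  req(cfg$psa$n_iterations >= 1, "psa$n_iterations", "must be >= 1")
  req(is.numeric(cfg$wtp) && cfg$wtp >= 0, "wtp", "must be >= 0")
  req(cfg$ae_accrual %in% c("all_cycles", "first_year"), "ae_accrual",
      "must be 'all_cycles' or 'first_year'")
  class(cfg) <- "foscea_config"
  invisible(cfg)
}

#' Load a model configuration from YAML
#'
#' @param path Path to a YAML config (see [write_config()] and the packaged
#'   `system.file("extdata", "jordan_fos.yaml", package = "foscea")`).
#' @return A validated `foscea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_foscea(sprintf("config file not found: %s", path),
                "foscea_config_error")
  }
  validate_config(yaml::read_yaml(path))
}

#' Write a model configuration to YAML
#'
#' @param cfg A `foscea_config` (or compatible list; validated first).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  # named atomic vectors must become YAML maps, not sequences, so the
  # names survive the round trip
  to_yaml_form <- function(x) {
    if (is.list(x)) {
      lapply(x, to_yaml_form)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(to_yaml_form(unclass(cfg)), path, precision = 15)
  invisible(path)
}

# treatment-level pieces -> (cost, effect); the single deterministic
# evaluation path shared by the base case and every PSA iteration.
evaluate_treatment <- function(trt, treatment, services, ae_drug_costs,
                               bundles, ae_management, ae_accrual,
                               spec, discount_rate, effect_def,
                               profile = NULL) {
  if (is.null(profile)) {
    profile <- transition_profile(trt, treatment$transition$p,
                                  treatment$transition$se)
  }
  trace <- run_cohort(spec, profile)
  cm <- build_cost_model(
    dose = treatment$dose,
    drug_cost_per_mg = treatment$drug_cost_per_mg$mean,
    service_costs = services,
    bundles = bundles,
    ae_annual = treatment$ae_annual,
    ae_management = ae_management,
    ae_drug_costs = ae_drug_costs,
    ae_accrual = ae_accrual)
  list(cost = total_expected_cost(trace, cm, discount_rate),
       effect = effect_measure(trace, effect_def),
       trace = trace)
}

#' Run the deterministic base-case analysis
#'
#' Evaluates every configured treatment at the mean parameter values:
#' cohort trace, total discounted cost, complete-response effect, and the
#' pairwise incremental analysis of the reference treatment against each
#' comparator.
#'
#' @param cfg A `foscea_config` (e.g. [default_config()]).
#' @return An object of class `cea_results`: list with `results` (data frame
#'   `treatment`, `cost`, `effect`), `incremental` (data frame `intervention`,
#'   `comparator`, `delta_cost`, `delta_effect`, `icer`, `dominance`),
#'   `traces` (named list of cohort traces), and `config`.
#' @export
#' @examples
#' res <- run_deterministic(default_config())
#' res$results
#' res$incremental
run_deterministic <- function(cfg) {
  cfg <- validate_config(cfg)
  spec <- model_spec(cfg$model$n_cycles, cfg$model$cycle_length_days,
                     cfg$model$variant)
  services <- unlist(cfg$services)[.services]
  ae_drug_costs <- vapply(cfg$ae_drug_cost_per_mg, `[[`, numeric(1), "mean")
  out <- lapply(names(cfg$treatments), function(trt) {
    evaluate_treatment(trt, cfg$treatments[[trt]], services, ae_drug_costs,
                       cfg$state_bundles, cfg$ae_management, cfg$ae_accrual,
                       spec, cfg$discount$annual_rate, cfg$model$effect)
  })
  names(out) <- names(cfg$treatments)
  results <- data.frame(
    treatment = names(out),
    cost = vapply(out, `[[`, numeric(1), "cost"),
    effect = vapply(out, `[[`, numeric(1), "effect"),
    row.names = NULL, stringsAsFactors = FALSE)
  ref <- cfg$reference
  comps <- setdiff(names(out), ref)
  inc <- do.call(rbind, lapply(comps, function(cmp) {
    r <- icer(ce_result(ref, out[[ref]]$cost, out[[ref]]$effect),
              ce_result(cmp, out[[cmp]]$cost, out[[cmp]]$effect))
    data.frame(intervention = ref, comparator = cmp,
               delta_cost = r$delta_cost, delta_effect = r$delta_effect,
               icer = r$icer, dominance = r$dominance,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, incremental = inc,
                 traces = lapply(out, `[[`, "trace"), config = cfg),
            class = "cea_results")
}

#' @export
print.cea_results <- function(x, ...) {
  cat("<cea_results> deterministic base case\n")
  df <- x$results
  df$cost <- round(df$cost, 2)
  df$effect_pct <- round(100 * df$effect, 2)
  print(df[, c("treatment", "cost", "effect_pct")], row.names = FALSE)
  cat("\nPairwise vs", x$config$reference, "(ICER in JOD per 1% CR):\n")
  inc <- x$incremental
  inc$icer <- round(inc$icer)
  inc$delta_cost <- round(inc$delta_cost, 2)
  inc$delta_effect_pct <- round(100 * inc$delta_effect, 2)
  print(inc[, c("comparator", "delta_cost", "delta_effect_pct", "icer",
                "dominance")], row.names = FALSE)
  invisible(x)
}
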