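# Cost accrual over the cohort trace: drug acquisition, per-state healthcare
# service bundles, and adverse-event management. All amounts in JOD.

#' Drug acquisition cost for one cycle
#'
#' Drug cost is computed per mg over the 90 days of a cycle. Cycle 1 uses the
#' titration daily dose; later cycles use the maintenance daily dose. The
#' model charges the full scheduled dose regardless of later dose reductions
#' (the wastage assumption): no credit is ever applied for a reduced dose.
#'
#' @param dose List with `titration` and `maintenance` daily doses (mg/day).
#' @param cost_per_mg Unit drug cost (JOD/mg).
#' @param cycle_index Cycle number, 1-based.
#' @param cycle_length_days Days per cycle (default 90).
#' @return Cost in JOD for the cycle.
#' @export
#' @examples
#' drug_cost_per_cycle(list(titration = 100, maintenance = 400), 0.013, 3)
drug_cost_per_cycle <- function(dose, cost_per_mg, cycle_index,
                                cycle_length_days = 90) {
  assert_scalar_number(cost_per_mg, "cost_per_mg", lower = 0)
  if (!is.numeric(cycle_index) || cycle_index < 1) {
    stop_foscea("`cycle_index` must be >= 1", "foscea_validation_error")
  }
  daily <- if (cycle_index == 1) dose$titration else dose$maintenance
  assert_scalar_number(daily, "daily dose", lower = .Machine$double.eps)
  daily * cycle_length_days * cost_per_mg
}

#' Convert an annual event probability to a per-cycle probability
#'
#' Assumes a constant hazard within the year, so the per-cycle probability
#' compounds back to the annual one over `cycles_per_year` cycles:
#' `1 - (1 - annual_p)^(1 / cycles_per_year)`.
#'
#' @param annual_p Annual probability in \[0, 1\] (vectorized).
#' @param cycles_per_year Cycles per year (default 4, 3-month cycles).
#' @return Per-cycle probability, in \[0, `annual_p`\].
#' @export
#' @examples
#' ae_cycle_probability(0.13)  # ~0.0342
ae_cycle_probability <- function(annual_p, cycles_per_year = 4) {
  if (!is.numeric(annual_p) || anyNA(annual_p) ||
      any(annual_p < 0) || any(annual_p > 1)) {
    stop_foscea("`annual_p` must be a probability in [0, 1]",
                "foscea_validation_error")
  }
  1 - (1 - annual_p)^(1 / cycles_per_year)
}

#' Default per-state healthcare service bundles
#'
#' Each trimester: seizure-free and partial responders have one neurologist
#' outpatient visit and an EEG; non-responders additionally have an emergency
#' department visit and one inpatient night; discontinued patients have only
#' the outpatient visit. Counts are configurable.
#'
#' @return Named list state -> named numeric vector of service counts.
#' @export
default_state_bundles <- function() {
  list(
    seizure_free     = c(neurologist_visit = 1, eeg = 1),
    partial_response = c(neurologist_visit = 1, eeg = 1),
    non_response     = c(emergency_visit = 1, inpatient_night = 1,
                         neurologist_visit = 1, eeg = 1),
    discontinued     = c(neurologist_visit = 1))
}

#' Healthcare service cost accrued by one state in one cycle
#'
#' @param state One of [health_states()].
#' @param bundles Named list state -> named service-count vector, e.g.
#'   [default_state_bundles()].
#' @param service_costs Named numeric vector of unit costs (JOD) covering
#'   every service named in the bundle.
#' @return Cost in JOD.
#' @export
#' @examples
#' state_cost_per_cycle("non_response", default_state_bundles(),
#'   c(inpatient_night = 100, emergency_visit = 30,
#'     neurologist_visit = 14, gp_visit = 8, eeg = 100))
state_cost_per_cycle <- function(state, bundles, service_costs) {
  if (!state %in% names(bundles)) {
    stop_foscea(sprintf("no service bundle for state '%s'", state),
                "foscea_validation_error")
  }
  bundle <- bundles[[state]]
  if (length(bundle) == 0L) return(0)
  missing <- setdiff(names(bundle), names(service_costs))
  if (length(missing)) {
    stop_foscea(sprintf("unit cost missing for service(s): %s",
                        paste(missing, collapse = ", ")),
                "foscea_validation_error")
  }
  if (any(service_costs < 0)) {
    stop_foscea("service unit costs must be nonnegative",
                "foscea_validation_error")
  }
  sum(bundle * service_costs[names(bundle)])
}

#' Default adverse-event management rules
#'
#' Ataxia is managed with acetazolamide; dizziness and nausea with
#' cinnarizine; fatigue and somnolence receive no drug. Every adverse event
#' triggers one GP visit. Management regimens (daily dose and treated days)
#' are not reported with the unit costs, so the defaults treat for the full
#' 90-day cycle at common label doses — conservative, in the spirit of the
#' wastage assumption — and are plain config fields.
#'
#' @return Named list AE -> list(drug, daily_dose_mg, days, gp_visits).
#' @export
default_ae_management <- function() {
  list(
    ataxia     = list(drug = "acetazolamide", daily_dose_mg = 250, days = 90,
                      gp_visits = 1),
    dizziness  = list(drug = "cinnarizine", daily_dose_mg = 50, days = 90,
                      gp_visits = 1),
    fatigue    = list(drug = NA_character_, daily_dose_mg = 0, days = 0,
                      gp_visits = 1),
    nausea     = list(drug = "cinnarizine", daily_dose_mg = 50, days = 90,
                      gp_visits = 1),
    somnolence = list(drug = NA_character_, daily_dose_mg = 0, days = 0,
                      gp_visits = 1))
}

#' Expected adverse-event management cost per cycle for one treatment
#'
#' Sums, over the five adverse events, the per-cycle event probability times
#' the management cost (drug regimen cost plus GP visits). Annual
#' probabilities are converted with [ae_cycle_probability()].
#'
#' @param ae_annual Named numeric vector of annual AE probabilities
#'   (ataxia, dizziness, fatigue, nausea, somnolence).
#' @param management AE management rules, see [default_ae_management()].
#' @param ae_drug_costs Named numeric vector of management-drug unit costs
#'   (JOD/mg), e.g. `c(acetazolamide = 0.001, cinnarizine = 0.001)`.
#' @param gp_cost GP visit unit cost (JOD).
#' @return Expected cost in JOD per cycle per at-risk patient.
#' @export
ae_expected_cost_per_cycle <- function(ae_annual, management, ae_drug_costs,
                                       gp_cost) {
  assert_scalar_number(gp_cost, "gp_cost", lower = 0)
  missing <- setdiff(names(ae_annual), names(management))
  if (length(missing)) {
    stop_foscea(sprintf("no management rule for adverse event(s): %s",
                        paste(missing, collapse = ", ")),
                "foscea_validation_error")
  }
  total <- 0
  for (ae in names(ae_annual)) {
    rule <- management[[ae]]
    p_cycle <- ae_cycle_probability(ae_annual[[ae]])
    drug_cost <- 0
    if (!is.na(rule$drug) && nzchar(rule$drug)) {
      if (!rule$drug %in% names(ae_drug_costs)) {
        stop_foscea(sprintf("no unit cost for management drug '%s'",
                            rule$drug), "foscea_validation_error")
      }
      drug_cost <- rule$daily_dose_mg * rule$days * ae_drug_costs[[rule$drug]]
    }
    total <- total + p_cycle * (drug_cost + rule$gp_visits * gp_cost)
  }
  total
}

#' Bundle one treatment's costing inputs
#'
#' @param dose List with `titration` and `maintenance` daily doses (mg/day).
#' @param drug_cost_per_mg Acquisition cost, JOD/mg.
#' @param service_costs Named numeric vector of healthcare unit costs.
#' @param bundles Per-state service bundles ([default_state_bundles()]).
#' @param ae_annual Named annual AE probabilities for this treatment.
#' @param ae_management AE rules ([default_ae_management()]).
#' @param ae_drug_costs Named JOD/mg costs for the management drugs.
#' @param ae_accrual `"all_cycles"` (default) accrues expected AE costs every
#'   cycle for the non-discontinued cohort fraction; `"first_year"` restricts
#'   accrual to the first four cycles.
#' @return An object of class `cost_model`.
#' @export
build_cost_model <- function(dose, drug_cost_per_mg, service_costs,
                             bundles = default_state_bundles(),
                             ae_annual = NULL,
                             ae_management = default_ae_management(),
                             ae_drug_costs = c(acetazolamide = 0.001,
                                               cinnarizine = 0.001),
                             ae_accrual = c("all_cycles", "first_year")) {
  ae_accrual <- match.arg(ae_accrual)
  assert_scalar_number(drug_cost_per_mg, "drug_cost_per_mg", lower = 0)
  for (s in health_states()) {
    if (!s %in% names(bundles)) {
      stop_foscea(sprintf("service bundle missing for state '%s'", s),
                  "foscea_validation_error")
    }
  }
  structure(list(dose = dose, drug_cost_per_mg = drug_cost_per_mg,
                 service_costs = service_costs, bundles = bundles,
                 ae_annual = ae_annual, ae_management = ae_management,
                 ae_drug_costs = ae_drug_costs, ae_accrual = ae_accrual),
            class = "cost_model")
}

#' Per-cycle cost breakdown over a cohort trace
#'
#' For each cycle: the non-discontinued (on-treatment) fraction accrues the
#' drug cost and the expected adverse-event cost; every state accrues its
#' service bundle. Discontinued patients are off drug and at no drug-related
#' adverse-event risk, but keep their follow-up outpatient visit.
#'
#' @param trace A [run_cohort()] trace.
#' @param cm A [build_cost_model()].
#' @param discount_rate Annual discount rate applied to year-2 cycles
#'   (see [discount_factor()]).
#' @return Data frame with columns `cycle`, `component` (`drug` | `services`
#'   | `ae`), `state` (`NA` for non-state components), `undiscounted`,
#'   `discounted`.
#' @export
cost_breakdown <- function(trace, cm, discount_rate = 0.035) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(cm, "cost_model"))
  n <- nrow(trace$occupancy)
  days <- trace$spec$cycle_length_days
  state_costs <- vapply(
    health_states(),
    function(s) state_cost_per_cycle(s, cm$bundles, cm$service_costs),
    numeric(1))
  ae_cost <- if (is.null(cm$ae_annual)) 0 else
    ae_expected_cost_per_cycle(cm$ae_annual, cm$ae_management,
                               cm$ae_drug_costs,
                               cm$service_costs[["gp_visit"]])
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    df <- discount_factor(t, discount_rate)
    occ <- trace$occupancy[t, ]
    on_treatment <- 1 - occ[["discontinued"]]
    drug <- on_treatment *
      drug_cost_per_cycle(cm$dose, cm$drug_cost_per_mg, t, days)
    ae_on <- cm$ae_accrual == "all_cycles" || t <= 4L
    ae <- if (ae_on) on_treatment * ae_cost else 0
    svc <- occ * state_costs
    rows[[t]] <- data.frame(
      cycle = t,
      component = c("drug", rep("services", 4L), "ae"),
      state = c(NA_character_, health_states(), NA_character_),
      undiscounted = c(drug, unname(svc), ae),
      discounted = df * c(drug, unname(svc), ae),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Total expected discounted cost over the horizon
#'
#' @inheritParams cost_breakdown
#' @return Total discounted cost in JOD.
#' @export
#' @examples
#' brv <- transition_profile("BRV", c(0.065, 0.355, 0.370, 0.210))
#' tr <- run_cohort(model_spec(), brv)
#' cm <- build_cost_model(
#'   dose = list(titration = 50, maintenance = 100),
#'   drug_cost_per_mg = 0.042,
#'   service_costs = c(inpatient_night = 100, emergency_visit = 30,
#'                     neurologist_visit = 14, gp_visit = 8, eeg = 100),
#'   ae_annual = c(ataxia = 0.03, dizziness = 0.13, fatigue = 0.11,
#'                 nausea = 0.05, somnolence = 0.14))
#' total_expected_cost(tr, cm)
total_expected_cost <- function(trace, cm, discount_rate = 0.035) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(cm, "cost_model"))
  n <- nrow(trace$occupancy)
  days <- trace$spec$cycle_length_days
  state_costs <- vapply(
    health_states(),
    function(s) state_cost_per_cycle(s, cm$bundles, cm$service_costs),
    numeric(1))
  ae_cost <- if (is.null(cm$ae_annual)) 0 else
    ae_expected_cost_per_cycle(cm$ae_annual, cm$ae_management,
                               cm$ae_drug_costs,
                               cm$service_costs[["gp_visit"]])
  cycles <- seq_len(n)
  df <- vapply(cycles, discount_factor, numeric(1), rate = discount_rate)
  on_treatment <- 1 - trace$occupancy[, "discontinued"]
  drug <- vapply(cycles, function(t)
    drug_cost_per_cycle(cm$dose, cm$drug_cost_per_mg, t, days), numeric(1))
  ae_on <- if (cm$ae_accrual == "all_cycles") rep(TRUE, n) else cycles <= 4L
  svc <- drop(trace$occupancy %*% state_costs)
  sum(df * (on_treatment * drug + svc + ifelse(ae_on, on_treatment * ae_cost, 0)))
}
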