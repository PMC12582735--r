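# Cost accrual: drug schedules, state bundles, adverse events, totals.

test_that("drug cost per cycle follows the dose schedule and unit cost", {
  # 0.013 JOD/mg * 400 mg/day * 90 days on a maintenance cycle
  lcm <- list(titration = 100, maintenance = 400)
  expect_equal(drug_cost_per_cycle(lcm, 0.013, 3), 468)
  # cycle 1 charges the titration dose
  expect_equal(drug_cost_per_cycle(lcm, 0.013, 1), 0.013 * 100 * 90)
  # zero unit cost zeroes every cycle
  expect_equal(drug_cost_per_cycle(lcm, 0, 5), 0)
  # linearity: half the daily dose costs half
  ds <- list(titration = 50, maintenance = 100)
  expect_equal(drug_cost_per_cycle(ds, 0.042, 1),
               drug_cost_per_cycle(ds, 0.042, 2) / 2)
  expect_error(drug_cost_per_cycle(list(titration = -1, maintenance = 10),
                                   0.042, 1),
               class = "foscea_validation_error")
  expect_error(drug_cost_per_cycle(ds, -0.1, 1),
               class = "foscea_validation_error")
})

test_that("annual adverse-event probabilities convert to per-cycle hazard shares", {
  expect_equal(ae_cycle_probability(0), 0)
  expect_equal(ae_cycle_probability(1), 1)
  expect_equal(ae_cycle_probability(0.13), 0.0342164, tolerance = 1e-6)
  # per-cycle probability compounds back to the annual one over 4 cycles
  set.seed(5)
  for (p in runif(10)) {
    pc <- ae_cycle_probability(p)
    expect_equal(1 - (1 - pc)^4, p, tolerance = 1e-12)
    expect_lte(pc, p)
  }
  expect_error(ae_cycle_probability(1.2), class = "foscea_validation_error")
})

test_that("state service bundles price out to the published per-cycle amounts", {
  b <- default_state_bundles()
  sc <- published_service_costs
  expect_equal(state_cost_per_cycle("seizure_free", b, sc), 114)
  expect_equal(state_cost_per_cycle("partial_response", b, sc), 114)
  expect_equal(state_cost_per_cycle("non_response", b, sc), 244)
  expect_equal(state_cost_per_cycle("discontinued", b, sc), 14)
  zero <- sc * 0
  for (s in health_states()) {
    expect_equal(state_cost_per_cycle(s, b, zero), 0)
  }
  expect_error(state_cost_per_cycle("remission", b, sc),
               class = "foscea_validation_error")
})

test_that("expected adverse-event cost sums probability-weighted management", {
  mgmt <- default_ae_management()
  dr <- c(acetazolamide = 0.001, cinnarizine = 0.001)
  ae0 <- c(ataxia = 0, dizziness = 0, fatigue = 0, nausea = 0, somnolence = 0)
  expect_equal(ae_expected_cost_per_cycle(ae0, mgmt, dr, 8), 0)

  # single GP-only adverse event: p_cycle * gp cost
  gp_only <- list(somnolence = list(drug = NA_character_, daily_dose_mg = 0,
                                    days = 0, gp_visits = 1))
  expect_equal(
    ae_expected_cost_per_cycle(c(somnolence = 0.2), gp_only, dr, 8),
    (1 - 0.8^0.25) * 8)

  # direct-summation oracle over the BRV annual probabilities, GP-only rules
  brv_ae <- c(ataxia = 0.03, dizziness = 0.13, fatigue = 0.11,
              nausea = 0.05, somnolence = 0.14)
  gp_rules <- lapply(brv_ae, function(...) list(drug = NA_character_,
    daily_dose_mg = 0, days = 0, gp_visits = 1))
  oracle <- sum((1 - (1 - brv_ae)^0.25) * 8)
  expect_equal(ae_expected_cost_per_cycle(brv_ae, gp_rules, dr, 8), oracle)

  # managed events add the regimen drug cost
  with_drug <- ae_expected_cost_per_cycle(brv_ae, default_ae_management(),
                                          dr, 8)
  expect_gt(with_drug, oracle)
  expect_error(
    ae_expected_cost_per_cycle(c(vertigo = 0.1), default_ae_management(),
                               dr, 8),
    class = "foscea_validation_error")
})

test_that("total discounted cost composes drug, service and AE components", {
  # zero unit costs everywhere -> zero total
  brv <- table1_profiles()$BRV
  tr <- run_cohort(model_spec(), brv)
  cm0 <- simple_cost_model(service_costs = published_service_costs * 0)
  expect_equal(total_expected_cost(tr, cm0), 0)

  # one cycle, whole cohort seizure-free, services only -> 114
  sf <- known_answer_cases()$certain_response
  tr1 <- run_cohort(model_spec(n_cycles = 1), sf)
  expect_equal(total_expected_cost(tr1, simple_cost_model()), 114)

  # homogeneity of degree 1 in the unit-cost vector
  cfg <- default_config()
  cm1 <- build_cost_model(
    dose = cfg$treatments$BRV$dose, drug_cost_per_mg = 0.042,
    service_costs = published_service_costs,
    ae_annual = cfg$treatments$BRV$ae_annual)
  cm2 <- build_cost_model(
    dose = cfg$treatments$BRV$dose, drug_cost_per_mg = 2 * 0.042,
    service_costs = 2 * published_service_costs,
    ae_annual = cfg$treatments$BRV$ae_annual,
    ae_drug_costs = 2 * c(acetazolamide = 0.001, cinnarizine = 0.001))
  expect_equal(total_expected_cost(tr, cm2), 2 * total_expected_cost(tr, cm1))

  # the itemized breakdown reconciles with the total
  bd <- cost_breakdown(tr, cm1)
  expect_equal(sum(bd$discounted), total_expected_cost(tr, cm1))
  expect_true(all(bd$discounted <= bd$undiscounted + 1e-12))
  expect_equal(names(bd),
               c("cycle", "component", "state", "undiscounted", "discounted"))

  # discontinued occupancy accrues no drug cost: with only drug costs,
  # a certain-discontinuation cohort costs nothing
  disc_tr <- run_cohort(model_spec(),
                        known_answer_cases()$certain_discontinuation)
  cm_drug <- simple_cost_model(drug_cost_per_mg = 1,
                               service_costs = published_service_costs * 0)
  expect_equal(total_expected_cost(disc_tr, cm_drug), 0)
})

test_that("total cost is monotone in unit costs, doses and AE probabilities", {
  set.seed(71)
  brv <- table1_profiles()$BRV
  tr <- run_cohort(model_spec(), brv)
  cfg <- default_config()
  base_args <- list(
    dose = list(titration = 50, maintenance = 100), drug_cost_per_mg = 0.042,
    service_costs = published_service_costs,
    ae_annual = cfg$treatments$BRV$ae_annual)
  base <- total_expected_cost(tr, do.call(build_cost_model, base_args))
  bump <- function(args) total_expected_cost(tr, do.call(build_cost_model, args))

  a <- base_args; a$drug_cost_per_mg <- 0.05
  expect_gte(bump(a), base)
  a <- base_args; a$service_costs["eeg"] <- 150
  expect_gte(bump(a), base)
  a <- base_args; a$dose$maintenance <- 200
  expect_gte(bump(a), base)
  a <- base_args; a$ae_annual["dizziness"] <- 0.5
  expect_gte(bump(a), base)
  # wastage: raising titration above maintenance never reduces cycle-1 cost
  a <- base_args; a$dose$titration <- 400
  expect_gte(bump(a), base)

  # per-mg cost ordering implies drug-cost ordering at equal doses
  per_mg <- c(BRV = 0.042, ESL = 0.004, LCM = 0.013, PER = 0.804)
  dose <- list(titration = 100, maintenance = 100)
  costs <- vapply(per_mg, function(c) drug_cost_per_cycle(dose, c, 2),
                  numeric(1))
  expect_equal(order(costs, decreasing = TRUE),
               order(per_mg, decreasing = TRUE))
})
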