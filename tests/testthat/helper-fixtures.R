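# Shared fixtures: the published model inputs, random valid profiles, and
# independent closed-form oracles used across the test files.

# the four published per-cycle transition profiles (with their SEs)
table1_profiles <- function() {
  cfg <- default_config()
  out <- lapply(names(cfg$treatments), function(trt)
    transition_profile(trt, cfg$treatments[[trt]]$transition$p,
                       cfg$treatments[[trt]]$transition$se))
  names(out) <- names(cfg$treatments)
  out
}

published_service_costs <- c(inpatient_night = 100, emergency_visit = 30,
                             neurologist_visit = 14, gp_visit = 8, eeg = 100)

# a random simplex-valid transition profile (no SEs unless asked)
random_profile <- function(label = "RND", concentration = 5, se_scale = 0) {
  g <- rgamma(4L, shape = concentration)
  p <- g / sum(g)
  transition_profile(label, p, se_scale * sqrt(p * (1 - p)))
}

# independent closed-form oracle: cumulative ever-seizure-free after n
# cycles when seizure-free and discontinuation absorb (geometric sum over
# the re-drawing partial/non-response mass)
ever_sf_closed_form <- function(p, n) {
  s <- p[2] + p[3]
  if (s == 1) return(0)
  p[1] * (1 - s^n) / (1 - s)
}

# a minimal cost model with configurable pieces, defaulting to the
# published unit costs and no adverse events
simple_cost_model <- function(dose = list(titration = 100, maintenance = 100),
                              drug_cost_per_mg = 0,
                              service_costs = published_service_costs,
                              ae_annual = NULL) {
  build_cost_model(dose = dose, drug_cost_per_mg = drug_cost_per_mg,
                   service_costs = service_costs, ae_annual = ae_annual)
}
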