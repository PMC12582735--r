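# Moment matching, parameter sampling, the PSA engine, plane and CEAC.

test_that("beta moment matching recovers the requested moments", {
  par <- beta_from_mean_se(0.065, 0.003)
  k <- 0.065 * 0.935 / 0.003^2 - 1
  expect_equal(par$alpha, 0.065 * k, tolerance = 1e-12)
  expect_equal(par$beta, 0.935 * k, tolerance = 1e-12)
  # analytic mean/SD of the matched distribution
  expect_equal(par$alpha / (par$alpha + par$beta), 0.065)
  v <- par$alpha * par$beta /
    ((par$alpha + par$beta)^2 * (par$alpha + par$beta + 1))
  expect_equal(sqrt(v), 0.003, tolerance = 1e-12)

  expect_error(beta_from_mean_se(0.5, 0.5),
               class = "foscea_infeasible_moments_error")
  expect_error(beta_from_mean_se(1.2, 0.1),
               class = "foscea_validation_error")
  expect_true(beta_from_mean_se(0.3, 0)$degenerate)

  # sampling oracle: empirical moments of 1e5 draws within 3 SE
  set.seed(103)
  n <- 1e5
  draws <- foscea:::rbeta_mean_se(n, 0.065, 0.003)
  expect_lt(abs(mean(draws) - 0.065), 3 * 0.003 / sqrt(n))
  expect_lt(abs(sd(draws) - 0.003), 3 * 0.003 / sqrt(2 * n))
  expect_equal(foscea:::rbeta_mean_se(5, 0.3, 0), rep(0.3, 5))
})

test_that("gamma moment matching recovers the requested moments", {
  par <- gamma_from_mean_se(100, 25)
  expect_equal(par$shape, 16)
  expect_equal(par$scale, 6.25)
  set.seed(107)
  for (i in 1:10) {
    m <- runif(1, 0.001, 500); s <- runif(1, 0.0001, m)
    p <- gamma_from_mean_se(m, s)
    expect_equal(p$shape * p$scale, m, tolerance = 1e-9)
  }
  expect_error(gamma_from_mean_se(-1, 2), class = "foscea_validation_error")
  expect_true(gamma_from_mean_se(10, 0)$degenerate)

  set.seed(109)
  n <- 1e5
  draws <- foscea:::rgamma_mean_se(n, 100, 25)
  expect_lt(abs(mean(draws) - 100), 3 * 25 / sqrt(n))
  expect_lt(abs(sd(draws) - 25), 3 * 25 / sqrt(2 * n) * 1.3)  # skew margin
})

test_that("percentage ranges map to standard errors linearly", {
  expect_equal(se_from_pct_range(100), 100 * 0.25 / 1.96)
  expect_equal(se_from_pct_range(100), 12.7551, tolerance = 1e-4)
  expect_equal(se_from_pct_range(50, 0), 0)
  expect_equal(se_from_pct_range(200, 0.25), 2 * se_from_pct_range(100, 0.25))
  expect_error(se_from_pct_range(0), class = "foscea_validation_error")
})

test_that("transition sampling stays on the simplex with residual non-response", {
  profs <- table1_profiles()
  # zero SEs return the profile unchanged
  brv0 <- transition_profile("BRV", profs$BRV$p)
  expect_identical(sample_transition_profile(brv0), brv0)

  # empirical mean of sampled seizure-free probability near its target
  set.seed(113)
  n <- 5e3
  draws <- vapply(seq_len(n), function(i)
    sample_transition_profile(profs$BRV)$p[["seizure_free"]], numeric(1))
  expect_lt(abs(mean(draws) - 0.065), 3 * 0.003 / sqrt(n))

  # tight simplex with large SEs: rejections occur, accepted draws valid
  tight <- transition_profile("TIGHT", c(0.55, 0.40, 0.02, 0.03),
                              c(0.05, 0.05, 0, 0.01))
  set.seed(127)
  for (i in 1:200) {
    d <- sample_transition_profile(tight)
    expect_gte(d$p[["non_response"]], 0)
    expect_equal(sum(d$p), 1, tolerance = 1e-12)
  }
})

test_that("a zero-uncertainty PSA reproduces the deterministic pipeline exactly", {
  cfg <- known_answer_cases()$zero_se_config
  det <- run_deterministic(cfg)
  psa <- run_psa(cfg, n_iterations = 50, seed = 1)
  for (trt in psa$treatments) {
    i <- match(trt, det$results$treatment)
    expect_identical(unname(psa$cost[, trt]),
                     rep(det$results$cost[i], 50))
    expect_identical(unname(psa$effect[, trt]),
                     rep(det$results$effect[i], 50))
  }
})

test_that("PSA runs are bit-reproducible under a fixed seed", {
  cfg <- default_config()
  a <- run_psa(cfg, n_iterations = 40, seed = 999)
  b <- run_psa(cfg, n_iterations = 40, seed = 999)
  expect_identical(a$cost, b$cost)
  expect_identical(a$effect, b$effect)
  expect_identical(a$discount_rates, b$discount_rates)
  c <- run_psa(cfg, n_iterations = 40, seed = 1000)
  expect_false(identical(a$cost, c$cost))
})

test_that("with shrunken uncertainty the PSA concentrates on the base case", {
  cfg <- unclass(default_config())
  for (trt in names(cfg$treatments)) {
    cfg$treatments[[trt]]$transition$se <-
      cfg$treatments[[trt]]$transition$se / 10
    cfg$treatments[[trt]]$drug_cost_per_mg$se <-
      cfg$treatments[[trt]]$drug_cost_per_mg$se / 10
  }
  for (d in names(cfg$ae_drug_cost_per_mg)) {
    cfg$ae_drug_cost_per_mg[[d]]$se <- cfg$ae_drug_cost_per_mg[[d]]$se / 10
  }
  cfg$cost_variation_pct <- 0.025
  cfg$ae_prob_variation_pct <- 0.025
  cfg$discount$psa_se <- 0.000625
  cfg <- validate_config(cfg)
  det <- run_deterministic(cfg)
  psa <- run_psa(cfg, n_iterations = 400, seed = 7)
  for (trt in psa$treatments) {
    i <- match(trt, det$results$treatment)
    expect_lt(abs(psa$summary$mean_cost[match(trt, psa$summary$treatment)] /
                    det$results$cost[i] - 1), 0.01)
    expect_lt(abs(psa$summary$mean_effect[match(trt, psa$summary$treatment)] /
                    det$results$effect[i] - 1), 0.01)
  }
})

test_that("plane quadrant fractions sum to one and respect the tie rules", {
  cloud <- known_answer_cases()$symmetric_cloud
  q <- icer_plane_quadrants(cloud, "B")
  expect_equal(sum(q), 1)
  expect_equal(unname(q[c("NE", "SE", "NW", "SW")]), rep(0.25, 4))

  # all-dominant synthetic result: everything in SE
  dom <- structure(list(
    cost = cbind(A = rep(900, 10), B = rep(1000, 10)),
    effect = cbind(A = rep(0.6, 10), B = rep(0.4, 10)),
    treatments = c("A", "B"), reference = "A", n_iterations = 10L,
    seed = 1L, discount_rates = rep(0.035, 10),
    summary = data.frame(treatment = c("A", "B"), mean_cost = c(900, 1000),
                         mean_effect = c(0.6, 0.4))), class = "psa_result")
  expect_equal(unname(icer_plane_quadrants(dom, "B")[["SE"]]), 1)

  # boundary ties: dC = 0 goes to the saving side, dE = 0 to non-effective
  tie <- structure(list(
    cost = cbind(A = c(1000, 1100), B = c(1000, 1000)),
    effect = cbind(A = c(0.6, 0.5), B = c(0.4, 0.5)),
    treatments = c("A", "B"), reference = "A", n_iterations = 2L,
    seed = 1L, discount_rates = rep(0.035, 2),
    summary = data.frame(treatment = c("A", "B"),
                         mean_cost = c(1050, 1000),
                         mean_effect = c(0.55, 0.45))), class = "psa_result")
  q <- icer_plane_quadrants(tie, "B")
  expect_equal(unname(q[["SE"]]), 0.5)  # dC = 0, dE > 0
  expect_equal(unname(q[["NW"]]), 0.5)  # dE = 0, dC > 0
  q2 <- icer_plane_quadrants(tie, "B", ties_cost = "tradeoff",
                             ties_effect = "effective")
  expect_equal(unname(q2[["NE"]]), 1)
  expect_error(icer_plane_quadrants(dom, "Z"),
               class = "foscea_validation_error")
})

test_that("the acceptability curve is the NMB exceedance frequency", {
  # two-point cloud straddling the WTP line: CEAC equals the mixture weight
  n <- 10L
  straddle <- structure(list(
    cost = cbind(A = c(rep(1500, 3), rep(100, 7)), B = rep(1000, n)),
    effect = cbind(A = rep(0.55, n), B = rep(0.50, n)),
    treatments = c("A", "B"), reference = "A", n_iterations = n,
    seed = 1L, discount_rates = rep(0.035, n),
    summary = data.frame(treatment = c("A", "B"), mean_cost = c(520, 1000),
                         mean_effect = c(0.55, 0.5))), class = "psa_result")
  # dE = 0.05 always; dC = +500 (w = 3/10) or -900 (w = 7/10);
  # at WTP 5000: NMB gain = 250 - dC -> positive only for the -900 arm
  tab <- ceac(straddle, c(0, 5000, 20000))
  expect_equal(tab$probability[tab$wtp == 0], 0.7)     # dC < 0 share
  expect_equal(tab$probability[tab$wtp == 5000], 0.7)
  expect_equal(tab$probability[tab$wtp == 20000], 1)   # line passed both arms

  # strictly dominant intervention is certain at every threshold
  dom <- structure(list(
    cost = cbind(A = rep(900, 5), B = rep(1000, 5)),
    effect = cbind(A = rep(0.6, 5), B = rep(0.4, 5)),
    treatments = c("A", "B"), reference = "A", n_iterations = 5L,
    seed = 1L, discount_rates = rep(0.035, 5),
    summary = data.frame(treatment = c("A", "B"), mean_cost = c(900, 1000),
                         mean_effect = c(0.6, 0.4))), class = "psa_result")
  expect_equal(ceac(dom, c(0, 9000, 1e6))$probability, rep(1, 3))

  # monotone in WTP when the intervention is always more effective
  cfg <- default_config()
  psa <- run_psa(cfg, n_iterations = 100, seed = 3)
  for (cmp in setdiff(psa$treatments, psa$reference)) {
    de <- psa$effect[, psa$reference] - psa$effect[, cmp]
    if (all(de > 0)) {
      tab <- ceac(psa, seq(0, 18000, by = 1000), comparators = cmp)
      expect_true(all(diff(tab$probability) >= 0))
    }
  }
  expect_error(ceac(psa, numeric(0)), class = "foscea_validation_error")
})
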