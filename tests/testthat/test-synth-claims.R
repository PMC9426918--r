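test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(n_providers = -5), "n_providers")
  expect_error(sim_config(seeker_fraction = 1.2), "seeker_fraction")
  expect_error(sim_config(dropout_prob = -0.1), "dropout_prob")
  expect_error(sim_config(mean_rx_per_quarter_normal = -1),
               "mean_rx_per_quarter_normal")
  expect_error(sim_config(beta_covariates = c(hepc = 1)), "beta_covariates")
})

test_that("degenerate fractions behave as stated", {
  pop <- simulate_population(sim_config(n_patients = 500, n_providers = 50,
                                        n_quarters = 4, seeker_fraction = 0))
  expect_identical(sum(pop$patients$seeker), 0L)

  sim <- simulate_claims(sim_config(n_patients = 400, n_providers = 40,
                                    n_quarters = 4, baseline_hazard = 0))
  expect_true(all(is.na(sim$patients$overdose_quarter)))
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_patients = 600, n_providers = 60, n_quarters = 6,
                    seed = 99)
  a <- simulate_claims(cfg)
  b <- simulate_claims(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$providers, b$providers)
  expect_identical(a$prescriptions, b$prescriptions)
})

test_that("seeker and lax counts follow their binomial expectations", {
  pop <- simulate_population(sim_config(n_patients = 10000,
                                        n_providers = 1000,
                                        n_quarters = 4,
                                        seeker_fraction = 0.02, seed = 17))
  # 3 binomial standard deviations around 200: sqrt(10000 * .02 * .98) = 14
  expect_lt(abs(sum(pop$patients$seeker) - 200), 3 * 14)
  m <- 1000; lf <- 0.30
  expect_lt(abs(sum(pop$providers$lax) - m * lf),
            3 * sqrt(m * lf * (1 - lf)))
})

test_that("prescriptions respect enrollment spans and rate switches", {
  sim <- small_sim()
  span <- sim$patients[match(sim$prescriptions$patient_id,
                             sim$patients$patient_id), ]
  expect_true(all(sim$prescriptions$quarter >= span$entry_quarter))
  expect_true(all(sim$prescriptions$quarter <= span$exit_quarter))
  expect_true(all(sim$prescriptions$mme > 0))

  # zero non-seeker rate: every record belongs to a seeker
  sim0 <- simulate_claims(sim_config(n_patients = 800, n_providers = 80,
                                     n_quarters = 6,
                                     mean_rx_per_quarter_normal = 0,
                                     seed = 3))
  who <- sim0$patients$seeker[match(sim0$prescriptions$patient_id,
                                    sim0$patients$patient_id)]
  expect_true(all(who == 1L))
})

test_that("events stop follow-up and stay inside the enrollment span", {
  sim <- small_sim(baseline_hazard = 5e-3)
  od <- sim$patients$overdose_quarter
  hit <- !is.na(od)
  expect_gt(sum(hit), 0)
  expect_true(all(od[hit] == sim$patients$exit_quarter[hit]))
  expect_true(all(od[hit] >= sim$patients$entry_quarter[hit]))
  expect_false(any(sim$prescriptions$quarter >
                     sim$patients$exit_quarter[
                       match(sim$prescriptions$patient_id,
                             sim$patients$patient_id)] ))
})

test_that("null hazard model matches its analytic event expectation", {
  # gamma = 0, beta = 0: every at-risk patient-quarter has probability h
  h <- 0.01
  cfg <- sim_config(n_patients = 5000, n_providers = 200, n_quarters = 8,
                    baseline_hazard = h, gamma_seeker = 0,
                    beta_covariates = c(hepc = 0, hiv = 0, cancer = 0,
                                        psych = 0, palliative = 0, mat = 0),
                    seed = 21)
  pop <- simulate_population(cfg)
  rx <- simulate_prescriptions(pop, cfg)
  pats <- simulate_outcomes(pop, rx, cfg)
  # exact expectation from the pre-event enrollment spans
  span <- pop$patients$exit_quarter - pop$patients$entry_quarter + 1L
  expected <- sum(1 - (1 - h)^span)
  observed <- sum(!is.na(pats$overdose_quarter))
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("event counts track the stated hazard at scale", {
  # ~100k patient-quarter analog of a rare-event cohort
  cfg <- sim_config(n_patients = 12500, n_providers = 800, n_quarters = 8,
                    baseline_hazard = 2e-4, dropout_prob = 0, seed = 8)
  pop <- simulate_population(cfg)
  rx <- simulate_prescriptions(pop, cfg)
  pats <- simulate_outcomes(pop, rx, cfg)
  X <- as.matrix(pop$patients[, c("hepc", "hiv", "cancer", "psych",
                                  "palliative", "mat")])
  hi <- pmin(2e-4 * exp(cfg$gamma_seeker * pop$patients$seeker +
                          drop(X %*% cfg$beta_covariates)), 1)
  span <- pop$patients$exit_quarter - pop$patients$entry_quarter + 1L
  expected <- sum(1 - (1 - hi)^span)
  observed <- sum(!is.na(pats$overdose_quarter))
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("hazards above one are truncated with a warning", {
  cfg <- sim_config(n_patients = 300, n_providers = 30, n_quarters = 4,
                    baseline_hazard = 0.5, gamma_seeker = 3,
                    seeker_fraction = 0.5, seed = 2)
  pop <- simulate_population(cfg)
  rx <- simulate_prescriptions(pop, cfg)
  expect_warning(simulate_outcomes(pop, rx, cfg), "truncated")
})

test_that("raising the seeker log-hazard adds events under shared seeds", {
  counts <- vapply(c(1, 2.5, 4), function(g) {
    cfg <- sim_config(n_patients = 4000, n_providers = 200, n_quarters = 8,
                      baseline_hazard = 2e-3, gamma_seeker = g, seed = 31)
    pop <- simulate_population(cfg)
    pats <- simulate_outcomes(pop,
                              simulate_prescriptions(pop, cfg), cfg)
    sum(!is.na(pats$overdose_quarter) & pats$seeker == 1L)
  }, numeric(1))
  # common random numbers: the event set can only grow with gamma
  expect_true(all(diff(counts) > 0))
})

test_that("claims tables survive a disk round trip", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_claims(sim$prescriptions, sim$patients, dir)
  back <- read_claims(dir)
  expect_equal(back$prescriptions, sim$prescriptions)
  expect_equal(back$patients, sim$patients)

  # empty record set still writes a valid header-only file
  empty <- sim$prescriptions[0, ]
  write_claims(empty, sim$patients, dir)
  expect_equal(nrow(read_claims(dir)$prescriptions), 0L)
})

test_that("malformed claims are rejected with the offending line", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  bad <- sim$prescriptions
  bad$mme[3] <- -10
  write_claims(bad, sim$patients, dir)
  expect_error(read_claims(dir), "line 4.*positive")
})
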