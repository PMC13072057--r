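test_that("initialization is stationary, reproducible, and respects single compartments", {
  m1 <- custom_circulation_model("only", 500, 800)
  e <- init_particles(m1, 200)
  expect_true(all(e$compartment == 1L))
  expect_true(all(e$residence_remaining <= 60 * 500 / 800 + 1e-9))

  m2 <- custom_circulation_model(c("a", "b"), c(1000, 4000), c(500, 2500))
  set.seed(7)
  e2 <- init_particles(m2, 1e5)
  p_hat <- mean(e2$compartment == 1L)
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))

  set.seed(123); ea <- init_particles(m2, 1000)
  set.seed(123); eb <- init_particles(m2, 1000)
  expect_identical(ea, eb)
  expect_error(init_particles(m2, 0), "at least 1")
})

test_that("stepping conserves particles; small dt only decrements the countdown", {
  m1 <- custom_circulation_model("only", 500, 800)
  e <- init_particles(m1, 50)
  e2 <- step_particles(e, m1, 0.05)
  expect_identical(e2$compartment, e$compartment)   # nowhere else to go
  expect_equal(e2$residence_remaining,
               ifelse(e$residence_remaining - 0.05 > 1e-12,
                      e$residence_remaining - 0.05,
                      e$residence_remaining - 0.05 + 60 * 500 / 800))

  m2 <- toy_model()
  set.seed(5)
  e3 <- init_particles(m2, 100)
  dt <- min(e3$residence_remaining) / 2
  e4 <- step_particles(e3, m2, dt)
  expect_identical(e4$compartment, e3$compartment)
  expect_equal(e4$residence_remaining, e3$residence_remaining - dt)
  expect_length(e4$compartment, 100)
})

test_that("long no-dose runs reproduce volume-proportional occupancy", {
  m <- toy_model()
  set.seed(11)
  e <- init_particles(m, 2e4)
  e <- advance_particles(e, m, 400, record_occupancy = TRUE)
  occ <- attr(e, "occupancy_time")
  occ <- occ / sum(occ)
  expected <- c(0.2, 0.4, 0.4)
  for (k in 1:3) {
    expect_lt(abs(occ[k] - expected[k]), 3 * sqrt(expected[k] * (1 - expected[k]) / 2e4))
  }
  # exponential residences share the same stationary law
  set.seed(12)
  e2 <- init_particles(m, 2e4, residence = "exponential")
  e2 <- advance_particles(e2, m, 400, record_occupancy = TRUE)
  occ2 <- attr(e2, "occupancy_time"); occ2 <- occ2 / sum(occ2)
  expect_lt(max(abs(occ2 - expected)), 3 * sqrt(0.4 * 0.6 / 2e4))
})

test_that("inverse-CDF organ-dose sampling matches delta, two-step and linear DVHs", {
  set.seed(21)
  s <- sample_organ_dose(delta_dvh(4, 1e-4), 500)
  expect_true(all(abs(s - 4) < 1e-4))

  # two-step DVH: half the volume at ~0 Gy, half at 10 Gy
  g <- seq(0, 10.01, by = 0.01)
  two <- dvh(g, ifelse(g <= 1e-12, 1, ifelse(g <= 10 + 1e-12, 0.5, 0)))
  s2 <- sample_organ_dose(two, 2e4)
  hi <- mean(s2 > 5)
  expect_lt(abs(hi - 0.5), 3 * sqrt(0.25 / 2e4))

  s3 <- sample_organ_dose(linear_dvh(10), 2e4)
  expect_lt(abs(mean(s3) - 5), 3 * sd(s3) / sqrt(2e4))
})

test_that("simulate_fraction: uniform limit, routing independence, flow-weighted mean", {
  m <- toy_model()
  sched <- beam_schedule("IMPT", n_fields = 4, field_beam_on = 30, n_fractions = 1)

  # identical delta DVHs everywhere: every particle gets the step dose,
  # whatever its route (within grid resolution of the step)
  dvhs <- list(a = delta_dvh(2, 1e-4), b = delta_dvh(2, 1e-4), c = delta_dvh(2, 1e-4))
  set.seed(31)
  e <- init_particles(m, 500)
  e <- simulate_fraction(m, dvhs, sched, e)
  expect_true(all(abs(e$cumulative_dose - 2) < 1e-4))

  # flow-weighted closed form: occupancies (0.2, 0.8), deltas (10, 0)
  m2 <- custom_circulation_model(c("hot", "cold"), c(1000, 4000), c(2000, 2000))
  dv2 <- list(hot = delta_dvh(10, 1e-3), cold = delta_dvh(0, 1e-3))
  set.seed(32)
  e2 <- init_particles(m2, 2e4)
  e2 <- simulate_fraction(m2, dv2, sched, e2)
  mu <- mean(e2$cumulative_dose)
  se <- sd(e2$cumulative_dose) / sqrt(2e4)
  target <- 0.2 * mean_dose(dv2$hot) + 0.8 * mean_dose(dv2$cold)
  expect_lt(abs(mu - target), 3 * se)

  # in-field compartment without a DVH is a configuration error naming it
  expect_error(simulate_fraction(m, dvhs[c("a", "b")], sched, e), "c")
  expect_error(simulate_fraction(m, c(dvhs, list(zz = delta_dvh(1))), sched, e), "zz")
})

test_that("course simulation is additive, linear in dose, and seed-deterministic", {
  m <- toy_model()
  dvhs <- list(a = delta_dvh(33, 0.01), b = delta_dvh(33, 0.01), c = delta_dvh(33, 0.01))
  sched <- beam_schedule("IMRT")  # 33 fractions
  r <- simulate_blood_dose(m, dvhs, sched, n_particles = 400, seed = 5)
  expect_lt(abs(r$metrics[["Dmean"]] - 33), r$bin_width)       # 33 x (33/33) Gy
  expect_lt(diff(range(r$per_particle_dose)), 0.01)            # step DVH

  # dose-axis scaling by 0.8 scales every metric by 0.8 within a bin
  dv <- list(a = linear_dvh(3), b = anchored_dvh(c(0, 1, 4), c(1, 0.4, 0)),
             c = delta_dvh(2))
  dv8 <- lapply(dv, scale_dose, factor = 0.8)
  r1 <- simulate_blood_dose(m, dv, sched, n_particles = 2000, seed = 9)
  r2 <- simulate_blood_dose(m, dv8, sched, n_particles = 2000, seed = 9)
  for (met in names(r1$metrics)) {
    if (met == "V0.9Gy") next                                  # not a dose-axis metric
    expect_lt(abs(r2$metrics[[met]] - 0.8 * r1$metrics[[met]]),
              r1$bin_width + 1e-9)
  }

  ra <- simulate_blood_dose(m, dv, sched, n_particles = 1000, seed = 77)
  rb <- simulate_blood_dose(m, dv, sched, n_particles = 1000, seed = 77)
  expect_identical(ra$per_particle_dose, rb$per_particle_dose)
})

test_that("resampling fractions preserves the mean but shrinks dispersion vs scaling one", {
  m <- toy_model()
  dv <- list(a = linear_dvh(5), b = linear_dvh(2), c = linear_dvh(1))
  sched <- beam_schedule("IMPT", n_fractions = 16)
  r_res <- simulate_blood_dose(m, dv, sched, n_particles = 8000, seed = 3,
                               fraction_mode = "resample")
  r_one <- simulate_blood_dose(m, dv, sched, n_particles = 8000, seed = 4,
                               fraction_mode = "scale_single")
  se <- sd(r_one$per_particle_dose) / sqrt(8000)
  expect_lt(abs(mean(r_res$per_particle_dose) - mean(r_one$per_particle_dose)), 4 * se)
  # var(sum of n draws) = n sigma^2 vs var(n x one draw) = n^2 sigma^2
  expect_lt(var(r_res$per_particle_dose), var(r_one$per_particle_dose) / 4)
})

test_that("stochastically dominated inputs never raise the blood mean (common random numbers)", {
  m <- toy_model()
  dv <- list(a = linear_dvh(5), b = linear_dvh(2), c = linear_dvh(1))
  sched <- beam_schedule("IMPT", n_fractions = 4)
  base <- simulate_blood_dose(m, dv, sched, n_particles = 3000, seed = 55)
  for (organ in names(dv)) {
    dv2 <- dv
    dv2[[organ]] <- scale_dose(dv[[organ]], 0.9)
    red <- simulate_blood_dose(m, dv2, sched, n_particles = 3000, seed = 55)
    expect_lte(red$metrics[["Dmean"]], base$metrics[["Dmean"]] + 1e-12)
  }
})

test_that("empirical blood DVH: counting example, survival shape, DKW band", {
  b <- blood_dvh_from_doses(c(0, 1, 2, 3), bin_width = 0.01)
  expect_equal(v_at_dose(b, 0.5), 0.75)
  expect_equal(v_at_dose(b, 2.5), 0.25)
  expect_equal(v_at_dose(b, 0), 1)
  expect_error(blood_dvh_from_doses(numeric(0)), "empty")

  bd <- blood_dvh_from_doses(rep(2.5, 100), bin_width = 0.01)
  expect_equal(max_dose(bd), 2.5, tolerance = 0.011)
  expect_equal(mean_dose(bd), 2.5, tolerance = 0.011)

  # mixture: 30% at ~U(0,2), 70% at ~U(4,6); empirical survival within DKW
  set.seed(66)
  n <- 2e4
  z <- ifelse(runif(n) < 0.3, runif(n, 0, 2), runif(n, 4, 6))
  bm <- blood_dvh_from_doses(z, bin_width = 0.01)
  s_true <- function(d) 0.3 * pmax(0, pmin(1, (2 - d) / 2)) +
    0.7 * pmax(0, pmin(1, (6 - d) / 2))
  eps <- sqrt(log(2 / 0.001) / (2 * n))  # 99.9% DKW band
  at <- seq(0, 6, by = 0.25)
  expect_lt(max(abs(v_at_dose(bm, at) - s_true(at))), eps + 1e-6)
})
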