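test_that("regimen expansion handles loading, misses and remediation", {
  reg <- regimen(300, 200, 12, 2)
  ev <- levipbpk:::regimen_events(reg)
  expect_length(ev, 4)
  expect_equal(vapply(ev, `[[`, 0, "amount"), c(300, 200, 200, 200))

  reg2 <- regimen(300, 200, 12, 2, miss_times = 12,
                  remediation = c(18, 250))
  ev2 <- levipbpk:::regimen_events(reg2)
  expect_equal(vapply(ev2, `[[`, 0, "time"), c(0, 18, 24, 36))
  expect_equal(vapply(ev2, `[[`, 0, "amount"), c(300, 250, 200, 200))

  expect_error(regimen(300, 200, 12, 2, miss_times = 24,
                       remediation = c(20, 250)), "after the missed")
})

test_that("washout: concentrations decay to nothing without maintenance", {
  reg <- regimen(200, 0, 12, 3)
  res <- simulate_regimen(child6_model, reg, fast_dis, dt = 0.1)
  tail_conc <- res$profile$conc_ug_per_mL[res$profile$time_h > 60]
  expect_lt(max(tail_conc), 0.05)
  expect_lt(res$metrics$c_trough_ss, 0.01)
})

test_that("regimen search returns the smallest feasible pair and detects infeasibility", {
  # unconstrained window: smallest grid pair comes back
  reg <- find_regimen(child4_model, c(0, Inf), c(150, 250), c(150, 250),
                      duration_days = 2, dissolution = fast_dis, dt = 0.25)
  expect_s3_class(reg, "regimen")
  expect_equal(reg$loading_dose, 150)
  expect_equal(reg$maintenance_dose, 150)

  # an impossibly narrow window has no solution
  res <- find_regimen(child4_model, c(10, 10.1), c(150, 200), c(150, 200),
                      duration_days = 2, dissolution = fast_dis, dt = 0.25)
  expect_false(isTRUE(res$feasible))
  expect_s3_class(res$best_candidate, "regimen")
})

test_that("a floor-constrained window forces a loading dose above maintenance", {
  reg <- find_regimen(child4_model, c(4, 30),
                      loading_grid = seq(150, 350, 50),
                      maintenance_grid = seq(150, 300, 50),
                      duration_days = 4, dissolution = fast_dis, dt = 0.1)
  expect_s3_class(reg, "regimen")
  expect_gt(reg$loading_dose, reg$maintenance_dose)
})

test_that("missed-dose candidates share the pre-miss trajectory and rank monotonically", {
  reg <- regimen(280, 222.6, 12, 5)
  sims <- lapply(c(250, 350), function(x) {
    rx <- regimen(280, 222.6, 12, 5, miss_times = 60,
                  remediation = c(72, x))
    simulate_regimen(child6_model, rx, fast_dis, dt = 0.1)$profile
  })
  pre <- sims[[1]]$time_h < 60
  expect_lt(max(abs(sims[[1]]$conc_ug_per_mL[pre] -
                      sims[[2]]$conc_ug_per_mL[pre])), 1e-9)
  # larger remedial dose gives pointwise >= concentrations after 72 h
  post <- sims[[1]]$time_h > 72.2
  expect_true(all(sims[[2]]$conc_ug_per_mL[post] >=
                    sims[[1]]$conc_ug_per_mL[post] - 1e-9))
})

test_that("miss + remediation obeys linear superposition", {
  g <- seq(0, 120, 0.1)
  reg_ref <- regimen(280, 222.6, 12, 5)
  ref <- simulate_pbpk(child6_model, levipbpk:::regimen_events(reg_ref),
                       fast_dis, g)
  reg_mr <- regimen(280, 222.6, 12, 5, miss_times = 60,
                    remediation = c(72, 300))
  mr <- simulate_pbpk(child6_model, levipbpk:::regimen_events(reg_mr),
                      fast_dis, g)
  # single-dose responses, shifted to the miss/remediation times
  one <- simulate_pbpk(child6_model, dose_event("oral", 222.6), fast_dis,
                       seq(0, 120, 0.1))
  shift <- function(prof, t0, scale = 1) {
    y <- approx(prof$time_h + t0, prof$conc_ug_per_mL * scale, xout = g,
                rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  # reference has 222.6 at 60 and at 72; the scenario removes the 60-h
  # dose and replaces the 72-h dose with 300 mg
  expected <- ref$conc_ug_per_mL - shift(one, 60) +
    shift(one, 72, (300 - 222.6) / 222.6)
  expect_lt(max(abs(mr$conc_ug_per_mL - expected)) /
              max(ref$conc_ug_per_mL), 1e-3)
})

test_that("degenerate remediation (no miss) picks the maintenance dose", {
  reg <- regimen(280, 222.6, 12, 4)
  res <- missed_dose_remediation(child6_model, reg, miss_time = NULL,
                                 remed_time = 48,
                                 candidates = c(222.6, 280),
                                 resume_time = 60,
                                 dissolution = fast_dis, dt = 0.1)
  expect_equal(attr(res, "chosen"), 222.6)
  expect_error(missed_dose_remediation(child6_model, reg, 60, 72,
                                       candidates = numeric(0)),
               "candidate")
})
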