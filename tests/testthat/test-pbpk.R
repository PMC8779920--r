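test_that("model assembly computes the clearance split", {
  expect_equal(adult_model$clearance_total, 0.063 * 64.19, tolerance = 1e-9)
  expect_equal(adult_model$clearance_renal,
               0.66 * adult_model$clearance_total)
  expect_equal(adult_model$clearance_renal + adult_model$clearance_hepatic,
               adult_model$clearance_total)

  # explicit per-kg override reproduces the printed pediatric arithmetic
  m <- assemble_model(lev, child6, cl_per_kg = 0.053)
  expect_equal(m$clearance_total, 0.053 * 22.26, tolerance = 1e-9)
  expect_equal(m$clearance_total, 1.18, tolerance = 0.01)

  cmp <- lev; cmp$renal_fraction <- 1 - 1e-12
  m2 <- assemble_model(cmp, adult_ref)
  expect_equal(m2$clearance_hepatic, 0, tolerance = 1e-9)

  bad <- flat_kps(1)
  expect_error(assemble_model(lev, adult_ref, kps = bad[-2]),
               "does not cover")
})

test_that("zero-clearance IV bolus conserves total drug mass", {
  mod0 <- assemble_model(lev, adult_ref, cl_per_kg = 1e-12)
  prof <- simulate_pbpk(mod0, dose_event("iv_bolus", 1500),
                        t_grid = seq(0, 24, 0.5))
  expect_lt(max(abs(body_amount(prof) - 1500)) / 1500, 1e-6)
})

test_that("reduced blood-liver model matches the closed-form linear solution", {
  ph <- reduced_physiology(q_liver = 80, v_liver = 30)
  cmp <- lev
  cmp$renal_fraction <- 1e-12       # all-hepatic elimination
  kps <- flat_kps(0.8)
  mod <- assemble_model(cmp, ph, kps = kps, cl_per_kg = 4 / 70)
  grid <- seq(0, 48, 0.25)
  prof <- simulate_pbpk(mod, dose_event("iv_bolus", 1000), t_grid = grid)

  # closed form by eigen-decomposition of the 4-state linear system
  # (venous, lung, arterial, liver); the tiny bystander tissues and
  # flows are below the comparison tolerance
  v_ven <- ph$blood_volume * 2 / 3
  v_art <- ph$blood_volume / 3
  v_lung <- ph$tissue_volumes[["lung"]]
  rbp <- cmp$blood_plasma_ratio
  q <- 80; co <- ph$cardiac_output
  r_lung <- rbp / (v_lung * 0.8)
  r_liv <- rbp / (30 * 0.8)
  clh <- mod$clearance_hepatic
  M <- rbind(
    c(-co / v_ven, 0, 0, q * r_liv),
    c(co / v_ven, -co * r_lung, 0, 0),
    c(0, co * r_lung, -co / v_art, 0),
    c(0, 0, q / v_art - clh / (v_art * rbp), -q * r_liv))
  eg <- eigen(M)
  a0 <- c(1000, 0, 0, 0)
  coefs <- solve(eg$vectors, a0)
  conc_cf <- vapply(grid, function(tt) {
    a <- Re(eg$vectors %*% (coefs * exp(eg$values * tt)))
    a[1] / v_ven / rbp
  }, 0)
  expect_lt(max(abs(prof$conc_ug_per_mL - conc_cf)) / max(conc_cf), 1e-3)
})

test_that("IV AUC0-inf equals dose/clearance regardless of partitioning", {
  for (kpval in c(0.5, 1.5)) {
    mod <- assemble_model(lev, adult_ref, kps = flat_kps(kpval))
    prof <- simulate_pbpk(mod, dose_event("iv_infusion", 1500, 0, 0.75),
                          t_grid = seq(0, 96, 0.05))
    nca <- run_nca(prof, 1500)
    expect_equal(nca$auc_0_inf, 1500 / mod$clearance_total,
                 tolerance = 5e-3)
  }
})

test_that("multiple-dose profiles superpose and scale linearly with dose", {
  g <- seq(0, 48, 0.1)
  p1 <- simulate_pbpk(adult_model, dose_event("oral", 500, 0), fast_dis, g)
  p2 <- simulate_pbpk(adult_model,
                      list(dose_event("oral", 500, 0),
                           dose_event("oral", 500, 12)), fast_dis, g)
  shifted <- approx(p1$time_h + 12, p1$conc_ug_per_mL, xout = g, rule = 1)$y
  shifted[is.na(shifted)] <- 0
  expect_lt(max(abs(p2$conc_ug_per_mL - (p1$conc_ug_per_mL + shifted))) /
              max(p2$conc_ug_per_mL), 1e-3)

  p3 <- simulate_pbpk(adult_model, dose_event("oral", 1000, 0), fast_dis, g)
  expect_lt(max(abs(p3$conc_ug_per_mL - 2 * p1$conc_ug_per_mL)) /
              max(p3$conc_ug_per_mL), 1e-3)
})

test_that("adult IV simulation reproduces the observed exposure", {
  prof <- simulate_pbpk(adult_model, dose_event("iv_infusion", 1500, 0, 0.75),
                        t_grid = seq(0, 48, 0.05))
  nca <- run_nca(prof, 1500)
  expect_lt(pe_percent(nca$c_max, 50.80), 20)
  expect_lt(pe_percent(nca$auc_0_inf, 370.70), 20)
})

test_that("simulation guards its inputs", {
  expect_error(simulate_pbpk(adult_model, dose_event("oral", 500),
                             dissolution = NULL),
               "dissolution")
  expect_error(simulate_pbpk(adult_model,
                             dose_event("oral", 500, time = 10),
                             fast_dis, t_grid = seq(0, 5, 1)),
               "cover")
  expect_error(dose_event("oral", -5), "amount")
  expect_error(dose_event("iv_infusion", 100), "duration")
})
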