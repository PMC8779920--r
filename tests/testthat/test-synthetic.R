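test_that("generated dissolution profiles meet the release constraints", {
  prof <- gen_dissolution("fast_idt", seed = 7)
  f <- function(t) prof$percent_dissolved[prof$time_min == t] / 100
  expect_gte(f(2.5), 0.85)
  expect_gte(f(5), 0.99)
  # noise-free generation returns the exact Weibull values
  clean <- gen_dissolution("fast_idt", seed = 1, noise_cv = 0)
  expect_equal(clean$percent_dissolved[1],
               100 * (1 - exp(-2.5 / 0.9)), tolerance = 1e-9)
  # determinism and distinct seeds
  expect_identical(gen_dissolution("fast_idt", seed = 7), prof)
  expect_false(identical(gen_dissolution("fast_idt", seed = 8), prof))
  # slowed profiles release much later
  slow <- gen_dissolution("slowed", seed = 7, noise_cv = 0)
  expect_lt(slow$percent_dissolved[1], 10)
})

test_that("dog dataset generator recovers the published group means", {
  spec <- dog_study_spec(bsv_cv = 0.10, seed = 1)
  dat <- gen_dog_dataset(spec)
  expect_identical(dat, gen_dog_dataset(spec))   # seed contract

  tab <- read.csv(system.file("extdata", "dog_pk_params.csv",
                              package = "levipbpk"))
  # noise-free truths reproduce the printed group Cmax/AUC (up to the
  # sampling-schedule discretization of the NCA)
  clean <- gen_dog_dataset(dog_study_spec(bsv_cv = 0, seed = 1))
  for (g in tab$formulation) {
    sub <- clean[clean$formulation == g & clean$animal == 1, ]
    row <- tab[tab$formulation == g, ]
    nca <- run_nca(sub[, c("time_h", "conc_ug_per_mL")], row$dose_mg)
    expect_equal(nca$c_max, row$cmax, tolerance = 0.03)
    expect_equal(nca$auc_0_inf, row$auc0inf, tolerance = 0.03)
  }
  # at 10% between-subject CV the group mean (n = 3) stays within two
  # standard errors of its sampling distribution around the targets
  for (g in tab$formulation) {
    sub <- dat[dat$formulation == g, ]
    row <- tab[tab$formulation == g, ]
    ncas <- lapply(split(sub, sub$animal), function(an) {
      run_nca(an[, c("time_h", "conc_ug_per_mL")], row$dose_mg)
    })
    cmax_mean <- mean(vapply(ncas, `[[`, 0, "c_max"))
    auc_mean <- mean(vapply(ncas, `[[`, 0, "auc_0_inf"))
    tol <- 2 * 0.10 / sqrt(spec$n_per_group)
    expect_lt(abs(cmax_mean - row$cmax) / row$cmax, tol)
    expect_lt(abs(auc_mean - row$auc0inf) / row$auc0inf, tol)
  }
})

test_that("dog generator degenerates correctly and round-trips kinetics", {
  spec0 <- dog_study_spec(formulations = "LEV-IDTs-1000", bsv_cv = 0,
                          seed = 3)
  dat <- gen_dog_dataset(spec0)
  by_animal <- split(dat$conc_ug_per_mL, dat$animal)
  expect_equal(by_animal[[1]], by_animal[[2]])
  expect_equal(by_animal[[2]], by_animal[[3]])

  # dense noise-free sampling recovers the elimination rate within 1%
  truth <- spec0$truth
  dense <- dog_study_spec(formulations = "LEV-IDTs-1000", bsv_cv = 0,
                          times = c(seq(0.25, 12, 0.25), seq(13, 72, 1)),
                          seed = 3)
  dd <- gen_dog_dataset(dense)
  an <- dd[dd$animal == 1, ]
  nca <- run_nca(an[, c("time_h", "conc_ug_per_mL")], 1000)
  expect_equal(nca$lambda_z, truth$ke, tolerance = 0.01)
  expect_error(dog_study_spec(formulations = "LEV-IDTs-9999"), "unknown")
})

test_that("clinical profile generator reproduces the observed parameters", {
  iv <- gen_clinical_profile("iv_1500")
  nca_iv <- run_nca(iv, 1500)
  expect_equal(nca_iv$auc_0_inf, 370.70, tolerance = 0.05 * 370.70)
  expect_equal(nca_iv$c_max, 50.80, tolerance = 0.05 * 50.80)

  oral <- gen_clinical_profile("oral_250")
  nca_oral <- run_nca(oral, 250)
  expect_equal(nca_oral$c_max, 5.51, tolerance = 0.05 * 5.51)
  expect_equal(nca_oral$auc_0_inf, 72.56, tolerance = 0.05 * 72.56)

  # dose linearity of the generator
  oral2 <- gen_clinical_profile("oral_250", dose_scale = 2)
  nca2 <- run_nca(oral2, 500)
  expect_equal(nca2$auc_0_inf, 2 * nca_oral$auc_0_inf, tolerance = 1e-6)

  expect_error(gen_clinical_profile("oral_9999"), "unknown regimen")

  # generated profiles round-trip through the package's profile format
  path <- tempfile(fileext = ".csv")
  write_profile(iv, path)
  back <- read_profile(path)
  expect_equal(back$conc_ug_per_mL, iv$conc_ug_per_mL)
})
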