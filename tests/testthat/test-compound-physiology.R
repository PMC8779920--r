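test_that("compound constructor enforces invariants", {
  expect_s3_class(lev, "compound_params")
  expect_equal(lev$molecular_weight, 170.21)
  expect_error(compound_params(170, 0.8, 16, 0.9, 1.11, 1.2, 1000, 1e-5,
                               clearance_plasma = 0.06, renal_fraction = 0.66,
                               vd_reference_range = c(0.5, 0.7)),
               "fup")
  expect_error(compound_params(170, 0.8, 16, 0.9, 1.11, 0.97, 1000, 1e-5,
                               clearance_plasma = 0.06, renal_fraction = 0.66,
                               vd_reference_range = c(0.7, 0.5)),
               "vd_reference_range")
  expect_error(compound_params(-170, 0.8, 16, 0.9, 1.11, 0.97, 1000, 1e-5,
                               clearance_plasma = 0.06, renal_fraction = 0.66,
                               vd_reference_range = c(0.5, 0.7)),
               "positive")
})

test_that("adult physiology scales from the 70-kg reference", {
  ref <- reference_physiology()
  at70 <- build_adult_physiology(70, 1.75, 30, "M")
  expect_equal(at70$tissue_volumes, ref$volumes)

  expect_equal(adult_ref$body_weight, 64.19)
  # linear volume scaling, weight^0.75 flow scaling
  a <- build_adult_physiology(60, 1.70, 30, "M")
  b <- build_adult_physiology(120, 1.70, 30, "M")
  expect_equal(unname(b$tissue_volumes / a$tissue_volumes),
               rep(2, length(a$tissue_volumes)))
  expect_equal(unname(b$tissue_blood_flows / a$tissue_blood_flows),
               rep(2^0.75, length(a$tissue_blood_flows)))
  expect_equal(a$blood_volume, 0.07 * 60)
  # flow closure: non-lung flows sum to cardiac output
  expect_equal(sum(a$tissue_blood_flows[setdiff(names(a$tissue_blood_flows),
                                                "lung")]),
               a$cardiac_output)
  expect_error(build_adult_physiology(-1, 1.7, 30), "positive")
  expect_error(build_adult_physiology(70, 1.7, 10), "age")
})

test_that("child physiology derives height from weight and BMI", {
  expect_equal(child6$height, sqrt(22.26 / 16.07), tolerance = 1e-12)
  expect_equal(child6$height, 1.177, tolerance = 1e-3)
  # 10 mg/kg dosing arithmetic for the 4-year-old
  expect_equal(10 * child4$body_weight, 177.8)
  # purity: repeated construction is identical
  expect_identical(build_child_physiology(6, 22.26, 16.07),
                   build_child_physiology(6, 22.26, 16.07))
  # body-water uplift present below age 12, absent for adults
  expect_gt(child6$water_uplift, 1)
  expect_equal(adult_ref$water_uplift, 1)
  expect_warning(build_child_physiology(0.2, 4, 14), "extrapolating")
})

test_that("every physiology carries the 9 GI compartments in order", {
  for (ph in list(adult_ref, child6, child4)) {
    expect_identical(ph$gi$name,
                     c("stomach", "duodenum", "jejunum1", "jejunum2",
                       "ileum1", "ileum2", "ileum3", "caecum", "colon"))
    expect_true(all(ph$gi$transit_h > 0))
  }
})

test_that("population sampling respects spec ranges, sex split and seed", {
  spec <- population_spec(n = 100, seed = 1)
  pop <- sample_population(spec)
  expect_length(pop, 100)
  sexes <- vapply(pop, `[[`, "", "sex")
  expect_equal(sum(sexes == "M"), 50)
  weights <- vapply(pop, `[[`, 0, "body_weight")
  expect_true(all(weights >= 54.33 & weights <= 67.91))
  bmis <- vapply(pop, `[[`, 0, "bmi")
  expect_true(all(bmis >= 21.3 & bmis <= 23.88))
  ages <- vapply(pop, `[[`, 0, "age")
  expect_true(all(ages >= 25 & ages <= 50))
  # anthropometric closure: BMI recomputable from stored weight/height
  for (ph in pop[1:10]) {
    expect_equal(ph$bmi, ph$body_weight / ph$height^2, tolerance = 1e-9)
  }
  # seed contract
  expect_identical(pop, sample_population(spec))
  expect_false(identical(pop, sample_population(population_spec(n = 100,
                                                                seed = 2))))
  expect_identical(sample_population(population_spec(n = 0)), list())
})

test_that("population sampling leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(sample_population(population_spec(n = 5, seed = 7)))
  expect_identical(.Random.seed, before)
})
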