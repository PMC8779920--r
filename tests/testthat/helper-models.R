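# Shared fixtures, built once per test run.

lev <- lev_compound()
fast_dis <- fit_dissolution(lev_fast_dissolution())

adult_ref <- build_adult_physiology(64.19, 1.70, 23.7, "M")
adult_model <- assemble_model(lev, adult_ref)

child6 <- build_child_physiology(6, 22.26, 16.07)
child6_model <- assemble_model(lev, child6)

child4 <- build_child_physiology(4, 17.78, 16)
child4_model <- assemble_model(lev, child4)

# a reduced physiology: essentially blood + liver, used for the
# closed-form disposition oracle
reduced_physiology <- function(q_liver = 80, v_liver = 30) {
  tiny_v <- 1e-6; tiny_q <- 1e-6
  vols <- setNames(rep(tiny_v, length(levipbpk:::TISSUES)),
                   levipbpk:::TISSUES)
  vols["liver"] <- v_liver
  co <- q_liver + 9 * tiny_q
  flows <- setNames(rep(tiny_q, length(levipbpk:::TISSUES)),
                    levipbpk:::TISSUES)
  flows["liver"] <- q_liver
  flows["lung"] <- co
  structure(list(
    age = 30, sex = "M", body_weight = 70, height = 1.75,
    bmi = 70 / 1.75^2, population = "adult",
    tissue_volumes = vols, tissue_blood_flows = flows,
    cardiac_output = co, blood_volume = 4.9, plasma_volume = 2.695,
    water_uplift = 1, gi = default_gi(70)
  ), class = "physiology")
}

flat_kps <- function(value = 1) {
  structure(setNames(rep(value, length(levipbpk:::TISSUES)),
                     levipbpk:::TISSUES), class = "kp_set")
}
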