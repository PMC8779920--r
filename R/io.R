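#' Load and validate a run configuration
#'
#' Configurations are hierarchical YAML with blocks `compound` (profile
#' name or path), `physiology` (or `population`), `regimen`, `simulation`
#' and `output`.  Schema violations are reported with their field paths
#' before any computation.
#'
#' @param path YAML file path, or a pre-parsed list.
#' @return the validated configuration list (class `run_config`).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  problems <- character()
  if (is.null(cfg$compound)) problems <- c(problems, "compound")
  if (is.null(cfg$physiology) && is.null(cfg$population)) {
    problems <- c(problems, "physiology|population")
  }
  if (!is.null(cfg$regimen)) {
    if (is.null(cfg$regimen$dose) && is.null(cfg$regimen$maintenance)) {
      problems <- c(problems, "regimen.dose")
    }
  }
  if (length(problems)) {
    stop("configuration schema violation at: ",
         paste(problems, collapse = ", "), call. = FALSE)
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

resolve_compound <- function(x) {
  if (inherits(x, "compound_params")) return(x)
  if (is.list(x) && !is.null(x$profile)) x <- x$profile
  if (identical(x, "levetiracetam")) return(lev_compound())
  if (is.character(x) && file.exists(x)) return(lev_compound(x))
  stop("cannot resolve compound profile: ", format(x), call. = FALSE)
}

resolve_physiology <- function(ph) {
  if (inherits(ph, "physiology")) return(ph)
  type <- if (is.null(ph$type)) "adult" else ph$type
  if (type == "adult") {
    build_adult_physiology(ph$weight, ph$height, ph$age,
                           if (is.null(ph$sex)) "M" else ph$sex)
  } else {
    build_child_physiology(ph$age, ph$weight,
                           if (is.null(ph$bmi)) 16 else ph$bmi)
  }
}

write_manifest <- function(dir, config, extra = list()) {
  manifest <- c(list(
    package = "levipbpk",
    version = as.character(utils::packageVersion("levipbpk")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a configured regimen and summarize it
#'
#' Orchestration entry point: resolves the compound and physiology,
#' assembles the PBPK model, simulates the configured dosing, runs NCA
#' and (if an output directory is configured) writes the profile, the NCA
#' table and a reproducibility manifest.
#'
#' @param config a `run_config` (or path to one).
#' @return list with `profile`, `nca`, `model` (invisibly when writing).
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- load_config(config)
  cmp <- resolve_compound(config$compound)
  phys <- resolve_physiology(config$physiology)
  model <- assemble_model(cmp, phys,
                          cl_per_kg = config$physiology$cl_per_kg)
  reg <- config$regimen
  route <- if (is.null(reg$route)) "oral" else reg$route
  t_end <- if (is.null(reg$t_end)) 48 else reg$t_end
  dt <- if (is.null(config$simulation$dt)) 0.05 else config$simulation$dt
  dissolution <- fit_dissolution(lev_fast_dissolution())
  if (!is.null(reg$dissolution) && file.exists(reg$dissolution)) {
    dissolution <- fit_dissolution(read_dissolution(reg$dissolution))
  }
  grid <- seq(0, t_end, dt)
  if (!is.null(reg$maintenance)) {
    rr <- regimen(if (is.null(reg$loading)) reg$maintenance else reg$loading,
                  reg$maintenance,
                  if (is.null(reg$interval)) 12 else reg$interval,
                  t_end / 24)
    prof <- simulate_pbpk(model, regimen_events(rr), dissolution, grid)
  } else {
    ev <- switch(route,
                 oral = dose_event("oral", reg$dose),
                 iv_bolus = dose_event("iv_bolus", reg$dose),
                 iv_infusion = dose_event("iv_infusion", reg$dose, 0,
                                          if (is.null(reg$duration)) 0.75
                                          else reg$duration))
    prof <- simulate_pbpk(model, ev, dissolution, grid)
  }
  nca <- run_nca(prof, if (is.null(reg$dose)) reg$maintenance else reg$dose)
  if (!is.null(config$output$dir)) {
    dir.create(config$output$dir, showWarnings = FALSE, recursive = TRUE)
    write_profile(prof[, c("time_h", "conc_ug_per_mL")],
                  file.path(config$output$dir, "profile.csv"))
    nca_df <- data.frame(parameter = c("cmax", "tmax", "auc0t", "auc0inf",
                                       "lambda_z", "half_life", "mrt_last"),
                         value = c(nca$c_max, nca$t_max, nca$auc_0_t,
                                   nca$auc_0_inf, nca$lambda_z,
                                   nca$half_life, nca$mrt_last))
    write.csv(nca_df, file.path(config$output$dir, "nca.csv"),
              row.names = FALSE, quote = FALSE)
    write_manifest(config$output$dir, config)
    return(invisible(list(profile = prof, nca = nca, model = model)))
  }
  list(profile = prof, nca = nca, model = model)
}

#' Validate the adult model against the published regimens
#'
#' Simulates all six published adult regimens (IV 1500 mg as a 0.75-h
#' infusion; oral 250--1500 mg with the packaged fast dissolution) using
#' each cohort's anthropometrics, runs NCA on each simulated profile and
#' compares Cmax/AUC against the observed values under the 20% prediction
#' error gate.
#'
#' @param compound a [compound_params()] (default packaged profile).
#' @param dt simulation output resolution, h.
#' @param t_end simulation horizon, h.
#' @param gate PE gate in percent.
#' @return a `validation_report` (attribute `simulations` carries the
#'   profiles).
#' @export
run_validate <- function(compound = lev_compound(), dt = 0.05, t_end = 48,
                         gate = 20) {
  regs <- lev_adult_regimens()
  observed <- lev_observed_adult_pk()
  observed$predicted <- NULL
  dissolution <- fit_dissolution(lev_fast_dissolution())
  grid <- seq(0, t_end, dt)
  sims <- list()
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    phys <- build_adult_physiology(r$weight_kg, r$height_m, r$age_y, "M")
    model <- assemble_model(compound, phys)
    ev <- if (r$route == "iv_infusion") {
      dose_event("iv_infusion", r$dose_mg, 0, 0.75)
    } else {
      dose_event("oral", r$dose_mg)
    }
    sims[[r$regimen]] <- simulate_pbpk(model, ev, dissolution, grid)
  }
  rep <- validate_against_observed(sims, observed, gate)
  attr(rep, "simulations") <- sims
  rep
}

#' Virtual bioequivalence run from a configuration
#'
#' Samples the configured virtual population and runs
#' [virtual_be_trial()] with test and reference dissolution profiles
#' (identical packaged fast profiles by default).
#'
#' @param config optional `run_config`; fields `population` (n, seed,
#'   ranges) and `vbe` (dose, limits, slow_factor for a degraded test
#'   product) are honoured.
#' @return a `be_report`.
#' @export
run_vbe <- function(config = list()) {
  pop_cfg <- config$population
  spec <- population_spec(
    n = if (is.null(pop_cfg$n)) 24 else pop_cfg$n,
    seed = if (is.null(config$seed)) 1L else config$seed)
  pop <- sample_population(spec)
  cmp <- if (is.null(config$compound)) lev_compound() else
    resolve_compound(config$compound)
  ref <- fit_dissolution(lev_fast_dissolution())
  test <- ref
  if (!is.null(config$vbe$slow_factor) && config$vbe$slow_factor != 1) {
    test <- dissolution_model("weibull", f_max = ref$f_max,
                              td = ref$td * config$vbe$slow_factor,
                              b = ref$b)
  }
  dose <- if (is.null(config$vbe$dose)) 1000 else config$vbe$dose
  limits <- if (is.null(config$vbe$limits)) c(85, 120) else config$vbe$limits
  virtual_be_trial(pop, cmp, test, ref, dose = dose, limits = limits)
}

#' Pediatric dose design / remediation from a configuration
#'
#' Builds the configured child model and either searches the configured
#' loading/maintenance grids against the therapeutic window or, when
#' `remediation.candidates` is present, ranks missed-dose remediation
#' candidates.
#'
#' @param config a `run_config`-style list with `physiology` (child) and
#'   either `design` (loading_grid, maintenance_grid, window) or
#'   `remediation` (regimen, miss/remediate times, candidates).
#' @return a [find_regimen()] or [missed_dose_remediation()] result.
#' @export
run_dose_design <- function(config) {
  cmp <- if (is.null(config$compound)) lev_compound() else
    resolve_compound(config$compound)
  phys <- resolve_physiology(config$physiology)
  model <- assemble_model(cmp, phys,
                          cl_per_kg = config$physiology$cl_per_kg)
  if (!is.null(config$remediation)) {
    rc <- config$remediation
    reg <- regimen(rc$loading, rc$maintenance,
                   if (is.null(rc$interval)) 12 else rc$interval,
                   if (is.null(rc$duration_days)) 7 else rc$duration_days)
    return(missed_dose_remediation(
      model, reg,
      miss_time = if (is.null(rc$miss_at)) 60 else rc$miss_at,
      remed_time = if (is.null(rc$remediate_at)) 72 else rc$remediate_at,
      candidates = rc$candidates,
      resume_time = if (is.null(rc$resume_at)) 84 else rc$resume_at))
  }
  dc <- config$design
  find_regimen(model,
               window = if (is.null(dc$window)) c(5, 19) else dc$window,
               loading_grid = dc$loading_grid,
               maintenance_grid = dc$maintenance_grid,
               interval = if (is.null(dc$interval)) 12 else dc$interval)
}

#' Non-compartmental analysis of profile files
#'
#' Thin wrapper running [run_nca()] on delimited profile files.
#'
#' @param files character vector of profile paths.
#' @param dose dose in mg (recycled).
#' @return data.frame of NCA parameters, one row per file.
#' @export
run_nca_files <- function(files, dose = NA_real_) {
  dose <- rep_len(dose, length(files))
  do.call(rbind, lapply(seq_along(files), function(i) {
    nca <- run_nca(read_profile(files[i]), dose[i])
    data.frame(file = files[i], cmax = nca$c_max, tmax = nca$t_max,
               auc0t = nca$auc_0_t, auc0inf = nca$auc_0_inf,
               lambda_z = nca$lambda_z, half_life = nca$half_life,
               mrt_last = nca$mrt_last)
  }))
}
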