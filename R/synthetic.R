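#' Generate an in vitro dissolution profile
#'
#' Emulates the pH 1.2 dissolution behaviour of the instant-dissolving
#' tablets: a Weibull release with time scale 0.9 min (shape 1), more
#' than 85% dissolved at 2.5 min and complete release at 5 min, with
#' multiplicative lognormal assay noise of at most a few percent.
#' Sampling points whose true release exceeds 99.5% are reported as
#' complete (100%), mirroring assay practice.  `kind = "slowed"` scales
#' the time constant by `slow_factor` to emulate a degraded formulation.
#'
#' @param kind `"fast_idt"` or `"slowed"`.
#' @param seed integer seed (profiles are seed-deterministic).
#' @param noise_cv multiplicative noise CV (default 0.02; 0 gives the
#'   exact Weibull values).
#' @param slow_factor time-scale multiplier for `kind = "slowed"`.
#' @param times sampling times, minutes.
#' @return data.frame `time_min`, `percent_dissolved`.
#' @export
#' @examples
#' gen_dissolution("fast_idt", seed = 7)
gen_dissolution <- function(kind = c("fast_idt", "slowed"), seed = 1L,
                            noise_cv = 0.02, slow_factor = 50,
                            times = c(2.5, 5, 10, 15, 20, 30)) {
  kind <- match.arg(kind)
  td <- if (kind == "fast_idt") 0.9 else 0.9 * slow_factor
  truth <- 1 - exp(-(times / td))
  frac <- with_seed(seed, {
    eps <- if (noise_cv > 0) rnorm(length(times), 0, noise_cv) else 0
    truth * exp(eps)
  })
  frac[truth >= 0.995] <- 1
  frac <- pmin(cummax(frac), 1)
  data.frame(time_min = times, percent_dissolved = 100 * frac)
}

# numeric inversion of the one-compartment oral Tmax relation
solve_ka_from_tmax <- function(tmax, ke) {
  f <- function(ka) log(ka / ke) / (ka - ke) - tmax
  hi <- 200
  if (f(hi) > 0) return(hi)
  uniroot(f, c(ke * 1.0001, hi), tol = 1e-10)$root
}

# invert Cmax(ka) at fixed ke and V (monotone increasing in ka, bounded
# above by dose/V); returns NA when the target is unattainable
solve_ka_from_cmax <- function(cmax, dose, ke, v) {
  cm <- function(ka) {
    tmx <- log(ka / ke) / (ka - ke)
    bateman(tmx, dose, ka, ke, v)
  }
  hi <- 500
  if (cmax >= cm(hi) || cmax <= cm(ke * 1.001)) return(NA_real_)
  uniroot(function(ka) cm(ka) - cmax, c(ke * 1.001, hi), tol = 1e-10)$root
}

bateman <- function(t, dose, ka, ke, v, f = 1) {
  if (abs(ka - ke) < 1e-9) ka <- ke * (1 + 1e-6)
  f * dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Dog study specification
#'
#' Defines the parallel-group beagle study: one group of `n_per_group`
#' animals per formulation/strength, one-compartment oral truth
#' parameters back-calculated from the published group summary table
#' (elimination rate from the half-life, apparent clearance from
#' dose/AUC0-inf, absorption rate solved so the closed-form Cmax matches
#' the published group Cmax, falling back to the published Tmax when the
#' Cmax is unattainable at the fixed ke and V/F), lognormal
#' between-subject variability, and the study sampling schedule (15, 30,
#' 45, 60 min; 1.5, 2, 4, 6, 8, 12, 24, 48 h).  Several printed group
#' summaries (notably the originator column) are not jointly consistent
#' with a one-compartment model; Cmax and AUC, the quantities the
#' bioequivalence statistics consume, take precedence over Tmax.
#'
#' @param formulations subset of the packaged group labels (default all).
#' @param n_per_group animals per group.
#' @param bsv_cv lognormal between-subject CV (fraction).
#' @param times sampling schedule, h.
#' @param seed integer seed.
#' @return an object of class `dog_study_spec` with the truth parameter
#'   table attached.
#' @export
dog_study_spec <- function(formulations = NULL, n_per_group = 3,
                           bsv_cv = 0.10,
                           times = c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 4, 6,
                                     8, 12, 24, 48),
                           seed = 1L) {
  stopifnot(n_per_group >= 1, bsv_cv >= 0,
            !is.unsorted(times, strictly = TRUE))
  tab <- read.csv(extdata_path("dog_pk_params.csv"))
  if (!is.null(formulations)) {
    missing <- setdiff(formulations, tab$formulation)
    if (length(missing)) stop("unknown formulation(s): ",
                              paste(missing, collapse = ", "), call. = FALSE)
    tab <- tab[tab$formulation %in% formulations, ]
  }
  truth <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    ke <- log(2) / r$hl_lambda_z
    cl_f <- r$dose_mg / r$auc0inf           # L/h (apparent)
    v_f <- cl_f / ke
    ka <- solve_ka_from_cmax(r$cmax, r$dose_mg, ke, v_f)
    if (is.na(ka)) ka <- solve_ka_from_tmax(r$tmax, ke)
    data.frame(formulation = r$formulation, dose_mg = r$dose_mg,
               ka = ka, ke = ke, v_f = v_f,
               cmax_target = r$cmax, auc0inf_target = r$auc0inf)
  }))
  structure(list(truth = truth, n_per_group = n_per_group,
                 bsv_cv = bsv_cv, times = times, seed = as.integer(seed)),
            class = "dog_study_spec")
}

#' Generate a parallel-group dog PK dataset
#'
#' Draws per-animal one-compartment parameters lognormally around the
#' group truths and evaluates the oral closed form at the study sampling
#' schedule.  Seed-deterministic; `bsv_cv = 0` returns identical animals
#' within each group.
#'
#' @param spec a [dog_study_spec()].
#' @return data.frame `formulation`, `dose_mg`, `animal`, `time_h`,
#'   `conc_ug_per_mL`.
#' @export
gen_dog_dataset <- function(spec) {
  stopifnot(inherits(spec, "dog_study_spec"))
  sdlog <- sqrt(log(1 + spec$bsv_cv^2))
  with_seed(spec$seed, {
    out <- lapply(seq_len(nrow(spec$truth)), function(i) {
      tr <- spec$truth[i, ]
      do.call(rbind, lapply(seq_len(spec$n_per_group), function(a) {
        mult <- if (spec$bsv_cv > 0) exp(rnorm(3, 0, sdlog)) else c(1, 1, 1)
        conc <- bateman(spec$times, tr$dose_mg, tr$ka * mult[1],
                        tr$ke * mult[2], tr$v_f * mult[3])
        data.frame(formulation = tr$formulation, dose_mg = tr$dose_mg,
                   animal = a, time_h = spec$times,
                   conc_ug_per_mL = conc)
      }))
    })
    do.call(rbind, out)
  })
}

#' Generate a clinical-like concentration-time profile
#'
#' Emulates the published adult profiles: a mono-exponential decline for
#' the IV regimen (initial concentration = observed Cmax, elimination
#' rate = Cmax/AUC0-inf) and a Bateman (one-compartment oral) curve for
#' the oral regimens, with the elimination rate and apparent volume
#' solved so that the analytic Cmax and AUC0-inf match the observed
#' values (absorption rate fixed at 3/h).  Non-compartmental analysis of
#' the generated profile reproduces the observed Cmax/AUC within a few
#' percent (sampling-grid discretization only).
#'
#' @param regimen_id one of the packaged regimen labels (`iv_1500`,
#'   `oral_250`, `oral_500`, `oral_750`, `oral_1000`, `oral_1500`).
#' @param times sampling times, h.
#' @param dose_scale optional multiplier applied to the dose (profile
#'   scales linearly).
#' @return data.frame `time_h`, `conc_ug_per_mL` with the generating
#'   parameters attached as attribute `params`.
#' @export
#' @examples
#' prof <- gen_clinical_profile("iv_1500")
#' run_nca(prof, 1500)$auc_0_inf  # ~370.7
gen_clinical_profile <- function(regimen_id,
                                 times = c(0.083, 0.25, 0.5, 0.75, 1, 1.5,
                                           2, 3, 4, 6, 8, 12, 16, 24, 36,
                                           48),
                                 dose_scale = 1) {
  obs <- lev_observed_adult_pk()
  obs <- obs[obs$regimen == regimen_id, ]
  if (!nrow(obs)) stop("unknown regimen: ", regimen_id, call. = FALSE)
  cmax <- obs$observed[obs$parameter == "cmax"]
  aucinf <- obs$observed[obs$parameter == "auc0inf"]
  reg <- lev_adult_regimens()
  dose <- reg$dose_mg[reg$regimen == regimen_id] * dose_scale
  if (startsWith(regimen_id, "iv")) {
    ke <- cmax / aucinf
    times <- unique(c(0, times))
    conc <- dose_scale * cmax * exp(-ke * times)
    params <- c(ke = ke, c0 = cmax * dose_scale)
  } else {
    ka <- 3
    cmax_fun <- function(ke) {
      v <- dose / dose_scale / (ke * aucinf)
      tmx <- log(ka / ke) / (ka - ke)
      bateman(tmx, dose / dose_scale, ka, ke, v)
    }
    ke <- uniroot(function(k) cmax_fun(k) - cmax,
                  c(1e-4, ka * 0.999), tol = 1e-12)$root
    v <- dose / dose_scale / (ke * aucinf)
    conc <- bateman(times, dose, ka, ke, v)
    params <- c(ka = ka, ke = ke, v_f = v)
  }
  out <- data.frame(time_h = times, conc_ug_per_mL = conc)
  attr(out, "params") <- params
  attr(out, "dose_mg") <- dose
  out
}
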