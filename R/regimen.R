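#' Multiple-dose regimen
#'
#' A loading dose followed by maintenance doses every `interval` hours
#' for `duration_days`, with optional missed doses and a remediation
#' dose.  A remediation dose given at a scheduled dosing time replaces
#' the scheduled dose.
#'
#' @param loading_dose mg (first administration; equal to
#'   `maintenance_dose` when no loading is intended).
#' @param maintenance_dose mg.
#' @param interval dosing interval, h.
#' @param duration_days length of the course, days.
#' @param miss_times scheduled dose times (h) that are skipped.
#' @param remediation `c(time_h, dose_mg)` or `NULL`.
#' @return an object of class `regimen`.
#' @export
#' @examples
#' reg <- regimen(300, 200, 12, 7)
regimen <- function(loading_dose, maintenance_dose, interval = 12,
                    duration_days = 7, miss_times = NULL,
                    remediation = NULL) {
  stopifnot(loading_dose >= 0, maintenance_dose >= 0, interval > 0,
            duration_days > 0)
  if (!is.null(remediation)) {
    stopifnot(length(remediation) == 2, remediation[2] > 0)
    if (length(miss_times) && remediation[1] <= max(miss_times)) {
      stop("remediation must come after the missed dose", call. = FALSE)
    }
  }
  structure(list(loading_dose = loading_dose,
                 maintenance_dose = maintenance_dose,
                 interval = interval, duration_days = duration_days,
                 miss_times = miss_times, remediation = remediation),
            class = "regimen")
}

# expand a regimen into oral dose events
regimen_events <- function(reg) {
  n_doses <- floor(reg$duration_days * 24 / reg$interval + 1e-9)
  sched <- seq(0, by = reg$interval, length.out = n_doses)
  doses <- rep(reg$maintenance_dose, length(sched))
  doses[1] <- reg$loading_dose
  keep <- rep(TRUE, length(sched))
  for (m in reg$miss_times) keep[abs(sched - m) < 1e-6] <- FALSE
  if (!is.null(reg$remediation)) {
    keep[abs(sched - reg$remediation[1]) < 1e-6] <- FALSE
  }
  events <- mapply(function(a, t) dose_event("oral", a, t),
                   doses[keep & doses > 0], sched[keep & doses > 0],
                   SIMPLIFY = FALSE)
  if (!is.null(reg$remediation)) {
    events <- c(events, list(dose_event("oral", reg$remediation[2],
                                        reg$remediation[1])))
  }
  events[order(vapply(events, `[[`, 0, "time"))]
}

#' Simulate a regimen and score it against the therapeutic window
#'
#' Runs the multiple-dose simulation and summarizes the final dosing
#' interval: steady-state trough and peak and the fraction of the
#' interval spent inside the therapeutic window (default 5--19 ug/mL,
#' the pediatric levetiracetam monotherapy reference range).  Course
#' extrema (minimum trough and maximum peak over the whole course after
#' the first dose) are attached for transient assessment of loading
#' regimens.
#'
#' @param model a `pbpk_model`.
#' @param reg a [regimen()].
#' @param dissolution a `dissolution_model`.
#' @param window therapeutic window, ug/mL.
#' @param dt output resolution, h.
#' @return a list with `profile` (`sim_profile`) and `metrics` (class
#'   `window_metrics`).
#' @export
simulate_regimen <- function(model, reg, dissolution,
                             window = c(5, 19), dt = 0.05) {
  events <- regimen_events(reg)
  if (!length(events)) stop("regimen contains no doses", call. = FALSE)
  t_end <- reg$duration_days * 24
  grid <- seq(0, t_end, dt)
  prof <- simulate_pbpk(model, events, dissolution, grid)
  iv_start <- t_end - reg$interval
  fin <- prof[prof$time_h >= iv_start - 1e-9, ]
  cc <- fin$conc_ug_per_mL
  in_window <- cc >= window[1] & cc <= window[2]
  # per-interval extrema over the whole course (post first dose)
  bounds <- seq(0, t_end, by = reg$interval)
  troughs <- vapply(bounds[-1], function(b) {
    prof$conc_ug_per_mL[which.min(abs(prof$time_h - b))]
  }, 0)
  peaks <- vapply(seq_len(length(bounds) - 1), function(i) {
    sel <- prof$time_h >= bounds[i] & prof$time_h <= bounds[i + 1]
    max(prof$conc_ug_per_mL[sel])
  }, 0)
  metrics <- structure(list(
    c_trough_ss = cc[length(cc)],
    c_peak_ss = max(cc),
    fraction_of_interval_in_window = mean(in_window),
    window = window,
    course_trough_min = min(troughs),
    course_peak_max = max(peaks),
    troughs = troughs, peaks = peaks
  ), class = "window_metrics")
  list(profile = prof, metrics = metrics)
}

#' @export
print.window_metrics <- function(x, ...) {
  cat(sprintf("<window_metrics> steady state trough %.2f, peak %.2f ug/mL; %.0f%% of interval in [%.0f, %.0f]\n",
              x$c_trough_ss, x$c_peak_ss,
              100 * x$fraction_of_interval_in_window,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Grid search for a loading/maintenance regimen
#'
#' Deterministically searches the loading x maintenance grid for the
#' smallest pair (maintenance first, then loading) whose simulated course
#' keeps every post-first-dose trough at or above the window floor and
#' every peak at or below the ceiling.  The loading dose governs the
#' early intervals, the maintenance dose the steady state.
#'
#' @param model a `pbpk_model`.
#' @param window therapeutic window, ug/mL.
#' @param loading_grid,maintenance_grid candidate doses, mg.
#' @param interval dosing interval, h.
#' @param duration_days simulated course length.
#' @param dissolution a `dissolution_model`.
#' @param dt output resolution, h.
#' @return the selected [regimen()], or (if no pair is feasible) a list
#'   with `feasible = FALSE` and the best candidate by fraction of time
#'   in window.
#' @export
find_regimen <- function(model, window, loading_grid, maintenance_grid,
                         interval = 12, duration_days = 5,
                         dissolution = fit_dissolution(lev_fast_dissolution()),
                         dt = 0.1) {
  stopifnot(length(loading_grid) >= 1, length(maintenance_grid) >= 1)
  best <- NULL; best_frac <- -1
  for (m in sort(maintenance_grid)) {
    for (l in sort(loading_grid)) {
      reg <- regimen(l, m, interval, duration_days)
      res <- simulate_regimen(model, reg, dissolution, window, dt)
      ok <- res$metrics$course_trough_min >= window[1] &&
        res$metrics$course_peak_max <= window[2]
      if (ok) return(reg)
      if (res$metrics$fraction_of_interval_in_window > best_frac) {
        best_frac <- res$metrics$fraction_of_interval_in_window
        best <- reg
      }
    }
  }
  list(feasible = FALSE, best_candidate = best,
       best_fraction_in_window = best_frac)
}

#' Missed-dose remediation analysis
#'
#' Simulates the missed-dose scenario (a scheduled dose at `miss_time` is
#' skipped; a remedial dose is taken at `remed_time`, replacing any dose
#' scheduled then; normal dosing resumes from `resume_time`) for each
#' candidate remedial dose, against the no-miss reference course.  A
#' candidate is acceptable when the profile (i) re-enters the reference
#' steady-state envelope `[trough_ss, peak_ss]` within one dosing
#' interval of the remediation, (ii) returns to the concentrations of
#' normal dosing -- its remediation-interval peak reaches the reference
#' peak over the same interval -- and (iii) never exceeds the reference
#' peak by more than `tol` (fractional, default 10%).  Among acceptable
#' candidates the chosen dose minimizes the integrated absolute deviation
#' from the reference profile over `[remed_time, end]`.
#'
#' @param model a `pbpk_model`.
#' @param reg the nominal [regimen()] (no miss events).
#' @param miss_time missed scheduled dose time, h.
#' @param remed_time remediation time, h.
#' @param candidates candidate remedial doses, mg.
#' @param resume_time time from which normal dosing resumes, h
#'   (informational; the schedule itself resumes at the next scheduled
#'   time after `remed_time`).
#' @param dissolution a `dissolution_model`.
#' @param tol allowed fractional overshoot of the reference peak.
#' @param dt output resolution, h.
#' @return an object of class `remediation_result`: ranking data.frame
#'   (attributes carry the reference metrics and profiles).
#' @export
missed_dose_remediation <- function(model, reg, miss_time = 60,
                                    remed_time = 72, candidates,
                                    resume_time = 84,
                                    dissolution = fit_dissolution(lev_fast_dissolution()),
                                    tol = 0.10, dt = 0.05) {
  if (!length(candidates)) stop("no candidate doses supplied", call. = FALSE)
  if (!is.null(miss_time) &&
      !(miss_time < remed_time && remed_time < resume_time)) {
    stop("need miss_time < remed_time < resume_time", call. = FALSE)
  }
  ref <- simulate_regimen(model, reg, dissolution, dt = dt)
  peak_ss <- ref$metrics$c_peak_ss
  trough_ss <- ref$metrics$c_trough_ss
  ref_conc <- ref$profile$conc_ug_per_mL
  tt <- ref$profile$time_h
  remed_win <- tt >= remed_time & tt <= remed_time + reg$interval
  ref_win_peak <- max(ref_conc[remed_win])
  rows <- lapply(sort(candidates), function(x) {
    reg_x <- regimen(reg$loading_dose, reg$maintenance_dose, reg$interval,
                     reg$duration_days,
                     miss_times = if (is.null(miss_time)) NULL else miss_time,
                     remediation = c(remed_time, x))
    sim <- simulate_regimen(model, reg_x, dissolution, dt = dt)
    cc <- sim$profile$conc_ug_per_mL
    post <- tt >= remed_time
    over <- max(cc[post] - peak_ss) / peak_ss
    in_env <- which(post & cc >= trough_ss & cc <= peak_ss &
                      tt <= remed_time + reg$interval)
    reentered <- length(in_env) > 0
    reaches <- max(cc[remed_win]) >= ref_win_peak
    deviation <- sum(abs(cc[post] - ref_conc[post])) * dt
    data.frame(dose = x,
               max_overshoot_frac = over,
               reenters_within_interval = reentered,
               reaches_reference_peak = reaches,
               acceptable = reentered && reaches && over <= tol,
               integrated_abs_deviation = deviation)
  })
  tab <- do.call(rbind, rows)
  acc <- tab[tab$acceptable, ]
  chosen <- if (nrow(acc)) acc$dose[which.min(acc$integrated_abs_deviation)]
    else NA_real_
  structure(tab, class = c("remediation_result", "data.frame"),
            chosen = chosen, peak_ss = peak_ss, trough_ss = trough_ss,
            reference = ref)
}

#' @export
print.remediation_result <- function(x, ...) {
  cat(sprintf("<remediation_result> reference envelope [%.2f, %.2f] ug/mL; chosen: %s mg\n",
              attr(x, "trough_ss"), attr(x, "peak_ss"),
              format(attr(x, "chosen"))))
  print(as.data.frame(x))
  invisible(x)
}
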