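#' Dose event
#'
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"oral"`.
#' @param amount dose, mg (> 0).
#' @param time dosing time, h (>= 0).
#' @param duration infusion duration, h (required for `iv_infusion`).
#' @return an object of class `dose_event`.
#' @export
dose_event <- function(route = c("oral", "iv_bolus", "iv_infusion"),
                       amount, time = 0, duration = NULL) {
  route <- match.arg(route)
  stopifnot(is.numeric(amount), amount > 0, time >= 0)
  if (route == "iv_infusion") {
    stopifnot(is.numeric(duration), duration > 0)
  } else {
    duration <- 0
  }
  structure(list(route = route, amount = amount, time = time,
                 duration = duration), class = "dose_event")
}

# Reference adult weight at which the per-kg clearance was derived; the
# anchor for allometric scaling of pediatric clearance.
ADULT_CL_REF_WEIGHT <- 64.19

#' Assemble a whole-body PBPK model
#'
#' Couples a compound, a physiology and a Kp set into a perfusion-limited
#' disposition model.  Total plasma clearance is `cl_per_kg * body
#' weight`; the default per-kg clearance is the compound's adult value
#' (0.063 L/h/kg for the packaged levetiracetam profile, derived from IV
#' data).  For pediatric physiologies the default is obtained by
#' allometric scaling (exponent 0.75) of the absolute adult clearance
#' from the 64.19-kg reference subject, the standard choice for a renally
#' cleared drug in children older than ~2 years.  Clearance splits 66%
#' renal (applied to renal arterial plasma inflow) with the remainder
#' hepatic (applied at the liver inlet; first-pass extraction is
#' negligible for levetiracetam since its clearance is far below liver
#' blood flow).
#'
#' @param compound a [compound_params()].
#' @param phys a `physiology`.
#' @param kps a `kp_set`; defaults to Berezhkovskiy coefficients computed
#'   from the packaged composition table with the physiology's water
#'   uplift.
#' @param cl_per_kg optional clearance override, L/h/kg.
#' @return an object of class `pbpk_model`.
#' @export
#' @examples
#' ph <- build_adult_physiology(64.19, 1.70, 23.7, "M")
#' mod <- assemble_model(lev_compound(), ph)
#' mod$clearance_total  # ~4.05 L/h
assemble_model <- function(compound, phys, kps = NULL, cl_per_kg = NULL) {
  if (is.null(kps)) {
    kps <- kp_berezhkovskiy(compound,
                            tissue_composition(phys$water_uplift))
  }
  missing <- setdiff(names(phys$tissue_volumes), names(kps))
  if (length(missing)) {
    stop("Kp set does not cover tissue(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bw <- phys$body_weight
  cl_total <- if (!is.null(cl_per_kg)) {
    cl_per_kg * bw
  } else if (identical(phys$population, "child")) {
    compound$clearance_plasma * ADULT_CL_REF_WEIGHT *
      (bw / ADULT_CL_REF_WEIGHT)^0.75
  } else {
    compound$clearance_plasma * bw
  }
  cl_renal <- compound$renal_fraction * cl_total
  structure(list(
    compound = compound, physiology = phys, kps = kps,
    clearance_total = cl_total,
    clearance_renal = cl_renal,
    clearance_hepatic = cl_total - cl_renal,
    vss = vss_from_kp(kps, phys)
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s in %s (%.2f kg)\n", x$compound$name,
              x$physiology$population, x$physiology$body_weight))
  cat(sprintf("  CL %.3f L/h (renal %.3f, hepatic %.3f); Vss %.3f L/kg\n",
              x$clearance_total, x$clearance_renal, x$clearance_hepatic,
              x$vss))
  invisible(x)
}

# Build the parameter environment for the coupled gut + body RHS.
pbpk_parms <- function(model, dissolution) {
  phys <- model$physiology
  tiss <- TISSUES
  kp <- unclass(model$kps)[tiss]
  vt <- phys$tissue_volumes[tiss]
  qt <- phys$tissue_blood_flows[tiss]
  p <- list(
    tissues = tiss,
    vt = vt, qt = qt, kp = kp,
    rbp = model$compound$blood_plasma_ratio,
    co = phys$cardiac_output,
    v_art = phys$blood_volume / 3,
    v_ven = phys$blood_volume * 2 / 3,
    clr = model$clearance_renal,
    clh = model$clearance_hepatic,
    # portal-drained organs feed the liver inlet
    q_liver_in = unname(qt["liver"] + qt["gut"] + qt["spleen"])
  )
  acat <- acat_params(model$compound, phys)
  p <- c(p, acat)
  p$dissolution <- dissolution
  p$t0_oral <- 0
  p$iv_rate <- 0
  p
}

# State layout of the coupled system
pbpk_state_names <- function() {
  c(paste0("u_", GI_SEGMENTS), paste0("d_", GI_SEGMENTS),
    paste0("abs_", GI_SEGMENTS), "gi_exit",
    paste0("A_", TISSUES), "A_art", "A_ven",
    "elim_renal", "elim_hepatic")
}

# Coupled right-hand side: 9-compartment gut lumen + 11 perfusion-limited
# tissues + arterial/venous blood with the lung in series.  Amounts in
# mg, flows in L/h; tissue outflow blood concentration is
# A_t * Rbp / (V_t * Kp_t).
pbpk_rhs <- function(t, state, p) {
  n <- 9L
  u <- state[1:n]
  d <- state[(n + 1):(2 * n)]
  i0 <- 3 * n + 1  # gi_exit index
  nt <- length(p$tissues)
  A <- state[(i0 + 1):(i0 + nt)]
  names(A) <- p$tissues
  A_art <- state[[i0 + nt + 1]]
  A_ven <- state[[i0 + nt + 2]]

  # --- gut lumen ---
  h <- if (any(u > 0)) dissolution_hazard(p$dissolution, t - p$t0_oral) else 0
  sat <- pmax(0, 1 - (d / p$vol_L) / p$sol_mg_L)
  diss <- h * u * sat
  inflow_u <- c(0, p$kt[-n] * u[-n])
  inflow_d <- c(0, p$kt[-n] * d[-n])
  du <- inflow_u - p$kt * u - diss
  dd <- inflow_d - p$kt * d + diss - p$ka * d
  dabs <- p$ka * d
  dexit <- p$kt[n] * (u[n] + d[n])
  portal_in <- sum(dabs)

  # --- body ---
  c_art <- A_art / p$v_art            # arterial blood conc, mg/L
  c_ven <- A_ven / p$v_ven
  c_out <- A * p$rbp / (p$vt * p$kp)  # tissue outflow blood conc
  dA <- p$qt * (c_art - c_out)

  # lung sits in series: receives total venous return
  dA["lung"] <- p$co * (c_ven - c_out["lung"])

  # liver receives hepatic artery + portal drainage (gut, spleen) +
  # absorbed drug; hepatic elimination acts on inlet plasma
  liver_in_blood <- p$qt[["liver"]] * c_art +
    p$qt[["gut"]] * c_out[["gut"]] + p$qt[["spleen"]] * c_out[["spleen"]] +
    portal_in
  c_liver_inlet_plasma <- liver_in_blood / (p$q_liver_in * p$rbp)
  elim_h <- p$clh * c_liver_inlet_plasma
  dA["liver"] <- liver_in_blood - p$q_liver_in * c_out[["liver"]] - elim_h

  # renal elimination as clearance of renal arterial plasma inflow
  elim_r <- p$clr * c_art / p$rbp
  dA["kidney"] <- dA["kidney"] - elim_r

  dart <- p$co * c_out[["lung"]] - sum(p$qt[setdiff(p$tissues, "lung")]) * c_art
  ven_return <- sum(p$qt[setdiff(p$tissues, c("lung", "liver", "gut", "spleen"))] *
                      c_out[setdiff(p$tissues, c("lung", "liver", "gut", "spleen"))]) +
    p$q_liver_in * c_out[["liver"]]
  dven <- ven_return - p$co * c_ven + p$iv_rate

  list(c(du, dd, dabs, dexit, dA, dart, dven, elim_r, elim_h))
}

#' Simulate a PBPK model under a dosing schedule
#'
#' Integrates the coupled gut/body system with a stiff-capable
#' variable-step solver (rtol 1e-8, atol 1e-10 mg), restarting the
#' integrator at every dose event.  Oral doses enter the stomach
#' (undissolved, or dissolved for immediate-release models) and reach the
#' liver inlet via the portal stream; IV doses enter venous blood as a
#' bolus or a constant-rate infusion.  The reported plasma concentration
#' is venous blood concentration divided by the blood:plasma ratio, in
#' ug/mL.
#'
#' @param model a `pbpk_model`.
#' @param doses a `dose_event` or list of them.
#' @param dissolution a `dissolution_model` (required when any dose is
#'   oral).
#' @param t_grid output times, h (sorted, spanning all dose times).
#' @return an object of class `sim_profile`: a data.frame with columns
#'   `time_h`, `conc_ug_per_mL`, one concentration column per tissue,
#'   `absorbed_mg`, `eliminated_mg`, plus attributes `model` and `doses`.
#' @export
#' @examples
#' ph <- build_adult_physiology(64.19, 1.70, 23.7, "M")
#' mod <- assemble_model(lev_compound(), ph)
#' prof <- simulate_pbpk(mod, dose_event("iv_infusion", 1500, 0, 0.75),
#'                       t_grid = seq(0, 24, 0.25))
#' max(prof$conc_ug_per_mL)
simulate_pbpk <- function(model, doses, dissolution = NULL,
                          t_grid = seq(0, 24, 0.1)) {
  if (inherits(doses, "dose_event")) doses <- list(doses)
  stopifnot(length(doses) >= 1, !is.unsorted(t_grid))
  routes <- vapply(doses, `[[`, "", "route")
  if (any(routes == "oral")) {
    if (is.null(dissolution)) {
      stop("oral doses require a dissolution model", call. = FALSE)
    }
    if (dissolution$form == "tabulated") {
      dissolution <- fit_dissolution(dissolution$table)
    }
  }
  if (is.null(dissolution)) dissolution <- dissolution_model("immediate")
  dose_times <- vapply(doses, `[[`, 0, "time")
  if (min(t_grid) > min(dose_times) || max(t_grid) < max(dose_times)) {
    stop("t_grid must cover all dose times", call. = FALSE)
  }
  p <- pbpk_parms(model, dissolution)
  sn <- pbpk_state_names()
  y <- setNames(numeric(length(sn)), sn)

  # integration legs split at dose starts and infusion ends
  breaks <- sort(unique(c(min(t_grid), max(t_grid), dose_times,
                          unlist(lapply(doses, function(d) {
                            if (d$route == "iv_infusion") d$time + d$duration
                          })))))
  breaks <- breaks[breaks >= min(t_grid) & breaks <= max(t_grid)]
  out_all <- NULL
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    for (dse in doses) {
      if (abs(dse$time - t0) < 1e-9) {
        if (dse$route == "iv_bolus") {
          y["A_ven"] <- y["A_ven"] + dse$amount
        } else if (dse$route == "oral") {
          if (dissolution$form == "immediate") {
            y["d_stomach"] <- y["d_stomach"] + dse$amount
          } else {
            y["u_stomach"] <- y["u_stomach"] + dse$amount
          }
          p$t0_oral <- t0
        }
      }
    }
    p$iv_rate <- 0
    for (dse in doses) {
      if (dse$route == "iv_infusion" &&
          dse$time <= t0 + 1e-9 && t0 + 1e-9 < dse$time + dse$duration) {
        p$iv_rate <- p$iv_rate + dse$amount / dse$duration
      }
    }
    times <- sort(unique(c(t0, t_grid[t_grid >= t0 & t_grid <= t1], t1)))
    if (length(times) < 2) times <- c(t0, t1)
    sol <- deSolve::lsoda(y, times, pbpk_rhs, p, rtol = 1e-8, atol = 1e-10,
                          maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0) {
      stop("PBPK integration failed in [", t0, ", ", t1, "] h; state: ",
           paste(signif(y, 4), collapse = ", "), call. = FALSE)
    }
    y <- sol[nrow(sol), -1]
    if (min(y) < -1e-6) {
      stop("negative state excursion beyond tolerance at t = ", t1,
           call. = FALSE)
    }
    y[y < 0] <- 0
    keep <- sol[, 1] %in% t_grid & !(sol[, 1] %in% if (is.null(out_all)) numeric() else out_all[, 1])
    out_all <- rbind(out_all, sol[keep, , drop = FALSE])
  }
  out <- as.data.frame(out_all)
  names(out)[1] <- "time_h"
  p_v <- model$physiology
  conc <- out$A_ven / (p_v$blood_volume * 2 / 3) / model$compound$blood_plasma_ratio
  prof <- data.frame(time_h = out$time_h, conc_ug_per_mL = conc)
  for (tn in TISSUES) {
    prof[[paste0("conc_", tn)]] <- out[[paste0("A_", tn)]] /
      p_v$tissue_volumes[[tn]]
  }
  prof$absorbed_mg <- rowSums(out[paste0("abs_", GI_SEGMENTS)])
  prof$eliminated_mg <- out$elim_renal + out$elim_hepatic
  prof$gut_lumen_mg <- rowSums(out[paste0("u_", GI_SEGMENTS)]) +
    rowSums(out[paste0("d_", GI_SEGMENTS)])
  prof$gi_exit_mg <- out$gi_exit
  prof$arterial_blood_mg <- out$A_art
  prof$venous_blood_mg <- out$A_ven
  structure(prof, class = c("sim_profile", "data.frame"),
            model = model, doses = doses)
}

#' Total drug amount in the body over a simulated profile
#'
#' Sum of tissue and blood amounts at each output time (mg); useful for
#' conservation checks.
#'
#' @param profile a `sim_profile`.
#' @return numeric vector, mg.
#' @export
body_amount <- function(profile) {
  model <- attr(profile, "model")
  phys <- model$physiology
  amt <- numeric(nrow(profile))
  for (tn in TISSUES) {
    amt <- amt + profile[[paste0("conc_", tn)]] * phys$tissue_volumes[[tn]]
  }
  amt + profile$arterial_blood_mg + profile$venous_blood_mg
}

#' Write / read simulated profiles
#'
#' Delimited text with header `time_h,conc_ug_per_mL[,...]`.
#'
#' @param profile data.frame with at least `time_h` and
#'   `conc_ug_per_mL`.
#' @param path file path.
#' @export
write_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- read.csv(path)
  if (!all(c("time_h", "conc_ug_per_mL") %in% names(tab))) {
    stop("profile file must have header time_h,conc_ug_per_mL",
         call. = FALSE)
  }
  tab
}
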