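#' Per-segment absorption/transit parameters
#'
#' Derives the compartmental absorption and transit rate constants from a
#' compound and a physiology.  Transit is first-order with
#' `kt = 1/transit_time` per segment; absorption from the dissolved pool
#' follows `ka = 2 * Peff_eff / R * ASF` (converted to 1/h), where
#' `Peff_eff = Peff_invitro * permeability_scale` is the calibrated
#' effective human permeability, `R` the segment radius and `ASF` the
#' segment absorption scale factor (zero in the stomach, declining
#' distally).
#'
#' @param compound a [compound_params()].
#' @param phys a `physiology`.
#' @return a list with named per-segment vectors `kt`, `ka`, `vol_L`,
#'   and the luminal solubility `sol_mg_L`.
#' @keywords internal
acat_params <- function(compound, phys) {
  gi <- phys$gi
  if (!identical(gi$name, GI_SEGMENTS)) {
    stop("physiology must carry all 9 GI compartments", call. = FALSE)
  }
  peff <- compound$effective_permeability * compound$permeability_scale
  ka <- 2 * peff * 3600 / gi$radius_cm * compound$asf[gi$name]
  list(kt = setNames(1 / gi$transit_h, gi$name),
       ka = setNames(ka, gi$name),
       vol_L = setNames(gi$volume_L, gi$name),
       sol_mg_L = compound$aqueous_solubility * 1000)
}

# Right-hand side of the gut-only transit/dissolution/absorption system.
# State: u[1..9] undissolved mg, d[1..9] dissolved mg, abs[1..9]
# cumulative absorbed mg, exit (cumulative mg leaving the colon).
# `t0_oral` is the dosing time anchoring the dissolution age.
acat_rhs <- function(t, state, p) {
  n <- 9L
  u <- state[1:n]
  d <- state[(n + 1):(2 * n)]
  h <- dissolution_hazard(p$dissolution, t - p$t0_oral)
  # solubility cap: dissolution stalls as luminal saturation is approached
  sat <- pmax(0, 1 - (d / p$vol_L) / p$sol_mg_L)
  diss <- h * u * sat
  inflow_u <- c(0, p$kt[-n] * u[-n])
  inflow_d <- c(0, p$kt[-n] * d[-n])
  du <- inflow_u - p$kt * u - diss
  dd <- inflow_d - p$kt * d + diss - p$ka * d
  dabs <- p$ka * d
  dexit <- p$kt[n] * (u[n] + d[n])
  list(c(du, dd, dabs, dexit))
}

#' Simulate gastrointestinal dissolution, transit and absorption
#'
#' Integrates the nine-compartment transit system for a single oral dose
#' and reports the total fraction absorbed, the per-segment absorbed
#' fractions and the portal input rate.  Absorption here is a sink (gut
#' lumen to portal blood); the systemic side does not feed back, so this
#' standalone simulation matches the absorption bookkeeping of the fully
#' coupled model.
#'
#' @param compound a [compound_params()].
#' @param phys a `physiology` with GI compartments.
#' @param dose oral dose, mg.
#' @param dissolution a `dissolution_model` (tabulated models are
#'   converted via [fit_dissolution()]).
#' @param t_end simulation horizon, h.
#' @param dt output resolution, h.
#' @return an object of class `absorption_result` with elements
#'   `fa_total`, `fraction_absorbed_by_segment`, `portal_input_rate`
#'   (a function of time, mg/h), and `states` (a data.frame of lumen
#'   amounts over time).
#' @export
#' @examples
#' ph <- build_adult_physiology(64.19, 1.70, 23.7, "M")
#' res <- simulate_gi(lev_compound(), ph, 1500,
#'                    dissolution_model("immediate"), t_end = 24)
#' res$fa_total
simulate_gi <- function(compound, phys, dose, dissolution, t_end = 24,
                        dt = 0.05) {
  stopifnot(dose > 0, t_end > 0)
  if (dissolution$form == "tabulated") {
    dissolution <- fit_dissolution(dissolution$table)
  }
  p <- acat_params(compound, phys)
  p$dissolution <- dissolution
  p$t0_oral <- 0
  y0 <- setNames(numeric(28), c(paste0("u_", GI_SEGMENTS),
                                paste0("d_", GI_SEGMENTS),
                                paste0("abs_", GI_SEGMENTS), "exit"))
  if (dissolution$form == "immediate") {
    y0["d_stomach"] <- dose
  } else {
    y0["u_stomach"] <- dose
  }
  times <- unique(sort(c(seq(0, t_end, by = dt), t_end)))
  out <- deSolve::lsoda(y0, times, acat_rhs, p, rtol = 1e-8, atol = 1e-10)
  if (attr(out, "istate")[1] < 0) {
    stop("ACAT integration failed; final state: ",
         paste(round(out[nrow(out), -1], 4), collapse = ", "), call. = FALSE)
  }
  states <- as.data.frame(out)
  names(states)[1] <- "time_h"
  final <- states[nrow(states), ]
  abs_seg <- unlist(final[paste0("abs_", GI_SEGMENTS)]) / dose
  names(abs_seg) <- GI_SEGMENTS
  d_mat <- as.matrix(states[paste0("d_", GI_SEGMENTS)])
  portal <- as.numeric(d_mat %*% p$ka)
  portal_fun <- approxfun(states$time_h, portal, rule = 2)
  structure(list(
    fa_total = sum(abs_seg),
    fraction_absorbed_by_segment = abs_seg,
    portal_input_rate = portal_fun,
    dose = dose,
    states = states
  ), class = "absorption_result")
}

#' Lumen mass balance of an absorption simulation
#'
#' Returns, per output time, the relative deviation of
#' (lumen + absorbed + exited) from the dose.
#'
#' @param res an `absorption_result`.
#' @return numeric vector of relative errors.
#' @export
acat_mass_balance <- function(res) {
  st <- res$states
  lumen <- rowSums(st[paste0("u_", GI_SEGMENTS)]) +
    rowSums(st[paste0("d_", GI_SEGMENTS)])
  absorbed <- rowSums(st[paste0("abs_", GI_SEGMENTS)])
  (lumen + absorbed + st$exit - res$dose) / res$dose
}

#' @export
print.absorption_result <- function(x, ...) {
  cat(sprintf("<absorption_result> Fa = %.1f%% of %.0f mg\n",
              100 * x$fa_total, x$dose))
  top <- sort(x$fraction_absorbed_by_segment, decreasing = TRUE)[1:3]
  cat("  top segments:",
      paste(sprintf("%s %.1f%%", names(top), 100 * top), collapse = ", "),
      "\n")
  invisible(x)
}
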