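#' Compound parameter set
#'
#' Container for the physicochemical and biopharmaceutic parameters that
#' drive partitioning, absorption and clearance.  All concentrations and
#' amounts in the package are in mg and L, so 1 mg/L is 1 ug/mL.
#'
#' @param molecular_weight g/mol.
#' @param log_p octanol--water log partition coefficient of the neutral
#'   species.
#' @param pka acid dissociation constant (levetiracetam, pKa 16.1, is
#'   un-ionized at any physiological pH, so partitioning uses the neutral
#'   species throughout).
#' @param log_d distribution coefficient at physiological pH.
#' @param blood_plasma_ratio whole-blood to plasma concentration ratio
#'   (Rbp).
#' @param fraction_unbound_plasma fraction unbound in plasma (fup), 0--1.
#' @param aqueous_solubility mg/mL.
#' @param effective_permeability in vitro effective permeability, cm/s.
#' @param permeability_scale one-time in vitro to in vivo permeability
#'   scale: the ACAT model uses
#'   `effective_permeability * permeability_scale` as the human jejunal
#'   permeability.  Calibrated once for the packaged levetiracetam profile
#'   (see the methods vignette) and not refit per run.
#' @param asf named numeric vector of segment absorption scale factors
#'   (one per gut segment, declining distally); `NULL` uses 1 for small
#'   intestine and 0 elsewhere.
#' @param clearance_plasma total plasma clearance, L/h/kg (adult
#'   reference).
#' @param renal_fraction fraction of total clearance that is renal, 0--1.
#' @param vd_reference_range literature steady-state volume of
#'   distribution bracket, L/kg, as `c(low, high)`.
#' @param name compound label.
#'
#' @return an object of class `compound_params`.
#' @export
#' @examples
#' lev <- lev_compound()
#' lev$log_p
compound_params <- function(molecular_weight, log_p, pka, log_d,
                            blood_plasma_ratio, fraction_unbound_plasma,
                            aqueous_solubility, effective_permeability,
                            permeability_scale = 1,
                            asf = NULL,
                            clearance_plasma,
                            renal_fraction,
                            vd_reference_range,
                            name = "compound") {
  num <- c(molecular_weight = molecular_weight,
           blood_plasma_ratio = blood_plasma_ratio,
           fraction_unbound_plasma = fraction_unbound_plasma,
           aqueous_solubility = aqueous_solubility,
           effective_permeability = effective_permeability,
           permeability_scale = permeability_scale,
           clearance_plasma = clearance_plasma,
           renal_fraction = renal_fraction)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all compound parameters must be positive and finite", call. = FALSE)
  }
  if (fraction_unbound_plasma > 1) stop("fup must be <= 1", call. = FALSE)
  if (renal_fraction > 1) stop("renal_fraction must be <= 1", call. = FALSE)
  stopifnot(length(vd_reference_range) == 2)
  if (vd_reference_range[1] >= vd_reference_range[2]) {
    stop("vd_reference_range must be (low, high) with low < high",
         call. = FALSE)
  }
  if (is.null(asf)) {
    asf <- setNames(rep(0, length(GI_SEGMENTS)), GI_SEGMENTS)
    asf[SI_SEGMENTS] <- 1
  }
  if (!all(GI_SEGMENTS %in% names(asf))) {
    stop("asf must be named for all gut segments", call. = FALSE)
  }
  structure(list(
    name = name,
    molecular_weight = molecular_weight,
    log_p = log_p, pka = pka, log_d = log_d,
    blood_plasma_ratio = blood_plasma_ratio,
    fraction_unbound_plasma = fraction_unbound_plasma,
    aqueous_solubility = aqueous_solubility,
    effective_permeability = effective_permeability,
    permeability_scale = permeability_scale,
    asf = asf[GI_SEGMENTS],
    clearance_plasma = clearance_plasma,
    renal_fraction = renal_fraction,
    vd_reference_range = vd_reference_range
  ), class = "compound_params")
}

#' Packaged levetiracetam compound profile
#'
#' Loads the shipped levetiracetam parameter profile (molecular weight
#' 170.21 g/mol, logP 0.8, Rbp 1.11, fup 0.97, in vitro permeability
#' 9.6e-6 cm/s with the one-time in-vivo calibration, adult plasma
#' clearance 0.063 L/h/kg with 66% renal) from the package's YAML
#' configuration.  The printed aqueous solubility carries inconsistent
#' units in its source; the profile reads it as 1.04 g/mL, so dissolution
#' is never solubility-limited.
#'
#' @param path optional path to an alternative profile YAML.
#' @return a `compound_params` object, with the literature clearance
#'   variants attached as attributes `cl_literature_adult` and
#'   `cl_literature_child` (L/h/kg).
#' @export
lev_compound <- function(path = NULL) {
  if (is.null(path)) path <- extdata_path("levetiracetam.yaml")
  cfg <- yaml::read_yaml(path)$compound
  cmp <- compound_params(
    molecular_weight = cfg$molecular_weight,
    log_p = cfg$log_p, pka = cfg$pka, log_d = cfg$log_d,
    blood_plasma_ratio = cfg$blood_plasma_ratio,
    fraction_unbound_plasma = cfg$fraction_unbound_plasma,
    aqueous_solubility = cfg$aqueous_solubility,
    effective_permeability = cfg$effective_permeability,
    permeability_scale = cfg$permeability_scale,
    asf = unlist(cfg$asf),
    clearance_plasma = cfg$clearance_plasma,
    renal_fraction = cfg$renal_fraction,
    vd_reference_range = unlist(cfg$vd_reference_range),
    name = cfg$name
  )
  attr(cmp, "cl_literature_adult") <- cfg$clearance_plasma_literature_adult
  attr(cmp, "cl_literature_child") <- cfg$clearance_plasma_literature_child
  cmp
}

#' @export
print.compound_params <- function(x, ...) {
  cat("<compound_params>", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol, logP %.2f, pKa %.1f, Rbp %.2f, fup %.2f\n",
              x$molecular_weight, x$log_p, x$pka,
              x$blood_plasma_ratio, x$fraction_unbound_plasma))
  cat(sprintf("  Peff %.3g cm/s (x%.1f in vivo), CL %.4f L/h/kg (%.0f%% renal)\n",
              x$effective_permeability, x$permeability_scale,
              x$clearance_plasma, 100 * x$renal_fraction))
  invisible(x)
}
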