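#' Tissue composition table
#'
#' Fractional water, neutral-lipid and phospholipid content per tissue
#' (plus plasma), from standard human composition compilations.  For
#' pediatric subjects the tissue water fractions are multiplied by the
#' physiology's body-water uplift (capped so fractions still sum below 1).
#'
#' @param water_uplift multiplicative uplift applied to tissue (not
#'   plasma) water fractions; 1 for adults.
#' @param path optional path to an alternative delimited composition
#'   table with columns `tissue`, `f_water`, `f_neutral_lipid`,
#'   `f_phospholipid`.
#' @return a data.frame with one row per tissue and a `plasma` row.
#' @export
tissue_composition <- function(water_uplift = 1, path = NULL) {
  if (is.null(path)) path <- extdata_path("tissue_composition.tsv")
  comp <- read.delim(path)
  need <- c("tissue", "f_water", "f_neutral_lipid", "f_phospholipid")
  if (!all(need %in% names(comp))) {
    stop("composition table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  idx <- comp$tissue != "plasma"
  comp$f_water[idx] <- pmin(comp$f_water[idx] * water_uplift,
                            1 - comp$f_neutral_lipid[idx] -
                              comp$f_phospholipid[idx] - 0.01)
  comp
}

# vegetable oil:water partition coefficient from logP (Poulin-Theil
# correlation); used for the lipid phase of all tissues by default.
d_vow <- function(log_p) 10^(1.115 * log_p - 1.35)

#' Berezhkovskiy tissue-to-plasma partition coefficients
#'
#' Computes perfusion-limited partition coefficients Kp from tissue
#' composition for a neutral (un-ionized) compound:
#'
#' \deqn{Kp_t = \frac{P (f_{nl,t} + 0.3 f_{ph,t}) + (f_{w,t} + 0.7 f_{ph,t})}
#'              {P (f_{nl,p} + 0.3 f_{ph,p}) + (f_{w,p} + 0.7 f_{ph,p})}
#'       \cdot \frac{fu_p}{fu_t}}
#'
#' with the Berezhkovskiy unbound-tissue-fraction correction
#' \eqn{fu_t = 1 / (1 + 0.5 (1 - fu_p)/fu_p)}.  The lipid-phase partition
#' coefficient `P` defaults to the vegetable-oil:water coefficient
#' (log D_vo:w = 1.115 logP - 1.35) for every tissue, the appropriate
#' single-lipid-phase treatment for a hydrophilic compound; `lipid =
#' "pow"` uses octanol:water for lean tissues (vegetable oil for adipose)
#' instead.  Levetiracetam (pKa 16.1) is un-ionized at all physiological
#' pH, so no ionic terms are needed.
#'
#' @param compound a [compound_params()].
#' @param comp a composition table from [tissue_composition()].
#' @param tissues tissues to compute (default: all canonical tissues).
#' @param lipid lipid-phase partition convention, `"dvow"` (default) or
#'   `"pow"`.
#' @param use_logd use logD instead of logP in the lipid correlation.
#' @return an object of class `kp_set`: a named numeric vector of Kp > 0.
#' @export
#' @examples
#' kps <- kp_berezhkovskiy(lev_compound(), tissue_composition())
#' kps["adipose"] < kps["muscle"]   # adipose lowest for hydrophilic LEV
kp_berezhkovskiy <- function(compound, comp = tissue_composition(),
                             tissues = TISSUES,
                             lipid = c("dvow", "pow"),
                             use_logd = FALSE) {
  lipid <- match.arg(lipid)
  lp <- if (use_logd) compound$log_d else compound$log_p
  fup <- compound$fraction_unbound_plasma
  fut <- 1 / (1 + 0.5 * (1 - fup) / fup)
  pl <- comp[comp$tissue == "plasma", ]
  if (nrow(pl) != 1) stop("composition table must include plasma", call. = FALSE)
  missing <- setdiff(tissues, comp$tissue)
  if (length(missing)) {
    stop("no tissue composition for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  p_adipose <- d_vow(lp)
  kp <- vapply(tissues, function(tn) {
    tc <- comp[comp$tissue == tn, ]
    p_t <- switch(lipid,
                  dvow = p_adipose,
                  pow = if (tn == "adipose") p_adipose else 10^lp)
    num <- p_t * (tc$f_neutral_lipid + 0.3 * tc$f_phospholipid) +
      (tc$f_water + 0.7 * tc$f_phospholipid)
    den <- p_t * (pl$f_neutral_lipid + 0.3 * pl$f_phospholipid) +
      (pl$f_water + 0.7 * pl$f_phospholipid)
    num / den * fup / fut
  }, numeric(1))
  if (any(kp <= 0)) stop("computed Kp must be positive", call. = FALSE)
  structure(kp, class = "kp_set")
}

#' Steady-state volume of distribution from partition coefficients
#'
#' \deqn{V_{ss} = (V_{plasma} + \sum_t Kp_t V_t) / BW} in L/kg.
#'
#' @param kps a `kp_set` covering every tissue of the physiology.
#' @param phys a `physiology`.
#' @return Vss in L/kg.
#' @export
#' @examples
#' ph <- build_adult_physiology(64.19, 1.70, 23.7, "M")
#' kp <- kp_berezhkovskiy(lev_compound(),
#'                        tissue_composition(ph$water_uplift))
#' vss_from_kp(kp, ph)  # ~0.6 L/kg, inside the 0.5-0.7 literature range
vss_from_kp <- function(kps, phys) {
  tiss <- names(phys$tissue_volumes)
  missing <- setdiff(tiss, names(kps))
  if (length(missing)) {
    stop("missing Kp for tissue(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unname((phys$plasma_volume +
            sum(unclass(kps)[tiss] * phys$tissue_volumes[tiss])) /
           phys$body_weight)
}

#' @export
print.kp_set <- function(x, ...) {
  cat("<kp_set> tissue:plasma partition coefficients\n")
  print(round(unclass(x), 3))
  invisible(x)
}
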