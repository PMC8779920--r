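#' Reference 70-kg physiology tables
#'
#' Returns the packaged scaling anchor: tissue volumes (L) and regional
#' blood flow fractions for a 70-kg reference human, the reference cardiac
#' output (350 L/h), blood volume per kg (0.07 L/kg) and the plasma
#' fraction of blood (0.55).  The liver flow fraction is the hepatic
#' artery only; total liver inflow additionally receives the portal
#' drainage of gut and spleen.
#'
#' @return a list with elements `volumes`, `flow_fractions`,
#'   `cardiac_output`, `blood_per_kg`, `plasma_fraction`, `weight`.
#' @export
reference_physiology <- function() {
  tab <- read.delim(extdata_path("reference_physiology_70kg.tsv"))
  vols <- setNames(tab$volume_L, tab$tissue)[TISSUES]
  flows <- setNames(tab$flow_fraction, tab$tissue)[TISSUES]
  list(volumes = vols, flow_fractions = flows,
       cardiac_output = 350, blood_per_kg = 0.07,
       plasma_fraction = 0.55, weight = 70)
}

#' Default fasted gastrointestinal compartments
#'
#' Nine serial gut compartments (stomach, duodenum, two jejunal, three
#' ileal, caecum, colon) with fasted-state radii, transit times, luminal
#' volumes and pH.  Radii scale with body size as (BW/70)^(1/3) and
#' luminal volumes linearly with body weight.
#'
#' @param weight body weight in kg used for size scaling.
#' @return a data.frame with one row per segment in canonical order.
#' @export
default_gi <- function(weight = 70) {
  gi <- read.delim(extdata_path("gi_defaults.tsv"))
  stopifnot(identical(gi$name, GI_SEGMENTS))
  gi$radius_cm <- gi$radius_cm * (weight / 70)^(1 / 3)
  gi$volume_L <- gi$volume_L * (weight / 70)
  gi
}

validate_physiology <- function(phys) {
  stopifnot(all(TISSUES %in% names(phys$tissue_volumes)),
            all(TISSUES %in% names(phys$tissue_blood_flows)))
  if (any(phys$tissue_volumes <= 0) || any(phys$tissue_blood_flows <= 0)) {
    stop("tissue volumes and flows must be positive", call. = FALSE)
  }
  flows <- phys$tissue_blood_flows
  if (abs(sum(flows[setdiff(TISSUES, "lung")]) - phys$cardiac_output) >
      1e-6 * phys$cardiac_output) {
    stop("tissue blood flows (excluding lung) must sum to cardiac output",
         call. = FALSE)
  }
  if (!identical(phys$gi$name, GI_SEGMENTS)) {
    stop("physiology must carry all 9 GI compartments in canonical order",
         call. = FALSE)
  }
  invisible(phys)
}

new_physiology <- function(age, sex, weight, height, population,
                           water_uplift = 1) {
  ref <- reference_physiology()
  vols <- ref$volumes * (weight / ref$weight)
  # sex affects only the muscle/adipose split; male is the reference
  if (identical(sex, "F")) {
    vols["muscle"] <- vols["muscle"] * 0.9
    vols["adipose"] <- vols["adipose"] * 1.1
  }
  co <- ref$cardiac_output * (weight / ref$weight)^0.75
  flows <- ref$flow_fractions * co
  flows["lung"] <- co
  blood <- ref$blood_per_kg * weight
  phys <- structure(list(
    age = age, sex = sex, body_weight = weight, height = height,
    bmi = weight / height^2,
    population = population,
    tissue_volumes = vols,
    tissue_blood_flows = flows,
    cardiac_output = co,
    blood_volume = blood,
    plasma_volume = ref$plasma_fraction * blood,
    water_uplift = water_uplift,
    gi = default_gi(weight)
  ), class = "physiology")
  validate_physiology(phys)
}

#' Build an adult physiology
#'
#' Scales the packaged 70-kg reference anatomy to an adult subject:
#' tissue volumes linearly with body weight, regional blood flows and
#' cardiac output with weight^0.75, blood volume as 0.07 L/kg.
#'
#' @param weight body weight, kg.
#' @param height height, m.
#' @param age age, years (>= 18).
#' @param sex "M" or "F"; sex shifts only the muscle/adipose split by
#'   +/-10%.
#' @return a `physiology` object.
#' @export
#' @examples
#' ph <- build_adult_physiology(64.19, 1.70, 23.7, "M")
#' ph$body_weight
build_adult_physiology <- function(weight, height, age, sex = "M") {
  if (!is.finite(weight) || weight <= 0 || !is.finite(height) || height <= 0) {
    stop("weight and height must be positive", call. = FALSE)
  }
  if (age < 18) stop("adult physiology requires age >= 18", call. = FALSE)
  sex <- match.arg(sex, c("M", "F"))
  new_physiology(age, sex, weight, height, population = "adult")
}

# Fraction of body weight that is water, interpolated from 0.75 at birth
# to the adult 0.60 by age 12.
body_water_fraction <- function(age) {
  0.60 + 0.15 * pmax(0, (12 - pmin(age, 12)) / 12)
}

#' Build a pediatric physiology
#'
#' Height is derived from weight and BMI as sqrt(weight/BMI); tissue
#' volumes scale linearly with weight and flows with weight^0.75 from the
#' 70-kg reference.  For children under 12 the tissue water fractions used
#' in partitioning are uplifted by the ratio of the age-interpolated body
#' water fraction (0.75 at birth to 0.60 at age 12) to the adult value.
#'
#' @param age years; the model spans 0.5--15 y (outside this a warning is
#'   issued and the scaling extrapolated).
#' @param weight kg.
#' @param bmi kg/m^2 (default 16 if not known).
#' @param sex "M" or "F".
#' @return a `physiology` object.
#' @export
#' @examples
#' ch <- build_child_physiology(6, 22.26, 16.07)
#' ch$height  # ~1.177 m
build_child_physiology <- function(age, weight, bmi = 16, sex = "M") {
  if (!is.finite(weight) || weight <= 0 || !is.finite(bmi) || bmi <= 0) {
    stop("weight and BMI must be positive", call. = FALSE)
  }
  if (age < 0.5 || age > 15) {
    warning("age outside the 0.5-15 y pediatric span; extrapolating",
            call. = FALSE)
  }
  sex <- match.arg(sex, c("M", "F"))
  height <- sqrt(weight / bmi)
  uplift <- body_water_fraction(age) / body_water_fraction(18)
  new_physiology(age, sex, weight, height, population = "child",
                 water_uplift = uplift)
}

#' Virtual population specification
#'
#' @param n number of subjects.
#' @param age_range years, `c(low, high)`.
#' @param sex_ratio_male fraction of males in 0--1.
#' @param weight_range kg, `c(low, high)`.
#' @param bmi_range kg/m^2, `c(low, high)`.
#' @param seed integer seed making the sample reproducible.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(n = 24, age_range = c(25, 50),
                            sex_ratio_male = 0.5,
                            weight_range = c(54.33, 67.91),
                            bmi_range = c(21.3, 23.88),
                            seed = 1L) {
  stopifnot(n >= 0, length(age_range) == 2, length(weight_range) == 2,
            length(bmi_range) == 2)
  if (sex_ratio_male < 0 || sex_ratio_male > 1) {
    stop("sex_ratio_male must be in [0, 1]", call. = FALSE)
  }
  if (diff(age_range) < 0 || diff(weight_range) < 0 || diff(bmi_range) < 0) {
    stop("ranges must be non-empty (low <= high)", call. = FALSE)
  }
  structure(list(n = as.integer(n), age_range = age_range,
                 sex_ratio_male = sex_ratio_male,
                 weight_range = weight_range, bmi_range = bmi_range,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a virtual adult population
#'
#' Draws `n` subjects with age, weight and BMI uniform within the
#' specification ranges (the source study reports only ranges) and a male
#' count of `round(n * sex_ratio_male)`.  Identical seeds give identical
#' populations; the caller's RNG state is preserved.
#'
#' @param spec a [population_spec()].
#' @return a list of `physiology` objects.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  if (n == 0) return(list())
  with_seed(spec$seed, {
    n_male <- round(n * spec$sex_ratio_male)
    sexes <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    ages <- runif(n, spec$age_range[1], spec$age_range[2])
    weights <- runif(n, spec$weight_range[1], spec$weight_range[2])
    bmis <- runif(n, spec$bmi_range[1], spec$bmi_range[2])
    lapply(seq_len(n), function(i) {
      build_adult_physiology(weight = weights[i],
                             height = sqrt(weights[i] / bmis[i]),
                             age = ages[i], sex = sexes[i])
    })
  })
}

#' @export
print.physiology <- function(x, ...) {
  cat(sprintf("<physiology> %s, %s, %.1f y, %.2f kg, %.3f m (BMI %.1f)\n",
              x$population, x$sex, x$age, x$body_weight, x$height, x$bmi))
  cat(sprintf("  cardiac output %.1f L/h, blood %.2f L (plasma %.2f L)\n",
              x$cardiac_output, x$blood_volume, x$plasma_volume))
  invisible(x)
}
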