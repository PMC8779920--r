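#' Bioequivalence dataset
#'
#' Per-subject PK parameters for a parallel or 2x2 crossover comparison
#' of a test vs a reference formulation.
#'
#' @param data data.frame with columns `subject`, `formulation`
#'   (`"test"`/`"reference"`), the parameter columns (any of `cmax`,
#'   `auc0t`, `auc0inf`), and for crossover designs `sequence`
#'   (`"TR"`/`"RT"`) and `period` (1/2).
#' @param design `"parallel"` or `"crossover_2x2"`.
#' @return an object of class `be_dataset`.
#' @export
be_dataset <- function(data, design = c("crossover_2x2", "parallel")) {
  design <- match.arg(design)
  stopifnot(all(c("subject", "formulation") %in% names(data)))
  params <- intersect(c("cmax", "auc0t", "auc0inf"), names(data))
  if (!length(params)) {
    stop("dataset needs at least one of cmax, auc0t, auc0inf", call. = FALSE)
  }
  if (!all(data$formulation %in% c("test", "reference"))) {
    stop("formulation must be 'test' or 'reference'", call. = FALSE)
  }
  for (p in params) {
    if (any(!is.finite(data[[p]]) | data[[p]] <= 0)) {
      stop("parameter values must be positive (log-transformable): ", p,
           call. = FALSE)
    }
  }
  if (design == "crossover_2x2") {
    if (!all(c("sequence", "period") %in% names(data))) {
      stop("crossover datasets need sequence and period columns",
           call. = FALSE)
    }
    counts <- table(data$subject)
    if (any(counts != 2)) {
      stop("each crossover subject must have exactly one test and one ",
           "reference record", call. = FALSE)
    }
  }
  structure(list(data = data, design = design, parameters = params),
            class = "be_dataset")
}

#' Two one-sided tests (TOST) bioequivalence analysis
#'
#' Log-transforms each PK parameter and computes the geometric mean ratio
#' (test/reference) with its 90% confidence interval (for `alpha` 0.05).
#' Parallel designs use the two-sample interval with pooled variance;
#' 2x2 crossover designs use the period-difference method (per-subject
#' half period differences, compared across sequences), which removes
#' period effects and estimates the within-subject residual.  The
#' formulation-effect ANOVA p-value is reported alongside.  The design is
#' declared bioequivalent for a parameter when the CI lies entirely
#' within the limits.
#'
#' @param dataset a [be_dataset()].
#' @param alpha one-sided significance level (CI coverage `1 - 2 alpha`).
#' @param limits bioequivalence limits in percent, default `c(80, 125)`.
#' @return an object of class `be_report`: data.frame with one row per
#'   parameter (`gmr`, `lower`, `upper` in percent, `pass`, `p_anova`,
#'   `df`).
#' @export
tost_be <- function(dataset, alpha = 0.05, limits = c(80, 125)) {
  stopifnot(inherits(dataset, "be_dataset"), length(limits) == 2)
  df <- dataset$data
  rows <- lapply(dataset$parameters, function(p) {
    y <- log(df[[p]])
    if (dataset$design == "parallel") {
      yt <- y[df$formulation == "test"]
      yr <- y[df$formulation == "reference"]
      n1 <- length(yt); n2 <- length(yr)
      if (n1 < 2 || n2 < 2) stop("need >= 2 subjects per arm", call. = FALSE)
      est <- mean(yt) - mean(yr)
      s2 <- ((n1 - 1) * var(yt) + (n2 - 1) * var(yr)) / (n1 + n2 - 2)
      se <- sqrt(s2 * (1 / n1 + 1 / n2))
      dfree <- n1 + n2 - 2
    } else {
      # period-difference method for the 2x2 crossover
      wide <- merge(
        df[df$period == 1, c("subject", "sequence", p)],
        df[df$period == 2, c("subject", p)],
        by = "subject", suffixes = c("_p1", "_p2"))
      d <- (log(wide[[paste0(p, "_p1")]]) - log(wide[[paste0(p, "_p2")]])) / 2
      dtr <- d[wide$sequence == "TR"]
      drt <- d[wide$sequence == "RT"]
      n1 <- length(dtr); n2 <- length(drt)
      if (n1 < 2 || n2 < 2) {
        stop("need >= 2 subjects per sequence", call. = FALSE)
      }
      est <- mean(dtr) - mean(drt)
      s2 <- ((n1 - 1) * var(dtr) + (n2 - 1) * var(drt)) / (n1 + n2 - 2)
      se <- sqrt(s2 * (1 / n1 + 1 / n2))
      dfree <- n1 + n2 - 2
    }
    if (se < 1e-12) {
      warning("zero variance for ", p,
              "; reporting degenerate CI at the exact ratio", call. = FALSE)
      se <- 0
    }
    tcrit <- qt(1 - alpha, dfree)
    lower <- exp(est - tcrit * se) * 100
    upper <- exp(est + tcrit * se) * 100
    p_anova <- if (se > 0) 2 * pt(-abs(est / se), dfree) else 0
    data.frame(parameter = p, gmr = exp(est) * 100,
               lower = lower, upper = upper,
               limit_lower = limits[1], limit_upper = limits[2],
               pass = lower >= limits[1] & upper <= limits[2],
               p_anova = p_anova, df = dfree)
  })
  structure(do.call(rbind, rows),
            class = c("be_report", "data.frame"),
            design = dataset$design, alpha = alpha, limits = limits)
}

#' @export
print.be_report <- function(x, ...) {
  cat(sprintf("<be_report> %s design, %.0f%% CI, limits %.0f-%.0f%%\n",
              attr(x, "design"), 100 * (1 - 2 * attr(x, "alpha")),
              attr(x, "limits")[1], attr(x, "limits")[2]))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-8s GMR %6.2f%%  CI [%6.2f, %6.2f]  %s\n",
                x$parameter[i], x$gmr[i], x$lower[i], x$upper[i],
                if (x$pass[i]) "PASS" else "FAIL"))
  }
  invisible(x)
}

#' Virtual crossover bioequivalence trial
#'
#' Simulates every virtual subject under both the test and the reference
#' dissolution profile (same physiology in both arms, as in a crossover),
#' runs non-compartmental analysis on each simulated profile and applies
#' the crossover TOST to Cmax, AUC0-t and AUC0-inf.  Between-subject
#' variability arises solely from the sampled physiologies; the
#' comparison is deterministic given the population.  An optional
#' lognormal residual (`residual_cv`) is available for power studies.
#'
#' @param population list of `physiology` objects (see
#'   [sample_population()]).
#' @param compound a [compound_params()].
#' @param test_dissolution,ref_dissolution `dissolution_model`s for the
#'   two formulations.
#' @param dose oral dose, mg (default 1000).
#' @param limits bioequivalence limits in percent; the virtual-trial
#'   acceptance band is `c(85, 120)`.
#' @param t_end simulation horizon, h.
#' @param dt output resolution, h.
#' @param residual_cv lognormal residual CV applied to the NCA parameters
#'   (default 0 = none); requires `seed`.
#' @param seed seed for the optional residual.
#' @return a `be_report` with attributes `nca` (per-subject parameter
#'   table) and `tmax` (median Tmax per arm).
#' @export
virtual_be_trial <- function(population, compound, test_dissolution,
                             ref_dissolution, dose = 1000,
                             limits = c(85, 120), t_end = 36, dt = 0.1,
                             residual_cv = 0, seed = NULL) {
  stopifnot(length(population) >= 4)
  grid <- seq(0, t_end, dt)
  recs <- vector("list", 2 * length(population))
  for (i in seq_along(population)) {
    phys <- population[[i]]
    model <- assemble_model(compound, phys)
    for (arm in c("test", "reference")) {
      dis <- if (arm == "test") test_dissolution else ref_dissolution
      prof <- tryCatch(
        simulate_pbpk(model, dose_event("oral", dose), dis, grid),
        error = function(e) {
          stop("virtual BE simulation failed for subject ", i, " (", arm,
               "): ", conditionMessage(e), call. = FALSE)
        })
      nca <- run_nca(prof, dose)
      recs[[2 * (i - 1) + (arm == "reference") + 1]] <- data.frame(
        subject = i, formulation = arm,
        sequence = if (i %% 2 == 1) "TR" else "RT",
        period = if (i %% 2 == 1) {
          if (arm == "test") 1 else 2
        } else {
          if (arm == "test") 2 else 1
        },
        cmax = nca$c_max, auc0t = nca$auc_0_t, auc0inf = nca$auc_0_inf,
        tmax = nca$t_max)
    }
  }
  tab <- do.call(rbind, recs)
  if (residual_cv > 0) {
    tab2 <- with_seed(seed, {
      sdlog <- sqrt(log(1 + residual_cv^2))
      for (p in c("cmax", "auc0t", "auc0inf")) {
        tab[[p]] <- tab[[p]] * exp(rnorm(nrow(tab), -sdlog^2 / 2, sdlog))
      }
      tab
    })
    tab <- tab2
  }
  ds <- be_dataset(tab, "crossover_2x2")
  rep <- tost_be(ds, limits = limits)
  attr(rep, "nca") <- tab
  attr(rep, "tmax") <- tapply(tab$tmax, tab$formulation, median)
  rep
}

#' Read / write bioequivalence datasets
#'
#' Delimited text `subject,sequence,period,formulation,cmax,auc0t,auc0inf`.
#'
#' @param path file path.
#' @param design dataset design.
#' @return a `be_dataset`.
#' @export
read_be_dataset <- function(path, design = "crossover_2x2") {
  be_dataset(read.csv(path), design)
}

#' @rdname read_be_dataset
#' @param dataset a `be_dataset` to write.
#' @export
write_be_dataset <- function(dataset, path) {
  write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
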