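#' Dissolution model
#'
#' In vitro release is represented by a Weibull cumulative release
#' \deqn{F(t) = f_{max} (1 - \exp(-(t/t_d)^b))} with `t` in minutes, by an
#' immediate-release flag (`F(t) = 1` for `t > 0`), or by a tabulated
#' profile (converted to a Weibull fit when used inside the transit
#' model).
#'
#' @param form `"weibull"`, `"immediate"` or `"tabulated"`.
#' @param f_max maximal released fraction (0--1).
#' @param td Weibull time scale, minutes.
#' @param b Weibull shape.
#' @param table data.frame `time_min`, `percent_dissolved` for
#'   `form = "tabulated"`.
#' @return an object of class `dissolution_model`.
#' @export
dissolution_model <- function(form = c("weibull", "immediate", "tabulated"),
                              f_max = 1, td = NULL, b = NULL, table = NULL) {
  form <- match.arg(form)
  if (form == "weibull") {
    stopifnot(is.numeric(td), td > 0, is.numeric(b), b > 0,
              f_max > 0, f_max <= 1)
  }
  if (form == "tabulated") {
    stopifnot(is.data.frame(table),
              all(c("time_min", "percent_dissolved") %in% names(table)))
    frac <- table$percent_dissolved / 100
    if (any(frac < -1e-9) || any(frac > 1 + 1e-9)) {
      stop("tabulated percent dissolved must lie in [0, 100]", call. = FALSE)
    }
  }
  structure(list(form = form, f_max = f_max, td = td, b = b, table = table),
            class = "dissolution_model")
}

#' Cumulative dissolved fraction
#'
#' @param model a `dissolution_model`.
#' @param t_min time since dosing, minutes.
#' @return fraction dissolved in `[0, 1]`.
#' @export
dissolution_fraction <- function(model, t_min) {
  switch(model$form,
         immediate = as.numeric(t_min > 0),
         weibull = model$f_max * (1 - exp(-(pmax(t_min, 0) / model$td)^model$b)),
         tabulated = {
           tab <- model$table
           approx(c(0, tab$time_min), c(0, tab$percent_dissolved / 100),
                  xout = pmax(t_min, 0), rule = 2)$y
         })
}

# Weibull release hazard (1/h) at time t_h (hours) since dosing; this is
# the fractional dissolution rate applied to the undissolved pool in the
# transit model.  Capped to keep the ODE system non-stiff; the cap
# corresponds to a dissolution half-time of ~2 s and is never binding for
# realistic profiles.
dissolution_hazard <- function(model, t_h, cap = 1200) {
  if (model$form == "immediate") return(cap)
  if (model$form == "tabulated") {
    stop("tabulated dissolution must be converted with fit_dissolution() ",
         "before simulation", call. = FALSE)
  }
  t_min <- pmax(t_h * 60, 1e-6)
  h <- (model$b / model$td) * (t_min / model$td)^(model$b - 1)  # 1/min
  min(h * 60, cap)
}

#' Fit a Weibull dissolution model to a tabulated profile
#'
#' Least-squares Weibull fit (via Levenberg-Marquardt) of cumulative
#' percent dissolved against time.  Profiles decreasing by more than 2
#' percentage points between successive times are rejected; if the fitted
#' curve misses any input point by more than 5 percentage points a
#' fit-quality warning is raised.
#'
#' @param profile data.frame with columns `time_min` and
#'   `percent_dissolved` (at least 3 points).
#' @return a Weibull `dissolution_model` with fitted `td`, `b`, `f_max`.
#' @export
#' @examples
#' fit <- fit_dissolution(data.frame(time_min = c(2.5, 5, 10),
#'                                   percent_dissolved = c(87, 100, 100)))
#' dissolution_fraction(fit, 2.5) >= 0.85
fit_dissolution <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("time_min", "percent_dissolved") %in% names(profile)))
  profile <- profile[order(profile$time_min), ]
  if (nrow(profile) < 3) stop("need at least 3 dissolution points", call. = FALSE)
  y <- profile$percent_dissolved
  if (y[length(y)] < y[1]) {
    stop("invalid dissolution profile: final point below first", call. = FALSE)
  }
  if (any(diff(y) < -2)) {
    stop("invalid dissolution profile: non-monotone beyond tolerance",
         call. = FALSE)
  }
  t <- profile$time_min
  frac <- y / 100
  fmax0 <- min(max(frac), 1)
  # initial td from the first time reaching ~63% of fmax
  i63 <- which(frac >= 0.63 * fmax0)[1]
  td0 <- if (is.na(i63)) max(t) else max(t[i63], 1e-3)
  fit <- try(minpack.lm::nlsLM(
    frac ~ fmax * (1 - exp(-(t / td)^b)),
    start = list(fmax = fmax0, td = td0, b = 1),
    lower = c(fmax = 1e-3, td = 1e-4, b = 0.05),
    upper = c(fmax = 1, td = 1e4, b = 10),
    control = nls.control(maxiter = 200)), silent = TRUE)
  cf <- if (inherits(fit, "try-error")) NULL else
    c(coef(fit)["fmax"], coef(fit)["td"], coef(fit)["b"])
  if (is.null(cf)) {
    # nearly saturated profiles leave too few informative points for the
    # full 3-parameter fit; fix fmax, then b if needed
    fit2 <- try(minpack.lm::nlsLM(
      frac ~ fmax0 * (1 - exp(-(t / td)^b)),
      start = list(td = td0, b = 1),
      lower = c(td = 1e-4, b = 0.05), upper = c(td = 1e4, b = 10),
      control = nls.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit2, "try-error")) {
      cf <- c(fmax = fmax0, coef(fit2)["td"], coef(fit2)["b"])
    } else {
      sse <- function(td) sum((frac - fmax0 * (1 - exp(-t / td)))^2)
      td_hat <- optimize(sse, c(1e-4, max(t) * 10))$minimum
      cf <- c(fmax = fmax0, td = td_hat, b = 1)
    }
  }
  model <- dissolution_model("weibull", f_max = unname(cf["fmax"]),
                             td = unname(cf["td"]), b = unname(cf["b"]))
  resid <- 100 * dissolution_fraction(model, t) - y
  if (max(abs(resid)) > 5) {
    warning(sprintf("dissolution fit misses inputs by up to %.1f%%",
                    max(abs(resid))), call. = FALSE)
  }
  model
}

#' Read / write dissolution profiles
#'
#' Delimited text with header `time_min,percent_dissolved`.
#'
#' @param path file path.
#' @return `read_dissolution`: a data.frame.
#' @export
read_dissolution <- function(path) {
  tab <- read.csv(path)
  if (!all(c("time_min", "percent_dissolved") %in% names(tab))) {
    stop("dissolution file must have header time_min,percent_dissolved",
         call. = FALSE)
  }
  tab
}

#' @rdname read_dissolution
#' @param profile data.frame to write.
#' @export
write_dissolution <- function(profile, path) {
  write.csv(profile[, c("time_min", "percent_dissolved")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Packaged fast (instant-dissolving tablet) dissolution profile
#'
#' The shipped pH 1.2 profile of the rapidly dissolving 1000 mg tablets:
#' more than 85% released at 2.5 min and complete release at 5 min.
#'
#' @return a data.frame `time_min`, `percent_dissolved`.
#' @export
lev_fast_dissolution <- function() {
  read_dissolution(extdata_path("dissolution_fast_1000mg.csv"))
}
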