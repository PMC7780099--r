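# Gas constant, J mol^-1 K^-1.
RGAS <- 8.314

# 30-minute half-loss rate constant, s^-1: k such that activity halves over
# a 30-min incubation.
K_HALF_30MIN <- log(2) / 1800

#' Thermal-inactivation series
#'
#' Container for first-order inactivation rate constants measured at a set of
#' incubation temperatures.
#'
#' @param temperature_C incubation temperatures, degrees Celsius.
#' @param k inactivation rate constants, s^-1 (must be positive).
#' @param label optional text label.
#' @return An `InactivationSeries` data.frame with columns `temperature_C`,
#'   `temperature_K`, `k`.
#' @export
inactivation_series <- function(temperature_C, k, label = "") {
  stopifnot(length(temperature_C) == length(k))
  temperature_K <- temperature_C + 273.15
  if (any(temperature_K <= 0)) stop("inactivation_series: temperatures must be above 0 K", call. = FALSE)
  if (anyDuplicated(temperature_C)) stop("inactivation_series: temperatures must be distinct", call. = FALSE)
  if (any(k <= 0)) stop("inactivation_series: rate constants must be positive", call. = FALSE)
  structure(data.frame(temperature_C = temperature_C,
                       temperature_K = temperature_K, k = k),
            label = label, class = c("InactivationSeries", "data.frame"))
}

#' Arrhenius fit of an inactivation series
#'
#' Ordinary least squares of ln k on 1/T (the Arrhenius plot): the activation
#' energy is minus the slope times the gas constant, and the intercept is the
#' log pre-exponential factor.
#'
#' @param series an [inactivation_series()] (or a data.frame with
#'   `temperature_C` and `k` columns), at least 3 points.
#' @return An `ArrheniusFit`: list with `ea_kj` (activation energy,
#'   kJ mol^-1), `lnA` (k in s^-1), `r_squared`, `n_points`.
#' @export
fit_arrhenius <- function(series) {
  if (!inherits(series, "InactivationSeries")) {
    series <- inactivation_series(series$temperature_C, series$k)
  }
  if (nrow(series) < 3L) stop("fit_arrhenius: need at least 3 points", call. = FALSE)
  x <- 1 / series$temperature_K
  y <- log(series$k)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  # suppress lm's note on zero-residual (noise-free) series
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(ea_kj = -slope * RGAS / 1000,
                 lnA = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_points = nrow(series)),
            class = "ArrheniusFit")
}

#' @export
print.ArrheniusFit <- function(x, ...) {
  cat(sprintf("ArrheniusFit: Ea %.2f kJ/mol, lnA %.3f, R^2 %.4f (n = %d)\n",
              x$ea_kj, x$lnA, x$r_squared, x$n_points))
  invisible(x)
}

#' T50% from an Arrhenius fit
#'
#' The temperature at which activity is halved over a 30-minute incubation,
#' obtained by inverting the Arrhenius law at the 30-min half-loss rate
#' constant k = ln 2 / 1800 s^-1:
#' `T50 = (Ea * 1000) / (R * (lnA - ln k))`, converted to Celsius.
#'
#' @param fit an `ArrheniusFit`.
#' @param k_half half-loss rate constant, s^-1 (default ln 2 / 1800).
#' @return A `T50Result`: list with `t50_C`, `k_half`.
#' @export
t50_from_fit <- function(fit, k_half = K_HALF_30MIN) {
  stopifnot(inherits(fit, "ArrheniusFit"), k_half > 0)
  if (fit$lnA <= log(k_half)) {
    stop("t50_from_fit: no finite positive-temperature solution (lnA <= ln k_half)",
         call. = FALSE)
  }
  t_k <- (fit$ea_kj * 1000) / (RGAS * (fit$lnA - log(k_half)))
  structure(list(t50_C = t_k - 273.15, k_half = k_half), class = "T50Result")
}

#' Two-state melting curve container
#'
#' @param temperature_C strictly increasing temperatures, Celsius.
#' @param signal spectroscopic signal (e.g. ellipticity at 222 nm), arbitrary
#'   units.
#' @param wavelength_nm optional note on the monitored wavelength.
#' @return A `MeltCurve` data.frame.
#' @export
melt_curve <- function(temperature_C, signal, wavelength_nm = 222) {
  stopifnot(length(temperature_C) == length(signal))
  if (any(diff(temperature_C) <= 0)) {
    stop("melt_curve: temperatures must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(temperature_C = temperature_C, signal = signal),
            wavelength_nm = wavelength_nm, class = c("MeltCurve", "data.frame"))
}

#' Two-state melt fit (Tm at fraction unfolded 0.5)
#'
#' Fits a native-to-denatured two-state transition with linear pre- and
#' post-transition baselines:
#' `y(T) = fN(T) + (fD(T) - fN(T)) / (1 + exp((Tm - T)/s))`,
#' where `fN`, `fD` are the folded/unfolded baselines.  The fraction unfolded
#' is then computed per point from the fitted baselines; by construction the
#' fitted curve crosses F_U = 0.5 at `Tm`.
#'
#' @param curve a [melt_curve()] with at least 8 points spanning the
#'   transition.
#' @param constant_baselines force zero baseline slopes.
#' @return A `TwoStateFit`: list with `tm_C`, `steepness_C` (transition width
#'   parameter, per degree), `baseline_folded` and `baseline_unfolded`
#'   (intercept, slope), `fraction_unfolded` (data.frame `temperature_C`,
#'   `f_u`), `residual_sd`.
#' @export
fit_two_state_melt <- function(curve, constant_baselines = FALSE) {
  if (!inherits(curve, "MeltCurve")) curve <- melt_curve(curve$temperature_C, curve$signal)
  if (nrow(curve) < 8L) stop("fit_two_state_melt: need at least 8 points", call. = FALSE)
  tt <- curve$temperature_C
  y <- curve$signal
  if (diff(range(y)) <= .Machine$double.eps^0.5 * max(abs(y), 1)) {
    stop("fit_two_state_melt: flat signal, no transition detectable", call. = FALSE)
  }
  n <- length(y)
  edge <- max(3L, floor(n / 5))
  lo_fit <- stats::lm(y[seq_len(edge)] ~ tt[seq_len(edge)])
  hi_idx <- seq(n - edge + 1L, n)
  hi_fit <- stats::lm(y[hi_idx] ~ tt[hi_idx])
  mid <- (mean(y[seq_len(edge)]) + mean(y[hi_idx])) / 2
  tm0 <- tt[which.min(abs(y - mid))]
  start <- list(aN = unname(stats::coef(lo_fit)[1]), bN = unname(stats::coef(lo_fit)[2]),
                aD = unname(stats::coef(hi_fit)[1]), bD = unname(stats::coef(hi_fit)[2]),
                tm = tm0, s = diff(range(tt)) / 20)
  if (constant_baselines) {
    start$bN <- NULL; start$bD <- NULL
    form <- y ~ aN + (aD - aN) / (1 + exp((tm - tt) / s))
  } else {
    form <- y ~ (aN + bN * tt) + ((aD + bD * tt) - (aN + bN * tt)) /
      (1 + exp((tm - tt) / s))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf("fit_two_state_melt: fit failure (%s)",
                                     conditionMessage(e)), call. = FALSE))
  cf <- as.list(stats::coef(fit))
  if (constant_baselines) cf$bN <- cf$bD <- 0
  f_n <- cf$aN + cf$bN * tt
  f_d <- cf$aD + cf$bD * tt
  f_u <- (stats::fitted(fit) - f_n) / (f_d - f_n)
  if (cf$tm < min(tt) || cf$tm > max(tt)) {
    stop("fit_two_state_melt: fitted midpoint outside the measured range; no transition detectable",
         call. = FALSE)
  }
  structure(list(tm_C = cf$tm, steepness_C = cf$s,
                 baseline_folded = c(intercept = cf$aN, slope = cf$bN),
                 baseline_unfolded = c(intercept = cf$aD, slope = cf$bD),
                 fraction_unfolded = data.frame(temperature_C = tt,
                                                f_u = pmin(1, pmax(0, f_u))),
                 residual_sd = stats::sd(stats::resid(fit))),
            class = "TwoStateFit")
}

#' @export
print.TwoStateFit <- function(x, ...) {
  cat(sprintf("TwoStateFit: Tm %.2f C, steepness %.3f C\n", x$tm_C, x$steepness_C))
  invisible(x)
}

#' Michaelis-Menten fit
#'
#' Nonlinear least squares of `v = Vmax * S / (KM + S)` (a direct fit, no
#' linearization).  When the enzyme concentration is supplied, Vmax is
#' converted to a turnover number kcat.
#'
#' @param data data.frame with columns `substrate_mM` and `rate`; at least 4
#'   substrate levels, at least one below and one above the apparent KM.
#' @param enzyme_conc optional enzyme concentration in the same units that
#'   make `rate / enzyme_conc` a per-second turnover.
#' @return An `MMFit`: list with `vmax`, `km_mM`, their standard errors,
#'   `kcat` (when `enzyme_conc` given) and `kcat_se`, `n_points`,
#'   `converged`.
#' @export
fit_michaelis_menten <- function(data, enzyme_conc = NULL) {
  s <- data$substrate_mM
  v <- data$rate
  if (length(unique(s[s > 0])) < 4L) {
    stop("fit_michaelis_menten: need at least 4 positive substrate levels", call. = FALSE)
  }
  vmax0 <- max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s[s > 0])
  resid_fn <- function(p) v - p[1] * s / (p[2] + s)
  # multiple starts: a grid that also covers unsaturated designs where the
  # apparent KM lies beyond the assayed substrate range
  starts <- list(c(vmax0, km0), c(vmax0 * 2, max(s)), c(vmax0 * 10, max(s) * 10))
  best <- NULL
  last_err <- "no start converged"
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(vmax = st[1], km = st[2]), fn = resid_fn,
                         lower = c(1e-12, 1e-12),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit) && fit$info %in% 1:4 &&
        (is.null(best) || fit$deviance < best$deviance)) best <- fit
  }
  if (is.null(best)) {
    stop(sprintf("fit_michaelis_menten: fit failure (%s)", last_err), call. = FALSE)
  }
  p <- stats::coef(best)
  dof <- max(1L, length(v) - 2L)
  sigma2 <- best$deviance / dof
  jtj <- best$hessian   # J'J approximation from nls.lm
  ses <- tryCatch(sqrt(diag(solve(jtj)) * sigma2),
                  error = function(e) c(vmax = Inf, km = Inf))
  out <- list(vmax = unname(p["vmax"]), vmax_se = unname(ses["vmax"]),
              km_mM = unname(p["km"]), km_se = unname(ses["km"]),
              n_points = length(v), converged = best$info %in% 1:4)
  if (!is.null(enzyme_conc)) {
    out$kcat <- out$vmax / enzyme_conc
    out$kcat_se <- out$vmax_se / enzyme_conc
  }
  structure(out, class = "MMFit")
}

#' @export
print.MMFit <- function(x, ...) {
  cat(sprintf("MMFit: Vmax %.4g +/- %.2g, KM %.4g +/- %.2g mM",
              x$vmax, x$vmax_se, x$km_mM, x$km_se))
  if (!is.null(x$kcat)) cat(sprintf(", kcat %.4g +/- %.2g s^-1", x$kcat, x$kcat_se))
  cat("\n")
  invisible(x)
}

#' Read a stability CSV and detect its schema
#'
#' Accepts the three tabular inputs of the stability analytics: inactivation
#' series (`temperature_C,k_per_s`), melting curves (`temperature_C,signal`)
#' and substrate-rate tables (`substrate_mM,rate`).
#'
#' @param path CSV path with a header line.
#' @return list with `schema` (one of `"inactivation"`, `"melt"`,
#'   `"kinetics"`) and `data` (the typed container).
#' @export
read_stability_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_stability_csv: file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("read_stability_csv: cannot parse %s (%s)",
                                                  path, conditionMessage(e)), call. = FALSE))
  cols <- names(df)
  has <- function(...) all(c(...) %in% cols)
  schema <- c(inactivation = has("temperature_C", "k_per_s"),
              melt = has("temperature_C", "signal"),
              kinetics = has("substrate_mM", "rate"))
  if (sum(schema) == 0L) {
    stop(sprintf("read_stability_csv: unrecognized columns [%s]; expected one of (temperature_C,k_per_s), (temperature_C,signal), (substrate_mM,rate)",
                 paste(cols, collapse = ",")), call. = FALSE)
  }
  if (sum(schema) > 1L) {
    stop(sprintf("read_stability_csv: ambiguous schema, candidates: %s",
                 paste(names(schema)[schema], collapse = ", ")), call. = FALSE)
  }
  schema <- names(schema)[schema]
  used <- switch(schema, inactivation = c("temperature_C", "k_per_s"),
                 melt = c("temperature_C", "signal"),
                 kinetics = c("substrate_mM", "rate"))
  for (col in used) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- which(!stats::complete.cases(df[used]))
  if (length(bad)) {
    stop(sprintf("read_stability_csv: malformed value at data line %d of %s",
                 bad[1L] + 1L, path), call. = FALSE)
  }
  data <- switch(schema,
                 inactivation = inactivation_series(df$temperature_C, df$k_per_s),
                 melt = melt_curve(df$temperature_C, df$signal),
                 kinetics = df)
  list(schema = schema, data = data)
}
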