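#' Regular acquisition time grid
#'
#' @param start First sampling time (default 0).
#' @param interval Sampling interval, > 0.
#' @param n_points Number of samples, >= 2.
#' @param unit Unit of `start` and `interval`: `"s"` or `"min"`. Times are
#'   stored internally in minutes (rate constants are per minute).
#' @return Object of class `time_grid` with the `times` vector in minutes.
#' @examples
#' g <- time_grid(interval = 11.9, n_points = 46)  # the study acquisition
#' range(g$times) * 60                             # 0 .. 535.5 s
#' @export
time_grid <- function(start = 0, interval, n_points, unit = c("s", "min")) {
  unit <- match.arg(unit)
  check_positive(interval, "interval")
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be >= 2")
  times <- start + interval * (seq_len(n_points) - 1L)
  if (unit == "s") times <- times / 60
  structure(list(times = times, n_points = n_points), class = "time_grid")
}

#' Concentration-time series
#'
#' One patient's sampled concentration curve. Times are in minutes,
#' concentrations in mM.
#'
#' @param times Strictly increasing numeric vector (minutes).
#' @param values Finite numeric vector, same length.
#' @param patient_id Label.
#' @return Object of class `conc_ts`.
#' @export
conc_ts <- function(times, values, patient_id = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("values must be finite")
  structure(list(patient_id = as.character(patient_id),
                 times = times, values = values),
            class = "conc_ts")
}

#' @export
print.conc_ts <- function(x, ...) {
  cat(sprintf("concentration-time series%s: %d samples, t in [%.3g, %.3g] min, peak %.4g mM\n",
              if (nzchar(x$patient_id)) paste0(" [", x$patient_id, "]") else "",
              length(x$times), min(x$times), max(x$times), max(x$values)))
  invisible(x)
}

#' @export
plot.conc_ts <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "b", pch = 16,
                 xlab = "time (min)", ylab = "concentration (mM)",
                 main = x$patient_id, ...)
  invisible(x)
}

#' @export
as.data.frame.conc_ts <- function(x, ...) {
  data.frame(patient_id = x$patient_id, time_min = x$times,
             value_mM = x$values)
}

#' Parametric AIF shapes
#'
#' Ground-truth arterial input function families for simulation. The Weibull
#' shape is the family pdf scaled by an amplitude (mM*min) - a pdf alone has
#' unit area, not physical concentration - with an optional onset delay. The
#' biexponential comparator is
#' `amplitude * (a1 exp(-m1 t) + a2 exp(-m2 t))` after the delay.
#'
#' @param k,c Weibull shape and scale (scale in minutes).
#' @param amplitude Curve scaling, >= 0 (0 gives the all-zero curve);
#'   mM*min for the Weibull family.
#' @param delay Onset delay in minutes, >= 0; the curve is zero before it.
#' @return Object of class `aif_shape`.
#' @examples
#' aif_weibull()                  # the worked-example shape, k=3, c=1.8498
#' aif_biexp(3.99, 4.78, 0.144, 0.0111)
#' @export
aif_weibull <- function(k = 3, c = 1.8498, amplitude = 1, delay = 0) {
  check_positive(k, "k")
  check_positive(c, "c")
  check_nonnegative(amplitude, "amplitude")
  check_nonnegative(delay, "delay")
  structure(list(family = "weibull_scaled",
                 params = list(k = k, c = c, amplitude = amplitude,
                               delay = delay),
                 time_unit = "min"),
            class = "aif_shape")
}

#' @rdname aif_weibull
#' @param a1,a2 Biexponential amplitudes (> 0).
#' @param m1,m2 Biexponential decay rates (1/min, > 0).
#' @export
aif_biexp <- function(a1, a2, m1, m2, amplitude = 1, delay = 0) {
  for (nm in c("a1", "a2", "m1", "m2"))
    check_positive(get(nm), nm)
  check_nonnegative(amplitude, "amplitude")
  check_nonnegative(delay, "delay")
  structure(list(family = "biexponential",
                 params = list(a1 = a1, a2 = a2, m1 = m1, m2 = m2,
                               amplitude = amplitude, delay = delay),
                 time_unit = "min"),
            class = "aif_shape")
}

aif_shape_eval <- function(shape, t) {
  p <- shape$params
  s <- pmax(t - p$delay, 0)
  v <- switch(shape$family,
    weibull_scaled = p$amplitude * stats::dweibull(s, shape = p$k, scale = p$c),
    biexponential = p$amplitude * (p$a1 * exp(-p$m1 * s) + p$a2 * exp(-p$m2 * s)))
  v[t < p$delay] <- 0
  v
}

#' Evaluate an AIF shape on a time grid
#'
#' @param shape An [aif_weibull()] or [aif_biexp()] shape.
#' @param grid A [time_grid()].
#' @param patient_id Label for the resulting curve.
#' @return A [conc_ts()] plasma curve, non-negative everywhere and zero
#'   before the onset delay.
#' @export
generate_aif_curve <- function(shape, grid, patient_id = "") {
  stopifnot(inherits(shape, "aif_shape"), inherits(grid, "time_grid"))
  conc_ts(grid$times, aif_shape_eval(shape, grid$times), patient_id)
}

#' Simulate a noisy tissue curve from an AIF
#'
#' The noiseless part is the two-compartment convolution (see
#' [tissue_response()]); additive homoscedastic Gaussian noise of standard
#' deviation `noise_sd` is then added independently per sample. Negative
#' noisy concentrations are not clipped: the observation model assumes
#' unbounded Gaussian noise.
#'
#' @param aif A [conc_ts()] plasma curve.
#' @param k1,k2 Rate constants (1/min), >= 0.
#' @param noise_sd Noise standard deviation (mM), >= 0.
#' @param seed Optional seed for reproducibility.
#' @return A [conc_ts()] tissue curve.
#' @export
generate_tissue_curve <- function(aif, k1, k2, noise_sd = 0, seed = NULL) {
  check_nonnegative(noise_sd, "noise_sd")
  clean <- tissue_response(aif, k1, k2)
  if (noise_sd > 0)
    clean$values <- clean$values +
      with_seed(seed, stats::rnorm(length(clean$values), 0, noise_sd))
  clean
}

#' Configuration of a simulated DCE-MRI study
#'
#' Defaults emulate the breast-cancer acquisition the method targets:
#' 12 patients, 46 frames every 11.9 s, a Weibull-shaped AIF with amplitude
#' 5 mM*min (peak plasma concentration about 2.9 mM), per-patient rate
#' constants drawn uniformly from ranges bracketing the reported per-patient
#' spread, and Gaussian noise with standard deviation 5% of each patient's
#' tissue peak.
#'
#' @param n_patients Number of simulated patients.
#' @param grid A [time_grid()]; default 46 points at 11.9 s.
#' @param aif An [aif_weibull()]/[aif_biexp()] shape.
#' @param k1_range,k2_range Uniform sampling intervals for K1, K2 (1/min).
#' @param noise_sd Absolute noise standard deviation (mM), or `NULL` to use
#'   `noise_frac` of each patient's noiseless tissue peak.
#' @param noise_frac Relative noise level (default 0.05).
#' @param baseline_frames Number of pre-injection frames: the AIF onset is
#'   delayed by that many sampling intervals, leaving near-zero baseline
#'   samples at the start of every curve (default 0; the study curves start
#'   at injection).
#' @param seed Integer seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_patients = 12L,
                         grid = time_grid(interval = 11.9, n_points = 46),
                         aif = aif_weibull(amplitude = 5),
                         k1_range = c(0.1, 1.1),
                         k2_range = c(0.01, 0.4),
                         noise_sd = NULL, noise_frac = 0.05,
                         baseline_frames = 0L, seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("n_patients must be >= 1")
  stopifnot(inherits(grid, "time_grid"), inherits(aif, "aif_shape"))
  if (any(k1_range <= 0) || any(k2_range <= 0) ||
      k1_range[1] > k1_range[2] || k2_range[1] > k2_range[2])
    stop("rate-constant ranges must be positive intervals")
  if (!is.null(noise_sd)) check_nonnegative(noise_sd, "noise_sd")
  check_nonnegative(noise_frac, "noise_frac")
  structure(list(n_patients = n_patients, grid = grid, aif = aif,
                 k1_range = k1_range, k2_range = k2_range,
                 noise_sd = noise_sd, noise_frac = noise_frac,
                 baseline_frames = as.integer(baseline_frames),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Simulate a multi-patient DCE-MRI study
#'
#' Draws per-patient rate constants uniformly from the configured ranges,
#' evaluates the AIF on the grid (shared across patients), and generates
#' noisy tissue curves. Fully reproducible under a fixed seed.
#'
#' @param cfg A [study_config()].
#' @return Object of class `aif_study`: a list of per-patient records
#'   `(patient_id, cp, ctis, k1, k2, noise_sd)` plus the `config`.
#' @examples
#' study <- simulate_study(study_config(n_patients = 2, seed = 7))
#' study$patients[[1]]$k1
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  shape <- cfg$aif
  if (cfg$baseline_frames > 0L) {
    dt <- diff(cfg$grid$times)[1L]
    shape$params$delay <- shape$params$delay + cfg$baseline_frames * dt
  }
  patients <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_patients), function(i) {
      id <- sprintf("patient_%02d", i)
      k1 <- stats::runif(1, cfg$k1_range[1], cfg$k1_range[2])
      k2 <- stats::runif(1, cfg$k2_range[1], cfg$k2_range[2])
      cp <- generate_aif_curve(shape, cfg$grid, patient_id = id)
      clean <- tissue_response(cp, k1, k2)
      sd_i <- if (is.null(cfg$noise_sd)) cfg$noise_frac * max(clean$values)
              else cfg$noise_sd
      ct <- clean
      if (sd_i > 0)
        ct$values <- ct$values + stats::rnorm(length(ct$values), 0, sd_i)
      list(patient_id = id, cp = cp, ctis = ct, k1 = k1, k2 = k2,
           noise_sd = sd_i)
    })
  })
  structure(list(patients = patients, config = cfg), class = "aif_study")
}

#' @export
print.aif_study <- function(x, ...) {
  cat(sprintf("Simulated DCE-MRI study: %d patients, %d frames (seed %d)\n",
              length(x$patients), x$config$grid$n_points, x$config$seed))
  k1 <- vapply(x$patients, `[[`, numeric(1), "k1")
  k2 <- vapply(x$patients, `[[`, numeric(1), "k2")
  cat(sprintf("  true K1 in [%.3f, %.3f], K2 in [%.3f, %.3f] 1/min\n",
              min(k1), max(k1), min(k2), max(k2)))
  invisible(x)
}

#' Contrast-agent concentration from T1 relaxation times
#'
#' Converts longitudinal relaxation times measured during and before contrast
#' into gadolinium concentration:
#' `Ct = (1 / r1) * (1 / T1(t) - 1 / T10)`.
#'
#' @param t1_t T1 during contrast (s), > 0; vectorized.
#' @param t10 Baseline T1 without contrast (s), > 0.
#' @param r1 Longitudinal relaxivity of the agent (l/s/mmol); default 4.24,
#'   the in-vivo Gd-DTPA value.
#' @return Concentration in mM.
#' @examples
#' conc_from_t1(0.5, 1.0)  # 0.2358 mM
#' @export
conc_from_t1 <- function(t1_t, t10, r1 = 4.24) {
  if (any(!is.finite(t1_t)) || any(t1_t <= 0))
    stop("'t1_t' must be positive")
  check_positive(t10, "t10")
  check_positive(r1, "r1")
  (1 / r1) * (1 / t1_t - 1 / t10)
}
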