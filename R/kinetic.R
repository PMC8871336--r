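#' Two-compartment tissue response to an arterial input
#'
#' Solves `dCtis/dt = K1 Cp(t) - K2 Ctis(t)`, `Ctis(0) = 0`, whose solution is
#' the convolution `Ctis(t) = K1 * integral_0^t Cp(u) exp(-K2 (t - u)) du`.
#' The integral is evaluated by the exact piecewise-linear recursion: the
#' input is taken linear on each sampling interval and the exponential kernel
#' integrated in closed form, a stable O(n) scheme whose only error is the
#' linear-interpolation error of `Cp` (second order in the grid spacing).
#'
#' @param cp A [conc_ts()] plasma curve (times in minutes).
#' @param k1 Influx rate constant (1/min), >= 0.
#' @param k2 Efflux rate constant (1/min), >= 0.
#' @return A [conc_ts()] tissue curve on the same grid.
#' @examples
#' g <- time_grid(interval = 11.9, n_points = 46)
#' cp <- generate_aif_curve(aif_weibull(), g)
#' ct <- tissue_response(cp, k1 = 0.25, k2 = 0.2)
#' @export
tissue_response <- function(cp, k1, k2) {
  stopifnot(inherits(cp, "conc_ts"))
  check_nonnegative(k1, "k1")
  check_nonnegative(k2, "k2")
  t <- cp$times
  v <- cp$values
  n <- length(t)
  out <- numeric(n)
  for (i in 2:n) {
    dt <- t[i] - t[i - 1L]
    a <- v[i - 1L]
    b <- v[i]
    z <- k2 * dt
    if (z < 1e-8) {
      # series limit of the kernel integrals, O(z) beyond the trapezoid
      seg <- a * dt * (1 - z / 2) + (b - a) * dt * (0.5 - z / 3)
      E <- 1 - z + z^2 / 2
    } else {
      E <- exp(-z)
      i0 <- -expm1(-z) / k2                          # int exp(-k2 (dt - s)) ds
      i1 <- if (z < 1e-4) {
        dt^2 * (0.5 - z / 3 + z^2 / 8)
      } else {
        (dt * (1 - E) / k2 - (1 - (1 + z) * E) / k2^2)
      }
      seg <- a * i0 + (b - a) / dt * i1
    }
    out[i] <- E * out[i - 1L] + k1 * seg
  }
  conc_ts(t, out, patient_id = cp$patient_id)
}

#' Murase design matrix for the linearized kinetic model
#'
#' Integrating the kinetic ODE gives the linear relation
#' `Ctis(t_i) = K1 * int_0^{t_i} Cp - K2 * int_0^{t_i} Ctis`, i.e. a linear
#' system `C = A K` with design row
#' `A(i) = (int_0^{t_i} Cp(u) du, -int_0^{t_i} Ctis(u) du)`, the integrals
#' taken by the trapezoidal rule.
#'
#' @param cp,ctis [conc_ts()] curves on the same grid.
#' @return Object of class `murase_design`: `A` (n x 2 matrix), `times`.
#' @export
murase_design <- function(cp, ctis) {
  stopifnot(inherits(cp, "conc_ts"), inherits(ctis, "conc_ts"))
  if (length(cp$times) != length(ctis$times) ||
      max(abs(cp$times - ctis$times)) > 1e-9)
    stop("plasma and tissue curves must share the same time grid")
  cum_cp <- c(0, pracma::cumtrapz(cp$times, cp$values)[-1L])
  cum_ct <- c(0, pracma::cumtrapz(ctis$times, ctis$values)[-1L])
  A <- cbind(cum_cp, -cum_ct)
  colnames(A) <- c("int_cp", "neg_int_ctis")
  structure(list(A = A, times = cp$times), class = "murase_design")
}

#' @export
print.murase_design <- function(x, ...) {
  cat(sprintf("Murase design matrix: %d rows\n", nrow(x$A)))
  print(utils::head(x$A, 3))
  if (nrow(x$A) > 3) cat("  ...\n")
  invisible(x)
}

#' Linear least-squares kinetic fit
#'
#' Ordinary least squares for `C = A K` built by [murase_design()]. The
#' solution is unconstrained: negative rate estimates are returned as-is with
#' a warning flag in the result.
#'
#' @param design A [murase_design()] object (or plain n x 2 matrix).
#' @param y Observed tissue concentrations (length n).
#' @return Object of class `kinfit`: `k1`, `k2`, `residual_norm`, `fitted`,
#'   `residuals`, `negative_flag`, `method = "llsq"`.
#' @export
llsq_fit <- function(design, y) {
  A <- if (inherits(design, "murase_design")) design$A else as.matrix(design)
  y <- as.numeric(y)
  if (nrow(A) != length(y)) stop("design and response lengths differ")
  if (nrow(A) < 3L) stop("need at least 3 time points")
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    d <- svd(A, nu = 0, nv = 0)$d
    stop(sprintf("rank-deficient design matrix (condition number %.3g)",
                 d[1] / max(d[length(d)], .Machine$double.xmin)))
  }
  k <- qr.coef(qrA, y)
  fitted <- drop(A %*% k)
  res <- y - fitted
  neg <- any(k < 0)
  if (neg)
    warning("unconstrained LLSQ produced a negative rate constant")
  structure(list(k1 = unname(k[1L]), k2 = unname(k[2L]),
                 residual_norm = sqrt(sum(res^2)),
                 fitted = fitted, residuals = res,
                 negative_flag = neg, method = "llsq",
                 design = A, y = y),
            class = "kinfit")
}

#' Fit the two-compartment kinetic model to a patient's curves
#'
#' Builds the Murase design matrix from the plasma and tissue curves and
#' estimates the rate constants by ordinary least squares
#' (`method = "llsq"`) or by Bayesian MAP with an entropy-based prior
#' (`method = "map"`, see [map_fit()]).
#'
#' @param cp,ctis [conc_ts()] curves on a common grid (times in minutes).
#' @param method `"llsq"` or `"map"`.
#' @param baseline_frames Number of leading pre-injection frames to drop
#'   before building the design matrix (default 0).
#' @param ... Passed to [map_fit()] for `method = "map"`.
#' @return A `kinfit` object; `coef()` gives `c(k1, k2)` in 1/min,
#'   `fitted()`/`residuals()` the modelled tissue curve and residuals, and
#'   `predict(fit, cp = ...)` the continuous-model tissue response
#'   [tissue_response()] at the fitted rates.
#' @examples
#' g <- time_grid(interval = 11.9, n_points = 46)
#' cp <- generate_aif_curve(aif_weibull(), g)
#' ct <- tissue_response(cp, 0.25, 0.2)
#' coef(kinetic_fit(cp, ct))
#' @export
kinetic_fit <- function(cp, ctis, method = c("llsq", "map"),
                        baseline_frames = 0L, ...) {
  method <- match.arg(method)
  if (baseline_frames > 0L) {
    keep <- -seq_len(baseline_frames)
    cp <- conc_ts(cp$times[keep], cp$values[keep], cp$patient_id)
    ctis <- conc_ts(ctis$times[keep], ctis$values[keep], ctis$patient_id)
  }
  design <- murase_design(cp, ctis)
  fit <- if (method == "llsq") llsq_fit(design, ctis$values)
         else map_fit(design, ctis$values, ...)
  fit$cp <- cp
  fit$patient_id <- cp$patient_id
  fit
}

#' @export
coef.kinfit <- function(object, ...) c(k1 = object$k1, k2 = object$k2)

#' @export
fitted.kinfit <- function(object, ...) object$fitted

#' @export
residuals.kinfit <- function(object, ...) object$residuals

#' @export
predict.kinfit <- function(object, cp = object$cp, ...) {
  if (is.null(cp)) stop("no plasma curve available; supply 'cp'")
  tissue_response(cp, max(object$k1, 0), max(object$k2, 0))
}

#' @export
print.kinfit <- function(x, ...) {
  cat(sprintf("Two-compartment kinetic fit (%s)\n", x$method))
  cat(sprintf("  K1 = %.4f 1/min, K2 = %.4f 1/min\n", x$k1, x$k2))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  if (isTRUE(x$negative_flag))
    cat("  note: unconstrained solution has a negative component\n")
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  m <- fit_metrics(object$fitted, object$y, n_params = 2L)
  out <- list(coef = coef(object), method = object$method, metrics = m,
              negative_flag = isTRUE(object$negative_flag),
              diagnostics = object$diagnostics)
  class(out) <- "summary.kinfit"
  out
}

#' @export
print.summary.kinfit <- function(x, ...) {
  cat(sprintf("Kinetic fit (%s): K1 = %.4f, K2 = %.4f (1/min)\n",
              x$method, x$coef[["k1"]], x$coef[["k2"]]))
  print(x$metrics)
  invisible(x)
}

#' @export
plot.kinfit <- function(x, ...) {
  graphics::plot(x$cp$times, x$y, pch = 16, col = "grey40",
                 xlab = "time (min)", ylab = "concentration (mM)",
                 main = "Tissue curve and kinetic fit", ...)
  graphics::lines(x$cp$times, x$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}
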