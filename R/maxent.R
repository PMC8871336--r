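#' Known functions for maximum-entropy moment constraints
#'
#' The maximum-entropy density has the exponential-family form
#' `f(x) = exp(-sum_k lambda_k * phi_k(x))`, where the `phi_k` are "known
#' functions" chosen by the analyst. The constant function `phi_0 = 1` carries
#' the normalization constraint and is always present.
#'
#' @param tag One of `"const"`, `"identity"`, `"power"`, `"log"`, `"xlogx"`.
#' @param p Exponent, required for `tag = "power"`.
#' @return Object of class `known_fun` with an `eval` closure.
#' @examples
#' kf_eval(known_fun("power", 3), 2)  # 8
#' @export
known_fun <- function(tag = c("const", "identity", "power", "log", "xlogx"),
                      p = NULL) {
  tag <- match.arg(tag)
  if (tag == "power") {
    if (is.null(p) || !is.numeric(p) || length(p) != 1L || !is.finite(p) ||
        p == 0)
      stop("power function needs a single nonzero finite exponent 'p'")
  }
  f <- switch(tag,
    const = function(x) rep(1, length(x)),
    identity = function(x) x,
    power = function(x) x^p,
    log = function(x) log(x),
    xlogx = function(x) x * log(x))
  label <- switch(tag,
    const = "1", identity = "x",
    power = sprintf("x^%g", p), log = "log(x)", xlogx = "x*log(x)")
  structure(list(tag = tag, p = p, eval = f, label = label),
            class = "known_fun")
}

#' @export
print.known_fun <- function(x, ...) {
  cat("known function:", x$label, "\n")
  invisible(x)
}

#' Evaluate a known function on a numeric vector
#' @param fn A [known_fun()].
#' @param x Numeric vector.
#' @return Numeric vector `phi(x)`.
#' @export
kf_eval <- function(fn, x) {
  stopifnot(inherits(fn, "known_fun"))
  fn$eval(x)
}

# Does the function set need a strictly positive support?
needs_positive_support <- function(functions) {
  any(vapply(functions, function(f) {
    f$tag %in% c("log", "xlogx") || (f$tag == "power" && (f$p < 0 || f$p != round(f$p)))
  }, logical(1)))
}

#' Default known-function set for AIF density fitting
#'
#' The constant, `log(x)` and `x^3` functions: the set whose maximum-entropy
#' solution is (for shape 3) exactly a Weibull density, used for blind AIF
#' estimation from plasma concentration samples.
#' @return List of three [known_fun()] objects.
#' @export
aif_function_set <- function() {
  list(known_fun("const"), known_fun("log"), known_fun("power", 3))
}

#' Empirical moment constraints
#'
#' Computes `mu_k = mean(phi_k(x))` for each known function over the sample;
#' the constant function's moment is fixed at 1 (normalization).
#'
#' @param samples Non-empty numeric vector, inside the evaluable domain of
#'   every function (strictly positive if any log-type function is present).
#' @param functions List of [known_fun()]; a leading `const` is added if
#'   missing.
#' @return Object of class `moment_constraints` with elements `functions`
#'   and `values`.
#' @examples
#' empirical_moments(c(1, 2, 3), list(known_fun("identity")))$values
#' @export
empirical_moments <- function(samples, functions) {
  if (length(samples) == 0L || !all(is.finite(samples)))
    stop("samples must be a non-empty finite numeric vector")
  if (inherits(functions, "known_fun")) functions <- list(functions)
  if (!any(vapply(functions, function(f) f$tag == "const", logical(1))))
    functions <- c(list(known_fun("const")), functions)
  if (functions[[1L]]$tag != "const")
    stop("the constant function must come first")
  if (needs_positive_support(functions) && any(samples <= 0)) {
    bad <- which(samples <= 0)
    stop(sprintf(
      "log-type constraint functions need positive samples; offending index: %d",
      bad[1L]))
  }
  values <- vapply(functions, function(f) mean(f$eval(samples)), numeric(1))
  values[1L] <- 1
  structure(list(functions = functions, values = values),
            class = "moment_constraints")
}

#' @export
print.moment_constraints <- function(x, ...) {
  cat("moment constraints:\n")
  for (i in seq_along(x$functions))
    cat(sprintf("  E[%s] = %.6g\n", x$functions[[i]]$label, x$values[i]))
  invisible(x)
}

validate_support <- function(support, functions) {
  if (!is.numeric(support) || length(support) != 2L || !all(is.finite(support)) ||
      support[1] >= support[2])
    stop("support must be a finite interval c(lower, upper) with lower < upper")
  if (needs_positive_support(functions) && support[1] <= 0)
    stop("support lower bound must be > 0 when log-type functions are present")
  support
}

# Evaluate the unnormalized density, the partition function and the moments
# G_k(lambda) on a fixed Simpson grid. Phi holds phi_k(x) by column.
maxent_quadrature <- function(lambda_free, Phi, grid) {
  expo <- if (length(lambda_free)) -drop(Phi[, -1L, drop = FALSE] %*% lambda_free)
          else rep(0, length(grid$x))
  m <- max(expo)
  w <- exp(expo - m)
  z0 <- sum(grid$w * w)            # integral of exp(expo - m)
  lambda0 <- m + log(z0)           # log partition function
  dens <- w / z0                   # normalized density on the grid
  G <- drop(crossprod(Phi, grid$w * dens))
  list(lambda0 = lambda0, density = dens, G = G)
}

#' Solve the maximum-entropy moment problem
#'
#' Finds the Lagrange multipliers `lambda` of the exponential-family density
#' `f(x) = exp(-sum_k lambda_k phi_k(x))` on a bounded support such that the
#' moment constraints `integral(phi_k f) = mu_k` hold. `lambda_0` is
#' eliminated analytically via normalization; the remaining multipliers are
#' found either by damped Newton descent on the convex dual
#' (`solver = "dual_descent"`) or by minimizing the sum of squared constraint
#' residuals with [tlbo()] (`solver = "tlbo"`). Integrals use fixed
#' 2001-point composite Simpson quadrature.
#'
#' @param constraints A [empirical_moments()] object (or compatible list with
#'   `functions` and `values`).
#' @param support Numeric interval `c(lower, upper)`.
#' @param solver `"dual_descent"` or `"tlbo"`.
#' @param control Optional list: `tol` (constraint residual tolerance,
#'   default 1e-5 for acceptance, solved well below), `max_iter`,
#'   `n_quad` (quadrature points), `bounds` (TLBO multiplier box, default
#'   [-20, 20] per free multiplier), `seed`, `population_size`.
#' @return Object of class `maxent`: `lambdas` (named, including `lambda0`),
#'   `functions`, `support`, `residuals`, `converged`, `solver`,
#'   `diagnostics`. If the residuals exceed the tolerance a warning is
#'   emitted and `converged` is `FALSE`; the residual vector is retained.
#' @examples
#' mc <- structure(list(functions = list(known_fun("const"),
#'                                       known_fun("identity")),
#'                      values = c(1, 2)), class = "moment_constraints")
#' fit <- maxent_solve(mc, support = c(0, 60))
#' coef(fit)  # close to lambda0 = log(2), lambda_x = 0.5
#' @export
maxent_solve <- function(constraints, support,
                         solver = c("dual_descent", "tlbo"),
                         control = list()) {
  solver <- match.arg(solver)
  functions <- constraints$functions
  mu <- constraints$values
  if (abs(mu[1L] - 1) > 1e-12) stop("mu_0 (normalization) must equal 1")
  support <- validate_support(support, functions)
  ctrl <- utils::modifyList(
    list(tol = 1e-5, max_iter = 200L, n_quad = 2001L, bounds = 20,
         seed = NULL, population_size = 40L, tlbo_iterations = 3000L),
    control)

  grid <- simpson_grid(support, ctrl$n_quad)
  Phi <- vapply(functions, function(f) f$eval(grid$x), numeric(length(grid$x)))
  Phi <- matrix(Phi, ncol = length(functions))
  nfree <- length(functions) - 1L
  mu_free <- mu[-1L]

  diagnostics <- list()
  if (nfree == 0L) {
    lam_free <- numeric(0)
  } else if (solver == "dual_descent") {
    # Convex dual: Psi(lambda) = log Z(lambda) + sum lambda_k mu_k;
    # gradient = mu - G, Hessian = Cov_f(phi) (positive semidefinite).
    lam_free <- rep(0, nfree)
    Phi1 <- Phi[, -1L, drop = FALSE]
    psi_val <- function(l) {
      q <- maxent_quadrature(l, Phi, grid)
      q$lambda0 + sum(l * mu_free)
    }
    iter <- 0L
    repeat {
      iter <- iter + 1L
      q <- maxent_quadrature(lam_free, Phi, grid)
      g <- mu_free - q$G[-1L]
      if (max(abs(g)) < 1e-12 || iter > ctrl$max_iter) break
      EPP <- crossprod(Phi1, (grid$w * q$density) * Phi1)
      H <- EPP - tcrossprod(q$G[-1L])
      step <- tryCatch(solve(H + diag(1e-10, nfree), g),
                       error = function(e) g)
      # backtracking line search on the dual
      f0 <- q$lambda0 + sum(lam_free * mu_free)
      alpha <- 1
      repeat {
        cand <- lam_free - alpha * step
        if (psi_val(cand) < f0 || alpha < 1e-10) break
        alpha <- alpha / 2
      }
      lam_free <- lam_free - alpha * step
    }
    diagnostics$iterations <- iter
  } else {
    b <- ctrl$bounds
    lower <- rep(-abs(b), nfree)
    upper <- rep(abs(b), nfree)
    obj <- function(l) {
      q <- maxent_quadrature(l, Phi, grid)
      sum((q$G[-1L] - mu_free)^2)
    }
    res <- tlbo(obj, lower, upper,
                control = tlbo_control(population_size = ctrl$population_size,
                                       max_iterations = ctrl$tlbo_iterations,
                                       tolerance = 1e-28, patience = 50L,
                                       seed = ctrl$seed))
    lam_free <- res$best_solution
    diagnostics <- list(iterations = res$iterations,
                        evaluations = res$evaluations,
                        trace = res$trace)
  }

  q <- maxent_quadrature(lam_free, Phi, grid)
  residuals <- q$G - mu
  converged <- max(abs(residuals)) <= ctrl$tol
  if (!converged)
    warning(sprintf(
      "maximum-entropy solver did not meet tolerance %g (max residual %g)",
      ctrl$tol, max(abs(residuals))))
  lambdas <- c(q$lambda0, lam_free)
  names(lambdas) <- paste0("lambda_",
                           vapply(functions, `[[`, "", "label"))
  names(lambdas)[1L] <- "lambda0"
  structure(list(lambdas = lambdas, functions = functions, support = support,
                 constraints = constraints, residuals = residuals,
                 converged = converged, solver = solver,
                 n_quad = ctrl$n_quad, diagnostics = diagnostics),
            class = "maxent")
}

#' Fit a maximum-entropy density to a sample
#'
#' Convenience wrapper: computes empirical moments of the chosen known
#' functions, picks a default support from the sample range, and solves the
#' moment problem.
#'
#' @param x Numeric sample.
#' @param functions List of [known_fun()]; default [aif_function_set()].
#' @param support Interval; default
#'   `c(max(1e-6, 0.5 * min(x)), 1.5 * max(x))`, which keeps log-type
#'   functions integrable near zero.
#' @inheritParams maxent_solve
#' @return A `maxent` object (see [maxent_solve()]) with the sample size in
#'   `$n`.
#' @examples
#' set.seed(1)
#' fit <- maxent(rweibull(500, 3, 1.85))
#' print(fit)
#' @export
maxent <- function(x, functions = aif_function_set(), support = NULL,
                   solver = c("dual_descent", "tlbo"), control = list()) {
  if (is.null(support))
    support <- c(max(1e-6, 0.5 * min(x)), 1.5 * max(x))
  mc <- empirical_moments(x, functions)
  fit <- maxent_solve(mc, support, solver = match.arg(solver),
                      control = control)
  fit$n <- length(x)
  fit$data <- x
  fit
}

#' Evaluate a fitted maximum-entropy density
#'
#' @param object A `maxent` object.
#' @param newdata Numeric vector of points; points outside the support get
#'   density 0.
#' @param ... Ignored.
#' @return Numeric vector of density values.
#' @export
predict.maxent <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  out <- numeric(length(x))
  inside <- x >= object$support[1] & x <= object$support[2] & is.finite(x)
  if (any(inside)) {
    xs <- x[inside]
    expo <- rep(-object$lambdas[1L], length(xs))
    for (k in seq_along(object$functions)[-1L])
      expo <- expo - object$lambdas[k] * object$functions[[k]]$eval(xs)
    out[inside] <- exp(expo)
  }
  out
}

#' @export
coef.maxent <- function(object, ...) object$lambdas

#' @export
print.maxent <- function(x, ...) {
  cat("Maximum-entropy density fit\n")
  cat("  f(x) = exp(-", paste(
    sprintf("%.4f*%s", unname(x$lambdas),
            vapply(x$functions, `[[`, "", "label")), collapse = " - "),
    ")\n", sep = "")
  cat(sprintf("  support [%.4g, %.4g], solver %s, converged: %s\n",
              x$support[1], x$support[2], x$solver, x$converged))
  cat(sprintf("  max constraint residual: %.3g\n", max(abs(x$residuals))))
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  ent <- density_entropy(object, object$support)
  out <- list(lambdas = object$lambdas, residuals = object$residuals,
              entropy = ent, converged = object$converged,
              solver = object$solver, support = object$support)
  class(out) <- "summary.maxent"
  out
}

#' @export
print.summary.maxent <- function(x, ...) {
  cat("Maximum-entropy density\n  multipliers:\n")
  print(x$lambdas)
  cat(sprintf("  differential entropy: %.4f nats\n", x$entropy))
  cat(sprintf("  max residual: %.3g (converged: %s, solver: %s)\n",
              max(abs(x$residuals)), x$converged, x$solver))
  invisible(x)
}

#' @export
plot.maxent <- function(x, n = 400, ...) {
  xs <- seq(x$support[1], x$support[2], length.out = n)
  if (!is.null(x$data)) {
    graphics::hist(x$data, freq = FALSE, breaks = "FD", col = "grey90",
                   border = "grey70", main = "Maximum-entropy density",
                   xlab = "x", ...)
    graphics::lines(xs, predict(x, xs), col = "firebrick", lwd = 2)
  } else {
    graphics::plot(xs, predict(x, xs), type = "l", col = "firebrick",
                   lwd = 2, xlab = "x", ylab = "density",
                   main = "Maximum-entropy density", ...)
  }
  invisible(x)
}

#' Serialize a fitted maximum-entropy density to JSON
#' @param object A `maxent` object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
maxent_to_json <- function(object, path = NULL) {
  payload <- list(
    functions = lapply(object$functions,
                       function(f) list(tag = f$tag, p = f$p)),
    lambdas = unname(object$lambdas),
    support = object$support,
    solver = object$solver,
    converged = object$converged,
    residuals = unname(object$residuals))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Blind AIF estimation from a plasma concentration curve
#'
#' Fits a maximum-entropy density to the plasma concentration-time curve and
#' reconstructs an estimated arterial input function from it. In
#' `mode = "value_density"` (the default) the density is fitted to the
#' concentration *values* and the estimated AIF at each time point is the
#' fitted density evaluated at the measured concentration,
#' `AIF(t_i) = f(Cp(t_i))`, optionally rescaled so its time integral matches
#' that of the measured curve. In `mode = "time_density"` time points are
#' resampled with probability proportional to concentration, the density is
#' fitted over time, and the AIF is `f(t)` times the curve's time integral.
#'
#' @param cp_curve A [conc_ts()] plasma curve, or a numeric vector of
#'   concentration samples (value mode only).
#' @param functions Known-function set; default [aif_function_set()].
#' @param mode `"value_density"` or `"time_density"`.
#' @param solver,control Passed to [maxent_solve()].
#' @param rescale Rescale the estimated AIF to match the measured curve's
#'   time integral (default `TRUE`; ignored for plain vector input).
#' @param n_resample Resample size for time mode (default 2000).
#' @param zero_floor In value mode, samples below `zero_floor * max(values)`
#'   are treated as zero concentration and excluded (with a logged count)
#'   when log-type functions are in play: late-time tail values many orders
#'   of magnitude below the peak are indistinguishable from zero and would
#'   otherwise dominate the log moment. Default 1e-3.
#' @return List of class `aif_fit`: `density` (a `maxent` object), `aif`
#'   (estimated AIF as a [conc_ts()], or vector for vector input), `mode`,
#'   `n_excluded` (non-positive samples dropped under log-type functions).
#' @export
fit_aif_density <- function(cp_curve, functions = aif_function_set(),
                            mode = c("value_density", "time_density"),
                            solver = c("dual_descent", "tlbo"),
                            control = list(), rescale = TRUE,
                            n_resample = 2000L, zero_floor = 1e-3) {
  mode <- match.arg(mode)
  solver <- match.arg(solver)
  is_curve <- inherits(cp_curve, "conc_ts")
  values <- if (is_curve) cp_curve$values else as.numeric(cp_curve)

  n_excluded <- 0L
  if (mode == "value_density") {
    samples <- values
    if (needs_positive_support(functions)) {
      keep <- samples > zero_floor * max(samples)
      n_excluded <- sum(!keep)
      if (n_excluded > 0L)
        message(sprintf("excluded %d zero-level samples under log-type functions",
                        n_excluded))
      samples <- samples[keep]
    }
    if (length(samples) < 2L) stop("too few usable samples for density fitting")
    fit <- maxent(samples, functions, solver = solver, control = control)
    est <- predict(fit, values)
    if (is_curve && rescale) {
      auc_cp <- pracma::trapz(cp_curve$times, values)
      auc_est <- pracma::trapz(cp_curve$times, est)
      if (auc_est > 0) est <- est * auc_cp / auc_est
    }
  } else {
    if (!is_curve) stop("time_density mode needs a conc_ts curve")
    w <- pmax(values, 0)
    if (sum(w) <= 0) stop("curve has no positive mass for time resampling")
    seed <- if (!is.null(control$seed)) control$seed else NULL
    samples <- with_seed(seed,
      sample(cp_curve$times, size = n_resample, replace = TRUE,
             prob = w / sum(w)))
    tspan <- range(cp_curve$times)
    supp <- c(max(1e-6, tspan[1]), tspan[2] * 1.000001 + 1e-6)
    fit <- maxent(samples, functions, support = supp, solver = solver,
                  control = control)
    auc_cp <- pracma::trapz(cp_curve$times, values)
    est <- predict(fit, cp_curve$times) * auc_cp
  }
  aif <- if (is_curve)
    conc_ts(cp_curve$times, est, patient_id = cp_curve$patient_id)
  else est
  structure(list(density = fit, aif = aif, mode = mode,
                 n_excluded = n_excluded),
            class = "aif_fit")
}

#' @export
print.aif_fit <- function(x, ...) {
  cat(sprintf("Blind AIF estimate (%s mode)\n", x$mode))
  print(x$density)
  invisible(x)
}
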