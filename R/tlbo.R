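#' Control settings for the teaching-learning-based optimizer
#'
#' @param population_size Number of learners (candidate solutions); at least 2.
#' @param max_iterations Maximum number of teacher+learner cycles.
#' @param tolerance Stop early when the best objective has improved by less
#'   than this over the last `patience` iterations.
#' @param patience Window length (iterations) for the improvement-based stop.
#' @param seed Optional integer seed; fixing it makes the run deterministic.
#' @param pairing Learner-phase pairing rule. `"self"` pairs each learner with
#'   one random distinct partner and steps along (better - worse) of the pair;
#'   `"random_pair"` draws both interacting learners at random (possibly
#'   excluding the one being updated), stepping along the same direction.
#' @return A list of class `tlbo_control`.
#' @export
tlbo_control <- function(population_size = 30L, max_iterations = 500L,
                         tolerance = 1e-12, patience = 20L, seed = NULL,
                         pairing = c("self", "random_pair")) {
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("population_size must be >= 2")
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop("max_iterations must be >= 1")
  check_nonnegative(tolerance, "tolerance")
  structure(list(population_size = population_size,
                 max_iterations = max_iterations,
                 tolerance = tolerance,
                 patience = as.integer(patience),
                 seed = seed,
                 pairing = match.arg(pairing)),
            class = "tlbo_control")
}

clip_to_bounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Objective evaluation treating non-finite values as +Inf (proposal rejected).
safe_objective <- function(fn, x) {
  v <- tryCatch(fn(x), error = function(e) Inf)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
}

#' TLBO teacher phase
#'
#' Each learner is moved toward the current best solution ("teacher") and away
#' from the population mean: `x_new = x_old + r * (x_teacher - Tf * m)`, with
#' `r ~ U(0,1)` drawn per learner, the teaching factor `Tf` drawn from {1, 2}
#' with equal probability per learner, and `m` the column mean of the
#' population at phase start. A proposal is accepted only if strictly better;
#' out-of-bounds coordinates are clipped.
#'
#' @param population Numeric matrix, one learner per row.
#' @param objectives Objective values aligned with the rows.
#' @param fn Objective function of a numeric vector.
#' @param lower,upper Box bounds (recycled per dimension).
#' @param r,tf Optional fixed random draws (per learner), for reproducing a
#'   hand-traced step; by default drawn from the current RNG stream.
#' @return List with updated `population`, `objectives` and the number of
#'   `evaluations` spent.
#' @export
tlbo_teacher_phase <- function(population, objectives, fn, lower, upper,
                               r = NULL, tf = NULL) {
  n <- nrow(population)
  m <- colMeans(population)
  teacher <- population[which.min(objectives), , drop = TRUE]
  if (is.null(r)) r <- stats::runif(n)
  if (is.null(tf)) tf <- sample(1:2, n, replace = TRUE)
  for (i in seq_len(n)) {
    prop <- clip_to_bounds(population[i, ] + r[i] * (teacher - tf[i] * m),
                           lower, upper)
    v <- safe_objective(fn, prop)
    if (v < objectives[i]) {
      population[i, ] <- prop
      objectives[i] <- v
    }
  }
  list(population = population, objectives = objectives, evaluations = n)
}

#' TLBO learner phase
#'
#' Each learner interacts with peers and steps along the difference between
#' the better and the worse of the interacting pair,
#' `x_new = x_old + r * (x_better - x_worse)`, accepting the proposal only on
#' strict improvement. See [tlbo_control()] for the pairing rule.
#'
#' @inheritParams tlbo_teacher_phase
#' @param pairing `"self"` or `"random_pair"` (see [tlbo_control()]).
#' @param partners Optional integer vector of preset partners (pairing
#'   `"self"` only), for hand-traced tests.
#' @return List with updated `population`, `objectives`, `evaluations`.
#' @export
tlbo_learner_phase <- function(population, objectives, fn, lower, upper,
                               pairing = c("self", "random_pair"),
                               r = NULL, partners = NULL) {
  pairing <- match.arg(pairing)
  n <- nrow(population)
  if (n < 2L) stop("learner phase needs a population of at least 2")
  if (is.null(r)) r <- stats::runif(n)
  # proposals are built from the phase-start population (snapshot semantics)
  base_pop <- population
  base_obj <- objectives
  for (i in seq_len(n)) {
    if (pairing == "self") {
      p <- if (is.null(partners)) sample(seq_len(n)[-i], 1L) else partners[i]
      pair <- c(i, p)
    } else {
      pair <- sample(seq_len(n), 2L)
    }
    better <- pair[which.min(base_obj[pair])]
    worse <- pair[pair != better][1L]
    step <- base_pop[better, ] - base_pop[worse, ]
    prop <- clip_to_bounds(base_pop[i, ] + r[i] * step, lower, upper)
    v <- safe_objective(fn, prop)
    if (v < objectives[i]) {
      population[i, ] <- prop
      objectives[i] <- v
    }
  }
  list(population = population, objectives = objectives, evaluations = n)
}

#' Teaching-learning-based optimization (TLBO)
#'
#' Population metaheuristic alternating a teacher phase (move toward the best
#' solution) and a learner phase (pairwise interaction), with greedy
#' acceptance, for minimizing a function over a bounded box. No algorithmic
#' hyperparameters beyond population size are required, and there is no
#' starting-point dependence: the initial population is uniform over the box.
#'
#' @param fn Objective function taking a numeric vector, returning a scalar;
#'   non-finite returns are treated as +Inf (the proposal is rejected).
#' @param lower,upper Finite numeric bounds, one per dimension.
#' @param control A [tlbo_control()] list.
#' @return Object of class `tlbo`: `best_solution`, `best_objective`,
#'   `trace` (best objective after each iteration, non-increasing),
#'   `evaluations`, `iterations`, `converged`.
#' @examples
#' res <- tlbo(function(x) sum(x^2), lower = c(-5, -5), upper = c(5, 5),
#'             control = tlbo_control(seed = 1, max_iterations = 100))
#' res$best_objective
#' @export
tlbo <- function(fn, lower, upper, control = tlbo_control()) {
  stopifnot(length(lower) == length(upper))
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper in every dimension")
  d <- length(lower)
  with_seed(control$seed, {
    n <- control$population_size
    pop <- matrix(stats::runif(n * d, rep(lower, each = n), rep(upper, each = n)),
                  nrow = n)
    obj <- apply(pop, 1L, function(x) safe_objective(fn, x))
    evals <- n
    trace <- numeric(control$max_iterations)
    iter <- 0L
    converged <- FALSE
    while (iter < control$max_iterations) {
      iter <- iter + 1L
      st <- tlbo_teacher_phase(pop, obj, fn, lower, upper)
      sl <- tlbo_learner_phase(st$population, st$objectives, fn, lower, upper,
                               pairing = control$pairing)
      pop <- sl$population
      obj <- sl$objectives
      evals <- evals + st$evaluations + sl$evaluations
      trace[iter] <- min(obj)
      if (iter > control$patience &&
          trace[iter - control$patience] - trace[iter] < control$tolerance) {
        converged <- TRUE
        break
      }
    }
    best <- which.min(obj)
    structure(list(best_solution = pop[best, , drop = TRUE],
                   best_objective = obj[best],
                   trace = trace[seq_len(iter)],
                   evaluations = evals,
                   iterations = iter,
                   converged = converged || iter == control$max_iterations),
              class = "tlbo")
  })
}

#' @export
print.tlbo <- function(x, ...) {
  cat("TLBO minimization\n")
  cat(sprintf("  best objective: %.6g after %d iterations (%d evaluations)\n",
              x$best_objective, x$iterations, x$evaluations))
  cat("  best solution:", format(x$best_solution, digits = 6), "\n")
  invisible(x)
}
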