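# Shared fixtures, all generated in code.

# Fine-grid biexponential plasma curve with a closed-form tissue response.
biexp_fixture <- function(dt = 0.01, t_max = 10, k1 = 0.25, k2 = 0.2,
                          a1 = 3.99, a2 = 4.78, m1 = 0.144, m2 = 0.0111) {
  n <- round(t_max / dt) + 1L
  grid <- time_grid(interval = dt, n_points = n, unit = "min")
  cp <- generate_aif_curve(aif_biexp(a1, a2, m1, m2), grid)
  closed <- function(t)
    k1 * (a1 * (exp(-m1 * t) - exp(-k2 * t)) / (k2 - m1) +
          a2 * (exp(-m2 * t) - exp(-k2 * t)) / (k2 - m2))
  list(grid = grid, cp = cp, k1 = k1, k2 = k2,
       ct_closed = closed(grid$times))
}

# Moment-constraint object without going through a sample.
make_constraints <- function(tags, values, p = NULL) {
  fns <- lapply(seq_along(tags), function(i)
    if (tags[i] == "power") known_fun("power", p[[i]]) else known_fun(tags[i]))
  structure(list(functions = fns, values = values),
            class = "moment_constraints")
}

study_grid <- function() time_grid(interval = 11.9, n_points = 46)
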