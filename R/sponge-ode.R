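# Predator-prey competition model of miRNA sponging: two miRNA species
# ("predators" X, Y) consume two mRNA species ("preys" A, B) at mass-action
# rates; a predator disappears when it consumes a prey, and all species are
# produced at a common constant rate.
#
#   dx/dt = rho - a11 x a - a12 x b
#   dy/dt = rho - a21 y a - a22 y b
#   da/dt = rho - a11 x a - a21 y a
#   db/dt = rho - a12 x b - a22 y b

#' Define a predator-prey scenario
#'
#' @param alpha 2x2 matrix of reaction rates, `alpha[i, j]` coupling
#'   predator i (X, Y) with prey j (A, B).
#' @param rho shared production rate of all species (default 0.002).
#' @param x0,y0,a0,b0 initial concentrations (defaults 0.25, 0.35, 0.3,
#'   0.2 — the published values).
#' @param t_end simulation horizon (default 1000 time units).
#' @param n_out number of uniform output grid points (default 1001).
#' @param label scenario name.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(alpha, rho = 0.002, x0 = 0.25, y0 = 0.35,
                          a0 = 0.3, b0 = 0.2, t_end = 1000, n_out = 1001L,
                          label = "custom") {
  alpha <- as.matrix(alpha)
  if (!identical(dim(alpha), c(2L, 2L)) || any(alpha < 0)) {
    abort("alpha must be a 2x2 matrix of non-negative rates")
  }
  if (rho < 0) abort("rho must be non-negative")
  if (any(c(x0, y0, a0, b0) < 0)) abort("initial concentrations must be non-negative")
  if (t_end <= 0) abort("t_end must be positive")
  structure(
    list(alpha = unname(alpha), rho = rho, x0 = x0, y0 = y0, a0 = a0,
         b0 = b0, t_end = t_end, n_out = as.integer(n_out), label = label),
    class = "scenario_spec"
  )
}

#' The three published competition scenarios
#'
#' * S1 — two predators compete for one prey with equal rates (0.5; the
#'   published account states equality but not the value).
#' * S2 — one prey, unequal rates: X at 0.75, Y at 0.25.
#' * S3 — two preys; both predators hit prey A at 0.9, but X takes prey B
#'   at 0.5 against Y's 0.1.
#'
#' One-prey scenarios are encoded with `b0 = 0` and zero B-column rates so
#' a single 4-state integrator covers all three.
#'
#' @return Named list of `scenario_spec` objects.
#' @export
scenario_library <- function() {
  list(
    S1 = scenario_spec(matrix(c(0.5, 0, 0.5, 0), 2L, byrow = TRUE),
                       b0 = 0, label = "S1"),
    S2 = scenario_spec(matrix(c(0.75, 0, 0.25, 0), 2L, byrow = TRUE),
                       b0 = 0, label = "S2"),
    S3 = scenario_spec(matrix(c(0.9, 0.5, 0.9, 0.1), 2L, byrow = TRUE),
                       label = "S3")
  )
}

ode_rhs <- function(state, rho, alpha) {
  x <- state[1L]; y <- state[2L]; a <- state[3L]; b <- state[4L]
  c(rho - alpha[1L, 1L] * x * a - alpha[1L, 2L] * x * b,
    rho - alpha[2L, 1L] * y * a - alpha[2L, 2L] * y * b,
    rho - alpha[1L, 1L] * x * a - alpha[2L, 1L] * y * a,
    rho - alpha[1L, 2L] * x * b - alpha[2L, 2L] * y * b)
}

# Dormand-Prince 5(4) coefficients
.dp <- list(
  c = c(0, 1/5, 3/10, 4/5, 8/9, 1, 1),
  a = list(
    numeric(0),
    c(1/5),
    c(3/40, 9/40),
    c(44/45, -56/15, 32/9),
    c(19372/6561, -25360/2187, 64448/6561, -212/729),
    c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
    c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84)
  ),
  b5 = c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0),
  b4 = c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
)

#' Simulate a competition scenario
#'
#' Adaptive embedded Runge-Kutta integration (Dormand-Prince 5(4) with
#' standard PI-free step control), sampled on the scenario's uniform
#' output grid.  The model is positivity-preserving (every loss term
#' vanishes at zero concentration and production is non-negative), so a
#' negative excursion beyond `-atol` is treated as an integrator failure;
#' round-off undershoots within tolerance are clamped to zero.
#'
#' @param spec a `scenario_spec`.
#' @param rtol,atol relative and absolute local error tolerances.
#' @return A `trajectory_set` data frame with columns `time`, `x`, `y`,
#'   `a`, `b`.
#' @export
simulate_scenario <- function(spec, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- seq(0, spec$t_end, length.out = spec$n_out)
  out <- matrix(NA_real_, spec$n_out, 4L)
  state <- c(spec$x0, spec$y0, spec$a0, spec$b0)
  out[1L, ] <- state
  t <- 0
  h <- min(spec$t_end / 100, 1)
  gi <- 2L
  k <- matrix(0, 7L, 4L)
  max_steps <- 1e6L
  steps <- 0L
  while (gi <= spec$n_out) {
    h <- min(h, grid[gi] - t)
    k[1L, ] <- ode_rhs(state, spec$rho, spec$alpha)
    for (s in 2L:7L) {
      inc <- colSums(k[seq_len(s - 1L), , drop = FALSE] * .dp$a[[s]])
      k[s, ] <- ode_rhs(state + h * inc, spec$rho, spec$alpha)
    }
    y5 <- state + h * colSums(k * .dp$b5)
    y4 <- state + h * colSums(k * .dp$b4)
    sc <- atol + rtol * pmax(abs(state), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (err <= 1) {
      t <- t + h
      state <- y5
      if (any(state < -atol)) {
        abort(sprintf("integrator produced negative concentration at t = %.4g", t))
      }
      state <- pmax(state, 0)
      while (gi <= spec$n_out && abs(t - grid[gi]) <= 1e-12 * max(1, t)) {
        out[gi, ] <- state
        gi <- gi + 1L
      }
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-16))^(1 / 5)))
    steps <- steps + 1L
    if (steps > max_steps) abort("integrator failed: step limit reached")
  }
  traj <- data.frame(time = grid, x = out[, 1L], y = out[, 2L],
                     a = out[, 3L], b = out[, 4L])
  attr(traj, "spec") <- spec
  class(traj) <- c("trajectory_set", "data.frame")
  traj
}

#' Pearson correlation of the two predator time courses
#'
#' The published reading of network connectivity for the model: the
#' concentrations of two miRNAs competing for a common target are linearly
#' correlated over time.
#'
#' @param traj a `trajectory_set`.
#' @param window optional `c(t_min, t_max)` restricting the correlation to
#'   a time interval; default is the full horizon.
#' @return Pearson r between `x(t)` and `y(t)`.
#' @export
trajectory_correlation <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  keep <- if (is.null(window)) {
    rep(TRUE, nrow(traj))
  } else {
    traj$time >= window[1L] & traj$time <= window[2L]
  }
  if (sum(keep) < 3L) abort("correlation window contains fewer than 3 grid points")
  stats::cor(traj$x[keep], traj$y[keep])
}

#' Two-node network representation of a scenario
#'
#' Simulates the scenario and connects the predator nodes X and Y iff the
#' trajectory correlation reaches the threshold (default 0.8, matching the
#' correlation-method network threshold).
#'
#' @param spec a `scenario_spec`.
#' @param threshold edge threshold on the predator correlation.
#' @param window optional correlation window (see
#'   [trajectory_correlation()]).
#' @param rtol,atol integrator tolerances.
#' @return A `mirna_network` on nodes X and Y with edge attribute `r`.
#' @export
scenario_network <- function(spec, threshold = 0.8, window = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  r <- trajectory_correlation(simulate_scenario(spec, rtol, atol), window)
  edges <- if (r >= threshold) matrix(c("X", "Y"), 1L) else NULL
  attrs <- if (!is.null(edges)) data.frame(r = r) else NULL
  net <- mirna_network(c("X", "Y"), edges, attrs, method = "correlation")
  attr(net, "r") <- r
  net
}

#' Endpoint correlation across an ensemble of perturbed systems
#'
#' Alternative reading of model-induced connectivity: correlate the final
#' predator concentrations across replicate systems whose initial
#' concentrations are jittered log-normally.  Provided because the
#' published account does not state how its correlation networks were
#' derived from the model; report both modes when they disagree.
#'
#' @param spec a `scenario_spec`.
#' @param n_reps number of replicate systems (default 200).
#' @param perturb_sd log-scale SD of the initial-condition jitter; must be
#'   positive (a zero jitter leaves nothing to correlate).
#' @param seed integer seed.
#' @param rtol,atol integrator tolerances (looser than the time-series
#'   default; the endpoint statistic is an ensemble property).
#' @return Pearson r of endpoint x against endpoint y.
#' @export
ensemble_correlation <- function(spec, n_reps = 200L, perturb_sd = 0.2,
                                 seed = NULL, rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.numeric(perturb_sd) || perturb_sd <= 0) {
    abort("perturb_sd must be positive; a zero jitter has undefined correlation")
  }
  if (n_reps < 3L) abort("n_reps must be at least 3")
  jit <- with_seed(seed, matrix(exp(stats::rnorm(4L * n_reps, 0, perturb_sd)),
                                n_reps, 4L))
  ends <- t(vapply(seq_len(n_reps), function(i) {
    sp <- spec
    sp$x0 <- spec$x0 * jit[i, 1L]
    sp$y0 <- spec$y0 * jit[i, 2L]
    sp$a0 <- spec$a0 * jit[i, 3L]
    sp$b0 <- spec$b0 * jit[i, 4L]
    sp$n_out <- 2L
    traj <- simulate_scenario(sp, rtol, atol)
    c(traj$x[2L], traj$y[2L])
  }, numeric(2L)))
  stats::cor(ends[, 1L], ends[, 2L])
}

#' Plot predator and prey trajectories
#'
#' Mirrors the published visual convention: predators in red, preys in
#' green.
#'
#' @param x a `trajectory_set`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trajectory_set <- function(x, ...) {
  spec <- attr(x, "spec")
  graphics::matplot(x$time, as.matrix(x[, c("x", "y", "a", "b")]),
                    type = "l", lty = c(1, 2, 1, 2),
                    col = c("red", "red", "green4", "green4"),
                    xlab = "t", ylab = "c",
                    main = spec$label %||% "", ...)
  graphics::legend("topleft", c("x (predator)", "y (predator)",
                                "a (prey)", "b (prey)"),
                   lty = c(1, 2, 1, 2),
                   col = c("red", "red", "green4", "green4"), bty = "n")
  invisible(x)
}
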