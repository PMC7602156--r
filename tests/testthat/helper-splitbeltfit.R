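# Shared fixtures for the test suite. All data are generated in code.

# Smaller swarm for unit tests of plumbing (the acceptance suite runs
# the default configuration).
quick_config <- function(seed = 1L, ...) {
  fit_config(seed = seed, swarm_size = 40L, stall_iters = 10L, ...)
}

# Fit the pure-mean model: both single-model parameters except c pinned
# (a = 0 makes b irrelevant), leaving one free parameter. Used for the
# closed-form interval checks.
pure_mean_fit <- function(y, seed = 1L) {
  b <- make_bounds("single", "+ve")
  b$lower[c("a", "b")] <- c(0, -0.1)
  b$upper[c("a", "b")] <- c(0, -0.1)
  fit_exp(y, "single", quick_config(seed = seed), bounds = b)
}

# Independent oracle for the overshoot: locate the interior extremum of
# the double-exponential trend by dense-grid bracketing followed by
# golden-section refinement; returns NULL when the grid shows no
# interior first-derivative sign change.
grid_extremum <- function(theta, n_hi = NULL) {
  th <- as.numeric(theta)
  if (is.null(n_hi)) {
    n_hi <- 10 * max(log(2) / abs(th[c(2L, 4L)]))
  }
  grid <- seq(0, n_hi, length.out = 20000L)
  f <- eval_double(th, grid)
  d <- diff(f)
  flips <- which(d[-length(d)] * d[-1L] < 0)
  if (length(flips) == 0L) return(NULL)
  i <- flips[1L]
  maximising <- d[i] > 0
  opt <- stats::optimize(function(n) eval_double(th, n),
                         lower = grid[i], upper = grid[i + 2L],
                         maximum = maximising, tol = 1e-12)
  list(ncrit = if (maximising) opt$maximum else opt$minimum,
       ycrit = opt$objective)
}

# Draw an admissible opposite-sign double-model parameter vector whose
# extremum is interior (verified by the grid oracle, not the formula).
random_overshoot_theta <- function() {
  repeat {
    s <- sample(c(-1, 1), 1L)
    th <- c(s * stats::runif(1, 0.05, 1),
            -stats::runif(1, 1e-3, log(2)),
            -s * stats::runif(1, 0.05, 1),
            -stats::runif(1, 1e-3, log(2)),
            stats::runif(1, -0.1, 0.1))
    if (th[4L] >= th[2L] - 1e-3) next
    if (abs(th[1L] + th[3L]) > 2) next
    if (!is.null(grid_extremum(th))) return(th)
  }
}
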