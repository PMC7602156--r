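#' Specification of a synthetic symmetry series
#'
#' Defines a generator of the data the exponential models assume: an
#' exponential trend (single or double) plus iid zero-mean Gaussian
#' noise, optionally plus a sinusoid mimicking the cyclic residual
#' trends seen in participant-level series. A spec whose trend (plus
#' sinusoid amplitude) ± 4 sigma leaves the admissible symmetry range
#' `[-1, 1]` is rejected outright: clipping generated values would
#' silently break the Gaussian-noise assumption.
#'
#' @param theta a [theta_single()] or [theta_double()].
#' @param sigma residual standard deviation (unitless, >= 0).
#' @param n number of strides.
#' @param seed seed used by [simulate_series()] unless overridden there.
#' @param cyclic optional `list(amplitude =, period =)` sinusoid
#'   `A sin(2 pi n / T)` added to the trend (period in strides).
#' @param label label for generated series.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(theta, sigma, n, seed = NULL, cyclic = NULL,
                            label = "simulated") {
  kind <- theta_kind(theta)
  sigma <- as.numeric(sigma)
  n <- as.integer(n)
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  amp <- 0
  if (!is.null(cyclic)) {
    if (!is.list(cyclic) || is.null(cyclic$amplitude) || is.null(cyclic$period)) {
      stop("cyclic must be list(amplitude =, period =)", call. = FALSE)
    }
    if (cyclic$period <= 0) stop("cyclic period must be positive", call. = FALSE)
    amp <- abs(cyclic$amplitude)
  }
  trend <- eval_trend(as.numeric(theta), seq_len(n))
  if (max(trend) + amp + 4 * sigma > 1 || min(trend) - amp - 4 * sigma < -1) {
    stop("rejected: trend +/- sinusoid +/- 4 sigma exits the symmetry range [-1, 1]",
         call. = FALSE)
  }
  structure(list(theta = theta, kind = kind, sigma = sigma, n = n,
                 seed = seed, cyclic = cyclic,
                 label = as.character(label)[1L]),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec '%s': %s exponential trend, N = %d, sigma = %g%s\n",
              x$label, x$kind, x$n, x$sigma,
              if (!is.null(x$cyclic))
                sprintf(", sinusoid A = %g, T = %g", x$cyclic$amplitude,
                        x$cyclic$period) else ""))
  invisible(x)
}

#' Generate a synthetic symmetry series
#'
#' Draws `y(n) = f(n; theta) [+ A sin(2 pi n / T)] + eps(n)` with
#' `eps ~ N(0, sigma^2)` iid over strides. Deterministic given the seed.
#'
#' @param spec a [simulation_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return A [symmetry_series()].
#' @export
#' @examples
#' s <- simulation_spec(theta_single(0.1, -0.02, 0.02), 0.006, 750, seed = 1)
#' y <- simulate_series(s)
simulate_series <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(seed)) seed <- spec$seed
  trend <- eval_trend(as.numeric(spec$theta), seq_len(spec$n))
  if (!is.null(spec$cyclic)) {
    trend <- trend + spec$cyclic$amplitude *
      sin(2 * pi * seq_len(spec$n) / spec$cyclic$period)
  }
  eps <- if (is.null(seed)) {
    stats::rnorm(spec$n, 0, spec$sigma)
  } else {
    withr::with_seed(as.integer(seed),
                     stats::rnorm(spec$n, 0, spec$sigma))
  }
  symmetry_series(trend + eps, label = spec$label)
}

#' Bundled example simulation specs
#'
#' Four specs emulating the statistical structure of group-averaged
#' adaptation and de-adaptation symmetry series over two training
#' sessions: double exponential trends with slow/fast half-lives,
#' residual SD in the 5–7e-3 range, ~750 strides for adaptation-like and
#' ~500 for de-adaptation-like phases. One adaptation spec carries
#' opposite-sign amplitudes and therefore a positive overshoot. The
#' parameter values are chosen to be of realistic magnitude for
#' split-belt treadmill training; they emulate, and do not replicate,
#' any particular experimental dataset.
#'
#' @return Named list of [simulation_spec()] objects:
#'   `adaptation1`, `adaptation2`, `deadaptation1`, `deadaptation2`.
#' @export
default_specs <- function() {
  list(
    adaptation1 = simulation_spec(
      theta_double(as = -0.090, bs = -log(2) / 235,
                   af = -0.048, bf = -log(2) / 21, c = 0.024),
      sigma = 0.0064, n = 750, seed = 101, label = "adaptation1"),
    adaptation2 = simulation_spec(
      theta_double(as = 0.050, bs = -log(2) / 30,
                   af = -0.113, bf = -log(2) / 8, c = 0.030),
      sigma = 0.0056, n = 750, seed = 102, label = "adaptation2"),
    deadaptation1 = simulation_spec(
      theta_double(as = 0.080, bs = -log(2) / 100,
                   af = 0.037, bf = -log(2) / 15, c = 0.024),
      sigma = 0.0070, n = 500, seed = 103, label = "deadaptation1"),
    deadaptation2 = simulation_spec(
      theta_double(as = 0.070, bs = -log(2) / 58,
                   af = 0.028, bf = -log(2) / 4, c = 0.027),
      sigma = 0.0062, n = 500, seed = 104, label = "deadaptation2"))
}
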