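#' Parameters of the single exponential trend model
#'
#' The single exponential model for a symmetry series is
#' \deqn{y(n) = f_1(n;\theta) + \epsilon(n), \quad
#'       f_1(n;\theta) = a e^{bn} + c,}
#' with zero-mean Gaussian residuals \eqn{\epsilon(n)}. For a decaying
#' trend the parameters have direct interpretations: `a` is the change in
#' symmetry from the start to the end of the phase, `b < 0` the rate
#' constant (per stride) and `c` the symmetry at the end of the phase.
#'
#' @param a change amplitude (unitless).
#' @param b rate constant per stride; decaying trends have `b <= 0`.
#' @param c final-value offset (unitless).
#' @return Named numeric vector of class `theta_single`.
#' @export
theta_single <- function(a, b, c) {
  th <- c(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c))
  if (any(!is.finite(th))) stop("parameters must be finite", call. = FALSE)
  class(th) <- c("theta_single", "theta")
  th
}

#' Parameters of the double exponential trend model
#'
#' The double exponential model
#' \deqn{f_2(n;\theta) = a_s e^{b_s n} + a_f e^{b_f n} + c}
#' decomposes the trend into a slow (`as`, `bs`) and a fast (`af`, `bf`)
#' exponential process; fitted instances satisfy `bf < bs <= 0` (the fast
#' process decays faster) and `|as + af| <= 2`.
#'
#' @param as,af slow/fast change amplitudes (unitless).
#' @param bs,bf slow/fast rate constants (per stride).
#' @param c final-value offset.
#' @return Named numeric vector of class `theta_double`.
#' @export
theta_double <- function(as, bs, af, bf, c) {
  th <- c(as = as.numeric(as), bs = as.numeric(bs), af = as.numeric(af),
          bf = as.numeric(bf), c = as.numeric(c))
  if (any(!is.finite(th))) stop("parameters must be finite", call. = FALSE)
  class(th) <- c("theta_double", "theta")
  th
}

theta_kind <- function(theta) {
  if (inherits(theta, "theta_single")) return("single")
  if (inherits(theta, "theta_double")) return("double")
  if (is.numeric(theta) && length(theta) == 3L) return("single")
  if (is.numeric(theta) && length(theta) == 5L) return("double")
  stop("theta must have 3 (single) or 5 (double) parameters", call. = FALSE)
}

#' Evaluate the single exponential trend
#'
#' @param theta a [theta_single()] (or numeric `c(a, b, c)`).
#' @param n stride indices; an integer scalar `n` is expanded to
#'   `1:n`, a vector is used as-is (real-valued indices are allowed,
#'   e.g. for locating an overshoot between strides).
#' @return Trend values \eqn{a e^{bn} + c}.
#' @export
#' @examples
#' eval_single(theta_single(1, -log(2), 0), 3)  # 0.5 0.25 0.125
eval_single <- function(theta, n) {
  theta <- as.numeric(theta)
  if (length(theta) != 3L) stop("single model needs 3 parameters",
                                call. = FALSE)
  n <- expand_strides(n)
  theta[1L] * exp(theta[2L] * n) + theta[3L]
}

#' Evaluate the double exponential trend
#'
#' @param theta a [theta_double()] (or numeric `c(as, bs, af, bf, c)`).
#' @inheritParams eval_single
#' @return Trend values \eqn{a_s e^{b_s n} + a_f e^{b_f n} + c}.
#' @export
eval_double <- function(theta, n) {
  theta <- as.numeric(theta)
  if (length(theta) != 5L) stop("double model needs 5 parameters",
                                call. = FALSE)
  n <- expand_strides(n)
  theta[1L] * exp(theta[2L] * n) + theta[3L] * exp(theta[4L] * n) + theta[5L]
}

expand_strides <- function(n) {
  if (length(n) == 1L && is.numeric(n) && n >= 1 && n == floor(n)) {
    return(seq_len(n))
  }
  as.numeric(n)
}

# Evaluate either model from a plain parameter vector.
eval_trend <- function(theta, n) {
  if (theta_kind(theta) == "single") eval_single(theta, n)
  else eval_double(theta, n)
}

#' Overshoot of the double exponential trend
#'
#' A double exponential trend can swing past its asymptote `c` when the
#' two amplitudes have opposite signs. Setting the first derivative of
#' \eqn{f_2} to zero gives the critical stride
#' \deqn{n_{crit} = \frac{\ln(-a_s b_s / (a_f b_f))}{b_f - b_s},}
#' and the overshoot value \eqn{y_{crit} = f_2(n_{crit})}. When
#' \eqn{a_s a_f \ge 0} the logarithm argument is non-positive and no
#' overshoot exists (reported as undefined, printed "UD").
#'
#' @param theta a [theta_double()].
#' @param n_max optional observed stride count; when given, the result
#'   carries an `observable` flag marking whether `ncrit` falls inside
#'   `[1, n_max]` (an extremum outside the observed range cannot be seen
#'   in the data).
#' @return List of class `overshoot_result` with elements `defined`,
#'   `ncrit`, `ycrit`, `observable` and `note`.
#' @export
#' @examples
#' overshoot(theta_double(0.5, -0.01, -0.5, -0.1, 0))  # ncrit ~ 25.58
overshoot <- function(theta, n_max = NULL) {
  th <- as.numeric(theta)
  if (length(th) != 5L) stop("overshoot is defined for the double model",
                             call. = FALSE)
  as_ <- th[1L]; bs <- th[2L]; af <- th[3L]; bf <- th[4L]
  und <- function(note) {
    structure(list(defined = FALSE, ncrit = NA_real_, ycrit = NA_real_,
                   observable = NA, note = note),
              class = "overshoot_result")
  }
  if (bs == bf) return(und("equal rate constants: denominator of ncrit is zero"))
  if (as_ * af >= 0) {
    return(und("amplitudes do not have opposite signs"))
  }
  arg <- -as_ * bs / (af * bf)
  if (!is.finite(arg) || arg <= 0) {
    return(und("log argument non-positive (zero amplitude or rate)"))
  }
  ncrit <- log(arg) / (bf - bs)
  ycrit <- eval_double(th, ncrit)
  observable <- if (is.null(n_max)) NA else (ncrit >= 1 && ncrit <= n_max)
  structure(list(defined = TRUE, ncrit = ncrit, ycrit = ycrit,
                 observable = observable, note = ""),
            class = "overshoot_result")
}

#' @export
print.overshoot_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("Overshoot: ycrit = %.4g at stride ncrit = %.2f%s\n",
                x$ycrit, x$ncrit,
                if (isFALSE(x$observable)) " (outside observed range)" else ""))
  } else {
    cat(sprintf("Overshoot: UD (%s)\n", x$note))
  }
  invisible(x)
}

#' Strides to complete approximately 50% of an exponential change
#'
#' For a decaying exponential with rate constant `rate < 0`,
#' \eqn{\lfloor \ln 2 / |rate| \rfloor} is the expected number of whole
#' strides needed to complete about half of the total change.
#'
#' @param rate rate constant (per stride), strictly negative.
#' @return Non-negative integer stride count.
#' @export
#' @examples
#' half_change_strides(-0.01)  # 69
half_change_strides <- function(rate) {
  rate <- as.numeric(rate)
  if (any(!is.finite(rate)) || any(rate >= 0)) {
    stop("half-change is defined only for decaying trends (rate < 0)",
         call. = FALSE)
  }
  as.integer(floor(log(2) / abs(rate)))
}

#' Common-language parameters of a fitted exponential trend
#'
#' Transforms regression parameters into quantities practitioners use:
#' initial asymmetry (`a + c`, or `as + af + c`), total change in
#' symmetry (`a`, or `as + af`), strides to 50% of the change (one per
#' exponential process), asymmetry at the end of the phase (`c`), the
#' overshoot (double model only; undefined for the single model), and
#' the residual standard deviation (about 68% of symmetry values fall
#' within one residual SD of the trend).
#'
#' @param theta a [theta_single()] or [theta_double()].
#' @param residual_sd residual scale estimate, e.g. `s` from a fit
#'   (`sqrt(SSE / (N - p))`); `NA` if unknown.
#' @param n_max optional observed stride count, forwarded to
#'   [overshoot()].
#' @return List of class `common_language`. The `degenerate` flag marks
#'   a double model with an amplitude of exactly zero — a boundary case
#'   no better than a single exponential model.
#' @export
to_common_language <- function(theta, residual_sd = NA_real_, n_max = NULL) {
  kind <- theta_kind(theta)
  th <- as.numeric(theta)
  if (kind == "single") {
    out <- list(
      model = "single",
      initial_asymmetry = th[1L] + th[3L],
      total_change = th[1L],
      half_change_strides = c(
        overall = if (th[2L] < 0) half_change_strides(th[2L]) else NA_integer_),
      final_asymmetry = th[3L],
      overshoot = structure(
        list(defined = FALSE, ncrit = NA_real_, ycrit = NA_real_,
             observable = NA, note = "single exponential model"),
        class = "overshoot_result"),
      residual_sd = residual_sd,
      degenerate = th[1L] == 0)
  } else {
    out <- list(
      model = "double",
      initial_asymmetry = th[1L] + th[3L] + th[5L],
      total_change = th[1L] + th[3L],
      half_change_strides = c(
        slow = if (th[2L] < 0) half_change_strides(th[2L]) else NA_integer_,
        fast = if (th[4L] < 0) half_change_strides(th[4L]) else NA_integer_),
      final_asymmetry = th[5L],
      overshoot = overshoot(th, n_max = n_max),
      residual_sd = residual_sd,
      degenerate = th[1L] == 0 || th[3L] == 0)
  }
  class(out) <- "common_language"
  out
}

#' @export
print.common_language <- function(x, digits = 3, ...) {
  cat(sprintf("Common-language parameters (%s exponential model)\n", x$model))
  cat(sprintf("  Asymmetry at beginning: %.*f\n", digits, x$initial_asymmetry))
  cat(sprintf("  Total change:           %.*f\n", digits, x$total_change))
  cat(sprintf("  Strides to 50%% change:  %s\n",
              paste(x$half_change_strides, collapse = "; ")))
  cat(sprintf("  Asymmetry at end:       %.*f\n", digits, x$final_asymmetry))
  if (x$model == "double") {
    cat("  ")
    print(x$overshoot)
  }
  cat(sprintf("  Residual SD:            %s\n",
              formatC(x$residual_sd, digits = digits, format = "g")))
  if (isTRUE(x$degenerate)) {
    cat("  Note: an amplitude is exactly 0 - double exponential model",
        "without an overshoot or a degenerate case\n")
  }
  invisible(x)
}

#' Map overshoot values over an amplitude/rate grid
#'
#' Enumerates admissible double-model parameter combinations over a grid
#' (amplitudes over `[-1, 1]`, rates over `[-ln 2, -1e-3]`, `c = 0`)
#' subject to `bf < bs` and `|as + af| <= 2`, and evaluates the
#' overshoot for each. This reproduces the numerical analysis used to
#' justify the amplitude bounds: every achievable overshoot lies in
#' `[-1, 1]` and requires amplitudes of opposite signs.
#'
#' @param as_values,af_values amplitude grids (default `seq(-1, 1, 0.1)`).
#' @param bs_values,bf_values rate grids (default 6 values spanning
#'   `[-ln 2, -1e-3]`).
#' @return `data.frame` with columns `as, bs, af, bf, defined, ncrit,
#'   ycrit`; inadmissible rate pairs (`bf >= bs`) are dropped.
#' @export
overshoot_map <- function(as_values = seq(-1, 1, by = 0.1),
                          af_values = seq(-1, 1, by = 0.1),
                          bs_values = default_rate_grid(),
                          bf_values = default_rate_grid()) {
  grid <- expand.grid(as = as_values, bs = bs_values, af = af_values,
                      bf = bf_values, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$bf < grid$bs & abs(grid$as + grid$af) <= 2, ,
               drop = FALSE]
  if (nrow(grid) == 0L) {
    stop("no admissible (as, bs, af, bf) combinations in the grid",
         call. = FALSE)
  }
  res <- lapply(seq_len(nrow(grid)), function(i) {
    os <- overshoot(c(grid$as[i], grid$bs[i], grid$af[i], grid$bf[i], 0))
    c(defined = os$defined, ncrit = os$ncrit, ycrit = os$ycrit)
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, defined = as.logical(res[, "defined"]),
               ncrit = res[, "ncrit"], ycrit = res[, "ycrit"])
  rownames(out) <- NULL
  out
}

# Rates spanning [-ln 2, -1e-3]; log-spaced because half-lives, not
# rates, are the natural scale.
default_rate_grid <- function(k = 6L) {
  -exp(seq(log(log(2)), log(1e-3), length.out = k))
}
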