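#' Akaike's information criterion for an exponential model fit
#'
#' \deqn{AIC = 2k + N \ln \sum_{n=1}^N \hat\epsilon(n)^2,}
#' where `k` counts the estimated parameters including the residual
#' variance: 4 for the full single and 6 for the full double exponential
#' model (free regression parameters + 1 in general).
#'
#' @param fit an [fit_exp()] result, or a plain SSE value.
#' @param n stride count (only when `fit` is a plain SSE).
#' @param k parameter count (defaults to free parameters + 1).
#' @return AIC value. A perfect fit (SSE = 0) has no finite AIC under
#'   this formula and raises an error.
#' @export
aic_exp <- function(fit, n = NULL, k = NULL) {
  if (inherits(fit, "exp_fit")) {
    sse <- fit$sse
    n <- fit$n
    if (is.null(k)) k <- fit$p + 1L
  } else {
    sse <- as.numeric(fit)
    if (is.null(n) || is.null(k)) {
      stop("n and k are required when passing a raw SSE", call. = FALSE)
    }
  }
  if (sse <= 0) {
    stop("AIC is undefined for a perfect fit (SSE = 0)", call. = FALSE)
  }
  2 * k + n * log(sse)
}

#' Select between the single and double exponential model by AIC
#'
#' Computes `delta = AIC(double) - AIC(single)` and selects the double
#' exponential model only when `delta < -2` (strictly); otherwise the
#' simpler single model is kept.
#'
#' @param fit_single,fit_double [fit_exp()] results on the same series.
#' @return List of class `aic_result` with `aic_single`, `aic_double`,
#'   `k_single`, `k_double`, `delta` and `selected`.
#' @export
select_model <- function(fit_single, fit_double) {
  stopifnot(inherits(fit_single, "exp_fit"), inherits(fit_double, "exp_fit"))
  if (fit_single$model != "single" || fit_double$model != "double") {
    stop("pass the single-model fit first and the double-model fit second",
         call. = FALSE)
  }
  if (fit_single$n != fit_double$n) {
    stop("fits were made on series of different lengths", call. = FALSE)
  }
  a1 <- aic_exp(fit_single)
  a2 <- aic_exp(fit_double)
  delta <- a2 - a1
  structure(list(aic_single = a1, aic_double = a2,
                 k_single = fit_single$p + 1L, k_double = fit_double$p + 1L,
                 delta = delta,
                 selected = if (delta < -2) "double" else "single"),
            class = "aic_result")
}

#' @export
print.aic_result <- function(x, ...) {
  cat(sprintf("AIC single = %.2f (k = %d), double = %.2f (k = %d)\n",
              x$aic_single, x$k_single, x$aic_double, x$k_double))
  cat(sprintf("delta = %.2f -> %s exponential model selected (rule: double iff delta < -2)\n",
              x$delta, x$selected))
  invisible(x)
}

#' Jacobian of the exponential trend with respect to its parameters
#'
#' Row `n` of the sensitivity matrix is
#' `[e^{bn}, a n e^{bn}, 1]` for the single model and
#' `[e^{b_s n}, a_s n e^{b_s n}, e^{b_f n}, a_f n e^{b_f n}, 1]` for the
#' double model.
#'
#' @param theta parameter vector (single or double).
#' @param n stride count (rows `1..n`) or vector of stride indices.
#' @param free optional logical mask; columns of pinned parameters are
#'   dropped.
#' @return `N x p` numeric matrix with parameter names as column names.
#' @export
model_jacobian <- function(theta, n, free = NULL) {
  kind <- theta_kind(theta)
  th <- as.numeric(theta)
  n <- expand_strides(n)
  J <- if (kind == "single") {
    e <- exp(th[2L] * n)
    cbind(a = e, b = th[1L] * n * e, c = 1)
  } else {
    es <- exp(th[2L] * n); ef <- exp(th[4L] * n)
    cbind(as = es, bs = th[1L] * n * es, af = ef, bf = th[3L] * n * ef,
          c = 1)
  }
  if (!is.null(free)) J <- J[, free, drop = FALSE]
  J
}

# Linearization artifacts: s^2, J, and the estimated variance matrix
# V = s^2 (J'J)^{-1} over the free parameters.
linearization <- function(fit) {
  J <- model_jacobian(fit$theta, fit$n, free = fit$free)
  s2 <- fit$s^2
  JtJ <- crossprod(J)
  V <- tryCatch(s2 * solve(JtJ), error = function(e) NULL)
  rc <- tryCatch(kappa(JtJ, exact = FALSE), error = function(e) Inf)
  list(jacobian = J, s2 = s2, vcov = V, p = ncol(J), condition = rc)
}

#' @export
vcov.exp_fit <- function(object, ...) linearization(object)$vcov

interval_estimate <- function(parameter, estimate, lower, upper, alpha,
                              method, note = "") {
  structure(list(parameter = parameter, estimate = estimate,
                 lower = lower, upper = upper, alpha = alpha,
                 method = method, note = note),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  fmt <- function(v) if (is.na(v)) "UD" else format(signif(v, digits))
  cat(sprintf("%s = %s, %.0f%% CI [%s, %s] (%s)%s\n", x$parameter,
              format(signif(x$estimate, digits)), 100 * (1 - x$alpha),
              fmt(x$lower), fmt(x$upper), x$method,
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

#' Linearized confidence intervals for the regression parameters
#'
#' Wald-type intervals \eqn{\hat\theta_j \pm \hat V_{jj}^{1/2}
#' t_{N-p,1-\alpha/2}} based on the linear approximation of the model at
#' \eqn{\hat\theta}, with \eqn{\hat V = s^2 (J^\top J)^{-1}} and
#' \eqn{s^2 = SSE/(N-p)}. These intervals assume the linearisation is
#' good; compare with [ci_profile()] when in doubt.
#'
#' @param fit an [fit_exp()] result.
#' @param alpha significance level (default 0.05 for 95% intervals).
#' @return List of `interval_estimate` objects, one per free parameter.
#'   A singular `J'J` yields undefined ("UD") endpoints with a
#'   conditioning note.
#' @export
ci_linearized <- function(fit, alpha = 0.05) {
  lin <- linearization(fit)
  nm <- names(which(fit$free))
  est <- as.numeric(fit$theta)[fit$free]
  if (is.null(lin$vcov) || any(diag(lin$vcov) < 0)) {
    return(stats::setNames(lapply(seq_along(nm), function(j) {
      interval_estimate(nm[j], est[j], NA_real_, NA_real_, alpha,
                        "linearized",
                        sprintf("J'J singular or indefinite (condition %.3g)",
                                lin$condition))
    }), nm))
  }
  tq <- stats::qt(1 - alpha / 2, fit$n - lin$p)
  half <- sqrt(diag(lin$vcov)) * tq
  stats::setNames(lapply(seq_along(nm), function(j) {
    interval_estimate(nm[j], est[j], est[j] - half[j], est[j] + half[j],
                      alpha, "linearized")
  }), nm)
}

# Re-optimise all parameters but the j-th (fixed at `value`), warm
# starting from `start_full`; returns the pure SSE at the constrained
# optimum. The profiled parameter may sit outside its fitting bounds
# (the profile search range is wider than the box).
profile_sse <- function(fit, series, j, value, start_full) {
  obj <- make_objective(as_symmetry_series(series)$values, fit$model,
                        fit$config)
  lower <- fit$bounds$lower
  upper <- fit$bounds$upper
  lower[j] <- value
  upper[j] <- value
  free <- (upper > lower) & fit$free
  start <- start_full
  start[j] <- value
  loc <- local_refine(start, obj, lower, upper, free, fit$config$local_tol)
  list(sse = obj$sse(loc$par), par = loc$par)
}

#' Exact (profile, F-based) confidence interval for one parameter
#'
#' Finds the two values \eqn{\theta_j^*} at which the profiled
#' sum-of-squares ratio reaches the F quantile,
#' \deqn{(N-p)\,\frac{\tilde S(\theta_j^*) - S(\hat\theta)}{S(\hat\theta)}
#'       = F_{1-\alpha}(1, N-p),}
#' where \eqn{\tilde S} re-optimises all remaining parameters with the
#' j-th fixed. Roots are bracketed between each parameter bound and the
#' estimate; if the statistic does not cross the quantile at a bound,
#' the bracket is extended to \eqn{\pm 10^2}, and an endpoint with still
#' no crossing is reported undefined ("UD"). Unlike [ci_linearized()]
#' this interval does not assume the model is well approximated
#' linearly.
#'
#' @param fit an [fit_exp()] result.
#' @param series the series that was fitted.
#' @param parameter parameter name (e.g. `"b"`, `"bs"`) or index among
#'   the free parameters.
#' @param alpha significance level.
#' @return An `interval_estimate` (endpoints `NA` = "UD" when no root
#'   exists within the extended range).
#' @export
ci_profile <- function(fit, series, parameter, alpha = 0.05) {
  nm_all <- names(fit$bounds$lower)
  j <- if (is.character(parameter)) match(parameter, nm_all)
       else as.integer(parameter)
  if (is.na(j) || j < 1L || j > length(nm_all) || !fit$free[j]) {
    stop("parameter must name a free parameter of the fit", call. = FALSE)
  }
  nu <- fit$n - fit$p
  S_hat <- fit$sse
  if (S_hat <= 0) {
    return(interval_estimate(nm_all[j], as.numeric(fit$theta)[j],
                             NA_real_, NA_real_, alpha, "profile",
                             "perfect fit: profile statistic degenerate"))
  }
  Fq <- stats::qf(1 - alpha, 1, nu)
  theta_hat <- as.numeric(fit$theta)
  est <- theta_hat[j]

  # warm-start continuation: remember the most recent profile solution
  last <- theta_hat
  g <- function(v) {
    pr <- profile_sse(fit, series, j, v, last)
    pr2 <- profile_sse(fit, series, j, v, theta_hat)
    if (is.finite(pr2$sse) && (!is.finite(pr$sse) || pr2$sse < pr$sse)) {
      pr <- pr2
    }
    if (is.finite(pr$sse)) last <<- pr$par
    nu * (pr$sse - S_hat) / S_hat - Fq
  }

  root_at <- function(near, far, hard) {
    # g(near) < 0 by construction (S~(est) = S_hat). Extend `far`
    # toward `hard` (+/-100) if needed; a non-finite profile there
    # (e.g. an overflowing positive rate) walks the bracket end back
    # toward the estimate until the profile is computable.
    finite_g <- function(at) {
      for (k in 1:8) {
        gv <- g(at)
        if (is.finite(gv)) return(list(at = at, g = gv))
        at <- near + (at - near) / 2
      }
      NULL
    }
    fe <- finite_g(far)
    if (is.null(fe)) {
      return(list(value = NA_real_,
                  note = "inner re-optimisation failed near the bracket end"))
    }
    if (fe$g <= 0) {
      fe <- finite_g(hard)
      if (is.null(fe)) {
        return(list(value = NA_real_,
                    note = "inner re-optimisation failed in the extended range"))
      }
      if (fe$g <= 0) {
        return(list(value = NA_real_, note = "no root within extended range"))
      }
    }
    far <- fe$at
    gf <- fe$g
    r <- tryCatch(
      stats::uniroot(g, lower = min(near, far), upper = max(near, far),
                     f.lower = if (near < far) -Fq else gf,
                     f.upper = if (near < far) gf else -Fq,
                     tol = 1e-8 * max(1, abs(far - near))),
      error = function(e) NULL)
    if (is.null(r)) return(list(value = NA_real_, note = "root finding failed"))
    list(value = r$root, note = "")
  }

  last <- theta_hat
  lo <- root_at(est, fit$bounds$lower[j], -100)
  last <- theta_hat
  hi <- root_at(est, fit$bounds$upper[j], 100)
  note <- trimws(paste(
    if (is.na(lo$value)) paste("lower:", lo$note) else "",
    if (is.na(hi$value)) paste("upper:", hi$note) else ""))
  interval_estimate(nm_all[j], est, lo$value, hi$value, alpha, "profile",
                    note)
}

#' Profile confidence intervals for every free parameter
#'
#' @inheritParams ci_profile
#' @return Named list of `interval_estimate` objects.
#' @export
ci_profile_all <- function(fit, series, alpha = 0.05) {
  nm <- names(which(fit$free))
  stats::setNames(lapply(nm, function(p) ci_profile(fit, series, p, alpha)),
                  nm)
}

#' Compare two confidence intervals by overlap
#'
#' No overlap between two confidence intervals is interpreted as a
#' statistically significant difference between the estimates. An
#' undefined ("UD") endpoint that prevents ruling out overlap makes the
#' verdict indeterminate, which is treated as overlapping (not
#' significant) — e.g. `[0.030, UD]` vs `[UD, UD]` overlaps.
#'
#' @param i1,i2 `interval_estimate` objects (from [ci_linearized()] or
#'   [ci_profile()]), or plain `list(lower =, upper =)` with `NA` for
#'   undefined endpoints.
#' @return List with `overlap` (`"yes"`, `"no"` or `"indeterminate"`)
#'   and `significant` (`TRUE` only for a definite non-overlap).
#' @export
compare_intervals <- function(i1, i2) {
  ep <- function(i, w) {
    v <- i[[w]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  l1 <- ep(i1, "lower"); u1 <- ep(i1, "upper")
  l2 <- ep(i2, "lower"); u2 <- ep(i2, "upper")
  apart <- function(u, l) !is.na(u) && !is.na(l) && u < l
  if (apart(u1, l2) || apart(u2, l1)) {
    return(list(overlap = "no", significant = TRUE))
  }
  if (anyNA(c(l1, u1, l2, u2))) {
    return(list(overlap = "indeterminate", significant = FALSE))
  }
  list(overlap = "yes", significant = FALSE)
}
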