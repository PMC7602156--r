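#' Common-language parameter table with confidence intervals
#'
#' Transforms a fitted model into the practitioner-facing quantities
#' (initial asymmetry, total change, strides to 50% change, final
#' asymmetry, overshoot, residual SD) and attaches 95% (or `1 - alpha`)
#' confidence intervals.
#'
#' Linearized CIs are available for every quantity via the delta method
#' on \eqn{\hat V = s^2 (J^\top J)^{-1}}. Profile (exact) CIs are
#' reported only where the quantity is a monotone function of a single
#' regression parameter — final asymmetry (`c`), strides to 50% change
#' (from the rate constant), and the single-model total change (`a`);
#' multi-parameter transforms (initial asymmetry, double-model total
#' change, overshoot) carry undefined ("UD") profile endpoints. Stride
#' counts are floored after transforming the rate-constant interval; a
#' rate interval touching 0 gives an unbounded ("UD") stride endpoint.
#'
#' @param fit an [fit_exp()] result.
#' @param series the fitted series (needed for profiling).
#' @param alpha significance level.
#' @param ci `"both"`, `"linearized"`, `"profile"` or `"none"`.
#' @return `data.frame` of class `common_language_table` with columns
#'   `quantity`, `estimate`, `lin_lower`, `lin_upper`, `prof_lower`,
#'   `prof_upper`, `note` (`NA` endpoints mean "UD").
#' @export
common_language_table <- function(fit, series = NULL, alpha = 0.05,
                                  ci = c("both", "linearized", "profile",
                                         "none")) {
  ci <- match.arg(ci)
  want_lin <- ci %in% c("both", "linearized")
  want_prof <- ci %in% c("both", "profile")
  if (want_prof && is.null(series)) {
    stop("profiling needs the fitted series", call. = FALSE)
  }
  th <- as.numeric(fit$theta)
  single <- fit$model == "single"
  cl <- to_common_language(fit$theta, residual_sd = fit$s, n_max = fit$n)
  lin <- if (want_lin) linearization(fit) else NULL
  tq <- stats::qt(1 - alpha / 2, fit$n - fit$p)

  delta_ci <- function(estimate, grad_full) {
    if (is.null(lin) || is.null(lin$vcov)) return(c(NA_real_, NA_real_))
    gfree <- grad_full[fit$free]
    half <- tq * sqrt(drop(t(gfree) %*% lin$vcov %*% gfree))
    c(estimate - half, estimate + half)
  }
  prof <- function(param) {
    if (!want_prof || !fit$free[param]) return(c(NA_real_, NA_real_))
    i <- ci_profile(fit, series, param, alpha)
    c(i$lower, i$upper)
  }
  # strides to 50% change from a rate-constant interval [lo, up];
  # monotone increasing in the rate, unbounded as the rate reaches 0
  strides_from <- function(iv) {
    f <- function(b) if (is.na(b) || b >= 0) NA_real_
                     else as.numeric(half_change_strides(b))
    c(f(iv[1L]), f(iv[2L]))
  }

  rows <- list()
  add <- function(quantity, estimate, lin_iv, prof_iv, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, estimate = estimate,
      lin_lower = lin_iv[1L], lin_upper = lin_iv[2L],
      prof_lower = prof_iv[1L], prof_upper = prof_iv[2L], note = note)
  }
  multi <- "multi-parameter transform: profile CI not available"

  if (single) {
    add("initial_asymmetry", cl$initial_asymmetry,
        delta_ci(cl$initial_asymmetry, c(1, 0, 1)),
        c(NA_real_, NA_real_), multi)
    add("total_change", cl$total_change,
        delta_ci(cl$total_change, c(1, 0, 0)), prof("a"))
    b_lin <- delta_ci(th[2L], c(0, 1, 0))
    b_prof <- prof("b")
    add("half_change_strides", as.numeric(cl$half_change_strides["overall"]),
        strides_from(b_lin), strides_from(b_prof),
        "transformed from the rate-constant interval")
    add("final_asymmetry", cl$final_asymmetry,
        delta_ci(cl$final_asymmetry, c(0, 0, 1)), prof("c"))
    add("overshoot", NA_real_, c(NA_real_, NA_real_), c(NA_real_, NA_real_),
        "single exponential model: no overshoot")
  } else {
    add("initial_asymmetry", cl$initial_asymmetry,
        delta_ci(cl$initial_asymmetry, c(1, 0, 1, 0, 1)),
        c(NA_real_, NA_real_), multi)
    add("total_change", cl$total_change,
        delta_ci(cl$total_change, c(1, 0, 1, 0, 0)),
        c(NA_real_, NA_real_), multi)
    bs_lin <- delta_ci(th[2L], c(0, 1, 0, 0, 0))
    bf_lin <- delta_ci(th[4L], c(0, 0, 0, 1, 0))
    add("half_change_strides_slow",
        as.numeric(cl$half_change_strides["slow"]),
        strides_from(bs_lin), strides_from(prof("bs")),
        "transformed from the rate-constant interval")
    add("half_change_strides_fast",
        as.numeric(cl$half_change_strides["fast"]),
        strides_from(bf_lin), strides_from(prof("bf")),
        "transformed from the rate-constant interval")
    add("final_asymmetry", cl$final_asymmetry,
        delta_ci(cl$final_asymmetry, c(0, 0, 0, 0, 1)), prof("c"))
    os <- cl$overshoot
    if (os$defined) {
      add("overshoot", os$ycrit,
          delta_ci(os$ycrit, overshoot_gradient(th)),
          c(NA_real_, NA_real_), multi)
    } else {
      add("overshoot", NA_real_, c(NA_real_, NA_real_),
          c(NA_real_, NA_real_), paste0("UD: ", os$note))
    }
  }
  add("residual_sd", cl$residual_sd, c(NA_real_, NA_real_),
      c(NA_real_, NA_real_), "point estimate only")

  out <- do.call(rbind, rows)
  class(out) <- c("common_language_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "model") <- fit$model
  out
}

# central-difference gradient of ycrit with respect to the double-model
# parameters (the overshoot has no convenient closed-form gradient)
overshoot_gradient <- function(th) {
  vapply(seq_along(th), function(j) {
    h <- 1e-6 * max(1, abs(th[j]))
    up <- th; up[j] <- th[j] + h
    dn <- th; dn[j] <- th[j] - h
    oup <- overshoot(up); odn <- overshoot(dn)
    if (!oup$defined || !odn$defined) return(NA_real_)
    (oup$ycrit - odn$ycrit) / (2 * h)
  }, numeric(1))
}

#' @export
print.common_language_table <- function(x, digits = 3, ...) {
  fmt <- function(v) ifelse(is.na(v), "UD", formatC(v, digits = digits,
                                                    format = "fg"))
  cat(sprintf("Common-language parameters (%s model, %.0f%% CIs)\n",
              attr(x, "model"), 100 * (1 - attr(x, "alpha"))))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-26s %8s  lin [%s, %s]  profile [%s, %s]\n",
                x$quantity[i], fmt(x$estimate[i]),
                fmt(x$lin_lower[i]), fmt(x$lin_upper[i]),
                fmt(x$prof_lower[i]), fmt(x$prof_upper[i])))
  }
  invisible(x)
}

#' Fit exponential trend models to a series and assemble a run report
#'
#' The end-to-end workflow behind the command-line interface: read or
#' accept a series (two-column step length input is converted to
#' symmetry first), fit the requested model(s), apply the AIC selection
#' rule when `model = "auto"`, compute parameter and common-language
#' confidence intervals, and collect residual diagnostics. With an
#' `output_dir` the report is serialised to JSON (full precision,
#' undefined endpoints as the string `"UD"`) alongside diagnostics CSV
#' tables. Fully automated: only the series is required.
#'
#' @param input path to a 1- or 2-column CSV, a [symmetry_series()], or
#'   a numeric vector.
#' @param model `"auto"` (fit both, select by AIC), `"single"` or
#'   `"double"`.
#' @param alpha significance level for all intervals.
#' @param seed master seed (ignored when `config` is supplied).
#' @param ci interval method(s): `"both"`, `"linearized"`, `"profile"`.
#' @param direction forwarded to [fit_exp()].
#' @param output_dir optional directory for JSON + CSV output.
#' @param config optional [fit_config()] overriding `seed`.
#' @return Object of class `run_report`.
#' @export
run_fit <- function(input, model = c("auto", "single", "double"),
                    alpha = 0.05, seed = 1L,
                    ci = c("both", "linearized", "profile"),
                    direction = c("auto", "+ve", "-ve", "race"),
                    output_dir = NULL, config = NULL) {
  model <- match.arg(model)
  ci <- match.arg(ci)
  direction <- match.arg(direction)
  if (is.null(config)) config <- fit_config(seed = seed)

  if (is.character(input)) {
    series <- read_series(input)
    input_desc <- input
  } else {
    series <- as_symmetry_series(input)
    input_desc <- if (nzchar(series$label)) series$label else "in-memory series"
  }

  fits <- list()
  if (model %in% c("auto", "single")) {
    fits$single <- fit_exp(series, "single", config, direction)
  }
  if (model %in% c("auto", "double")) {
    fits$double <- fit_exp(series, "double", config, direction)
  }
  aic <- if (model == "auto") select_model(fits$single, fits$double) else NULL
  chosen_name <- if (model == "auto") aic$selected else model
  chosen <- fits[[chosen_name]]

  param_ci <- list()
  if (ci %in% c("both", "linearized")) {
    param_ci$linearized <- ci_linearized(chosen, alpha)
  }
  if (ci %in% c("both", "profile")) {
    param_ci$profile <- ci_profile_all(chosen, series, alpha)
  }
  cl_table <- common_language_table(chosen, series, alpha, ci)
  diag <- residual_diagnostics(chosen)

  report <- structure(list(
    input = input_desc,
    n = series$n,
    model_requested = model,
    model_used = chosen_name,
    direction_used = chosen$bounds$direction,
    overshoot_variant = chosen$bounds$overshoot_variant,
    fits = fits,
    aic = aic,
    parameter_ci = param_ci,
    common_language = cl_table,
    diagnostics = diag,
    warning_flags = c(non_converged = !chosen$converged),
    alpha = alpha,
    config = chosen$config,
    seed = chosen$seed_used,
    files = character(0)), class = "run_report")

  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    json_path <- file.path(output_dir, "report.json")
    writeLines(report_json(report), json_path)
    csvs <- write_diagnostics(diag, output_dir,
                              prefix = paste0(chosen_name, "_model"))
    report$files <- c(json_path, csvs)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: %s (%d strides)\n", x$input, x$n))
  if (!is.null(x$aic)) print(x$aic)
  cat(sprintf("Model used: %s exponential (direction %s)\n", x$model_used,
              x$direction_used))
  print(x$fits[[x$model_used]])
  print(x$common_language)
  if (x$warning_flags[["non_converged"]]) {
    cat("WARNING: local refinement did not report convergence\n")
  }
  invisible(x)
}

# ---- JSON serialisation -------------------------------------------------

ud <- function(v) if (is.null(v) || is.na(v)) "UD" else v

interval_to_list <- function(i) {
  list(parameter = i$parameter, estimate = i$estimate,
       lower = ud(i$lower), upper = ud(i$upper), alpha = i$alpha,
       method = i$method, note = i$note)
}

fit_to_list <- function(f) {
  list(model = f$model,
       theta = as.list(stats::setNames(as.numeric(f$theta),
                                       names(f$bounds$lower))),
       sse = f$sse, s = f$s, penalty_at_optimum = f$penalty_at_optimum,
       n = f$n, p = f$p,
       direction = f$bounds$direction,
       overshoot_variant = f$bounds$overshoot_variant,
       converged = f$converged,
       restart_costs = f$restart_costs$cost,
       seed_used = f$seed_used)
}

config_to_list <- function(cfg) unclass(cfg)

#' Serialise a run report to JSON
#'
#' Numbers are written at full precision; undefined interval endpoints
#' become the string `"UD"`.
#'
#' @param report a [run_fit()] result.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  cl <- report$common_language
  cl_list <- lapply(seq_len(nrow(cl)), function(i) {
    list(quantity = cl$quantity[i], estimate = ud(cl$estimate[i]),
         linearized = list(lower = ud(cl$lin_lower[i]),
                           upper = ud(cl$lin_upper[i])),
         profile = list(lower = ud(cl$prof_lower[i]),
                        upper = ud(cl$prof_upper[i])),
         note = cl$note[i])
  })
  obj <- list(
    input = report$input,
    n = report$n,
    model_requested = report$model_requested,
    model_used = report$model_used,
    direction_used = report$direction_used,
    aic = if (!is.null(report$aic)) unclass(report$aic),
    fits = lapply(report$fits, fit_to_list),
    parameter_ci = lapply(report$parameter_ci,
                          function(m) lapply(m, interval_to_list)),
    common_language = cl_list,
    warning_flags = as.list(report$warning_flags),
    alpha = report$alpha,
    seed = report$seed,
    config = config_to_list(report$config))
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                   pretty = TRUE)
}

#' Write a simulated symmetry series to CSV
#'
#' @param spec a [simulation_spec()] or the name of a bundled default
#'   (see [default_specs()]).
#' @param path output CSV path.
#' @param seed overrides the spec's seed when given.
#' @return The path, invisibly.
#' @export
run_simulate <- function(spec, path, seed = NULL) {
  if (is.character(spec)) {
    specs <- default_specs()
    if (!spec %in% names(specs)) {
      stop(sprintf("unknown default spec '%s' (available: %s)", spec,
                   paste(names(specs), collapse = ", ")), call. = FALSE)
    }
    spec <- specs[[spec]]
  }
  write_series(simulate_series(spec, seed = seed), path)
}
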