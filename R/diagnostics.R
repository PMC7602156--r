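#' Residual diagnostics for a fitted exponential model
#'
#' Builds the data behind the three diagnostic plots used to judge model
#' adequacy: residuals across strides (constant-variance check), a
#' histogram and a normal QQ pairing (normality checks; the QQ plot
#' deserves more weight than the histogram, which can mislead).
#'
#' @param fit an [fit_exp()] result.
#' @return Object of class `diagnostic_bundle`: `residuals` (data.frame
#'   `stride`, `residual`), `histogram` (`breaks`, `counts`, `mids`) and
#'   `qq` (data.frame `theoretical`, `sample`, sorted). Histogram bins
#'   follow Freedman–Diaconis, falling back to 10 bins when the IQR
#'   degenerates.
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  r <- fit$residuals
  N <- length(r)
  nb <- if (stats::IQR(r) > 0) max(1L, grDevices::nclass.FD(r)) else 10L
  h <- graphics::hist(r, breaks = nb, plot = FALSE)
  q <- stats::qnorm((seq_len(N) - 0.5) / N)
  structure(list(
    residuals = data.frame(stride = seq_len(N), residual = r),
    histogram = list(breaks = h$breaks, counts = h$counts, mids = h$mids),
    qq = data.frame(theoretical = q, sample = sort(r))),
    class = "diagnostic_bundle")
}

#' @export
print.diagnostic_bundle <- function(x, ...) {
  cat(sprintf("Residual diagnostics: %d residuals, %d histogram bins\n",
              nrow(x$residuals), length(x$histogram$counts)))
  invisible(x)
}

#' Plot residual diagnostics
#'
#' Renders the residuals-vs-stride, histogram and QQ panels with base
#' graphics. Purely a convenience; the tested surface is the data bundle.
#'
#' @param x a `diagnostic_bundle`.
#' @param ... ignored.
#' @export
plot.diagnostic_bundle <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  graphics::plot(x$residuals$stride, x$residuals$residual,
                 xlab = "Stride", ylab = "Residual", pch = 20,
                 col = "grey40", main = "Residuals across strides")
  graphics::abline(h = 0, lty = 2)
  graphics::plot(x$histogram$mids, x$histogram$counts, type = "h", lwd = 6,
                 lend = 1, xlab = "Residual", ylab = "Count",
                 main = "Histogram")
  graphics::plot(x$qq$theoretical, x$qq$sample,
                 xlab = "Standard normal quantiles",
                 ylab = "Residual quantiles", pch = 20, col = "grey40",
                 main = "QQ plot")
  graphics::abline(0, stats::sd(x$residuals$residual), lty = 2)
  invisible(x)
}

#' Write a diagnostic bundle to CSV files
#'
#' @param bundle a `diagnostic_bundle`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_diagnostics <- function(bundle, dir, prefix = "diagnostics") {
  stopifnot(inherits(bundle, "diagnostic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("residuals", "histogram", "qq"), ".csv"))
  utils::write.csv(bundle$residuals, paths[1L], row.names = FALSE)
  utils::write.csv(
    data.frame(bin_lower = utils::head(bundle$histogram$breaks, -1L),
               bin_upper = bundle$histogram$breaks[-1L],
               count = bundle$histogram$counts),
    paths[2L], row.names = FALSE)
  utils::write.csv(bundle$qq, paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Centered moving average (plotting aesthetics only)
#'
#' A k-point centered moving average with shrinking windows at the
#' edges, used to smooth plotted series for aesthetic reasons. Smoothed
#' data must never be fitted; [fit_exp()] always consumes the raw
#' series.
#'
#' @param series a [symmetry_series()] or numeric vector.
#' @param window odd window width (default 3).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(series, window = 3L) {
  x <- if (inherits(series, "symmetry_series")) series$values
       else as.numeric(series)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window > length(x)) stop("window exceeds series length", call. = FALSE)
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}
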