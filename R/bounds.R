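#' Detect the direction of the trend in a symmetry series
#'
#' The direction from which the series approaches its final value is
#' inferred from the sign of the difference between the mean symmetry of
#' the first and the last `window` strides: `"+ve"` (approach from
#' above; positive total change) when the difference is positive,
#' otherwise `"-ve"`. For short series the window shrinks to
#' `floor(N / 2)` so the two windows never overlap. The rule is a
#' heuristic and can fail on noisy series; [fit_exp()] can race both
#' directions instead (`direction = "race"`).
#'
#' @param series a [symmetry_series()] or numeric vector.
#' @param window stride count per window (default 50).
#' @return `"+ve"` or `"-ve"`, with attribute `tie = TRUE` when the mean
#'   difference is exactly zero.
#' @export
detect_direction <- function(series, window = 50L) {
  series <- as_symmetry_series(series)
  y <- series$values
  n <- length(y)
  if (n < 2L) stop("need at least 2 strides to detect a direction",
                   call. = FALSE)
  w <- min(as.integer(window), n %/% 2L)
  w <- max(w, 1L)
  d <- mean(y[seq_len(w)]) - mean(y[seq.int(n - w + 1L, n)])
  out <- if (d > 0) "+ve" else "-ve"
  if (d == 0) attr(out, "tie") <- TRUE
  out
}

#' Parameter bound sets for the exponential trend models
#'
#' Constructs the bound set for a (model, direction, overshoot) choice.
#' Under the assumption that symmetry varies within `[-1, 1]`: the
#' offset `c` is bounded by `[-1, 1]`; all rate constants by
#' `[-ln 2, 0]` (a 50% change in a single stride being the fastest
#' admissible decay); the single-model amplitude by `[0, 2]` (`"+ve"`)
#' or `[-2, 0]` (`"-ve"`); and the double-model amplitudes by sign
#' patterns depending on whether an overshoot (opposite-sign
#' amplitudes) is admitted:
#'
#' | direction | overshoot | as | af |
#' |---|---|---|---|
#' | +ve | no  | \[0, 1\]  | \[0, 1\]  |
#' | +ve | yes | \[-1, 0\] | \[0, 1\]  |
#' | -ve | no  | \[-1, 0\] | \[-1, 0\] |
#' | -ve | yes | \[0, 1\]  | \[-1, 0\] |
#'
#' @param model `"single"` or `"double"`.
#' @param direction `"+ve"` or `"-ve"`.
#' @param overshoot_variant `"no"` or `"yes"`; only for the double model.
#' @return Object of class `bound_set`: list with named `lower`/`upper`
#'   vectors and the defining enums.
#' @export
make_bounds <- function(model = c("single", "double"),
                        direction = c("+ve", "-ve"),
                        overshoot_variant = c("no", "yes")) {
  model <- match.arg(model)
  direction <- match.arg(direction)
  rate <- c(-log(2), 0)
  offs <- c(-1, 1)
  if (model == "single") {
    if (!missing(overshoot_variant)) {
      stop("the single model has no overshoot bound variant", call. = FALSE)
    }
    amp <- if (direction == "+ve") c(0, 2) else c(-2, 0)
    lower <- c(a = amp[1L], b = rate[1L], c = offs[1L])
    upper <- c(a = amp[2L], b = rate[2L], c = offs[2L])
    overshoot_variant <- "n/a"
  } else {
    overshoot_variant <- match.arg(overshoot_variant)
    pos <- c(0, 1); neg <- c(-1, 0)
    amps <- switch(paste(direction, overshoot_variant),
                   "+ve no" = list(as = pos, af = pos),
                   "+ve yes" = list(as = neg, af = pos),
                   "-ve no" = list(as = neg, af = neg),
                   "-ve yes" = list(as = pos, af = neg))
    lower <- c(as = amps$as[1L], bs = rate[1L], af = amps$af[1L],
               bf = rate[1L], c = offs[1L])
    upper <- c(as = amps$as[2L], bs = rate[2L], af = amps$af[2L],
               bf = rate[2L], c = offs[2L])
  }
  structure(list(lower = lower, upper = upper, model = model,
                 direction = direction,
                 overshoot_variant = overshoot_variant),
            class = "bound_set")
}

#' @export
print.bound_set <- function(x, ...) {
  cat(sprintf("Bounds (%s model, %s direction%s):\n", x$model, x$direction,
              if (x$overshoot_variant %in% c("no", "yes"))
                paste0(", overshoot ", x$overshoot_variant) else ""))
  for (nm in names(x$lower)) {
    cat(sprintf("  %-3s [%.4g, %.4g]\n", nm, x$lower[[nm]], x$upper[[nm]]))
  }
  invisible(x)
}
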