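#' Stride-indexed step length symmetry series
#'
#' A symmetry series holds one unitless symmetry value per stride,
#' \eqn{y(n)} for \eqn{n = 1, \dots, N}. Perfect symmetry between the two
#' legs corresponds to 0; positive values indicate a longer fast-leg step.
#' All values must be finite and lie within \eqn{[-1, 1]}, the range the
#' parameter bounds of the exponential trend models assume.
#'
#' @param values numeric vector of per-stride symmetry values.
#' @param label optional free-text tag (e.g. phase/session).
#' @return An object of class `symmetry_series`: a list with elements
#'   `values`, `n` (stride count) and `label`.
#' @seealso [compute_symmetry()], [read_series()], [fit_exp()]
#' @export
#' @examples
#' symmetry_series(c(0.1, 0.05, 0.0), label = "adaptation")
symmetry_series <- function(values, label = "") {
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("a symmetry series needs at least one stride", call. = FALSE)
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    stop(sprintf("non-finite symmetry value at stride %d", bad[1L]),
         call. = FALSE)
  }
  out <- which(values < -1 | values > 1)
  if (length(out)) {
    stop(sprintf(
      "symmetry value %g at stride %d is outside [-1, 1]",
      values[out[1L]], out[1L]), call. = FALSE)
  }
  structure(list(values = values, n = length(values),
                 label = as.character(label)[1L]),
            class = "symmetry_series")
}

#' @export
print.symmetry_series <- function(x, ...) {
  cat(sprintf("Symmetry series%s: %d strides, range [%.4g, %.4g]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              x$n, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.numeric.symmetry_series <- function(x, ...) x$values

#' @export
length.symmetry_series <- function(x) x$n

# Coerce numeric vectors on the way into fitting functions.
as_symmetry_series <- function(x, label = "") {
  if (inherits(x, "symmetry_series")) return(x)
  if (is.numeric(x)) return(symmetry_series(x, label = label))
  stop("expected a symmetry_series or a numeric vector", call. = FALSE)
}

#' Per-stride fast/slow step length pairs
#'
#' Step lengths of the fast and slow leg over strides, the raw input from
#' which step length symmetry is computed. Both step lengths must be
#' strictly positive (the symmetry denominator is their sum) and the two
#' vectors equally long.
#'
#' @param lf fast-leg step length per stride (any consistent length unit).
#' @param ls slow-leg step length per stride.
#' @param label optional free-text tag.
#' @return An object of class `step_length_series`.
#' @export
step_length_series <- function(lf, ls, label = "") {
  lf <- as.numeric(lf); ls <- as.numeric(ls)
  if (length(lf) != length(ls)) {
    stop(sprintf("step length vectors differ in length (%d vs %d)",
                 length(lf), length(ls)), call. = FALSE)
  }
  if (length(lf) < 1L) stop("need at least one stride", call. = FALSE)
  bad <- which(!is.finite(lf) | !is.finite(ls))
  if (length(bad)) {
    stop(sprintf("non-finite step length at stride %d", bad[1L]),
         call. = FALSE)
  }
  pos <- which(lf <= 0 | ls <= 0)
  if (length(pos)) {
    stop(sprintf("non-positive step length at stride %d", pos[1L]),
         call. = FALSE)
  }
  structure(list(lf = lf, ls = ls, n = length(lf),
                 label = as.character(label)[1L]),
            class = "step_length_series")
}

#' @export
print.step_length_series <- function(x, ...) {
  cat(sprintf("Step length series%s: %d strides\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "", x$n))
  invisible(x)
}

#' Step length symmetry from fast/slow step lengths
#'
#' Computes the per-stride step length symmetry
#' \deqn{y(n) = \frac{l_f(n) - l_s(n)}{l_f(n) + l_s(n)},}
#' the difference between fast- and slow-leg step lengths normalised to
#' their sum. The normalisation caters to inter-individual variability in
#' absolute step lengths and guarantees values strictly inside
#' \eqn{(-1, 1)} for positive step lengths.
#'
#' @param steps a [step_length_series()], or the fast-leg step length
#'   vector when `ls` is given.
#' @param ls slow-leg step lengths (optional convenience form).
#' @param label passed to the resulting series.
#' @return A [symmetry_series()].
#' @export
#' @examples
#' compute_symmetry(c(0.6, 0.5), c(0.4, 0.5))$values  # 0.2, 0
compute_symmetry <- function(steps, ls = NULL, label = NULL) {
  if (!inherits(steps, "step_length_series")) {
    steps <- step_length_series(steps, ls,
                                label = if (is.null(label)) "" else label)
  }
  y <- (steps$lf - steps$ls) / (steps$lf + steps$ls)
  symmetry_series(y, label = if (is.null(label)) steps$label else label)
}

#' Group-average symmetry series across participants
#'
#' Per-stride mean over a list of symmetry series. Series of unequal
#' length are truncated to the shortest series before averaging so that
#' the per-stride mean is always over the full group; no imputation is
#' performed.
#'
#' @param series list of [symmetry_series()] (or numeric vectors).
#' @param label label for the averaged series.
#' @return A [symmetry_series()] of length `min(N_i)`.
#' @export
group_average <- function(series, label = "group average") {
  if (!is.list(series) || length(series) == 0L) {
    stop("need a non-empty list of symmetry series", call. = FALSE)
  }
  series <- lapply(series, as_symmetry_series)
  n <- min(vapply(series, function(s) s$n, integer(1)))
  mat <- vapply(series, function(s) s$values[seq_len(n)], numeric(n))
  if (n == 1L) mat <- matrix(mat, nrow = 1L)
  symmetry_series(rowMeans(mat), label = label)
}

#' Read a symmetry or step length series from CSV
#'
#' A one-column file is read as a symmetry series, a two-column file as
#' fast,slow step length pairs. A header row is optional and detected by
#' attempting numeric conversion of the first row. Rows are assigned
#' stride indices 1..N in file order.
#'
#' @param path CSV file path.
#' @param as_symmetry if `TRUE` (default) a two-column file is converted
#'   to symmetry via [compute_symmetry()]; otherwise the
#'   [step_length_series()] is returned.
#' @param label label for the series (defaults to the file name).
#' @return A [symmetry_series()] or [step_length_series()].
#' @export
read_series <- function(path, as_symmetry = TRUE, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- utils::read.csv(path, header = FALSE, nrows = 1L,
                           colClasses = "character",
                           strip.white = TRUE)
  has_header <- anyNA(suppressWarnings(as.numeric(unlist(first))))
  df <- utils::read.csv(path, header = has_header,
                        colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 1L || ncol(df) > 2L) {
    stop(sprintf("expected 1 or 2 columns, found %d in %s", ncol(df), path),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop(sprintf("no data rows in %s", path), call. = FALSE)
  offset <- if (has_header) 1L else 0L
  parse_col <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop(sprintf("malformed %s value '%s' at row %d of %s",
                   what, x[bad[1L]], bad[1L] + offset, path), call. = FALSE)
    }
    v
  }
  if (is.null(label)) label <- basename(path)
  if (ncol(df) == 1L) {
    v <- parse_col(df[[1L]], "symmetry")
    out <- which(v < -1 | v > 1)
    if (length(out)) {
      stop(sprintf("symmetry value %g outside [-1, 1] at row %d of %s",
                   v[out[1L]], out[1L] + offset, path), call. = FALSE)
    }
    return(symmetry_series(v, label = label))
  }
  steps <- step_length_series(parse_col(df[[1L]], "fast step length"),
                              parse_col(df[[2L]], "slow step length"),
                              label = label)
  if (as_symmetry) compute_symmetry(steps) else steps
}

#' Write a symmetry series to CSV
#'
#' One value per row, with a `symmetry` header column.
#'
#' @param series a [symmetry_series()] or numeric vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  series <- as_symmetry_series(series)
  utils::write.csv(data.frame(symmetry = series$values), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
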