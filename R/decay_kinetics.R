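# Protein half-life from cycloheximide-chase time courses.  Band
# intensities after translation blockade are modelled as first-order
# decay, I(t) = I0 * exp(-k t); ln(intensity) is regressed on time by
# ordinary least squares and half-life = ln(2) / k.

#' Fit a first-order decay and report the half-life
#'
#' OLS of `ln(intensity)` on time; `k = -slope`, `half_life = ln(2)/k`.
#' A non-decaying series (k <= 0) is returned with `half_life = Inf` and
#' `decaying = FALSE` rather than a negative half-life.  Zero or negative
#' intensities are invalid (the log is undefined); supply a small
#' positive floor explicitly via `epsilon` if a quantification pipeline
#' produced zeros.
#'
#' @param times Numeric vector of chase times in hours (>= 3 distinct).
#' @param intensities Positive relative band intensities, same length.
#' @param epsilon Optional floor applied to intensities before the log
#'   (default NULL: zeros are an error).
#' @return List of class `half_life_fit`: `k` (per hour), `half_life`
#'   (hours), `r_squared`, `n_points`, `decaying`.
#' @export
#' @examples
#' fit_half_life(c(0, 4, 8), c(1, 0.5, 0.25))$half_life  # 4
fit_half_life <- function(times, intensities, epsilon = NULL) {
  if (is.data.frame(times)) {
    intensities <- times$intensity
    times <- times$time_h
  }
  if (length(times) != length(intensities))
    sf_stop("times and intensities must have equal length")
  if (length(times) < 3 || length(unique(times)) < 3)
    sf_stop("need at least 3 points at 3 distinct times")
  if (any(times < 0)) sf_stop("times must be nonnegative")
  if (!is.null(epsilon)) intensities <- pmax(intensities, epsilon)
  if (any(intensities <= 0))
    sf_stop("intensities must be positive (use epsilon to floor zeros)")

  fit <- stats::lm(log(intensities) ~ times)
  k <- -unname(stats::coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
  decaying <- k > 0
  structure(list(k = k,
                 half_life = if (decaying) log(2) / k else Inf,
                 r_squared = r2,
                 n_points = length(times),
                 decaying = decaying),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$decaying)
    cat(sprintf("Half-life %.3g h (k = %.4g /h, r^2 = %.3f, n = %d)\n",
                x$half_life, x$k, x$r_squared, x$n_points))
  else
    cat(sprintf("Non-decaying series (k = %.4g /h, n = %d)\n", x$k, x$n_points))
  invisible(x)
}

#' Read a decay-series CSV
#'
#' Header `time_h,intensity[,condition]`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_decay_series <- function(path) {
  if (!file.exists(path)) sf_stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "intensity") %in% names(df)))
    sf_stop("decay CSV needs columns time_h,intensity",
            class = "screenforge_format_error")
  df
}

#' Fit half-lives per condition
#'
#' @param series data.frame with `time_h`, `intensity` and optionally
#'   `condition` (fitted separately per level).
#' @return data.frame `condition, k, half_life, r_squared, n_points`.
#' @export
fit_half_life_by_condition <- function(series) {
  if (!"condition" %in% names(series)) series$condition <- "all"
  out <- lapply(split(series, series$condition), function(d) {
    f <- fit_half_life(d$time_h, d$intensity)
    data.frame(condition = d$condition[1], k = f$k, half_life = f$half_life,
               r_squared = f$r_squared, n_points = f$n_points,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
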