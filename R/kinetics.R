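# Thrombus growth-profile metrics, linear-baseline peak areas of dR/R
# traces, and cGMP -> Ca2+ lead-lag estimation by derivative
# cross-correlation.

trapz <- function(t, x) sum(diff(t) * (utils::head(x, -1) + utils::tail(x, -1)) / 2)

#' Thrombus growth metrics
#'
#' Characterizes an area-versus-time profile by: time to maximal thrombus
#' size (`t_max`, earliest frame of the global maximum), maximal size
#' (`A_max`), half-dissolution time (`t_half_dissolution`, the time from
#' the maximum to the first crossing of 50% of the maximum, linearly
#' interpolated between frames; censored if never reached), area under the
#' curve (`auc`, trapezoidal integral of `A - baseline` between `t_injury`
#' and `t_end`), and the stabilized size at the end (`A_end`).
#'
#' @param t Time grid (s), strictly increasing, length >= 3.
#' @param A Thrombus area (um^2) per time point.
#' @param t_end End of the evaluation interval (s, within the support;
#'   default the last time point).
#' @param baseline Baseline area subtracted in the AUC (default 0, the
#'   pre-injury area in a laser-injury model).
#' @param t_injury Start of the AUC integration (default the first time
#'   point).
#' @return An object of class `kinetics_report`: list with `t_max`,
#'   `A_max`, `t_half_dissolution`, `half_censored`, `auc`, `auc_raw`
#'   (no baseline subtraction), `A_end`, `t_end`.
#' @export
growth_metrics <- function(t, A, t_end = max(t), baseline = 0,
                           t_injury = min(t)) {
  if (length(t) < 3) stop("need at least 3 time points")
  if (length(t) != length(A)) stop("t and A must have equal length")
  if (any(diff(t) <= 0)) stop("time grid must be strictly increasing")
  if (t_end > max(t) || t_end < min(t)) stop("t_end outside the trace support")
  A_max <- max(A)
  i_max <- which(A == A_max)[1]          # ties resolve to the earliest frame
  t_max <- t[i_max]
  half <- A_max / 2
  t_half <- NA_real_; censored <- TRUE
  if (A_max > 0 && i_max < length(A)) {
    below <- which(A[(i_max + 1):length(A)] <= half)
    if (length(below) > 0) {
      j <- i_max + below[1]
      # linear interpolation between the bracketing frames
      # (A[j-1] > half >= A[j], so the denominator is nonzero)
      t_cross <- t[j - 1] + (half - A[j - 1]) * (t[j] - t[j - 1]) /
        (A[j] - A[j - 1])
      t_half <- t_cross - t_max
      censored <- FALSE
    }
  }
  sel <- t >= t_injury & t <= t_end
  auc_raw <- trapz(t[sel], A[sel])
  auc <- trapz(t[sel], A[sel] - baseline)
  A_end <- stats::approx(t, A, xout = t_end)$y
  structure(list(t_max = t_max, A_max = A_max,
                 t_half_dissolution = t_half, half_censored = censored,
                 auc = auc, auc_raw = auc_raw, baseline = baseline,
                 A_end = A_end, t_end = t_end),
            class = "kinetics_report")
}

#' @export
print.kinetics_report <- function(x, ...) {
  cat("Thrombus growth metrics\n")
  cat(sprintf("  t_max: %.6g s   A_max: %.6g um^2\n", x$t_max, x$A_max))
  if (x$half_censored)
    cat(sprintf("  t_half_dissolution: censored (> %.6g s observed span)\n",
                x$t_end - x$t_max))
  else
    cat(sprintf("  t_half_dissolution: %.6g s\n", x$t_half_dissolution))
  cat(sprintf("  AUC: %.6g um^2*s (baseline %.6g)   A_end(%.6g s): %.6g um^2\n",
              x$auc, x$baseline, x$t_end, x$A_end))
  invisible(x)
}

#' Peak area above a linear baseline
#'
#' Trapezoidal integral of `x` minus the linear chord connecting the trace
#' values at the two borders (linear-baseline drift correction with
#' manually defined peak borders).
#'
#' @param t Time grid (s).
#' @param x Trace values.
#' @param borders `c(start, end)` in seconds, `start < end`, both within
#'   the trace support.
#' @return Peak area in trace-units * s.
#' @export
peak_area <- function(t, x, borders) {
  if (length(borders) != 2 || borders[1] >= borders[2])
    stop("borders must be c(start, end) with start < end")
  if (borders[1] < min(t) || borders[2] > max(t))
    stop("peak borders outside the trace support")
  x0 <- stats::approx(t, x, xout = borders[1])$y
  x1 <- stats::approx(t, x, xout = borders[2])$y
  inner <- t > borders[1] & t < borders[2]
  tt <- c(borders[1], t[inner], borders[2])
  xx <- c(x0, x[inner], x1)
  chord <- x0 + (x1 - x0) * (tt - borders[1]) / (borders[2] - borders[1])
  trapz(tt, xx - chord)
}

#' Lead-lag between two traces by derivative cross-correlation
#'
#' Estimates the time shift between `x` and `y` as the argmax over
#' `[-max_lag, max_lag]` of the normalized cross-correlation of the
#' first-difference traces (differencing suppresses slow drifts). The
#' correlation peak is refined to sub-frame resolution by parabolic
#' interpolation. A negative lag means `x` precedes `y`. When the traces
#' are anticorrelated (e.g. cGMP vs. Ca2+), set `invert_y = TRUE` to flip
#' the sign of `y` first. The estimate is flagged low-confidence when the
#' peak correlation is below 0.5.
#'
#' @param x,y Numeric traces on a common regular time grid.
#' @param dt Seconds per frame.
#' @param max_lag Maximal lag magnitude to scan (s, >= `dt`).
#' @param invert_y Multiply `y` by -1 before correlating.
#' @return List with `lag` (s), `peak_correlation`, `low_confidence`,
#'   and the full `lags` / `correlation` profile.
#' @export
lead_lag <- function(x, y, dt = 1, max_lag = 10, invert_y = FALSE) {
  if (length(x) != length(y)) stop("traces must have equal length")
  if (max_lag < dt) stop("max_lag must be >= dt")
  L <- as.integer(floor(max_lag / dt))
  if (length(x) < 2 * L + 2)
    stop("traces too short for the requested max_lag")
  dx <- diff(x)
  dy <- diff(y) * if (invert_y) -1 else 1
  n <- length(dx)
  lags <- (-L):L
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- dx[seq_len(n - l)]; b <- dy[seq_len(n - l) + l]
    } else {
      a <- dx[seq_len(n + l) - l]; b <- dy[seq_len(n + l)]
    }
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      return(NA_real_)
    stats::cor(a[ok], b[ok])
  }, numeric(1))
  i <- which.max(cc)
  delta <- 0
  if (i > 1 && i < length(cc) &&
      !anyNA(cc[(i - 1):(i + 1)])) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) delta <- 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  peak <- cc[i]
  list(lag = -(lags[i] + delta) * dt, peak_correlation = peak,
       low_confidence = is.na(peak) || peak < 0.5,
       lags = -lags * dt, correlation = cc)
}

#' Settling time of a baseline-normalized trace
#'
#' Time after `t_event` at which the trace re-enters the band
#' `[-band, band]` around zero and stays inside it for the remainder of
#' the recording. Used to quantify the return of the dR/R trace to
#' baseline after flow cessation.
#'
#' @param t Time grid (s).
#' @param dxx Baseline-normalized trace (e.g. dR/R); `NA` frames ignored.
#' @param t_event Event time (s), e.g. flow-off.
#' @param band Half-width of the acceptance band (default 0.05, i.e.
#'   within 5% of baseline).
#' @return Settling time in seconds, or `NA` if the trace never settles.
#' @export
settling_time <- function(t, dxx, t_event, band = 0.05) {
  sel <- t >= t_event & !is.na(dxx)
  tt <- t[sel]; xx <- dxx[sel]
  inside <- abs(xx) <= band
  if (!any(inside)) return(NA_real_)
  stays <- rev(cumprod(rev(inside))) > 0
  if (!any(stays)) return(NA_real_)
  tt[which(stays)[1]] - t_event
}
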