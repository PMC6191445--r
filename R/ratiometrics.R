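# Background-corrected per-region channel traces, the FRET ratio
# R = F480/F535, baseline normalization (dR/R), SNR-based exclusion,
# Hill-type sensor calibration (forward and inverse with a saturation
# bound), and the Fura-2 Ca2+ ratio F340/F380.

#' Hill-type cGMP sensor calibration model
#'
#' Maps a cGMP concentration to the CFP/YFP emission ratio:
#' `R(c) = r_min + (r_max - r_min) * c^n / (ec50^n + c^n)`, strictly
#' increasing in `c`. Concentrations inferred at or above `c_sat` are
#' reported as saturated (the sensor cannot quantify beyond this bound and
#' the estimate becomes a lower bound).
#'
#' @param ec50 Half-saturating concentration (uM, > 0).
#' @param hill_n Hill coefficient (> 0).
#' @param r_min,r_max Ratio bounds, `r_max > r_min > 0`.
#' @param c_sat Upper quantification bound (uM, > `ec50`); default 3.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(ec50 = 0.5, hill_n = 1, r_min = 1, r_max = 2,
                         c_sat = 3) {
  if (!(r_max > r_min && r_min > 0)) stop("need r_max > r_min > 0")
  if (ec50 <= 0 || hill_n <= 0) stop("ec50 and hill_n must be > 0")
  if (c_sat <= ec50) stop("c_sat must exceed ec50")
  structure(list(ec50 = ec50, hill_n = hill_n, r_min = r_min, r_max = r_max,
                 c_sat = c_sat), class = "sensor_model")
}

#' Sensor forward model: cGMP concentration to FRET ratio
#'
#' @param c cGMP concentration(s) in uM (>= 0). Accepts vectors/matrices.
#' @param model A [sensor_model()].
#' @return FRET ratio(s), same shape as `c`.
#' @export
sensor_forward <- function(c, model = sensor_model()) {
  stopifnot(inherits(model, "sensor_model"))
  if (any(c < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  occ <- c^model$hill_n / (model$ec50^model$hill_n + c^model$hill_n)
  model$r_min + (model$r_max - model$r_min) * occ
}

#' Sensor inverse model: FRET ratio to cGMP concentration
#'
#' Exact algebraic inverse of [sensor_forward()], clipped to `[0, Inf)`.
#' Ratios outside `[r_min, r_max]` (beyond `tol`) are clipped and flagged.
#' When the inferred concentration reaches `c_sat` the sensor is saturated:
#' `saturated = TRUE` and the reported `c` is the lower bound `c_sat`
#' (the raw algebraic estimate remains available as `c_raw`).
#'
#' @param R FRET ratio(s).
#' @param model A [sensor_model()].
#' @param tol Tolerance for out-of-range ratios before flagging.
#' @return data.frame with columns `c` (reported concentration, uM),
#'   `c_raw` (unclipped algebraic inverse), `saturated`, `clipped`.
#' @export
sensor_inverse <- function(R, model = sensor_model(), tol = 1e-6) {
  stopifnot(inherits(model, "sensor_model"))
  clipped <- !is.na(R) & (R < model$r_min - tol | R > model$r_max + tol)
  Rc <- pmin(pmax(R, model$r_min), model$r_max)
  occ <- (Rc - model$r_min) / (model$r_max - model$r_min)
  c_raw <- ifelse(occ >= 1, Inf, model$ec50 * (occ / (1 - occ))^(1 / model$hill_n))
  saturated <- !is.na(c_raw) & c_raw >= model$c_sat
  c_rep <- ifelse(saturated, model$c_sat, c_raw)
  data.frame(c = c_rep, c_raw = c_raw, saturated = saturated,
             clipped = clipped)
}

#' Estimate per-channel, per-frame background fluorescence
#'
#' Either from an explicit background rectangle (which must not intersect
#' any whole-thrombus mask), or -- by default -- as the median intensity of
#' all pixels outside the whole mask dilated by `dilate_px` pixels.
#'
#' @param stack A `time_lapse_stack`.
#' @param masks A `mask_series` with a `whole` label (required unless
#'   `bg_roi` is given).
#' @param bg_roi Optional rectangle `list(y = c(y0, y1), x = c(x0, x1))`
#'   (1-based inclusive pixel indices).
#' @param dilate_px Dilation radius (pixels) applied to the whole mask
#'   before excluding it from the default background region.
#' @return data.frame with columns `frame`, `channel`, `background`.
#' @export
estimate_background <- function(stack, masks = NULL, bg_roi = NULL,
                                dilate_px = 5) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  dims <- dim(stack$data)
  n <- dims[4]
  if (!is.null(bg_roi)) {
    ys <- bg_roi$y[1]:bg_roi$y[2]; xs <- bg_roi$x[1]:bg_roi$x[2]
    if (min(ys) < 1 || max(ys) > dims[1] || min(xs) < 1 || max(xs) > dims[2])
      stop("bg_roi outside the image")
    if (!is.null(masks)) {
      roi <- matrix(FALSE, dims[1], dims[2]); roi[ys, xs] <- TRUE
      for (k in seq_len(n))
        if (any(roi & masks$masks$whole[, , k]))
          stop("bg_roi intersects the thrombus mask in frame ", k - 1L)
    }
    sel <- function(k) {
      ok <- matrix(FALSE, dims[1], dims[2]); ok[ys, xs] <- TRUE; ok
    }
    reduce <- mean
  } else {
    if (is.null(masks)) stop("either masks or bg_roi must be supplied")
    brush <- EBImage::makeBrush(2L * as.integer(dilate_px) + 1L, "disc")
    sel <- function(k) {
      m <- masks$masks$whole[, , k]
      if (any(m))
        m <- EBImage::imageData(EBImage::dilate(m * 1, brush)) > 0
      !m
    }
    reduce <- stats::median
  }
  out <- expand.grid(frame = seq_len(n) - 1L,
                     channel = stack$channel_names,
                     stringsAsFactors = FALSE)
  out$background <- NA_real_
  for (k in seq_len(n)) {
    ok <- sel(k)
    if (!any(ok)) stop("no background pixels available in frame ", k - 1L)
    for (ch in stack$channel_names) {
      ci <- match(ch, stack$channel_names)
      out$background[out$frame == k - 1L & out$channel == ch] <-
        reduce(stack$data[, , ci, k][ok])
    }
  }
  out
}

channel_alias <- c(EM480 = "F480", EM535 = "F535",
                   EX340 = "F340", EX380 = "F380")

#' Extract background-corrected regional traces
#'
#' For every region and frame, the trace value is the mean over the mask
#' pixels of (raw intensity - background). Frames with an empty mask yield
#' `NA` and are flagged; downstream operations skip them.
#'
#' @param stack A `time_lapse_stack`.
#' @param masks A `mask_series` (any subset of whole/core/periphery).
#' @param background data.frame from [estimate_background()], or a single
#'   number used for all channels and frames.
#' @return A `region_traces` data.frame with columns `frame`, `t`,
#'   `region`, `n_px`, `empty` and one column per channel (`F480`, `F535`,
#'   and `F340`, `F380` when present).
#' @export
extract_traces <- function(stack, masks, background = 0) {
  stopifnot(inherits(stack, "time_lapse_stack"), inherits(masks, "mask_series"))
  dims <- dim(stack$data)
  if (!identical(dims[1:2], dim(masks$masks[[1]])[1:2]) ||
      dims[4] != dim(masks$masks[[1]])[3])
    stop("stack and masks are dimensionally inconsistent")
  n <- dims[4]
  bgm <- matrix(NA_real_, n, length(stack$channel_names),
                dimnames = list(NULL, stack$channel_names))
  if (is.numeric(background) && is.null(dim(background)) &&
      length(background) == 1L) {
    bgm[] <- background
  } else {
    for (ch in stack$channel_names)
      bgm[, ch] <- background$background[background$channel == ch][
        order(background$frame[background$channel == ch])]
  }
  out <- NULL
  for (region in masks$labels) {
    df <- data.frame(frame = seq_len(n) - 1L,
                     t = (seq_len(n) - 1L) * stack$dt,
                     region = region,
                     n_px = apply(masks$masks[[region]], 3, sum))
    df$empty <- df$n_px == 0L
    for (ch in stack$channel_names) {
      ci <- match(ch, stack$channel_names)
      vals <- vapply(seq_len(n), function(k) {
        m <- masks$masks[[region]][, , k]
        if (!any(m)) return(NA_real_)
        mean(stack$data[, , ci, k][m]) - bgm[k, ch]
      }, numeric(1))
      df[[channel_alias[[ch]]]] <- vals
    }
    out <- rbind(out, df)
  }
  for (region in unique(out$region))
    if (all(out$empty[out$region == region]))
      stop("region '", region, "' is empty in every frame")
  rownames(out) <- NULL
  class(out) <- c("region_traces", "data.frame")
  out
}

#' FRET ratio traces
#'
#' `R = F480 / F535` per region and frame. Frames with `F535 <= 0` (after
#' background correction) are flagged invalid; an error is raised if more
#' than half of the non-empty frames of any region are invalid.
#'
#' @param traces A `region_traces` data.frame from [extract_traces()].
#' @return data.frame with columns `frame`, `t`, `region`, `R`, `valid`.
#' @export
compute_ratio <- function(traces) {
  stopifnot(all(c("F480", "F535", "region") %in% names(traces)))
  out <- traces[c("frame", "t", "region")]
  out$valid <- !traces$empty & !is.na(traces$F535) & traces$F535 > 0
  out$R <- ifelse(out$valid, traces$F480 / traces$F535, NA_real_)
  for (region in unique(out$region)) {
    sub <- out[out$region == region & !traces$empty[out$region == region], ]
    if (nrow(sub) > 0 && mean(!sub$valid) > 0.5)
      stop("more than 50% invalid ratio frames in region '", region, "'")
  }
  out
}

#' Normalize a trace to its baseline
#'
#' `dX/X = (X - mean(X over the baseline window)) / mean(X over the
#' baseline window)`. Invariant under multiplication of the raw trace by
#' any positive constant.
#'
#' @param x Numeric trace (may contain `NA`).
#' @param t Time grid (s), same length as `x`.
#' @param baseline_window `c(start, end)` in seconds (half-open
#'   `[start, end)`); must contain at least 3 valid (non-`NA`) frames.
#' @return Numeric vector `dX/X` with the baseline mean as attribute
#'   `baseline`.
#' @export
normalize_to_baseline <- function(x, t, baseline_window) {
  sel <- t >= baseline_window[1] & t < baseline_window[2] & !is.na(x)
  if (sum(sel) < 3) stop("baseline window must contain at least 3 valid frames")
  b <- mean(x[sel])
  structure((x - b) / b, baseline = b)
}

#' Add baseline-normalized ratio (dR/R) per region
#'
#' @param ratio data.frame from [compute_ratio()].
#' @param baseline_window `c(start, end)` in seconds.
#' @return `ratio` with additional columns `dR_over_R` and `R_baseline`.
#' @export
delta_ratio <- function(ratio, baseline_window) {
  out <- NULL
  for (region in unique(ratio$region)) {
    sub <- ratio[ratio$region == region, ]
    x <- ifelse(sub$valid, sub$R, NA_real_)
    d <- normalize_to_baseline(x, sub$t, baseline_window)
    sub$dR_over_R <- as.numeric(d)
    sub$R_baseline <- attr(d, "baseline")
    out <- rbind(out, sub)
  }
  rownames(out) <- NULL
  out
}

#' Signal-to-noise filter for ratio traces
#'
#' SNR is defined as the maximal absolute deviation of `R` from its
#' baseline mean within the response window, divided by the SD of `R` over
#' the baseline window. Traces with SNR below the threshold are excluded
#' (the reference workflow excluded measurements with SNR < 2.5). A
#' zero-variance baseline yields SNR = Inf and the trace is retained with
#' a warning.
#'
#' @param ratio data.frame from [compute_ratio()] (or [delta_ratio()]).
#' @param baseline_window,response_window `c(start, end)` in seconds.
#' @param threshold SNR exclusion threshold (default 2.5).
#' @return data.frame with one row per region: `region`, `snr`,
#'   `excluded`, plus a `log` attribute describing each decision.
#' @export
snr_filter <- function(ratio, baseline_window, response_window,
                       threshold = 2.5) {
  res <- NULL; log <- character()
  for (region in unique(ratio$region)) {
    sub <- ratio[ratio$region == region & ratio$valid, ]
    base <- sub$R[sub$t >= baseline_window[1] & sub$t < baseline_window[2]]
    resp <- sub$R[sub$t >= response_window[1] & sub$t < response_window[2]]
    if (length(base) < 2 || length(resp) < 1)
      stop("baseline and response windows must contain valid frames")
    sd_b <- stats::sd(base)
    dev <- max(abs(resp - mean(base)))
    if (sd_b == 0) {
      snr <- Inf
      warning("zero-variance baseline in region '", region,
              "': SNR set to Inf, trace retained")
    } else snr <- dev / sd_b
    excluded <- snr < threshold
    log <- c(log, sprintf("region=%s snr=%.3f threshold=%.2f %s", region,
                          snr, threshold,
                          if (excluded) "EXCLUDED" else "retained"))
    res <- rbind(res, data.frame(region = region, snr = snr,
                                 excluded = excluded))
  }
  rownames(res) <- NULL
  attr(res, "log") <- log
  res
}

#' Fura-2 Ca2+ ratio traces
#'
#' `Ca signal = F340 / F380` per region and frame (classic Fura-2
#' convention; the ratio increases with intracellular Ca2+). Optionally
#' also returns the sign-inverted baseline-normalized trace used to
#' compare the chronology of cGMP and Ca2+ changes.
#'
#' @param traces A `region_traces` data.frame containing `F340` and `F380`.
#' @param baseline_window Optional `c(start, end)` (s); when given, an
#'   `inv_dca` column (`-dCa/Ca`) is added.
#' @return data.frame with columns `frame`, `t`, `region`, `ca_ratio`,
#'   `valid` (and `inv_dca` when requested).
#' @export
fura_ratio <- function(traces, baseline_window = NULL) {
  for (ch in c("F340", "F380"))
    if (!ch %in% names(traces))
      stop("traces are missing required channel: ", ch)
  out <- traces[c("frame", "t", "region")]
  out$valid <- !traces$empty & !is.na(traces$F380) & traces$F380 > 0
  out$ca_ratio <- ifelse(out$valid, traces$F340 / traces$F380, NA_real_)
  if (!is.null(baseline_window)) {
    out$inv_dca <- NA_real_
    for (region in unique(out$region)) {
      i <- out$region == region
      d <- normalize_to_baseline(ifelse(out$valid[i], out$ca_ratio[i], NA),
                                 out$t[i], baseline_window)
      out$inv_dca[i] <- -as.numeric(d)
    }
  }
  out
}
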