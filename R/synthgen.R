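# Synthetic dual-emission (optionally dual-excitation) thrombus movies with
# full ground truth. The generator encodes the signal model the analysis
# pipeline is validated against: a growing/dissolving thrombus disc, a flow
# on/off schedule driving first-order cGMP kinetics with a periphery > core
# gradient, a saturating Hill-type sensor mapping cGMP to the CFP/YFP
# emission ratio, Ca2+ anticorrelated with cGMP at a time lag, and
# Poisson + Gaussian camera noise.

#' Flow on/off schedule
#'
#' Describes the superfusion protocol of a flow-chamber experiment as a set
#' of half-open `[start, end)` intervals (seconds) during which buffer flow
#' is on, on a regular frame grid.
#'
#' @param on_windows List of numeric length-2 vectors `c(start, end)` in
#'   seconds; windows must be sorted, non-overlapping and contained in
#'   `[0, duration]`. An empty list means flow is off throughout.
#' @param duration Total duration of the recording in seconds.
#' @param dt Seconds per frame (> 0). Default 1 (1 Hz acquisition).
#' @param shear_rate_on Wall shear rate (1/s) applied while flow is on.
#' @return An object of class `flow_schedule`.
#' @seealso [flow_indicator()], [simulate_region_cgmp()]
#' @export
flow_schedule <- function(on_windows = list(), duration = 300, dt = 1,
                          shear_rate_on = 500) {
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a positive number of seconds")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be > 0")
  if (is.matrix(on_windows)) on_windows <- split(on_windows, row(on_windows))
  on_windows <- lapply(on_windows, as.numeric)
  for (w in on_windows) {
    if (length(w) != 2L || anyNA(w))
      stop("each flow window must be c(start, end)")
    if (w[1] >= w[2]) stop("flow window start must be < end")
    if (w[1] < 0 || w[2] > duration)
      stop("flow windows must lie within [0, duration]")
  }
  if (length(on_windows) > 1L) {
    starts <- vapply(on_windows, `[`, numeric(1), 1L)
    ends <- vapply(on_windows, `[`, numeric(1), 2L)
    o <- order(starts)
    if (is.unsorted(starts)) stop("flow windows must be sorted by start time")
    if (any(starts[o][-1L] < ends[o][-length(ends)]))
      stop("flow windows must not overlap")
  }
  structure(list(on_windows = on_windows, duration = duration, dt = dt,
                 shear_rate_on = shear_rate_on),
            class = "flow_schedule")
}

#' Per-frame flow indicator
#'
#' @param schedule A [flow_schedule()].
#' @return Integer vector (0 = flow off, 1 = flow on), one entry per frame,
#'   for frames at times `0, dt, 2*dt, ...` (half-open window convention:
#'   a frame at time `t` is "on" iff `start <= t < end` for some window).
#' @export
flow_indicator <- function(schedule) {
  stopifnot(inherits(schedule, "flow_schedule"))
  n <- n_frames(schedule)
  t <- (seq_len(n) - 1) * schedule$dt
  ind <- integer(n)
  for (w in schedule$on_windows) ind[t >= w[1] & t < w[2]] <- 1L
  ind
}

n_frames <- function(schedule) as.integer(round(schedule$duration / schedule$dt))

frame_times <- function(schedule) (seq_len(n_frames(schedule)) - 1) * schedule$dt

#' cGMP kinetics parameters
#'
#' First-order (single-exponential) relaxation of the regional cGMP
#' concentration towards a flow-state dependent target:
#' `dc/dt = (c_target - c) / tau`, with `c_target = c_on_<region>` while
#' flow is on and `c_base` while it is off, and `tau = tau_on` or `tau_off`
#' accordingly. Defaults put the periphery above the sensor saturation
#' bound (3 uM) and make baseline recovery complete within ~20 s of flow
#' cessation (3 * tau_off = 15 s).
#'
#' @param c_base Resting cGMP concentration (uM).
#' @param c_on_core,c_on_periphery Flow-on target concentrations (uM);
#'   must satisfy `c_on_periphery >= c_on_core >= c_base >= 0`.
#' @param tau_on,tau_off Relaxation time constants (s), both > 0.
#' @return An object of class `cgmp_kinetics`.
#' @export
cgmp_kinetics <- function(c_base = 0.1, c_on_core = 0.8, c_on_periphery = 4,
                          tau_on = 4, tau_off = 5) {
  if (!(c_on_periphery >= c_on_core && c_on_core >= c_base && c_base >= 0))
    stop("need c_on_periphery >= c_on_core >= c_base >= 0")
  if (tau_on <= 0 || tau_off <= 0) stop("tau_on and tau_off must be > 0")
  structure(list(c_base = c_base, c_on_core = c_on_core,
                 c_on_periphery = c_on_periphery,
                 tau_on = tau_on, tau_off = tau_off),
            class = "cgmp_kinetics")
}

#' Simulate regional cGMP traces for a flow schedule
#'
#' Integrates the first-order kinetics exactly on the frame grid
#' (piecewise-constant target, exponential update per frame), separately
#' for the thrombus core and periphery.
#'
#' @param schedule A [flow_schedule()].
#' @param kinetics A [cgmp_kinetics()].
#' @return data.frame with columns `frame`, `t`, `core`, `periphery` (uM).
#' @export
simulate_region_cgmp <- function(schedule, kinetics = cgmp_kinetics()) {
  stopifnot(inherits(schedule, "flow_schedule"),
            inherits(kinetics, "cgmp_kinetics"))
  if (schedule$dt >= min(kinetics$tau_on, kinetics$tau_off) / 2)
    warning("frame interval dt >= tau/2: kinetics are barely resolved on this grid")
  ind <- flow_indicator(schedule)
  n <- length(ind)
  out <- data.frame(frame = seq_len(n) - 1L, t = frame_times(schedule))
  for (region in c("core", "periphery")) {
    c_on <- if (region == "core") kinetics$c_on_core else kinetics$c_on_periphery
    cc <- numeric(n)
    cc[1] <- kinetics$c_base
    for (k in seq_len(n - 1L)) {
      target <- if (ind[k] == 1L) c_on else kinetics$c_base
      tau <- if (ind[k] == 1L) kinetics$tau_on else kinetics$tau_off
      cc[k + 1L] <- target + (cc[k] - target) * exp(-schedule$dt / tau)
    }
    out[[region]] <- cc
  }
  out
}

#' Thrombus area profile
#'
#' Unimodal thrombus area vs. time: baseline `A_base` until injury at
#' `t_injury`, growth to `A_max` at `t_max`, then dissolution to `A_end` at
#' `t_end`. `shape = "linear"` gives a piecewise-linear (triangular)
#' profile; `shape = "logistic"` uses knot-normalized logistic segments
#' (sigmoidal growth/dissolution passing exactly through the knots).
#'
#' @param A_max Maximal thrombus area (um^2).
#' @param t_max Time of maximal area (s); `t_injury < t_max < t_end`.
#' @param A_end Stabilized area at `t_end` (um^2), `A_base <= A_end <= A_max`.
#' @param t_end End of the recording (s).
#' @param A_base Pre-injury area (um^2, typically 0).
#' @param t_injury Time of injury (s).
#' @param dt Grid spacing in seconds.
#' @param shape `"linear"` or `"logistic"`.
#' @return An object of class `area_profile` with fields `t`, `A` and the
#'   generating parameters.
#' @export
area_profile <- function(A_max = 500, t_max = 60, A_end = 200, t_end = 299,
                         A_base = 0, t_injury = 0, dt = 1,
                         shape = c("linear", "logistic")) {
  shape <- match.arg(shape)
  if (!(t_injury < t_max && t_max < t_end))
    stop("need t_injury < t_max < t_end")
  if (!(A_base <= A_end && A_end <= A_max))
    stop("need A_base <= A_end <= A_max")
  if (A_base < 0) stop("areas must be >= 0")
  t <- seq(0, t_end, by = dt)
  A <- numeric(length(t))
  rise <- t >= t_injury & t <= t_max
  fall <- t > t_max
  if (shape == "linear") {
    A[t < t_injury] <- A_base
    A[rise] <- A_base + (A_max - A_base) * (t[rise] - t_injury) / (t_max - t_injury)
    A[fall] <- A_max + (A_end - A_max) * (t[fall] - t_max) / (t_end - t_max)
  } else {
    lseg <- function(tt, t0, t1, y0, y1) {
      s <- stats::plogis(10 * ((tt - (t0 + t1) / 2) / (t1 - t0)))
      s0 <- stats::plogis(-5); s1 <- stats::plogis(5)
      y0 + (y1 - y0) * (s - s0) / (s1 - s0)
    }
    A[t < t_injury] <- A_base
    A[rise] <- lseg(t[rise], t_injury, t_max, A_base, A_max)
    A[fall] <- lseg(t[fall], t_max, t_end, A_max, A_end)
  }
  structure(list(t = t, A = A, A_base = A_base, A_max = A_max, A_end = A_end,
                 t_injury = t_injury, t_max = t_max, t_end = t_end,
                 shape = shape),
            class = "area_profile")
}

#' Ca2+ coupling model
#'
#' Regional Ca2+ follows the (normalized) cGMP excursion with a time lag
#' and a sign coupling: `coupling = -1` (default) makes Ca2+ fall when cGMP
#' rises, reproducing the suppression of Ca2+ signaling by the
#' NO-cGMP-cGKI pathway; cGMP changes precede Ca2+ changes by `lag`.
#'
#' @param ca_base,ca_high Low/high Ca2+ signal levels (arbitrary units).
#' @param lag Delay (s, >= 0) of the Ca2+ change after the cGMP change.
#' @param coupling `-1` (anticorrelated, default) or `+1`.
#' @return An object of class `ca_model`.
#' @export
ca_model <- function(ca_base = 0.1, ca_high = 1, lag = 2, coupling = -1) {
  if (lag < 0) stop("lag must be >= 0")
  if (!coupling %in% c(-1, 1)) stop("coupling must be -1 or +1")
  structure(list(ca_base = ca_base, ca_high = ca_high, lag = lag,
                 coupling = coupling), class = "ca_model")
}

#' Simulate regional Ca2+ traces from cGMP traces
#'
#' @param cgmp data.frame from [simulate_region_cgmp()].
#' @param kinetics The [cgmp_kinetics()] that produced `cgmp` (used to
#'   normalize the excursion per region).
#' @param model A [ca_model()].
#' @return data.frame with columns `frame`, `t`, `core`, `periphery`
#'   (Ca2+ signal, arbitrary units).
#' @export
simulate_region_ca <- function(cgmp, kinetics, model = ca_model()) {
  stopifnot(inherits(model, "ca_model"), inherits(kinetics, "cgmp_kinetics"))
  out <- cgmp[c("frame", "t")]
  for (region in c("core", "periphery")) {
    c_on <- if (region == "core") kinetics$c_on_core else kinetics$c_on_periphery
    amp <- c_on - kinetics$c_base
    u <- if (amp > 0) (cgmp[[region]] - kinetics$c_base) / amp else rep(0, nrow(cgmp))
    u <- pmin(pmax(u, 0), 1)
    u_lag <- stats::approx(cgmp$t, u, xout = cgmp$t - model$lag, rule = 2)$y
    canorm <- if (model$coupling == -1) 1 - u_lag else u_lag
    out[[region]] <- model$ca_base + (model$ca_high - model$ca_base) * canorm
  }
  out
}

#' Camera noise model
#'
#' @param background_level Constant background fluorescence per channel
#'   (counts, >= 0).
#' @param shot_noise If `TRUE`, pixel values are Poisson-distributed around
#'   their expectation (signal-dependent counting noise).
#' @param read_noise_sd Additive Gaussian read noise SD (counts, >= 0).
#' @param seed Integer seed; identical seeds give bit-identical movies.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(background_level = 100, shot_noise = TRUE,
                        read_noise_sd = 3, seed = 1L) {
  if (background_level < 0) stop("background_level must be >= 0")
  if (read_noise_sd < 0) stop("read_noise_sd must be >= 0")
  structure(list(background_level = background_level,
                 shot_noise = isTRUE(shot_noise),
                 read_noise_sd = read_noise_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Rendering geometry and brightness parameters
#'
#' The thrombus is rendered as a centered disc of area `A(t)` whose
#' brightness (platelet density) declines linearly from `center_gain` x the
#' rim value at the center to 1 x at the rim, and continues with the same
#' slope into a diffuse skirt outside the rim (loose, flow-exposed
#' platelets), reaching zero at `center_gain/(center_gain-1)` times the
#' radius. This emulates the gradual intensity falloff of real thrombi and
#' makes the intensity-based core criterion (20% above the whole-thrombus
#' threshold) carve out approximately the inner 80% of the radius.
#'
#' @param width,height Frame size in pixels.
#' @param pixel_size Pixel edge length (um/pixel).
#' @param center Optional `c(y, x)` thrombus center (pixels); default is
#'   the frame center.
#' @param periphery_frac Relative width of the peripheral annulus
#'   (fraction of the current radius; default 0.2).
#' @param center_gain Center-to-rim brightness ratio (> 1).
#' @param fret_total Total CFP+YFP signal at the rim (counts); split
#'   between the channels according to the FRET ratio.
#' @param f340_base,f340_amp,f380_base,f380_amp Fura-2 channel intensities
#'   (counts) at the rim: `F340 = f340_base + f340_amp * ca_norm`,
#'   `F380 = f380_base - f380_amp * ca_norm` with `ca_norm` in `[0, 1]`.
#' @return An object of class `synth_geometry`.
#' @export
synth_geometry <- function(width = 128, height = 128, pixel_size = 0.5,
                           center = NULL, periphery_frac = 0.2,
                           center_gain = 2, fret_total = 4000,
                           f340_base = 800, f340_amp = 600,
                           f380_base = 1600, f380_amp = 600) {
  if (width < 8 || height < 8) stop("frame too small")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (periphery_frac <= 0 || periphery_frac >= 1)
    stop("periphery_frac must be in (0, 1)")
  if (center_gain <= 1) stop("center_gain must be > 1")
  if (fret_total <= 0) stop("fret_total must be > 0")
  if (f380_base - f380_amp <= 0 || f340_base <= 0)
    stop("Fura channel intensities must stay positive")
  if (is.null(center)) center <- c((height + 1) / 2, (width + 1) / 2)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixel_size = pixel_size, center = center,
                 periphery_frac = periphery_frac, center_gain = center_gain,
                 fret_total = fret_total,
                 f340_base = f340_base, f340_amp = f340_amp,
                 f380_base = f380_base, f380_amp = f380_amp),
            class = "synth_geometry")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Render a synthetic thrombus movie
#'
#' Renders a multi-channel time-lapse stack from an area profile and
#' regional cGMP (and optionally Ca2+) traces, together with pixel-exact
#' ground truth. Per pixel, the expected FRET-pair emissions are
#' `CFP = S * d * R/(1+R)` and `YFP = S * d * 1/(1+R)` plus background,
#' where `d` is the radial density profile, `R = sensor_forward(c)` for the
#' pixel's regional cGMP concentration, and `S = fret_total`; thus the
#' background-corrected CFP/YFP ratio of any thrombus pixel equals the
#' sensor curve exactly, CFP and YFP move in opposite directions when cGMP
#' changes, and the CFP+YFP sum (used for segmentation) is independent of
#' cGMP. Skirt pixels outside the true rim carry the periphery
#' concentration. Noise is Poisson (optional) plus Gaussian read noise,
#' clipped to the 16-bit range and rounded to integer counts.
#'
#' @param geometry A [synth_geometry()].
#' @param profile An [area_profile()].
#' @param cgmp data.frame from [simulate_region_cgmp()]; must share the
#'   profile's frame grid.
#' @param sensor A [sensor_model()].
#' @param noise A [noise_model()].
#' @param ca Optional [ca_model()]; when given, `ca_traces` must be
#'   supplied too and Fura-2 channels EX340/EX380 are rendered.
#' @param ca_traces Optional data.frame from [simulate_region_ca()].
#' @param dt Seconds per frame (stored in the stack metadata).
#' @return List with components `stack` (a `time_lapse_stack`) and `truth`
#'   (a `ground_truth`: `masks` per frame for whole/core/periphery,
#'   regional `c_region` and `ca_region` traces, and all parameters).
#' @export
render_movie <- function(geometry, profile, cgmp, sensor = sensor_model(),
                         noise = noise_model(), ca = NULL, ca_traces = NULL,
                         dt = 1) {
  stopifnot(inherits(geometry, "synth_geometry"),
            inherits(profile, "area_profile"),
            inherits(sensor, "sensor_model"),
            inherits(noise, "noise_model"))
  n <- nrow(cgmp)
  if (length(profile$A) != n)
    stop("area profile and cGMP traces must share the frame grid")
  if (max(abs(profile$t - cgmp$t)) > 1e-9)
    stop("area profile and cGMP traces must share the time grid")
  if (!is.null(ca) && is.null(ca_traces))
    stop("ca_traces must be supplied together with a ca_model")
  H <- geometry$height; W <- geometry$width
  cy <- geometry$center[1]; cx <- geometry$center[2]
  A_px <- profile$A / geometry$pixel_size^2
  r <- sqrt(A_px / pi)
  rmax <- max(r)
  if (rmax > min(cy - 1, cx - 1, H - cy, W - cx))
    stop("thrombus disc at maximal area does not fit in the frame")
  D <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, "+"))
  g <- geometry$center_gain
  channels <- c("EM480", "EM535")
  with_fura <- !is.null(ca)
  if (with_fura) channels <- c(channels, "EX340", "EX380")
  C <- length(channels)
  data <- array(0, dim = c(H, W, C, n))
  masks <- list(whole = array(FALSE, c(H, W, n)),
                core = array(FALSE, c(H, W, n)),
                periphery = array(FALSE, c(H, W, n)))
  wmean_c <- rep(NA_real_, n); wmean_ca <- rep(NA_real_, n)
  bg <- noise$background_level
  with_seed(noise$seed, {
    for (k in seq_len(n)) {
      rk <- r[k]
      d <- if (rk > 0) pmax(0, g - (g - 1) * D / rk) else matrix(0, H, W)
      whole <- rk > 0 & D <= rk
      core <- rk > 0 & D <= (1 - geometry$periphery_frac) * rk
      periph <- whole & !core
      masks$whole[, , k] <- whole
      masks$core[, , k] <- core
      masks$periphery[, , k] <- periph
      cpix <- matrix(cgmp$periphery[k], H, W)
      cpix[core] <- cgmp$core[k]
      Rpix <- sensor_forward(cpix, sensor)
      expected <- list(
        EM480 = bg + geometry$fret_total * d * Rpix / (1 + Rpix),
        EM535 = bg + geometry$fret_total * d / (1 + Rpix))
      if (with_fura) {
        anorm <- matrix((ca_traces$periphery[k] - ca$ca_base) /
                          (ca$ca_high - ca$ca_base), H, W)
        anorm[core] <- (ca_traces$core[k] - ca$ca_base) / (ca$ca_high - ca$ca_base)
        expected$EX340 <- bg + d * (geometry$f340_base + geometry$f340_amp * anorm)
        expected$EX380 <- bg + d * (geometry$f380_base - geometry$f380_amp * anorm)
      }
      for (ci in seq_len(C)) {
        ev <- expected[[channels[ci]]]
        v <- if (noise$shot_noise) rpois(length(ev), lambda = ev) else ev
        if (noise$read_noise_sd > 0)
          v <- v + rnorm(length(ev), sd = noise$read_noise_sd)
        data[, , ci, k] <- matrix(pmin(pmax(round(v), 0), 65535), H, W)
      }
      if (any(whole)) {
        wts <- d[whole]
        cw <- cpix[whole]
        wmean_c[k] <- sum(wts * cw) / sum(wts)
        if (with_fura) {
          capix <- matrix(ca_traces$periphery[k], H, W)
          capix[core] <- ca_traces$core[k]
          wmean_ca[k] <- sum(wts * capix[whole]) / sum(wts)
        }
      }
    }
  })
  stack <- time_lapse_stack(data, channel_names = channels, dt = dt,
                            pixel_size = geometry$pixel_size)
  flags <- data.frame(frame = cgmp$frame, t = cgmp$t,
                      empty = !apply(masks$whole, 3, any))
  mask_series <- structure(list(masks = masks, labels = names(masks),
                                flags = flags, dt = dt,
                                pixel_size = geometry$pixel_size,
                                provenance = list(source = "synthetic ground truth")),
                           class = "mask_series")
  c_region <- cbind(cgmp, whole = wmean_c)
  ca_region <- if (with_fura) cbind(ca_traces, whole = wmean_ca) else NULL
  truth <- structure(list(masks = mask_series, c_region = c_region,
                          ca_region = ca_region,
                          params = list(geometry = geometry, profile = profile,
                                        sensor = sensor, noise = noise, ca = ca,
                                        dt = dt)),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Simulate a complete thrombus movie with defaults
#'
#' Convenience wrapper: builds the flow schedule, cGMP (and optionally
#' Ca2+) kinetics, and area profile, then renders the stack. All defaults
#' reproduce the reference study conditions: 1 Hz acquisition for 300 s,
#' flow on between 60 and 120 s at 500 1/s, resting cGMP 0.1 uM rising to
#' 0.8 uM in the core and 4 uM (beyond sensor saturation) in the periphery,
#' thrombus growing to 500 um^2 at 60 s and dissolving to 200 um^2.
#'
#' @param duration,dt,on_windows,shear_rate_on Passed to [flow_schedule()].
#' @param kinetics A [cgmp_kinetics()].
#' @param profile An [area_profile()] on the same grid, or `NULL` for the
#'   default profile.
#' @param geometry A [synth_geometry()].
#' @param sensor A [sensor_model()].
#' @param noise A [noise_model()].
#' @param ca Optional [ca_model()] to add Fura-2 channels.
#' @return List with `stack`, `truth`, `schedule`, `kinetics`, `profile`.
#' @export
simulate_thrombus_movie <- function(duration = 300, dt = 1,
                                    on_windows = list(c(60, 120)),
                                    shear_rate_on = 500,
                                    kinetics = cgmp_kinetics(),
                                    profile = NULL,
                                    geometry = synth_geometry(),
                                    sensor = sensor_model(),
                                    noise = noise_model(),
                                    ca = NULL) {
  schedule <- flow_schedule(on_windows, duration = duration, dt = dt,
                            shear_rate_on = shear_rate_on)
  cgmp <- simulate_region_cgmp(schedule, kinetics)
  if (is.null(profile))
    profile <- area_profile(A_max = 500, t_max = 60, A_end = 200,
                            t_end = duration - dt, dt = dt)
  ca_traces <- if (!is.null(ca)) simulate_region_ca(cgmp, kinetics, ca) else NULL
  rendered <- render_movie(geometry, profile, cgmp, sensor = sensor,
                           noise = noise, ca = ca, ca_traces = ca_traces,
                           dt = dt)
  c(rendered, list(schedule = schedule, kinetics = kinetics, profile = profile))
}

#' Threshold an operator would set on a synthetic movie
#'
#' The intensity of the rendered thrombus rim in the CFP+YFP sum image:
#' `2 * background_level + fret_total`. Thresholding the blurred sum image
#' at this value recovers the true thrombus boundary.
#'
#' @param geometry A [synth_geometry()].
#' @param noise A [noise_model()].
#' @return Threshold in counts.
#' @export
rim_threshold <- function(geometry, noise) {
  2 * noise$background_level + geometry$fret_total
}
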