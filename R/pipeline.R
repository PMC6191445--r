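# End-to-end orchestration: simulate (or read) a stack, segment it,
# extract background-corrected regional ratio traces, calibrate cGMP,
# compute growth kinetics and (when Ca2+ channels are present) the
# cGMP -> Ca2+ lead-lag, and write a reproducible report bundle.

#' Pipeline run configuration
#'
#' @param input `"simulate"` (default) to generate a synthetic movie, or a
#'   path to a TIFF stack readable by [read_stack()].
#' @param sim Named list of arguments for [simulate_thrombus_movie()]
#'   (used when `input = "simulate"`).
#' @param channel_names Channel labels for TIFF input.
#' @param seg A [segmentation_params()]. A threshold of `"auto"` resolves
#'   to the generator's rim intensity for simulated input (the value a
#'   manual operator would set) and to Otsu for file input.
#' @param sensor A [sensor_model()] used for inverse calibration.
#' @param baseline_window,response_window `c(start, end)` in seconds, or
#'   `NULL` to derive them from the flow schedule (baseline: the 10 frames
#'   preceding the first flow-on event; response: the union span of the
#'   flow-on windows).
#' @param snr_threshold SNR exclusion threshold (default 2.5).
#' @param seed Seed for simulated input (overrides `sim$noise`'s seed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = "simulate", sim = list(), channel_names = NULL,
                       seg = segmentation_params(threshold = "auto"),
                       sensor = sensor_model(),
                       baseline_window = NULL, response_window = NULL,
                       snr_threshold = 2.5, seed = 1L) {
  if (!identical(input, "simulate") && !file.exists(input))
    stop("input file does not exist: ", input)
  structure(list(input = input, sim = sim, channel_names = channel_names,
                 seg = seg, sensor = sensor,
                 baseline_window = baseline_window,
                 response_window = response_window,
                 snr_threshold = snr_threshold, seed = as.integer(seed)),
            class = "run_config")
}

seg_params_resolved <- function(config, sim_result) {
  p <- config$seg
  if (identical(p$threshold, "auto")) {
    thr <- if (!is.null(sim_result))
      rim_threshold(sim_result$truth$params$geometry,
                    sim_result$truth$params$noise)
    else "otsu"
    p <- segmentation_params(blur_sigma = p$blur_sigma, threshold = thr,
                             core_factor = p$core_factor,
                             core_method = p$core_method,
                             erode_px = p$erode_px)
  }
  p
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate/read the stack; blurred-sum segmentation
#' with core/periphery partition; background estimation; regional trace
#' extraction; FRET ratio, dR/R and SNR filtering; inverse sensor
#' calibration; growth kinetics from the whole-mask area; Fura-2 ratio and
#' cGMP -> Ca2+ lead-lag when Ca channels are present; and a summary of
#' regional responses (flow-on means, periphery vs. core ordering,
#' settling time after each flow-off, sustained-response detection at
#' 3 x baseline SD for at least 3 consecutive frames).
#'
#' @param config A [run_config()].
#' @return A `pipeline_bundle` list with all intermediate tables, the
#'   summary, and (for simulated input) the ground truth.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  sim <- NULL
  if (identical(config$input, "simulate")) {
    args <- config$sim
    if (is.null(args$noise)) args$noise <- noise_model(seed = config$seed)
    else args$noise$seed <- config$seed
    sim <- do.call(simulate_thrombus_movie, args)
    stack <- sim$stack
    schedule <- sim$schedule
  } else {
    stack <- read_stack(config$input, channel_names = config$channel_names)
    schedule <- NULL
  }
  seg <- seg_params_resolved(config, sim)
  blurred <- preprocess_stack(stack, seg)
  masks <- segment_whole(blurred, seg)
  masks <- split_core_periphery(blurred, masks, seg)
  background <- estimate_background(stack, masks)
  traces <- extract_traces(stack, masks, background)
  ratio <- compute_ratio(traces)

  on_windows <- if (!is.null(schedule)) schedule$on_windows else list()
  dt <- stack$dt
  baseline_window <- config$baseline_window
  if (is.null(baseline_window)) {
    if (length(on_windows) == 0)
      stop("baseline_window must be given when there is no flow-on event")
    t_on <- on_windows[[1]][1]
    baseline_window <- c(t_on - 10 * dt, t_on)
  }
  response_window <- config$response_window
  if (is.null(response_window) && length(on_windows) > 0)
    response_window <- c(on_windows[[1]][1],
                         on_windows[[length(on_windows)]][2])
  ratio <- delta_ratio(ratio, baseline_window)
  snr <- if (!is.null(response_window))
    snr_filter(ratio, baseline_window, response_window,
               threshold = config$snr_threshold) else NULL
  inv <- sensor_inverse(ratio$R, config$sensor)
  ratio$c_uM <- inv$c
  ratio$saturated <- inv$saturated

  areas <- mask_areas(masks)
  wa <- areas[areas$label == "whole", ]
  kinetics <- growth_metrics(wa$t_s, wa$area_um2)

  fura <- NULL; lag <- NULL
  if (all(c("EX340", "EX380") %in% stack$channel_names)) {
    fura <- fura_ratio(traces, baseline_window = baseline_window)
    w <- ratio$region == "whole"
    fw <- fura[fura$region == "whole", ]
    lag <- lead_lag(ratio$dR_over_R[w], fw$ca_ratio, dt = dt,
                    max_lag = 10 * dt, invert_y = TRUE)
  }

  summary <- summarize_regions(ratio, on_windows, baseline_window, dt)
  bundle <- list(config = config, stack_info = list(
                   dim = dim(stack$data), channels = stack$channel_names,
                   dt = dt, pixel_size = stack$pixel_size),
                 seg = seg, truth = if (!is.null(sim)) sim$truth else NULL,
                 schedule = schedule, masks = masks, background = background,
                 traces = traces, ratio = ratio, snr = snr, areas = areas,
                 kinetics = kinetics, fura = fura, lead_lag = lag,
                 summary = summary)
  class(bundle) <- "pipeline_bundle"
  bundle
}

summarize_regions <- function(ratio, on_windows, baseline_window, dt) {
  regions <- unique(ratio$region)
  on_sel <- rep(FALSE, nrow(ratio))
  for (w in on_windows)
    on_sel <- on_sel | (ratio$t >= w[1] & ratio$t < w[2])
  rows <- lapply(regions, function(rg) {
    i <- ratio$region == rg & ratio$valid
    base <- ratio$dR_over_R[i & ratio$t >= baseline_window[1] &
                              ratio$t < baseline_window[2]]
    sd_b <- stats::sd(base)
    resp <- ratio$dR_over_R[i & on_sel]
    # sustained response: >= 3 consecutive frames beyond 3 x baseline SD
    responder <- FALSE
    if (length(resp) >= 3 && !is.na(sd_b) && sd_b > 0) {
      hits <- abs(resp) > 3 * sd_b
      runs <- rle(hits)
      responder <- any(runs$lengths[runs$values] >= 3)
    }
    data.frame(region = rg,
               mean_dRR_flow_on = if (any(on_sel)) mean(resp, na.rm = TRUE)
                                  else NA_real_,
               baseline_sd = sd_b, responder = responder)
  })
  out <- do.call(rbind, rows)
  settle <- NA_real_
  if (length(on_windows) > 0) {
    w <- ratio$region == "whole"
    settle <- settling_time(ratio$t[w], ratio$dR_over_R[w],
                            t_event = on_windows[[length(on_windows)]][2],
                            band = 0.05)
  }
  mo <- out$mean_dRR_flow_on
  names(mo) <- out$region
  list(regions = out,
       periphery_exceeds_core = if (all(c("core", "periphery") %in% out$region))
         isTRUE(mo[["periphery"]] > mo[["core"]]) else NA,
       settle_after_last_off_s = settle)
}

#' Write the pipeline report bundle to disk
#'
#' Writes `traces.csv` (regional channel/ratio traces), `areas.csv`,
#' `kinetics.csv`, `snr.csv`, `summary.json`, `sensor.json`, `config.json`
#' and a `manifest.json` listing every written file with its MD5 checksum.
#' Re-writing an unchanged bundle reproduces identical checksums.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param outdir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory is not writable")
  files <- character()
  wr_csv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  tr <- merge(bundle$traces,
              bundle$ratio[c("frame", "region", "R", "dR_over_R", "c_uM",
                             "saturated")],
              by = c("frame", "region"), sort = FALSE)
  tr <- tr[order(tr$region, tr$frame), ]
  names(tr)[names(tr) == "t"] <- "t_s"
  wr_csv(tr, "traces.csv")
  wr_csv(bundle$areas, "areas.csv")
  k <- bundle$kinetics
  wr_csv(data.frame(t_max_s = k$t_max, A_max_um2 = k$A_max,
                    t_half_dissolution_s = k$t_half_dissolution,
                    half_censored = k$half_censored, auc_um2s = k$auc,
                    auc_raw_um2s = k$auc_raw, A_end_um2 = k$A_end,
                    t_end_s = k$t_end),
         "kinetics.csv")
  if (!is.null(bundle$snr)) wr_csv(bundle$snr, "snr.csv")
  wr_json <- function(x, name) {
    p <- file.path(outdir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    files <<- c(files, p)
  }
  wr_json(bundle$summary, "summary.json")
  wr_json(unclass(bundle$config$sensor), "sensor.json")
  cfg <- bundle$config
  wr_json(list(input = cfg$input, seed = cfg$seed,
               snr_threshold = cfg$snr_threshold,
               seg = unclass(bundle$seg),
               baseline_window = cfg$baseline_window,
               response_window = cfg$response_window),
          "config.json")
  manifest <- list(
    package = "cgflow",
    version = as.character(utils::packageVersion("cgflow")),
    seed = cfg$seed,
    files = lapply(files, function(p)
      list(name = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
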