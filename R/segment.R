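# Dynamic thrombus segmentation. The whole thrombus is segmented per frame
# by thresholding the Gaussian-blurred CFP+YFP sum image; the mask is then
# partitioned into a core (pixels at least core_factor x threshold, i.e.
# ~20% above the whole-thrombus threshold) and a periphery (the remainder).

#' Segmentation parameters
#'
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0; default 2).
#' @param threshold Intensity threshold in counts, `"otsu"` to derive it
#'   automatically from the brightest frame of the blurred sum movie, or
#'   `"auto"` (pipeline use: resolves to the generator's rim intensity for
#'   simulated input and to Otsu otherwise).
#' @param core_factor The core is defined as pixels at or above
#'   `core_factor * threshold` (> 1; default 1.2, i.e. 20% above).
#' @param core_method `"intensity"` (default, the intensity criterion) or
#'   `"morphological"` (erode the whole mask by `erode_px` pixels instead).
#' @param erode_px Erosion radius in pixels for the morphological variant.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(blur_sigma = 2, threshold = "otsu",
                                core_factor = 1.2,
                                core_method = c("intensity", "morphological"),
                                erode_px = 3) {
  core_method <- match.arg(core_method)
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (core_factor <= 1) stop("core_factor must be > 1")
  if (!(identical(threshold, "otsu") || identical(threshold, "auto") ||
        (is.numeric(threshold) && length(threshold) == 1L && threshold > 0)))
    stop("threshold must be a positive count value, \"otsu\" or \"auto\"")
  structure(list(blur_sigma = blur_sigma, threshold = threshold,
                 core_factor = core_factor, core_method = core_method,
                 erode_px = erode_px),
            class = "segmentation_params")
}

#' Blurred CFP+YFP sum movie
#'
#' Sums the two FRET emission channels pixelwise and applies a Gaussian
#' blur (sigma in pixels) per frame; this blurred sum movie defines the
#' dynamic binary mask.
#'
#' @param stack A `time_lapse_stack` containing channels `EM480` and
#'   `EM535`.
#' @param params A [segmentation_params()].
#' @return A 3D array (height x width x frames) of class `blurred_movie`
#'   with `dt` and `pixel_size` attributes.
#' @export
preprocess_stack <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  for (ch in c("EM480", "EM535"))
    if (!ch %in% stack$channel_names)
      stop("stack is missing required channel: ", ch)
  i480 <- match("EM480", stack$channel_names)
  i535 <- match("EM535", stack$channel_names)
  dims <- dim(stack$data)
  out <- array(0, dim = dims[c(1, 2, 4)])
  for (k in seq_len(dims[4])) {
    s <- stack$data[, , i480, k] + stack$data[, , i535, k]
    if (params$blur_sigma > 0)
      s <- EBImage::imageData(EBImage::gblur(s, sigma = params$blur_sigma))
    out[, , k] <- s
  }
  structure(out, dt = stack$dt, pixel_size = stack$pixel_size,
            class = c("blurred_movie", "array"))
}

resolve_threshold <- function(blurred, params) {
  if (identical(params$threshold, "otsu") ||
      identical(params$threshold, "auto")) {
    totals <- apply(blurred, 3, sum)
    bright <- blurred[, , which.max(totals)]
    mx <- max(bright)
    if (mx <= 0) return(Inf)
    EBImage::otsu(EBImage::Image(bright / mx), range = c(0, 1)) * mx
  } else {
    params$threshold
  }
}

largest_component <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  if (max(lab) <= 1) return(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

new_mask_series <- function(masks, flags, dt, pixel_size, provenance) {
  structure(list(masks = masks, labels = names(masks), flags = flags,
                 dt = dt, pixel_size = pixel_size, provenance = provenance),
            class = "mask_series")
}

#' Segment the whole thrombus per frame
#'
#' Thresholds the blurred sum movie; per frame, the whole-thrombus mask is
#' the largest connected component of the at-or-above-threshold pixels.
#' Frames with an empty mask are flagged, not dropped. If the threshold
#' exceeds the global maximum every frame is flagged empty and a warning is
#' issued.
#'
#' @param blurred Output of [preprocess_stack()] (or any H x W x T array).
#' @param params A [segmentation_params()].
#' @return A `mask_series` with the `whole` label, per-frame empty flags
#'   and the resolved threshold in `$provenance`.
#' @export
segment_whole <- function(blurred, params = segmentation_params()) {
  dims <- dim(blurred)
  stopifnot(length(dims) == 3L)
  thr <- resolve_threshold(blurred, params)
  n <- dims[3]
  whole <- array(FALSE, dims)
  empty <- logical(n)
  if (thr > max(blurred)) {
    warning("threshold exceeds the global maximum intensity; all frames empty")
    empty[] <- TRUE
  } else {
    for (k in seq_len(n)) {
      m <- blurred[, , k] >= thr
      if (!any(m)) { empty[k] <- TRUE; next }
      whole[, , k] <- largest_component(m)
    }
  }
  dt <- attr(blurred, "dt") %||% 1
  px <- attr(blurred, "pixel_size") %||% 1
  flags <- data.frame(frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) * dt,
                      empty = empty)
  new_mask_series(list(whole = whole), flags, dt, px,
                  provenance = list(threshold = thr, params = params))
}

#' Partition the whole-thrombus mask into core and periphery
#'
#' With the default intensity criterion the core is the part of the whole
#' mask whose blurred sum intensity is at least `core_factor` x the
#' whole-thrombus threshold; the periphery is the remainder, so that per
#' frame core and periphery partition the whole mask exactly. The
#' morphological variant erodes the whole mask by `erode_px` pixels
#' instead.
#'
#' @param blurred Output of [preprocess_stack()] used for `masks`.
#' @param masks A `mask_series` from [segment_whole()].
#' @param params A [segmentation_params()]; `core_factor` must be > 1.
#' @return A `mask_series` with labels `whole`, `core` and `periphery`.
#' @export
split_core_periphery <- function(blurred, masks,
                                 params = segmentation_params()) {
  stopifnot(inherits(masks, "mask_series"), "whole" %in% masks$labels)
  thr <- masks$provenance$threshold
  if (is.null(thr)) thr <- resolve_threshold(blurred, params)
  whole <- masks$masks$whole
  n <- dim(whole)[3]
  core <- array(FALSE, dim(whole))
  if (params$core_method == "intensity") {
    for (k in seq_len(n))
      core[, , k] <- whole[, , k] & (blurred[, , k] >= params$core_factor * thr)
  } else {
    brush <- EBImage::makeBrush(2L * as.integer(params$erode_px) + 1L, "disc")
    for (k in seq_len(n)) {
      if (!any(whole[, , k])) next
      core[, , k] <- EBImage::imageData(
        EBImage::erode(whole[, , k] * 1, brush)) > 0
    }
  }
  periphery <- whole & !core
  new_mask_series(list(whole = whole, core = core, periphery = periphery),
                  masks$flags, masks$dt, masks$pixel_size,
                  provenance = c(masks$provenance,
                                 list(core_factor = params$core_factor,
                                      core_method = params$core_method)))
}

#' Per-frame mask areas
#'
#' @param masks A `mask_series`.
#' @return data.frame with columns `frame`, `t_s`, `label`, `area_px`,
#'   `area_um2`.
#' @export
mask_areas <- function(masks) {
  stopifnot(inherits(masks, "mask_series"))
  out <- do.call(rbind, lapply(masks$labels, function(lab) {
    counts <- apply(masks$masks[[lab]], 3, sum)
    data.frame(frame = seq_along(counts) - 1L,
               t_s = (seq_along(counts) - 1L) * masks$dt,
               label = lab, area_px = counts,
               area_um2 = counts * masks$pixel_size^2)
  }))
  rownames(out) <- NULL
  out
}

#' Jaccard overlap between two mask series
#'
#' @param a,b `mask_series` objects sharing frame count and image size.
#' @param label Mask label to compare (default `"whole"`).
#' @param per_frame If `TRUE`, return the per-frame Jaccard index (NA for
#'   frames empty in both); otherwise (default) the pooled Jaccard over all
#'   frames, `sum(|intersection|) / sum(|union|)`.
#' @return Numeric scalar (pooled) or vector (per frame).
#' @export
mask_jaccard <- function(a, b, label = "whole", per_frame = FALSE) {
  ma <- a$masks[[label]]; mb <- b$masks[[label]]
  stopifnot(!is.null(ma), !is.null(mb), identical(dim(ma), dim(mb)))
  if (!per_frame) {
    inter <- sum(ma & mb); uni <- sum(ma | mb)
    return(if (uni == 0) NA_real_ else inter / uni)
  }
  vapply(seq_len(dim(ma)[3]), function(k) {
    uni <- sum(ma[, , k] | mb[, , k])
    if (uni == 0) NA_real_ else sum(ma[, , k] & mb[, , k]) / uni
  }, numeric(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
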