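# Stack I/O: multi-page TIFF with channel-interleaved pages (channel
# fastest within each time point) plus a JSON sidecar carrying channel
# names, frame interval and pixel size.

#' Multi-channel time-lapse stack
#'
#' @param data 4D numeric array, height x width x channels x frames, all
#'   intensities >= 0.
#' @param channel_names Ordered channel labels (e.g. `"EM480"`, `"EM535"`,
#'   `"EX340"`, `"EX380"`).
#' @param dt Seconds per frame (> 0).
#' @param pixel_size Pixel edge length (um/pixel).
#' @return An object of class `time_lapse_stack`.
#' @export
time_lapse_stack <- function(data, channel_names, dt = 1, pixel_size = 1) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (height x width x channels x frames)")
  if (dim(data)[3] != length(channel_names))
    stop("channel_names must match the number of channels")
  if (dt <= 0) stop("dt must be > 0")
  if (min(data) < 0) stop("intensities must be >= 0")
  structure(list(data = data, channel_names = channel_names, dt = dt,
                 pixel_size = pixel_size), class = "time_lapse_stack")
}

#' @export
print.time_lapse_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("time_lapse_stack: %d frames x %d channels (%s), %dx%d px, dt = %g s, pixel = %g um\n",
              d[4], d[3], paste(x$channel_names, collapse = ", "),
              d[1], d[2], x$dt, x$pixel_size))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack as multi-page 16-bit TIFF
#'
#' Pages are interleaved channel-fastest (page `(t-1)*C + c`). Metadata
#' (channel names, dt, pixel size) goes to a JSON sidecar next to the TIFF.
#'
#' @param stack A [time_lapse_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "time_lapse_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  for (k in seq_len(d[4]))
    for (ci in seq_len(d[3]))
      pages[[(k - 1) * d[3] + ci]] <- stack$data[, , ci, k] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(channel_names = stack$channel_names,
                            dt = stack$dt, pixel_size = stack$pixel_size,
                            frames = d[4]),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Pages must be channel-interleaved (channel fastest). Metadata is taken
#' from the JSON sidecar written by [write_stack()] when present;
#' explicitly supplied arguments always win over sidecar metadata. The
#' page count must be divisible by the channel count.
#'
#' @param path TIFF path.
#' @param channel_names Ordered channel labels; required if no sidecar.
#' @param dt Seconds per frame; default from sidecar, else 1.
#' @param pixel_size um/pixel; default from sidecar, else 1.
#' @return A [time_lapse_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, dt = NULL,
                       pixel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE) else list()
  channel_names <- channel_names %||% meta$channel_names
  if (is.null(channel_names))
    stop("channel layout unresolvable: supply channel_names ",
         "(no JSON sidecar found at ", sidecar_path(path), ")")
  dt <- dt %||% meta$dt %||% 1
  pixel_size <- pixel_size %||% meta$pixel_size %||% 1
  C <- length(channel_names)
  if (length(pages) %% C != 0)
    stop(length(pages), " pages are not divisible by ", C, " channels")
  n <- length(pages) %/% C
  d1 <- dim(pages[[1]])
  data <- array(0, dim = c(d1[1], d1[2], C, n))
  for (k in seq_len(n))
    for (ci in seq_len(C))
      data[, , ci, k] <- pages[[(k - 1) * C + ci]]
  time_lapse_stack(data, channel_names, dt = dt, pixel_size = pixel_size)
}

#' Write a mask series as multi-page 8-bit TIFFs
#'
#' One TIFF per label (0/255), label in the filename.
#'
#' @param masks A `mask_series`.
#' @param dir Output directory.
#' @param prefix Filename prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_masks <- function(masks, dir, prefix = "mask") {
  stopifnot(inherits(masks, "mask_series"))
  paths <- character()
  for (lab in masks$labels) {
    m <- masks$masks[[lab]]
    pages <- lapply(seq_len(dim(m)[3]), function(k) m[, , k] * 1)
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, lab))
    tiff::writeTIFF(pages, p, bits.per.sample = 8L, compression = "none",
                    reduce = FALSE)
    paths[lab] <- p
  }
  invisible(paths)
}
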