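# Shared synthetic fixtures, built once per test run and cached.
# Small frames keep the suite fast; the acceptance tests use the full
# 256 x 256 geometry.

demo_geometry <- function(px = 96) synth_geometry(width = px, height = px)

demo_profile <- function(t_end = 149, A_max = 300)
  area_profile(A_max = A_max, t_max = 40, A_end = 0.4 * A_max, t_end = t_end)

# default-conditions movie, 96 px, 150 frames, flow on 40-90 s
demo_movie <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_free = FALSE, with_ca = FALSE) {
    key <- paste0("m", noise_free, with_ca)
    if (is.null(cache[[key]])) {
      noise <- if (noise_free)
        noise_model(shot_noise = FALSE, read_noise_sd = 0, seed = 42)
      else noise_model(seed = 42)
      cache[[key]] <- simulate_thrombus_movie(
        duration = 150, on_windows = list(c(40, 90)),
        geometry = demo_geometry(), profile = demo_profile(),
        noise = noise, ca = if (with_ca) ca_model() else NULL)
    }
    cache[[key]]
  }
})

demo_seg_params <- function(...)
  segmentation_params(threshold = rim_threshold(demo_geometry(),
                                                noise_model()), ...)

# segmentation + traces for the default demo movie, cached
demo_analysis <- local({
  cache <- new.env(parent = emptyenv())
  function(noise_free = FALSE, with_ca = FALSE) {
    key <- paste0("a", noise_free, with_ca)
    if (is.null(cache[[key]])) {
      mv <- demo_movie(noise_free, with_ca)
      sp <- demo_seg_params()
      blurred <- preprocess_stack(mv$stack, sp)
      masks <- split_core_periphery(blurred, segment_whole(blurred, sp), sp)
      background <- estimate_background(mv$stack, masks)
      traces <- extract_traces(mv$stack, masks, background)
      ratio <- delta_ratio(compute_ratio(traces), c(30, 40))
      cache[[key]] <- list(mv = mv, masks = masks, background = background,
                           traces = traces, ratio = ratio)
    }
    cache[[key]]
  }
})
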