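# Parallel-plate flow-chamber hydrodynamics: conversion between volumetric
# flow rate, wall shear rate and wall shear stress.

#' Flow-chamber geometry
#'
#' Ideal parallel-plate chamber. The wall shear rate for a Newtonian fluid
#' is `gamma_dot = 6 Q / (w h^2)` (consistent units); an optional
#' multiplicative `correction` accommodates slide-specific manufacturer
#' factors (default 1, the ideal chamber). The parallel-plate approximation
#' requires a wide, shallow channel; a warning is issued (and a flag set)
#' when `width < 10 * height`.
#'
#' @param width Channel width in mm.
#' @param height Channel height in mm.
#' @param viscosity Dynamic viscosity in dyn*s/cm^2 (poise). Default 0.01
#'   (1 cP, aqueous buffer) -- the value under which a shear rate of
#'   500 1/s corresponds to a shear stress of 5 dyn/cm^2.
#' @param correction Dimensionless correction factor (> 0) applied to the
#'   ideal parallel-plate shear rate.
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(width = 5, height = 0.1, viscosity = 0.01,
                         correction = 1) {
  if (width <= 0 || height <= 0 || viscosity <= 0 || correction <= 0)
    stop("chamber width, height, viscosity and correction must be > 0")
  ok <- width >= 10 * height
  if (!ok)
    warning("width < 10 * height: parallel-plate approximation may be poor")
  structure(list(width = width, height = height, viscosity = viscosity,
                 correction = correction, parallel_plate_ok = ok),
            class = "chamber_spec")
}

#' Wall shear rate from volumetric flow rate
#'
#' @param Q Flow rate in mL/min (>= 0).
#' @param chamber A [chamber_spec()].
#' @return Wall shear rate in 1/s (linear in `Q`).
#' @export
shear_rate_from_flow <- function(Q, chamber = chamber_spec()) {
  if (any(Q < 0)) stop("flow rate must be >= 0")
  Q_cm3s <- Q / 60                       # mL/min -> cm^3/s
  w_cm <- chamber$width / 10             # mm -> cm
  h_cm <- chamber$height / 10
  chamber$correction * 6 * Q_cm3s / (w_cm * h_cm^2)
}

#' Wall shear stress from shear rate
#'
#' Newtonian relation `tau = eta * gamma_dot`.
#'
#' @param shear_rate Wall shear rate in 1/s (>= 0).
#' @param viscosity Dynamic viscosity in dyn*s/cm^2 (>= 0).
#' @return Shear stress in dyn/cm^2.
#' @export
shear_stress <- function(shear_rate, viscosity = 0.01) {
  if (any(shear_rate < 0) || any(viscosity < 0))
    stop("shear rate and viscosity must be >= 0")
  viscosity * shear_rate
}

#' Flow rate required for a target wall shear rate
#'
#' Exact algebraic inverse of [shear_rate_from_flow()].
#'
#' @param target Target shear rate in 1/s (>= 0).
#' @param chamber A [chamber_spec()].
#' @return Flow rate in mL/min.
#' @export
flow_for_target_shear <- function(target, chamber = chamber_spec()) {
  if (any(target < 0)) stop("target shear rate must be >= 0")
  w_cm <- chamber$width / 10
  h_cm <- chamber$height / 10
  Q_cm3s <- target * w_cm * h_cm^2 / (6 * chamber$correction)
  Q_cm3s * 60
}

#' Full shear summary for a flow rate
#'
#' @param Q Flow rate in mL/min.
#' @param chamber A [chamber_spec()].
#' @return List with `flow_rate` (mL/min), `shear_rate` (1/s) and
#'   `shear_stress` (dyn/cm^2).
#' @export
shear_result <- function(Q, chamber = chamber_spec()) {
  rate <- shear_rate_from_flow(Q, chamber)
  list(flow_rate = Q, shear_rate = rate,
       shear_stress = shear_stress(rate, chamber$viscosity))
}
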