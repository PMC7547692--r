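# Daily bucket hydrology: rainfall partitioning, soil-moisture accounting,
# and the moisture factor regulating decomposition. A deliberately simple
# single-bucket scheme at the daily step; Manning's roughness enters the
# sediment-transport coefficient, not a sub-daily routing scheme.

#' Create a per-cell soil-moisture state
#'
#' @param theta Initial volumetric soil moisture (scalar or per-cell vector).
#' @param porosity,field_capacity,wilting_point Volumetric constants with
#'   `0 <= wilting_point < field_capacity < porosity <= 1`.
#' @param depth_m Bucket depth (m) converting moisture to storage (default
#'   1, the active soil column).
#' @return A `moisture_state` object.
#' @export
moisture_state <- function(theta = 0.18, porosity = 0.45,
                           field_capacity = 0.32, wilting_point = 0.08,
                           depth_m = 1) {
  if (!(wilting_point >= 0 && wilting_point < field_capacity &&
        field_capacity < porosity && porosity <= 1)) {
    stop("need 0 <= wilting < field capacity < porosity <= 1",
         call. = FALSE)
  }
  if (any(theta < 0 | theta > porosity)) {
    stop("theta must lie in [0, porosity]", call. = FALSE)
  }
  structure(list(theta = theta, porosity = porosity,
                 field_capacity = field_capacity,
                 wilting_point = wilting_point, depth_m = depth_m),
            class = "moisture_state")
}

#' Partition daily rainfall into infiltration and runoff
#'
#' Infiltration-excess and saturation-excess partition: infiltration is
#' limited by the infiltration capacity and by the remaining pore space;
#' the remainder runs off. Closure is exact:
#' `infiltration + runoff = precip`.
#'
#' @param precip Daily precipitation, mm (scalar or per-cell).
#' @param state A [moisture_state()].
#' @param infiltration_capacity mm/day.
#' @return List with `infiltration` and `runoff` (mm/day).
#' @export
partition_rainfall <- function(precip, state, infiltration_capacity = 20) {
  if (any(precip < 0)) stop("precip must be >= 0", call. = FALSE)
  pore_space_mm <- (state$porosity - state$theta) * state$depth_m * 1000
  infil <- pmin(precip, infiltration_capacity, pmax(pore_space_mm, 0))
  list(infiltration = infil, runoff = precip - infil)
}

#' Advance the soil-moisture bucket one day
#'
#' Adds infiltration, removes actual evapotranspiration (demand capped by
#' water available above the wilting point) and free drainage above field
#' capacity. The daily water balance closes to machine precision; the
#' realized terms are returned alongside the new state.
#'
#' @param state A [moisture_state()].
#' @param infiltration mm/day.
#' @param et_demand mm/day.
#' @param drainage_coefficient Fraction (1/day) of above-field-capacity
#'   storage drained per day.
#' @return List: `state` (updated), `actual_et`, `drainage` (mm/day).
#' @export
update_moisture <- function(state, infiltration, et_demand = 0,
                            drainage_coefficient = 0.5) {
  if (any(infiltration < 0) || any(et_demand < 0) ||
      drainage_coefficient < 0) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  depth_mm <- state$depth_m * 1000
  theta <- state$theta + infiltration / depth_mm
  theta <- pmin(theta, state$porosity)
  avail_mm <- pmax(theta - state$wilting_point, 0) * depth_mm
  aet <- pmin(et_demand, avail_mm)
  theta <- theta - aet / depth_mm
  excess_mm <- pmax(theta - state$field_capacity, 0) * depth_mm
  drain <- drainage_coefficient * excess_mm
  theta <- theta - drain / depth_mm
  state$theta <- theta
  list(state = state, actual_et = aet, drainage = drain)
}

#' Soil-moisture factor regulating decomposition
#'
#' Piecewise linear in volumetric moisture: rises from 0 at oven-dry to 1 at
#' field capacity (the optimum), then declines linearly towards a floor of
#' `wet_floor` at saturation — very dry or very wet (oxygen-limited) soils
#' decompose slower.
#'
#' @param theta Volumetric soil moisture in `[0, porosity]`.
#' @param field_capacity,porosity Volumetric constants.
#' @param wet_floor Factor value at saturation (default 0.25).
#' @return `f_d` in `[0, 1]`.
#' @export
moisture_factor <- function(theta, field_capacity, porosity,
                            wet_floor = 0.25) {
  if (any(theta < 0 | theta > porosity + 1e-12)) {
    stop("theta outside [0, porosity]", call. = FALSE)
  }
  ifelse(theta <= field_capacity,
         theta / field_capacity,
         1 - (1 - wet_floor) * (theta - field_capacity) /
           (porosity - field_capacity))
}

#' Accumulate runoff into per-cell unit discharge
#'
#' Routes each cell's local runoff down the D8 network and converts the
#' accumulated volumetric discharge to a unit discharge (m2/day, per unit
#' contour width `cell_size`).
#'
#' @param runoff_mm Per-cell daily runoff depth (mm/day), length `n_cells`.
#' @param network A `flow_network` from [route_flow()].
#' @param domain A [grid_domain()].
#' @return Numeric vector of unit discharge (m2/day) per cell.
#' @export
unit_discharge <- function(runoff_mm, network, domain) {
  if (length(runoff_mm) != n_cells(domain)) {
    stop("runoff field does not match the domain", call. = FALSE)
  }
  if (is.null(network$receiver)) stop("unrouted network", call. = FALSE)
  local <- (runoff_mm / 1000) * domain$cell_size  # m/day * dx -> m2/day
  cpp_accumulate(local, network$order, network$receiver)
}
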