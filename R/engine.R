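# Orchestration of the daily coupled step over multi-decadal runs, with
# per-cell lateral (transport) and vertical (transformation) flux ledgers
# whose sum is the total SOC stock change.

#' Define a management scenario
#'
#' @param litter_multiplier Multiplier on the ambient litter input (the
#'   study grid uses 0.5, 1 and 2).
#' @param target_mrt_years Target surface humus mean residence time in
#'   years (the study grid uses 10 to 24.4 in steps of 2.9).
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(litter_multiplier = 1,
                          target_mrt_years = NULL) {
  if (litter_multiplier <= 0) {
    stop("litter multiplier must be > 0", call. = FALSE)
  }
  if (!is.null(target_mrt_years) && target_mrt_years <= 0) {
    stop("target MRT must be > 0", call. = FALSE)
  }
  structure(list(litter_multiplier = litter_multiplier,
                 target_mrt_years = target_mrt_years),
            class = "scenario_spec")
}

#' Define a simulation run configuration
#'
#' @param duration_years Simulated duration (>= 1; the reference experiment
#'   uses 50).
#' @param reporting_interval_days Interval of the summary time series.
#' @param tillage_month Calendar month of annual tillage on cropland
#'   (default April; applied on the 1st).
#' @param tillage_depth Mixing depth (m).
#' @param scenario Optional [scenario_spec()].
#' @param seed Integer seed for the weather generator.
#' @param start_year First calendar year.
#' @param reroute_interval_days How often the D8 network is recomputed as
#'   the terrain evolves.
#' @param transport_enabled Switch for the whole lateral-transport branch.
#' @param record_monthly Keep per-cell monthly flux aggregates (needed for
#'   climatologies).
#' @return A `run_config` object.
#' @export
run_config <- function(duration_years = 50, reporting_interval_days = 365,
                       tillage_month = 4, tillage_depth = 0.20,
                       scenario = NULL, seed = 1, start_year = 2001,
                       reroute_interval_days = 30,
                       transport_enabled = TRUE, record_monthly = TRUE) {
  if (duration_years < 1) stop("duration must be >= 1 year", call. = FALSE)
  structure(list(duration_years = duration_years,
                 reporting_interval_days = reporting_interval_days,
                 tillage_month = tillage_month,
                 tillage_depth = tillage_depth,
                 scenario = scenario, seed = seed, start_year = start_year,
                 reroute_interval_days = reroute_interval_days,
                 transport_enabled = transport_enabled,
                 record_monthly = record_monthly),
            class = "run_config")
}

#' Assemble the initial simulation state
#'
#' @param dem An `elevation_grid` from [generate_dem()] (or with the same
#'   fields).
#' @param columns A `soc_columns` set from [build_initial_columns()].
#' @param moisture A [moisture_state()] (scalar theta is recycled over
#'   cells).
#' @return A `simulation_state`.
#' @export
simulation_state <- function(dem, columns, moisture = moisture_state()) {
  ncell <- n_cells(dem$domain)
  stopifnot(nrow(columns$thickness) == ncell)
  theta <- rep(moisture$theta, length.out = ncell)
  moisture$theta <- theta
  structure(list(
    domain = dem$domain,
    elev = dem$elev,
    soil_thickness = dem$soil_thickness,
    landcover = as.character(dem$landcover),
    parcel = as.integer(dem$parcel),
    cols = columns[c("thickness", "C_l", "C_h", "C_b")],
    c_vol = if (!is.null(columns$c_vol)) columns$c_vol else numeric(ncell),
    nominal_layering = columns$thickness[1, ],
    moisture = moisture,
    ledger_lat = numeric(ncell),
    ledger_vert = numeric(ncell),
    init_stock = rowSums(columns$thickness *
                           (columns$C_l + columns$C_h + columns$C_b)),
    network = NULL,
    days_since_route = Inf,
    soc_export = 0, sed_export = 0,
    litter_total = 0, efflux_total = 0,
    pool_deficit = 0, thickness_deficit = 0,
    clock = NULL
  ), class = "simulation_state")
}

# Daily litter input per cell (kg C/m2/day) from the deterministic NDVI
# curves and per-class litter curves.
litter_for_date <- function(date, landcover, litter_curves, multiplier = 1) {
  rate_nat <- ndvi_to_litter(generate_ndvi("natural", date),
                             litter_curves$natural)
  rate_crop <- ndvi_to_litter(generate_ndvi("cornfield", date),
                              litter_curves$crop)
  multiplier * ifelse(landcover == "crop", rate_crop, rate_nat)
}

#' Advance the coupled simulation by one day
#'
#' Operator-split daily step in the order: bucket hydrology; sediment
#' transport and Exner elevation update; lateral SOC transport; vertical
#' SOC transformation; bioturbation. Annual tillage is applied to cropland
#' cells on the 1st of the tillage month. The per-cell ledgers are updated
#' so that `stock - initial stock = lateral + vertical` holds to machine
#' precision at any time.
#'
#' @param state A [simulation_state()].
#' @param precip_mm Daily precipitation (mm).
#' @param date Date of the step.
#' @param tparams A [transport_params()].
#' @param xparams A [transform_params()].
#' @param litter_curves List with elements `natural` and `crop`
#'   ([ndvi_litter_curve()]s).
#' @param config A [run_config()].
#' @return The updated state.
#' @export
step_day <- function(state, precip_mm, date, tparams, xparams,
                     litter_curves, config = run_config(),
                     .mo = NULL, .dom = NULL) {
  domain <- state$domain
  ncell <- n_cells(domain)
  dx <- domain$cell_size
  if (is.null(.mo)) {
    lt <- as.POSIXlt(date)
    .mo <- lt$mon + 1L
    .dom <- lt$mday
  }
  mo <- .mo
  dom <- .dom
  nl <- length(state$nominal_layering)

  ## 1. hydrology -------------------------------------------------------
  part <- partition_rainfall(precip_mm, state$moisture)
  upd <- update_moisture(state$moisture, part$infiltration,
                         et_demand = monthly_et_demand()[mo])
  state$moisture <- upd$state
  f_inst <- moisture_factor(state$moisture$theta,
                            state$moisture$field_capacity,
                            state$moisture$porosity)
  # decomposition responds to antecedent moisture (weeks-scale microbial
  # memory), not to day-scale wetting spikes
  alpha <- exp(-1 / xparams$f_memory_days)
  if (is.null(state$f_d_smooth)) state$f_d_smooth <- f_inst
  state$f_d_smooth <- alpha * state$f_d_smooth + (1 - alpha) * f_inst
  f_d <- state$f_d_smooth

  if (config$transport_enabled) {
    ## 2. sediment transport and elevation ------------------------------
    if (state$days_since_route >= config$reroute_interval_days) {
      state$network <- route_flow(state$elev, domain)
      state$days_since_route <- 0
    }
    state$days_since_route <- state$days_since_route + 1
    runoff <- rep(part$runoff, length.out = ncell)
    manning_scale <- tparams$manning_ref /
      tparams$manning_n[state$landcover]
    div_qd <- diffusion_divergence(state$elev, tparams$D_x, tparams$D_y,
                                   dx)
    any_runoff <- any(runoff > 0)
    if (any_runoff) {
      q <- unit_discharge(runoff, state$network, domain)
      ovl <- overland_divergence(state$network, q, tparams, manning_scale)
      div_qs <- as_grid_matrix(ovl$divergence, domain)
    } else {
      ovl <- NULL
      div_qs <- matrix(0, domain$n_rows, domain$n_cols)
    }
    stepped <- step_elevation(state$elev, state$soil_thickness, div_qd,
                              div_qs, dt = 1,
                              D_max = max(tparams$D_x, tparams$D_y),
                              cell_size = dx)
    state$elev <- stepped$elev
    state$soil_thickness <- stepped$soil_thickness
    state$thickness_deficit <- state$thickness_deficit +
      stepped$thickness_deficit
    state$sed_export <- state$sed_export +
      (if (any_runoff) ovl$outlet_export * dx else 0)

    ## 3. lateral SOC transport -----------------------------------------
    div_soc <- matrix(0, ncell, 3)
    pools <- c("C_l", "C_h", "C_b")
    for (p in 1:3) {
      cm <- as_grid_matrix(state$cols[[pools[p]]][, 1], domain)
      div_soc[, p] <- as.numeric(
        soc_diffusive_flux(cm, state$elev, tparams$D_x, tparams$D_y,
                           tparams$k_soc, dx))
    }
    if (any_runoff) {
      conc1 <- cbind(state$cols$C_l[, 1], state$cols$C_h[, 1],
                     state$cols$C_b[, 1])
      adv <- soc_advective_flux(conc1, state$network, ovl, tparams$k_soc)
      div_soc <- div_soc + adv$divergence
      state$soc_export <- state$soc_export +
        sum(adv$outlet_export) * dx
    }
    dM <- -div_soc                     # kg C/m2 over dt = 1 day
    dz <- -as.numeric(div_qd + div_qs)
    ex <- apply_surface_exchange(state$cols, dM, dz,
                                 nominal = state$nominal_layering)
    state$cols <- ex$cols
    state$ledger_lat <- state$ledger_lat + rowSums(dM) + ex$deficit_cells
    state$pool_deficit <- state$pool_deficit + ex$pool_deficit
    state$thickness_deficit <- state$thickness_deficit +
      ex$thickness_deficit
  }

  ## 4. vertical transformation ----------------------------------------
  litter <- litter_for_date(date, state$landcover, litter_curves,
                            multiplier = scenario_litter(config)) # kg/m2/d
  kh_mult <- scenario_kh_multiplier(config, xparams)
  w_root <- root_litter_weights(state$nominal_layering, xparams)
  mids <- cumsum(state$nominal_layering) - state$nominal_layering / 2
  surf_mask <- mids <= 0.05
  if (is.null(state$c_inert)) {
    # mineral-stabilized humus grows towards the profile's deep asymptote
    state$c_inert <- outer(state$c_vol,
                           1 - exp(-mids / xparams$inert_efold))
  }
  efflux_areal <- numeric(ncell)
  for (k in seq_len(nl)) {
    zk <- state$cols$thickness[, k]
    I_k <- (if (k == 1) xparams$surface_fraction * litter else 0) +
      (1 - xparams$surface_fraction) * litter * w_root[k]
    res <- transform_step(list(C_l = state$cols$C_l[, k],
                               C_h = state$cols$C_h[, k],
                               C_b = state$cols$C_b[, k]),
                          I_litter = I_k / zk, params = xparams,
                          f_d = f_d, dt = 1,
                          kh_multiplier = if (surf_mask[k]) kh_mult else 1,
                          C_inert = state$c_inert[, k])
    state$cols$C_l[, k] <- res$C_l
    state$cols$C_h[, k] <- res$C_h
    state$cols$C_b[, k] <- res$C_b
    efflux_areal <- efflux_areal + res$co2_efflux * zk
  }
  dvert <- litter - efflux_areal
  state$ledger_vert <- state$ledger_vert + dvert
  state$litter_total <- state$litter_total + sum(litter)
  state$efflux_total <- state$efflux_total + sum(efflux_areal)

  ## 5. bioturbation ----------------------------------------------------
  state$cols <- bioturbation_step_cells(state$cols, xparams, dt = 1)

  ## tillage: cropland, 1st of the tillage month ------------------------
  if (!is.null(config$tillage_month) && mo == config$tillage_month &&
      dom == 1L) {
    state$cols <- tillage_mix_cells(state$cols, config$tillage_depth,
                                    mask = state$landcover == "crop")
  }
  state$clock <- date
  state
}

scenario_litter <- function(config) {
  if (is.null(config$scenario)) 1 else config$scenario$litter_multiplier
}

scenario_kh_multiplier <- function(config, xparams) {
  if (is.null(config$scenario) ||
      is.null(config$scenario$target_mrt_years)) {
    xparams$kh_surface_multiplier
  } else {
    calibrate_residence_time(config$scenario$target_mrt_years, xparams)
  }
}

#' Per-cell areal SOC stocks of a simulation state
#' @param state A [simulation_state()].
#' @return Numeric vector, kg C/m2.
#' @export
state_stocks <- function(state) {
  rowSums(state$cols$thickness *
            (state$cols$C_l + state$cols$C_h + state$cols$C_b))
}

#' Run the coupled co-evolution simulation
#'
#' Steps [step_day()] over the configured duration, driven by a generated
#' (or supplied) daily weather series; deterministic given the seeds.
#'
#' @param state A [simulation_state()] (consumed; the final state is
#'   returned).
#' @param config A [run_config()].
#' @param tparams,xparams Transport and transformation parameters.
#' @param litter_curves List with `natural` and `crop` litter curves
#'   (defaults from [default_litter_curve()]).
#' @param forcing Optional `daily_forcing` covering the run; generated from
#'   [weather_params()] with `config$seed` when omitted.
#' @return A `coevolution_run`: the final `state`, per-cell `stock_change`,
#'   `ledger_lat`, `ledger_vert` (kg C/m2), monthly flux aggregates
#'   (`monthly`, g C/m2/month, with `year`/`month` index), a reporting
#'   `series` data frame, and run totals.
#' @export
run_coevolution <- function(state, config = run_config(),
                            tparams = transport_params(),
                            xparams = transform_params(),
                            litter_curves = list(
                              natural = default_litter_curve("natural"),
                              crop = default_litter_curve("crop")),
                            forcing = NULL) {
  if (is.null(forcing)) {
    forcing <- generate_weather(weather_params(seed = config$seed),
                                n_years = ceiling(config$duration_years),
                                start_year = config$start_year)
  }
  n_days <- min(nrow(forcing), round(config$duration_years * 365.25))
  if (n_days < 1) {
    return(finish_run(state, NULL, NULL, config))
  }
  dates <- forcing$date[seq_len(n_days)]
  ncell <- n_cells(state$domain)
  mo_id <- format(dates, "%Y-%m")
  mo_levels <- unique(mo_id)
  mo_idx <- match(mo_id, mo_levels)
  if (config$record_monthly) {
    mon_lat <- matrix(0, ncell, length(mo_levels))
    mon_vert <- matrix(0, ncell, length(mo_levels))
  }
  rep_every <- max(1L, as.integer(config$reporting_interval_days))
  rep_rows <- list()
  prev_lat <- state$ledger_lat
  prev_vert <- state$ledger_vert
  lt_all <- as.POSIXlt(dates)
  mo_all <- lt_all$mon + 1L
  dom_all <- lt_all$mday
  for (i in seq_len(n_days)) {
    state <- step_day(state, forcing$precip_mm[i], dates[i], tparams,
                      xparams, litter_curves, config,
                      .mo = mo_all[i], .dom = dom_all[i])
    if (config$record_monthly) {
      mon_lat[, mo_idx[i]] <- mon_lat[, mo_idx[i]] +
        (state$ledger_lat - prev_lat)
      mon_vert[, mo_idx[i]] <- mon_vert[, mo_idx[i]] +
        (state$ledger_vert - prev_vert)
      prev_lat <- state$ledger_lat
      prev_vert <- state$ledger_vert
    }
    if (i %% rep_every == 0 || i == n_days) {
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        date = dates[i],
        mean_stock = mean(state_stocks(state)),
        mean_lat = mean(state$ledger_lat),
        mean_vert = mean(state$ledger_vert))
    }
  }
  monthly <- if (config$record_monthly) {
    ym <- strsplit(mo_levels, "-")
    list(year = as.integer(vapply(ym, `[`, "", 1)),
         month = as.integer(vapply(ym, `[`, "", 2)),
         lateral = mon_lat * 1000,     # kg C/m2 -> g C/m2 per month
         vertical = mon_vert * 1000)
  } else NULL
  finish_run(state, monthly, do.call(rbind, rep_rows), config)
}

finish_run <- function(state, monthly, series, config) {
  stocks <- state_stocks(state)
  structure(list(
    state = state,
    stock_change = stocks - state$init_stock,
    ledger_lat = state$ledger_lat,
    ledger_vert = state$ledger_vert,
    monthly = monthly,
    series = series,
    totals = list(litter = state$litter_total,
                  efflux = state$efflux_total,
                  soc_export = state$soc_export,
                  sed_export = state$sed_export,
                  pool_deficit = state$pool_deficit,
                  thickness_deficit = state$thickness_deficit),
    config = config
  ), class = "coevolution_run")
}
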