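# Synthetic watershed inputs: terrain, daily weather, NDVI-driven litter.
# These generators stand in for the restricted LiDAR terrain, station
# weather record, and satellite NDVI of the study catchments, reproducing
# the statistical structure the analysis assumes rather than the real maps.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Smooth (cosine-kernel) blur of a matrix, reflecting at the edges; used to
# correlate the random gully-incision noise over a few cells.
smooth_field <- function(m, passes = 2) {
  for (p in seq_len(passes)) {
    pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    m <- (pad[1:nrow(m), ] + 2 * pad[2:(nrow(m) + 1), ] +
            pad[3:(nrow(m) + 2), ]) / 4
    pad <- cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
    m <- (pad[, 1:ncol(m)] + 2 * pad[, 2:(ncol(m) + 1)] +
            pad[, 3:(ncol(m) + 2)]) / 4
  }
  m
}

#' Generate a synthetic gullied or consolidated-gully terrain
#'
#' `kind = "natural"` carves a main valley along a sine-bend channel into an
#' inclined surface and superimposes correlated side-gully incision noise.
#' `kind = "consolidated"` keeps the same hillslopes but replaces the valley
#' floor with a staircase of near-flat farmland parcels separated by step
#' risers, the topographic expression of check dams. All randomness flows
#' from `seed`; identical arguments give bit-identical grids.
#'
#' @param domain A [grid_domain()]; the outlet is forced to the southern edge
#'   at the channel mouth.
#' @param kind `"natural"` or `"consolidated"`.
#' @param relief Total relief in metres (>= 0); 0 gives a uniform grid.
#' @param seed Integer seed.
#' @param n_parcels Number of flat parcels for the consolidated kind.
#' @return An `elevation_grid`: list with `elev` and `landcover` matrices
#'   (landcover `"natural"` or `"crop"`), `parcel` integer matrix (0 outside
#'   parcels), `soil_thickness` matrix (m, initially 1), `domain`, `kind`.
#' @export
generate_dem <- function(domain, kind = c("natural", "consolidated"),
                         relief = 25, seed = 1, n_parcels = 6) {
  kind <- match.arg(kind)
  if (!is.numeric(relief) || relief < 0) {
    stop("relief must be >= 0", call. = FALSE)
  }
  nr <- domain$n_rows; nc <- domain$n_cols
  with_seed(seed, {
    t_up <- (seq_len(nr) - 1) / (nr - 1)       # 0 at outlet edge, 1 upstream
    ch_col <- (nc + 1) / 2 +
      0.18 * nc * sin(2 * pi * 1.5 * t_up)     # sine-bend channel path
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    dist_ch <- abs(cols - matrix(ch_col, nr, nc)) / (nc / 2)
    base <- matrix(relief * 0.35 * t_up, nr, nc)        # downstream gradient
    hill <- relief * 0.65 * pmin(dist_ch, 1)^1.4        # valley cross-section
    noise <- smooth_field(matrix(rnorm(nr * nc), nr, nc), passes = 3)
    elev <- base + hill + relief * 0.06 * noise
    # keep the channel mouth the lowest point so the outlet is unambiguous
    outlet_col <- max(1L, min(nc, as.integer(round(ch_col[1]))))
    domain$outlet <- c(1L, outlet_col)
    elev[1, outlet_col] <- min(elev) - 0.01 * max(relief, 1e-12)
    landcover <- matrix("natural", nr, nc)
    parcel <- matrix(0L, nr, nc)
    if (kind == "consolidated" && relief > 0) {
      half_w <- pmax(2, (0.16 - 0.06 * t_up) * nc)      # valley-floor width
      in_valley <- abs(cols - matrix(ch_col, nr, nc)) <=
        matrix(half_w, nr, nc)
      breaks <- round(seq(1, nr * 0.92, length.out = n_parcels + 1))
      floor_lvl <- relief * 0.35 * t_up[breaks[-length(breaks)]] +
        relief * 0.02
      for (p in seq_len(n_parcels)) {
        rows_p <- breaks[p]:(breaks[p + 1] - 1)
        mask <- in_valley & (matrix(seq_len(nr), nr, nc) %in% rows_p)
        elev[mask] <- floor_lvl[p]                      # exactly flat parcel
        parcel[mask] <- p
        landcover[mask] <- "crop"
      }
      # the outlet drain sits just below the lowest parcel and is not
      # itself farmland
      elev[1, outlet_col] <- min(floor_lvl) - 0.01 * relief
      parcel[1, outlet_col] <- 0L
      landcover[1, outlet_col] <- "natural"
    }
    if (relief == 0) elev[] <- 0
    structure(list(elev = elev, landcover = landcover, parcel = parcel,
                   soil_thickness = matrix(1, nr, nc), domain = domain,
                   kind = kind, relief = relief),
              class = "elevation_grid")
  })
}

#' Monthly precipitation statistics emulating the An'sai station record
#'
#' A synthetic calibration table (the real 2008--2017 record is not
#' redistributable) constructed so that the implied mean annual precipitation
#' is 560 mm with the July--September monsoon maximum characteristic of the
#' Loess Plateau. Columns: month, mean precipitation (mm), wet-day
#' probability, gamma shape and scale (mm) of wet-day amounts, and wet-after-
#' wet persistence of the occurrence chain.
#'
#' @return A 12-row data frame.
#' @export
ansai_weather_stats <- function() {
  mean_mm <- c(3.2, 5.4, 16.2, 27.0, 43.2, 59.5, 129.7, 124.3, 86.5, 48.6,
               13.0, 3.4)
  p_wet <- c(0.04, 0.07, 0.13, 0.17, 0.23, 0.27, 0.35, 0.35, 0.30, 0.19,
             0.10, 0.04)
  days <- c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  shape <- rep(0.85, 12)
  data.frame(
    month = 1:12,
    mean_mm = mean_mm,
    p_wet = p_wet,
    shape = shape,
    scale = mean_mm / (days * p_wet * shape),
    p_wet_wet = pmin(0.8, p_wet + 0.35)
  )
}

#' Build stochastic weather-generator parameters
#'
#' A two-state Markov occurrence chain (dry/wet) with monthly transition
#' probabilities and gamma-distributed wet-day amounts. The default
#' statistics come from [ansai_weather_stats()].
#'
#' @param stats Data frame like [ansai_weather_stats()].
#' @param seed Integer seed carried with the parameters.
#' @return A `weather_params` object.
#' @export
weather_params <- function(stats = ansai_weather_stats(), seed = 1) {
  if (any(stats$p_wet < 0 | stats$p_wet > 1)) {
    stop("wet-day probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(stats$p_wet > 0 & (stats$shape <= 0 | stats$scale <= 0))) {
    stop("gamma shape and scale must be > 0 for wet months", call. = FALSE)
  }
  monsoon <- mean(stats$mean_mm[7:9]) >= max(stats$mean_mm[-(7:9)])
  if (!monsoon && any(stats$mean_mm > 0)) {
    warning("July-September do not hold the annual precipitation maximum")
  }
  p <- stats$p_wet
  p11 <- pmin(stats$p_wet_wet, 0.999)
  p01 <- ifelse(p >= 1, 1, pmin(1, p * (1 - p11) / (1 - p)))
  structure(list(stats = stats, p01 = p01, p11 = p11, seed = seed),
            class = "weather_params")
}

#' Generate a daily precipitation series
#'
#' Simulates the Markov-chain/gamma weather generator over whole calendar
#' years starting 1 January of `start_year`.
#'
#' @param params A [weather_params()] object.
#' @param n_years Number of years (>= 1).
#' @param start_year First calendar year.
#' @return A `daily_forcing` data frame (`date`, `precip_mm`).
#' @export
generate_weather <- function(params, n_years, start_year = 2001) {
  if (!inherits(params, "weather_params")) {
    stop("params must come from weather_params()", call. = FALSE)
  }
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1)),
               by = "day")
  mo <- as.integer(format(dates, "%m"))
  n <- length(dates)
  with_seed(params$seed, {
    wet <- logical(n)
    # start the chain from the stationary wet probability of month 1
    wet[1] <- runif(1) < params$stats$p_wet[mo[1]]
    u <- runif(n)
    for (i in 2:n) {
      pr <- if (wet[i - 1]) params$p11[mo[i]] else params$p01[mo[i]]
      wet[i] <- u[i] < pr
    }
    precip <- numeric(n)
    idx <- which(wet & params$stats$p_wet[mo] > 0)
    if (length(idx)) {
      precip[idx] <- rgamma(length(idx),
                            shape = params$stats$shape[mo[idx]],
                            scale = params$stats$scale[mo[idx]])
    }
    structure(data.frame(date = dates, precip_mm = precip),
              class = c("daily_forcing", "data.frame"))
  })
}

# 365-day phase of a date, so the deterministic seasonal curves are exactly
# periodic with period 365 days.
date_phase <- function(dates) {
  as.numeric(as.Date(dates) - as.Date("2001-01-01")) %% 365
}

#' Deterministic seasonal NDVI curve per landcover class
#'
#' Smooth growing-season (May--September) curves: the cornfield of the
#' consolidated gully peaks higher than the surrounding natural cover, and
#' both are near-dormant in winter. Exactly periodic with period 365 days.
#'
#' @param kind `"natural"` or `"cornfield"`.
#' @param dates Date vector spanning at least one day.
#' @return Numeric NDVI values in `[0, 1]`.
#' @export
generate_ndvi <- function(kind = c("natural", "cornfield"), dates) {
  kind <- match.arg(kind)
  if (length(dates) == 0) stop("empty date sequence", call. = FALSE)
  doy <- date_phase(dates)
  if (kind == "natural") {
    base <- 0.14; amp <- 0.48; peak <- 200; width <- 62
  } else {
    base <- 0.10; amp <- 0.74; peak <- 205; width <- 48
  }
  pmin(1, pmax(0, base + amp * exp(-((doy - peak) / width)^2)))
}

#' Define an NDVI-to-litter-input curve
#'
#' Litter input is an exponentially increasing (hence convex) function of
#' NDVI: `rate = baseline * exp(coefficient * ndvi / ref_scale)` in
#' kg C/m2/day. Late in the growing season NDVI saturates while litterfall
#' accelerates, which the exponential captures.
#'
#' @param baseline Rate at NDVI = 0 (kg C/m2/day, > 0).
#' @param coefficient Dimensionless exponent coefficient (> 0).
#' @param ref_scale NDVI reference scale (default 1).
#' @return An `ndvi_litter_curve` object.
#' @export
ndvi_litter_curve <- function(baseline, coefficient, ref_scale = 1) {
  if (baseline <= 0 || coefficient <= 0 || ref_scale <= 0) {
    stop("baseline, coefficient and ref_scale must be > 0", call. = FALSE)
  }
  structure(list(baseline = baseline, coefficient = coefficient,
                 ref_scale = ref_scale), class = "ndvi_litter_curve")
}

#' Default litter curves per landcover class
#'
#' Coefficients chosen once so that, with the default turnover parameters,
#' the annual mean litter input sustains a surface SOC steady state near the
#' observed ~4.0 kg C/m3 at the current (12.9-year) surface residence time
#' (see the methods vignette for the calibration argument).
#'
#' @param kind `"crop"` (cornfield) or `"natural"`.
#' @return An [ndvi_litter_curve()].
#' @export
default_litter_curve <- function(kind = c("crop", "natural")) {
  kind <- match.arg(kind)
  if (kind == "crop") {
    ndvi_litter_curve(baseline = 5.23e-05, coefficient = 3.0)
  } else {
    ndvi_litter_curve(baseline = 4.62e-05, coefficient = 3.0)
  }
}

#' Convert NDVI to a litter input rate
#'
#' @param ndvi NDVI value(s) in `[0, 1]`.
#' @param curve An [ndvi_litter_curve()].
#' @return Litter input rate(s), kg C/m2/day; at least `baseline` and
#'   strictly increasing in NDVI.
#' @export
ndvi_to_litter <- function(ndvi, curve) {
  if (any(ndvi < 0 | ndvi > 1)) {
    stop("ndvi must lie in [0, 1]", call. = FALSE)
  }
  curve$baseline * exp(curve$coefficient * ndvi / curve$ref_scale)
}

#' Generate a synthetic surface SOC survey
#'
#' Emulates the field survey design: one sample per regular sampling block
#' (denser along the consolidated gully). Sampled values are the class-wise
#' surface contents consistent with the turnover model's current steady
#' state (~4.0 kg C/m3, i.e. ~3.08 g C/kg at 1300 kg/m3 bulk density) plus
#' a smooth spatial trend and measurement noise, truncated above the deep
#' content so the exponential profile amplitude stays positive.
#'
#' @param dem An `elevation_grid` from [generate_dem()].
#' @param spacing_cells Sampling-block edge in cells (default 8, i.e. 16 m
#'   at 2 m cells).
#' @param seed Integer seed.
#' @param mean_g_kg Class means, named `natural` and `crop` (g C/kg).
#' @param sd_g_kg Measurement/microsite noise (g C/kg).
#' @return Data frame `x`, `y`, `concentration` (g C/kg).
#' @export
generate_surface_samples <- function(dem, spacing_cells = 8, seed = 1,
                                     mean_g_kg = c(natural = 3.08,
                                                   crop = 3.08),
                                     sd_g_kg = 0.15) {
  domain <- dem$domain
  dx <- domain$cell_size
  with_seed(seed, {
    rows <- seq(ceiling(spacing_cells / 2), domain$n_rows, by = spacing_cells)
    cols <- seq(ceiling(spacing_cells / 2), domain$n_cols, by = spacing_cells)
    pts <- expand.grid(row = rows, col = cols)
    # densify along the gully parcels (narrow features)
    if (any(dem$parcel > 0)) {
      pr <- which(dem$parcel > 0, arr.ind = TRUE)
      sub <- pr[seq(1, nrow(pr), by = max(1, spacing_cells^2 %/% 2)), ,
                drop = FALSE]
      pts <- rbind(pts, data.frame(row = sub[, 1], col = sub[, 2]))
    }
    lc <- dem$landcover[cbind(pts$row, pts$col)]
    base <- mean_g_kg[ifelse(lc == "crop", "crop", "natural")]
    x <- (pts$col - 0.5) * dx
    y <- (pts$row - 0.5) * dx
    trend <- 0.25 * sin(x / (domain$n_cols * dx / 3)) *
      cos(y / (domain$n_rows * dx / 3))
    conc <- base + trend + rnorm(nrow(pts), sd = sd_g_kg)
    floor_c <- ifelse(lc == "crop", 2.27, 2.55) + 0.2
    data.frame(x = x, y = y, concentration = pmax(conc, floor_c))
  })
}

#' Assemble a ready-to-run synthetic watershed
#'
#' Convenience wrapper chaining [generate_dem()],
#' [generate_surface_samples()], [interpolate_surface()],
#' [build_initial_columns()] (class-wise profile shape constants),
#' [spinup_columns()] and [simulation_state()].
#'
#' @param kind `"natural"` or `"consolidated"`.
#' @param n_rows,n_cols Grid size.
#' @param seed Integer seed (drives terrain and survey noise).
#' @param relief Relief (m).
#' @param cell_size Cell size (m).
#' @param xparams A [transform_params()] used for the steady-state
#'   partition.
#' @param interp_method Passed to [interpolate_surface()].
#' @return A [simulation_state()] ready for [run_coevolution()].
#' @export
build_watershed <- function(kind = c("natural", "consolidated"),
                            n_rows = 32, n_cols = 32, seed = 1,
                            relief = 25, cell_size = 2,
                            xparams = transform_params(),
                            interp_method = "idw") {
  kind <- match.arg(kind)
  dom <- grid_domain(n_rows, n_cols, cell_size)
  dem <- generate_dem(dom, kind, relief = relief, seed = seed)
  pts <- generate_surface_samples(dem, seed = seed + 1)
  surf <- interpolate_surface(pts, dem$domain, method = interp_method)
  # class-wise profile shape: crops in the parcels, trees/shrubs elsewhere
  crop <- dem$landcover == "crop"
  pc <- reference_profile("crop"); pn <- reference_profile("natural")
  cols_c <- build_initial_columns(pmax(surf, pc$c + 0.05), b = pc$b,
                                  c = pc$c)
  cols_n <- build_initial_columns(pmax(surf, pn$c + 0.05), b = pn$b,
                                  c = pn$c)
  cols <- cols_n
  for (f in c("C_l", "C_h", "C_b")) cols[[f]][crop, ] <- cols_c[[f]][crop, ]
  cols$c_vol[crop] <- cols_c$c_vol[crop]
  cols <- spinup_columns(cols, as.character(dem$landcover), xparams)
  simulation_state(dem, cols)
}

#' Monthly reference evapotranspiration demand (mm/day)
#'
#' Fixed monthly climatology representative of the semi-arid Loess Plateau,
#' used as the atmospheric moisture demand of the daily bucket water balance.
#'
#' @return Numeric vector of length 12.
#' @export
monthly_et_demand <- function() {
  c(0.5, 0.8, 1.8, 3.0, 4.2, 4.8, 4.6, 4.0, 2.8, 1.8, 0.9, 0.5)
}
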