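# Post-processing of run outputs: sink/source zoning, stock-change
# statistics and PDFs, monthly climatologies, management-scenario sweeps,
# and linear areal upscaling.

ZONE_LEVELS <- c("ultimate_sink", "deposition_dominated",
                 "accumulation_dominated", "ultimate_source",
                 "erosion_dominated", "decomposition_dominated")

#' Classify a cell by its lateral and vertical SOC fluxes
#'
#' `x` is the lateral (transport) flux, positive for net deposition; `y` is
#' the vertical (transformation) flux, positive for net uptake from the
#' atmosphere. Both positive: ultimate sink; both negative: ultimate
#' source; opposite signs: the larger-magnitude process dominates
#' (deposition/erosion if `|x| > |y|`, accumulation/decomposition
#' otherwise). The CO2 tag is `sink` when `y > 0`. Boundary ties: `x = 0`
#' resolves to the transformation-dominated class, `y = 0` with `x != 0`
#' to the transport-dominated class, and the origin to `"neutral"`.
#'
#' @param x,y Finite flux values (same units), vectorized.
#' @return Data frame with `zone` (factor over the six classes, plus the
#'   internal `"neutral"`), `co2` (`"sink"`/`"source"`), `gain` (logical,
#'   `x + y > 0`).
#' @export
classify_zone <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("fluxes must be finite", call. = FALSE)
  }
  zone <- character(length(x))
  zone[x > 0 & y > 0] <- "ultimate_sink"
  zone[x < 0 & y < 0] <- "ultimate_source"
  opp <- !(x > 0 & y > 0) & !(x < 0 & y < 0) & !(x == 0 & y == 0)
  dom_t <- opp & abs(x) > abs(y)
  zone[dom_t & x > 0] <- "deposition_dominated"
  zone[dom_t & x < 0] <- "erosion_dominated"
  dom_f <- opp & abs(x) <= abs(y)
  zone[dom_f & y > 0] <- "accumulation_dominated"
  zone[dom_f & y < 0] <- "decomposition_dominated"
  # y == 0 with |x| <= |y| means x == y == 0
  zone[x == 0 & y == 0] <- "neutral"
  data.frame(zone = factor(zone, levels = c(ZONE_LEVELS, "neutral")),
             co2 = ifelse(y > 0, "sink", "source"),
             gain = (x + y) > 0)
}

#' Area percentages of the six sink/source zones
#'
#' @param x,y Per-cell lateral and vertical fluxes.
#' @return List: `percent` (named vector over the six zones, summing to
#'   100 excluding any neutral cells), `sink_percent` and `source_percent`
#'   (the `x + y > 0` / `< 0` bands).
#' @export
zone_fractions <- function(x, y) {
  if (length(x) == 0) stop("empty grid", call. = FALSE)
  cls <- classify_zone(x, y)
  counted <- cls$zone != "neutral"
  n <- sum(counted)
  if (n == 0) stop("all cells neutral; no zones to tabulate", call. = FALSE)
  tab <- table(factor(cls$zone[counted], levels = ZONE_LEVELS))
  pct <- stats::setNames(100 * as.numeric(tab) / n, ZONE_LEVELS)
  list(percent = pct,
       sink_percent = 100 * sum((x + y) > 0) / length(x),
       source_percent = 100 * sum((x + y) < 0) / length(x))
}

#' Spatial statistics and PDFs of a stock-change decomposition
#'
#' The total change at every cell is the sum of the lateral and vertical
#' ledger entries, so the spatial means decompose exactly:
#' `mean(total) = mean(lateral) + mean(vertical)`.
#'
#' @param total Per-cell total stock change (kg C/m2); defaults to
#'   `lateral + vertical`.
#' @param lateral,vertical Per-cell ledger entries (kg C/m2).
#' @param breaks Histogram rule or break vector (default
#'   Freedman-Diaconis).
#' @return List of per-component `mean`s and `pdf`s (each a `density`-style
#'   list with `mids`, `density`, `counts`; the density integrates to 1).
#' @export
stock_change_stats <- function(lateral, vertical, total = NULL,
                               breaks = "FD") {
  if (is.null(total)) total <- lateral + vertical
  stopifnot(length(total) == length(lateral),
            length(lateral) == length(vertical))
  comp <- list(total = total, lateral = lateral, vertical = vertical)
  out <- lapply(comp, function(v) {
    h <- if (length(unique(v)) == 1) {
      list(mids = unique(v), density = Inf, counts = length(v))
    } else {
      hh <- graphics::hist(v, breaks = breaks, plot = FALSE)
      list(mids = hh$mids, density = hh$density, counts = hh$counts)
    }
    list(mean = mean(v), pdf = h)
  })
  out$identity_residual <- max(abs(total - (lateral + vertical)))
  out
}

#' Monthly climatology of flux series
#'
#' Means and standard deviations across same-calendar-month samples of the
#' transformation (vertical), transport (lateral) and total flux.
#'
#' @param monthly The `monthly` element of a `coevolution_run` (per-cell
#'   monthly fluxes, g C/m2/month), or a data frame with columns `month`,
#'   `lateral`, `vertical` (one row per year-month).
#' @param cells Optional cell subset over which spatial means are taken.
#' @return A 12-row data frame: per-month mean and sd of transformation,
#'   transport and total flux (g C/m2/month); total mean equals the sum of
#'   the component means.
#' @export
monthly_climatology <- function(monthly, cells = NULL) {
  if (is.list(monthly) && !is.data.frame(monthly)) {
    sel <- if (is.null(cells)) seq_len(nrow(monthly$lateral)) else cells
    df <- data.frame(
      month = monthly$month,
      lateral = colMeans(monthly$lateral[sel, , drop = FALSE]),
      vertical = colMeans(monthly$vertical[sel, , drop = FALSE]))
  } else df <- monthly
  if (max(table(df$month)) < 2) {
    stop("need >= 2 years to compute monthly standard deviations",
         call. = FALSE)
  }
  agg <- function(v, f) tapply(v, factor(df$month, levels = 1:12), f)
  data.frame(
    month = 1:12,
    transform_mean = as.numeric(agg(df$vertical, mean)),
    transform_sd = as.numeric(agg(df$vertical, sd)),
    transport_mean = as.numeric(agg(df$lateral, mean)),
    transport_sd = as.numeric(agg(df$lateral, sd)),
    total_mean = as.numeric(agg(df$vertical + df$lateral, mean)),
    total_sd = as.numeric(agg(df$vertical + df$lateral, sd))
  )
}

#' Sweep management scenarios over litter input and residence time
#'
#' Runs the coupled model once per (litter multiplier, target residence
#' time) pair on the supplied initial state and summarizes the spatial
#' distribution of the resulting stock change over the gully (cropland)
#' cells as box-plot statistics (median, quartiles, 1.5 IQR whiskers).
#' Failed member runs are reported and the sweep continues.
#'
#' @param make_state A zero-argument function returning a fresh
#'   [simulation_state()] (each scenario starts from the same initial
#'   condition).
#' @param base_config A [run_config()]; its scenario slot is replaced per
#'   member.
#' @param litter_multipliers,mrt_years The scenario grid (defaults: the
#'   3 x 6 management grid, 0.5/1/2 x 10..24.4 yr).
#' @param tparams,xparams,litter_curves Passed to [run_coevolution()].
#' @param cells Cell subset summarized (default: cropland parcel cells).
#' @return A data frame with one row per scenario: `litter`, `mrt_years`,
#'   `q1`, `median`, `q3`, `lower_whisker`, `upper_whisker`, `mean`, `n`,
#'   `error` (NA on success).
#' @export
scenario_sweep <- function(make_state, base_config,
                           litter_multipliers = c(0.5, 1, 2),
                           mrt_years = c(10, 12.9, 15.8, 18.7, 21.6, 24.4),
                           tparams = transport_params(),
                           xparams = transform_params(),
                           litter_curves = list(
                             natural = default_litter_curve("natural"),
                             crop = default_litter_curve("crop")),
                           cells = NULL) {
  grid <- expand.grid(litter = litter_multipliers, mrt = mrt_years)
  if (nrow(grid) == 0) stop("empty scenario grid", call. = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$scenario <- scenario_spec(grid$litter[i], grid$mrt[i])
    res <- tryCatch({
      st <- make_state()
      sel <- if (is.null(cells)) which(st$parcel > 0) else cells
      if (length(sel) == 0) sel <- seq_len(n_cells(st$domain))
      run <- run_coevolution(st, cfg, tparams, xparams, litter_curves)
      v <- run$stock_change[sel]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      data.frame(litter = grid$litter[i], mrt_years = grid$mrt[i],
                 q1 = q[1], median = q[2], q3 = q[3],
                 lower_whisker = max(min(v), q[1] - 1.5 * iqr),
                 upper_whisker = min(max(v), q[3] + 1.5 * iqr),
                 mean = mean(v), n = length(v), error = NA_character_)
    }, error = function(e) {
      data.frame(litter = grid$litter[i], mrt_years = grid$mrt[i],
                 q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                 lower_whisker = NA_real_, upper_whisker = NA_real_,
                 mean = NA_real_, n = 0L, error = conditionMessage(e))
    })
    rows[[i]] <- res
  }
  do.call(rbind, rows)
}

#' Linearly upscale a per-area carbon rate to a region
#'
#' `rate` in g C/m2/yr times `area` in km2 gives Mg C/yr per km2-aggregate;
#' divided by 1000, Gg C/yr: `Gg = rate * area / 1000`.
#'
#' @param rate_g_m2_yr Per-area rate (g C/m2/yr).
#' @param area_km2 Region area (km2, >= 0).
#' @return Upscaled rate in Gg C/yr; linear in both arguments.
#' @export
upscale_rate <- function(rate_g_m2_yr, area_km2) {
  if (any(area_km2 < 0)) stop("area must be >= 0", call. = FALSE)
  rate_g_m2_yr * area_km2 / 1000
}
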