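# Vertical SOC biogeochemistry: three-pool turnover (litter, humus,
# microbial biomass), bioturbation as depth-dependent diffusion, tillage
# mixing, and residence-time scenario machinery.

#' Biogeochemical transformation parameters
#'
#' The total-pool balance is
#' `d(C_l + C_h + C_b)/dt = I_litter - r_r (K_l C_l + K_h C_h)` with
#' decomposition rates `K_l = phi f_d k_l C_b` and `K_h = phi f_d k_h C_b`.
#' Internal transfers conserve mass: litter decomposition sends the fraction
#' `r_r` to CO2, `r_h` to humus and the remainder to microbial biomass;
#' humus decomposition sends `r_r` to CO2 and the remainder to biomass;
#' biomass mortality returns carbon to humus. Mortality is
#' density-dependent (rate `mortality * C_b / c_b_ref`, i.e. a quadratic
#' loss term): linear microbial models make every equilibrium
#' concentration independent of litter input because the biomass — and
#' with it every decomposition rate — scales proportionally with input;
#' the quadratic closure stabilizes the biomass pool so that standing
#' stocks grow with litter input, as observed.
#'
#' @param k_l,k_h Decomposition rate coefficients, m3/(kg C day). The
#'   defaults, together with `c_b_ref` and `f_d_ref`, put the surface humus
#'   mean residence time at ~12.9 years (the estimated current condition).
#' @param r_r Respired (CO2) fraction, within `[0, 1 - r_h]`; typically
#'   0.6--0.8.
#' @param r_h Humified fraction of decomposed litter.
#' @param phi Carbon-nitrogen reduction ratio; ~1 in fertilized cropland.
#' @param mortality Microbial biomass mortality rate at the reference
#'   biomass `c_b_ref` (1/day); the realized rate is
#'   `mortality * C_b / c_b_ref`.
#' @param D0_bioturb Surface bioturbation diffusivity (m2/day; default
#'   1e-4 m2/yr).
#' @param z_bioturb E-folding depth of the bioturbation profile (m).
#' @param surface_fraction Fraction of litter input delivered to the
#'   surface layer (above-ground litterfall); the remainder is root-derived
#'   and distributed exponentially over the top `root_depth`.
#' @param root_depth,root_efold Root-litter distribution depth and
#'   e-folding (m).
#' @param c_b_ref,f_d_ref Reference microbial biomass (kg C/m3) and
#'   moisture factor used to define mean residence times.
#' @param f_memory_days E-folding memory (days) of the antecedent-moisture
#'   average the decomposition factor responds to; microbial activity
#'   integrates moisture over weeks rather than tracking daily spikes.
#' @param inert_efold Depth scale (m) over which the profile's deep
#'   asymptotic carbon becomes inert: decomposition acts on the humus
#'   excess above `c * (1 - exp(-z / inert_efold))`, expressing the
#'   growing mineral-associated (stable) fraction with depth. With the
#'   default 0.1 m the observed exponential depth profile is close to a
#'   steady state of the turnover model.
#' @param kh_surface_multiplier Scenario multiplier on `k_h` in layers whose
#'   midpoint lies within the top 5 cm (set by
#'   [calibrate_residence_time()]).
#' @return A `transform_params` object.
#' @export
transform_params <- function(k_l = 0.25, k_h = 1.384e-2, r_r = 0.7,
                             r_h = 0.2, phi = 1, mortality = 0.0085,
                             D0_bioturb = 1e-4 / 365, z_bioturb = 0.3,
                             surface_fraction = 0.6, root_depth = 0.3,
                             root_efold = 0.1, c_b_ref = 0.0685,
                             f_d_ref = 0.32, f_memory_days = 21,
                             inert_efold = 0.10,
                             kh_surface_multiplier = 1) {
  if (r_h < 0 || r_h > 1) stop("r_h must lie in [0, 1]", call. = FALSE)
  if (r_r < 0 || r_r > 1 - r_h) {
    stop("configuration error: need 0 <= r_r <= 1 - r_h", call. = FALSE)
  }
  if (any(c(k_l, k_h, mortality, D0_bioturb, z_bioturb) < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  structure(list(k_l = k_l, k_h = k_h, r_r = r_r, r_h = r_h, phi = phi,
                 mortality = mortality, D0_bioturb = D0_bioturb,
                 z_bioturb = z_bioturb,
                 surface_fraction = surface_fraction,
                 root_depth = root_depth, root_efold = root_efold,
                 c_b_ref = c_b_ref, f_d_ref = f_d_ref,
                 f_memory_days = f_memory_days,
                 inert_efold = inert_efold,
                 kh_surface_multiplier = kh_surface_multiplier),
            class = "transform_params")
}

#' Moisture- and nitrogen-regulated decomposition rates
#'
#' `K_l = phi * f_d * k_l * C_b` and `K_h = phi * f_d * k_h * C_b` (1/day):
#' decomposition requires microbial biomass and slows when the soil is too
#' dry or too wet or nitrogen limits microbial demand.
#'
#' @param C_b Microbial biomass concentration (kg C/m3, >= 0).
#' @param f_d Moisture factor in `[0, 1]`.
#' @param phi C/N reduction ratio in `[0, 1]`.
#' @param k_l,k_h Rate coefficients (m3/(kg C day)).
#' @return List with `K_l` and `K_h` (1/day).
#' @export
decomposition_rates <- function(C_b, f_d, phi, k_l, k_h) {
  if (any(C_b < 0)) stop("C_b must be >= 0", call. = FALSE)
  if (any(f_d < 0 | f_d > 1) || any(phi < 0 | phi > 1)) {
    stop("f_d and phi must lie in [0, 1]", call. = FALSE)
  }
  list(K_l = phi * f_d * k_l * C_b, K_h = phi * f_d * k_h * C_b)
}

#' Advance the three pools of one layer by one step
#'
#' Explicit integration (with automatic sub-stepping when rates are stiff
#' relative to `dt`) of the pool system; the total obeys the balance
#' `d(total)/dt = I_litter - r_r (K_l C_l + K_h C_h)` exactly up to
#' round-off, and the CO2 efflux equals the respired share.
#'
#' @param pools List or vector with `C_l`, `C_h`, `C_b` (kg C/m3; each may
#'   be a vector over cells).
#' @param I_litter Volumetric litter input to this layer (kg C/m3/day).
#' @param params A [transform_params()].
#' @param f_d Moisture factor in `[0, 1]`.
#' @param dt Time step (days).
#' @param kh_multiplier Optional multiplier on `k_h` (surface residence-time
#'   scenarios).
#' @param C_inert Inert (mineral-stabilized) humus concentration excluded
#'   from decomposition (kg C/m3, default 0).
#' @return List: updated `C_l`, `C_h`, `C_b` and `co2_efflux`
#'   (kg C/m3 released over the step).
#' @export
transform_step <- function(pools, I_litter, params, f_d, dt = 1,
                           kh_multiplier = 1, C_inert = 0) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  C_l <- pools$C_l; C_h <- pools$C_h; C_b <- pools$C_b
  r_r <- params$r_r; r_h <- params$r_h; m <- params$mortality
  kh <- params$k_h * kh_multiplier
  cbr <- params$c_b_ref
  # sub-step so first-order losses stay well under the pool size
  rmax <- max(params$phi * f_d * params$k_l * max(C_b, 0),
              params$phi * f_d * kh * max(C_b, 0),
              m * max(C_b, 0) / cbr)
  n_sub <- max(1L, ceiling(rmax * dt / 0.5))
  h <- dt / n_sub
  efflux <- 0
  for (s in seq_len(n_sub)) {
    K <- decomposition_rates(C_b, f_d, params$phi, params$k_l, kh)
    dec_l <- K$K_l * C_l
    dec_h <- K$K_h * pmax(C_h - C_inert, 0)  # stabilized share untouched
    mort <- m * C_b^2 / cbr          # density-dependent mortality
    C_l <- C_l + h * (I_litter - dec_l)
    C_h <- C_h + h * (r_h * dec_l - dec_h + mort)
    C_b <- C_b + h * ((1 - r_r - r_h) * dec_l + (1 - r_r) * dec_h - mort)
    efflux <- efflux + h * r_r * (dec_l + dec_h)
    C_l <- pmax(C_l, 0); C_h <- pmax(C_h, 0); C_b <- pmax(C_b, 0)
  }
  list(C_l = C_l, C_h = C_h, C_b = C_b, co2_efflux = efflux)
}

#' Closed-form steady state of the three-pool system
#'
#' With constant volumetric input `I` and moisture factor, the equilibrium
#' biomass under density-dependent mortality is
#' `C_b* = sqrt(c_b_ref * I (1 - r_r - r_r r_h) / (mortality * r_r))`
#' (equal to `c_b_ref` at the reference input), with
#' `C_h* = (r_h I + mortality C_b*^2 / c_b_ref) / (phi f_d k_h C_b*)` and
#' `C_l* = I / (phi f_d k_l C_b*)`, so standing stocks scale with the
#' square root of litter input; an inert humus share `C_inert` adds as an
#' offset. Used as the analytic limit that long simulations must approach.
#'
#' @param I Volumetric litter input (kg C/m3/day).
#' @param params A [transform_params()].
#' @param f_d Moisture factor.
#' @param kh_multiplier Multiplier on `k_h`.
#' @param C_inert Inert humus concentration (kg C/m3).
#' @return List with `C_l`, `C_h`, `C_b` and `total`.
#' @export
equilibrium_pools <- function(I, params, f_d, kh_multiplier = 1,
                              C_inert = 0) {
  r_r <- params$r_r; r_h <- params$r_h; m <- params$mortality
  kh <- params$k_h * kh_multiplier
  C_b <- sqrt(params$c_b_ref * I * (1 - r_r - r_r * r_h) / (m * r_r))
  # I = 0 has the all-zero equilibrium (decomposition needs biomass)
  C_h <- ifelse(I > 0,
                C_inert + (r_h * I + m * C_b^2 / params$c_b_ref) /
                  (params$phi * f_d * kh * C_b), C_inert)
  C_l <- ifelse(I > 0, I / (params$phi * f_d * params$k_l * C_b), 0)
  list(C_l = C_l, C_h = C_h, C_b = C_b, total = C_l + C_h + C_b)
}

#' Mix the SOC column diffusively by bioturbation
#'
#' Depth-dependent diffusion `D(z) = D0 exp(-z / z_b)` applied to each pool
#' with zero-flux boundaries at the surface and the column base; total
#' column mass is conserved to machine precision and the operator only
#' smooths (sub-steps automatically if the explicit scheme would be
#' unstable).
#'
#' @param column An [soc_column()].
#' @param params A [transform_params()] (supplies `D0_bioturb`,
#'   `z_bioturb`).
#' @param dt Time step (days).
#' @return The mixed `soc_column`.
#' @export
bioturbation_step <- function(column, params, dt = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  z <- column$thickness
  nl <- length(z)
  if (nl < 2) return(column)
  iface_depth <- cumsum(z)[-nl]
  D <- params$D0_bioturb * exp(-iface_depth / params$z_bioturb)
  dz_c <- (z[-nl] + z[-1]) / 2
  lim <- min(pmin(z[-nl], z[-1]) * dz_c)
  n_sub <- max(1L, ceiling(max(D) * dt / (0.4 * lim)))
  h <- dt / n_sub
  for (p in c("C_l", "C_h", "C_b")) {
    C <- column[[p]]
    for (s in seq_len(n_sub)) {
      flux <- -D * (C[-1] - C[-nl]) / dz_c   # downward-positive, kg/m2/day
      dM <- c(-flux, 0) + c(0, flux)
      C <- C + h * dM / z
    }
    column[[p]] <- C
  }
  column
}

# Vectorized bioturbation over a column set (matrices [ncell, nl]).
bioturbation_step_cells <- function(cols, params, dt = 1) {
  z <- cols$thickness
  nl <- ncol(z)
  if (nl < 2) return(cols)
  cum <- z %*% upper.tri(diag(nl), diag = TRUE)  # row-wise cumsum
  iface <- cum[, -nl, drop = FALSE]
  D <- params$D0_bioturb * exp(-iface / params$z_bioturb)
  dz_c <- (z[, -nl, drop = FALSE] + z[, -1, drop = FALSE]) / 2
  lim <- min(pmin(z[, -nl], z[, -1]) * dz_c)
  n_sub <- max(1L, ceiling(max(D) * dt / (0.4 * lim)))
  h <- dt / n_sub
  for (p in c("C_l", "C_h", "C_b")) {
    C <- cols[[p]]
    for (s in seq_len(n_sub)) {
      flux <- -D * (C[, -1, drop = FALSE] - C[, -nl, drop = FALSE]) / dz_c
      C <- C + h * (cbind(-flux, 0) + cbind(0, flux)) / z
    }
    cols[[p]] <- C
  }
  cols
}

#' Tillage: uniformly mix the top of the column
#'
#' Homogenizes each pool's concentration over `[0, depth]` (default the
#' traditional 20 cm plough depth, applied in April before seeding); mass
#' over the mixed depth is conserved exactly and deeper layers are
#' untouched. A layer straddling the mixing plane keeps a volume-weighted
#' blend of the mixed and original concentration.
#'
#' @param column An [soc_column()].
#' @param depth Mixing depth (m), not exceeding the column thickness.
#' @return The mixed `soc_column`.
#' @export
tillage_mix <- function(column, depth = 0.20) {
  z <- column$thickness
  if (depth > sum(z) + 1e-12) {
    stop("tillage depth exceeds the column thickness", call. = FALSE)
  }
  top <- cumsum(c(0, z))[seq_along(z)]
  in_frac <- pmax(0, pmin(depth - top, z)) / z   # fraction of layer mixed
  for (p in c("C_l", "C_h", "C_b")) {
    C <- column[[p]]
    mixed_mass <- sum(C * z * in_frac)
    C_mix <- mixed_mass / depth
    column[[p]] <- in_frac * C_mix + (1 - in_frac) * C
  }
  column
}

# Vectorized tillage over a column set; mask selects the cells tilled.
tillage_mix_cells <- function(cols, depth, mask) {
  z <- cols$thickness
  cum <- z %*% upper.tri(diag(ncol(z)), diag = TRUE)
  top <- cbind(0, cum)[, seq_len(ncol(z)), drop = FALSE]
  in_frac <- pmax(0, pmin(depth - top, z)) / z
  for (p in c("C_l", "C_h", "C_b")) {
    C <- cols[[p]]
    C_mix <- rowSums(C * z * in_frac) / depth
    mixed <- in_frac * C_mix + (1 - in_frac) * C
    C[mask, ] <- mixed[mask, ]
    cols[[p]] <- C
  }
  cols
}

#' Surface humus mean residence time implied by a parameter set
#'
#' Defined as the inverse of the reference-state first-order humus loss
#' rate `r_r * phi * f_d_ref * k_h * C_b_ref` (surface layers only, where
#' scenario multipliers apply).
#'
#' @param params A [transform_params()].
#' @return Mean residence time in years (365-day years).
#' @export
current_residence_time <- function(params) {
  lambda <- params$r_r * params$phi * params$f_d_ref * params$k_h *
    params$kh_surface_multiplier * params$c_b_ref
  1 / lambda / 365
}

#' Calibrate the surface `k_h` multiplier to a target residence time
#'
#' Returns the multiplier on `k_h` (applied only to layers whose midpoint
#' lies within the top 0.05 m) such that the reference-state first-order
#' humus loss rate equals `1 / target_mrt`. Inverse proportionality: a
#' doubled residence time halves the surface decomposition rate.
#'
#' @param target_mrt_years Target mean residence time (years, > 0).
#' @param params A [transform_params()] supplying the reference state.
#' @return The scalar multiplier.
#' @export
calibrate_residence_time <- function(target_mrt_years, params) {
  if (target_mrt_years <= 0) stop("target MRT must be > 0", call. = FALSE)
  lambda_target <- 1 / (target_mrt_years * 365)
  base <- params$r_r * params$phi * params$f_d_ref * params$k_h *
    params$c_b_ref
  lambda_target / base
}

#' Partition initial columns at the turnover steady state
#'
#' Re-partitions each layer's (unchanged) total concentration into pools
#' consistent with the three-pool steady state under the ambient litter
#' input: microbial biomass and fast litter take their closed-form
#' equilibrium values (see [equilibrium_pools()]) and the humus pool takes
#' the remainder. Deep layers receive almost no litter, so their biomass
#' equilibrium is ~0 and the deep carbon is effectively immobile, matching
#' the observed stability of SOC at depth. Starting from this state removes
#' the large spurious respiration pulse a uniform pool split would produce.
#'
#' @param columns A `soc_columns` set from [build_initial_columns()].
#' @param landcover Per-cell class vector (`"natural"`/`"crop"`).
#' @param xparams A [transform_params()].
#' @param litter_curves List with `natural` and `crop`
#'   [ndvi_litter_curve()]s.
#' @param f_d Reference moisture factor (default `xparams$f_d_ref`).
#' @return The re-partitioned `soc_columns`.
#' @export
spinup_columns <- function(columns, landcover,
                           xparams = transform_params(),
                           litter_curves = list(
                             natural = default_litter_curve("natural"),
                             crop = default_litter_curve("crop")),
                           f_d = NULL) {
  if (is.null(f_d)) f_d <- xparams$f_d_ref
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  mean_litter <- c(
    natural = mean(ndvi_to_litter(generate_ndvi("natural", dates),
                                  litter_curves$natural)),
    crop = mean(ndvi_to_litter(generate_ndvi("cornfield", dates),
                               litter_curves$crop)))
  L <- mean_litter[ifelse(landcover == "crop", "crop", "natural")]
  layering <- columns$thickness[1, ]
  w_root <- root_litter_weights(layering, xparams)
  for (k in seq_along(layering)) {
    zk <- columns$thickness[, k]
    I_k <- ((if (k == 1) xparams$surface_fraction else 0) +
              (1 - xparams$surface_fraction) * w_root[k]) * L / zk
    eq <- equilibrium_pools(I_k, xparams, f_d)
    total <- columns$C_l[, k] + columns$C_h[, k] + columns$C_b[, k]
    C_b <- pmin(eq$C_b, 0.2 * total)
    C_l <- pmin(eq$C_l, 0.5 * (total - C_b))
    columns$C_b[, k] <- C_b
    columns$C_l[, k] <- C_l
    columns$C_h[, k] <- total - C_b - C_l
  }
  columns
}

# Root-litter distribution weights over the column layers: exponential over
# the top root_depth, normalized to sum to 1 (returns per-layer fraction).
root_litter_weights <- function(layering, params) {
  top <- cumsum(c(0, layering))[seq_along(layering)]
  bot <- cumsum(layering)
  a <- pmin(top, params$root_depth)
  b <- pmin(bot, params$root_depth)
  w <- exp(-a / params$root_efold) - exp(-b / params$root_efold)
  w <- pmax(w, 0)
  if (sum(w) <= 0) w[1] <- 1
  w / sum(w)
}
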