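# Initial SOC depth profiles: exponential-with-depth concentration curves,
# nonlinear fitting, surface interpolation, and column construction.

#' Exponential-with-depth SOC profile parameters
#'
#' SOC content declines exponentially with depth towards a stable deep
#' value: `SOC(Z) = a * exp(-b * Z) + c`, with `Z` zero at the surface and
#' positive downward. `a + c` is the surface content, `b` the decay rate
#' (1/m) and `c` the immobile deep content.
#'
#' @param a,b,c Positive parameters (g C/kg for `a`, `c`; 1/m for `b`).
#' @return A `profile_params` object.
#' @export
profile_params <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) stop("a, b and c must be > 0", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "profile_params")
}

#' Reference fitted profiles for the two landcover classes
#'
#' The depth-profile constants fitted to deep soil cores: trees/shrubs
#' (natural cover) `8.04 exp(-9.63 Z) + 2.55`; crops (consolidated-gully
#' cornfield) `3.71 exp(-7.06 Z) + 2.27`, in g C/kg with Z in metres.
#'
#' @param kind `"natural"` (trees/shrubs) or `"crop"`.
#' @return A [profile_params()] object.
#' @export
reference_profile <- function(kind = c("natural", "crop")) {
  kind <- match.arg(kind)
  if (kind == "natural") profile_params(8.04, 9.63, 2.55)
  else profile_params(3.71, 7.06, 2.27)
}

#' Evaluate an SOC depth profile
#'
#' @param params A [profile_params()] object.
#' @param depth Depth(s) in metres, >= 0.
#' @return SOC content in g C/kg; lies in `(c, a + c]` and is strictly
#'   decreasing in depth.
#' @export
profile_value <- function(params, depth) {
  if (any(depth < 0)) stop("depth must be >= 0", call. = FALSE)
  params$a * exp(-params$b * depth) + params$c
}

#' Fit an exponential SOC depth profile to sample points
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `concentration ~ a exp(-b depth) + c` with positivity bounds. Requires at
#' least 4 samples at >= 3 distinct depths so the three parameters are
#' identified.
#'
#' @param samples Data frame with columns `depth` (m) and `concentration`
#'   (g C/kg).
#' @return A [profile_params()] with a `fit` attribute (the `nls` object).
#' @export
fit_profile <- function(samples) {
  stopifnot(all(c("depth", "concentration") %in% names(samples)))
  if (nrow(samples) < 4 || length(unique(samples$depth)) < 3) {
    stop("under-determined: need >= 4 samples at >= 3 distinct depths",
         call. = FALSE)
  }
  conc <- samples$concentration
  c0 <- max(min(conc) * 0.9, 1e-6)
  a0 <- max(max(conc) - c0, 1e-6)
  # crude decay-rate start from the half-range depth
  mid <- (max(conc) + min(conc)) / 2
  d_mid <- samples$depth[which.min(abs(conc - mid))]
  b0 <- if (d_mid > 0) log(2) / d_mid else 5
  fit <- tryCatch(
    minpack.lm::nlsLM(
      concentration ~ a * exp(-b * depth) + c,
      data = samples,
      start = list(a = a0, b = b0, c = c0),
      lower = c(a = 1e-9, b = 1e-9, c = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("profile fit failed: ", conditionMessage(e),
           "; residual sum of squares at start = ",
           format(sum((conc - (a0 * exp(-b0 * samples$depth) + c0))^2)),
           call. = FALSE)
    }
  )
  cf <- coef(fit)
  out <- profile_params(max(cf[["a"]], 1e-9), max(cf[["b"]], 1e-9),
                        max(cf[["c"]], 1e-9))
  attr(out, "fit") <- fit
  out
}

#' Back-calculate the surface amplitude `a` from two layer observations
#'
#' Given SOC contents observed at two depths (the 5 cm and 15 cm layer
#' midpoints) and class-wide `b`, `c`, returns the least-squares `a` for
#' the exponential profile evaluated at those two depths. This is the
#' closed-form single-parameter solution
#' `a = sum((obs - c) * e_i) / sum(e_i^2)` with `e_i = exp(-b * z_i)`.
#'
#' @param soc_5cm,soc_15cm Observed contents (g C/kg) at 0.05 m and 0.15 m.
#' @param b Decay rate (1/m).
#' @param c Deep content (g C/kg).
#' @param depths Evaluation depths in metres (default `c(0.05, 0.15)`).
#' @return The scalar `a` (> 0).
#' @export
back_calculate_a <- function(soc_5cm, soc_15cm, b, c,
                             depths = c(0.05, 0.15)) {
  if (any(c(soc_5cm, soc_15cm, b, c) <= 0)) {
    stop("inputs must be > 0", call. = FALSE)
  }
  obs <- c(soc_5cm, soc_15cm)
  if (all(obs <= c)) {
    stop("no signal: both observations at or below the deep content c",
         call. = FALSE)
  }
  e <- exp(-b * depths)
  a <- sum((obs - c) * e) / sum(e^2)
  if (a <= 0) stop("no signal: least-squares a is non-positive",
                   call. = FALSE)
  a
}

#' Interpolate surface SOC point samples over the grid
#'
#' Ordinary kriging with an exponential variogram fitted by weighted least
#' squares to the empirical semivariogram; a singular or degenerate kriging
#' system falls back to deterministic inverse-distance weighting (power 2)
#' with a warning. Both interpolators are exact at the sample locations.
#'
#' @param points Data frame with columns `x`, `y` (m) and `concentration`
#'   (g C/kg, > 0).
#' @param domain A [grid_domain()].
#' @param method `"ordinary_kriging"` or `"idw"`.
#' @param idw_power Inverse-distance power (default 2).
#' @return A `surface_soc_map`: matrix of g C/kg over the domain with the
#'   domain as attribute.
#' @export
interpolate_surface <- function(points, domain,
                                method = c("ordinary_kriging", "idw"),
                                idw_power = 2) {
  method <- match.arg(method)
  if (nrow(points) == 0) stop("no sample points supplied", call. = FALSE)
  stopifnot(all(c("x", "y", "concentration") %in% names(points)))
  grid <- cell_coordinates(domain)
  vals <- if (nrow(points) == 1) {
    rep(points$concentration[1], nrow(grid))
  } else if (method == "idw") {
    idw_predict(points, grid, idw_power)
  } else {
    ok <- tryCatch(kriging_predict(points, grid),
                   error = function(e) NULL)
    if (is.null(ok)) {
      warning("kriging system singular; falling back to IDW")
      idw_predict(points, grid, idw_power)
    } else ok
  }
  m <- as_grid_matrix(vals, domain)
  structure(m, domain = domain, class = c("surface_soc_map", "matrix"))
}

idw_predict <- function(points, grid, power) {
  d2 <- outer(grid$x, points$x, "-")^2 + outer(grid$y, points$y, "-")^2
  d <- sqrt(d2)
  w <- 1 / pmax(d, .Machine$double.eps)^power
  pred <- (w %*% points$concentration) / rowSums(w)
  at <- apply(d, 1, function(r) {
    j <- which(r < 1e-9)
    if (length(j)) j[1] else NA_integer_
  })
  hit <- !is.na(at)
  pred[hit] <- points$concentration[at[hit]]
  as.numeric(pred)
}

# Exponential-variogram ordinary kriging. gamma(h) = nugget +
# psill * (1 - exp(-h / range)); parameters from weighted least squares on
# binned empirical semivariances (weights = pair counts).
kriging_predict <- function(points, grid) {
  n <- nrow(points)
  dx <- outer(points$x, points$x, "-")
  dy <- outer(points$y, points$y, "-")
  h <- sqrt(dx^2 + dy^2)
  g <- 0.5 * outer(points$concentration, points$concentration, "-")^2
  iu <- upper.tri(h)
  hv <- h[iu]; gv <- g[iu]
  if (length(hv) < 3 || max(hv) <= 0) stop("degenerate layout")
  nb <- min(12, max(4, floor(length(hv) / 4)))
  brk <- seq(0, max(hv), length.out = nb + 1)
  bin <- cut(hv, brk, include.lowest = TRUE)
  eh <- tapply(hv, bin, mean)
  eg <- tapply(gv, bin, mean)
  cnt <- tapply(gv, bin, length)
  keep <- !is.na(eg)
  eh <- eh[keep]; eg <- eg[keep]; cnt <- cnt[keep]
  if (length(eh) < 3 || all(eg == 0)) stop("flat variogram")
  s0 <- max(eg); r0 <- max(eh) / 3
  obj <- function(p) {
    nug <- exp(p[1]); ps <- exp(p[2]); rg <- exp(p[3])
    gm <- nug + ps * (1 - exp(-eh / rg))
    sum(cnt * (gm - eg)^2)
  }
  opt <- stats::optim(log(c(s0 * 0.05 + 1e-9, s0, r0)), obj,
                      method = "Nelder-Mead")
  nug <- exp(opt$par[1]); ps <- exp(opt$par[2]); rg <- exp(opt$par[3])
  vgm <- function(hh) nug + ps * (1 - exp(-hh / rg))
  # ordinary kriging system on semivariances with the unbiasedness row
  A <- rbind(cbind(vgm(h), 1), c(rep(1, n), 0))
  diag(A)[1:n] <- 0
  gx <- outer(grid$x, points$x, "-")
  gy <- outer(grid$y, points$y, "-")
  gh <- sqrt(gx^2 + gy^2)
  B <- rbind(t(vgm(gh)), 1)
  lam <- solve(A, B)
  pred <- as.numeric(crossprod(lam[1:n, , drop = FALSE],
                               points$concentration))
  # exactness at (numerically coincident) sample locations
  at <- apply(gh, 1, function(r) {
    j <- which(r < 1e-9)
    if (length(j)) j[1] else NA_integer_
  })
  hit <- !is.na(at)
  pred[hit] <- points$concentration[at[hit]]
  pred
}

#' Default vertical layering of the 1 m active soil column
#'
#' Layer thicknesses between 0.05 and 0.60 m, finest at the surface where
#' SOC gradients and the transport coupling are strongest.
#'
#' @return Numeric vector of layer thicknesses (m) summing to 1.
#' @export
default_layering <- function() c(0.05, 0.05, 0.10, 0.10, 0.15, 0.25, 0.30)

#' Construct a single SOC column
#'
#' @param thickness Layer thicknesses (m), each within `[0.05, 0.60]`.
#' @param C_l,C_h,C_b Per-layer pool concentrations (kg C/m3, >= 0).
#' @param bulk_density Bulk density (kg/m3).
#' @return A `soc_column` object.
#' @export
soc_column <- function(thickness, C_l, C_h, C_b, bulk_density = 1300) {
  nl <- length(thickness)
  stopifnot(length(C_l) == nl, length(C_h) == nl, length(C_b) == nl)
  if (any(thickness < 0.05 - 1e-9 | thickness > 0.60 + 1e-9)) {
    stop("layer thicknesses must lie within [0.05, 0.60] m", call. = FALSE)
  }
  if (any(c(C_l, C_h, C_b) < 0)) {
    stop("pool concentrations must be >= 0", call. = FALSE)
  }
  structure(list(thickness = thickness, C_l = C_l, C_h = C_h, C_b = C_b,
                 bulk_density = bulk_density), class = "soc_column")
}

#' Build initial SOC columns for every grid cell
#'
#' Per-layer total concentration equals the exponential profile evaluated at
#' the layer midpoint (g C/kg converted to kg C/m3 through the bulk
#' density); pools are a fixed partition of the total.
#'
#' @param surface A `surface_soc_map` (g C/kg) from [interpolate_surface()],
#'   or a plain matrix; its values set the surface content `a + c` per cell.
#' @param b,c Class-wide decay rate (1/m) and deep content (g C/kg).
#' @param layering Layer thicknesses (m), default [default_layering()].
#' @param bulk_density kg/m3 (default 1300, typical compacted loess).
#' @param pool_fractions Named or ordered fractions `(f_l, f_h, f_b)`
#'   summing to 1.
#' @return A `soc_columns` object: list of matrices `[cell, layer]`
#'   (`thickness`, `C_l`, `C_h`, `C_b`) plus metadata.
#' @export
build_initial_columns <- function(surface, b, c,
                                  layering = default_layering(),
                                  bulk_density = 1300,
                                  pool_fractions = c(f_l = 0.10, f_h = 0.85,
                                                     f_b = 0.05)) {
  f <- as.numeric(pool_fractions)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9) {
    stop("pool fractions must be >= 0 and sum to 1", call. = FALSE)
  }
  vals <- as.numeric(surface)             # g C/kg at the surface (a + c)
  a <- vals - c
  if (any(a <= 0)) {
    stop("surface contents must exceed the deep content c", call. = FALSE)
  }
  mids <- cumsum(layering) - layering / 2
  ncell <- length(vals)
  nl <- length(layering)
  # g C/kg -> kg C/m3: conc * bulk_density / 1000
  total <- (outer(a, exp(-b * mids)) + c) * bulk_density / 1000
  structure(list(
    thickness = matrix(layering, ncell, nl, byrow = TRUE),
    C_l = total * f[1], C_h = total * f[2], C_b = total * f[3],
    bulk_density = bulk_density, pool_fractions = f,
    b = b, c = c,
    c_vol = rep(c * bulk_density / 1000, ncell)  # stable deep C, kg/m3
  ), class = "soc_columns")
}

#' Integrate a column's areal SOC stock
#'
#' @param column An [soc_column()] (or one cell of a `soc_columns` set).
#' @return Areal stock, kg C/m2: sum of layer thickness times total
#'   concentration.
#' @export
integrate_stock <- function(column) {
  sum(column$thickness * (column$C_l + column$C_h + column$C_b))
}

#' Per-cell areal SOC stocks of a column set
#'
#' @param columns A `soc_columns` object.
#' @return Numeric vector (kg C/m2), one value per cell.
#' @export
integrate_stocks <- function(columns) {
  rowSums(columns$thickness * (columns$C_l + columns$C_h + columns$C_b))
}
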