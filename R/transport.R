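# Lateral SOC transport: surface-layer carbon moves with the sediment
# fluxes through the enrichment ratio k_soc. Divergences are in
# kg C/m2/day (positive = carbon leaving the cell).

#' Divergence of the diffusion-driven SOC flux
#'
#' Conservative face-flux discretization of
#' `div(k_soc C1 q_d)`: each face carries the sediment diffusion flux times
#' the donor-side (higher-elevation) surface concentration, so eroding cells
#' export their own carbon. With uniform `C1` and `k_soc = 1` this reduces
#' exactly to `C1 * diffusion_divergence()`.
#'
#' @param conc Surface-layer concentration matrix (kg C/m3), same shape as
#'   `elev` (one pool; call per pool).
#' @param elev Elevation matrix.
#' @param D_x,D_y Diffusivities (m2/day).
#' @param k_soc Enrichment ratio.
#' @param cell_size Cell size (m).
#' @return Matrix of SOC divergence (kg C/m2/day).
#' @export
soc_diffusive_flux <- function(conc, elev, D_x, D_y, k_soc, cell_size) {
  if (!all(dim(conc) == dim(elev))) {
    stop("concentration and elevation grids differ in shape", call. = FALSE)
  }
  nr <- nrow(elev); nc <- ncol(elev)
  fl <- diffusion_face_fluxes(elev, D_x, D_y, cell_size)
  Cx <- matrix(0, nr, nc + 1)
  if (nc > 1) {
    left <- conc[, 1:(nc - 1)]; right <- conc[, 2:nc]
    # donor side: flux > 0 moves east, donor is the west (left) cell
    Cx[, 2:nc] <- ifelse(fl$Fx[, 2:nc] > 0, left, right)
  }
  Cy <- matrix(0, nr + 1, nc)
  if (nr > 1) {
    south <- conc[1:(nr - 1), ]; north <- conc[2:nr, ]
    Cy[2:nr, ] <- ifelse(fl$Fy[2:nr, ] > 0, south, north)
  }
  Fx <- k_soc * Cx * fl$Fx
  Fy <- k_soc * Cy * fl$Fy
  (Fx[, -1, drop = FALSE] - Fx[, -(nc + 1), drop = FALSE] +
     Fy[-1, , drop = FALSE] - Fy[-(nr + 1), , drop = FALSE]) / cell_size
}

#' Divergence of the overland-flow SOC flux
#'
#' Mirrors the two branches of the sediment law: detachment-limited cells
#' erode local surface carbon at `k_soc * C1 * D_c`; elsewhere the outgoing
#' flux carries the local surface concentration,
#' `(k_soc C1,out q_s,out - sum(k_soc C1,in q_s,in)) / d_s`, and net
#' deposition delivers carbon at the upstream donors' concentrations and
#' pool proportions.
#'
#' @param conc Matrix `[n_cells, n_pools]` of surface-layer pool
#'   concentrations (kg C/m3).
#' @param network A `flow_network`.
#' @param overland Result of [overland_divergence()] (needs the branch
#'   flags).
#' @param k_soc Enrichment ratio.
#' @return List: `divergence` (`[n_cells, n_pools]`, kg C/m2/day),
#'   `outlet_export` (kg C/m/day per pool).
#' @export
soc_advective_flux <- function(conc, network, overland, k_soc) {
  if (is.null(overland$limited)) {
    stop("overland result lacks branch flags", call. = FALSE)
  }
  conc <- as.matrix(conc)
  cpp_soc_overland(network$order, network$receiver, overland$limited,
                   overland$outflux, overland$detachment, conc, k_soc,
                   network$domain$cell_size)
}

#' Update the surface layer of one SOC column after transport
#'
#' Discretizes the surface-layer balance
#' `d(C1 z1)/dt = g1 z1 - div(q_C)`: pool mass changes by
#' `(g1 z1 - div) * dt`, the layer thickness follows the sediment
#' divergence, and erosion deeper than the surface layer consumes sublayers
#' top-down. Pools are floored at zero with the clipped deficit recorded in
#' the `pool_deficit` attribute.
#'
#' @param column An [soc_column()].
#' @param soc_divergence Per-pool divergence `c(l, h, b)` (kg C/m2/day).
#' @param sediment_divergence Scalar sediment divergence (m/day).
#' @param g1 Per-pool transformation rate `c(l, h, b)` (kg C/m3/day),
#'   default zero.
#' @param dt Time step (days, > 0).
#' @return The updated `soc_column` (layer structure re-meshed to the
#'   original nominal thicknesses, bottom layer absorbing the change).
#' @export
update_surface_layer <- function(column, soc_divergence,
                                 sediment_divergence, g1 = c(0, 0, 0),
                                 dt = 1) {
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  cols <- list(thickness = matrix(column$thickness, 1),
               C_l = matrix(column$C_l, 1),
               C_h = matrix(column$C_h, 1),
               C_b = matrix(column$C_b, 1))
  dM <- matrix((g1 * column$thickness[1] - soc_divergence) * dt, 1)
  dz <- -sediment_divergence * dt
  res <- apply_surface_exchange(cols, dM, dz, nominal = column$thickness)
  out <- structure(list(thickness = as.numeric(res$cols$thickness),
                        C_l = as.numeric(res$cols$C_l),
                        C_h = as.numeric(res$cols$C_h),
                        C_b = as.numeric(res$cols$C_b),
                        bulk_density = column$bulk_density),
                   class = "soc_column")
  attr(out, "pool_deficit") <- res$pool_deficit
  attr(out, "thickness_deficit") <- res$thickness_deficit
  out
}

# Vectorized surface-layer exchange + Eulerian re-mesh for a column set.
# cols: list of [ncell, nl] matrices; dM: [ncell, 3] pool mass change
# (kg C/m2) applied to the surface layer; dz: per-cell surface thickness
# change (m). After the exchange every layer above the bottom is remapped
# back to its nominal thickness, material advecting through layer
# interfaces at the donor layer's concentration; the bottom layer absorbs
# the net thickness change (floored at a minimal residual).
apply_surface_exchange <- function(cols, dM, dz,
                                   nominal = default_layering(),
                                   z_floor = 1e-4) {
  nl <- ncol(cols$thickness)
  pools <- c("C_l", "C_h", "C_b")
  z1 <- cols$thickness[, 1]
  new_z1 <- z1 + dz
  thickness_deficit <- sum(pmax(z_floor - new_z1, 0))
  new_z1 <- pmax(new_z1, z_floor)
  deficit_cells <- numeric(nrow(cols$thickness))
  for (p in seq_along(pools)) {
    M <- cols[[pools[p]]][, 1] * z1 + dM[, p]
    deficit_cells <- deficit_cells + pmax(-M, 0)
    cols[[pools[p]]][, 1] <- pmax(M, 0) / new_z1
  }
  pool_deficit <- sum(deficit_cells)
  cols$thickness[, 1] <- new_z1
  # remap: push layer k back to nominal by exchanging with layer k+1
  for (k in seq_len(nl - 1)) {
    zk <- cols$thickness[, k]
    d <- nominal[k] - zk                  # >0: borrow from below
    if (!any(d != 0)) next
    zk1 <- cols$thickness[, k + 1]
    avail <- zk1 - z_floor
    over <- d > avail
    if (any(over)) {
      thickness_deficit <- thickness_deficit + sum((d - avail)[over])
      d[over] <- pmax(avail[over], 0)
    }
    new_zk <- zk + d
    new_zk1 <- zk1 - d
    borrow <- d > 0
    for (p in pools) {
      Ck <- cols[[p]][, k]; Ck1 <- cols[[p]][, k + 1]
      donor <- Ck
      donor[borrow] <- Ck1[borrow]
      move <- d * donor
      cols[[p]][, k] <- (Ck * zk + move) / new_zk
      cols[[p]][, k + 1] <- (Ck1 * zk1 - move) / new_zk1
    }
    cols$thickness[, k] <- new_zk
    cols$thickness[, k + 1] <- new_zk1
  }
  list(cols = cols, pool_deficit = pool_deficit,
       deficit_cells = deficit_cells,
       thickness_deficit = thickness_deficit)
}
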