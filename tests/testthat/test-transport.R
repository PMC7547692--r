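test_that("diffusive SOC flux factorizes and matches an upwind stencil oracle", {
  dx <- 2
  x <- (seq_len(12) - 0.5) * dx
  mound <- matrix(rep(50 - 0.03 * (x - 12)^2, each = 6), 6, 12)
  D <- 2e-4
  # zero concentration: zero flux
  expect_true(all(soc_diffusive_flux(matrix(0, 6, 12), mound, D, D, 1.5,
                                     dx) == 0))
  # uniform concentration and k_soc = 1: exactly C x sediment divergence
  sed <- diffusion_divergence(mound, D, D, dx)
  soc <- soc_diffusive_flux(matrix(2.5, 6, 12), mound, D, D, 1, dx)
  expect_equal(soc, 2.5 * sed)
  # spatially varying concentration on a 1-D ramp vs an independently
  # written donor-upwind face-flux oracle
  ramp <- matrix(rep(seq(10, 0, length.out = 12), each = 6), 6, 12)
  conc <- matrix(rep(seq(1, 4, length.out = 12), each = 6), 6, 12)
  k <- 1.7
  got <- soc_diffusive_flux(conc, ramp, D, D, k, dx)
  oracle <- matrix(0, 6, 12)
  for (j in 1:12) {
    # east and west face sediment fluxes (zero at the boundary)
    fE <- if (j < 12) -D * (ramp[1, j + 1] - ramp[1, j]) / dx else 0
    fW <- if (j > 1) -D * (ramp[1, j] - ramp[1, j - 1]) / dx else 0
    cE <- if (j < 12) (if (fE > 0) conc[1, j] else conc[1, j + 1]) else 0
    cW <- if (j > 1) (if (fW > 0) conc[1, j - 1] else conc[1, j]) else 0
    oracle[, j] <- (k * cE * fE - k * cW * fW) / dx
  }
  expect_equal(got, oracle, tolerance = 1e-14)
  expect_error(soc_diffusive_flux(matrix(1, 3, 3), mound, D, D, 1, dx),
               "shape")
})

test_that("advective SOC flux follows the sediment branches with donor concentrations", {
  # 3-cell cascade with distinct surface concentrations
  order <- 1:3
  receiver <- c(2L, 3L, 0L)
  ds <- 2
  qs_cap <- c(0.6, 0.1, 0)
  dc <- c(0.1, 0.001, 0)
  sed <- socscape:::cpp_overland_divergence(order, receiver, qs_cap, dc, ds)
  conc <- cbind(c(2, 5, 1))   # one pool
  k <- 1.0
  soc <- socscape:::cpp_soc_overland(order, receiver, sed$limited,
                                     sed$outflux, dc, conc, k, ds)
  # cell 1 detachment-limited: k * C1 * Dc
  expect_true(sed$limited[1])
  expect_equal(soc$divergence[1, 1], k * 2 * 0.1)
  # cell 2 transport-limited: (k C2 qs_out - k C1_in q_in)/ds; its inflow
  # carries the donor concentration (cell 1 eroded carbon)
  in_soc <- soc$divergence[1, 1] * ds
  expect_equal(soc$divergence[2, 1],
               (k * 5 * sed$outflux[2] - in_soc) / ds)
  # explicit ledger: total divergence equals outlet export
  expect_equal(sum(soc$divergence) * ds, soc$outlet_export[1])
  # zero sediment flux: zero SOC flux
  z <- socscape:::cpp_soc_overland(order, receiver, rep(FALSE, 3),
                                   rep(0, 3), rep(0, 3), conc, k, ds)
  expect_true(all(z$divergence == 0))
})

test_that("uniform surface carbon makes SOC flux proportional to sediment flux", {
  dem <- generate_dem(grid_domain(16, 16), "natural", relief = 20,
                      seed = 6)
  net <- route_flow(dem)
  q <- unit_discharge(rep(12, 256), net, dem$domain)
  ovl <- overland_divergence(net, q, transport_params())
  conc <- cbind(rep(3.5, 256))
  soc <- soc_advective_flux(conc, net, ovl, k_soc = 1)
  expect_equal(soc$divergence[, 1], 3.5 * ovl$divergence,
               tolerance = 1e-12)
  # global SOC conservation under transport alone
  expect_lt(abs(sum(soc$divergence) * 2 - sum(soc$outlet_export)),
            1e-10 * max(1, sum(soc$outlet_export)))
})

test_that("surface-layer updates keep the carbon ledger exact", {
  col <- soc_column(thickness = default_layering(),
                    C_l = rep(0.4, 7), C_h = rep(3.4, 7),
                    C_b = rep(0.07, 7))
  # zero divergence and zero transformation: column unchanged
  same <- update_surface_layer(col, c(0, 0, 0), 0)
  expect_equal(same$C_h, col$C_h)
  expect_equal(same$thickness, col$thickness)
  # pure deposition of known mass raises the stock by exactly that mass
  dep <- c(0.002, 0.01, 0.0005)            # kg/m2/day arriving
  got <- update_surface_layer(col, -dep, -0.001, dt = 1)
  expect_equal(integrate_stock(got) - integrate_stock(col), sum(dep),
               tolerance = 1e-12)
  # alternating erosion/deposition: final stock = initial + ledger sum
  set.seed(9)
  cur <- col
  ledger <- 0
  for (i in 1:30) {
    d <- rnorm(3, sd = c(2e-3, 2e-3, 2e-4))  # divergence ~ pool size
    sed <- rnorm(1, sd = 5e-4)
    cur <- update_surface_layer(cur, d, sed, dt = 1)
    # clipped (would-be negative) pool mass is logged, not invented
    ledger <- ledger - sum(d) + attr(cur, "pool_deficit")
  }
  expect_equal(integrate_stock(cur) - integrate_stock(col), ledger,
               tolerance = 1e-10)
  # transport never creates negative pools
  expect_true(all(cur$C_l >= 0 & cur$C_h >= 0 & cur$C_b >= 0))
})
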