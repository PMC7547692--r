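test_that("flow routing resolves pits and reproduces brute-force areas", {
  rg <- ramp_grid(8, 8)
  net <- route_flow(rg$elev, rg$domain)
  # on a monotone plane every receiver is strictly downslope
  has <- net$receiver > 0
  fv <- as.numeric(net$filled)
  expect_true(all(fv[has] > fv[net$receiver[has]]))
  expect_equal(net$drainage_area[which(net$receiver == 0)], 8 * 8 * 4)
  # a single interior pit is filled and drains outward
  pit <- rg$elev
  pit[4, 4] <- -5
  netp <- route_flow(pit, rg$domain)
  expect_true(all(all_drain_to_outlet(netp, 64)))
  # random DEM: drainage areas equal brute-force reachability counts
  set.seed(7)
  dom <- grid_domain(16, 16, outlet = c(1L, 8L))
  rnd <- matrix(runif(256, 0, 5), 16, 16)
  rnd[1, 8] <- -1
  netr <- route_flow(rnd, dom)
  counts <- numeric(256)
  for (i in seq_len(256)) {
    j <- i
    repeat {
      counts[j] <- counts[j] + 1
      if (netr$receiver[j] == 0) break
      j <- netr$receiver[j]
    }
  }
  expect_equal(netr$drainage_area, counts * 4)
  expect_warning(route_flow(matrix(1, 8, 8), grid_domain(8, 8)),
                 "all-equal")
})

test_that("diffusion divergence matches second-difference analytics", {
  dx <- 2
  expect_true(all(diffusion_divergence(matrix(3, 6, 6), 1e-4, 1e-4, dx)
                  == 0))
  # 1-D linear ramp: constant flux, zero interior divergence
  ramp <- matrix(rep(seq(0, 10, length.out = 8), each = 6), 6, 8)
  dv <- diffusion_divergence(ramp, 2e-4, 2e-4, dx)
  expect_true(all(abs(dv[, 2:7]) < 1e-15))
  # parabolic mound: divergence = -D * d2eta/dx2 at interior cells
  x <- (seq_len(20) - 0.5) * dx
  mound <- matrix(rep(100 - 0.05 * (x - 20)^2, each = 6), 6, 20,
                  byrow = FALSE)
  D <- 3e-4
  dvp <- diffusion_divergence(mound, D, D, dx)
  expect_equal(dvp[3, 5:16], rep(D * 2 * 0.05, 12), tolerance = 1e-10)
  # closed domain: area-weighted divergence sums to zero
  set.seed(1)
  noisy <- matrix(runif(64), 8, 8)
  expect_lt(abs(sum(diffusion_divergence(noisy, 1e-4, 2e-4, dx))), 1e-14)
  expect_error(diffusion_divergence(noisy, -1, 1, dx), "diffusivities")
})

test_that("overland transport honours the detachment-limited min() branches", {
  # 3-cell cascade: steep -> steep -> outlet, hand-checkable
  order <- 1:3
  receiver <- c(2L, 3L, 0L)
  ds <- 2
  # detachment-limited: shortfall (cap - in)/ds = 3 * Dc at cell 1
  qs_cap <- c(0.6, 0.0, 0)
  dc <- c(0.1, 0.05, 0)
  res <- socscape:::cpp_overland_divergence(order, receiver, qs_cap, dc, ds)
  expect_equal(res$divergence[1], 0.1)        # min() takes D_c
  expect_true(res$limited[1])
  expect_equal(res$outflux[1], 0.1 * ds)      # inflow 0 + Dc * ds
  # slope-break deposition: cell 2 has no capacity, deposits all inflow
  expect_equal(res$divergence[2], -res$outflux[1] / ds)
  expect_false(res$limited[2])
  # outlet passes inflow through: global mass balance telescopes
  expect_equal(res$outlet_export, res$outflux[2])
  expect_equal(sum(res$divergence) * ds, res$outlet_export)
  # zero discharge: zero divergence
  rg <- ramp_grid(6, 6)
  net <- route_flow(rg$elev, rg$domain)
  z <- overland_divergence(net, rep(0, 36), transport_params())
  expect_true(all(z$divergence == 0))
})

test_that("sediment mass is conserved to machine precision each step", {
  dem <- generate_dem(grid_domain(16, 16), "natural", relief = 20,
                      seed = 3)
  net <- route_flow(dem)
  q <- unit_discharge(rep(15, 256), net, dem$domain)
  tp <- transport_params()
  ovl <- overland_divergence(net, q, tp)
  # domain-integrated erosion equals the outlet export exactly
  expect_lt(abs(sum(ovl$divergence) * 2 - ovl$outlet_export),
            1e-12 * max(ovl$outlet_export, 1))
  dv <- diffusion_divergence(dem$elev, tp$D_x, tp$D_y, 2)
  st <- step_elevation(dem$elev, dem$soil_thickness, dv,
                       as_grid_matrix(ovl$divergence, dem$domain),
                       dt = 1, D_max = tp$D_x, cell_size = 2)
  change <- sum(st$elev - dem$elev) * 4
  expect_lt(abs(change + ovl$outlet_export * 2 * 1),
            1e-10 * max(abs(change), 1))
})

test_that("elevation stepping obeys its contracts", {
  e <- matrix(5, 6, 6)
  thick <- matrix(1, 6, 6)
  zero <- matrix(0, 6, 6)
  s0 <- step_elevation(e, thick, zero, zero, 1, 1e-5, 2)
  expect_identical(s0$elev, e)
  d <- matrix(0.002, 6, 6)
  s1 <- step_elevation(e, thick, d, zero, 1, 1e-5, 2)
  expect_true(all(s1$elev == 5 - 0.002))
  expect_true(all(s1$soil_thickness == 1 - 0.002))
  expect_error(step_elevation(e, thick, zero, zero, 1, D_max = 2,
                              cell_size = 2), "CFL")
  # pure diffusion monotonically decreases total relief
  set.seed(2)
  bumpy <- matrix(runif(144, 0, 2), 12, 12)
  relief <- diff(range(bumpy))
  cur <- bumpy
  for (i in 1:20) {
    dv <- diffusion_divergence(cur, 5e-2, 5e-2, 2)
    cur <- step_elevation(cur, matrix(10, 12, 12), dv,
                          matrix(0, 12, 12), 1, 5e-2, 2)$elev
    expect_lte(diff(range(cur)), relief + 1e-12)
    relief <- diff(range(cur))
  }
})
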