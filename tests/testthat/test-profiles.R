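test_that("depth profile evaluates, bounds and decreases as expected", {
  shrub <- profile_params(8.04, 9.63, 2.55)
  expect_equal(profile_value(shrub, 0), 8.04 + 2.55)
  expect_lt(abs(profile_value(shrub, 1.5) - 2.55), 1e-4)
  crop <- profile_params(3.71, 7.06, 2.27)
  # independent arithmetic oracle at Z = 0.1 m
  expect_equal(profile_value(crop, 0.1), 3.71 * exp(-7.06 * 0.1) + 2.27)
  z <- seq(0, 1, by = 0.01)
  v <- profile_value(crop, z)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > crop$c & v <= crop$a + crop$c))
  expect_error(profile_value(crop, -0.1), "depth")
  expect_error(profile_params(-1, 2, 3), "> 0")
})

test_that("profile fitting recovers known parameters", {
  truth <- list(a = 5.2, b = 8.1, c = 2.4)
  z <- seq(0, 0.9, length.out = 12)
  clean <- data.frame(depth = z,
                      concentration = truth$a * exp(-truth$b * z) + truth$c)
  fit <- fit_profile(clean)
  expect_lt(abs(fit$a - truth$a) / truth$a, 1e-6)
  expect_lt(abs(fit$b - truth$b) / truth$b, 1e-6)
  expect_lt(abs(fit$c - truth$c) / truth$c, 1e-6)
  # two distinct depths only: under-determined
  dup <- data.frame(depth = rep(c(0.05, 0.15), 3),
                    concentration = rep(c(5, 4), 3))
  expect_error(fit_profile(dup), "under-determined")
})

test_that("profile fitting is nearly unbiased under measurement noise", {
  truth <- list(a = 3.71, b = 7.06, c = 2.27)
  z <- seq(0.025, 0.975, length.out = 20)
  mu <- truth$a * exp(-truth$b * z) + truth$c
  set.seed(101)
  est <- t(replicate(500, {
    s <- data.frame(depth = z, concentration = mu + rnorm(20, sd = 0.2))
    f <- fit_profile(s)
    c(f$a, f$b, f$c)
  }))
  bias <- abs(apply(est, 2, median) / unlist(truth) - 1)
  expect_true(all(bias < 0.05))
})

test_that("surface amplitude back-calculation matches its least-squares oracle", {
  # consistent inputs: exact recovery
  a <- 3.71; b <- 7.06; c <- 2.27
  o <- a * exp(-b * c(0.05, 0.15)) + c
  expect_lt(abs(back_calculate_a(o[1], o[2], b, c) - a), 1e-9)
  # degenerate b -> 0 with equal observations: a = o - c
  expect_equal(back_calculate_a(5, 5, 1e-12, 2), 3, tolerance = 1e-6)
  # perturbed observations: brute-force grid minimization oracle
  obs <- o + c(0.31, -0.22)
  sse <- function(aa) sum((aa * exp(-b * c(0.05, 0.15)) + c - obs)^2)
  grid <- seq(0.5, 8, by = 1e-4)
  a_star <- grid[which.min(vapply(grid, sse, 0))]
  expect_lt(abs(back_calculate_a(obs[1], obs[2], b, c) - a_star), 1e-3)
  expect_error(back_calculate_a(2.0, 2.1, 5, 2.5), "no signal")
})

test_that("surface interpolation is exact at samples and matches IDW arithmetic", {
  dom <- grid_domain(8, 8, cell_size = 2)
  one <- data.frame(x = 5, y = 5, concentration = 4.2)
  m1 <- interpolate_surface(one, dom)
  expect_true(all(m1 == 4.2))
  pts <- data.frame(x = c(1, 9, 5), y = c(1, 3, 13),
                    concentration = c(3, 5, 4))
  rows <- ceiling(pts$y / 2); cols <- ceiling(pts$x / 2)
  m <- interpolate_surface(pts, dom, method = "idw")
  expect_equal(m[cbind(rows, cols)], pts$concentration, tolerance = 1e-8)
  # too few points for a variogram: kriging falls back to IDW, loudly
  expect_warning(mk3 <- interpolate_surface(pts, dom,
                                            method = "ordinary_kriging"),
                 "falling back")
  expect_equal(mk3[cbind(rows, cols)], pts$concentration,
               tolerance = 1e-8)
  # a richer survey supports a fitted variogram; kriging stays exact
  set.seed(31)
  many <- data.frame(x = (sample(8, 12, TRUE) - 0.5) * 2,
                     y = (sample(8, 12, TRUE) - 0.5) * 2)
  many <- unique(many)
  many$concentration <- 3 + 0.1 * many$x + 0.05 * many$y +
    rnorm(nrow(many), sd = 0.1)
  mk <- interpolate_surface(many, dom, method = "ordinary_kriging")
  rr <- ceiling(many$y / 2); cc <- ceiling(many$x / 2)
  expect_equal(mk[cbind(rr, cc)], many$concentration, tolerance = 1e-6)
  # hand-computed inverse-distance weights at one target cell
  m_idw <- interpolate_surface(pts, dom, method = "idw")
  gx <- 7; gy <- 7   # centre of cell (4, 4)
  d2 <- (gx - pts$x)^2 + (gy - pts$y)^2
  w <- 1 / d2
  expect_equal(m_idw[4, 4], sum(w * pts$concentration) / sum(w),
               tolerance = 1e-12)
  expect_true(all(m_idw >= min(pts$concentration) &
                    m_idw <= max(pts$concentration)))
  expect_error(interpolate_surface(pts[0, ], dom), "no sample")
})

test_that("initial columns follow the profile and integrate correctly", {
  dom <- grid_domain(4, 4)
  surf <- matrix(5.98, 4, 4)
  b <- 7.06; cc <- 2.27; bd <- 1300
  cols <- build_initial_columns(surf, b, cc, bulk_density = bd)
  # per-layer totals equal the profile at layer midpoints
  lay <- default_layering()
  mids <- cumsum(lay) - lay / 2
  expected <- ((5.98 - cc) * exp(-b * mids) + cc) * bd / 1000
  total1 <- cols$C_l[1, ] + cols$C_h[1, ] + cols$C_b[1, ]
  expect_equal(total1, expected)
  # all columns identical for a constant surface map
  expect_equal(max(apply(cols$C_h, 2, function(x) diff(range(x)))), 0)
  # column integral vs the analytic integral of the profile over [0, 1] m
  stock <- integrate_stocks(cols)[1]
  analytic <- ((5.98 - cc) / b * (1 - exp(-b)) + cc) * bd / 1000
  expect_lt(abs(stock - analytic) / analytic, 0.02)
  # pool partition contracts
  all_h <- build_initial_columns(surf, b, cc,
                                 pool_fractions = c(0, 1, 0))
  expect_true(all(all_h$C_l == 0) && all(all_h$C_b == 0))
  expect_error(build_initial_columns(surf, b, cc,
                                     pool_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
})

test_that("stock integration is additive and linear", {
  col <- soc_column(thickness = c(0.5, 0.5), C_l = c(0.5, 0.5),
                    C_h = c(0.4, 0.4), C_b = c(0.1, 0.1))
  expect_equal(integrate_stock(col), 1)  # 1 kg/m3 over 1 m
  zero <- soc_column(c(0.5, 0.5), c(0, 0), c(0, 0), c(0, 0))
  expect_equal(integrate_stock(zero), 0)
  toy <- soc_column(thickness = c(0.1, 0.3, 0.6),
                    C_l = c(1, 0, 0), C_h = c(2, 3, 1), C_b = c(0, 0, 0.5))
  expect_equal(integrate_stock(toy),
               0.1 * 3 + 0.3 * 3 + 0.6 * 1.5)
  # linear in concentrations
  toy2 <- toy
  toy2$C_h <- 2 * toy$C_h
  expect_equal(integrate_stock(toy2) - integrate_stock(toy),
               sum(toy$thickness * toy$C_h))
})
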