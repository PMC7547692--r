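test_that("decomposition rates follow the biomass-moisture-nitrogen product", {
  expect_equal(decomposition_rates(0, 0.5, 1, 0.2, 0.01),
               list(K_l = 0, K_h = 0))
  expect_equal(decomposition_rates(0.07, 1, 1, 0.2, 0.01)$K_l, 0.2 * 0.07)
  set.seed(3)
  for (i in 1:20) {
    cb <- runif(1, 0, 0.5); fd <- runif(1); ph <- runif(1)
    kl <- runif(1, 0, 0.3); kh <- runif(1, 0, 0.05)
    K <- decomposition_rates(cb, fd, ph, kl, kh)
    expect_equal(K$K_l, ph * fd * kl * cb)
    expect_equal(K$K_h, ph * fd * kh * cb)
  }
  expect_error(decomposition_rates(0.1, 1.5, 1, 0.1, 0.01), "\\[0, 1\\]")
  expect_error(transform_params(r_r = 0.9, r_h = 0.2), "r_r")
})

test_that("pool transformation honours the total-carbon balance identity", {
  xp <- transform_params()
  # no biomass and no input: nothing happens
  still <- transform_step(list(C_l = 0.5, C_h = 2, C_b = 0), 0, xp, 0.5)
  expect_equal(still[c("C_l", "C_h", "C_b")],
               list(C_l = 0.5, C_h = 2, C_b = 0))
  expect_equal(still$co2_efflux, 0)
  # at the closed-form equilibrium the efflux rate equals the input
  I <- 2.5e-3
  eq <- equilibrium_pools(I, xp, f_d = 0.3)
  stepped <- transform_step(eq[c("C_l", "C_h", "C_b")], I, xp, 0.3, dt = 1)
  expect_equal(stepped$co2_efflux, I, tolerance = 1e-6)
  expect_equal(stepped$C_h, eq$C_h, tolerance = 1e-6)
  # per-step balance: d(total) = (I - efflux) for arbitrary states
  p <- list(C_l = 0.8, C_h = 3.1, C_b = 0.12)
  out <- transform_step(p, I, xp, 0.6, dt = 1)
  d_tot <- (out$C_l + out$C_h + out$C_b) - (p$C_l + p$C_h + p$C_b)
  expect_equal(d_tot, I - out$co2_efflux, tolerance = 1e-12)
})

test_that("daily stepping tracks a fine-step integration oracle", {
  xp <- transform_params()
  run_traj <- function(dt, years = 10) {
    p <- list(C_l = 0.4, C_h = 3.5, C_b = 0.07)
    for (i in seq_len(years * 365 / dt)) {
      p <- transform_step(p, 2.5e-3, xp, 0.3, dt)[c("C_l", "C_h", "C_b")]
    }
    unlist(p)
  }
  coarse <- run_traj(1)
  fine <- run_traj(0.1)
  expect_true(all(abs(coarse - fine) / pmax(abs(fine), 1e-9) < 0.005))
})

test_that("long simulations reach the closed-form steady state", {
  xp <- transform_params()
  I <- 2.5e-3
  eq <- equilibrium_pools(I, xp, f_d = 0.3)
  p <- list(C_l = 0.01, C_h = 1, C_b = 0.01)
  for (i in seq_len(150 * 365)) {
    p <- transform_step(p, I, xp, 0.3, dt = 1)[c("C_l", "C_h", "C_b")]
  }
  total <- p$C_l + p$C_h + p$C_b
  expect_lt(abs(total - eq$total) / eq$total, 0.01)
})

test_that("equilibrium stock grows with residence time; finite-horizon gains saturate", {
  xp <- transform_params()
  mrts <- c(10, 12.9, 15.8, 18.7, 21.6, 24.4)
  mult <- vapply(mrts, calibrate_residence_time, 0, params = xp)
  eq_tot <- vapply(mult, function(m)
    equilibrium_pools(2.5e-3, xp, 0.3, kh_multiplier = m)$total, 0)
  expect_true(all(diff(eq_tot) > 0))
  # 20-year stock change from the current state: diminishing increments
  horizon <- function(m) {
    p <- list(C_l = 0.45, C_h = 3.4, C_b = 0.0685)
    for (i in seq_len(20 * 365)) {
      p <- transform_step(p, 2.5e-3, xp, 0.3, dt = 1,
                          kh_multiplier = m)[c("C_l", "C_h", "C_b")]
    }
    p$C_l + p$C_h + p$C_b
  }
  stocks <- vapply(mult, horizon, 0)
  expect_true(all(diff(stocks) > 0))                   # monotone in MRT
  gains <- diff(stocks)
  expect_lt(gains[5], gains[1])                        # saturation
})

test_that("residence-time calibration is an exact inverse relationship", {
  xp <- transform_params()
  cur <- current_residence_time(xp)
  expect_equal(calibrate_residence_time(cur, xp), 1, tolerance = 1e-12)
  expect_equal(calibrate_residence_time(2 * cur, xp), 0.5,
               tolerance = 1e-12)
  for (mrt in c(10, 12.9, 15.8, 18.7, 21.6, 24.4)) {
    m <- calibrate_residence_time(mrt, xp)
    realized <- xp$r_r * xp$phi * xp$f_d_ref * xp$k_h * m * xp$c_b_ref
    expect_lt(abs(realized - 1 / (mrt * 365)), 1e-9)
  }
  expect_error(calibrate_residence_time(-1, xp), "> 0")
})

test_that("bioturbation mixes diffusively while conserving column mass", {
  xp <- transform_params()
  uniform <- soc_column(default_layering(), rep(1, 7), rep(2, 7),
                        rep(0.1, 7))
  mixed <- bioturbation_step(uniform, xp, dt = 1)
  expect_equal(mixed$C_h, uniform$C_h)
  # two-layer step profile: mass conserved, gradient reduced
  stepc <- soc_column(rep(0.1, 10), c(rep(4, 5), rep(1, 5)),
                      rep(2, 10), rep(0.1, 10))
  out <- stepc
  for (i in 1:200) out <- bioturbation_step(out, xp, dt = 30)
  expect_equal(sum(out$C_l * out$thickness),
               sum(stepc$C_l * stepc$thickness), tolerance = 1e-12)
  expect_lt(max(out$C_l) - min(out$C_l), max(stepc$C_l) - min(stepc$C_l))
  expect_lte(max(out$C_l), max(stepc$C_l) + 1e-12)
  # pulse spreading against the closed-form diffusion solution
  nl <- 20
  z <- rep(0.05, nl)
  mid <- cumsum(z) - 0.025
  C0 <- exp(-((mid - 0.5) / 0.08)^2)
  deep_mix <- transform_params(D0_bioturb = 5e-5, z_bioturb = 1e6)
  col <- soc_column(z, C0, rep(0, nl), rep(0, nl))
  Tdays <- 30
  for (i in seq_len(Tdays)) col <- bioturbation_step(col, deep_mix, 1)
  D <- 5e-5
  s2 <- 0.08^2 / 2 + 2 * D * Tdays      # variance grows as 2 D t
  analytic <- 0.08 / sqrt(2 * s2) * exp(-((mid - 0.5)^2) / (2 * s2))
  l2 <- sqrt(mean((col$C_l - analytic)^2)) / sqrt(mean(analytic^2))
  expect_lt(l2, 0.02)
})

test_that("tillage homogenizes the plough depth and conserves mass", {
  even <- soc_column(default_layering(), rep(1, 7), rep(3, 7),
                     rep(0.1, 7))
  expect_equal(tillage_mix(even, 0.2)$C_h, even$C_h)
  # top-heavy 20 cm: 10 and 2 in equal thickness mix to 6
  two <- soc_column(c(0.1, 0.1, 0.4, 0.4), C_l = c(0, 0, 0, 0),
                    C_h = c(10, 2, 1, 1), C_b = c(0, 0, 0, 0))
  mixed <- tillage_mix(two, 0.2)
  expect_equal(mixed$C_h, c(6, 6, 1, 1))
  expect_equal(integrate_stock(mixed), integrate_stock(two))
  # arbitrary layering intersecting the mixing plane
  odd <- soc_column(c(0.08, 0.24, 0.30, 0.38),
                    C_l = c(0.9, 0.2, 0.05, 0),
                    C_h = c(5, 3, 2.4, 2.2), C_b = c(0.1, 0.05, 0.01, 0))
  m2 <- tillage_mix(odd, 0.2)
  expect_lt(abs(integrate_stock(m2) - integrate_stock(odd)), 1e-12)
  expect_equal(m2$C_h[3:4], odd$C_h[3:4])  # below plough depth untouched
  expect_error(tillage_mix(odd, 2), "exceeds")
})

test_that("steady-state spin-up preserves layer totals", {
  surf <- matrix(3.1, 4, 4)
  cols <- build_initial_columns(surf, b = 7.06, c = 2.27)
  before <- cols$C_l + cols$C_h + cols$C_b
  sp <- spinup_columns(cols, rep("crop", 16))
  after <- sp$C_l + sp$C_h + sp$C_b
  expect_equal(after, before, tolerance = 1e-12)
  expect_true(all(sp$C_l >= 0 & sp$C_h >= 0 & sp$C_b >= 0))
})
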