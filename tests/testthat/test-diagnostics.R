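test_that("depth integration weights layers and partial fractions", {
  g <- make_grid(4, 3, 4, 1e4, 1e4, 200, stretch = 0) # 50 m layers
  u1 <- empty_tracers(g, 1)$N
  expect_equal(depth_integrate(u1, g, 75), matrix(75, 4, 3))
  expect_equal(depth_integrate(0 * u1, g, 75), matrix(0, 4, 3))
  # two layers 0-50 at 2.0 and 50-100 at 1.0, z_max 75: 2*50 + 1*25
  f <- 0 * u1; f[, , 1] <- 2; f[, , 2] <- 1
  expect_equal(depth_integrate(f, g, 75), matrix(125, 4, 3))
  # linearity and additivity over depth ranges
  set.seed(21)
  a <- array(runif(48), dim(u1)); b <- array(runif(48), dim(u1))
  expect_equal(depth_integrate(a + 2 * b, g, 120),
               depth_integrate(a, g, 120) + 2 * depth_integrate(b, g, 120))
  expect_equal(depth_integrate(a, g, 200),
               depth_integrate(a, g, 100) +
                 (depth_integrate(a, g, 200) - depth_integrate(a, g, 100)))
  expect_error(depth_integrate(a, g, 300), "water column")
})

test_that("transect extraction interpolates bilinearly and exactly", {
  g <- make_grid(20, 10, 3, 5e3, 5e3, 60, stretch = 0)
  const <- empty_tracers(g, 3.5)$N
  tr <- transect_spec(rbind(c(10, 10), c(80, 40)), interval_km = 7)
  sec <- extract_transect(const, g, tr)
  expect_equal(max(abs(sec$section - 3.5)), 0)
  expect_equal(sec$distance_km[length(sec$distance_km)],
               sqrt(70^2 + 30^2))
  # linear-in-x field sampled along x: exactly linear
  lin <- const
  for (i in 1:20) lin[i, , ] <- i # linear in cell-center x
  trx <- transect_spec(rbind(c(12.5, 25), c(77.5, 25)), interval_km = 5)
  secx <- extract_transect(lin, g, trx)
  expect_equal(secx$section[, 1],
               (12.5 + (seq_along(secx$distance_km) - 1) * 5) / 5 + 0.5,
               tolerance = 1e-12)
  # degenerate zero-length transect: single column profile
  tr0 <- transect_spec(rbind(c(33, 22), c(33, 22)))
  sec0 <- extract_transect(const, g, tr0)
  expect_equal(dim(sec0$section), c(1, 3))
  expect_error(extract_transect(const, g,
                                transect_spec(rbind(c(-5, 10), c(50, 10)))),
               "outside")
})

test_that("transect extraction commutes with field arithmetic", {
  g <- make_grid(12, 9, 4, 5e3, 5e3, 100)
  set.seed(22)
  tr <- initial_state(g, scenario_config())
  tr$P <- array(runif(12 * 9 * 4), c(12, 9, 4))
  tr$Z <- array(runif(12 * 9 * 4), c(12, 9, 4))
  sp <- transect_spec(rbind(c(10, 10), c(50, 40)), 4)
  sP <- extract_transect(tr$P, g, sp)$section
  sZ <- extract_transect(tr$Z, g, sp)$section
  sB <- extract_transect(plankton_biomass(tr), g, sp)$section
  expect_equal(sP + sZ, sB)
})

test_that("plankton biomass is P plus Z, excluding detritus", {
  tr <- list(P = array(1, c(2, 2, 2)), Z = array(2, c(2, 2, 2)),
             D = array(5, c(2, 2, 2)))
  expect_equal(plankton_biomass(tr), array(3, c(2, 2, 2)))
  tr0 <- list(P = array(0, c(2, 2, 2)), Z = array(0, c(2, 2, 2)),
              D = array(5, c(2, 2, 2)))
  expect_equal(max(plankton_biomass(tr0)), 0)
})

test_that("nitrogen budget record closes for a default-physics run", {
  cfg <- run_config(grid = list(nx = 12, ny = 9, nz = 8, dx = 2.5e4,
                                dy = 2.5e4),
                    flow = list(jet_width_km = 80, w_cell_sigma_km = 30,
                                edge_taper_km = 50),
                    scenario = list(run_days = 15,
                                    snapshot_days = c(5, 10, 15)),
                    numerics = list(dt_s = 3600))
  run <- run_simulation(cfg)
  b <- nitrogen_budget(run)
  expect_equal(nrow(b), 4)
  expect_true(all(abs(b$residual) < 1e-8))
  # recycled-closure run (beta = 1, sinking off): inventory is constant
  cfg2 <- run_config(grid = cfg$grid, flow = cfg$flow,
                     scenario = cfg$scenario,
                     bio = list(beta = 1),
                     numerics = list(dt_s = 3600, sinking = FALSE))
  run2 <- run_simulation(cfg2)
  b2 <- nitrogen_budget(run2)
  expect_equal(b2$closure, rep(0, 4))
  tot <- b2$N + b2$P + b2$Z + b2$D
  expect_equal(tot / tot[1], rep(1, 4), tolerance = 1e-8)
})

test_that("the default transect crosses both gyres inside the domain", {
  g <- make_grid(40, 30, 10, 1e4, 1e4, 300)
  cfg <- wide_jet_config()
  tr <- default_transect(cfg, g)
  v <- tr$vertices_km
  expect_gte(nrow(v), 3)
  expect_true(all(v[, 1] >= 0 & v[, 1] <= 400))
  expect_true(all(v[, 2] >= 0 & v[, 2] <= 300))
  # last leg is zonal across the eastern gyre
  expect_equal(v[nrow(v), 2], v[nrow(v) - 1, 2])
  expect_no_error(extract_transect(initial_state(g)$N, g, tr))
})
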