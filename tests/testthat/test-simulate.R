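test_that("box model conserves nitrogen when closure loss is recycled", {
  p <- bio_params(beta = 1) # all quadratic mortality recycled
  ts <- run_box(p, I = 40, init = c(N = 2, P = 0.3, Z = 0.2, D = 0.1),
                t_end = 100)
  expect_equal(ts$total_N, rep(2.6, nrow(ts)), tolerance = 1e-8)
  # zero initial state stays zero
  ts0 <- run_box(bio_params(), 40, c(N = 0, P = 0, Z = 0, D = 0), 10)
  expect_equal(max(abs(as.matrix(ts0[, c("N", "P", "Z", "D")]))), 0)
})

test_that("box model recovers the maximum growth rate under saturation", {
  # no grazing, mortality or excretion: pure exponential phytoplankton
  p <- bio_params(r_Z = 0, m_P = 0, m_Z = 0, mu_Z = 0)
  ts <- run_box(p, I = 1e9, init = c(N = 1e9, P = 1e-3, Z = 0, D = 0),
                t_end = 5, dt = 0.5)
  slope <- stats::coef(stats::lm(log(P) ~ time, ts))[["time"]]
  expect_equal(slope, 1.3, tolerance = 1e-5)
})

test_that("compiled biology kernel matches the R source terms", {
  g <- make_grid(4, 3, 6, 1e3, 1e3, 120, stretch = 0)
  p <- bio_params()
  set.seed(11)
  st <- empty_tracers(g)
  for (nm in c("N", "P", "Z", "D"))
    st[[nm]] <- array(runif(72, 0, 3), c(4, 3, 6))
  dt_days <- 1e-5 # one tiny Euler-like step: RK4 ~ tendencies * dt
  bs <- alborun:::bio_step_cpp(st$N, st$P, st$Z, st$D, 4L, 3L, 6L, g$dz,
                               g$kmax, alborun:::bio_params_vector(p),
                               dt_days, 1L, g$dx * g$dy)
  for (i in 1:4) for (j in 1:3) {
    I <- light_profile(st$P[i, j, ], g$dz, p)
    d <- source_terms(list(N = st$N[i, j, ], P = st$P[i, j, ],
                           Z = st$Z[i, j, ], D = st$D[i, j, ]), I, p)
    expect_equal((bs$N[i, j, ] - st$N[i, j, ]) / dt_days, d$dN,
                 tolerance = 1e-4)
    expect_equal((bs$P[i, j, ] - st$P[i, j, ]) / dt_days, d$dP,
                 tolerance = 1e-4)
    expect_equal((bs$Z[i, j, ] - st$Z[i, j, ]) / dt_days, d$dZ,
                 tolerance = 1e-4)
    expect_equal((bs$D[i, j, ] - st$D[i, j, ]) / dt_days, d$dD,
                 tolerance = 1e-4)
  }
})

test_that("a coupled step closes the nitrogen budget to round-off", {
  g <- small_grid(nz = 8, depth = 300, stretch = 2)
  fl <- fixture_flows(g, edge_taper_km = 10)$gyre
  p <- bio_params()
  set.seed(12)
  st <- empty_tracers(g)
  for (nm in c("N", "P", "Z", "D"))
    st[[nm]] <- array(runif(g$nx * g$ny * g$nz, 0, 2),
                      c(g$nx, g$ny, g$nz))
  m0 <- total_mass(st, g)
  out <- step_tracers(st, fl, g, p, dt = 1800)
  m1 <- total_mass(out$state, g)
  area <- g$dx * g$dy
  resid <- (m1 - m0 + sum(out$bottom_export) * area +
              sum(out$closure_loss) * area - out$clamp_mass) / m0
  expect_lt(abs(resid), 1e-10)
  # zero state is a fixed point
  z <- empty_tracers(g)
  outz <- step_tracers(z, fl, g, p, dt = 1800)
  expect_equal(max(abs(unlist(outz$state[c("N", "P", "Z", "D")]))), 0)
  # NaN detection aborts
  bad <- st; bad$N[1, 1, 1] <- NaN
  expect_error(step_tracers(bad, fl, g, p, 1800), "NaN")
})

test_that("a detritus-only column follows the remineralization-sinking oracle", {
  # 1 column, no flow: D remineralizes to N while sinking out the bottom
  g <- make_grid(1, 1, 6, 1e3, 1e3, 60, stretch = 0)
  fl <- fixture_flows(g)$zero
  p <- bio_params()
  st <- empty_tracers(g)
  st$D[1, 1, ] <- c(1, 0.8, 0.6, 0.4, 0.2, 0.1)
  # independent oracle: ODE for the 6-layer column with upwind sinking
  rhs <- function(t, y, parms) {
    D <- y[1:6]; ws <- p$w_Dmax * D / (p$S_D + D) # m/day
    flx <- c(0, ws * D)                           # downward at interfaces
    dD <- -p$eps * D + (flx[1:6] - flx[2:7]) / 10
    dN <- p$eps * D
    list(c(dD, dN))
  }
  oracle <- deSolve::ode(c(st$D[1, 1, ], rep(0, 6)),
                         seq(0, 2, by = 0.5), rhs, NULL,
                         rtol = 1e-10, atol = 1e-12)
  dt <- 450 # splitting (sinking before biology) is first order in dt
  out <- st; expo <- 0
  for (s in seq_len(2 * 86400 / dt)) {
    stp <- step_tracers(out, fl, g, p, dt, kappa_h = 0, kappa_v = 0,
                        dt_bio_days = 0.005)
    out <- stp$state; expo <- expo + stp$bottom_export[1, 1]
  }
  fin <- oracle[nrow(oracle), -1]
  expect_equal(out$D[1, 1, ], unname(fin[1:6]), tolerance = 5e-3)
  expect_equal(out$N[1, 1, ], unname(fin[7:12]), tolerance = 5e-3)
  # N gain matches the remineralization integral (budget: total change
  # equals -export)
  tot0 <- sum(st$D[1, 1, ] * 10)
  tot1 <- sum((out$D[1, 1, ] + out$N[1, 1, ]) * 10)
  expect_equal(tot1 - tot0, -expo, tolerance = 1e-10)
})

test_that("a 1-cell 3-D run reproduces the 0-D box trajectories", {
  # transparent water so the single layer sees exactly I_s
  p <- bio_params(k_w = 0, k_b = 0)
  g <- make_grid(1, 1, 1, 1e3, 1e3, 10, stretch = 0)
  fl <- fixture_flows(g)$zero
  st <- empty_tracers(g)
  init <- c(N = 2, P = 0.1, Z = 0.1, D = 0.05)
  st$N[] <- init["N"]; st$P[] <- init["P"]
  st$Z[] <- init["Z"]; st$D[] <- init["D"]
  dt <- 1800
  for (s in seq_len(30 * 86400 / dt))
    st <- step_tracers(st, fl, g, p, dt, sinking = FALSE)$state
  box <- run_box(p, I = p$I_s, init = init, t_end = 30)
  fin <- box[nrow(box), ]
  expect_equal(st$N[1, 1, 1], fin$N, tolerance = 1e-5)
  expect_equal(st$P[1, 1, 1], fin$P, tolerance = 1e-5)
  expect_equal(st$Z[1, 1, 1], fin$Z, tolerance = 1e-5)
  expect_equal(st$D[1, 1, 1], fin$D, tolerance = 1e-5)
})

test_that("the default step sizes are in the converged regime", {
  base <- list(grid = list(nx = 16, ny = 12, nz = 10, dx = 2.5e4,
                           dy = 2.5e4),
               flow = list(jet_width_km = 80, w_cell_sigma_km = 30,
                           edge_taper_km = 50),
               scenario = list(run_days = 20, snapshot_days = 20))
  out <- lapply(list(list(dt_s = 3600), list(dt_s = 1800),
                     list(dt_s = 3600, dt_bio_days = 0.01)),
                function(num) {
    cfg <- do.call(run_config, c(base, list(numerics = num)))
    run <- run_simulation(cfg)
    depth_integrate(plankton_biomass(run$snapshots$day20), run$grid, 75)
  })
  # halving the transport step changes euphotic biomass by several percent
  expect_lt(max(abs(out[[2]] - out[[1]])) / max(out[[1]]), 0.1)
  # refining the biological sub-step changes next to nothing (RK4)
  expect_lt(max(abs(out[[3]] - out[[1]])) / max(out[[1]]), 1e-4)
})

test_that("runs are deterministic and budget-closed at every snapshot", {
  cfg <- run_config(grid = list(nx = 16, ny = 12, nz = 10, dx = 2e4,
                                dy = 2e4),
                    flow = list(jet_width_km = 70, w_cell_sigma_km = 25,
                                edge_taper_km = 40),
                    scenario = list(run_days = 20,
                                    snapshot_days = c(10, 20)),
                    numerics = list(dt_s = 3600))
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$budget, r2$budget)
  expect_true(all(abs(r1$budget$residual) < 1e-8))
  # budget terms are non-negative and non-decreasing
  expect_true(all(diff(r1$budget$export) >= 0))
  expect_true(all(diff(r1$budget$closure) >= 0))
  # fields stay non-negative
  expect_gte(min(unlist(r1$snapshots$day20[c("N", "P", "Z", "D")])), 0)
})
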