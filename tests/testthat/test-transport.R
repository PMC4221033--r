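test_that("advection is exact for trivial flows and unit-CFL pulses", {
  g <- small_grid()
  fx <- fixture_flows(g, edge_taper_km = 10)
  set.seed(3)
  C <- array(runif(g$nx * g$ny * g$nz), c(g$nx, g$ny, g$nz))
  # zero flow: identity
  expect_identical(advect(C, fx$zero, g, 600), C)
  # uniform field under a divergence-free flow: unchanged
  U <- array(1, c(g$nx, g$ny, g$nz))
  expect_lt(max(abs(advect(U, fx$rotation, g, 600) - 1)), 1e-12)
  expect_lt(max(abs(advect(U, fx$gyre, g, 600) - 1)), 1e-12)
  # unit-CFL 1-D pulse: exact one-cell shift
  g1 <- make_grid(30, 1, 1, 1000, 1000, 10, stretch = 0)
  f1 <- fixture_flows(g1, u_channel = 1)$channel
  Cp <- array(0, c(30, 1, 1)); Cp[10, 1, 1] <- 1
  Cs <- advect(Cp, f1, g1, 1000)
  expect_equal(Cs[11, 1, 1], 1)
  expect_equal(sum(abs(Cs[-11, 1, 1])), 0)
  # CFL violation errors with sub-stepping advice
  expect_error(advect(Cp, f1, g1, 2000), "sub-step")
})

test_that("advection conserves mass and stays positive over many steps", {
  g <- small_grid()
  fx <- fixture_flows(g, edge_taper_km = 10)
  vol <- alborun:::cell_volumes(g)
  set.seed(4)
  C <- array(runif(g$nx * g$ny * g$nz), c(g$nx, g$ny, g$nz))
  m0 <- sum(C * vol)
  for (s in 1:1000) C <- advect(C, fx$gyre, g, 900)
  expect_lt(abs(sum(C * vol) - m0) / m0, 1e-10)
  expect_gte(min(C), -1e-14)
})

test_that("advection error decreases under grid refinement (rotating patch)", {
  err <- sapply(c(16, 32), function(n) {
    g <- make_grid(n, n, 1, 64e3 / n, 64e3 / n, 10, stretch = 0)
    omega <- 2e-6
    fl <- fixture_flows(g, omega = omega)$rotation  # no taper: pure rotation
    xm <- (seq_len(n) - 0.5) * g$dx; L <- n * g$dx
    patch <- function(x0, y0)
      array(outer(exp(-(xm - x0)^2 / (2 * 6e3^2)),
                  exp(-(xm - y0)^2 / (2 * 6e3^2))), c(n, n, 1))
    C <- patch(L / 2 + 12e3, L / 2)
    quarter <- (pi / 2) / omega
    nsteps <- ceiling(quarter / (0.3 * g$dx / (omega * L / 2)))
    for (s in seq_len(nsteps)) C <- advect(C, fl, g, quarter / nsteps)
    exact <- patch(L / 2, L / 2 + 12e3)  # quarter turn counterclockwise
    mean(abs(C - exact))
  })
  expect_lt(err[2], err[1])
})

test_that("diffusion conserves mass, damps variance, equilibrates two boxes", {
  g <- small_grid()
  set.seed(5)
  C <- array(runif(g$nx * g$ny * g$nz), c(g$nx, g$ny, g$nz))
  expect_equal(diffuse(array(1, dim(C)), 10, 1e-5, g, 600),
               array(1, dim(C)))
  vol <- alborun:::cell_volumes(g)
  m0 <- sum(C * vol); v0 <- stats::var(as.vector(C))
  for (s in 1:50) C <- diffuse(C, 50, 1e-4, g, 600)
  expect_lt(abs(sum(C * vol) - m0) / m0, 1e-12)
  expect_lt(stats::var(as.vector(C)), v0)
  # two equal boxes approach the mean like exp(-2 kv t / (dz * dzw))
  g2 <- make_grid(1, 1, 2, 100, 100, 20, stretch = 0)
  C2 <- array(c(2, 0), c(1, 1, 2))
  kv <- 1e-4; dt <- 20; nst <- 500
  for (s in 1:nst) C2 <- diffuse(C2, 0, kv, g2, dt)
  lam <- 2 * kv / (10 * 10)
  expect_equal(C2[1, 1, 1], 1 + exp(-lam * nst * dt), tolerance = 1e-3)
  expect_equal(C2[1, 1, 2], 1 - exp(-lam * nst * dt), tolerance = 1e-3)
  expect_true(all(diff(sapply(1:5, function(i) {
    C2 <<- diffuse(C2, 0, kv, g2, dt); C2[1, 1, 1]
  })) < 0)) # monotone approach from above
  expect_error(diffuse(C2, 1e9, 0, g2, 600), "stability")
})

test_that("sinking moves detritus down conservatively and exports at depth", {
  g <- make_grid(2, 2, 4, 1e3, 1e3, 40, stretch = 0)
  p <- bio_params()
  z <- empty_tracers(g)
  out <- sink(z$D, g, p, 600)
  expect_equal(max(abs(out$D)), 0)
  expect_equal(max(abs(out$bottom_export)), 0)
  # first-order transfer from an occupied top layer
  D <- array(0, c(2, 2, 4)); D[, , 1] <- 1
  dt <- 600
  out <- sink(D, g, p, dt)
  wD <- sinking_velocity(1, p) / 86400
  expect_equal(out$D[1, 1, 2] * g$dz[2], wD * 1 * dt)
  # column conservation: change in column content = -export
  set.seed(6)
  D <- array(runif(16), c(2, 2, 4))
  col0 <- apply(D, c(1, 2), function(x) sum(x * g$dz))
  Dc <- D; expo <- matrix(0, 2, 2)
  for (s in 1:200) {
    out <- sink(Dc, g, p, 3600)
    Dc <- out$D; expo <- expo + out$bottom_export
  }
  col1 <- apply(Dc, c(1, 2), function(x) sum(x * g$dz))
  expect_equal(col1 - col0, -expo, tolerance = 1e-12)
  expect_true(all(Dc >= 0))
  expect_error(sink(D, g, p, 2e5), "sub-step")
})

test_that("land columns stay empty and transport respects the mask", {
  H <- matrix(100, 6, 5); H[3, 3] <- 0; H[4, 3] <- 40
  g <- make_grid(6, 5, 4, 2e3, 2e3, 100, stretch = 0, H = H)
  expect_equal(g$kmax[3, 3], 0L)
  expect_equal(g$kmax[4, 3], 1L) # only the 0-25 m layer is wet
  fx <- fixture_flows(g)
  set.seed(8)
  C <- empty_tracers(g, 1)$N * array(runif(120), c(6, 5, 4))
  C <- C * alborun:::wet_cells(g)
  vol <- alborun:::cell_volumes(g)
  m0 <- sum(C * vol)
  for (s in 1:20) {
    C <- advect(C, fx$gyre, g, 600)
    C <- diffuse(C, 20, 1e-4, g, 600)
  }
  expect_equal(sum(C[3, 3, ]), 0)
  expect_lt(abs(sum(C * vol) - m0) / m0, 1e-12)
})
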