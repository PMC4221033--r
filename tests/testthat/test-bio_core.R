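test_that("limitation factors match their closed forms and bounds", {
  p <- bio_params()
  # Michaelis-Menten nutrient limitation
  expect_equal(nutrient_limitation(0, p), 0)
  expect_equal(nutrient_limitation(p$K_N, p), 0.5)
  expect_equal(nutrient_limitation(1.5, p), 0.75) # 1.5 / (1.5 + 0.5)
  # saturating-exponential light response
  expect_equal(light_limitation(0, p), 0)
  expect_equal(light_limitation(1e9, p), 1)
  expect_equal(light_limitation(40, p), 1 - exp(-1.2))
  # bounds and monotonicity over a sweep
  N <- seq(0, 50, length.out = 200)
  fN <- nutrient_limitation(N, p)
  expect_true(all(fN >= 0 & fN < 1))
  expect_true(all(diff(fN) > 0))
  I <- seq(0, 500, length.out = 200)
  fI <- light_limitation(I, p)
  expect_true(all(fI >= 0 & fI <= 1))
  expect_true(all(diff(fI) > 0))
  # domain errors
  expect_error(nutrient_limitation(-0.1, p), ">= 0")
  expect_error(light_limitation(-1, p), ">= 0")
})

test_that("light profile attenuates by water and self-shading", {
  p <- bio_params()
  # pure water, closed form: I_s exp(-k_w z) at midpoints
  I <- light_profile(c(0, 0, 0), 10, p)
  expect_equal(I, 40 * exp(-0.05 * c(5, 15, 25)))
  # k_w * z = 1 at z = 20 m
  expect_equal(light_profile(c(0, 0), c(20, 20), p)[2],
               40 * exp(-0.05 * 30))
  # uniform P = 1: effective attenuation k_w + k_b = 0.09 m^-1
  I1 <- light_profile(rep(1, 4), 10, p)
  expect_equal(I1, 40 * exp(-0.09 * c(5, 15, 25, 35)))
  # strictly decreasing with depth
  set.seed(1)
  Irand <- light_profile(runif(20, 0, 3), runif(20, 1, 30), p)
  expect_true(all(diff(Irand) < 0))
  expect_error(light_profile(c(1, 1), c(10, -1), p), "positive")
  expect_error(light_profile(c(-1, 1), 10, p), ">= 0")
})

test_that("grazing has the shared-saturation form and its limits", {
  p <- bio_params()
  expect_equal(grazing(0, 0, 1, p), list(G_P = 0, G_D = 0))
  # defaults: G_P = 0.5*1*1/(0.5 + 1 + 0.25), G_D with a2 D on top
  gz <- grazing(1, 0.5, 1, p)
  expect_equal(gz$G_P, 0.5 / 1.75)
  expect_equal(gz$G_D, 0.125 / 1.75)
  # saturation of total specific grazing at r_Z
  gz <- grazing(1e12, 0, 1, p)
  expect_equal(gz$G_P, p$r_Z, tolerance = 1e-9)
  # bound (G_P + G_D) <= r_Z Z and linearity in Z at fixed food
  set.seed(7)
  P <- runif(100, 0, 10); D <- runif(100, 0, 10); Z <- runif(100, 0, 10)
  gz <- grazing(P, D, Z, p)
  expect_true(all(gz$G_P + gz$G_D <= p$r_Z * Z + 1e-12))
  gz2 <- grazing(P, D, 2 * Z, p)
  expect_equal(gz2$G_P + gz2$G_D, 2 * (gz$G_P + gz$G_D))
  expect_error(grazing(-1, 0, 0, p), ">= 0")
})

test_that("sinking velocity saturates at w_Dmax", {
  p <- bio_params()
  expect_equal(sinking_velocity(0, p), 0)
  expect_equal(sinking_velocity(1e12, p), 8, tolerance = 1e-9)
  expect_equal(sinking_velocity(p$S_D, p), 4) # half saturation
  D <- seq(0, 10, length.out = 100)
  expect_true(all(diff(sinking_velocity(D, p)) > 0))
  expect_error(sinking_velocity(-1, p), ">= 0")
})

test_that("source terms route fluxes as specified", {
  p <- bio_params()
  z0 <- source_terms(list(N = 0, P = 0, Z = 0, D = 0), 40, p)
  expect_equal(unlist(z0), c(dN = 0, dP = 0, dZ = 0, dD = 0))
  # remineralization only
  d1 <- source_terms(list(N = 0, P = 0, Z = 0, D = 1), 40, p)
  expect_equal(d1$dN, 0.25)
  expect_equal(d1$dD, -0.25)
  expect_equal(d1$dP, 0)
  expect_equal(d1$dZ, 0)
  # closure with Z = 1: sum of tendencies = -(1-beta) m_Z
  s <- source_terms(list(N = 2, P = 1.3, Z = 1, D = 0.4), 17, p)
  expect_equal(s$dN + s$dP + s$dZ + s$dD, -0.05)
})

test_that("nitrogen closure identity holds over a million random states", {
  p <- bio_params()
  n <- 1e6
  st <- random_state(n)
  I <- runif(n, 0, 100)
  d <- source_terms(st, I, p)
  resid <- d$dN + d$dP + d$dZ + d$dD + (1 - p$beta) * p$m_Z * st$Z^2
  scale <- pmax(abs(d$dN), abs(d$dP), abs(d$dZ), abs(d$dD), 1e-300)
  expect_lt(max(abs(resid) / scale), 1e-12)
})

test_that("parameter validation enforces ranges and defaults match print", {
  p <- bio_params()
  expect_equal(p$r_P, 1.3)
  expect_equal(p$w_Dmax, 8.0)
  expect_error(bio_params(K_N = -0.5), "K_N")
  expect_error(bio_params(gamma = 1.2), "gamma")
})
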