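# Shared fixtures: small grids and states built in code.

small_grid <- function(nx = 8, ny = 6, nz = 5, dx = 5e3, dy = 5e3,
                       depth = 200, stretch = 1) {
  make_grid(nx, ny, nz, dx, dy, depth, stretch)
}

# a grid fine enough to host the default Alboran-like jet quickly
flow_test_grid <- function() make_grid(40, 30, 10, 1e4, 1e4, 300)

# flow config with a jet wide enough for a 10-km grid
wide_jet_config <- function(...) flow_config(jet_width_km = 35, ...)

random_state <- function(n, seed = 42, max = 5) {
  set.seed(seed)
  list(N = runif(n, 0, max), P = runif(n, 0, max),
       Z = runif(n, 0, max), D = runif(n, 0, max))
}

total_mass <- function(tr, g) {
  vol <- alborun:::cell_volumes(g)
  sum(tr$N * vol) + sum(tr$P * vol) + sum(tr$Z * vol) + sum(tr$D * vol)
}
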