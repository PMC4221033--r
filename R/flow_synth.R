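#' Configuration of the synthetic jet-gyre flow
#'
#' Parameters of the idealized Alboran-like circulation: an eastward
#' meandering surface-intensified jet wrapped around two anticyclonic
#' gyres (a western, WAG-like, and an eastern, EAG-like one), with
#' localized ageostrophic vertical-velocity cells on the jet flanks.
#' Defaults reproduce the observed kinematics: a 15-20 km wide jet with
#' 0.7 m s^-1 surface speed near the inflow, confined to roughly the upper
#' 100 m, weakening to about half its strength by the eastern gyre, and
#' up/downwelling cells reaching 50 m day^-1 at 50 m depth.
#'
#' The meander phase default places the meander crests over the two gyre
#' centers so the jet arcs around their northern peripheries.
#'
#' @param jet_y0_km Mean latitude (y, km) of the jet axis.
#' @param jet_width_km Full jet width (km); the cross-jet speed profile is
#'   `sech^2` with scale half this width.
#' @param jet_speed_ms Target maximum surface current speed (m s^-1).
#' @param meander_amplitude_km,meander_wavelength_km,meander_phase
#'   Sinusoidal meander of the jet axis
#'   `y(x) = jet_y0 + A sin(2 pi x / lambda + phase)`.
#' @param taper_decay_km E-folding scale of the eastward weakening; the
#'   amplitude envelope is `0.5 + 0.5 exp(-x / taper_decay_km)`, i.e. the
#'   jet asymptotically loses half its strength downstream.
#' @param z_decay_m Vertical e-folding depth (m) of the horizontal flow.
#' @param gyres Data frame with one row per gyre: `x_km`, `y_km` (center),
#'   `radius_km`, `speed_ms` (peak azimuthal speed). Positive speeds give
#'   anticyclonic (clockwise) rotation.
#' @param w_max_mday Target maximum vertical speed (m day^-1).
#' @param w_depth_m Depth (m) at which `|w|` attains its maximum.
#' @param w_cell_sigma_km Gaussian radius (km) of each vertical-velocity
#'   cell.
#' @param w_cell_offset_km Cross-axis offset of the cells from the jet
#'   axis; default half the jet width (cells sit on the jet flanks).
#' @param edge_taper_km Width (km) of the smooth taper bringing the flow
#'   to rest at the closed lateral boundaries.
#' @param seed Integer seed for optional random meander-phase jitter.
#' @param phase_jitter Standard deviation (radians) of the optional
#'   random perturbation of the meander phase (0 = none, the default).
#' @return A `flow_config` object (named list).
#' @export
flow_config <- function(jet_y0_km = 150, jet_width_km = 17.5,
                        jet_speed_ms = 0.7,
                        meander_amplitude_km = 30,
                        meander_wavelength_km = 160,
                        meander_phase = pi / 2 - 2 * pi * 110 / 160,
                        taper_decay_km = 90, z_decay_m = 100,
                        gyres = data.frame(
                          x_km = c(110, 270), y_km = c(110, 115),
                          radius_km = c(55, 45), speed_ms = c(0.35, 0.30)),
                        w_max_mday = 50, w_depth_m = 50,
                        w_cell_sigma_km = 12,
                        w_cell_offset_km = jet_width_km / 2,
                        edge_taper_km = 25, seed = 1L, phase_jitter = 0) {
  stopifnot(jet_width_km > 0, jet_speed_ms >= 0, meander_wavelength_km > 0,
            z_decay_m > 0, w_max_mday >= 0, w_depth_m > 0,
            w_cell_sigma_km > 0, edge_taper_km >= 0,
            all(gyres$radius_km > 0), all(gyres$speed_ms >= 0),
            phase_jitter >= 0)
  structure(list(jet_y0_km = jet_y0_km, jet_width_km = jet_width_km,
                 jet_speed_ms = jet_speed_ms,
                 meander_amplitude_km = meander_amplitude_km,
                 meander_wavelength_km = meander_wavelength_km,
                 meander_phase = meander_phase,
                 taper_decay_km = taper_decay_km, z_decay_m = z_decay_m,
                 gyres = gyres, w_max_mday = w_max_mday,
                 w_depth_m = w_depth_m, w_cell_sigma_km = w_cell_sigma_km,
                 w_cell_offset_km = w_cell_offset_km,
                 edge_taper_km = edge_taper_km, seed = as.integer(seed),
                 phase_jitter = phase_jitter),
            class = "flow_config")
}

# f-plane planetary vorticity at 36 N (s^-1).
#' Coriolis parameter used on the f-plane (36 degrees N)
#' @export
f_coriolis <- function() 8.6e-5

SEC_PER_DAY <- 86400

# smoothstep window: 0 at the boundary, 1 beyond `taper` (m) inside.
edge_window <- function(coord, len, taper) {
  if (taper <= 0) return(rep(1, length(coord)))
  d <- pmin(coord, len - coord)
  t <- pmin(pmax(d / taper, 0), 1)
  t * t * (3 - 2 * t)
}

# jet axis y(x) in m; x in m
jet_axis <- function(x, cfg, phase = cfg$meander_phase) {
  1000 * (cfg$jet_y0_km + cfg$meander_amplitude_km *
            sin(2 * pi * x / (1000 * cfg$meander_wavelength_km) + phase))
}

# eastward amplitude taper (dimensionless, 1 at x=0 decaying to 1/2)
jet_taper <- function(x, cfg) {
  0.5 + 0.5 * exp(-pmax(x, 0) / (1000 * cfg$taper_decay_km))
}

# vertical profile of the w cells at interface depths: 0 at surface and
# bottom, peak exactly 1 at depth zp (C^1 piecewise sinusoid)
w_vertical_profile <- function(z, zp, H) {
  s <- ifelse(z <= zp, sin(pi * z / (2 * zp)),
              cos(pi * (z - zp) / (2 * (H - zp))))
  s[z >= H] <- 0
  s
}

#' Synthesize a divergence-free jet-gyre flow field
#'
#' Builds the three-dimensional velocity field on a C-staggered grid from
#' two analytic parts. The non-divergent part comes from a streamfunction
#' (meandering jet plus Gaussian anticyclones, tapered eastward, decaying
#' with depth, and brought smoothly to rest at the closed boundaries), so
#' its discrete horizontal divergence vanishes identically. The divergent
#' part comes from a velocity potential built of Gaussian cells placed on
#' the jet flanks by an arc-length rule: every half meander wavelength,
#' offset by half the jet width across the axis, upwelling on the
#' anticyclonic (southern) flank of trough-to-crest segments and
#' downwelling on the cyclonic flank of crest-to-trough segments. The
#' vertical velocity is obtained by discrete vertical integration of the
#' horizontal divergence from the surface (`w = 0` there), so the discrete
#' continuity equation holds cell by cell to round-off; the per-layer
#' potential coefficients are chosen so `w` vanishes again at the bottom
#' and peaks at the configured depth.
#'
#' Both parts are auto-scaled so the maximum surface speed and the maximum
#' `|w|` at the configured depth hit their targets within 0.1%.
#'
#' @param cfg A [flow_config()].
#' @param g A [make_grid()] grid; must resolve the jet width with at least
#'   3 cells and have no land.
#' @return A `flow_field` object: arrays `u` (`nx+1` x `ny` x `nz`), `v`
#'   (`nx` x `ny+1` x `nz`) in m s^-1, and `w` (`nx` x `ny` x `nz+1`,
#'   interface 1 at the surface) in m s^-1, positive upward, plus the
#'   generating `cfg`.
#' @examples
#' g <- make_grid(20, 15, 10, 2e4, 2e4, 300)
#' fl <- make_jet_gyre_flow(flow_config(jet_width_km = 70), g)
#' max(abs(flow_divergence(fl, g)))
#' @export
make_jet_gyre_flow <- function(cfg, g) {
  stopifnot(inherits(cfg, "flow_config"), inherits(g, "model_grid"))
  if (1000 * cfg$jet_width_km < 3 * max(g$dx, g$dy))
    stop("make_jet_gyre_flow: grid does not resolve the jet width with ",
         ">= 3 cells; refine the grid or widen the jet", call. = FALSE)
  if (any(g$kmax < g$nz))
    stop("make_jet_gyre_flow: flow synthesis requires an all-sea, ",
         "flat-bottom grid", call. = FALSE)
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  Lx <- nx * g$dx; Ly <- ny * g$dy; H <- max(g$z_w)
  phase <- cfg$meander_phase
  if (cfg$phase_jitter > 0) {
    set.seed(cfg$seed)
    phase <- phase + stats::rnorm(1, 0, cfg$phase_jitter)
  }

  # --- non-divergent part: streamfunction at cell corners -----------------
  xc <- (0:nx) * g$dx; yc <- (0:ny) * g$dy
  Ws <- 1000 * cfg$jet_width_km / 2
  yj <- jet_axis(xc, cfg, phase)
  Tx <- jet_taper(xc, cfg)
  # jet: u = -dpsi/dy = T U sech^2((y - yj)/Ws) eastward
  psi <- -outer(Tx * cfg$jet_speed_ms * Ws, rep(1, ny + 1)) *
    tanh(outer(-yj, yc, function(a, b) a + b) / Ws)
  for (gi in seq_len(nrow(cfg$gyres))) {
    gx <- 1000 * cfg$gyres$x_km[gi]; gy <- 1000 * cfg$gyres$y_km[gi]
    sg <- 0.6 * 1000 * cfg$gyres$radius_km[gi]
    A <- cfg$gyres$speed_ms[gi] * sg * exp(0.5)
    r2 <- outer((xc - gx)^2, (yc - gy)^2, "+")
    psi <- psi + A * exp(-r2 / (2 * sg^2))
  }
  win <- outer(edge_window(xc, Lx, 1000 * cfg$edge_taper_km),
               edge_window(yc, Ly, 1000 * cfg$edge_taper_km))
  psi <- psi * win
  hz <- exp(-g$z_mid / cfg$z_decay_m)
  u_psi <- array(0, c(nx + 1, ny, nz))
  v_psi <- array(0, c(nx, ny + 1, nz))
  du <- -(psi[, 2:(ny + 1), drop = FALSE] - psi[, 1:ny, drop = FALSE]) / g$dy
  dv <- (psi[2:(nx + 1), , drop = FALSE] - psi[1:nx, , drop = FALSE]) / g$dx
  for (k in seq_len(nz)) {
    u_psi[, , k] <- du * hz[k]
    v_psi[, , k] <- dv * hz[k]
  }

  # --- divergent part: up/downwelling cells on the jet flanks -------------
  # The target vertical-velocity pattern S(x, y) is a sum of discrete
  # Gaussian patches (no compensating rings: the return flow is left to
  # the broad, weak far field), balanced to zero net column exchange.
  # The divergent horizontal flow realizing it comes from a velocity
  # potential solved from the discrete Neumann Poisson problem
  # lap(Phi) = S on cell centers, so the staggered-face divergence
  # reproduces S up to solver round-off and the vertically integrated w
  # vanishes again at the bottom.
  xm <- (seq_len(nx) - 0.5) * g$dx  # cell centers
  ym <- (seq_len(ny) - 0.5) * g$dy
  lam <- 1000 * cfg$meander_wavelength_km
  # axis midline crossings: 2 pi x / lam + phase = m pi
  mrange <- ceiling(phase / pi) : floor((2 * pi * Lx / lam + phase) / pi)
  S <- matrix(0, nx, ny)
  sig <- 1000 * cfg$w_cell_sigma_km
  off <- 1000 * cfg$w_cell_offset_km
  for (m in mrange) {
    x0 <- (m * pi - phase) * lam / (2 * pi)
    if (x0 < 0 || x0 > Lx) next
    ascending <- cos(2 * pi * x0 / lam + phase) > 0
    y0 <- jet_axis(x0, cfg, phase)
    amp <- jet_taper(x0, cfg)
    if (ascending) {
      # trough -> crest: upwelling cell on the anticyclonic (south) flank
      yc0 <- y0 - off; sgn <- +1
    } else {
      # crest -> trough: downwelling cell on the cyclonic (north) flank
      yc0 <- y0 + off; sgn <- -1
    }
    if (yc0 < 0 || yc0 > Ly) next
    r2 <- outer((xm - x0)^2, (ym - yc0)^2, "+")
    S <- S + sgn * amp * exp(-r2 / (2 * sig^2))
  }
  S <- S * outer(edge_window(xm, Lx, 1000 * cfg$edge_taper_km),
                 edge_window(ym, Ly, 1000 * cfg$edge_taper_km))
  # balance the up and down cells so the basin exchanges no net volume
  spos <- sum(S[S > 0]); sneg <- -sum(S[S < 0])
  if (spos > 0 && sneg > 0) {
    S[S < 0] <- S[S < 0] * spos / sneg
    S <- S - mean(S)
  }
  # per-layer coefficients c_k so that w(z) follows the target profile
  s_w <- w_vertical_profile(g$z_w, cfg$w_depth_m, H)
  ck <- diff(s_w) / g$dz
  u_div <- array(0, c(nx + 1, ny, nz))
  v_div <- array(0, c(nx, ny + 1, nz))
  if (cfg$w_max_mday > 0 && any(S != 0)) {
    Phi <- solve_neumann_poisson(S, g)
    dPx <- (Phi[2:nx, , drop = FALSE] - Phi[1:(nx - 1), , drop = FALSE]) / g$dx
    dPy <- (Phi[, 2:ny, drop = FALSE] - Phi[, 1:(ny - 1), drop = FALSE]) / g$dy
    for (k in seq_len(nz)) {
      u_div[2:nx, , k] <- dPx * ck[k]
      v_div[, 2:ny, k] <- dPy * ck[k]
    }
    # scale so max |w| at the interface nearest the configured depth hits
    # the target (w depends linearly on the potential amplitude)
    w_raw <- integrate_w(u_div, v_div, g)
    kd <- which.min(abs(g$z_w - cfg$w_depth_m))
    mx <- max(abs(w_raw[, , kd]))
    if (mx > 0) {
      sc <- (cfg$w_max_mday / SEC_PER_DAY) / mx
      u_div <- u_div * sc
      v_div <- v_div * sc
    }
  }

  # --- calibrate the surface speed of the rotational part -----------------
  surf_speed <- function(scale) {
    us <- scale * u_psi[, , 1] + u_div[, , 1]
    vs <- scale * v_psi[, , 1] + v_div[, , 1]
    ucc <- (us[1:nx, ] + us[2:(nx + 1), ]) / 2
    vcc <- (vs[, 1:ny] + vs[, 2:(ny + 1)]) / 2
    max(sqrt(ucc^2 + vcc^2))
  }
  target <- cfg$jet_speed_ms
  if (target > 0 && surf_speed(1) > 0) {
    sc <- stats::uniroot(function(s) surf_speed(s) - target,
                         lower = 0, upper = 20, tol = 1e-12)$root
  } else sc <- 0
  u <- sc * u_psi + u_div
  v <- sc * v_psi + v_div
  w <- integrate_w(u, v, g)
  structure(list(u = u, v = v, w = w, cfg = cfg), class = "flow_field")
}

# Solve lap(Phi) = S with no-flux (Neumann) boundaries on cell centers,
# using exactly the staggered-face gradient/divergence operators of the
# grid, so that the face velocities built from Phi reproduce S as their
# discrete divergence. The singular Neumann system (S sums to zero) is
# closed by pinning the first node.
solve_neumann_poisson <- function(S, g) {
  nx <- g$nx; ny <- g$ny
  n <- nx * ny
  id <- function(i, j) i + nx * (j - 1)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(a, b, w) {
    ii <<- c(ii, a); jj <<- c(jj, b); vv <<- c(vv, w)
  }
  ix <- 1 / g$dx^2; iy <- 1 / g$dy^2
  # assemble by interior faces (vectorized over face lists)
  if (nx > 1) {
    i <- rep(1:(nx - 1), ny); j <- rep(1:ny, each = nx - 1)
    a <- id(i, j); b <- id(i + 1, j)
    add(c(a, b, a, b), c(a, b, b, a), c(rep(-ix, 2 * length(a)),
                                        rep(ix, 2 * length(a))))
  }
  if (ny > 1) {
    i <- rep(1:nx, ny - 1); j <- rep(1:(ny - 1), each = nx)
    a <- id(i, j); b <- id(i, j + 1)
    add(c(a, b, a, b), c(a, b, b, a), c(rep(-iy, 2 * length(a)),
                                        rep(iy, 2 * length(a))))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  rhs <- as.vector(S)
  # pin node 1 to remove the Neumann null space
  A[1, ] <- 0; A[1, 1] <- 1; rhs[1] <- 0
  matrix(as.vector(Matrix::solve(A, rhs)), nx, ny)
}

# discrete vertical integration of -div_h from the surface; returns w
# (m/s, positive up) on interfaces, so continuity holds exactly per cell
integrate_w <- function(u, v, g) {
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  w <- array(0, c(nx, ny, nz + 1))
  for (k in seq_len(nz)) {
    divh <- (matrix(u[2:(nx + 1), , k], nx, ny) -
               matrix(u[1:nx, , k], nx, ny)) / g$dx +
      (matrix(v[, 2:(ny + 1), k], nx, ny) -
         matrix(v[, 1:ny, k], nx, ny)) / g$dy
    w[, , k + 1] <- w[, , k] + g$dz[k] * divh
  }
  w
}

#' @export
print.flow_field <- function(x, ...) {
  nx <- dim(x$w)[1]; ny <- dim(x$w)[2]
  us <- (x$u[1:nx, , 1] + x$u[2:(nx + 1), , 1]) / 2
  vs <- (x$v[, 1:ny, 1] + x$v[, 2:(ny + 1), 1]) / 2
  cat(sprintf("flow_field: %d x %d x %d; max surface speed %.3f m/s, max |w| %.1f m/day\n",
              nx, ny, dim(x$u)[3], max(sqrt(us^2 + vs^2)),
              max(abs(x$w)) * SEC_PER_DAY))
  invisible(x)
}

#' Discrete divergence of a flow field
#'
#' Cell-by-cell discrete divergence (s^-1): the quantity guaranteed to be
#' at round-off level for every synthesized field.
#'
#' @param flow A `flow_field`.
#' @param g The grid it lives on.
#' @return Array of dim `c(nx, ny, nz)`.
#' @export
flow_divergence <- function(flow, g) {
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  d <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    d[, , k] <- (matrix(flow$u[2:(nx + 1), , k], nx, ny) -
                   matrix(flow$u[1:nx, , k], nx, ny)) / g$dx +
      (matrix(flow$v[, 2:(ny + 1), k], nx, ny) -
         matrix(flow$v[, 1:ny, k], nx, ny)) / g$dy +
      (matrix(flow$w[, , k], nx, ny) -
         matrix(flow$w[, , k + 1], nx, ny)) / g$dz[k]
  }
  d
}

#' Normalized relative vorticity at the surface
#'
#' Vertical component of the relative vorticity of the surface layer,
#' `(dv/dx - du/dy) / f`, from centered differences of cell-centered
#' velocities (one-sided at the domain edges). Magnitudes approaching 0.5
#' indicate strongly nonlinear, ageostrophic flow (Rossby number ~ 0.5).
#'
#' @param flow A `flow_field`.
#' @param g The grid.
#' @param f Planetary vorticity (s^-1); default the 36 N f-plane value.
#' @return Matrix `nx` x `ny` of zeta/f.
#' @export
relative_vorticity <- function(flow, g, f = f_coriolis()) {
  nx <- g$nx; ny <- g$ny
  uc <- (flow$u[1:nx, , 1] + flow$u[2:(nx + 1), , 1]) / 2
  vc <- (flow$v[, 1:ny, 1] + flow$v[, 2:(ny + 1), 1]) / 2
  ddx <- function(M) {
    out <- M
    if (nx > 2) out[2:(nx - 1), ] <- (M[3:nx, ] - M[1:(nx - 2), ]) / (2 * g$dx)
    out[1, ] <- (M[2, ] - M[1, ]) / g$dx
    out[nx, ] <- (M[nx, ] - M[nx - 1, ]) / g$dx
    out
  }
  ddy <- function(M) {
    out <- M
    if (ny > 2) out[, 2:(ny - 1)] <- (M[, 3:ny] - M[, 1:(ny - 2)]) / (2 * g$dy)
    out[, 1] <- (M[, 2] - M[, 1]) / g$dy
    out[, ny] <- (M[, ny] - M[, ny - 1]) / g$dy
    out
  }
  (ddx(vc) - ddy(uc)) / f
}

#' Simple reference flows for transport tests
#'
#' A named set of analytically simple flow fields on a given grid: `zero`
#' (rest), `channel` (uniform eastward `u`), `rotation` (solid-body
#' rotation about the domain center, brought to rest near the boundaries),
#' and `gyre` (a single Gaussian anticyclone). All are discretely
#' divergence-free with `w = 0`.
#'
#' @param g A [make_grid()] grid.
#' @param u_channel Channel speed (m s^-1).
#' @param omega Solid-body angular rate (s^-1).
#' @param edge_taper_km Boundary taper applied to `rotation` and `gyre`.
#' @return Named list of `flow_field` objects.
#' @export
fixture_flows <- function(g, u_channel = 0.1, omega = 1e-5,
                          edge_taper_km = 0) {
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  zeroflow <- structure(list(u = array(0, c(nx + 1, ny, nz)),
                             v = array(0, c(nx, ny + 1, nz)),
                             w = array(0, c(nx, ny, nz + 1)),
                             cfg = NULL), class = "flow_field")
  channel <- zeroflow
  channel$u[] <- u_channel
  from_psi <- function(psi) {
    u <- array(0, c(nx + 1, ny, nz)); v <- array(0, c(nx, ny + 1, nz))
    du <- -(psi[, 2:(ny + 1)] - psi[, 1:ny]) / g$dy
    dv <- (psi[2:(nx + 1), ] - psi[1:nx, ]) / g$dx
    for (k in seq_len(nz)) { u[, , k] <- du; v[, , k] <- dv }
    structure(list(u = u, v = v, w = array(0, c(nx, ny, nz + 1)),
                   cfg = NULL), class = "flow_field")
  }
  xc <- (0:nx) * g$dx; yc <- (0:ny) * g$dy
  Lx <- nx * g$dx; Ly <- ny * g$dy
  win <- outer(edge_window(xc, Lx, 1000 * edge_taper_km),
               edge_window(yc, Ly, 1000 * edge_taper_km))
  r2 <- outer((xc - Lx / 2)^2, (yc - Ly / 2)^2, "+")
  rotation <- from_psi(0.5 * omega * r2 * win)
  sg <- min(Lx, Ly) / 6
  gyre <- from_psi(0.2 * sg * exp(0.5) * exp(-r2 / (2 * sg^2)) * win)
  list(zero = zeroflow, channel = channel, rotation = rotation, gyre = gyre)
}
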