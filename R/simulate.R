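#' One coupled transport-biology step
#'
#' Advances the four tracer fields over `dt` seconds by operator
#' splitting in the fixed order advection, diffusion, detritus sinking,
#' biology. Advection and diffusion are sub-stepped internally to satisfy
#' their stability limits; the biology is integrated with an RK4 sub-step
#' (at most `dt_bio_days` long) whose scaled-tendency limiter prevents
#' any pool from crossing zero, and the irradiance profile is recomputed
#' from the evolving phytoplankton column at every stage.
#'
#' @param state A `tracer_fields` list (`N`, `P`, `Z`, `D`).
#' @param flow A `flow_field` on the same grid.
#' @param g The [make_grid()] grid.
#' @param p A [bio_params()] set.
#' @param dt Step length (s).
#' @param kappa_h,kappa_v Diffusivities (m^2 s^-1). The horizontal
#'   default is half the 20 m^2 s^-1 constant viscosity of the parent
#'   circulation model; the vertical default is its stated minimum.
#' @param dt_bio_days Maximum biological sub-step (days).
#' @param scheme Advection scheme, see [advect()].
#' @param sinking Logical; include detritus sinking.
#' @param biology Logical; include the biological source terms.
#' @param n_adv,n_dif Advective / diffusive sub-step counts; computed
#'   from the stability limits when `NULL`. A steady-flow driver can
#'   precompute them once.
#' @return List with `state` (updated), `bottom_export` (`nx` x `ny`
#'   matrix, mmol N m^-2 this step), `closure_loss` (same shape; the
#'   permanent (1-beta) mortality loss), and `clamp_mass` (mmol N added
#'   by negativity clamps, normally 0).
#' @export
step_tracers <- function(state, flow, g, p, dt, kappa_h = 10,
                         kappa_v = 1e-6, dt_bio_days = 0.05,
                         scheme = "superbee", sinking = TRUE,
                         biology = TRUE, n_adv = NULL, n_dif = NULL) {
  for (nm in c("N", "P", "Z", "D"))
    if (anyNA(state[[nm]]))
      stop("step_tracers: NaN detected in ", nm, call. = FALSE)
  if (is.null(n_adv)) {
    cfl <- max(cfl_number(flow, g, dt))
    n_adv <- max(1L, ceiling(cfl / 0.45))
  }
  st <- adv4_step_cpp(state$N, state$P, state$Z, state$D, flow$u, flow$v,
                      flow$w, g$nx, g$ny, g$nz, g$dx, g$dy, g$dz, g$kmax,
                      dt / n_adv, if (scheme == "superbee") 1L else 0L,
                      as.integer(n_adv))
  state[c("N", "P", "Z", "D")] <- st[c("N", "P", "Z", "D")]
  if (is.null(n_dif))
    n_dif <- max(1L, ceiling(diffusion_stability(kappa_h, kappa_v, g, dt) / 0.9))
  st <- diff4_step_cpp(state$N, state$P, state$Z, state$D, g$nx, g$ny,
                       g$nz, g$dx, g$dy, g$dz, g$z_mid, g$kmax, kappa_h,
                       kappa_v, dt / n_dif, as.integer(n_dif))
  state[c("N", "P", "Z", "D")] <- st[c("N", "P", "Z", "D")]
  expo <- matrix(0, g$nx, g$ny)
  if (sinking) {
    n_snk <- max(1L, ceiling((p$w_Dmax / 86400) * dt / (0.9 * min(g$dz))))
    for (s in seq_len(n_snk)) {
      sk <- sink(state$D, g, p, dt / n_snk)
      state$D <- sk$D
      expo <- expo + sk$bottom_export
    }
  }
  closure <- matrix(0, g$nx, g$ny)
  clamp <- 0
  if (biology) {
    dt_days <- dt / 86400
    nsub <- max(1L, ceiling(dt_days / dt_bio_days))
    bs <- bio_step_cpp(state$N, state$P, state$Z, state$D,
                       g$nx, g$ny, g$nz, g$dz, g$kmax,
                       bio_params_vector(p), dt_days, nsub,
                       g$dx * g$dy)
    state$N <- bs$N; state$P <- bs$P; state$Z <- bs$Z; state$D <- bs$D
    closure <- matrix(bs$closure_map, g$nx, g$ny)
    clamp <- bs$clamp_mass
  }
  list(state = state, bottom_export = expo, closure_loss = closure,
       clamp_mass = clamp)
}

#' 0-D box integration of the biological model
#'
#' Integrates the source-sink terms at fixed irradiance with an
#' error-controlled solver ([deSolve::ode()], lsoda). The verification
#' harness for the plankton closures: no transport, no sinking. Two
#' budget accumulators are carried along: the time integral of the
#' quadratic zooplankton mortality flux, and the permanent closure loss
#' `(1 - beta)` of it, so routing fractions can be recovered from a run.
#'
#' @param p A [bio_params()] set.
#' @param I Irradiance (W m^-2), held fixed.
#' @param init Named numeric with `N`, `P`, `Z`, `D` (mmol N m^-3).
#' @param t_end Integration length (days).
#' @param dt Output interval (days).
#' @param rtol,atol Solver tolerances.
#' @return Data frame with columns `time, N, P, Z, D, mz_integral,
#'   closure_loss, total_N` (the running `N+P+Z+D`).
#' @examples
#' ts <- run_box(bio_params(), I = 40,
#'               init = c(N = 2, P = 0.1, Z = 0.1, D = 0), t_end = 10)
#' tail(ts, 1)
#' @export
run_box <- function(p, I, init, t_end, dt = 0.25, rtol = 1e-10,
                    atol = 1e-12) {
  y0 <- c(N = unname(init["N"]), P = unname(init["P"]),
          Z = unname(init["Z"]), D = unname(init["D"]),
          mz_integral = 0, closure_loss = 0)
  rhs <- function(t, y, parms) {
    st <- list(N = max(y[1], 0), P = max(y[2], 0),
               Z = max(y[3], 0), D = max(y[4], 0))
    d <- source_terms(st, I, p)
    mz <- p$m_Z * st$Z^2
    list(c(d$dN, d$dP, d$dZ, d$dD, mz, (1 - p$beta) * mz))
  }
  times <- unique(c(seq(0, t_end, by = dt), t_end))
  out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  out$total_N <- out$N + out$P + out$Z + out$D
  out
}

#' Surface-speed jet-core mask
#'
#' Cells whose surface current speed exceeds a threshold, used to turn
#' "inside the meandering jet" into a definite region.
#'
#' @param flow A `flow_field`.
#' @param g The grid.
#' @param threshold Speed threshold (m s^-1).
#' @return Logical `nx` x `ny` matrix.
#' @export
jet_core_mask <- function(flow, g, threshold = 0.3) {
  nx <- g$nx; ny <- g$ny
  uc <- (matrix(flow$u[1:nx, , 1], nx, ny) +
           matrix(flow$u[2:(nx + 1), , 1], nx, ny)) / 2
  vc <- (matrix(flow$v[, 1:ny, 1], nx, ny) +
           matrix(flow$v[, 2:(ny + 1), 1], nx, ny)) / 2
  sqrt(uc^2 + vc^2) > threshold
}

#' Gyre-interior mask
#'
#' Cells within a fraction of each configured gyre radius of its center:
#' the quiescent anticyclone cores that should stay oligotrophic.
#'
#' @param cfg A [flow_config()] (its `gyres` table).
#' @param g The grid.
#' @param fraction Fraction of the gyre radius (default one half).
#' @return Logical `nx` x `ny` matrix.
#' @export
gyre_interior_mask <- function(cfg, g, fraction = 0.5) {
  xm <- (seq_len(g$nx) - 0.5) * g$dx
  ym <- (seq_len(g$ny) - 0.5) * g$dy
  m <- matrix(FALSE, g$nx, g$ny)
  for (gi in seq_len(nrow(cfg$gyres))) {
    r2 <- outer((xm - 1000 * cfg$gyres$x_km[gi])^2,
                (ym - 1000 * cfg$gyres$y_km[gi])^2, "+")
    m <- m | (r2 <= (fraction * 1000 * cfg$gyres$radius_km[gi])^2)
  }
  m
}

#' Run the full coupled simulation
#'
#' Integrates the nutrient-starved scenario under the synthetic jet-gyre
#' flow for the configured number of days, storing snapshots and a
#' nitrogen budget record at the snapshot days. Deterministic: the same
#' configuration (including its seed) reproduces the output bit for bit.
#'
#' @param cfg A [run_config()] (or a config file path, which is passed
#'   through [load_config()]).
#' @param flow Optional externally supplied `flow_field` (otherwise
#'   synthesized from `cfg$flow`).
#' @param quiet Suppress per-snapshot progress lines.
#' @return A `run_output` object: `snapshots` (named list of
#'   `tracer_fields` by day), `budget` (data frame: time, inventories of
#'   N/P/Z/D in mmol N, cumulative bottom export, closure loss, clamp
#'   mass, and the budget residual), `bottom_export` / `closure_loss`
#'   cumulative maps (mmol N m^-2), the `grid`, `flow`, `config`, and
#'   `config_hash`.
#' @export
run_simulation <- function(cfg, flow = NULL, quiet = TRUE) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  g <- do.call(make_grid, cfg$grid)
  p <- do.call(bio_params, cfg$bio)
  sc <- do.call(scenario_config, cfg$scenario)
  if (is.null(flow)) {
    fcfg <- do.call(flow_config, cfg$flow)
    flow <- make_jet_gyre_flow(fcfg, g)
  }
  num <- cfg$numerics
  state <- initial_state(g, sc)
  vol <- cell_volumes(g)
  area <- g$dx * g$dy
  inv <- function(a) sum(a * vol)
  total0 <- inv(state$N) + inv(state$P) + inv(state$Z) + inv(state$D)

  dt <- num$dt_s
  n_steps <- round(sc$run_days * 86400 / dt)
  if (abs(n_steps * dt - sc$run_days * 86400) > 1e-6)
    stop("run_simulation: dt_s must divide the run length", call. = FALSE)
  snap_steps <- round(sc$snapshot_days * 86400 / dt)

  expo <- matrix(0, g$nx, g$ny)
  closure <- matrix(0, g$nx, g$ny)
  clamp <- 0
  snapshots <- list()
  budget <- NULL
  record <- function(day) {
    tN <- inv(state$N); tP <- inv(state$P)
    tZ <- inv(state$Z); tD <- inv(state$D)
    ex <- sum(expo) * area; cl <- sum(closure) * area
    total <- tN + tP + tZ + tD
    resid <- (total - total0 + ex + cl - clamp) /
      max(total0, total, ex + cl)
    rbind(budget, data.frame(time = day, N = tN, P = tP, Z = tZ, D = tD,
                             export = ex, closure = cl, clamp = clamp,
                             residual = resid))
  }
  budget <- record(0)
  n_adv <- max(1L, ceiling(max(cfl_number(flow, g, dt)) / 0.45))
  n_dif <- max(1L, ceiling(diffusion_stability(num$kappa_h, num$kappa_v,
                                               g, dt) / 0.9))
  for (s in seq_len(n_steps)) {
    st <- step_tracers(state, flow, g, p, dt, kappa_h = num$kappa_h,
                       kappa_v = num$kappa_v,
                       dt_bio_days = num$dt_bio_days,
                       scheme = num$scheme, sinking = num$sinking,
                       biology = num$biology, n_adv = n_adv,
                       n_dif = n_dif)
    state <- st$state
    expo <- expo + st$bottom_export
    closure <- closure + st$closure_loss
    clamp <- clamp + st$clamp_mass
    if (s %in% snap_steps) {
      day <- s * dt / 86400
      snapshots[[sprintf("day%g", day)]] <- state
      budget <- record(day)
      if (!quiet)
        message(sprintf("day %g: residual %.2e", day,
                        budget$residual[nrow(budget)]))
    }
  }
  structure(list(snapshots = snapshots, budget = budget,
                 bottom_export = expo, closure_loss = closure,
                 clamp_mass = clamp, grid = g, flow = flow, bio = p,
                 scenario = sc, config = cfg,
                 config_hash = config_hash(cfg)),
            class = "run_output")
}

#' @export
print.run_output <- function(x, ...) {
  b <- x$budget[nrow(x$budget), ]
  cat(sprintf("run_output: %d snapshots, day %g\n",
              length(x$snapshots), b$time))
  cat(sprintf("  final inventories (mmol N): N %.3e P %.3e Z %.3e D %.3e\n",
              b$N, b$P, b$Z, b$D))
  cat(sprintf("  cumulative export %.3e, closure loss %.3e, residual %.2e\n",
              b$export, b$closure, b$residual))
  invisible(x)
}
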