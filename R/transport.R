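#' Courant numbers of a flow on a grid
#'
#' Per-cell total Courant number `(|u|/dx + |v|/dy + |w|/dz) dt` used to
#' decide advective sub-stepping.
#'
#' @param flow A `flow_field`.
#' @param g The grid.
#' @param dt Time step (s).
#' @return Array of dim `c(nx, ny, nz)`.
#' @export
cfl_number <- function(flow, g, dt) {
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  out <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    umax <- pmax(abs(matrix(flow$u[1:nx, , k], nx, ny)),
                 abs(matrix(flow$u[2:(nx + 1), , k], nx, ny)))
    vmax <- pmax(abs(matrix(flow$v[, 1:ny, k], nx, ny)),
                 abs(matrix(flow$v[, 2:(ny + 1), k], nx, ny)))
    wmax <- pmax(abs(matrix(flow$w[, , k], nx, ny)),
                 abs(matrix(flow$w[, , k + 1], nx, ny)))
    out[, , k] <- dt * (umax / g$dx + vmax / g$dy + wmax / g$dz[k])
  }
  out
}

#' Advect a tracer field
#'
#' One conservative finite-volume advection step under a prescribed flow,
#' using donor-cell upwinding with an optional superbee flux limiter
#' (a TVD second-order correction). Fluxes through the domain boundary,
#' land, and the bottom are zero, so total tracer mass is conserved to
#' round-off in the closed domain; under a discretely divergence-free
#' flow a uniform field is reproduced exactly.
#'
#' @param C Tracer array of dim `c(nx, ny, nz)` (mmol N m^-3).
#' @param flow A `flow_field` on the same grid.
#' @param g The [make_grid()] grid.
#' @param dt Time step (s). The total Courant number must not exceed 1 in
#'   any cell; otherwise an error asks for sub-stepping.
#' @param scheme `"superbee"` (default) or `"upwind"` (first order).
#' @return Updated tracer array.
#' @export
advect <- function(C, flow, g, dt, scheme = c("superbee", "upwind")) {
  scheme <- match.arg(scheme)
  stopifnot(all(dim(C) == c(g$nx, g$ny, g$nz)))
  cfl <- max(cfl_number(flow, g, dt))
  if (cfl > 1 + 1e-12)
    stop(sprintf(paste0("advect: Courant number %.3f exceeds 1; sub-step ",
                        "the advection (use at least %d sub-steps)"),
                 cfl, ceiling(cfl)), call. = FALSE)
  adv_step_cpp(C, flow$u, flow$v, flow$w, g$nx, g$ny, g$nz, g$dx, g$dy,
               g$dz, g$kmax, dt, if (scheme == "superbee") 1L else 0L)
}

#' Diffuse a tracer field
#'
#' One explicit step of horizontal plus vertical Laplacian diffusion with
#' no-flux boundaries. Mass-conserving; variance non-increasing.
#'
#' @param C Tracer array of dim `c(nx, ny, nz)`.
#' @param kappa_h Horizontal diffusivity (m^2 s^-1).
#' @param kappa_v Vertical diffusivity (m^2 s^-1).
#' @param g The grid.
#' @param dt Time step (s); the explicit stability limit
#'   `dt (2 kh/dx^2 + 2 kh/dy^2 + 2 kv/dz_min^2) <= 1` must hold.
#' @return Updated tracer array.
#' @export
diffuse <- function(C, kappa_h, kappa_v, g, dt) {
  stopifnot(all(dim(C) == c(g$nx, g$ny, g$nz)), kappa_h >= 0, kappa_v >= 0)
  s <- diffusion_stability(kappa_h, kappa_v, g, dt)
  if (s > 1 + 1e-12)
    stop(sprintf(paste0("diffuse: explicit stability number %.3f exceeds ",
                        "1; sub-step the diffusion"), s), call. = FALSE)
  diff_step_cpp(C, g$nx, g$ny, g$nz, g$dx, g$dy, g$dz, g$z_mid, g$kmax,
                kappa_h, kappa_v, dt)
}

diffusion_stability <- function(kappa_h, kappa_v, g, dt) {
  dz_min <- min(g$dz)
  dt * (2 * kappa_h / g$dx^2 + 2 * kappa_h / g$dy^2 +
          2 * kappa_v / dz_min^2)
}

#' Sink detritus through the water column
#'
#' One upwind (donor = layer above) vertical sinking step using the
#' concentration-dependent [sinking_velocity()] evaluated per cell. The
#' flux through the bottom of each column is returned as export so the
#' nitrogen budget closes.
#'
#' @param D Detritus array of dim `c(nx, ny, nz)` (mmol N m^-3).
#' @param g The grid.
#' @param p A [bio_params()] set (`S_D`, `w_Dmax`).
#' @param dt Time step (s); `w_Dmax dt` must not exceed the thinnest
#'   layer.
#' @return List with `D` (updated array) and `bottom_export`
#'   (`nx` x `ny` matrix, mmol N m^-2 exported this step).
#' @export
sink <- function(D, g, p, dt) {
  stopifnot(all(dim(D) == c(g$nx, g$ny, g$nz)))
  w_ms <- p$w_Dmax / 86400
  if (w_ms * dt > min(g$dz) + 1e-12)
    stop("sink: w_Dmax * dt exceeds the thinnest layer; sub-step",
         call. = FALSE)
  out <- sink_step_cpp(D, g$nx, g$ny, g$nz, g$dz, g$kmax, p$S_D, w_ms, dt)
  list(D = out$D, bottom_export = matrix(out$export, g$nx, g$ny))
}
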