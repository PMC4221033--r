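#' Rectangular z-coordinate model grid
#'
#' Builds the fixed-depth (rigid-lid) rectangular mesh the tracer and flow
#' fields live on. Coordinates: `x` eastward, `y` northward, `z` positive
#' downward with layer index 1 at the surface. Tracers are cell-centered;
#' velocities live on cell faces (Arakawa C staggering): `u` on x-faces
#' (`nx+1` x `ny` x `nz`), `v` on y-faces, `w` on horizontal interfaces
#' (`nx` x `ny` x `nz+1`, interface 1 at the surface).
#'
#' Layers may be stretched so that spacing is finer near the surface:
#' interface depths follow `H * (exp(s k/nz) - 1) / (exp(s) - 1)` for
#' stretching factor `s > 0` (equidistant when `s = 0`).
#'
#' @param nx,ny,nz Number of cells in x, y, z.
#' @param dx,dy Horizontal spacings (m).
#' @param depth Water-column depth `H` (m) of the deepest columns.
#' @param stretch Vertical stretching factor (0 = uniform layers).
#' @param H Optional per-column static depth (m), an `nx` x `ny` matrix;
#'   columns shallower than `depth` have their lowest layers masked dry.
#'   Default: flat bottom at `depth` everywhere.
#' @return An object of class `model_grid` with elements `nx, ny, nz, dx,
#'   dy`, interface depths `z_w` (length `nz+1`), midpoints `z_mid`,
#'   thicknesses `dz`, per-column wet layer count `kmax` (`nx` x `ny`
#'   integer matrix), and the land/sea `mask` (`kmax > 0`).
#' @examples
#' g <- make_grid(nx = 10, ny = 8, nz = 5, dx = 1e4, dy = 1e4, depth = 100)
#' g$dz
#' @export
make_grid <- function(nx, ny, nz, dx, dy, depth, stretch = 2, H = NULL) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dy > 0, depth > 0,
            stretch >= 0)
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  dx <- as.numeric(dx); dy <- as.numeric(dy)
  depth <- as.numeric(depth); stretch <- as.numeric(stretch)
  k <- 0:nz
  z_w <- if (stretch == 0) depth * k / nz
         else depth * (exp(stretch * k / nz) - 1) / (exp(stretch) - 1)
  dz <- diff(z_w)
  z_mid <- z_w[-(nz + 1)] + dz / 2
  if (is.null(H)) H <- matrix(depth, nx, ny)
  stopifnot(is.matrix(H), nrow(H) == nx, ncol(H) == ny, all(H >= 0))
  # wet layer count: deepest interface not below the column depth
  kmax <- matrix(vapply(H, function(h) sum(z_w[-1] <= h + 1e-9), 1L),
                 nx, ny)
  structure(list(nx = nx, ny = ny, nz = nz, dx = dx, dy = dy,
                 z_w = z_w, z_mid = z_mid, dz = dz, H = H,
                 kmax = kmax, mask = kmax > 0L),
            class = "model_grid")
}

#' @export
print.model_grid <- function(x, ...) {
  cat(sprintf("model_grid: %d x %d x %d cells, dx=%g m, dy=%g m, depth %g m\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, max(x$H)))
  cat(sprintf("  layer thickness %.2f m (surface) to %.2f m (bottom)\n",
              x$dz[1], x$dz[x$nz]))
  invisible(x)
}

# 3-D logical array of wet cells.
wet_cells <- function(g) {
  outer3 <- array(FALSE, c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) outer3[, , k] <- g$kmax >= k
  outer3
}

# Cell volumes (m^3) as an [nx, ny, nz] array (dry cells get 0).
cell_volumes <- function(g) {
  v <- array(0, c(g$nx, g$ny, g$nz))
  w <- wet_cells(g)
  for (k in seq_len(g$nz)) v[, , k] <- g$dx * g$dy * g$dz[k] * w[, , k]
  v
}

#' Empty tracer field set on a grid
#'
#' @param g A [make_grid()] grid.
#' @param value Fill value for wet cells (dry cells are 0).
#' @return List of arrays `N`, `P`, `Z`, `D` of dim `c(nx, ny, nz)`,
#'   class `tracer_fields`.
#' @export
empty_tracers <- function(g, value = 0) {
  w <- wet_cells(g)
  a <- array(0, c(g$nx, g$ny, g$nz))
  a[w] <- value
  structure(list(N = a, P = a, Z = a, D = a), class = "tracer_fields")
}
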