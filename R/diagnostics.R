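#' Depth-integrate a tracer field
#'
#' Layer-thickness-weighted vertical sum from the surface down to `z_max`
#' (m), including the partial top fraction of the layer straddling
#' `z_max`. With the 75 m winter euphotic-layer convention this yields
#' the euphotic inventory maps (mmol N m^-2).
#'
#' @param field Tracer array of dim `c(nx, ny, nz)` (mmol N m^-3).
#' @param g The [make_grid()] grid.
#' @param z_max Integration depth (m); must lie within the water column.
#' @return `nx` x `ny` matrix (mmol N m^-2).
#' @examples
#' g <- make_grid(4, 3, 4, 1e4, 1e4, 100, stretch = 0)
#' depth_integrate(empty_tracers(g, 1)$N, g, 75)  # 75 everywhere
#' @export
depth_integrate <- function(field, g, z_max) {
  stopifnot(all(dim(field) == c(g$nx, g$ny, g$nz)))
  if (z_max <= 0 || z_max > max(g$z_w) + 1e-9)
    stop("depth_integrate: z_max outside the water column", call. = FALSE)
  out <- matrix(0, g$nx, g$ny)
  for (k in seq_len(g$nz)) {
    top <- g$z_w[k]; bot <- g$z_w[k + 1]
    if (top >= z_max) break
    frac <- (min(bot, z_max) - top)
    out <- out + matrix(field[, , k], g$nx, g$ny) * frac
  }
  out
}

#' Transect specification
#'
#' A polyline in domain coordinates along which vertical sections are
#' sampled.
#'
#' @param vertices_km Two-column matrix (x, y in km) of polyline
#'   vertices; at least two.
#' @param interval_km Sampling interval along the line (km).
#' @return A `transect_spec` object.
#' @export
transect_spec <- function(vertices_km, interval_km = 5) {
  vertices_km <- as.matrix(vertices_km)
  stopifnot(ncol(vertices_km) == 2, nrow(vertices_km) >= 2,
            interval_km > 0)
  structure(list(vertices_km = vertices_km, interval_km = interval_km),
            class = "transect_spec")
}

#' Default analysis transect
#'
#' A polyline crossing the western gyre diagonally (southwest to
#' northeast through its center) and then running zonally across the
#' eastern gyre, built from the configured gyre geometry.
#'
#' @param cfg A [flow_config()].
#' @param g The grid (to clip the line to the domain).
#' @param interval_km Sampling interval (km).
#' @return A [transect_spec()].
#' @export
default_transect <- function(cfg, g, interval_km = 5) {
  gy <- cfg$gyres
  lx <- g$nx * g$dx / 1000; ly <- g$ny * g$dy / 1000
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  d1 <- 0.9 * gy$radius_km[1]
  v <- rbind(c(gy$x_km[1] - d1, gy$y_km[1] - d1),
             c(gy$x_km[1] + d1, gy$y_km[1] + d1),
             c(gy$x_km[2] - gy$radius_km[2], gy$y_km[2]),
             c(gy$x_km[2] + 1.2 * gy$radius_km[2], gy$y_km[2]))
  v[, 1] <- clip(v[, 1], g$dx / 2000, lx - g$dx / 2000)
  v[, 2] <- clip(v[, 2], g$dy / 2000, ly - g$dy / 2000)
  transect_spec(v, interval_km)
}

#' Extract a vertical section along a transect
#'
#' Samples a tracer field at regular intervals along a polyline using
#' bilinear horizontal interpolation of cell-centered values (exact for
#' fields linear in x and y), at every layer. Distance is cumulative
#' along the polyline.
#'
#' @param field Tracer array of dim `c(nx, ny, nz)`.
#' @param g The grid.
#' @param t A [transect_spec()]; vertices must lie inside the domain.
#' @return List with `distance_km` (sample positions), `z_mid` (layer
#'   midpoints, m), and `section` (distance x depth matrix).
#' @export
extract_transect <- function(field, g, t) {
  stopifnot(inherits(t, "transect_spec"),
            all(dim(field) == c(g$nx, g$ny, g$nz)))
  v <- t$vertices_km * 1000
  lx <- g$nx * g$dx; ly <- g$ny * g$dy
  if (any(v[, 1] < 0 | v[, 1] > lx | v[, 2] < 0 | v[, 2] > ly))
    stop("extract_transect: vertex outside the domain", call. = FALSE)
  # sample points along the polyline
  seg <- diff(v)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  dist <- if (total == 0) 0 else
    unique(c(seq(0, total, by = t$interval_km * 1000), total))
  cum <- c(0, cumsum(seg_len))
  pts <- vapply(dist, function(d) {
    i <- max(which(cum <= d + 1e-9)); i <- min(i, nrow(seg))
    frac <- if (seg_len[i] == 0) 0 else (d - cum[i]) / seg_len[i]
    v[i, ] + frac * seg[i, ]
  }, numeric(2))
  xs <- pts[1, ]; ys <- pts[2, ]
  # bilinear interpolation on cell centers (clamped at the edges)
  fi <- pmin(pmax(xs / g$dx + 0.5, 1), g$nx)
  fj <- pmin(pmax(ys / g$dy + 0.5, 1), g$ny)
  i0 <- pmin(floor(fi), g$nx - 1); i0[g$nx == 1] <- 1
  j0 <- pmin(floor(fj), g$ny - 1); j0[g$ny == 1] <- 1
  tx <- fi - i0; ty <- fj - j0
  i1 <- pmin(i0 + 1, g$nx); j1 <- pmin(j0 + 1, g$ny)
  sec <- matrix(0, length(dist), g$nz)
  for (k in seq_len(g$nz)) {
    M <- matrix(field[, , k], g$nx, g$ny)
    sec[, k] <- (1 - tx) * (1 - ty) * M[cbind(i0, j0)] +
      tx * (1 - ty) * M[cbind(i1, j0)] +
      (1 - tx) * ty * M[cbind(i0, j1)] +
      tx * ty * M[cbind(i1, j1)]
  }
  list(distance_km = dist / 1000, z_mid = g$z_mid, section = sec)
}

#' Plankton biomass field
#'
#' Phytoplankton plus zooplankton, elementwise; detritus is excluded by
#' definition.
#'
#' @param fields A `tracer_fields` list.
#' @return Array of the same shape as the inputs (mmol N m^-3).
#' @export
plankton_biomass <- function(fields) {
  fields$P + fields$Z
}

#' Nitrogen budget record of a run
#'
#' Recomputes the compartment inventories at every stored snapshot by
#' volume-weighted summation and combines them with the run's cumulative
#' bottom export and closure-loss accumulators; the residual
#' `|change in inventory + losses|` (relative) quantifies conservation.
#'
#' @param run A [run_simulation()] output.
#' @param g Grid (defaults to the run's own).
#' @return Data frame: `time`, inventories `N, P, Z, D` (mmol N),
#'   cumulative `export` and `closure` losses, `clamp` repair mass, and
#'   the relative `residual` at each snapshot.
#' @export
nitrogen_budget <- function(run, g = run$grid) {
  vol <- cell_volumes(g)
  rows <- lapply(seq_len(nrow(run$budget)), function(r) {
    day <- run$budget$time[r]
    if (day == 0) return(run$budget[r, ])
    snap <- run$snapshots[[sprintf("day%g", day)]]
    if (is.null(snap)) return(run$budget[r, ])
    out <- run$budget[r, ]
    out$N <- sum(snap$N * vol); out$P <- sum(snap$P * vol)
    out$Z <- sum(snap$Z * vol); out$D <- sum(snap$D * vol)
    total0 <- sum(run$budget[1, c("N", "P", "Z", "D")])
    total <- out$N + out$P + out$Z + out$D
    out$residual <- (total - total0 + out$export + out$closure -
                       out$clamp) / max(total0, total)
    out
  })
  do.call(rbind, rows)
}

#' Quick-look map of a depth-integrated field
#'
#' Presentation-only helper: an image of an `nx` x `ny` map (e.g. from
#' [depth_integrate()]) in domain kilometers. All quantitative analysis
#' should read the numeric fields directly.
#'
#' @param map `nx` x `ny` matrix.
#' @param g The grid.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return The map, invisibly.
#' @export
plot_field <- function(map, g, main = "", ...) {
  x <- (seq_len(g$nx) - 0.5) * g$dx / 1000
  y <- (seq_len(g$ny) - 0.5) * g$dy / 1000
  graphics::image(x, y, map, xlab = "x (km)", ylab = "y (km)",
                  main = main, col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(map)
}

#' Quick-look vertical section along a transect
#'
#' Presentation-only helper for [extract_transect()] output; depth is
#' drawn increasing downward.
#'
#' @param sec List from [extract_transect()].
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return `sec`, invisibly.
#' @export
plot_section <- function(sec, main = "", ...) {
  graphics::image(sec$distance_km, sec$z_mid, sec$section,
                  ylim = rev(range(sec$z_mid)),
                  xlab = "distance (km)", ylab = "depth (m)",
                  main = main, col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(sec)
}
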