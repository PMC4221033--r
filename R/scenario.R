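#' Scenario configuration: the nutrient-starved initial state
#'
#' Parameters of the biological initial condition and run reporting. The
#' defaults reproduce the study setup: nitrate identically zero in the
#' upper 100 m (the initial profile is reduced so the euphotic layer holds
#' no nitrate at all), rising linearly to a deep climatological value by
#' 250 m; small seed phytoplankton and zooplankton stocks confined to the
#' upper 100 m; no initial detritus. With closed lateral boundaries, any
#' plankton production beyond the seed is then attributable solely to
#' vertical (diapycnal) nutrient supply from below.
#'
#' The deep nitrate value is a configurable stand-in for the unpublished
#' climatological profile and should be treated as a sensitivity axis.
#'
#' @param euphotic_depth_m Depth (m) of the euphotic-layer integration
#'   used by the diagnostics (winter convention, 75 m).
#' @param nitrate_zero_depth_m Depth (m) above which initial nitrate is
#'   exactly zero.
#' @param deep_nitrate Deep nitrate concentration (mmol N m^-3).
#' @param ramp_depth_m Depth (m) at which nitrate reaches `deep_nitrate`
#'   (linear ramp from `nitrate_zero_depth_m`).
#' @param seed_P,seed_Z Seed phytoplankton / zooplankton concentrations
#'   (mmol N m^-3).
#' @param seed_depth_m Depth extent (m) of the seed populations.
#' @param init_D Initial detritus concentration (mmol N m^-3).
#' @param run_days Integration length (days).
#' @param snapshot_days Days at which tracer snapshots are stored.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(euphotic_depth_m = 75,
                            nitrate_zero_depth_m = 100,
                            deep_nitrate = 8.0, ramp_depth_m = 250,
                            seed_P = 0.05, seed_Z = 0.05,
                            seed_depth_m = 100, init_D = 0,
                            run_days = 120,
                            snapshot_days = c(30, 60, 90, 120)) {
  stopifnot(euphotic_depth_m > 0, nitrate_zero_depth_m >= 0,
            ramp_depth_m > nitrate_zero_depth_m, deep_nitrate >= 0,
            seed_P >= 0, seed_Z >= 0, seed_depth_m >= 0, init_D >= 0,
            run_days > 0, all(snapshot_days > 0),
            all(snapshot_days <= run_days))
  structure(list(euphotic_depth_m = euphotic_depth_m,
                 nitrate_zero_depth_m = nitrate_zero_depth_m,
                 deep_nitrate = deep_nitrate, ramp_depth_m = ramp_depth_m,
                 seed_P = seed_P, seed_Z = seed_Z,
                 seed_depth_m = seed_depth_m, init_D = init_D,
                 run_days = run_days,
                 snapshot_days = sort(unique(snapshot_days))),
            class = "scenario_config")
}

#' Initial nitrate profile
#'
#' Exactly zero above the nitrate-zero depth, then a linear ramp to the
#' configured deep value by the ramp depth, constant below: monotone
#' non-decreasing with depth.
#'
#' @param depths Depths (m, positive down, sorted increasing) at which to
#'   evaluate, typically layer midpoints.
#' @param cfg A [scenario_config()].
#' @return Nitrate concentrations (mmol N m^-3), one per depth.
#' @examples
#' initial_nitrate_profile(c(50, 150, 250, 400), scenario_config())
#' @export
initial_nitrate_profile <- function(depths, cfg = scenario_config()) {
  stopifnot(!is.unsorted(depths))
  z0 <- cfg$nitrate_zero_depth_m; z1 <- cfg$ramp_depth_m
  frac <- pmin(pmax((depths - z0) / (z1 - z0), 0), 1)
  cfg$deep_nitrate * frac
}

#' Initial tracer state on a grid
#'
#' Nitrate from [initial_nitrate_profile()] at layer midpoints; seed
#' phytoplankton and zooplankton in the layers whose midpoints lie above
#' the seed depth; detritus at its initial value; everything zero on land.
#'
#' @param g A [make_grid()] grid.
#' @param cfg A [scenario_config()].
#' @return A `tracer_fields` list (`N`, `P`, `Z`, `D` arrays).
#' @export
initial_state <- function(g, cfg = scenario_config()) {
  tr <- empty_tracers(g)
  wc <- wet_cells(g)
  nprof <- initial_nitrate_profile(g$z_mid, cfg)
  for (k in seq_len(g$nz)) {
    tr$N[, , k] <- nprof[k] * wc[, , k]
    if (g$z_mid[k] <= cfg$seed_depth_m) {
      tr$P[, , k] <- cfg$seed_P * wc[, , k]
      tr$Z[, , k] <- cfg$seed_Z * wc[, , k]
    }
    tr$D[, , k] <- cfg$init_D * wc[, , k]
  }
  tr
}
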