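default_numerics <- function() {
  list(dt_s = 1800, dt_bio_days = 0.05, kappa_h = 10, kappa_v = 1e-6,
       scheme = "superbee", sinking = TRUE, biology = TRUE)
}

default_grid <- function() {
  list(nx = 80, ny = 60, nz = 20, dx = 5000, dy = 5000, depth = 300,
       stretch = 2)
}

block_defaults <- function() {
  list(grid = default_grid(),
       flow = unclass(flow_config()),
       scenario = lapply(formals(scenario_config), eval),
       bio = lapply(formals(bio_params), eval),
       numerics = default_numerics())
}

merge_block <- function(block, defaults, override) {
  if (is.null(override)) return(defaults)
  if (!is.list(override))
    stop("load_config: block '", block, "' must be a mapping",
         call. = FALSE)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop("load_config: unknown key '", bad[1], "' in block '", block,
         "'", call. = FALSE)
  utils::modifyList(defaults, override)
}

#' Build a full run configuration
#'
#' Assembles and validates the nested configuration driving
#' [run_simulation()]: blocks `grid`, `flow`, `scenario`, `bio`,
#' `numerics`, plus an integer `seed` (used only by optional random flow
#' perturbations). Every omitted key takes its default — the published
#' parameter value wherever one is printed — and unknown keys are
#' rejected by name. Validation runs eagerly through the block
#' constructors, so e.g. a negative `K_N` fails here with a message
#' naming `K_N`.
#'
#' @param grid,flow,scenario,bio,numerics Named lists of overrides for
#'   the corresponding block ([make_grid()], [flow_config()],
#'   [scenario_config()], [bio_params()], and the stepping controls
#'   `dt_s`, `dt_bio_days`, `kappa_h`, `kappa_v`, `scheme`, `sinking`,
#'   `biology`).
#' @param seed Integer random seed recorded in the configuration.
#' @return A validated `run_config` object (all defaults filled in).
#' @export
run_config <- function(grid = list(), flow = list(), scenario = list(),
                       bio = list(), numerics = list(), seed = 1L) {
  defs <- block_defaults()
  if (!is.null(flow$gyres) && !is.data.frame(flow$gyres))
    flow$gyres <- as.data.frame(lapply(flow$gyres, unlist))
  cfg <- list(grid = merge_block("grid", defs$grid, grid),
              flow = merge_block("flow", defs$flow, flow),
              scenario = merge_block("scenario", defs$scenario, scenario),
              bio = merge_block("bio", defs$bio, bio),
              numerics = merge_block("numerics", defs$numerics, numerics),
              seed = as.integer(seed))
  cfg$flow$seed <- cfg$seed
  # eager validation through the constructors
  do.call(make_grid, cfg$grid)
  do.call(flow_config, cfg$flow)
  do.call(scenario_config, cfg$scenario)
  do.call(bio_params, cfg$bio)
  stopifnot(cfg$numerics$dt_s > 0, cfg$numerics$dt_bio_days > 0,
            cfg$numerics$kappa_h >= 0, cfg$numerics$kappa_v >= 0,
            cfg$numerics$scheme %in% c("superbee", "upwind"),
            is.logical(cfg$numerics$sinking),
            is.logical(cfg$numerics$biology))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Reads the documented plain-text (YAML) configuration format, fills
#' defaults, validates the schema (unknown keys are rejected by name),
#' and computes the provenance hash. An empty file yields the full
#' default configuration.
#'
#' @param path Path to a YAML file with any of the blocks `grid`,
#'   `flow`, `scenario`, `bio`, `numerics` and a scalar `seed`.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("grid", "flow", "scenario", "bio", "numerics", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("load_config: unknown top-level key '", bad[1], "'",
         call. = FALSE)
  run_config(grid = raw$grid %||% list(), flow = raw$flow %||% list(),
             scenario = raw$scenario %||% list(),
             bio = raw$bio %||% list(),
             numerics = raw$numerics %||% list(),
             seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Provenance hash of a configuration
#'
#' MD5 of the canonical (fully defaulted, key-sorted, 17-significant-
#' digit) YAML rendering of a `run_config`; identical configurations
#' hash identically regardless of how they were specified.
#'
#' @param cfg A [run_config()].
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.data.frame(x)) x <- as.list(x)
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      return(lapply(x, canon))
    }
    if (is.numeric(x)) return(format(x, digits = 17))
    x
  }
  txt <- yaml::as.yaml(canon(unclass(cfg)))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a simulation output to disk
#'
#' Writes a `run_output` as a self-describing plain-text bundle in a
#' directory: `meta.yaml` (configuration, its hash, software version,
#' grid shape), `fields.csv` (long format: time, variable, i, j, k,
#' value), `budget.csv`, and the cumulative `export` / `closure` maps.
#' Values are formatted with 17 significant digits so a read-back
#' reproduces every double bit-exactly.
#'
#' @param run A [run_simulation()] output.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_output <- function(run, path) {
  stopifnot(inherits(run, "run_output"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  g <- run$grid
  meta <- list(config_hash = run$config_hash,
               package_version = as.character(utils::packageVersion("alborun")),
               grid_dims = c(g$nx, g$ny, g$nz),
               snapshot_days = as.numeric(sub("day", "",
                                              names(run$snapshots))),
               units = list(concentration = "mmol N m-3",
                            inventory = "mmol N",
                            export = "mmol N m-2"),
               config = canonical_config_list(run$config))
  yaml::write_yaml(meta, file.path(path, "meta.yaml"), precision = 17)
  rows <- list()
  for (nm in names(run$snapshots)) {
    day <- as.numeric(sub("day", "", nm))
    snap <- run$snapshots[[nm]]
    for (var in c("N", "P", "Z", "D")) {
      a <- snap[[var]]
      rows[[paste(nm, var)]] <- data.frame(
        time = day, var = var,
        i = rep(seq_len(g$nx), times = g$ny * g$nz),
        j = rep(rep(seq_len(g$ny), each = g$nx), times = g$nz),
        k = rep(seq_len(g$nz), each = g$nx * g$ny),
        value = fmt17(as.vector(a)))
    }
  }
  utils::write.csv(do.call(rbind, rows), file.path(path, "fields.csv"),
                   row.names = FALSE, quote = FALSE)
  b <- run$budget
  for (cc in setdiff(names(b), "time")) b[[cc]] <- fmt17(b[[cc]])
  utils::write.csv(b, file.path(path, "budget.csv"), row.names = FALSE,
                   quote = FALSE)
  maps <- data.frame(i = rep(seq_len(g$nx), times = g$ny),
                     j = rep(seq_len(g$ny), each = g$nx),
                     export = fmt17(as.vector(run$bottom_export)),
                     closure = fmt17(as.vector(run$closure_loss)))
  utils::write.csv(maps, file.path(path, "maps.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

canonical_config_list <- function(cfg) {
  x <- unclass(cfg)
  x$flow$gyres <- as.list(x$flow$gyres)
  x
}

#' Read back a simulation output bundle
#'
#' Inverse of [write_output()]: reconstructs the snapshots, budget
#' table, and cumulative maps (bit-exactly) plus the stored metadata.
#'
#' @param path Directory written by [write_output()].
#' @return List with `snapshots`, `budget`, `bottom_export`,
#'   `closure_loss`, `meta`.
#' @export
read_output <- function(path) {
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  d <- meta$grid_dims
  f <- utils::read.csv(file.path(path, "fields.csv"),
                       colClasses = c("numeric", "character", "integer",
                                      "integer", "integer", "numeric"))
  snapshots <- list()
  for (day in sort(unique(f$time))) {
    snap <- list()
    fd <- f[f$time == day, ]
    for (var in c("N", "P", "Z", "D")) {
      v <- fd$value[fd$var == var]
      snap[[var]] <- array(v, dim = d)
    }
    snapshots[[sprintf("day%g", day)]] <-
      structure(snap, class = "tracer_fields")
  }
  budget <- utils::read.csv(file.path(path, "budget.csv"))
  maps <- utils::read.csv(file.path(path, "maps.csv"))
  list(snapshots = snapshots, budget = budget,
       bottom_export = matrix(maps$export, d[1], d[2]),
       closure_loss = matrix(maps$closure, d[1], d[2]),
       meta = meta)
}
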