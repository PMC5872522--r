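#' Default run configuration
#'
#' The nested configuration consumed by [read_config()] and the CLI. The
#' defaults are the full-scale baseline condition: the 150 x 150 x 100
#' lattice at 20 um spacing, the baseline probabilities and adhesion
#' strength, density-matched initial counts for 30000 skin and 5000
#' melanoma cells, a four-day run, and 26-connectivity nest analysis with
#' the 4-agent filter. `seed` has no default: every run must state one.
#'
#' @return Nested list with blocks `geometry`, `parameters`, `initial`,
#'   `run`, `analysis`.
#' @export
default_config <- function() {
  list(
    geometry = list(nx = 150L, ny = 150L, nz = 100L, delta_um = 20),
    parameters = list(tau_h = 0.01, Pm_m = 0.075, Pm_s = 0.3,
                      Pp_m = 4e-4, Pp_s = 2.5e-4, q = 0.7),
    initial = list(N_s0 = 9549L, N_m0 = 1592L),
    run = list(duration_h = 96, snapshot_every_steps = 0L, seed = NULL),
    analysis = list(connectivity = 26L, min_agents = 4L,
                    area_convention = "count"))
}

validate_config <- function(config) {
  def <- default_config()
  for (block in names(config)) {
    if (!block %in% names(def))
      warning("unknown config block: ", block, call. = FALSE)
    else {
      unknown <- setdiff(names(config[[block]]), names(def[[block]]))
      if (length(unknown))
        warning("unknown config key(s) in ", block, ": ",
                paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  merged <- def
  for (block in intersect(names(config), names(def)))
    merged[[block]][names(config[[block]])] <- config[[block]]
  g <- merged$geometry
  lattice_geometry(g$nx, g$ny, g$nz, g$delta_um)   # range checks
  p <- merged$parameters
  model_parameters(p$tau_h, g$delta_um, p$Pm_m, p$Pm_s, p$Pp_m, p$Pp_s, p$q)
  if (is.null(merged$run$seed))
    stop("config must set run$seed", call. = FALSE)
  stopifnot(merged$initial$N_s0 >= 0, merged$initial$N_m0 >= 0,
            merged$run$duration_h >= 0,
            merged$analysis$connectivity %in% c(6L, 26L),
            merged$analysis$min_agents >= 1,
            merged$analysis$area_convention %in% c("count", "projected"))
  merged
}

#' Read and validate a run configuration
#'
#' YAML configuration with blocks `geometry`, `parameters`, `initial`,
#' `run` and `analysis`; unspecified keys take the [default_config()]
#' values, unknown keys raise a warning, and a missing `run: seed` is an
#' error. Out-of-range values (probabilities outside \[0, 1\], `q > 1`,
#' non-positive lattice sizes) are rejected.
#'
#' @param path Path to a YAML file.
#' @return The validated, fully populated configuration list.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_geometry <- function(config) {
  g <- config$geometry
  lattice_geometry(g$nx, g$ny, g$nz, g$delta_um)
}

config_parameters <- function(config) {
  p <- config$parameters
  model_parameters(tau = p$tau_h, delta = config$geometry$delta_um,
                   Pm_m = p$Pm_m, Pm_s = p$Pm_s,
                   Pp_m = p$Pp_m, Pp_s = p$Pp_s, q = p$q)
}

#' Write / read an agent snapshot as CSV
#'
#' One row per agent with columns `step`, `t_hours`, `agent_id`, `species`,
#' `i`, `j`, `k` (0-based sites); the header is always written, so an empty
#' state round-trips as a header-only file. Reading restores the snapshot
#' data frame; pass `geom` to reattach the geometry.
#'
#' @param snapshot A snapshot data frame (as produced by [seed_surface()]
#'   or [simulate_ibm()]).
#' @param path Output CSV path.
#' @return `write_snapshot()` returns the path invisibly; `read_snapshot()`
#'   returns the snapshot data frame.
#' @export
write_snapshot <- function(snapshot, path) {
  out <- data.frame(step = rep(attr(snapshot, "step") %||% 0L,
                               nrow(snapshot)),
                    t_hours = rep(attr(snapshot, "t_hours") %||% 0,
                                  nrow(snapshot)),
                    agent_id = snapshot$agent_id,
                    species = snapshot$species,
                    i = snapshot$i, j = snapshot$j, k = snapshot$k)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_snapshot
#' @param geom Optional [lattice_geometry()] to attach on read.
#' @export
read_snapshot <- function(path, geom = NULL) {
  df <- utils::read.csv(path, colClasses = c(
    step = "integer", t_hours = "numeric", agent_id = "integer",
    species = "character", i = "integer", j = "integer", k = "integer"))
  snap <- df[, c("agent_id", "species", "i", "j", "k")]
  attr(snap, "step") <- if (nrow(df)) df$step[1] else 0L
  attr(snap, "t_hours") <- if (nrow(df)) df$t_hours[1] else 0
  if (!is.null(geom)) attr(snap, "geom") <- geom
  snap
}

#' Write a nest table and summary
#'
#' @param analysis Output of [analyze_nests()].
#' @param nests_path CSV path for the per-nest table.
#' @param summary_path Optional JSON path for the area summary.
#' @return `nests_path` invisibly.
#' @export
write_nest_table <- function(analysis, nests_path, summary_path = NULL) {
  cols <- c("label", "n_agents", "area_um2", "area_mm2",
            "centroid_i", "centroid_j", "centroid_k")
  utils::write.csv(analysis$nests[, cols], nests_path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(summary_path)) {
    s <- analysis$summary
    jsonlite::write_json(
      list(n_nests = s$n_nests, median_um2 = s$median, q1_um2 = s$q1,
           q3_um2 = s$q3, whisker_lo_um2 = s$whisker_lo,
           whisker_hi_um2 = s$whisker_hi, outliers_um2 = s$outliers),
      summary_path, auto_unbox = TRUE, digits = NA, null = "null",
      na = "null")
  }
  invisible(nests_path)
}

#' Deterministic fixture snapshots for tests and demos
#'
#' Hand-constructed agent configurations on a 20 x 20 x 12 lattice
#' (`delta = 20` um):
#' * `two_blocks` — two 2 x 2 x 2 melanoma cubes separated by several
#'   vacant sites: two 8-agent nests.
#' * `diagonal_pair` — two melanoma agents touching only diagonally: one
#'   nest under 26-connectivity, two under 6-connectivity.
#' * `triplet_and_quad` — melanoma clusters of sizes 3 and 4: the 4-agent
#'   filter keeps exactly one.
#' * `enclosed_agent` — a melanoma agent whose 26 Moore neighbours are all
#'   melanoma (adhesion count a = 26).
#' * `mixed_neighbourhood` — a melanoma agent with 3 skin and 2 melanoma
#'   Moore neighbours (a = 2).
#'
#' @param name Fixture name.
#' @return A snapshot data frame with a `geom` attribute.
#' @export
make_fixture <- function(name = c("two_blocks", "diagonal_pair",
                                  "triplet_and_quad", "enclosed_agent",
                                  "mixed_neighbourhood")) {
  name <- match.arg(name)
  geom <- lattice_geometry(20, 20, 12)
  cube <- function(i0, j0, k0, n = 2)
    expand.grid(i = i0:(i0 + n - 1), j = j0:(j0 + n - 1),
                k = k0:(k0 + n - 1))
  sites <- switch(name,
    two_blocks = {
      s <- rbind(cube(2, 2, 2), cube(10, 10, 6))
      s$species <- "melanoma"
      s
    },
    diagonal_pair = data.frame(i = c(5, 6), j = c(5, 6), k = c(5, 6),
                               species = "melanoma"),
    triplet_and_quad = {
      s <- data.frame(i = c(2, 3, 4, 10, 11, 12, 13),
                      j = c(5, 5, 5, 8, 8, 8, 8),
                      k = c(0, 0, 0, 0, 0, 0, 0))
      s$species <- "melanoma"
      s
    },
    enclosed_agent = {
      s <- cube(4, 4, 4, 3)       # 3x3x3 block, centre at (5,5,5)
      s$species <- "melanoma"
      s
    },
    mixed_neighbourhood = {
      data.frame(i = c(5, 6, 4, 5, 6, 5),
                 j = c(5, 5, 5, 6, 6, 4),
                 k = c(5, 5, 5, 5, 5, 5),
                 species = c("melanoma", "melanoma", "melanoma",
                             "skin", "skin", "skin"))
    })
  snap <- data.frame(agent_id = seq_len(nrow(sites)),
                     species = sites$species,
                     i = as.integer(sites$i), j = as.integer(sites$j),
                     k = as.integer(sites$k))
  attr(snap, "geom") <- geom
  attr(snap, "t_hours") <- 0
  attr(snap, "step") <- 0L
  snap
}

#' Write a plain-text run log
#'
#' Records the configuration digest, seed, package version and the
#' engine's per-phase event tallies (attempted = aborted + succeeded in
#' each phase).
#'
#' @param result An `ibm_result` from [simulate_ibm()].
#' @param path Log file path.
#' @param config Optional configuration list to digest into the log.
#' @param seed The seed the run used.
#' @return `path` invisibly.
#' @export
write_run_log <- function(result, path, config = NULL, seed = NA) {
  m <- result$tallies$motility
  p <- result$tallies$proliferation
  lines <- c(
    sprintf("melnest %s", as.character(utils::packageVersion("melnest"))),
    sprintf("seed: %s", seed),
    sprintf("config_hash: %s",
            if (is.null(config)) "none"
            else sum(utf8ToInt(paste(deparse(config), collapse = "")))),
    sprintf("lattice: %d x %d x %d, delta = %g um",
            result$geom$nx, result$geom$ny, result$geom$nz,
            result$geom$delta),
    sprintf("steps: %d (t = %g h)", result$n_steps,
            result$n_steps * result$params$tau),
    sprintf("motility: attempted=%d gate=%d adhesion=%d boundary=%d crowding=%d moved=%d",
            m[["attempted"]], m[["aborted_gate"]], m[["aborted_adhesion"]],
            m[["aborted_boundary"]], m[["aborted_crowding"]], m[["moved"]]),
    sprintf("proliferation: attempted=%d gate=%d crowding=%d births=%d",
            p[["attempted"]], p[["aborted_gate"]], p[["aborted_crowding"]],
            p[["births"]]))
  writeLines(lines, path)
  invisible(path)
}
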