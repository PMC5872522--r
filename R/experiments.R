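#' Scenario specification for nest-formation experiments
#'
#' Named perturbations of the baseline co-culture condition:
#' * `baseline` — the reference parameter set ([model_parameters()]).
#' * `no_melanoma_proliferation` — `Pp_m = 0`, emulating gamma-irradiated
#'   (non-proliferative) melanoma cells.
#' * `half_proliferation` — melanoma proliferation probability halved
#'   (`Pp_m = 2e-4`).
#' * `half_adhesion` — adhesion strength halved (`q = 0.35`).
#' * `custom` — supply `overrides` explicitly.
#'
#' @param name Scenario name (see above).
#' @param N_m0 Initial melanoma agent count at full scale (a 3 mm x 3 mm
#'   surface); scaled automatically for reduced geometries by
#'   [run_scenario()]. Defaults to the density-matched equivalent of 5000
#'   experimental melanoma cells.
#' @param N_s0 Initial skin agent count at full scale.
#' @param overrides Named list of [model_parameters()] fields replacing
#'   baseline values (used with `name = "custom"`, or to extend a named
#'   scenario).
#' @param replicates Number of stochastic replicates.
#' @param seeds Integer seeds, one per replicate.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("baseline", "no_melanoma_proliferation",
                                   "half_proliferation", "half_adhesion",
                                   "custom"),
                          N_m0 = density_matched_count(5000),
                          N_s0 = density_matched_count(30000),
                          overrides = list(),
                          replicates = 5,
                          seeds = seq_len(replicates)) {
  name <- match.arg(name)
  preset <- switch(name,
                   baseline = list(),
                   no_melanoma_proliferation = list(Pp_m = 0),
                   half_proliferation = list(Pp_m = 2e-4),
                   half_adhesion = list(q = 0.35),
                   custom = list())
  preset[names(overrides)] <- overrides
  stopifnot(length(seeds) == replicates)
  structure(list(name = name, N_m0 = as.integer(N_m0),
                 N_s0 = as.integer(N_s0), overrides = preset,
                 replicates = as.integer(replicates),
                 seeds = as.integer(seeds)),
            class = "scenario_spec")
}

scenario_parameters <- function(spec, base = model_parameters()) {
  p <- unclass(base)
  p[names(spec$overrides)] <- spec$overrides
  do.call(model_parameters, p)
}

#' Scale a full-surface agent count to a reduced lattice
#'
#' Initial counts are quoted for the full 3 mm x 3 mm surface; on a
#' reduced lattice they are scaled by the surface-area ratio so the seeding
#' density is preserved (to within one agent).
#'
#' @param n Full-scale agent count.
#' @param geom Target [lattice_geometry()].
#' @param full_side_um Full-scale surface side length, um.
#' @return Integer scaled count.
#' @export
scale_count <- function(n, geom, full_side_um = 3000) {
  frac <- (geom$nx * geom$delta) * (geom$ny * geom$delta) / full_side_um^2
  as.integer(round(n * frac))
}

#' Run one scenario over replicates
#'
#' Seeds the surface with the (geometry-scaled) skin and melanoma counts,
#' runs the simulation for `duration_h` hours per replicate, and applies
#' the nest quantification to each final snapshot. The default geometry,
#' 75 x 75 x 60 sites (1.5 mm x 1.5 mm x 1.2 mm), is a quarter-surface
#' reduction of the full domain that preserves seeding density and local
#' cluster statistics while keeping run time modest; pass
#' `geom = lattice_geometry()` for the full 150 x 150 x 100 domain.
#'
#' @param spec A [scenario_spec()].
#' @param geom A [lattice_geometry()].
#' @param duration_h Simulated duration, hours (default 96 h = four days).
#' @param base Baseline [model_parameters()] the scenario perturbs.
#' @param min_agents,connectivity Nest-analysis settings.
#' @return An object of class `experiment_result`: list with `spec`,
#'   `geom`, `params`, `replicates` (per-replicate list of `nests`,
#'   `summary`, `counts`, `seed`), and `pooled_areas` (all replicates'
#'   filtered nest areas, um^2).
#' @export
run_scenario <- function(spec, geom = lattice_geometry(75, 75, 60),
                         duration_h = 96, base = model_parameters(),
                         min_agents = 4, connectivity = 26) {
  stopifnot(inherits(spec, "scenario_spec"))
  params <- scenario_parameters(spec, base)
  N_s <- scale_count(spec$N_s0, geom)
  N_m <- scale_count(spec$N_m0, geom)
  reps <- lapply(seq_len(spec$replicates), function(r) {
    set.seed(spec$seeds[r])
    init <- seed_surface(N_s, N_m, geom)
    res <- simulate_ibm(init, params, duration_h = duration_h, geom = geom)
    an <- analyze_nests(res$final, connectivity = connectivity,
                        min_agents = min_agents, geom = geom)
    list(seed = spec$seeds[r], nests = an$nests, summary = an$summary,
         counts = population_counts(res$final), tallies = res$tallies)
  })
  structure(list(spec = spec, geom = geom, params = params,
                 duration_h = duration_h,
                 N_s0_scaled = N_s, N_m0_scaled = N_m,
                 replicates = reps,
                 pooled_areas = unlist(lapply(reps,
                                              function(r) r$nests$area_um2))),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("scenario '%s': %d replicate(s), %d x %d x %d lattice, %g h\n",
              x$spec$name, length(x$replicates),
              x$geom$nx, x$geom$ny, x$geom$nz, x$duration_h))
  cat(sprintf("  seeded %d skin + %d melanoma agents\n",
              x$N_s0_scaled, x$N_m0_scaled))
  s <- summarize_nests(x$pooled_areas)
  cat(sprintf("  pooled: %d nests, median %.0f um^2 (%.4f mm^2)\n",
              s$n_nests, s$median, s$median * 1e-6))
  invisible(x)
}

#' Fold change of median nest area between two scenarios
#'
#' Ratio of pooled median nest areas, `median(a) / median(b)`, with a
#' seeded percentile bootstrap interval (resampling each pooled area list
#' with replacement).
#'
#' @param result_a,result_b [run_scenario()] results (numerator,
#'   denominator).
#' @param n_boot Bootstrap resamples.
#' @param conf Interval coverage.
#' @param boot_seed Seed for the bootstrap resampling.
#' @return List with `fold_change`, `ci` (length-2 vector), `median_a`,
#'   `median_b`, `n_boot`.
#' @export
compare_scenarios <- function(result_a, result_b, n_boot = 1000,
                              conf = 0.95, boot_seed = 1L) {
  a <- if (inherits(result_a, "experiment_result")) result_a$pooled_areas
       else result_a
  b <- if (inherits(result_b, "experiment_result")) result_b$pooled_areas
       else result_b
  if (length(a) == 0L || length(b) == 0L)
    stop("fold change undefined: a condition produced no nests after ",
         "filtering", call. = FALSE)
  med_a <- stats::median(a)
  med_b <- stats::median(b)
  set.seed(boot_seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(a, replace = TRUE)) /
      stats::median(sample(b, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(fold_change = med_a / med_b,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7)),
       median_a = med_a, median_b = med_b, n_boot = n_boot)
}
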