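SPECIES_CODES <- c(melanoma = 1L, skin = 2L)

species_to_code <- function(species) {
  code <- SPECIES_CODES[species]
  if (anyNA(code)) stop("unknown species label", call. = FALSE)
  unname(code)
}

code_to_species <- function(code) names(SPECIES_CODES)[code]

#' Seed the lattice surface with skin and melanoma agents
#'
#' Places `N_s` skin and `N_m` melanoma agents on the top layer (`k = 0`),
#' drawing the combined set of surface sites uniformly without replacement,
#' as when cell suspensions are pipetted onto the skin surface. With the
#' default full-scale geometry and the density-matched counts (9549 skin,
#' 398/1592/2706 melanoma) this reproduces the experimental seeding
#' densities.
#'
#' @param N_s,N_m Non-negative skin and melanoma agent counts;
#'   `N_s + N_m` must not exceed `nx * ny`.
#' @param geom A [lattice_geometry()].
#' @return A snapshot data frame with columns `agent_id`, `species`, `i`,
#'   `j`, `k` (0-based sites) and attributes `geom`, `t_hours = 0`,
#'   `step = 0`.
#' @export
#' @examples
#' set.seed(1)
#' s <- seed_surface(100, 30, lattice_geometry(50, 50, 40))
#' table(s$species)
seed_surface <- function(N_s, N_m, geom = lattice_geometry()) {
  stopifnot(N_s >= 0, N_m >= 0)
  n_surface <- geom$nx * geom$ny
  if (N_s + N_m > n_surface)
    stop(sprintf("cannot place %d agents on a %d-site surface",
                 N_s + N_m, n_surface), call. = FALSE)
  n <- N_s + N_m
  picks <- sample.int(n_surface, n) - 1L
  snap <- data.frame(
    agent_id = seq_len(n),
    species = rep(c("skin", "melanoma"), c(N_s, N_m)),
    i = picks %% geom$nx,
    j = picks %/% geom$nx,
    k = rep(0L, n))
  attr(snap, "geom") <- geom
  attr(snap, "t_hours") <- 0
  attr(snap, "step") <- 0L
  snap
}

snapshot_from_engine <- function(raw, geom, tau) {
  n <- length(raw$i)
  snap <- data.frame(agent_id = seq_len(n),
                     species = if (n) code_to_species(raw$species)
                               else character(),
                     i = raw$i, j = raw$j, k = raw$k)
  attr(snap, "geom") <- geom
  attr(snap, "t_hours") <- raw$step * tau
  attr(snap, "step") <- raw$step
  snap
}

#' Run the individual-based simulation
#'
#' Advances an initial agent configuration through `n_steps` discrete time
#' steps of duration `tau`. Each step runs a motility phase then a
#' proliferation phase; in each phase, N agents (the count at phase start)
#' are selected one at a time with replacement. A selected agent moves to a
#' uniformly drawn von Neumann neighbour with probability `Pm` of its
#' species — melanoma agents pass a further adhesion gate `(1 - q)^a` — and
#' proliferates with probability `Pp`, placing a same-species daughter on a
#' uniformly drawn vacant von Neumann site (aborted if all six are
#' occupied). Moves onto occupied sites or through the horizontal
#' boundaries are aborted. All randomness comes from R's RNG stream, so
#' `set.seed()` makes runs exactly reproducible.
#'
#' @param init A snapshot data frame as from [seed_surface()] (columns
#'   `species`, `i`, `j`, `k`) with a `geom` attribute, or pass `geom`
#'   explicitly.
#' @param params A [model_parameters()] object.
#' @param duration_h Simulated duration, hours; `n_steps = round(duration_h
#'   / tau)`.
#' @param geom Lattice geometry; defaults to `attr(init, "geom")`.
#' @param snapshot_every_steps If positive, record a snapshot every that
#'   many steps (the final state is always recorded).
#' @return An object of class `ibm_result`: a list with `final` (snapshot
#'   data frame), `snapshots` (list of snapshot data frames, including the
#'   initial state), `tallies` (per-phase event counts), `params`, `geom`,
#'   `n_steps`.
#' @export
#' @examples
#' set.seed(42)
#' g <- lattice_geometry(30, 30, 20)
#' res <- simulate_ibm(seed_surface(200, 60, g), model_parameters(),
#'                     duration_h = 1)
#' nrow(res$final)
simulate_ibm <- function(init, params = model_parameters(), duration_h = 96,
                         geom = attr(init, "geom"),
                         snapshot_every_steps = 0L) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(geom, "lattice_geometry"), duration_h >= 0)
  n_steps <- as.integer(round(duration_h / params$tau))
  snap_steps <- if (snapshot_every_steps > 0)
    seq(snapshot_every_steps, n_steps, by = snapshot_every_steps)
  else integer()
  raw <- cpp_run(geom$nx, geom$ny, geom$nz,
                 as.integer(init$i), as.integer(init$j), as.integer(init$k),
                 species_to_code(init$species),
                 params$Pm_m, params$Pm_s, params$Pp_m, params$Pp_s,
                 params$q, n_steps, as.integer(snap_steps))
  snaps <- c(list(snapshot_from_engine(
                list(step = 0L, i = init$i, j = init$j, k = init$k,
                     species = species_to_code(init$species)),
                geom, params$tau)),
             lapply(raw$snapshots, snapshot_from_engine, geom = geom,
                    tau = params$tau))
  final <- snapshot_from_engine(raw$final, geom, params$tau)
  structure(list(final = final, snapshots = snaps, tallies = raw$tallies,
                 params = params, geom = geom, n_steps = n_steps),
            class = "ibm_result")
}

#' @export
print.ibm_result <- function(x, ...) {
  n <- table(factor(x$final$species, levels = names(SPECIES_CODES)))
  cat(sprintf("IBM run: %d steps (t = %g h) on %d x %d x %d lattice\n",
              x$n_steps, x$n_steps * x$params$tau,
              x$geom$nx, x$geom$ny, x$geom$nz))
  cat(sprintf("  final agents: %d melanoma, %d skin\n",
              n[["melanoma"]], n[["skin"]]))
  m <- x$tallies$motility
  cat(sprintf("  moves: %d / %d selections succeeded\n",
              as.integer(m[["moved"]]), as.integer(m[["attempted"]])))
  p <- x$tallies$proliferation
  cat(sprintf("  births: %d / %d selections\n",
              as.integer(p[["births"]]), as.integer(p[["attempted"]])))
  invisible(x)
}

#' Population counts of a snapshot
#'
#' @param snapshot A snapshot data frame.
#' @return Named integer vector with `melanoma`, `skin` and `total` counts.
#' @export
population_counts <- function(snapshot) {
  tab <- table(factor(snapshot$species, levels = names(SPECIES_CODES)))
  c(melanoma = as.integer(tab[["melanoma"]]),
    skin = as.integer(tab[["skin"]]),
    total = nrow(snapshot))
}

#' Mean squared displacement of independent single-agent walks
#'
#' Runs `n_walks` single-agent simulations on an otherwise empty lattice
#' (so exclusion and adhesion never act) and returns each agent's squared
#' displacement after `duration_h` hours. On an empty lattice the walk's
#' theoretical mean squared displacement is `6 * D * t` with
#' `D = Pm * delta^2 / (6 * tau)`. The lattice must be large enough that no
#' walk can cross half a lateral period; displacements are measured from
#' the centre start site.
#'
#' @param n_walks Number of independent walks.
#' @param params A [model_parameters()] object; the melanoma species is
#'   used with `q = 0` unless `species = "skin"`.
#' @param duration_h Walk duration, hours.
#' @param species Agent species for the walk.
#' @param geom Lattice geometry; defaults to a cube comfortably larger than
#'   the walk's expected range.
#' @return Numeric vector of squared displacements, um^2.
#' @export
msd_walks <- function(n_walks, params = model_parameters(),
                      duration_h = 10, species = "melanoma",
                      geom = NULL) {
  pm <- if (species == "melanoma") params$Pm_m else params$Pm_s
  n_steps <- round(duration_h / params$tau)
  if (is.null(geom)) {
    # ~8 sd of the per-axis displacement, odd-sized so a centre site exists
    span <- 2L * as.integer(ceiling(8 * sqrt(pm * n_steps / 3))) + 5L
    geom <- lattice_geometry(span, span, span, params$delta)
  }
  centre <- c(geom$nx %/% 2L, geom$ny %/% 2L, geom$nz %/% 2L)
  p0 <- model_parameters(tau = params$tau, delta = params$delta,
                         Pm_m = pm, Pm_s = pm, Pp_m = 0, Pp_s = 0, q = 0)
  init <- data.frame(agent_id = 1L, species = species,
                     i = centre[1], j = centre[2], k = centre[3])
  attr(init, "geom") <- geom
  vapply(seq_len(n_walks), function(w) {
    fin <- simulate_ibm(init, p0, duration_h = duration_h, geom = geom)$final
    sum(((c(fin$i, fin$j, fin$k) - centre) * params$delta)^2)
  }, numeric(1))
}
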