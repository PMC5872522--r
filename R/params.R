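#' Model parameters for the skin/melanoma lattice IBM
#'
#' Bundles the per-step probabilities and lattice/time discretisation that
#' define one simulation condition. The defaults are the baseline co-culture
#' parameter set: time step `tau = 0.01` h, lattice spacing `delta = 20` um,
#' melanoma motility probability `Pm_m = 0.075`, skin motility probability
#' `Pm_s = 0.3`, melanoma proliferation probability `Pp_m = 4e-4`, skin
#' proliferation probability `Pp_s = 2.5e-4`, and adhesion strength
#' `q = 0.7`.
#'
#' @param tau Time step duration, hours. Must be positive.
#' @param delta Lattice spacing, micrometres. Must be positive.
#' @param Pm_m,Pm_s Per-step motility probabilities for melanoma and skin
#'   agents, each in \[0, 1\].
#' @param Pp_m,Pp_s Per-step proliferation probabilities for melanoma and
#'   skin agents, each in \[0, 1\].
#' @param q Melanoma-melanoma adhesion strength in \[0, 1\]; `q = 0` is no
#'   adhesion, `q = 1` immobilises melanoma agents touching other melanoma
#'   agents.
#' @return An object of class `model_parameters`.
#' @seealso [derive_rates()], [adhesion_modifier()]
#' @export
#' @examples
#' p <- model_parameters()
#' derive_rates(p)
model_parameters <- function(tau = 0.01, delta = 20,
                             Pm_m = 0.075, Pm_s = 0.3,
                             Pp_m = 4e-4, Pp_s = 2.5e-4,
                             q = 0.7) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            is.numeric(delta), length(delta) == 1L, delta > 0)
  for (p in list(Pm_m = Pm_m, Pm_s = Pm_s, Pp_m = Pp_m, Pp_s = Pp_s, q = q)) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("probabilities and q must be single values in [0, 1]", call. = FALSE)
  }
  structure(list(tau = tau, delta = delta,
                 Pm_m = Pm_m, Pm_s = Pm_s,
                 Pp_m = Pp_m, Pp_s = Pp_s, q = q),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("IBM model parameters\n")
  cat(sprintf("  tau = %g h, delta = %g um, q = %g\n", x$tau, x$delta, x$q))
  cat(sprintf("  melanoma: Pm = %g, Pp = %g\n", x$Pm_m, x$Pp_m))
  cat(sprintf("  skin:     Pm = %g, Pp = %g\n", x$Pm_s, x$Pp_s))
  r <- derive_rates(x)
  cat(sprintf("  rates: lambda_m = %g /h, lambda_s = %g /h, D_m = %g, D_s = %g um^2/h\n",
              r$lambda_m, r$lambda_s, r$D_m, r$D_s))
  invisible(x)
}

#' Convert per-step probabilities to continuum rates
#'
#' The per-step probabilities map to a proliferation rate
#' `lambda = Pp / tau` (per hour) and a cell diffusivity
#' `D = Pm * delta^2 / (6 * tau)` (um^2 per hour) for each species. With the
#' baseline parameters this gives `lambda_m = 0.04` /h, `lambda_s = 0.025`
#' /h, `D_m = 500` um^2/h and `D_s = 2000` um^2/h.
#'
#' @param params A [model_parameters()] object.
#' @return A list with elements `lambda_m`, `lambda_s` (per hour) and
#'   `D_m`, `D_s` (um^2 per hour).
#' @export
derive_rates <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  list(lambda_m = params$Pp_m / params$tau,
       lambda_s = params$Pp_s / params$tau,
       D_m = params$Pm_m * params$delta^2 / (6 * params$tau),
       D_s = params$Pm_s * params$delta^2 / (6 * params$tau))
}

#' Convert continuum rates back to per-step probabilities
#'
#' Inverse of [derive_rates()]: `Pp = lambda * tau` and
#' `Pm = 6 * D * tau / delta^2`. Round-trips exactly for representable
#' inputs.
#'
#' @param rates A list with `lambda_m`, `lambda_s`, `D_m`, `D_s` as returned
#'   by [derive_rates()].
#' @param tau Time step, hours.
#' @param delta Lattice spacing, um.
#' @param q Adhesion strength carried through unchanged.
#' @return A [model_parameters()] object.
#' @export
probs_from_rates <- function(rates, tau = 0.01, delta = 20, q = 0.7) {
  model_parameters(tau = tau, delta = delta,
                   Pm_m = 6 * rates$D_m * tau / delta^2,
                   Pm_s = 6 * rates$D_s * tau / delta^2,
                   Pp_m = rates$lambda_m * tau,
                   Pp_s = rates$lambda_s * tau,
                   q = q)
}

#' Adhesion-modified motility probability
#'
#' A potentially motile melanoma agent moves with probability reduced by the
#' factor `(1 - q)^a`, where `a` is the number of melanoma agents among the
#' 26 Moore-neighbourhood sites. With `a = 0` the modifier is 1 for any `q`;
#' with `q = 1` any melanoma contact freezes the agent.
#'
#' @param q Adhesion strength in \[0, 1\].
#' @param a Integer count of melanoma Moore neighbours, 0 to 26.
#' @return The modifier `(1 - q)^a`, a probability.
#' @export
#' @examples
#' adhesion_modifier(0.7, 1)  # 0.3
adhesion_modifier <- function(q, a) {
  stopifnot(is.numeric(q), all(q >= 0 & q <= 1))
  if (any(a != as.integer(a)) || any(a < 0) || any(a > 26))
    stop("a must be an integer count in 0..26", call. = FALSE)
  (1 - q)^a
}

#' Density-matched agent count for a square subregion
#'
#' Experiments seed cells uniformly inside a disc; the simulation seeds
#' agents uniformly on a square surface. The agent count that matches the
#' experimental surface density is `n_cells * side^2 / (pi * r_disc^2)`,
#' rounded to the nearest integer (halves away from zero). For a 3 mm disc
#' and a 3 mm square this maps 30000 skin cells to 9549 agents and 1250,
#' 5000 and 8500 melanoma cells to 398, 1592 and 2706 agents.
#'
#' @param n_cells Cell count seeded in the experimental disc.
#' @param r_disc Disc radius (any length unit, consistent with `side`).
#' @param side Side length of the square lattice surface.
#' @return Integer agent count.
#' @export
#' @examples
#' density_matched_count(30000)  # 9549
density_matched_count <- function(n_cells, r_disc = 3, side = 3) {
  stopifnot(is.numeric(n_cells), all(n_cells >= 0), r_disc > 0, side > 0)
  x <- n_cells * side^2 / (pi * r_disc^2)
  # round half away from zero (base round() rounds halves to even)
  as.integer(trunc(x + 0.5 * sign(x)))
}
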