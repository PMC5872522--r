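#' Lattice geometry for the 3D skin model
#'
#' Defines the site grid: `nx` by `ny` lateral sites and `nz` depth layers,
#' with spacing `delta` micrometres. Coordinates are 0-based; `k = 0` is the
#' top (seeding) surface and `k` increases downward. Boundaries are periodic
#' in `i` and `j` (the lattice represents the central region of a laterally
#' uniform tissue) and closed (no-flux) at `k = 0` and `k = nz - 1`. The
#' default geometry, 150 x 150 x 100 sites at 20 um, spans a physical
#' 3 mm x 3 mm x 2 mm block.
#'
#' @param nx,ny Lateral site counts, at least 1.
#' @param nz Depth site count, at least 1.
#' @param delta Lattice spacing, micrometres.
#' @return An object of class `lattice_geometry`.
#' @export
#' @examples
#' g <- lattice_geometry()
#' c(g$nx, g$ny, g$nz) * g$delta / 1000  # physical extent in mm
lattice_geometry <- function(nx = 150, ny = 150, nz = 100, delta = 20) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, delta > 0,
            nx == as.integer(nx), ny == as.integer(ny), nz == as.integer(nz))
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), delta = delta),
            class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat(sprintf("lattice: %d x %d x %d sites, delta = %g um (%g x %g x %g mm)\n",
              x$nx, x$ny, x$nz, x$delta,
              x$nx * x$delta / 1000, x$ny * x$delta / 1000,
              x$nz * x$delta / 1000))
  invisible(x)
}

in_domain <- function(site, geom) {
  site[1] >= 0 && site[1] < geom$nx &&
    site[2] >= 0 && site[2] < geom$ny &&
    site[3] >= 0 && site[3] < geom$nz
}

check_site <- function(site, geom) {
  if (length(site) != 3L || any(site != as.integer(site)))
    stop("site must be three integer indices (i, j, k)", call. = FALSE)
  if (!in_domain(site, geom))
    stop(sprintf("site (%d, %d, %d) is outside the %d x %d x %d domain",
                 site[1], site[2], site[3], geom$nx, geom$ny, geom$nz),
         call. = FALSE)
  invisible(as.integer(site))
}

# Fixed direction order shared with the C++ engine: +x, -x, +y, -y, +z, -z.
vn_offsets <- matrix(c(1L, 0L, 0L, -1L, 0L, 0L,
                       0L, 1L, 0L, 0L, -1L, 0L,
                       0L, 0L, 1L, 0L, 0L, -1L),
                     ncol = 3, byrow = TRUE)

#' von Neumann neighbours of a lattice site
#'
#' Returns the axis-adjacent sites of `site` in the fixed direction order
#' +x, -x, +y, -y, +z, -z, with lateral indices wrapped periodically.
#' Vertical neighbours that fall above the surface (`k < 0`) or below the
#' bottom layer (`k >= nz`) are dropped, so interior sites have 6 neighbours
#' and surface/bottom sites have 5; movement and daughter placement draw
#' from all 6 directions and treat an out-of-domain target as an aborted
#' event rather than re-drawing.
#'
#' @param site Integer vector `c(i, j, k)`, 0-based, in-domain.
#' @param geom A [lattice_geometry()].
#' @return Integer matrix with columns `i`, `j`, `k`, one row per in-domain
#'   neighbour.
#' @export
von_neumann_neighbors <- function(site, geom) {
  site <- check_site(site, geom)
  nb <- sweep(vn_offsets, 2, site, "+")
  keep <- nb[, 3] >= 0 & nb[, 3] < geom$nz
  nb <- nb[keep, , drop = FALSE]
  nb[, 1] <- nb[, 1] %% geom$nx
  nb[, 2] <- nb[, 2] %% geom$ny
  colnames(nb) <- c("i", "j", "k")
  nb
}

#' Moore neighbours of a lattice site
#'
#' Returns the sites differing by -1/0/+1 in each index (the centre site
#' excluded), laterally wrapped and vertically clipped, consistent with the
#' movement boundary conditions. Interior sites have 26 neighbours; a
#' surface site has 17. On degenerate lattices (an axis of length 1 or 2)
#' wrapping can make distinct offsets land on the same site; duplicates are
#' removed, and the centre site itself is never returned.
#'
#' @inheritParams von_neumann_neighbors
#' @return Integer matrix with columns `i`, `j`, `k`.
#' @export
moore_neighbors <- function(site, geom) {
  site <- check_site(site, geom)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  nb <- sweep(off, 2, site, "+")
  nb <- nb[nb[, 3] >= 0 & nb[, 3] < geom$nz, , drop = FALSE]
  nb[, 1] <- nb[, 1] %% geom$nx
  nb[, 2] <- nb[, 2] %% geom$ny
  nb <- unique(nb)
  nb <- nb[!(nb[, 1] == site[1] & nb[, 2] == site[2] & nb[, 3] == site[3]), ,
           drop = FALSE]
  dimnames(nb) <- list(NULL, c("i", "j", "k"))
  nb
}

#' Empty occupancy grid
#'
#' An occupancy grid couples a [lattice_geometry()] with an agent registry
#' under volume exclusion: each site holds at most one agent, and every
#' registered agent occupies exactly one site. Agents have an integer id, a
#' species (`"melanoma"` or `"skin"`) and a site.
#'
#' @param geom A [lattice_geometry()].
#' @return An object of class `occupancy_grid` with fields `geom`, `sites`
#'   (integer array `nx x ny x nz`, 0 = vacant, otherwise agent id) and
#'   `agents` (data frame with columns `id`, `species`, `i`, `j`, `k`).
#' @export
occupancy_grid <- function(geom = lattice_geometry()) {
  structure(list(geom = geom,
                 sites = array(0L, dim = c(geom$nx, geom$ny, geom$nz)),
                 agents = data.frame(id = integer(), species = character(),
                                     i = integer(), j = integer(),
                                     k = integer())),
            class = "occupancy_grid")
}

site_index <- function(grid, site) {
  cbind(site[1] + 1L, site[2] + 1L, site[3] + 1L)
}

#' Place a new agent on a vacant site
#'
#' @param grid An [occupancy_grid()].
#' @param species `"melanoma"` or `"skin"`.
#' @param site Integer vector `c(i, j, k)`, 0-based; must be vacant and
#'   in-domain.
#' @return The updated grid; the new agent's id is `nrow(grid$agents)`.
#' @export
place_agent <- function(grid, species, site) {
  stopifnot(inherits(grid, "occupancy_grid"))
  species <- match.arg(species, c("melanoma", "skin"))
  site <- check_site(site, grid$geom)
  if (grid$sites[site_index(grid, site)] != 0L)
    stop(sprintf("exclusion violation: site (%d, %d, %d) is occupied",
                 site[1], site[2], site[3]), call. = FALSE)
  id <- nrow(grid$agents) + 1L
  grid$sites[site_index(grid, site)] <- id
  grid$agents <- rbind(grid$agents,
                       data.frame(id = id, species = species,
                                  i = site[1], j = site[2], k = site[3]))
  grid
}

#' Move a registered agent to a vacant site
#'
#' The move is atomic: the source site is vacated exactly when the target is
#' filled, so the exclusion invariant is preserved.
#'
#' @param grid An [occupancy_grid()].
#' @param id Agent id.
#' @param target Integer vector `c(i, j, k)`, vacant and in-domain.
#' @return The updated grid.
#' @export
move_agent <- function(grid, id, target) {
  stopifnot(inherits(grid, "occupancy_grid"))
  row <- match(id, grid$agents$id)
  if (is.na(row)) stop("unknown agent id", call. = FALSE)
  target <- check_site(target, grid$geom)
  if (grid$sites[site_index(grid, target)] != 0L)
    stop(sprintf("exclusion violation: site (%d, %d, %d) is occupied",
                 target[1], target[2], target[3]), call. = FALSE)
  src <- c(grid$agents$i[row], grid$agents$j[row], grid$agents$k[row])
  grid$sites[site_index(grid, src)] <- 0L
  grid$sites[site_index(grid, target)] <- id
  grid$agents$i[row] <- target[1]
  grid$agents$j[row] <- target[2]
  grid$agents$k[row] <- target[3]
  grid
}

#' Count melanoma agents in the Moore neighbourhood
#'
#' The adhesion count `a`: the number of the (up to 26) Moore-neighbourhood
#' sites occupied by melanoma agents. Skin agents never contribute.
#'
#' @param grid An [occupancy_grid()].
#' @param site Integer vector `c(i, j, k)`.
#' @return Integer in 0..26.
#' @export
count_melanoma_neighbors <- function(grid, site) {
  stopifnot(inherits(grid, "occupancy_grid"))
  nb <- moore_neighbors(site, grid$geom)
  if (nrow(nb) == 0L) return(0L)
  ids <- grid$sites[nb + 1L]
  ids <- ids[ids != 0L]
  if (length(ids) == 0L) return(0L)
  sum(grid$agents$species[match(ids, grid$agents$id)] == "melanoma")
}

#' Verify grid/registry consistency
#'
#' Checks the exclusion invariant: every registered agent occupies exactly
#' the site the grid maps to its id, and every non-vacant grid entry points
#' to a registered agent.
#'
#' @param grid An [occupancy_grid()].
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_grid <- function(grid) {
  stopifnot(inherits(grid, "occupancy_grid"))
  occ <- which(grid$sites != 0L, arr.ind = TRUE)
  ids <- grid$sites[grid$sites != 0L]
  if (anyDuplicated(ids)) stop("agent id appears at more than one site")
  if (length(ids) != nrow(grid$agents))
    stop("grid occupancy count disagrees with agent registry")
  ord <- match(grid$agents$id, ids)
  if (anyNA(ord)) stop("registered agent missing from grid")
  agree <- occ[ord, , drop = FALSE] - 1L
  if (!all(agree[, 1] == grid$agents$i & agree[, 2] == grid$agents$j &
           agree[, 3] == grid$agents$k))
    stop("agent registry position disagrees with grid")
  invisible(TRUE)
}
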