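# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Torus/slab neighbour oracle: enumerate every site and keep those whose
# wrapped per-axis distance is at most 1 (Moore) or exactly one axis off by
# 1 (von Neumann), with plain (non-wrapped) distance in k.
oracle_neighbors <- function(site, geom, type = c("moore", "vn")) {
  type <- match.arg(type)
  wrapdist <- function(a, b, n) {
    d <- abs(a - b)
    min(d, n - d)
  }
  out <- NULL
  for (i in 0:(geom$nx - 1)) for (j in 0:(geom$ny - 1))
    for (k in 0:(geom$nz - 1)) {
      di <- wrapdist(i, site[1], geom$nx)
      dj <- wrapdist(j, site[2], geom$ny)
      dk <- abs(k - site[3])
      if (di == 0 && dj == 0 && dk == 0) next
      hit <- if (type == "moore") di <= 1 && dj <= 1 && dk <= 1
             else di + dj + dk == 1
      if (hit) out <- rbind(out, c(i = i, j = j, k = k))
    }
  if (is.null(out)) matrix(integer(), 0, 3,
                           dimnames = list(NULL, c("i", "j", "k")))
  else out
}

# Brute-force flood fill over melanoma agents: repeatedly grow a component
# from an unvisited agent using pairwise wrapped-distance adjacency.
oracle_components <- function(mel, geom, connectivity = 26) {
  n <- nrow(mel)
  if (n == 0L) return(integer())
  wrapdist <- function(a, b, n) pmin(abs(a - b), n - abs(a - b))
  adjacent <- function(p, q) {
    di <- wrapdist(mel$i[p], mel$i[q], geom$nx)
    dj <- wrapdist(mel$j[p], mel$j[q], geom$ny)
    dk <- abs(mel$k[p] - mel$k[q])
    if (connectivity == 26) di <= 1 && dj <= 1 && dk <= 1 &&
      (di + dj + dk > 0)
    else di + dj + dk == 1
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in seq_len(n)) {
        if (comp[q] == 0L && adjacent(p, q)) {
          comp[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  comp
}

# Random sparse snapshot on a small lattice for labelling property tests.
random_snapshot <- function(geom, n_mel, n_skin = 0) {
  total <- geom$nx * geom$ny * geom$nz
  picks <- sample.int(total, n_mel + n_skin) - 1L
  snap <- data.frame(
    agent_id = seq_len(n_mel + n_skin),
    species = rep(c("melanoma", "skin"), c(n_mel, n_skin)),
    i = picks %% geom$nx,
    j = (picks %/% geom$nx) %% geom$ny,
    k = picks %/% (geom$nx * geom$ny))
  attr(snap, "geom") <- geom
  attr(snap, "t_hours") <- 0
  attr(snap, "step") <- 0L
  snap
}

# Exclusion check on a snapshot: site keys must be unique.
expect_exclusion <- function(snap, geom) {
  key <- snap$i + geom$nx * (snap$j + geom$ny * snap$k)
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(snap$i >= 0 & snap$i < geom$nx &
                  snap$j >= 0 & snap$j < geom$ny &
                  snap$k >= 0 & snap$k < geom$nz))
}
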