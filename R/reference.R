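# Pure-R reference implementation of the update algorithm. Deliberately
# slow and direct: used in tests as an independent check that the compiled
# engine implements the documented draw order and update rules. Both
# engines consume R's RNG stream in the same order, so identical seeds must
# give identical trajectories.

ref_state <- function(init, geom) {
  grid <- array(0L, dim = c(geom$nx, geom$ny, geom$nz))
  n <- nrow(init)
  for (r in seq_len(n)) {
    if (grid[init$i[r] + 1L, init$j[r] + 1L, init$k[r] + 1L] != 0L)
      stop("initial condition violates exclusion")
    grid[init$i[r] + 1L, init$j[r] + 1L, init$k[r] + 1L] <- r
  }
  list(geom = geom, grid = grid,
       i = as.integer(init$i), j = as.integer(init$j),
       k = as.integer(init$k),
       melanoma = init$species == "melanoma")
}

ref_moore_count <- function(st, i, j, k) {
  a <- 0L
  for (dk in -1:1) {
    kk <- k + dk
    if (kk < 0 || kk >= st$geom$nz) next
    for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      id <- st$grid[(i + di) %% st$geom$nx + 1L,
                    (j + dj) %% st$geom$ny + 1L, kk + 1L]
      if (id != 0L && st$melanoma[id]) a <- a + 1L
    }
  }
  a
}

ref_draw_index <- function(n) min(floor(runif(1) * n), n - 1) + 1L

# direction order +x, -x, +y, -y, +z, -z (matches vn_offsets)
ref_step <- function(st, params) {
  geom <- st$geom
  N <- length(st$i)
  for (s in seq_len(N)) {           # motility phase, pool frozen at N
    ag <- ref_draw_index(N)
    pm <- if (st$melanoma[ag]) params$Pm_m else params$Pm_s
    if (runif(1) >= pm) next
    if (st$melanoma[ag]) {
      a <- ref_moore_count(st, st$i[ag], st$j[ag], st$k[ag])
      if (runif(1) >= (1 - params$q)^a) next
    }
    dir <- ref_draw_index(6)
    ti <- (st$i[ag] + vn_offsets[dir, 1]) %% geom$nx
    tj <- (st$j[ag] + vn_offsets[dir, 2]) %% geom$ny
    tk <- st$k[ag] + vn_offsets[dir, 3]
    if (tk < 0 || tk >= geom$nz) next
    if (st$grid[ti + 1L, tj + 1L, tk + 1L] != 0L) next
    st$grid[st$i[ag] + 1L, st$j[ag] + 1L, st$k[ag] + 1L] <- 0L
    st$grid[ti + 1L, tj + 1L, tk + 1L] <- ag
    st$i[ag] <- ti; st$j[ag] <- tj; st$k[ag] <- tk
  }
  N <- length(st$i)
  for (s in seq_len(N)) {           # proliferation phase
    ag <- ref_draw_index(N)
    pp <- if (st$melanoma[ag]) params$Pp_m else params$Pp_s
    if (runif(1) >= pp) next
    vac <- NULL
    for (dir in 1:6) {
      tk <- st$k[ag] + vn_offsets[dir, 3]
      if (tk < 0 || tk >= geom$nz) next
      ti <- (st$i[ag] + vn_offsets[dir, 1]) %% geom$nx
      tj <- (st$j[ag] + vn_offsets[dir, 2]) %% geom$ny
      if (st$grid[ti + 1L, tj + 1L, tk + 1L] == 0L)
        vac <- rbind(vac, as.integer(c(ti, tj, tk)))
    }
    if (is.null(vac)) next
    pick <- vac[ref_draw_index(nrow(vac)), ]
    st$i <- c(st$i, pick[1]); st$j <- c(st$j, pick[2])
    st$k <- c(st$k, pick[3])
    st$melanoma <- c(st$melanoma, st$melanoma[ag])
    st$grid[pick[1] + 1L, pick[2] + 1L, pick[3] + 1L] <- length(st$i)
  }
  st
}

ref_run <- function(init, params, n_steps, geom = attr(init, "geom")) {
  st <- ref_state(init, geom)
  for (step in seq_len(n_steps)) st <- ref_step(st, params)
  data.frame(agent_id = seq_along(st$i),
             species = ifelse(st$melanoma, "melanoma", "skin"),
             i = st$i, j = st$j, k = st$k)
}
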