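test_that("surface seeding places exact counts on distinct top-layer sites", {
  g <- lattice_geometry(150, 150, 100)
  set.seed(3)
  snap <- seed_surface(9549, 2706, g)
  expect_identical(nrow(snap), 12255L)
  expect_identical(unname(population_counts(snap)[c("skin", "melanoma")]),
                   c(9549L, 2706L))
  expect_true(all(snap$k == 0L))
  expect_exclusion(snap, g)

  expect_identical(nrow(seed_surface(0, 0, g)), 0L)
  expect_error(seed_surface(22500, 1, g), "cannot place")
})

test_that("compiled engine reproduces the pure-R reference trajectory", {
  cases <- list(
    list(g = lattice_geometry(8, 8, 6), Ns = 15, Nm = 10,
         p = model_parameters(Pm_m = 0.4, Pm_s = 0.6, Pp_m = 0.08,
                              Pp_s = 0.05, q = 0.5), steps = 15),
    list(g = lattice_geometry(5, 5, 3), Ns = 8, Nm = 8,
         p = model_parameters(Pm_m = 1, Pm_s = 1, Pp_m = 0.2,
                              Pp_s = 0.2, q = 0), steps = 10),
    list(g = lattice_geometry(6, 6, 4), Ns = 0, Nm = 12,
         p = model_parameters(Pm_m = 0.5, Pm_s = 0.5, Pp_m = 0,
                              Pp_s = 0, q = 1), steps = 12))
  for (cs in cases) {
    set.seed(101)
    init <- seed_surface(cs$Ns, cs$Nm, cs$g)
    set.seed(2024)
    fast <- simulate_ibm(init, cs$p, duration_h = cs$steps * cs$p$tau,
                         geom = cs$g)$final
    set.seed(2024)
    slow <- melnest:::ref_run(init, cs$p, cs$steps, cs$g)
    expect_identical(fast$i, slow$i)
    expect_identical(fast$j, slow$j)
    expect_identical(fast$k, slow$k)
    expect_identical(fast$species, slow$species)
  }
})

test_that("runs are deterministic in the seed and exclusion always holds", {
  g <- lattice_geometry(20, 20, 10)
  p <- model_parameters(Pm_m = 0.3, Pm_s = 0.5, Pp_m = 0.02, Pp_s = 0.01)
  set.seed(5)
  init <- seed_surface(60, 40, g)
  set.seed(77)
  a <- simulate_ibm(init, p, duration_h = 0.5, geom = g,
                    snapshot_every_steps = 10)
  set.seed(77)
  b <- simulate_ibm(init, p, duration_h = 0.5, geom = g,
                    snapshot_every_steps = 10)
  expect_identical(a$final, b$final)
  for (s in a$snapshots) expect_exclusion(s, g)

  set.seed(78)
  c_ <- simulate_ibm(init, p, duration_h = 0.5, geom = g)
  expect_false(identical(a$final, c_$final))
})

test_that("zero probabilities freeze the state and species are conserved", {
  g <- lattice_geometry(15, 15, 8)
  set.seed(9)
  init <- seed_surface(40, 30, g)
  p0 <- model_parameters(Pm_m = 0, Pm_s = 0, Pp_m = 0, Pp_s = 0)
  res <- simulate_ibm(init, p0, duration_h = 1, geom = g)
  expect_identical(res$final$i, init$i)
  expect_identical(res$final$k, init$k)

  # melanoma conservation without melanoma proliferation
  pm <- model_parameters(Pp_m = 0)
  res2 <- simulate_ibm(init, pm, duration_h = 2, geom = g,
                       snapshot_every_steps = 50)
  for (s in res2$snapshots)
    expect_identical(population_counts(s)[["melanoma"]], 30L)
  expect_true(population_counts(res2$final)[["skin"]] >= 40L)
})

test_that("event tallies are complete: attempted equals aborted plus succeeded", {
  g <- lattice_geometry(12, 12, 6)
  set.seed(4)
  init <- seed_surface(50, 30, g)
  res <- simulate_ibm(init, model_parameters(Pm_m = 0.5, Pm_s = 0.5,
                                             Pp_m = 0.05, Pp_s = 0.05,
                                             q = 0.8),
                      duration_h = 0.3, geom = g)
  m <- res$tallies$motility
  expect_identical(m[["attempted"]],
                   m[["aborted_gate"]] + m[["aborted_adhesion"]] +
                     m[["aborted_boundary"]] + m[["aborted_crowding"]] +
                     m[["moved"]])
  p <- res$tallies$proliferation
  expect_identical(p[["attempted"]],
                   p[["aborted_gate"]] + p[["aborted_crowding"]] +
                     p[["births"]])
})

test_that("a lone agent moves at the Bernoulli gate rate", {
  g <- lattice_geometry(41, 41, 41)
  p <- model_parameters(Pm_m = 0.075, Pp_m = 0, Pp_s = 0, q = 0.7)
  init <- data.frame(agent_id = 1L, species = "melanoma",
                     i = 20L, j = 20L, k = 20L)
  set.seed(12)
  res <- simulate_ibm(init, p, duration_h = 40, geom = g)
  m <- res$tallies$motility
  frac <- m[["moved"]] / m[["attempted"]]
  # 4000 selections; binomial 3-sigma band around Pm
  se <- sqrt(0.075 * 0.925 / m[["attempted"]])
  expect_lt(abs(frac - 0.075), 3 * se)
  expect_identical(m[["aborted_adhesion"]], 0)  # a = 0 throughout
})

test_that("maximal adhesion freezes a contacting melanoma block", {
  g <- lattice_geometry(12, 12, 8)
  block <- expand.grid(i = 4:6, j = 4:6, k = 2:4)
  init <- data.frame(agent_id = seq_len(nrow(block)), species = "melanoma",
                     i = block$i, j = block$j, k = block$k)
  p <- model_parameters(Pm_m = 1, Pp_m = 0, Pp_s = 0, q = 1)
  set.seed(21)
  res <- simulate_ibm(init, p, duration_h = 10, geom = g)  # 1000 steps
  expect_identical(res$final$i, init$i)
  expect_identical(res$final$j, init$j)
  expect_identical(res$final$k, init$k)
  expect_identical(res$tallies$motility[["moved"]], 0)
})

test_that("crowded agents cannot proliferate and daughters inherit species", {
  g <- lattice_geometry(9, 9, 5)
  centre <- data.frame(i = 4L, j = 4L, k = 2L)
  ring <- as.data.frame(von_neumann_neighbors(c(4, 4, 2), g))
  init <- data.frame(agent_id = seq_len(1 + nrow(ring)),
                     species = c("melanoma", rep("skin", nrow(ring))),
                     i = c(centre$i, ring$i), j = c(centre$j, ring$j),
                     k = c(centre$k, ring$k))
  # only the enclosed melanoma agent may attempt proliferation
  p <- model_parameters(Pm_m = 0, Pm_s = 0, Pp_m = 1, Pp_s = 0)
  set.seed(31)
  res <- simulate_ibm(init, p, duration_h = 0.05, geom = g)
  expect_identical(population_counts(res$final)[["melanoma"]], 1L)
  expect_gt(res$tallies$proliferation[["aborted_crowding"]], 0)

  # free parent with Pp = 1 births exactly one daughter per selection
  lone <- data.frame(agent_id = 1L, species = "melanoma",
                     i = 4L, j = 4L, k = 2L)
  set.seed(32)
  res2 <- simulate_ibm(lone, p, duration_h = 0.01, geom = g)
  expect_identical(population_counts(res2$final)[["melanoma"]], 2L)
  expect_identical(unique(res2$final$species), "melanoma")
})

test_that("proliferation-only growth matches the exponential rate", {
  g <- lattice_geometry(40, 40, 30)   # 48000 sites
  p <- model_parameters(Pm_m = 0, Pm_s = 0, Pp_m = 0.004, Pp_s = 0)
  lambda <- derive_rates(p)$lambda_m  # 0.4 /h
  t_end <- 2.5                        # lambda * t = 1
  set.seed(55)
  n_rep <- 20
  rates <- vapply(seq_len(n_rep), function(r) {
    picks <- sample.int(g$nx * g$ny * g$nz, 300) - 1L
    init <- data.frame(agent_id = seq_len(300), species = "melanoma",
                       i = picks %% g$nx, j = (picks %/% g$nx) %% g$ny,
                       k = picks %/% (g$nx * g$ny))
    fin <- simulate_ibm(init, p, duration_h = t_end, geom = g)$final
    log(nrow(fin) / 300) / t_end
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(n_rep)
  expect_lt(abs(mean(rates) - lambda), 3 * se + 1e-12)
})

test_that("single-walker mean squared displacement recovers the diffusivity", {
  p <- model_parameters()
  set.seed(202)
  sq <- msd_walks(400, p, duration_h = 10)
  msd <- mean(sq)
  want <- 6 * derive_rates(p)$D_m * 10
  se <- stats::sd(sq) / sqrt(length(sq))
  expect_lt(abs(msd - want), 3 * se)
})

test_that("without adhesion melanoma displacements match skin at equal Pm", {
  p <- model_parameters(Pm_m = 0.3, Pm_s = 0.3, Pp_m = 0, Pp_s = 0, q = 0)
  set.seed(66)
  d_mel <- msd_walks(150, p, duration_h = 5, species = "melanoma")
  set.seed(67)
  d_skin <- msd_walks(150, p, duration_h = 5, species = "skin")
  ks <- suppressWarnings(stats::ks.test(d_mel, d_skin))
  expect_gt(ks$p.value, 0.01)
})
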