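test_that("constructed fixtures label as expected", {
  two <- analyze_nests(make_fixture("two_blocks"), min_agents = 1)
  expect_identical(nrow(two$nests), 2L)
  expect_identical(two$nests$n_agents, c(8L, 8L))

  diag26 <- label_nests(make_fixture("diagonal_pair"), connectivity = 26)
  expect_identical(max(diag26$label), 1L)
  diag6 <- label_nests(make_fixture("diagonal_pair"), connectivity = 6)
  expect_identical(max(diag6$label), 2L)

  empty <- label_nests(seed_surface(0, 0, lattice_geometry(5, 5, 3)))
  expect_identical(nrow(empty), 0L)
  expect_identical(summarize_nests(numeric())$n_nests, 0L)
})

test_that("the small-nest filter keeps only components of four or more", {
  tq <- analyze_nests(make_fixture("triplet_and_quad"))
  expect_identical(nrow(tq$nests), 1L)
  expect_identical(tq$nests$n_agents, 4L)

  sizes <- data.frame(n_agents = c(3, 4, 17))
  expect_identical(filter_nests(sizes)$n_agents, c(4, 17))
  expect_identical(filter_nests(sizes, min_agents = 1), sizes)
  singletons <- data.frame(n_agents = rep(1, 5))
  expect_identical(nrow(filter_nests(singletons)), 0L)
  expect_error(filter_nests(sizes, min_agents = 0), "at least 1")
})

test_that("nest area follows the per-agent convention", {
  expect_identical(nest_area(1, 20), 400)
  expect_identical(nest_area(4, 20), 1600)
  expect_identical(nest_area(375, 20), 150000)  # 0.15 mm^2
  expect_identical(nest_area(2, 10), 200)
})

test_that("projected areas count distinct surface columns", {
  # a 2x2x2 block projects to 4 columns; a 1x1x3 column projects to 1
  g <- lattice_geometry(10, 10, 6)
  snap <- data.frame(
    agent_id = 1:11,
    species = "melanoma",
    i = c(rep(c(1, 2), each = 4), rep(7, 3)),
    j = c(rep(c(1, 1, 2, 2), 2), rep(7, 3)),
    k = c(rep(c(0, 1), 4), 0:2))
  attr(snap, "geom") <- g
  an <- analyze_nests(snap, min_agents = 1, convention = "projected")
  expect_identical(sort(an$nests$area_um2), c(400, 1600))
  an_count <- analyze_nests(snap, min_agents = 1)
  expect_identical(sort(an_count$nests$area_um2), c(1200, 3200))
})

test_that("labelling agrees with the brute-force flood-fill oracle", {
  set.seed(88)
  for (trial in 1:40) {
    g <- lattice_geometry(sample(3:8, 1), sample(3:8, 1), sample(2:6, 1))
    n_sites <- g$nx * g$ny * g$nz
    n_mel <- sample.int(min(25, n_sites - 1), 1)
    snap <- random_snapshot(g, n_mel, n_skin = sample(0:5, 1))
    for (conn in c(26, 6)) {
      lab <- label_nests(snap, connectivity = conn)
      want <- oracle_components(lab[, c("i", "j", "k")], g, conn)
      # same partition up to label renaming
      expect_identical(max(lab$label), max(want))
      cross <- table(lab$label, want)
      expect_true(all(rowSums(cross > 0) == 1))
      expect_true(all(colSums(cross > 0) == 1))
    }
  }
})

test_that("labelling is permutation-invariant and conserves agents", {
  set.seed(17)
  g <- lattice_geometry(8, 8, 5)
  snap <- random_snapshot(g, 30, n_skin = 10)
  lab <- label_nests(snap)
  perm <- snap[sample(nrow(snap)), ]
  attr(perm, "geom") <- g
  lab_p <- label_nests(perm)
  key <- function(d) d$i + 100 * d$j + 10000 * d$k
  part <- function(d) {
    sets <- split(key(d), d$label)
    sort(unname(vapply(sets, function(s) paste(sort(s), collapse = ","), "")))
  }
  expect_identical(part(lab), part(lab_p))

  tab <- nest_table(lab)
  expect_identical(sum(tab$n_agents), 30L)
  kept <- filter_nests(tab)
  dropped <- tab[tab$n_agents < 4, ]
  expect_identical(sum(kept$n_agents) + sum(dropped$n_agents), 30L)
})

test_that("boxplot summary applies linear quartiles and 1.5 IQR whiskers", {
  s <- summarize_nests(c(1, 2, 3, 4, 100))
  # type-7 quartiles of {1,2,3,4,100}: q1 = 2, med = 3, q3 = 4; fence 7
  expect_identical(s$median, 3)
  expect_identical(s$q1, 2)
  expect_identical(s$q3, 4)
  expect_identical(s$whisker_hi, 4)
  expect_identical(s$outliers, 100)

  one <- summarize_nests(42)
  expect_identical(one$median, 42)
  expect_identical(length(one$outliers), 0L)
  expect_true(one$q1 <= one$median && one$median <= one$q3)
})

test_that("erosion splitting refines merged nests deterministically", {
  g <- lattice_geometry(20, 20, 8)
  # dumbbell: two 3x3x3 blocks joined by a single-agent bridge
  blk <- function(i0) expand.grid(i = i0:(i0 + 2), j = 4:6, k = 2:4)
  cells <- rbind(blk(2), data.frame(i = 5, j = 5, k = 3), blk(6))
  cells <- unique(cells)
  snap <- data.frame(agent_id = seq_len(nrow(cells)), species = "melanoma",
                     i = cells$i, j = cells$j, k = cells$k)
  attr(snap, "geom") <- g
  lab <- label_nests(snap)
  expect_identical(max(lab$label), 1L)           # bridge merges the blocks
  split <- split_merged_nests(lab)
  expect_identical(max(split$label), 2L)
  expect_identical(nrow(split), nrow(lab))       # no agent lost
  # 27 agents per block; the bridge agent joins one of them
  expect_identical(sort(as.integer(table(split$label))), c(27L, 28L))
  split2 <- split_merged_nests(lab)
  expect_identical(split, split2)                # deterministic

  # an isolated small cluster fully eroded away keeps its own label
  iso <- data.frame(agent_id = 1:2, species = "melanoma",
                    i = c(1, 2), j = c(1, 1), k = c(0, 0))
  attr(iso, "geom") <- g
  lab_iso <- split_merged_nests(label_nests(iso))
  expect_identical(max(lab_iso$label), 1L)
})
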