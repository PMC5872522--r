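#' Label melanoma nests by connected-component analysis
#'
#' Partitions the melanoma agents of a snapshot into nests: maximal sets of
#' agents mutually reachable through the chosen lattice adjacency. The
#' default 26-connectivity (Moore) mirrors the adhesion neighbourhood, so
#' diagonally touching agents belong to one nest; 6-connectivity (von
#' Neumann) is available. Adjacency wraps laterally, matching the
#' simulation's periodic boundaries, and skin agents are ignored. Unlike
#' image-based nest measurement, which can require manual separation of
#' merged nests, the labelling is fully deterministic.
#'
#' @param snapshot A snapshot data frame (columns `species`, `i`, `j`, `k`)
#'   with a `geom` attribute, or supply `geom`.
#' @param connectivity 26 (default) or 6.
#' @param geom A [lattice_geometry()].
#' @return A data frame of melanoma agents with columns `i`, `j`, `k` and
#'   `label` (nest id, 1-based, in decreasing nest-size order); attribute
#'   `geom` is carried over.
#' @export
label_nests <- function(snapshot, connectivity = 26,
                        geom = attr(snapshot, "geom")) {
  stopifnot(inherits(geom, "lattice_geometry"))
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  bad <- setdiff(unique(snapshot$species), names(SPECIES_CODES))
  if (length(bad))
    stop("unknown species label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  mel <- snapshot[snapshot$species == "melanoma", c("i", "j", "k")]
  rownames(mel) <- NULL
  n <- nrow(mel)
  if (n == 0L) {
    mel$label <- integer()
    attr(mel, "geom") <- geom
    return(mel)
  }
  key <- mel$i + geom$nx * (mel$j + geom$ny * mel$k)
  if (anyDuplicated(key)) stop("snapshot violates exclusion", call. = FALSE)

  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == "6") off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  # half the offsets suffice: each undirected adjacency found once
  off <- off[off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
             (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), , drop = FALSE]

  edges <- NULL
  for (r in seq_len(nrow(off))) {
    kk <- mel$k + off[r, 3]
    ok <- kk >= 0 & kk < geom$nz
    nb_key <- (mel$i + off[r, 1]) %% geom$nx +
      geom$nx * (((mel$j + off[r, 2]) %% geom$ny) + geom$ny * kk)
    hit <- match(nb_key, key)
    src <- which(ok & !is.na(hit))
    if (length(src))
      edges <- rbind(edges, cbind(src, hit[src]))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  # relabel so label 1 is the largest nest; ties broken by first appearance
  sizes <- comp$csize
  ord <- order(-sizes, seq_along(sizes))
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(sizes)
  mel$label <- relab[comp$membership]
  attr(mel, "geom") <- geom
  mel
}

#' Split merged nests by erosion cores
#'
#' Nests that grow close together can fuse through thin bridges of agents,
#' so connected-component labelling reports one large component where an
#' observer would see several adjacent nests. This deterministic splitter
#' is the morphological "declumping" standard in image analysis: agents are
#' eroded `depth` times (an agent survives an erosion pass if every
#' in-domain von Neumann neighbour site is melanoma; the top and bottom
#' boundaries count as filled), the surviving cores are relabelled by
#' 26-connectivity, and the eroded agents are assigned to the nearest core
#' by breadth-first geodesic reconstruction through the 26-adjacency
#' (equidistant ties resolve deterministically by agent scan order). Components eroded away entirely keep their
#' original label as a single nest, so the partition refines — never
#' coarsens — the input labelling and every agent keeps a nest.
#'
#' @param labelled Labelled melanoma agents from [label_nests()].
#' @param depth Erosion passes; `depth = 1` cuts single-agent necks.
#' @param geom A [lattice_geometry()]; defaults to the carried attribute.
#' @return The labelled data frame with a refined `label` column
#'   (renumbered 1..n in decreasing size order).
#' @export
split_merged_nests <- function(labelled, depth = 1,
                               geom = attr(labelled, "geom")) {
  stopifnot(inherits(geom, "lattice_geometry"), depth >= 1)
  n <- nrow(labelled)
  if (n == 0L) return(labelled)
  key <- labelled$i + geom$nx * (labelled$j + geom$ny * labelled$k)

  moore_off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  moore_off <- moore_off[rowSums(abs(moore_off)) > 0, , drop = FALSE]
  adj <- matrix(NA_integer_, n, 26)
  for (r in 1:26) {
    kk <- labelled$k + moore_off[r, 3]
    ok <- kk >= 0 & kk < geom$nz
    nbk <- (labelled$i + moore_off[r, 1]) %% geom$nx +
      geom$nx * (((labelled$j + moore_off[r, 2]) %% geom$ny) + geom$ny * kk)
    hit <- match(nbk, key)
    hit[!ok] <- NA_integer_
    adj[, r] <- hit
  }

  core <- rep(TRUE, n)
  for (d in seq_len(depth)) {
    keep <- rep(TRUE, n)
    for (r in seq_len(nrow(vn_offsets))) {
      kk <- labelled$k + vn_offsets[r, 3]
      indom <- kk >= 0 & kk < geom$nz
      nbk <- (labelled$i + vn_offsets[r, 1]) %% geom$nx +
        geom$nx * (((labelled$j + vn_offsets[r, 2]) %% geom$ny) +
                   geom$ny * kk)
      hit <- match(nbk, key)
      vacant <- indom & (is.na(hit) | !core[ifelse(is.na(hit), 1L, hit)])
      keep <- keep & !vacant
    }
    core <- core & keep
  }

  lab <- rep(0L, n)
  if (any(core)) {
    ed <- which(!is.na(adj), arr.ind = TRUE)
    ed <- ed[core[ed[, 1]] & core[adj[ed]], , drop = FALSE]
    gcore <- igraph::make_empty_graph(n, directed = FALSE)
    if (nrow(ed)) gcore <- igraph::add_edges(gcore, rbind(ed[, 1], adj[ed]))
    memb <- igraph::components(gcore)$membership
    lab[core] <- as.integer(factor(memb[core]))
    frontier <- which(lab > 0L)
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (u in adj[v, ]) {
          if (!is.na(u) && lab[u] == 0L) {
            lab[u] <- lab[v]
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
  }
  if (any(lab == 0L))
    lab[lab == 0L] <- max(lab) + as.integer(factor(labelled$label[lab == 0L]))
  sizes <- tabulate(lab)
  ord <- order(-sizes, seq_along(sizes))
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(sizes)
  labelled$label <- relab[lab]
  labelled
}

#' Tabulate nests from labelled agents
#'
#' @param labelled Output of [label_nests()].
#' @param delta Lattice spacing, um; defaults to the carried geometry's.
#' @return A data frame with one row per nest: `label`, `n_agents`,
#'   `area_um2`, `area_mm2`, `centroid_i/j/k`, `bbox_*` index ranges.
#' @export
nest_table <- function(labelled, delta = attr(labelled, "geom")$delta) {
  if (nrow(labelled) == 0L)
    return(data.frame(label = integer(), n_agents = integer(),
                      area_um2 = numeric(), area_mm2 = numeric(),
                      centroid_i = numeric(), centroid_j = numeric(),
                      centroid_k = numeric(),
                      bbox_i0 = integer(), bbox_i1 = integer(),
                      bbox_j0 = integer(), bbox_j1 = integer(),
                      bbox_k0 = integer(), bbox_k1 = integer()))
  sp <- split(labelled, labelled$label)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(label = d$label[1], n_agents = nrow(d),
               area_um2 = nest_area(nrow(d), delta),
               area_mm2 = nest_area(nrow(d), delta) * 1e-6,
               centroid_i = mean(d$i), centroid_j = mean(d$j),
               centroid_k = mean(d$k),
               bbox_i0 = min(d$i), bbox_i1 = max(d$i),
               bbox_j0 = min(d$j), bbox_j1 = max(d$j),
               bbox_k0 = min(d$k), bbox_k1 = max(d$k))
  }))
  out <- out[order(out$label), ]
  rownames(out) <- NULL
  out
}

#' Filter out small nests
#'
#' Keeps nests with at least `min_agents` members. The default of 4 drops
#' the extremely small clusters that would not register as nests.
#'
#' @param nests A nest table from [nest_table()] (or any data frame with an
#'   `n_agents` column).
#' @param min_agents Minimum nest size, at least 1.
#' @return The filtered nest table.
#' @export
filter_nests <- function(nests, min_agents = 4) {
  if (min_agents < 1) stop("min_agents must be at least 1", call. = FALSE)
  nests[nests$n_agents >= min_agents, , drop = FALSE]
}

#' Nest area from agent count
#'
#' Each agent contributes `delta^2` of area: at the default 20 um spacing,
#' 400 um^2 per agent, so a 375-agent nest measures 0.15 mm^2. The
#' alternative projected convention counts distinct `(i, j)` columns
#' instead, approximating what a top-down photograph of the surface would
#' show; pass the labelled agents and `convention = "projected"` for that.
#'
#' @param x Agent count (numeric) for `convention = "count"`, or a labelled
#'   agent data frame for `"projected"`.
#' @param delta Lattice spacing, um.
#' @param convention `"count"` (default) or `"projected"`.
#' @return Area in um^2 (vector for vector input; for `"projected"`, one
#'   value per nest label).
#' @export
nest_area <- function(x, delta = 20, convention = c("count", "projected")) {
  convention <- match.arg(convention)
  if (convention == "count") {
    stopifnot(is.numeric(x))
    return(x * delta^2)
  }
  stopifnot(is.data.frame(x))
  vapply(split(x, x$label),
         function(d) nrow(unique(d[, c("i", "j")])) * delta^2,
         numeric(1))
}

#' Boxplot-style summary of nest areas
#'
#' Median and quartiles (linear interpolation), whiskers at the most
#' extreme observations within 1.5 interquartile ranges of the quartiles,
#' and the observations outside the whiskers flagged as outliers — the
#' standard boxplot convention.
#'
#' @param areas Numeric vector of nest areas (um^2).
#' @return An object of class `nest_summary`: list with `n_nests`,
#'   `median`, `q1`, `q3`, `iqr`, `whisker_lo`, `whisker_hi`, `outliers`.
#' @export
summarize_nests <- function(areas) {
  stopifnot(is.numeric(areas))
  if (length(areas) == 0L)
    return(structure(list(n_nests = 0L, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, iqr = NA_real_,
                          whisker_lo = NA_real_, whisker_hi = NA_real_,
                          outliers = numeric()),
                     class = "nest_summary"))
  qs <- unname(stats::quantile(areas, c(0.25, 0.5, 0.75), type = 7))
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- areas >= lo_fence & areas <= hi_fence
  structure(list(n_nests = length(areas), median = qs[2],
                 q1 = qs[1], q3 = qs[3], iqr = iqr,
                 whisker_lo = min(areas[inside]),
                 whisker_hi = max(areas[inside]),
                 outliers = sort(areas[!inside])),
            class = "nest_summary")
}

#' @export
print.nest_summary <- function(x, ...) {
  if (x$n_nests == 0L) {
    cat("nest summary: no nests\n")
    return(invisible(x))
  }
  cat(sprintf("nest summary: %d nests\n", x$n_nests))
  cat(sprintf("  median %.0f um^2 (%.4f mm^2), IQR [%.0f, %.0f] um^2\n",
              x$median, x$median * 1e-6, x$q1, x$q3))
  cat(sprintf("  whiskers [%.0f, %.0f], %d outlier(s)\n",
              x$whisker_lo, x$whisker_hi, length(x$outliers)))
  invisible(x)
}

#' Full nest quantification of a snapshot
#'
#' Labels melanoma nests, drops those below the size filter, and returns
#' the nest table and area summary.
#'
#' @inheritParams label_nests
#' @param min_agents Minimum nest size retained (default 4).
#' @param convention Area convention passed to [nest_area()].
#' @return List with `nests` (filtered nest table) and `summary`
#'   (a `nest_summary`).
#' @export
analyze_nests <- function(snapshot, connectivity = 26, min_agents = 4,
                          convention = c("count", "projected"),
                          geom = attr(snapshot, "geom")) {
  convention <- match.arg(convention)
  lab <- label_nests(snapshot, connectivity, geom)
  nests <- nest_table(lab, geom$delta)
  if (convention == "projected" && nrow(nests) > 0L) {
    proj <- nest_area(lab, geom$delta, "projected")
    nests$area_um2 <- unname(proj[as.character(nests$label)])
    nests$area_mm2 <- nests$area_um2 * 1e-6
  }
  nests <- filter_nests(nests, min_agents)
  list(nests = nests, summary = summarize_nests(nests$area_um2))
}
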