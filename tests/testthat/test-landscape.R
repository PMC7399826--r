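kB <- 0.0083144621

test_that("free-energy differences equal -kT log count ratios exactly", {
  x <- c(rep(0.25, 100), rep(0.75, 10))
  y <- c(rep(0.25, 100), rep(0.75, 10))
  f <- fel_from_points(x, y, temperature = 400, bins = 2)
  occ <- which(f$occupied)
  expect_equal(sum(f$occupied), 2)
  expect_equal(min(f$G[occ]), 0)
  expect_equal(max(f$G[occ]), kB * 400 * log(10))
  # uniform occupancy -> flat zero surface
  g <- expand.grid(x = 1:4, y = 1:4)
  fu <- fel_from_points(g$x, g$y, 300, bins = 4)
  expect_true(all(fu$G[fu$occupied] == 0))
  # doubling all counts changes nothing
  f2 <- fel_from_points(rep(x, 2), rep(y, 2), 400, bins = 2)
  expect_equal(f2$G, f$G)
})

test_that("masked bins stay masked and degenerate input errors", {
  f <- fel_from_points(c(0, 1), c(0, 1), 300, bins = 3)
  expect_true(all(is.na(f$G[!f$occupied])))
  expect_equal(sum(f$occupied), 2)
  expect_error(fel_from_points(c(1, 1), c(2, 2), 300), "distinct")
  expect_error(fel_from_points(1:5, 1:5, -1), "temperature")
})

# build a surface with a planted G grid by inverting G -> counts
fel_from_grid <- function(G, temperature = 300) {
  kT <- kB * temperature
  counts <- round(exp(-G / kT) * 1e6)
  xs <- rep(seq_len(nrow(G)), times = ncol(G))
  ys <- rep(seq_len(ncol(G)), each = nrow(G))
  x <- rep(xs, counts); y <- rep(ys, counts)
  fel_from_points(x, y, temperature, bins = dim(G))
}

test_that("minima detection finds planted wells and respects thresholds", {
  # single-basin paraboloid
  g <- outer((1:7 - 4)^2, (1:7 - 4)^2, `+`) * 0.1
  f <- fel_from_grid(g)
  mn <- find_minima(f)
  expect_equal(nrow(mn), 1)
  expect_equal(c(mn$i, mn$j), c(4, 4))
  # double well with a saddle between
  g2 <- matrix(5, 5, 5)
  g2[2, 2] <- 0; g2[4, 4] <- 1; g2[3, 3] <- 3
  f2 <- fel_from_grid(g2)
  mn2 <- find_minima(f2)
  expect_equal(nrow(mn2), 2)
  expect_equal(c(mn2$i[1], mn2$j[1]), c(2, 2))
  expect_equal(c(mn2$i[2], mn2$j[2]), c(4, 4))
  expect_equal(nrow(find_minima(f2, depth_threshold = 0.5)), 1)
  # flat surface has no strict minima
  expect_equal(nrow(find_minima(fel_from_grid(matrix(1, 4, 4)))), 0)
})

test_that("minimal-gradient path matches exhaustive search on a small grid", {
  set.seed(61)
  # 1D-like double well strip with a planted saddle column
  strip <- rbind(c(0.0, 2.0, 4.0, 2.0, 0.5),
                 c(1.0, 3.0, 4.5, 3.0, 1.5))
  f <- fel_from_grid(t(strip))  # 5 x 2 grid
  p <- minimal_gradient_path(f, c(1, 1), c(5, 1))
  expect_equal(p$cells[1, ], c(i = 1, j = 1))
  expect_equal(p$cells[nrow(p$cells), ], c(i = 5, j = 1))
  expect_true(3 %in% p$cells[, 1])  # crosses the saddle column
  # exhaustive enumeration oracle over all simple paths
  G <- f$G
  best <- Inf
  enumerate <- function(cell, visited, w) {
    if (w >= best) return()
    if (all(cell == c(5, 1))) { best <<- min(best, w); return() }
    nb <- confshape:::.neighbours8(cell[1], cell[2], nrow(G), ncol(G))
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, ]
      key <- paste(v, collapse = ",")
      if (key %in% visited || !f$occupied[v[1], v[2]]) next
      enumerate(v, c(visited, key), w + abs(G[v[1], v[2]] - G[cell[1], cell[2]]))
    }
  }
  enumerate(c(1, 1), "1,1", 0)
  expect_equal(p$total_weight, best, tolerance = 1e-9)
  # reversal symmetry of the total weight
  pr <- minimal_gradient_path(f, c(5, 1), c(1, 1))
  expect_equal(pr$total_weight, p$total_weight, tolerance = 1e-12)
  # trivial and error cases
  p0 <- minimal_gradient_path(f, c(2, 1), c(2, 1))
  expect_equal(nrow(p0$cells), 1)
  expect_error(minimal_gradient_path(f, c(1, 1), c(100, 1)), "occupied")
})

test_that("paths cannot cross masked regions", {
  # two occupied islands separated by an unoccupied column
  x <- c(rep(1, 5), rep(5, 5)); y <- c(1:5, 1:5)
  f <- fel_from_points(x, y, 300, bins = c(5, 5))
  expect_error(minimal_gradient_path(f, c(1, 1), c(5, 1)), "no occupied path")
})

test_that("basin representatives come from the majority conformer", {
  set.seed(62)
  base1 <- matrix(rnorm(15), ncol = 3)
  base2 <- base1 + 3
  # 80/20 split inside one basin at identical collective variables
  frames <- c(replicate(8, base1 + matrix(rnorm(15, 0, 0.01), ncol = 3),
                        simplify = FALSE),
              replicate(2, base2 + matrix(rnorm(15, 0, 0.01), ncol = 3),
                        simplify = FALSE))
  ens <- new_ensemble(point_atoms(5), frames)
  x <- rep(0.5, 10); y <- rep(0.5, 10)
  f <- fel_from_points(c(x, 0, 1), c(y, 0, 1), 300, bins = 3)
  # drop the two padding points from the frame map
  f$frame_bins <- f$frame_bins[1:10, ]
  mn <- data.frame(i = 2, j = 2)
  reps <- basin_representatives(f, ens, mn, basin_radius = 0,
                                cluster_cutoff = 0.5, selection = "all")
  expect_equal(reps[[1]]$n_frames, 10)
  expect_lt(kabsch_rmsd(base1, reps[[1]]$conformation$xyz), 0.1)
  # empty basin warns and returns NULL
  mn2 <- data.frame(i = 1, j = 3)
  expect_warning(r2 <- basin_representatives(f, ens, mn2, 0, 0.5, "all"),
                 "no frames")
  expect_null(r2[[1]])
})
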