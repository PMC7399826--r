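test_that("RMSD of a rigid copy is zero and identity is exact", {
  set.seed(14)
  A <- matrix(rnorm(45), ncol = 3)
  R <- random_rotation()
  B <- sweep(A %*% t(R), 2, c(2, -1, 4), `+`)
  expect_lt(kabsch_rmsd(A, B), 1e-8)
  expect_identical(kabsch_rmsd(A, A), 0)
  expect_error(kabsch_rmsd(A, A[1:10, ]), "size")
})

test_that("RMSD equals the quaternion-method oracle and is symmetric", {
  set.seed(15)
  for (r in 1:20) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- A
    B[1, ] <- B[1, ] + rnorm(3)        # one displaced atom
    if (r > 10) B <- matrix(rnorm(30), ncol = 3)  # unrelated sets
    expect_equal(kabsch_rmsd(A, B), quaternion_rmsd(A, B),
                 tolerance = 1e-8)
    expect_equal(kabsch_rmsd(A, B), kabsch_rmsd(B, A), tolerance = 1e-10)
  }
})

test_that("superposition never produces a reflection", {
  set.seed(16)
  for (r in 1:10) {
    A <- matrix(rnorm(24), ncol = 3)
    B <- matrix(rnorm(24), ncol = 3)
    expect_equal(det(kabsch_superpose(A, B)$rotation), 1, tolerance = 1e-9)
  }
})

test_that("GROMOS clustering recovers planted groups and degenerate cases", {
  set.seed(21)
  # identical frames -> one cluster
  base <- matrix(rnorm(15), ncol = 3)
  ens1 <- new_ensemble(point_atoms(5), replicate(6, base, simplify = FALSE))
  cl1 <- gromos_cluster(ens1, cutoff = 0.1, selection = "all")
  expect_equal(length(cl1$sizes), 1)
  expect_equal(cl1$sizes, 6)
  # two tight groups of genuinely different shape (RMSD is blind to
  # translation), inter-group RMSD >> cutoff >> intra-group
  base2 <- matrix(rnorm(15, 0, 3), ncol = 3)
  grp <- random_cloud_ensemble(12, list(base, base2), noise = 0.01)
  cl2 <- gromos_cluster(grp$ensemble, cutoff = 0.2, selection = "all")
  expect_equal(length(cl2$sizes), 2)
  split_ids <- split(cl2$assignments, grp$labels)
  expect_true(all(vapply(split_ids, function(x) length(unique(x)) == 1,
                         logical(1))))
  expect_false(split_ids[[1]][1] == split_ids[[2]][1])
  # cutoff below all pairwise distances -> singletons
  sing <- random_cloud_ensemble(5, list(base), noise = 0.5)
  cl3 <- gromos_cluster(sing$ensemble, cutoff = 1e-6, selection = "all")
  expect_equal(cl3$sizes, rep(1, 5))
})

test_that("clustering matches the exhaustive brute-force oracle", {
  set.seed(22)
  for (trial in 1:25) {
    nf <- sample(5:50, 1)
    base <- matrix(rnorm(12), ncol = 3)
    frames <- lapply(seq_len(nf), function(i)
      base + matrix(rnorm(12, 0, runif(1, 0.05, 0.6)), ncol = 3))
    ens <- new_ensemble(point_atoms(4), frames)
    rm <- pairwise_rmsd(ens, "all")
    cutoff <- quantile(rm[upper.tri(rm)], runif(1, 0.2, 0.8))
    got <- gromos_cluster(rm, cutoff)
    want <- brute_force_gromos(rm, cutoff)
    expect_identical(got$assignments, want$assignments)
    expect_identical(got$sizes, want$sizes)
    expect_identical(got$centrotypes, want$centers)
    # invariants
    expect_equal(sum(got$sizes), nf)
    expect_true(all(diff(got$sizes) <= 0))
    for (k in seq_along(got$sizes))
      expect_equal(got$assignments[got$centrotypes[k]], k)
  }
})

test_that("RMSD filtering retains exactly the frames below the cutoff", {
  set.seed(23)
  ref <- make_chain(20, 1, seed = 101)
  near <- lapply(1:4, function(i)
    ref$xyz + matrix(rnorm(length(ref$xyz), 0, 0.005), ncol = 3))
  far <- lapply(5:10, function(i) make_chain(20, 0, seed = 200 + i)$xyz)
  ens <- new_ensemble(ref$atoms, c(near, far))
  keep <- rmsd_filter(ens, ref, cutoff = 0.1)
  expect_identical(as.integer(keep), 1:4)
  r <- attr(keep, "rmsd")
  expect_true(all(r[1:4] < 0.1) && all(r[5:10] >= 0.1))
  # the reference itself is always retained; cutoff 0 retains nothing
  ens2 <- new_ensemble(ref$atoms, c(list(ref$xyz), far))
  expect_true(1 %in% rmsd_filter(ens2, ref, cutoff = 1e-9))
  expect_length(rmsd_filter(ens2, ref, cutoff = 0), 0)
})
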