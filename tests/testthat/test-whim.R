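test_that("eigensystem matches a brute-force covariance decomposition", {
  set.seed(101)
  X <- matrix(rnorm(600), ncol = 3) %*% diag(c(2, 1, 0.3))
  es <- whim_eigensystem(X)
  # independent route: explicit population covariance, base eigen
  Xc <- sweep(X, 2, colMeans(X))
  cv <- t(Xc) %*% Xc / nrow(X)
  expect_equal(es$values, sort(eigen(cv)$values, decreasing = TRUE),
               tolerance = 1e-10)
  # scores reproduce the eigenvalues as score variances
  expect_equal(colMeans(es$scores^2), es$values, tolerance = 1e-10)
})

test_that("eigensystem handles limiting configurations", {
  line <- cbind(seq(0, 9.9, 0.1), 0, 0)
  es <- whim_eigensystem(line)
  expect_equal(es$values[2:3], c(0, 0), tolerance = 1e-12)
  cube <- as.matrix(expand.grid(c(0, 1), c(0, 1), c(0, 1)))
  expect_equal(whim_eigensystem(cube)$values, rep(0.25, 3))
  expect_error(whim_eigensystem(matrix(0, 2, 3)), "3 points")
})

test_that("descriptor values follow the closed-form identities", {
  # symmetric cloud, lambda = (1,1,1): K = 0, T = 3, A = 3, V = 2^3 - 1
  oct <- make_isotropic_cloud(6, symmetrize = TRUE)$xyz * sqrt(3)
  w <- whim_vector(oct)
  expect_equal(unname(w["K"]), 0, tolerance = 1e-12)
  expect_equal(unname(w[c("T", "A", "V")]), c(3, 3, 7), tolerance = 1e-9)
  # collinear chain: K = 1, theta1 = 1, theta2 = 0, for any spacing
  for (sp in c(0.1, 0.38, 2)) {
    wl <- whim_vector(make_collinear_chain(30, sp)$xyz)
    expect_equal(unname(wl[c("K", "theta1", "theta2")]), c(1, 1, 0),
                 tolerance = 1e-12)
  }
  # lambda = (2,1,1): theta1 = 0.5, theta2 = 0.25, K = 0.25 (hand values)
  base <- make_isotropic_cloud(6, symmetrize = TRUE)$xyz
  stretched <- base %*% diag(c(sqrt(2) * sqrt(3), sqrt(3), sqrt(3)))
  ws <- whim_vector(stretched)
  expect_equal(unname(ws[c("theta1", "theta2", "K")]), c(0.5, 0.25, 0.25),
               tolerance = 1e-10)
})

test_that("V identity and theta ordering hold on random clouds", {
  set.seed(77)
  for (r in 1:50) {
    X <- matrix(rnorm(150), ncol = 3) %*% diag(runif(3, 0.1, 3))
    w <- whim_vector(X)
    expect_equal(unname(w["V"]),
                 unname(w["T"] + w["A"] +
                          w["lambda1"] * w["lambda2"] * w["lambda3"]),
                 tolerance = 1e-12)
    th3 <- 1 - w[["theta1"]] - w[["theta2"]]
    expect_true(w[["theta1"]] >= w[["theta2"]] &&
                  w[["theta2"]] >= th3 - 1e-12 && th3 >= -1e-12)
    expect_true(w[["K"]] >= 0 && w[["K"]] <= 1)
    expect_equal(unname(w["D"]),
                 unname((w["eta1"] + w["eta2"] + w["eta3"]) / 3))
  }
})

test_that("all 13 descriptors are rigid-motion invariant", {
  set.seed(7)
  X <- make_chain(40, 1, seed = 3)$xyz
  w0 <- whim_vector(X)
  for (r in 1:25) {
    R <- random_rotation()
    t <- rnorm(3, 0, 5)
    w1 <- whim_vector(sweep(X %*% t(R), 2, t, `+`))
    expect_equal(w1, w0, tolerance = 1e-8)
  }
})

test_that("K increases strictly with prolate aspect ratio", {
  set.seed(12)
  base <- matrix(rnorm(3000), ncol = 3)
  Ks <- vapply(c(1, 2, 5, 10, 100), function(a) {
    unname(whim_vector(base %*% diag(c(a, 1, 1)))["K"])
  }, numeric(1))
  expect_true(all(diff(Ks) > 0))
})

test_that("density descriptors match closed-form kurtosis values", {
  set.seed(9)
  # uniform scores along one axis: kurtosis 9/5 -> eta = 5/9
  n <- 1e5
  X <- cbind(runif(n, -1, 1), rnorm(n, 0, 0.1), rnorm(n, 0, 0.01))
  es <- whim_eigensystem(X)
  dd <- density_descriptors(es$scores, es$values)
  expect_equal(dd$eta1, 5 / 9, tolerance = 0.02)
  # Gaussian scores: kurtosis 3 -> eta = 1/3
  expect_equal(dd$eta2, 1 / 3, tolerance = 0.02)
  # two symmetric point masses per axis: kurtosis 1 -> eta = 1
  pm <- as.matrix(expand.grid(c(-1, 1), c(-0.2, 0.2), c(-0.04, 0.04)))
  es2 <- whim_eigensystem(pm)
  dd2 <- density_descriptors(es2$scores, es2$values)
  expect_equal(dd2$eta1, 1, tolerance = 1e-10)
  # zero-variance axis is reported by index
  line <- make_collinear_chain(10)$xyz
  esl <- whim_eigensystem(line)
  expect_error(density_descriptors(esl$scores, esl$values), "axis 2, 3")
  expect_error(whim_vector(matrix(1, 5, 3) * 0 + 1), "variance")
})

test_that("whim_table computes one row per frame with the 13 columns", {
  ts <- make_two_state_ensemble(4, n_residues = 12, seed = 8)
  tab <- suppressWarnings(whim_table(ts$ensemble))
  expect_equal(nrow(tab), 4)
  expect_true(all(whim_columns() %in% names(tab)))
  w1 <- suppressWarnings(
    whim_vector(select_atoms(ts$ensemble, "backbone5")$frames[[2]]))
  expect_equal(unlist(tab[2, whim_columns()]), w1, ignore_attr = TRUE)
})
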