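test_that("essential-dynamics PCA matches a brute-force eigendecomposition", {
  set.seed(51)
  ts <- make_two_state_ensemble(30, n_residues = 10, seed = 17)
  model <- fit_pca_cartesian(ts$ensemble)
  # independent route: superpose with the model's own reference, then
  # eigendecompose the explicit covariance of the flattened coordinates
  ca <- select_atoms(ts$ensemble, "calpha")
  X <- do.call(rbind, lapply(ca$frames, function(f) {
    as.vector(t(kabsch_superpose(model$mean_structure, f)$coords))
  }))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)$values
  evf <- ev / sum(ev)
  k <- length(model$explained_variance_fraction)
  expect_equal(model$explained_variance_fraction, evf[seq_len(k)],
               tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(model$loadings %*% t(model$loadings),
               diag(nrow(model$loadings)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("explained fractions are invariant to a global input rotation", {
  set.seed(52)
  ts <- make_two_state_ensemble(12, n_residues = 8, seed = 3)
  m0 <- fit_pca_cartesian(ts$ensemble)
  R <- random_rotation()
  rot <- new_ensemble(ts$ensemble$topology,
                      lapply(ts$ensemble$frames, function(f) f %*% t(R)))
  m1 <- fit_pca_cartesian(rot)
  expect_equal(m1$explained_variance_fraction,
               m0$explained_variance_fraction, tolerance = 1e-6)
})

test_that("two distinct frames give a one-direction space; degenerate input errors", {
  ts <- make_two_state_ensemble(2, n_residues = 8, seed = 4)
  m <- fit_pca_cartesian(ts$ensemble)
  expect_equal(m$explained_variance_fraction[1], 1, tolerance = 1e-9)
  same <- new_ensemble(ts$ensemble$topology,
                       list(ts$ensemble$frames[[1]],
                            ts$ensemble$frames[[1]]))
  expect_error(fit_pca_cartesian(same), "variance")
  expect_error(fit_pca_cartesian(subset_frames(ts$ensemble, 1)), "frames")
})

test_that("WHIM-space PCA autoscales and matches a brute-force oracle", {
  set.seed(53)
  ts <- make_two_state_ensemble(40, n_residues = 15, seed = 21)
  tab <- suppressWarnings(whim_table(ts$ensemble))
  model <- fit_pca_whim(tab)
  X <- as.matrix(tab[, model$feature_names])
  Xs <- scale(X)  # base-R autoscaling oracle (sd with n-1)
  expect_equal(colMeans(Xs), rep(0, ncol(Xs)), tolerance = 1e-12,
               ignore_attr = TRUE)
  ev <- eigen(crossprod(Xs) / (nrow(Xs) - 1), symmetric = TRUE)$values
  k <- length(model$explained_variance_fraction)
  expect_equal(model$explained_variance_fraction, (ev / sum(ev))[1:k],
               tolerance = 1e-8)
  # PC1 separates the two planted shape classes
  sc <- project_pca(model, tab)
  cls <- split(sc[, 1], ts$labels)
  expect_true(abs(mean(cls$extended) - mean(cls$compact)) >
                2 * sqrt((var(cls$extended) + var(cls$compact)) / 2))
  # constant column is named in the error
  tab2 <- tab; tab2$K <- 1
  expect_error(fit_pca_whim(tab2), "K")
})

test_that("projection is consistent, linear, and centred", {
  set.seed(54)
  ts <- make_two_state_ensemble(25, n_residues = 12, seed = 31)
  tab <- suppressWarnings(whim_table(ts$ensemble))
  model <- fit_pca_whim(tab)
  # model mean projects to the origin
  mu <- setNames(model$mean, model$feature_names)
  expect_equal(as.numeric(project_pca(model, mu)), c(0, 0),
               tolerance = 1e-10)
  # training rows reproduce their training scores (full-rank check via svd)
  sc <- project_pca(model, tab, n_components = 2)
  Xs <- scale(as.matrix(tab[, model$feature_names]))
  ref <- Xs %*% t(model$loadings[1:2, , drop = FALSE])
  expect_equal(sc, ref, tolerance = 1e-10, ignore_attr = TRUE)
  # linearity in the pre-autoscaled space
  x <- unlist(tab[1, model$feature_names]); y <- unlist(tab[2, model$feature_names])
  a <- 0.3
  px <- project_pca(model, x); py <- project_pca(model, y)
  pmix <- project_pca(model, a * x + (1 - a) * y)
  expect_equal(as.numeric(pmix), as.numeric(a * px + (1 - a) * py),
               tolerance = 1e-10)
})

test_that("out-of-sample projection equals hand linear algebra on a toy model", {
  set.seed(55)
  tab <- data.frame(K = c(0.2, 0.4, 0.6, 0.8), T = c(1, 3, 2, 4))
  model <- fit_pca_whim(tab)
  x <- c(K = 0.3, T = 1.2)
  hand <- ((x[model$feature_names] - model$mean) / model$scale) %*%
    t(model$loadings[1:2, ])
  expect_equal(project_pca(model, x), hand, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("cartesian projection of training frames reproduces scores and JSON round-trips", {
  ts <- make_two_state_ensemble(10, n_residues = 8, seed = 41)
  model <- fit_pca_cartesian(ts$ensemble)
  sc <- project_pca(model, ts$ensemble)
  sc3 <- project_pca(model, get_frame(ts$ensemble, 3))
  expect_equal(as.numeric(sc3), as.numeric(sc[3, ]), tolerance = 1e-8)
  path <- withr::local_tempfile(fileext = ".json")
  pca_to_json(model, path)
  back <- pca_from_json(path)
  expect_equal(back$loadings, model$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(project_pca(back, get_frame(ts$ensemble, 3))),
               as.numeric(sc3), tolerance = 1e-8)
})
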