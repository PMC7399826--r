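#' Principal-axis eigensystem of an atomic point cloud
#'
#' Eigendecomposition of the (optionally weighted) covariance matrix of
#' centred coordinates, the geometric core of the WHIM descriptors. The
#' covariance is normalised by the total weight (population convention,
#' i.e. division by n for unit weights). Eigenvector signs are fixed by
#' making each eigenvector's largest-magnitude component positive, so
#' scores are deterministic.
#'
#' @param coords numeric n x 3 matrix, nm.
#' @param weights optional positive weights, length n (default: unit).
#' @return list with `values` (3 eigenvalues, descending, nm^2), `vectors`
#'   (3 x 3, columns are principal axes) and `scores` (n x 3 projections of
#'   the centred coordinates onto the axes).
#' @export
whim_eigensystem <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive and match the number of points")
  w <- weights / sum(weights)
  ctr <- colSums(coords * w)
  x <- sweep(coords, 2, ctr)
  cv <- crossprod(x * w, x)  # sum_i w_i x_i x_i^T, total weight 1
  es <- eigen(cv, symmetric = TRUE)
  vals <- pmax(es$values, 0)
  vecs <- es$vectors
  for (m in 1:3) {
    k <- which.max(abs(vecs[, m]))
    if (vecs[k, m] < 0) vecs[, m] <- -vecs[, m]
  }
  list(values = vals, vectors = vecs, scores = x %*% vecs,
       degenerate = sum(vals) < 1e-300)
}

#' Density descriptors from principal-axis scores
#'
#' Per axis m the kurtosis of the score distribution is
#' kappa_m = (sum_i s_im^4 / n) / lambda_m^2 and the density descriptor is
#' its inverse, eta_m = 1/kappa_m; D is the mean of the three.
#'
#' @param scores n x 3 score matrix (from [whim_eigensystem()]).
#' @param eigenvalues the 3 axis variances.
#' @return named list `eta1`, `eta2`, `eta3`, `D`.
#' @export
density_descriptors <- function(scores, eigenvalues) {
  tot <- sum(eigenvalues)
  bad <- which(eigenvalues <= 1e-12 * max(tot, 1e-300))
  if (length(bad))
    stop("zero eigenvalue on axis ", paste(bad, collapse = ", "),
         ": density descriptor undefined")
  n <- nrow(scores)
  eta <- vapply(1:3, function(m) {
    kappa <- (sum(scores[, m]^4) / n) / eigenvalues[m]^2
    1 / kappa
  }, numeric(1))
  list(eta1 = eta[1], eta2 = eta[2], eta3 = eta[3], D = mean(eta))
}

#' The 13 WHIM descriptors of a point cloud
#'
#' From the principal-axis eigenvalues lambda_1 >= lambda_2 >= lambda_3
#' (axis variances, nm^2) the descriptors are: the eigenvalues themselves
#' (size along each axis); the shape shares theta_m = lambda_m / sum(lambda)
#' for m = 1, 2; the global sizes T = sum(lambda),
#' A = lambda1 lambda2 + lambda1 lambda3 + lambda2 lambda3 and
#' V = prod(1 + lambda_m) - 1 = T + A + lambda1 lambda2 lambda3; the global
#' shape index K = sum_m |lambda_m/sum(lambda) - 1/3| / (4/3), which is 0
#' for spherically isotropic clouds and 1 for strictly collinear ones; and
#' the density descriptors eta_1..3 (inverse kurtosis of the axis scores)
#' with D their mean. eta_m is NA on axes of zero variance (e.g. a
#' collinear chain), where the score distribution degenerates.
#'
#' K, theta, eta and D are scale-invariant; lambda, T, A and V carry the
#' nm^2 scale of the coordinates.
#'
#' @inheritParams whim_eigensystem
#' @return named numeric vector of length 13: `lambda1..3`, `theta1..2`,
#'   `T`, `A`, `V`, `K`, `eta1..3`, `D`.
#' @export
whim_vector <- function(coords, weights = NULL) {
  es <- whim_eigensystem(coords, weights)
  l <- es$values
  tot <- sum(l)
  if (tot <= 0) stop("total variance is zero: shape undefined")
  theta <- l / tot
  K <- sum(abs(theta - 1 / 3)) / (4 / 3)
  Tsz <- sum(l)
  A <- l[1] * l[2] + l[1] * l[3] + l[2] * l[3]
  V <- prod(1 + l) - 1
  eta <- rep(NA_real_, 3)
  n <- nrow(es$scores)
  for (m in 1:3) {
    if (l[m] > 1e-12 * tot) {
      kappa <- (sum(es$scores[, m]^4) / n) / l[m]^2
      eta[m] <- 1 / kappa
    }
  }
  D <- if (anyNA(eta)) NA_real_ else mean(eta)
  c(lambda1 = l[1], lambda2 = l[2], lambda3 = l[3],
    theta1 = theta[1], theta2 = theta[2],
    T = Tsz, A = A, V = V, K = K,
    eta1 = eta[1], eta2 = eta[2], eta3 = eta[3], D = D)
}

#' Per-frame WHIM descriptor table of an ensemble
#'
#' Applies [whim_vector()] to the chosen atom selection of every frame.
#'
#' @param ensemble an `ensemble`.
#' @param selection atom selection passed to [select_atoms()]; the
#'   backbone (N, H, CA, C, O) by default.
#' @param weights optional per-atom weights (after selection).
#' @return data.frame with a `frame` column (1-based) and the 13
#'   descriptor columns.
#' @export
whim_table <- function(ensemble, selection = "backbone5", weights = NULL) {
  sub <- select_atoms(ensemble, selection)
  rows <- t(vapply(sub$frames, function(f) whim_vector(f, weights),
                   numeric(13)))
  data.frame(frame = seq_len(nrow(rows)), rows)
}

#' Names of the 13 WHIM descriptor columns
#' @return character vector.
#' @export
whim_columns <- function() {
  c("lambda1", "lambda2", "lambda3", "theta1", "theta2",
    "T", "A", "V", "K", "eta1", "eta2", "eta3", "D")
}
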