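# Independent oracles and geometric fixtures used across the suite. These
# deliberately avoid the package's own code paths wherever they serve as a
# cross-check.

# Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Quaternion (Horn) method for the minimal RMSD between two point sets:
# an algebraically independent alternative to the SVD-based Kabsch route.
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  M <- crossprod(B0, A0)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lam) / nrow(A)
  sqrt(max(0, msd))
}

# Exhaustive re-derivation of GROMOS clustering: recompute neighbour
# counts from scratch every round on the remaining frames.
brute_force_gromos <- function(rmsd_matrix, cutoff) {
  n <- nrow(rmsd_matrix)
  remaining <- seq_len(n)
  assignments <- integer(n)
  centers <- integer(0)
  sizes <- integer(0)
  while (length(remaining)) {
    counts <- vapply(remaining, function(i) {
      sum(rmsd_matrix[i, setdiff(remaining, i)] < cutoff)
    }, integer(1))
    center <- remaining[which.max(counts)]
    members <- remaining[rmsd_matrix[center, remaining] < cutoff |
                           remaining == center]
    centers <- c(centers, center)
    sizes <- c(sizes, length(members))
    assignments[members] <- length(centers)
    remaining <- setdiff(remaining, members)
  }
  ord <- order(-sizes, centers)
  relabel <- integer(length(centers))
  relabel[ord] <- seq_along(centers)
  list(assignments = relabel[assignments], centers = centers[ord],
       sizes = sizes[ord])
}

# Monte-Carlo SASA oracle: random points on each expanded sphere.
monte_carlo_sasa <- function(xyz, radii, probe, n_mc = 1e5) {
  n <- nrow(xyz)
  total <- 0
  for (i in seq_len(n)) {
    Ri <- radii[i] + probe
    p <- matrix(rnorm(3 * n_mc), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * Ri
    p <- sweep(p, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      Rj <- radii[j] + probe
      d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      exposed <- exposed & d2 >= Rj^2
    }
    total <- total + 4 * pi * Ri^2 * mean(exposed)
  }
  total
}

# Small atom table for bare point-cloud conformations.
point_atoms <- function(n, element = "C", radius = 0.17) {
  data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
             resno = seq_len(n), chain = "A", element = element,
             vdw_radius = radius, stringsAsFactors = FALSE)
}

point_conformation <- function(xyz, element = "C", radius = 0.17) {
  new_conformation(point_atoms(nrow(xyz), element, radius), xyz)
}

# Idealised flat antiparallel two-strand ladder: backbone N, H, CA, C, O
# placed so that the canonical reciprocal N-H...O=C bonds form between
# x-aligned residue pairs of the two strands (0.48 nm strand spacing,
# carbonyls facing each other).
make_flat_sheet <- function(n = 8, spacing = 0.35, sep = 0.48) {
  res <- list()
  for (i in 1:n) {
    x <- i * spacing
    res[[i]] <- list(N = c(x - 0.12, 0, 0), H = c(x - 0.12, 0.10, 0),
                     CA = c(x, 0, 0.05 * (-1)^i), C = c(x + 0.12, 0, 0),
                     O = c(x + 0.12, 0.123, 0))
  }
  for (j in 1:n) {
    x <- (n + 1 - j) * spacing
    res[[n + j]] <- list(N = c(x + 0.12, sep, 0),
                         H = c(x + 0.12, sep - 0.10, 0),
                         CA = c(x, sep, 0.05 * (-1)^j),
                         C = c(x - 0.12, sep, 0),
                         O = c(x - 0.12, sep - 0.123, 0))
  }
  confshape:::.conformation_from_residues(res)
}

# Ensemble of random rigid placements of small point clouds, optionally
# from several distinct base shapes (for clustering tests).
random_cloud_ensemble <- function(n_frames, base_list, noise = 0) {
  n_at <- nrow(base_list[[1]])
  labels <- sample(rep_len(seq_along(base_list), n_frames))
  frames <- lapply(labels, function(l) {
    b <- base_list[[l]]
    b + matrix(rnorm(length(b), 0, noise), ncol = 3)
  })
  list(ensemble = new_ensemble(point_atoms(n_at), frames), labels = labels)
}
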