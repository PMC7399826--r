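#' Minimal RMSD under optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of B onto A over all proper rotations and
#' translations (no reflection), via the SVD of the cross-covariance
#' matrix, followed by the root-mean-square deviation.
#'
#' @param A,B m x 3 coordinate matrices, nm, equal atom counts (m >= 3).
#' @return RMSD in nm.
#' @export
kabsch_rmsd <- function(A, B) {
  if (identical(dim(A), dim(B)) && all(A == B)) return(0)
  fit <- kabsch_superpose(A, B)
  sqrt(mean(rowSums((fit$coords - A)^2)))
}

#' Optimal rigid superposition of B onto A
#'
#' @inheritParams kabsch_rmsd
#' @return list with `rotation` (3 x 3, proper), `coords` (B superposed
#'   onto A) and the centroids used.
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("coordinate sets differ in size")
  if (nrow(A) < 3) stop("need at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  coords <- sweep(B0 %*% t(R), 2, ca, `+`)
  list(rotation = R, coords = coords, centroid_fixed = ca,
       centroid_mobile = cb)
}

#' Pairwise RMSD matrix of an ensemble
#'
#' @param ensemble an `ensemble`.
#' @param selection atom selection for the comparison (default backbone).
#' @return symmetric n_frames x n_frames matrix of minimal RMSDs (nm).
#' @export
pairwise_rmsd <- function(ensemble, selection = "backbone5") {
  sub <- if (identical(selection, "all")) ensemble else
    suppressWarnings(select_atoms(ensemble, selection))
  nf <- n_frames(sub)
  m <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in 1:(nf - 1)) {
      for (j in (i + 1):nf) {
        m[i, j] <- m[j, i] <- kabsch_rmsd(sub$frames[[i]], sub$frames[[j]])
      }
    }
  }
  m
}

#' GROMOS conformational clustering
#'
#' Daura neighbour-counting algorithm: count, for every unassigned frame,
#' its neighbours at RMSD strictly below the cutoff; the frame with most
#' neighbours (ties broken by lowest frame index) becomes the centrotype
#' of a new cluster containing it and its neighbours; remove them and
#' repeat. Clusters are numbered by decreasing size (ties by centrotype
#' frame index).
#'
#' @param ensemble an `ensemble`, or a precomputed symmetric RMSD matrix.
#' @param cutoff neighbour cutoff, nm (strict `<`).
#' @param selection atom selection when an ensemble is given.
#' @return object of class `cluster_result`: list with `assignments`
#'   (frame -> cluster id), `centrotypes` (per-cluster frame index),
#'   `sizes`, and `cutoff`.
#' @export
gromos_cluster <- function(ensemble, cutoff, selection = "backbone5") {
  if (cutoff <= 0) stop("cutoff must be > 0")
  rm <- if (is.matrix(ensemble)) ensemble else
    pairwise_rmsd(ensemble, selection)
  nf <- nrow(rm)
  neigh <- rm < cutoff
  diag(neigh) <- FALSE
  remaining <- rep(TRUE, nf)
  assignments <- integer(nf)
  centrotypes <- integer(0)
  sizes <- integer(0)
  k <- 0
  while (any(remaining)) {
    counts <- colSums(neigh[remaining, , drop = FALSE])
    counts[!remaining] <- -1L
    center <- which.max(counts)  # ties -> lowest index
    members <- which(remaining & (neigh[, center] | seq_len(nf) == center))
    k <- k + 1
    assignments[members] <- k
    centrotypes[k] <- center
    sizes[k] <- length(members)
    remaining[members] <- FALSE
  }
  # renumber by decreasing size, ties by centrotype index
  ord <- order(-sizes, centrotypes)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(assignments = relabel[assignments],
                 centrotypes = centrotypes[ord],
                 sizes = sizes[ord], cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("GROMOS clustering:", length(x$sizes), "cluster(s), cutoff",
      x$cutoff, "nm\n")
  df <- data.frame(cluster = seq_along(x$sizes), size = x$sizes,
                   percent = round(100 * x$sizes / sum(x$sizes), 1),
                   centrotype_frame = x$centrotypes)
  print(head(df, 10), row.names = FALSE)
  invisible(x)
}

# Match reference atoms onto the ensemble topology by (chain, resno, name).
.map_reference <- function(topology, reference, selection) {
  want <- switch(selection, backbone5 = c("N", "H", "CA", "C", "O"),
                 calpha = "CA", all = unique(topology$name))
  tkey <- paste(topology$chain, topology$resno, topology$name)
  rat <- reference$atoms
  rkey <- paste(rat$chain, rat$resno, rat$name)
  tsel <- which(topology$name %in% want)
  common <- intersect(tkey[tsel], rkey)
  if (length(common) < 3) {
    stop("reference does not map onto the ensemble topology; unmatched: ",
         paste(head(setdiff(tkey[tsel], rkey), 10), collapse = ", "))
  }
  list(ens_idx = match(common, tkey), ref_idx = match(common, rkey))
}

#' Filter ensemble frames by RMSD to a reference structure
#'
#' Keeps the frames whose minimal backbone RMSD to the reference is
#' strictly below the cutoff, e.g. to pool bound-like conformations before
#' clustering.
#'
#' @param ensemble an `ensemble`.
#' @param reference a `conformation`; atoms are matched onto the ensemble
#'   topology by chain, residue number and atom name.
#' @param cutoff RMSD cutoff, nm (strict `<`).
#' @param selection atom subset used for the RMSD (default backbone).
#' @return integer vector of retained frame indices (original order), with
#'   attribute `rmsd` carrying every frame's RMSD to the reference.
#' @export
rmsd_filter <- function(ensemble, reference, cutoff, selection = "backbone5") {
  mp <- .map_reference(ensemble$topology, reference, selection)
  ref <- reference$xyz[mp$ref_idx, , drop = FALSE]
  r <- vapply(ensemble$frames, function(f) {
    kabsch_rmsd(ref, f[mp$ens_idx, , drop = FALSE])
  }, numeric(1))
  keep <- which(r < cutoff)
  attr(keep, "rmsd") <- r
  keep
}

#' Keep a subset of frames of an ensemble
#' @param ensemble an `ensemble`.
#' @param idx frame indices to keep, in order.
#' @return the sub-ensemble.
#' @export
subset_frames <- function(ensemble, idx) {
  new_ensemble(ensemble$topology, ensemble$frames[idx],
               if (!is.null(ensemble$frame_labels))
                 ensemble$frame_labels[idx])
}
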