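# Deterministic generators of conformations and ensembles with known shape
# classes, mixture fractions and secondary structure. All generators are
# pure functions of their arguments (including the seed): identical calls
# give bit-identical output, and the caller's RNG state is left untouched.
#
# Geometry constants (nm / degrees):
#   CA-CA virtual bond 0.38, hard-core CA-CA exclusion 0.30,
#   N-CA 0.1458, CA-C 0.1525, C-N 0.1329, C=O 0.1231, N-H 0.10,
#   angles N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8,
#   omega 180.
.BB <- list(ca_ca = 0.38, hard_core = 0.30,
            n_ca = 0.1458, ca_c = 0.1525, c_n = 0.1329, c_o = 0.1231,
            n_h = 0.10,
            ang_ncac = 111.2, ang_cacn = 116.2, ang_cnca = 121.7,
            ang_caco = 120.8, omega = 180)

.peptide_atom_table <- function(n_res, atom_names) {
  n_at <- length(atom_names)
  el <- substr(sub("^[0-9]*", "", atom_names), 1, 1)
  data.frame(
    serial = seq_len(n_res * n_at),
    name = rep(atom_names, n_res),
    resname = "ALA",
    resno = rep(seq_len(n_res), each = n_at),
    chain = "A",
    element = rep(el, n_res),
    vdw_radius = .assign_radii(rep(el, n_res)),
    stringsAsFactors = FALSE)
}

# Build a full backbone (N, H, CA, C, O) chain from uniform torsions.
.build_backbone <- function(n_res, phi, psi, omega = .BB$omega) {
  g <- .BB
  res <- vector("list", n_res)
  n1 <- c(0, 0, 0)
  ca1 <- c(g$n_ca, 0, 0)
  ang <- g$ang_ncac * pi / 180
  c1 <- ca1 + g$ca_c * c(-cos(ang), sin(ang), 0)
  res[[1]] <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(n_res)) {
    r <- res[[i]]
    # carbonyl O: trans to the next N direction (dihedral psi + 180)
    res[[i]]$O <- .place_atom(r$N, r$CA, r$C, g$c_o, g$ang_caco, psi + 180)
    if (i == n_res) break
    nn <- .place_atom(r$N, r$CA, r$C, g$c_n, g$ang_cacn, psi)
    nca <- .place_atom(r$CA, r$C, nn, g$n_ca, g$ang_cnca, omega)
    nc <- .place_atom(r$C, nn, nca, g$ca_c, g$ang_ncac, phi)
    res[[i + 1]] <- list(N = nn, CA = nca, C = nc)
  }
  res <- .with_amide_h(res)
  .conformation_from_residues(res)
}

.conformation_from_residues <- function(res_list,
                                        order = c("N", "H", "CA", "C", "O")) {
  rows <- list(); names_v <- c(); resno_v <- c()
  for (i in seq_along(res_list)) {
    for (nm in order) {
      if (!is.null(res_list[[i]][[nm]])) {
        rows[[length(rows) + 1]] <- res_list[[i]][[nm]]
        names_v <- c(names_v, nm)
        resno_v <- c(resno_v, i)
      }
    }
  }
  el <- substr(names_v, 1, 1)
  atoms <- data.frame(serial = seq_along(names_v), name = names_v,
                      resname = "ALA", resno = resno_v, chain = "A",
                      element = el, vdw_radius = .assign_radii(el),
                      stringsAsFactors = FALSE)
  new_conformation(atoms, do.call(rbind, rows))
}

#' Strictly collinear chain (shape-index limit K = 1)
#'
#' Atoms on a straight line; the principal-axis spectrum is rank 1
#' (lambda2 = lambda3 = 0), so the WHIM shape index is exactly 1 for any
#' spacing.
#'
#' @param n_atoms number of atoms (>= 3).
#' @param spacing inter-atom spacing, nm (default 0.38).
#' @return a `conformation` of CA pseudo-atoms.
#' @export
make_collinear_chain <- function(n_atoms, spacing = 0.38) {
  if (n_atoms < 3) stop("need >= 3 atoms")
  xyz <- cbind((seq_len(n_atoms) - 1) * spacing, 0, 0)
  new_conformation(.peptide_atom_table(n_atoms, "CA"), xyz)
}

#' Isotropic point cloud (shape-index limit K = 0)
#'
#' With `symmetrize = TRUE` returns a point set whose covariance
#' eigenvalues are exactly equal -- the 6 regular-octahedron vertices
#' (`n_atoms = 6`) or the 8 cube vertices (`n_atoms = 8`) -- giving K = 0
#' exactly. Otherwise samples `n_atoms` points uniformly in a unit ball
#' (K near 0 for large n).
#'
#' @param n_atoms number of atoms (>= 4; must be 6 or 8 when
#'   `symmetrize = TRUE`).
#' @param seed RNG seed for the ball sample.
#' @param symmetrize exact-symmetry construction instead of sampling.
#' @return a `conformation` of CA pseudo-atoms.
#' @export
make_isotropic_cloud <- function(n_atoms, seed = 1, symmetrize = FALSE) {
  if (n_atoms < 4) stop("need >= 4 atoms")
  if (symmetrize) {
    xyz <- switch(as.character(n_atoms),
      "6" = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1)),
      "8" = as.matrix(expand.grid(c(-0.5, 0.5), c(-0.5, 0.5),
                                  c(-0.5, 0.5))),
      stop("symmetrize supports n_atoms = 6 (octahedron) or 8 (cube)"))
    colnames(xyz) <- NULL
  } else {
    xyz <- .with_seed(seed, {
      p <- matrix(rnorm(3 * n_atoms), ncol = 3)
      r <- runif(n_atoms)^(1 / 3)
      p * (r / sqrt(rowSums(p^2)))
    })
  }
  new_conformation(.peptide_atom_table(n_atoms, "CA"), xyz)
}

#' Ideal alpha-helix backbone
#'
#' Full backbone (N, H, CA, C, O) built at phi = -57, psi = -47 degrees
#' with standard bond lengths and angles; interior residues form the
#' canonical i -> i+4 hydrogen-bond ladder.
#'
#' @param n_residues number of residues (>= 6).
#' @return a `conformation`.
#' @export
make_ideal_helix <- function(n_residues) {
  if (n_residues < 6) stop("need >= 6 residues")
  .build_backbone(n_residues, phi = -57, psi = -47)
}

#' Uniform-torsion backbone chain
#'
#' Full backbone with every residue at the same (phi, psi); the default
#' phi = psi = 180 gives a fully extended chain with no internal hydrogen
#' bonds.
#'
#' @param n_residues number of residues (>= 2).
#' @param phi,psi backbone torsions, degrees.
#' @return a `conformation`.
#' @export
make_extended_chain <- function(n_residues, phi = 180, psi = 180) {
  if (n_residues < 2) stop("need >= 2 residues")
  .build_backbone(n_residues, phi = phi, psi = psi)
}

# Complete a CA trace to an N, CA, C, O backbone by schematic geometry:
# shape-faithful, not hydrogen-bond-faithful.
.complete_backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  res <- vector("list", n)
  prev_d <- c(0, 0, 1)
  for (i in seq_len(n)) {
    d <- if (i < n) .unit(ca[i + 1, ] - ca[i, ]) else prev_d
    ref <- if (abs(sum(d * c(0, 0, 1))) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    q <- .unit(.vcross(d, ref))
    o_dir <- .unit(.vcross(d, q))
    res[[i]] <- list(
      N = ca[i, ] - .BB$n_ca * .unit(d - 0.4 * q),
      CA = ca[i, ],
      C = ca[i, ] + .BB$ca_c * .unit(d + 0.4 * q),
      O = ca[i, ] + .BB$ca_c * .unit(d + 0.4 * q) + .BB$c_o * o_dir)
    prev_d <- d
  }
  .conformation_from_residues(res, order = c("N", "CA", "C", "O"))
}

#' Self-avoiding random chain with tunable compactness
#'
#' A self-avoiding CA random walk (step 0.38 nm, hard-core exclusion
#' 0.30 nm) whose step choice is weighted by
#' exp(persistence * cos(turn angle) - bias * distance-to-centroid):
#' bias 0 with no persistence gives an expanded coil, a large bias a
#' collapsed globule, and positive persistence a locally stiff, elongated
#' chain (worm-like-chain style). The CA trace is completed to an
#' N, CA, C, O backbone by schematic standard geometry.
#'
#' @param n_residues chain length.
#' @param compactness_bias non-negative collapse strength (default 0).
#' @param seed RNG seed.
#' @param persistence non-negative directional stiffness (default 0).
#' @param n_candidates candidate directions per step (default 40).
#' @return a `conformation`; attribute `ca_trace` carries the raw CA
#'   coordinates.
#' @export
make_chain <- function(n_residues, compactness_bias = 0, seed = 1,
                       persistence = 0, n_candidates = 40) {
  if (compactness_bias < 0) stop("compactness_bias must be >= 0")
  if (n_residues < 3) stop("need >= 3 residues")
  g <- .BB
  ca <- .with_seed(seed, {
    for (attempt in 1:50) {
      m <- matrix(0, n_residues, 3)
      m[2, ] <- c(g$ca_ca, 0, 0)
      ok <- TRUE
      for (i in 3:n_residues) {
        dirs <- matrix(rnorm(3 * n_candidates), ncol = 3)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        cand <- sweep(dirs * g$ca_ca, 2, m[i - 1, ], `+`)
        prev <- m[seq_len(i - 2), , drop = FALSE]
        d2 <- outer(rowSums(cand^2), rep(1, nrow(prev))) +
          outer(rep(1, nrow(cand)), rowSums(prev^2)) -
          2 * tcrossprod(cand, prev)
        mind2 <- do.call(pmin, as.data.frame(d2))
        valid <- which(mind2 >= g$hard_core^2)
        if (!length(valid)) { ok <- FALSE; break }
        ctr <- colMeans(m[seq_len(i - 1), , drop = FALSE])
        dctr <- sqrt(rowSums(sweep(cand[valid, , drop = FALSE], 2,
                                   ctr)^2))
        cosang <- (dirs[valid, , drop = FALSE] %*%
                     ((m[i - 1, ] - m[i - 2, ]) / g$ca_ca))[, 1]
        w <- exp(persistence * cosang - compactness_bias * dctr)
        pick <- valid[sample.int(length(valid), 1, prob = w / sum(w))]
        m[i, ] <- cand[pick, ]
      }
      if (ok) break
    }
    if (!ok) stop("chain placement failed after bounded retries")
    m
  })
  conf <- .complete_backbone_from_ca(ca)
  attr(conf, "ca_trace") <- ca
  conf
}

#' Two-state synthetic conformational ensemble
#'
#' Each frame is drawn from the extended class (a stiff, elongated chain:
#' persistence `extended_persistence`, no collapse bias) with probability
#' `fraction_extended`, otherwise from the compact class (a collapsed
#' globule: collapse bias `compact_bias`), emulating the mixed
#' compact/extended ensembles of disordered peptides in solution. The two
#' classes are well separated in the WHIM shape index K, so the mixture is
#' clearly bimodal. The true class labels are returned so downstream
#' recovery (deconvolution, clustering) can be scored against ground
#' truth. Identical arguments produce bit-identical ensembles.
#'
#' @param n_frames number of frames.
#' @param n_residues residues per chain (default 70).
#' @param fraction_extended probability of the extended class
#'   (default 0.7).
#' @param extended_bias,compact_bias compactness biases of the two classes
#'   (defaults 0 and 8).
#' @param extended_persistence directional stiffness of the extended
#'   class (default 2.5).
#' @param seed RNG seed.
#' @return list with `ensemble` and `labels` (character, "extended" or
#'   "compact").
#' @export
make_two_state_ensemble <- function(n_frames, n_residues = 70,
                                    fraction_extended = 0.7,
                                    extended_bias = 0, compact_bias = 8,
                                    extended_persistence = 2.5,
                                    seed = 1) {
  if (fraction_extended < 0 || fraction_extended > 1)
    stop("fraction_extended must be in [0, 1]")
  draws <- .with_seed(seed, list(
    u = runif(n_frames),
    frame_seeds = sample.int(.Machine$integer.max - 1, n_frames)))
  labels <- ifelse(draws$u < fraction_extended, "extended", "compact")
  confs <- lapply(seq_len(n_frames), function(i) {
    ext <- labels[i] == "extended"
    make_chain(n_residues,
               compactness_bias = if (ext) extended_bias else compact_bias,
               seed = draws$frame_seeds[i],
               persistence = if (ext) extended_persistence else 0)
  })
  ens <- new_ensemble(confs[[1]]$atoms, lapply(confs, `[[`, "xyz"),
                      frame_labels = labels)
  list(ensemble = ens, labels = labels)
}
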