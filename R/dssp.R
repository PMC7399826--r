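#' Kabsch-Sander backbone hydrogen-bond energy
#'
#' Electrostatic model of the backbone N-H...O=C hydrogen bond:
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol with
#' inter-atom distances in Angstrom (inputs are in nm and converted).
#' A hydrogen bond is counted when E < -0.5 kcal/mol. Distances below
#' 0.05 nm are clamped to 0.05 nm and the result carries attribute
#' `degenerate = TRUE`.
#'
#' @param donor_N,donor_H,acceptor_C,acceptor_O 3-vectors, nm.
#' @return energy in kcal/mol.
#' @export
hbond_energy <- function(donor_N, donor_H, acceptor_C, acceptor_O) {
  rON <- sqrt(sum((acceptor_O - donor_N)^2))
  rCH <- sqrt(sum((acceptor_C - donor_H)^2))
  rOH <- sqrt(sum((acceptor_O - donor_H)^2))
  rCN <- sqrt(sum((acceptor_C - donor_N)^2))
  clamped <- any(c(rON, rCH, rOH, rCN) < 0.05)
  rON <- max(rON, 0.05); rCH <- max(rCH, 0.05)
  rOH <- max(rOH, 0.05); rCN <- max(rCN, 0.05)
  # 0.084 * 332 with r in Angstrom; coordinates are nm, hence /10
  e <- 0.084 * 332 * (1 / (rON * 10) + 1 / (rCH * 10) -
                      1 / (rOH * 10) - 1 / (rCN * 10))
  if (clamped) attr(e, "degenerate") <- TRUE
  e
}

.HBOND_CUTOFF <- -0.5   # kcal/mol
.BEND_ANGLE <- 70       # degrees

# n_res x n_res logical matrix: hb[d, a] TRUE when the amide of residue d
# donates a hydrogen bond to the carbonyl of residue a.
.hbond_matrix <- function(res) {
  n <- length(res)
  hb <- matrix(FALSE, n, n)
  for (d in seq_len(n)) {
    rd <- res[[d]]
    if (is.null(rd$N) || is.null(rd$H)) next
    for (a in seq_len(n)) {
      if (abs(d - a) < 2) next
      ra <- res[[a]]
      if (is.null(ra$C) || is.null(ra$O)) next
      e <- hbond_energy(rd$N, rd$H, ra$C, ra$O)
      hb[d, a] <- e < .HBOND_CUTOFF
    }
  }
  hb
}

#' Assign per-residue secondary structure
#'
#' A faithful-but-simplified implementation of the Kabsch-Sander rules:
#' backbone amide-to-carbonyl hydrogen bonds are detected with the
#' electrostatic energy model ([hbond_energy()], cutoff -0.5 kcal/mol;
#' missing amide hydrogens are reconstructed geometrically). n-turns at
#' offsets 3/4/5 define G/H/I helices (two consecutive turns of the same
#' offset), parallel and antiparallel bridge patterns define strand (E;
#' isolated bridges B), remaining turn-bracketed residues are T, and
#' residues where the chain direction changes by more than 70 degrees
#' (C-alpha i-2, i, i+2) are bends S. Everything else is coil C. When a
#' residue matches several patterns the priority is
#' H > E > B > G > I > T > S > C.
#'
#' The eight classes are reduced to five categories:
#' H/G/I -> Helix, E/B -> Strand, T -> Turn, S -> Bend, C -> Coil.
#'
#' @param conformation a `conformation` with backbone N, CA, C, O per
#'   residue (H optional).
#' @return object of class `ss_assignment`: list with `classes` (8-state
#'   character vector) and `categories` (factor with levels Helix, Strand,
#'   Turn, Bend, Coil).
#' @export
assign_secondary_structure <- function(conformation) {
  res <- .residue_atoms(conformation)
  n <- length(res)
  if (n < 5) {
    warning("fewer than 5 residues: all residues assigned coil")
    cls <- rep("C", n)
    return(.ss_result(cls))
  }
  res <- .with_amide_h(res)
  hb <- .hbond_matrix(res)

  # n-turn at acceptor residue i, offset k: donor i+k bonds acceptor i
  turn <- list()
  for (k in 3:5) {
    t_k <- rep(FALSE, n)
    for (i in seq_len(n - k)) t_k[i] <- hb[i + k, i]
    turn[[as.character(k)]] <- t_k
  }

  helix <- list()
  for (k in 3:5) {
    h_k <- rep(FALSE, n)
    t_k <- turn[[as.character(k)]]
    for (i in 2:(n - k)) {
      if (t_k[i - 1] && t_k[i]) h_k[i:(i + k - 1)] <- TRUE
    }
    helix[[as.character(k)]] <- h_k
  }

  # bridges (parallel / antiparallel), |i - j| >= 3
  bridge <- rep(FALSE, n)
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (abs(i - j) < 3) next
      par <- (hb[j, i - 1] && hb[i + 1, j]) || (hb[i, j - 1] && hb[j + 1, i])
      anti <- (hb[i, j] && hb[j, i]) ||
        (j + 1 <= n && i - 1 >= 1 && j - 1 >= 1 && i + 1 <= n &&
         hb[j + 1, i - 1] && hb[i + 1, j - 1])
      if (par || anti) { bridge[i] <- TRUE; bridge[j] <- TRUE }
    }
  }
  # extended (ladder) vs isolated bridge
  extended <- bridge & (c(FALSE, bridge[-n]) | c(bridge[-1], FALSE))

  # turn flag: residues bracketed by any n-turn
  tflag <- rep(FALSE, n)
  for (k in 3:5) {
    t_k <- turn[[as.character(k)]]
    for (i in which(t_k)) {
      lo <- min(i + 1, n); hi <- min(i + k - 1, n)
      tflag[lo:hi] <- TRUE
    }
  }

  # bend: direction change at Calpha over i-2 -> i -> i+2
  sflag <- rep(FALSE, n)
  for (i in 3:(n - 2)) {
    a <- res[[i - 2]]$CA; b <- res[[i]]$CA; c <- res[[i + 2]]$CA
    if (is.null(a) || is.null(b) || is.null(c)) next
    sflag[i] <- .angle_deg(b - a, c - b) > .BEND_ANGLE
  }

  cls <- rep("C", n)
  cls[sflag] <- "S"
  cls[tflag] <- "T"
  cls[helix[["5"]]] <- "I"
  cls[helix[["3"]]] <- "G"
  cls[bridge & !extended] <- "B"
  cls[extended] <- "E"
  cls[helix[["4"]]] <- "H"
  .ss_result(cls)
}

.ss_category_map <- c(H = "Helix", G = "Helix", I = "Helix",
                      E = "Strand", B = "Strand",
                      T = "Turn", S = "Bend", C = "Coil")

.ss_result <- function(cls) {
  structure(list(
    classes = cls,
    categories = factor(unname(.ss_category_map[cls]),
                        levels = c("Helix", "Strand", "Turn", "Bend", "Coil"))
  ), class = "ss_assignment")
}

#' Ensemble-averaged secondary-structure fractions
#'
#' Assigns secondary structure to every frame and reports the category
#' fractions pooled over all residues and frames, plus the per-residue
#' category fractions over frames (helix propensity profiles etc.).
#'
#' @param ensemble an `ensemble` with backbone atoms.
#' @return list with `fractions` (named numeric: coil, bend, turn, helix,
#'   strand; sums to 1) and `per_residue` (n_residues x 5 matrix of
#'   fractions over frames).
#' @export
ss_fractions <- function(ensemble) {
  nf <- n_frames(ensemble)
  cats <- c("Helix", "Strand", "Turn", "Bend", "Coil")
  counts <- NULL
  for (i in seq_len(nf)) {
    a <- assign_secondary_structure(get_frame(ensemble, i))
    m <- outer(as.character(a$categories), cats, `==`)
    counts <- if (is.null(counts)) m + 0 else counts + m
  }
  colnames(counts) <- cats
  per_res <- counts / nf
  tot <- colSums(counts) / sum(counts)
  fr <- c(coil = unname(tot["Coil"]), bend = unname(tot["Bend"]),
          turn = unname(tot["Turn"]), helix = unname(tot["Helix"]),
          strand = unname(tot["Strand"]))
  list(fractions = fr, per_residue = per_res)
}
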