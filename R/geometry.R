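# Internal 3D geometry helpers shared by the builders and the
# secondary-structure module. All lengths in nm, angles in degrees at the
# interfaces (radians internally).

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place atom D from reference atoms A-B-C with bond length |CD|, angle
# B-C-D and dihedral A-B-C-D (natural extension reference frame).
.place_atom <- function(a, b, c, length, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d2 <- length * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

.angle_deg <- function(u, v) {
  cosang <- sum(.unit(u) * .unit(v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Rotation matrix from an axis (unit vector) and angle in radians.
.rotation_matrix <- function(axis, theta) {
  u <- .unit(axis)
  ct <- cos(theta); st <- sin(theta)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# Split a conformation into residues, returning a list of per-residue
# named coordinate lists (N, CA, C, O, H when present).
.residue_atoms <- function(conformation) {
  at <- conformation$atoms
  key <- paste(at$chain, at$resno)
  res_keys <- unique(key)
  lapply(res_keys, function(k) {
    idx <- which(key == k)
    coords <- list()
    for (i in idx) coords[[at$name[i]]] <- conformation$xyz[i, ]
    coords
  })
}

# Reconstruct missing backbone amide hydrogens: H sits 0.10 nm from N,
# opposing the bisector of the N->CA and N->C(prev) directions. The first
# residue has no preceding carbonyl and gets no H.
.with_amide_h <- function(res_list) {
  n <- length(res_list)
  if (n < 2) return(res_list)
  for (i in 2:n) {
    r <- res_list[[i]]
    if (!is.null(r$H)) next
    prev <- res_list[[i - 1]]
    if (is.null(r$N) || is.null(r$CA) || is.null(prev$C)) next
    bis <- .unit(r$CA - r$N) + .unit(prev$C - r$N)
    res_list[[i]]$H <- r$N - 0.10 * .unit(bis)
  }
  res_list
}
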