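#' Free-energy surface over two collective variables
#'
#' Bins the points into a 2D histogram, estimates the probability density
#' P on occupied bins, and converts it to a free energy
#' G = -kT ln(P), shifted so the global minimum is exactly 0. Unoccupied
#' bins are masked (G = NA): no pseudo-counts are imputed. With a
#' histogram estimate the free-energy difference between two occupied bins
#' is exactly -kT ln of their count ratio.
#'
#' @param x,y equal-length numeric vectors of the two collective
#'   variables, one entry per frame.
#' @param temperature simulation temperature, K.
#' @param bins integer (or length-2 integer) bin counts; default 60 x 60.
#' @param x_range,y_range optional axis ranges (default data range).
#' @return object of class `fel`: list with `x_edges`, `y_edges`,
#'   `x_centers`, `y_centers`, `G` (nx x ny matrix, kJ/mol, NA where
#'   unoccupied), `counts`, `occupied`, `kT` (kJ/mol), `temperature` and
#'   `frame_bins` (n x 2 bin indices per input point).
#' @export
fel_from_points <- function(x, y, temperature, bins = c(60, 60),
                            x_range = NULL, y_range = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (temperature <= 0) stop("temperature must be > 0")
  if (length(unique(paste(x, y))) < 2) stop("need >= 2 distinct points")
  if (length(bins) == 1) bins <- c(bins, bins)
  if (is.null(x_range)) x_range <- range(x)
  if (is.null(y_range)) y_range <- range(y)
  xe <- seq(x_range[1], x_range[2], length.out = bins[1] + 1)
  ye <- seq(y_range[1], y_range[2], length.out = bins[2] + 1)
  ix <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, bins[1], bins[2])
  for (k in seq_along(ix)) counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  occupied <- counts > 0L
  kT <- .kB * temperature
  G <- matrix(NA_real_, bins[1], bins[2])
  # P proportional to counts; the additive shift fixes min(G) = 0 exactly
  G[occupied] <- -kT * log(counts[occupied] / max(counts))
  structure(list(x_edges = xe, y_edges = ye,
                 x_centers = (xe[-1] + xe[-length(xe)]) / 2,
                 y_centers = (ye[-1] + ye[-length(ye)]) / 2,
                 G = G, counts = counts, occupied = occupied, kT = kT,
                 temperature = temperature,
                 frame_bins = cbind(i = ix, j = iy)),
            class = "fel")
}

#' @export
print.fel <- function(x, ...) {
  cat("free-energy surface:", nrow(x$G), "x", ncol(x$G), "bins,",
      sum(x$occupied), "occupied; G range [0,",
      format(max(x$G, na.rm = TRUE), digits = 4), "] kJ/mol at",
      x$temperature, "K\n")
  invisible(x)
}

.neighbours8 <- function(i, j, ni, nj) {
  di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
  keep <- !(di == 0 & dj == 0)
  ii <- i + di[keep]; jj <- j + dj[keep]
  ok <- ii >= 1 & ii <= ni & jj >= 1 & jj <= nj
  cbind(ii[ok], jj[ok])
}

#' Local free-energy minima of a surface
#'
#' Occupied bins strictly lower than all their occupied 8-neighbours,
#' with G below `depth_threshold`, sorted by G ascending.
#'
#' @param surface a `fel`.
#' @param depth_threshold report only minima with G below this (kJ/mol,
#'   default Inf).
#' @return data.frame with columns `i`, `j` (bin indices), `x`, `y` (bin
#'   centres) and `G`; possibly empty.
#' @export
find_minima <- function(surface, depth_threshold = Inf) {
  G <- surface$G
  ni <- nrow(G); nj <- ncol(G)
  out <- NULL
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    if (!surface$occupied[i, j] || G[i, j] >= depth_threshold) next
    nb <- .neighbours8(i, j, ni, nj)
    gnb <- G[nb]
    gnb <- gnb[!is.na(gnb)]
    if (all(G[i, j] < gnb)) {
      out <- rbind(out, data.frame(i = i, j = j,
                                   x = surface$x_centers[i],
                                   y = surface$y_centers[j],
                                   G = G[i, j]))
    }
  }
  if (is.null(out))
    return(data.frame(i = integer(0), j = integer(0), x = numeric(0),
                      y = numeric(0), G = numeric(0)))
  out[order(out$G, out$i, out$j), , drop = FALSE]
}

#' Minimal-gradient pathway between two cells of a surface
#'
#' Shortest path over the occupied 8-connected grid minimising the
#' accumulated absolute free-energy change sum(|dG|) between consecutive
#' cells (Dijkstra with deterministic lowest-linear-index tie-breaking).
#' The resulting cell sequence traces the route of gentlest energetic
#' variation connecting two basins, e.g. a compact-state minimum and an
#' extended-state minimum.
#'
#' @param surface a `fel`.
#' @param start,end length-2 integer vectors (i, j) of occupied cells.
#' @return object of class `grid_path`: list with `cells` (ordered n x 2
#'   matrix), `G_profile` and `total_weight` (sum |dG|, kJ/mol).
#' @export
minimal_gradient_path <- function(surface, start, end) {
  G <- surface$G
  ni <- nrow(G); nj <- ncol(G)
  chk <- function(cell, what) {
    if (length(cell) != 2 || cell[1] < 1 || cell[1] > ni ||
        cell[2] < 1 || cell[2] > nj || !surface$occupied[cell[1], cell[2]])
      stop(what, " cell is not an occupied bin")
  }
  chk(start, "start"); chk(end, "end")
  id <- function(i, j) (j - 1L) * ni + i
  s <- id(start[1], start[2]); e <- id(end[1], end[2])
  nv <- ni * nj
  dist <- rep(Inf, nv); prev <- rep(NA_integer_, nv)
  done <- rep(FALSE, nv)
  dist[s] <- 0
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]   # ties -> lowest linear index
    if (u == e) break
    done[u] <- TRUE
    ui <- ((u - 1L) %% ni) + 1L; uj <- ((u - 1L) %/% ni) + 1L
    nb <- .neighbours8(ui, uj, ni, nj)
    for (r in seq_len(nrow(nb))) {
      vi <- nb[r, 1]; vj <- nb[r, 2]
      if (!surface$occupied[vi, vj]) next
      v <- id(vi, vj)
      if (done[v]) next
      alt <- dist[u] + abs(G[vi, vj] - G[ui, uj])
      if (alt < dist[v]) { dist[v] <- alt; prev[v] <- u }
    }
  }
  if (!is.finite(dist[e]))
    stop("no occupied path connects the requested cells")
  cells <- e
  while (cells[1] != s) cells <- c(prev[cells[1]], cells)
  ij <- cbind(((cells - 1L) %% ni) + 1L, ((cells - 1L) %/% ni) + 1L)
  colnames(ij) <- c("i", "j")
  profile <- G[ij]
  structure(list(cells = ij, G_profile = profile,
                 total_weight = dist[e]), class = "grid_path")
}

#' @export
print.grid_path <- function(x, ...) {
  cat("minimal-gradient path:", nrow(x$cells), "cells, total |dG| =",
      format(x$total_weight, digits = 5), "kJ/mol\n")
  invisible(x)
}

#' Representative conformation of each free-energy basin
#'
#' For each minimum, the frames whose bins lie within `basin_radius`
#' (Chebyshev distance in bins) are pooled and GROMOS-clustered; the
#' centrotype of the largest cluster represents the basin.
#'
#' @param surface a `fel` built from per-frame collective variables of
#'   `ensemble` (its `frame_bins` maps frames to bins).
#' @param ensemble the `ensemble` behind the surface.
#' @param minima data.frame with `i`, `j` columns (e.g. [find_minima()]).
#' @param basin_radius basin half-width in bins (default 1).
#' @param cluster_cutoff GROMOS RMSD cutoff, nm.
#' @param selection atom selection for the clustering RMSD.
#' @return list, one entry per minimum: NULL for an empty basin (with a
#'   warning), else a list with `frame` (ensemble frame index of the
#'   representative), `conformation`, `n_frames` and `cluster_sizes`.
#' @export
basin_representatives <- function(surface, ensemble, minima,
                                  basin_radius = 1, cluster_cutoff,
                                  selection = "backbone5") {
  fb <- surface$frame_bins
  out <- vector("list", nrow(minima))
  for (m in seq_len(nrow(minima))) {
    sel <- which(abs(fb[, 1] - minima$i[m]) <= basin_radius &
                 abs(fb[, 2] - minima$j[m]) <= basin_radius)
    if (!length(sel)) {
      warning("basin ", m, " contains no frames; skipped")
      next
    }
    cl <- gromos_cluster(subset_frames(ensemble, sel), cluster_cutoff,
                         selection)
    rep_frame <- sel[cl$centrotypes[1]]
    out[[m]] <- list(frame = rep_frame,
                     conformation = get_frame(ensemble, rep_frame),
                     n_frames = length(sel), cluster_sizes = cl$sizes)
  }
  out
}

#' Write a free-energy surface as a TSV grid
#'
#' Long format: one row per bin with the bin centres and G (NA when
#' unoccupied).
#'
#' @param surface a `fel`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fel <- function(surface, path) {
  df <- expand.grid(i = seq_along(surface$x_centers),
                    j = seq_along(surface$y_centers))
  df$x_center <- surface$x_centers[df$i]
  df$y_center <- surface$y_centers[df$j]
  df$G <- surface$G[cbind(df$i, df$j)]
  write_descriptor_table(df, path)
}
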