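# Fix PC signs: each component's largest-magnitude loading positive.
.fix_signs <- function(loadings) {
  for (i in seq_len(nrow(loadings))) {
    k <- which.max(abs(loadings[i, ]))
    if (loadings[i, k] < 0) loadings[i, ] <- -loadings[i, ]
  }
  loadings
}

.new_pc_model <- function(kind, mean, scale, loadings, var_per_pc, total_var,
                          extra = list()) {
  evf <- var_per_pc / total_var
  structure(c(list(kind = kind, mean = mean, scale = scale,
                   loadings = loadings,
                   explained_variance_fraction = evf), extra),
            class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("PCA model (", x$kind, "): ", nrow(x$loadings), " components x ",
      ncol(x$loadings), " features\n", sep = "")
  cat("explained variance fractions:",
      paste(format(head(x$explained_variance_fraction, 5), digits = 3),
            collapse = " "), "\n")
  invisible(x)
}

# Iteratively superpose all frames (already reduced to the wanted atoms)
# to the running mean structure; returns list of fitted frames + mean.
.superpose_to_mean <- function(frames, rounds = 2) {
  ref <- frames[[1]]
  for (r in seq_len(rounds)) {
    fitted <- lapply(frames, function(f) kabsch_superpose(ref, f)$coords)
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  # final pass against the frozen reference, so out-of-sample projection
  # (which superposes to this reference) reproduces training scores
  fitted <- lapply(frames, function(f) kabsch_superpose(ref, f)$coords)
  list(frames = fitted, mean = ref)
}

#' Essential-dynamics PCA on C-alpha coordinates
#'
#' All frames are iteratively superposed (Kabsch, 2 refinement rounds) to
#' the ensemble mean structure, then PCA is performed on the flattened
#' C-alpha coordinate vectors (covariance over frames, n-1 convention).
#' The leading components span the dominant collective motions.
#'
#' @param ensemble an `ensemble` containing CA atoms, >= 2 frames.
#' @return a `pc_model` of kind `"cartesian_ED"`; carries the mean
#'   structure used as the superposition reference.
#' @export
fit_pca_cartesian <- function(ensemble) {
  if (n_frames(ensemble) < 2) stop("essential dynamics needs >= 2 frames")
  ca <- select_atoms(ensemble, "calpha")
  sup <- .superpose_to_mean(ca$frames)
  X <- do.call(rbind, lapply(sup$frames, function(f) as.vector(t(f))))
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(Xc^2) < 1e-20) stop("zero total variance: identical frames")
  sv <- svd(Xc)
  n <- nrow(X)
  var_pc <- sv$d^2 / (n - 1)
  keep <- var_pc > 1e-12 * sum(var_pc)
  loadings <- .fix_signs(t(sv$v[, keep, drop = FALSE]))
  .new_pc_model("cartesian_ED", colMeans(X), rep(1, ncol(X)), loadings,
                var_pc[keep], sum(var_pc),
                extra = list(mean_structure = sup$mean,
                             topology = ca$topology))
}

#' PCA on the autoscaled WHIM descriptor table
#'
#' Each of the 13 descriptor columns is autoscaled (centred to mean 0,
#' divided by its sample standard deviation) before PCA, so descriptors of
#' different magnitude contribute equally.
#'
#' @param table data.frame holding the 13 WHIM columns (extra columns such
#'   as `frame` are ignored); >= 2 rows, no constant column.
#' @return a `pc_model` of kind `"whim"`.
#' @export
fit_pca_whim <- function(table) {
  cols <- intersect(whim_columns(), names(table))
  if (length(cols) < 2) stop("table does not contain WHIM columns")
  X <- as.matrix(table[, cols])
  if (nrow(X) < 2) stop("need >= 2 rows")
  if (anyNA(X)) stop("NA in descriptor table (degenerate frames?)")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-15))
    stop("constant column(s): ", paste(cols[sds < 1e-15], collapse = ", "))
  mu <- colMeans(X)
  Xs <- sweep(sweep(X, 2, mu), 2, sds, `/`)
  sv <- svd(Xs)
  n <- nrow(X)
  var_pc <- sv$d^2 / (n - 1)
  keep <- var_pc > 1e-12 * sum(var_pc)
  loadings <- .fix_signs(t(sv$v[, keep, drop = FALSE]))
  .new_pc_model("whim", mu, sds, loadings, var_pc[keep], sum(var_pc),
                extra = list(feature_names = cols))
}

#' Project items into a fitted PCA space
#'
#' For a `cartesian_ED` model, a conformation (or ensemble) is reduced to
#' its C-alpha atoms, superposed onto the model's mean structure, and
#' projected; for a `whim` model, a WHIM descriptor vector (or table) is
#' autoscaled with the training mean/scale and projected. Projecting a
#' training item reproduces its training scores.
#'
#' @param model a `pc_model`.
#' @param item a `conformation`, an `ensemble`, a named WHIM vector (from
#'   [whim_vector()]), or a descriptor data.frame.
#' @param n_components number of leading components to return (default 2).
#' @return score matrix, one row per item.
#' @export
project_pca <- function(model, item, n_components = 2) {
  nc <- min(n_components, nrow(model$loadings))
  L <- model$loadings[seq_len(nc), , drop = FALSE]
  if (model$kind == "cartesian_ED") {
    frames <- if (inherits(item, "conformation")) {
      conf <- item
      keep <- conf$atoms$name == "CA"
      list(conf$xyz[keep, , drop = FALSE])
    } else if (inherits(item, "ensemble")) {
      select_atoms(item, "calpha")$frames
    } else stop("cartesian_ED model expects a conformation or ensemble")
    if (nrow(frames[[1]]) * 3 != ncol(L))
      stop("feature mismatch: model has ", ncol(L) / 3,
           " CA atoms, item has ", nrow(frames[[1]]))
    do.call(rbind, lapply(frames, function(f) {
      fitted <- kabsch_superpose(model$mean_structure, f)$coords
      (as.vector(t(fitted)) - model$mean) %*% t(L)
    }))
  } else {
    X <- if (is.data.frame(item)) {
      as.matrix(item[, model$feature_names, drop = FALSE])
    } else if (is.numeric(item)) {
      if (is.null(names(item)))
        matrix(item, nrow = 1,
               dimnames = list(NULL, model$feature_names))
      else matrix(item[model$feature_names], nrow = 1,
                  dimnames = list(NULL, model$feature_names))
    } else stop("whim model expects a descriptor vector or data.frame")
    if (ncol(X) != ncol(L) || anyNA(X)) stop("feature mismatch")
    Xs <- sweep(sweep(X, 2, model$mean), 2, model$scale, `/`)
    Xs %*% t(L)
  }
}

#' Serialise a PCA model to JSON
#' @param model a `pc_model`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
pca_to_json <- function(model, path) {
  obj <- list(kind = model$kind, mean = model$mean, scale = model$scale,
              loadings = model$loadings,
              explained_variance_fraction = model$explained_variance_fraction)
  if (!is.null(model$mean_structure))
    obj$mean_structure <- model$mean_structure
  if (!is.null(model$feature_names)) obj$feature_names <- model$feature_names
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a PCA model serialised with [pca_to_json()]
#' @param path JSON path.
#' @return a `pc_model`.
#' @export
pca_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  extra <- list()
  if (!is.null(obj$mean_structure))
    extra$mean_structure <- as.matrix(obj$mean_structure)
  if (!is.null(obj$feature_names)) extra$feature_names <- obj$feature_names
  structure(c(list(kind = obj$kind, mean = obj$mean, scale = obj$scale,
                   loadings = as.matrix(obj$loadings),
                   explained_variance_fraction =
                     obj$explained_variance_fraction), extra),
            class = "pc_model")
}
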