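# Sum of k Gaussian curves evaluated at x; par = (a1, m1, s1, a2, ...)
.gauss_sum <- function(x, par) {
  k <- length(par) / 3
  y <- 0
  for (i in seq_len(k)) {
    a <- par[3 * i - 2]; m <- par[3 * i - 1]; s <- par[3 * i]
    y <- y + a * exp(-(x - m)^2 / (2 * s^2))
  }
  y
}

.r_squared <- function(obs, fitted) {
  1 - sum((obs - fitted)^2) / sum((obs - mean(obs))^2)
}

# Evaluate .Random.seed-preserving expression with a fixed seed
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.fit_k_gaussians <- function(centers, dens, k, n_restarts = 10) {
  base_means <- quantile(centers, probs = (seq_len(k) - 0.5) / k,
                         names = FALSE, type = 7)
  base_sd <- max(sd(centers) / k, diff(range(centers)) / 50)
  base_amp <- max(dens)
  span <- diff(range(centers))
  lower <- rep(c(0, min(centers) - span, span / 1e4), k)
  upper <- rep(c(Inf, max(centers) + span, span * 2), k)
  best <- NULL
  .with_seed(20201107 + k, {
    for (r in seq_len(n_restarts)) {
      means <- base_means
      sds <- rep(base_sd, k)
      amps <- rep(base_amp / k * 2, k)
      if (r > 1) {  # jittered restarts
        means <- means + rnorm(k, 0, span / 10)
        sds <- sds * exp(rnorm(k, 0, 0.3))
        amps <- amps * exp(rnorm(k, 0, 0.3))
      }
      start <- as.vector(rbind(amps, means, sds))
      fit <- tryCatch(
        minpack.lm::nls.lm(
          par = start,
          fn = function(p) dens - .gauss_sum(centers, p),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      r2 <- .r_squared(dens, .gauss_sum(centers, fit$par))
      if (is.null(best) || r2 > best$r2) best <- list(par = fit$par, r2 = r2)
    }
  })
  best
}

#' Deconvolute a distribution into the minimum number of Gaussians
#'
#' Bins the values into a density histogram and fits sums of k = 1, 2, ...
#' Gaussian curves by nonlinear least squares, returning the smallest k
#' whose coefficient of determination on the binned densities exceeds
#' `r2_threshold` (default 0.990). Component areas give the population
#' fractions. Fitting uses quantile-spaced initial means with jittered
#' restarts under an internal fixed seed, so results are deterministic.
#'
#' @param values numeric vector (>= 100 finite values).
#' @param r2_threshold required R^2 (default 0.990).
#' @param max_components largest k tried (default 6); if no k reaches the
#'   threshold the best fit is returned flagged `converged = FALSE`.
#' @param bins number of histogram bins; default Freedman-Diaconis.
#' @param binwidth alternative to `bins`: fixed bin width in the units of
#'   `values` (useful for bounded indices where a natural resolution
#'   exists, e.g. 0.05 on the WHIM shape index).
#' @return object of class `mixture_fit`: list with `components`
#'   (data.frame mean, sd, amplitude, fraction; sorted by mean),
#'   `n_components`, `r_squared`, `fractions`, `converged`, and
#'   `histogram` (bin_centers, bin_densities).
#' @export
fit_minimum_gaussians <- function(values, r2_threshold = 0.990,
                                  max_components = 6, bins = NULL,
                                  binwidth = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 100) stop("need at least 100 finite values")
  if (sd(values) < 1e-15) stop("zero-variance input: nothing to deconvolute")
  if (is.null(bins)) {
    bins <- if (!is.null(binwidth)) ceiling(diff(range(values)) / binwidth)
            else max(10, grDevices::nclass.FD(values))
  }
  h <- graphics::hist(values, breaks = seq(min(values), max(values),
                                           length.out = bins + 1),
                      plot = FALSE)
  centers <- h$mids
  dens <- h$density
  best <- NULL
  for (k in seq_len(max_components)) {
    fit <- .fit_k_gaussians(centers, dens, k)
    if (is.null(fit)) next
    if (is.null(best) || fit$r2 > best$r2) best <- c(fit, list(k = k))
    if (fit$r2 > r2_threshold) { best <- c(fit, list(k = k)); break }
  }
  if (is.null(best)) stop("all Gaussian fits failed")
  par <- best$par
  k <- best$k
  comp <- data.frame(
    amplitude = par[seq(1, 3 * k, by = 3)],
    mean = par[seq(2, 3 * k, by = 3)],
    sd = par[seq(3, 3 * k, by = 3)])
  area <- comp$amplitude * comp$sd  # component integral / sqrt(2*pi)
  comp$fraction <- area / sum(area)
  comp <- comp[order(comp$mean), c("mean", "sd", "amplitude", "fraction")]
  rownames(comp) <- NULL
  structure(list(components = comp, n_components = k,
                 r_squared = best$r2, fractions = comp$fraction,
                 converged = best$r2 > r2_threshold,
                 histogram = list(bin_centers = centers,
                                  bin_densities = dens)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Gaussian deconvolution:", x$n_components, "component(s), R^2 =",
      format(x$r_squared, digits = 5),
      if (!x$converged) "(threshold not reached)" else "", "\n")
  print(transform(x$components, fraction_percent = 100 * fraction,
                  fraction = NULL), row.names = FALSE)
  invisible(x)
}

#' Two-state population split of a fitted mixture
#'
#' Collapses a Gaussian deconvolution into two populations (e.g. compact
#' vs extended) by integrating the fitted mixture density on either side
#' of a threshold. When no threshold is given, the antimode of the fitted
#' mixture (the density minimum between the outermost component means) is
#' used. Grouping fitted components into interpretable states this way is
#' robust to how many Gaussians the minimum-components rule needed.
#'
#' @param fit a `mixture_fit`.
#' @param threshold optional split point in descriptor units.
#' @return list with `threshold`, `below` and `above` (mass fractions
#'   summing to 1).
#' @export
two_state_split <- function(fit, threshold = NULL) {
  cmp <- fit$components
  if (is.null(threshold)) {
    if (nrow(cmp) < 2)
      stop("cannot locate an antimode of a single-component fit")
    xs <- seq(min(cmp$mean), max(cmp$mean), length.out = 512)
    dens <- vapply(xs, function(x)
      sum(cmp$amplitude * exp(-(x - cmp$mean)^2 / (2 * cmp$sd^2))),
      numeric(1))
    threshold <- xs[which.min(dens)]
  }
  above <- sum(cmp$fraction * stats::pnorm(threshold, cmp$mean, cmp$sd,
                                           lower.tail = FALSE))
  list(threshold = threshold, below = 1 - above, above = above)
}

#' Write a deconvolution report as TSV
#' @param fit a `mixture_fit`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mixture_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_components=%d r_squared=%.6f converged=%s",
                     fit$n_components, fit$r_squared, fit$converged), con)
  writeLines("component\tmean\tsd\tfraction_percent", con)
  for (i in seq_len(nrow(fit$components))) {
    writeLines(sprintf("%d\t%.10g\t%.10g\t%.6f", i,
                       fit$components$mean[i], fit$components$sd[i],
                       100 * fit$components$fraction[i]), con)
  }
  invisible(path)
}
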