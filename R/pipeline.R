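#' Default run configuration
#'
#' Central home of every tunable analysis parameter, with the values used
#' throughout: 0.14 nm SASA probe, R^2 threshold 0.990 for the Gaussian
#' deconvolution, 1.0 nm RMSD filter cutoff against the reference, 400 K
#' landscape temperature, 60 x 60 free-energy bins.
#'
#' @return nested list of defaults; override entries via [run_config()] or
#'   a YAML file via [read_run_config()].
#' @export
default_config <- function() {
  list(
    input = list(ensemble = NULL, reference = NULL),
    temperature = 400,
    selection = "backbone5",
    sasa = list(probe_radius_nm = 0.14, n_points = 960, radii = NULL),
    secondary_structure = FALSE,
    deconvolution = list(r2_threshold = 0.990, max_components = 6,
                         bins = NULL, binwidth_K = 0.05,
                         binwidth_SAS = NULL),
    fel = list(bins = 60, depth_threshold = Inf, basin_radius = 1),
    cluster = list(gromos_cutoff = 0.5, rmsd_filter_cutoff = 1.0),
    output_dir = NULL,
    seed = 1
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Build a run configuration
#' @param ... named overrides of [default_config()] entries (nested lists
#'   merged recursively).
#' @return validated config list.
#' @export
run_config <- function(...) {
  cfg <- .merge_config(default_config(), list(...))
  validate_config(cfg)
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file; keys mirror [default_config()].
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- .merge_config(default_config(), yaml::read_yaml(path))
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#' @param cfg config list.
#' @return invisibly, the config; errors on invalid entries.
#' @export
validate_config <- function(cfg) {
  if (cfg$temperature <= 0) stop("temperature must be > 0")
  if (cfg$sasa$probe_radius_nm < 0) stop("sasa probe radius must be >= 0")
  if (cfg$deconvolution$r2_threshold <= 0 ||
      cfg$deconvolution$r2_threshold > 1)
    stop("deconvolution r2_threshold must be in (0, 1]")
  if (cfg$cluster$gromos_cutoff <= 0) stop("gromos_cutoff must be > 0")
  for (what in c("ensemble", "reference")) {
    p <- cfg$input[[what]]
    if (is.character(p) && !file.exists(p))
      stop("input ", what, " path does not exist: ", p)
  }
  invisible(cfg)
}

.log_line <- function(logfile, level, ...) {
  msg <- paste0("[", level, "] ", paste0(...))
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

.stage <- function(name, logfile, expr) {
  .log_line(logfile, "INFO", "stage ", name, " started")
  r <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  .log_line(logfile, "INFO", "stage ", name, " done")
  r
}

#' Run the full shape-analysis pipeline
#'
#' Stages, in order: load the ensemble; per-frame WHIM descriptor and SASA
#' table (plus optional secondary-structure fractions); Gaussian
#' deconvolution of the K and SASA distributions; free-energy landscapes
#' in K/SASA, essential-dynamics PC1/PC2 and WHIM PC1/PC2 spaces with
#' minima, basin representatives and the minimal-gradient path between the
#' two lowest minima of the WHIM space; projection of the reference
#' structure into both PC spaces; RMSD filtering against the reference
#' followed by GROMOS clustering of the retained frames. Every numeric
#' artifact is a pure function of the config and inputs, so re-running
#' reproduces it byte-identically. Single-frame inputs produce the
#' descriptor table only, with the remaining stages skipped and logged.
#'
#' @param config list from [run_config()] / [read_run_config()]. The
#'   ensemble (and optional reference) may be given as file paths or as
#'   in-memory objects.
#' @return invisibly, a list of stage results; files are written under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  out_dir <- config$output_dir
  if (is.null(out_dir)) stop("config$output_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  manifest <- list(config = config[setdiff(names(config), "input")],
                   stages = character(0), complete = FALSE)
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  on.exit(save_manifest())
  done <- function(s) manifest$stages <<- c(manifest$stages, s)
  res <- list()

  ens <- .stage("load", logfile, {
    e <- config$input$ensemble
    if (is.character(e)) e <- read_multimodel_pdb(e)
    if (!inherits(e, "ensemble")) stop("no ensemble provided")
    e
  })
  done("load")
  reference <- config$input$reference
  if (is.character(reference)) reference <- get_frame(
    read_multimodel_pdb(reference), 1)
  nf <- n_frames(ens)
  .log_line(logfile, "INFO", "loaded ", nf, " frames, ",
            nrow(ens$topology), " atoms")

  res$descriptors <- .stage("descriptors", logfile, {
    tab <- suppressWarnings(whim_table(ens, config$selection))
    tab$SAS <- sasa_ensemble(ens, config$sasa$probe_radius_nm,
                             config$sasa$n_points, config$sasa$radii)
    write_descriptor_table(tab, file.path(out_dir, "descriptors.tsv"))
    tab
  })
  done("descriptors")

  if (isTRUE(config$secondary_structure)) {
    res$secondary_structure <- .stage("secondary_structure", logfile, {
      ssf <- ss_fractions(ens)
      pr <- data.frame(residue_index = seq_len(nrow(ssf$per_residue)),
                       helix = ssf$per_residue[, "Helix"],
                       strand = ssf$per_residue[, "Strand"],
                       turn = ssf$per_residue[, "Turn"],
                       bend = ssf$per_residue[, "Bend"],
                       coil = ssf$per_residue[, "Coil"])
      write_descriptor_table(pr, file.path(out_dir, "ss_per_residue.tsv"))
      ssf
    })
    done("secondary_structure")
  }

  if (nf < 2) {
    .log_line(logfile, "WARNING",
              "single-frame input: deconvolution, landscapes and ",
              "clustering skipped")
    manifest$complete <- TRUE
    return(invisible(res))
  }

  if (nf < 100) {
    .log_line(logfile, "WARNING", "fewer than 100 frames: deconvolution ",
              "skipped (distribution fitting needs >= 100 values)")
  } else res$deconv <- .stage("deconvolution", logfile, {
    dc <- config$deconvolution
    fits <- list(K = fit_minimum_gaussians(res$descriptors$K,
                                           dc$r2_threshold,
                                           dc$max_components, dc$bins,
                                           dc$binwidth_K),
                 SAS = fit_minimum_gaussians(res$descriptors$SAS,
                                             dc$r2_threshold,
                                             dc$max_components, dc$bins,
                                             dc$binwidth_SAS))
    write_mixture_report(fits$K, file.path(out_dir, "deconv_K.tsv"))
    write_mixture_report(fits$SAS, file.path(out_dir, "deconv_SAS.tsv"))
    fits
  })
  if (!is.null(res$deconv)) done("deconvolution")

  res$pca <- .stage("pca", logfile, {
    ed <- fit_pca_cartesian(ens)
    whim <- fit_pca_whim(res$descriptors)
    pca_to_json(ed, file.path(out_dir, "pca_ed.json"))
    pca_to_json(whim, file.path(out_dir, "pca_whim.json"))
    list(ed = ed, whim = whim,
         ed_scores = project_pca(ed, ens),
         whim_scores = project_pca(whim, res$descriptors))
  })
  done("pca")

  res$fel <- .stage("landscapes", logfile, {
    spaces <- list(
      K_SAS = cbind(res$descriptors$K, res$descriptors$SAS),
      ED = res$pca$ed_scores[, 1:2, drop = FALSE],
      WHIM = res$pca$whim_scores[, 1:2, drop = FALSE])
    lapply(setNames(names(spaces), names(spaces)), function(nm) {
      xy <- spaces[[nm]]
      fel <- fel_from_points(xy[, 1], xy[, 2], config$temperature,
                             config$fel$bins)
      write_fel(fel, file.path(out_dir, paste0("fel_", nm, ".tsv")))
      minima <- find_minima(fel, config$fel$depth_threshold)
      write_descriptor_table(minima,
                             file.path(out_dir,
                                       paste0("minima_", nm, ".tsv")))
      list(surface = fel, minima = minima)
    })
  })
  done("landscapes")

  res$pathway <- .stage("pathway", logfile, {
    mn <- res$fel$WHIM$minima
    if (nrow(mn) < 2) {
      .log_line(logfile, "WARNING",
                "fewer than 2 WHIM-space minima: pathway skipped")
      NULL
    } else {
      p <- tryCatch(
        minimal_gradient_path(res$fel$WHIM$surface,
                              c(mn$i[1], mn$j[1]), c(mn$i[2], mn$j[2])),
        error = function(e) {
          .log_line(logfile, "WARNING", "pathway skipped: ",
                    conditionMessage(e))
          NULL
        })
      if (!is.null(p))
        write_descriptor_table(
          data.frame(i = p$cells[, 1], j = p$cells[, 2], G = p$G_profile),
          file.path(out_dir, "path_WHIM.tsv"))
      p
    }
  })
  done("pathway")

  res$basins <- .stage("basin_representatives", logfile, {
    mn <- res$fel$K_SAS$minima
    if (nrow(mn) == 0) return(NULL)
    reps <- withCallingHandlers(
      basin_representatives(res$fel$K_SAS$surface, ens,
                            mn[seq_len(min(5, nrow(mn))), ],
                            config$fel$basin_radius,
                            config$cluster$gromos_cutoff,
                            config$selection),
      warning = function(w) {
        .log_line(logfile, "WARNING", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    for (b in seq_along(reps)) {
      if (!is.null(reps[[b]]))
        write_pdb_conformation(reps[[b]]$conformation,
                               file.path(out_dir,
                                         sprintf("basin_%d.pdb", b)))
    }
    reps
  })
  done("basin_representatives")

  if (!is.null(reference)) {
    res$reference <- .stage("reference", logfile, {
      ref_whim <- whim_vector(
        reference$xyz[reference$atoms$name %in%
                        c("N", "H", "CA", "C", "O"), , drop = FALSE])
      proj <- list(ed = project_pca(res$pca$ed, reference),
                   whim = project_pca(res$pca$whim, ref_whim))
      keep <- rmsd_filter(ens, reference,
                          config$cluster$rmsd_filter_cutoff,
                          config$selection)
      cl <- NULL
      if (length(keep) >= 1) {
        cl <- gromos_cluster(subset_frames(ens, keep),
                             config$cluster$gromos_cutoff,
                             config$selection)
        report <- data.frame(
          cluster_id = seq_along(cl$sizes), size = cl$sizes,
          percent = 100 * cl$sizes / sum(cl$sizes),
          centrotype_frame = keep[cl$centrotypes])
        write_descriptor_table(report,
                               file.path(out_dir, "cluster_report.tsv"))
      } else {
        .log_line(logfile, "WARNING",
                  "no frames below the RMSD filter cutoff")
      }
      write_descriptor_table(
        data.frame(frame = seq_len(nf),
                   rmsd_to_reference = attr(keep, "rmsd"),
                   retained = seq_len(nf) %in% keep),
        file.path(out_dir, "rmsd_to_reference.tsv"))
      list(projections = proj, retained = keep, clusters = cl)
    })
    done("reference")
  }

  manifest$complete <- TRUE
  .log_line(logfile, "INFO", "pipeline complete")
  invisible(res)
}
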