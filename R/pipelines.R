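# End-to-end pipelines tying the stages together: mosaic analysis
# (per-class statistics, DRP/effective radius, random-null comparison,
# density, acuity) and spectra analysis (filtering, lambda_max, bandwidth,
# ranked mixture fits). Each run writes its artifacts plus a JSON manifest
# recording the seed and a hash of the analysis-relevant configuration.

#' Default pipeline configuration
#'
#' Bundles the analysis constants: window size, soma sizes, the 20-replicate
#' random null, DRP bin width 1 um and radius 15 um, Matthiessen's ratio
#' 2.55, the 0.5 mm target, alpha = 0.05, and the 350-750 nm / 2 nm
#' spectral grid.
#'
#' @param ... Named overrides of any default entry.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    window = c(52, 52),
    soma = soma_sizes(),
    n_null_replicates = 20,
    drp_bin_width = 1,
    drp_max_radius = 15,
    matthiessen = 2.55,
    target_size_mm = 0.5,
    alpha = 0.05,
    grid = default_grid(),
    fourier_cutoff_nm = 40,
    lens_radius_mm = 0.32)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg[order(names(cfg))], file = tmp, control = c("all", "digits17"))
  unname(tools::md5sum(tmp))
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full mosaic analysis pipeline
#'
#' For every cone class present with enough cells: mosaic statistics
#' (interior NND and Voronoi summaries), DRP with effective radius, and a
#' z-score comparison of each scalar statistic against a matched
#' soma-constrained random null. Also computes the cone cell density and,
#' if a lens radius is configured, the theoretical acuity. All artifacts
#' are written under `out_dir` and indexed by `manifest.json`.
#'
#' @param field A [cone_field()] or path to a centroid CSV.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage s of the null simulation for
#'   class c uses deterministic offsets of it.
#' @param config A [pipeline_config()] list.
#' @return The manifest, invisibly (list with per-class results and file
#'   paths).
#' @export
run_mosaic_pipeline <- function(field, out_dir, seed = 0,
                                config = pipeline_config()) {
  if (is.character(field)) field <- read_cone_field(field)
  stopifnot(inherits(field, "cone_field"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, config_hash = config_hash(config),
                   window_um = field$window, files = list(),
                   classes = list())
  write_cone_field(field, file.path(out_dir, "field.csv"))
  manifest$files$field <- "field.csv"
  present <- names(which(table(field$label) >= 4))
  for (ci in seq_along(present)) {
    cls <- present[ci]
    res <- tryCatch(
      mosaic_class_stage(field, cls, seed + 1000 * ci, config, out_dir),
      error = function(e) list(error = conditionMessage(e)))
    manifest$classes[[cls]] <- res
  }
  dens <- cone_cell_density(field)
  ac <- acuity(dens, lens_radius = config$lens_radius_mm,
               matthiessen = config$matthiessen,
               target_size = config$target_size_mm)
  write_json(unclass(ac), file.path(out_dir, "acuity.json"))
  manifest$files$acuity <- "acuity.json"
  manifest$density_mm2 <- dens
  write_json(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# One cone class of the mosaic pipeline: statistics, DRP, null comparison,
# and the per-class artifact files. Errors (class too sparse for interior
# statistics, guard zone empty, infeasible null packing) are caught by the
# caller and recorded in the manifest instead of aborting the whole run.
mosaic_class_stage <- function(field, cls, stage_seed, config, out_dir) {
  ms <- mosaic_summary(field, cls)
  drp <- density_recovery_profile(
    autocorrelogram(field, cls, config$drp_max_radius),
    config$drp_bin_width)
  ens <- simulate_null_ensemble(
    field, cls, soma = config$soma,
    n_replicates = config$n_null_replicates, seed = stage_seed,
    drp_max_radius = config$drp_max_radius,
    drp_bin_width = config$drp_bin_width)
  obs <- field_scalar_stats(field, cls, config$drp_max_radius,
                            config$drp_bin_width)
  comps <- lapply(colnames(ens$statistics), function(st)
    compare_to_null(obs[[st]], ens, st, alpha = config$alpha))
  names(comps) <- colnames(ens$statistics)

  cell_csv <- paste0("cells_", cls, ".csv")
  utils::write.csv(mosaic_cell_table(field, cls),
                   file.path(out_dir, cell_csv), row.names = FALSE)
  drp_csv <- paste0("drp_", cls, ".csv")
  write_drp(drp, file.path(out_dir, drp_csv))
  stats_json <- paste0("stats_", cls, ".json")
  write_json(list(
    cone_class = cls, n_total = ms$n_total, n_interior = ms$n_interior,
    nnd = ms$nnd, voronoi = ms$voronoi,
    drp = list(mean_density_mm2 = drp$mean_density,
               effective_radius_um = drp$effective_radius,
               n_reference = drp$n_reference),
    null_comparison = lapply(comps, function(cmp)
      list(observed = cmp$observed, null_mean = cmp$null_mean,
           null_sd = cmp$null_sd, z = cmp$z_score, p = cmp$p_value,
           significant = cmp$significant))),
    file.path(out_dir, stats_json))
  list(stats = stats_json, cells = cell_csv, drp = drp_csv)
}

#' Run the spectra analysis pipeline
#'
#' Each input spectrum is Fourier filtered, its single-pigment lambda_max
#' and half-maximum bandwidth estimated, and the candidate pigment sets
#' fit and ranked by least sum of squares.
#'
#' @param spectra List of [spectrum()] objects or CSV paths (non-empty).
#' @param candidate_sets List of lambda_max vectors passed to
#'   [fit_mixture()].
#' @param out_dir Output directory.
#' @param config A [pipeline_config()] list.
#' @return The manifest, invisibly.
#' @export
run_spectra_pipeline <- function(spectra, candidate_sets, out_dir,
                                 config = pipeline_config()) {
  if (!length(spectra)) stop("empty spectrum list")
  if (inherits(spectra, "spectrum") || is.character(spectra) &&
      length(spectra) == 1L)
    spectra <- list(spectra)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), spectra = list())
  for (si in seq_along(spectra)) {
    s <- spectra[[si]]
    if (is.character(s)) s <- read_spectrum(s)
    filt <- fourier_filter(s, config$fourier_cutoff_nm)
    lm <- estimate_lambda_max(filt)
    bw <- tryCatch(half_max_bandwidth_wavenumber(filt),
                   error = function(e) NA_real_)
    fits <- fit_mixture(s, candidate_sets)
    name <- sprintf("spectrum_%02d", si)
    write_spectrum(filt, file.path(out_dir, paste0(name, "_filtered.csv")))
    report <- list(
      lambda_max_nm = lm$lambda_max,
      half_max_bandwidth_cm1 = bw,
      fits = lapply(fits, function(f)
        list(pigments_nm = f$lambda_max, k = f$k, p = f$p, ss = f$ss,
             converged = f$converged)))
    write_json(report, file.path(out_dir, paste0(name, "_fits.json")))
    manifest$spectra[[name]] <- report
  }
  write_json(manifest, file.path(out_dir, "spectra_manifest.json"))
  invisible(manifest)
}
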