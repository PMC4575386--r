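# End-to-end orchestration: simulate -> preprocess -> detect -> calibrate ->
# align -> differential -> fingerprint, with every stage parameter in one
# config, file outputs per stage, and a manifest for reproducibility.

#' Build a pipeline run configuration
#'
#' All stage parameters with their defaults: 50-channel average smoothing,
#' 100-channel baseline filter, dual peak threshold (S/N 3, 200 mV), 2 Da /
#' 500 ppm match tolerances, 10 internal calibration references, significance
#' levels 0.05/0.01.
#'
#' @param seed Experiment seed (recorded in every output manifest).
#' @param replicates Replicates per condition (default 6).
#' @param concentrations `"all"` or `"reference"` (see [make_design()]).
#' @param smooth_width,baseline_width,noise_window Channel widths for the
#'   preprocessing and noise stages.
#' @param snr_min,abs_min_mv Peak detection thresholds.
#' @param tol_da,tol_ppm Match tolerances (alignment and reference
#'   selection).
#' @param calib_tol_ppm Wider ppm window for matching calibration references
#'   (must admit the uncorrected drift).
#' @param n_calib_refs,majority_frac Internal calibration reference
#'   selection.
#' @param calibrate Run internal recalibration (default `TRUE`).
#' @param alpha Marker significance levels.
#' @param grubbs_alpha Outlier screening level.
#' @param log_pca Log-transform ratios before PCA.
#' @param out_dir Output directory (`NULL`: no files written).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, replicates = 6, concentrations = "all",
                       smooth_width = 50, baseline_width = 100,
                       noise_window = 2501, snr_min = 3, abs_min_mv = 200,
                       tol_da = 2, tol_ppm = 500, calib_tol_ppm = 2000,
                       n_calib_refs = 10,
                       majority_frac = 0.5, calibrate = TRUE,
                       alpha = c(0.05, 0.01), grubbs_alpha = 0.05,
                       log_pca = TRUE, out_dir = NULL) {
  cfg <- list(seed = seed, replicates = replicates,
              concentrations = concentrations, smooth_width = smooth_width,
              baseline_width = baseline_width, noise_window = noise_window,
              snr_min = snr_min, abs_min_mv = abs_min_mv, tol_da = tol_da,
              tol_ppm = tol_ppm, calib_tol_ppm = calib_tol_ppm,
              n_calib_refs = n_calib_refs,
              majority_frac = majority_frac, calibrate = calibrate,
              alpha = alpha, grubbs_alpha = grubbs_alpha, log_pca = log_pca,
              out_dir = out_dir)
  num <- c("replicates", "smooth_width", "baseline_width", "noise_window",
           "snr_min", "abs_min_mv", "tol_da", "tol_ppm", "calib_tol_ppm",
           "n_calib_refs",
           "majority_frac", "alpha", "grubbs_alpha")
  bad <- num[vapply(cfg[num], function(v) any(!is.finite(v) | v <= 0),
                    logical(1))]
  if (length(bad)) stop("non-positive config parameters: ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with `run_config` fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Fixed stage order: simulate -> smooth -> baseline-subtract -> detect ->
#' select calibration references -> recalibrate peak lists -> match across
#' spectra -> summarize conditions -> marker table -> relative changes ->
#' change matrix -> PCA. With `out_dir` set, every stage artifact is written
#' (design, peak lists, consensus table, marker table and rendering, relative
#' changes, PCA scores/loadings/variance) along with `manifest.json`
#' recording the full config, seed, config hash and package version, so a
#' rerun with the same config reproduces the outputs. Stage errors abort with
#' the stage name (and sample id where applicable). Degenerate settings that
#' detect no peaks at all complete with warnings and empty tables.
#'
#' @param config A `run_config`.
#' @param model Optional `spectrum_model`; default [make_default_truth()]
#'   with the config seed.
#' @return Invisibly, a list with `config`, `model`, `design`, `peaklists`,
#'   `references`, `consensus`, `summary`, `marker_table`, `relative_change`,
#'   `change_matrix`, `pca`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), model = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr, sample = NULL) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "'",
           if (!is.null(sample)) paste0(" (sample ", sample, ")"),
           " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  model <- model %||% stage("simulate", make_default_truth(config$seed))
  design <- stage("simulate", make_design(model, config$replicates,
                                          config$concentrations))
  sim <- stage("simulate", simulate_experiment(model, design, config$seed))
  peaklists <- vector("list", length(sim$spectra))
  for (i in seq_along(sim$spectra)) {
    id <- names(sim$spectra)[i]
    sp <- stage("preprocess",
                preprocess_spectrum(sim$spectra[[i]], config$smooth_width,
                                    config$baseline_width), id)
    peaklists[[i]] <- stage("detect",
                            detect_peaks(sp, config$snr_min,
                                         config$abs_min_mv,
                                         config$noise_window), id)
  }
  names(peaklists) <- names(sim$spectra)
  n_detected <- sum(vapply(peaklists, function(p) nrow(p$peaks), integer(1)))
  references <- NULL
  if (config$calibrate && n_detected > 0) {
    references <- tryCatch(
      select_calibration_peaks(peaklists, config$n_calib_refs,
                               config$majority_frac, config$tol_da,
                               config$calib_tol_ppm),
      error = function(e) {
        warning("calibration reference selection failed (",
                conditionMessage(e), "); continuing uncalibrated")
        NULL
      })
    if (!is.null(references)) {
      peaklists <- lapply(peaklists, function(pl) {
        if (!nrow(pl$peaks)) return(pl)
        stage("calibrate",
              calibrate(pl, references, config$tol_da,
                        config$calib_tol_ppm),
              pl$sample_id)
      })
    }
  } else if (n_detected == 0) {
    warning("no peaks detected in any spectrum; downstream tables are empty")
  }
  consensus <- stage("align",
                     match_peaks(peaklists, config$tol_da, config$tol_ppm))
  summary <- stage("align", summarize_conditions(consensus, design))
  marker <- NULL
  rc <- NULL
  cm <- NULL
  pca <- NULL
  if (length(consensus$mass)) {
    marker <- stage("differential",
                    build_marker_table(consensus, design,
                                       comparison =
                                         model$reference_concentration,
                                       alpha = config$alpha,
                                       grubbs_alpha = config$grubbs_alpha))
    rc <- stage("differential", relative_change(summary))
    cm <- stage("fingerprint", build_change_matrix(rc))
    if (nrow(cm) >= 2) {
      pca <- stage("fingerprint",
                   pca_fingerprint(cm, log_transform = config$log_pca))
    }
  } else {
    marker <- structure(
      data.frame(label = character(), mass = numeric(), toxin = character(),
                 concentration = numeric(), n_used = integer(),
                 mean_treated = numeric(), mean_control = numeric(),
                 rel_change = numeric(), t = numeric(), p = numeric(),
                 direction = character(), mark = character(),
                 untestable = logical()),
      class = c("marker_table", "data.frame"))
  }
  manifest <- list(config = unclass(config),
                   config_hash = config_hash(config), seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("toxprint")),
                   n_spectra = length(sim$spectra),
                   n_consensus_peaks = length(consensus$mass),
                   references = references)
  result <- list(config = config, model = model, design = design,
                 peaklists = peaklists, references = references,
                 consensus = consensus, summary = summary,
                 marker_table = marker, relative_change = rc,
                 change_matrix = cm, pca = pca, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_design(result$design, p("design.csv"))
  write_peaklists(result$peaklists, p("peaklists.csv"))
  write_consensus(result$consensus, p("consensus.csv"))
  utils::write.csv(as.data.frame(result$marker_table), p("marker_table.csv"),
                   row.names = FALSE)
  if (nrow(result$marker_table))
    writeLines(render_marker_table(result$marker_table),
               p("marker_table.txt"))
  if (!is.null(result$relative_change))
    utils::write.csv(result$relative_change$ratio, p("relative_change.csv"))
  if (!is.null(result$pca)) {
    utils::write.csv(result$pca$scores, p("pca_scores.csv"))
    utils::write.csv(result$pca$loadings, p("pca_loadings.csv"))
    utils::write.csv(data.frame(component = seq_along(result$pca$explained),
                                explained = result$pca$explained),
                     p("pca_variance.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
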