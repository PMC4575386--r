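# Ground-truthed synthetic experiments: whole-cell linear-mode MALDI-TOF
# spectra with known peak panels and toxin effect profiles, plus viability
# plates with a known 4PL dose-response. Everything is seeded and
# reproducible; every simulated spectrum carries its emitted truth table.

#' Construct a spectrum forward model
#'
#' The forward model describes how a whole-cell profile spectrum arises:
#' Gaussian peaks (width growing linearly in m/z, as linear-TOF resolution
#' does) on a decaying-exponential chemical-noise baseline, additive Gaussian
#' detector noise, a per-spectrum multiplicative spot intensity factor, a
#' per-peak biological replicate factor, and a small per-spectrum affine
#' mass-axis drift in the sqrt(m/z) domain (TOF flight time scales with
#' sqrt(m/z)).
#'
#' @param peaks Data frame with columns `label`, `mass` (Da), `abundance`
#'   (mV) and `width` (Gaussian sigma, Da).
#' @param effects Named list: `effects[[toxin]][[as.character(conc)]]` is a
#'   numeric vector of per-peak fold changes (> 0).
#' @param concentrations Named list of the concentration grid per toxin.
#' @param reference_concentration Named numeric: the per-toxin comparison
#'   concentration used for the marker table.
#' @param baseline List with `amplitude` (mV), `decay` (Da) and `constant`
#'   (mV): baseline(m) = amplitude * exp(-(m - grid_from)/decay) + constant.
#' @param noise_sd Additive detector noise SD (mV).
#' @param bio_cv Per-peak lognormal replicate variability (sdlog).
#' @param scale_sd Per-spectrum lognormal spot intensity variability (sdlog).
#' @param drift_slope_sd SD of the sqrt-domain drift slope around 1 (clamped
#'   to |slope - 1| < 1e-3).
#' @param drift_intercept_sd SD of the sqrt-domain drift intercept
#'   (sqrt-Da).
#' @param grid_from,grid_to,grid_step m/z grid (Da).
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(peaks, effects, concentrations,
                           reference_concentration,
                           baseline = list(amplitude = 150, decay = 3000,
                                           constant = 10),
                           noise_sd = 15, bio_cv = 0.015, scale_sd = 0.3,
                           drift_slope_sd = 2e-4, drift_intercept_sd = 0.003,
                           grid_from = 2000, grid_to = 20000,
                           grid_step = 0.2) {
  stopifnot(is.data.frame(peaks),
            all(c("label", "mass", "abundance", "width") %in% names(peaks)))
  if (nrow(peaks)) {
    stopifnot(all(peaks$mass >= grid_from), all(peaks$mass <= grid_to),
              all(peaks$abundance > 0), all(peaks$width > 0))
  }
  stopifnot(noise_sd >= 0, bio_cv >= 0, scale_sd >= 0, grid_step > 0)
  for (tox in names(effects)) {
    for (cc in names(effects[[tox]])) {
      f <- effects[[tox]][[cc]]
      if (length(f) != nrow(peaks) || any(f <= 0))
        stop("effect profile for ", tox, " @ ", cc,
             " must hold one positive fold change per peak")
    }
  }
  structure(list(peaks = peaks, effects = effects,
                 concentrations = concentrations,
                 reference_concentration = reference_concentration,
                 baseline = baseline, noise_sd = noise_sd, bio_cv = bio_cv,
                 scale_sd = scale_sd, drift_slope_sd = drift_slope_sd,
                 drift_intercept_sd = drift_intercept_sd,
                 grid = list(from = grid_from, to = grid_to,
                             step = grid_step)),
            class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("spectrum_model: %d peaks, grid %g-%g Da step %g, noise %g mV\n",
              nrow(x$peaks), x$grid$from, x$grid$to, x$grid$step, x$noise_sd))
  cat("  toxins:", paste(names(x$effects), collapse = ", "), "\n")
  invisible(x)
}

# Fold change magnitudes encoding the fixture's direction/mark annotations at
# the reference concentration of each toxin.
fold_for_annotation <- function(direction, mark) {
  if (direction == "none") return(1)
  mag <- if (mark == "**") 2.5 else 2.0
  if (direction == "up") mag else 1 / mag
}

#' Default ground-truth spectrum model
#'
#' Builds the default synthetic truth: the 15 marker peaks of the packaged
#' fixture (labels A-O, 4562-15292 Da) with per-toxin fold-change profiles
#' whose signs reproduce the fixture's annotated directions at each toxin's
#' reference concentration (copper sulfate 9 mg/L, acridine 150 uM, BNF
#' 50 uM). Fold changes at other concentrations scale geometrically with
#' concentration (log fold proportional to dose), giving the
#' concentration-dependent profiles the differential and PCA stages expect.
#' Optional unlabelled background peaks (fold 1 under every treatment) can be
#' added to emulate the busier regions of real whole-cell spectra.
#'
#' @param seed Integer seed; base abundances and background peak positions are
#'   drawn deterministically from it.
#' @param n_background Number of extra non-marker peaks (default 0).
#' @param ... Passed on to [spectrum_model()] (noise levels, grid, drift).
#' @return A `spectrum_model` with `nrow(model$peaks) == 15 + n_background`.
#' @export
make_default_truth <- function(seed = 1, n_background = 0, ...) {
  fx <- load_marker_fixture()
  toxins <- fixture_toxins()
  conc_grid <- list(copper_sulfate = c(2, 4, 6, 9, 12),
                    acridine = c(50, 100, 150),
                    bnf = c(10, 30, 50))
  ref <- c(copper_sulfate = 9, acridine = 150, bnf = 50)
  with_seed(seed, {
    abundance <- stats::runif(nrow(fx), 900, 2600)
    peaks <- data.frame(label = fx$label, mass = as.numeric(fx$mass),
                        abundance = abundance,
                        width = peak_sigma(fx$mass))
    if (n_background > 0) {
      bg_mass <- numeric(0)
      while (length(bg_mass) < n_background) {
        cand <- stats::runif(1, 2500, 19000)
        if (all(abs(cand - c(peaks$mass, bg_mass)) > 100))
          bg_mass <- c(bg_mass, cand)
      }
      bg <- data.frame(label = paste0("bg", seq_len(n_background)),
                       mass = sort(bg_mass),
                       abundance = stats::runif(n_background, 300, 1500),
                       width = peak_sigma(sort(bg_mass)))
      peaks <- rbind(peaks, bg)
      peaks <- peaks[order(peaks$mass), ]
      rownames(peaks) <- NULL
    }
    effects <- list()
    for (tox in toxins) {
      ref_fold <- vapply(seq_len(nrow(fx)), function(i) {
        fold_for_annotation(fx[[paste0(tox, "_direction")]][i],
                            fx[[paste0(tox, "_mark")]][i])
      }, numeric(1))
      ref_fold <- ref_fold[match(peaks$label, fx$label)]
      ref_fold[is.na(ref_fold)] <- 1  # background peaks unaffected
      effects[[tox]] <- list()
      for (cc in conc_grid[[tox]]) {
        effects[[tox]][[as.character(cc)]] <-
          exp(log(ref_fold) * cc / ref[[tox]])
      }
    }
    spectrum_model(peaks, effects, conc_grid, ref, ...)
  })
}

# Gaussian sigma (Da) as an affine function of mass: FWHM = 6 + 2.5e-4 * m,
# wide enough to survive the default 50-channel smoothing yet narrow enough to
# resolve the closest marker pair (14 Da at m/z 4562).
peak_sigma <- function(mass) (6 + 2.5e-4 * mass) / (2 * sqrt(2 * log(2)))

model_baseline <- function(model, mz) {
  b <- model$baseline
  b$amplitude * exp(-(mz - model$grid$from) / b$decay) + b$constant
}

model_grid <- function(model) {
  seq(model$grid$from, model$grid$to, by = model$grid$step)
}

# Fold-change vector for one condition; errors on unknown conditions.
condition_folds <- function(model, toxin, concentration, is_control) {
  if (is_control) {
    if (!toxin %in% names(model$effects))
      stop("unknown condition: ", condition_id(toxin, concentration, TRUE))
    return(rep(1, nrow(model$peaks)))
  }
  eff <- model$effects[[toxin]]
  key <- as.character(concentration)
  if (is.null(eff) || is.null(eff[[key]]))
    stop("unknown condition: ", condition_id(toxin, concentration, FALSE))
  eff[[key]]
}

#' Simulate one whole-cell spectrum
#'
#' Forward-simulates a profile spectrum for one condition and replicate:
#' per-peak heights are base abundance x fold change x per-spectrum spot
#' factor x per-peak replicate factor; peak positions are displaced by the
#' spectrum's sqrt-domain calibration drift; Gaussian peak shapes, the
#' chemical-noise baseline and additive detector noise are summed on the grid.
#' The emitted truth (drifted positions and heights) is stored in
#' `$truth`.
#'
#' @param model A `spectrum_model`.
#' @param toxin Toxin name (must exist in the model's effect profiles).
#' @param concentration Concentration (ignored for controls).
#' @param is_control Logical; control condition (all folds 1).
#' @param replicate Replicate index; equal seeds with different replicates
#'   give different noise realizations.
#' @param seed Experiment-level seed.
#' @return A `raw_spectrum` with a `truth` data frame
#'   (`label`, `true_mass`, `mass`, `height`).
#' @export
simulate_spectrum <- function(model, toxin, concentration = NA_real_,
                              is_control = FALSE, replicate = 1L, seed = 1) {
  folds <- condition_folds(model, toxin, concentration, is_control)
  cond_idx <- match(toxin, names(model$effects)) * 1000 +
    (if (is_control) 0 else match(as.character(concentration),
                                  names(model$effects[[toxin]])))
  sseed <- derive_seed(seed, cond_idx, replicate)
  mz <- model_grid(model)
  with_seed(sseed, {
    slope <- 1 + max(-9.99e-4, min(9.99e-4,
                                   stats::rnorm(1, 0, model$drift_slope_sd)))
    intercept <- stats::rnorm(1, 0, model$drift_intercept_sd)
    spot <- if (model$scale_sd > 0) stats::rlnorm(1, 0, model$scale_sd) else 1
    biol <- if (model$bio_cv > 0)
      stats::rlnorm(nrow(model$peaks), 0, model$bio_cv)
    else rep(1, nrow(model$peaks))
    heights <- model$peaks$abundance * folds * spot * biol
    obs_mass <- (slope * sqrt(model$peaks$mass) + intercept)^2
    intensity <- model_baseline(model, mz)
    for (i in seq_len(nrow(model$peaks))) {
      s <- model$peaks$width[i]
      win <- which(mz >= obs_mass[i] - 6 * s & mz <= obs_mass[i] + 6 * s)
      intensity[win] <- intensity[win] +
        heights[i] * exp(-((mz[win] - obs_mass[i])^2) / (2 * s^2))
    }
    if (model$noise_sd > 0)
      intensity <- intensity + stats::rnorm(length(mz), 0, model$noise_sd)
    truth <- data.frame(label = model$peaks$label,
                        true_mass = model$peaks$mass, mass = obs_mass,
                        height = heights)
    attr(truth, "drift") <- c(slope = slope, intercept = intercept)
    raw_spectrum(mz, intensity,
                 sample_id = paste0(condition_id(toxin, concentration,
                                                 is_control),
                                    ":r", replicate),
                 toxin = toxin, concentration = concentration,
                 is_control = is_control, replicate = replicate,
                 truth = truth)
  })
}

#' Build an experiment design table
#'
#' One row per sample: each toxin series gets its treated concentrations plus
#' exactly one control condition, each with `replicates` independent
#' replicates (default 6 independent experiments).
#'
#' @param model A `spectrum_model`.
#' @param replicates Replicates per condition (default 6).
#' @param concentrations `"all"` for the full grid or `"reference"` for the
#'   per-toxin comparison concentration only; alternatively a named list of
#'   concentration vectors.
#' @param toxins Which toxin series to include (default all in the model).
#' @return Data frame with columns `sample_id`, `toxin`, `concentration`,
#'   `is_control`, `replicate`.
#' @export
make_design <- function(model, replicates = 6,
                        concentrations = c("all", "reference"),
                        toxins = names(model$effects)) {
  if (replicates < 1) stop("replicates must be at least 1")
  if (is.character(concentrations)) {
    concentrations <- match.arg(concentrations)
    conc <- if (concentrations == "all") model$concentrations[toxins]
    else lapply(model$reference_concentration[toxins], identity)
  } else conc <- concentrations[toxins]
  rows <- list()
  for (tox in toxins) {
    cc <- c(NA_real_, unlist(conc[[tox]], use.names = FALSE))
    for (ci in seq_along(cc)) {
      is_ctrl <- is.na(cc[ci])
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <-
          data.frame(sample_id = paste0(condition_id(tox, cc[ci], is_ctrl),
                                        ":r", r),
                     toxin = tox, concentration = cc[ci],
                     is_control = is_ctrl, replicate = r)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full experiment
#'
#' One spectrum per design row, each with independently drawn drift, spot and
#' replicate factors, plus the combined truth table (emitted masses and
#' heights per sample) for downstream recall/precision scoring. Regeneration
#' with the same seed is bit-identical.
#'
#' @param model A `spectrum_model`.
#' @param design Design table from [make_design()].
#' @param seed Experiment seed.
#' @return List with `spectra` (named list of `raw_spectrum`), `design`,
#'   `truth` (long data frame), and `model`.
#' @export
simulate_experiment <- function(model, design, seed = 1) {
  if (!nrow(design)) stop("design has no rows")
  if (any(!design$toxin %in% names(model$effects)))
    stop("design names toxins absent from the model")
  spectra <- vector("list", nrow(design))
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    d <- design[i, ]
    sp <- simulate_spectrum(model, d$toxin, d$concentration, d$is_control,
                            d$replicate, seed)
    sp$sample_id <- d$sample_id
    spectra[[i]] <- sp
    tr <- sp$truth
    tr$sample_id <- d$sample_id
    truth[[i]] <- tr
  }
  names(spectra) <- design$sample_id
  list(spectra = spectra, design = design,
       truth = do.call(rbind, truth), model = model, seed = seed)
}

#' Construct a viability dose-response truth
#'
#' @param ec50 True EC50 (> 0, concentration units).
#' @param hill Hill slope (> 0 for a decreasing response).
#' @param top,bottom Upper/lower plateaus in percent viability (`top >
#'   bottom`).
#' @param noise_sd Additive noise SD on the percent scale.
#' @return An object of class `viability_truth`.
#' @export
viability_truth <- function(ec50 = 8.23, hill = 2, top = 100, bottom = 0,
                            noise_sd = 5) {
  stopifnot(ec50 > 0, top > bottom, noise_sd >= 0)
  structure(list(ec50 = ec50, hill = hill, top = top, bottom = bottom,
                 noise_sd = noise_sd), class = "viability_truth")
}

# The 4PL response at given doses (percent of control).
four_pl <- function(dose, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (dose / ec50)^hill)
}

#' Simulate a viability plate
#'
#' Generates raw plate readouts (arbitrary fluorescence units) for treated
#' wells at each dose, untreated control wells, and cell-free blank wells,
#' with the true response following a four-parameter logistic curve in
#' percent-of-control units.
#'
#' @param truth A `viability_truth`.
#' @param doses Positive dose vector (at least 2 distinct values).
#' @param replicates Wells per dose (default 4 independent experiments).
#' @param seed Seed.
#' @param blank_mean,control_span Raw-signal scale: blank level and the
#'   blank-to-control span in instrument units.
#' @return Data frame of class `viability_plate` with columns `dose`,
#'   `signal`, `well_type` (`treated`/`control`/`blank`), `replicate`.
#' @export
simulate_viability <- function(truth, doses, replicates = 4, seed = 1,
                               blank_mean = 2000, control_span = 28000) {
  stopifnot(inherits(truth, "viability_truth"))
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(unique(doses)) < 2) stop("need at least 2 distinct doses")
  with_seed(seed, {
    unit <- control_span / 100  # raw units per percent viability
    rows <- list()
    for (r in seq_len(replicates)) {
      resp <- four_pl(doses, truth$bottom, truth$top, truth$ec50, truth$hill)
      if (truth$noise_sd > 0)
        resp <- resp + stats::rnorm(length(doses), 0, truth$noise_sd)
      rows[[length(rows) + 1L]] <-
        data.frame(dose = doses, signal = blank_mean + resp * unit,
                   well_type = "treated", replicate = r)
      ctrl <- 100 + if (truth$noise_sd > 0)
        stats::rnorm(1, 0, truth$noise_sd) else 0
      blk <- if (truth$noise_sd > 0)
        stats::rnorm(1, 0, truth$noise_sd / 5) else 0
      rows[[length(rows) + 1L]] <-
        data.frame(dose = c(0, 0), signal = c(blank_mean + ctrl * unit,
                                              blank_mean + blk * unit),
                   well_type = c("control", "blank"), replicate = r)
    }
    plate <- do.call(rbind, rows)
    class(plate) <- c("viability_plate", "data.frame")
    plate
  })
}
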