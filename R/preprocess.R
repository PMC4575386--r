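# Spectrum preprocessing: average smoothing, morphological baseline
# estimation/subtraction, and internal mass recalibration in the sqrt(m/z)
# domain. Window widths are expressed in channels (grid samples), rounded up
# to odd for centring.

#' Smooth a spectrum with a centred moving average
#'
#' @param spectrum A `raw_spectrum`.
#' @param width_channels Window width in channels (default 50; rounded up to
#'   odd). Edges use shrinking windows, so total ion current is preserved for
#'   interior-supported signals.
#' @return The smoothed `raw_spectrum` (same m/z grid).
#' @export
smooth_spectrum <- function(spectrum, width_channels = 50) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (width_channels < 1) stop("width_channels must be at least 1")
  if (width_channels == 1) return(spectrum)
  spectrum$intensity <- moving_average(spectrum$intensity, width_channels)
  spectrum
}

#' Estimate the chemical-noise baseline
#'
#' Morphological min-then-mean filter: a centred rolling minimum of the given
#' width suppresses peaks (narrow maxima never survive a minimum filter wider
#' than they are), and a rolling mean of the same width smooths the resulting
#' lower envelope back toward the true baseline.
#'
#' @param spectrum A `raw_spectrum` (ideally already smoothed).
#' @param width_channels Filter width in channels (default 100; rounded up to
#'   odd). Must be at least 3 and comfortably wider than the peaks.
#' @return Numeric baseline vector (mV) aligned to the spectrum grid.
#' @export
estimate_baseline <- function(spectrum, width_channels = 100) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (width_channels < 3) stop("width_channels must be at least 3")
  lower <- rolling_min(spectrum$intensity, width_channels)
  moving_average(lower, width_channels)
}

#' Subtract a baseline, clipping at zero
#'
#' @param spectrum A `raw_spectrum`.
#' @param baseline Numeric vector from [estimate_baseline()], same length.
#' @return The baseline-subtracted `raw_spectrum`; the number of channels
#'   clipped at zero is recorded in the `n_clipped` field.
#' @export
subtract_baseline <- function(spectrum, baseline) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  if (length(baseline) != length(spectrum$intensity))
    stop("baseline length (", length(baseline),
         ") does not match spectrum length (", length(spectrum$intensity), ")")
  resid <- spectrum$intensity - baseline
  spectrum$n_clipped <- sum(resid < 0)
  spectrum$intensity <- pmax(resid, 0)
  spectrum
}

#' Smooth and baseline-subtract in one call
#'
#' Convenience wrapper running the fixed preprocessing order
#' smooth -> estimate baseline -> subtract.
#'
#' @inheritParams smooth_spectrum
#' @param baseline_width Baseline filter width in channels (default 100).
#' @return The preprocessed `raw_spectrum`.
#' @export
preprocess_spectrum <- function(spectrum, width_channels = 50,
                                baseline_width = 100) {
  sm <- smooth_spectrum(spectrum, width_channels)
  subtract_baseline(sm, estimate_baseline(sm, baseline_width))
}

#' Select internal calibration reference masses
#'
#' Clusters peak masses across spectra (single-linkage chaining with a
#' mass-dependent tolerance wide enough to span uncorrected drift), keeps
#' clusters present in more than `majority_frac` of the spectra, drops
#' ambiguous clusters (ones to which a single spectrum contributes more than
#' one peak, as happens when two close species chain together), and picks
#' `n_refs` of the rest spread as evenly as possible across the mass range
#' (greedy farthest-point selection). Cluster median masses are returned,
#' sorted.
#'
#' @param peaklists List of at least 3 `peak_list` objects.
#' @param n_refs Number of reference masses wanted (default 10).
#' @param majority_frac Minimum fraction of spectra a cluster must appear in
#'   (default 0.5, exclusive).
#' @param tol_da,tol_ppm Cluster link tolerance: max(tol_da, tol_ppm * mass).
#' @return Sorted numeric vector of reference masses. If fewer than `n_refs`
#'   clusters qualify, all qualifying masses are returned with a warning;
#'   fewer than 2 is an error.
#' @export
select_calibration_peaks <- function(peaklists, n_refs = 10,
                                     majority_frac = 0.5,
                                     tol_da = 2, tol_ppm = 2000) {
  if (length(peaklists) < 3) stop("need at least 3 peak lists")
  pooled <- do.call(rbind, lapply(seq_along(peaklists), function(i) {
    p <- peaklists[[i]]$peaks
    if (!nrow(p)) return(NULL)
    data.frame(mass = p$mass, list_idx = i)
  }))
  if (is.null(pooled) || nrow(pooled) < 2)
    stop("fewer than 2 qualifying calibration clusters")
  cl <- chain_cluster(pooled$mass, tol_da, tol_ppm)
  presence <- tapply(pooled$list_idx, cl, function(ix) length(unique(ix)))
  multiplicity <- tapply(pooled$list_idx, cl, function(ix) max(table(ix)))
  medians <- tapply(pooled$mass, cl, stats::median)
  keep <- presence > majority_frac * length(peaklists) & multiplicity == 1
  masses <- sort(as.vector(medians[keep]))
  if (length(masses) < 2) stop("fewer than 2 qualifying calibration clusters")
  if (length(masses) <= n_refs) {
    if (length(masses) < n_refs)
      warning("only ", length(masses), " qualifying clusters for ", n_refs,
              " requested references")
    return(masses)
  }
  sort(farthest_point(masses, n_refs))
}

# Greedy farthest-point subset: start from the extremes, repeatedly add the
# mass with the largest distance to the current selection.
farthest_point <- function(masses, k) {
  sel <- c(which.min(masses), which.max(masses))
  while (length(sel) < k) {
    d <- vapply(seq_along(masses), function(i) {
      if (i %in% sel) -Inf else min(abs(masses[i] - masses[sel]))
    }, numeric(1))
    sel <- c(sel, which.max(d))
  }
  masses[sel]
}

# Single-linkage chain clustering of sorted masses: a new cluster starts
# wherever the gap to the previous mass exceeds the local tolerance.
chain_cluster <- function(masses, tol_da, tol_ppm) {
  ord <- order(masses)
  m <- masses[ord]
  gap <- diff(m)
  tol <- mass_tolerance((m[-length(m)] + m[-1]) / 2, tol_da, tol_ppm)
  cl_sorted <- cumsum(c(1L, as.integer(gap > tol)))
  cl <- integer(length(masses))
  cl[ord] <- cl_sorted
  cl
}

#' Internal mass recalibration in the sqrt(m/z) domain
#'
#' Matches observed peaks to reference masses (nearest neighbour within
#' `tol_da + tol_ppm * mass`), fits the affine map
#' sqrt(m_ref) = a * sqrt(m_obs) + b by least squares, and applies it to the
#' object's mass axis. TOF flight time is proportional to sqrt(m/z), so an
#' affine sqrt-domain map is the physically natural drift family. If the fit
#' would increase the RMS reference residual the identity map is kept.
#'
#' @param x A `peak_list` or a preprocessed `raw_spectrum`.
#' @param reference_masses Sorted reference masses (>= 2 must match).
#' @param tol_da,tol_ppm Matching tolerance; the per-reference window is
#'   `tol_da + tol_ppm * 1e-6 * mass`. The 2000 ppm default admits the whole
#'   physically admissible drift family (|sqrt-domain slope - 1| < 1e-3
#'   shifts masses by up to 2e-3 relative).
#' @param ... For spectra: `snr_min`, `abs_min_mv` forwarded to
#'   [detect_peaks()] to locate matchable peaks.
#' @return The calibrated object with a `calibration` field (class
#'   `calibration_model`: coefficients `a`, `b`, per-reference residuals
#'   before/after in Da, and `n_refs_used`).
#' @export
calibrate <- function(x, reference_masses, tol_da = 2, tol_ppm = 2000, ...) {
  UseMethod("calibrate")
}

fit_sqrt_calibration <- function(observed, reference_masses, tol_da, tol_ppm) {
  tol <- tol_da + tol_ppm * 1e-6 * reference_masses
  obs_match <- rep(NA_real_, length(reference_masses))
  for (i in seq_along(reference_masses)) {
    d <- abs(observed - reference_masses[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tol[i]) obs_match[i] <- observed[j]
  }
  ok <- !is.na(obs_match)
  if (sum(ok) < 2)
    stop("fewer than 2 reference masses matched within tolerance")
  xo <- sqrt(obs_match[ok]); yr <- sqrt(reference_masses[ok])
  fit <- stats::lm.fit(cbind(1, xo), yr)
  b <- fit$coefficients[[1]]; a <- fit$coefficients[[2]]
  if (!is.finite(a) || a <= 0) stop("calibration map is not increasing")
  pre <- obs_match[ok] - reference_masses[ok]
  post <- (a * xo + b)^2 - reference_masses[ok]
  if (sqrt(mean(post^2)) > sqrt(mean(pre^2))) {  # keep identity if no gain
    a <- 1; b <- 0; post <- pre
  }
  structure(list(a = a, b = b, residuals_pre_da = pre,
                 residuals_post_da = post, n_refs_used = sum(ok),
                 reference_masses = reference_masses[ok]),
            class = "calibration_model")
}

apply_calibration_masses <- function(masses, model) {
  (model$a * sqrt(masses) + model$b)^2
}

#' @rdname calibrate
#' @export
calibrate.peak_list <- function(x, reference_masses, tol_da = 2,
                                tol_ppm = 2000, ...) {
  if (!nrow(x$peaks)) stop("peak list is empty; nothing to calibrate")
  model <- fit_sqrt_calibration(x$peaks$mass, reference_masses, tol_da,
                                tol_ppm)
  x$peaks$mass <- apply_calibration_masses(x$peaks$mass, model)
  if (any(diff(x$peaks$mass) <= 0)) stop("corrected mass axis not monotone")
  x$calibration <- model
  x
}

#' @rdname calibrate
#' @export
calibrate.raw_spectrum <- function(x, reference_masses, tol_da = 2,
                                   tol_ppm = 2000, snr_min = 3,
                                   abs_min_mv = 200, ...) {
  pl <- detect_peaks(x, snr_min = snr_min, abs_min_mv = abs_min_mv)
  if (!nrow(pl$peaks)) stop("no peaks detected; cannot calibrate spectrum")
  model <- fit_sqrt_calibration(pl$peaks$mass, reference_masses, tol_da,
                                tol_ppm)
  x$mz <- apply_calibration_masses(x$mz, model)
  if (any(diff(x$mz) <= 0)) stop("corrected mass axis not monotone")
  x$calibration <- model
  x
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration_model: sqrt-domain a=%.8f b=%.5f, %d refs, RMS %.3f -> %.3f Da\n",
    x$a, x$b, x$n_refs_used, sqrt(mean(x$residuals_pre_da^2)),
    sqrt(mean(x$residuals_post_da^2))))
  invisible(x)
}
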