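# Noise estimation and peak detection with the dual threshold
# (S/N >= 3 and absolute ion abundance >= 200 mV).

#' Construct a peak list
#'
#' @param peaks Data frame with columns `mass` (Da), `abundance` (mV, > 0)
#'   and `snr`, sorted by mass.
#' @param sample_id,toxin,concentration,is_control,replicate Sample metadata.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(peaks, sample_id = "sample", toxin = NA_character_,
                      concentration = NA_real_, is_control = FALSE,
                      replicate = 1L) {
  stopifnot(is.data.frame(peaks),
            all(c("mass", "abundance", "snr") %in% names(peaks)))
  if (nrow(peaks)) {
    stopifnot(all(diff(peaks$mass) > 0), all(peaks$abundance > 0),
              all(peaks$snr >= 0))
  }
  structure(list(peaks = peaks, sample_id = sample_id, toxin = toxin,
                 concentration = concentration,
                 is_control = isTRUE(is_control),
                 replicate = as.integer(replicate)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("peak_list '%s': %d peaks\n", x$sample_id, nrow(x$peaks)))
  invisible(x)
}

#' Estimate the per-channel noise level
#'
#' Robust local noise: a rolling median removes the local signal level, and
#' 1.4826 times the rolling median absolute deviation of the remainder
#' estimates the Gaussian noise SD, insensitive to sparse peaks. Values are
#' floored at machine epsilon so S/N is always defined.
#'
#' @param spectrum A baseline-subtracted `raw_spectrum`.
#' @param window_channels Odd window width in channels, at least 11
#'   (default 2501).
#' @return Numeric vector of per-channel noise SD estimates (mV).
#' @export
estimate_noise <- function(spectrum, window_channels = 2501) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  w <- as.integer(window_channels)
  if (w %% 2L == 0L || w < 11L)
    stop("window_channels must be odd and at least 11")
  n <- length(spectrum$intensity)
  if (w > n) stop("window width (", w, ") exceeds spectrum length (", n, ")")
  x <- spectrum$intensity
  # local level from a (decimated) rolling median, then the MAD of the
  # remainder evaluated on window-sized blocks and linearly interpolated
  # between block centres: full-window statistical efficiency without a
  # full-resolution rolling median of the deviations
  d <- max(1L, w %/% 501L)
  idx <- seq(1L, n, by = d)
  k <- odd_width(max(11L, min(length(idx) - 2L, w %/% d)))
  med_s <- stats::runmed(x[idx], k, endrule = "median")
  med <- if (d == 1L) med_s
  else stats::approx(idx, med_s, xout = seq_len(n), rule = 2)$y
  dev <- abs(x - med)
  block <- pmin((seq_len(n) - 1L) %/% w + 1L, max(1L, n %/% w))
  mads <- tapply(dev, block, stats::median)
  centres <- tapply(seq_len(n), block, stats::median)
  noise <- if (length(mads) == 1L) rep(1.4826 * mads[[1L]], n)
  else 1.4826 * stats::approx(centres, mads, xout = seq_len(n), rule = 2)$y
  pmax(noise, .Machine$double.eps)
}

#' Detect peaks with the dual S/N and absolute-abundance threshold
#'
#' Local maxima of the preprocessed (smoothed, baseline-subtracted) spectrum
#' are kept when the apex exceeds both the absolute abundance threshold and
#' `snr_min` times the local noise level. Plateau ties resolve to the
#' lowest-mass channel; maxima closer than the local full width at half
#' maximum are merged into the taller one; the reported mass is the
#' intensity-weighted centroid over the apex +/- `centroid_k` channels.
#'
#' @param spectrum A preprocessed `raw_spectrum`.
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param abs_min_mv Minimum apex abundance in mV (default 200).
#' @param noise_window Window for [estimate_noise()] (default 2501 channels).
#' @param centroid_k Half-width in channels of the centroid window (default
#'   3).
#' @return A `peak_list` (possibly empty) carrying the spectrum's metadata.
#' @export
detect_peaks <- function(spectrum, snr_min = 3, abs_min_mv = 200,
                         noise_window = 2501, centroid_k = 3) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  x <- spectrum$intensity
  mz <- spectrum$mz
  n <- length(x)
  noise <- estimate_noise(spectrum, noise_window)
  # strict rise on the left, non-strict on the right: plateau ties keep the
  # lowest-mass channel
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                  x[2:(n - 1L)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= abs_min_mv & x[cand] / noise[cand] >= snr_min]
  if (length(cand) > 1L) {
    fw <- vapply(cand, function(i) local_fwhm(x, mz, i), numeric(1))
    cand <- merge_close_maxima(cand, mz, x, fw)
  }
  if (!length(cand)) {
    pk <- data.frame(mass = numeric(0), abundance = numeric(0),
                     snr = numeric(0))
  } else {
    centroid <- vapply(cand, function(i) {
      win <- max(1L, i - centroid_k):min(n, i + centroid_k)
      sum(mz[win] * x[win]) / sum(x[win])
    }, numeric(1))
    pk <- data.frame(mass = centroid, abundance = x[cand],
                     snr = x[cand] / noise[cand])
    pk <- pk[order(pk$mass), ]
    pk <- pk[c(TRUE, diff(pk$mass) > 0), ]
    rownames(pk) <- NULL
  }
  peak_list(pk, sample_id = spectrum$sample_id, toxin = spectrum$toxin,
            concentration = spectrum$concentration,
            is_control = spectrum$is_control,
            replicate = spectrum$replicate)
}

# Width at half the apex height, in Da, by walking outwards. The walk also
# stops at the first valley (intensity rising again), so overlapping
# neighbours do not inflate the width estimate.
local_fwhm <- function(x, mz, i, max_walk = 400L) {
  half <- x[i] / 2
  n <- length(x)
  l <- i
  while (l > 1L && x[l] > half && x[l - 1L] <= x[l] && i - l < max_walk)
    l <- l - 1L
  r <- i
  while (r < n && x[r] > half && x[r + 1L] <= x[r] && r - i < max_walk)
    r <- r + 1L
  mz[r] - mz[l]
}

# Merge maxima closer than the larger of their local FWHMs, keeping the
# taller apex.
merge_close_maxima <- function(cand, mz, x, fw) {
  keep <- rep(TRUE, length(cand))
  i <- 1L
  while (i < length(cand)) {
    j <- i + 1L
    while (j <= length(cand) && !keep[j]) j <- j + 1L
    if (j > length(cand)) break
    if (keep[i] && mz[cand[j]] - mz[cand[i]] < max(fw[i], fw[j])) {
      if (x[cand[j]] >= x[cand[i]]) keep[i] <- FALSE else keep[j] <- FALSE
      if (!keep[i]) i <- j
    } else i <- j
  }
  cand[keep]
}
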