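# Shared fixtures, all built in code.

# A flat spectrum at a constant intensity.
flat_spectrum <- function(value = 100, n = 1000, from = 2000, step = 1) {
  mz <- seq(from, by = step, length.out = n)
  raw_spectrum(mz, rep(value, n))
}

# Minimal single-toxin model: given peaks, all fold changes 1 at
# concentration 1; noise/drift/biology switched off unless requested.
test_model <- function(peaks, noise_sd = 0, bio_cv = 0, scale_sd = 0,
                       drift_slope_sd = 0, drift_intercept_sd = 0,
                       baseline = list(amplitude = 0, decay = 3000,
                                       constant = 0),
                       grid_step = 1, folds = rep(1, nrow(peaks)), ...) {
  spectrum_model(peaks,
                 effects = list(tox = list("1" = folds)),
                 concentrations = list(tox = 1),
                 reference_concentration = c(tox = 1),
                 baseline = baseline, noise_sd = noise_sd, bio_cv = bio_cv,
                 scale_sd = scale_sd, drift_slope_sd = drift_slope_sd,
                 drift_intercept_sd = drift_intercept_sd,
                 grid_step = grid_step, ...)
}

test_peaks_df <- function(masses = c(5000, 7000, 9000, 12000, 16000),
                          abundance = rep(1000, length(masses))) {
  data.frame(label = make_test_labels(length(masses)), mass = masses,
             abundance = abundance,
             width = (6 + 2.5e-4 * masses) / (2 * sqrt(2 * log(2))))
}

make_test_labels <- function(n) paste0("p", seq_len(n))

# Build a consensus_table directly from an abundance matrix (peaks x
# samples); columns named by sample id.
manual_consensus <- function(mass, abundance, samples) {
  out <- list(mass = mass, label = LETTERS[seq_along(mass)],
              abundance = abundance, samples = samples)
  class(out) <- "consensus_table"
  out
}

# Minimal mzML writer (uncompressed 64-bit little-endian arrays) used to
# exercise the mzML reader.
write_test_mzml <- function(mz, intensity, path) {
  enc <- function(v) {
    gsub("\n", "",
         jsonlite::base64_enc(writeBin(as.numeric(v), raw(), size = 8,
                                       endian = "little")),
         fixed = TRUE)
  }
  b1 <- enc(mz)
  b2 <- enc(intensity)
  arr <- function(b, acc, nm) {
    paste0('<binaryDataArray encodedLength="', nchar(b), '">',
           '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
           '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
           '<cvParam cvRef="MS" accession="', acc, '" name="', nm,
           '" value=""/>', '<binary>', b, '</binary></binaryDataArray>')
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><spectrumList count="1">',
    '<spectrum index="0" id="scan=1" defaultArrayLength="', length(mz), '">',
    '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="1"/>',
    '<binaryDataArrayList count="2">',
    arr(b1, "MS:1000514", "m/z array"),
    arr(b2, "MS:1000515", "intensity array"),
    '</binaryDataArrayList></spectrum></spectrumList></run></mzML>')
  writeLines(xml, path)
  path
}
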