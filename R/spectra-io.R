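# Readers and writers for spectra, peak lists, designs, and the packaged
# marker fixture.

#' Construct a raw spectrum object
#'
#' A `raw_spectrum` holds one acquired (or simulated) profile spectrum on a
#' strictly increasing m/z grid, with intensities in millivolts and the sample
#' metadata needed downstream (toxin, concentration, control flag, replicate).
#'
#' @param mz Numeric vector of m/z values (Da), strictly increasing.
#' @param intensity Numeric vector of intensities (mV), same length as `mz`.
#' @param sample_id Character scalar identifying the spotted sample.
#' @param toxin Toxin name (or `NA` if not applicable).
#' @param concentration Exposure concentration in the toxin's units.
#' @param is_control Logical; `TRUE` for control treatments.
#' @param replicate Replicate (independent experiment) index.
#' @param truth Optional data frame of emitted ground-truth peaks
#'   (`true_mass`, `mass`, `height`) carried by simulated spectra.
#' @return An object of class `raw_spectrum`.
#' @export
raw_spectrum <- function(mz, intensity, sample_id = "sample",
                         toxin = NA_character_, concentration = NA_real_,
                         is_control = FALSE, replicate = 1L, truth = NULL) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (length(mz) < 2L) stop("a spectrum needs at least two points")
  if (anyNA(mz) || any(!is.finite(mz))) stop("mz contains non-finite values")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity contains non-finite values")
  if (any(mz <= 0)) stop("mz contains non-positive masses")
  if (any(diff(mz) <= 0)) stop("mz must be strictly increasing")
  structure(list(mz = mz, intensity = intensity, sample_id = sample_id,
                 toxin = toxin, concentration = concentration,
                 is_control = isTRUE(is_control),
                 replicate = as.integer(replicate), truth = truth),
            class = "raw_spectrum")
}

#' @export
print.raw_spectrum <- function(x, ...) {
  cat(sprintf("raw_spectrum '%s': %d points, m/z %.1f-%.1f, max %.1f mV\n",
              x$sample_id, length(x$mz), min(x$mz), max(x$mz),
              max(x$intensity)))
  if (!is.na(x$toxin))
    cat(sprintf("  condition: %s\n",
                condition_id(x$toxin, x$concentration, x$is_control)))
  invisible(x)
}

#' Read a spectrum from disk
#'
#' Text spectra are two-column (m/z, intensity) files, whitespace- or
#' comma-delimited (auto-detected); `#`-prefixed comment lines and a header
#' line are skipped. Metadata are taken from a YAML sidecar `<path>.meta.yaml`
#' when present. mzML files (profile spectra, read-only) are read through the
#' mzR package when it is installed.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"txt"`, or `"mzML"`.
#' @param scan Scan number for mzML input (default first).
#' @return A `raw_spectrum`.
#' @export
read_spectrum <- function(path, format = c("auto", "txt", "mzML"), scan = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzML" else "txt"
  }
  if (format == "mzML") return(read_spectrum_mzml(path, scan))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)
  sep_comma <- grepl(",", lines[[min(2L, length(lines))]], fixed = TRUE)
  split_line <- function(l) {
    if (sep_comma) strsplit(l, ",")[[1]] else strsplit(trimws(l), "\\s+")[[1]]
  }
  first <- suppressWarnings(as.numeric(split_line(lines[[1]])))
  if (anyNA(first) && !any(is.nan(first))) lines <- lines[-1L]  # header line
  parts <- lapply(lines, split_line)
  ncol <- unique(lengths(parts))
  if (length(ncol) != 1L || ncol < 2L)
    stop("expected two columns (m/z, intensity) in ", path)
  raw_vals <- vapply(parts, function(p) p[1:2], character(2))
  vals <- suppressWarnings(array(as.numeric(raw_vals), dim(raw_vals)))
  if (any(is.nan(vals))) stop("non-finite values in ", path)
  if (anyNA(vals)) stop("non-numeric values in ", path)
  meta <- read_sidecar(path)
  raw_spectrum(vals[1, ], vals[2, ],
               sample_id = meta$sample_id %||% tools::file_path_sans_ext(basename(path)),
               toxin = meta$toxin %||% NA_character_,
               concentration = meta$concentration %||% NA_real_,
               is_control = meta$is_control %||% FALSE,
               replicate = meta$replicate %||% 1L)
}

read_sidecar <- function(path) {
  side <- paste0(path, ".meta.yaml")
  if (file.exists(side)) yaml::read_yaml(side) else list()
}

read_spectrum_mzml <- function(path, scan = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the mzR package")
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  pk <- mzR::peaks(fh, scan)
  raw_spectrum(pk[, 1], pk[, 2],
               sample_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a spectrum as two-column text
#'
#' Writes whitespace-delimited (m/z, intensity) text with a comment header and
#' a YAML metadata sidecar (`<path>.meta.yaml`) recording sample identity,
#' condition and replicate so that [read_spectrum()] round-trips.
#'
#' @param spectrum A `raw_spectrum`.
#' @param path Output file path.
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sidecar = TRUE) {
  stopifnot(inherits(spectrum, "raw_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# m/z intensity_mV"), con)
  writeLines(sprintf("%.6f %.6f", spectrum$mz, spectrum$intensity), con)
  if (sidecar) {
    meta <- list(sample_id = spectrum$sample_id, toxin = spectrum$toxin,
                 concentration = spectrum$concentration,
                 is_control = spectrum$is_control,
                 replicate = spectrum$replicate)
    yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

#' Load the packaged marker-peak fixture
#'
#' Returns the 15-row marker panel (labels A-O, masses 4562-15292 Da) with the
#' per-toxin direction of change and significance mark for copper sulfate,
#' acridine and BNF (beta-naphthoflavone) exposures of RTL-W1 cells.
#'
#' @return A data frame of class `marker_fixture` with columns `label`, `mass`
#'   and, for each toxin, `<toxin>_direction` (`none`/`up`/`down`) and
#'   `<toxin>_mark` (`none`/`*`/`**`).
#' @export
load_marker_fixture <- function() {
  path <- system.file("extdata", "table2_markers.csv", package = "toxprint",
                      mustWork = TRUE)
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(fx) == 15L, !anyDuplicated(fx$label),
            all(diff(fx$mass) > 0), fx$mass[1] == 4562, fx$mass[15] == 15292)
  class(fx) <- c("marker_fixture", "data.frame")
  fx
}

#' Toxins annotated in the marker fixture
#' @return Character vector of toxin identifiers.
#' @export
fixture_toxins <- function() c("copper_sulfate", "acridine", "bnf")

#' Write / read peak lists as CSV
#'
#' One row per detected peak: `sample_id`, `toxin`, `concentration`,
#' `is_control`, `replicate`, `mass`, `abundance_mV`, `snr`.
#'
#' @param peaklists A list of `peak_list` objects.
#' @param path CSV file path.
#' @return `path` invisibly for the writer; a list of `peak_list` objects for
#'   the reader.
#' @export
write_peaklists <- function(peaklists, path) {
  rows <- do.call(rbind, lapply(peaklists, function(pl) {
    if (!nrow(pl$peaks)) return(NULL)
    data.frame(sample_id = pl$sample_id, toxin = pl$toxin,
               concentration = pl$concentration, is_control = pl$is_control,
               replicate = pl$replicate, mass = pl$peaks$mass,
               abundance_mV = pl$peaks$abundance, snr = pl$peaks$snr)
  }))
  if (is.null(rows))
    rows <- data.frame(sample_id = character(), toxin = character(),
                       concentration = numeric(), is_control = logical(),
                       replicate = integer(), mass = numeric(),
                       abundance_mV = numeric(), snr = numeric())
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaklists
#' @export
read_peaklists <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(rows, rows$sample_id), function(d) {
    d <- d[order(d$mass), ]
    peak_list(data.frame(mass = d$mass, abundance = d$abundance_mV,
                         snr = d$snr),
              sample_id = d$sample_id[1], toxin = d$toxin[1],
              concentration = d$concentration[1],
              is_control = d$is_control[1], replicate = d$replicate[1])
  })
}

#' Write / read an experiment design table as CSV
#' @param design Data frame with columns `sample_id`, `toxin`,
#'   `concentration`, `is_control`, `replicate`.
#' @param path CSV file path.
#' @export
write_design <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
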