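# Cross-spectrum peak matching into a consensus table and per-condition
# replicate summaries.

#' Match peak masses across spectra
#'
#' Pools all peak masses and clusters them by single-linkage chaining with a
#' mass-dependent link threshold `max(tol_da, tol_ppm * 1e-6 * mass)`. Each
#' cluster becomes one consensus row (consensus mass = cluster median,
#' letter labels assigned in ascending mass order); the abundance matrix holds
#' each sample's apex abundance, 0 where the sample contributed no peak. If a
#' sample contributes several peaks to one cluster, the most abundant is
#' used. Clustering is invariant to the order of the input lists.
#'
#' @param peaklists List of `peak_list` objects (>= 1).
#' @param tol_da,tol_ppm Link tolerance (defaults 2 Da, 500 ppm).
#' @return An object of class `consensus_table`: `mass` (sorted consensus
#'   masses), `label`, `abundance` (peaks x samples matrix, mV), and
#'   `samples` (metadata data frame).
#' @export
match_peaks <- function(peaklists, tol_da = 2, tol_ppm = 500) {
  if (!length(peaklists)) stop("need at least 1 peak list")
  samples <- do.call(rbind, lapply(peaklists, function(pl) {
    data.frame(sample_id = pl$sample_id, toxin = pl$toxin,
               concentration = pl$concentration, is_control = pl$is_control,
               replicate = pl$replicate)
  }))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  pooled <- do.call(rbind, lapply(peaklists, function(pl) {
    if (!nrow(pl$peaks)) return(NULL)
    data.frame(mass = pl$peaks$mass, abundance = pl$peaks$abundance,
               sample_id = pl$sample_id)
  }))
  if (is.null(pooled)) {
    out <- list(mass = numeric(0), label = character(0),
                abundance = matrix(0, 0, nrow(samples),
                                   dimnames = list(NULL, samples$sample_id)),
                samples = samples)
    class(out) <- "consensus_table"
    return(out)
  }
  cl <- chain_cluster(pooled$mass, tol_da, tol_ppm)
  cl_ids <- sort(unique(cl))
  med <- vapply(split(pooled$mass, cl)[as.character(cl_ids)], stats::median,
                numeric(1))
  ord <- order(med)
  cons_mass <- unname(med[ord])
  n_pk <- length(cons_mass)
  row_map <- integer(max(cl))
  row_map[cl_ids[ord]] <- seq_len(n_pk)
  ab <- matrix(0, n_pk, nrow(samples),
               dimnames = list(NULL, samples$sample_id))
  # ascending-abundance assignment: a sample's most abundant peak in a
  # cluster wins
  o <- order(pooled$abundance)
  ab[cbind(row_map[cl[o]], match(pooled$sample_id[o], samples$sample_id))] <-
    pooled$abundance[o]
  out <- list(mass = cons_mass, label = make_labels(n_pk), abundance = ab,
              samples = samples)
  class(out) <- "consensus_table"
  out
}

#' @export
print.consensus_table <- function(x, ...) {
  cat(sprintf("consensus_table: %d peaks x %d samples\n", length(x$mass),
              ncol(x$abundance)))
  invisible(x)
}

#' Summarize replicate abundances per condition
#'
#' Means, sample SDs and replicate counts of consensus-peak abundances per
#' condition (toxin x concentration, controls included). Samples absent from
#' a condition's consensus row count as 0 mV (the absence convention that
#' keeps paired tests defined).
#'
#' @param table A `consensus_table`.
#' @param design Design data frame covering every sample in the table.
#' @return A data frame of class `condition_summary` with columns `label`,
#'   `mass`, `toxin`, `concentration`, `is_control`, `condition`, `n`,
#'   `mean`, `sd`.
#' @export
summarize_conditions <- function(table, design) {
  stopifnot(inherits(table, "consensus_table"))
  missing <- setdiff(table$samples$sample_id, design$sample_id)
  if (length(missing))
    stop("samples without design entry: ", paste(missing, collapse = ", "))
  empty <- data.frame(label = character(), mass = numeric(),
                      toxin = character(), concentration = numeric(),
                      is_control = logical(), condition = character(),
                      n = integer(), mean = numeric(), sd = numeric())
  if (!length(table$mass)) {
    class(empty) <- c("condition_summary", "data.frame")
    return(empty)
  }
  meta <- design[match(colnames(table$abundance), design$sample_id), ]
  cond <- condition_id(meta$toxin, meta$concentration, meta$is_control)
  rows <- list()
  for (cc in unique(cond)) {
    j <- which(cond == cc)
    sub <- table$abundance[, j, drop = FALSE]
    rows[[cc]] <- data.frame(
      label = table$label, mass = table$mass,
      toxin = meta$toxin[j[1]], concentration = meta$concentration[j[1]],
      is_control = meta$is_control[j[1]], condition = cc,
      n = length(j), mean = rowMeans(sub),
      sd = apply(sub, 1, stats::sd))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("condition_summary", "data.frame")
  out
}

#' Write a consensus table as CSV with a JSON design sidecar
#'
#' @param table A `consensus_table`.
#' @param path CSV path (rows = peaks, columns = samples); sample metadata are
#'   written to `<path>.meta.json`.
#' @export
write_consensus <- function(table, path) {
  df <- data.frame(label = table$label, mass = table$mass,
                   table$abundance, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(table$samples, paste0(path, ".meta.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
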