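# PCA fingerprints of relative-change profiles: a peaks x treatments matrix,
# its principal components (treatments as variables, as in a variables factor
# map), and a simple log-ratio cosine dissimilarity between profiles.

#' Build the peaks x treatments change matrix
#'
#' Rows are the marker peaks, columns the treatment conditions (toxin x
#' concentration) plus one pooled control column (the mean of the per-series
#' control-to-control ratios, identically 1 on the ratio scale). Peaks that
#' could not be normalized in some treatment (zero control mean) are dropped
#' with a report.
#'
#' @param rc A `relative_change_matrix` from [relative_change()] on the ratio
#'   scale.
#' @param zero_floor Ratios of exactly 0 (peak absent in every treated
#'   replicate) are floored at this positive value so that log-scale analyses
#'   stay defined; set `NULL` to keep zeros. Floored cells are reported.
#' @return Numeric matrix (peaks x treatments + control) with attributes
#'   `col_meta` (toxin/concentration per column, control rows `NA`) and
#'   `dropped`/`floored` reports.
#' @export
build_change_matrix <- function(rc, zero_floor = 0.01) {
  stopifnot(inherits(rc, "relative_change_matrix"))
  if (rc$scale != "ratio")
    stop("build_change_matrix expects ratios (scale = 'ratio')")
  m <- rc$ratio
  if (ncol(m) < 2 || nrow(m) < 2)
    stop("need at least 2 treatments and 2 peaks")
  dropped <- rownames(m)[apply(m, 1, anyNA)]
  m <- m[!rownames(m) %in% dropped, , drop = FALSE]
  floored <- character(0)
  if (!is.null(zero_floor) && any(m == 0)) {
    floored <- rownames(m)[apply(m == 0, 1, any)]
    m[m == 0] <- zero_floor
  }
  out <- cbind(m, control = 1)
  col_meta <- rbind(rc$col_meta,
                    data.frame(condition = "control", toxin = NA_character_,
                               concentration = NA_real_))
  attr(out, "col_meta") <- col_meta
  attr(out, "dropped") <- dropped
  attr(out, "floored") <- floored
  out
}

#' Principal component analysis of a change matrix
#'
#' Column-centred (optionally unit-scaled) PCA with peaks as observations and
#' treatments as variables, so the loadings give the variables factor map.
#' Ratios are log-transformed by default (fold changes are multiplicative).
#' The sign of each component is fixed deterministically: the
#' largest-magnitude loading is made positive.
#'
#' @param mat Numeric matrix (rows = peaks, columns = treatments), finite,
#'   at least 2 x 2.
#' @param center,scale. Passed to the decomposition (defaults: centre, no
#'   unit scaling).
#' @param log_transform Take logs first (requires positive entries; default
#'   `TRUE`).
#' @return An object of class `pca_result`: `scores` (peaks x components),
#'   `loadings` (treatments x components), `explained` (variance fractions),
#'   `sdev`, `center`.
#' @export
pca_fingerprint <- function(mat, center = TRUE, scale. = FALSE,
                            log_transform = TRUE) {
  mat <- as.matrix(mat)
  col_meta <- attr(mat, "col_meta")
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("matrix must be at least 2 x 2")
  if (any(!is.finite(mat))) stop("matrix contains non-finite values")
  if (log_transform) {
    if (any(mat <= 0))
      stop("log transform requires positive entries; use log_transform = FALSE")
    mat <- log(mat)
  }
  centred <- scale(mat, center = center, scale = FALSE)
  if (all(abs(centred) < 1e-300)) stop("matrix has zero variance")
  if (isTRUE(scale.)) {
    sds <- apply(centred, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance column; cannot unit-scale")
  }
  pc <- stats::prcomp(mat, center = center, scale. = scale.)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = loadings, explained = expl,
                 sdev = pc$sdev, center = pc$center, col_meta = col_meta),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              length(x$explained), 100 * x$explained[1],
              100 * (if (length(x$explained) > 1) x$explained[2] else 0)))
  invisible(x)
}

#' Cosine dissimilarity between two fingerprint profiles
#'
#' Profiles are relative-change vectors over the same peak panel; they are
#' log-transformed (fold changes are multiplicative) and compared by cosine
#' dissimilarity, so the measure is 0 for proportional log-profiles and 2 for
#' antipodal ones.
#'
#' @param profile_a,profile_b Equal-length positive ratio vectors.
#' @param log_transform Log-transform first (default `TRUE`; set `FALSE` if
#'   the inputs are already log ratios).
#' @return Dissimilarity in `[0, 2]`.
#' @export
fingerprint_distance <- function(profile_a, profile_b, log_transform = TRUE) {
  if (length(profile_a) != length(profile_b)) stop("length mismatch")
  a <- if (log_transform) log(profile_a) else profile_a
  b <- if (log_transform) log(profile_b) else profile_b
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("zero profile vector; dissimilarity undefined")
  1 - sum(a * b) / (na * nb)
}

#' Are treatment groups separable in the (PC1, PC2) loading plane?
#'
#' For each pair of groups, checks whether a line through the origin
#' separates the two groups' (PC1, PC2) loading vectors -- the testable
#' version of "toxins occupy different sectors of the variables factor map".
#'
#' @param pca A `pca_result`.
#' @param groups Factor/character vector over the matrix columns (length =
#'   rows of `pca$loadings`); `NA` entries (e.g. the control column) are
#'   ignored.
#' @return `TRUE` when every pair of groups is separable.
#' @export
toxin_separation <- function(pca, groups) {
  stopifnot(inherits(pca, "pca_result"))
  if (length(groups) != nrow(pca$loadings))
    stop("groups must have one entry per loading row")
  keep <- !is.na(groups)
  ang <- atan2(pca$loadings[keep, 2], pca$loadings[keep, 1])
  grp <- as.character(groups[keep])
  gs <- unique(grp)
  for (i in seq_along(gs)) {
    for (j in seq_len(i - 1L)) {
      if (!separable_by_origin_line(ang[grp == gs[i]], ang[grp == gs[j]]))
        return(FALSE)
    }
  }
  TRUE
}

# Two sets of 2D directions are separable by a line through the origin iff
# some rotation puts all of A in the upper half-plane and all of B in the
# lower. Candidate boundaries need only be checked just past each vector.
separable_by_origin_line <- function(a, b) {
  for (theta in c(a, b)) {
    for (eps in c(1e-9, -1e-9)) {
      ra <- (a - theta - eps) %% (2 * pi)
      rb <- (b - theta - eps) %% (2 * pi)
      if ((all(ra < pi) && all(rb >= pi)) || (all(rb < pi) && all(ra >= pi)))
        return(TRUE)
    }
  }
  FALSE
}
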