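# Differential marker statistics: Grubbs screening, control-normalized
# relative changes, paired t tests, the marker table with arrow/asterisk
# annotation, and bookkeeping over marked peaks. No multiple-testing
# correction is applied across peaks: marks are per-peak paired-t results,
# which is the convention the marker panel encodes.

#' Grubbs' single-outlier test
#'
#' Computes G = max|x - mean| / sd and compares it with the two-sided
#' critical value G = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2)) where t is
#' the upper alpha/(2n) quantile of the t distribution with n - 2 degrees of
#' freedom. At most one value is flagged per call; iterate externally for
#' repeated exclusion.
#'
#' @param values Numeric vector, n >= 3.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Index of the flagged outlier, or `integer(0)` when none (including
#'   the zero-spread case).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs' test needs at least 3 values")
  s <- stats::sd(values)
  if (s == 0) return(integer(0))
  dev <- abs(values - mean(values))
  g <- max(dev) / s
  tq <- stats::qt(1 - alpha / (2 * n), n - 2)
  g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  if (g > g_crit) which.max(dev) else integer(0)
}

#' Paired two-sample t test with direction
#'
#' Classical paired t on the per-replicate differences, two-sided. Degenerate
#' differences are handled explicitly: all-zero differences give t = 0,
#' p = 1; constant non-zero differences give an infinite statistic (p = 0)
#' with a `degenerate` note.
#'
#' @param treated,control Equal-length (>= 2) per-replicate abundances,
#'   paired by replicate index.
#' @return List with `t`, `p`, `df`, `direction` (`up`/`down`/`none`) and
#'   `degenerate`.
#' @export
paired_t_test <- function(treated, control) {
  if (length(treated) != length(control))
    stop("treated and control must have equal length")
  if (length(treated) < 2) stop("need at least 2 pairs")
  d <- treated - control
  md <- mean(d)
  direction <- if (md > 0) "up" else if (md < 0) "down" else "none"
  if (stats::sd(d) == 0) {
    if (md == 0) return(list(t = 0, p = 1, df = length(d) - 1L,
                             direction = "none", degenerate = FALSE))
    return(list(t = sign(md) * Inf, p = 0, df = length(d) - 1L,
                direction = direction, degenerate = TRUE))
  }
  ht <- stats::t.test(treated, control, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), direction = direction, degenerate = FALSE)
}

#' Control-normalized relative changes
#'
#' Per peak and treatment condition, the ratio of the treated mean abundance
#' to the toxin series' own control mean. Peaks whose control mean is zero in
#' some series cannot be normalized there; they are set `NA` and reported in
#' the `excluded` attribute.
#'
#' @param summary A `condition_summary` from [summarize_conditions()]; each
#'   toxin series must include its control condition.
#' @param scale `"ratio"` (treated/control, control = 1) or `"ratio_minus_1"`
#'   (change relative to control, control = 0).
#' @return A `relative_change_matrix`: list with `ratio` (peaks x treatments
#'   matrix), `col_meta` (toxin/concentration per column), `sd` (delta-method
#'   SDs of the ratios), and attribute-like `excluded` report.
#' @export
relative_change <- function(summary, scale = c("ratio", "ratio_minus_1")) {
  stopifnot(inherits(summary, "condition_summary"))
  scale <- match.arg(scale)
  treated <- summary[!summary$is_control, ]
  controls <- summary[summary$is_control, ]
  if (!nrow(controls)) stop("summary contains no control condition")
  labels <- unique(summary$label)
  conds <- unique(treated$condition)
  ratio <- matrix(NA_real_, length(labels), length(conds),
                  dimnames = list(labels, conds))
  sds <- ratio
  col_meta <- data.frame(condition = conds,
                         toxin = treated$toxin[match(conds,
                                                     treated$condition)],
                         concentration =
                           treated$concentration[match(conds,
                                                       treated$condition)])
  excluded <- list()
  for (j in seq_along(conds)) {
    tr <- treated[treated$condition == conds[j], ]
    ctl <- controls[controls$toxin == col_meta$toxin[j], ]
    if (!nrow(ctl))
      stop("no control condition for toxin ", col_meta$toxin[j])
    cm <- ctl$mean[match(tr$label, ctl$label)]
    ok <- !is.na(cm) & cm > 0
    ratio[match(tr$label[ok], labels), j] <- tr$mean[ok] / cm[ok]
    sds[match(tr$label[ok], labels), j] <- tr$sd[ok] / cm[ok]
    if (any(!ok))
      excluded[[conds[j]]] <- tr$label[!ok]
  }
  if (scale == "ratio_minus_1") ratio <- ratio - 1
  out <- list(ratio = ratio, col_meta = col_meta, sd = sds, scale = scale,
              excluded = excluded)
  class(out) <- "relative_change_matrix"
  out
}

#' Build the marker table
#'
#' Per consensus peak and toxin: one-pass Grubbs exclusion in each arm at
#' `grubbs_alpha` (an excluded value removes its replicate pair), a paired
#' two-sample t test of treated versus the series' control, the direction of
#' deviation, and a significance mark (`*` for p < 0.05, `**` for p < 0.01).
#' Peaks left with fewer than 3 pairs are marked untestable rather than
#' dropped.
#'
#' @param table A `consensus_table`.
#' @param design Design data frame covering all samples.
#' @param comparison Named vector of the comparison concentration per toxin;
#'   default: the highest treated concentration present in the design.
#' @param alpha Two significance levels, default `c(0.05, 0.01)`.
#' @param grubbs_alpha Grubbs screening level (default 0.05).
#' @return A data frame of class `marker_table`, rows sorted by mass, with
#'   columns `label`, `mass`, `toxin`, `concentration`, `n_used`,
#'   `mean_treated`, `mean_control`, `rel_change`, `t`, `p`, `direction`,
#'   `mark`, `untestable`.
#' @export
build_marker_table <- function(table, design, comparison = NULL,
                               alpha = c(0.05, 0.01), grubbs_alpha = 0.05) {
  stopifnot(inherits(table, "consensus_table"))
  alpha <- sort(alpha, decreasing = TRUE)
  toxins <- unique(design$toxin[!design$is_control])
  if (is.null(comparison)) {
    comparison <- vapply(toxins, function(tox) {
      max(design$concentration[design$toxin == tox & !design$is_control])
    }, numeric(1))
  }
  rows <- list()
  for (tox in toxins) {
    tr_meta <- design[design$toxin == tox & !design$is_control &
                        design$concentration == comparison[[tox]], ]
    ct_meta <- design[design$toxin == tox & design$is_control, ]
    common <- intersect(tr_meta$replicate, ct_meta$replicate)
    if (!length(common))
      stop("toxin ", tox, " has no paired treated/control replicates")
    tr_ids <- tr_meta$sample_id[match(common, tr_meta$replicate)]
    ct_ids <- ct_meta$sample_id[match(common, ct_meta$replicate)]
    for (r in seq_along(table$mass)) {
      tre <- table$abundance[r, tr_ids]
      ctl <- table$abundance[r, ct_ids]
      drop <- integer(0)
      if (length(tre) >= 3) {
        drop <- union(grubbs_test(tre, grubbs_alpha),
                      grubbs_test(ctl, grubbs_alpha))
      }
      if (length(drop)) {
        tre <- tre[-drop]
        ctl <- ctl[-drop]
      }
      untestable <- length(tre) < 3
      if (untestable) {
        tt <- list(t = NA_real_, p = NA_real_,
                   direction = if (mean(tre) > mean(ctl)) "up"
                   else if (mean(tre) < mean(ctl)) "down" else "none")
        mark <- "none"
      } else {
        tt <- paired_t_test(tre, ctl)
        mark <- if (!is.na(tt$p) && tt$p < alpha[2]) "**"
        else if (!is.na(tt$p) && tt$p < alpha[1]) "*" else "none"
      }
      if (identical(tt$direction, "none")) mark <- "none"
      rows[[length(rows) + 1L]] <- data.frame(
        label = table$label[r], mass = table$mass[r], toxin = tox,
        concentration = comparison[[tox]], n_used = length(tre),
        mean_treated = mean(tre), mean_control = mean(ctl),
        rel_change = if (mean(ctl) > 0) mean(tre) / mean(ctl) else NA_real_,
        t = tt$t, p = tt$p, direction = tt$direction, mark = mark,
        untestable = untestable)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$mass, match(out$toxin, toxins)), ]
  rownames(out) <- NULL
  class(out) <- c("marker_table", "data.frame")
  out
}

#' Count significantly changed peaks for a toxin
#'
#' @param x A `marker_table` or `marker_fixture`.
#' @param toxin Toxin name.
#' @return Number of peaks whose mark is not `none` for that toxin.
#' @export
count_significant <- function(x, toxin) UseMethod("count_significant")

#' @export
count_significant.marker_fixture <- function(x, toxin) {
  col <- paste0(toxin, "_mark")
  if (!col %in% names(x)) stop("unknown toxin: ", toxin)
  sum(x[[col]] != "none")
}

#' @export
count_significant.marker_table <- function(x, toxin) {
  if (!nrow(x)) return(0L)
  if (!toxin %in% x$toxin) stop("unknown toxin: ", toxin)
  sum(x$mark[x$toxin == toxin] != "none")
}

marked_labels <- function(x) {
  if (inherits(x, "marker_fixture")) {
    toxins <- sub("_mark$", "", grep("_mark$", names(x), value = TRUE))
    out <- lapply(toxins, function(tox) x$label[x[[paste0(tox, "_mark")]] != "none"])
    names(out) <- toxins
    out
  } else {
    lapply(split(x, x$toxin), function(d) d$label[d$mark != "none"])
  }
}

#' Shared and toxin-specific marker peaks
#'
#' @param x A `marker_table` or `marker_fixture` covering >= 1 toxin.
#' @return List with `shared` (labels marked for every toxin) and `specific`
#'   (named list of labels marked for exactly one toxin).
#' @export
shared_and_specific <- function(x) {
  sets <- marked_labels(x)
  shared <- Reduce(intersect, sets)
  all_labels <- unique(unlist(sets))
  count <- vapply(all_labels, function(l) {
    sum(vapply(sets, function(s) l %in% s, logical(1)))
  }, numeric(1))
  specific <- lapply(sets, function(s) sort(s[count[s] == 1]))
  list(shared = sort(shared), specific = specific)
}

#' Render a marker table in arrow/asterisk notation
#'
#' @param x A `marker_table`.
#' @return Character vector of text lines (one header plus one line per
#'   peak), with an up/down arrow and the significance mark per toxin.
#' @export
render_marker_table <- function(x) {
  stopifnot(inherits(x, "marker_table"))
  toxins <- unique(x$toxin)
  labs <- unique(x$label)
  header <- paste(c(sprintf("%-6s %-9s", "peak", "mass"),
                    sprintf("%-22s", toxins)), collapse = "")
  lines <- vapply(labs, function(l) {
    d <- x[x$label == l, ]
    cells <- vapply(toxins, function(tox) {
      dd <- d[d$toxin == tox, ]
      if (!nrow(dd) || dd$mark == "none") "-"
      else paste0(if (dd$direction == "up") "↑" else "↓", " ",
                  dd$mark)
    }, character(1))
    paste(c(sprintf("%-6s %-9.0f", l, d$mass[1]),
            sprintf("%-22s", cells)), collapse = "")
  }, character(1))
  c(header, unname(lines))
}
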