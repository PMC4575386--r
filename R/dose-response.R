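# Viability normalization, four-parameter logistic (4PL) EC50 fitting with
# asymmetric confidence intervals on log(EC50), ROUT-style automatic outlier
# detection, and one-way ANOVA with Dunnett many-to-one comparisons.

#' Normalize a viability plate to percent of control
#'
#' percent = 100 * (signal - mean(blank)) / (mean(control) - mean(blank)).
#' Blank wells anchor 0 % and untreated control wells 100 %; the mapping is
#' invariant to adding a constant to every raw signal.
#'
#' @param plate Data frame with columns `dose`, `signal`, `well_type`
#'   (`treated`/`control`/`blank`), `replicate`.
#' @return The plate with a `percent` column added.
#' @export
normalize_viability <- function(plate) {
  stopifnot(all(c("dose", "signal", "well_type") %in% names(plate)))
  blank <- plate$signal[plate$well_type == "blank"]
  ctrl <- plate$signal[plate$well_type == "control"]
  if (!length(blank) || !length(ctrl))
    stop("plate needs at least one blank and one control well")
  if (mean(ctrl) <= mean(blank))
    stop("mean control signal must exceed mean blank signal")
  plate$percent <- 100 * (plate$signal - mean(blank)) /
    (mean(ctrl) - mean(blank))
  plate
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose/ec50)^hill)` with the
#' EC50 parameterized on the log scale. Starting values come from the data
#' (plateaus from the response range, EC50 from the dose nearest the
#' mid-response); on failure a small multistart grid over Hill slopes and
#' log-dose quantiles is tried. The 95 % CI is asymptotic on log(EC50) and
#' exponentiated, giving the usual asymmetric interval. Zero doses are not
#' log-representable and must be excluded beforehand (they enter the analysis
#' through normalization, not as curve points).
#'
#' @param doses Positive dose vector (>= 4 distinct values).
#' @param responses Responses (percent viability), same length.
#' @param level CI level (default 0.95).
#' @return An object of class `dose_response_fit`: `ec50`, `hill`, `top`,
#'   `bottom`, `ci95_ec50`, `se_log_ec50`, `fitted`, `residuals`, `rss`,
#'   `df`, `converged`.
#' @export
fit_4pl <- function(doses, responses, level = 0.95) {
  if (length(doses) != length(responses)) stop("length mismatch")
  if (any(doses <= 0)) stop("doses must be positive (exclude zero-dose anchors)")
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  if (stats::sd(responses) == 0)
    stop("responses are constant; the curve is unidentifiable")
  dat <- data.frame(ld = log(doses), y = responses)
  form <- y ~ bottom + (top - bottom) / (1 + exp(hill * (ld - lec)))
  mid <- (max(responses) + min(responses)) / 2
  starts <- list(list(bottom = min(responses), top = max(responses),
                      lec = dat$ld[which.min(abs(responses - mid))],
                      hill = 1))
  for (h in c(0.5, 1, 2, 4))
    for (q in stats::quantile(dat$ld, c(0.25, 0.5, 0.75)))
      starts[[length(starts) + 1L]] <-
        list(bottom = min(responses), top = max(responses), lec = unname(q),
             hill = h)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("4PL fit did not converge from any start (",
         length(starts), " starts tried)")
  fit <- best$fit
  cf <- stats::coef(fit)
  df <- length(doses) - 4L
  se_lec <- tryCatch(sqrt(stats::vcov(fit)["lec", "lec"]),
                     error = function(e) NA_real_)
  tq <- if (df > 0) stats::qt(1 - (1 - level) / 2, df) else NA_real_
  ci <- if (is.finite(se_lec) && is.finite(tq))
    exp(cf[["lec"]] + c(-1, 1) * tq * se_lec) else c(NA_real_, NA_real_)
  structure(list(ec50 = exp(cf[["lec"]]), hill = cf[["hill"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 ci95_ec50 = ci, se_log_ec50 = se_lec,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit), rss = best$rss, df = df,
                 converged = TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "dose_response_fit: EC50 %.4g (95%% CI %.4g-%.4g), hill %.3g, top %.3g, bottom %.3g\n",
    x$ec50, x$ci95_ec50[1], x$ci95_ec50[2], x$hill, x$top, x$bottom))
  invisible(x)
}

#' Automatic outlier detection for dose-response points
#'
#' ROUT-style procedure: a robust preliminary 4PL fit (iteratively reweighted
#' soft-L1 loss), residual scale from the median absolute deviation, a t-tail
#' probability per point, and an FDR (Benjamini-Hochberg) outlier call at
#' rate `q`. Flagged points are removed and the curve refit, unless more than
#' 30 % of points are flagged (flags are then returned but the refit is
#' declined with a warning).
#'
#' @param doses,responses As in [fit_4pl()].
#' @param q FDR rate for outlier calls (default 0.01).
#' @return List with `flags` (logical per point), `scale` (robust residual
#'   SD), `refit` (a `dose_response_fit` without the flagged points, or
#'   `NULL`).
#' @export
detect_response_outliers <- function(doses, responses, q = 0.01) {
  n <- length(doses)
  if (n < 6) {
    warning("fewer than 6 points: outlier detection is underpowered; ",
            "no points flagged")
    return(list(flags = rep(FALSE, n), scale = NA_real_, refit = NULL))
  }
  fit <- fit_4pl(doses, responses)
  # iteratively reweighted least squares approximating a soft-L1 loss
  w <- rep(1, n)
  dat <- data.frame(ld = log(doses), y = responses)
  form <- y ~ bottom + (top - bottom) / (1 + exp(hill * (ld - lec)))
  st <- list(bottom = fit$bottom, top = fit$top, lec = log(fit$ec50),
             hill = fit$hill)
  r <- fit$residuals
  for (it in 1:5) {
    s <- max(1.4826 * stats::mad(r, center = 0), 1e-12)
    w <- 1 / sqrt(1 + (r / s)^2)
    rf <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(rf)) break
    r <- dat$y - stats::predict(rf, dat)
    st <- as.list(stats::coef(rf))
  }
  scale <- max(1.4826 * stats::mad(r, center = 0), 1e-12)
  pvals <- 2 * stats::pt(-abs(r / scale), df = n - 4)
  flags <- stats::p.adjust(pvals, method = "BH") < q
  refit <- NULL
  if (mean(flags) > 0.3) {
    warning(sum(flags), " of ", n, " points flagged (> 30%); refit declined")
  } else if (any(flags)) {
    refit <- tryCatch(fit_4pl(doses[!flags], responses[!flags]),
                      error = function(e) NULL)
  }
  list(flags = flags, scale = scale, refit = refit)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' F test across all groups, then each treated group is compared with the
#' shared control using the pooled error variance. Adjusted p-values come
#' from the maximum-modulus distribution of the comparison statistics -- a
#' multivariate t with the Dunnett correlation structure -- integrated by
#' seeded randomized quasi-Monte-Carlo (mvtnorm); unbalanced groups are
#' handled through the exact correlation matrix.
#'
#' @param groups Named list of numeric vectors (each n >= 2), treatment
#'   groups.
#' @param control Name or index of the control group in `groups`.
#' @param alpha Family-wise error level for the `significant` flag
#'   (default 0.05).
#' @param mc_seed Seed for the quasi-Monte-Carlo integration (determinism).
#' @return List with `f`, `p_f` (ANOVA), and `comparisons`: a data frame of
#'   `group`, `diff`, `t`, `p_adj`, `significant`.
#' @export
anova_dunnett <- function(groups, control = 1, alpha = 0.05, mc_seed = 1) {
  if (is.numeric(control)) control <- names(groups)[control]
  if (is.null(names(groups)) || !control %in% names(groups))
    stop("control group not found")
  if (length(groups) < 3) stop("need at least 2 treated groups plus control")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  ni <- lengths(groups)
  k <- length(groups)
  N <- length(y)
  mse <- sum(unlist(lapply(groups, function(v) (v - mean(v))^2))) / (N - k)
  if (mse <= 0) stop("zero within-group variance everywhere; test undefined")
  av <- stats::anova(stats::lm(y ~ g))
  treated <- setdiff(names(groups), control)
  nc <- ni[[control]]
  tstat <- vapply(treated, function(gr) {
    (mean(groups[[gr]]) - mean(groups[[control]])) /
      sqrt(mse * (1 / ni[[gr]] + 1 / nc))
  }, numeric(1))
  lam <- sqrt(ni[treated] / (ni[treated] + nc))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  df <- N - k
  p_adj <- vapply(seq_along(tstat), function(i) {
    with_seed(mc_seed, {
      1 - mvtnorm::pmvt(lower = rep(-abs(tstat[i]), length(tstat)),
                        upper = rep(abs(tstat[i]), length(tstat)),
                        df = df, corr = corr, sigma = NULL,
                        algorithm = mvtnorm::GenzBretz(maxpts = 100000,
                                                       abseps = 1e-4))[1]
    })
  }, numeric(1))
  p_adj <- pmin(pmax(p_adj, 0), 1)
  comparisons <- data.frame(
    group = treated,
    diff = vapply(treated, function(gr) mean(groups[[gr]]) -
                    mean(groups[[control]]), numeric(1)),
    t = tstat, p_adj = p_adj, significant = p_adj < alpha)
  rownames(comparisons) <- NULL
  list(f = av$`F value`[1], p_f = av$`Pr(>F)`[1], df = c(k - 1, df),
       comparisons = comparisons)
}
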