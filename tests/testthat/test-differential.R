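# Grubbs screening, paired tests, relative changes, marker table and its
# bookkeeping.

test_that("Grubbs flags a gross outlier and only that", {
  x <- c(1.0, 1.1, 0.9, 1.05, 0.95, 5.0)
  idx <- grubbs_test(x, alpha = 0.05)
  expect_equal(idx, 6L)
  # oracle: direct G statistic against the t-based critical value
  g <- max(abs(x - mean(x))) / sd(x)
  n <- 6
  tq <- qt(1 - 0.05 / (2 * n), n - 2)
  gcrit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  expect_gt(g, gcrit)
  expect_length(grubbs_test(c(1, 1.1, 0.9, 1.05, 0.95, 1.02)), 0)
  expect_length(grubbs_test(rep(3, 6)), 0)
  expect_error(grubbs_test(c(1, 2)), "at least 3")
})

test_that("Grubbs null flag rate sits near its alpha", {
  set.seed(51)
  flags <- 0L
  for (i in 1:2000) flags <- flags + length(grubbs_test(rnorm(6)))
  expect_gt(flags / 2000, 0.03)
  expect_lt(flags / 2000, 0.07)
})

test_that("paired t matches the textbook formula and handles degeneracy", {
  ctrl <- c(100, 102, 98, 101, 99, 100)
  diffs <- c(10, 12, 8, 11, 9, 10)
  res <- paired_t_test(ctrl + diffs, ctrl)
  # oracle: t = mean(d) / (sd(d)/sqrt(n)), p from t with n-1 df
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(6))
  expect_equal(res$t, t_hand)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 5))
  expect_equal(res$direction, "up")

  same <- paired_t_test(ctrl, ctrl)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$direction, "none")

  const <- paired_t_test(ctrl + 5, ctrl)
  expect_true(const$degenerate)
  expect_equal(const$p, 0)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("paired t type-I error is calibrated on null data", {
  set.seed(52)
  rej <- 0L
  for (i in 1:2000) {
    if (paired_t_test(rnorm(6), rnorm(6))$p < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 2000, 0.035)
  expect_lt(rej / 2000, 0.065)
})

test_that("relative changes are ratios to each series' own control", {
  sm <- data.frame(
    label = rep(c("A", "B"), 2), mass = rep(c(5000, 8000), 2),
    toxin = "tox", concentration = c(1, 1, NA, NA),
    is_control = c(FALSE, FALSE, TRUE, TRUE),
    condition = rep(c("tox:1", "tox:control"), each = 2),
    n = 6, mean = c(1000, 500, 500, 500), sd = c(50, 40, 30, 20))
  class(sm) <- c("condition_summary", "data.frame")
  rc <- relative_change(sm)
  expect_equal(unname(rc$ratio["A", "tox:1"]), 2)
  expect_equal(unname(rc$ratio["B", "tox:1"]), 1)

  # treated == control everywhere -> 1.0
  sm1 <- sm
  sm1$mean <- c(500, 500, 500, 500)
  class(sm1) <- class(sm)
  expect_true(all(relative_change(sm1)$ratio == 1))

  # zero control mean: excluded with a report, not silently dropped
  sm0 <- sm
  sm0$mean[3] <- 0
  class(sm0) <- class(sm)
  rc0 <- relative_change(sm0)
  expect_true(is.na(rc0$ratio["A", "tox:1"]))
  expect_equal(rc0$excluded[["tox:1"]], "A")

  no_ctl <- sm[!sm$is_control, ]
  class(no_ctl) <- class(sm)
  expect_error(relative_change(no_ctl), "no control")
})

test_that("the marker table marks directions, excludes outliers, and flags untestable peaks", {
  n <- 6
  design <- data.frame(
    sample_id = c(paste0("t", 1:n), paste0("c", 1:n)), toxin = "tox",
    concentration = rep(c(1, NA), each = n),
    is_control = rep(c(FALSE, TRUE), each = n), replicate = rep(1:n, 2))
  treated <- c(980, 1010, 1000, 1030, 995, 1015)
  control <- c(490, 515, 500, 520, 498, 507)
  ab <- rbind(c(treated, control),                          # clear up peak
              c(505, 492, 511, 498, 503, 496,
                499, 508, 494, 502, 506, 497),              # null peak
              c(480, 490, 500, 510, 470, 495,
                495, 505, 500, 490, 510, 5000))
  # third row: a gross control outlier that Grubbs must remove
  colnames(ab) <- design$sample_id
  tab <- manual_consensus(c(5000, 8000, 12000), ab, design[, 1:5])
  mt <- build_marker_table(tab, design, comparison = c(tox = 1))
  up <- mt[mt$mass == 5000, ]
  expect_equal(up$direction, "up")
  expect_equal(up$mark, "**")
  expect_equal(mt[mt$mass == 8000, ]$mark, "none")
  out_row <- mt[mt$mass == 12000, ]
  expect_equal(out_row$n_used, 5)  # the outlier pair was dropped

  # treated identical to control: no direction, no mark
  ab2 <- rbind(c(rep(400, n), rep(400, n)))
  colnames(ab2) <- design$sample_id
  mt2 <- build_marker_table(manual_consensus(5000, ab2, design[, 1:5]),
                            design, comparison = c(tox = 1))
  expect_equal(mt2$direction, "none")
  expect_equal(mt2$mark, "none")
})

test_that("marks are monotone in the p-value thresholds", {
  # same direction, increasingly strong evidence never weakens the mark
  rank_of <- function(mark) match(mark, c("none", "*", "**"))
  set.seed(54)
  design <- data.frame(
    sample_id = c(paste0("t", 1:6), paste0("c", 1:6)), toxin = "tox",
    concentration = rep(c(1, NA), each = 6),
    is_control = rep(c(FALSE, TRUE), each = 6), replicate = rep(1:6, 2))
  shifts <- c(10, 60, 300)
  marks <- vapply(shifts, function(s) {
    ab <- matrix(c(rnorm(6, 500 + s, 40), rnorm(6, 500, 40)), nrow = 1)
    colnames(ab) <- design$sample_id
    build_marker_table(manual_consensus(5000, ab, design[, 1:5]), design,
                       comparison = c(tox = 1))$mark
  }, character(1))
  expect_true(all(diff(vapply(marks, rank_of, numeric(1))) >= 0))
})

test_that("null experiments yield unmarked tables in most runs", {
  # all fold changes 1: replicate abundances share the generator's
  # structure (dominant per-spectrum spot factor, small per-peak biological
  # factor), which ties the 15 per-peak tests together, so the family-wise
  # false-mark rate stays near the single-test level
  m <- make_default_truth(1)
  design <- data.frame(
    sample_id = c(paste0("t", 1:6), paste0("c", 1:6)), toxin = "tox",
    concentration = rep(c(1, NA), each = 6),
    is_control = rep(c(FALSE, TRUE), each = 6), replicate = rep(1:6, 2))
  set.seed(56)
  clean <- vapply(1:1000, function(i) {
    ab <- vapply(seq_len(12), function(j) {
      spot <- rlnorm(1, 0, m$scale_sd)
      m$peaks$abundance * spot * rlnorm(15, 0, m$bio_cv)
    }, numeric(15))
    colnames(ab) <- design$sample_id
    mt <- build_marker_table(manual_consensus(m$peaks$mass, ab,
                                              design[, 1:5]),
                             design, comparison = c(tox = 1))
    all(mt$mark == "none")
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("significance counting matches the fixture and the rendering", {
  fx <- load_marker_fixture()
  expect_equal(count_significant(fx, "copper_sulfate"), 8)
  expect_equal(count_significant(fx, "acridine"), 7)
  expect_equal(count_significant(fx, "bnf"), 9)
  expect_error(count_significant(fx, "mercury"), "unknown toxin")

  empty <- structure(
    data.frame(label = character(), mass = numeric(), toxin = character(),
               mark = character()),
    class = c("marker_table", "data.frame"))
  expect_equal(count_significant(empty, "tox"), 0L)
})

test_that("shared and specific marker sets match the fixture", {
  fx <- load_marker_fixture()
  ss <- shared_and_specific(fx)
  expect_equal(ss$shared, c("C", "K", "L"))
  expect_equal(ss$specific$copper_sulfate, c("G", "I", "J", "N", "O"))
  expect_equal(ss$specific$bnf, c("B", "E", "H"))
  expect_equal(ss$specific$acridine, "M")
})

test_that("rendered tables agree with count_significant", {
  set.seed(55)
  design <- data.frame(
    sample_id = c(paste0("t", 1:6), paste0("c", 1:6)), toxin = "tox",
    concentration = rep(c(1, NA), each = 6),
    is_control = rep(c(FALSE, TRUE), each = 6), replicate = rep(1:6, 2))
  ab <- rbind(c(rnorm(6, 1200, 40), rnorm(6, 500, 40)),
              c(rnorm(6, 520, 40), rnorm(6, 500, 40)))
  colnames(ab) <- design$sample_id
  mt <- build_marker_table(manual_consensus(c(5000, 9000), ab,
                                            design[, 1:5]),
                           design, comparison = c(tox = 1))
  txt <- render_marker_table(mt)
  n_arrows <- sum(vapply(txt[-1], function(l) {
    grepl("↑|↓", l)
  }, logical(1)))
  expect_equal(n_arrows, count_significant(mt, "tox"))
})
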