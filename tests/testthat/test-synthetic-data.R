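# The synthetic-data generator: default truth panel, forward model,
# experiment assembly, viability plates.

test_that("default truth reproduces the marker panel and its effect signs", {
  m <- make_default_truth(seed = 1)
  fx <- load_marker_fixture()
  expect_equal(nrow(m$peaks), 15L)
  expect_equal(m$peaks$mass, as.numeric(fx$mass))
  expect_equal(m$peaks$label, fx$label)

  # row K: copper sulfate and acridine up, BNF down at the reference doses
  k <- which(m$peaks$label == "K")
  expect_equal(m$peaks$mass[k], 11295)
  expect_gt(m$effects$copper_sulfate[["9"]][k], 1)
  expect_gt(m$effects$acridine[["150"]][k], 1)
  expect_lt(m$effects$bnf[["50"]][k], 1)

  # every annotated arrow of the panel is reproduced in sign, every
  # unannotated cell is fold 1, at each toxin's reference concentration
  for (tox in fixture_toxins()) {
    ref <- as.character(m$reference_concentration[[tox]])
    folds <- m$effects[[tox]][[ref]]
    dirs <- fx[[paste0(tox, "_direction")]]
    expect_true(all(folds[dirs == "up"] > 1))
    expect_true(all(folds[dirs == "down"] < 1))
    expect_true(all(folds[dirs == "none"] == 1))
  }
})

test_that("default truth is deterministic and background peaks are inert", {
  expect_identical(make_default_truth(7), make_default_truth(7))
  m <- make_default_truth(2, n_background = 10)
  expect_equal(nrow(m$peaks), 25L)
  bg <- grepl("^bg", m$peaks$label)
  for (tox in names(m$effects))
    for (cc in names(m$effects[[tox]]))
      expect_true(all(m$effects[[tox]][[cc]][bg] == 1))
})

test_that("noise-free forward model places apexes at base abundance plus baseline", {
  pk <- test_peaks_df()
  m <- test_model(pk, baseline = list(amplitude = 120, decay = 3000,
                                      constant = 5))
  sp <- simulate_spectrum(m, "tox", is_control = TRUE, replicate = 1,
                          seed = 1)
  for (i in seq_len(nrow(pk))) {
    j <- which.min(abs(sp$mz - pk$mass[i]))
    base <- 120 * exp(-(sp$mz[j] - 2000) / 3000) + 5
    # apex on the grid: within grid interpolation error of height + baseline
    expect_equal(sp$intensity[j], pk$abundance[i] + base,
                 tolerance = 1e-2)
  }
  expect_equal(sp$truth$height, pk$abundance)
  expect_equal(sp$truth$mass, pk$mass)  # identity drift
})

test_that("peak-free zero-baseline spectra are pure noise at the requested SD", {
  m <- test_model(test_peaks_df()[0, ], noise_sd = 12)
  sp <- simulate_spectrum(m, "tox", is_control = TRUE, seed = 5)
  expect_gte(length(sp$mz), 10000)
  expect_equal(sd(sp$intensity), 12, tolerance = 0.1 * 12)
  expect_lt(abs(mean(sp$intensity)), 1)
})

test_that("replicates share truth masses but not noise", {
  m <- test_model(test_peaks_df(), noise_sd = 10)
  a <- simulate_spectrum(m, "tox", 1, FALSE, replicate = 1, seed = 9)
  b <- simulate_spectrum(m, "tox", 1, FALSE, replicate = 2, seed = 9)
  expect_equal(a$truth$mass, b$truth$mass)
  expect_false(identical(a$intensity, b$intensity))
  expect_identical(a$intensity,
                   simulate_spectrum(m, "tox", 1, FALSE, 1, 9)$intensity)
})

test_that("unknown conditions are rejected by name", {
  m <- test_model(test_peaks_df())
  expect_error(simulate_spectrum(m, "tox", 99, FALSE), "tox:99")
  expect_error(simulate_spectrum(m, "mercury", 1, FALSE), "mercury")
})

test_that("experiments have one spectrum per design row and regenerate identically", {
  m <- make_default_truth(1)
  design <- make_design(m, replicates = 6, concentrations = "reference",
                        toxins = c("copper_sulfate", "acridine"))
  # 2 toxins x (1 treated + 1 control) x 6 replicates
  expect_equal(nrow(design), 24L)
  expect_error(make_design(m, replicates = 0), "at least 1")
  # controls: exactly one control condition per toxin series
  ctl <- unique(design[design$is_control, c("toxin", "concentration")])
  expect_equal(nrow(ctl), 2L)

  small <- make_design(m, replicates = 2, concentrations = "reference",
                       toxins = "bnf")
  sim1 <- simulate_experiment(m, small, seed = 3)
  sim2 <- simulate_experiment(m, small, seed = 3)
  expect_identical(serialize(sim1, NULL), serialize(sim2, NULL))
  expect_equal(length(sim1$spectra), nrow(small))
  # control spectra emit base abundances scaled only by nuisance factors;
  # with a fold of 1 the expected emitted height is the base abundance
  ctl_truth <- sim1$truth[grepl("control", sim1$truth$sample_id), ]
  expect_equal(nrow(ctl_truth), 2L * nrow(m$peaks))
})

test_that("viability plates follow the 4PL truth", {
  tr <- viability_truth(ec50 = 10, hill = 2, top = 100, bottom = 0,
                        noise_sd = 0)
  pl <- simulate_viability(tr, doses = c(0.1, 1, 10, 100), replicates = 2,
                           seed = 1)
  norm <- normalize_viability(pl)
  at <- function(d) mean(norm$percent[norm$well_type == "treated" &
                                        norm$dose == d])
  expect_equal(at(10), 50)        # dose = EC50 -> midpoint
  expect_equal(at(0.1), 100, tolerance = 1e-4)  # low dose -> top
  resp <- vapply(c(0.1, 1, 10, 100), at, numeric(1))
  expect_true(all(diff(resp) < 0))  # strictly decreasing
  expect_error(simulate_viability(tr, doses = c(-1, 2)), "positive")
  expect_error(simulate_viability(tr, doses = c(5, 5)), "distinct")
})
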