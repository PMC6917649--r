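test_that("panel generation honours counts, labels and marker structure", {
  expect_length(generate_panel(panel_config(0, 0)), 0)

  panel <- generate_panel(panel_config(seed = 42))
  expect_length(panel, 30)
  labels <- vapply(panel, `[[`, "", "subspecies")
  expect_equal(sum(labels == "lupuloides") / 30, 19 / 30)
  expect_equal(mean(labels == "lupuloides"), 0.6333, tolerance = 1e-3)

  for (tr in panel) {
    expect_true(all(tr$cone >= 0) && all(tr$leaf >= 0))
    mp <- leaf_profile(tr$leaf)$malonyl_proportion
    if (tr$subspecies == "lupulus") {
      expect_identical(unname(tr$cone[c("XGA", "MXH")]), c(0, 0))
      expect_gt(mp, 0.20)
    } else {
      expect_true(all(tr$cone[c("XGA", "MXH")] > 0))
      expect_lt(mp, 0.10)
    }
  }
})

test_that("generation is a pure function of the seed", {
  a <- generate_panel(panel_config(seed = 7))
  b <- generate_panel(panel_config(seed = 7))
  expect_identical(a, b)
  c <- generate_panel(panel_config(seed = 8))
  expect_false(identical(a, c))

  tr <- a[[1]]
  expect_identical(measure_truth(tr, "cone", 2), measure_truth(tr, "cone", 2))
  expect_false(identical(measure_truth(tr, "cone", 1),
                         measure_truth(tr, "cone", 2)))
})

test_that("invalid configurations are rejected", {
  expect_error(panel_config(n_lupuloides = -1), "non-negative")
  expect_error(panel_config(replicate_noise_cv = NaN), "finite")
  bad <- default_trait_params()
  bad$mean[1] <- bad$hi[1] + 1
  expect_error(panel_config(trait_params = bad), "invalid trait parameters")
})

test_that("truncated-normal sampler hits the target mean despite truncation", {
  # trait with strongly asymmetric truncation (mean near the low edge)
  withr::with_seed(99, {
    x <- rtruncnorm_target(20000, 0.67, (1.15 - 0.47) / 6, 0.47, 1.15)
  })
  expect_true(all(x >= 0.47 & x <= 1.15))
  expect_equal(mean(x), 0.67, tolerance = 0.005)
})

test_that("empirical class means converge to the configured class means", {
  big <- generate_panel(panel_config(n_lupuloides = 400, n_lupulus = 400,
                                     seed = 5))
  labels <- vapply(big, `[[`, "", "subspecies")
  alpha <- vapply(big, function(tr) unname(tr$cone["COH"] + tr$cone["nADH"]),
                  numeric(1))
  expect_lt(abs(mean(alpha[labels == "lupuloides"]) - 6.65), 0.2)
  expect_lt(abs(mean(alpha[labels == "lupulus"]) - 4.58), 0.2)
  mal <- vapply(big, function(tr) leaf_profile(tr$leaf)$malonyl_proportion,
                numeric(1))
  expect_lt(abs(mean(mal[labels == "lupuloides"]) - 0.0343), 0.0015)
  expect_lt(abs(mean(mal[labels == "lupulus"]) - 0.391), 0.012)
})

test_that("null sample gives a flat trace at the baseline", {
  tr <- simulate_trace(c(XHU = 0), c(XHU = 3.1), 1500, noise_sd = 0,
                       baseline_mau = 2)
  expect_true(all(tr$absorbance_mau == 2))
  expect_true(all(diff(tr$time_min) > 0))
})

test_that("noiseless peak areas conserve response_factor x concentration", {
  # closed-form Gaussian integral vs trapezoid on the sampled trace
  for (conc in c(0.002, 0.05, 0.3)) {
    tr <- simulate_trace(c(A = conc), c(A = 4), 1500, noise_sd = 0,
                         baseline_mau = 0)
    win <- tr$time_min >= 3.8 & tr$time_min <= 4.2
    area <- pracma::trapz(tr$time_min[win], tr$absorbance_mau[win])
    expect_equal(area, 1500 * conc, tolerance = 0.005)
  }
})

test_that("doubling concentrations doubles noiseless areas (linearity)", {
  conc <- c(XHU = 0.02, DXH = 0.01)
  rt <- c(XHU = 3.1, DXH = 2.1)
  t1 <- simulate_trace(conc, rt, 1500, noise_sd = 0, baseline_mau = 0)
  t2 <- simulate_trace(2 * conc, rt, 1500, noise_sd = 0, baseline_mau = 0)
  expect_equal(t2$absorbance_mau, 2 * t1$absorbance_mau, tolerance = 1e-12)
})

test_that("a nonzero compound without a catalogue entry is an error", {
  expect_error(simulate_trace(c(XHU = 0.1, BAD = 0.1), c(XHU = 3.1), 1500),
               "BAD")
})

test_that("lupulus leaf traces show the malonyl peaks at 4.20 and 4.60", {
  tr <- demo_truths()[["lupulus"]]
  ch <- simulate_chromatogram(tr, "leaf", 350, replicate = 0, noise_sd = 0)
  peaks <- detect_peaks(ch)
  expect_true(any(abs(peaks$apex_time - 4.60) < 0.02))
  expect_true(any(abs(peaks$apex_time - 4.20) < 0.03))
  # combined malonyl share of total flavonol signal exceeds the 0.20 bound
  mp <- leaf_profile(tr$leaf)$malonyl_proportion
  expect_gt(mp, 0.20)
})

test_that("calibration series has the documented design", {
  s <- generate_calibration_series("XHU", seed = 3)
  expect_equal(nrow(s), 21)
  expect_equal(range(s$concentration_mg_ml), c(0.001, 0.5))
  expect_equal(length(unique(s$concentration_mg_ml)), 7)

  s0 <- generate_calibration_series("XHU", noise_cv = 0)
  expect_equal(s0$area, 1500 * s0$concentration_mg_ml)

  expect_error(generate_calibration_series("XHU", low = 0.5, high = 0.1),
               "low < high")
})

test_that("chromatogram and truth files round-trip through text", {
  tr <- demo_truths()[["lupuloides"]]
  ch <- simulate_chromatogram(tr, "cone", 370, replicate = 1, noise_sd = 0.2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_chromatogram(ch, path)
  back <- read_chromatogram(path)
  expect_equal(back$absorbance_mau, ch$absorbance_mau, tolerance = 1e-9)
  expect_equal(back$channel_nm, 370)
  expect_equal(back$metadata[["tissue"]], "cone")

  tpath <- withr::local_tempfile(fileext = ".csv")
  write_panel_truths(list(tr), tpath)
  tab <- read.csv(tpath)
  expect_equal(nrow(tab), 14)
  labs <- read.csv(paste0(tpath, ".labels.csv"))
  expect_equal(labs$subspecies, "lupuloides")
})
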