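test_that("peak detection on flat and two-Gaussian traces", {
  expect_equal(nrow(detect_peaks(flat_chrom())), 0)
  expect_error(detect_peaks(as_chromatogram(c(0, 1), c(0, 0))), "3 samples")

  # two noiseless Gaussians > 6 widths apart: both apexes found exactly
  times <- seq(0, 3, by = 1 / 1200)
  sd <- 0.02
  y <- 50 * exp(-0.5 * ((times - 1) / sd)^2) +
    80 * exp(-0.5 * ((times - 2.5) / sd)^2)
  peaks <- detect_peaks(as_chromatogram(times, y), smooth_pts = 1)
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$apex_time, c(1, 2.5), tolerance = 1 / 1200)
  expect_true(all(peaks$window_start < peaks$apex_time &
                    peaks$apex_time < peaks$window_end))
  # windows are disjoint (may share a boundary sample)
  expect_true(peaks$window_end[1] <= peaks$window_start[2])
})

test_that("lupuloides cone trace yields the four prenylchalcone peaks", {
  tr <- demo_truths()[["lupuloides"]]
  ch <- simulate_chromatogram(tr, "cone", 370, replicate = 1, noise_sd = 0.2)
  peaks <- assign_peaks(detect_peaks(ch), channel_nm = 370, tissue = "cone")
  expect_setequal(peaks$compound_id, c("DXH", "XGA", "XHU", "MXH"))
})

test_that("trapezoidal integration matches the analytic Gaussian area", {
  ch <- gaussian_chrom(area = 1, baseline = 0)
  expect_equal(integrate_peak(ch, c(0.8, 1.2), "zero"), 1, tolerance = 0.005)
  expect_equal(integrate_peak(flat_chrom(0), c(0.5, 1.5), "zero"), 0)

  # constant baseline is removed exactly by linear endpoint anchoring
  chb <- gaussian_chrom(area = 1, baseline = 7)
  a <- integrate_peak(chb, c(0.8, 1.2), "linear_endpoints")
  expect_equal(a, 1, tolerance = 0.01)

  expect_error(integrate_peak(ch, c(1.2, 0.8)), "start < end")
  expect_error(integrate_peak(ch, c(1.9, 2.5)), "outside")
})

test_that("trapezoid agrees with a fine-grid Riemann-sum oracle", {
  withr::with_seed(12, {
    for (i in 1:20) {
      area <- runif(1, 0.5, 50)
      rt <- runif(1, 0.5, 1.5)
      sd <- runif(1, 0.015, 0.04)
      ch <- gaussian_chrom(area = area, rt = rt, sd = sd, baseline = 0)
      got <- integrate_peak(ch, c(rt - 6 * sd, rt + 6 * sd), "zero")
      # midpoint Riemann sum on a 20x finer grid
      tg <- seq(rt - 6 * sd, rt + 6 * sd, length.out = 24000)
      mid <- (tg[-1] + tg[-length(tg)]) / 2
      oracle <- sum(area / (sd * sqrt(2 * pi)) *
                      exp(-0.5 * ((mid - rt) / sd)^2) * diff(tg))
      expect_equal(got, oracle, tolerance = 1e-3)
    }
  })
})

test_that("calibration fitting is exact on exact lines", {
  pts <- data.frame(concentration_mg_ml = c(0.01, 0.1, 0.3),
                    area = 100 * c(0.01, 0.1, 0.3))
  cal <- fit_calibration(pts, "XHU")
  expect_equal(cal$slope, 100)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1)
  expect_equal(cal$valid_range, c(0.01, 0.3))

  # closed-form OLS: (0,1),(1,2),(2,3) -> y = x + 1
  cal2 <- fit_calibration(data.frame(c(0, 1, 2), c(1, 2, 3)))
  expect_equal(cal2$slope, 1)
  expect_equal(cal2$intercept, 1)
  expect_equal(cal2$r_squared, 1)

  expect_error(fit_calibration(data.frame(c(1, 1), c(2, 3))), "degenerate")
})

test_that("default synthetic series calibrates with r2 above 0.999", {
  cal <- fit_calibration(generate_calibration_series("XHU", seed = 21), "XHU")
  expect_gt(cal$r_squared, 0.999)
})

test_that("refitting a curve on its own noiseless predictions is idempotent", {
  cal <- fit_calibration(generate_calibration_series("Qrut", seed = 4), "Qrut")
  conc <- exp(seq(log(0.001), log(0.5), length.out = 7))
  refit <- fit_calibration(
    data.frame(concentration_mg_ml = conc,
               area = cal$intercept + cal$slope * conc), "Qrut")
  expect_equal(refit$slope, cal$slope)
  expect_equal(refit$intercept, cal$intercept)
  expect_equal(refit$r_squared, 1)
})

test_that("quantify applies the curve and extraction bookkeeping", {
  curve <- structure(list(compound_id = "XHU", slope = 100, intercept = 0,
                          r_squared = 1, valid_range = c(0.001, 0.5)),
                     class = "hop_calibration")
  ext <- extraction_record(500, 50, 1)
  q <- quantify(10, curve, ext)
  expect_equal(q$concentration_mg_ml, 0.1)
  expect_equal(q$percent_dw, 1.0)
  expect_equal(q$flag, "")

  # area equal to the intercept -> zero
  curve$intercept <- 2
  expect_equal(quantify(2, curve, ext)$percent_dw, 0)

  # affine linearity: doubling (area - intercept) doubles percent dw
  q1 <- quantify(12, curve, ext)
  q2 <- quantify(22, curve, ext)
  expect_equal(q2$percent_dw, 2 * q1$percent_dw)

  expect_equal(quantify(2.01, curve, ext)$flag, "below_lowest_calibrant")
  expect_error(quantify(1e5, curve, ext), "dilute")
  curve$slope <- -1
  expect_error(quantify(10, curve, ext), "slope")
})

test_that("ICE-3 quantitation reproduces the defined composition", {
  ice3 <- ice3_composition(total_mg_ml = 1)
  std_areas <- c(COH = 200, nADH = 440, COL = 190, nADL = 160)
  ext <- extraction_record(500, 50, 1)  # 1 mg/ml corresponds to 10 % dw
  pct <- quantify_bitter_acids(std_areas, ice3, std_areas, ext)
  expect_equal(unname(pct["COH"]), 1.388)
  expect_equal(unname(pct["nADL"]), 1.084)
  expect_equal(unname(quantify_bitter_acids(
    c(COH = 0, nADH = 0, COL = 0, nADL = 0), ice3, std_areas, ext)),
    rep(0, 4))
  expect_error(quantify_bitter_acids(std_areas, ice3, std_areas[-1], ext),
               "COH")
})

test_that("noiseless round-trip recovers cone composition and COH share", {
  truths <- demo_truths(seed = 77)
  tr <- truths[["lupuloides"]]
  tr$replicate_noise_cv <- 0
  ch <- simulate_chromatogram(tr, "cone", 320, replicate = 0, noise_sd = 0)
  peaks <- assign_peaks(detect_peaks(ch), channel_nm = 320, tissue = "cone")
  areas <- stats::setNames(vapply(seq_len(nrow(peaks)), function(i) {
    integrate_peak(ch, c(peaks$window_start[i], peaks$window_end[i]))
  }, numeric(1)), peaks$compound_id)
  std <- channel_response_factor(320) * ice3_composition()$fractions
  pct <- quantify_bitter_acids(areas, ice3_composition(), std,
                               default_extraction("cone", 320))
  true_prop <- tr$cone[["COH"]] / (tr$cone[["COH"]] + tr$cone[["nADH"]])
  got_prop <- pct[["COH"]] / (pct[["COH"]] + pct[["nADH"]])
  expect_equal(got_prop, true_prop, tolerance = 0.01 / true_prop)
  expect_equal(unname(pct), unname(tr$cone[names(pct)]), tolerance = 0.01)
})

test_that("the co-eluting flavonol pair is flagged and apportioned", {
  tr <- demo_truths(seed = 55)[["lupulus"]]
  ch <- simulate_chromatogram(tr, "leaf", 350, replicate = 0, noise_sd = 0)
  peaks <- assign_peaks(detect_peaks(ch), channel_nm = 350, tissue = "leaf")
  joint <- peaks[grepl("\\+", peaks$compound_id), ]
  expect_equal(nrow(joint), 1)
  expect_equal(joint$flag, "coeluting")
  expect_setequal(strsplit(joint$compound_id, "+", fixed = TRUE)[[1]],
                  c("Krut", "Qmal"))

  pct <- stats::setNames(
    c(1, 1, 0.5, 0.36),
    c("Qrut", "Qglc", "Kmal", "Krut+Qmal"))
  out <- apportion_coeluting(pct, ratio = 5)
  expect_equal(out[["Qmal"]], 0.1)
  expect_equal(out[["Krut"]], 0.26)
  expect_false(any(grepl("\\+", names(out))))
})
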