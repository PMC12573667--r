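test_that("netOD follows the background-corrected log ratio", {
  expect_equal(compute_netod(30000, 30000, 0), 0)
  expect_equal(compute_netod(20000, 40000, 0), log10(2))
  expect_equal(compute_netod(20000, 40000, 1000), log10(39000 / 19000))
  expect_error(compute_netod(500, 40000, 1000), "background")
  expect_error(compute_netod(20000, 900, 1000), "unexposed")
})

test_that("ROI means are plain pixel averages", {
  expect_equal(extract_roi_mean(matrix(7, 20, 20), spacing = 1), 7)
  img <- matrix(c(10, 30, 20, 40), 2, 2)  # {10,20,30,40}
  expect_equal(extract_roi_mean(img, center = c(1, 1), roi_size = 2,
                                spacing = 1), 25)
  checker <- outer(1:10, 1:10, function(i, j) 100 * ((i + j) %% 2))
  expect_equal(extract_roi_mean(checker, roi_size = 4, spacing = 1), 50)
  expect_error(extract_roi_mean(img, center = c(0.2, 1), roi_size = 2,
                                spacing = 1), "outside")
})

test_that("calibration fitting recovers a noiseless generating model", {
  doses <- c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10)
  films <- simulate_calibration_films(doses, noise_sd = 0, replicates = 1)
  red <- films[films$channel == "red", ]
  netod <- compute_netod(red$intensity, attr(films, "unexposed"),
                         attr(films, "background"))
  curve <- fit_calibration(netod, red$dose)
  expect_equal(curve$b, 10, tolerance = 1e-6)
  expect_equal(curve$c, 50, tolerance = 1e-6)
  expect_equal(curve$n, 2.5, tolerance = 1e-6)
  expect_gt(curve$r2, 1 - 1e-10)
  # round trip: dose -> netOD (generator) -> dose (fitted curve)
  back <- netod_to_dose(netod, curve)
  expect_equal(back, red$dose, tolerance = 1e-6)
})

test_that("calibration fitting rejects degenerate input", {
  expect_error(fit_calibration(rep(0, 8), c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10)),
               "degenerate")
  expect_error(fit_calibration(c(0, 0.1), c(0, 1)), "distinct")
})

test_that("channel calibration at realistic noise is accurate and selects red", {
  films <- simulate_calibration_films(noise_sd = 0.002, replicates = 8,
                                      seed = 4)
  fits <- fit_calibration_channels(films)
  expect_identical(fits$selected, "red")
  expect_gt(fits$curves$red$r2, 0.99)
  expect_equal(nrow(films[films$channel == "red", ]), 64)
})

test_that("channel selection is invariant to intensity rescaling", {
  films <- simulate_calibration_films(noise_sd = 0.002, replicates = 8,
                                      seed = 9)
  fits1 <- fit_calibration_channels(films)
  scaled <- films
  scaled$intensity <- films$intensity * 0.37
  fits2 <- fit_calibration_channels(scaled,
                                    unexposed = attr(films, "unexposed") * 0.37,
                                    background = attr(films, "background") * 0.37)
  expect_identical(fits1$selected, fits2$selected)
  expect_equal(fits1$curves$red$b, fits2$curves$red$b, tolerance = 1e-8)
})

test_that("netOD-to-dose conversion clips out-of-range input and checks channels", {
  doses <- c(0, 0.1, 0.2, 0.5, 1, 2, 5, 10)
  films <- simulate_calibration_films(doses, noise_sd = 0, replicates = 1)
  red <- films[films$channel == "red", ]
  netod <- compute_netod(red$intensity, attr(films, "unexposed"),
                         attr(films, "background"))
  curve <- fit_calibration(netod, red$dose)
  expect_equal(netod_to_dose(0, curve), 0)
  m <- matrix(sort(runif(9, 0, max(netod))), 3)
  dm <- netod_to_dose(m, curve)
  expect_s3_class(dm, "dose_map")
  expect_true(all(diff(as.vector(dm$values)) >= 0))  # monotone in netOD
  expect_warning(netod_to_dose(max(netod) * 2, curve), "clipped")
  expect_error(netod_to_dose(0.1, curve, channel = "blue"), "mismatch")
})

test_that("relative dose rescaling preserves ratios and the PVDR", {
  spec <- grid_pattern_spec("striped")
  dm <- render_dose_map(make_pattern_mask(spec, spacing = 0.25), 5, spec,
                        spacing = 0.25)
  down <- rescale_dose_map(dm, 2)
  up <- rescale_dose_map(dm, 10)
  expect_equal(down$values, dm$values * 0.4, tolerance = 1e-12)
  expect_equal(up$values, dm$values * 2, tolerance = 1e-12)
  expect_equal(rescale_dose_map(dm, 5)$values, dm$values)
  expect_equal(peak_valley_stats(up)$pvdr, peak_valley_stats(dm)$pvdr,
               tolerance = 1e-12)
  expect_error(rescale_dose_map(dm, 0), "positive")
})

test_that("calibration film generator behaves physically", {
  films0 <- simulate_calibration_films(noise_sd = 0, replicates = 1)
  red <- films0[films0$channel == "red", ]
  expect_equal(red$intensity[red$dose == 0], 40000)
  expect_true(all(diff(red$intensity[order(red$dose)]) < 0))  # darkening
  expect_error(simulate_calibration_films(noise_sd = -1), "noise_sd")
})
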