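# Rate laws, buffer map and proliferation kinetics.

test_that("scaled OCR follows the literal pH-coupled law", {
  p <- metabolic_params("NX", "LG", "animal")
  # at saturation the realized rate is (7.4 - 4.95) * Vmax
  expect_equal(ocr(1e9, 7.4, p), 17 * 2.45, tolerance = 1e-6)
  # closed form at arbitrary points
  for (o2 in c(5, 12, 60, 180)) {
    for (ph in c(6.5, 7.0, 7.4)) {
      expect_equal(ocr(o2, ph, p),
                   17 * (ph - 4.95) * o2 / (12 * (ph - 4.95) + o2),
                   tolerance = 1e-12)
    }
  }
  expect_equal(ocr(100, 4.95, p), 0) # respiration ceases at the offset pH
  expect_equal(ocr(100, 4.00, p), 0)
  expect_error(ocr(-1, 7.4, p), "non-negative")
})

test_that("normalized OCR variant saturates at the tabulated Vmax", {
  p <- metabolic_params("NX", "LG", "animal", ocr_ph_form = "normalized")
  expect_equal(ocr(1e9, 7.4, p), 17, tolerance = 1e-6)
  expect_equal(ocr(12, 7.4, p), 8.5, tolerance = 1e-9) # half-saturation at Km
  pd <- metabolic_params("NX", "LG", "degenerated", ocr_ph_form = "normalized")
  expect_equal(ocr(1e9, 7.4, pd), 62, tolerance = 1e-5)
})

test_that("GCR is Michaelis-Menten with regime-specific Vmax", {
  p <- metabolic_params("NX", "LG")
  expect_equal(gcr(1e9, p), 143, tolerance = 1e-5)
  expect_equal(gcr(2, p), 71.5, tolerance = 1e-9)
  expect_equal(gcr(0, p), 0)
  expect_error(gcr(-0.1, p), "non-negative")
  expect_equal(gcr(1e9, metabolic_params("PX", "LG")), 103, tolerance = 1e-4)
  expect_equal(gcr(1e9, metabolic_params("HX", "LG")), 165, tolerance = 1e-4)
})

test_that("LPR couples to GCR through the regime ratio and the pH response", {
  p <- metabolic_params("NX", "LG")
  expect_equal(lpr(1e9, 7.4, p), 1.4 * 143, tolerance = 1e-4) # 200.2
  expect_equal(lpr(0, 7.4, p), 0)
  # anchored pH response: ~200 -> ~150 -> ~50 nmol/10^6 cells/h
  expect_equal(lpr(1e9, 6.7, p), 0.75 * 1.4 * 143, tolerance = 1e-4)
  expect_equal(lpr(1e9, 6.2, p), 0.25 * 1.4 * 143, tolerance = 1e-4)
  expect_equal(lpr(1e9, 6.2, p), 50, tolerance = 0.1)
  expect_equal(lpr(1e9, 5.0, p), lpr(1e9, 6.2, p)) # clamped below 6.2
  # explicit tabulated-Vmax mode
  pt <- metabolic_params("NX", "LG", lpr_mode = "table")
  expect_equal(lpr(1e9, 7.4, pt), 207, tolerance = 1e-4)
})

test_that("rates preserve regime orderings and monotonicity", {
  ratios <- vapply(c("NX", "PX", "HX"), function(r)
    metabolic_params(r, "LG")$lac_gluc_ratio, 0)
  expect_true(ratios["HX"] > ratios["PX"] && ratios["PX"] > ratios["NX"])
  # at equal glucose and pH, LPR ordering follows the ratio ordering
  l <- vapply(c("NX", "PX", "HX"), function(r)
    lpr(5.5, 7.4, metabolic_params(r, "LG")), 0)
  expect_true(l[["HX"]] > l[["PX"]])
  # lpr / gcr equals the ratio exactly at fresh-media pH
  for (r in c("NX", "PX", "HX")) {
    p <- metabolic_params(r, "LG")
    expect_equal(lpr(3, 7.4, p) / gcr(3, p), p$lac_gluc_ratio,
                 tolerance = 1e-12)
  }
  p <- metabolic_params("NX", "LG")
  o2 <- seq(0, 200, by = 5)
  expect_true(all(diff(ocr(o2, 7.2, p)) > 0))
  ph <- seq(5.2, 7.4, by = 0.1)
  expect_true(all(diff(ocr(50, ph, p)) > 0))
  expect_true(all(diff(gcr(seq(0, 30, by = 1), p)) > 0))
  expect_true(all(ocr(o2, 7.0, p) >= 0) && all(gcr(o2, p) >= 0))
})

test_that("pH falls linearly with lactate down to the buffer floor", {
  b <- buffer_model(slope = 0.141)
  expect_equal(ph_from_lactate(0, b), 7.4)
  expect_equal(ph_from_lactate(2, b), 7.4 - 0.141 * 2, tolerance = 1e-12)
  expect_equal(ph_from_lactate(100, b), 6.0) # floor
  lac <- seq(0, 15, by = 0.5)
  expect_true(all(diff(ph_from_lactate(lac, b)) <= 0))
  expect_error(buffer_model(slope = -1), "non-negative")
})

test_that("population growth is exponential and capped", {
  pop <- cell_population(5000, 0.348, 28571)
  expect_equal(population(0, pop), 5000)
  expect_equal(population(5, pop), min(5000 * exp(0.348 * 5), 28571),
               tolerance = 1e-12)
  expect_equal(population(20, pop), 28571) # confluency cap
  # doubling time of the observed expansion ~2 days
  expect_equal(log(2) / 0.348, 1.99, tolerance = 1e-2)
})

test_that("growth-rate closed form recovers the observed expansions", {
  expect_equal(growth_rate_from_doubling(5000, 28571, 5), 0.3486,
               tolerance = 1e-4)
  expect_equal(growth_rate_from_doubling(5000, 5000, 3), 0)
  # slower expansion reaching the same confluency in 13.5 days
  expect_equal(growth_rate_from_doubling(5000, 28571, 13.5), 0.129,
               tolerance = 1e-3)
  expect_error(growth_rate_from_doubling(0, 100, 1), "positive")
})
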