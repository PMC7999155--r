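gauss_run <- function(area, apex = 5, sd = 0.1, mz = 500.25, charge = 2L,
                      rt = seq(3, 7, by = 0.05), baseline = 0) {
  h <- area / (sd * sqrt(2 * pi))
  env <- averagine_envelope(mass_from_mz(mz, charge), 3)
  lapply(seq_along(rt), function(i) {
    y <- h * exp(-(rt[i] - apex)^2 / (2 * sd^2))
    mzv <- mz + (0:2) * 1.00335483 / charge
    intv <- y * env
    if (baseline > 0) { mzv <- c(mzv, 400.1); intv <- c(intv, baseline) }
    new_spectrum(mzv, intv, 1L, scan_id = as.character(i), rt = rt[i])
  })
}

test_that("EIC apex lands on the planted elution peak and scales linearly", {
  ms1 <- gauss_run(area = 1000, apex = 5)
  tr <- extract_eic(ms1, 500.25, 2L)
  expect_equal(tr$rt[which.max(tr$intensity)], 5, tolerance = 0.051)
  ig <- integrate_eic(tr, c(4, 6))
  expect_equal(ig$area, 1000, tolerance = 0.01 * 1000)
  # doubling intensities doubles the area
  ms1x2 <- lapply(ms1, function(s) { s$intensity <- 2 * s$intensity; s })
  ig2 <- integrate_eic(extract_eic(ms1x2, 500.25, 2L), c(4, 6))
  expect_equal(ig2$area, 2 * ig$area, tolerance = 1e-9)
})

test_that("an infinitely narrow window rejects off-grid masses", {
  ms1 <- gauss_run(area = 1000)
  off <- extract_eic(ms1, 500.31, 2L, resolving_power = 1e9)
  expect_true(all(off$intensity == 0))
})

test_that("integration matches closed forms on simple shapes", {
  # rectangle of height h and width w on a zero baseline
  rt <- seq(0, 10, by = 0.1)
  y <- ifelse(rt >= 4 & rt <= 6, 100, 0)
  tr <- data.frame(rt = rt, intensity = y)
  ig <- integrate_eic(tr, c(3, 7))
  expect_equal(ig$area, 200, tolerance = 0.06 * 200)  # trapezoid edge effect
  expect_lt(ig$background_area, 1e-9)
  expect_true(ig$ab_ratio > 1e6)
  # pure flat baseline: everything is background
  trb <- data.frame(rt = rt, intensity = rep(50, length(rt)))
  igb <- integrate_eic(trb, c(3, 7))
  expect_equal(igb$area, 0, tolerance = 1e-9)
  expect_equal(igb$background_area, 50 * 4, tolerance = 1e-6)
  expect_lt(igb$ab_ratio, 0.01)
  # degenerate window
  expect_true(integrate_eic(trb, c(20, 21))$flagged)
})

test_that("recovery arithmetic matches the load-normalized definition", {
  expect_equal(recovery_percent(1, 1, 1, 1), 100)
  # lossless enrichment under the study loads
  expect_equal(recovery_percent(157.142857, 1, 11, 0.07), 100,
               tolerance = 1e-6)
  expect_equal(recovery_percent(9.43, 1, 11, 0.07), 6.0, tolerance = 0.01)
  expect_warning(r <- recovery_percent(1, 0, 11, 0.07), "undefined")
  expect_true(is.na(r))
})

test_that("CV matches its closed form and is scale invariant", {
  expect_equal(cv_percent(c(8, 10, 12)), 20.0)
  expect_equal(cv_percent(c(1, 1, 1)), 0)
  set.seed(5)
  x <- rlnorm(10, 10, 0.3)
  expect_equal(cv_percent(x), cv_percent(137 * x), tolerance = 1e-9)
  expect_error(cv_percent(5), "2 replicates")
})

test_that("enrichment summary recovers the planted depletion contrast", {
  rec <- data.frame(
    peptidoform = sprintf("p%02d", 1:20),
    recovery_percent = c(rep(100, 10), rep(1, 10)),
    group = rep(c("arp", "non_arp"), each = 10),
    cv = c(rep(5, 9), 30, rep(10, 5), rep(25, 5)))
  s <- enrichment_summary(rec)
  expect_equal(unname(s$medians["arp"]), 100)
  expect_equal(unname(s$medians["non_arp"]), 1)
  expect_equal(s$median_ratio, 100)
  expect_equal(unname(s$cv_pass_fraction["arp"]), 0.9)
  expect_equal(unname(s$cv_pass_fraction["non_arp"]), 0.5)
  one <- enrichment_summary(data.frame(peptidoform = c("a", "b"),
                                       recovery_percent = c(42, 7),
                                       group = c("arp", "non_arp")))
  expect_equal(unname(one$medians), c(42, 7))
})

test_that("upscale comparison pairs peptides and reports ratios", {
  low <- data.frame(peptidoform = c("a", "b", "c"), area = c(1, 2, 4))
  high <- data.frame(peptidoform = c("a", "b", "d"), area = c(1, 2, 8))
  u <- upscale_compare(low, high)
  expect_equal(u$ratios$ratio, c(1, 1))
  expect_equal(u$median_ratio, 1)
  expect_identical(u$n_excluded, 2L)  # c and d unpaired
  expect_error(upscale_compare(low[0, ], high), "shared")
})

test_that("ion-mobility filter applies the resolving-power window", {
  f <- data.frame(id = 1:3, drift_time = c(5.0, 5.2, NA))
  kept <- ion_mobility_filter(f, predicted = 5.0, resolving_power = 15)
  # window is +/- 5/(2*15) = 0.167 ms: 5.0 kept, 5.2 removed, NA kept
  expect_setequal(kept$id, c(1L, 3L))
  # infinite resolving power keeps exact matches only
  kept2 <- ion_mobility_filter(f[1:2, ], predicted = 5.0,
                               resolving_power = 1e12)
  expect_identical(kept2$id, 1L)
  expect_message(ion_mobility_filter(data.frame(id = 1), 5), "pass-through")
})

test_that("recovery and CV are invariant to global intensity rescaling", {
  ms1 <- gauss_run(area = 500, baseline = 10)
  sc <- lapply(ms1, function(s) { s$intensity <- 3.7 * s$intensity; s })
  a1 <- integrate_eic(extract_eic(ms1, 500.25, 2L), c(4, 6))$area
  a2 <- integrate_eic(extract_eic(sc, 500.25, 2L), c(4, 6))$area
  expect_equal(a2 / a1, 3.7, tolerance = 1e-9)
  expect_equal(recovery_percent(a1, a1 / 157.142857, 11, 0.07),
               recovery_percent(a2, a2 / 157.142857, 11, 0.07),
               tolerance = 1e-9)
})
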