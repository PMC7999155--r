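test_that("error model is robust and floored", {
  em0 <- fit_error_model(rep(0, 20))
  expect_identical(em0$mean_ppm, 0)
  expect_identical(em0$sd_ppm, 0.5)  # degeneracy floor
  set.seed(21)
  em <- fit_error_model(rnorm(1000, 2, 5))
  expect_equal(em$mean_ppm, 2, tolerance = 0.5)
  expect_equal(em$sd_ppm, 5, tolerance = 0.7)
  # a single gross outlier barely moves the robust location
  emo <- fit_error_model(c(rep(0, 99), 100))
  expect_lt(abs(emo$mean_ppm), 0.1)
  expect_error(fit_error_model(1:5), "at least")
})

test_that("criteria map onto confident / ambiguous / rejected correctly", {
  em <- list(mean_ppm = 0, sd_ppm = 5, n = 100)
  psm <- data.frame(coverage = 0.8, site_confirmed = TRUE,
                    precursor_error_ppm = 1)
  rep_ok <- data.frame(is_candidate = TRUE)
  fe <- data.frame(area = 100, ab_ratio = 50)
  fn <- data.frame(area = 1, ab_ratio = 0.5)
  v <- apply_criteria(psm, rep_ok, fe, fn, em)
  expect_true(all(v$criteria == "pass"))
  expect_identical(v$verdict, "confident")
  # site localization fails only -> ambiguous
  psm5 <- transform(psm, site_confirmed = FALSE)
  expect_identical(apply_criteria(psm5, rep_ok, fe, fn, em)$verdict,
                   "ambiguous")
  # large precursor error only -> ambiguous
  psm6 <- transform(psm, precursor_error_ppm = 30)
  expect_identical(apply_criteria(psm6, rep_ok, fe, fn, em)$verdict,
                   "ambiguous")
  # low coverage -> rejected (criterion 4 is not in the ambiguous set)
  psm4 <- transform(psm, coverage = 0.4)
  expect_identical(apply_criteria(psm4, rep_ok, fe, fn, em)$verdict,
                   "rejected")
  # enriched intensity not above non-enriched -> rejected
  fn_hi <- data.frame(area = 1000, ab_ratio = 20)
  expect_identical(apply_criteria(psm, rep_ok, fe, fn_hi, em)$verdict,
                   "rejected")
  # unresolved enriched peak -> rejected
  fe_bad <- data.frame(area = 100, ab_ratio = 1)
  expect_identical(apply_criteria(psm, rep_ok, fe_bad, fn, em)$verdict,
                   "rejected")
})

test_that("missing fractions leave criteria 1-2 not evaluable", {
  em <- list(mean_ppm = 0, sd_ppm = 5, n = 100)
  psm <- data.frame(coverage = 0.8, site_confirmed = TRUE,
                    precursor_error_ppm = 1)
  v <- apply_criteria(psm, data.frame(is_candidate = TRUE), NULL, NULL, em)
  expect_identical(unname(v$criteria[c("c1", "c2")]),
                   c("not_evaluable", "not_evaluable"))
  expect_identical(v$verdict, "confident")
  # chimera annotation is carried in the notes
  v2 <- apply_criteria(psm, data.frame(is_candidate = TRUE), NULL, NULL, em,
                       chimera = TRUE)
  expect_match(v2$notes, "2 m/z")
})

test_that("multi-PTM ambiguity resolves to the form with matched site ions", {
  reg <- arp_registry()
  # three-modification reading vs the two-modification acrolein reading
  md3 <- mod_frame(c(2, 4, 5), c("lys_semialdehyde", "cam", "cam"))
  md2 <- mod_frame(c(4, 5), c("cys_acrolein", "cam"))
  s <- render_form_spectrum("LKECCEKPLLEK", md3, 3L)
  alt3 <- new_peptidoform("LKECCEKPLLEK", md3)
  alt2 <- new_peptidoform("LKECCEKPLLEK", md2)
  # the two readings are near-isobaric at the precursor level (they differ
  # by the documented 0.036 Da bookkeeping discrepancy)
  expect_lt(abs(alt3$neutral_mass - alt2$neutral_mass), 0.05)
  out <- resolve_modification_ambiguity(s, list(alt2, alt3), reg)
  expect_false(out$ambiguous)
  expect_identical(out$best$label, alt3$label)
  expect_true(out$records$matched_discriminating[out$records$chosen] > 0)
})

test_that("a single alternative is returned unchanged", {
  pf <- new_peptidoform("PEPTIDER")
  s <- render_form_spectrum("PEPTIDER",
                            data.frame(pos = integer(), id = character(),
                                       delta = numeric()), 2L)
  out <- resolve_modification_ambiguity(s, list(pf))
  expect_identical(out$best$label, pf$label)
  expect_false(out$ambiguous)
})

test_that("no matched discriminating ions leaves all alternatives ambiguous", {
  reg <- arp_registry()
  md_a <- mod_frame(2, "lys_semialdehyde")
  md_b <- mod_frame(8, "lys_semialdehyde")
  # a spectrum containing only ions shared by both site assignments
  fa <- theoretical_fragments(new_peptidoform("LKCASLQK", md_a), reg,
                              max_fragment_charge = 1L)
  fb <- theoretical_fragments(new_peptidoform("LKCASLQK", md_b), reg,
                              max_fragment_charge = 1L)
  shared <- intersect(round(fa$mz, 3), round(fb$mz, 3))
  s <- new_spectrum(shared, rep(100, length(shared)), 2L, scan_id = "amb",
                    precursor_mz = mz_from_mass(
                      peptide_mass("LKCASLQK", md_a), 2),
                    precursor_charge = 2L, rt = 1)
  out <- resolve_modification_ambiguity(
    s, list(new_peptidoform("LKCASLQK", md_a),
            new_peptidoform("LKCASLQK", md_b)), reg)
  expect_true(out$ambiguous)
  expect_null(out$best)
})

test_that("every validated peptide receives exactly one verdict", {
  fx <- fx_noiseless()
  v <- fx$res$verdicts
  expect_identical(anyDuplicated(v$peptidoform), 0L)
  expect_true(all(v$verdict %in% c("confident", "ambiguous", "rejected")))
  # confident peptides are a subset of the FDR-passing set
  expect_true(all(v$peptidoform[v$verdict == "confident"] %in%
                    fx$res$fdr$peptides$label))
})
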