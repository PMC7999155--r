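test_that("b/y series satisfy the mass-completeness identity", {
  reg <- arp_registry()
  forms <- list(
    new_peptidoform("PEPTIDER"),
    new_peptidoform("LKCASLQK", mod_frame(c(2, 3), c("lys_semialdehyde", "cam")))
  )
  for (pf in forms) {
    fr <- theoretical_fragments(pf, reg, max_fragment_charge = 1L)
    n <- nchar(pf$sequence)
    for (i in seq_len(n - 1)) {
      b <- fr$mz[fr$series == "b" & fr$index == i & fr$loss == "none"]
      y <- fr$mz[fr$series == "y" & fr$index == n - i & fr$loss == "none"]
      expect_equal((b - proton_mass()) + (y - proton_mass()),
                   pf$neutral_mass, tolerance = 1e-6)
    }
  }
})

test_that("ARP loss variants follow the reporter profile", {
  reg <- arp_registry()
  # FULL_TAG: tag losses on modified b/y and the precursor
  pf <- new_peptidoform("LKCASLQK",
                        mod_frame(c(2, 3), c("lys_semialdehyde", "cam")))
  fr <- theoretical_fragments(pf, reg, max_fragment_charge = 1L)
  y7 <- fr[fr$series == "y" & fr$index == 7, ]
  expect_setequal(y7$loss, c("none", "tag_partial", "tag_full"))
  expect_equal(y7$mz[y7$loss == "tag_full"],
               y7$mz[y7$loss == "none"] - 331.139, tolerance = 1e-6)
  b2 <- fr[fr$series == "b" & fr$index == 2, ]
  expect_true(all(c("tag_partial", "tag_full") %in% b2$loss))
  expect_true(any(fr$series == "precursor" & fr$loss == "tag_full"))
  # unmodified y ions carry no losses
  y3 <- fr[fr$series == "y" & fr$index == 3, ]
  expect_identical(y3$loss, "none")
  # BIOTIN_ONLY: keto loss on modified y only, no tag losses
  pf2 <- new_peptidoform("LCTVATLR", mod_frame(c(2, 6), c("cam", "thr_2a3k")))
  fr2 <- theoretical_fragments(pf2, reg, max_fragment_charge = 1L)
  expect_true(any(fr2$series == "y" & fr2$loss == "keto"))
  expect_false(any(fr2$loss %in% c("tag_partial", "tag_full")))
  expect_false(any(fr2$series == "b" & fr2$loss == "keto"))
  y3k <- fr2[fr2$series == "y" & fr2$index == 3 & fr2$loss == "keto", ]
  expect_equal(y3k$mz, fr2$mz[fr2$series == "y" & fr2$index == 3 &
                                fr2$loss == "none"] - 288.126,
               tolerance = 1e-6)
  # unmodified peptide: no loss variants at all
  fr3 <- theoretical_fragments(new_peptidoform("PEPTIDER"), reg)
  expect_true(all(fr3$loss == "none"))
})

test_that("self-match yields full coverage, confirmed site, ~0 ppm error", {
  md <- mod_frame(c(2, 3), c("lys_semialdehyde", "cam"))
  s <- render_form_spectrum("LKCASLQK", md, 2L)
  psm <- match_spectrum(s, new_peptidoform("LKCASLQK", md))
  expect_gte(psm$sequence_coverage, 0.5)
  expect_true(psm$site_confirmed)
  expect_lt(abs(psm$precursor_error_ppm), 0.01)
  expect_gt(psm$score, 5)
})

test_that("isomeric site assignments are discriminated by fragments", {
  md_true <- mod_frame(c(2, 3), c("lys_semialdehyde", "cam"))
  md_wrong <- mod_frame(c(3, 8), c("cam", "lys_semialdehyde"))
  s <- render_form_spectrum("LKCASLQK", md_true, 2L)
  psm_true <- match_spectrum(s, new_peptidoform("LKCASLQK", md_true))
  psm_wrong <- match_spectrum(s, new_peptidoform("LKCASLQK", md_wrong))
  expect_gt(psm_true$score, psm_wrong$score)
  expect_true(psm_true$site_confirmed)
  expect_false(psm_wrong$site_confirmed)
})

test_that("the printed Fig 2 precursor error is sub-ppm", {
  m <- peptide_mass("LKCASLQK",
                    mod_frame(c(2, 3), c("lys_semialdehyde", "cam")))
  expect_lt(abs(ppm_error(630.315, mz_from_mass(m, 2))), 1)
})

test_that("score is zero without matches, deterministic, monotone in k", {
  expect_identical(score_psm(0, 20, 50, 900, 500, 20), 0)
  s1 <- score_psm(10, 20, 50, 900, 500, 20, 0.5)
  expect_identical(s1, score_psm(10, 20, 50, 900, 500, 20, 0.5))
  ks <- vapply(1:20, function(k) score_psm(k, 20, 50, 900, 500, 20),
               numeric(1))
  expect_true(all(diff(ks) > 0))
  # all matched on a sparse spectrum scores above half matched
  expect_gt(score_psm(20, 20, 25, 900, 500, 20),
            score_psm(10, 20, 25, 900, 500, 20))
})

test_that("peptide-level q-values follow the hand-computed sequence", {
  mk <- function(label, score, decoy)
    data.frame(scan_id = label, rank = 1L, label = label, score = score,
               is_decoy = decoy, shared_with_target = FALSE,
               stringsAsFactors = FALSE)
  psms <- rbind(mk("t1", 10, FALSE), mk("t2", 9, FALSE), mk("t3", 8, FALSE),
                mk("d1", 7.5, TRUE), mk("t4", 7, FALSE))
  out <- fdr_filter(psms, 0.05)
  expect_setequal(out$peptides$label, c("t1", "t2", "t3"))
  qs <- out$all_peptides
  expect_equal(qs$q_value[qs$label == "t4"], 0.25)
  expect_equal(qs$q_value[qs$label == "t3"], 0)
  # threshold 1 retains every target
  expect_identical(nrow(fdr_filter(psms, 1.0)$peptides), 4L)
  # all decoys above all targets -> nothing retained at 5%
  psms2 <- rbind(mk("d1", 10, TRUE), mk("d2", 9, TRUE), mk("t1", 5, FALSE))
  expect_identical(nrow(fdr_filter(psms2, 0.05)$peptides), 0L)
  # no decoys and no decoy-search provenance -> hard error
  expect_error(fdr_filter(mk("t1", 10, FALSE), 0.05), "decoy")
})

test_that("two-pass search assigns planted forms in the ARP pass", {
  fx <- fx_noiseless()
  psms <- fx$res$psms
  pf <- fx$man$peptidoforms
  best <- psms[psms$rank == 1L & !psms$is_decoy, ]
  arp_labels <- pf$label[pf$class == "arp"]
  hit <- best[best$label %in% arp_labels, ]
  expect_true(all(hit$pass == 2L))  # standard pass cannot explain ARP masses
  bg <- best[best$label %in% pf$label[pf$class != "arp"], ]
  expect_true(all(bg$pass == 1L))   # unmodified forms assigned in pass 1
})
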