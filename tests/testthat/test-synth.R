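test_that("manifests and rendered runs are reproducible from the seed", {
  cfg <- synth_config("enrichment", n_peptides = 8L, replicates = 1L)
  m1 <- generate_truth(cfg, seed = 42)
  m2 <- generate_truth(cfg, seed = 42)
  expect_identical(m1, m2)
  r1 <- render_run(m1, m1$runs$run_id[1])
  r2 <- render_run(m2, m2$runs$run_id[1])
  expect_identical(r1, r2)
  m3 <- generate_truth(cfg, seed = 43)
  expect_false(identical(m1$peptidoforms, m3$peptidoforms))
})

test_that("the dilution scenario plants a constant spike across ratios", {
  cfg <- synth_config("dilution", n_peptides = 6L, replicates = 2L,
                      intensity_cv = 0)
  man <- generate_truth(cfg, seed = 3)
  expect_identical(nrow(man$runs), 6L)  # 3 ratios x 2 replicates
  expect_setequal(unique(man$runs$group),
                  c("ratio_9", "ratio_49", "ratio_249"))
  # expected areas identical across ratio groups (constant spike abundance)
  a <- man$areas
  expect_equal(a[, man$runs$group == "ratio_9"],
               a[, man$runs$group == "ratio_249"],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero ARP fraction yields a background-only manifest", {
  man <- generate_truth(synth_config("enrichment", n_peptides = 6L,
                                     arp_fraction = 0), seed = 1)
  expect_false(any(man$peptidoforms$class == "arp"))
})

test_that("rendered ARP spectra carry the planted precursor and reporters", {
  # plant the Lys199 semialdehyde form of LKCASLQK explicitly
  reg <- arp_registry()
  md <- mod_frame(c(2, 3), c("lys_semialdehyde", "cam"))
  pf <- new_peptidoform("LKCASLQK", md)
  pep <- data.frame(id = "pep001", sequence = "LKCASLQK", protein = "HSA_SYN",
                    start = 198, end = 205,
                    mods = paste(sprintf("%d:%s:%.6f", md$pos, md$id,
                                         md$delta), collapse = ";"),
                    label = pf$label, neutral_mass = pf$neutral_mass,
                    charge = 2L, mz = mz_from_mass(pf$neutral_mass, 2),
                    class = "arp", rt_apex = 5, rt_sd = 0.08,
                    base_area = 1e5, stringsAsFactors = FALSE)
  runs <- data.frame(run_id = "enr_1", fraction = "enriched", replicate = 1L,
                     load = 11, group = "enrichment", cal_factor = 1,
                     stringsAsFactors = FALSE)
  man <- structure(list(
    seed = 1L,
    config = synth_config("enrichment", mz_jitter_ppm_sd = 0,
                          intensity_cv = 0, baseline_level = 0,
                          n_noise_peaks_ms2 = 0, n_baseline_ms1 = 0,
                          rt_max = 10),
    registry = reg, proteins = read_fasta(panel_fasta()),
    peptidoforms = pep, runs = runs,
    areas = matrix(1e5, 1, 1, dimnames = list("pep001", "enr_1"))),
    class = "arp_truth_manifest")
  spectra <- render_run(man, "enr_1")
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  expect_length(ms2, 1)
  s <- ms2[[1]]
  expect_equal(s$precursor_mz, 630.315, tolerance = 0.001)
  near <- function(target) any(abs(s$mz - target) / target * 1e6 < 20)
  expect_true(near(227.085))
  expect_true(near(299.117))   # FULL_TAG profile
  expect_true(near(332.139))
  # modified y7 with the full-tag loss
  y7 <- peptide_mass("KCASLQK", mod_frame(c(1, 2),
                                          c("lys_semialdehyde", "cam"))) +
    proton_mass() - 331.139
  expect_true(near(y7))
  # MS1 envelope present at the apex with the lock-mass reference
  ms1 <- Filter(function(s) s$ms_level == 1L, spectra)
  apex <- ms1[[which.min(abs(vapply(ms1, `[[`, numeric(1), "rt") - 5))]]
  expect_true(any(abs(apex$mz - 785.843) < 0.01))
  expect_true(any(abs(apex$mz - pep$mz) / pep$mz * 1e6 < 1))
})

test_that("precursor jitter follows the configured half-normal magnitude", {
  fx <- fx_noisy()
  pf <- fx$man$peptidoforms
  errs <- unlist(lapply(fx$ds$spectra[paste0("enr_", 1:3)], function(run) {
    ms2 <- Filter(function(s) s$ms_level == 2L, run)
    vapply(ms2, function(s) {
      id <- sub("^enr_\\d+_", "", s$scan_id)
      theo <- pf$mz[pf$id == id]
      abs(ppm_error(s$precursor_mz, theo))
    }, numeric(1))
  }))
  # E|X| of N(0, 10 ppm) is 10 * sqrt(2/pi) ~ 8.0 ppm
  expect_equal(mean(errs), 8, tolerance = 0.25 * 8)
})

test_that("datasets round-trip losslessly through mzML and MGF files", {
  cfg <- synth_config("enrichment", n_peptides = 5L, replicates = 1L,
                      rt_max = 6, ms1_rt_step = 0.2)
  man <- generate_truth(cfg, seed = 2)
  dir <- file.path(tempdir(), "synthds")
  ds <- render_dataset(man, dir)
  expect_true(file.exists(file.path(dir, "runs.tsv")))
  expect_true(file.exists(file.path(dir, "panel.fasta")))
  expect_true(file.exists(file.path(dir, "truth_peptidoforms.tsv")))
  back <- load_dataset(dir)
  expect_identical(names(back$spectra), man$runs$run_id)
  for (r in names(back$spectra)) {
    orig <- ds$spectra[[r]]
    got <- back$spectra[[r]]
    expect_length(got, length(orig))
    for (i in seq_along(orig)) {
      expect_equal(got[[i]]$mz, orig[[i]]$mz, tolerance = 1e-6)
      expect_equal(got[[i]]$intensity, orig[[i]]$intensity,
                   tolerance = 1e-4)
      expect_identical(got[[i]]$ms_level, orig[[i]]$ms_level)
    }
  }
  # MGF side carries the MS2 scans
  mgf <- read_spectra(file.path(dir, paste0(man$runs$run_id[1], ".mgf")))
  n_ms2 <- sum(vapply(ds$spectra[[1]], `[[`, integer(1), "ms_level") == 2L)
  expect_length(mgf, n_ms2)
})
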