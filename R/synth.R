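#' @title Ground-truth synthetic datasets
#' @description Generates fully annotated synthetic LC-MS/MS datasets
#'   (FASTA + mzML/MGF + run manifest) that exercise every pipeline stage:
#'   tryptic peptides from a bundled HSA-derived panel, a configurable subset
#'   carrying ARP-carbonyl adducts, CID-like b/y spectra with the
#'   profile-mandated reporter ions and tag losses, and MS1 3-isotope
#'   envelopes along a shared retention-time axis for enriched and
#'   non-enriched fractions with enrichment/depletion, background
#'   interference, and replicate noise.
#' @name synth
NULL

.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Path to the bundled protein panel
#' @return FASTA path inside the installed package.
#' @export
panel_fasta <- function() {
  system.file("extdata", "panel.fasta", package = "arpmap", mustWork = TRUE)
}

#' Default synthetic scenario configuration
#'
#' The defaults mirror the study conditions: triplicate enriched
#' (5.8% eluate, 11 ug equivalent on column) vs non-enriched (70 ng) runs,
#' lossless trapping of ARP peptides, ~100-fold depletion of ordinary
#' background peptides, avidin-sticky HPY-motif background peptides that
#' survive enrichment, 10 ppm m/z jitter (SD), 20% replicate intensity CV,
#' and a low flat chemical baseline.
#'
#' @param scenario `"enrichment"`, `"upscale"`, `"dilution"`, or
#'   `"noise_only"`.
#' @param ... Named overrides of any default listed below.
#' @return Named list of generator settings.
#' @export
synth_config <- function(scenario = c("enrichment", "upscale", "dilution",
                                      "noise_only"), ...) {
  scenario <- match.arg(scenario)
  cfg <- list(
    scenario = scenario,
    n_peptides = 50L,          # planted peptidoforms in total
    arp_fraction = 0.6,        # share carrying one ARP adduct
    replicates = 3L,
    load_enriched = 11,        # ug equivalents on column
    load_non_enriched = 0.07,
    depletion_factor = 100,    # background loss during enrichment
    upscale_gain = 7.3,        # net signal gain of the 10x load scenario
    dilution_ratios = c(9, 49, 249),
    n_noise_scans = 500L,
    rt_max = 20,               # min
    rt_peak_sd = 0.08,         # min, chromatographic peak SD
    ms1_rt_step = 0.05,        # min between MS1 scans
    area_meanlog = log(1e5),
    area_sdlog = 0.5,
    mz_jitter_ppm_sd = 10,
    intensity_cv = 0.2,
    baseline_level = 20,       # mean intensity of chemical background peaks
    n_baseline_ms1 = 20L,      # background peaks per MS1 scan
    n_noise_peaks_ms2 = 30L,
    chimera_pairs = 0L,
    calibration_ppm = 0,       # per-run multiplicative miscalibration
    with_drift = TRUE,
    min_length = 6L, max_length = 20L, max_missed = 1L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Generate a ground-truth manifest
#'
#' Deterministically (bit-exact for a given config and seed) plans a
#' synthetic experiment: which panel peptides are planted, their ARP
#' modifications (drawn from registry-eligible residues), charges, retention
#' apexes, per-run expected areas under the fraction design, and all noise
#' parameters. The manifest is the oracle that tests and acceptance checks
#' compare pipeline output against.
#'
#' @param config From [synth_config()].
#' @param seed Integer seed.
#' @param registry Modification registry.
#' @param proteins Protein panel (defaults to the bundled panel).
#' @return An `arp_truth_manifest` list: `seed`, `config`, `registry`,
#'   `proteins`, `peptidoforms`, `runs`, `areas` (peptide x run matrix of
#'   expected integrated areas).
#' @export
generate_truth <- function(config = synth_config(), seed = 1L,
                           registry = arp_registry(),
                           proteins = read_fasta(panel_fasta())) {
  .with_seed(seed, {
    if (config$scenario == "noise_only") {
      runs <- data.frame(run_id = "noise_1", fraction = "enriched",
                         replicate = 1L, load = config$load_enriched,
                         group = "noise", cal_factor = 1,
                         stringsAsFactors = FALSE)
      man <- list(seed = seed, config = config, registry = registry,
                  proteins = proteins,
                  peptidoforms = data.frame(), runs = runs,
                  areas = matrix(numeric(0), 0, 1,
                                 dimnames = list(NULL, runs$run_id)))
      class(man) <- "arp_truth_manifest"
      return(man)
    }
    peps <- digest_database(proteins, max_missed = config$max_missed,
                            min_length = config$min_length,
                            max_length = config$max_length, semi = FALSE)
    peps <- peps[!peps$is_decoy, , drop = FALSE]
    peps <- peps[!duplicated(peps$sequence), , drop = FALSE]
    sticky <- grepl("HPY", peps$sequence)
    n <- min(config$n_peptides, nrow(peps))
    n_arp <- round(n * config$arp_fraction)
    cam_delta <- registry$delta_mass[registry$id == "cam"]
    arp_reg <- registry[registry$profile != "NONE", , drop = FALSE]
    # ARP peptides need at least one eligible residue outside fixed-CAM Cys
    elig_ok <- vapply(peps$sequence, function(s) {
      es <- eligible_sites(s, arp_reg)
      cys <- which(strsplit(s, "")[[1]] == "C")
      any(!es$pos %in% cys)
    }, logical(1))
    arp_pool <- which(elig_ok & !sticky)
    n_arp <- min(n_arp, length(arp_pool))
    arp_idx <- sample(arp_pool, n_arp)
    bg_pool <- setdiff(seq_len(nrow(peps)), arp_idx)
    # keep sticky peptides preferentially in the background set
    bg_idx <- c(which(sticky & seq_len(nrow(peps)) %in% bg_pool),
                sample(setdiff(bg_pool, which(sticky))))
    bg_idx <- utils::head(unique(bg_idx), n - n_arp)
    plan <- list()
    build_form <- function(i, class) {
      s <- peps$sequence[i]
      aa <- strsplit(s, "")[[1]]
      cys <- which(aa == "C")
      md <- if (length(cys))
        data.frame(pos = cys, id = "cam", delta = cam_delta,
                   stringsAsFactors = FALSE)
      else data.frame(pos = integer(), id = character(), delta = numeric())
      if (class == "arp") {
        es <- eligible_sites(s, arp_reg)
        es <- es[!es$pos %in% cys, , drop = FALSE]
        pick <- es[sample(nrow(es), 1L), , drop = FALSE]
        md <- rbind(md, pick)
      }
      pf <- new_peptidoform(s, md, protein = peps$protein[i],
                            start = peps$start[i], end = peps$end[i],
                            n_variable = as.integer(class == "arp"))
      z <- if (nchar(s) >= 12 || pf$neutral_mass > 1600) 3L else 2L
      data.frame(id = NA_character_, sequence = s, protein = peps$protein[i],
                 start = peps$start[i], end = peps$end[i],
                 mods = .encode_mods(md), label = pf$label,
                 neutral_mass = pf$neutral_mass, charge = z,
                 mz = mz_from_mass(pf$neutral_mass, z),
                 class = class, stringsAsFactors = FALSE)
    }
    for (i in arp_idx) plan[[length(plan) + 1L]] <- build_form(i, "arp")
    for (i in bg_idx)
      plan[[length(plan) + 1L]] <-
        build_form(i, if (sticky[i]) "sticky" else "background")
    pf <- do.call(rbind, plan)
    pf$id <- sprintf("pep%03d", seq_len(nrow(pf)))
    pf$rt_apex <- stats::runif(nrow(pf), 2, config$rt_max - 2)
    pf$rt_sd <- config$rt_peak_sd
    pf$base_area <- stats::rlnorm(nrow(pf), config$area_meanlog,
                                  config$area_sdlog)
    if (config$chimera_pairs > 0) {
      arp_rows <- which(pf$class == "arp")
      np <- min(config$chimera_pairs, floor(length(arp_rows) / 2))
      for (k in seq_len(np)) {
        a <- arp_rows[2 * k - 1L]; b <- arp_rows[2 * k]
        pf$rt_apex[b] <- pf$rt_apex[a]
      }
    }
    runs <- switch(config$scenario,
      enrichment = {
        rbind(
          data.frame(run_id = sprintf("enr_%d", seq_len(config$replicates)),
                     fraction = "enriched", replicate = seq_len(config$replicates),
                     load = config$load_enriched, group = "enrichment",
                     cal_factor = 1, stringsAsFactors = FALSE),
          data.frame(run_id = sprintf("non_%d", seq_len(config$replicates)),
                     fraction = "non_enriched",
                     replicate = seq_len(config$replicates),
                     load = config$load_non_enriched, group = "enrichment",
                     cal_factor = 1, stringsAsFactors = FALSE))
      },
      upscale = {
        rbind(
          data.frame(run_id = sprintf("low_%d", seq_len(config$replicates)),
                     fraction = "enriched", replicate = seq_len(config$replicates),
                     load = 0.2, group = "low", cal_factor = 1,
                     stringsAsFactors = FALSE),
          data.frame(run_id = sprintf("high_%d", seq_len(config$replicates)),
                     fraction = "enriched", replicate = seq_len(config$replicates),
                     load = 2.0, group = "high", cal_factor = 1,
                     stringsAsFactors = FALSE))
      },
      dilution = {
        do.call(rbind, lapply(config$dilution_ratios, function(r)
          data.frame(run_id = sprintf("r%d_%d", r, seq_len(config$replicates)),
                     fraction = "enriched", replicate = seq_len(config$replicates),
                     load = config$load_enriched, group = paste0("ratio_", r),
                     cal_factor = 1, stringsAsFactors = FALSE)))
      }
    )
    runs$cal_factor <- 1 + config$calibration_ppm * 1e-6
    eff <- function(class, fraction, group) {
      if (config$scenario == "enrichment") {
        if (fraction == "non_enriched") return(1)
        switch(class, arp = 1, sticky = 1,
               background = 1 / config$depletion_factor)
      } else if (config$scenario == "upscale") {
        # net gain of the high-load condition relative to low, per unit load
        if (group == "high") config$upscale_gain * 0.2 / 2.0 else 1
      } else 1  # dilution: constant spike abundance
    }
    areas <- matrix(0, nrow(pf), nrow(runs),
                    dimnames = list(pf$id, runs$run_id))
    load_ref <- if (config$scenario == "enrichment")
      config$load_non_enriched else runs$load[1]
    for (j in seq_len(nrow(runs))) {
      e <- vapply(seq_len(nrow(pf)), function(i)
        eff(pf$class[i], runs$fraction[j], runs$group[j]), numeric(1))
      noise <- if (config$intensity_cv > 0)
        stats::rlnorm(nrow(pf), -log(1 + config$intensity_cv^2) / 2,
                      sqrt(log(1 + config$intensity_cv^2)))
      else rep(1, nrow(pf))
      areas[, j] <- pf$base_area * (runs$load[j] / load_ref) * e * noise
    }
    man <- list(seed = seed, config = config, registry = registry,
                proteins = proteins, peptidoforms = pf, runs = runs,
                areas = areas)
    class(man) <- "arp_truth_manifest"
    man
  })
}

#' @export
print.arp_truth_manifest <- function(x, ...) {
  cat("<ground-truth manifest> scenario '", x$config$scenario, "', seed ",
      x$seed, "\n  ", nrow(x$peptidoforms), " planted peptidoforms (",
      sum(x$peptidoforms$class == "arp"), " ARP), ", nrow(x$runs),
      " runs\n", sep = "")
  invisible(x)
}

# Render the MS2 peak list of one planted peptidoform (noiseless m/z; jitter
# applied by the caller).
.render_ms2_peaks <- function(pf_row, registry) {
  md <- decode_mods(pf_row$mods)
  pf <- new_peptidoform(pf_row$sequence, md)
  frags <- theoretical_fragments(pf, registry, max_fragment_charge = 1L)
  mz <- frags$mz
  int <- stats::runif(length(mz), 300, 1000)
  arp_ids <- md$id[md$id %in% registry$id[registry$profile != "NONE"]]
  if (length(arp_ids)) {
    prof <- registry$profile[match(arp_ids, registry$id)]
    k <- arp_constants()
    rep_mz <- k$reporter_biotin_mz
    if (any(prof == "FULL_TAG"))
      rep_mz <- c(rep_mz, k$reporter_arp_fragment_mz,
                  k$reporter_arp_protonated_mz)
    mz <- c(mz, rep_mz)
    int <- c(int, stats::runif(length(rep_mz), 600, 1000))
  }
  # theoretical coincidences (e.g. isobaric b/y) would duplicate m/z values;
  # keep the more intense peak
  agg <- tapply(int, mz, max)
  list(mz = as.numeric(names(agg)), intensity = as.numeric(agg))
}

#' Render the spectra of one run in memory
#'
#' Deterministic given the manifest and run id: MS1 scans along the RT grid
#' with 3-isotope Gaussian elution profiles (areas equal to the manifest's
#' expected areas), the lock-mass reference peak at every MS1 scan, chemical
#' baseline peaks, and one MS2 scan at each planted peptidoform's apex with
#' the profile-mandated reporter ions and tag-loss peaks. All m/z values are
#' multiplied by the run's calibration factor and jittered per the config.
#'
#' @param manifest From [generate_truth()].
#' @param run_id One of `manifest$runs$run_id`.
#' @param ms2 Render MS2 scans (default TRUE for enriched fractions).
#' @return List of `arp_spectrum` objects ordered by retention time.
#' @export
render_run <- function(manifest, run_id,
                       ms2 = NULL) {
  cfg <- manifest$config
  runs <- manifest$runs
  j <- match(run_id, runs$run_id)
  if (is.na(j)) stop("unknown run: ", run_id)
  if (is.null(ms2))
    ms2 <- runs$fraction[j] == "enriched"
  .with_seed((manifest$seed %% 1000000) * 1009 + j, {
    cal <- runs$cal_factor[j]
    jit <- function(mz) mz * (1 + stats::rnorm(length(mz), 0,
                                               cfg$mz_jitter_ppm_sd * 1e-6))
    out <- list()
    if (cfg$scenario == "noise_only") {
      for (i in seq_len(cfg$n_noise_scans)) {
        npk <- cfg$n_noise_peaks_ms2 + 10L
        out[[length(out) + 1L]] <- new_spectrum(
          mz = sort(stats::runif(npk, 100, 1200)),
          intensity = stats::rexp(npk, 1 / 200) + 1,
          ms_level = 2L, run_id = run_id, scan_id = sprintf("noise%04d", i),
          rt = stats::runif(1, 0, cfg$rt_max),
          precursor_mz = stats::runif(1, 400, 900), precursor_charge = 2L)
      }
      return(out[order(vapply(out, `[[`, numeric(1), "rt"))])
    }
    pf <- manifest$peptidoforms
    areas <- manifest$areas[, run_id]
    grid <- seq(0, cfg$rt_max, by = cfg$ms1_rt_step)
    env <- lapply(seq_len(nrow(pf)), function(i)
      averagine_envelope(pf$neutral_mass[i], 3L))
    iso_mz <- lapply(seq_len(nrow(pf)), function(i)
      pf$mz[i] + (0:2) * .ISOTOPE_SPACING / pf$charge[i])
    h <- areas / (pf$rt_sd * sqrt(2 * pi))  # Gaussian apex heights
    scan_num <- 0L
    for (rt in grid) {
      scan_num <- scan_num + 1L
      gauss <- h * exp(-(rt - pf$rt_apex)^2 / (2 * pf$rt_sd^2))
      on <- which(gauss > 1e-3 * pmax(h, 1))
      mzv <- 785.843
      intv <- 5000
      for (i in on) {
        mzv <- c(mzv, iso_mz[[i]])
        intv <- c(intv, gauss[i] * env[[i]])
      }
      if (cfg$n_baseline_ms1 > 0 && cfg$baseline_level > 0) {
        mzv <- c(mzv, stats::runif(cfg$n_baseline_ms1, 100, 1200))
        intv <- c(intv, stats::rexp(cfg$n_baseline_ms1,
                                    1 / cfg$baseline_level))
      }
      out[[length(out) + 1L]] <- new_spectrum(
        mz = jit(mzv) * cal, intensity = intv, ms_level = 1L,
        run_id = run_id, scan_id = sprintf("ms1_%04d", scan_num), rt = rt)
    }
    if (ms2) {
      for (i in seq_len(nrow(pf))) {
        pk <- .render_ms2_peaks(pf[i, ], manifest$registry)
        mzv <- pk$mz; intv <- pk$intensity
        if (cfg$n_noise_peaks_ms2 > 0 && cfg$baseline_level > 0) {
          mzv <- c(mzv, stats::runif(cfg$n_noise_peaks_ms2, 100,
                                     max(pk$mz) + 100))
          intv <- c(intv, stats::rexp(cfg$n_noise_peaks_ms2,
                                      1 / (2 * cfg$baseline_level)))
        }
        prec <- jit(pf$mz[i]) * cal
        dt <- if (cfg$with_drift)
          predict_drift_time(pf$mz[i], pf$charge[i]) else NA_real_
        out[[length(out) + 1L]] <- new_spectrum(
          mz = jit(mzv) * cal, intensity = intv, ms_level = 2L,
          run_id = run_id,
          scan_id = paste0(run_id, "_", pf$id[i]),
          rt = pf$rt_apex[i], precursor_mz = prec,
          precursor_charge = pf$charge[i], drift_time = dt)
      }
    }
    out[order(vapply(out, `[[`, numeric(1), "rt"))]
  })
}

#' Render a complete dataset
#'
#' Either in memory (`dir = NULL`) or to files: per run an mzML (MS1 + MS2)
#' and an MGF (MS2 only), plus the panel FASTA, a run-manifest TSV, and the
#' planted truth as TSV.
#'
#' @param manifest From [generate_truth()].
#' @param dir Output directory, or NULL for an in-memory dataset.
#' @return A dataset list: `runs` (manifest table incl. file paths when
#'   written), `spectra` (named list of per-run spectra; in-memory mode
#'   only), `proteins`, `truth` (the manifest).
#' @export
render_dataset <- function(manifest, dir = NULL) {
  runs <- manifest$runs
  spectra <- lapply(runs$run_id, function(r) render_run(manifest, r))
  names(spectra) <- runs$run_id
  if (is.null(dir))
    return(list(runs = runs, spectra = spectra,
                proteins = manifest$proteins, truth = manifest))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs$path <- file.path(dir, paste0(runs$run_id, ".mzML"))
  for (k in seq_along(spectra)) {
    write_mzml(spectra[[k]], runs$path[k])
    ms2 <- Filter(function(s) s$ms_level == 2L, spectra[[k]])
    if (length(ms2))
      write_mgf(ms2, file.path(dir, paste0(runs$run_id[k], ".mgf")))
  }
  write_fasta(manifest$proteins, file.path(dir, "panel.fasta"))
  utils::write.table(runs, file.path(dir, "runs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(manifest$peptidoforms))
    utils::write.table(manifest$peptidoforms,
                       file.path(dir, "truth_peptidoforms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(manifest$areas, check.names = FALSE),
                     file.path(dir, "truth_areas.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE)
  list(runs = runs, spectra = spectra, proteins = manifest$proteins,
       truth = manifest, dir = dir)
}
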