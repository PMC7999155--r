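#' @title Pipeline orchestration
#' @description Ties the stages together: lock-mass recalibration, reporter
#'   triage, two-pass database search, peptide-level FDR, precursor-error
#'   modelling, EIC quantitation, six-criterion validation, and recovery /
#'   enrichment summaries.
#' @name pipeline
NULL

#' Default run configuration
#'
#' @param ... Named overrides. Defaults: precursor tolerance 15 ppm (the
#'   typical +/-2 SD band; the candidate gate is 3x), fragment and reporter
#'   tolerances 20 ppm, 5% peptide FDR, fixed carbamidomethylation, at most
#'   3 variable modifications, up to 3 missed cleavages, peptide length
#'   6-45, semi-tryptic search on, TOF resolving power 20000 with 3
#'   isotopes, A/B quantifiability gate 10, CV threshold 20%, reporter
#'   intensity floor 1% of base peak, ion-mobility resolving power 15.
#' @return Named list.
#' @export
default_config <- function(...) {
  cfg <- list(
    prec_tol_ppm = 15, frag_tol_ppm = 20, reporter_tol_ppm = 20,
    reporter_floor = 0.01,
    fdr_threshold = 0.05,
    cam_mode = "fixed", max_variable_mods = 3L,
    max_missed = 3L, min_length = 6L, max_length = 45L, semi = TRUE,
    placement_cap = 30L,
    resolving_power = 20000, n_isotopes = 3L,
    rt_half_window = 0.5, ab_quant_threshold = 10, min_ab_ratio = 3,
    cv_threshold = 20, im_resolving_power = 15,
    lockmass_mz = 785.843, lockmass_tol = 0.5,
    error_model_floor = 0.5, error_model_min_n = 10L
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a rendered dataset from disk
#'
#' Reads the run manifest, the per-run spectra (mzML), and the FASTA panel
#' written by [render_dataset()].
#'
#' @param dir Dataset directory.
#' @return Dataset list (`runs`, `spectra`, `proteins`), as used by
#'   [run_pipeline()].
#' @export
load_dataset <- function(dir) {
  runs <- read_run_manifest(file.path(dir, "runs.tsv"))
  spectra <- lapply(seq_len(nrow(runs)), function(i) {
    p <- runs$path[i]
    if (!file.exists(p)) p <- file.path(dir, basename(p))
    read_spectra(p, run_id = runs$run_id[i])
  })
  names(spectra) <- runs$run_id
  list(runs = runs, spectra = spectra,
       proteins = read_fasta(file.path(dir, "panel.fasta")))
}

#' Run the full identification / validation / quantitation pipeline
#'
#' @param dataset Dataset list (`runs`, `spectra`, `proteins`) from
#'   [render_dataset()] or [load_dataset()].
#' @param config From [default_config()].
#' @param registry Modification registry.
#' @param quantify Extract and integrate EICs and evaluate criteria 1-2
#'   (default TRUE; requires MS1 spectra).
#' @return List: `triage`, `psms`, `fdr` (list with `peptides`,
#'   `all_peptides`), `error_model`, `features`, `recovery`, `verdicts`,
#'   `config`.
#' @export
run_pipeline <- function(dataset, config = default_config(),
                         registry = arp_registry(), quantify = TRUE) {
  runs <- dataset$runs
  spectra <- dataset$spectra
  # lock-mass recalibration per run (skipped when the reference is absent)
  for (r in names(spectra)) {
    obs <- estimate_lockmass(spectra[[r]], config$lockmass_mz,
                             config$lockmass_tol)
    if (is.finite(obs))
      spectra[[r]] <- lockmass_recalibrate(spectra[[r]], obs,
                                           config$lockmass_mz,
                                           config$lockmass_tol)
  }
  all_spec <- do.call(c, unname(spectra))
  tri <- triage_spectra(all_spec, tol_ppm = config$reporter_tol_ppm,
                        min_rel_intensity = config$reporter_floor)
  psms <- search_spectra(all_spec, dataset$proteins, registry, config)
  if (!nrow(psms)) stop("search produced no PSMs")
  fdr <- fdr_filter(psms, config$fdr_threshold)
  targets1 <- psms[psms$rank == 1L & !psms$is_decoy, , drop = FALSE]
  em <- fit_error_model(targets1, min_n = min(config$error_model_min_n,
                                              nrow(targets1)),
                        sd_floor = config$error_model_floor)
  features <- NULL
  recovery <- NULL
  if (quantify) {
    # quantify every retained peptidoform in every run, at the RT of its
    # identifying scan
    peps <- fdr$peptides
    if (nrow(peps)) {
      scan_rt <- vapply(all_spec, function(s)
        if (s$ms_level == 2L) s$rt else NA_real_, numeric(1))
      names(scan_rt) <- vapply(all_spec, `[[`, character(1), "scan_id")
      targets <- data.frame(
        peptidoform = peps$label,
        mz = mz_from_mass(peps$neutral_mass, peps$charge),
        charge = peps$charge,
        rt = unname(scan_rt[peps$scan_id]),
        stringsAsFactors = FALSE)
      feats <- lapply(seq_len(nrow(runs)), function(j) {
        ms1 <- Filter(function(s) s$ms_level == 1L,
                      spectra[[runs$run_id[j]]])
        if (!length(ms1)) return(NULL)
        f <- quantify_run(ms1, targets, run_id = runs$run_id[j],
                          rt_half_window = config$rt_half_window,
                          resolving_power = config$resolving_power,
                          n_isotopes = config$n_isotopes)
        f$fraction <- runs$fraction[j]
        f$replicate <- runs$replicate[j]
        f
      })
      features <- do.call(rbind, feats)
      if (!is.null(features) &&
          all(c("enriched", "non_enriched") %in% features$fraction)) {
        load_enr <- runs$load[runs$fraction == "enriched"][1]
        load_non <- runs$load[runs$fraction == "non_enriched"][1]
        recovery <- recovery_table(features, load_enr, load_non,
                                   config$ab_quant_threshold)
      }
    }
  }
  verdicts <- if (nrow(fdr$peptides))
    validate_peptides(fdr$peptides, tri, features, em,
                      min_ab_ratio = config$min_ab_ratio)
  else NULL
  list(triage = tri, psms = psms, fdr = fdr, error_model = em,
       features = features, recovery = recovery, verdicts = verdicts,
       config = config)
}

#' Write pipeline result tables
#'
#' @param result From [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) if (!is.null(x) && nrow(x))
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(result$triage, "triage.tsv")
  wr(result$psms, "psms.tsv")
  wr(result$fdr$all_peptides, "peptides_all.tsv")
  wr(result$fdr$peptides, "peptides_passing.tsv")
  wr(result$features, "features.tsv")
  wr(result$recovery, "recovery.tsv")
  wr(result$verdicts, "verdicts.tsv")
  jsonlite::write_json(result$error_model,
                       file.path(dir, "error_model.json"), auto_unbox = TRUE)
  invisible(dir)
}
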