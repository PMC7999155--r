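#' @title Six-criterion confidence classification
#' @description Applies the confidence criteria to proposed ARP peptides:
#'   (1) resolved chromatographic peak in the enriched fractions,
#'   (2) higher relative intensity in enriched than non-enriched fractions,
#'   (3) ARP reporter ions present in the tandem mass spectrum,
#'   (4) peptide sequence coverage above 50%,
#'   (5) fragment ions confirming the modification site, and
#'   (6) precursor error within +/-2 standard deviations of the dataset
#'   error mean.
#'   Peptides failing only among criteria 5-6 are ambiguous; any other
#'   failure rejects. Also resolves isobaric / multi-PTM assignment
#'   ambiguities by re-scoring alternatives against the spectrum.
#' @name validate
NULL

#' Robust precursor-error model
#'
#' Median and MAD-based standard deviation (1.4826 x MAD) of the precursor
#' errors of a PSM population. A floor of `sd_floor` ppm avoids a degenerate
#' band when all errors coincide.
#'
#' @param errors_ppm Numeric vector of precursor errors in ppm, or a PSM
#'   data.frame with a `precursor_error_ppm` column.
#' @param min_n Minimum number of PSMs (default 10).
#' @param sd_floor Lower bound on the fitted SD in ppm (default 0.5).
#' @return List `mean_ppm`, `sd_ppm`, `n`.
#' @export
fit_error_model <- function(errors_ppm, min_n = 10L, sd_floor = 0.5) {
  if (is.data.frame(errors_ppm)) errors_ppm <- errors_ppm$precursor_error_ppm
  errors_ppm <- errors_ppm[is.finite(errors_ppm)]
  if (length(errors_ppm) < min_n)
    stop("need at least ", min_n, " PSMs to fit the error model (got ",
         length(errors_ppm), ")")
  m <- stats::median(errors_ppm)
  s <- max(1.4826 * stats::mad(errors_ppm, constant = 1), sd_floor)
  list(mean_ppm = m, sd_ppm = s, n = length(errors_ppm))
}

#' Apply the six confidence criteria to one proposed peptide
#'
#' Criteria 1-2 need chromatographic features from both fractions; when a
#' fraction is absent they are `not_evaluable` and excluded from the all-pass
#' requirement. Criterion 1 is operationalized as an enriched-fraction
#' feature with area/background >= `min_ab_ratio`. A chimera note is attached
#' when another precursor was observed within 2 m/z units at overlapping
#' retention time.
#'
#' @param psm One PSM row (from [search_spectra()], rank 1).
#' @param reporter One triage row for the same scan ([detect_reporters()]),
#'   or NULL.
#' @param feature_enriched,feature_non_enriched One-row feature data.frames
#'   for this peptidoform ([quantify_run()]), or NULL when the fraction was
#'   not measured.
#' @param error_model From [fit_error_model()].
#' @param min_ab_ratio Area/background floor for a "resolved" peak
#'   (default 3).
#' @param chimera Logical: another candidate precursor within 2 m/z units.
#' @return List with `criteria` (named `c1`..`c6`, values `pass`/`fail`/
#'   `not_evaluable`), `verdict` (`confident`/`ambiguous`/`rejected`) and
#'   `notes`.
#' @export
apply_criteria <- function(psm, reporter = NULL, feature_enriched = NULL,
                           feature_non_enriched = NULL, error_model,
                           min_ab_ratio = 3, chimera = FALSE) {
  crit <- c(c1 = "not_evaluable", c2 = "not_evaluable", c3 = "not_evaluable",
            c4 = "fail", c5 = "fail", c6 = "fail")
  notes <- character(0)
  if (!is.null(feature_enriched) && nrow(feature_enriched)) {
    ab <- feature_enriched$ab_ratio[1]  # Inf (zero background) passes
    crit["c1"] <- if (isTRUE(!is.na(ab) && ab >= min_ab_ratio))
      "pass" else "fail"
    if (!is.null(feature_non_enriched) && nrow(feature_non_enriched)) {
      crit["c2"] <- if (feature_enriched$area[1] >
                        feature_non_enriched$area[1]) "pass" else "fail"
    }
  }
  if (!is.null(reporter) && nrow(reporter))
    crit["c3"] <- if (isTRUE(reporter$is_candidate[1])) "pass" else "fail"
  crit["c4"] <- if (isTRUE(psm$coverage > 0.5)) "pass" else "fail"
  crit["c5"] <- if (isTRUE(as.logical(psm$site_confirmed))) "pass" else "fail"
  dev <- abs(psm$precursor_error_ppm - error_model$mean_ppm)
  crit["c6"] <- if (isTRUE(dev <= 2 * error_model$sd_ppm)) "pass" else "fail"
  if (chimera) notes <- c(notes, "chimeric coelution within 2 m/z units")
  hard <- crit[c("c1", "c2", "c3", "c4")]
  soft <- crit[c("c5", "c6")]
  verdict <- if (any(hard == "fail")) "rejected"
  else if (all(soft == "pass")) "confident"
  else "ambiguous"
  list(criteria = crit, verdict = verdict, notes = notes)
}

#' Validate a table of FDR-passing peptides
#'
#' Joins PSMs with reporter evidence and per-fraction features, fits nothing
#' (the error model is supplied), and returns one verdict row per peptide.
#'
#' @param peptides Retained peptide PSM rows ([fdr_filter()]`$peptides`).
#' @param reporters Triage table ([triage_spectra()]).
#' @param features Feature table with `peptidoform`, `fraction`, `area`,
#'   `ab_ratio` columns (means across replicates are taken per fraction), or
#'   NULL.
#' @param error_model From [fit_error_model()].
#' @param min_ab_ratio See [apply_criteria()].
#' @return data.frame: peptide label, criteria `c1`..`c6`, `verdict`, `notes`.
#' @export
validate_peptides <- function(peptides, reporters = NULL, features = NULL,
                              error_model, min_ab_ratio = 3) {
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    rep_row <- if (!is.null(reporters))
      reporters[reporters$scan_id == p$scan_id &
                  reporters$run_id == p$run_id, , drop = FALSE] else NULL
    fe <- fn <- NULL
    chim <- FALSE
    if (!is.null(features) && nrow(features)) {
      f <- features[features$peptidoform == p$label, , drop = FALSE]
      agg <- function(fr) {
        x <- f[f$fraction == fr, , drop = FALSE]
        if (!nrow(x)) return(NULL)
        data.frame(area = mean(x$area), ab_ratio = mean(x$ab_ratio))
      }
      fe <- agg("enriched"); fn <- agg("non_enriched")
      if ("chimera" %in% names(f)) chim <- any(f$chimera)
    }
    v <- apply_criteria(p, rep_row, fe, fn, error_model,
                        min_ab_ratio = min_ab_ratio, chimera = chim)
    out <- data.frame(peptidoform = p$label, scan_id = p$scan_id,
                      run_id = p$run_id, stringsAsFactors = FALSE)
    for (k in names(v$criteria)) out[[k]] <- v$criteria[[k]]
    out$verdict <- v$verdict
    out$notes <- paste(v$notes, collapse = "; ")
    out
  })
  do.call(rbind, rows)
}

#' Resolve an isobaric / multi-PTM assignment ambiguity
#'
#' Re-scores each alternative peptidoform against the spectrum and prefers
#' the one whose site-discriminating ions (theoretical fragments whose m/z is
#' unique to that alternative) are matched. If no alternative matches any of
#' its discriminating ions, all are reported ambiguous.
#'
#' @param spectrum The MS2 `arp_spectrum`.
#' @param alternatives List of `peptidoform` objects, isobaric within the
#'   precursor tolerance.
#' @param registry Modification registry.
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @return List: `best` (chosen peptidoform or NULL), `ambiguous` (logical),
#'   `records` data.frame with per-alternative score, matched discriminating
#'   ions, and decision.
#' @export
resolve_modification_ambiguity <- function(spectrum, alternatives,
                                           registry = arp_registry(),
                                           frag_tol_ppm = 20) {
  stopifnot(length(alternatives) >= 1)
  if (length(alternatives) == 1L)
    return(list(best = alternatives[[1]], ambiguous = FALSE,
                records = data.frame(label = alternatives[[1]]$label,
                                     score = NA_real_, n_discriminating = 0L,
                                     matched_discriminating = 0L,
                                     chosen = TRUE,
                                     stringsAsFactors = FALSE)))
  psms <- lapply(alternatives, function(p)
    match_spectrum(spectrum, p, registry, frag_tol_ppm = frag_tol_ppm))
  theo <- lapply(alternatives, function(p)
    theoretical_fragments(p, registry))
  round_mz <- function(x) round(x, 3)
  all_sets <- lapply(theo, function(t) unique(round_mz(t$mz)))
  n_alt <- length(alternatives)
  recs <- lapply(seq_len(n_alt), function(i) {
    others <- unique(unlist(all_sets[-i]))
    mine <- all_sets[[i]]
    disc <- setdiff(mine, others)
    matched <- round_mz(psms[[i]]$matches$mz)
    data.frame(label = alternatives[[i]]$label, score = psms[[i]]$score,
               n_discriminating = length(disc),
               matched_discriminating = sum(matched %in% disc),
               chosen = FALSE, stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (all(recs$matched_discriminating == 0))
    return(list(best = NULL, ambiguous = TRUE, records = recs))
  ord <- order(-recs$matched_discriminating, -recs$score)
  recs$chosen[ord[1]] <- TRUE
  list(best = alternatives[[ord[1]]], ambiguous = FALSE, records = recs)
}
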