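#' @title Reporter-ion spectrum triage
#' @description Screens MS/MS spectra for the ARP diagnostic ions (biotin
#'   fragment m/z 227.085, ARP fragment 299.117, protonated ARP 332.139) to
#'   flag candidate ARP-peptide spectra. Triage is advisory: non-candidate
#'   spectra are still searched, and the reporter evidence feeds the
#'   confidence criteria.
#' @name triage
NULL

.REPORTERS <- c(biotin = 227.085, arp_fragment = 299.117,
                arp_protonated = 332.139)

#' Detect ARP reporter ions in one MS/MS spectrum
#'
#' For each reporter the nearest peak within `tol_ppm` is recorded. The
#' spectrum is a candidate ARP spectrum when the 227.085 biotin ion is found
#' at or above `min_rel_intensity` of the base peak.
#'
#' @param spectrum An MS2 `arp_spectrum`.
#' @param tol_ppm Matching tolerance in ppm (default 20).
#' @param min_rel_intensity Candidate floor as a fraction of the base peak
#'   (default 0.01).
#' @return One-row data.frame: per reporter the observed m/z, ppm error and
#'   relative intensity (NA when absent), plus `is_candidate`.
#' @export
detect_reporters <- function(spectrum, tol_ppm = 20, min_rel_intensity = 0.01) {
  stopifnot(spectrum$ms_level == 2L)
  base <- if (length(spectrum$intensity)) max(spectrum$intensity) else NA_real_
  out <- list(scan_id = spectrum$scan_id, run_id = spectrum$run_id)
  found_biotin_rel <- NA_real_
  for (nm in names(.REPORTERS)) {
    target <- .REPORTERS[[nm]]
    obs <- NA_real_; err <- NA_real_; rel <- NA_real_
    if (length(spectrum$mz)) {
      i <- which.min(abs(spectrum$mz - target))
      e <- ppm_error(spectrum$mz[i], target)
      if (abs(e) <= tol_ppm) {
        obs <- spectrum$mz[i]; err <- e
        rel <- spectrum$intensity[i] / base
      }
    }
    if (nm == "biotin") found_biotin_rel <- rel
    out[[paste0(nm, "_mz")]] <- obs
    out[[paste0(nm, "_ppm")]] <- err
    out[[paste0(nm, "_rel")]] <- rel
  }
  out$is_candidate <- isTRUE(!is.na(found_biotin_rel) &&
                               found_biotin_rel >= min_rel_intensity)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Triage a set of spectra
#'
#' @param spectra List of `arp_spectrum` objects (MS1 entries are ignored).
#' @inheritParams detect_reporters
#' @return data.frame, one row per MS2 spectrum (see [detect_reporters()]).
#' @export
triage_spectra <- function(spectra, tol_ppm = 20, min_rel_intensity = 0.01) {
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  do.call(rbind, lapply(ms2, detect_reporters, tol_ppm = tol_ppm,
                        min_rel_intensity = min_rel_intensity))
}
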