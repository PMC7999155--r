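#' @title Peptide-spectrum matching and scoring
#' @description Matches theoretical fragments to observed peaks (nearest peak
#'   within a ppm tolerance, one peak per fragment), computes backbone
#'   sequence coverage, modification-site localization, precursor error, and
#'   a transparent tail-probability score.
#' @name psm_match
NULL

#' Match one spectrum against one peptidoform
#'
#' Each theoretical fragment is assigned its nearest observed peak within
#' `frag_tol_ppm`; a peak satisfies at most one fragment and the smaller
#' absolute ppm error wins ties. Sequence coverage is the fraction of the
#' `length - 1` backbone bonds bracketed by at least one matched b or y ion.
#' The modification site is confirmed when the matched fragments confine the
#' mass shift to the modified residue (both flanking bonds covered, peptide
#' termini counting as boundaries).
#'
#' @param spectrum An MS2 `arp_spectrum`.
#' @param peptidoform A `peptidoform`.
#' @param registry Modification registry.
#' @param frag_tol_ppm Fragment tolerance in ppm (default 20).
#' @param prec_tol_ppm Precursor tolerance used for the generous candidate
#'   gate (3 x this value; default 15).
#' @param max_fragment_charge Highest fragment charge considered.
#' @return A `psm` list: `peptidoform`, `scan_id`, `run_id`, `charge`,
#'   `precursor_error_ppm`, `matches` (data.frame of matched fragments),
#'   `n_theoretical`, `n_matched`, `sequence_coverage`, `site_confirmed`,
#'   `score`, `matched_intensity_fraction`.
#' @export
match_spectrum <- function(spectrum, peptidoform, registry = arp_registry(),
                           frag_tol_ppm = 20, prec_tol_ppm = 15,
                           max_fragment_charge = 2L) {
  stopifnot(spectrum$ms_level == 2L)
  z <- spectrum$precursor_charge
  if (is.na(z)) stop("precursor charge unknown for scan ", spectrum$scan_id)
  theo_mz <- mz_from_mass(peptidoform$neutral_mass, z)
  prec_err <- ppm_error(spectrum$precursor_mz, theo_mz)
  frags <- theoretical_fragments(peptidoform, registry,
                                 max_fragment_charge = max_fragment_charge)
  nf <- nrow(frags)
  obs_mz <- spectrum$mz; obs_int <- spectrum$intensity
  matched_peak <- rep(NA_integer_, nf)
  matched_ppm <- rep(NA_real_, nf)
  if (length(obs_mz) && nf) {
    i <- findInterval(frags$mz, obs_mz)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(obs_mz))
    d_lo <- abs(obs_mz[lo] - frags$mz); d_hi <- abs(obs_mz[hi] - frags$mz)
    nearest <- ifelse(d_lo <= d_hi, lo, hi)
    perr <- ppm_error(obs_mz[nearest], frags$mz)
    ok <- abs(perr) <= frag_tol_ppm
    # one peak per fragment, smallest |ppm| first
    ord <- order(abs(perr))
    used <- logical(length(obs_mz))
    for (j in ord) {
      if (!ok[j]) next
      pk <- nearest[j]
      if (used[pk]) next
      used[pk] <- TRUE
      matched_peak[j] <- pk
      matched_ppm[j] <- perr[j]
    }
  }
  hit <- !is.na(matched_peak)
  matches <- cbind(frags[hit, , drop = FALSE],
                   observed_mz = obs_mz[matched_peak[hit]],
                   intensity = obs_int[matched_peak[hit]],
                   ppm = matched_ppm[hit])
  n <- nchar(peptidoform$sequence)
  bonds_hit <- unique(c(
    matches$index[matches$series == "b"],
    n - matches$index[matches$series == "y"]
  ))
  bonds_hit <- bonds_hit[bonds_hit >= 1 & bonds_hit <= n - 1]
  coverage <- if (n > 1) length(bonds_hit) / (n - 1) else 0
  boundaries <- c(0L, n, bonds_hit)
  md <- peptidoform$mods
  arp_sites <- if (nrow(md)) {
    prof <- registry$profile[match(md$id, registry$id)]
    md$pos[is.na(prof) | prof != "NONE"]
  } else integer(0)
  site_confirmed <- length(arp_sites) > 0 &&
    all(vapply(arp_sites, function(p)
      ((p - 1L) %in% boundaries) && (p %in% boundaries), logical(1)))
  if (!length(arp_sites)) site_confirmed <- NA
  mif <- if (sum(obs_int) > 0) sum(matches$intensity) / sum(obs_int) else 0
  sc <- score_psm(n_matched = sum(hit), n_theoretical = nf,
                  n_peaks = length(obs_mz),
                  mz_range = if (length(obs_mz) > 1) diff(range(obs_mz)) else 1,
                  mean_mz = if (length(obs_mz)) mean(obs_mz) else 500,
                  frag_tol_ppm = frag_tol_ppm,
                  matched_intensity_fraction = mif)
  structure(list(
    peptidoform = peptidoform, scan_id = spectrum$scan_id,
    run_id = spectrum$run_id, charge = z,
    precursor_error_ppm = prec_err, matches = matches,
    n_theoretical = nf, n_matched = sum(hit),
    sequence_coverage = coverage, site_confirmed = site_confirmed,
    matched_intensity_fraction = mif, score = sc
  ), class = "psm")
}

#' Tail-probability PSM score
#'
#' `-log10` of the binomial tail probability of matching at least `n_matched`
#' of `n_theoretical` fragments by chance, where the chance of a random
#' fragment landing on some peak follows from the observed peak density and
#' the matching window width, plus a bonus equal to the fraction of total
#' peak intensity carried by matched peaks. Zero matches score 0; the score
#' is deterministic in its inputs.
#'
#' @param n_matched,n_theoretical Matched and total theoretical fragments.
#' @param n_peaks Number of observed peaks.
#' @param mz_range Observed m/z span.
#' @param mean_mz Mean observed m/z (sets the ppm window width in Da).
#' @param frag_tol_ppm Fragment tolerance in ppm.
#' @param matched_intensity_fraction Fraction of total intensity matched.
#' @return Non-negative numeric score.
#' @export
score_psm <- function(n_matched, n_theoretical, n_peaks, mz_range, mean_mz,
                      frag_tol_ppm, matched_intensity_fraction = 0) {
  if (n_matched <= 0 || n_theoretical <= 0) return(0)
  width <- 2 * frag_tol_ppm * 1e-6 * mean_mz
  p <- min(0.99, max(1e-9, n_peaks * width / max(mz_range, width)))
  tail <- stats::pbinom(n_matched - 1L, n_theoretical, p, lower.tail = FALSE)
  -log10(max(tail, 1e-300)) + matched_intensity_fraction
}

#' @export
print.psm <- function(x, ...) {
  cat("<psm> scan ", x$scan_id, "  ", x$peptidoform$label, " (", x$charge,
      "+)\n  score ", sprintf("%.2f", x$score), "  matched ", x$n_matched,
      "/", x$n_theoretical, "  coverage ",
      sprintf("%.0f%%", 100 * x$sequence_coverage),
      "  precursor ", sprintf("%+.1f ppm", x$precursor_error_ppm),
      "  site ", ifelse(is.na(x$site_confirmed), "n/a",
                        ifelse(x$site_confirmed, "confirmed", "unconfirmed")),
      "\n", sep = "")
  invisible(x)
}
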