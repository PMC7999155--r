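#' @title Spectrum container and MS data IO
#' @description Centroided spectra as light S3 objects, reading/writing mzML
#'   (via mzR) and MGF, run manifests, and multiplicative lock-mass
#'   recalibration against the m/z 785.843 reference.
#' @name spectra_io
NULL

#' Construct a centroided spectrum
#'
#' Peaks are sorted ascending by m/z; duplicate m/z values within a spectrum
#' are merged by intensity sum with a warning.
#'
#' @param mz,intensity Numeric peak vectors (same length, intensity >= 0).
#' @param ms_level 1 or 2.
#' @param run_id,scan_id Identifiers.
#' @param rt Retention time in minutes.
#' @param precursor_mz,precursor_charge Precursor (MS2 only; charge may be NA).
#' @param drift_time Ion-mobility drift time in ms, or NA.
#' @return An `arp_spectrum` object.
#' @export
new_spectrum <- function(mz, intensity, ms_level, run_id = "run1",
                         scan_id = NA_character_, rt = NA_real_,
                         precursor_mz = NA_real_, precursor_charge = NA_integer_,
                         drift_time = NA_real_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0),
            ms_level %in% c(1L, 2L))
  if (ms_level == 2L && is.na(precursor_mz))
    stop("MS2 spectrum requires a precursor m/z")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    warning("duplicate m/z values merged in scan ", scan_id)
    agg <- rowsum(intensity, group = mz)
    mz <- as.numeric(rownames(agg)); intensity <- as.numeric(agg)
  }
  structure(list(
    run_id = run_id, scan_id = scan_id, ms_level = as.integer(ms_level),
    rt = rt, precursor_mz = precursor_mz,
    precursor_charge = as.integer(precursor_charge),
    drift_time = drift_time, mz = mz, intensity = intensity
  ), class = "arp_spectrum")
}

#' @export
print.arp_spectrum <- function(x, ...) {
  cat("<spectrum> run ", x$run_id, " scan ", x$scan_id, " MS", x$ms_level,
      "  rt ", sprintf("%.3f", x$rt), " min  ", length(x$mz), " peaks",
      sep = "")
  if (x$ms_level == 2L)
    cat("  precursor ", sprintf("%.4f", x$precursor_mz), " (",
        ifelse(is.na(x$precursor_charge), "?", x$precursor_charge), "+)",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Read centroided spectra from mzML or MGF
#'
#' Format is chosen by extension (`.mzML` via mzR, `.mgf` via the built-in
#' codec). Spectra are returned in file order with peak invariants enforced.
#' MGF carries MS2 only; mzML carries both levels plus optional drift times.
#'
#' @param path File path.
#' @param run_id Run identifier attached to every spectrum (defaults to the
#'   file base name).
#' @return List of `arp_spectrum` objects (possibly empty, with a warning).
#' @export
read_spectra <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(run_id))
    run_id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "mgf") return(.read_mgf(path, run_id))
  if (ext %in% c("mzml", "mzxml")) return(.read_mzml(path, run_id))
  stop("unsupported spectrum format: .", ext, " (use mzML or MGF)")
}

.read_mzml <- function(path, run_id) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (!nrow(hd)) {
    warning("no spectra in ", path)
    return(list())
  }
  if (!is.null(hd$centroided) && any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra in ", path, ": centroided data required")
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(nrow(hd)), function(i) {
    p <- pk[[i]]
    dt <- if ("ionMobilityDriftTime" %in% names(hd))
      hd$ionMobilityDriftTime[i] else NA_real_
    new_spectrum(
      mz = p[, 1], intensity = p[, 2], ms_level = hd$msLevel[i],
      run_id = run_id, scan_id = as.character(hd$acquisitionNum[i]),
      rt = hd$retentionTime[i] / 60,
      precursor_mz = if (hd$msLevel[i] == 2L) hd$precursorMZ[i] else NA_real_,
      precursor_charge = if (hd$msLevel[i] == 2L && !is.na(hd$precursorCharge[i])
                             && hd$precursorCharge[i] > 0)
        hd$precursorCharge[i] else NA_integer_,
      drift_time = dt
    )
  })
}

.read_mgf <- function(path, run_id) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) {
    warning("empty MGF file: ", path)
    return(list())
  }
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF (unbalanced BEGIN/END IONS): ", path)
  if (!length(begins)) {
    warning("no spectra in ", path)
    return(list())
  }
  out <- vector("list", length(begins))
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*$", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    getv <- function(key) if (key %in% keys) vals[match(key, keys)] else NA
    pep <- getv("PEPMASS")
    if (is.na(pep)) stop("MGF spectrum ", k, " lacks PEPMASS in ", path)
    pep_fields <- strsplit(trimws(pep), "\\s+")[[1]]
    prec_mz <- as.numeric(pep_fields[1])
    charge <- getv("CHARGE")
    z <- if (!is.na(charge)) as.integer(sub("\\+$", "", charge))
    else if (length(pep_fields) >= 2) as.integer(pep_fields[2])
    else NA_integer_
    rt_s <- suppressWarnings(as.numeric(getv("RTINSECONDS")))
    title <- getv("TITLE")
    dt <- suppressWarnings(as.numeric(getv("ION_MOBILITY")))
    pk_lines <- block[!kv]
    pk_lines <- pk_lines[nzchar(trimws(pk_lines))]
    if (length(pk_lines)) {
      pkm <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "\\s+"),
                                   function(x) as.numeric(x[1:2])))
      if (anyNA(pkm)) stop("malformed peak line in MGF spectrum ", k,
                           " of ", path)
    } else pkm <- matrix(numeric(0), ncol = 2)
    out[[k]] <- new_spectrum(
      mz = pkm[, 1], intensity = pkm[, 2], ms_level = 2L, run_id = run_id,
      scan_id = if (!is.na(title)) title else as.character(k),
      rt = if (is.na(rt_s)) NA_real_ else rt_s / 60,
      precursor_mz = prec_mz, precursor_charge = z, drift_time = dt
    )
  }
  out
}

#' Write MS2 spectra to MGF
#'
#' Emits TITLE, RTINSECONDS, PEPMASS, CHARGE (and ION_MOBILITY when drift
#' times are present). MS1 spectra are skipped with a warning.
#'
#' @param spectra List of `arp_spectrum` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  if (length(ms2) < length(spectra))
    warning("skipping ", length(spectra) - length(ms2), " MS1 spectra (MGF is MS2-only)")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (s in ms2) {
    hdr <- c("BEGIN IONS",
             paste0("TITLE=", s$scan_id),
             if (!is.na(s$rt)) paste0("RTINSECONDS=", format(s$rt * 60, digits = 10)),
             paste0("PEPMASS=", format(s$precursor_mz, digits = 12)),
             if (!is.na(s$precursor_charge)) paste0("CHARGE=", s$precursor_charge, "+"),
             if (!is.na(s$drift_time)) paste0("ION_MOBILITY=", format(s$drift_time, digits = 8)))
    writeLines(hdr, con)
    if (length(s$mz))
      writeLines(paste(format(s$mz, digits = 12, trim = TRUE, scientific = FALSE),
                       format(s$intensity, digits = 8, trim = TRUE,
                              scientific = FALSE)), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Write spectra to mzML
#'
#' Serializes MS1 and MS2 spectra through mzR (ProteoWizard backend),
#' preserving retention times, precursors, and drift times.
#'
#' @param spectra List of `arp_spectrum` objects.
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  n <- length(spectra)
  stopifnot(n > 0)
  pk <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  ms1_idx <- 0L
  prec_scan <- integer(n)
  for (i in seq_len(n)) {
    if (spectra[[i]]$ms_level == 1L) ms1_idx <- i
    prec_scan[i] <- if (spectra[[i]]$ms_level == 2L) ms1_idx else 0L
  }
  num <- function(f) vapply(spectra, function(s) {
    v <- s[[f]]; if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  lvl <- vapply(spectra, function(s) s$ms_level, integer(1))
  npk <- vapply(spectra, function(s) length(s$mz), integer(1))
  tic <- vapply(spectra, function(s) sum(s$intensity), numeric(1))
  bp <- function(f) vapply(spectra, function(s) {
    if (!length(s$mz)) return(NA_real_)
    f(s)
  }, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = 1L, peaksCount = npk, totIonCurrent = tic,
    retentionTime = num("rt") * 60,
    basePeakMZ = bp(function(s) s$mz[which.max(s$intensity)]),
    basePeakIntensity = bp(function(s) max(s$intensity)),
    collisionEnergy = ifelse(lvl == 2L, 30, 0),
    ionisationEnergy = 0, lowMZ = bp(function(s) min(s$mz)),
    highMZ = bp(function(s) max(s$mz)),
    precursorScanNum = prec_scan,
    precursorMZ = ifelse(lvl == 2L, num("precursor_mz"), 0),
    precursorCharge = ifelse(lvl == 2L & !is.na(num("precursor_charge")),
                             as.integer(num("precursor_charge")), 0L),
    precursorIntensity = ifelse(lvl == 2L, 100, 0),
    mergedScan = 0L, mergedResultScanNum = 0L, mergedResultStartScanNum = 0L,
    mergedResultEndScanNum = 0L, injectionTime = 0,
    filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = num("drift_time"),
    isolationWindowTargetMZ = ifelse(lvl == 2L, num("precursor_mz"), NA_real_),
    isolationWindowLowerOffset = ifelse(lvl == 2L, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(lvl == 2L, 1, NA_real_),
    scanWindowLowerLimit = 50, scanWindowUpperLimit = 5000,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read a run manifest
#'
#' TSV with columns `run_id`, `path`, `fraction` (`enriched` or
#' `non_enriched`), `replicate`, `load` (on-column load in consistent mass
#' units, e.g. µg).
#'
#' @param path Manifest TSV path.
#' @return Validated data.frame.
#' @export
read_run_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "path", "fraction", "replicate", "load")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("run manifest missing column(s): ", paste(missing, collapse = ", "))
  if (any(!m$fraction %in% c("enriched", "non_enriched")))
    stop("fraction must be 'enriched' or 'non_enriched'")
  if (any(!is.finite(m$load) | m$load <= 0))
    stop("every run needs a positive load")
  m
}

#' Lock-mass recalibration
#'
#' Applies a single multiplicative factor `reference_mz / observed_reference`
#' to every peak and precursor m/z (a ppm-like TOF error model). With a
#' time-indexed table of observed reference values the factor is applied
#' piecewise-constant by retention time. Observed values farther than
#' `tolerance` from the reference leave the block uncorrected with a warning.
#'
#' @param spectra List of `arp_spectrum` objects.
#' @param observed_reference Single observed m/z of the reference, or a
#'   data.frame `rt_start`, `observed` (piecewise by retention time, minutes).
#' @param reference_mz Reference m/z (default 785.843).
#' @param tolerance Maximum |observed - reference| in Da (default 0.5).
#' @return Recalibrated spectra list.
#' @export
lockmass_recalibrate <- function(spectra, observed_reference,
                                 reference_mz = 785.843, tolerance = 0.5) {
  factor_for <- function(rt) {
    obs <- if (is.data.frame(observed_reference)) {
      tab <- observed_reference[order(observed_reference$rt_start), ]
      i <- findInterval(rt, tab$rt_start)
      tab$observed[max(i, 1L)]
    } else observed_reference
    if (!is.finite(obs) || abs(obs - reference_mz) > tolerance) {
      warning("observed reference ", obs, " outside +/-", tolerance,
              " Da of ", reference_mz, "; block left uncorrected")
      return(1)
    }
    reference_mz / obs
  }
  lapply(spectra, function(s) {
    f <- factor_for(s$rt)
    s$mz <- s$mz * f
    if (!is.na(s$precursor_mz)) s$precursor_mz <- s$precursor_mz * f
    s
  })
}

#' Estimate the observed lock-mass reference of a run
#'
#' Median m/z of the most intense MS1 peak within `tolerance` of the
#' reference across all MS1 scans that contain one.
#'
#' @param spectra List of `arp_spectrum` objects (one run).
#' @param reference_mz Reference m/z (default 785.843).
#' @param tolerance Search window in Da (default 0.5).
#' @return Observed reference m/z, or NA if never seen.
#' @export
estimate_lockmass <- function(spectra, reference_mz = 785.843,
                              tolerance = 0.5) {
  obs <- vapply(spectra, function(s) {
    if (s$ms_level != 1L || !length(s$mz)) return(NA_real_)
    sel <- abs(s$mz - reference_mz) <= tolerance
    if (!any(sel)) return(NA_real_)
    s$mz[sel][which.max(s$intensity[sel])]
  }, numeric(1))
  obs <- obs[is.finite(obs)]
  if (!length(obs)) return(NA_real_)
  stats::median(obs)
}

#' Summarize a spectra list
#'
#' @param spectra List of `arp_spectrum` objects.
#' @return data.frame with one row per spectrum (ids, level, rt, precursor,
#'   peak count, drift time).
#' @export
spectra_table <- function(spectra) {
  data.frame(
    run_id = vapply(spectra, `[[`, character(1), "run_id"),
    scan_id = vapply(spectra, `[[`, character(1), "scan_id"),
    ms_level = vapply(spectra, `[[`, integer(1), "ms_level"),
    rt = vapply(spectra, `[[`, numeric(1), "rt"),
    precursor_mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    precursor_charge = vapply(spectra, `[[`, integer(1), "precursor_charge"),
    n_peaks = vapply(spectra, function(s) length(s$mz), integer(1)),
    drift_time = vapply(spectra, `[[`, numeric(1), "drift_time"),
    stringsAsFactors = FALSE
  )
}
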