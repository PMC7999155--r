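#' @title Database search and target-decoy FDR
#' @description Two-pass database search over a mass-indexed peptide set.
#'   Pass 1 considers only the standard modifications (carbamidomethyl per
#'   the configured mode, Met oxidation); pass 2 re-searches unassigned scans
#'   with the full ARP registry. Candidates are generated by decomposing the
#'   precursor mass into an unmodified peptide mass plus a combination of at
#'   most `max_variable_mods` registry deltas, then enumerating site
#'   placements. Decoys are searched identically and drive peptide-level
#'   q-values.
#' @name search
NULL

.encode_mods <- function(md) {
  if (!nrow(md)) return("")
  paste(sprintf("%d:%s:%.6f", md$pos, md$id, md$delta), collapse = ";")
}

#' Decode a modification string
#'
#' Inverse of the `pos:id:delta;...` encoding used in PSM tables.
#' @param s Encoded string ("" for none).
#' @return data.frame `pos`, `id`, `delta`.
#' @export
decode_mods <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(pos = integer(), id = character(), delta = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(pos = vapply(parts, function(x) as.integer(x[1]), integer(1)),
             id = vapply(parts, `[`, character(1), 2),
             delta = vapply(parts, function(x) as.numeric(x[3]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Build a mass-indexed peptide set
#'
#' Digests targets and decoys, applies fixed carbamidomethylation when
#' configured, dedupes by (sequence, decoy status), and sorts by base mass.
#'
#' @param proteins Protein data.frame including decoys (see [make_decoys()]).
#' @param registry Modification registry.
#' @param max_missed,min_length,max_length,semi Digestion parameters.
#' @param cam_mode `"fixed"` or `"variable"`.
#' @return data.frame sorted by `base_mass`, with `n_fixed_cam` and
#'   `shared_with_target` columns.
#' @export
build_peptide_index <- function(proteins, registry, max_missed = 3L,
                                min_length = 6L, max_length = 45L,
                                semi = FALSE, cam_mode = "fixed") {
  peps <- digest_database(proteins, max_missed, min_length, max_length, semi)
  if (!nrow(peps)) stop("empty database after digestion")
  key <- paste(peps$sequence, peps$is_decoy)
  peps <- peps[!duplicated(key), , drop = FALSE]
  peps <- flag_shared_decoys(peps)
  cam_delta <- if (cam_mode == "fixed" && "cam" %in% registry$id)
    registry$delta_mass[registry$id == "cam"] else 0
  n_cys <- vapply(strsplit(peps$sequence, ""), function(a) sum(a == "C"),
                  integer(1))
  base <- vapply(peps$sequence, peptide_mass, numeric(1), USE.NAMES = FALSE)
  peps$n_fixed_cam <- if (cam_delta > 0) n_cys else 0L
  peps$base_mass <- base + peps$n_fixed_cam * cam_delta
  peps <- peps[order(peps$base_mass), , drop = FALSE]
  rownames(peps) <- NULL
  peps
}

# Multiset combinations of variable mod indices, sizes 0..max_n.
.mod_combos <- function(registry, max_n) {
  k <- nrow(registry)
  combos <- list(integer(0))
  if (max_n >= 1 && k)
    combos <- c(combos, lapply(seq_len(k), function(i) i))
  if (max_n >= 2 && k)
    for (i in seq_len(k)) for (j in i:k)
      combos[[length(combos) + 1L]] <- c(i, j)
  if (max_n >= 3 && k)
    for (i in seq_len(k)) for (j in i:k) for (l in j:k)
      combos[[length(combos) + 1L]] <- c(i, j, l)
  delta <- vapply(combos, function(ix) sum(registry$delta_mass[ix]), numeric(1))
  list(members = combos, delta = delta)
}

# Enumerate distinct-site placements of the mods in `ids` (registry row
# indices) over one peptide; returns list of mods data.frames.
.placements <- function(sequence, ids, registry, blocked = integer(0),
                        cap = 30L) {
  if (!length(ids)) return(list(data.frame(pos = integer(), id = character(),
                                           delta = numeric())))
  sites <- eligible_sites(sequence, registry[unique(ids), , drop = FALSE])
  sites <- sites[!sites$pos %in% blocked, , drop = FALSE]
  if (!nrow(sites)) return(list())
  out <- list()
  recur <- function(i, used, acc) {
    if (length(out) >= cap) return(invisible())
    if (i > length(ids)) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    id_i <- registry$id[ids[i]]
    cand <- sites[sites$id == id_i & !sites$pos %in% used, , drop = FALSE]
    if (i > 1 && ids[i] == ids[i - 1]) {
      prev <- acc$pos[nrow(acc)]
      cand <- cand[cand$pos > prev, , drop = FALSE] # break multiset symmetry
    }
    for (r in seq_len(nrow(cand)))
      recur(i + 1L, c(used, cand$pos[r]), rbind(acc, cand[r, , drop = FALSE]))
    invisible()
  }
  recur(1L, integer(0),
        data.frame(pos = integer(), id = character(), delta = numeric()))
  out
}

.psm_row <- function(psm, pep_row, pass, rank) {
  p <- psm$peptidoform
  data.frame(
    scan_id = psm$scan_id, run_id = psm$run_id, rank = rank,
    sequence = p$sequence, label = p$label, mods = .encode_mods(p$mods),
    protein = pep_row$protein, start = pep_row$start, end = pep_row$end,
    charge = psm$charge, is_decoy = pep_row$is_decoy,
    shared_with_target = pep_row$shared_with_target,
    neutral_mass = p$neutral_mass,
    precursor_error_ppm = psm$precursor_error_ppm,
    coverage = psm$sequence_coverage, score = psm$score,
    site_confirmed = psm$site_confirmed, n_matched = psm$n_matched,
    n_theoretical = psm$n_theoretical,
    matched_intensity_fraction = psm$matched_intensity_fraction,
    pass = pass, stringsAsFactors = FALSE
  )
}

#' Two-pass database search
#'
#' @param spectra List of `arp_spectrum` objects (MS1 entries ignored).
#' @param proteins Target protein data.frame; decoys are appended
#'   automatically unless already present.
#' @param registry Modification registry.
#' @param config Search configuration, see [default_config()]. Fields used:
#'   `prec_tol_ppm`, `frag_tol_ppm`, `max_variable_mods`, `cam_mode`,
#'   `max_missed`, `min_length`, `max_length`, `semi`, `placement_cap`.
#' @return data.frame of PSMs: per scan the best assignment (`rank` 1) and,
#'   when available, the runner-up (`rank` 2) for ambiguity resolution.
#'   Unassigned scans are absent.
#' @export
search_spectra <- function(spectra, proteins, registry = arp_registry(),
                           config = default_config()) {
  if (!any(!proteins$is_decoy)) stop("no target proteins")
  if (!any(proteins$is_decoy))
    proteins <- rbind(proteins, make_decoys(proteins))
  index <- build_peptide_index(
    proteins, registry, config$max_missed, config$min_length,
    config$max_length, config$semi, config$cam_mode)
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  keep <- vapply(ms2, function(s) !is.na(s$precursor_charge), logical(1))
  if (any(!keep))
    message("skipping ", sum(!keep), " MS2 scan(s) with unknown charge")
  ms2 <- ms2[keep]
  std_ids <- intersect(c("met_ox", if (config$cam_mode == "variable") "cam"),
                       registry$id)
  pass1_reg <- registry[registry$id %in% std_ids, , drop = FALSE]
  pass2_reg <- registry[registry$id != "cam" | config$cam_mode == "variable", ,
                        drop = FALSE]
  res1 <- .search_pass(ms2, index, pass1_reg, registry, config, pass = 1L)
  # a scan counts as assigned in pass 1 only when the match is substantive;
  # chance single-fragment hits must not shield a scan from the ARP pass
  assigned <- unique(res1$scan_id[res1$rank == 1L & res1$coverage >= 0.5 &
                                    res1$n_matched >= 5L])
  rest <- Filter(function(s) !s$scan_id %in% assigned, ms2)
  res2 <- .search_pass(rest, index, pass2_reg, registry, config, pass = 2L)
  out <- rbind(res1, res2)
  if (is.null(out) || !nrow(out)) return(data.frame())
  # where both passes proposed an assignment, keep the better-scoring pass
  best1 <- out[out$rank == 1L, c("scan_id", "pass", "score")]
  keep_pass <- vapply(split(best1, best1$scan_id), function(b)
    b$pass[which.max(b$score)], integer(1))
  out <- out[keep_pass[out$scan_id] == out$pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "decoys_searched") <- TRUE
  out
}

.search_pass <- function(ms2, index, var_registry, full_registry, config,
                         pass) {
  empty <- data.frame()
  if (!length(ms2)) return(empty)
  combos <- .mod_combos(var_registry, config$max_variable_mods)
  gate <- 3 * config$prec_tol_ppm
  masses <- index$base_mass
  rows <- list()
  for (s in ms2) {
    M <- mass_from_mz(s$precursor_mz, s$precursor_charge)
    tol <- gate * 1e-6 * M
    targets <- M - combos$delta
    lo <- findInterval(targets - tol, masses)
    hi <- findInterval(targets + tol, masses)
    cand_combo <- which(hi > lo)
    best <- NULL; second <- NULL; best_row <- NULL; second_row <- NULL
    for (ci in cand_combo) {
      ids <- combos$members[[ci]]
      for (pi in seq(lo[ci] + 1L, hi[ci])) {
        pep <- index[pi, ]
        blocked <- integer(0)
        fixed <- data.frame(pos = integer(), id = character(),
                            delta = numeric())
        if (pep$n_fixed_cam > 0) {
          cys <- which(strsplit(pep$sequence, "")[[1]] == "C")
          fixed <- data.frame(pos = cys, id = "cam",
                              delta = full_registry$delta_mass[
                                full_registry$id == "cam"],
                              stringsAsFactors = FALSE)
          blocked <- cys
        }
        placements <- .placements(pep$sequence, ids, var_registry,
                                  blocked = blocked,
                                  cap = config$placement_cap)
        for (pl in placements) {
          md <- rbind(fixed, pl)
          pf <- new_peptidoform(pep$sequence, md, protein = pep$protein,
                                start = pep$start, end = pep$end,
                                n_variable = nrow(pl))
          psm <- match_spectrum(s, pf, full_registry,
                                frag_tol_ppm = config$frag_tol_ppm,
                                prec_tol_ppm = config$prec_tol_ppm)
          if (psm$n_matched == 0) next
          better <- function(a, ar, b, br) {
            if (is.null(b)) return(TRUE)
            if (a$score != b$score) return(a$score > b$score)
            !ar$is_decoy && br$is_decoy # target wins score ties
          }
          if (better(psm, pep, best, best_row)) {
            if (!is.null(best) && best$peptidoform$label !=
                psm$peptidoform$label) {
              second <- best; second_row <- best_row
            }
            best <- psm; best_row <- pep
          } else if (psm$peptidoform$label != best$peptidoform$label &&
                     better(psm, pep, second, second_row)) {
            second <- psm; second_row <- pep
          }
        }
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- .psm_row(best, best_row, pass, 1L)
      if (!is.null(second))
        rows[[length(rows) + 1L]] <- .psm_row(second, second_row, pass, 2L)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Peptide-level target-decoy FDR filter
#'
#' Keeps the best PSM per peptidoform (sequence + modifications), ranks
#' peptides by score, estimates `q = decoys at or above score / targets at or
#' above score` (monotonized from the bottom), and retains target peptides
#' with `q <= q_threshold`. Decoy peptides whose sequence also occurs among
#' targets are excluded from the decoy count.
#'
#' @param psms PSM data.frame from [search_spectra()] (rank-1 rows are used).
#'   A hard error is raised when no decoy PSMs are present and the table does
#'   not carry [search_spectra()]'s decoys-searched provenance (i.e. FDR
#'   would be estimated against a decoy-free search).
#' @param q_threshold Peptide FDR threshold (default 0.05).
#' @return List with `peptides` (retained targets with `q_value`) and
#'   `all_peptides` (every competing peptide with its q-value).
#' @export
fdr_filter <- function(psms, q_threshold = 0.05) {
  stopifnot(nrow(psms) > 0)
  p <- psms[psms$rank == 1L, , drop = FALSE]
  if (!any(p$is_decoy) && !isTRUE(attr(psms, "decoys_searched")))
    stop("no decoy PSMs: FDR is undefined (search with decoys included)")
  if ("shared_with_target" %in% names(p))
    p <- p[!(p$is_decoy & p$shared_with_target), , drop = FALSE]
  # best PSM per peptidoform
  key <- paste(p$label, p$is_decoy)
  p <- p[order(-p$score), , drop = FALSE]
  p <- p[!duplicated(paste(p$label, p$is_decoy)), , drop = FALSE]
  dec <- cumsum(p$is_decoy)
  tar <- cumsum(!p$is_decoy)
  q <- ifelse(tar > 0, dec / tar, Inf)
  q <- rev(cummin(rev(q)))
  p$q_value <- q
  list(peptides = p[!p$is_decoy & p$q_value <= q_threshold, , drop = FALSE],
       all_peptides = p)
}
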