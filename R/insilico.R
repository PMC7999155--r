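#' @title In-silico digestion and peptidoform enumeration
#' @description Tryptic digestion of protein databases (K/R, not before P,
#'   protein termini count as cleavage sites), optional semi-specific
#'   peptides, enumeration of modified peptidoforms against a modification
#'   registry, and pseudo-reversed decoy construction for target-decoy FDR.
#' @name insilico
NULL

.CANONICAL_AA <- names(.RESIDUE_FORMULA)

#' Read a protein FASTA database
#'
#' Accession is the first whitespace-delimited token of the header; the rest
#' is the description. Sequences containing non-canonical letters (B, J, O,
#' U, X, Z, ...) are dropped with a warning. The `">DECOY_"` accession prefix
#' marks decoys.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `description`, `sequence`,
#'   `is_decoy`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  ok <- !grepl(paste0("[^", paste(.CANONICAL_AA, collapse = ""), "]"), seqs) &
    nzchar(seqs)
  if (any(!ok))
    warning("dropping ", sum(!ok), " sequence(s) with non-canonical residues: ",
            paste(utils::head(accession[!ok], 5), collapse = ", "))
  data.frame(accession = accession[ok], description = description[ok],
             sequence = unname(seqs[ok]),
             is_decoy = startsWith(accession[ok], "DECOY_"),
             stringsAsFactors = FALSE)
}

#' Write a protein FASTA database
#'
#' @param proteins data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nzchar(proteins$description),
                      paste(proteins$accession, proteins$description),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# 0-based cleavage boundaries for trypsin (after K/R not before P), including
# the protein termini.
.cleavage_sites <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[cut_after + 1L] != "P" |
                           cut_after == n]
  sort(unique(c(0L, cut_after, n)))
}

#' Tryptic digestion of one protein
#'
#' Cleaves C-terminal to K/R except before Pro; protein termini are treated
#' as valid cleavage sites. With `semi = TRUE`, peptides with exactly one
#' non-tryptic terminus are additionally emitted (every peptide then has at
#' least one tryptic terminus).
#'
#' @param sequence Protein sequence (or a one-row protein data.frame).
#' @param max_missed Maximum missed cleavage sites (default 3).
#' @param min_length,max_length Peptide length bounds (defaults 6 and 45).
#' @param semi Also emit semi-specific peptides (default FALSE).
#' @return data.frame with `sequence`, `start`, `end` (1-based, inclusive,
#'   protein coordinates), `missed_cleavages`, `nterm_tryptic`,
#'   `cterm_tryptic`.
#' @examples
#' digest("AKRG", max_missed = 1, min_length = 1)
#' @export
digest <- function(sequence, max_missed = 3L, min_length = 6L,
                   max_length = 45L, semi = FALSE) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty protein sequence")
  stopifnot(max_missed >= 0)
  sites <- .cleavage_sites(sequence)
  k <- length(sites)
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + 1L + max_missed)) {
      a <- sites[i]; b <- sites[j]
      len <- b - a
      mc <- j - i - 1L
      if (len >= min_length && len <= max_length) {
        rows[[length(rows) + 1L]] <- c(a + 1L, b, mc, 1L, 1L)
      }
      if (semi && a + min_length <= b - 1L) {
        # ragged C-terminus (tryptic N-terminus)
        for (b2 in seq(a + min_length, b - 1L)) {
          if (b2 - a > max_length) break
          if (b2 %in% sites) next
          mc2 <- sum(sites > a & sites < b2)
          if (mc2 > max_missed) break
          rows[[length(rows) + 1L]] <- c(a + 1L, b2, mc2, 1L, 0L)
        }
        # ragged N-terminus (tryptic C-terminus)
        for (a2 in seq(a + 1L, b - min_length)) {
          if (a2 > b - min_length) break
          if (b - a2 > max_length) next
          if (a2 %in% sites) next
          mc2 <- sum(sites > a2 & sites < b)
          rows[[length(rows) + 1L]] <- c(a2 + 1L, b, mc2, 0L, 1L)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      nterm_tryptic = logical(), cterm_tryptic = logical()))
  m <- do.call(rbind, rows)
  m <- unique(m)
  out <- data.frame(
    sequence = substring(sequence, m[, 1], m[, 2]),
    start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    missed_cleavages = as.integer(m[, 3]),
    nterm_tryptic = m[, 4] == 1L, cterm_tryptic = m[, 5] == 1L,
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$end), , drop = FALSE]
}

#' Digest a protein database
#'
#' Applies [digest()] to every protein and annotates peptides with their
#' protein accession and decoy status.
#'
#' @inheritParams digest
#' @param proteins Protein data.frame (see [read_fasta()]).
#' @return data.frame of peptides with `protein` and `is_decoy` columns.
#' @export
digest_database <- function(proteins, max_missed = 3L, min_length = 6L,
                            max_length = 45L, semi = FALSE) {
  pieces <- lapply(seq_len(nrow(proteins)), function(i) {
    d <- digest(proteins$sequence[i], max_missed, min_length, max_length, semi)
    if (nrow(d)) {
      d$protein <- proteins$accession[i]
      d$is_decoy <- proteins$is_decoy[i]
    } else {
      d$protein <- character(0); d$is_decoy <- logical(0)
    }
    d
  })
  do.call(rbind, pieces)
}

#' Eligible modification sites in a peptide
#'
#' @param sequence Peptide sequence.
#' @param registry Modification registry.
#' @return data.frame `pos`, `id`, `delta` of every allowed (site, mod) pair,
#'   honoring residue and positional (`nterm`/`cterm`) constraints.
#' @export
eligible_sites <- function(sequence, registry) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  rows <- list()
  for (r in seq_len(nrow(registry))) {
    res <- strsplit(registry$residues[r], "")[[1]]
    pos <- which(aa %in% res)
    pos <- switch(registry$position[r],
                  nterm = pos[pos == 1L],
                  cterm = pos[pos == n],
                  pos)
    if (length(pos))
      rows[[length(rows) + 1L]] <- data.frame(
        pos = pos, id = registry$id[r], delta = registry$delta_mass[r],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pos = integer(), id = character(), delta = numeric()))
  do.call(rbind, rows)
}

#' Enumerate modified peptidoforms of one peptide
#'
#' Cartesian assignment of registry modifications to eligible residues with
#' at most one modification per site and at most `max_variable_mods` variable
#' modifications. With `cam_mode = "fixed"`, carbamidomethyl is applied to
#' every Cys as a fixed modification and does not count as variable.
#'
#' @param sequence Peptide sequence (or one peptide row from [digest()]).
#' @param registry Modification registry.
#' @param max_variable_mods Maximum number of variable modifications.
#' @param cam_mode `"fixed"` or `"variable"` carbamidomethylation.
#' @param cap Maximum number of forms per peptide before erroring
#'   (default 10000).
#' @return List of peptidoforms; each is a list with `sequence`, `mods`
#'   (data.frame `pos`, `id`, `delta`), `n_variable`, `neutral_mass`, and a
#'   `label` in bracket notation (e.g. `LK[+312.089]C[+57.022]ASLQK`).
#' @export
enumerate_peptidoforms <- function(sequence, registry, max_variable_mods = 3L,
                                   cam_mode = c("fixed", "variable"),
                                   cap = 10000L) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  cam_mode <- match.arg(cam_mode)
  stopifnot(max_variable_mods >= 0)
  aa <- strsplit(sequence, "")[[1]]
  fixed <- data.frame(pos = integer(), id = character(), delta = numeric())
  var_registry <- registry
  if (cam_mode == "fixed" && "cam" %in% registry$id) {
    cys <- which(aa == "C")
    if (length(cys))
      fixed <- data.frame(pos = cys, id = "cam",
                          delta = registry$delta_mass[registry$id == "cam"],
                          stringsAsFactors = FALSE)
    var_registry <- registry[registry$id != "cam", , drop = FALSE]
  }
  sites <- eligible_sites(sequence, var_registry)
  sites <- sites[!sites$pos %in% fixed$pos, , drop = FALSE]
  forms <- list(fixed)
  if (max_variable_mods > 0 && nrow(sites)) {
    positions <- sort(unique(sites$pos))
    build <- function(prefix, pi) {
      if (length(forms) > cap)
        stop("combinatorial cap (", cap, ") exceeded for peptide ", sequence)
      if (pi > length(positions)) return(invisible())
      p <- positions[pi]
      # skip this site
      build(prefix, pi + 1L)
      if (nrow(prefix) - nrow(fixed) < max_variable_mods) {
        here <- sites[sites$pos == p, , drop = FALSE]
        for (r in seq_len(nrow(here))) {
          nxt <- rbind(prefix, here[r, , drop = FALSE])
          forms[[length(forms) + 1L]] <<- nxt
          build(nxt, pi + 1L)
        }
      }
      invisible()
    }
    build(fixed, 1L)
  }
  if (length(forms) > cap)
    stop("combinatorial cap (", cap, ") exceeded for peptide ", sequence)
  lapply(forms, function(md) {
    md <- md[order(md$pos), , drop = FALSE]
    new_peptidoform(sequence, md, n_variable = nrow(md) - nrow(fixed))
  })
}

#' Construct a peptidoform
#'
#' @param sequence Peptide sequence.
#' @param mods data.frame with `pos`, `id`, `delta` (at most one per site).
#' @param protein,start,end Optional protein coordinates.
#' @param n_variable Number of variable modifications among `mods`.
#' @return A `peptidoform` list with computed `neutral_mass` and `label`.
#' @export
new_peptidoform <- function(sequence, mods = NULL, protein = NA_character_,
                            start = NA_integer_, end = NA_integer_,
                            n_variable = NA_integer_) {
  if (is.null(mods))
    mods <- data.frame(pos = integer(), id = character(), delta = numeric())
  mods <- mods[order(mods$pos), , drop = FALSE]
  rownames(mods) <- NULL
  structure(list(
    sequence = sequence, mods = mods, protein = protein,
    start = start, end = end, n_variable = n_variable,
    neutral_mass = peptide_mass(sequence, if (nrow(mods)) mods else NULL),
    label = format_peptidoform(sequence, mods)
  ), class = "peptidoform")
}

#' Bracket notation for a modified peptide
#'
#' Renders e.g. `LK[+312.089]EC[+57.022]C[+57.022]EKPLLEK`, with deltas
#' printed at 3 decimals.
#'
#' @param sequence Peptide sequence.
#' @param mods data.frame `pos`, `delta`.
#' @return Character string.
#' @export
format_peptidoform <- function(sequence, mods) {
  aa <- strsplit(sequence, "")[[1]]
  if (!is.null(mods) && nrow(mods)) {
    tag <- sprintf("[%+.3f]", mods$delta)
    aa[mods$pos] <- paste0(aa[mods$pos], tag)
  }
  paste(aa, collapse = "")
}

#' @export
print.peptidoform <- function(x, ...) {
  cat("<peptidoform> ", x$label, "  M = ", sprintf("%.4f", x$neutral_mass),
      " Da", sep = "")
  if (!is.na(x$protein)) cat("  (", x$protein, " ", x$start, "-", x$end, ")",
                             sep = "")
  cat("\n")
  invisible(x)
}

#' Pseudo-reversed decoy database
#'
#' One decoy per target protein: each tryptic segment is reversed in place
#' while its C-terminal K/R is preserved, so decoy peptides keep tryptic
#' termini and the precursor mass distribution of the targets. Accessions are
#' prefixed `DECOY_`.
#'
#' @param proteins Target protein data.frame.
#' @return Decoy protein data.frame (`is_decoy = TRUE`).
#' @export
make_decoys <- function(proteins) {
  rev_seq <- vapply(proteins$sequence, function(s) {
    sites <- .cleavage_sites(s)
    aa <- strsplit(s, "")[[1]]
    out <- aa
    for (i in seq_len(length(sites) - 1L)) {
      a <- sites[i] + 1L; b <- sites[i + 1L]
      if (b > a) {
        seg <- aa[a:b]
        last <- seg[length(seg)]
        if (last %in% c("K", "R")) {
          out[a:b] <- c(rev(seg[-length(seg)]), last)
        } else {
          out[a:b] <- rev(seg)
        }
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(accession = paste0("DECOY_", proteins$accession),
             description = proteins$description,
             sequence = rev_seq, is_decoy = TRUE, stringsAsFactors = FALSE)
}

#' Flag decoy peptides identical to any target peptide
#'
#' Palindromic or low-complexity segments can yield decoy peptides whose
#' sequence equals a target peptide; those must not be counted in FDR
#' estimation.
#'
#' @param peptides Digested peptide data.frame with `sequence`, `is_decoy`.
#' @return The input with a logical `shared_with_target` column.
#' @export
flag_shared_decoys <- function(peptides) {
  targets <- unique(peptides$sequence[!peptides$is_decoy])
  peptides$shared_with_target <- peptides$is_decoy &
    peptides$sequence %in% targets
  peptides
}
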