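#' @title ARP-carbonyl modification registry
#' @description The shipped registry of ARP-derivatized carbonyl modifications
#'   with residue specificity, mass deltas (stored at full computed precision),
#'   reporter/loss profiles, and the two standard non-ARP modifications
#'   (carbamidomethyl, Met oxidation). User registries can be loaded from
#'   TSV or JSON with the same schema.
#' @name registry
NULL

.PROFILES <- c("FULL_TAG", "BIOTIN_ONLY", "BIOTIN_MINIMAL", "NONE")

.registry_row <- function(id, name, residues, position, base_delta, profile,
                          oxime = TRUE, provenance = "formula_derived") {
  delta <- if (oxime) arp_adduct_delta(base_delta) else base_delta
  data.frame(
    id = id, name = name, residues = residues, position = position,
    base_delta = base_delta, delta_mass = delta, profile = profile,
    oxime = oxime, provenance = provenance, stringsAsFactors = FALSE
  )
}

#' Shipped modification registry
#'
#' One row per modification: `id`, human-readable `name`, `residues`
#' (concatenated one-letter codes), `position` (`any`, `nterm`, `cterm`,
#' relative to the peptide), `base_delta` (pre-derivatization carbonyl shift,
#' Da), `delta_mass` (observed shift, Da; `base_delta` plus the oxime addition
#' for oxime-type entries), `profile` (reporter/loss profile), `oxime`
#' (logical), `provenance`. ARP entries for the semialdehyde oximes of
#' Lys/Pro/Arg carry the FULL_TAG profile (reporters 227.085/299.117/332.139
#' plus tag losses of 227.085 and 331.139 Da); the Thr/Ser keto-acid oximes
#' carry BIOTIN_ONLY (227.085 plus a modified-y loss of 288.126 Da); all other
#' ARP adducts default to BIOTIN_MINIMAL (227.085 only). Carbamidomethyl and
#' Met oxidation are non-ARP (`profile` NONE, `oxime` FALSE).
#'
#' @param include_non_arp Include carbamidomethyl and Met oxidation rows
#'   (default TRUE).
#' @return data.frame, one modification per row.
#' @export
arp_registry <- function(include_non_arp = TRUE) {
  fm <- formula_mass
  rows <- rbind(
    .registry_row("lys_semialdehyde", "Lys -> aminoadipic semialdehyde (MCO) + ARP",
                  "K", "any", fm("O") - fm("NH3"), "FULL_TAG"),
    .registry_row("backbone_cleavage_al", "Radical N-terminal backbone cleavage (Ala/Leu) + ARP",
                  "AL", "nterm", fm("O") - fm("NH3"), "BIOTIN_MINIMAL"),
    .registry_row("lys_oxidation_298", "Lys alternative oxidation product + ARP",
                  "K", "any", fm("O") - fm("NH3") - fm("CH2"), "BIOTIN_MINIMAL"),
    .registry_row("leu_oxidation_313", "Leu alternative oxidation product + ARP",
                  "L", "any", fm("O") - fm("CH4"), "BIOTIN_MINIMAL"),
    .registry_row("gln_asn_imide", "Gln/Asn cyclic imide intermediate + ARP (ring opening)",
                  "QN", "any", fm("OH") - fm("NH2"), "BIOTIN_MINIMAL"),
    .registry_row("glu_asp_isoimide", "Glu/Asp cyclic isoimide intermediate + ARP",
                  "ED", "any", 0.0, "BIOTIN_MINIMAL"),
    .registry_row("pro_glu_semialdehyde", "Pro -> glutamic semialdehyde (MCO) + ARP",
                  "P", "any", fm("O"), "FULL_TAG"),
    .registry_row("arg_glu_semialdehyde", "Arg -> glutamic semialdehyde (MCO) + ARP",
                  "R", "any", fm("C5H7NO2") - fm("C6H12N4O"), "FULL_TAG"),
    .registry_row("thr_2a3k", "Thr -> 2-amino-3-ketobutyric acid (MCO) + ARP",
                  "T", "any", -fm("H2"), "BIOTIN_ONLY"),
    .registry_row("ser_aldehyde", "Ser oxidation product + ARP",
                  "S", "any", -fm("H2"), "BIOTIN_ONLY"),
    .registry_row("met_aldehyde", "Met oxidation to side-chain aldehyde + ARP",
                  "M", "any", fm("O") - fm("CH4S"), "BIOTIN_MINIMAL"),
    .registry_row("lys_glycation", "Lys glycation (Amadori, AGE) + ARP",
                  "K", "any", fm("C6H10O5"), "BIOTIN_MINIMAL"),
    .registry_row("lys_mda_mgo", "Lys malondialdehyde/methylglyoxal Michael adduct + ARP",
                  "K", "any", fm("C3H4O2"), "BIOTIN_MINIMAL"),
    .registry_row("lys_crotonaldehyde", "Lys crotonaldehyde Michael adduct + ARP",
                  "K", "any", fm("C4H6O"), "BIOTIN_MINIMAL"),
    .registry_row("lys_acrolein", "Lys acrolein Michael adduct + ARP",
                  "K", "any", fm("C3H4O"), "BIOTIN_MINIMAL"),
    .registry_row("lys_aldoamine", "Lys aldoamine product + ARP",
                  "K", "any", fm("C2H2O"), "BIOTIN_MINIMAL"),
    .registry_row("cys_acrolein", "Cys acrolein Michael adduct + ARP",
                  "C", "any", fm("C3H4O"), "BIOTIN_MINIMAL"),
    .registry_row("cys_glyoxal", "Cys glyoxal adduct + ARP (C14H21N5O5S)",
                  "C", "any", fm("C2H2O2"), "BIOTIN_MINIMAL")
  )
  if (include_non_arp) {
    rows <- rbind(
      rows,
      .registry_row("cam", "Carbamidomethyl (iodoacetamide)", "C", "any",
                    formula_mass("C2H3NO"), "NONE", oxime = FALSE,
                    provenance = "paper_printed"),
      .registry_row("met_ox", "Methionine oxidation", "M", "any",
                    formula_mass("O"), "NONE", oxime = FALSE,
                    provenance = "paper_printed")
    )
  }
  validate_registry(rows)
  rows
}

#' Validate a modification registry
#'
#' Asserts the schema and the oxime self-consistency invariant:
#' `|delta_mass - (base_delta + oxime_addition)| <= 0.001` Da for every
#' oxime-type entry, non-empty residue specificity, and known profiles.
#'
#' @param registry data.frame with the registry schema.
#' @return The registry, invisibly, or an error.
#' @export
validate_registry <- function(registry) {
  need <- c("id", "name", "residues", "position", "base_delta", "delta_mass",
            "profile", "oxime")
  missing <- setdiff(need, names(registry))
  if (length(missing))
    stop("registry missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(registry$id))
    stop("duplicate registry ids")
  if (any(!nzchar(registry$residues)))
    stop("registry entries must target at least one residue")
  if (any(!registry$profile %in% .PROFILES))
    stop("unknown reporter profile(s)")
  ox <- registry$oxime
  if (any(ox)) {
    dev <- abs(registry$delta_mass[ox] -
                 (registry$base_delta[ox] + arp_constants()$oxime_addition))
    if (any(dev > 0.001))
      stop("oxime self-consistency violated for: ",
           paste(registry$id[ox][dev > 0.001], collapse = ", "))
  }
  invisible(registry)
}

#' Read a modification registry from TSV or JSON
#'
#' TSV columns: `id`, `name`, `residues`, `position`, `base_delta`,
#' `delta_mass`, `profile`, `oxime` (and optional `provenance`). JSON is an
#' array of objects with the same keys. Missing `position` defaults to
#' `"any"`; missing `provenance` to `"user"`.
#'
#' @param path File path (`.tsv`/`.txt` or `.json`).
#' @return Validated registry data.frame.
#' @export
read_registry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  if (is.null(df$position)) df$position <- "any"
  if (is.null(df$provenance)) df$provenance <- "user"
  df$oxime <- as.logical(df$oxime)
  validate_registry(df)
  df
}

#' Write a modification registry
#'
#' @param registry Registry data.frame.
#' @param path Output path; format chosen by extension (`.json` or TSV).
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(registry, path, dataframe = "rows", digits = NA)
  } else {
    utils::write.table(registry, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Find isobaric modification conflicts
#'
#' Enumerates all single modifications and unordered combinations of two
#' modifications (repetition allowed) and reports every pair of distinct
#' combinations whose total mass deltas agree within `tolerance`. This is the
#' audit that exposes, e.g., the Cys ARP-glyoxal adduct being exactly isobaric
#' with carbamidomethylation plus a Gln/Asn imide ARP adduct.
#'
#' @param registry Registry data.frame.
#' @param tolerance Maximum absolute mass difference in Da (> 0).
#' @param max_combo Maximum modifications per side (1 or 2; default 2).
#' @return data.frame with columns `combo_a`, `combo_b` (ids joined by `+`),
#'   `delta_a`, `delta_b`, `diff` (absolute difference, Da).
#' @examples
#' conflicts <- find_isobaric_conflicts(arp_registry(), tolerance = 0.005)
#' @export
find_isobaric_conflicts <- function(registry, tolerance, max_combo = 2L) {
  stopifnot(nrow(registry) >= 1, tolerance > 0)
  ids <- registry$id
  deltas <- registry$delta_mass
  combos <- data.frame(label = ids, delta = deltas, stringsAsFactors = FALSE)
  if (max_combo >= 2L && length(ids) >= 1L) {
    idx <- which(upper.tri(matrix(0, length(ids), length(ids)), diag = TRUE),
                 arr.ind = TRUE)
    combos <- rbind(combos, data.frame(
      label = paste(ids[idx[, 1]], ids[idx[, 2]], sep = "+"),
      delta = deltas[idx[, 1]] + deltas[idx[, 2]],
      stringsAsFactors = FALSE
    ))
  }
  n <- nrow(combos)
  if (n < 2)
    return(data.frame(combo_a = character(), combo_b = character(),
                      delta_a = numeric(), delta_b = numeric(),
                      diff = numeric(), stringsAsFactors = FALSE))
  ord <- order(combos$delta)
  combos <- combos[ord, , drop = FALSE]
  out <- vector("list", 0L)
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && combos$delta[j] - combos$delta[i] <= tolerance) {
      out[[length(out) + 1L]] <- data.frame(
        combo_a = combos$label[i], combo_b = combos$label[j],
        delta_a = combos$delta[i], delta_b = combos$delta[j],
        diff = abs(combos$delta[j] - combos$delta[i]),
        stringsAsFactors = FALSE
      )
      j <- j + 1L
    }
  }
  if (!length(out))
    return(data.frame(combo_a = character(), combo_b = character(),
                      delta_a = numeric(), delta_b = numeric(),
                      diff = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$diff), , drop = FALSE]
}
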