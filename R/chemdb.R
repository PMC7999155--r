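#' @title Monoisotopic mass arithmetic for ARP proteomics
#' @description Element and residue mass tables, formula parsing, peptide and
#'   m/z arithmetic, and the oxime adduct mass used throughout the package.
#' @name chemdb
NULL

# Monoisotopic masses (Da), CODATA/AME values.
.ELEMENTS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.9720711744,
  P = 30.97376163
)

.PROTON <- 1.007276466879
.WATER  <- 2 * 1.00782503207 + 15.9949146196
.ISOTOPE_SPACING <- 1.00335483  # C13 - C12

# Residue elemental compositions (the 20 canonical amino acids).
.RESIDUE_FORMULA <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",  V = "C5H9NO",
  T = "C4H7NO2", C = "C3H5NOS",  L = "C6H11NO",  I = "C6H11NO", N = "C4H6N2O2",
  D = "C4H5NO3", Q = "C5H8N2O2", K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",
  H = "C6H7N3O", F = "C9H9NO",   R = "C6H12N4O", Y = "C9H9NO2", W = "C11H10N2O"
)

#' Monoisotopic element table
#'
#' @return Named numeric vector of monoisotopic element masses in Da.
#' @export
element_table <- function() .ELEMENTS

#' Proton mass
#' @return Mass of a proton in Da.
#' @export
proton_mass <- function() .PROTON

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula such as `"C12H21N5O4S"` and returns the sum of
#' monoisotopic element masses times counts. The empty formula has mass 0.
#'
#' @param formula Elemental formula string (elements C, H, N, O, S, P).
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass("H2O")          # 18.0106
#' formula_mass("C12H21N5O4S")  # the ARP reagent, 331.131
#' @export
formula_mass <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  if (!nzchar(formula)) return(0)
  if (nzchar(gsub("([A-Z][a-z]?)([0-9]*)", "", formula)))
    stop("cannot parse formula: '", formula, "'")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  total <- 0
  for (tok in toks) {
    sym <- gsub("[0-9]", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!sym %in% names(.ELEMENTS))
      stop("unknown element symbol '", sym, "' in formula '", formula, "'")
    total <- total + .ELEMENTS[[sym]] * n
  }
  total
}

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of residue (chain) masses in Da for the 20
#'   canonical amino acids, computed from elemental compositions.
#' @export
residue_masses <- function() {
  vapply(.RESIDUE_FORMULA, formula_mass, numeric(1))
}

.RESIDUE_MASS <- vapply(.RESIDUE_FORMULA, formula_mass, numeric(1))

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus any modification mass deltas.
#'
#' @param sequence Peptide sequence, one-letter codes.
#' @param mods Either `NULL`, a numeric vector of deltas named or indexed by
#'   position, or a two-column structure (`pos`, `delta`) such as
#'   `data.frame(pos = 3, delta = 57.02146)`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("G")  # 75.0320
#' peptide_mass("LKCASLQK", data.frame(pos = c(3, 2), delta = c(57.02146, 312.08923)))
#' @export
peptide_mass <- function(sequence, mods = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  m <- sum(.RESIDUE_MASS[aa]) + .WATER
  if (!is.null(mods) && length(mods)) {
    md <- .as_mod_frame(mods)
    if (any(md$pos < 1 | md$pos > length(aa)))
      stop("modification position out of range for '", sequence, "'")
    if (anyDuplicated(md$pos))
      stop("more than one modification on the same residue")
    m <- m + sum(md$delta)
  }
  m
}

# Accepts data.frame(pos, delta), list of c(pos, delta) pairs, or an empty thing.
.as_mod_frame <- function(mods) {
  if (is.data.frame(mods)) {
    stopifnot(all(c("pos", "delta") %in% names(mods)))
    return(data.frame(pos = as.integer(mods$pos), delta = as.numeric(mods$delta)))
  }
  if (is.list(mods)) {
    pos <- vapply(mods, function(x) as.numeric(x[[1]]), numeric(1))
    delta <- vapply(mods, function(x) as.numeric(x[[2]]), numeric(1))
    return(data.frame(pos = as.integer(pos), delta = delta))
  }
  stop("mods must be a data.frame(pos, delta) or a list of (pos, delta) pairs")
}

#' m/z of a protonated ion
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z = (M + z * proton) / z.
#' @examples
#' mz_from_mass(1258.6162, 2)  # 630.315
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  (neutral_mass + charge * .PROTON) / charge
}

#' Neutral mass from an observed m/z
#'
#' Inverse of [mz_from_mass()].
#' @param mz Observed m/z.
#' @param charge Positive integer charge state.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1")
  mz * charge - charge * .PROTON
}

#' ARP reagent constants
#'
#' Masses tied to the aldehyde reactive probe
#' (O-(biotinylcarbazoylmethyl)hydroxylamine, C12H21N5O4S): the net oxime
#' addition (ARP minus water), the diagnostic reporter ions, the tag and
#' keto-adduct neutral losses, and the lock-mass reference. Reporter and loss
#' values are the instrument-facing constants at their conventional printed
#' precision; `oxime_addition` and `arp_neutral_mass` are computed at full
#' precision from the elemental formula.
#'
#' @return Named list of constants (Da or m/z as indicated by the name).
#' @export
arp_constants <- function() {
  arp <- formula_mass("C12H21N5O4S")
  list(
    arp_neutral_formula = "C12H21N5O4S",
    arp_neutral_mass = arp,
    oxime_addition = arp - .WATER,
    reporter_biotin_mz = 227.085,
    reporter_arp_fragment_mz = 299.117,
    reporter_arp_protonated_mz = 332.139,
    tag_loss_partial = 227.085,
    tag_loss_full = 331.139,
    keto_loss = 288.126,
    lockmass_reference_mz = 785.843
  )
}

#' Mass shift of an ARP oxime adduct
#'
#' The derivatization adds the ARP reagent to a carbonyl as an oxime with loss
#' of one water, so the observed shift is the pre-derivatization carbonyl
#' shift plus `mass(C12H21N5O4S) - mass(H2O)`.
#'
#' @param base_carbonyl_delta Mass shift of the underlying carbonyl
#'   modification before derivatization, in Da (e.g. +0.984 for the Gln/Asn
#'   imide intermediate, -1.0316 for lysine semialdehyde).
#' @return Observed ARP adduct mass shift in Da.
#' @examples
#' arp_adduct_delta(0.984016)   # Gln/Asn, +314.105
#' arp_adduct_delta(-1.031634)  # Lys semialdehyde, +312.089
#' @export
arp_adduct_delta <- function(base_carbonyl_delta) {
  base_carbonyl_delta + (formula_mass("C12H21N5O4S") - .WATER)
}

#' Approximate isotope envelope weights (averagine)
#'
#' Relative abundances of the first `n` isotopologues of a peptide-like
#' molecule of the given mass, from a Poisson approximation parameterized on
#' the averagine composition. Used to render synthetic MS1 envelopes and as
#' the relative-abundance model for 3-isotope EIC extraction.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param n Number of isotopes (default 3).
#' @return Numeric vector of length `n`, normalized to sum to 1.
#' @export
averagine_envelope <- function(mass, n = 3L) {
  # averagine: C4.9384 H7.7583 N1.3577 O1.4773 S0.0417 per 111.1254 Da
  per_unit <- 4.9384 * 0.0107 + 7.7583 * 0.000115 + 1.3577 * 0.003664 +
    1.4773 * 0.00038 + 0.0417 * 0.0076
  lambda <- per_unit * mass / 111.1254
  w <- stats::dpois(seq_len(n) - 1L, lambda)
  w / sum(w)
}

#' Parts-per-million error
#' @param observed,theoretical m/z values.
#' @return Signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
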