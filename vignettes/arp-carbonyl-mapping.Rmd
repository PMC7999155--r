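---
title: "Mapping ARP-derivatized protein carbonylation sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping ARP-derivatized protein carbonylation sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arpmap)
```

## The analytical problem

Carbonylation introduces reactive aldehyde or keto groups into protein side
chains, either by direct metal-catalyzed oxidation (Lys, Pro, Arg, Thr →
semialdehydes and keto acids) or by adduction of reactive carbonyl species
(acrolein, malondialdehyde, glyoxal, crotonaldehyde) and glycation. These
PTMs are chemically heterogeneous and sub-stoichiometric, so they are
derivatized with the aldehyde reactive probe (ARP), a biotinylated
hydroxylamine. The oxime condensation adds

$$\Delta m_{\text{obs}} \;=\; \Delta m_{\text{carbonyl}} \;+\;
  \underbrace{m(\mathrm{C_{12}H_{21}N_5O_4S}) - m(\mathrm{H_2O})}_{+313.1209\ \mathrm{Da}}$$

to the peptide, and the biotin moiety allows avidin enrichment of the
labelled peptides. `arpmap` implements the downstream computational
workflow: recognizing ARP spectra from their diagnostic ions, searching them
against a protein database with ARP-specific fragmentation rules,
classifying the proposals with a six-criterion confidence scheme, and
quantifying enrichment, recovery and reproducibility from extracted ion
chromatograms.

## The modification registry

Each registry entry stores the *pre-derivatization* carbonyl shift
(`base_delta`, derived from an elemental-composition difference such as
$\mathrm{O - NH_3}$ for the lysine semialdehyde) and the observed shift
`delta_mass = base_delta + oxime addition`, kept at full floating-point
precision; the conventional 3-decimal values (+312.089, +314.105, +313.121,
…) are treated as display/acceptance values, not stored truth. A load-time
invariant asserts `|delta_mass − (base_delta + oxime)| ≤ 0.001 Da` for every
oxime-type entry.

Two bookkeeping quirks are documented rather than "fixed":

* The Met side-chain aldehyde computes to +281.1124 Da from
  $\mathrm{O - CH_4S}$ plus the oxime addition, while the conventional
  rounded value is +281.111; the registry stores the computed value.
* The worked multi-PTM example peptide `LK[+312.089]EC[+57.022]C[+57.022]EKPLLEK`
  is sometimes described with a "remaining" shift of 312.125 Da; the two
  readings differ by 0.036 Da and the registry uses the
  composition-derived +312.089.

Reporter/loss profiles follow the observed fragmentation chemistry:
semialdehyde oximes of Lys/Pro/Arg show reporters at *m/z* 227.085, 299.117
and 332.139 plus tag losses of 227.085/331.139 Da (`FULL_TAG`); Thr/Ser
keto-acid oximes show only the biotin reporter plus a 288.126 Da loss from
modified y ions (`BIOTIN_ONLY`). All other ARP adducts are assigned
`BIOTIN_MINIMAL` (227.085 only), because only that ion is guaranteed across
all ARP spectra. The registry is user-extensible from TSV/JSON with the same
schema (`read_registry()`).

`find_isobaric_conflicts()` enumerates 1- and 2-modification combinations
and reports pairs within a mass tolerance. The practically important hit is
exact by elemental composition: the Cys ARP-glyoxal adduct
($\mathrm{+C_{14}H_{21}N_5O_5S}$) equals carbamidomethyl-Cys plus a Gln/Asn
imide adduct, so site-discriminating fragments — not precursor mass — must
decide between them (`resolve_modification_ambiguity()`).

## Search model

**Digestion.** Trypsin cleaves C-terminal to K/R but not before Pro;
protein termini count as cleavage sites, up to 3 missed cleavages, peptide
length 6–45 (bounds chosen to keep the search space realistic; both are
configurable). Semi-specific peptides (exactly one non-tryptic terminus) are
supported and on by default for search, since enriched samples frequently
contain ragged termini; the synthetic generator emits fully tryptic peptides
only, and the bundled examples therefore run with `semi = FALSE`.

**Decoys.** The decoy strategy is pseudo-reversal: each tryptic segment is
reversed in place with its C-terminal K/R preserved, keeping decoy peptides
tryptic and mass-matched. Decoy peptides identical to a target sequence
(palindromes) are flagged and excluded from the decoy count. Segment
reversal around K/R–P junctions can relocate a cleavage site; this is the
standard, accepted imprecision of pseudo-reversal.

**Candidate generation.** Pre-enumerating every peptidoform with up to 3
variable modifications over a registry touching most residue types is
combinatorially infeasible. The search instead indexes *unmodified*
(fixed-CAM) peptide masses and decomposes each precursor as
`peptide mass + combination of ≤ max_variable_mods registry deltas`
(all such combination deltas are precomputed), then enumerates concrete site
placements only for peptides that match a decomposition within the
candidate gate (3 × the precursor tolerance). `enumerate_peptidoforms()`
still provides literal enumeration with a 10,000-form cap for small-scale
work.

**Two passes.** Pass 1 searches with standard modifications only
(carbamidomethylation per the configured mode, Met oxidation); scans without
a substantive assignment (backbone coverage ≥ 50% and ≥ 5 matched
fragments) are re-searched in pass 2 with the full ARP registry. Where both
passes propose an assignment the better-scoring pass wins. This mirrors the
common first-pass/PTM-pass search structure while remaining fully
transparent.

**Scoring.** Each theoretical fragment (b/y at charges 1–2, plus the
profile-mandated loss ions on modified fragments and the precursor) is
matched to its nearest observed peak within 20 ppm, one peak per fragment,
smallest |ppm| winning ties. The score is
$-\log_{10} P\!\left(X \ge k\right)$ for $X \sim \mathrm{Binom}(n, p)$ with
$k$ matched of $n$ theoretical fragments and $p$ the chance of a random
fragment landing on any peak (peak count × window width / spectrum span),
plus the matched-intensity fraction as a bonus term. The score is
deterministic, monotone in $k$, and zero for zero matches. It is
deliberately simple — a transparent replacement for proprietary search-engine
scores, not a re-implementation of them.

**Coverage and site localization.** Sequence coverage is defined as the
fraction of the $L-1$ backbone bonds bracketed by at least one matched b or
y ion (the criterion "coverage above 50%" does not define coverage
precisely; this is the package's operational definition). A modification
site is *confirmed* when both flanking bonds are covered (peptide termini
count as boundaries), which confines the mass shift to that residue.

**FDR.** Peptide-level: best PSM per peptidoform, targets and decoys
competing on score; $q$ = decoys/targets at or above each score cut,
monotonized; the default threshold is 0.05. A search without decoys raises
a hard error rather than reporting an undefined FDR.

## Validation criteria

The confidence scheme evaluates, per FDR-passing peptide: (1) a resolved
chromatographic peak in the enriched fraction — operationalized as EIC
area/background ≥ 3, since no numeric definition of "resolved" exists;
(2) enriched intensity above non-enriched (raw areas, per the criterion's
literal wording; load-normalized comparison is available as a flag);
(3) reporter ions present (the triage flag); (4) coverage > 50%;
(5) site-confirming fragments; (6) precursor error within ±2 SD of the
dataset error model. Criteria 1–2 are `not_evaluable` without paired
fractions and are then excluded from the all-pass requirement. Failures
confined to {5, 6} yield *ambiguous*; any other failure *rejected*;
otherwise *confident*. Likely chimeras (another candidate precursor within
2 m/z units at overlapping retention time) are annotated, not rejected.

The error model uses the median and $1.4826 \times$ MAD rather than mean/SD
so that single gross outliers do not widen the acceptance band, with a 0.5
ppm floor to avoid degeneracy on noiseless data.

## Quantitation

EICs sum the three first isotopologues (spacing 1.00335/z; relative
abundances follow a Poisson-averagine approximation) in windows of
± m/z / 20,000, the instrument's TOF resolving power. Integration is
trapezoidal above a baseline drawn between the medians of the first and
last three in-window points — "background area" has no published numeric
definition, so this edge-median baseline is the package's. Peptides are
considered quantifiable before enrichment when area/background > 10 in the
non-enriched fraction.

The recovery equation is implemented in its load-normalizing orientation,

$$\mathrm{Recovery\,\%} = 100 \times
  \frac{A_{\text{enr}}}{A_{\text{non}}} \times
  \frac{L_{\text{non}}}{L_{\text{enr}}},$$

because with the study loads (11 µg enriched-equivalent vs 70 ng
non-enriched) this makes a lossless enrichment equal exactly 100% — the
printed form of the equation is typographically ambiguous about the
orientation of the load ratio. The upscale comparison reports the *mean of
per-peptide ratios* (labelled as such; whether a published fold-gain is a
mean of ratios or a ratio of means is generally unstated). CV is
$100 \times s/\bar{x}$ over replicate areas. The ion-mobility filter keeps
features within `predicted/(2 × 15)` ms of the predicted drift time,
a FWHM-style window at resolving power 15.

Lock-mass recalibration multiplies every m/z by
`785.843 / observed reference` (per run, or piecewise by retention time);
a multiplicative ppm-like model is the natural choice for TOF error, though
an additive correction would be equally defensible. References farther than
0.5 Da from 785.843 leave the block uncorrected with a warning.

## The synthetic generator

`generate_truth()` plans an experiment deterministically from a seed:
tryptic peptides from a bundled HSA-derived panel (a mature-albumin-like
sequence carrying the documented carbonylation hotspot peptides, plus three
synthetic background proteins, one with the avidin-sticky HPY motif), a
configurable fraction carrying one ARP adduct at a registry-eligible site,
charges 2–3, Gaussian elution peaks (SD 0.08 min) on a 20-min axis, and
log-normal base abundances. Scenario templates mirror the study designs:

* `enrichment` — triplicate enriched (load 11) vs non-enriched (load 0.07)
  runs; ARP and HPY-sticky peptides survive enrichment losslessly,
  background peptides are depleted 100-fold (the observed median contrast
  between ARP and non-derivatized recoveries);
* `dilution` — constant spike across 9:1 / 49:1 / 249:1 matrix ratios;
* `upscale` — 0.2 vs 2.0 load units with a net planted gain of 7.3
  (a 10× load at 73% efficiency);
* `noise_only` — 500 reporter-free random MS2 scans for FDR control checks.

Default noise: 10 ppm m/z jitter (SD), 20% replicate intensity CV, a low
exponential chemical baseline, and a lock-mass reference peak in every MS1
scan. `render_run()` draws MS2 peak lists from the theoretical fragments
(charge 1 b/y ladder, reporter ions and tag losses per profile) with
uniform intensities — deliberately non-physical, since no public intensity
model exists for these spectra, but sufficient to exercise matching,
localization and triage. What the generator does **not** emulate:
CID intensity physics, peak-shape asymmetry beyond Gaussians, cross-run
retention drift, isotope-pattern interference from co-isolated precursors,
and real chimeric fragmentation. Passing the planted-truth checks therefore
demonstrates correctness of the computational chain, not instrument-level
performance on biological samples.

Problem sizes in the shipped tests were chosen to exercise every stage at
desk scale: a 50-peptide enrichment scenario (clean and with the default
noise model), a 500-scan noise-only FDR check, a 20-peptide recovery
identity, and a 100-peptide upscale recovery.

## Numerical choices and edge cases

* Monoisotopic masses throughout (CODATA/AME element values); average mass
  is out of scope.
* Proton mass 1.00727646688 Da; water 18.01056 Da; isotope spacing
  1.00335483 Da.
* A peak with zero background integrates to `ab_ratio = Inf` and counts as
  resolved (criterion 1).
* Duplicate m/z values within a spectrum are merged by intensity sum with a
  warning; peaks are always stored sorted.
* Score ties between a target and a decoy candidate resolve to the target
  (the conservative convention is debatable; ties are vanishingly rare with
  continuous scores).
* Seeds: every stochastic routine takes or derives from a single integer
  seed and restores the caller's RNG state, so `generate_truth()` /
  `render_run()` are bit-reproducible.

## Known limitations

* The score is uncalibrated across peptide lengths (longer peptides have
  more theoretical fragments); FDR control absorbs this, but scores are not
  comparable across datasets.
* Site localization is binary (confined / not confined); no probabilistic
  localization score is computed.
* One modification per residue, at most 3 variable modifications by default;
  heavily multi-labelled peptides require raising the limit explicitly.
* The 1% base-peak reporter-intensity floor for triage is a free parameter;
  no published minimum exists.
* I/L are indistinguishable by mass and not disambiguated.
* Protein-level inference and FDR are out of scope.
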