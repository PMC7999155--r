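test_that("tryptic digestion follows the cleavage rules", {
  d0 <- digest("AKRG", max_missed = 0, min_length = 1)
  expect_setequal(d0$sequence, c("AK", "R", "G"))
  expect_identical(d0$missed_cleavages, c(0L, 0L, 0L))
  # no cleavage before proline
  expect_setequal(digest("AKPG", max_missed = 0, min_length = 1)$sequence,
                  "AKPG")
  d1 <- digest("AKRG", max_missed = 1, min_length = 1)
  expect_setequal(d1$sequence, c("AK", "R", "G", "AKR", "RG"))
  expect_error(digest(""), "empty")
})

test_that("0-missed-cleavage peptides reconstruct the protein exactly", {
  set.seed(101)
  aa <- names(element_table())  # not amino acids; use residue table instead
  alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (i in 1:10) {
    prot <- paste(sample(alphabet, sample(20:80, 1), replace = TRUE),
                  collapse = "")
    d <- digest(prot, max_missed = 0, min_length = 1, max_length = 1000)
    d <- d[order(d$start), ]
    expect_identical(paste(d$sequence, collapse = ""), prot)
    # coordinates map back onto the protein
    expect_identical(substring(prot, d$start, d$end), d$sequence)
  }
})

test_that("semi-tryptic digestion keeps one tryptic terminus", {
  prot <- read_fasta(panel_fasta())$sequence[2]
  full <- digest(prot, max_missed = 2, semi = FALSE)
  semi <- digest(prot, max_missed = 2, semi = TRUE)
  expect_true(all(full$sequence %in% semi$sequence))
  expect_true(all(semi$nterm_tryptic | semi$cterm_tryptic))
  expect_identical(substring(prot, semi$start, semi$end), semi$sequence)
  expect_true(all(semi$missed_cleavages <= 2))
})

test_that("peptidoform enumeration covers the cartesian assignments", {
  reg <- arp_registry()
  reg_small <- reg[reg$id %in% c("cam", "lys_semialdehyde"), ]
  forms <- enumerate_peptidoforms("LKCASLQK", reg_small,
                                  max_variable_mods = 1, cam_mode = "fixed")
  labels <- vapply(forms, `[[`, character(1), "label")
  expect_true("LKC[+57.021]ASLQK" %in% labels)
  expect_true("LK[+312.089]C[+57.021]ASLQK" %in% labels)
  expect_true("LKC[+57.021]ASLQK[+312.089]" %in% labels)
  expect_length(forms, 3)  # fixed-CAM only, +K2, +K8
  # max_variable_mods = 0 keeps only the fixed-CAM form
  forms0 <- enumerate_peptidoforms("LKCASLQK", reg_small,
                                   max_variable_mods = 0, cam_mode = "fixed")
  expect_length(forms0, 1)
  expect_identical(forms0[[1]]$label, "LKC[+57.021]ASLQK")
  # no eligible site -> single unmodified form
  lys_only <- reg[reg$id == "lys_semialdehyde", ]
  expect_length(enumerate_peptidoforms("GGGG", lys_only, 3, "variable"), 1)
  # combinatorial cap
  expect_error(
    enumerate_peptidoforms("KKKKKKKKKK", reg[reg$residues == "K", ],
                           max_variable_mods = 3, cap = 10),
    "cap")
})

test_that("every peptidoform's mass is consistent with the mass module", {
  reg <- arp_registry()
  forms <- enumerate_peptidoforms("LKCASLQK", reg, max_variable_mods = 2)
  for (f in forms)
    expect_equal(f$neutral_mass,
                 peptide_mass(f$sequence,
                              if (nrow(f$mods)) f$mods else NULL),
                 tolerance = 1e-9)
})

test_that("pseudo-reversed decoys preserve tryptic structure", {
  prot <- read_fasta(panel_fasta())
  dec <- make_decoys(prot)
  expect_identical(nrow(dec), nrow(prot))
  expect_true(all(startsWith(dec$accession, "DECOY_")))
  expect_true(all(dec$is_decoy))
  expect_identical(nchar(dec$sequence), nchar(prot$sequence))
  expect_length(intersect(dec$accession, prot$accession), 0)
  # terminal residue of each protein preserved in class
  last <- function(s) substring(s, nchar(s), nchar(s))
  expect_identical(last(dec$sequence[1]) %in% c("K", "R"),
                   last(prot$sequence[1]) %in% c("K", "R"))
  # fully tryptic decoy peptides keep the target mass multiset; this exact
  # identity requires a Pro-free protein (K/R-P junctions can relocate
  # cleavage sites under segment reversal)
  pfree <- data.frame(accession = "PF", description = "",
                      sequence = "MAGEKLVNDERSTWYHQKFEILCDNKGSTAR",
                      is_decoy = FALSE, stringsAsFactors = FALSE)
  dpf <- make_decoys(pfree)
  pt <- digest(pfree$sequence, max_missed = 0, min_length = 1,
               max_length = 1000)
  pd <- digest(dpf$sequence, max_missed = 0, min_length = 1,
               max_length = 1000)
  expect_equal(sort(vapply(pt$sequence, peptide_mass, numeric(1))),
               sort(vapply(pd$sequence, peptide_mass, numeric(1))),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("decoy peptides identical to targets are flagged", {
  peps <- data.frame(
    sequence = c("ABCK", "ABCK", "XYZR"),
    is_decoy = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  flagged <- flag_shared_decoys(peps)
  expect_identical(flagged$shared_with_target, c(FALSE, TRUE, FALSE))
})

test_that("FASTA reading rejects non-canonical sequences with a warning", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">P1 fine", "PEPTIDEK", ">P2 selenocysteine", "PEPUK",
               ">P3 unknown", "PEPXK"), f)
  expect_warning(prot <- read_fasta(f), "non-canonical")
  expect_identical(prot$accession, "P1")
  # round trip
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(prot, f2)
  expect_identical(read_fasta(f2)$sequence, prot$sequence)
})
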