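# Shared fixtures, built once per session and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

noiseless_cfg <- function(...) {
  synth_config("enrichment", mz_jitter_ppm_sd = 0, intensity_cv = 0,
               baseline_level = 0, n_noise_peaks_ms2 = 0, n_baseline_ms1 = 0,
               ...)
}

# 50-peptide noiseless enrichment scenario + full pipeline result
fx_noiseless <- function() fixture("noiseless", function() {
  man <- generate_truth(noiseless_cfg(), seed = 7)
  ds <- render_dataset(man)
  res <- run_pipeline(ds, default_config(semi = FALSE))
  list(man = man, ds = ds, res = res)
})

# same scenario under the default noise model (10 ppm jitter, background)
fx_noisy <- function() fixture("noisy", function() {
  man <- generate_truth(synth_config("enrichment"), seed = 11)
  ds <- render_dataset(man)
  res <- run_pipeline(ds, default_config(semi = FALSE))
  list(man = man, ds = ds, res = res)
})

# render an MS2 spectrum directly from a peptidoform's theoretical fragments
# (noiseless; used for matching tests)
render_form_spectrum <- function(sequence, mods, charge,
                                 registry = arp_registry(),
                                 scan_id = "t1", extra_mz = numeric(0)) {
  pf <- new_peptidoform(sequence, mods)
  fr <- theoretical_fragments(pf, registry, max_fragment_charge = 1L)
  k <- arp_constants()
  rep_mz <- numeric(0)
  if (nrow(mods)) {
    prof <- registry$profile[match(mods$id, registry$id)]
    if (any(prof != "NONE", na.rm = TRUE)) rep_mz <- k$reporter_biotin_mz
    if (any(prof == "FULL_TAG", na.rm = TRUE))
      rep_mz <- c(rep_mz, k$reporter_arp_fragment_mz,
                  k$reporter_arp_protonated_mz)
  }
  mz <- unique(c(fr$mz, rep_mz, extra_mz))
  new_spectrum(mz = mz, intensity = rep(500, length(mz)), ms_level = 2L,
               scan_id = scan_id, rt = 10,
               precursor_mz = mz_from_mass(pf$neutral_mass, charge),
               precursor_charge = charge)
}

cam_delta <- function() arp_registry()$delta_mass[arp_registry()$id == "cam"]

# order-agnostic lookup of a reported conflict between two combinations
conflict_between <- function(cf, a, b) {
  canon <- function(x) vapply(strsplit(x, "+", fixed = TRUE), function(p)
    paste(sort(p), collapse = "+"), character(1))
  ca <- canon(cf$combo_a); cb <- canon(cf$combo_b)
  a <- canon(a); b <- canon(b)
  (ca == a & cb == b) | (ca == b & cb == a)
}

mod_frame <- function(pos, id) {
  reg <- arp_registry()
  data.frame(pos = pos, id = id, delta = reg$delta_mass[match(id, reg$id)],
             stringsAsFactors = FALSE)
}
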