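#' @title Theoretical fragmentation with ARP-specific losses
#' @description b/y fragment ladders (charges 1..max) plus the ARP tag-loss
#'   variants dictated by each modification's reporter profile: FULL_TAG
#'   adducts lose 227.085 (partial) or 331.139 Da (full tag) from the
#'   precursor and from fragments carrying the modification; BIOTIN_ONLY
#'   (keto-type) adducts lose 288.126 Da from modified y ions.
#' @name fragments
NULL

#' Theoretical fragments of a peptidoform
#'
#' @param peptidoform A `peptidoform` (see [new_peptidoform()]), or a peptide
#'   sequence with `mods` given separately.
#' @param registry Modification registry (maps mod ids to reporter profiles;
#'   mods with unknown ids get no loss variants).
#' @param max_fragment_charge Highest fragment charge (default 2).
#' @param mods Optional data.frame `pos`, `id`, `delta` when `peptidoform`
#'   is a bare sequence.
#' @return data.frame with `series` (`b`/`y`/`precursor`), `index`, `charge`,
#'   `loss` (`none`/`tag_partial`/`tag_full`/`keto`), `mz`, `carries_mod`.
#' @export
theoretical_fragments <- function(peptidoform, registry = arp_registry(),
                                  max_fragment_charge = 2L, mods = NULL) {
  if (is.character(peptidoform))
    peptidoform <- new_peptidoform(peptidoform, mods)
  seqn <- peptidoform$sequence
  md <- peptidoform$mods
  aa <- strsplit(seqn, "")[[1]]
  n <- length(aa)
  delta_at <- numeric(n)
  full_tag_at <- keto_at <- logical(n)
  mod_at <- logical(n)
  if (nrow(md)) {
    delta_at[md$pos] <- md$delta
    mod_at[md$pos] <- TRUE
    prof <- registry$profile[match(md$id, registry$id)]
    prof[is.na(prof)] <- "NONE"
    full_tag_at[md$pos[prof == "FULL_TAG"]] <- TRUE
    keto_at[md$pos[prof == "BIOTIN_ONLY"]] <- TRUE
  }
  cum <- cumsum(.RESIDUE_MASS[aa] + delta_at)
  total <- cum[n] + .WATER
  i <- seq_len(n - 1L)
  b_neutral <- cum[i]
  y_neutral <- total - cum[n - i]
  b_mod <- cumsum(mod_at)[i] > 0
  y_mod <- cumsum(rev(mod_at))[i] > 0  # y_i spans the last i residues
  b_full <- cumsum(full_tag_at)[i] > 0
  y_full <- cumsum(rev(full_tag_at))[i] > 0
  y_keto <- cumsum(rev(keto_at))[i] > 0
  k <- arp_constants()
  series <- c(rep("b", n - 1L), rep("y", n - 1L))
  index <- c(i, i)
  neutral <- c(b_neutral, y_neutral)
  carries <- c(b_mod, y_mod)
  loss <- rep("none", 2L * (n - 1L))
  add_loss <- function(sel_series, sel, loss_name, loss_da) {
    if (!any(sel)) return(invisible())
    series <<- c(series, rep(sel_series, sum(sel)))
    index <<- c(index, i[sel])
    neutral <<- c(neutral, (if (sel_series == "b") b_neutral else y_neutral)[sel] - loss_da)
    carries <<- c(carries, rep(TRUE, sum(sel)))
    loss <<- c(loss, rep(loss_name, sum(sel)))
    invisible()
  }
  add_loss("b", b_full, "tag_partial", k$tag_loss_partial)
  add_loss("b", b_full, "tag_full", k$tag_loss_full)
  add_loss("y", y_full, "tag_partial", k$tag_loss_partial)
  add_loss("y", y_full, "tag_full", k$tag_loss_full)
  add_loss("y", y_keto, "keto", k$keto_loss)
  if (any(full_tag_at)) {
    series <- c(series, "precursor", "precursor")
    index <- c(index, n, n)
    neutral <- c(neutral, total - k$tag_loss_partial, total - k$tag_loss_full)
    carries <- c(carries, TRUE, TRUE)
    loss <- c(loss, "tag_partial", "tag_full")
  }
  zs <- seq_len(max_fragment_charge)
  m <- length(series)
  out <- data.frame(
    series = rep(series, times = max_fragment_charge),
    index = rep(index, times = max_fragment_charge),
    charge = rep(zs, each = m),
    loss = rep(loss, times = max_fragment_charge),
    mz = as.numeric(vapply(zs, function(z) (neutral + z * .PROTON) / z,
                           numeric(m))),
    carries_mod = rep(carries, times = max_fragment_charge),
    stringsAsFactors = FALSE
  )
  out <- out[out$mz > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}
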