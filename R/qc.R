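#' Per-residue confidence profile of a chain
#'
#' Structure predictors write the per-residue pLDDT score (0-100) into the
#' B-factor column, uniformly across the atoms of each residue; the profile
#' is read from the representative atom (CA when present, otherwise the
#' first atom of the residue).
#'
#' @param model an [assembly_model].
#' @param chain_id chain to profile.
#' @return An object of class `confidence_profile`: list with `chain_id`,
#'   `residue_numbers` and parallel `plddt`.
#' @export
plddt_profile <- function(model, chain_id) {
  a <- model$atoms[model$atoms$chain == chain_id, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain not in model: ", chain_id)
  key <- paste(a$resno, a$ins, sep = "\r")
  resn <- numeric(0); pl <- numeric(0)
  for (k in unique(key)) {
    sub <- a[key == k, , drop = FALSE]
    rep_atom <- if (any(sub$name == "CA")) sub[sub$name == "CA", ][1, ] else sub[1, ]
    resn <- c(resn, rep_atom$resno)
    pl <- c(pl, rep_atom$b)
  }
  if (any(pl < 0 | pl > 100))
    warning("pLDDT outside [0,100] in chain ", chain_id,
            ": B-factors may not be confidence scores")
  structure(list(chain_id = chain_id, residue_numbers = as.integer(resn),
                 plddt = pl),
            class = "confidence_profile")
}

#' @export
print.confidence_profile <- function(x, ...) {
  cat(sprintf("confidence_profile chain %s: %d residues, pLDDT %.1f-%.1f (mean %.1f)\n",
              x$chain_id, length(x$plddt), min(x$plddt), max(x$plddt),
              mean(x$plddt)))
  invisible(x)
}

# centered running mean, window truncated at the ends
smooth_profile <- function(v, window = 5L) {
  if (window <= 1L) return(v)
  n <- length(v)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    mean(v[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Confidently folded residue intervals of a profile
#'
#' A residue belongs to the folded mask when its smoothed pLDDT (centered
#' running mean, edge-truncated) reaches the threshold and it sits in a run
#' of at least `min_run` such residues. The complement is treated as
#' flexible/loop. "Folded" has no universal definition for predicted
#' models; window and min_run are documented tunables.
#'
#' @param profile a [plddt_profile] result.
#' @param threshold pLDDT gate in (0, 100), default 70.
#' @param min_run minimum run length in residues, default 8.
#' @param window smoothing window (residues), default 5.
#' @return list of integer `c(first, last)` residue-number intervals
#'   (possibly empty).
#' @export
folded_mask <- function(profile, threshold = 70, min_run = 8L, window = 5L) {
  stopifnot(inherits(profile, "confidence_profile"))
  if (length(profile$plddt) == 0L) stop("empty confidence profile")
  if (threshold <= 0 || threshold >= 100) stop("threshold must be in (0, 100)")
  sm <- smooth_profile(profile$plddt, window)
  above <- sm >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  lapply(which(keep), function(i) {
    c(profile$residue_numbers[starts[i]], profile$residue_numbers[ends[i]])
  })
}

mask_residues <- function(mask) {
  if (!length(mask)) return(integer(0))
  sort(unique(unlist(lapply(mask, function(r) seq.int(r[1], r[2])))))
}

# contiguous residue-number runs -> list of c(first, last)
runs_to_intervals <- function(resn) {
  if (!length(resn)) return(list())
  resn <- sort(unique(resn))
  brk <- c(0L, which(diff(resn) != 1L), length(resn))
  lapply(seq_len(length(brk) - 1L), function(i) {
    c(resn[brk[i] + 1L], resn[brk[i + 1L]])
  })
}

#' Accept or reject a predicted model from its confidence profiles
#'
#' Level-1 validation gate for predicted structures: a model passes when
#' every residue of the confidently folded regions reaches the pLDDT
#' threshold. Loop/terminal residues below the threshold do not cause
#' rejection (they rarely affect the fold) but are reported in
#' `flagged_segments`. A chain with no folded region at all (empty mask, or
#' folded fraction below `min_folded_fraction`) fails: nothing in it passed
#' the confidence gate.
#'
#' @param model an [assembly_model].
#' @param threshold pLDDT gate, default 70 (80 is the stricter literature
#'   gate).
#' @param min_folded_fraction minimum fraction of residues that must lie in
#'   the folded mask for the chain to count as confidently folded, default
#'   0.3.
#' @param min_run,window passed to [folded_mask].
#' @return An object of class `qc_verdict`: list with `accepted`,
#'   `folded_fraction_above_threshold`, `flagged_segments` (per chain),
#'   `per_chain` details and `notes`.
#' @export
accept_model <- function(model, threshold = 70, min_folded_fraction = 0.3,
                         min_run = 8L, window = 5L) {
  per_chain <- list()
  notes <- character(0)
  flagged <- list()
  ok_all <- TRUE
  frac_all <- numeric(0)
  for (ch in chain_ids(model)) {
    pr <- plddt_profile(model, ch)
    mask <- folded_mask(pr, threshold = threshold, min_run = min_run,
                        window = window)
    in_mask <- pr$residue_numbers %in% mask_residues(mask)
    folded_frac <- mean(in_mask)
    above <- pr$plddt >= threshold
    frac_above <- if (any(in_mask)) mean(above[in_mask]) else 0
    low <- runs_to_intervals(pr$residue_numbers[!above])
    chain_ok <- folded_frac >= min_folded_fraction && frac_above == 1
    if (folded_frac < min_folded_fraction)
      notes <- c(notes, sprintf(
        "chain %s: folded fraction %.2f below %.2f (no confidently folded core)",
        ch, folded_frac, min_folded_fraction))
    per_chain[[ch]] <- list(folded_mask = mask, folded_fraction = folded_frac,
                            fraction_above = frac_above, accepted = chain_ok)
    flagged[[ch]] <- low
    ok_all <- ok_all && chain_ok
    frac_all <- c(frac_all, frac_above)
  }
  structure(list(accepted = ok_all,
                 folded_fraction_above_threshold = min(frac_all),
                 flagged_segments = flagged, per_chain = per_chain,
                 threshold = threshold, notes = notes),
            class = "qc_verdict")
}

#' @export
print.qc_verdict <- function(x, ...) {
  cat(sprintf("qc_verdict: %s (threshold %g)\n",
              if (x$accepted) "ACCEPTED" else "REJECTED", x$threshold))
  for (ch in names(x$per_chain)) {
    pc <- x$per_chain[[ch]]
    flags <- x$flagged_segments[[ch]]
    cat(sprintf("  chain %s: folded %.0f%%, above-threshold-in-mask %.0f%%, %d flagged segment(s)\n",
                ch, 100 * pc$folded_fraction, 100 * pc$fraction_above,
                length(flags)))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Confidence gain of a chain upon complex formation
#'
#' Compares a chain's pLDDT profile predicted in a complex against the same
#' chain predicted alone: a trustworthy complex should score at least as
#' high, so the gate passes when the mean delta over the folded regions (of
#' the stand-alone prediction) is not below `tolerance` (default -1 pLDDT,
#' absorbing run-to-run predictor noise).
#'
#' @param profile_in_complex,profile_alone [plddt_profile] results over the
#'   identical residue set.
#' @param tolerance lowest acceptable mean delta, default -1.
#' @param threshold,min_run,window folded-mask parameters for the
#'   stand-alone profile.
#' @return list with per-residue `delta`, `mean_delta` (over the folded
#'   mask, or over all residues when the mask is empty) and boolean `pass`.
#' @export
complex_gain <- function(profile_in_complex, profile_alone, tolerance = -1,
                         threshold = 70, min_run = 8L, window = 5L) {
  if (!identical(profile_in_complex$residue_numbers,
                 profile_alone$residue_numbers))
    stop("profiles cover different residue sets")
  delta <- profile_in_complex$plddt - profile_alone$plddt
  mask <- folded_mask(profile_alone, threshold = threshold,
                      min_run = min_run, window = window)
  in_mask <- profile_alone$residue_numbers %in% mask_residues(mask)
  mean_delta <- if (any(in_mask)) mean(delta[in_mask]) else mean(delta)
  list(residue_numbers = profile_alone$residue_numbers, delta = delta,
       mean_delta = mean_delta, pass = mean_delta >= tolerance)
}

#' Inter-chain PAE block summary
#'
#' Summarizes the off-diagonal PAE block between two chains — the
#' predictor's confidence in their relative placement. The (a,b) and (b,a)
#' blocks are pooled (symmetric treatment).
#'
#' @param pae a [pae_matrix] with chain ranges attached.
#' @param chain_a,chain_b chain ids.
#' @param cutoff "confident contact" PAE cutoff in Angstrom, default 10.
#' @return list with `mean`, `median`, `fraction_below_cutoff`, `cutoff`
#'   and `n` (block entries summarized).
#' @export
interchain_pae <- function(pae, chain_a, chain_b, cutoff = 10) {
  stopifnot(inherits(pae, "pae_matrix"))
  if (is.null(pae$chain_ranges))
    stop("PAE matrix carries no chain ranges; read it with a companion model")
  for (ch in c(chain_a, chain_b))
    if (is.null(pae$chain_ranges[[ch]]))
      stop("chain not in PAE chain ranges: ", ch)
  ra <- pae$chain_ranges[[chain_a]]
  rb <- pae$chain_ranges[[chain_b]]
  ia <- seq.int(ra[1], ra[2]); ib <- seq.int(rb[1], rb[2])
  block <- c(pae$values[ia, ib], pae$values[ib, ia])
  list(mean = mean(block), median = stats::median(block),
       fraction_below_cutoff = mean(block < cutoff), cutoff = cutoff,
       n = length(block))
}

#' Tab-separated QC report
#'
#' One row per chain: chain id, folded fraction, fraction of folded
#' residues above threshold, verdict, flagged intervals.
#'
#' @param verdict a [accept_model] result.
#' @param path output path (NULL returns the data.frame only).
#' @return data.frame of the report, invisibly when written.
#' @export
qc_report <- function(verdict, path = NULL) {
  stopifnot(inherits(verdict, "qc_verdict"))
  rows <- lapply(names(verdict$per_chain), function(ch) {
    pc <- verdict$per_chain[[ch]]
    fl <- verdict$flagged_segments[[ch]]
    data.frame(chain = ch, folded_fraction = pc$folded_fraction,
               fraction_above_threshold = pc$fraction_above,
               verdict = if (pc$accepted) "accept" else "reject",
               flagged = paste(vapply(fl, function(r)
                 sprintf("%d-%d", r[1], r[2]), character(1)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
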