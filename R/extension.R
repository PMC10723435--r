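# PBS / RTT option generation, pegRNA assembly, and the in-silico flap
# verifier that reconstructs the edited locus from an emitted design.

#' Canonical SpCas9 sgRNA scaffold (76 nt)
#'
#' Default scaffold placed between the spacer and the 3' extension. A
#' configuration value, never hard-coded in the design logic.
#'
#' @return Character scalar, 76 nt.
#' @export
default_scaffold <- function() {
  paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTG",
         "GCACCGAGTCGGTGC")
}

.check_valid_candidate <- function(candidate) {
  if (!inherits(candidate, "spacer_candidate")) {
    .stop_pegforge("pegforge_invalid_input", "expected a spacer_candidate")
  }
  if (!isTRUE(candidate$valid_for_pe)) {
    .stop_pegforge("pegforge_invalid_candidate",
                   "candidate is not valid for prime editing (edit is 5' of the nick)")
  }
}

# order option list by |length - preferred|, warned options last among ties,
# shorter first as the final tie-break
.rank_options <- function(opts, preferred) {
  if (length(opts) == 0L) return(opts)
  len <- vapply(opts, function(x) x$length, integer(1L))
  warned <- vapply(opts, function(x) length(x$warning_reasons) > 0L, logical(1L))
  opts[order(abs(len - preferred), warned, len)]
}

#' Primer-binding-site (PBS) options for a spacer candidate
#'
#' The PBS hybridizes with the 3' end of the nicked protospacer strand: its
#' sequence is the reverse complement of the `length` nucleotides immediately
#' 5' of the nick on that strand. One option per feasible length in
#' `length_range`; options at or below the GC threshold carry a `"low_gc"`
#' low-efficiency warning. Options are ranked by distance from the preferred
#' length (12 nt), warned options last among ties, shorter first.
#'
#' @param candidate A valid-for-PE `spacer_candidate`.
#' @param spec The `edit_spec` the candidate came from.
#' @param length_range Integer `c(min, max)` PBS lengths (default 8-17).
#' @param preferred Preferred PBS length (default 12).
#' @param gc_warn_threshold Warn when GC percent is at or below this (default 30).
#' @return List of `pbs_option` records, ranked.
#' @export
pbs_options <- function(candidate, spec, length_range = c(8L, 17L),
                        preferred = 12L, gc_warn_threshold = 30) {
  .check_valid_candidate(candidate)
  wt <- spec$wt_sequence
  L <- nchar(wt)
  nick <- candidate$nick_index
  opts <- list()
  for (len in seq.int(length_range[1L], length_range[2L])) {
    if (candidate$strand == "+") {
      if (nick - len < 0L) next
      seq <- reverse_complement(.sub0(wt, nick - len, nick))
    } else {
      if (nick + len > L) next
      # protospacer strand is the bottom strand; its `len` nt 5' of the nick
      # occupy top interval [nick, nick+len), and the double reverse
      # complement lands back on the top-strand slice
      seq <- .sub0(wt, nick, nick + len)
    }
    gc <- gc_percent(seq)
    reasons <- character(0L)
    if (gc <= gc_warn_threshold) reasons <- c(reasons, "low_gc")
    opts[[length(opts) + 1L]] <- structure(
      list(length = len, sequence = seq, gc = gc,
           low_efficiency_warning = length(reasons) > 0L,
           warning_reasons = reasons, candidate_id = candidate$id),
      class = "pbs_option")
  }
  if (length(opts) == 0L) {
    .stop_pegforge(
      "pegforge_insufficient_flank",
      sprintf("no PBS length in [%d,%d] fits the flank 5' of the nick at %d",
              length_range[1L], length_range[2L], nick))
  }
  .rank_options(opts, preferred)
}

#' Reverse-transcriptase-template (RTT) options for a spacer candidate
#'
#' The RTT templates the new 3' DNA flap: its sequence is the reverse
#' complement of the first `length` nucleotides 3' of the nick on the
#' *edited* protospacer strand. Only lengths that span the full edit and
#' leave at least `min_post_edit_homology` nt of homology 3' of the edit are
#' emitted (the flap must re-anneal beyond the edit). A `"first_base_c"`
#' warning is attached when the scaffold-adjacent first nucleotide of the
#' template is C, a configuration known to reduce editing efficiency.
#' Options are ranked by distance from the preferred length (14 nt), warned
#' options last among ties, shorter first.
#'
#' @param candidate A valid-for-PE `spacer_candidate`.
#' @param spec The `edit_spec` the candidate came from.
#' @param length_range Integer `c(min, max)` RTT lengths (default 8-31).
#' @param preferred Preferred RTT length (default 14).
#' @param min_post_edit_homology Minimum nt of post-edit homology (default 5).
#' @return List of `rtt_option` records, ranked.
#' @export
rtt_options <- function(candidate, spec, length_range = c(8L, 31L),
                        preferred = 14L, min_post_edit_homology = 5L) {
  .check_valid_candidate(candidate)
  ed <- spec$edited_sequence
  Le <- nchar(ed)
  delta <- Le - nchar(spec$wt_sequence)
  nick_e <- if (candidate$strand == "+") candidate$nick_index else
    candidate$nick_index + delta
  opts <- list()
  for (len in seq.int(length_range[1L], length_range[2L])) {
    if (candidate$strand == "+") {
      if (nick_e + len > Le) next
      peh <- nick_e + len - spec$edited_edit_end
      if (peh < min_post_edit_homology) next
      seq <- reverse_complement(.sub0(ed, nick_e, nick_e + len))
    } else {
      if (nick_e - len < 0L) next
      peh <- spec$edit_start - (nick_e - len)
      if (peh < min_post_edit_homology) next
      seq <- .sub0(ed, nick_e - len, nick_e)
    }
    reasons <- character(0L)
    first_c <- substr(seq, 1L, 1L) == "C"
    if (first_c) reasons <- c(reasons, "first_base_c")
    opts[[length(opts) + 1L]] <- structure(
      list(length = len, sequence = seq, covers_edit = TRUE,
           post_edit_homology = as.integer(peh),
           first_templated_base_c = first_c,
           warning_reasons = reasons, candidate_id = candidate$id),
      class = "rtt_option")
  }
  if (length(opts) == 0L) {
    need <- if (candidate$strand == "+") {
      spec$edited_edit_end - nick_e + min_post_edit_homology
    } else {
      nick_e - spec$edit_start + min_post_edit_homology
    }
    .stop_pegforge(
      "pegforge_rtt_infeasible",
      sprintf("no RTT length in [%d,%d] spans the edit with %d nt of post-edit homology (minimal feasible length: %d)",
              length_range[1L], length_range[2L], min_post_edit_homology, need))
  }
  .rank_options(opts, preferred)
}

.apply_five_prime_g <- function(spacer, policy) {
  policy <- match.arg(policy, c("prepend", "substitute", "none"))
  if (policy == "none" || substr(spacer, 1L, 1L) == "G") return(spacer)
  if (policy == "prepend") paste0("G", spacer)
  else paste0("G", substr(spacer, 2L, nchar(spacer)))
}

#' Assemble a complete pegRNA design
#'
#' Concatenates spacer, scaffold and the 3' extension (RTT then PBS, 5'->3')
#' and aggregates efficiency warnings: `low_gc` and `first_base_c` from the
#' parts, `polyT` when spacer or extension contains a TTTT run (a Pol III
#' terminator would truncate the transcript), and `pam_not_disrupted` when
#' the edit leaves PAM and seed intact so the edited allele can be re-cut.
#' The hU6 5'-G policy is applied to the emitted spacer (default: prepend a
#' G when the spacer does not already start with one).
#'
#' @param candidate A valid-for-PE `spacer_candidate`.
#' @param pbs A `pbs_option` derived from the same candidate.
#' @param rtt An `rtt_option` derived from the same candidate.
#' @param scaffold Scaffold sequence (default [default_scaffold()]).
#' @param strategy One of `"PE2"`, `"PE3"`, `"PE3b"`.
#' @param five_prime_g_policy `"prepend"` (default), `"substitute"` or `"none"`.
#' @return A `pegrna_design`.
#' @export
assemble_pegrna <- function(candidate, pbs, rtt, scaffold = default_scaffold(),
                            strategy = c("PE2", "PE3", "PE3b"),
                            five_prime_g_policy = "prepend") {
  strategy <- match.arg(strategy)
  .check_valid_candidate(candidate)
  if (!identical(pbs$candidate_id, candidate$id) ||
      !identical(rtt$candidate_id, candidate$id)) {
    .stop_pegforge("pegforge_part_mismatch",
                   "pbs/rtt options were not derived from this spacer candidate")
  }
  spacer_out <- .apply_five_prime_g(candidate$spacer_sequence,
                                    five_prime_g_policy)
  extension <- paste0(rtt$sequence, pbs$sequence)
  warnings <- unique(c(pbs$warning_reasons, rtt$warning_reasons))
  if (grepl("TTTT", spacer_out, fixed = TRUE) ||
      grepl("TTTT", extension, fixed = TRUE)) {
    warnings <- c(warnings, "polyT")
  }
  if (!isTRUE(candidate$pam_or_seed_disrupted)) {
    warnings <- c(warnings, "pam_not_disrupted")
  }
  structure(
    list(
      spacer = candidate,
      spacer_emitted = spacer_out,
      scaffold = scaffold,
      rtt = rtt,
      pbs = pbs,
      full_sequence = paste0(spacer_out, scaffold, extension),
      strategy = strategy,
      warnings = warnings
    ),
    class = "pegrna_design")
}

#' @export
print.pegrna_design <- function(x, ...) {
  cat(sprintf("<pegrna_design> %s | spacer %s (%d nt) | PBS %d nt | RTT %d nt\n",
              x$strategy, x$spacer$id, nchar(x$spacer_emitted),
              x$pbs$length, x$rtt$length))
  cat(sprintf("  full pegRNA (%d nt): %s\n", nchar(x$full_sequence),
              x$full_sequence))
  if (length(x$warnings) > 0L) {
    cat("  warnings:", paste(x$warnings, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct the edited locus implied by a pegRNA design
#'
#' Models flap resolution: the reverse-transcribed 3' flap (the complement of
#' the RT template) replaces the corresponding window 3' of the nick on the
#' protospacer strand, and the resulting top-strand sequence is returned. For
#' every design this package emits, the result equals the edited sequence of
#' the input edit specification — the round-trip check that the RT template
#' actually encodes the requested edit.
#'
#' @param design A `pegrna_design`.
#' @param spec The `edit_spec` the design was built for.
#' @return Top-strand DNA string of the predicted post-editing locus.
#' @export
predict_edited_locus <- function(design, spec) {
  stopifnot(inherits(design, "pegrna_design"))
  wt <- spec$wt_sequence
  L <- nchar(wt)
  delta <- nchar(spec$edited_sequence) - L
  nick <- design$spacer$nick_index
  len <- design$rtt$length
  if (design$spacer$strand == "+") {
    flap_top <- reverse_complement(design$rtt$sequence)
    wt_end <- nick + len - delta
    if (wt_end > L || wt_end < nick) {
      .stop_pegforge("pegforge_flap_error",
                     "RT template does not span the edit window")
    }
    paste0(.sub0(wt, 0L, nick), flap_top, .sub0(wt, wt_end, L))
  } else {
    flap_top <- design$rtt$sequence  # template read on the top strand
    wt_start <- nick - len + delta
    if (wt_start < 0L || wt_start > nick) {
      .stop_pegforge("pegforge_flap_error",
                     "RT template does not span the edit window")
    }
    paste0(.sub0(wt, 0L, wt_start), flap_top, .sub0(wt, nick, L))
  }
}
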