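# PE3 / PE3b secondary nicking-guide design.
#
# The secondary guide directs the nickase to the strand opposite the pegRNA
# nick. A PE3 guide matches wild-type and edited alleles alike; a PE3b guide
# overlaps the edit so its site exists only after editing, which delays the
# second nick until the edit is installed and sharply reduces indels.

# peg nick index mapped into edited-sequence coordinates
.peg_nick_edited <- function(peg_candidate, spec) {
  delta <- nchar(spec$edited_sequence) - nchar(spec$wt_sequence)
  if (peg_candidate$strand == "+") peg_candidate$nick_index
  else peg_candidate$nick_index + delta
}

# The wild-type window corresponding to edited-sequence interval [a, b):
# anchored on the left flank when the site starts 5' of the edit, on the
# right flank otherwise (coordinates there are shifted by the edit's length
# change). Returns NA when the window runs off the wild-type sequence.
.wt_window <- function(spec, a, b) {
  delta <- nchar(spec$edited_sequence) - nchar(spec$wt_sequence)
  w <- b - a
  start <- if (a < spec$edit_start) a else a - delta
  if (start < 0L || start + w > nchar(spec$wt_sequence)) return(NA_character_)
  .sub0(spec$wt_sequence, start, start + w)
}

.hamming_positions <- function(a, b) {
  which(.chars(a) != .chars(b)) - 1L
}

#' Classify a candidate nicking site as PE3, PE3b or invalid
#'
#' A site located on the edited sequence is `PE3b` iff its protospacer+PAM
#' interval intersects the edit and the corresponding wild-type window
#' differs at one or more positions (the site is specific to the edited
#' allele); `PE3` iff the site reads identically in wild-type and edited
#' sequences; `invalid` otherwise (e.g. the PAM does not actually match the
#' edited sequence).
#'
#' @param site List with `strand`, `protospacer_interval`, `pam_interval`
#'   (0-based half-open, on the edited sequence) and `pam_pattern`.
#' @param spec The `edit_spec`.
#' @return List with `mode` (`"PE3"`, `"PE3b"` or `"invalid"`),
#'   `wt_mismatch_count` and `mismatch_positions` (0-based offsets within the
#'   protospacer+PAM window).
#' @export
classify_pe3b <- function(site, spec) {
  ed <- spec$edited_sequence
  a <- min(site$protospacer_interval[1L], site$pam_interval[1L])
  b <- max(site$protospacer_interval[2L], site$pam_interval[2L])
  pam_seq <- .sub0(ed, site$pam_interval[1L], site$pam_interval[2L])
  if (site$strand == "-") pam_seq <- reverse_complement(pam_seq)
  if (!matches_iupac(pam_seq, site$pam_pattern)) {
    return(list(mode = "invalid", wt_mismatch_count = NA_integer_,
                mismatch_positions = integer(0L)))
  }
  ed_win <- .sub0(ed, a, b)
  wt_win <- .wt_window(spec, a, b)
  if (is.na(wt_win)) {
    mism <- seq_len(nchar(ed_win)) - 1L  # no aligned wild-type window at all
  } else {
    mism <- .hamming_positions(ed_win, wt_win)
  }
  overlaps <- .interval_overlaps(a, b, spec$edit_start, spec$edited_edit_end)
  if (length(mism) == 0L) {
    list(mode = "PE3", wt_mismatch_count = 0L, mismatch_positions = integer(0L))
  } else if (overlaps) {
    list(mode = "PE3b", wt_mismatch_count = length(mism),
         mismatch_positions = mism)
  } else {
    list(mode = "invalid", wt_mismatch_count = length(mism),
         mismatch_positions = mism)
  }
}

#' Enumerate PE3/PE3b secondary nicking guides
#'
#' Scans the strand opposite the pegRNA spacer of the *edited* sequence for
#' protospacer+PAM sites, classifies each as PE3b (edited-allele specific)
#' or PE3 (present in both alleles), and computes the signed nick-to-nick
#' offset (positive when the secondary nick lies 3' of the pegRNA nick on the
#' pegRNA protospacer strand). PE3 candidates are kept only when the offset
#' falls inside `pe3_window`; PE3b candidates are exempt from the window
#' since allele-specific matching, not distance, defines them. PE3b guides
#' are listed first, then by ascending absolute offset within each mode.
#'
#' @param spec An `edit_spec`.
#' @param peg_candidate The selected valid-for-PE `spacer_candidate`.
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @param pe3_window Signed nick-to-nick window for PE3 guides (default
#'   `c(40, 90)`).
#' @param spacer_len Guide length (default 20).
#' @return List of `nick_guide` records (possibly empty).
#' @export
enumerate_nick_guides <- function(spec, peg_candidate, pam_pattern = "NGG",
                                  pe3_window = c(40L, 90L), spacer_len = 20L) {
  .check_valid_candidate(peg_candidate)
  pam_pattern <- toupper(pam_pattern)
  opp <- if (peg_candidate$strand == "+") "-" else "+"
  ed <- spec$edited_sequence
  Le <- nchar(ed)
  plen <- nchar(pam_pattern)
  peg_nick_e <- .peg_nick_edited(peg_candidate, spec)
  out <- list()
  for (p in .pam_match_starts(ed, pam_pattern, opp)) {
    if (opp == "+") {
      if (p < spacer_len) next
      proto <- c(p - spacer_len, p)
      pam <- c(p, p + plen)
      nick2 <- p - 3L
      spacer_seq <- .sub0(ed, proto[1L], proto[2L])
      pam_seq <- .sub0(ed, pam[1L], pam[2L])
    } else {
      if (p + plen + spacer_len > Le) next
      proto <- c(p + plen, p + plen + spacer_len)
      pam <- c(p, p + plen)
      nick2 <- p + plen + 3L
      spacer_seq <- reverse_complement(.sub0(ed, proto[1L], proto[2L]))
      pam_seq <- reverse_complement(.sub0(ed, pam[1L], pam[2L]))
    }
    cls <- classify_pe3b(
      list(strand = opp, protospacer_interval = proto, pam_interval = pam,
           pam_pattern = pam_pattern), spec)
    if (cls$mode == "invalid") next
    d <- if (peg_candidate$strand == "+") nick2 - peg_nick_e
         else peg_nick_e - nick2
    if (cls$mode == "PE3" &&
        (d < pe3_window[1L] || d > pe3_window[2L])) next
    out[[length(out) + 1L]] <- structure(
      list(
        mode = cls$mode,
        strand = opp,
        protospacer_interval = as.integer(proto),
        pam_interval = as.integer(pam),
        spacer_sequence = spacer_seq,
        pam_sequence = pam_seq,
        nick_index_edited = as.integer(nick2),
        nick_to_nick_distance = as.integer(d),
        wt_mismatch_count = cls$wt_mismatch_count,
        mismatch_positions = cls$mismatch_positions
      ),
      class = "nick_guide")
  }
  if (length(out) == 0L) return(out)
  mode <- vapply(out, function(x) x$mode, character(1L))
  d <- vapply(out, function(x) x$nick_to_nick_distance, integer(1L))
  start <- vapply(out, function(x) x$protospacer_interval[1L], integer(1L))
  out[order(mode != "PE3b", abs(d), start)]
}

#' @export
print.nick_guide <- function(x, ...) {
  cat(sprintf(
    "<nick_guide> %s, %s strand, protospacer [%d,%d) on edited seq, nick-to-nick %+d, wt mismatches %d\n",
    x$mode, x$strand, x$protospacer_interval[1L], x$protospacer_interval[2L],
    x$nick_to_nick_distance, x$wt_mismatch_count))
  invisible(x)
}

#' Tabulate nicking-guide candidates
#'
#' @param guides List of `nick_guide` records.
#' @return A data.frame, one row per guide.
#' @export
nick_guide_table <- function(guides) {
  if (length(guides) == 0L) {
    return(data.frame(
      mode = character(0L), strand = character(0L),
      protospacer_start = integer(0L), protospacer_end = integer(0L),
      spacer_sequence = character(0L), pam_sequence = character(0L),
      nick_index_edited = integer(0L), nick_to_nick_distance = integer(0L),
      wt_mismatch_count = integer(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(guides, function(x) {
    data.frame(
      mode = x$mode, strand = x$strand,
      protospacer_start = x$protospacer_interval[1L],
      protospacer_end = x$protospacer_interval[2L],
      spacer_sequence = x$spacer_sequence,
      pam_sequence = x$pam_sequence,
      nick_index_edited = x$nick_index_edited,
      nick_to_nick_distance = x$nick_to_nick_distance,
      wt_mismatch_count = x$wt_mismatch_count,
      stringsAsFactors = FALSE)
  }))
}
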