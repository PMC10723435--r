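# Spacer enumeration and ranking.
#
# Cut geometry is the standard SpCas9 nickase geometry: a blunt nick 3 nt
# 5' of the PAM on the protospacer strand, recorded as an inter-base index on
# the top strand (identical on both strands).

SEED_LEN <- 10L  # PAM-proximal protospacer positions counted as the seed

.candidate_id <- function(strand, proto_start) {
  sprintf("%s:%d", strand, proto_start)
}

# 0-based start positions where `pattern` (IUPAC) matches `seq` exactly on the
# given strand of the top-strand string. For "-" the match is of the
# reverse-complemented pattern against the top strand.
.pam_match_starts <- function(seq, pattern, strand) {
  pat <- if (strand == "+") pattern else .revcomp_iupac(pattern)
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                   Biostrings::DNAString(seq),
                                   fixed = "subject")
  Biostrings::start(hits) - 1L
}

.make_candidate <- function(spec, strand, proto_start, spacer_len, pam_start,
                            pam_len) {
  wt <- spec$wt_sequence
  proto_iv <- c(proto_start, proto_start + spacer_len)
  pam_iv <- c(pam_start, pam_start + pam_len)
  if (strand == "+") {
    nick <- pam_start - 3L
    spacer_seq <- .sub0(wt, proto_iv[1L], proto_iv[2L])
    pam_seq <- .sub0(wt, pam_iv[1L], pam_iv[2L])
    valid <- spec$edit_start >= nick
    dist <- spec$edit_start - nick
  } else {
    nick <- pam_iv[2L] + 3L
    spacer_seq <- reverse_complement(.sub0(wt, proto_iv[1L], proto_iv[2L]))
    pam_seq <- reverse_complement(.sub0(wt, pam_iv[1L], pam_iv[2L]))
    valid <- spec$wt_edit_end <= nick
    dist <- nick - spec$wt_edit_end
  }
  cand <- structure(
    list(
      id = .candidate_id(strand, proto_start),
      strand = strand,
      protospacer_interval = as.integer(proto_iv),
      pam_interval = as.integer(pam_iv),
      spacer_sequence = spacer_seq,
      pam_sequence = pam_seq,
      nick_index = as.integer(nick),
      nick_to_edit_distance = as.integer(dist),
      pam_or_seed_disrupted = NA,
      valid_for_pe = valid
    ),
    class = "spacer_candidate"
  )
  cand$pam_or_seed_disrupted <- edit_disrupts_site(cand, spec)
  cand
}

#' @export
print.spacer_candidate <- function(x, ...) {
  cat(sprintf(
    "<spacer_candidate> %s strand, protospacer [%d,%d), PAM %s, nick %d, dist %d%s%s\n",
    x$strand, x$protospacer_interval[1L], x$protospacer_interval[2L],
    x$pam_sequence, x$nick_index, x$nick_to_edit_distance,
    if (x$valid_for_pe) "" else " [invalid for PE]",
    if (isTRUE(x$pam_or_seed_disrupted)) " [PAM/seed disrupted]" else ""
  ))
  invisible(x)
}

#' Enumerate candidate pegRNA spacers on both strands
#'
#' Scans the wild-type sequence on both strands for every site where a
#' `spacer_len`-mer protospacer abuts a PAM-pattern match, computes the nick
#' position (3 nt 5' of the PAM on the protospacer strand) and the
#' nick-to-edit distance, and flags validity for prime editing (the whole
#' edit must lie 3' of the nick on the protospacer strand, because reverse
#' transcription extends the nicked strand 3' across the edit). The result is
#' ordered by [rank_spacers()].
#'
#' @param spec An `edit_spec` from [parse_edit_input()].
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`, SpCas9).
#' @param spacer_len Protospacer length in nt (default 20, minimum 16).
#' @return List of `spacer_candidate` records (possibly empty, with a
#'   `diagnostic` attribute explaining why).
#' @export
enumerate_spacers <- function(spec, pam_pattern = "NGG", spacer_len = 20L) {
  stopifnot(inherits(spec, "edit_spec"))
  spacer_len <- as.integer(spacer_len)
  if (spacer_len < 16L) {
    .stop_pegforge("pegforge_invalid_input", "spacer_len must be >= 16")
  }
  if (!is.character(pam_pattern) || nchar(pam_pattern) == 0L) {
    .stop_pegforge("pegforge_invalid_input", "pam_pattern must be nonempty")
  }
  pam_pattern <- toupper(pam_pattern)
  wt <- spec$wt_sequence
  L <- nchar(wt)
  plen <- nchar(pam_pattern)
  out <- list()
  for (p in .pam_match_starts(wt, pam_pattern, "+")) {
    if (p >= spacer_len) {
      out[[length(out) + 1L]] <-
        .make_candidate(spec, "+", p - spacer_len, spacer_len, p, plen)
    }
  }
  for (p in .pam_match_starts(wt, pam_pattern, "-")) {
    if (p + plen + spacer_len <= L) {
      out[[length(out) + 1L]] <-
        .make_candidate(spec, "-", p + plen, spacer_len, p, plen)
    }
  }
  if (length(out) == 0L) {
    attr(out, "diagnostic") <- sprintf(
      "no %d-nt protospacer adjacent to a '%s' PAM found on either strand of the %d-nt target",
      spacer_len, pam_pattern, L)
    return(out)
  }
  rank_spacers(out)
}

#' Rank spacer candidates by nick-to-edit distance
#'
#' Valid-for-PE candidates come first, ordered by ascending nick-to-edit
#' distance; ties are broken by (a) PAM/seed-disrupting candidates first
#' (their edited allele resists re-cutting), (b) `+` strand before `-`,
#' (c) leftmost protospacer start. Invalid candidates follow, ordered by the
#' same keys on the absolute distance. The order is total and deterministic.
#'
#' @param candidates List of `spacer_candidate` records from one edit spec.
#' @return The same candidates, reordered.
#' @export
rank_spacers <- function(candidates) {
  if (length(candidates) == 0L) return(candidates)
  valid <- vapply(candidates, function(x) x$valid_for_pe, logical(1L))
  dist <- vapply(candidates, function(x) x$nick_to_edit_distance, integer(1L))
  disrupt <- vapply(candidates, function(x) isTRUE(x$pam_or_seed_disrupted),
                    logical(1L))
  strand <- vapply(candidates, function(x) x$strand, character(1L))
  start <- vapply(candidates, function(x) x$protospacer_interval[1L],
                  integer(1L))
  ord <- order(!valid, abs(dist), !disrupt, strand != "+", start)
  candidates[ord]
}

#' Does the edit disrupt the PAM or seed of a candidate site?
#'
#' `TRUE` iff the edit interval intersects the PAM or the 10 PAM-proximal
#' protospacer positions (the seed). Used for re-cut-protection annotation and
#' ranking tie-breaks; zero-width (insertion) edits count when the insertion
#' point falls strictly inside the window.
#'
#' @param candidate A `spacer_candidate`.
#' @param spec The `edit_spec` it was derived from.
#' @return Logical.
#' @export
edit_disrupts_site <- function(candidate, spec) {
  pam <- candidate$pam_interval
  if (candidate$strand == "+") {
    win <- c(pam[1L] - SEED_LEN, pam[2L])
  } else {
    win <- c(pam[1L], pam[2L] + SEED_LEN)
  }
  .interval_overlaps(win[1L], win[2L], spec$edit_start, spec$wt_edit_end)
}

# all 0-based start positions of exact occurrences of `motif` in `seq`
# (overlapping occurrences included)
.find_exact <- function(seq, motif) {
  if (nchar(motif) > nchar(seq)) return(integer(0L))
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                   Biostrings::DNAString(seq))
  Biostrings::start(hits) - 1L
}

#' Validate a user-supplied custom spacer against the target
#'
#' Locates the spacer exactly once in the wild-type sequence (on either
#' strand) adjacent to a PAM match and returns the full candidate record,
#' exactly as [enumerate_spacers()] would have produced it.
#'
#' @param spec An `edit_spec`.
#' @param spacer Spacer sequence, 5'->3' as it appears in the guide.
#' @param pam_pattern IUPAC PAM pattern (default `"NGG"`).
#' @return A `spacer_candidate`.
#' @export
validate_custom_spacer <- function(spec, spacer, pam_pattern = "NGG") {
  spacer <- .check_dna(spacer, "spacer")
  if (nchar(spacer) < 16L) {
    .stop_pegforge("pegforge_invalid_input", "spacer must be >= 16 nt")
  }
  pam_pattern <- toupper(pam_pattern)
  wt <- spec$wt_sequence
  L <- nchar(wt)
  plen <- nchar(pam_pattern)
  n <- nchar(spacer)
  plus <- .find_exact(wt, spacer)
  minus <- .find_exact(wt, reverse_complement(spacer))
  total <- length(plus) + length(minus)
  if (total == 0L) {
    .stop_pegforge("pegforge_spacer_not_found",
                   sprintf("spacer '%s' not found on either strand", spacer))
  }
  if (total > 1L) {
    .stop_pegforge(
      "pegforge_spacer_ambiguous",
      sprintf("spacer '%s' found %d times; the target site must be unique",
              spacer, total))
  }
  if (length(plus) == 1L) {
    i <- plus
    pam_at <- i + n
    if (pam_at + plen > L ||
        !matches_iupac(.sub0(wt, pam_at, pam_at + plen), pam_pattern)) {
      .stop_pegforge("pegforge_no_adjacent_pam",
                     sprintf("spacer found at [%d,%d) on + strand but no '%s' PAM follows",
                             i, i + n, pam_pattern))
    }
    .make_candidate(spec, "+", i, n, pam_at, plen)
  } else {
    i <- minus  # protospacer occupies [i, i+n) on top; PAM is upstream on top
    if (i - plen < 0L ||
        !matches_iupac(reverse_complement(.sub0(wt, i - plen, i)), pam_pattern)) {
      .stop_pegforge("pegforge_no_adjacent_pam",
                     sprintf("spacer found at [%d,%d) on - strand but no '%s' PAM follows",
                             i, i + n, pam_pattern))
    }
    .make_candidate(spec, "-", i, n, i - plen, plen)
  }
}

#' Tabulate spacer candidates
#'
#' @param candidates List of `spacer_candidate` records.
#' @return A data.frame, one row per candidate (coordinates 0-based half-open).
#' @export
spacer_table <- function(candidates) {
  if (length(candidates) == 0L) {
    return(data.frame(
      strand = character(0L), protospacer_start = integer(0L),
      protospacer_end = integer(0L), pam_start = integer(0L),
      pam_end = integer(0L), spacer_sequence = character(0L),
      pam_sequence = character(0L), nick_index = integer(0L),
      nick_to_edit_distance = integer(0L), pam_or_seed_disrupted = logical(0L),
      valid_for_pe = logical(0L), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(candidates, function(x) {
    data.frame(
      strand = x$strand,
      protospacer_start = x$protospacer_interval[1L],
      protospacer_end = x$protospacer_interval[2L],
      pam_start = x$pam_interval[1L],
      pam_end = x$pam_interval[2L],
      spacer_sequence = x$spacer_sequence,
      pam_sequence = x$pam_sequence,
      nick_index = x$nick_index,
      nick_to_edit_distance = x$nick_to_edit_distance,
      pam_or_seed_disrupted = x$pam_or_seed_disrupted,
      valid_for_pe = x$valid_for_pe,
      stringsAsFactors = FALSE
    )
  }))
}
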