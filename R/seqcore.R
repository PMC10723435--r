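# Sequence primitives, coordinate conventions and edit-notation parsing.
#
# Conventions used package-wide: coordinates are 0-based, half-open, on the
# top (input) strand; nick positions are inter-base indices on the top strand.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy sets; targets must be plain ACGT, ambiguity codes are
# allowed only in PAM patterns.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.stop_pegforge <- function(class, msg) {
  stop(structure(
    class = c(class, "pegforge_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# substring in 0-based half-open coordinates
.sub0 <- function(x, start, end) {
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.check_dna <- function(seq, what = "sequence", allow_empty = FALSE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    .stop_pegforge("pegforge_invalid_input",
                   sprintf("%s must be a single character string", what))
  }
  if (nchar(seq) == 0L) {
    if (allow_empty) return(toupper(seq))
    .stop_pegforge("pegforge_invalid_input", sprintf("%s is empty", what))
  }
  up <- toupper(seq)
  bad <- setdiff(unique(.chars(up)), DNA_BASES)
  if (length(bad) > 0L) {
    .stop_pegforge(
      "pegforge_alphabet_error",
      sprintf("%s contains non-ACGT character(s): %s", what,
              paste(sQuote(bad), collapse = ", "))
    )
  }
  up
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement of a plain A/C/G/T string. The operation is
#' an involution: applying it twice returns the input.
#'
#' @param seq Single DNA string (upper or lower case A/C/G/T).
#' @return The reverse complement, upper-cased.
#' @examples
#' reverse_complement("TGCAG")  # "CTGCA"
#' @export
reverse_complement <- function(seq) {
  seq <- .check_dna(seq, "seq")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# reverse complement for IUPAC patterns (PAM patterns may be degenerate)
.revcomp_iupac <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

#' GC content of a DNA sequence, in percent
#'
#' @param seq Nonempty DNA string.
#' @return Percentage of G+C bases, in `[0, 100]`.
#' @examples
#' gc_percent("GATC")  # 50
#' @export
gc_percent <- function(seq) {
  seq <- .check_dna(seq, "seq")
  ch <- .chars(seq)
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

#' Test a DNA string against an IUPAC pattern of equal length
#'
#' Position-wise membership of each base of `seq` in the degeneracy set of the
#' corresponding IUPAC code of `pattern` (e.g. the PAM pattern `"NGG"`).
#'
#' @param seq DNA string (A/C/G/T only).
#' @param pattern IUPAC pattern of the same length.
#' @return `TRUE` iff every position matches.
#' @examples
#' matches_iupac("AGG", "NGG")  # TRUE
#' @export
matches_iupac <- function(seq, pattern) {
  seq <- .check_dna(seq, "seq")
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L) {
    .stop_pegforge("pegforge_invalid_input", "pattern must be a nonempty string")
  }
  pattern <- toupper(pattern)
  if (nchar(seq) != nchar(pattern)) {
    .stop_pegforge("pegforge_length_mismatch",
                   sprintf("seq (%d nt) and pattern (%d nt) differ in length",
                           nchar(seq), nchar(pattern)))
  }
  pc <- .chars(pattern)
  unknown <- setdiff(unique(pc), names(IUPAC_SETS))
  if (length(unknown) > 0L) {
    .stop_pegforge("pegforge_unknown_iupac",
                   sprintf("unknown IUPAC code(s): %s",
                           paste(sQuote(unknown), collapse = ", ")))
  }
  sc <- .chars(seq)
  all(vapply(seq_along(sc), function(i) sc[i] %in% IUPAC_SETS[[pc[i]]],
             logical(1L)))
}

# ---- EditSpec ---------------------------------------------------------------

new_edit_spec <- function(wt_sequence, edited_sequence, edit_start,
                          wt_edit_end, edited_edit_end, edit_type) {
  spec <- structure(
    list(
      wt_sequence = wt_sequence,
      edited_sequence = edited_sequence,
      edit_start = as.integer(edit_start),
      wt_edit_end = as.integer(wt_edit_end),
      edited_edit_end = as.integer(edited_edit_end),
      edit_type = edit_type
    ),
    class = "edit_spec"
  )
  validate_edit_spec(spec)
  spec
}

validate_edit_spec <- function(spec) {
  with(spec, {
    stopifnot(
      edit_start >= 0L, wt_edit_end >= edit_start, edited_edit_end >= edit_start,
      wt_edit_end <= nchar(wt_sequence), edited_edit_end <= nchar(edited_sequence)
    )
    if (.sub0(wt_sequence, 0L, edit_start) !=
        .sub0(edited_sequence, 0L, edit_start)) {
      .stop_pegforge("pegforge_editspec_invariant", "left flanks differ")
    }
    if (.sub0(wt_sequence, wt_edit_end, nchar(wt_sequence)) !=
        .sub0(edited_sequence, edited_edit_end, nchar(edited_sequence))) {
      .stop_pegforge("pegforge_editspec_invariant", "right flanks differ")
    }
  })
  invisible(spec)
}

#' @export
print.edit_spec <- function(x, ...) {
  cat(sprintf("<edit_spec> %s edit, wt %d nt -> edited %d nt\n",
              x$edit_type, nchar(x$wt_sequence), nchar(x$edited_sequence)))
  cat(sprintf("  wt interval [%d,%d)  replaced by  edited interval [%d,%d)\n",
              x$edit_start, x$wt_edit_end, x$edit_start, x$edited_edit_end))
  cat(sprintf("  wt region '%s' -> '%s'\n",
              .sub0(x$wt_sequence, x$edit_start, x$wt_edit_end),
              .sub0(x$edited_sequence, x$edit_start, x$edited_edit_end)))
  invisible(x)
}

.classify_edit <- function(region, replacement) {
  if (nchar(region) == 0L) "insertion"
  else if (nchar(replacement) == 0L) "deletion"
  else if (nchar(region) == nchar(replacement)) "substitution"
  else "complex"
}

# common-prefix length of two strings
.lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- .chars(a); cb <- .chars(b)
  i <- 0L
  while (i < n && ca[i + 1L] == cb[i + 1L]) i <- i + 1L
  i
}

#' Parse the parenthesis edit notation into an edit specification
#'
#' The wild-type sequence is given with the region to edit wrapped in a single
#' pair of parentheses, and the replacement text separately (empty for a
#' deletion, while an empty parenthesized region marks an insertion point).
#' The edit interval is normalized to the minimal differing region by trimming
#' the common prefix and suffix of region vs replacement, so distance-to-edit
#' metrics do not depend on how generously the edit was bracketed.
#'
#' @param wt_notation Wild-type sequence containing exactly one `( ... )` pair.
#' @param replacement Replacement text (possibly empty).
#' @return An `edit_spec` with 0-based half-open edit intervals on the
#'   wild-type and edited sequences, and an `edit_type` of
#'   `"substitution"`, `"insertion"`, `"deletion"` or `"complex"`.
#' @examples
#' parse_edit_input("ACGT(A)CGT", "G")     # single-base substitution
#' parse_edit_input("ACGT()ACGT", "TT")    # insertion
#' parse_edit_input("AC(GT)AC", "")        # deletion
#' @export
parse_edit_input <- function(wt_notation, replacement = "") {
  if (!is.character(wt_notation) || length(wt_notation) != 1L) {
    .stop_pegforge("pegforge_invalid_input", "wt_notation must be one string")
  }
  n_open <- lengths(regmatches(wt_notation, gregexpr("(", wt_notation, fixed = TRUE)))
  n_close <- lengths(regmatches(wt_notation, gregexpr(")", wt_notation, fixed = TRUE)))
  if (n_open != 1L || n_close != 1L) {
    .stop_pegforge(
      "pegforge_parse_error",
      sprintf("expected exactly one '(...)' pair, found %d '(' and %d ')'",
              n_open, n_close)
    )
  }
  open_at <- regexpr("(", wt_notation, fixed = TRUE)[1L]
  close_at <- regexpr(")", wt_notation, fixed = TRUE)[1L]
  if (close_at < open_at) {
    .stop_pegforge("pegforge_parse_error", "')' precedes '('")
  }
  left <- .check_dna(substr(wt_notation, 1L, open_at - 1L),
                     "left flank", allow_empty = TRUE)
  region <- .check_dna(substr(wt_notation, open_at + 1L, close_at - 1L),
                       "parenthesized region", allow_empty = TRUE)
  right <- .check_dna(substr(wt_notation, close_at + 1L, nchar(wt_notation)),
                      "right flank", allow_empty = TRUE)
  replacement <- .check_dna(replacement, "replacement", allow_empty = TRUE)
  if (nchar(region) == 0L && nchar(replacement) == 0L) {
    .stop_pegforge("pegforge_empty_edit",
                   "parenthesized region and replacement are both empty")
  }
  # normalize to the minimal differing interval
  p <- .lcp(region, replacement)
  r2 <- substr(region, p + 1L, nchar(region))
  q2 <- substr(replacement, p + 1L, nchar(replacement))
  s <- .lcp(paste(rev(.chars(r2)), collapse = ""),
            paste(rev(.chars(q2)), collapse = ""))
  region_min <- substr(r2, 1L, nchar(r2) - s)
  repl_min <- substr(q2, 1L, nchar(q2) - s)
  if (nchar(region_min) == 0L && nchar(repl_min) == 0L) {
    .stop_pegforge("pegforge_empty_edit",
                   sprintf("edit region '%s' equals the replacement", region))
  }
  edit_start <- nchar(left) + p
  new_edit_spec(
    wt_sequence = paste0(left, region, right),
    edited_sequence = paste0(left, replacement, right),
    edit_start = edit_start,
    wt_edit_end = edit_start + nchar(region_min),
    edited_edit_end = edit_start + nchar(repl_min),
    edit_type = .classify_edit(region_min, repl_min)
  )
}

#' Infer an edit specification from a wild-type / edited sequence pair
#'
#' Alternative input route: the full edited sequence is supplied instead of a
#' replacement text, and the minimal edit interval is inferred by trimming the
#' longest common prefix and suffix.
#'
#' @param wt_sequence Wild-type DNA string.
#' @param edited_sequence Full edited DNA string.
#' @return An `edit_spec`.
#' @export
parse_edit_pair <- function(wt_sequence, edited_sequence) {
  wt <- .check_dna(wt_sequence, "wt_sequence")
  ed <- .check_dna(edited_sequence, "edited_sequence")
  if (wt == ed) {
    .stop_pegforge("pegforge_empty_edit",
                   "wild-type and edited sequences are identical")
  }
  p <- .lcp(wt, ed)
  wr <- paste(rev(.chars(wt)), collapse = "")
  er <- paste(rev(.chars(ed)), collapse = "")
  s <- .lcp(wr, er)
  # prefix and suffix may overlap when the edit is a pure indel in a repeat
  s <- min(s, nchar(wt) - p, nchar(ed) - p)
  region <- .sub0(wt, p, nchar(wt) - s)
  repl <- .sub0(ed, p, nchar(ed) - s)
  new_edit_spec(
    wt_sequence = wt, edited_sequence = ed,
    edit_start = p,
    wt_edit_end = nchar(wt) - s,
    edited_edit_end = nchar(ed) - s,
    edit_type = .classify_edit(region, repl)
  )
}

#' Read the first record of a FASTA file as edit-notation input
#'
#' Minimal single-record FASTA reader. The sequence line(s) may contain the
#' parenthesized edit region, which standard DNA FASTA readers reject, so this
#' reader is deliberately plain-text.
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return A list with `description` and `sequence` (whitespace stripped).
#' @export
read_fasta_input <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) {
    .stop_pegforge("pegforge_parse_error", "no FASTA header ('>') found")
  }
  first <- headers[1L]
  end <- if (length(headers) > 1L) headers[2L] - 1L else length(lines)
  seq <- gsub("[[:space:]]", "", paste(lines[(first + 1L):end], collapse = ""))
  if (first + 1L > end || nchar(seq) == 0L) {
    .stop_pegforge("pegforge_parse_error", "first FASTA record has no sequence")
  }
  list(description = sub("^>\\s*", "", lines[first]), sequence = seq)
}

# overlap of two half-open intervals, with zero-width intervals treated as
# inter-base points (a point disrupts a window only strictly inside it)
.interval_overlaps <- function(a1, a2, b1, b2) {
  if (a1 == a2) return(b1 < a1 && a1 < b2)
  if (b1 == b2) return(a1 < b1 && b1 < a2)
  max(a1, b1) < min(a2, b2)
}
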