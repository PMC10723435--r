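# Synthetic target generator: random loci with a planted protospacer+PAM and
# an edit placed a known distance 3' of the nick, so the whole pipeline is
# testable without external data.

.random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate reproducible synthetic design fixtures
#'
#' Each fixture is a random target guaranteed to contain at least one
#' spacer+NGG site whose nick lies 0-20 nt (configurable) 5' of the edit, so
#' a valid prime-editing design always exists. Substitutions, insertions and
#' deletions are mixed according to `edit_mix`; half the fixtures (on
#' average) are mirrored onto the minus strand. The same seed always yields
#' the same fixtures.
#'
#' @param seed Integer seed.
#' @param n Number of fixtures (>= 1).
#' @param target_len_range Target length range in nt (default 150-300).
#' @param edit_mix Named weights for `substitution`, `insertion`, `deletion`.
#' @param edit_distance_range Range of nick-to-edit distances to plant
#'   (default 0-20 nt).
#' @return List of fixtures; each has `wt_notation`, `replacement`, `spec`
#'   (the expected `edit_spec`) and the planted `strand`.
#' @export
generate_fixtures <- function(seed, n, target_len_range = c(150L, 300L),
                              edit_mix = c(substitution = 1, insertion = 1,
                                           deletion = 1),
                              edit_distance_range = c(0L, 20L)) {
  if (n < 1L) .stop_pegforge("pegforge_invalid_input", "n must be >= 1")
  target_len_range <- as.integer(target_len_range)
  if (target_len_range[1L] < 120L) {
    .stop_pegforge("pegforge_invalid_input",
                   "targets shorter than 120 nt cannot host the planted site plus flanks")
  }
  mix_names <- c("substitution", "insertion", "deletion")
  w <- edit_mix[mix_names]
  w[is.na(w)] <- 0
  if (sum(w) <= 0) {
    .stop_pegforge("pegforge_invalid_input", "edit_mix has no positive weight")
  }
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    L <- sample(seq.int(target_len_range[1L], target_len_range[2L]), 1L)
    type <- sample(mix_names, 1L, prob = w)
    d <- sample(seq.int(edit_distance_range[1L], edit_distance_range[2L]), 1L)
    # plus-strand frame: [left flank a][protospacer 20][NGG PAM][right flank]
    # nick at a+17; the edit starts d nt 3' of the nick and the right flank
    # leaves room for the longest RTT (31 nt past the nick) plus slack
    a <- sample(seq.int(5L, L - 100L), 1L)
    proto <- .random_dna(20L)
    pam <- paste0(sample(DNA_BASES, 1L), "GG")
    right_len <- L - a - 23L
    wt <- paste0(.random_dna(a), proto, pam, .random_dna(right_len))
    edit_start <- a + 17L + d
    if (type == "substitution") {
      wlen <- sample(1L:3L, 1L)
      region <- .sub0(wt, edit_start, edit_start + wlen)
      repl_chars <- vapply(seq_len(wlen), function(j) {
        ref <- substr(region, j, j)
        if (j == 1L || j == wlen) sample(setdiff(DNA_BASES, ref), 1L)
        else sample(DNA_BASES, 1L)
      }, character(1L))
      # both ends must differ so the interval is already minimal
      if (wlen > 1L) {
        repl_chars[wlen] <- sample(setdiff(DNA_BASES,
                                           substr(region, wlen, wlen)), 1L)
      }
      replacement <- paste(repl_chars, collapse = "")
      region_end <- edit_start + wlen
    } else if (type == "insertion") {
      region <- ""
      replacement <- .random_dna(sample(1L:5L, 1L))
      region_end <- edit_start
    } else {
      wlen <- sample(1L:5L, 1L)
      region <- .sub0(wt, edit_start, edit_start + wlen)
      replacement <- ""
      region_end <- edit_start + wlen
    }
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") {
      left <- .sub0(wt, 0L, edit_start)
      right <- .sub0(wt, region_end, L)
      wt_m <- reverse_complement(wt)
      region_m <- if (nchar(region) > 0L) reverse_complement(region) else ""
      replacement_m <- if (nchar(replacement) > 0L)
        reverse_complement(replacement) else ""
      notation <- paste0(reverse_complement(right), "(", region_m, ")",
                         reverse_complement(left))
      fixture_notation <- notation
      fixture_replacement <- replacement_m
    } else {
      fixture_notation <- paste0(.sub0(wt, 0L, edit_start), "(", region, ")",
                                 .sub0(wt, region_end, L))
      fixture_replacement <- replacement
    }
    spec <- parse_edit_input(fixture_notation, fixture_replacement)
    list(wt_notation = fixture_notation, replacement = fixture_replacement,
         spec = spec, strand = strand, edit_type = type,
         planted_distance = d)
  })
}
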