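# Independent brute-force oracles, written in plain base R with their own
# IUPAC table and complement map so they share no code path with the package.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_rc <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_iupac_match <- function(seq, pattern) {
  sc <- strsplit(seq, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  if (length(sc) != length(pc)) return(FALSE)
  all(mapply(function(s, p) s %in% ORACLE_IUPAC[[p]], sc, pc))
}

# every (strand, protospacer start) pair where a spacer_len-mer abuts a PAM
oracle_scan_spacers <- function(wt, pam = "NGG", spacer_len = 20L) {
  L <- nchar(wt)
  plen <- nchar(pam)
  out <- character(0L)
  for (p in 0:(L - plen)) {
    window <- substr(wt, p + 1L, p + plen)
    if (oracle_iupac_match(window, pam) && p >= spacer_len) {
      out <- c(out, sprintf("+:%d", p - spacer_len))
    }
    if (oracle_iupac_match(oracle_rc(window), pam) &&
        p + plen + spacer_len <= L) {
      out <- c(out, sprintf("-:%d", p + plen))
    }
  }
  sort(out)
}

# every (enzyme, strand, position) occurrence of a recognition motif
oracle_scan_motif <- function(seq, motif) {
  L <- nchar(seq)
  m <- nchar(motif)
  rc <- oracle_rc(motif)
  out <- character(0L)
  if (m > L) return(out)
  for (p in 0:(L - m)) {
    w <- substr(seq, p + 1L, p + m)
    if (w == motif) out <- c(out, sprintf("+:%d", p))
    if (w == rc) out <- c(out, sprintf("-:%d", p))
  }
  sort(out)
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mirror an edit_spec onto the opposite strand (coordinates reflected)
mirror_spec <- function(spec) {
  Lw <- nchar(spec$wt_sequence)
  Le <- nchar(spec$edited_sequence)
  pegforge:::new_edit_spec(
    wt_sequence = oracle_rc(spec$wt_sequence),
    edited_sequence = oracle_rc(spec$edited_sequence),
    edit_start = Lw - spec$wt_edit_end,
    wt_edit_end = Lw - spec$edit_start,
    edited_edit_end = Le - spec$edit_start,
    edit_type = spec$edit_type)
}

candidate_keys <- function(cands) {
  sort(vapply(cands, function(x)
    sprintf("%s:%d", x$strand, x$protospacer_interval[1L]), character(1L)))
}

# spec's worked toy target: 34 nt, + strand protospacer [4,24) with AGG PAM,
# nick at 21, A>G substitution at top index 22
toy_notation <- function() {
  list(wt_notation = "TTTTAAGGCTTCATACGGATCT(A)CAGGCCCGATT",
       replacement = "G")
}
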