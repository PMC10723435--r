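# Golden-gate cloning: oligo design, Type IIS digestion simulation and
# one-pot assembly verification.

# Type IIS enzyme geometry: recognition site, spacer between site and cut on
# the recognition strand, and 5' overhang width.
TYPE_IIS_ENZYMES <- list(
  BbsI = list(site = "GAAGAC", spacer = 2L, overhang = 4L),
  BsaI = list(site = "GGTCTC", spacer = 1L, overhang = 4L)
)

.enzyme_info <- function(enzyme) {
  if (!enzyme %in% names(TYPE_IIS_ENZYMES)) {
    .stop_pegforge("pegforge_unknown_enzyme",
                   sprintf("unknown Type IIS enzyme '%s'", enzyme))
  }
  TYPE_IIS_ENZYMES[[enzyme]]
}

.is_palindromic <- function(x) identical(x, reverse_complement(x))

.check_overhang <- function(x, what) {
  if (is.null(x) || !is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    .stop_pegforge("pegforge_overhang_config",
                   sprintf("%s overhang missing or empty", what))
  }
  x <- .check_dna(x, what)
  if (nchar(x) != 4L) {
    .stop_pegforge("pegforge_overhang_config",
                   sprintf("%s overhang must be 4 nt, got '%s'", what, x))
  }
  if (.is_palindromic(x)) {
    .stop_pegforge("pegforge_palindromic_overhang",
                   sprintf("%s overhang '%s' is self-complementary (self-ligation risk)",
                           what, x))
  }
  x
}

#' Find Type IIS recognition sites on both strands
#'
#' @param seq DNA string.
#' @param enzymes Character vector of enzyme names (default BbsI and BsaI).
#' @return data.frame with columns `enzyme`, `strand`, `position` (0-based
#'   start of the recognition sequence occurrence on the top strand).
#' @export
internal_site_check <- function(seq, enzymes = c("BbsI", "BsaI")) {
  seq <- .check_dna(seq, "seq")
  rows <- list()
  for (e in enzymes) {
    info <- .enzyme_info(e)
    for (pos in .find_exact(seq, info$site)) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = e, strand = "+", position = pos, stringsAsFactors = FALSE)
    }
    for (pos in .find_exact(seq, reverse_complement(info$site))) {
      rows[[length(rows) + 1L]] <- data.frame(
        enzyme = e, strand = "-", position = pos, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(enzyme = character(0L), strand = character(0L),
                      position = integer(0L), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$position, out$enzyme, out$strand), , drop = FALSE]
}

new_oligo_pair <- function(name, sense, antisense, overhang_top,
                           overhang_bottom, purpose) {
  structure(
    list(name = name, sense = sense, antisense = antisense,
         overhang_top = overhang_top, overhang_bottom = overhang_bottom,
         purpose = purpose),
    class = "oligo_pair")
}

#' @export
print.oligo_pair <- function(x, ...) {
  cat(sprintf("<oligo_pair> %s (%s)\n  sense     5'-%s-3' (%d nt)\n  antisense 5'-%s-3' (%d nt)\n",
              x$name, x$purpose, x$sense, nchar(x$sense),
              x$antisense, nchar(x$antisense)))
  invisible(x)
}

#' Check the annealing invariant of an oligo pair
#'
#' For a `guide_duplex` pair, verifies that annealing sense and antisense
#' yields a perfectly complementary duplex core with single-stranded 5'
#' extensions equal to the declared overhangs. For a synthesized
#' `pegrna_fragment`, verifies that the two strands are full-length reverse
#' complements (blunt double-stranded fragment).
#'
#' @param pair An `oligo_pair`.
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
check_annealing <- function(pair) {
  stopifnot(inherits(pair, "oligo_pair"))
  if (pair$purpose == "guide_duplex") {
    nt <- nchar(pair$overhang_top)
    nb <- nchar(pair$overhang_bottom)
    core_s <- substr(pair$sense, nt + 1L, nchar(pair$sense))
    core_a <- substr(pair$antisense, nb + 1L, nchar(pair$antisense))
    if (!identical(core_s, reverse_complement(core_a))) {
      .stop_pegforge("pegforge_annealing_error",
                     "duplex core is not perfectly complementary")
    }
    if (substr(pair$sense, 1L, nt) != pair$overhang_top ||
        substr(pair$antisense, 1L, nb) != pair$overhang_bottom) {
      .stop_pegforge("pegforge_annealing_error",
                     "5' extensions do not equal the declared overhangs")
    }
  } else {
    if (!identical(pair$antisense, reverse_complement(pair$sense))) {
      .stop_pegforge("pegforge_annealing_error",
                     "fragment strands are not reverse complements")
    }
  }
  invisible(TRUE)
}

#' Sense/antisense oligos for golden-gate cloning of a guide spacer
#'
#' Builds the classic annealed-duplex cloning pair for a U6 guide cassette:
#' `sense = overhang_top + spacer`, `antisense = overhang_bottom +
#' reverse_complement(spacer)`, leaving 4-nt 5' extensions that ligate into
#' the Type IIS-digested backbone.
#'
#' @param spacer_sequence Guide spacer, already satisfying the 5'-G policy.
#' @param overhangs List with `top` and `bottom` 4-nt overhangs (defaults
#'   `CACC`/`AAAC`, the ubiquitous hU6 convention).
#' @param name Oligo-pair name for the order sheet.
#' @return An `oligo_pair` of purpose `"guide_duplex"`.
#' @export
guide_duplex_oligos <- function(spacer_sequence,
                                overhangs = list(top = "CACC", bottom = "AAAC"),
                                name = "guide") {
  spacer <- .check_dna(spacer_sequence, "spacer")
  top <- .check_overhang(overhangs$top, "top")
  bottom <- .check_overhang(overhangs$bottom, "bottom")
  pair <- new_oligo_pair(
    name = name,
    sense = paste0(top, spacer),
    antisense = paste0(bottom, reverse_complement(spacer)),
    overhang_top = top, overhang_bottom = bottom,
    purpose = "guide_duplex")
  check_annealing(pair)
  pair
}

#' Synthesized BbsI fragment carrying a pegRNA cassette
#'
#' Emits the double-stranded fragment ordered for synthesis: the pegRNA
#' cassette flanked by convergent Type IIS recognition sites positioned so
#' digestion releases the cassette with the configured 4-nt overhangs, ready
#' for golden-gate cloning into a U6 backbone. Errors if the cassette itself
#' contains a recognition site (digestion would cut the insert).
#'
#' @param design A `pegrna_design`.
#' @param enzyme Type IIS enzyme (default `"BbsI"`).
#' @param overhang_config List with `upstream` (top-strand 5' overhang at the
#'   promoter junction) and `downstream` (bottom-strand 5' overhang at the
#'   terminator junction), both 4 nt.
#' @return An `oligo_pair` of purpose `"pegrna_fragment"`; the fragment top
#'   strand is in `$sense`.
#' @export
pegrna_fragment <- function(design, enzyme = "BbsI",
                            overhang_config = list(upstream = "CACC",
                                                   downstream = "AAAC")) {
  stopifnot(inherits(design, "pegrna_design"))
  info <- .enzyme_info(enzyme)
  up <- .check_overhang(overhang_config$upstream, "upstream")
  down <- .check_overhang(overhang_config$downstream, "downstream")
  cassette <- design$full_sequence
  internal <- internal_site_check(cassette, enzyme)
  if (nrow(internal) > 0L) {
    .stop_pegforge(
      "pegforge_internal_site",
      sprintf("pegRNA cassette contains %s recognition site(s) at position(s) %s",
              enzyme, paste(internal$position, collapse = ", ")))
  }
  pad <- "CA"  # terminal padding so the outermost cuts are internal
  spacer_nt <- paste(rep("A", info$spacer), collapse = "")
  top <- paste0(pad, info$site, spacer_nt, up, cassette,
                reverse_complement(down), spacer_nt,
                reverse_complement(info$site), pad)
  # junction sequences could in principle recreate a site; refuse rather than
  # emit a fragment that will not digest cleanly
  hits <- internal_site_check(top, enzyme)
  if (sum(hits$strand == "+") != 1L || sum(hits$strand == "-") != 1L) {
    .stop_pegforge("pegforge_internal_site",
                   "fragment flanks recreate an unintended recognition site")
  }
  new_oligo_pair(
    name = "pegRNA_fragment",
    sense = top, antisense = reverse_complement(top),
    overhang_top = up, overhang_bottom = down,
    purpose = "pegrna_fragment")
}

# ---- digestion / ligation simulator ----------------------------------------

new_gg_insert <- function(left_key, core, right_key) {
  structure(list(left_key = left_key, core = core, right_key = right_key),
            class = "gg_insert")
}

#' Simulate Type IIS digestion of one double-stranded fragment
#'
#' Finds the convergent recognition-site pair, computes the cut positions
#' from the enzyme geometry (BbsI: GAAGAC + 2-nt spacer, BsaI: GGTCTC + 1-nt
#' spacer, both leaving 4-nt 5' overhangs) and returns the released insert:
#' its duplex core and the two 4-nt overhang keys (each recorded as the
#' top-strand 4-mer at the junction). Digestion is idempotent: an already
#' released insert (no recognition sites remain) is returned unchanged.
#'
#' @param fragment An `oligo_pair`, a top-strand string, or a `gg_insert`.
#' @param enzyme Type IIS enzyme name.
#' @return A `gg_insert`.
#' @export
digest_fragment <- function(fragment, enzyme = "BbsI") {
  if (inherits(fragment, "gg_insert")) return(fragment)
  seq <- if (inherits(fragment, "oligo_pair")) fragment$sense else
    .check_dna(fragment, "fragment")
  info <- .enzyme_info(enzyme)
  hits <- internal_site_check(seq, enzyme)
  plus <- hits$position[hits$strand == "+"]
  minus <- hits$position[hits$strand == "-"]
  if (length(plus) == 0L || length(minus) == 0L) {
    .stop_pegforge(
      "pegforge_digest_error",
      sprintf("fragment lacks a convergent %s site pair (found %d '+' and %d '-' sites)",
              enzyme, length(plus), length(minus)))
  }
  s <- min(plus)   # leftmost rightward-cutting site
  q <- max(minus)  # rightmost leftward-cutting site
  left_cut <- s + 6L + info$spacer            # top-strand cut, left end
  right_cut <- q - info$spacer - info$overhang  # top-strand cut, right end
  if (left_cut + info$overhang > right_cut) {
    .stop_pegforge("pegforge_digest_error",
                   "recognition sites are divergent or too close to release an insert")
  }
  new_gg_insert(
    left_key = .sub0(seq, left_cut, left_cut + info$overhang),
    core = .sub0(seq, left_cut + info$overhang, right_cut),
    right_key = .sub0(seq, right_cut, right_cut + info$overhang))
}

#' Default golden-gate backbone descriptor
#'
#' The destination vector is modeled as a descriptor — its junction overhangs
#' and annotated promoter/terminator — rather than a full plasmid sequence.
#' The promoter and stuffer sequences here are short synthetic stand-ins
#' (site-free by construction); the real plasmid set is not modeled.
#'
#' @param terminator Append a polyT (TTTTTTT) Pol III terminator downstream
#'   of the insert (default `TRUE`).
#' @param upstream_key Top-strand 4-mer the backbone presents to the first
#'   insert's left overhang (default `"CACC"`).
#' @param downstream_key Top-strand 4-mer matching the last insert's right
#'   overhang (default `"GTTT"`, the top-strand face of an `AAAC` bottom
#'   overhang).
#' @return A `gg_backbone` descriptor.
#' @export
default_backbone <- function(terminator = TRUE, upstream_key = "CACC",
                             downstream_key = "GTTT") {
  structure(
    list(
      name = "synthetic-hU6-backbone",
      promoter = "hU6",
      promoter_seq = "TTCACGCATAGCAGTATACGCTAGTCACGTAT",  # synthetic, site-free
      upstream_key = .check_overhang(upstream_key, "backbone upstream"),
      downstream_key = .check_overhang(downstream_key, "backbone downstream"),
      terminator = if (isTRUE(terminator)) "TTTTTTT" else "",
      stuffer = "CGATACGTCATGCATGACTATCGCGT"  # synthetic vector body
    ),
    class = "gg_backbone")
}

#' Simulate a one-pot golden-gate assembly
#'
#' Digests every part, checks the released inserts for residual recognition
#' sites and duplicate or palindromic overhangs, then ligates by unique
#' overhang complementarity into a single circular product: backbone ->
#' insert 1 -> ... -> insert N -> backbone. Success requires exactly one
#' circular product whose promoter is immediately followed by the cassette(s)
#' in order and whose insert region retains no recognition site.
#'
#' @param parts List of fragments (`oligo_pair`, top-strand string or
#'   `gg_insert`).
#' @param backbone A `gg_backbone` descriptor (default [default_backbone()]).
#' @param enzyme Type IIS enzyme used for the assembly.
#' @return An `assembly_report`: `success`, `product_sequence` (circular,
#'   canonical rotation starting at the promoter), `junction_list`,
#'   `residual_sites`, `transcription_unit` (single-insert assemblies) and
#'   `diagnostics`.
#' @export
simulate_golden_gate <- function(parts, backbone = default_backbone(),
                                 enzyme = "BbsI") {
  stopifnot(inherits(backbone, "gg_backbone"), length(parts) >= 1L)
  diagnostics <- character(0L)
  fail <- function(msg) {
    structure(
      list(success = FALSE, product_sequence = NA_character_,
           junction_list = character(0L), residual_sites = NA_integer_,
           transcription_unit = NA_character_,
           diagnostics = c(diagnostics, msg)),
      class = "assembly_report")
  }
  inserts <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    ins <- tryCatch(digest_fragment(parts[[i]], enzyme),
                    pegforge_error = function(e) e)
    if (inherits(ins, "condition")) {
      return(fail(sprintf("part %d: %s", i, conditionMessage(ins))))
    }
    inserts[[i]] <- ins
  }
  residual <- sum(vapply(inserts, function(x)
    nrow(internal_site_check(x$core, enzyme)), integer(1L)))
  if (residual > 0L) {
    return(fail(sprintf("residual internal %s site(s) in released insert(s): %d",
                        enzyme, residual)))
  }
  left_keys <- vapply(inserts, function(x) x$left_key, character(1L))
  right_keys <- vapply(inserts, function(x) x$right_key, character(1L))
  all_keys <- c(left_keys, backbone$downstream_key)
  if (anyDuplicated(all_keys) || anyDuplicated(c(right_keys, backbone$upstream_key))) {
    return(fail("duplicate overhang among junctions"))
  }
  pal <- vapply(unique(c(left_keys, right_keys, backbone$upstream_key,
                         backbone$downstream_key)),
                .is_palindromic, logical(1L))
  if (any(pal)) {
    return(fail(sprintf("palindromic overhang(s): %s",
                        paste(names(pal)[pal], collapse = ", "))))
  }
  # walk the unique-overhang chain from the backbone
  chain <- integer(0L)
  cur <- backbone$upstream_key
  remaining <- seq_along(inserts)
  while (length(remaining) > 0L) {
    nxt <- remaining[left_keys[remaining] == cur]
    if (length(nxt) != 1L) {
      return(fail(sprintf("unligatable overhang set: no unique continuation from '%s'",
                          cur)))
    }
    chain <- c(chain, nxt)
    cur <- right_keys[nxt]
    remaining <- setdiff(remaining, nxt)
  }
  if (cur != backbone$downstream_key) {
    return(fail(sprintf("unligatable overhang set: final overhang '%s' does not close on the backbone ('%s')",
                        cur, backbone$downstream_key)))
  }
  cores <- vapply(inserts[chain], function(x) x$core, character(1L))
  inner_keys <- if (length(chain) > 1L)
    right_keys[chain[-length(chain)]] else character(0L)
  insert_region <- paste0(
    backbone$upstream_key,
    paste(vapply(seq_along(cores), function(i) {
      paste0(cores[i], if (i < length(cores)) inner_keys[i] else "")
    }, character(1L)), collapse = ""),
    backbone$downstream_key)
  product <- paste0(backbone$promoter_seq, insert_region,
                    backbone$terminator, backbone$stuffer)
  residual_product <- nrow(internal_site_check(insert_region, enzyme))
  if (residual_product > 0L) {
    return(fail("ligated insert region recreates a recognition site"))
  }
  tu <- if (length(cores) == 1L) paste0(cores, backbone$terminator)
        else NA_character_
  structure(
    list(
      success = TRUE,
      product_sequence = product,
      junction_list = c(backbone$upstream_key, inner_keys,
                        backbone$downstream_key),
      residual_sites = 0L,
      transcription_unit = tu,
      diagnostics = diagnostics),
    class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report> %s, %d junction(s)%s\n",
              if (x$success) "success" else "FAILED",
              length(x$junction_list),
              if (length(x$diagnostics) > 0L)
                paste0("; ", paste(x$diagnostics, collapse = "; ")) else ""))
  invisible(x)
}
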