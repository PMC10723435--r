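# Minimal GenBank flat-file writer for the annotated assembled construct.
# Hand-rolled on purpose: only LOCUS/FEATURES/ORIGIN records are needed and
# no installed package writes GenBank.

.gb_feature <- function(key, start1, end1, label) {
  c(sprintf("     %-16s%d..%d", key, start1, end1),
    sprintf("                     /label=\"%s\"", label))
}

.gb_origin <- function(seq) {
  n <- nchar(seq)
  lines <- character(0L)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off,
                              paste(tolower(blocks), collapse = " ")))
  }
  lines
}

#' Write the assembled construct as an annotated GenBank file
#'
#' Annotates the simulated circular assembly product of one emitted design:
#' promoter, golden-gate junctions, spacer, scaffold, RTT, PBS and (when
#' modeled) the polyT terminator.
#'
#' @param design_entry One element of `design_report$designs` whose cloning
#'   kit contains a successful assembly.
#' @param config The `design_config` used for the run.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_construct_genbank <- function(design_entry, config, path) {
  kit <- design_entry$cloning
  if (is.null(kit$assembly) || !isTRUE(kit$assembly$success)) {
    .stop_pegforge("pegforge_invalid_input",
                   "design entry has no successful simulated assembly")
  }
  design <- design_entry$design
  backbone <- default_backbone(
    terminator = config$terminator,
    upstream_key = config$overhangs$fragment_upstream,
    downstream_key = reverse_complement(config$overhangs$fragment_downstream))
  seq <- kit$assembly$product_sequence
  # feature layout mirrors the product construction in simulate_golden_gate
  at <- 0L
  feats <- list()
  push <- function(key, len, label) {
    if (len > 0L) {
      feats[[length(feats) + 1L]] <<- .gb_feature(key, at + 1L, at + len, label)
    }
    at <<- at + len
  }
  push("promoter", nchar(backbone$promoter_seq), backbone$promoter)
  push("misc_feature", 4L, "GG junction (upstream)")
  push("misc_feature", nchar(design$spacer_emitted), "spacer")
  push("misc_feature", nchar(design$scaffold), "sgRNA scaffold")
  push("misc_feature", design$rtt$length, "RT template")
  push("misc_feature", design$pbs$length, "primer binding site")
  push("misc_feature", 4L, "GG junction (downstream)")
  push("terminator", nchar(backbone$terminator), "polyT terminator")
  push("misc_feature", nchar(backbone$stuffer), "vector body (synthetic)")
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular SYN %s",
            "pegforge_construct", nchar(seq),
            format(Sys.Date(), "%d-%b-%Y")),
    sprintf("DEFINITION  Simulated golden-gate product, %s strategy pegRNA cassette.",
            design$strategy),
    "FEATURES             Location/Qualifiers",
    unlist(feats),
    "ORIGIN",
    .gb_origin(seq),
    "//")
  writeLines(lines, path)
  invisible(path)
}

#' A deterministic worked-example target
#'
#' A 120-nt synthetic locus built from a GC-balanced repeat with one planted
#' protospacer+AGG site and a central T>A substitution 2 nt 3' of the nick.
#' Used in the package documentation and examples; every PBS length 8-17 at
#' this locus clears the 30% GC threshold, so the preferred-length ranking is
#' visible undisturbed.
#'
#' @return List with `wt_notation` and `replacement`.
#' @export
demo_target <- function() {
  unit <- "ACGTG"
  left <- substr(strrep(unit, 8L), 1L, 39L)              # [0,39)
  proto <- strrep("GACGT", 4L)                           # [39,59), starts with G
  pam <- "AGG"                                           # [59,62)
  right <- substr(strrep(unit, 12L), 1L, 120L - 62L)     # [62,120)
  wt <- paste0(left, proto, pam, right)
  stopifnot(nchar(wt) == 120L, substr(wt, 59L, 59L) == "T")
  # nick at 56 (0-based inter-base); edit at top index 58: T -> A
  list(wt_notation = paste0(.sub0(wt, 0L, 58L), "(T)", .sub0(wt, 59L, 120L)),
       replacement = "A")
}
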