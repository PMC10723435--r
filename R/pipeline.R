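# End-to-end design driver and structured report writers.

`%||%` <- function(a, b) if (is.null(a)) b else a

.strategies_for <- function(config) {
  switch(config$strategy,
         all = c("PE2", "PE3", "PE3b"),
         pe2 = "PE2", pe3 = "PE3", pe3b = "PE3b")
}

#' Run the complete pegRNA design pipeline
#'
#' Executes the five-step flow: parse the edit input, enumerate (or validate)
#' spacers, build PBS/RTT options with warnings, select PE3/PE3b secondary
#' nicking guides per strategy, assemble pegRNAs and cloning kits, and verify
#' every emitted design twice — the predicted edited locus must equal the
#' requested edited sequence, and simulated golden-gate assembly of the
#' emitted fragment must succeed with the intended transcription unit. The
#' run is deterministic for a fixed input and configuration.
#'
#' @param spec_input An `edit_spec`, or a wild-type notation string with the
#'   edit in parentheses (then `replacement` supplies the replacement text).
#' @param config A `design_config` (default [design_config()]).
#' @param replacement Replacement text when `spec_input` is a notation string.
#' @param custom_spacer Optional user-supplied spacer; validated against the
#'   target instead of enumerating.
#' @return A `design_report` with `status` (`"ok"` or `"no_valid_spacer"`),
#'   the ranked candidate tables, the emitted designs with their cloning kits
#'   and verification flags, and structured notes.
#' @export
run_design <- function(spec_input, config = design_config(),
                       replacement = NULL, custom_spacer = NULL) {
  stopifnot(inherits(config, "design_config"))
  spec <- if (inherits(spec_input, "edit_spec")) spec_input
          else parse_edit_input(spec_input, replacement %||% "")
  notes <- character(0L)
  if (!is.null(custom_spacer)) {
    spacers <- list(validate_custom_spacer(spec, custom_spacer,
                                           config$pam_pattern))
  } else {
    spacers <- enumerate_spacers(spec, config$pam_pattern, config$spacer_len)
  }
  valid <- Filter(function(x) x$valid_for_pe, spacers)
  if (length(valid) == 0L) {
    diag <- attr(spacers, "diagnostic") %||%
      "no candidate places the edit 3' of a nick"
    return(structure(
      list(status = "no_valid_spacer", input = spec, config = config,
           spacers = spacer_table(spacers), nick_guides = nick_guide_table(list()),
           designs = list(), notes = c(notes, diag)),
      class = "design_report"))
  }
  chosen <- valid[seq_len(min(config$n_spacers, length(valid)))]
  strategies <- .strategies_for(config)
  designs <- list()
  for (cand in chosen) {
    pbs_all <- tryCatch(
      pbs_options(cand, spec, config$pbs_range, config$pbs_preferred,
                  config$gc_warn_threshold),
      pegforge_error = function(e) e)
    rtt_all <- tryCatch(
      rtt_options(cand, spec, config$rtt_range, config$rtt_preferred,
                  config$min_post_edit_homology),
      pegforge_error = function(e) e)
    if (inherits(pbs_all, "condition") || inherits(rtt_all, "condition")) {
      msg <- if (inherits(pbs_all, "condition")) conditionMessage(pbs_all)
             else conditionMessage(rtt_all)
      notes <- c(notes, sprintf("spacer %s skipped: %s", cand$id, msg))
      next
    }
    guides <- enumerate_nick_guides(spec, cand, config$pam_pattern,
                                    config$pe3_window, config$spacer_len)
    guides_by_mode <- list(
      PE3 = Filter(function(g) g$mode == "PE3", guides),
      PE3b = Filter(function(g) g$mode == "PE3b", guides))
    for (strategy in strategies) {
      eff_strategy <- strategy
      if (strategy %in% c("PE3", "PE3b") &&
          length(guides_by_mode[[strategy]]) == 0L) {
        note_tag <- sprintf("no %s candidate for spacer %s", strategy, cand$id)
        if (config$strategy == "all") {
          # 'all' already covers the other strategies; just record the gap
          notes <- c(notes, note_tag)
          next
        }
        fallback <- toupper(config$pe3b_fallback)
        if (strategy == "PE3b" && fallback != "NONE" &&
            (fallback == "PE2" ||
             length(guides_by_mode[[fallback]]) > 0L)) {
          notes <- c(notes, sprintf("%s; falling back to %s", note_tag, fallback))
          eff_strategy <- fallback
        } else {
          notes <- c(notes, note_tag)
          next
        }
      }
      nick_guide <- if (eff_strategy %in% c("PE3", "PE3b"))
        guides_by_mode[[eff_strategy]][[1L]] else NULL
      n_pbs <- min(config$n_pbs, length(pbs_all))
      n_rtt <- min(config$n_rtt, length(rtt_all))
      for (pi in seq_len(n_pbs)) {
        for (ri in seq_len(n_rtt)) {
          design <- assemble_pegrna(cand, pbs_all[[pi]], rtt_all[[ri]],
                                    config$scaffold, eff_strategy,
                                    config$five_prime_g_policy)
          locus <- predict_edited_locus(design, spec)
          kit <- .build_cloning_kit(design, nick_guide, config)
          if (is.null(kit$fragment)) {
            # cassette cannot be released cleanly (internal Type IIS site):
            # not a usable reagent, so it is excluded rather than emitted
            notes <- c(notes, sprintf("design dropped (uncloneable): %s",
                                      kit$diagnostics))
            next
          }
          designs[[length(designs) + 1L]] <- list(
            design = design,
            nick_guide = nick_guide,
            cloning = kit,
            predicted_locus = locus,
            verified_locus = identical(locus, spec$edited_sequence),
            verified_assembly = kit$assembly_ok)
        }
      }
    }
  }
  structure(
    list(status = if (length(designs) > 0L) "ok" else "no_design",
         input = spec, config = config,
         spacers = spacer_table(spacers),
         nick_guides = nick_guide_table(
           if (length(chosen) > 0L)
             enumerate_nick_guides(spec, chosen[[1L]], config$pam_pattern,
                                   config$pe3_window, config$spacer_len)
           else list()),
         designs = designs, notes = unique(notes)),
    class = "design_report")
}

.build_cloning_kit <- function(design, nick_guide, config) {
  fragment <- tryCatch(
    pegrna_fragment(design, config$enzymes$pegrna,
                    list(upstream = config$overhangs$fragment_upstream,
                         downstream = config$overhangs$fragment_downstream)),
    pegforge_error = function(e) e)
  if (inherits(fragment, "condition")) {
    return(list(fragment = NULL, assembly = NULL, assembly_ok = FALSE,
                guide_oligos = NULL,
                diagnostics = conditionMessage(fragment)))
  }
  backbone <- default_backbone(
    terminator = config$terminator,
    upstream_key = config$overhangs$fragment_upstream,
    downstream_key = reverse_complement(config$overhangs$fragment_downstream))
  assembly <- simulate_golden_gate(list(fragment), backbone,
                                   config$enzymes$pegrna)
  expected_tu <- paste0(design$full_sequence, backbone$terminator)
  guide_oligos <- if (!is.null(nick_guide)) {
    guide_duplex_oligos(
      .apply_five_prime_g(nick_guide$spacer_sequence,
                          config$five_prime_g_policy),
      list(top = config$overhangs$duplex_top,
           bottom = config$overhangs$duplex_bottom),
      name = sprintf("%s_nick_guide", nick_guide$mode))
  } else NULL
  list(fragment = fragment, assembly = assembly,
       assembly_ok = isTRUE(assembly$success) &&
         identical(assembly$transcription_unit, expected_tu),
       guide_oligos = guide_oligos, diagnostics = assembly$diagnostics)
}

#' @export
print.design_report <- function(x, ...) {
  cat(sprintf("<design_report> status: %s; %d spacer candidate(s), %d emitted design(s)\n",
              x$status, nrow(x$spacers), length(x$designs)))
  if (length(x$designs) > 0L) {
    top <- x$designs[[1L]]
    cat("  top design:\n")
    print(top$design)
    cat(sprintf("  verified: locus %s, assembly %s\n",
                top$verified_locus, top$verified_assembly))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Tabulate the emitted designs of a report
#'
#' @param report A `design_report`.
#' @return data.frame with one row per emitted design.
#' @export
design_table <- function(report) {
  if (length(report$designs) == 0L) {
    return(data.frame(
      strategy = character(0L), spacer_strand = character(0L),
      spacer_start = integer(0L), spacer_sequence = character(0L),
      nick_to_edit_distance = integer(0L), pbs_length = integer(0L),
      pbs_gc = numeric(0L), rtt_length = integer(0L),
      post_edit_homology = integer(0L), nick_guide_mode = character(0L),
      warnings = character(0L), verified_locus = logical(0L),
      verified_assembly = logical(0L), full_sequence = character(0L),
      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(report$designs, function(d) {
    data.frame(
      strategy = d$design$strategy,
      spacer_strand = d$design$spacer$strand,
      spacer_start = d$design$spacer$protospacer_interval[1L],
      spacer_sequence = d$design$spacer_emitted,
      nick_to_edit_distance = d$design$spacer$nick_to_edit_distance,
      pbs_length = d$design$pbs$length,
      pbs_gc = d$design$pbs$gc,
      rtt_length = d$design$rtt$length,
      post_edit_homology = d$design$rtt$post_edit_homology,
      nick_guide_mode = if (is.null(d$nick_guide)) "" else d$nick_guide$mode,
      warnings = paste(d$design$warnings, collapse = ";"),
      verified_locus = d$verified_locus,
      verified_assembly = d$verified_assembly,
      full_sequence = d$design$full_sequence,
      stringsAsFactors = FALSE)
  }))
}

# plain-list view of a report for canonical JSON serialization
.report_as_list <- function(report) {
  list(
    status = report$status,
    input = list(
      wt_sequence = report$input$wt_sequence,
      edited_sequence = report$input$edited_sequence,
      edit_start = report$input$edit_start,
      wt_edit_end = report$input$wt_edit_end,
      edited_edit_end = report$input$edited_edit_end,
      edit_type = report$input$edit_type),
    config = unclass(report$config)[setdiff(names(report$config),
                                            "random_seed")],
    spacers = report$spacers,
    nick_guides = report$nick_guides,
    designs = lapply(report$designs, function(d) {
      list(
        strategy = d$design$strategy,
        spacer = d$design$spacer[c("id", "strand", "protospacer_interval",
                                   "pam_interval", "spacer_sequence",
                                   "pam_sequence", "nick_index",
                                   "nick_to_edit_distance",
                                   "pam_or_seed_disrupted", "valid_for_pe")],
        spacer_emitted = d$design$spacer_emitted,
        pbs = unclass(d$design$pbs),
        rtt = unclass(d$design$rtt),
        full_sequence = d$design$full_sequence,
        warnings = d$design$warnings,
        nick_guide = if (is.null(d$nick_guide)) NULL else
          unclass(d$nick_guide),
        verified_locus = d$verified_locus,
        verified_assembly = d$verified_assembly)
    }),
    notes = report$notes)
}

#' Serialize a design report to canonical JSON
#'
#' The serialization is stable: the same input and configuration always
#' produce byte-identical JSON.
#'
#' @param report A `design_report`.
#' @return A JSON string.
#' @export
report_json <- function(report) {
  as.character(jsonlite::toJSON(.report_as_list(report), auto_unbox = TRUE,
                                digits = 8, pretty = TRUE, null = "null",
                                dataframe = "rows"))
}

#' Write the full output set of a design run
#'
#' Writes `report.json`, `designs.tsv`, `spacers.tsv`, `nick_guides.tsv`,
#' `oligos.tsv`, `oligos.fasta`, `pegrnas.fasta` and (for the top verified
#' design) `construct.gb` into `out_dir`.
#'
#' @param report A `design_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the vector of written paths.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  wr <- function(name) {
    p <- file.path(out_dir, name)
    paths <<- c(paths, p)
    p
  }
  writeLines(report_json(report), wr("report.json"))
  .write_tsv(design_table(report), wr("designs.tsv"))
  .write_tsv(report$spacers, wr("spacers.tsv"))
  .write_tsv(report$nick_guides, wr("nick_guides.tsv"))
  oligos <- .oligo_sheet(report)
  .write_tsv(oligos, wr("oligos.tsv"))
  .write_fasta(stats::setNames(oligos$sequence, oligos$name),
               wr("oligos.fasta"))
  if (length(report$designs) > 0L) {
    peg <- vapply(report$designs, function(d) d$design$full_sequence,
                  character(1L))
    names(peg) <- sprintf("pegRNA_%02d_%s", seq_along(peg),
                          vapply(report$designs,
                                 function(d) d$design$strategy, character(1L)))
    .write_fasta(peg, wr("pegrnas.fasta"))
    top <- Filter(function(d) d$verified_locus && d$verified_assembly,
                  report$designs)
    if (length(top) > 0L) {
      write_construct_genbank(top[[1L]], report$config, wr("construct.gb"))
    }
  }
  invisible(paths)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_fasta <- function(named_seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(named_seqs)) {
    writeLines(c(paste0(">", nm),
                 gsub(sprintf("(.{60})"), "\\1\n", named_seqs[[nm]])), con)
  }
}

.oligo_sheet <- function(report) {
  rows <- list()
  add <- function(name, sequence) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, sequence = sequence, length = nchar(sequence),
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(report$designs)) {
    d <- report$designs[[i]]
    if (!is.null(d$cloning$fragment)) {
      add(sprintf("design%02d_%s_fragment", i, d$design$strategy),
          d$cloning$fragment$sense)
    }
    if (!is.null(d$cloning$guide_oligos)) {
      g <- d$cloning$guide_oligos
      add(sprintf("design%02d_%s_sense", i, g$name), g$sense)
      add(sprintf("design%02d_%s_antisense", i, g$name), g$antisense)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(name = character(0L), sequence = character(0L),
                      length = integer(0L), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
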