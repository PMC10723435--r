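# Design configuration: one record with every tunable knob of the pipeline.

#' Build a design configuration
#'
#' Collects every tunable parameter of the design pipeline with its default.
#' Defaults follow standard SpCas9 prime-editing practice: a 20-nt spacer
#' against an NGG PAM, PBS lengths 8-17 nt anchored at 12 nt with a 30% GC
#' warning threshold, RTT lengths 8-31 nt anchored at 14 nt, a minimum of
#' 5 nt post-edit homology, and a signed PE3 nick-to-nick window of 40-90 nt.
#'
#' @param pam_pattern IUPAC PAM pattern.
#' @param spacer_len Protospacer length (nt).
#' @param pbs_range,pbs_preferred PBS length range and preferred anchor (nt).
#' @param rtt_range,rtt_preferred RTT length range and preferred anchor (nt).
#' @param gc_warn_threshold PBS GC percentage at or below which a low
#'   efficiency warning is attached.
#' @param min_post_edit_homology Minimum nt of flap homology 3' of the edit.
#' @param pe3_window Signed nick-to-nick window for PE3 guides (nt).
#' @param strategy `"pe2"`, `"pe3"`, `"pe3b"` or `"all"`.
#' @param five_prime_g_policy `"prepend"`, `"substitute"` or `"none"`.
#' @param scaffold sgRNA scaffold sequence.
#' @param overhangs List of 4-nt overhangs: `duplex_top`, `duplex_bottom`
#'   (guide duplex) and `fragment_upstream`, `fragment_downstream`
#'   (synthesized pegRNA fragment).
#' @param enzymes List naming the Type IIS enzymes: `pegrna` (cassette
#'   cloning) and `parts` (multi-part assembly).
#' @param terminator Model a polyT terminator downstream of the cassette.
#' @param n_spacers,n_pbs,n_rtt How many top-ranked spacers / PBS / RTT
#'   options to combine into emitted designs.
#' @param pe3b_fallback Strategy used when `strategy = "pe3b"` finds no
#'   PE3b site: `"pe3"`, `"pe2"` or `"none"`.
#' @param random_seed Seed for fixture generation only; the design pipeline
#'   itself is deterministic.
#' @return A `design_config` list.
#' @export
design_config <- function(pam_pattern = "NGG",
                          spacer_len = 20L,
                          pbs_range = c(8L, 17L),
                          pbs_preferred = 12L,
                          rtt_range = c(8L, 31L),
                          rtt_preferred = 14L,
                          gc_warn_threshold = 30,
                          min_post_edit_homology = 5L,
                          pe3_window = c(40L, 90L),
                          strategy = c("all", "pe2", "pe3", "pe3b"),
                          five_prime_g_policy = c("prepend", "substitute", "none"),
                          scaffold = default_scaffold(),
                          overhangs = list(duplex_top = "CACC",
                                           duplex_bottom = "AAAC",
                                           fragment_upstream = "CACC",
                                           fragment_downstream = "AAAC"),
                          enzymes = list(pegrna = "BbsI", parts = "BsaI"),
                          terminator = TRUE,
                          n_spacers = 3L,
                          n_pbs = 3L,
                          n_rtt = 3L,
                          pe3b_fallback = c("pe3", "pe2", "none"),
                          random_seed = NULL) {
  strategy <- match.arg(strategy)
  five_prime_g_policy <- match.arg(five_prime_g_policy)
  pe3b_fallback <- match.arg(pe3b_fallback)
  .check_range <- function(r, preferred, what) {
    r <- as.integer(r)
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < 1L) {
      .stop_pegforge("pegforge_config_error",
                     sprintf("%s range must be an ordered positive pair", what))
    }
    if (preferred < r[1L] || preferred > r[2L]) {
      .stop_pegforge("pegforge_config_error",
                     sprintf("preferred %s length %d outside range [%d,%d]",
                             what, preferred, r[1L], r[2L]))
    }
    r
  }
  pbs_range <- .check_range(pbs_range, pbs_preferred, "PBS")
  rtt_range <- .check_range(rtt_range, rtt_preferred, "RTT")
  if (gc_warn_threshold < 0 || gc_warn_threshold > 100) {
    .stop_pegforge("pegforge_config_error",
                   "gc_warn_threshold must lie in [0, 100]")
  }
  pe3_window <- as.integer(pe3_window)
  if (length(pe3_window) != 2L || pe3_window[1L] > pe3_window[2L]) {
    .stop_pegforge("pegforge_config_error",
                   "pe3_window must be an ordered pair")
  }
  structure(
    list(
      pam_pattern = toupper(pam_pattern),
      spacer_len = as.integer(spacer_len),
      pbs_range = pbs_range, pbs_preferred = as.integer(pbs_preferred),
      rtt_range = rtt_range, rtt_preferred = as.integer(rtt_preferred),
      gc_warn_threshold = gc_warn_threshold,
      min_post_edit_homology = as.integer(min_post_edit_homology),
      pe3_window = pe3_window,
      strategy = strategy,
      five_prime_g_policy = five_prime_g_policy,
      scaffold = toupper(scaffold),
      overhangs = overhangs,
      enzymes = enzymes,
      terminator = isTRUE(terminator),
      n_spacers = as.integer(n_spacers),
      n_pbs = as.integer(n_pbs),
      n_rtt = as.integer(n_rtt),
      pe3b_fallback = pe3b_fallback,
      random_seed = random_seed
    ),
    class = "design_config")
}

#' Read a design configuration from a YAML file
#'
#' Keys mirror the arguments of [design_config()] 1:1; unknown keys are an
#' error, omitted keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `design_config`.
#' @export
read_design_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(design_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    .stop_pegforge("pegforge_config_error",
                   sprintf("unknown configuration key(s): %s",
                           paste(bad, collapse = ", ")))
  }
  do.call(design_config, vals)
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat(sprintf("  PAM %s, spacer %d nt, strategy %s\n",
              x$pam_pattern, x$spacer_len, x$strategy))
  cat(sprintf("  PBS %d-%d nt (preferred %d, GC warning <= %g%%)\n",
              x$pbs_range[1L], x$pbs_range[2L], x$pbs_preferred,
              x$gc_warn_threshold))
  cat(sprintf("  RTT %d-%d nt (preferred %d, post-edit homology >= %d nt)\n",
              x$rtt_range[1L], x$rtt_range[2L], x$rtt_preferred,
              x$min_post_edit_homology))
  cat(sprintf("  PE3 window [%d,%d] nt, 5'-G policy %s\n",
              x$pe3_window[1L], x$pe3_window[2L], x$five_prime_g_policy))
  invisible(x)
}
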