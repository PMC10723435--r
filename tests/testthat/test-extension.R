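toy <- toy_notation()
toy_spec <- parse_edit_input(toy$wt_notation, toy$replacement)
toy_cand <- enumerate_spacers(toy_spec, "NGG", 20L)[[1]]

test_that("PBS sequences are the reverse complement of the pre-nick window", {
  opt <- pbs_options(toy_cand, toy_spec, length_range = c(4L, 4L),
                     preferred = 4L)[[1]]
  expect_equal(opt$sequence, "GATC")  # revcomp of top[17,21) = "GATC"
  expect_equal(opt$gc, 50)
  expect_false(opt$low_efficiency_warning)

  # independent string-slicing oracle on random fixtures, both strands
  fixtures <- generate_fixtures(seed = 31, n = 30)
  for (fx in fixtures) {
    cands <- Filter(function(x) x$valid_for_pe,
                    enumerate_spacers(fx$spec, "NGG", 20L))
    cand <- cands[[1]]
    wt <- fx$spec$wt_sequence
    for (opt in pbs_options(cand, fx$spec)) {
      nick <- cand$nick_index
      expected <- if (cand$strand == "+") {
        oracle_rc(substr(wt, nick - opt$length + 1, nick))
      } else {
        oracle_rc(oracle_rc(substr(wt, nick + 1, nick + opt$length)))
      }
      expect_identical(opt$sequence, expected)
      expect_identical(opt$low_efficiency_warning, opt$gc <= 30)
    }
  }
})

test_that("all-AT context triggers the low_gc warning", {
  spec <- parse_edit_input(
    paste0(strrep("TA", 18), "TTTT", "AGG", "ATATAT(A)TATATATATATATAT"), "C")
  cand <- Filter(function(x) x$valid_for_pe && x$strand == "+",
                 enumerate_spacers(spec, "NGG", 20L))[[1]]
  for (opt in pbs_options(cand, spec)) {
    expect_equal(opt$gc, 0)
    expect_true("low_gc" %in% opt$warning_reasons)
    expect_true(opt$low_efficiency_warning)
  }
})

test_that("warning-free PBS options rank by |length - 12|, shorter first on ties", {
  demo <- demo_target()
  spec <- parse_edit_input(demo$wt_notation, demo$replacement)
  cand <- enumerate_spacers(spec, "NGG", 20L)[[1]]
  opts <- pbs_options(cand, spec)
  expect_true(all(!vapply(opts, function(x) x$low_efficiency_warning, logical(1))))
  lens <- vapply(opts, function(x) x$length, integer(1))
  expect_equal(lens[1], 12L)
  expect_true(all(diff(abs(lens - 12L)) >= 0))
  expect_equal(lens[2], 11L)  # shorter first among the |d| = 1 tie
})

test_that("RTT options span the edit, carry homology and match the toy derivation", {
  opt <- rtt_options(toy_cand, toy_spec, length_range = c(5L, 5L),
                     preferred = 5L, min_post_edit_homology = 3L)[[1]]
  expect_equal(opt$sequence, "CTGCA")  # revcomp of edited top[21,26) = "TGCAG"
  expect_true(opt$covers_edit)
  expect_equal(opt$post_edit_homology, 3L)
  expect_true(opt$first_templated_base_c)

  # a 1-nt template cannot span an edit at distance 1: suppressed
  expect_error(rtt_options(toy_cand, toy_spec, length_range = c(1L, 1L),
                           preferred = 1L, min_post_edit_homology = 0L),
               class = "pegforge_rtt_infeasible")
  short <- rtt_options(toy_cand, toy_spec, length_range = c(1L, 5L),
                       preferred = 5L, min_post_edit_homology = 0L)
  expect_true(all(vapply(short, function(x) x$covers_edit, logical(1))))
  expect_true(all(vapply(short, function(x) x$length, integer(1)) >= 2L))
})

test_that("warning-free spanning RTT options rank 14 first", {
  # G-free downstream flank: no RTT starts with C, so ranking is undisturbed
  wt_left <- substr(strrep("ACGTG", 8), 1, 39)
  proto <- strrep("GACGT", 4)
  target <- paste0(wt_left, proto, "AGG", substr(strrep("ACT", 20), 1, 58))
  spec <- parse_edit_input(
    paste0(substr(target, 1, 58), "(T)", substr(target, 60, 120)), "A")
  cand <- enumerate_spacers(spec, "NGG", 20L)[[1]]
  opts <- rtt_options(cand, spec)
  expect_true(all(!vapply(opts, function(x) x$first_templated_base_c, logical(1))))
  lens <- vapply(opts, function(x) x$length, integer(1))
  expect_equal(lens[1], 14L)
  expect_true(all(diff(abs(lens - 14L)) >= 0))
})

test_that("RTT sequences match an independent edited-strand oracle on both strands", {
  fixtures <- generate_fixtures(seed = 32, n = 30)
  for (fx in fixtures) {
    spec <- fx$spec
    cand <- Filter(function(x) x$valid_for_pe,
                   enumerate_spacers(spec, "NGG", 20L))[[1]]
    ed <- spec$edited_sequence
    delta <- nchar(ed) - nchar(spec$wt_sequence)
    nick_e <- if (cand$strand == "+") cand$nick_index else
      cand$nick_index + delta
    for (opt in rtt_options(cand, spec)) {
      expected <- if (cand$strand == "+") {
        oracle_rc(substr(ed, nick_e + 1, nick_e + opt$length))
      } else {
        oracle_rc(oracle_rc(substr(ed, nick_e - opt$length + 1, nick_e)))
      }
      expect_identical(opt$sequence, expected)
      expect_true(opt$covers_edit)
      expect_gte(opt$post_edit_homology, 5L)
    }
  }
})

test_that("assemble_pegrna concatenates parts, applies 5'-G policy and aggregates warnings", {
  pbs <- pbs_options(toy_cand, toy_spec, c(4L, 4L), preferred = 4L)[[1]]
  rtt <- rtt_options(toy_cand, toy_spec, c(5L, 5L), preferred = 5L,
                     min_post_edit_homology = 3L)[[1]]
  d <- assemble_pegrna(toy_cand, pbs, rtt)
  expect_equal(substr(d$full_sequence, nchar(d$full_sequence) - 8,
                      nchar(d$full_sequence)), "CTGCAGATC")
  expect_identical(d$full_sequence,
                   paste0(d$spacer_emitted, d$scaffold, "CTGCA", "GATC"))
  # toy spacer starts with A: prepend policy emits a 21-nt G-spacer
  expect_equal(nchar(d$spacer_emitted), 21L)
  expect_equal(substr(d$spacer_emitted, 1, 1), "G")
  sub <- assemble_pegrna(toy_cand, pbs, rtt, five_prime_g_policy = "substitute")
  expect_equal(nchar(sub$spacer_emitted), 20L)
  expect_equal(substr(sub$spacer_emitted, 1, 1), "G")
  none <- assemble_pegrna(toy_cand, pbs, rtt, five_prime_g_policy = "none")
  expect_identical(none$spacer_emitted, toy_cand$spacer_sequence)

  # polyT run in the extension is flagged
  fake_pbs <- structure(list(length = 4L, sequence = "TTTT", gc = 0,
                             low_efficiency_warning = TRUE,
                             warning_reasons = "low_gc",
                             candidate_id = toy_cand$id), class = "pbs_option")
  warned <- assemble_pegrna(toy_cand, fake_pbs, rtt)
  expect_true("polyT" %in% warned$warnings)
  expect_true("low_gc" %in% warned$warnings)

  # parts from another candidate are rejected
  other <- fake_pbs
  other$candidate_id <- "-:99"
  expect_error(assemble_pegrna(toy_cand, other, rtt),
               class = "pegforge_part_mismatch")
})

test_that("predict_edited_locus reproduces the edited toy locus and the identity case", {
  pbs <- pbs_options(toy_cand, toy_spec, c(4L, 4L), preferred = 4L)[[1]]
  rtt <- rtt_options(toy_cand, toy_spec, c(5L, 5L), preferred = 5L,
                     min_post_edit_homology = 3L)[[1]]
  d <- assemble_pegrna(toy_cand, pbs, rtt)
  expect_identical(predict_edited_locus(d, toy_spec), toy_spec$edited_sequence)

  # an identity template (copied from wild type) leaves the locus unchanged
  wt <- toy_spec$wt_sequence
  ident_rtt <- structure(
    list(length = 5L,
         sequence = reverse_complement(substr(wt, 22, 26)),
         covers_edit = FALSE, post_edit_homology = 0L,
         first_templated_base_c = FALSE, warning_reasons = character(0),
         candidate_id = toy_cand$id), class = "rtt_option")
  ident_spec <- structure(toy_spec, class = "edit_spec")
  ident_spec$edited_sequence <- wt
  ident_spec$edited_edit_end <- ident_spec$wt_edit_end
  d2 <- assemble_pegrna(toy_cand, pbs, ident_rtt)
  expect_identical(predict_edited_locus(d2, ident_spec), wt)
})

test_that("round-trip holds for every option pair over random fixtures", {
  fixtures <- generate_fixtures(seed = 33, n = 40)
  for (fx in fixtures) {
    spec <- fx$spec
    cand <- Filter(function(x) x$valid_for_pe,
                   enumerate_spacers(spec, "NGG", 20L))[[1]]
    pbs <- pbs_options(cand, spec)[[1]]
    for (rtt in rtt_options(cand, spec)) {
      d <- assemble_pegrna(cand, pbs, rtt)
      expect_identical(predict_edited_locus(d, spec), spec$edited_sequence)
    }
  }
})

test_that("option ranking is deterministic and improves toward the preferred length", {
  fixtures <- generate_fixtures(seed = 34, n = 10)
  for (fx in fixtures) {
    cand <- Filter(function(x) x$valid_for_pe,
                   enumerate_spacers(fx$spec, "NGG", 20L))[[1]]
    a <- pbs_options(cand, fx$spec)
    b <- pbs_options(cand, fx$spec)
    expect_identical(a, b)
    warn <- vapply(a, function(x) x$low_efficiency_warning, logical(1))
    lens <- vapply(a, function(x) x$length, integer(1))
    if (all(!warn)) expect_true(all(diff(abs(lens - 12L)) >= 0))
    r <- rtt_options(cand, fx$spec)
    rw <- vapply(r, function(x) length(x$warning_reasons) > 0, logical(1))
    rl <- vapply(r, function(x) x$length, integer(1))
    if (all(!rw)) expect_true(all(diff(abs(rl - 14L)) >= 0))
  }
})
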