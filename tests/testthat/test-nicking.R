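# A hand-built locus where the edit CREATES the opposite-strand PAM:
# [25 nt A][protospacer CAGTA x4][PAM TGG][ATCGA x6], nick at 42,
# AT>CC substitution at [44,46) creates a CCG (minus-strand NGG) at [44,47).
pe3b_locus <- function() {
  wt <- paste0(strrep("A", 25), strrep("CAGTA", 4), "TGG", strrep("ATCGA", 6))
  list(spec = parse_edit_input(
    paste0(substr(wt, 1, 44), "(", substr(wt, 45, 46), ")",
           substr(wt, 47, nchar(wt))), "CC"),
    wt = wt)
}

test_that("an edit-created opposite-strand site is classified PE3b with counted mismatches", {
  spec <- pe3b_locus()$spec
  peg <- Filter(function(x) x$valid_for_pe && x$strand == "+",
                enumerate_spacers(spec, "NGG", 20L))[[1]]
  expect_equal(peg$nick_index, 42L)
  guides <- enumerate_nick_guides(spec, peg)
  expect_gte(length(guides), 1L)
  g <- guides[[1]]
  expect_equal(g$mode, "PE3b")
  expect_equal(g$strand, "-")
  expect_equal(g$pam_interval, c(44L, 47L))
  expect_equal(g$protospacer_interval, c(47L, 67L))
  expect_equal(g$wt_mismatch_count, 2L)   # the two substituted bases
  expect_equal(g$nick_to_nick_distance, 8L)  # nick at 50 vs peg nick at 42
  # the guide reads the edited strand: spacer is the revcomp of edited [47,67)
  expect_identical(g$spacer_sequence,
                   oracle_rc(substr(spec$edited_sequence, 48, 67)))
})

test_that("classify_pe3b distinguishes PE3, PE3b and invalid sites", {
  spec <- pe3b_locus()$spec
  # site far from the edit, identical in both alleles -> PE3
  far <- classify_pe3b(list(strand = "-", protospacer_interval = c(5L, 25L),
                            pam_interval = c(2L, 5L), pam_pattern = "NNN"),
                       spec)
  expect_equal(far$mode, "PE3")
  expect_equal(far$wt_mismatch_count, 0L)
  # the edit-created PAM -> PE3b (wild-type window fails to match)
  created <- classify_pe3b(list(strand = "-",
                                protospacer_interval = c(47L, 67L),
                                pam_interval = c(44L, 47L),
                                pam_pattern = "NGG"), spec)
  expect_equal(created$mode, "PE3b")
  expect_equal(created$wt_mismatch_count, 2L)
  # a site whose PAM does not match the edited sequence -> invalid
  bad <- classify_pe3b(list(strand = "-", protospacer_interval = c(28L, 48L),
                            pam_interval = c(25L, 28L), pam_pattern = "NGG"),
                       spec)
  expect_equal(bad$mode, "invalid")
})

test_that("a target with no opposite-strand site yields no nicking guides", {
  demo <- demo_target()  # repeat-built locus with no CC dinucleotide
  spec <- parse_edit_input(demo$wt_notation, demo$replacement)
  peg <- enumerate_spacers(spec, "NGG", 20L)[[1]]
  expect_length(enumerate_nick_guides(spec, peg), 0L)
})

test_that("PE3/PE3b contracts hold for every guide over random fixtures", {
  fixtures <- generate_fixtures(seed = 41, n = 120)
  n_pe3b <- 0L
  n_pe3 <- 0L
  for (fx in fixtures) {
    spec <- fx$spec
    peg <- Filter(function(x) x$valid_for_pe,
                  enumerate_spacers(spec, "NGG", 20L))[[1]]
    ed <- spec$edited_sequence
    wt <- spec$wt_sequence
    delta <- nchar(ed) - nchar(wt)
    for (g in enumerate_nick_guides(spec, peg)) {
      # never on the pegRNA strand
      expect_true(g$strand != peg$strand)
      # the spacer matches the edited sequence exactly at its coordinates
      window <- substr(ed, g$protospacer_interval[1] + 1,
                       g$protospacer_interval[2])
      expect_identical(g$spacer_sequence,
                       if (g$strand == "+") window else oracle_rc(window))
      # direct string comparison against the aligned wild-type window
      a <- min(g$protospacer_interval[1], g$pam_interval[1])
      b <- max(g$protospacer_interval[2], g$pam_interval[2])
      wt_start <- if (a < spec$edit_start) a else a - delta
      wt_window <- substr(wt, wt_start + 1, wt_start + (b - a))
      ed_window <- substr(ed, a + 1, b)
      mism <- sum(strsplit(ed_window, "")[[1]] != strsplit(wt_window, "")[[1]])
      if (g$mode == "PE3b") {
        n_pe3b <- n_pe3b + 1L
        expect_gte(mism, 1L)
        expect_equal(g$wt_mismatch_count, mism)
      } else {
        n_pe3 <- n_pe3 + 1L
        expect_equal(mism, 0L)
        # PE3 guides respect the signed nick-to-nick window
        expect_gte(g$nick_to_nick_distance, 40L)
        expect_lte(g$nick_to_nick_distance, 90L)
      }
    }
  }
  # the fixture suite exercises both modes
  expect_gt(n_pe3b, 0L)
  expect_gt(n_pe3, 0L)
})

test_that("guide enumeration matches the brute-force scan of the edited opposite strand", {
  fixtures <- generate_fixtures(seed = 42, n = 60)
  for (fx in fixtures) {
    spec <- fx$spec
    peg <- Filter(function(x) x$valid_for_pe,
                  enumerate_spacers(spec, "NGG", 20L))[[1]]
    opp <- if (peg$strand == "+") "-" else "+"
    all_sites <- oracle_scan_spacers(spec$edited_sequence, "NGG", 20L)
    opp_sites <- sort(sub("^.:", "", grep(paste0("^\\", opp, ":"), all_sites,
                                          value = TRUE)))
    guides <- enumerate_nick_guides(spec, peg, pe3_window = c(-10000L, 10000L))
    got <- sort(as.character(vapply(guides, function(g)
      g$protospacer_interval[1], integer(1))))
    # with an unbounded window, emitted guides are exactly the classifiable
    # (non-invalid) opposite-strand sites
    expect_true(all(got %in% opp_sites))
    invalid <- setdiff(opp_sites, got)
    for (s in as.integer(invalid)) {
      proto <- c(s, s + 20L)
      pam <- if (opp == "+") c(s + 20L, s + 23L) else c(s - 3L, s)
      cls <- classify_pe3b(list(strand = opp, protospacer_interval = proto,
                                pam_interval = pam, pam_pattern = "NGG"),
                           spec)
      expect_equal(cls$mode, "invalid")
    }
  }
})
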