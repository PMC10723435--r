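toy <- toy_notation()
toy_spec <- parse_edit_input(toy$wt_notation, toy$replacement)

test_that("toy target yields the hand-derived candidate geometry", {
  cands <- enumerate_spacers(toy_spec, "NGG", 20L)
  keys <- candidate_keys(cands)
  expect_true("+:4" %in% keys)
  cand <- cands[[which(vapply(cands, function(x) x$id, character(1)) == "+:4")]]
  expect_equal(cand$protospacer_interval, c(4L, 24L))
  expect_equal(cand$pam_interval, c(24L, 27L))
  expect_equal(cand$pam_sequence, "AGG")
  expect_equal(cand$spacer_sequence, "AAGGCTTCATACGGATCTAC")
  expect_equal(cand$nick_index, 21L)
  expect_equal(cand$nick_to_edit_distance, 1L)
  expect_true(cand$valid_for_pe)
})

test_that("a GG-free target produces an empty candidate list with a diagnostic", {
  spec <- parse_edit_input(paste0(strrep("A", 30), "(A)", strrep("A", 29)), "T")
  cands <- enumerate_spacers(spec, "NGG", 20L)
  expect_length(cands, 0)
  expect_match(attr(cands, "diagnostic"), "no 20-nt protospacer")
})

test_that("enumeration equals an independent brute-force scan on random fixtures", {
  fixtures <- generate_fixtures(seed = 21, n = 200)
  for (fx in fixtures) {
    cands <- enumerate_spacers(fx$spec, "NGG", 20L)
    expect_identical(candidate_keys(cands),
                     oracle_scan_spacers(fx$spec$wt_sequence, "NGG", 20L))
  }
})

test_that("enumeration is strand-symmetric under target mirroring", {
  fixtures <- generate_fixtures(seed = 22, n = 60)
  for (fx in fixtures) {
    spec <- fx$spec
    L <- nchar(spec$wt_sequence)
    cands <- enumerate_spacers(spec, "NGG", 20L)
    mirrored <- enumerate_spacers(mirror_spec(spec), "NGG", 20L)
    expected <- sort(vapply(cands, function(x) {
      sprintf("%s:%d", if (x$strand == "+") "-" else "+",
              L - x$protospacer_interval[2L])
    }, character(1)))
    expect_identical(candidate_keys(mirrored), expected)
    # validity and distance are mirror-invariant
    by_key <- function(cs) {
      o <- order(vapply(cs, function(x) x$id, character(1)))
      cs[o]
    }
    m_keyed <- vapply(mirrored, function(x)
      sprintf("%s:%d", x$strand, x$protospacer_interval[1L]), character(1))
    for (cand in cands) {
      mk <- sprintf("%s:%d", if (cand$strand == "+") "-" else "+",
                    L - cand$protospacer_interval[2L])
      m <- mirrored[[match(mk, m_keyed)]]
      expect_equal(m$valid_for_pe, cand$valid_for_pe)
      expect_equal(m$nick_to_edit_distance, cand$nick_to_edit_distance)
      expect_equal(m$nick_index, L - cand$nick_index)
    }
  }
})

test_that("every candidate nick sits 3 nt from the PAM-proximal protospacer boundary", {
  fixtures <- generate_fixtures(seed = 23, n = 40)
  for (fx in fixtures) {
    for (cand in enumerate_spacers(fx$spec, "NGG", 20L)) {
      if (cand$strand == "+") {
        expect_equal(cand$nick_index, cand$pam_interval[1L] - 3L)
        expect_equal(cand$nick_index, cand$protospacer_interval[2L] - 3L)
      } else {
        expect_equal(cand$nick_index, cand$pam_interval[2L] + 3L)
        expect_equal(cand$nick_index, cand$protospacer_interval[1L] + 3L)
      }
      if (cand$valid_for_pe) {
        expect_gte(cand$nick_to_edit_distance, 0L)
        # the whole edit lies 3' of the nick on the protospacer strand
        if (cand$strand == "+") {
          expect_gte(fx$spec$edit_start, cand$nick_index)
        } else {
          expect_lte(fx$spec$wt_edit_end, cand$nick_index)
        }
      }
    }
  }
})

stub_candidate <- function(valid, dist, disrupted, strand, start) {
  structure(list(id = sprintf("%s:%d", strand, start), strand = strand,
                 protospacer_interval = c(start, start + 20L),
                 pam_interval = c(start + 20L, start + 23L),
                 spacer_sequence = "", pam_sequence = "",
                 nick_index = start + 17L, nick_to_edit_distance = dist,
                 pam_or_seed_disrupted = disrupted, valid_for_pe = valid),
            class = "spacer_candidate")
}

test_that("rank_spacers applies the documented key order and tie-breaks", {
  a <- stub_candidate(TRUE, 9L, FALSE, "+", 0L)
  b <- stub_candidate(TRUE, 1L, FALSE, "+", 40L)
  expect_equal(rank_spacers(list(a, b))[[1]]$id, b$id)     # smaller distance first

  inv <- stub_candidate(FALSE, 0L, FALSE, "+", 0L)
  expect_equal(rank_spacers(list(inv, a))[[1]]$id, a$id)   # valid before invalid

  c1 <- stub_candidate(TRUE, 3L, TRUE, "-", 10L)
  c2 <- stub_candidate(TRUE, 3L, FALSE, "+", 0L)
  expect_equal(rank_spacers(list(c2, c1))[[1]]$id, c1$id)  # disrupting first

  d1 <- stub_candidate(TRUE, 3L, FALSE, "+", 50L)
  d2 <- stub_candidate(TRUE, 3L, FALSE, "-", 10L)
  expect_equal(rank_spacers(list(d2, d1))[[1]]$id, d1$id)  # '+' before '-'

  e1 <- stub_candidate(TRUE, 3L, FALSE, "+", 10L)
  e2 <- stub_candidate(TRUE, 3L, FALSE, "+", 50L)
  expect_equal(rank_spacers(list(e2, e1))[[1]]$id, e1$id)  # leftmost first

  # permutation invariance
  all_c <- list(a, b, inv, c1, c2, d1)
  ids <- function(x) vapply(x, function(y) y$id, character(1))
  set.seed(1)
  for (i in 1:5) {
    expect_identical(ids(rank_spacers(sample(all_c))), ids(rank_spacers(all_c)))
  }
})

test_that("edit_disrupts_site covers PAM, seed and distal cases", {
  cands <- enumerate_spacers(toy_spec, "NGG", 20L)
  cand <- cands[[which(candidate_keys(cands) == "+:4")[1]]]
  # toy edit at index 22 = protospacer position 19 of 20, inside the seed
  expect_true(edit_disrupts_site(cand, toy_spec))

  # edit inside the PAM
  pam_spec <- parse_edit_input("TTTTAAGGCTTCATACGGATCTAC(A)GGCCCGATT", "T")
  pam_cand <- enumerate_spacers(pam_spec, "NGG", 20L)
  pc <- pam_cand[[which(vapply(pam_cand, function(x) x$id, character(1)) == "+:4")]]
  expect_true(edit_disrupts_site(pc, pam_spec))

  # edit far downstream of the PAM
  far <- parse_edit_input(
    paste0("TTTTAAGGCTTCATACGGATCTACAGG", strrep("CAT", 17), "(T)CA"), "A")
  fc <- enumerate_spacers(far, "NGG", 20L)
  f1 <- fc[[which(vapply(fc, function(x) x$id, character(1)) == "+:4")]]
  expect_false(edit_disrupts_site(f1, far))
})

test_that("validate_custom_spacer matches enumeration and rejects bad spacers", {
  cand <- validate_custom_spacer(toy_spec, "AAGGCTTCATACGGATCTAC", "NGG")
  enum <- enumerate_spacers(toy_spec, "NGG", 20L)
  ref <- enum[[which(vapply(enum, function(x) x$id, character(1)) == "+:4")]]
  expect_identical(cand, ref)

  expect_error(validate_custom_spacer(toy_spec, "GATTACAGATTACAGATTAC"),
               class = "pegforge_spacer_not_found")

  rep_unit <- "AAGGCTTCATACGGATCTAC"
  rep_spec <- parse_edit_input(
    paste0("TTTT", rep_unit, "AGG", rep_unit, "AGG", "(C)CCGATT"), "G")
  expect_error(validate_custom_spacer(rep_spec, rep_unit),
               class = "pegforge_spacer_ambiguous")

  # present exactly once but with no adjacent PAM
  no_pam <- parse_edit_input("TTTTAAGGCTTCATACGGATCTAC(A)TTCCCGATT", "G")
  expect_error(validate_custom_spacer(no_pam, "AAGGCTTCATACGGATCTAC"),
               class = "pegforge_no_adjacent_pam")
})
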