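test_that("substitution enumeration finds differing canonical columns only", {
  expect_equal(enumerate_substitutions("ALKF", "ALKF")$n_events, 0L)
  ev <- enumerate_substitutions("ALKF", "ALKW")
  expect_equal(ev$n_events, 1L)
  expect_equal(ev$events$column, 4L)
  expect_equal(ev$events$ancestral_state, "F")
  expect_equal(ev$events$derived_state, "W")
  expect_equal(ev$events$label, "f4W")
  # gap/missing columns are excluded from events but counted
  ev2 <- enumerate_substitutions("AL-KXF", "TLW-XW")
  expect_equal(ev2$events$column, c(1L, 6L))
  expect_equal(ev2$n_excluded_gap_columns, 3L)
  expect_error(enumerate_substitutions("ALK", "ALKF"), "length")
})

test_that("enumeration is symmetric with states swapped", {
  withr::with_seed(55, {
    a <- paste(sample(c(aa_alphabet()$symbols, "-"), 60, TRUE), collapse = "")
    b <- paste(sample(c(aa_alphabet()$symbols, "-"), 60, TRUE), collapse = "")
  })
  ab <- enumerate_substitutions(a, b)$events
  ba <- enumerate_substitutions(b, a)$events
  expect_equal(ab$column, ba$column)
  expect_equal(ab$ancestral_state, ba$derived_state)
  expect_equal(ab$derived_state, ba$ancestral_state)
})

test_that("reference numbering maps ungapped columns and anchors gaps", {
  m <- matrix(c("M", "K", "-", "-", "L", "F",
                "M", "K", "A", "A", "L", "F"), nrow = 2, byrow = TRUE,
              dimnames = list(c("ref", "other"), NULL))
  aln <- alignment_from_matrix(m)
  nm <- map_reference_numbering(aln, "ref", offset = 415L)
  expect_equal(nm$number, c(415L, 416L, NA, NA, 417L, 418L))
  expect_equal(nm$anchor[3:4], c("416+1", "416+2"))
  # identity map over its own length with offset 1
  aln2 <- alignment_from_matrix(matrix(c("A", "C", "D"), 1, 3,
                                       dimnames = list("r", NULL)))
  expect_equal(map_reference_numbering(aln2, "r")$number, 1:3)
  expect_error(map_reference_numbering(aln, "nope"), "not in alignment")
  # events pick up the reference number
  ev <- enumerate_substitutions("MK--LF", "MK--LW", nm)
  expect_equal(ev$events$reference_number, 418L)
  expect_equal(ev$events$label, "f418W")
})

test_that("conservation filter tolerates gaps and respects max_exceptions", {
  ev <- enumerate_substitutions("AAAA", "TTTT")
  desc <- alignment_from_matrix(matrix(
    c("T", "T", "T", "G",
      "T", "T", "G", "G",
      "T", "-", "G", "G",
      "T", "T", "-", "-",
      "T", "T", "T", "T",
      "T", "T", "T", "G"), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("d", 1:6), NULL)))
  rep1 <- conservation_filter(ev, desc, max_exceptions = 1L)
  # col1: 6/6 match; col2: 5 match 1 gap; col3: 3 match 2 mismatch 1 gap;
  # col4: 1 match 5 mismatch
  expect_equal(rep1$events$conservation_count, c(6, 5, 3, 1))
  expect_equal(rep1$events$n_gapped, c(0, 1, 1, 1))
  expect_equal(rep1$events$retained, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep1$n_retained, 2L)
  expect_true(all(with(rep1$events,
    conservation_count + n_mismatch + n_gapped == n_descendants)))
  # max_exceptions = n_descendants retains everything
  expect_equal(conservation_filter(ev, desc, 6L)$n_retained, 4L)
  # descendants identical to the derived ancestor retain all events
  desc_same <- alignment_from_matrix(matrix("T", 3, 4,
    dimnames = list(paste0("e", 1:3), NULL)))
  expect_equal(conservation_filter(ev, desc_same, 0L)$n_retained, 4L)
  expect_error(conservation_filter(enumerate_substitutions("AAAAA", "TTTTT"),
                                   desc), "frame|shorter")
})

test_that("pairwise identity honours all denominator conventions", {
  expect_equal(pairwise_identity("ALKF", "ALKF")$percent, 100)
  expect_equal(pairwise_identity("AAAA", "AATT")$percent, 50)
  r <- pairwise_identity("AA--A", "AAA-A", "both-ungapped")
  expect_equal(r$percent, 100)          # 3 matches / 3 both-ungapped
  expect_equal(pairwise_identity("AA--A", "AAA-A",
                                 "either-ungapped")$percent, 75)
  expect_equal(pairwise_identity("AA--A", "AAA-A",
                                 "alignment-length")$percent, 60)
  # symmetry under every convention
  for (conv in c("both-ungapped", "either-ungapped", "alignment-length")) {
    expect_equal(pairwise_identity("AW-KF", "AL-KW", conv)$percent,
                 pairwise_identity("AL-KW", "AW-KF", conv)$percent)
  }
  expect_error(pairwise_identity("--", "--"), "no comparable")
})
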