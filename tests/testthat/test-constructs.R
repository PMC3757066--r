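test_that("region swaps splice donor columns into the backbone", {
  aln <- gapped_alignment(c("bb", "dn"), c("AAAA-AAA", "CC-CCCCC"))
  whole <- swap_region(aln, "bb", "dn", list(c(0L, 8L)))
  expect_equal(whole$residues, "CCCCCCC")
  none <- swap_region(aln, "bb", "dn", list())
  expect_equal(none$residues, "AAAAAAA")

  mid <- swap_region(aln, "bb", "dn", list(c(2L, 5L)))
  expect_equal(mid$residues, degap("AA-CCAAA"))
  # swapping the same region back recovers the backbone
  aln2 <- gapped_alignment(c("chim", "bb"),
                           c(paste0("AA", "-CC", "AAA"), "AAAA-AAA"))
  back <- swap_region(aln2, "chim", "bb", list(c(2L, 5L)))
  expect_equal(back$residues, "AAAAAAA")

  expect_error(swap_region(aln, "bb", "dn", list(c(4L, 10L))), "bounds")
  expect_error(swap_region(aln, "bb", "dn", list(c(0L, 3L), c(2L, 5L))),
               "overlap")
})

test_that("events apply with ancestral-state checking", {
  anc <- "ACGTACGTA"
  del <- data.frame(kind = "deletion", col_start = 2L, col_end = 11L,
                    ancestral = "GTACGTA", derived = "", anc_pos = 2L,
                    allele_pos = 2L, label = NA, region = NA,
                    stringsAsFactors = FALSE)
  expect_equal(nchar(apply_event(paste0(anc, "CC"), del)),
               nchar(anc) + 2L - 7L)

  sub <- data.frame(kind = "substitution", col_start = 4L, col_end = 5L,
                    ancestral = "A", derived = "G", anc_pos = 4L,
                    allele_pos = 4L, label = NA, region = NA,
                    stringsAsFactors = FALSE)
  out <- apply_event(anc, sub)
  expect_equal(sum(strsplit(out, "")[[1]] != strsplit(anc, "")[[1]]), 1L)

  # refuses to apply when the ancestral state does not match
  bad <- sub; bad$ancestral <- "T"
  expect_error(apply_event(anc, bad), "mismatch")

  # apply then re-call recovers the same single event
  ev <- call_mutations(anc, "ACGTGCGTA")
  expect_equal(nrow(ev), 1L)
  redone <- call_mutations(anc,
    paste0(substr(anc, 1, 4), "G", substr(anc, 6, 9)))
  expect_equal(redone$ancestral, ev$ancestral)
  expect_equal(redone$derived, ev$derived)
})

test_that("transversion scrambling is a paired involution avoiding complements", {
  expect_equal(scramble_transversions("ACGT", positions = 1:4), "CATG")

  win <- scramble_transversions("TTGGAACCGG", interval = c(2L, 10L),
                                positions = c(2, 4, 6, 8))
  orig <- strsplit("TTGGAACCGG", "")[[1]]
  got <- strsplit(win, "")[[1]]
  changed <- which(got != orig)
  expect_equal(changed, c(2L, 4L, 6L, 8L) + 2L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_true(all(got[changed] != orig[changed]))
  expect_true(all(got[changed] != comp[orig[changed]]))

  twice <- scramble_transversions(win, interval = c(2L, 10L),
                                  positions = c(2, 4, 6, 8))
  expect_equal(twice, "TTGGAACCGG")
  expect_error(scramble_transversions("ACGT", positions = 5L), "out of range")
})

test_that("sub-deletions slice cleanly out of a parent deletion", {
  parent <- data.frame(kind = "deletion", col_start = 10L, col_end = 19L,
                       ancestral = "ACGTACGTA", derived = "", anc_pos = 10L,
                       allele_pos = 10L, label = "E", region = "core",
                       stringsAsFactors = FALSE)
  e8del <- slice_deletion(parent, 0L, 8L)
  expect_equal(e8del$ancestral, "ACGTACGT")
  expect_equal(e8del$anc_pos, 10L)
  edsx1 <- slice_deletion(parent, 8L, 9L)
  expect_equal(edsx1$ancestral, "A")
  expect_equal(edsx1$anc_pos, 18L)
  seq <- paste0(paste(rep("G", 10), collapse = ""), "ACGTACGTA", "GGGG")
  expect_equal(nchar(apply_event(seq, e8del)), nchar(seq) - 8L)
  expect_equal(nchar(apply_event(seq, edsx1)), nchar(seq) - 1L)
  expect_error(slice_deletion(e8del, 0L, 9L))
})

test_that("designed constructs differ from the backbone only where specified", {
  set.seed(17)
  aln <- get_paper_ds()$alignment
  chim <- swap_region(aln, aln$ids[1], aln$ids[5], list(c(100L, 300L)))
  bb_row <- aln$rows[[aln$ids[1]]]
  chim_row <- paste0(substr(bb_row, 1, 100),
                     substr(aln$rows[[aln$ids[5]]], 101, 300),
                     substr(bb_row, 301, nchar(bb_row)))
  expect_equal(chim$residues, degap(chim_row))
  ev <- call_mutations(paste0(bb_row), chim_row)
  expect_true(all(ev$col_start >= 100L & ev$col_end <= 300L))
})
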