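test_that("consensus scanning matches hand-checked windows", {
  abdb <- motif("ABD-B", "TTTAY")
  s <- scan_motif("GTTTATG", abdb, strands = "forward")
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$start, s$end), c(1L, 6L))
  expect_equal(s$matched, "TTTAT")

  # minus-strand match mapped to forward coordinates
  s2 <- scan_motif("CATAAA", abdb, strands = "both")
  expect_equal(nrow(s2), 1L)
  expect_equal(c(s2$start, s2$end, s2$strand), c("1", "6", "-"))

  dsx <- motif("DSX", "RNNACWAWGTNNY")
  s3 <- scan_motif("AGGACAAAGTGGC", dsx)
  expect_true(any(s3$start == 0L & s3$end == 13L & s3$strand == "+"))

  expect_error(motif("bad", "TTTAX"), "IUPAC")
})

test_that("scanner agrees with the naive regex oracle", {
  set.seed(77)
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  for (k in 1:120) {
    seq <- random_dna(sample(20:300, 1L))
    cons <- paste(sample(codes, sample(3:13, 1L), replace = TRUE,
                         prob = c(rep(4, 4), rep(1, 11))), collapse = "")
    got <- scan_motif(seq, motif("m", cons), strands = "both")
    want <- naive_scan(seq, cons, strands = "both")
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
  }
})

test_that("scanning the reverse complement mirrors the site set", {
  set.seed(99)
  for (k in 1:25) {
    seq <- random_dna(120)
    m <- motif("DSX", "RNNACWAWGTNNY")
    fwd <- scan_motif(seq, m, strands = "both")
    rev <- scan_motif(revcomp(seq), m, strands = "both")
    mirrored <- data.frame(start = 120L - fwd$end,
                           strand = as.character(ifelse(fwd$strand == "+", "-", "+")),
                           stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$start, mirrored$strand), , drop = FALSE]
    expect_equal(rev$start, mirrored$start)
    expect_equal(rev$strand, mirrored$strand)
  }
})

test_that("site diffing calls conserved, lost and gained states", {
  tr <- ape::read.tree(text = "(((P1:1,P2:1):1,A1:1):1,O1:1);")
  anc <- "GGTTTACGGGG"
  ing <- c("P1", "P2", "A1")
  m <- list(motif("ABD-B", "TTTAY"))

  # allele identical to ancestor: all sites conserved, none gained
  aln <- gapped_alignment(c(ing, "O1"), rep(anc, 4))
  rec <- fitch_reconstruct(aln, tr, ing)
  d <- diff_sites(rec, aln, "A1", m)
  expect_true(all(d$status == "conserved"))
  expect_equal(nrow(d), 1L)

  # substitution inside the ancestral site: lost
  mut <- "GGTGTACGGGG"
  aln2 <- gapped_alignment(c(ing, "O1"), c(anc, anc, mut, anc))
  rec2 <- fitch_reconstruct(aln2, tr, ing)
  d2 <- diff_sites(rec2, aln2, "A1", m)
  expect_equal(d2$status[d2$frame == "ancestor"], "lost")

  # allele carries TTTAT where the ancestor had TCTAT: gained
  anc3 <- "GGTCTATGGGG"
  gain <- "GGTTTATGGGG"
  aln3 <- gapped_alignment(c(ing, "O1"), c(anc3, anc3, gain, anc3))
  rec3 <- fitch_reconstruct(aln3, tr, ing)
  d3 <- diff_sites(rec3, aln3, "A1", m)
  expect_true(any(d3$status == "gained" & d3$frame == "allele"))

  # self-diff of the ancestor-equal allele yields only conserved
  d4 <- diff_sites(rec, aln, "P1", m)
  expect_true(all(d4$status == "conserved"))
})

test_that("event/site overlap uses half-open interval arithmetic", {
  ev <- data.frame(kind = "deletion", col_start = 10L, col_end = 19L,
                   ancestral = "GGGGGGGGG", derived = "", anc_pos = 10L,
                   allele_pos = 10L, label = "E", region = "core",
                   stringsAsFactors = FALSE)
  sites <- data.frame(seq_id = "anc", start = c(18L, 40L, 12L),
                      end = c(31L, 45L, 15L), strand = "+",
                      matched = "x", motif_name = c("DSX", "ABD-B", "ABD-B"),
                      stringsAsFactors = FALSE)
  ov <- overlap_events_sites(ev, sites)
  expect_equal(nrow(ov), 2L)
  expect_equal(ov$overlap_bp[ov$motif_name == "DSX"], 1L)      # 1 bp clip
  expect_equal(ov$overlap_bp[ov$site_start == 12L], 3L)        # nested site
})

test_that("post-edit site evaluation re-anchors the window correctly", {
  dsx <- motif("DSX", "RNNACWAWGTNNY")
  # 9-bp deletion ending exactly 1 bp into a DSX site whose new upstream
  # base still satisfies the first consensus position
  seq <- paste0("CCCCCCCCC", "A", "GGGGGGGG", "GCCACAATGTCCT", "AA")
  del <- data.frame(kind = "deletion", col_start = 10L, col_end = 19L,
                    ancestral = "GGGGGGGGG", derived = "", anc_pos = 10L,
                    allele_pos = 10L, label = "E", region = "core",
                    stringsAsFactors = FALSE)
  site <- scan_motif(seq, dsx, strands = "forward")
  expect_equal(site$start, 18L)
  expect_true(evaluate_site_after_edit(seq, del, site[1, ], dsx))

  # substitution of an invariant consensus position kills the match
  sub <- data.frame(kind = "substitution", col_start = 21L, col_end = 22L,
                    ancestral = "A", derived = "G", anc_pos = 21L,
                    allele_pos = 21L, label = "x", region = "core",
                    stringsAsFactors = FALSE)
  expect_false(evaluate_site_after_edit(seq, sub, site[1, ], dsx))

  # an event entirely outside the site leaves the status unchanged
  far <- data.frame(kind = "substitution", col_start = 0L, col_end = 1L,
                    ancestral = "C", derived = "A", anc_pos = 0L,
                    allele_pos = 0L, label = "y", region = "flank",
                    stringsAsFactors = FALSE)
  expect_true(evaluate_site_after_edit(seq, far, site[1, ], dsx))
})
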