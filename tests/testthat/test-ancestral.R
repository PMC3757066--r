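test_that("MRCA state sets match hand-checkable cases", {
  # constant column across ingroup and outgroup is unambiguous
  tr <- ape::read.tree(text = "((P1:1,(P2:1,P3:1):1):1,O1:1);")
  aln <- gapped_alignment(c("P1", "P2", "P3", "O1"),
                          c("AA", "AA", "AG", "AA"))
  rec <- fitch_reconstruct(aln, tr, c("P1", "P2", "P3"))
  expect_equal(rec$state_sets[[1]], "A")
  # one derived tip state: MRCA stays ancestral, unambiguous
  expect_equal(rec$state_sets[[2]], "A")
  expect_equal(substr(rec$consensus, 2, 2), "A")
  expect_equal(rec$polymorphic_cols, 1L)
  expect_equal(length(rec$ambiguous_cols), 0L)

  # balanced ingroup split with a gap-only outgroup is ambiguous,
  # containing both A and G (checked against the labeling oracle)
  tr2 <- ape::read.tree(text = "((P1:1,P2:1):1,O1:1);")
  aln2 <- gapped_alignment(c("P1", "P2", "O1"), c("AC", "GC", "-C"))
  rec2 <- fitch_reconstruct(aln2, tr2, c("P1", "P2"))
  expect_true(all(c("A", "G") %in% rec2$state_sets[[1]]))
  expect_equal(rec2$ambiguous_cols, 0L)
  oracle <- brute_force_mpr(tr2, c(P1 = "A", P2 = "G", O1 = "-"),
                            ape::getMRCA(tr2, c("P1", "P2")))
  expect_setequal(rec2$state_sets[[1]], oracle$set)
})

test_that("reconstruction validates its inputs", {
  tr <- ape::read.tree(text = "((P1:1,P2:1):1,O1:1);")
  aln <- gapped_alignment(c("P1", "P2"), c("A", "A"))
  expect_error(fitch_reconstruct(aln, tr, c("P1", "P2")), "absent")
  aln <- gapped_alignment(c("P1", "P2", "O1"), c("A", "A", "A"))
  expect_error(fitch_reconstruct(aln, tr, character(0)), "empty ingroup")
  # a non-monophyletic "ingroup" whose MRCA spans the outgroup is rejected
  expect_error(fitch_reconstruct(aln, tr, c("P1", "O1")),
               "exclude at least one outgroup")
})

test_that("DP equals the brute-force labeling oracle on random trees", {
  set.seed(101)
  for (k in 1:150) {
    n <- sample(3:7, 1L)
    tr <- ape::rtree(n)
    states <- sample(BASES5, n, replace = TRUE)
    names(states) <- tr$tip.label
    # pick a random internal "MRCA" clade: use the clade of a random internal node
    node <- sample((n + 1L):(n + tr$Nnode), 1L)
    tips_in <- ape::extract.clade(tr, node)$tip.label
    if (length(tips_in) == n) next  # need at least one outgroup
    rows <- unname(states[tr$tip.label])
    keep <- any(rows != "-")
    if (!keep) next
    aln <- gapped_alignment(tr$tip.label, rows)
    rec <- fitch_reconstruct(aln, tr, tips_in)
    mrca <- if (length(tips_in) == 1L) match(tips_in, tr$tip.label)
            else ape::getMRCA(tr, tips_in)
    oracle <- brute_force_mpr(tr, states, mrca)
    expect_equal(rec$score, oracle$score)
    expect_setequal(rec$state_sets[[1]], oracle$set)
  }
})

test_that("outgroups shift the MRCA state set by at most one mutation", {
  # Outgroup information cannot push the MRCA toward states that are costly
  # for the ingroup subtree: every state in the full-tree MPR set has an
  # ingroup-only conditional cost within one mutation of the ingroup-only
  # optimum (the single edge above the MRCA), and the ingroup-only set is
  # exactly the set of conditional-cost minimizers.
  set.seed(23)
  for (k in 1:25) {
    tr <- make_ingroup_tree(4, 2)
    ing <- grep("^P", tr$tip.label, value = TRUE)
    states <- sample(BASES5, length(tr$tip.label), replace = TRUE)
    names(states) <- tr$tip.label
    if (all(states == "-") || all(states[ing] == "-")) next
    aln <- gapped_alignment(tr$tip.label, unname(states[tr$tip.label]))
    full <- fitch_reconstruct(aln, tr, ing)
    sub_tr <- ape::keep.tip(tr, ing)
    sub_aln <- gapped_alignment(ing, unname(states[ing]))
    part <- fitch_reconstruct(sub_aln, sub_tr, ing)
    oracle <- brute_force_mpr(sub_tr, states[ing],
                              ape::getMRCA(sub_tr, ing))
    expect_setequal(part$state_sets[[1]], oracle$set)
    slack <- oracle$cost_by_state[full$state_sets[[1]]] - oracle$score
    expect_true(all(slack <= 1))
  }
})

test_that("alternate reconstructions enumerate the ambiguity product", {
  # (((P1,P2),O1),O2) with P1=A,P2=G,O1=A,O2=G is binary-ambiguous {A,G}
  tr <- ape::read.tree(text = "(((P1:1,P2:1):1,O1:1):1,O2:1);")
  amb_col <- c(P1 = "A", P2 = "G", O1 = "A", O2 = "G")
  const_col <- c(P1 = "C", P2 = "C", O1 = "C", O2 = "C")
  build <- function(n_amb) {
    cols <- c(rep(list(amb_col), n_amb), list(const_col))
    rows <- vapply(names(amb_col), function(id)
      paste(vapply(cols, `[[`, character(1), id), collapse = ""), character(1))
    gapped_alignment(names(amb_col), unname(rows))
  }
  rec3 <- fitch_reconstruct(build(3), tr, c("P1", "P2"))
  expect_equal(length(rec3$ambiguous_cols), 3L)
  alts <- enumerate_alternates(rec3, 100L)
  expect_equal(length(alts), 8L)
  expect_equal(attr(alts, "total_count"), 8)
  expect_equal(alts[[1]], rec3$consensus)
  expect_equal(anyDuplicated(alts), 0L)

  rec0 <- fitch_reconstruct(build(0), tr, c("P1", "P2"))
  alts0 <- enumerate_alternates(rec0, 10L)
  expect_equal(as.character(alts0), rec0$consensus)
  expect_equal(attr(alts0, "total_count"), 1)

  rec8 <- fitch_reconstruct(build(8), tr, c("P1", "P2"))
  alts8 <- enumerate_alternates(rec8, 50L)
  expect_equal(length(alts8), 50L)
  expect_equal(attr(alts8, "total_count"), 256)
  # every alternate only varies at ambiguous columns, within the state set
  for (a in alts8[1:10]) {
    ch <- strsplit(a, "")[[1]]
    for (j in seq_along(ch))
      expect_true(ch[j] %in% rec8$state_sets[[j]])
  }
})

test_that("pairwise identity excludes gapped columns", {
  aln <- gapped_alignment(c("a", "b", "c", "d"),
                          c("ACGT", "ACGT", "ACGA", "AC-T"))
  expect_equal(pairwise_identity(aln, "a", "b"), 1.0)
  expect_equal(pairwise_identity(aln, "a", "c"), 0.75)
  expect_equal(pairwise_identity(aln, "d", "a"), 1.0)  # 3/3 comparable
  gappy <- gapped_alignment(c("x", "y", "z"), c("A-", "-C", "AC"))
  expect_error(pairwise_identity(gappy, "x", "y"), "no comparable")
})

test_that("consensus recovers the true ancestor on the study-scale preset", {
  ds <- get_paper_ds()
  rec <- get_paper_recon()
  cons <- strsplit(rec$consensus, "")[[1]]
  truth <- strsplit(ds$ancestor_row, "")[[1]]
  expect_gte(mean(cons == truth), 0.99)
})
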