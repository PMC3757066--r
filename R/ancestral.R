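# Minimum-change ancestral reconstruction at the ingroup MRCA.
#
# The per-column state space is {A,C,G,T,-}: gaps are treated as a fifth
# character state; indel event semantics are applied afterwards by the
# mutation catalogue. The reconstruction is exact unit-cost parsimony: an
# up/down dynamic program over node states that returns, per column, the
# full set of states the ingroup MRCA takes in at least one minimum-change
# labeling (the MPR set). Multifurcating nodes are handled natively; the
# minimal cost equals that of any binary resolution.

# Exact per-pattern DP. tipstate: integer vector (1..5) indexed by tip
# number. Returns the MPR state-set (integer codes) at `node` and the
# minimal mutation count.
.mpr_column <- function(tipstate, edge_po, n_node, root, node) {
  INF <- 1e9
  n_tip <- length(tipstate)
  up <- matrix(0, n_node, 5L)
  up[seq_len(n_tip), ] <- INF
  up[cbind(seq_len(n_tip), tipstate)] <- 0
  minc <- matrix(0, n_node, 5L)
  for (e in seq_len(nrow(edge_po))) {      # postorder: children before parents
    p <- edge_po[e, 1L]; v <- edge_po[e, 2L]
    m <- pmin(up[v, ], min(up[v, ]) + 1)   # min_s up[v,s] + [s != t]
    minc[v, ] <- m
    up[p, ] <- up[p, ] + m
  }
  score <- min(up[root, ])
  down <- matrix(0, n_node, 5L)
  for (e in rev(seq_len(nrow(edge_po)))) { # preorder: parents before children
    p <- edge_po[e, 1L]; v <- edge_po[e, 2L]
    rest <- down[p, ] + up[p, ] - minc[v, ]
    down[v, ] <- pmin(rest, min(rest) + 1)
  }
  total <- up[node, ] + down[node, ]
  list(set = which(abs(total - score) < 0.5), score = score)
}

#' Parsimony reconstruction of the ingroup-ancestral sequence
#'
#' Infers, for every alignment column, the set of states `{A,C,G,T,-}` that
#' the most recent common ancestor (MRCA) of the ingroup takes in at least
#' one minimum-change labeling of the supplied rooted tree, then resolves a
#' single consensus row by a deterministic tie-break (see Details).
#'
#' @details Ambiguous columns (MPR set larger than one) are resolved by, in
#' order: the state carried by the plurality of outgroup leaves at that
#' column; then the plurality of ingroup leaves; then alphabetical order with
#' `-` last. The full state set is always retained, so downstream code can
#' enumerate alternate reconstructions. Polymorphic columns are counted from
#' the ingroup rows only, at column granularity (a multi-column indel
#' polymorphism contributes one count per column; event-level counts live in
#' [call_mutations()]).
#'
#' @param aln A [gapped_alignment()] containing every tree leaf.
#' @param tree A rooted `phylo` tree whose tip labels are alignment ids.
#'   Multifurcations are allowed.
#' @param ingroup Character vector of tip labels forming the ingroup; its
#'   MRCA must exclude at least one outgroup leaf.
#' @return An object of class `ancestral_reconstruction`: `state_sets` (list,
#'   one character vector per column), `consensus` (gapped row), `ambiguous_cols`
#'   and `polymorphic_cols` (0-based), `score` (total minimal mutation count),
#'   `tie_breaks` (data.frame: col, states, chosen, rule), `ingroup`,
#'   `outgroup`, `n_cols`.
#' @export
fitch_reconstruct <- function(aln, tree, ingroup) {
  stopifnot(inherits(aln, "gapped_alignment"), inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, aln$ids)
  if (length(missing))
    stop("tree leaves absent from alignment: ", paste(missing, collapse = ", "))
  if (length(ingroup) == 0L) stop("empty ingroup")
  if (!all(ingroup %in% tips))
    stop("ingroup names not in tree: ",
         paste(setdiff(ingroup, tips), collapse = ", "))
  outgroup <- setdiff(tips, ingroup)
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  mrca <- if (length(ingroup) == 1L) match(ingroup, tips)
          else ape::getMRCA(tree, ingroup)
  if (length(outgroup)) {
    under <- tips[.tips_under(tree, mrca)]
    if (all(outgroup %in% under))
      stop("ingroup MRCA must exclude at least one outgroup leaf")
  }
  edge_po <- ape::reorder.phylo(tree, "postorder")$edge

  M <- aln_matrix(aln)[tips, , drop = FALSE]
  codes <- matrix(match(M, .BASES5), nrow = nrow(M))
  pat_key <- apply(codes, 2L, paste, collapse = ",")
  uniq <- !duplicated(pat_key)
  res_by_pat <- lapply(which(uniq), function(j)
    .mpr_column(codes[, j], edge_po, n_node, root, mrca))
  names(res_by_pat) <- pat_key[uniq]

  n_cols <- aln$n_cols
  state_sets <- vector("list", n_cols)
  score <- 0
  for (j in seq_len(n_cols)) {
    r <- res_by_pat[[pat_key[j]]]
    state_sets[[j]] <- .BASES5[r$set]
    score <- score + r$score
  }

  ing_m <- M[ingroup, , drop = FALSE]
  out_m <- M[outgroup, , drop = FALSE]
  polymorphic <- which(apply(ing_m, 2L, function(x) length(unique(x)) > 1L)) - 1L
  ambiguous <- which(lengths(state_sets) > 1L) - 1L

  cons <- character(n_cols)
  tb <- list()
  for (j in seq_len(n_cols)) {
    s <- state_sets[[j]]
    if (length(s) == 1L) { cons[j] <- s; next }
    pick <- .plurality(out_m[, j], s)
    rule <- "outgroup_plurality"
    if (is.na(pick)) { pick <- .plurality(ing_m[, j], s); rule <- "ingroup_plurality" }
    if (is.na(pick)) {
      pick <- s[order(match(s, .BASES5))][1L]   # alphabetical, '-' last
      rule <- "alphabetical"
    }
    cons[j] <- pick
    tb[[length(tb) + 1L]] <- data.frame(
      col = j - 1L, states = paste(s, collapse = ""), chosen = pick,
      rule = rule, stringsAsFactors = FALSE)
  }
  tie_breaks <- if (length(tb)) do.call(rbind, tb) else
    data.frame(col = integer(), states = character(), chosen = character(),
               rule = character(), stringsAsFactors = FALSE)

  structure(list(
    state_sets = state_sets,
    consensus = paste(cons, collapse = ""),
    ambiguous_cols = as.integer(ambiguous),
    polymorphic_cols = as.integer(polymorphic),
    score = score,
    tie_breaks = tie_breaks,
    ingroup = ingroup, outgroup = outgroup,
    n_cols = n_cols), class = "ancestral_reconstruction")
}

# unique plurality state among `chars` restricted to candidate set `s`;
# NA if no votes or tied
.plurality <- function(chars, s) {
  if (!length(chars)) return(NA_character_)
  tab <- table(factor(chars, levels = s))
  if (sum(tab) == 0L) return(NA_character_)
  top <- which(tab == max(tab))
  if (length(top) != 1L) return(NA_character_)
  names(tab)[top]
}

# logical over tip indices: does tip descend from `node`?
.tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) {
    out <- rep(FALSE, n_tip); out[node] <- TRUE; return(out)
  }
  kids <- tree$edge[, 2][tree$edge[, 1] == node]
  Reduce(`|`, lapply(kids, .tips_under, tree = tree))
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("<ancestral_reconstruction> %d columns, %d polymorphic,",
                     " %d ambiguous, parsimony score %d\n"),
              x$n_cols, length(x$polymorphic_cols), length(x$ambiguous_cols),
              as.integer(x$score)))
  invisible(x)
}

#' Enumerate alternate ancestral reconstructions
#'
#' Takes the Cartesian product of the MPR state sets over the ambiguous
#' columns, in deterministic lexicographic order (per column: the consensus
#' state first, remaining states in `A,C,G,T,-` order; the first ambiguous
#' column is the most significant digit). The first element is always the
#' primary consensus.
#'
#' @param recon An `ancestral_reconstruction`.
#' @param max_count Maximum number of alternates to return (>= 1).
#' @return Character vector of gapped consensus rows (length
#'   `min(max_count, total)`), with attribute `total_count` giving the full
#'   product of ambiguous state-set sizes.
#' @export
enumerate_alternates <- function(recon, max_count) {
  stopifnot(inherits(recon, "ancestral_reconstruction"), max_count >= 1)
  amb <- recon$ambiguous_cols
  cons <- strsplit(recon$consensus, "")[[1]]
  if (!length(amb)) {
    out <- recon$consensus
    attr(out, "total_count") <- 1
    return(out)
  }
  sets <- lapply(amb, function(cc) {
    s <- recon$state_sets[[cc + 1L]]
    c(cons[cc + 1L], setdiff(s[order(match(s, .BASES5))], cons[cc + 1L]))
  })
  sizes <- lengths(sets)
  total <- prod(sizes)
  k <- min(max_count, total)
  out <- character(k)
  digits <- rep(1L, length(sets))
  for (i in seq_len(k)) {
    row <- cons
    row[amb + 1L] <- mapply(function(s, d) s[d], sets, digits)
    out[i] <- paste(row, collapse = "")
    # odometer increment, last column fastest (lexicographic order)
    j <- length(digits)
    while (j >= 1L) {
      digits[j] <- digits[j] + 1L
      if (digits[j] <= sizes[j]) break
      digits[j] <- 1L; j <- j - 1L
    }
  }
  attr(out, "total_count") <- total
  out
}

#' Pairwise sequence identity between two alignment rows
#'
#' Identity is computed over comparable columns only: columns where neither
#' row carries a gap. A pair with zero comparable columns is an error.
#'
#' @param aln A `gapped_alignment`.
#' @param idA,idB Record ids.
#' @return Fraction of matching comparable columns, in `[0, 1]`.
#' @export
pairwise_identity <- function(aln, idA, idB) {
  a <- strsplit(.aln_row(aln, idA), "")[[1]]
  b <- strsplit(.aln_row(aln, idB), "")[[1]]
  comp <- a != .GAP & b != .GAP
  if (!any(comp)) stop("undefined identity: no comparable columns between ",
                       idA, " and ", idB)
  sum(a[comp] == b[comp]) / sum(comp)
}

#' Mean pairwise identity over a set of records
#'
#' @param aln A `gapped_alignment`.
#' @param ids Record ids (default: all).
#' @return Mean of [pairwise_identity()] over all unordered pairs.
#' @export
mean_pairwise_identity <- function(aln, ids = aln$ids) {
  prs <- utils::combn(ids, 2L)
  mean(vapply(seq_len(ncol(prs)),
              function(k) pairwise_identity(aln, prs[1L, k], prs[2L, k]),
              numeric(1)))
}
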