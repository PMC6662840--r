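# Independent oracles used across the suite. These deliberately avoid the
# package's own reconstruction code paths.

# Minimum number of losses over ALL ancestral-state assignments with at
# most a single gain (root presence counts as the gain), by exhaustive
# enumeration. Vectorized over assignments; leaves with NA state are free.
bruteDolloMinLosses <- function(column, tree) {
  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  st <- rep(NA_real_, ntot)
  st[seq_len(ntip)] <- column[tree$tip.label]
  free <- which(is.na(st))
  k <- length(free)
  A <- if (k == 0) matrix(0, nrow = 1, ncol = 0)
       else as.matrix(expand.grid(rep(list(0:1), k)))
  S <- matrix(st, nrow = ntot, ncol = nrow(A))
  if (k > 0) S[free, ] <- t(A)
  P <- S[tree$edge[, 1L], , drop = FALSE]
  C <- S[tree$edge[, 2L], , drop = FALSE]
  root <- ntip + 1L
  gains <- colSums(P == 0 & C == 1) + S[root, ]
  losses <- colSums(P == 1 & C == 0)
  feasible <- gains <= 1
  # a column with a 1-leaf always admits a single-gain solution
  if (!any(feasible)) return(NA_integer_)
  min(losses[feasible])
}

# deterministic random rooted binary tree with branch lengths
randomTimedTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$edge.length <- round(tr$edge.length * 10, 3) + 0.1
  tr
}

# exhaustive null for the loss-concordance permutation test: enumerate all
# pairs of non-nested k-subsets of the eligible edges
exhaustiveConcordanceP <- function(a, b, tree) {
  elA <- dollotrace:::.eligibleEdges(a, tree)
  elB <- dollotrace:::.eligibleEdges(b, tree)
  parent <- dollotrace:::.parentVec(tree)
  ids <- dollotrace:::.edgeIds(tree)
  nonNested <- function(set) {
    for (i in set) for (j in set)
      if (i != j && dollotrace:::.isAncestor(parent, i, j)) return(FALSE)
    TRUE
  }
  subsets <- function(el, k) {
    if (k == 0) return(list(integer(0)))
    cs <- utils::combn(el, k, simplify = FALSE)
    Filter(nonNested, cs)
  }
  kA <- length(lossEdges(a)); kB <- length(lossEdges(b))
  sa <- subsets(elA, kA); sb <- subsets(elB, kB)
  obs <- lossConcordance(a, b)$jaccard
  tot <- 0L; hit <- 0L
  for (x in sa) for (y in sb) {
    tot <- tot + 1L
    if (lossConcordance(ids[x], ids[y])$jaccard >= obs) hit <- hit + 1L
  }
  hit / tot
}

# all rooted binary leaf-labeled shapes are overkill; a fixed bank of
# hand-picked small topologies exercises caterpillar, balanced and
# polytomy-free shapes
smallTreeBank <- function() {
  list(
    readSpeciesTree("((A:1,B:1):1,C:2);", text = TRUE),
    readSpeciesTree("((A:1,B:1):1,(C:1,D:1):1);", text = TRUE),
    readSpeciesTree("(((A:1,B:1):1,C:2):1,D:3);", text = TRUE),
    readSpeciesTree("(((A:1,B:2):1,(C:1,D:1):2):1,(E:2,F:2):1);",
                    text = TRUE),
    readSpeciesTree("((((A:1,B:1):1,C:2):1,D:3):1,(E:2,F:2):2);",
                    text = TRUE)
  )
}
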