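.lossSet <- function(x) {
  if (methods::is(x, "EventSet")) lossEdges(x) else as.character(x)
}

#' Strict co-evolution of two loss patterns
#'
#' Two genes strictly co-evolve when they were lost on exactly the same
#' branches. Two genes lost nowhere co-evolve vacuously (co-retention).
#'
#' @param a,b [EventSet-class] objects or character vectors of loss-branch
#'   ids (on the same tree).
#' @return logical.
#' @export
strictCoevolution <- function(a, b) {
  setequal(.lossSet(a), .lossSet(b))
}

#' Concordance of two loss patterns (Jaccard index)
#'
#' Quantifies the overlap of loss-branch sets as
#' \eqn{|A \cap B| / |A \cup B|}, defined as 1 when both sets are empty.
#' This statistic (and its permutation null, [concordanceNull()]) is a
#' quantitative companion to the qualitative strict test; it is a
#' package-defined measure, reported as such.
#'
#' @param a,b [EventSet-class] objects or loss-branch id vectors.
#' @return list with `jaccard` in \[0, 1\] and `shared` (branch count).
#' @export
lossConcordance <- function(a, b) {
  A <- unique(.lossSet(a)); B <- unique(.lossSet(b))
  shared <- length(intersect(A, B))
  uni <- length(union(A, B))
  list(jaccard = if (uni == 0L) 1 else shared / uni, shared = shared)
}

## edges eligible for re-placed losses: strict descendants of the gain
.eligibleEdges <- function(events, tree) {
  ids <- .edgeIds(tree)
  g <- gainEdge(events)
  node <- if (is.na(g) || identical(g, "ROOT")) .rootNode(tree)
          else .nodeFromId(tree, g)
  setdiff(.cladeNodes(tree, node), node)
}

.sampleNonNested <- function(eligible, k, parent) {
  if (k == 0L) return(integer(0))
  repeat {
    pick <- eligible[sample.int(length(eligible), k)]
    ok <- TRUE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j && .isAncestor(parent, pick[i], pick[j])) { ok <- FALSE; break }
    }
    if (ok) return(pick)
  }
}

#' Permutation null for loss-pattern concordance
#'
#' Generates a null by independently re-placing each gene's losses
#' uniformly at random on its eligible edges (strict descendants of its
#' gain branch, with nested placements rejected), recomputing the Jaccard
#' concordance each time. The p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})} and is
#' bit-for-bit reproducible for a given seed.
#'
#' @param a,b [EventSet-class] objects reconstructed on `tree`.
#' @param tree rooted [ape::phylo].
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `p.value`, `observed` Jaccard, and `nPerm`.
#' @export
concordanceNull <- function(a, b, tree, nPerm = 10000, seed) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (missing(seed)) stop("a seed is required for a reproducible null")
  ids <- .edgeIds(tree)
  parent <- .parentVec(tree)
  obs <- lossConcordance(a, b)$jaccard
  elA <- .eligibleEdges(a, tree); kA <- length(lossEdges(a))
  elB <- .eligibleEdges(b, tree); kB <- length(lossEdges(b))
  if (length(elA) < kA || length(elB) < kB)
    stop("fewer eligible edges than losses to place")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(nPerm)) {
    pa <- ids[.sampleNonNested(elA, kA, parent)]
    pb <- ids[.sampleNonNested(elB, kB, parent)]
    if (lossConcordance(pa, pb)$jaccard >= obs) hits <- hits + 1L
  }
  list(p.value = (1 + hits) / (1 + nPerm), observed = obs, nPerm = nPerm)
}

#' Read heterodimer pairing rules from TSV
#'
#' Columns: `typeI`, `typeII`, `rank`, `promiscuous`. Ranks must be unique
#' per type I keratin.
#'
#' @param path TSV file; `#` comments skipped.
#' @return data.frame of pairing rules.
#' @export
readPairingRules <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("typeI", "typeII", "rank", "promiscuous")
  if (!all(need %in% colnames(df)))
    stop("pairing rules need columns: ", paste(need, collapse = ", "))
  df$promiscuous <- as.logical(df$promiscuous)
  dup <- stats::aggregate(rank ~ typeI, df,
                          function(r) anyDuplicated(r) > 0L)
  if (any(dup$rank)) stop("ranks must be unique per type I keratin")
  df
}

#' Infer putative type I:type II keratin heterodimers for one species
#'
#' Functional keratin filaments require a type I:type II heterodimer. For
#' every intact type I keratin the highest-priority intact type II partner
#' is emitted; a promiscuous type I keratin (one that tolerates several
#' type II partners) emits all intact partners from its top available rank
#' downwards. Keratins that are not intact in the species are never
#' listed; a type I keratin with no intact partner yields no pair.
#'
#' @param states named character vector of presence states keyed by
#'   keratin symbol, covering all symbols in `rules`.
#' @param rules pairing rules data.frame (see [readPairingRules()]).
#' @return character vector of pairs formatted `"KII:KI"`, in rule order.
#' @export
inferHeterodimers <- function(states, rules) {
  need <- unique(c(rules$typeI, rules$typeII))
  missing <- setdiff(need, names(states))
  if (length(missing))
    stop("states must cover all rule symbols; missing: ",
         paste(missing, collapse = ", "))
  out <- character(0)
  for (t1 in unique(rules$typeI)) {
    if (!identical(unname(states[t1]), "INTACT")) next
    sub <- rules[rules$typeI == t1, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    ok <- sub[states[sub$typeII] == "INTACT", , drop = FALSE]
    if (!nrow(ok)) next
    chosen <- if (any(sub$promiscuous)) ok else ok[1L, , drop = FALSE]
    out <- c(out, paste0(chosen$typeII, ":", t1))
  }
  out
}
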