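#' Read a rooted species tree from Newick
#'
#' Accepts standard Newick with optional internal labels and branch
#' lengths in million years; `[&...]` comment tags (as written by
#' [writeAnnotatedNewick()]) are stripped before parsing. Unrooted trees
#' and trees with duplicated labels are hard errors. Trees without branch
#' lengths parse fine; event dating is simply unavailable for them.
#'
#' @param path file path, or a Newick string when `text = TRUE`.
#' @param text interpret `path` as Newick text.
#' @return an [ape::phylo] tree.
#' @export
readSpeciesTree <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  nwk <- gsub("\\[&[^]]*\\]", "", paste(lines, collapse = ""))
  tree <- ape::read.tree(text = nwk)
  if (is.null(tree)) stop("could not parse Newick input")
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  .edgeIds(tree)  # errors on duplicated internal labels
  tree
}

#' Write a Newick tree with gain/loss events as edge comments
#'
#' Serializes the tree with `[&gain=GENE]` / `[&loss=GENE]` comment tags
#' appended to the branch carrying each event. [readSpeciesTree()] strips
#' the tags, so write-then-read is the identity on topology, labels and
#' branch lengths. Events whose gain is `ROOT` are tagged on the root
#' node.
#'
#' @param tree an [ape::phylo] tree.
#' @param events an [EventSet-class] or list of them.
#' @param path optional output file; when `NULL` the Newick string is
#'   returned invisibly only.
#' @return the annotated Newick string, invisibly when written to file.
#' @export
writeAnnotatedNewick <- function(tree, events, path = NULL) {
  if (methods::is(events, "EventSet")) events <- list(events)
  ids <- .edgeIds(tree)
  tags <- stats::setNames(vector("list", length(ids) + 1L),
                          c(ids, "ROOT"))
  for (ev in events) {
    g <- gainEdge(ev)
    if (!is.na(g)) tags[[g]] <- c(tags[[g]], paste0("gain=", ev@gene))
    for (e in lossEdges(ev))
      tags[[e]] <- c(tags[[e]], paste0("loss=", ev@gene))
  }
  len <- .edgeLenOf(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  ntip <- length(tree$tip.label)
  root <- .rootNode(tree)
  fmt <- function(node) {
    ch <- kids[[as.character(node)]]
    lab <- if (node <= ntip) ids[node]
           else if (!is.null(tree$node.label) &&
                    nzchar(tree$node.label[node - ntip]))
             tree$node.label[node - ntip] else ""
    core <- if (is.null(ch)) lab
            else paste0("(", paste(vapply(ch, fmt, character(1)),
                                   collapse = ","), ")", lab)
    if (node != root && !is.na(len[node]))
      core <- paste0(core, ":", format(len[node], scientific = FALSE))
    tg <- tags[[if (node == root) "ROOT" else ids[node]]]
    if (!is.null(tg)) core <- paste0(core, "[&", paste(tg, collapse = ","),
                                     "]")
    core
  }
  nwk <- paste0(fmt(root), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}

## shared postorder presence flags: has1/has0 per node for a binary column
.presenceFlags <- function(tree, bin) {
  ntot <- .nTotal(tree)
  has1 <- logical(ntot); has0 <- logical(ntot)
  ntip <- length(tree$tip.label)
  has1[seq_len(ntip)] <- !is.na(bin) & bin == 1
  has0[seq_len(ntip)] <- !is.na(bin) & bin == 0
  ed <- .postorderEdges(tree)
  for (k in seq_len(nrow(ed))) {
    has1[ed[k, 1L]] <- has1[ed[k, 1L]] || has1[ed[k, 2L]]
    has0[ed[k, 1L]] <- has0[ed[k, 1L]] || has0[ed[k, 2L]]
  }
  list(has1 = has1, has0 = has0)
}

.eventInterval <- function(tree, ages, ids, node, event, gene) {
  if (identical(node, "ROOT"))
    return(data.frame(gene = gene, event = event, edge = "ROOT",
                      olderMY = NA_real_,
                      youngerMY = ages[.rootNode(tree)],
                      stringsAsFactors = FALSE))
  parent <- .parentVec(tree)[node]
  data.frame(gene = gene, event = event, edge = ids[node],
             olderMY = ages[parent], youngerMY = ages[node],
             stringsAsFactors = FALSE)
}

#' Dollo maximum-parsimony reconstruction of one gene's history
#'
#' Under Dollo parsimony a gene arises exactly once and can only be lost
#' thereafter. The gain is placed on the edge above the most recent common
#' ancestor of all leaves carrying a functional gene (state 1), or at/above
#' the root when that MRCA is the root or when `ancestralAtRoot = TRUE`
#' (for genes known to predate the sampled clade). Within the gain clade,
#' one loss is placed on each maximal edge whose subtree contains at least
#' one known state-0 leaf and no state-1 leaf. Uninformative leaves (`NA`)
#' impose no constraint: they join whichever resolution minimizes events
#' and never force a loss. The reconstruction is unique and deterministic.
#'
#' @param column named vector of binarized leaf states (1, 0, `NA`; or
#'   "1"/"0"/"?"), names = tip labels. Tips absent from the column are
#'   treated as uninformative.
#' @param tree a rooted [ape::phylo] tree.
#' @param ancestralAtRoot place the gain at/above the root regardless of
#'   the in-matrix MRCA.
#' @param gene gene name recorded in the result.
#' @return an [EventSet-class]. With no state-1 leaf, an empty event set
#'   (gain `NA`, no losses).
#' @export
dolloReconstruct <- function(column, tree, ancestralAtRoot = FALSE,
                             gene = "gene") {
  bin <- .binaryColumn(column, tree)
  ids <- .edgeIds(tree)
  ones <- which(!is.na(bin) & bin == 1)
  if (!length(ones))
    return(methods::new("EventSet", gene = gene,
                        gainEdge = NA_character_,
                        lossEdges = character(0),
                        intervals = data.frame()))
  root <- .rootNode(tree)
  gainNode <- if (ancestralAtRoot) root
              else if (length(ones) == 1L) ones
              else ape::getMRCA(tree, ones)
  gainId <- if (gainNode == root) "ROOT" else ids[gainNode]
  fl <- .presenceFlags(tree, bin)
  parent <- .parentVec(tree)
  clade <- setdiff(.cladeNodes(tree, gainNode), gainNode)
  lossNodes <- clade[!fl$has1[clade] & fl$has0[clade] &
                       fl$has1[parent[clade]]]
  ## sanity: losses are never nested
  for (v in lossNodes) for (w in lossNodes)
    if (v != w && .isAncestor(parent, v, w))
      stop("internal error: nested loss edges")
  ages <- .nodeAges(tree)
  intervals <- data.frame()
  if (!is.null(ages)) {
    intervals <- rbind(
      .eventInterval(tree, ages, ids,
                     if (gainId == "ROOT") "ROOT" else gainNode,
                     "gain", gene),
      do.call(rbind, c(list(data.frame()),
                       lapply(lossNodes, .eventInterval, tree = tree,
                              ages = ages, ids = ids, event = "loss",
                              gene = gene))))
  }
  methods::new("EventSet", gene = gene, gainEdge = gainId,
               lossEdges = ids[lossNodes], intervals = intervals)
}

#' Sankoff minimum-cost reconstruction of a binary gain/loss character
#'
#' Classic two-state Sankoff dynamic program: bottom-up cost vectors with
#' per-edge transition costs (`costGain` for 0 to 1, `costLoss` for 1 to
#' 0), plus `costGain` charged when the root itself carries the gene (the
#' gene must have been gained on the root stem). Uninformative leaves have
#' zero cost in both states. The backtrace is deterministic: ties resolve
#' in pre-order toward the shallower event placement (state 0), which
#' keeps ambiguous resolutions aligned with Dollo's maximal-depth loss
#' edges. With
#' `costGain >= (1 + nLeaves) * costLoss` regains are prohibitively
#' expensive and the implied events coincide with [dolloReconstruct()].
#'
#' @param column named vector of binarized leaf states (see
#'   [dolloReconstruct()]).
#' @param tree rooted [ape::phylo].
#' @param costGain,costLoss positive event costs.
#' @return list with `cost` (minimal total), `states` (named 0/1 vector
#'   over all nodes), `gainEdges` (edge ids, `"ROOT"` possible) and
#'   `lossEdges`.
#' @export
sankoffReconstruct <- function(column, tree, costGain = 1, costLoss = 1) {
  if (costGain <= 0 || costLoss <= 0) stop("costs must be positive")
  bin <- .binaryColumn(column, tree)
  ntot <- .nTotal(tree)
  ntip <- length(tree$tip.label)
  ids <- .edgeIds(tree)
  ## S[node, s+1] = min cost of the subtree given node has state s
  S <- matrix(0, ntot, 2L)
  for (i in seq_len(ntip)) {
    if (is.na(bin[i])) next
    S[i, ] <- if (bin[i] == 1) c(Inf, 0) else c(0, Inf)
  }
  tc <- matrix(c(0, costLoss, costGain, 0), 2L, 2L)  # tc[s+1, t+1]
  ed <- .postorderEdges(tree)
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    for (s in 1:2)
      S[p, s] <- S[p, s] + min(tc[s, 1L] + S[ch, 1L],
                               tc[s, 2L] + S[ch, 2L])
  }
  root <- .rootNode(tree)
  totals <- c(S[root, 1L], S[root, 2L] + costGain)
  rootState <- if (totals[2L] < totals[1L]) 1L else 0L
  states <- integer(ntot)
  states[root] <- rootState
  pre <- ed[rev(seq_len(nrow(ed))), , drop = FALSE]  # parents first
  for (k in seq_len(nrow(pre))) {
    p <- pre[k, 1L]; ch <- pre[k, 2L]
    s <- states[p] + 1L
    cands <- c(tc[s, 1L] + S[ch, 1L], tc[s, 2L] + S[ch, 2L])
    ## ties resolve to state 0 in pre-order: an event on this edge rather
    ## than deeper, which keeps ambiguous (all-unknown) resolutions
    ## identical to the Dollo placement at maximal depth
    states[ch] <- if (cands[2L] < cands[1L]) 1L else 0L
  }
  gains <- character(0); losses <- character(0)
  if (rootState == 1L) gains <- "ROOT"
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    if (states[p] == 0L && states[ch] == 1L) gains <- c(gains, ids[ch])
    if (states[p] == 1L && states[ch] == 0L) losses <- c(losses, ids[ch])
  }
  names(states) <- ids
  list(cost = min(totals), states = states,
       gainEdges = gains, lossEdges = losses)
}

#' Count independent loss events, merging shared ancestral lesions
#'
#' By default simply the number of loss branches in the event set. When
#' species groups carrying a lesion at the same aligned position (from
#' [sharedLesions()]) are supplied together with the tree, losses wholly
#' contained in one group are interpreted as a single ancestral
#' inactivation and collapsed onto the stem branch of the group's MRCA
#' before counting.
#'
#' @param events an [EventSet-class].
#' @param tree the tree the events were reconstructed on (required with
#'   `sharedGroups`).
#' @param sharedGroups list of character vectors of species sharing an
#'   aligned lesion.
#' @return integer loss count.
#' @export
countIndependentLosses <- function(events, tree = NULL,
                                   sharedGroups = NULL) {
  losses <- lossEdges(events)
  if (is.null(sharedGroups)) return(length(losses))
  if (is.null(tree)) stop("tree required to merge shared-lesion groups")
  ids <- .edgeIds(tree)
  parent <- .parentVec(tree)
  dt <- .descTips(tree)
  tipLab <- tree$tip.label
  for (grp in sharedGroups) {
    if (length(grp) < 2L) next
    inGroup <- vapply(losses, function(e) {
      node <- .nodeFromId(tree, e)
      all(tipLab[dt[[node]]] %in% grp)
    }, logical(1))
    if (sum(inGroup) >= 2L) {
      merged <- losses[inGroup]
      tips <- match(grp, tipLab)
      tips <- tips[!is.na(tips)]
      m <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
      losses <- c(losses[!inGroup], ids[m])
    }
  }
  length(unique(losses))
}

#' Date an event to its branch interval
#'
#' Under parsimony an event is resolved only to a branch; its time is the
#' interval spanned by that branch: older bound = age of the parent node,
#' younger bound = age of the child node (leaves at 0 MY). For a gain at
#' `"ROOT"` the older bound is unknown (`NA`).
#'
#' @param tree rooted [ape::phylo] with branch lengths in MY.
#' @param edge edge id (child-node label) or `"ROOT"`.
#' @return numeric `c(olderMY, youngerMY)`.
#' @export
dateEvent <- function(tree, edge) {
  ages <- .nodeAges(tree)
  if (is.null(ages))
    stop("dating unavailable: tree has no branch lengths")
  if (identical(edge, "ROOT"))
    return(c(olderMY = NA_real_, youngerMY = ages[.rootNode(tree)]))
  node <- .nodeFromId(tree, edge)
  parent <- .parentVec(tree)[node]
  if (parent == 0L)
    return(c(olderMY = NA_real_, youngerMY = ages[node]))
  c(olderMY = ages[parent], youngerMY = ages[node])
}

#' Write reconstructed events to TSV or JSON
#'
#' Serializes an [eventsReport()] result (or a single [EventSet-class])
#' for downstream tooling: the event table as TSV, and gain/loss edges
#' with their time intervals as JSON.
#'
#' @param report result of [eventsReport()] or an [EventSet-class].
#' @param path output file; format chosen by extension (`.json` vs TSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
writeEvents <- function(report, path) {
  if (methods::is(report, "EventSet"))
    report <- list(events = eventIntervals(report),
                   eventSets = stats::setNames(list(report),
                                               report@gene))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- lapply(report$eventSets, function(ev)
      list(gene = ev@gene, gain = gainEdge(ev), losses = lossEdges(ev),
           intervals = eventIntervals(ev)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    utils::write.table(report$events, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Per-gene gain/loss report over a presence matrix
#'
#' Applies [dolloReconstruct()] to every gene column of the matrix and
#' tabulates gain branch, loss branches and (when branch lengths exist)
#' time intervals. Row order is deterministic: genes in matrix order, then
#' the gain, then loss edges in tree pre-order.
#'
#' @param pm a [PresenceMatrix-class].
#' @param tree rooted [ape::phylo] covering the matrix species.
#' @param ancestralAtRoot character vector of genes whose gain is forced
#'   to the root (genes known to predate the sampled clade).
#' @return list with `events` (data.frame: gene, event, edge, olderMY,
#'   youngerMY), `eventSets` (named list of [EventSet-class]) and `newick`
#'   (annotated Newick string).
#' @export
eventsReport <- function(pm, tree, ancestralAtRoot = character(0)) {
  stopifnot(methods::is(pm, "PresenceMatrix"))
  genes <- colnames(presenceStates(pm))
  ids <- .edgeIds(tree)
  pre <- c("ROOT", ids[ape::reorder.phylo(tree, "cladewise")$edge[, 2L]])
  sets <- lapply(genes, function(g)
    dolloReconstruct(binarizeStates(pm, g), tree,
                     ancestralAtRoot = g %in% ancestralAtRoot, gene = g))
  names(sets) <- genes
  rows <- lapply(sets, function(ev) {
    if (is.na(gainEdge(ev))) return(NULL)
    edges <- c(gainEdge(ev), lossEdges(ev))
    kinds <- c("gain", rep("loss", length(lossEdges(ev))))
    o <- order(match(edges, pre))
    iv <- t(vapply(edges, function(e)
      tryCatch(dateEvent(tree, e),
               error = function(e2) c(NA_real_, NA_real_)), numeric(2)))
    data.frame(gene = ev@gene, event = kinds[o], edge = edges[o],
               olderMY = iv[o, 1L], youngerMY = iv[o, 2L],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  events <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(events))
    events <- data.frame(gene = character(0), event = character(0),
                         edge = character(0), olderMY = numeric(0),
                         youngerMY = numeric(0))
  list(events = events, eventSets = sets,
       newick = writeAnnotatedNewick(tree, sets))
}
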