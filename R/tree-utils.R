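## Internal helpers over ape "phylo" trees.
##
## Edges are identified throughout the package by their CHILD node: leaf
## edges by the leaf label, internal edges by the internal node label, or
## "node<N>" (ape node number) when the node is unlabeled. "ROOT" denotes
## the (virtual) edge above the root.

.nTotal <- function(tree) length(tree$tip.label) + tree$Nnode

.rootNode <- function(tree) length(tree$tip.label) + 1L

.edgeIds <- function(tree) {
  ntip <- length(tree$tip.label)
  ids <- character(.nTotal(tree))
  ids[seq_len(ntip)] <- tree$tip.label
  nl <- tree$node.label
  for (i in seq_len(tree$Nnode)) {
    lab <- if (!is.null(nl) && length(nl) >= i && !is.na(nl[i]) &&
               nzchar(nl[i])) nl[i] else paste0("node", ntip + i)
    ids[ntip + i] <- lab
  }
  if (anyDuplicated(ids))
    stop("tree node labels are not unique: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ids
}

.nodeFromId <- function(tree, id) {
  ids <- .edgeIds(tree)
  n <- match(id, ids)
  if (is.na(n)) stop("unknown edge/node identifier: ", id)
  n
}

.parentVec <- function(tree) {
  p <- integer(.nTotal(tree))
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p  # root maps to 0
}

.edgeLenOf <- function(tree) {
  len <- rep(NA_real_, .nTotal(tree))
  if (!is.null(tree$edge.length)) len[tree$edge[, 2L]] <- tree$edge.length
  len  # branch length of the edge above each node; NA at root
}

.postorderEdges <- function(tree) ape::reorder.phylo(tree, "postorder")$edge

## descendant tip numbers for every node
.descTips <- function(tree) {
  ntot <- .nTotal(tree)
  ntip <- length(tree$tip.label)
  res <- vector("list", ntot)
  for (i in seq_len(ntip)) res[[i]] <- i
  ed <- .postorderEdges(tree)
  for (k in seq_len(nrow(ed)))
    res[[ed[k, 1L]]] <- c(res[[ed[k, 1L]]], res[[ed[k, 2L]]])
  res
}

## all nodes (incl. `node` itself) in the clade rooted at `node`
.cladeNodes <- function(tree, node) {
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    out <- c(out, v)
    ch <- kids[[as.character(v)]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  out
}

## node ages in MY: leaves at 0, internal node age = max path length to a
## descendant leaf (exact for ultrametric timed trees)
.nodeAges <- function(tree) {
  if (is.null(tree$edge.length)) return(NULL)
  ages <- rep(0, .nTotal(tree))
  ed <- .postorderEdges(tree)
  len <- .edgeLenOf(tree)
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    ages[p] <- max(ages[p], ages[ch] + len[ch])
  }
  ages
}

## TRUE iff `anc` is a strict ancestor of node `v`
.isAncestor <- function(parent, anc, v) {
  while (v != 0L) {
    v <- parent[v]
    if (v == anc) return(TRUE)
  }
  FALSE
}

## binarize a leaf-state column to 1/0/NA against the tree's tips;
## tips absent from the column are uninformative (NA)
.binaryColumn <- function(column, tree) {
  tips <- tree$tip.label
  extra <- setdiff(names(column), tips)
  if (length(extra))
    stop("leaf not present in the tree: ", paste(extra, collapse = ", "))
  v <- rep(NA_real_, length(tips))
  names(v) <- tips
  if (is.character(column)) {
    column <- vapply(column, function(x)
      switch(x, "1" = 1, "0" = 0, "?" = NA_real_,
             stop("binarized states must be 1, 0 or ?")), numeric(1))
  }
  v[names(column)] <- as.numeric(column)
  if (any(!v %in% c(0, 1) & !is.na(v)))
    stop("binarized states must be 1, 0 or NA")
  v
}
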