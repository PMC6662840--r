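## Synthetic-data generators. Every generator takes an explicit seed and
## restores the caller's RNG state, so identical inputs give byte-identical
## outputs and adding a generator never perturbs other streams.

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a Dollo gain/loss character on a timed tree
#'
#' The gene is present from `gainEdge` downward. On every descendant edge
#' of length `t` (MY) whose parent still carries the gene, a loss occurs
#' with probability \eqn{1 - e^{-\lambda t}}; once lost the gene stays
#' lost (Dollo irreversibility), so planted losses are never nested.
#' Leaves outside the gain clade are `ABSENT`; leaves that lost the gene
#' are `PSEUDOGENE`; carriers are `INTACT`.
#'
#' @param tree rooted [ape::phylo] with branch lengths in MY.
#' @param gainEdge edge id (child-node label) or `"ROOT"`.
#' @param lossRate expected losses per MY per lineage (>= 0).
#' @param seed RNG seed.
#' @return list with `states` (named per-leaf state strings) and `truth`
#'   (list: `gainEdge`, `lossEdges`, `eligibleEdges` - edges whose parent
#'   carried the gene, i.e. the edges on which a loss could have
#'   happened).
#' @export
simulateDolloCharacter <- function(tree, gainEdge, lossRate, seed) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths")
  if (lossRate < 0) stop("lossRate must be >= 0")
  ids <- .edgeIds(tree)
  gainNode <- if (identical(gainEdge, "ROOT")) .rootNode(tree)
              else .nodeFromId(tree, gainEdge)
  len <- .edgeLenOf(tree)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  ntip <- length(tree$tip.label)
  present <- logical(.nTotal(tree))
  present[gainNode] <- TRUE
  lossEdges <- character(0)
  eligible <- character(0)
  .withSeed(seed, {
    stack <- gainNode
    while (length(stack)) {
      v <- stack[[1L]]; stack <- stack[-1L]
      ch <- kids[[as.character(v)]]
      for (c in ch) {
        if (present[v]) {
          eligible <- c(eligible, ids[c])
          lost <- stats::runif(1) < 1 - exp(-lossRate * len[c])
          present[c] <- !lost
          if (lost) lossEdges <- c(lossEdges, ids[c])
        }
        stack <- c(stack, c)
      }
    }
  })
  clade <- .cladeNodes(tree, gainNode)
  states <- rep("ABSENT", ntip)
  inClade <- intersect(clade, seq_len(ntip))
  states[inClade] <- ifelse(present[inClade], "INTACT", "PSEUDOGENE")
  names(states) <- tree$tip.label
  list(states = states,
       truth = list(gainEdge = gainEdge, lossEdges = lossEdges,
                    eligibleEdges = eligible))
}

#' Plant inactivating lesions into an intact coding model
#'
#' Applies a lesion specification to an intact [CodingModel-class]:
#' `PREMATURE_STOP` substitutes the codon with a random stop (TGA/TAA/
#' TAG), `FRAMESHIFT_INDEL` deletes or inserts `shift` nucleotides
#' (`|shift| mod 3 != 0`) at the codon start, `START_LOSS` mutates the
#' initial ATG. Exon widths are adjusted so the model stays valid. The
#' exact planted positions are returned as ground truth for round-trip
#' testing against [scanORF()] / [compareToReference()].
#'
#' @param model intact [CodingModel-class].
#' @param lesionSpec data.frame with columns `kind`, `codon` and optional
#'   `shift` (frameshift length in nt, default -1); two lesions at one
#'   codon are a hard error.
#' @param seed RNG seed (stop-codon choice).
#' @return list with `model` (mutated) and `truth` (the spec, with the
#'   planted codons and substituted stop codons filled in).
#' @export
mutateCDS <- function(model, lesionSpec, seed = 1) {
  if (is.null(lesionSpec) || nrow(lesionSpec) == 0L)
    return(list(model = model, truth = lesionSpec))
  if (!"shift" %in% colnames(lesionSpec)) lesionSpec$shift <- -1L
  if (anyDuplicated(lesionSpec$codon))
    stop("lesion position collision at codon ",
         lesionSpec$codon[duplicated(lesionSpec$codon)][1L])
  cds <- as.character(model@cds)
  ncod <- nchar(cds) %/% 3L
  if (any(lesionSpec$codon < 1L | lesionSpec$codon > ncod))
    stop("lesion position outside the CDS")
  widths <- IRanges::width(model@exons)
  starts <- IRanges::start(model@exons)
  gaps <- if (length(starts) > 1L)
    starts[-1L] - (starts[-length(starts)] + widths[-length(widths)])
  else integer(0)
  truth <- lesionSpec
  truth$planted <- NA_character_
  .withSeed(seed, {
    ## substitutions first, then indels from the 3' end so earlier
    ## coordinates stay valid
    subs <- lesionSpec[lesionSpec$kind != "FRAMESHIFT_INDEL", , drop = FALSE]
    for (i in seq_len(nrow(subs))) {
      k <- subs$codon[i]
      nt <- 3L * k - 2L
      repl <- switch(subs$kind[i],
                     PREMATURE_STOP = sample(c("TGA", "TAA", "TAG"), 1L),
                     START_LOSS = "GTG",
                     stop("unsupported lesion kind: ", subs$kind[i]))
      substr(cds, nt, nt + 2L) <- repl
      truth$planted[truth$codon == k] <- repl
    }
    ind <- lesionSpec[lesionSpec$kind == "FRAMESHIFT_INDEL", , drop = FALSE]
    ind <- ind[order(-ind$codon), , drop = FALSE]
    for (i in seq_len(nrow(ind))) {
      shift <- as.integer(ind$shift[i])
      if (shift %% 3L == 0L)
        stop("frameshift length must not be a multiple of 3")
      nt <- 3L * ind$codon[i] - 2L
      if (shift < 0L) {
        cds <- paste0(substr(cds, 1L, nt - 1L),
                      substr(cds, nt - shift, nchar(cds)))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), shift, replace = TRUE),
                     collapse = "")
        cds <- paste0(substr(cds, 1L, nt - 1L), ins,
                      substr(cds, nt, nchar(cds)))
        truth$planted[truth$codon == ind$codon[i]] <- ins
      }
      ## shrink/grow the exon containing the edit
      cum <- cumsum(widths)
      ex <- which(cum >= nt)[1L]
      widths[ex] <- widths[ex] + shift
    }
  })
  newStarts <- integer(length(widths))
  if (length(widths)) {
    newStarts[1L] <- starts[1L]
    for (i in seq_len(length(widths) - 1L))
      newStarts[i + 1L] <- newStarts[i] + widths[i] + gaps[i]
  }
  mutated <- newCodingModel(model@geneId, model@species,
                            cbind(newStarts, newStarts + widths - 1L),
                            cds, model@strand, model@rodDomain,
                            model@geneticCode)
  list(model = mutated, truth = truth)
}

#' Apply an edit script to a locus map
#'
#' Emulates lineage-specific locus differences: drop genes, insert new
#' ones, or invert the whole region (reversing gene order and flipping
#' every strand). Coordinates are re-spaced deterministically on a
#' 10-kb grid. Dropping a symbol listed in `anchors` warns (the synteny
#' window downstream will come back incomplete) but is not an error.
#'
#' @param map a [LocusMap-class].
#' @param drop symbols to remove.
#' @param insert data.frame with columns `symbol` and `after` (symbol to
#'   insert after; `""` = at the start).
#' @param invert invert the whole map.
#' @param anchors symbols relied upon downstream (for the warning only).
#' @return a new [LocusMap-class].
#' @export
shuffleLocus <- function(map, drop = character(0), insert = NULL,
                         invert = FALSE, anchors = character(0)) {
  if (!length(drop) && (is.null(insert) || !nrow(insert)) && !invert)
    return(map)  # empty edit script: identity
  sym <- geneSymbols(map)
  st <- as.character(GenomicRanges::strand(locusFeatures(map)))
  hitAnchor <- intersect(tolower(drop), tolower(anchors))
  if (length(hitAnchor))
    warning("dropping anchor gene(s): ", paste(hitAnchor, collapse = ", "))
  keep <- !(tolower(sym) %in% tolower(drop))
  sym <- sym[keep]; st <- st[keep]
  if (!is.null(insert) && nrow(insert)) {
    for (i in seq_len(nrow(insert))) {
      pos <- if (!nzchar(insert$after[i])) 0L
             else {
               j <- which(tolower(sym) == tolower(insert$after[i]))
               if (!length(j)) length(sym) else j[1L]
             }
      sym <- append(sym, insert$symbol[i], after = pos)
      st <- append(st, "+", after = pos)
    }
  }
  if (invert) {
    sym <- rev(sym)
    st <- rev(ifelse(st == "+", "-", "+"))
  }
  n <- length(sym)
  start <- 1000L + (seq_len(n) - 1L) * 10000L
  region <- if (length(locusFeatures(map)))
    as.character(GenomicRanges::seqnames(locusFeatures(map)))[1L] else "region"
  newLocusMap(speciesName(map), region, sym, start, start + 1999L, st)
}

#' Simulate a qPCR Ct table under the efficiency-2 model
#'
#' For each tissue the target gene's Ct is
#' \eqn{Ct_{base} - \log_2(fold) + N(0, sd)} and the reference gene's Ct
#' is a constant plus the same Gaussian noise, so that with `noiseSd = 0`
#' the relative quantities reproduce the fold changes exactly.
#'
#' @param foldChanges named positive numeric, fold change per tissue.
#' @param nPerGroup named integer, samples per tissue (same names).
#' @param noiseSd Gaussian Ct noise standard deviation (cycles).
#' @param seed RNG seed.
#' @param gene,referenceGene gene symbols written into the table.
#' @param baseCt target Ct at fold = 1; referenceCt reference gene Ct.
#' @param referenceCt see above.
#' @return list with `table` (Ct data.frame) and `truth` (fold changes).
#' @export
simulateQpcr <- function(foldChanges, nPerGroup, noiseSd = 0.5, seed = 1,
                         gene = "KRT24", referenceGene = "GAPDH",
                         baseCt = 30, referenceCt = 20) {
  if (any(foldChanges <= 0)) stop("fold changes must be > 0")
  if (!setequal(names(foldChanges), names(nPerGroup)))
    stop("foldChanges and nPerGroup must name the same tissues")
  rows <- .withSeed(seed, {
    out <- list()
    for (tissue in names(foldChanges)) {
      n <- nPerGroup[[tissue]]
      idx <- length(out)
      for (j in seq_len(n)) {
        sid <- paste0(tissue, "_", j)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sid, tissue = tissue, gene = gene,
          ct = baseCt - log2(foldChanges[[tissue]]) +
            stats::rnorm(1, 0, noiseSd),
          efficiency = 2, stringsAsFactors = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sid, tissue = tissue, gene = referenceGene,
          ct = referenceCt + stats::rnorm(1, 0, noiseSd),
          efficiency = 2, stringsAsFactors = FALSE)
      }
    }
    out
  })
  list(table = do.call(rbind, rows), truth = list(fold = foldChanges))
}

#' Generate a random intact ORF
#'
#' ATG start, random non-stop internal codons, terminal TAA. Convenience
#' generator for tests and simulations.
#'
#' @param nCodons total codon count including start and stop.
#' @param seed RNG seed.
#' @return character CDS of length `3 * nCodons`.
#' @export
randomIntactCDS <- function(nCodons = 300, seed = 1) {
  stopifnot(nCodons >= 3)
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all64, c("TAA", "TAG", "TGA"))
  .withSeed(seed, {
    body <- sample(sense, nCodons - 2L, replace = TRUE)
    paste0("ATG", paste(body, collapse = ""), "TAA")
  })
}
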