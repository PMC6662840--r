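#' @import methods
#' @importFrom GenomicRanges GRanges start end strand
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

## state alphabet shared by the presence matrix and the ortholog caller
.STATE_ALPHABET <- c("INTACT", "PSEUDOGENE", "ABSENT", "UNKNOWN",
                     "HOMOLOG_UNRESOLVED")

.LESION_KINDS <- c("PREMATURE_STOP", "FRAMESHIFT_INDEL", "START_LOSS",
                   "TERMINAL_STOP_LOSS")

#' LocusMap: ordered gene features of one genomic region in one species
#'
#' A `LocusMap` holds the gene-level features of a single genomic window in
#' one species, as a [GenomicRanges::GRanges] with metadata columns
#' `gene_id` and `symbol`, sorted by start coordinate. It is the substrate
#' of synteny-based positional orthology: gene order between conserved
#' flanking anchors is compared across species.
#'
#' @slot species single species identifier.
#' @slot features `GRanges` sorted by start; `mcols` carry `gene_id`
#'   (unique) and `symbol`.
#' @export
setClass("LocusMap",
         representation(species = "character", features = "GRanges"))

setValidity("LocusMap", function(object) {
  msg <- character(0)
  if (length(object@species) != 1L || is.na(object@species))
    msg <- c(msg, "species must be a single string")
  gr <- object@features
  if (length(gr)) {
    mc <- S4Vectors::mcols(gr)
    if (!all(c("gene_id", "symbol") %in% colnames(mc)))
      msg <- c(msg, "features must carry gene_id and symbol columns")
    else {
      if (anyDuplicated(mc$gene_id))
        msg <- c(msg, paste0("duplicate gene_id: ",
                             mc$gene_id[duplicated(mc$gene_id)][1L]))
      if (any(!nzchar(mc$symbol)))
        msg <- c(msg, "empty gene symbol")
    }
    if (length(unique(as.character(GenomicRanges::seqnames(gr)))) > 1L)
      msg <- c(msg, "all features must share one sequence region")
    if (is.unsorted(GenomicRanges::start(gr)))
      msg <- c(msg, "features must be sorted by start")
    if (any(!as.character(GenomicRanges::strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "strand must be + or -")
  }
  if (length(msg)) msg else TRUE
})

#' GeneWindow: result of extracting an anchor-bounded window
#'
#' Returned by [extractWindow()]. A missing anchor is reported as status
#' `WINDOW_INCOMPLETE` (a value, not an error), so that fragmented
#' assemblies propagate to presence state `UNKNOWN` rather than fabricating
#' gene losses.
#'
#' @slot status `"OK"` or `"WINDOW_INCOMPLETE"`.
#' @slot features `GRanges` strictly between the anchors, ordered in
#'   anchor-to-anchor reading direction.
#' @slot missingAnchors anchors not found (empty when status is `"OK"`).
#' @export
setClass("GeneWindow",
         representation(status = "character", features = "GRanges",
                        missingAnchors = "character"))

setValidity("GeneWindow", function(object) {
  if (!object@status %in% c("OK", "WINDOW_INCOMPLETE"))
    return("status must be OK or WINDOW_INCOMPLETE")
  if (object@status == "OK" && length(object@missingAnchors))
    return("OK window cannot have missing anchors")
  TRUE
})

#' OrthologCall: synteny-based positional orthology verdict
#'
#' @slot targetSymbol symbol searched for.
#' @slot querySpecies species of the query map.
#' @slot status one of ORTHOLOG, HOMOLOG_UNRESOLVED, ABSENT_FROM_WINDOW,
#'   WINDOW_INCOMPLETE.
#' @slot leftAnchor,rightAnchor nearest conserved flanking symbols used
#'   (may be empty strings).
#' @slot evidence number of flanking anchors recovered in the query (0-2);
#'   an ORTHOLOG call requires 2.
#' @slot candidates symbols of candidate genes found inside the window.
#' @export
setClass("OrthologCall",
         representation(targetSymbol = "character",
                        querySpecies = "character",
                        status = "character",
                        leftAnchor = "character",
                        rightAnchor = "character",
                        evidence = "integer",
                        candidates = "character"))

setValidity("OrthologCall", function(object) {
  ok <- c("ORTHOLOG", "HOMOLOG_UNRESOLVED", "ABSENT_FROM_WINDOW",
          "WINDOW_INCOMPLETE")
  if (!object@status %in% ok)
    return(paste("status must be one of:", paste(ok, collapse = ", ")))
  if (object@evidence < 0L || object@evidence > 2L)
    return("evidence must be in 0..2")
  if (object@status == "ORTHOLOG" && object@evidence != 2L)
    return("ORTHOLOG requires evidence == 2")
  TRUE
})

#' CodingModel: exon structure and spliced CDS of one gene
#'
#' @slot geneId gene identifier.
#' @slot species species identifier.
#' @slot exons [IRanges::IRanges] of coding-exon intervals in transcription
#'   order (1-based inclusive, non-overlapping).
#' @slot strand `"+"` or `"-"`.
#' @slot cds spliced coding sequence (`DNAString`), concatenated in
#'   transcription order; minus-strand exons are reverse-complemented
#'   before concatenation.
#' @slot rodDomain optional codon interval `c(first, last)` marking the
#'   central intermediate-filament (rod) domain; `integer(0)` when
#'   unannotated.
#' @slot geneticCode NCBI genetic code id (default "1", the standard code).
#' @export
setClass("CodingModel",
         representation(geneId = "character", species = "character",
                        exons = "IRanges", strand = "character",
                        cds = "DNAString", rodDomain = "integer",
                        geneticCode = "character"))

setValidity("CodingModel", function(object) {
  msg <- character(0)
  ex <- object@exons
  if (length(ex)) {
    if (any(IRanges::width(ex) < 1L)) msg <- c(msg, "empty exon interval")
    ov <- IRanges::findOverlaps(ex, ex)
    if (length(ov) > length(ex)) msg <- c(msg, "overlapping exons")
    if (sum(IRanges::width(ex)) != length(object@cds))
      msg <- c(msg, "CDS length must equal the summed exon widths")
  }
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  rd <- object@rodDomain
  if (length(rd) == 2L) {
    ncod <- length(object@cds) %/% 3L
    if (rd[1L] < 1L || rd[2L] < rd[1L] || rd[2L] > max(ncod, 1L))
      msg <- c(msg, "rodDomain must lie within the codon range of the CDS")
  } else if (length(rd) != 0L) {
    msg <- c(msg, "rodDomain must be integer(0) or c(first, last)")
  }
  if (length(msg)) msg else TRUE
})

#' IntegrityReport: lesion list and functional status of one gene
#'
#' Produced by [scanORF()] and refined by [assessFunctionality()]. A gene
#' is `INTACT` iff its lesion list is empty, otherwise `PSEUDOGENE`
#' (candidate); whether the lesions actually abolish function is a separate
#' call stored in `functionalCall`.
#'
#' @slot geneId,species identifiers.
#' @slot status `"INTACT"` or `"PSEUDOGENE"`.
#' @slot lesions data.frame with columns `kind`, `codon`, `detail`.
#' @slot nmdPredicted TRUE when a premature stop lies upstream of the last
#'   exon-exon junction (see [predictNMD()]).
#' @slot truncatesRod TRUE when a premature stop truncates the annotated
#'   rod domain.
#' @slot ambiguousCodons codon indices containing ambiguous bases (N);
#'   never counted as lesions.
#' @slot functionalCall `"functional"`, `"nonfunctional"`, or `""` before
#'   [assessFunctionality()] has been applied.
#' @export
setClass("IntegrityReport",
         representation(geneId = "character", species = "character",
                        status = "character", lesions = "data.frame",
                        nmdPredicted = "logical", truncatesRod = "logical",
                        ambiguousCodons = "integer",
                        functionalCall = "character"))

setValidity("IntegrityReport", function(object) {
  msg <- character(0)
  if (!object@status %in% c("INTACT", "PSEUDOGENE"))
    msg <- c(msg, "status must be INTACT or PSEUDOGENE")
  les <- object@lesions
  if (!all(c("kind", "codon", "detail") %in% colnames(les)))
    msg <- c(msg, "lesions must have columns kind, codon, detail")
  else {
    if (nrow(les) && any(!les$kind %in% .LESION_KINDS))
      msg <- c(msg, "unknown lesion kind")
    if (nrow(les) && any(les$codon < 1L))
      msg <- c(msg, "lesion codon positions must be >= 1")
    if ((nrow(les) == 0L) != (object@status == "INTACT"))
      msg <- c(msg, "status INTACT iff lesions empty")
    if (nrow(les) == 0L && object@nmdPredicted)
      msg <- c(msg, "nmdPredicted must be FALSE without lesions")
  }
  if (length(msg)) msg else TRUE
})

#' PresenceMatrix: species-by-gene functional-gene states
#'
#' Cell values come from the five-state alphabet INTACT, PSEUDOGENE,
#' ABSENT, UNKNOWN, HOMOLOG_UNRESOLVED. For parsimony reconstruction the
#' matrix is binarized: 1 = functional gene present (INTACT), 0 = no
#' functional gene (PSEUDOGENE, ABSENT), `NA` = uninformative (UNKNOWN,
#' HOMOLOG_UNRESOLVED). The binarization is a slot and can be customized.
#'
#' @slot states character matrix, rownames species, colnames genes.
#' @slot binarization named numeric vector over the state alphabet with
#'   values 1, 0 or NA.
#' @export
setClass("PresenceMatrix",
         representation(states = "matrix", binarization = "numeric"))

setValidity("PresenceMatrix", function(object) {
  m <- object@states
  msg <- character(0)
  if (!is.character(m)) msg <- c(msg, "states must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "states must have species rownames and gene colnames")
  if (is.character(m) && any(!m %in% .STATE_ALPHABET))
    msg <- c(msg, "states must come from the five-state alphabet")
  b <- object@binarization
  if (is.null(names(b)) || !all(.STATE_ALPHABET %in% names(b)))
    msg <- c(msg, "binarization must name every state")
  if (length(msg)) msg else TRUE
})

#' EventSet: reconstructed gain and loss events for one gene
#'
#' Edges are identified by their child node: a leaf edge by the leaf label,
#' an internal edge by the internal node label (or `"node<N>"` when the
#' node is unlabeled). `gainEdge == "ROOT"` means the gene was already
#' present at or before the root; `NA` means no gain (no functional gene
#' anywhere).
#'
#' @slot gene gene name.
#' @slot gainEdge edge id, `"ROOT"`, or `NA`.
#' @slot lossEdges edge ids of independent losses; never nested.
#' @slot intervals data.frame (`event`, `edge`, `olderMY`, `youngerMY`)
#'   with event time intervals in million years, when branch lengths exist;
#'   zero rows otherwise.
#' @export
setClass("EventSet",
         representation(gene = "character", gainEdge = "character",
                        lossEdges = "character", intervals = "data.frame"))

setValidity("EventSet", function(object) {
  if (anyDuplicated(object@lossEdges)) return("duplicated loss edges")
  TRUE
})

## ---- show methods ---------------------------------------------------------

setMethod("show", "LocusMap", function(object) {
  cat("LocusMap of", object@species, "with", length(object@features),
      "gene feature(s)")
  if (length(object@features))
    cat(" on", unique(as.character(GenomicRanges::seqnames(object@features))))
  cat("\n")
  if (length(object@features))
    cat("  order:", paste(S4Vectors::mcols(object@features)$symbol,
                          collapse = " - "), "\n")
})

setMethod("show", "GeneWindow", function(object) {
  cat("GeneWindow [", object@status, "] ", length(object@features),
      " gene(s)", sep = "")
  if (length(object@missingAnchors))
    cat("; missing anchor(s):",
        paste(object@missingAnchors, collapse = ", "))
  cat("\n")
})

setMethod("show", "OrthologCall", function(object) {
  cat("OrthologCall ", object@targetSymbol, " in ", object@querySpecies,
      ": ", object@status, " (evidence ", object@evidence, "/2)\n", sep = "")
})

setMethod("show", "CodingModel", function(object) {
  cat("CodingModel", object@geneId, "(", object@species, "):",
      length(object@exons), "exon(s),", length(object@cds), "nt CDS,",
      "strand", object@strand, "\n")
})

setMethod("show", "IntegrityReport", function(object) {
  cat("IntegrityReport", object@geneId, "(", object@species, "):",
      object@status, "-", nrow(object@lesions), "lesion(s); NMD:",
      object@nmdPredicted, "\n")
})

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix:", nrow(object@states), "species x",
      ncol(object@states), "gene(s)\n")
  print(object@states)
})

setMethod("show", "EventSet", function(object) {
  cat("EventSet for", object@gene, "- gain:",
      ifelse(is.na(object@gainEdge), "<none>", object@gainEdge),
      "; losses:",
      if (length(object@lossEdges)) paste(object@lossEdges, collapse = ", ")
      else "<none>", "\n")
})
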