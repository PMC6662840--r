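#' Construct a CodingModel
#'
#' @param geneId,species identifiers.
#' @param exons matrix/data.frame with two columns (start, end) or an
#'   [IRanges::IRanges]; 1-based inclusive coding-exon intervals in
#'   transcription order.
#' @param cds spliced coding sequence (character or `DNAString`).
#' @param strand "+" or "-".
#' @param rodDomain optional `c(firstCodon, lastCodon)` of the
#'   intermediate-filament rod domain.
#' @param geneticCode NCBI genetic code id (default "1").
#' @return a [CodingModel-class].
#' @export
newCodingModel <- function(geneId, species, exons, cds, strand = "+",
                           rodDomain = integer(0), geneticCode = "1") {
  if (!methods::is(exons, "IRanges")) {
    exons <- as.matrix(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[, 1L]),
                              end = as.integer(exons[, 2L]))
  }
  methods::new("CodingModel", geneId = geneId, species = species,
               exons = exons, strand = strand,
               cds = Biostrings::DNAString(toupper(as.character(cds))),
               rodDomain = as.integer(rodDomain),
               geneticCode = geneticCode)
}

#' Splice a CDS out of a genomic sequence
#'
#' Concatenates the exon intervals in transcription order; minus-strand
#' exons are each reverse-complemented and the pieces joined 5' to 3'.
#'
#' @param exons two-column matrix / `IRanges` of 1-based inclusive exon
#'   intervals, in transcription order.
#' @param genome genomic sequence (character or `DNAString`).
#' @param strand "+" or "-".
#' @return spliced CDS as a character string.
#' @export
spliceCDS <- function(exons, genome, strand = "+") {
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  if (!methods::is(exons, "IRanges")) {
    exons <- as.matrix(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[, 1L]),
                              end = as.integer(exons[, 2L]))
  }
  g <- Biostrings::DNAString(toupper(as.character(genome)))
  if (length(exons) &&
      (min(IRanges::start(exons)) < 1L || max(IRanges::end(exons)) > length(g)))
    stop("exon interval out of range of the genomic sequence")
  parts <- lapply(seq_along(exons), function(i) {
    piece <- Biostrings::subseq(g, IRanges::start(exons)[i],
                                IRanges::end(exons)[i])
    if (strand == "-") piece <- Biostrings::reverseComplement(piece)
    as.character(piece)
  })
  paste(unlist(parts), collapse = "")
}

.codonSplit <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

.codonAA <- function(codons, geneticCode = "1") {
  gc <- Biostrings::getGeneticCode(geneticCode)
  aa <- unname(gc[codons])
  aa  # NA for codons containing N or other ambiguity
}

.emptyLesions <- function() {
  data.frame(kind = character(0), codon = integer(0), detail = character(0),
             stringsAsFactors = FALSE)
}

.lesionRow <- function(kind, codon, detail) {
  data.frame(kind = kind, codon = as.integer(codon), detail = detail,
             stringsAsFactors = FALSE)
}

#' Scan an ORF for inactivating lesions
#'
#' Translates the spliced CDS in frame 0 with the model's genetic code.
#' Every stop codon before the last codon is a `PREMATURE_STOP` lesion;
#' a non-ATG first codon is `START_LOSS`; a missing terminal stop is
#' `TERMINAL_STOP_LOSS`. Codons containing ambiguous bases (N) are
#' recorded as ambiguous and never become lesions: assembly gaps must not
#' create pseudogene calls. The NMD prediction (see [predictNMD()]) is
#' filled in from the model's exon structure.
#'
#' @param model a [CodingModel-class] with CDS length a multiple of 3 and
#'   at least one codon; a length not divisible by 3 is a hard error
#'   directing the caller to [compareToReference()] (a frameshift is
#'   involved and needs an alignment).
#' @param nmdMargin nucleotide margin for the NMD rule, passed to
#'   [predictNMD()].
#' @return an [IntegrityReport-class].
#' @export
scanORF <- function(model, nmdMargin = 0) {
  cds <- as.character(model@cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length is not a multiple of 3; a frameshift is likely - ",
         "use compareToReference() with an intact reference CDS")
  codons <- .codonSplit(cds)
  aa <- .codonAA(codons, model@geneticCode)
  amb <- which(is.na(aa))
  last <- length(codons)
  les <- .emptyLesions()
  premature <- setdiff(which(aa == "*"), last)
  premature <- premature[!is.na(premature)]
  for (k in premature)
    les <- rbind(les, .lesionRow("PREMATURE_STOP", k,
                                 paste0("stop codon ", codons[k])))
  if (!(1L %in% amb) && codons[1L] != "ATG")
    les <- rbind(les, .lesionRow("START_LOSS", 1L,
                                 paste0("first codon ", codons[1L])))
  if (!(last %in% amb) && !identical(aa[last], "*"))
    les <- rbind(les, .lesionRow("TERMINAL_STOP_LOSS", last,
                                 paste0("last codon ", codons[last])))
  rep <- methods::new("IntegrityReport", geneId = model@geneId,
                      species = model@species,
                      status = if (nrow(les)) "PSEUDOGENE" else "INTACT",
                      lesions = les, nmdPredicted = FALSE,
                      truncatesRod = FALSE,
                      ambiguousCodons = as.integer(amb),
                      functionalCall = "")
  rep@nmdPredicted <- predictNMD(rep, model, margin = nmdMargin)
  methods::validObject(rep)
  rep
}

#' Detect frameshift indels against an intact reference CDS
#'
#' Computes a global pairwise alignment (match +1, mismatch -1, gap open
#' -4, gap extend -1; Biostrings' deterministic traceback) of the query
#' against an intact reference coding sequence. Every gap run whose length
#' is not a multiple of 3 is a `FRAMESHIFT_INDEL`, positioned at the codon
#' containing its first aligned reference base. The query is then
#' re-scanned in its own frame 0 (the frame implied by the cumulative
#' indels from the start codon) and downstream stop codons are reported as
#' `PREMATURE_STOP`. Lesion positions may shift by about one codon under
#' other alignment parameterizations.
#'
#' @param query,reference nucleotide strings (character or `DNAString`);
#'   the reference must be an intact ORF.
#' @param geneticCode NCBI genetic code id.
#' @return data.frame of lesions (`kind`, `codon`, `detail`); zero rows
#'   when the query carries no frameshift and no premature stop.
#' @export
compareToReference <- function(query, reference, geneticCode = "1") {
  query <- toupper(as.character(query))
  reference <- toupper(as.character(reference))
  if (!nzchar(query) || !nzchar(reference))
    stop("empty sequence")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = sub,
    gapOpening = 4, gapExtension = 1)
  q <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  state <- ifelse(q == "-", "D", ifelse(s == "-", "I", "M"))
  runs <- rle(state)
  pos <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  refBefore <- cumsum(s != "-")  # reference coordinate at each column
  les <- .emptyLesions()
  firstShiftCodon <- NA_integer_
  for (i in seq_along(runs$values)) {
    if (runs$values[i] == "M") next
    L <- runs$lengths[i]
    if (L %% 3L == 0L) next
    col <- pos[i]
    refpos <- if (s[col] != "-") refBefore[col]
              else refBefore[col] + 1L  # insertion: next reference base
    codon <- (refpos - 1L) %/% 3L + 1L
    kind <- if (runs$values[i] == "D") "deletion" else "insertion"
    les <- rbind(les, .lesionRow("FRAMESHIFT_INDEL", codon,
                                 sprintf("%d-nt %s", L, kind)))
    if (is.na(firstShiftCodon)) firstShiftCodon <- codon
  }
  ## re-scan the query in its own frame 0 for (now shifted) stops
  codons <- .codonSplit(query)
  if (length(codons) >= 1L) {
    aa <- .codonAA(codons, geneticCode)
    premature <- which(aa == "*")
    premature <- premature[!is.na(premature) & premature < length(codons)]
    ## stops upstream of any frameshift are genuine in-frame stops too
    for (k in premature)
      les <- rbind(les, .lesionRow("PREMATURE_STOP", k,
                                   paste0("stop codon ", codons[k])))
  }
  les[order(les$codon, les$kind), , drop = FALSE]
}

#' Predict nonsense-mediated decay from stop position and exon structure
#'
#' A transcript is predicted to undergo NMD when a premature stop codon
#' lies at least `margin` nucleotides 5' of the last exon-exon junction of
#' the spliced CDS. The default `margin = 0` is the literal
#' "before the last exon" rule; `margin = 50` gives the canonical 50-nt
#' rule. Single-exon models never predict NMD.
#'
#' @param report an [IntegrityReport-class].
#' @param model the matching [CodingModel-class] (>= 1 exon).
#' @param margin nucleotides upstream of the last junction required.
#' @return logical.
#' @export
predictNMD <- function(report, model, margin = 0) {
  ex <- model@exons
  if (length(ex) < 1L) stop("model must have at least one exon")
  if (length(ex) == 1L) return(FALSE)
  les <- lesions(report)
  stops <- les$codon[les$kind == "PREMATURE_STOP"]
  if (!length(stops)) return(FALSE)
  total <- sum(IRanges::width(ex))
  lastJunction <- total - IRanges::width(ex)[length(ex)]
  any(lastJunction - 3L * stops >= margin)
}

#' Classify a lesioned gene as functional or nonfunctional
#'
#' Nonfunctional iff NMD is predicted, or any frameshift indel is present,
#' or a premature stop truncates the annotated rod domain (the central
#' intermediate-filament domain required for cytoskeletal function). With
#' no rod-domain annotation, any premature stop is considered
#' inactivating. Near-C-terminal truncations downstream of the rod domain,
#' without NMD, are tolerated.
#'
#' @param report an [IntegrityReport-class].
#' @param model the matching [CodingModel-class].
#' @return the report, with `functionalCall` and `truncatesRod` set.
#' @export
assessFunctionality <- function(report, model) {
  les <- lesions(report)
  stops <- les$codon[les$kind == "PREMATURE_STOP"]
  frameshift <- any(les$kind == "FRAMESHIFT_INDEL")
  rd <- model@rodDomain
  trunc <- if (length(rd) == 2L) any(stops <= rd[2L]) else FALSE
  stopKills <- if (length(rd) == 2L) trunc else length(stops) > 0L
  nonfunctional <- isTRUE(report@nmdPredicted) || frameshift || stopKills
  report@truncatesRod <- trunc
  report@functionalCall <- if (nonfunctional) "nonfunctional" else "functional"
  report
}

#' Group species whose premature stops fall in the same aligned column
#'
#' Maps each species' premature-stop codons onto columns of a supplied
#' multiple alignment of the coding sequences and groups species whose
#' stops share an aligned codon column. A shared column is interpreted
#' downstream as a single ancestral inactivation (the loss is collapsed
#' onto the stem of the species' clade by
#' [countIndependentLosses()]). Species without premature stops become
#' singleton groups.
#'
#' @param reports named list of [IntegrityReport-class] objects, keyed by
#'   species.
#' @param alignment named character vector (or `DNAStringSet`) of gapped,
#'   aligned CDS sequences covering every species in `reports`.
#' @return list of character vectors of species names; deterministic
#'   order (by first appearance in `reports`).
#' @export
sharedLesions <- function(reports, alignment) {
  if (length(reports) < 1L) stop("at least one report required")
  alignment <- vapply(as.list(alignment), as.character, character(1))
  spp <- names(reports)
  if (is.null(spp) || any(!nzchar(spp)))
    stop("reports must be a named list keyed by species")
  missing <- setdiff(spp, names(alignment))
  if (length(missing))
    stop("species missing from alignment: ", paste(missing, collapse = ", "))
  cols <- lapply(spp, function(sp) {
    les <- lesions(reports[[sp]])
    stops <- les$codon[les$kind == "PREMATURE_STOP"]
    if (!length(stops)) return(integer(0))
    gapped <- strsplit(alignment[[sp]], "")[[1L]]
    ungappedPos <- which(gapped != "-")
    vapply(stops, function(k) {
      nt <- 3L * k - 2L  # first base of the stop codon
      if (nt > length(ungappedPos))
        stop("stop codon beyond aligned sequence for ", sp)
      ungappedPos[nt]
    }, integer(1))
  })
  names(cols) <- spp
  ## union-find over shared columns
  parent <- seq_along(spp)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(spp)) for (j in seq_len(i - 1L)) {
    if (length(intersect(cols[[i]], cols[[j]]))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_along(spp), find, integer(1))
  unname(lapply(unique(roots), function(r) spp[roots == r]))
}
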