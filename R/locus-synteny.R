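#' Construct a LocusMap from feature vectors
#'
#' Internal constructor shared by the file readers and the simulator.
#' Coordinates are 1-based inclusive. Features are sorted by start; a
#' duplicated `gene_id` is a hard error.
#'
#' @param species species identifier.
#' @param region scaffold/chromosome name.
#' @param symbol gene symbols.
#' @param start,end 1-based inclusive coordinates.
#' @param strand "+" or "-" per feature.
#' @param gene_id unique feature ids; defaults to `make.unique(symbol)`.
#' @return a [LocusMap-class].
#' @export
newLocusMap <- function(species, region, symbol, start, end, strand,
                        gene_id = NULL) {
  strand <- gsub("−", "-", as.character(strand))
  if (is.null(gene_id)) gene_id <- make.unique(as.character(symbol))
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ", gene_id[duplicated(gene_id)][1L])
  if (length(start) && any(start < 1L)) stop("start coordinates must be >= 1")
  if (length(start) && any(end < start)) stop("start must be <= end")
  o <- order(start)
  gr <- GenomicRanges::GRanges(
    seqnames = if (length(start)) rep(region[1L], length(start))
               else character(0),
    ranges = IRanges::IRanges(start = as.integer(start[o]),
                              end = as.integer(end[o])),
    strand = strand[o])
  S4Vectors::mcols(gr)$gene_id <- as.character(gene_id[o])
  S4Vectors::mcols(gr)$symbol <- as.character(symbol[o])
  methods::new("LocusMap", species = species, features = gr)
}

#' Read a per-species gene-coordinate map
#'
#' Parses gene features from GFF3 (type `gene` records only; symbol taken
#' from the `gene_name` or `Name` attribute, id from `ID`), BED6 (0-based
#' half-open starts shifted to the 1-based inclusive internal convention)
#' or a simple TSV dialect with header
#' `species  region  symbol  start  end  strand`. Features are sorted by
#' start on read; an empty file yields an empty map.
#'
#' @param path input file.
#' @param format one of `"gff3"`, `"bed"`, `"tsv"`.
#' @param species species identifier for gff3/bed input (those formats do
#'   not carry one); defaults to the file base name.
#' @return a [LocusMap-class].
#' @export
readLocusMap <- function(path, format = c("gff3", "bed", "tsv"),
                         species = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (is.null(species))
    species <- sub("\\.[^.]*$", "", basename(path))

  if (format == "tsv") {
    if (!length(body))
      return(newLocusMap(species, "region", character(0), integer(0),
                         integer(0), character(0)))
    df <- utils::read.delim(text = body, header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("species", "region", "symbol", "start", "end", "strand")
    if (!all(need %in% colnames(df)))
      stop("TSV locus map must have columns: ", paste(need, collapse = ", "))
    if (nrow(df) == 0L)
      return(newLocusMap(species, "region", character(0), integer(0),
                         integer(0), character(0)))
    sp <- unique(df$species)
    if (length(sp) > 1L)
      stop("TSV contains several species; use one file (or fixture loader) per species")
    return(newLocusMap(sp, df$region[1L], df$symbol, df$start, df$end,
                       df$strand))
  }

  if (!length(body))
    return(newLocusMap(species, "region", character(0), integer(0),
                       integer(0), character(0)))

  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")  # converts to 1-based
    sym <- if (!is.null(gr$name)) gr$name else stop("BED input needs a name column")
    return(newLocusMap(species,
                       as.character(GenomicRanges::seqnames(gr))[1L],
                       sym, GenomicRanges::start(gr),
                       GenomicRanges::end(gr),
                       as.character(GenomicRanges::strand(gr))))
  }

  ## gff3
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (!length(gr))
    return(newLocusMap(species, "region", character(0), integer(0),
                       integer(0), character(0)))
  mc <- S4Vectors::mcols(gr)
  sym <- if ("gene_name" %in% colnames(mc) && !all(is.na(mc$gene_name)))
    mc$gene_name else mc$Name
  if (is.null(sym) || any(is.na(sym) | !nzchar(sym)))
    stop("GFF3 gene records must carry a gene_name or Name attribute")
  ids <- if ("ID" %in% colnames(mc) && !any(is.na(mc$ID))) mc$ID
         else make.unique(as.character(sym))
  newLocusMap(species, as.character(GenomicRanges::seqnames(gr))[1L],
              as.character(sym), GenomicRanges::start(gr),
              GenomicRanges::end(gr),
              as.character(GenomicRanges::strand(gr)),
              gene_id = as.character(ids))
}

.symbolIndex <- function(map, symbol, what = "symbol") {
  sym <- geneSymbols(map)
  hit <- which(tolower(sym) == tolower(symbol))
  if (length(hit) > 1L)
    stop("duplicated ", what, " in map: ", symbol)
  if (!length(hit)) {
    ## fall back to the unique gene_id (duplicated symbols get .1/.2
    ## suffixed ids on read)
    ids <- S4Vectors::mcols(locusFeatures(map))$gene_id
    hit <- which(tolower(ids) == tolower(symbol))
  }
  hit  # integer(0) when absent
}

#' Extract the gene window between two conserved anchors
#'
#' Returns the features strictly between `leftAnchor` and `rightAnchor`,
#' read in the `leftAnchor` to `rightAnchor` direction: if the right
#' anchor precedes the left anchor genomically (the locus is inverted in
#' this assembly), the feature list is reversed and every strand flipped,
#' so that homologous windows from either orientation compare equal.
#' A missing anchor yields a `WINDOW_INCOMPLETE` [GeneWindow-class], not an
#' error; a duplicated anchor symbol is a hard error.
#'
#' @param map a [LocusMap-class].
#' @param leftAnchor,rightAnchor anchor gene symbols (case-insensitive).
#' @return a [GeneWindow-class].
#' @export
extractWindow <- function(map, leftAnchor, rightAnchor) {
  il <- .symbolIndex(map, leftAnchor, "anchor")
  ir <- .symbolIndex(map, rightAnchor, "anchor")
  missing <- c(leftAnchor[!length(il)], rightAnchor[!length(ir)])
  if (length(missing))
    return(methods::new("GeneWindow", status = "WINDOW_INCOMPLETE",
                        features = GenomicRanges::GRanges(),
                        missingAnchors = missing))
  gr <- locusFeatures(map)
  lo <- min(il, ir); hi <- max(il, ir)
  idx <- if (hi - lo >= 2L) seq.int(lo + 1L, hi - 1L) else integer(0)
  win <- gr[idx]
  if (ir < il && length(win)) {
    win <- rev(win)
    GenomicRanges::strand(win) <-
      ifelse(as.character(GenomicRanges::strand(win)) == "+", "-", "+")
  }
  methods::new("GeneWindow", status = "OK", features = win,
               missingAnchors = character(0))
}

#' Immediate neighbors of a gene in a locus map
#'
#' Returns the symbols of the two flanking genes. With
#' `sidedness = "transcript"` (default) sides are read relative to the
#' focal gene's transcription direction, so `left` is the 5'-side
#' neighbor: for a minus-strand focal gene the genomic neighbors swap.
#' `sidedness = "genomic"` gives plain coordinate left/right.
#'
#' @param map a [LocusMap-class].
#' @param symbol focal gene symbol (must occur exactly once).
#' @param sidedness `"transcript"` or `"genomic"`.
#' @return named character vector `c(left = ..., right = ...)`; `NA` where
#'   the map ends.
#' @export
locusNeighbors <- function(map, symbol,
                           sidedness = c("transcript", "genomic")) {
  sidedness <- match.arg(sidedness)
  i <- .symbolIndex(map, symbol)
  if (!length(i)) stop("symbol not found in map: ", symbol)
  sym <- geneSymbols(map)
  left <- if (i > 1L) sym[i - 1L] else NA_character_
  right <- if (i < length(sym)) sym[i + 1L] else NA_character_
  if (sidedness == "transcript") {
    st <- as.character(GenomicRanges::strand(locusFeatures(map)))[i]
    if (st == "-") { tmp <- left; left <- right; right <- tmp }
  }
  c(left = left, right = right)
}

#' Call a positional ortholog by shared synteny
#'
#' Locates the nearest `anchorSet` members flanking `targetSymbol` in the
#' reference map, then inspects the corresponding anchor-bounded window of
#' the query map. A single exact-symbol candidate gives `ORTHOLOG`
#' (evidence 2); a homolog-pattern match (default `"<symbol>-like"`) or
#' multiple candidates give `HOMOLOG_UNRESOLVED` (never an arbitrary
#' pick); an intact but empty window gives `ABSENT_FROM_WINDOW`; a missing
#' anchor (query or reference side) gives `WINDOW_INCOMPLETE`, which
#' downstream maps to presence state `UNKNOWN` so that fragmented
#' assemblies never fabricate losses.
#'
#' @param query,reference [LocusMap-class] objects.
#' @param targetSymbol gene searched for (must be present in the
#'   reference).
#' @param anchorSet symbols of conserved genes usable as anchors; each may
#'   occur at most once per map.
#' @param homologPattern regular expression for unresolved homolog names;
#'   `NULL` uses `"^<symbol>-like"` (case-insensitive).
#' @return an [OrthologCall-class].
#' @export
callOrthologBySynteny <- function(query, reference, targetSymbol, anchorSet,
                                  homologPattern = NULL) {
  if (is.null(homologPattern))
    homologPattern <- paste0("^", gsub("([^[:alnum:]_])", "\\\\\\1",
                                       targetSymbol), "-like")
  ti <- .symbolIndex(reference, targetSymbol)
  if (!length(ti)) stop("target absent from reference map: ", targetSymbol)
  refSym <- geneSymbols(reference)
  anchorIdx <- which(tolower(refSym) %in% tolower(anchorSet))
  leftIdx <- anchorIdx[anchorIdx < ti]
  rightIdx <- anchorIdx[anchorIdx > ti]
  leftA <- if (length(leftIdx)) refSym[max(leftIdx)] else ""
  rightA <- if (length(rightIdx)) refSym[min(rightIdx)] else ""

  mkCall <- function(status, evidence, candidates = character(0)) {
    methods::new("OrthologCall", targetSymbol = targetSymbol,
                 querySpecies = speciesName(query), status = status,
                 leftAnchor = leftA, rightAnchor = rightA,
                 evidence = as.integer(evidence), candidates = candidates)
  }

  if (!nzchar(leftA) || !nzchar(rightA)) {
    ## the reference window itself runs off the map end
    present <- sum(nzchar(c(leftA, rightA)) &
                     vapply(c(leftA, rightA), function(a)
                       nzchar(a) && length(.symbolIndex(query, a)) == 1L,
                       logical(1)))
    return(mkCall("WINDOW_INCOMPLETE", present))
  }
  win <- extractWindow(query, leftA, rightA)
  if (windowStatus(win) == "WINDOW_INCOMPLETE")
    return(mkCall("WINDOW_INCOMPLETE", 2L - length(win@missingAnchors)))
  sym <- geneSymbols(win)
  exact <- sym[tolower(sym) == tolower(targetSymbol)]
  alike <- sym[grepl(homologPattern, sym, ignore.case = TRUE)]
  cand <- c(exact, alike)
  if (!length(cand)) return(mkCall("ABSENT_FROM_WINDOW", 2L))
  if (length(exact) == 1L && !length(alike))
    return(mkCall("ORTHOLOG", 2L, exact))
  mkCall("HOMOLOG_UNRESOLVED", 2L, cand)
}

#' Map an ortholog call (and optional integrity report) to a presence state
#'
#' `WINDOW_INCOMPLETE` maps to `UNKNOWN` (fragmented assemblies must not
#' fabricate losses); `ABSENT_FROM_WINDOW` to `ABSENT`;
#' `HOMOLOG_UNRESOLVED` stays as is; an `ORTHOLOG` is `INTACT` unless its
#' [IntegrityReport-class] says the coding sequence is a pseudogene.
#'
#' @param call an [OrthologCall-class].
#' @param report optional [IntegrityReport-class] for the called ortholog.
#' @return one presence-state string.
#' @export
presenceState <- function(call, report = NULL) {
  switch(callStatus(call),
         WINDOW_INCOMPLETE = "UNKNOWN",
         ABSENT_FROM_WINDOW = "ABSENT",
         HOMOLOG_UNRESOLVED = "HOMOLOG_UNRESOLVED",
         ORTHOLOG = if (!is.null(report) &&
                        integrityStatus(report) == "PSEUDOGENE")
           "PSEUDOGENE" else "INTACT")
}
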