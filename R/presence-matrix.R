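.DEFAULT_BINARIZATION <- c(INTACT = 1, PSEUDOGENE = 0, ABSENT = 0,
                           UNKNOWN = NA, HOMOLOG_UNRESOLVED = NA)

#' Construct a PresenceMatrix
#'
#' @param states character matrix (rownames species, colnames genes) over
#'   the five-state alphabet INTACT, PSEUDOGENE, ABSENT, UNKNOWN,
#'   HOMOLOG_UNRESOLVED.
#' @param binarization named numeric mapping states to 1 (functional gene
#'   present), 0 (no functional gene) or `NA` (uninformative). The default
#'   maps PSEUDOGENE to 0: the matrix records presence/absence of
#'   *functional* genes.
#' @return a [PresenceMatrix-class].
#' @export
PresenceMatrix <- function(states, binarization = .DEFAULT_BINARIZATION) {
  methods::new("PresenceMatrix", states = states,
               binarization = binarization)
}

#' Read a presence/state matrix from TSV
#'
#' Rows are species, columns genes, cells from the five-state alphabet.
#' The first column must be named `species`. `#` comment lines are
#' skipped.
#'
#' @param path TSV file.
#' @param binarization see [PresenceMatrix()].
#' @return a [PresenceMatrix-class].
#' @export
readPresenceMatrix <- function(path,
                               binarization = .DEFAULT_BINARIZATION) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "species")
    stop("first column of a state matrix must be 'species'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$species
  mode(m) <- "character"
  PresenceMatrix(m, binarization)
}

#' Binarize one gene column of a presence matrix
#'
#' @param pm a [PresenceMatrix-class].
#' @param gene gene (column) name.
#' @return named numeric vector over species with values 1, 0 or `NA`.
#' @export
binarizeStates <- function(pm, gene) {
  m <- presenceStates(pm)
  if (!gene %in% colnames(m)) stop("gene not in matrix: ", gene)
  stats::setNames(unname(pm@binarization[m[, gene]]), rownames(m))
}
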