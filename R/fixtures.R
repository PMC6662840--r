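## multi-species locus-map TSV -> named list of LocusMap
.readLocusMapSet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  lapply(split(df, df$species)[unique(df$species)], function(d)
    newLocusMap(d$species[1L], d$region[1L], d$symbol, d$start, d$end,
                d$strand))
}

#' Load a packaged fixture
#'
#' Packaged, validated data objects describing the keratin KRT24 locus and
#' its presence/absence across species. A fixture cell exists only for
#' species whose state is explicitly documented; unstudied species are
#' omitted rather than guessed, and the fixture trees' branch lengths are
#' approximate divergence times for dating illustration only (see file
#' headers under `inst/extdata`).
#'
#' Available fixtures:
#' \describe{
#'   \item{mammal_tree}{rooted timed tree (MY) of the species scored for
#'     functional Krt24: camels and alpaca, cattle, hippopotamus,
#'     cetaceans, pinnipeds (Otaroidea and Phocidae), human, mouse and
#'     blind mole rat. Internal nodes labeled with clade names.}
#'   \item{krt24_states}{[PresenceMatrix-class] of functional-Krt24 states
#'     on the mammal tree: inactivated in the genus Camelus (alpaca
#'     intact), in cetaceans (hippopotamus intact) and in Otaroidea
#'     (walrus, fur seal, sea lion; Phocidae intact).}
#'   \item{fig4_states}{list with `tree` (timed tetrapod-mammal tree) and
#'     `states` (KRT223/KRT224 presence): Krt223 intact in galago, sifaka
#'     and tree shrew but a pseudogene in human; Krt224 intact in platypus
#'     and Tasmanian devil, absent from the investigated placentals, with
#'     a pseudogene remnant in human.}
#'   \item{human_keratin_locus}{[LocusMap-class] of the human type I
#'     keratin cluster window bordered by KRT222 and KRT12, with KRT24
#'     flanked by KRT222 and KRT25.}
#'   \item{tetrapod_locus_maps}{named list of [LocusMap-class] for human,
#'     alligator (a Krt24-like gene between Krt222 and Krt10), chicken
#'     (no Krt24 homolog), platypus (three Krt24-like genes, Krt224 on
#'     the 3' side), galago (Krt223 5' of Krt24) and Tasmanian devil
#'     (Krt224 3' of Krt24).}
#'   \item{pairing_rules}{default type I:type II keratin pairing rules:
#'     K14-K5, K12-K3, K10-K1 (fallback K2), K24-K3 (fallbacks K4, K5,
#'     promiscuous).}
#' }
#'
#' @param name fixture name (see above); anything else is a hard error.
#' @return the parsed, validated fixture object.
#' @export
loadFixture <- function(name) {
  fx <- function(f) system.file("extdata", f, package = "dollotrace",
                                mustWork = TRUE)
  switch(name,
         mammal_tree = readSpeciesTree(fx("mammal_tree.nwk")),
         krt24_states = readPresenceMatrix(fx("krt24_states.tsv")),
         fig4_states = list(
           tree = readSpeciesTree(fx("fig4_tree.nwk")),
           states = readPresenceMatrix(fx("fig4_states.tsv"))),
         human_keratin_locus = readLocusMap(fx("human_keratin_locus.tsv"),
                                            format = "tsv"),
         tetrapod_locus_maps = .readLocusMapSet(fx("tetrapod_locus_maps.tsv")),
         pairing_rules = readPairingRules(fx("pairing_rules.tsv")),
         stop("unknown fixture: ", name))
}
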