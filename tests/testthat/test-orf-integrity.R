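# convenience: single-exon model from a CDS string
cdsModel <- function(cds, nExons = 1, gene = "g", species = "sp",
                     rod = integer(0)) {
  n <- nchar(cds)
  if (nExons == 1) {
    ex <- cbind(1, n)
  } else {
    # split into nExons contiguous pieces (multiples of 3 not required)
    cuts <- floor(seq(0, n, length.out = nExons + 1))
    ex <- cbind(head(cuts, -1) + 1, cuts[-1])
  }
  newCodingModel(gene, species, ex, cds, "+", rodDomain = rod)
}

test_that("spliceCDS concatenates exons in transcription order", {
  expect_equal(spliceCDS(cbind(1, 6), "ATGTAA", "+"), "ATGTAA")
  expect_equal(spliceCDS(cbind(1, 6), "TTACAT", "-"), "ATGTAA")
  # exon split vs single exon on the same bases
  g <- "ATGAAACCCGGGTTTTAA"
  expect_equal(spliceCDS(rbind(c(1, 9), c(10, 18)), g, "+"),
               spliceCDS(cbind(1, 18), g, "+"))
  expect_error(spliceCDS(cbind(1, 100), "ATG", "+"), "out of range")
})

test_that("scanORF classifies intact and lesioned coding sequences", {
  intact <- randomIntactCDS(300, seed = 11)
  rep0 <- scanORF(cdsModel(intact))
  expect_equal(integrityStatus(rep0), "INTACT")
  expect_equal(nrow(lesions(rep0)), 0)
  expect_false(nmdPredicted(rep0))

  # premature stop planted at codon 150
  mut <- paste0(substr(intact, 1, 447), "TGA", substr(intact, 451, 900))
  rep1 <- scanORF(cdsModel(mut))
  expect_equal(integrityStatus(rep1), "PSEUDOGENE")
  les <- lesions(rep1)
  expect_equal(les$kind, "PREMATURE_STOP")
  expect_equal(les$codon, 150L)

  # a stop at the last codon is terminal, not premature
  expect_equal(integrityStatus(scanORF(cdsModel("ATGTAA"))), "INTACT")

  # all premature stop occurrences are reported
  mut2 <- paste0(substr(mut, 1, 597), "TAA", substr(mut, 601, 900))
  expect_equal(lesions(scanORF(cdsModel(mut2)))$codon, c(150L, 200L))

  # start and terminal-stop loss
  noStart <- paste0("GTG", substr(intact, 4, 900))
  expect_true("START_LOSS" %in% lesions(scanORF(cdsModel(noStart)))$kind)
  noEnd <- paste0(substr(intact, 1, 897), "AAA")
  expect_true("TERMINAL_STOP_LOSS" %in%
                lesions(scanORF(cdsModel(noEnd)))$kind)
})

test_that("ambiguous codons are counted but never become lesions", {
  intact <- randomIntactCDS(100, seed = 3)
  withN <- paste0(substr(intact, 1, 149), "N", substr(intact, 151, 300))
  rep <- scanORF(cdsModel(withN))
  expect_equal(integrityStatus(rep), "INTACT")
  expect_equal(rep@ambiguousCodons, 50L)
})

test_that("a CDS length not divisible by 3 points to compareToReference", {
  m <- suppressWarnings(
    newCodingModel("g", "sp", cbind(1, 7), "ATGAAAT", "+"))
  expect_error(scanORF(m), "compareToReference")
})

test_that("scanORF never flags translate-verified intact ORFs (fuzz)", {
  for (s in 1:25) {
    cds <- randomIntactCDS(sample(50:200, 1), seed = 1000 + s)
    expect_equal(integrityStatus(scanORF(cdsModel(cds))), "INTACT")
  }
})

test_that("compareToReference finds frameshifts at the planted codon", {
  ref <- randomIntactCDS(300, seed = 7)
  expect_equal(nrow(compareToReference(ref, ref)), 0)

  # 1-nt deletion at base 100 -> frameshift at codon 34
  del1 <- paste0(substr(ref, 1, 99), substr(ref, 101, 900))
  les <- compareToReference(del1, ref)
  fs <- les[les$kind == "FRAMESHIFT_INDEL", ]
  expect_equal(nrow(fs), 1)
  expect_equal(fs$codon, 34L)
  # the first downstream frame-0 stop of the mutated sequence is reported
  codons <- substring(del1, seq(1, nchar(del1) - 2, 3),
                      seq(3, nchar(del1), 3))
  firstStop <- which(codons %in% c("TAA", "TAG", "TGA"))[1]
  ps <- les[les$kind == "PREMATURE_STOP", ]
  expect_true(firstStop %in% ps$codon)

  # in-frame 3-nt deletion -> no frameshift
  del3 <- paste0(substr(ref, 1, 99), substr(ref, 103, 900))
  expect_false("FRAMESHIFT_INDEL" %in% compareToReference(del3, ref)$kind)

  expect_error(compareToReference("", ref), "empty")
})

test_that("codon-multiple gap runs never yield frameshift lesions (fuzz)", {
  ref <- randomIntactCDS(200, seed = 21)
  set.seed(42)
  for (i in 1:10) {
    at <- sample(10:500, 1)
    k <- 3 * sample(1:3, 1)
    del <- paste0(substr(ref, 1, at - 1), substr(ref, at + k, nchar(ref)))
    expect_false("FRAMESHIFT_INDEL" %in% compareToReference(del, ref)$kind)
  }
})

test_that("NMD follows the last exon-exon junction rule with margin", {
  intact <- randomIntactCDS(300, seed = 5)
  stopped <- paste0(substr(intact, 1, 297), "TGA", substr(intact, 301, 900))
  # codon 100 stop; 8 exons -> stop far upstream of the last junction
  m8 <- cdsModel(stopped, nExons = 8)
  r8 <- scanORF(m8)
  expect_true(nmdPredicted(r8))

  # stop inside the last exon -> no NMD
  lastExonStop <- paste0(substr(intact, 1, 867), "TGA",
                         substr(intact, 871, 900))
  m2 <- newCodingModel("g", "sp", rbind(c(1, 450), c(451, 900)),
                       lastExonStop, "+")
  expect_false(nmdPredicted(scanORF(m2)))

  # single-exon genes can never trigger NMD
  expect_false(nmdPredicted(scanORF(cdsModel(stopped, nExons = 1))))

  # margin threshold: stop exactly margin nt upstream -> TRUE, one closer
  # -> FALSE. Junction at 600; stop codon ending at 550 is 50 nt upstream.
  mkStopAt <- function(endNt) {
    s <- intact
    paste0(substr(s, 1, endNt - 3), "TGA", substr(s, endNt + 1, 900))
  }
  mJ <- function(cds) newCodingModel("g", "sp",
                                     rbind(c(1, 600), c(601, 900)), cds, "+")
  # codon k ends at nt 3k; 550 is not a codon boundary, so bracket the
  # 50-nt margin with 3k = 549 (51 nt upstream) and 3k = 552 (48 nt)
  r549 <- scanORF(mJ(mkStopAt(549)))
  r552 <- scanORF(mJ(mkStopAt(552)))
  expect_true(predictNMD(r549, mJ(mkStopAt(549)), margin = 50))
  expect_false(predictNMD(r552, mJ(mkStopAt(552)), margin = 50))
  # and with a junction placed to make the distance exactly 50:
  mJ2 <- function(cds) newCodingModel("g", "sp",
                                      rbind(c(1, 599), c(600, 900)), cds, "+")
  r <- scanORF(mJ2(mkStopAt(549)))
  expect_true(predictNMD(r, mJ2(mkStopAt(549)), margin = 50))
})

test_that("NMD is monotone in stop position", {
  intact <- randomIntactCDS(200, seed = 9)
  model <- function(cds) cdsModel(cds, nExons = 4)
  plant <- function(k) paste0(substr(intact, 1, 3 * k - 3), "TGA",
                              substr(intact, 3 * k + 1, 600))
  hits <- vapply(5:195, function(k) {
    cds <- plant(k)
    predictNMD(scanORF(model(cds)), model(cds))
  }, logical(1))
  # once FALSE (stop too close to the 3' end), never TRUE again
  expect_false(is.unsorted(rev(hits)))
})

test_that("functionality follows NMD, frameshift and rod-domain truncation", {
  intact <- randomIntactCDS(300, seed = 13)
  plant <- function(k) paste0(substr(intact, 1, 3 * k - 3), "TGA",
                              substr(intact, 3 * k + 1, 900))

  # stop inside the rod domain -> nonfunctional, truncatesRod
  m <- cdsModel(plant(100), nExons = 1, rod = c(80, 250))
  r <- assessFunctionality(scanORF(m), m)
  expect_equal(functionalCall(r), "nonfunctional")
  expect_true(truncatesRod(r))

  # intact -> functional
  m0 <- cdsModel(intact, rod = c(80, 250))
  expect_equal(functionalCall(assessFunctionality(scanORF(m0), m0)),
               "functional")

  # near-C-terminal stop, downstream of rod, single exon (no NMD)
  m2 <- cdsModel(plant(297), nExons = 1, rod = c(80, 250))
  r2 <- assessFunctionality(scanORF(m2), m2)
  expect_equal(functionalCall(r2), "functional")
  expect_false(truncatesRod(r2))

  # same stop but NMD-triggering exon structure -> nonfunctional
  m3 <- cdsModel(plant(100), nExons = 6)
  r3 <- scanORF(m3)
  expect_true(nmdPredicted(r3))
  expect_equal(functionalCall(assessFunctionality(r3, m3)),
               "nonfunctional")

  # without rod annotation any premature stop is inactivating
  m4 <- cdsModel(plant(297), nExons = 1)
  expect_equal(functionalCall(assessFunctionality(scanORF(m4), m4)),
               "nonfunctional")
})

test_that("sharedLesions groups species by aligned stop column", {
  ref <- randomIntactCDS(100, seed = 17)
  plant <- function(cds, k) paste0(substr(cds, 1, 3 * k - 3), "TGA",
                                   substr(cds, 3 * k + 1, nchar(cds)))
  walrus <- plant(ref, 40)
  seaLion <- plant(ref, 40)
  phocid <- ref
  reports <- list(
    walrus = scanORF(cdsModel(walrus, species = "walrus")),
    sea_lion = scanORF(cdsModel(seaLion, species = "sea_lion")),
    phocid = scanORF(cdsModel(phocid, species = "phocid")))
  aln <- c(walrus = walrus, sea_lion = seaLion, phocid = phocid)
  groups <- sharedLesions(reports, aln)
  expect_true(list(c("walrus", "sea_lion")) %in% groups ||
                any(vapply(groups, function(g)
                  setequal(g, c("walrus", "sea_lion")), logical(1))))
  expect_length(groups, 2)

  # single report -> one singleton group
  expect_equal(sharedLesions(reports["walrus"], aln["walrus"]),
               list("walrus"))

  # stops at different planted columns -> singleton groups
  reports2 <- list(a = scanORF(cdsModel(plant(ref, 30), species = "a")),
                   b = scanORF(cdsModel(plant(ref, 60), species = "b")))
  aln2 <- c(a = plant(ref, 30), b = plant(ref, 60))
  expect_length(sharedLesions(reports2, aln2), 2)

  expect_error(sharedLesions(reports, aln[1:2]), "missing from alignment")
})
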