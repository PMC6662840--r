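test_that("Newick reading validates rooting and labels", {
  tr <- readSpeciesTree("((A:1,B:1):1,C:2);", text = TRUE)
  expect_equal(ape::Ntip(tr), 3)
  expect_true(ape::is.rooted(tr))

  # no branch lengths: parses, dating unavailable
  tr2 <- readSpeciesTree("((A,B),C);", text = TRUE)
  expect_null(tr2$edge.length)
  expect_error(dateEvent(tr2, "A"), "dating unavailable")

  # internal polytomies are allowed
  poly <- readSpeciesTree("((A:1,B:1,C:1):1,D:2);", text = TRUE)
  expect_equal(ape::Ntip(poly), 4)
  # a basal star (unrooted) and duplicated labels are hard errors
  expect_error(readSpeciesTree("(A:1,B:1,C:1,D:1);", text = TRUE),
               "rooted")
  expect_error(readSpeciesTree("((A:1,A:1):1,C:2);", text = TRUE),
               "duplicated tip")
})

test_that("annotated Newick round-trips topology, labels and lengths", {
  tr <- loadFixture("mammal_tree")
  pm <- loadFixture("krt24_states")
  ev <- dolloReconstruct(binarizeStates(pm, "KRT24"), tr, gene = "KRT24")
  f <- withr::local_tempfile(fileext = ".nwk")
  writeAnnotatedNewick(tr, ev, f)
  txt <- readLines(f)
  expect_true(grepl("\\[&loss=KRT24\\]", txt))
  back <- readSpeciesTree(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_true(isTRUE(ape::all.equal.phylo(back, tr,
                                          use.edge.length = FALSE)))
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
})

test_that("the Krt24 matrix yields three independent losses on the stems of
           Camelus, Cetacea and Otaroidea", {
  tr <- loadFixture("mammal_tree")
  pm <- loadFixture("krt24_states")
  ev <- dolloReconstruct(binarizeStates(pm, "KRT24"), tr,
                         ancestralAtRoot = TRUE, gene = "KRT24")
  expect_equal(gainEdge(ev), "ROOT")
  expect_setequal(lossEdges(ev), c("Camelus", "Cetacea", "Otaroidea"))
  expect_equal(countIndependentLosses(ev), 3L)
})

test_that("an all-present gene gains at the MRCA with no losses", {
  tr <- loadFixture("mammal_tree")
  col <- stats::setNames(rep(1, ape::Ntip(tr)), tr$tip.label)
  ev <- dolloReconstruct(col, tr)
  expect_equal(gainEdge(ev), "ROOT")  # MRCA of all leaves is the root
  expect_length(lossEdges(ev), 0)
  # no functional gene anywhere: empty event set
  ev0 <- dolloReconstruct(stats::setNames(rep(0, ape::Ntip(tr)),
                                          tr$tip.label), tr)
  expect_true(is.na(gainEdge(ev0)))
})

test_that("Dollo equals the brute-force single-gain minimum (exhaustive columns)", {
  for (tr in smallTreeBank()) {
    n <- ape::Ntip(tr)
    cols <- expand.grid(rep(list(0:1), n))
    for (i in seq_len(nrow(cols))) {
      col <- stats::setNames(as.numeric(cols[i, ]), tr$tip.label)
      ev <- dolloReconstruct(col, tr)
      expect_equal(length(lossEdges(ev)), bruteDolloMinLosses(col, tr),
                   info = paste("column", paste(col, collapse = "")))
    }
  }
  # with uninformative leaves, exhaustive over the 3-state alphabet at n=4
  tr <- smallTreeBank()[[2]]
  cols <- expand.grid(rep(list(c(0, 1, NA)), 4))
  for (i in seq_len(nrow(cols))) {
    col <- stats::setNames(as.numeric(cols[i, ]), tr$tip.label)
    if (!any(col %in% 1)) next
    expect_equal(length(lossEdges(dolloReconstruct(col, tr))),
                 bruteDolloMinLosses(col, tr))
  }
})

test_that("Sankoff basics: cherry cost, all-unknown cost, tie preference", {
  cherry <- readSpeciesTree("(A:1,B:1);", text = TRUE)
  res <- sankoffReconstruct(c(A = 1, B = 0), cherry, 1, 1)
  expect_equal(res$cost, 1)
  resQ <- sankoffReconstruct(c(A = NA, B = NA), cherry, 1, 1)
  expect_equal(resQ$cost, 0)
  expect_error(sankoffReconstruct(c(A = 1, B = 0), cherry, 0, 1),
               "positive")
})

test_that("Sankoff with prohibitive regain cost reproduces Dollo events", {
  set.seed(77)
  for (rep in 1:40) {
    tr <- randomTimedTree(sample(4:8, 1), seed = 5000 + rep)
    n <- ape::Ntip(tr)
    col <- stats::setNames(sample(c(0, 1, NA), n, replace = TRUE,
                                  prob = c(0.4, 0.4, 0.2)), tr$tip.label)
    if (!any(col %in% 1)) next
    dollo <- dolloReconstruct(col, tr)
    sank <- sankoffReconstruct(col, tr, costGain = (1 + n) * 1, costLoss = 1)
    expect_equal(sort(sank$lossEdges), sort(lossEdges(dollo)))
    expect_equal(sank$gainEdges, gainEdge(dollo))
  }
})

test_that("losses are never nested and unknowns never add losses", {
  set.seed(99)
  for (rep in 1:30) {
    tr <- randomTimedTree(sample(4:8, 1), seed = 6000 + rep)
    n <- ape::Ntip(tr)
    col <- stats::setNames(sample(c(0, 1), n, replace = TRUE),
                           tr$tip.label)
    if (!any(col == 1)) next
    ev <- dolloReconstruct(col, tr)
    # nested check via the tree
    parent <- dollotrace:::.parentVec(tr)
    nodes <- vapply(lossEdges(ev), dollotrace:::.nodeFromId,
                    integer(1), tree = tr)
    for (v in nodes) for (w in nodes)
      if (v != w)
        expect_false(dollotrace:::.isAncestor(parent, v, w))
    # flipping any 0 to unknown never increases the loss count
    for (z in which(col == 0)) {
      col2 <- col; col2[z] <- NA
      expect_lte(length(lossEdges(dolloReconstruct(col2, tr))),
                 length(lossEdges(ev)))
    }
  }
})

test_that("shared ancestral lesions collapse sister losses onto their stem", {
  tr <- loadFixture("mammal_tree")
  # two otariid sisters each lost independently by reconstruction
  col <- stats::setNames(rep(1, ape::Ntip(tr)), tr$tip.label)
  col["Callorhinus_ursinus"] <- 0
  col["Zalophus_californianus"] <- 0
  ev <- dolloReconstruct(col, tr)
  # both 0-leaves are sisters -> Dollo already merges them at Otariidae
  expect_equal(lossEdges(ev), "Otariidae")

  # non-sister losses merged only through a shared lesion group
  col2 <- stats::setNames(rep(1, ape::Ntip(tr)), tr$tip.label)
  col2[c("Odobenus_rosmarus", "Callorhinus_ursinus")] <- 0
  ev2 <- dolloReconstruct(col2, tr)
  expect_length(lossEdges(ev2), 2)
  expect_equal(countIndependentLosses(ev2), 2L)
  merged <- countIndependentLosses(
    ev2, tr, sharedGroups = list(c("Odobenus_rosmarus",
                                   "Callorhinus_ursinus")))
  expect_equal(merged, 1L)
  expect_equal(countIndependentLosses(
    methods::new("EventSet", gene = "g", gainEdge = "ROOT",
                 lossEdges = character(0), intervals = data.frame())), 0L)
})

test_that("events date to their branch interval", {
  tr <- readSpeciesTree("((A:5,B:5)N1:3,C:8)R;", text = TRUE)
  expect_equal(unname(dateEvent(tr, "A")), c(5, 0))
  expect_equal(unname(dateEvent(tr, "N1")), c(8, 5))
  expect_equal(unname(dateEvent(tr, "ROOT")), c(NA_real_, 8))
  # zero-length edge: degenerate interval
  tz <- readSpeciesTree("((A:5,B:5)N1:0,C:5)R;", text = TRUE)
  expect_equal(unname(dateEvent(tz, "N1")), c(5, 5))
  # fixture intervals equal recomputed parent/child ages
  tr2 <- loadFixture("mammal_tree")
  iv <- dateEvent(tr2, "Cetacea")
  expect_equal(unname(iv), c(54, 32))
  ev <- dolloReconstruct(binarizeStates(loadFixture("krt24_states"),
                                        "KRT24"), tr2, gene = "KRT24")
  ivs <- eventIntervals(ev)
  expect_true(all(ivs$olderMY >= ivs$youngerMY, na.rm = TRUE))
  expect_true(all(ivs$youngerMY >= 0))
  ages <- dollotrace:::.nodeAges(tr2)
  expect_true(all(ivs$olderMY <= max(ages), na.rm = TRUE))
})

test_that("events serialize to TSV and JSON", {
  f4 <- loadFixture("fig4_states")
  rep <- eventsReport(f4$states, f4$tree, ancestralAtRoot = "KRT224")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  writeEvents(rep, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$edge, rep$events$edge)
  writeEvents(rep, json)
  parsed <- jsonlite::fromJSON(json)
  expect_setequal(names(parsed), c("KRT223", "KRT224"))
  expect_equal(parsed$KRT224$losses, "Placentalia")
})

test_that("the flanking-gene matrix places two gene losses on the human lineage", {
  f4 <- loadFixture("fig4_states")
  rep <- eventsReport(f4$states, f4$tree,
                      ancestralAtRoot = "KRT224")
  tr <- f4$tree
  # edges on the root-to-human path, identified by child node
  parent <- dollotrace:::.parentVec(tr)
  ids <- dollotrace:::.edgeIds(tr)
  v <- match("Homo_sapiens", ids)
  path <- character(0)
  while (v != 0 && v != dollotrace:::.rootNode(tr)) {
    path <- c(path, ids[v]); v <- parent[v]
  }
  lossRows <- rep$events[rep$events$event == "loss", ]
  onPath <- lossRows[lossRows$edge %in% path, ]
  expect_gte(length(unique(onPath$gene)), 2)
  expect_setequal(unique(onPath$gene), c("KRT223", "KRT224"))

  # single all-present gene: single gain row, no losses
  pm1 <- PresenceMatrix(matrix("INTACT", nrow = ape::Ntip(tr), ncol = 1,
                               dimnames = list(tr$tip.label, "G")))
  r1 <- eventsReport(pm1, tr)
  expect_equal(nrow(r1$events), 1)
  expect_equal(r1$events$event, "gain")
})
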