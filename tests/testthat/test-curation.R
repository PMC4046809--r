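test_that("phyletic patterns classify homolog distributions", {
  tab <- makeHits(list(
    list("p1", "Escherichia", 200), list("p1", "Bacillus", 150),
    list("p1", "Salpingoeca", 300),                       # self hits ignored
    list("p2", "Chlamydomonas", 200), list("p2", "Emiliania", 150),
    list("p3", "Chlamydomonas", 200), list("p3", "Escherichia", 150),
    list("p4", "Chlamydomonas", 200), list("p4", "Homo", 150),
    list("p5", "Salpingoeca", 300)))
  expect_equal(phyleticPattern(tab, "p1"), "PROK_ONLY")
  expect_equal(phyleticPattern(tab, "p2"), "ALGA_ONLY")
  expect_equal(phyleticPattern(tab, "p3"), "PROK_ALGA_ONLY")
  expect_equal(phyleticPattern(tab, "p4"), "BROAD")
  expect_equal(phyleticPattern(tab, "p5"), "NO_HOMOLOGY")
})

test_that("direction and donor rules follow the curation conventions", {
  expect_equal(inferDirection("PROK_ONLY"), "INTO_FOCAL")
  expect_equal(inferDirection("ALGA_ONLY"), "INTO_FOCAL")
  expect_equal(inferDirection("PROK_ALGA_ONLY"), "INTO_FOCAL")
  expect_equal(inferDirection("BROAD", treePassed = TRUE), "INTO_FOCAL")
  expect_equal(inferDirection("BROAD", treePassed = FALSE), "UNDETERMINED")
  expect_equal(inferDirection("BROAD"), "UNDETERMINED")

  mk <- function(comp) {
    full <- stats::setNames(integer(length(GROUP_LEVELS)), GROUP_LEVELS)
    full[names(comp)] <- comp
    new("CladeTestResult", passed = TRUE, support = 90,
        cladeLeaves = "q", donorComposition = full, violation = "",
        minSupport = 70)
  }
  expect_equal(classifyDonor(mk(c(ALGA = 5L))), "ALGA")
  expect_equal(classifyDonor(mk(c(PROKARYOTE = 3L))), "BACTERIA")
  expect_equal(classifyDonor(mk(c(ALGA = 2L, PROKARYOTE = 2L))), "EITHER")
  ## pattern route without a passing tree
  expect_equal(classifyDonor(pattern = "PROK_ONLY"), "BACTERIA")
  expect_equal(classifyDonor(pattern = "ALGA_ONLY"), "ALGA")
  expect_equal(classifyDonor(pattern = "PROK_ALGA_ONLY"), "EITHER")
  expect_error(classifyDonor(pattern = "BROAD"), "accepted")
  ## margin rule demotes a pure call when the two donor scores are close
  tops <- data.frame(group = c("ALGA", "PROKARYOTE"), bitscore = c(200, 195))
  expect_equal(classifyDonor(mk(c(ALGA = 3L)), tops = tops, margin = 1.1),
               "EITHER")
  expect_equal(classifyDonor(mk(c(ALGA = 3L)), tops = tops, margin = 1.01),
               "ALGA")
})

test_that("curateGenes combines tree and pattern evidence routes", {
  tab <- makeHits(list(
    ## broad distribution, passing tree -> accepted via tree
    list("t1", "Escherichia", 300), list("t1", "Homo", 150),
    ## restricted pattern, no tree -> accepted via pattern
    list("t2", "Escherichia", 250), list("t2", "Bacillus", 200),
    ## broad, failing tree -> rejected
    list("t3", "Homo", 300), list("t3", "Escherichia", 100),
    ## self only -> no call
    list("t4", "Salpingoeca", 200)))
  trees <- list(
    t1 = parseGeneTree("((t1,Escherichia)92,(Homo,Saccharomyces)90,Chlamydomonas);",
                       SCHEME, "t1"),
    t3 = parseGeneTree("((t3,Homo)95,(Escherichia,Saccharomyces)90,Chlamydomonas);",
                       SCHEME, "t3"))
  led <- curateGenes(tab, trees = trees)
  rec <- records(led)
  rownames(rec) <- rec$gene_id
  expect_equal(rec[c("t1", "t2", "t3", "t4"), "status"],
               c("ACCEPTED", "ACCEPTED", "REJECTED", "NO_CALL"))
  expect_equal(rec["t1", "evidence"], "tree")
  expect_equal(rec["t2", "evidence"], "pattern")
  expect_equal(rec["t1", "donor_class"], "BACTERIA")
  expect_equal(rec["t2", "donor_class"], "BACTERIA")
  expect_equal(rec["t1", "direction"], "INTO_FOCAL")
  expect_true(is.na(rec["t3", "donor_class"]))
  ## ledger invariants hold by construction
  expect_true(validObject(led))
})

test_that("event collapsing merges focal clades and splits separated leaves", {
  mkLedger <- function(genes) {
    new("CurationLedger", records = data.frame(
      gene_id = genes, status = "ACCEPTED", phyletic_pattern = "PROK_ONLY",
      tree_passed = TRUE, tree_support = 90, evidence = "tree",
      donor_class = "BACTERIA", direction = "INTO_FOCAL",
      stringsAsFactors = FALSE))
  }
  famMap <- c(q1 = "famA", q2 = "famA")
  ## adjacent paralogs: one event
  t1 <- ape::read.tree(text = "((q1,q2)88,Escherichia,Chlamydomonas);")
  ev1 <- collapseEvents(mkLedger(c("q1", "q2")), trees = list(famA = t1),
                        familyMap = famMap)
  expect_equal(length(unique(clusters(ev1)$event_id)), 1L)
  ## paralogs separated by a donor leaf: two events
  t2 <- ape::read.tree(text = "((q1,Escherichia)90,(q2,Bacillus)85);")
  ev2 <- collapseEvents(mkLedger(c("q1", "q2")), trees = list(famA = t2),
                        familyMap = famMap)
  expect_equal(length(unique(clusters(ev2)$event_id)), 2L)
  ## three singleton families: three events
  ev3 <- collapseEvents(mkLedger(c("a", "b", "c")))
  expect_equal(length(unique(clusters(ev3)$event_id)), 3L)
  expect_true(validObject(ev3))
  ## accepted gene missing from its family tree: error record, own event
  expect_warning(
    ev4 <- collapseEvents(mkLedger(c("q1", "q2", "q3")),
                          trees = list(famA = t1),
                          familyMap = c(famMap, q3 = "famA")),
    "missing")
  expect_equal(attr(ev4, "errors")$gene_id, "q3")
  expect_equal(length(unique(clusters(ev4)$event_id)), 2L)

  ## invariance under rerooting and child permutation
  set.seed(77)
  nwk <- "(((q1,q2)88,(q3,Escherichia)70)60,(Homo,Saccharomyces)90,(q4,Chlamydomonas)80);"
  led <- mkLedger(c("q1", "q2", "q3", "q4"))
  fm <- stats::setNames(rep("famA", 4), c("q1", "q2", "q3", "q4"))
  base <- clusters(collapseEvents(led, trees = list(
    famA = ape::read.tree(text = nwk)), familyMap = fm))
  basePart <- split(base$gene_id, base$event_id)
  canon <- function(p) unname(lapply(p[order(vapply(p, min, ""))], sort))
  for (i in 1:10) {
    phy <- ape::read.tree(text = shuffleNewick(nwk))
    og <- sample(c("Escherichia", "Homo", "Saccharomyces", "Chlamydomonas"), 1)
    phy <- ape::root(phy, outgroup = og, resolve.root = FALSE, edgelabel = TRUE)
    cl <- clusters(collapseEvents(led, trees = list(famA = phy),
                                  familyMap = fm))
    expect_equal(canon(split(cl$gene_id, cl$event_id)), canon(basePart))
  }
})

test_that("homolog sharing applies the E-value cutoff", {
  second <- data.frame(query_id = c("g1", "g2", "g2"),
                       evalue = c(1e-50, 1e-30, 1e-35))
  fl <- homologSharing(c("g1", "g2", "g3"), second)
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE))  # 1e-30 misses 1e-40; no hit
  ## boundary: exactly at the cutoff counts as shared
  expect_true(homologSharing("g", data.frame(query_id = "g", evalue = 1e-40))[["g"]])
  ## tightening the cutoff never increases the shared count
  set.seed(31)
  sh <- data.frame(query_id = sprintf("g%d", 1:50),
                   evalue = 10^-stats::runif(50, 20, 60))
  counts <- vapply(c(1e-30, 1e-40, 1e-50),
                   function(e) sum(homologSharing(sh$query_id, sh, e)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("consensus accounting reports rates and the missed-by-all count", {
  genes <- sprintf("g%02d", 1:20)
  led <- new("CurationLedger", records = data.frame(
    gene_id = genes, status = rep(c("ACCEPTED", "REJECTED"), c(12, 8)),
    phyletic_pattern = "PROK_ONLY", tree_passed = TRUE, tree_support = 90,
    evidence = "tree",
    donor_class = rep(c("BACTERIA", NA), c(12, 8)),
    direction = "INTO_FOCAL", stringsAsFactors = FALSE))
  mkv <- function(det, pred) {
    data.frame(query_id = genes, detector = det,
               flag = ifelse(genes %in% pred, "predicted", "not_predicted"),
               score = NA_real_, stringsAsFactors = FALSE)
  }
  v <- new("DetectorVerdicts", verdicts = rbind(
    mkv("a", genes[c(1:10, 13:16)]),   # 10 accepted + 4 rejected
    mkv("b", genes[c(3:12)]),          # 10 accepted
    mkv("c", character(0))))           # predicts nothing
  cons <- consensusAccounting(v, led)
  per <- cons$perDetector
  rownames(per) <- per$detector
  expect_equal(per["a", "predicted_accepted"], 10)
  expect_equal(per["a", "positive_rate"], 10 / 14)
  expect_equal(per["a", "false_negative_rate"], 2 / 12)
  expect_equal(per["b", "false_negative_rate"], 2 / 12)
  expect_true(is.na(per["c", "positive_rate"]))
  expect_equal(cons$acceptedTotal, 12)
  expect_equal(cons$unionPredictedAccepted, 12)
  expect_equal(cons$missedByAll, 0)
  ## remove detector b: genes 11 and 12 are now missed by all
  cons2 <- consensusAccounting(
    new("DetectorVerdicts",
        verdicts = rbind(mkv("a", genes[c(1:10, 13:16)]),
                         mkv("c", character(0)))), led)
  expect_equal(cons2$missedByAll, 2)
})

test_that("scaffold-neighbor heuristic flags genes without kin context", {
  led <- new("CurationLedger", records = data.frame(
    gene_id = c("a", "b", "c"), status = "ACCEPTED",
    phyletic_pattern = "PROK_ONLY", tree_passed = TRUE, tree_support = 90,
    evidence = "tree", donor_class = "BACTERIA", direction = "INTO_FOCAL",
    stringsAsFactors = FALSE))
  go <- data.frame(
    gene_id = c("x1", "a", "x2", "x3", "b", "x4", "c", "x5"),
    scaffold = c("s1", "s1", "s1", "s2", "s2", "s2", "s3", "s3"),
    position = c(1, 2, 3, 1, 2, 3, 1, 2),
    kin_affiliated = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  fl <- flagContamination(led, go)
  ## a: one kin neighbor -> cleared; b: no kin neighbors -> flagged;
  ## c: scaffold end, single kin neighbor -> cleared
  expect_equal(fl, c(a = FALSE, b = TRUE, c = FALSE))
})
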