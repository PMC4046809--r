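test_that("newick parsing attaches groups and supports in both dialects", {
  gt <- parseGeneTree("((q:1,Escherichia:1)95:1,(Homo:1,Saccharomyces:1)90:1,Chlamydomonas:1);",
                      SCHEME, query = "q")
  expect_s4_class(gt, "GeneTree")
  expect_equal(length(gt@tree$tip.label), 5L)
  expect_equal(sort(supports(gt)[!is.na(supports(gt))]), c(90, 95))
  expect_equal(unname(gt@groups["q"]), "SELF")

  ## dual ml/distance labels combine conservatively (min) by default
  gt2 <- parseGeneTree("((q,Escherichia)95/60,(Homo,Saccharomyces)90/85,Chlamydomonas);",
                       SCHEME, query = "q")
  expect_setequal(supports(gt2)[!is.na(supports(gt2))], c(60, 85))
  gt2f <- parseGeneTree("((q,Escherichia)95/60,(Homo,Saccharomyces)90/85,Chlamydomonas);",
                        SCHEME, query = "q", combine = "first")
  expect_setequal(supports(gt2f)[!is.na(supports(gt2f))], c(95, 90))

  ## fractional supports are rescaled, asterisks mean unknown
  gt3 <- parseGeneTree("((q,Escherichia)0.95,(Homo,Saccharomyces)*,Chlamydomonas);",
                       SCHEME, query = "q")
  sup <- supports(gt3)
  expect_equal(sup[!is.na(sup)], 95)

  ## error paths: duplicate labels, missing query, unmappable leaf
  expect_error(parseGeneTree("((q,Homo),(Homo,Escherichia));", SCHEME, "q"),
               "duplicate")
  expect_error(parseGeneTree("((a,Homo),(Drosophila,Escherichia));", SCHEME, "q"),
               "query leaf missing")
  expect_error(parseGeneTree("((q,Wookiee),(Homo,Escherichia));", SCHEME, "q"),
               "Wookiee")

  ## supports absent entirely: valid tree, all supports unknown
  gt4 <- parseGeneTree("((q,Escherichia),(Homo,Saccharomyces),Chlamydomonas);",
                       SCHEME, query = "q")
  expect_true(all(is.na(supports(gt4))))
  expect_false(cladeTest(gt4, minSupport = 50)@passed)  # fail-closed
})

test_that("cladeTest applies the donor-monophyly rule", {
  ## supported query+prokaryote cherry passes at 70
  r1 <- cladeTest(parseGeneTree("((q,Escherichia)95,((Homo,Drosophila)88,Saccharomyces)90);",
                                SCHEME, "q"), minSupport = 70)
  expect_true(r1@passed)
  expect_equal(r1@support, 95)
  expect_setequal(r1@cladeLeaves, c("q", "Escherichia"))
  expect_equal(r1@donorComposition[["PROKARYOTE"]], 1L)

  ## kin sister blocks the call
  r2 <- cladeTest(parseGeneTree("((q,Homo)99,(Escherichia,Bacillus)95);",
                                SCHEME, "q"), minSupport = 70)
  expect_false(r2@passed)
  expect_match(r2@violation, "kin|donor")

  ## composition fine but support too low: reported as insufficient support
  r3 <- cladeTest(parseGeneTree("((q,Escherichia)60,((Homo,Drosophila)40,Saccharomyces)30);",
                                SCHEME, "q"), minSupport = 70)
  expect_false(r3@passed)
  expect_match(r3@violation, "insufficient support")
  expect_equal(r3@support, 60)

  ## self leaves are always allowed inside the clade
  r4 <- cladeTest(parseGeneTree("(((q,Salpingoeca)90,Escherichia)85,(Homo,Saccharomyces)90,Chlamydomonas);",
                                SCHEME, "q"), minSupport = 70)
  expect_true(r4@passed)
  expect_setequal(r4@cladeLeaves, c("q", "Salpingoeca", "Escherichia"))

  ## OTHER_EUK leaves: lenient passes, strict fails
  nwk <- "(((q,Dictyostelium)90,Escherichia)85,(Homo,Saccharomyces)90,Chlamydomonas);"
  expect_true(cladeTest(parseGeneTree(nwk, SCHEME, "q"), minSupport = 70,
                        allowOtherEuk = TRUE)@passed)
  expect_false(cladeTest(parseGeneTree(nwk, SCHEME, "q"), minSupport = 70,
                         allowOtherEuk = FALSE)@passed)
})

test_that("cladeTest agrees with exhaustive bipartition enumeration", {
  skip_if_not_installed("phangorn")
  set.seed(202)
  for (i in 1:60) {
    gt <- randomGeneTreeFixture()
    ms <- sample(c(50, 70, 90), 1)
    lenient <- sample(c(TRUE, FALSE), 1)
    got <- cladeTest(gt, minSupport = ms, allowOtherEuk = lenient)
    want <- bruteCladeTest(gt, minSupport = ms, allowOtherEuk = lenient)
    expect_equal(got@passed, want$passed)
    if (want$passed) {
      expect_equal(length(got@cladeLeaves), want$minSize)
      ## the reported clade satisfies the definition directly
      g <- gt@groups[setdiff(got@cladeLeaves, "q")]
      expect_gte(sum(g %in% c("PROKARYOTE", "ALGA")), 1)
      expect_equal(sum(g == "KIN"), 0)
      expect_gte(got@support, ms)
    }
  }
})

test_that("clade calls are invariant to rerooting and child order", {
  set.seed(303)
  for (i in 1:25) {
    gt <- randomGeneTreeFixture()
    base <- cladeTest(gt, minSupport = 70)
    ## reroot at random leaves, supports following their edges
    for (og in sample(gt@tree$tip.label, 2)) {
      r <- ape::root(gt@tree, outgroup = og, resolve.root = FALSE,
                     edgelabel = TRUE)
      res <- cladeTest(geneTree(r, SCHEME, "q"), minSupport = 70)
      expect_equal(res@passed, base@passed)
      if (base@passed) {
        expect_equal(res@support, base@support)
        expect_setequal(res@cladeLeaves, base@cladeLeaves)
      }
    }
    ## permute child order at the string level
    nwk <- ape::write.tree(gt@tree)
    for (k in 1:2) {
      res <- cladeTest(parseGeneTree(shuffleNewick(nwk), SCHEME, "q"),
                       minSupport = 70)
      expect_equal(res@passed, base@passed)
      if (base@passed) expect_setequal(res@cladeLeaves, base@cladeLeaves)
    }
  }
})

test_that("passing sets shrink as the support threshold rises", {
  set.seed(404)
  gts <- replicate(40, randomGeneTreeFixture(), simplify = FALSE)
  passing <- lapply(c(50, 70, 90), function(ms) {
    which(vapply(gts, function(g) cladeTest(g, minSupport = ms)@passed,
                 logical(1)))
  })
  expect_true(all(passing[[2]] %in% passing[[1]]))
  expect_true(all(passing[[3]] %in% passing[[2]]))
})

test_that("batchScreen scores tree collections and logs parse failures", {
  set.seed(21)
  sim <- simulateGenome(simulationConfig(nGenes = 30, hgtFraction = 0.2,
                                         noiseSd = 0, seed = 9))
  gts <- lapply(sim$truth$gene_id, geneTreeFor, sim = sim)
  names(gts) <- sim$truth$gene_id
  v <- verdicts(batchScreen(gts, minSupport = 50))
  expect_setequal(v$query_id[v$flag == "predicted"],
                  sim$truth$gene_id[sim$truth$is_hgt])
  expect_true(all(v$detector == "tree_screen"))

  ## manifest input with one broken file: verdicts for the rest, error logged
  d <- tempfile(); dir.create(d)
  writeLines("((q1,Escherichia)95,(Homo,Saccharomyces)90,Chlamydomonas);",
             file.path(d, "ok.nwk"))
  writeLines("((q2,Wookiee)95,(Homo,Saccharomyces)90);", file.path(d, "bad.nwk"))
  manifest <- data.frame(path = file.path(d, c("ok.nwk", "bad.nwk")),
                         query = c("q1", "q2"), stringsAsFactors = FALSE)
  expect_warning(vb <- batchScreen(manifest, scheme = SCHEME, minSupport = 50),
                 "skipped")
  expect_equal(verdicts(vb)$query_id, "q1")
  expect_equal(nrow(attr(vb, "errors")), 1L)
})
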