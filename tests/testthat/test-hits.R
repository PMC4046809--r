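hitLine <- function(q, s, bits, e, cov, tax, ann = "hypothetical protein") {
  paste(q, s, bits, e, cov, tax, ann, sep = "\t")
}

test_that("parsing preserves valid rows and rejects invariant violations", {
  f <- tmpFile(c("# comment line",
                 hitLine("q1", "s1", 250, "1e-60", 0.9, "Escherichia"),
                 hitLine("q1", "s2", 100, "1e-20", 0.5, "Homo"),
                 hitLine("q2", "s3", 80, "1e-10", 0.3, "Chlamydomonas")))
  tab <- parseHits(f, SCHEME)
  expect_s4_class(tab, "HitTable")
  expect_equal(nrow(hits(tab)), 3L)
  expect_equal(hits(tab)$group, c("PROKARYOTE", "KIN", "ALGA"))

  ## out-of-range coverage, malformed row, unknown taxon: dropped and logged
  f2 <- tmpFile(c(hitLine("q1", "s1", 250, "1e-60", 1.2, "Escherichia"),
                  "q1\tonly-three\tfields",
                  hitLine("q1", "s2", 90, "1e-12", 0.7, "Martianus"),
                  hitLine("q1", "s3", 90, "1e-12", 0.7, "Homo")))
  expect_warning(expect_warning(tab2 <- parseHits(f2, SCHEME)))
  expect_equal(nrow(hits(tab2)), 1L)
  err <- attr(tab2, "errors")
  expect_setequal(err$reason, c("coverage outside [0, 1]",
                                "wrong field count", "unknown taxon"))
  expect_setequal(err$line, 1:3)

  ## empty file: empty table with a warning
  expect_warning(empty <- parseHits(tmpFile("# nothing"), SCHEME), "empty")
  expect_equal(nrow(hits(empty)), 0L)
})

test_that("the three exclusion rules remove the documented hits", {
  tab <- makeHits(list(
    list("q1", "Escherichia", 250, 1e-60, 0.9),
    list("q1", "Escherichia", 240, 1e-55, 0.09),             # low coverage
    list("q1", "Salpingoeca", 400, 1e-90, 0.95),             # self hit
    list("q1", "Escherichia", 300, 1e-70, 0.9,
         "Synthetic Construct beta-lactamase"),              # artificial
    list("q1", "Homo", 120, 1e-20, 0.8),
    list("q1", "Chlamydomonas", 90, 1e-3, 0.8)))             # weak E-value
  ft <- filterHits(tab)
  expect_equal(hits(ft)$subject_taxon, c("Escherichia", "Homo"))
  expect_equal(nrow(hits(ft)), 2L)
  expect_length(appliedFilters(ft), 1L)
  ## filtering an empty table is valid
  expect_equal(nrow(hits(filterHits(filterHits(tab, evalueMax = 0)))), 0L)
})

test_that("filters are monotone in their thresholds and commute", {
  set.seed(42)
  df <- do.call(rbind, lapply(1:8, function(i) randomHitDf(paste0("q", i))))
  df$subject_annotation[sample(nrow(df), 10)] <- "plasmid vector"
  tab <- hitTable(df, SCHEME)

  counts <- vapply(c(1e-40, 1e-20, 1e-10, 1e-5, 1),
                   function(e) nrow(hits(filterHits(tab, evalueMax = e))),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))  # looser cutoff keeps at least as many
  counts2 <- vapply(c(0, 0.1, 0.3, 0.6, 0.9),
                    function(cv) nrow(hits(filterHits(tab, minCoverage = cv))),
                    numeric(1))
  expect_true(all(diff(counts2) <= 0))

  ## rule order does not matter
  a <- filterHits(filterHits(filterHits(tab, evalueMax = 1e-10,
                                        minCoverage = 0,
                                        excludeAnnotations = character(0),
                                        excludeGroups = character(0)),
                             minCoverage = 0.3, evalueMax = Inf,
                             excludeAnnotations = character(0),
                             excludeGroups = character(0)),
                  excludeGroups = "SELF", evalueMax = Inf, minCoverage = 0,
                  excludeAnnotations = "plasmid")
  b <- filterHits(tab, evalueMax = 1e-10, minCoverage = 0.3,
                  excludeAnnotations = "plasmid", excludeGroups = "SELF")
  expect_equal(hits(a), hits(b))
})

test_that("topHitPerGroup maximizes bitscore with documented tie-breaks", {
  tab <- makeHits(list(
    list("q1", "Escherichia", 100, 1e-20, 0.9),
    list("q1", "Bacillus", 250, 1e-50, 0.9),
    list("q1", "Synechococcus", 30, 1e-6, 0.9),
    list("q1", "Homo", 250, 1e-60, 0.9),
    list("q1", "Drosophila", 250, 1e-50, 0.9)))
  top <- topHitPerGroup(tab, "q1")
  expect_equal(top$bitscore[top$group == "PROKARYOTE"], 250)
  expect_equal(top$subject_taxon[top$group == "PROKARYOTE"], "Bacillus")
  ## equal bitscores: the lower E-value wins
  expect_equal(top$subject_taxon[top$group == "KIN"], "Homo")
  ## groups without hits are absent
  expect_false("ALGA" %in% top$group)
  expect_error(topHitPerGroup(tab, "q9"), "q9")

  ## agreement with exhaustive comparison over random tables
  set.seed(7)
  for (i in 1:25) {
    df <- randomHitDf("q")
    t2 <- hitTable(df, SCHEME)
    top2 <- topHitPerGroup(t2, "q")
    h <- hits(t2)
    for (g in unique(h$group)) {
      expect_equal(top2$bitscore[top2$group == g], max(h$bitscore[h$group == g]))
    }
  }
})

test_that("filtering never raises a group's top bitscore", {
  set.seed(11)
  for (i in 1:10) {
    tab <- hitTable(randomHitDf("q"), SCHEME)
    ft <- filterHits(tab, evalueMax = 1e-20, minCoverage = 0.5)
    if (!nrow(hits(ft)) || !("q" %in% hits(ft)$query_id)) next
    before <- topHitPerGroup(tab, "q")
    after <- topHitPerGroup(ft, "q")
    for (g in intersect(before$group, after$group)) {
      expect_lte(after$bitscore[after$group == g],
                 before$bitscore[before$group == g])
    }
  }
})

test_that("hit tables round-trip through TSV with an audit header", {
  tab <- filterHits(makeHits(list(
    list("q1", "Escherichia", 250, 1e-60, 0.9),
    list("q1", "Homo", 120, 1e-20, 0.8))))
  f <- tempfile(fileext = ".tsv")
  writeHits(tab, f)
  expect_true(any(grepl("^# filter:", readLines(f))))
  again <- parseHits(f, SCHEME)
  expect_equal(hits(again)[c("query_id", "subject_taxon", "bitscore")],
               hits(tab)[c("query_id", "subject_taxon", "bitscore")])
})

test_that("YAML filter configs map onto filterHits arguments", {
  f <- tmpFile(c("evalue_max: 1.0e-10", "min_coverage: 0.25",
                 "exclude_annotations:", "  - plasmid",
                 "exclude_groups:", "  - SELF"), ext = ".yaml")
  cfg <- readFilterConfig(f)
  expect_equal(cfg$evalueMax, 1e-10)
  expect_equal(cfg$minCoverage, 0.25)
  expect_equal(cfg$excludeAnnotations, "plasmid")
  expect_equal(cfg$excludeGroups, "SELF")
})
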