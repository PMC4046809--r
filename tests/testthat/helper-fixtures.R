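## shared fixtures and independent oracles for the test suite

SCHEME <- defaultScheme()

## quick hit-table builder: rows as (query, taxon, bitscore[, evalue, coverage,
## annotation])
makeHits <- function(rows, scheme = SCHEME) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[[1]], subject_id = paste0(r[[2]], "|", r[[1]]),
               bitscore = as.numeric(r[[3]]),
               evalue = if (length(r) >= 4) as.numeric(r[[4]]) else 1e-30,
               coverage = if (length(r) >= 5) as.numeric(r[[5]]) else 0.8,
               subject_taxon = r[[2]],
               subject_annotation = if (length(r) >= 6) r[[6]]
                                    else "hypothetical protein",
               stringsAsFactors = FALSE)
  }))
  hitTable(df, scheme)
}

## random hit table over the scaffold taxa, one query
randomHitDf <- function(query = "q", n = NULL) {
  n <- n %||% sample(3:25, 1)
  tx <- sample(setdiff(taxa(SCHEME), "Monosiga"), n, replace = TRUE)
  data.frame(query_id = query,
             subject_id = sprintf("%s|%d", tolower(tx), seq_len(n)),
             bitscore = round(stats::runif(n, 5, 500), 1),
             evalue = 10^-stats::runif(n, 1, 80),
             coverage = round(stats::runif(n, 0.15, 1), 2),
             subject_taxon = tx, subject_annotation = "hypothetical protein",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent alien-index oracle: one linear scan over all hit rows, no
## per-group indexing
bruteAlienIndex <- function(df, query, close = "KIN",
                            distant = c("PROKARYOTE", "ALGA")) {
  rows <- df[df$query_id == query, , drop = FALSE]
  cb <- suppressWarnings(max(rows$bitscore[rows$group %in% close]))
  db <- suppressWarnings(max(rows$bitscore[rows$group %in% distant]))
  if (!is.finite(cb) && !is.finite(db)) return(NA_real_)
  if (!is.finite(db)) return(0)
  if (!is.finite(cb) || cb == 0) return(Inf)
  db / cb
}

## independent clade-test oracle: exhaustive bipartition enumeration through
## phangorn::Descendants, applying the acceptance definition literally
bruteCladeTest <- function(gt, donorGroups = c("PROKARYOTE", "ALGA"),
                           minSupport = 70, allowOtherEuk = TRUE) {
  phy <- gt@tree
  nt <- length(phy$tip.label)
  grp <- gt@groups[phy$tip.label]
  q <- match(queryLeaf(gt), phy$tip.label)
  desc <- phangorn::Descendants(phy, (nt + 1):(nt + phy$Nnode), "tips")
  sides <- list()
  for (j in seq_along(desc)) {
    if (nt + j == nt + 1) next  # root
    below <- desc[[j]]
    side <- if (q %in% below) sort(below) else sort(setdiff(seq_len(nt), below))
    if (length(side) < 2 || length(side) > nt - 1) next
    key <- paste(side, collapse = ",")
    supp <- gt@supports[j]
    if (is.na(supp)) supp <- 0
    if (is.null(sides[[key]]) || supp > sides[[key]]$supp) {
      sides[[key]] <- list(side = side, supp = supp)
    }
  }
  pass <- Filter(function(sp) {
    g <- grp[setdiff(sp$side, q)]
    sum(g %in% donorGroups) >= 1 && sum(g == "KIN") == 0 &&
      (allowOtherEuk || sum(g == "OTHER_EUK") == 0) &&
      sp$supp >= minSupport
  }, sides)
  if (!length(pass)) return(list(passed = FALSE))
  sizes <- vapply(pass, function(sp) length(sp$side), integer(1))
  list(passed = TRUE, minSize = min(sizes))
}

## random support-annotated gene tree over scaffold taxa + query leaf "q"
randomGeneTreeFixture <- function(nLeaves = sample(5:12, 1)) {
  phy <- ape::unroot(ape::rtree(nLeaves))
  phy$tip.label <- sample(c("q", sample(setdiff(taxa(SCHEME), "Monosiga"),
                                        nLeaves - 1)))
  sup <- sample(c(NA_real_, 2:100), phy$Nnode, replace = TRUE)
  phy$node.label <- ifelse(is.na(sup), "", as.character(sup))
  geneTree(phy, SCHEME, "q")
}

## shuffle child order at every node of a newick string (pure string level,
## independent of ape's internals)
shuffleNewick <- function(nwk) {
  shuf <- function(s) {
    if (!startsWith(s, "(")) return(s)
    chars <- strsplit(s, "")[[1]]
    depth <- 0
    cut <- NA
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1
      if (chars[i] == ")") {
        depth <- depth - 1
        if (depth == 0) { cut <- i; break }
      }
    }
    inner <- substr(s, 2, cut - 1)
    label <- substr(s, cut + 1, nchar(s))
    parts <- character(0)
    depth <- 0
    start <- 1
    ich <- strsplit(inner, "")[[1]]
    for (i in seq_along(ich)) {
      if (ich[i] == "(") depth <- depth + 1
      if (ich[i] == ")") depth <- depth - 1
      if (ich[i] == "," && depth == 0) {
        parts <- c(parts, substr(inner, start, i - 1))
        start <- i + 1
      }
    }
    parts <- c(parts, substr(inner, start, nchar(inner)))
    parts <- vapply(parts, shuf, character(1), USE.NAMES = FALSE)
    paste0("(", paste(sample(parts), collapse = ","), ")", label)
  }
  paste0(shuf(sub(";\\s*$", "", nwk)), ";")
}

## write lines to a temp file, returning the path
tmpFile <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
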