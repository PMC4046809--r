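## synthetic_data module: seeded simulator planting transfers into gene families

## taxonomic distance of each subject group from the gene's origin; bitscore
## decays linearly with this distance. "VERT" is a vertically inherited
## opisthokont gene; the donor rows describe planted transfers.
.DIST <- rbind(
  VERT     = c(SELF = 0.2, KIN = 1.0, PROKARYOTE = 3.0, ALGA = 2.5, OTHER_EUK = 2.0),
  ALGA     = c(SELF = 0.2, KIN = 3.5, PROKARYOTE = 2.5, ALGA = 1.0, OTHER_EUK = 3.0),
  BACTERIA = c(SELF = 0.2, KIN = 3.5, PROKARYOTE = 1.0, ALGA = 2.5, OTHER_EUK = 3.0),
  EITHER   = c(SELF = 0.2, KIN = 3.5, PROKARYOTE = 1.0, ALGA = 1.0, OTHER_EUK = 3.0))

## background (non-attachment) bootstrap supports are kept below the 50/70
## screening thresholds so the planted attachment edge alone decides the test
.BG_SUPPORT <- c(20, 45)

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the package is validated under: a
#' 500-gene synthetic focal genome with 20% planted transfers, donors mixed in
#' the proportions of the curated reference survey (240 algal : 139 bacterial
#' : 26 ambiguous), roughly half the transfer events predating the split from
#' the sister species (213/405), moderate bitscore noise, and strong bootstrap
#' support on true attachment edges.
#'
#' @param nGenes genes in the synthetic genome (default 500).
#' @param hgtFraction fraction of genes that are planted transfers
#'   (default 0.2).
#' @param donorMix named proportions over \code{ALGA}, \code{BACTERIA},
#'   \code{EITHER} (default 240:139:26).
#' @param duplicationProb probability a planted gene joins the previous
#'   transfer's family as a post-transfer duplicate (default 0.2).
#' @param preSplitFraction fraction of transfer events shared with the sister
#'   species (default 213/405).
#' @param scoreDecay bitscore decline per unit taxonomic distance
#'   (default 40).
#' @param noiseSd Gaussian bitscore noise sd (default 10); also degrades the
#'   attachment-edge bootstrap support by \code{(noiseSd/2)|N(0,1)|}.
#' @param supportStrong range of attachment supports for well-supported
#'   transfers (default 85-100).
#' @param supportWeak range for weakly supported transfers (default 30-65),
#'   applied to a \code{weakSupportFraction} of transfers to exercise the
#'   50/70 thresholds.
#' @param weakSupportFraction fraction of transfers using \code{supportWeak}
#'   (default 0).
#' @param baseScore bitscore of a perfect homolog before decay (default 300).
#' @param seed RNG seed (default 1).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nGenes = 500, hgtFraction = 0.2,
                             donorMix = c(ALGA = 240, BACTERIA = 139,
                                          EITHER = 26) / 405,
                             duplicationProb = 0.2,
                             preSplitFraction = 213 / 405,
                             scoreDecay = 40, noiseSd = 10,
                             supportStrong = c(85, 100),
                             supportWeak = c(30, 65),
                             weakSupportFraction = 0,
                             baseScore = 300, seed = 1) {
  new("SimulationConfig", nGenes = nGenes, hgtFraction = hgtFraction,
      donorMix = donorMix / sum(donorMix),
      duplicationProb = duplicationProb,
      preSplitFraction = preSplitFraction, scoreDecay = scoreDecay,
      noiseSd = noiseSd, supportStrong = supportStrong,
      supportWeak = supportWeak,
      weakSupportFraction = weakSupportFraction, baseScore = baseScore,
      seed = seed)
}

.bgSup <- function() as.character(round(stats::runif(1, .BG_SUPPORT[1],
                                                     .BG_SUPPORT[2])))

## newick for one gene family on the fixed 23-taxon scaffold
.familyNewick <- function(type, members, preSplit, attachSup) {
  s <- .bgSup
  blk <- members[1]
  if (length(members) > 1) {
    for (k in 2:length(members)) blk <- sprintf("(%s,%s)%s", blk, members[k], s())
  }
  met <- sprintf("((Homo,Drosophila)%s,Nematostella)%s", s(), s())
  fun <- sprintf("(Saccharomyces,Neurospora)%s", s())
  str2 <- sprintf("((Thalassiosira,Phaeodactylum)%s,Phytophthora)%s", s(), s())
  alv <- sprintf("(Tetrahymena,Emiliania)%s", s())
  oth <- sprintf("(Dictyostelium,(Naegleria,Trypanosoma)%s)%s", s(), s())
  prokB <- sprintf("(Sulfolobus,Methanococcus)%s", s())
  if (type == "VERT") {
    cho <- sprintf("(%s,Salpingoeca)%s", blk, s())
    opi <- sprintf("((%s,%s)%s,%s)%s", cho, met, s(), fun, s())
    green <- sprintf("((Chlamydomonas,Ostreococcus)%s,Cyanidioschyzon)%s",
                     s(), s())
    prokA <- sprintf("((Escherichia,Bacillus)%s,Synechococcus)%s", s(), s())
  } else {
    if (preSplit) blk <- sprintf("(%s,Salpingoeca)%s", blk, s())
    opi <- sprintf("(%s,%s)%s", met, fun, s())
    if (type == "ALGA") {
      qatt <- sprintf("(%s,Chlamydomonas)%d", blk, attachSup)
      green <- sprintf("((%s,Ostreococcus)%s,Cyanidioschyzon)%s",
                       qatt, s(), s())
      prokA <- sprintf("((Escherichia,Bacillus)%s,Synechococcus)%s", s(), s())
    } else if (type == "BACTERIA") {
      qatt <- sprintf("(%s,Escherichia)%d", blk, attachSup)
      green <- sprintf("((Chlamydomonas,Ostreococcus)%s,Cyanidioschyzon)%s",
                       s(), s())
      prokA <- sprintf("((%s,Bacillus)%s,Synechococcus)%s", qatt, s(), s())
    } else {  # EITHER: attach to a mixed bacterial + algal clade
      qatt <- sprintf("(%s,(Escherichia,Chlamydomonas)%s)%d",
                      blk, s(), attachSup)
      green <- sprintf("(Ostreococcus,Cyanidioschyzon)%s", s())
      prokA <- sprintf("((%s,Bacillus)%s,Synechococcus)%s", qatt, s(), s())
    }
  }
  alg <- sprintf("((%s,%s)%s,%s)%s", green, str2, s(), alv, s())
  sprintf("(%s,(%s,%s)%s,(%s,%s)%s);", opi, alg, oth, s(), prokA, prokB, s())
}

#' Simulate a synthetic focal genome with planted transfers
#'
#' Emits, for every gene, BLAST-style hits against a fixed 23-taxon scaffold
#' spanning all five analysis groups, a bootstrap-annotated family gene tree,
#' hits against the sister-species proteome, and ground-truth labels.
#' Vertically inherited genes score best against kin taxa and nest with the
#' kin clade; planted transfers score best against their donor group (by a
#' margin set by \code{scoreDecay}) and are regrafted inside the donor clade
#' with attachment support drawn from \code{supportStrong} (degraded by
#' noise). Bitscores are the base score minus a per-group taxonomic-distance
#' penalty plus Gaussian noise, floored at zero; E-values are a fixed
#' strictly decreasing function of the bitscore (the contract is the
#' ordering, not the values). A few hits per genome carry artificial-sequence
#' annotations, sub-10% coverage, or self-group subjects so the filtering
#' rules are exercised. All randomness flows from the config seed; two runs
#' with the same config are identical.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return a list of class \code{HgtSimulation}: \code{hits} (a
#'   \linkS4class{HitTable}), \code{trees} (named list of
#'   \linkS4class{GeneTree} family trees), \code{newick} (their source
#'   strings), \code{familyMap} (gene id -> family id), \code{secondHits}
#'   (data.frame of sister-proteome hits), \code{truth} (data.frame:
#'   \code{gene_id}, \code{is_hgt}, \code{donor_group}, \code{pre_split},
#'   \code{n_paralogs}, \code{family}), \code{plantedEvents} (number of
#'   planted acquisition events), \code{scheme}, and \code{config}.
#' @seealso \code{\link{simulationConfig}}, \code{\link{runPipeline}},
#'   \code{\link{writeSimulation}}
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  scheme <- defaultScheme()
  .withSeed(config@seed, .simulate(config, scheme))
}

.simulate <- function(cfg, scheme) {
  n <- as.integer(cfg@nGenes)
  emptyTruth <- data.frame(
    gene_id = character(0), is_hgt = logical(0), donor_group = character(0),
    pre_split = logical(0), n_paralogs = integer(0), family = character(0),
    stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(
      hits = hitTable(data.frame(
        query_id = character(0), subject_id = character(0),
        bitscore = numeric(0), evalue = numeric(0), coverage = numeric(0),
        subject_taxon = character(0), subject_annotation = character(0),
        stringsAsFactors = FALSE), scheme),
      trees = list(), newick = character(0),
      familyMap = stats::setNames(character(0), character(0)),
      secondHits = data.frame(query_id = character(0),
                              subject_id = character(0),
                              bitscore = numeric(0), evalue = numeric(0),
                              stringsAsFactors = FALSE),
      truth = emptyTruth, plantedEvents = 0L,
      scheme = scheme, config = cfg), class = "HgtSimulation"))
  }
  ids <- sprintf("g%04d", seq_len(n))
  nH <- round(n * cfg@hgtFraction)
  isH <- seq_len(n) %in% (if (nH > 0) sort(sample.int(n, nH)) else integer(0))

  donorLevels <- c("ALGA", "BACTERIA", "EITHER")
  mix <- cfg@donorMix[donorLevels]
  mix[is.na(mix)] <- 0
  fam <- ifelse(isH, NA_character_, ids)
  donor <- rep(NA_character_, n)
  preSplit <- rep(NA, n)
  curFam <- NULL; curDonor <- NULL; curPre <- NULL
  for (i in which(isH)) {
    if (!is.null(curFam) && stats::runif(1) < cfg@duplicationProb) {
      fam[i] <- curFam; donor[i] <- curDonor; preSplit[i] <- curPre
    } else {
      curFam <- ids[i]
      curDonor <- sample(donorLevels, 1, prob = mix)
      curPre <- stats::runif(1) < cfg@preSplitFraction
      fam[i] <- curFam; donor[i] <- curDonor; preSplit[i] <- curPre
    }
  }
  origin <- ifelse(isH, donor, "VERT")

  ## hits against the full scaffold (all taxa but the focal genome itself)
  taxTab <- groupTable(scheme)
  subj <- taxTab[taxTab$taxon != "Monosiga", , drop = FALSE]
  ns <- nrow(subj)
  gi <- rep(seq_len(n), each = ns)
  ti <- rep(seq_len(ns), times = n)
  dist <- .DIST[cbind(origin[gi], subj$group[ti])]
  score <- pmax(0, cfg@baseScore - cfg@scoreDecay * dist +
                     stats::rnorm(n * ns, 0, cfg@noiseSd))
  hitsDf <- data.frame(
    query_id = ids[gi],
    subject_id = sprintf("%s|%s", tolower(subj$taxon[ti]), ids[gi]),
    bitscore = round(score, 1),
    evalue = 10^(-round(score, 1) / 10),
    coverage = round(stats::runif(n * ns, 0.60, 0.95), 2),
    subject_taxon = subj$taxon[ti],
    subject_annotation = "hypothetical protein",
    stringsAsFactors = FALSE)
  ## junk rows exercising the exclusion rules (removed by filterHits)
  junkArt <- which(stats::runif(n) < 0.05)
  junkCov <- which(stats::runif(n) < 0.05)
  junk <- rbind(
    if (length(junkArt)) data.frame(
      query_id = ids[junkArt],
      subject_id = sprintf("cloning_vector|%s", ids[junkArt]),
      bitscore = cfg@baseScore + 50, evalue = 1e-80, coverage = 0.9,
      subject_taxon = "Escherichia",
      subject_annotation = "synthetic construct cloning vector",
      stringsAsFactors = FALSE),
    if (length(junkCov)) data.frame(
      query_id = ids[junkCov],
      subject_id = sprintf("fragment|%s", ids[junkCov]),
      bitscore = cfg@baseScore + 50, evalue = 1e-80, coverage = 0.05,
      subject_taxon = "Homo", subject_annotation = "hypothetical protein",
      stringsAsFactors = FALSE))
  hitsDf <- rbind(hitsDf, junk)
  hitsDf <- hitsDf[order(hitsDf$query_id), , drop = FALSE]

  ## family trees
  families <- unique(fam)
  newick <- character(length(families))
  names(newick) <- families
  attach <- stats::setNames(rep(NA_integer_, length(families)), families)
  for (f in families) {
    members <- ids[fam == f]
    type <- origin[match(f, ids)]
    att <- NA_integer_
    if (type != "VERT") {
      rng <- if (stats::runif(1) < cfg@weakSupportFraction) cfg@supportWeak
             else cfg@supportStrong
      att <- max(0L, as.integer(round(
        stats::runif(1, rng[1], rng[2]) -
          (cfg@noiseSd / 2) * abs(stats::rnorm(1)))))
      attach[f] <- att
    }
    newick[f] <- .familyNewick(type, members, isTRUE(preSplit[match(f, ids)]),
                               att)
  }
  trees <- lapply(families, function(f) {
    parseGeneTree(newick[[f]], scheme, query = ids[fam == f][1],
                  focalLeaves = ids[fam == f])
  })
  names(trees) <- families

  ## sister-proteome hits: strong for vertical genes and pre-split transfers,
  ## weak for post-split transfers
  s2 <- ifelse(!isH, 600, ifelse(preSplit, 500, 300)) +
    stats::rnorm(n, 0, cfg@noiseSd)
  secondHits <- data.frame(
    query_id = ids, subject_id = sprintf("salpingoeca|%s", ids),
    bitscore = round(s2, 1), evalue = 10^(-round(s2, 1) / 10),
    stringsAsFactors = FALSE)

  famSize <- table(fam)
  truth <- data.frame(
    gene_id = ids, is_hgt = isH, donor_group = donor, pre_split = preSplit,
    n_paralogs = as.integer(famSize[fam]), family = fam,
    stringsAsFactors = FALSE)
  structure(list(
    hits = hitTable(hitsDf, scheme),
    trees = trees, newick = newick,
    familyMap = stats::setNames(fam, ids),
    secondHits = secondHits, truth = truth,
    plantedEvents = length(unique(fam[isH])),
    scheme = scheme, config = cfg), class = "HgtSimulation")
}

#' Gene tree for one simulated gene
#'
#' Returns the gene's family tree with the query slot set to that gene, ready
#' for \code{\link{cladeTest}}.
#'
#' @param sim an \code{HgtSimulation}.
#' @param gene a simulated gene id.
#' @return a \linkS4class{GeneTree}.
#' @export
geneTreeFor <- function(sim, gene) {
  f <- sim$familyMap[[gene]]
  if (is.null(f) || is.na(f)) stop("unknown simulated gene: ", gene)
  gt <- sim$trees[[f]]
  gt@query <- gene
  validObject(gt)
  gt
}

#' Write a simulation bundle to disk
#'
#' Emits the hit table, sister-proteome hits, per-family newick trees with a
#' manifest, the taxonomy scheme, the truth table, and the configuration as
#' plain text. Every file carries a header comment with a digest of the
#' configuration so bundles are self-identifying.
#'
#' @param sim an \code{HgtSimulation}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "trees"), showWarnings = FALSE)
  cfg <- sim$config
  cfgLines <- c(
    sprintf("nGenes=%d", as.integer(cfg@nGenes)),
    sprintf("hgtFraction=%g", cfg@hgtFraction),
    sprintf("donorMix=%s", paste(sprintf("%s:%g", names(cfg@donorMix),
                                         cfg@donorMix), collapse = ",")),
    sprintf("duplicationProb=%g", cfg@duplicationProb),
    sprintf("preSplitFraction=%g", cfg@preSplitFraction),
    sprintf("scoreDecay=%g", cfg@scoreDecay),
    sprintf("noiseSd=%g", cfg@noiseSd),
    sprintf("supportStrong=%g-%g", cfg@supportStrong[1], cfg@supportStrong[2]),
    sprintf("supportWeak=%g-%g", cfg@supportWeak[1], cfg@supportWeak[2]),
    sprintf("weakSupportFraction=%g", cfg@weakSupportFraction),
    sprintf("baseScore=%g", cfg@baseScore),
    sprintf("seed=%d", as.integer(cfg@seed)))
  stamp <- sprintf("# config %s", .digest(cfgLines))
  writeLines(c(stamp, paste0("# ", cfgLines)), file.path(dir, "config.txt"))

  writeHits(sim$hits, file.path(dir, "hits.tsv"))
  writeScheme(sim$scheme, file.path(dir, "scheme.tsv"))

  con <- file(file.path(dir, "second_hits.tsv"), "w")
  writeLines(stamp, con)
  utils::write.table(sim$secondHits, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  con <- file(file.path(dir, "truth.tsv"), "w")
  writeLines(stamp, con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)

  fams <- names(sim$newick)
  manifest <- data.frame(family = fams,
                         path = file.path("trees", paste0(fams, ".nwk")),
                         query = vapply(sim$trees, queryLeaf, character(1)),
                         members = vapply(fams, function(f) {
                           paste(names(sim$familyMap)[sim$familyMap == f],
                                 collapse = ",")
                         }, character(1)),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    writeLines(sim$newick[[manifest$family[i]]],
               file.path(dir, manifest$path[i]))
  }
  con <- file(file.path(dir, "manifest.tsv"), "w")
  writeLines(stamp, con)
  utils::write.table(manifest, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(dir)
}
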