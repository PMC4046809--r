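#' @import methods
NULL

setOldClass("phylo")

#' TaxonomyScheme: taxon-to-group assignments
#'
#' Maps each taxon name, via the longest matching prefix of its semicolon
#' lineage path, to one of the five analysis groups in
#' \code{\link{GROUP_LEVELS}}. The default scheme follows the convention of
#' choanoflagellate HGT surveys: the focal lineage is the choanoflagellates,
#' kin are metazoans and fungi, prokaryotes cover bacteria and archaea (the
#' domain is retained so reports can distinguish them), and "algae" is defined
#' loosely as lineages with primary, secondary or tertiary plastids plus
#' oomycetes and ciliates.
#'
#' @slot assignments data.frame with columns \code{taxon}, \code{lineage},
#'   \code{group}, \code{domain}.
#' @slot groupDefs data.frame with columns \code{group}, \code{prefix} (the
#'   lineage prefixes defining each group).
#' @slot selfLineage lineage prefix of the focal group.
#' @slot kinLineages lineage prefixes of the vertical-kin group.
#' @slot algalGroups lineage prefixes treated as algae sensu lato.
#' @seealso \code{\link{loadScheme}}, \code{\link{defaultScheme}},
#'   \code{\link{groupOf}}
#' @export
setClass("TaxonomyScheme",
  representation(assignments = "data.frame", groupDefs = "data.frame",
                 selfLineage = "character", kinLineages = "character",
                 algalGroups = "character"))

setValidity("TaxonomyScheme", function(object) {
  a <- object@assignments
  need <- c("taxon", "lineage", "group", "domain")
  if (!all(need %in% names(a))) {
    return(paste("assignments must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(a$taxon)) return("duplicate taxon names in scheme")
  if (!all(a$group %in% GROUP_LEVELS)) {
    return(paste("unknown group label(s):",
                 paste(setdiff(unique(a$group), GROUP_LEVELS), collapse = ", ")))
  }
  if (length(object@algalGroups) < 11) {
    return("algalGroups must cover the nine plastid-bearing lineages plus oomycetes and ciliates")
  }
  TRUE
})

#' HitTable: taxonomically labelled homology hits
#'
#' Tabular homology hits (BLAST outfmt-6 style) grouped by query, each hit
#' carrying its subject's analysis group, plus a provenance record of the
#' filters applied so far.
#'
#' @slot hits data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{bitscore}, \code{evalue}, \code{coverage} (fraction of query length
#'   aligned, in [0,1]), \code{subject_taxon}, \code{subject_annotation},
#'   \code{group}.
#' @slot filters character vector describing filters already applied.
#' @seealso \code{\link{parseHits}}, \code{\link{filterHits}},
#'   \code{\link{topHitPerGroup}}
#' @export
setClass("HitTable",
  representation(hits = "data.frame", filters = "character"))

setValidity("HitTable", function(object) {
  h <- object@hits
  need <- c("query_id", "subject_id", "bitscore", "evalue", "coverage",
            "subject_taxon", "subject_annotation", "group")
  if (!all(need %in% names(h))) {
    return(paste("hits must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(h)) {
    if (any(!is.finite(h$bitscore)) || any(h$bitscore < 0)) {
      return("bitscore must be finite and non-negative")
    }
    if (any(h$evalue < 0)) return("evalue must be non-negative")
    if (any(h$coverage < 0 | h$coverage > 1)) {
      return("coverage must be a fraction in [0, 1]")
    }
    if (!all(h$group %in% GROUP_LEVELS)) return("unknown group label in hits")
  }
  TRUE
})

#' GeneTree: unrooted, support-annotated gene tree
#'
#' A leaf-labelled unrooted tree with per-internal-edge bootstrap supports
#' (0-100, \code{NA} when absent), a leaf-to-group map, and the identity of the
#' focal query leaf. Focal-genome paralog leaves are mapped to \code{SELF}.
#'
#' @slot tree an \code{ape} \code{phylo} object.
#' @slot query the query leaf label.
#' @slot groups named character vector: leaf label to analysis group.
#' @slot supports numeric vector, one value per internal node (edge above it);
#'   \code{NA} means no support was annotated and is treated as 0 in tests.
#' @seealso \code{\link{parseGeneTree}}, \code{\link{cladeTest}}
#' @export
setClass("GeneTree",
  representation(tree = "phylo", query = "character",
                 groups = "character", supports = "numeric"))

setValidity("GeneTree", function(object) {
  tl <- object@tree$tip.label
  if (anyDuplicated(tl)) return("duplicate leaf labels")
  if (!(object@query %in% tl)) {
    return(paste("query leaf", object@query, "not in tree"))
  }
  if (!all(tl %in% names(object@groups))) return("every leaf needs a group")
  if (!all(object@groups[tl] %in% GROUP_LEVELS)) {
    return("unknown group label on a leaf")
  }
  if (length(object@supports) != object@tree$Nnode) {
    return("need one support slot per internal node")
  }
  s <- object@supports[!is.na(object@supports)]
  if (length(s) && (any(s < 0) || any(s > 100))) {
    return("supports must lie in [0, 100]")
  }
  TRUE
})

#' CladeTestResult: outcome of a donor-monophyly test
#'
#' Result of scanning the internal edges of a gene tree for a supported split
#' that places the query with donor-group leaves and no kin leaves.
#'
#' @slot passed logical.
#' @slot support support of the reported edge (NA when failed with no
#'   candidate edge).
#' @slot cladeLeaves leaf labels on the query side of the reported split.
#' @slot donorComposition named integer: group counts inside the clade,
#'   query excluded.
#' @slot violation reason string when failed ("" when passed).
#' @slot minSupport the support threshold the test used.
#' @export
setClass("CladeTestResult",
  representation(passed = "logical", support = "numeric",
                 cladeLeaves = "character", donorComposition = "integer",
                 violation = "character", minSupport = "numeric"))

#' AlienScore: alien-index screening result for one query
#'
#' The alien index is the ratio of the best (bit-score) hit among distantly
#' related taxa (candidate donors) to the best hit among close relatives. It
#' is \code{Inf} when the query has donor-group homologs but none among close
#' relatives, and undefined (\code{NA}, status \code{NO_HOMOLOGY}) when it has
#' neither.
#'
#' @slot query query id.
#' @slot closeBest best bitscore among close groups (NA if none).
#' @slot distantBest best bitscore among distant groups (NA if none).
#' @slot ai the alien index (distant / close).
#' @slot candidate logical, \code{ai >= threshold}.
#' @slot threshold threshold used.
#' @slot status "OK" or "NO_HOMOLOGY".
#' @seealso \code{\link{alienIndex}}
#' @export
setClass("AlienScore",
  representation(query = "character", closeBest = "numeric",
                 distantBest = "numeric", ai = "numeric",
                 candidate = "logical", threshold = "numeric",
                 status = "character"))

#' DetectorVerdicts: per-query, per-detector prediction flags
#'
#' Long-format table of tri-state detector verdicts: \code{predicted},
#' \code{not_predicted}, or \code{not_run}.
#'
#' @slot verdicts data.frame with columns \code{query_id}, \code{detector},
#'   \code{flag}, \code{score} (detector score such as the alien index or the
#'   best clade support; NA where not applicable).
#' @seealso \code{\link{screenGenome}}, \code{\link{batchScreen}},
#'   \code{\link{importCandidates}}, \code{\link{mergeVerdicts}}
#' @export
setClass("DetectorVerdicts", representation(verdicts = "data.frame"))

setValidity("DetectorVerdicts", function(object) {
  v <- object@verdicts
  need <- c("query_id", "detector", "flag", "score")
  if (!all(need %in% names(v))) {
    return(paste("verdicts must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(v) && !all(v$flag %in% FLAG_LEVELS)) {
    return("flags must be predicted / not_predicted / not_run")
  }
  if (anyDuplicated(v[c("query_id", "detector")])) {
    return("one verdict per (query, detector)")
  }
  TRUE
})

#' CurationLedger: per-gene curation records
#'
#' One row per gene: detector flags, phyletic pattern, clade-test outcome,
#' donor class, transfer direction, final status, event id, homolog sharing
#' with a second proteome, and the manual-evidence checklist fields (shared
#' indels, conserved residues, gene structure, alignment quality,
#' contamination) that an operator sets; the package never decides those
#' automatically.
#'
#' @slot records data.frame; see \code{\link{curateGenes}} for columns.
#' @export
setClass("CurationLedger", representation(records = "data.frame"))

setValidity("CurationLedger", function(object) {
  r <- object@records
  need <- c("gene_id", "status", "phyletic_pattern", "tree_passed",
            "tree_support", "evidence", "donor_class", "direction")
  if (!all(need %in% names(r))) {
    return(paste("records must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(r$gene_id)) return("duplicate gene ids")
  if (nrow(r)) {
    if (!all(r$status %in% STATUS_LEVELS)) return("unknown status label")
    acc <- r$status == "ACCEPTED"
    if (any(acc & !(r$donor_class %in% DONOR_LEVELS))) {
      return("accepted genes must carry a donor class")
    }
    restricted <- r$phyletic_pattern %in%
      c("PROK_ONLY", "ALGA_ONLY", "PROK_ALGA_ONLY")
    okTree <- !is.na(r$tree_passed) & r$tree_passed
    if (any(acc & !(okTree | restricted))) {
      return("accepted genes need a passing clade test or a restricted phyletic pattern")
    }
  }
  TRUE
})

#' EventClusters: acquired genes collapsed into transfer events
#'
#' Paralogous acquired genes that form a single focal clade in their family
#' tree count as one acquisition event.
#'
#' @slot clusters data.frame with columns \code{event_id}, \code{gene_id},
#'   \code{donor_class}.
#' @seealso \code{\link{collapseEvents}}
#' @export
setClass("EventClusters", representation(clusters = "data.frame"))

setValidity("EventClusters", function(object) {
  cl <- object@clusters
  need <- c("event_id", "gene_id", "donor_class")
  if (!all(need %in% names(cl))) {
    return(paste("clusters must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cl$gene_id)) {
    return("each gene belongs to exactly one event")
  }
  TRUE
})

#' SummaryReport: headline statistics of a curation ledger
#'
#' Genome fraction of acquired genes, donor-class and event counts, detector
#' overlap rates, homolog-sharing split with a second proteome, and
#' functional-category percentages. All percentages are rounded half-up to
#' one decimal.
#'
#' @slot stats named list; see \code{\link{summarizeLedger}}.
#' @export
setClass("SummaryReport", representation(stats = "list"))

#' SimulationConfig: parameters of the planted-transfer simulator
#'
#' @slot nGenes number of genes in the synthetic focal genome.
#' @slot hgtFraction fraction of genes that are planted transfers.
#' @slot donorMix proportions over ALGA / BACTERIA / EITHER donors.
#' @slot duplicationProb probability a planted gene is a post-transfer
#'   duplicate joining the previous transfer's family.
#' @slot preSplitFraction fraction of transfer events shared with the second
#'   (sister) species, i.e. predating the focal-lineage split.
#' @slot scoreDecay bitscore decline per unit taxonomic distance.
#' @slot noiseSd standard deviation of Gaussian bitscore noise; also degrades
#'   bootstrap support on the query-attachment edge.
#' @slot supportStrong range (length 2) of bootstrap supports for confident
#'   query-attachment edges.
#' @slot supportWeak range for weak attachment supports, used for a
#'   \code{weakSupportFraction} of transfers to exercise the 50/70 thresholds.
#' @slot weakSupportFraction fraction of transfers whose attachment support is
#'   drawn from \code{supportWeak}.
#' @slot baseScore bitscore of a perfect homolog before decay.
#' @slot seed RNG seed; runs are bit-for-bit reproducible given the seed.
#' @seealso \code{\link{simulationConfig}}, \code{\link{simulateGenome}}
#' @export
setClass("SimulationConfig",
  representation(nGenes = "numeric", hgtFraction = "numeric",
                 donorMix = "numeric", duplicationProb = "numeric",
                 preSplitFraction = "numeric", scoreDecay = "numeric",
                 noiseSd = "numeric", supportStrong = "numeric",
                 supportWeak = "numeric", weakSupportFraction = "numeric",
                 baseScore = "numeric", seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  fr <- c(object@hgtFraction, object@duplicationProb,
          object@preSplitFraction, object@weakSupportFraction)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@nGenes < 0) return("nGenes must be non-negative")
  if (abs(sum(object@donorMix) - 1) > 1e-8) return("donorMix must sum to 1")
  if (!all(names(object@donorMix) %in% DONOR_LEVELS)) {
    return("donorMix names must be ALGA / BACTERIA / EITHER")
  }
  for (s in list(object@supportStrong, object@supportWeak)) {
    if (length(s) != 2 || any(s < 0 | s > 100) || s[1] > s[2]) {
      return("support ranges must be increasing pairs in [0, 100]")
    }
  }
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  TRUE
})
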