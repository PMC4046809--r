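#' @rdname groupOf
#' @export
setGeneric("groupOf", function(scheme, taxon) standardGeneric("groupOf"))

#' @rdname filterHits
#' @export
setGeneric("filterHits", function(x, ...) standardGeneric("filterHits"))

#' @rdname topHitPerGroup
#' @export
setGeneric("topHitPerGroup", function(x, query) standardGeneric("topHitPerGroup"))

#' @rdname alienIndex
#' @export
setGeneric("alienIndex", function(x, query, ...) standardGeneric("alienIndex"))

#' @rdname cladeTest
#' @export
setGeneric("cladeTest", function(x, ...) standardGeneric("cladeTest"))

#' Accessors for HGTscan containers
#'
#' \code{hits} returns the hit data.frame of a \linkS4class{HitTable};
#' \code{appliedFilters} its filter provenance; \code{records} the per-gene
#' data.frame of a \linkS4class{CurationLedger}; \code{verdicts} the
#' long-format flags of a \linkS4class{DetectorVerdicts}; \code{clusters} the
#' event table of an \linkS4class{EventClusters}; \code{reportStats} the
#' statistics list of a \linkS4class{SummaryReport}; \code{taxa} and
#' \code{groupTable} the taxon names and assignment table of a
#' \linkS4class{TaxonomyScheme}; \code{queries} the query ids present in a
#' \linkS4class{HitTable}; \code{queryLeaf} and \code{supports} the query
#' label and per-internal-node supports of a \linkS4class{GeneTree}.
#'
#' @param x an HGTscan object.
#' @return the underlying data described above.
#' @name accessors
#' @aliases hits records verdicts clusters reportStats taxa groupTable
#'   queries queryLeaf supports appliedFilters
NULL

#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))
#' @rdname accessors
#' @export
setGeneric("appliedFilters", function(x) standardGeneric("appliedFilters"))
#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))
#' @rdname accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("reportStats", function(x) standardGeneric("reportStats"))
#' @rdname accessors
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))
#' @rdname accessors
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))
#' @rdname accessors
#' @export
setGeneric("queries", function(x) standardGeneric("queries"))
#' @rdname accessors
#' @export
setGeneric("queryLeaf", function(x) standardGeneric("queryLeaf"))
#' @rdname accessors
#' @export
setGeneric("supports", function(x) standardGeneric("supports"))

setMethod("hits", "HitTable", function(x) x@hits)
setMethod("appliedFilters", "HitTable", function(x) x@filters)
setMethod("queries", "HitTable", function(x) unique(x@hits$query_id))
setMethod("records", "CurationLedger", function(x) x@records)
setMethod("verdicts", "DetectorVerdicts", function(x) x@verdicts)
setMethod("clusters", "EventClusters", function(x) x@clusters)
setMethod("reportStats", "SummaryReport", function(x) x@stats)
setMethod("taxa", "TaxonomyScheme", function(x) x@assignments$taxon)
setMethod("groupTable", "TaxonomyScheme", function(x) x@assignments)
setMethod("queryLeaf", "GeneTree", function(x) x@query)
setMethod("supports", "GeneTree", function(x) x@supports)

setMethod("show", "TaxonomyScheme", function(object) {
  a <- object@assignments
  cat("TaxonomyScheme with", nrow(a), "taxa\n")
  print(table(factor(a$group, levels = GROUP_LEVELS)))
})

setMethod("show", "HitTable", function(object) {
  h <- object@hits
  cat("HitTable:", nrow(h), "hits over", length(unique(h$query_id)),
      "queries\n")
  if (length(object@filters)) {
    cat("filters applied:\n")
    for (f in object@filters) cat("  -", f, "\n")
  }
})

setMethod("show", "GeneTree", function(object) {
  cat("GeneTree with", length(object@tree$tip.label), "leaves; query",
      object@query, "\n")
  cat("group composition:\n")
  print(table(factor(object@groups[object@tree$tip.label],
                     levels = GROUP_LEVELS)))
})

setMethod("show", "CladeTestResult", function(object) {
  if (object@passed) {
    cat(sprintf("cladeTest: PASSED (support %.0f >= %.0f), clade of %d leaves\n",
                object@support, object@minSupport, length(object@cladeLeaves)))
  } else {
    cat(sprintf("cladeTest: failed (%s)\n", object@violation))
  }
})

setMethod("show", "AlienScore", function(object) {
  cat(sprintf("AlienScore[%s]: ai = %s (distant %s / close %s) -> %s\n",
              object@query, format(object@ai),
              format(object@distantBest), format(object@closeBest),
              if (object@status == "NO_HOMOLOGY") "NO_HOMOLOGY"
              else if (object@candidate) "candidate" else "not a candidate"))
})

setMethod("show", "DetectorVerdicts", function(object) {
  v <- object@verdicts
  cat("DetectorVerdicts:", length(unique(v$query_id)), "queries x",
      length(unique(v$detector)), "detectors\n")
  print(table(v$detector, v$flag))
})

setMethod("show", "CurationLedger", function(object) {
  r <- object@records
  cat("CurationLedger with", nrow(r), "genes\n")
  print(table(factor(r$status, levels = STATUS_LEVELS)))
})

setMethod("show", "EventClusters", function(object) {
  cl <- object@clusters
  cat("EventClusters:", length(unique(cl$event_id)), "events over",
      nrow(cl), "genes\n")
})

setMethod("show", "SummaryReport", function(object) {
  s <- object@stats
  cat(sprintf("SummaryReport: %d acquired genes of %d (%.1f%%)\n",
              s$accepted_total, s$genome_total, s$genome_fraction))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %d genes, %.0f%% planted transfers, noise sd %.1f, seed %d\n",
    object@nGenes, 100 * object@hgtFraction, object@noiseSd,
    as.integer(object@seed)))
})
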