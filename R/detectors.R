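## detectors module: alien-index screening and external candidate lists

.newVerdicts <- function(df) {
  rownames(df) <- NULL
  new("DetectorVerdicts", verdicts = df)
}

#' Alien index of one query
#'
#' Computes the bit-score ratio between the top hit from distantly related
#' taxa (the candidate donor groups, by default prokaryotes and algae) and the
#' top hit from closely related taxa (by default the kin group: metazoans and
#' fungi; other eukaryotes count toward neither side unless configured). The
#' query is a transfer candidate when the ratio is at least \code{threshold};
#' 1.2 is the conventional default, and the comparison is inclusive so a gene
#' scoring exactly at the threshold is retained. The table should already be
#' filtered (self hits excluded).
#'
#' A query with donor-group hits but no close hits scores \code{Inf} (a
#' candidate); one with close hits but no donor hits scores 0; one with no
#' hits on either side is \code{NO_HOMOLOGY} and never a candidate, since a
#' transfer call rests on donor-group homology.
#'
#' @param x a filtered \linkS4class{HitTable}.
#' @param query query id.
#' @param closeGroups groups counted as close relatives (default
#'   \code{"KIN"}).
#' @param distantGroups groups counted as candidate donors (default
#'   \code{c("PROKARYOTE", "ALGA")}).
#' @param threshold candidate threshold on the ratio (default 1.2; must be
#'   positive).
#' @param ... unused.
#' @return an \linkS4class{AlienScore}.
#' @rdname alienIndex
#' @export
setMethod("alienIndex", "HitTable", function(x, query,
    closeGroups = "KIN", distantGroups = c("PROKARYOTE", "ALGA"),
    threshold = 1.2, ...) {
  stopifnot(threshold > 0)
  h <- x@hits[x@hits$query_id == query, , drop = FALSE]
  best <- function(groups) {
    b <- h$bitscore[h$group %in% groups]
    if (length(b)) max(b) else NA_real_
  }
  closeBest <- best(closeGroups)
  distantBest <- best(distantGroups)
  if (is.na(closeBest) && is.na(distantBest)) {
    return(new("AlienScore", query = query, closeBest = NA_real_,
               distantBest = NA_real_, ai = NA_real_, candidate = FALSE,
               threshold = threshold, status = "NO_HOMOLOGY"))
  }
  ai <- if (is.na(distantBest)) {
    0
  } else if (is.na(closeBest) || closeBest == 0) {
    Inf
  } else {
    distantBest / closeBest
  }
  new("AlienScore", query = query, closeBest = closeBest,
      distantBest = distantBest, ai = ai, candidate = ai >= threshold,
      threshold = threshold, status = "OK")
})

#' Screen a genome's queries with the alien index
#'
#' Runs \code{\link{alienIndex}} over a list of queries and returns one
#' tri-state verdict per query. Queries absent from the hit table (or with no
#' usable homology) are flagged \code{not_predicted} with an \code{NA} score.
#' Deterministic given its inputs.
#'
#' @param x a filtered \linkS4class{HitTable}.
#' @param queryIds queries to screen; defaults to the queries present in the
#'   table.
#' @param detector detector name recorded on the verdicts (default
#'   \code{"alien_index"}).
#' @inheritParams alienIndex,HitTable-method
#' @return a \linkS4class{DetectorVerdicts}.
#' @export
screenGenome <- function(x, queryIds = NULL, detector = "alien_index",
                         closeGroups = "KIN",
                         distantGroups = c("PROKARYOTE", "ALGA"),
                         threshold = 1.2) {
  queryIds <- queryIds %||% queries(x)
  if (!length(queryIds)) {
    return(.newVerdicts(data.frame(
      query_id = character(0), detector = character(0),
      flag = character(0), score = numeric(0), stringsAsFactors = FALSE)))
  }
  present <- queryIds %in% x@hits$query_id
  score <- rep(NA_real_, length(queryIds))
  flag <- rep("not_predicted", length(queryIds))
  for (i in which(present)) {
    a <- alienIndex(x, queryIds[i], closeGroups = closeGroups,
                    distantGroups = distantGroups, threshold = threshold)
    score[i] <- a@ai
    if (a@candidate) flag[i] <- "predicted"
  }
  .newVerdicts(data.frame(query_id = queryIds, detector = detector,
                          flag = flag, score = score,
                          stringsAsFactors = FALSE))
}

#' Import an externally produced candidate list
#'
#' Reads a one-id-per-line candidate list from a phylogeny- or
#' lineage-probability-based detector run outside the package (DarkHorse-style
#' tools are not reimplemented here) and turns it into a verdict fragment over
#' a known query universe: listed queries are \code{predicted}, all others
#' \code{not_predicted}. Duplicated ids are deduplicated with a message; ids
#' not in \code{queryIds} are dropped with a warning.
#'
#' @param path text file, one query id per line (\code{#} comments allowed).
#' @param detector detector name to record.
#' @param queryIds the full query universe.
#' @return a \linkS4class{DetectorVerdicts}.
#' @export
importCandidates <- function(path, detector, queryIds) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !grepl("^#", ids)]
  if (anyDuplicated(ids)) {
    message("deduplicated ", sum(duplicated(ids)), " candidate id(s)")
    ids <- unique(ids)
  }
  unknown <- setdiff(ids, queryIds)
  if (length(unknown)) {
    warning("ignoring ", length(unknown), " candidate id(s) not in the query set: ",
            paste(utils::head(unknown, 5), collapse = ", "))
    ids <- setdiff(ids, unknown)
  }
  .newVerdicts(data.frame(
    query_id = queryIds, detector = detector,
    flag = ifelse(queryIds %in% ids, "predicted", "not_predicted"),
    score = NA_real_, stringsAsFactors = FALSE))
}

#' Merge verdict fragments from several detectors
#'
#' Binds fragments; a (query, detector) pair present in more than one fragment
#' keeps its first occurrence. Queries missing for a detector are filled in as
#' \code{not_run}.
#'
#' @param ... \linkS4class{DetectorVerdicts} objects.
#' @param queryIds optional full query universe used to pad \code{not_run}
#'   rows; defaults to the union of queries seen.
#' @return a \linkS4class{DetectorVerdicts}.
#' @export
mergeVerdicts <- function(..., queryIds = NULL) {
  vs <- lapply(list(...), verdicts)
  v <- do.call(rbind, vs)
  v <- v[!duplicated(v[c("query_id", "detector")]), , drop = FALSE]
  queryIds <- queryIds %||% unique(v$query_id)
  dets <- unique(v$detector)
  full <- expand.grid(query_id = queryIds, detector = dets,
                      stringsAsFactors = FALSE)
  m <- merge(full, v, by = c("query_id", "detector"), all.x = TRUE,
             sort = FALSE)
  m$flag[is.na(m$flag)] <- "not_run"
  m <- m[order(match(m$detector, dets), match(m$query_id, queryIds)), ,
         drop = FALSE]
  .newVerdicts(m)
}
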