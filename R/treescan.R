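## treescan module: newick parsing and donor-monophyly tests on unrooted trees

## tip sets below each node, one postorder sweep
.tipSets <- function(phy) {
  nt <- length(phy$tip.label)
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- i
  for (e in ape::postorder(phy)) {
    p <- phy$edge[e, 1]
    ch <- phy$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

.parseSupportLabel <- function(s, combine = "min") {
  s <- trimws(s)
  if (!nzchar(s) || s == "*") return(NA_real_)
  v <- suppressWarnings(as.numeric(strsplit(s, "/", fixed = TRUE)[[1]]))
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  if (combine == "min") min(v) else v[1]
}

#' Wrap a phylo object as a GeneTree
#'
#' Maps every leaf to its analysis group through the scheme; the query leaf
#' and any labels listed in \code{focalLeaves} (e.g. focal-genome paralogs in
#' a family tree, whose labels are gene ids rather than taxon names) are
#' mapped to \code{SELF}. Leaves that are neither focal nor known taxa are an
#' error listing the offending labels.
#'
#' @param phy an \code{ape} \code{phylo}.
#' @param scheme a \linkS4class{TaxonomyScheme}.
#' @param query the query leaf label.
#' @param focalLeaves labels treated as focal-genome (SELF) leaves; the query
#'   is always included.
#' @param supports optional numeric vector of per-internal-node supports; by
#'   default parsed from \code{phy$node.label} (dual "ml/distance" labels are
#'   combined according to \code{combine}, \code{""} and \code{"*"} mean
#'   unknown, and all-fractional labels are rescaled to 0-100).
#' @param combine how to combine dual supports: \code{"min"} (conservative
#'   default) or \code{"first"}.
#' @return a \linkS4class{GeneTree}.
#' @export
geneTree <- function(phy, scheme, query, focalLeaves = character(0),
                     supports = NULL, combine = c("min", "first")) {
  combine <- match.arg(combine)
  tl <- phy$tip.label
  if (anyDuplicated(tl)) {
    stop("duplicate leaf labels: ",
         paste(unique(tl[duplicated(tl)]), collapse = ", "))
  }
  if (!(query %in% tl)) stop("query leaf missing from tree: ", query)
  focalLeaves <- union(focalLeaves, query)
  grp <- stats::setNames(rep(NA_character_, length(tl)), tl)
  grp[tl %in% focalLeaves] <- "SELF"
  rest <- tl[!(tl %in% focalLeaves)]
  known <- rest %in% scheme@assignments$taxon
  if (any(!known)) {
    stop("leaves with unmappable taxa: ", paste(rest[!known], collapse = ", "))
  }
  grp[rest] <- unname(groupOf(scheme, rest))
  if (is.null(supports)) {
    labs <- phy$node.label
    supports <- if (is.null(labs)) {
      rep(NA_real_, phy$Nnode)
    } else {
      vapply(labs, .parseSupportLabel, numeric(1), combine = combine,
             USE.NAMES = FALSE)
    }
    nz <- supports[!is.na(supports)]
    if (length(nz) && max(nz) <= 1) supports <- supports * 100
  }
  new("GeneTree", tree = phy, query = query, groups = grp,
      supports = supports)
}

#' Parse a bootstrap-annotated newick gene tree
#'
#' Reads a newick file (or string) as an unrooted tree with bootstrap supports
#' on internal edges. Both common support dialects are accepted: plain
#' internal-node labels (\code{(A,B)95}) and dual \code{ml/distance} labels
#' (\code{(A,B)95/80}), the latter combined with \code{combine} (minimum by
#' default: when two analyses disagree the weaker support is the honest one).
#' \code{"*"} or empty labels mean no support and behave as support 0 in clade
#' tests; labels all at most 1 are read as fractions and rescaled to 0-100.
#'
#' @param x path to a newick file, or a newick string (anything containing
#'   \code{"("} is treated as a string).
#' @inheritParams geneTree
#' @return a \linkS4class{GeneTree}.
#' @seealso \code{\link{cladeTest}}, \code{\link{batchScreen}}
#' @examples
#' scheme <- defaultScheme()
#' gt <- parseGeneTree("((q1,Escherichia)95,(Homo,Saccharomyces)90,Chlamydomonas);",
#'                     scheme, query = "q1")
#' cladeTest(gt, minSupport = 70)
#' @export
parseGeneTree <- function(x, scheme, query, focalLeaves = character(0),
                          combine = c("min", "first")) {
  phy <- if (grepl("(", x[1], fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(x)
  }
  if (is.null(phy)) stop("could not parse newick input")
  geneTree(phy, scheme, query, focalLeaves = focalLeaves,
           combine = match.arg(combine))
}

## enumerate the unique non-trivial splits of the tree as query-side tip sets;
## duplicate splits (a binary root shows the same split twice) keep the larger
## annotated support
.querySideSplits <- function(gt) {
  phy <- gt@tree
  nt <- length(phy$tip.label)
  root <- nt + 1L
  qtip <- match(gt@query, phy$tip.label)
  sets <- .tipSets(phy)
  out <- list()
  for (v in seq(nt + 1L, nt + phy$Nnode)) {
    if (v == root) next
    below <- sets[[v]]
    side <- if (qtip %in% below) below else setdiff(seq_len(nt), below)
    if (length(side) < 2L || length(side) > nt - 1L) next
    supp <- gt@supports[v - nt]
    key <- paste(sort(side), collapse = ",")
    if (!is.null(out[[key]])) {
      prev <- out[[key]]$support
      if (is.na(prev) || (!is.na(supp) && supp > prev)) {
        out[[key]]$support <- supp
      }
    } else {
      out[[key]] <- list(side = sort(side), support = supp)
    }
  }
  out
}

#' Test for a supported query + donor clade excluding kin
#'
#' Scans every internal-edge bipartition of the unrooted gene tree for a split
#' whose query side consists of the query, at least one donor-group leaf, any
#' number of focal-lineage (SELF) leaves -- a homolog shared with a sister
#' species never argues against transfer -- and, per policy, no kin leaves
#' ever, with other eukaryotes tolerated (\code{allowOtherEuk = TRUE}, the
#' lenient default: in real gene trees stray eukaryotic sequences often branch
#' with prokaryotic homologs) or forbidden (strict). Edges without a support
#' annotation count as support 0, so an unsupported clade never passes. Among
#' passing splits the smallest query side is reported (ties to the best
#' supported).
#'
#' The criterion follows curated transfer surveys: monophyly of the query with
#' prokaryote/algal homologs at \code{minSupport} (70 for curation, 50 for
#' batch screening) to the exclusion of metazoan/fungal sequences.
#'
#' @param x a \linkS4class{GeneTree}.
#' @param donorGroups donor analysis groups (default prokaryotes and algae).
#' @param minSupport bootstrap threshold in [0, 100] (default 70).
#' @param allowOtherEuk lenient (default) vs strict handling of
#'   \code{OTHER_EUK} leaves inside the clade.
#' @param ... unused.
#' @return a \linkS4class{CladeTestResult}; failure is a result, not an error.
#' @rdname cladeTest
#' @export
setMethod("cladeTest", "GeneTree", function(x,
    donorGroups = c("PROKARYOTE", "ALGA"), minSupport = 70,
    allowOtherEuk = TRUE, ...) {
  stopifnot(minSupport >= 0, minSupport <= 100)
  phy <- x@tree
  tl <- phy$tip.label
  grp <- x@groups[tl]
  qtip <- match(x@query, tl)
  splits <- .querySideSplits(x)
  best <- NULL
  bestComposition <- NULL  # composition ok but support too low
  sawKinBlocked <- FALSE
  for (sp in splits) {
    side <- sp$side
    supp <- if (is.na(sp$support)) 0 else sp$support
    others <- setdiff(side, qtip)
    g <- grp[others]
    nDonor <- sum(g %in% donorGroups)
    nKin <- sum(g == "KIN")
    nOther <- sum(g == "OTHER_EUK")
    if (nKin > 0 && nDonor > 0) sawKinBlocked <- TRUE
    compOk <- nDonor >= 1 && nKin == 0 && (allowOtherEuk || nOther == 0)
    if (!compOk) next
    if (supp >= minSupport) {
      if (is.null(best) || length(side) < length(best$side) ||
          (length(side) == length(best$side) && supp > best$supp)) {
        best <- list(side = side, supp = supp)
      }
    } else if (is.null(bestComposition) || supp > bestComposition$supp) {
      bestComposition <- list(side = side, supp = supp)
    }
  }
  if (!is.null(best)) {
    inClade <- setdiff(best$side, qtip)
    comp <- table(factor(grp[inClade], levels = GROUP_LEVELS))
    return(new("CladeTestResult", passed = TRUE, support = best$supp,
               cladeLeaves = tl[best$side],
               donorComposition = stats::setNames(as.integer(comp),
                                                  names(comp)),
               violation = "", minSupport = minSupport))
  }
  if (!is.null(bestComposition)) {
    inClade <- setdiff(bestComposition$side, qtip)
    comp <- table(factor(grp[inClade], levels = GROUP_LEVELS))
    return(new("CladeTestResult", passed = FALSE,
               support = bestComposition$supp,
               cladeLeaves = tl[bestComposition$side],
               donorComposition = stats::setNames(as.integer(comp),
                                                  names(comp)),
               violation = sprintf("insufficient support (best %.0f < %.0f)",
                                   bestComposition$supp, minSupport),
               minSupport = minSupport))
  }
  new("CladeTestResult", passed = FALSE, support = NA_real_,
      cladeLeaves = character(0),
      donorComposition = stats::setNames(integer(length(GROUP_LEVELS)),
                                          GROUP_LEVELS),
      violation = if (sawKinBlocked) "kin leaves inside every donor clade"
                  else "no donor-containing clade",
      minSupport = minSupport)
})

#' Batch tree screening
#'
#' Runs \code{\link{cladeTest}} over a collection of gene trees at the
#' screening threshold (default 50, the batch-screening convention; curation
#' uses 70) and returns one verdict per tree's query, with the best supporting
#' edge's value as the score. Trees may be given as a named list of
#' \linkS4class{GeneTree} objects, or as a manifest data.frame with columns
#' \code{path} and \code{query} (newick files parsed with \code{scheme}).
#' An optional manifest column \code{members} (comma-separated leaf labels)
#' names focal-genome paralog leaves to map to \code{SELF}. Unparseable
#' manifest entries are skipped with a per-tree error record in
#' \code{attr(, "errors")}.
#'
#' @param trees list of \linkS4class{GeneTree}s, or a manifest data.frame.
#' @param scheme a \linkS4class{TaxonomyScheme}; required with a manifest.
#' @param donorGroups donor groups, as in \code{\link{cladeTest}}.
#' @param minSupport screening support threshold (default 50).
#' @param allowOtherEuk clade policy, as in \code{\link{cladeTest}}.
#' @param detector detector name recorded on verdicts (default
#'   \code{"tree_screen"}).
#' @return a \linkS4class{DetectorVerdicts}.
#' @export
batchScreen <- function(trees, scheme = NULL,
                        donorGroups = c("PROKARYOTE", "ALGA"),
                        minSupport = 50, allowOtherEuk = TRUE,
                        detector = "tree_screen") {
  errors <- data.frame(item = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  if (is.data.frame(trees)) {
    stopifnot(!is.null(scheme), all(c("path", "query") %in% names(trees)))
    parsed <- list()
    for (i in seq_len(nrow(trees))) {
      focal <- if ("members" %in% names(trees)) {
        strsplit(trees$members[i], ",", fixed = TRUE)[[1]]
      } else character(0)
      gt <- tryCatch(
        parseGeneTree(trees$path[i], scheme, trees$query[i],
                      focalLeaves = focal),
        error = function(e) e)
      if (inherits(gt, "error")) {
        errors <- rbind(errors, data.frame(item = trees$path[i],
                                           reason = conditionMessage(gt)))
      } else {
        parsed[[trees$query[i]]] <- gt
      }
    }
    if (nrow(errors)) {
      warning(nrow(errors), " tree(s) skipped; see attr(, 'errors')")
    }
    trees <- parsed
  }
  rows <- lapply(trees, function(gt) {
    res <- cladeTest(gt, donorGroups = donorGroups, minSupport = minSupport,
                     allowOtherEuk = allowOtherEuk)
    data.frame(query_id = gt@query, detector = detector,
               flag = if (res@passed) "predicted" else "not_predicted",
               score = res@support, stringsAsFactors = FALSE)
  })
  v <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(query_id = character(0), detector = character(0),
               flag = character(0), score = numeric(0),
               stringsAsFactors = FALSE)
  }
  out <- .newVerdicts(v)
  attr(out, "errors") <- errors
  out
}
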