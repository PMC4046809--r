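## curation module: consensus curation, donor/direction calls, event collapsing

#' Phyletic distribution pattern of a query
#'
#' Classifies the taxonomic spread of a query's homologs after filtering,
#' self-group hits excluded: \code{PROK_ONLY} when all remaining hits are
#' prokaryotic, \code{ALGA_ONLY} when all algal, \code{PROK_ALGA_ONLY} when
#' confined to the two donor groups, \code{BROAD} otherwise, and
#' \code{NO_HOMOLOGY} when nothing non-self remains.
#'
#' @param x a filtered \linkS4class{HitTable}.
#' @param query query id.
#' @return one of \code{\link{PATTERN_LEVELS}}.
#' @export
phyleticPattern <- function(x, query) {
  h <- hits(x)
  g <- unique(h$group[h$query_id == query & h$group != "SELF"])
  if (!length(g)) return("NO_HOMOLOGY")
  if (all(g == "PROKARYOTE")) return("PROK_ONLY")
  if (all(g == "ALGA")) return("ALGA_ONLY")
  if (all(g %in% c("PROKARYOTE", "ALGA"))) return("PROK_ALGA_ONLY")
  "BROAD"
}

#' Infer the direction of a transfer
#'
#' Genes found only in the donor groups (and the focal lineage) are read as
#' transfers into the focal genome, as are broadly distributed genes whose
#' accepted clade is donor-affiliated; everything else is left undetermined.
#' The asymmetry is ecological: a phagotroph eats bacteria and algae, and the
#' reverse direction would require ancestors of major donor lineages as
#' recipients.
#'
#' @param pattern a phyletic pattern label.
#' @param treePassed did the curation clade test pass (may be \code{NA} when
#'   no tree was available).
#' @return \code{"INTO_FOCAL"} or \code{"UNDETERMINED"}.
#' @export
inferDirection <- function(pattern, treePassed = NA) {
  if (pattern %in% c("PROK_ONLY", "ALGA_ONLY", "PROK_ALGA_ONLY")) {
    return("INTO_FOCAL")
  }
  if (pattern == "BROAD" && isTRUE(treePassed)) return("INTO_FOCAL")
  "UNDETERMINED"
}

#' Classify the donor of an accepted gene
#'
#' For tree-supported acceptances, the donor class is read off the supporting
#' clade: all algal donor leaves give \code{ALGA}, all prokaryotic give
#' \code{BACTERIA}, a mixed clade gives \code{EITHER}. For pattern-route
#' acceptances (restricted distribution without a passing clade),
#' \code{PROK_ONLY} maps to \code{BACTERIA}, \code{ALGA_ONLY} to \code{ALGA},
#' and \code{PROK_ALGA_ONLY} to \code{EITHER}. Optionally, a pure clade is
#' demoted to \code{EITHER} when the best algal and prokaryotic bitscores are
#' within a ratio \code{margin} of each other (off by default).
#'
#' @param treeResult a \linkS4class{CladeTestResult}, or \code{NULL}.
#' @param pattern the gene's phyletic pattern.
#' @param tops optional data.frame from \code{\link{topHitPerGroup}} used for
#'   the margin rule.
#' @param margin optional ratio margin for the tie rule (e.g. 1.1);
#'   \code{NULL} disables it.
#' @return \code{"ALGA"}, \code{"BACTERIA"} or \code{"EITHER"}.
#' @export
classifyDonor <- function(treeResult = NULL, pattern = NULL, tops = NULL,
                          margin = NULL) {
  cls <- NULL
  if (!is.null(treeResult) && treeResult@passed) {
    comp <- treeResult@donorComposition
    nA <- comp[["ALGA"]]
    nP <- comp[["PROKARYOTE"]]
    cls <- if (nA > 0 && nP > 0) "EITHER"
           else if (nA > 0) "ALGA"
           else if (nP > 0) "BACTERIA"
           else "EITHER"  # supported but donor-ambiguous
  } else if (!is.null(pattern)) {
    cls <- switch(pattern,
                  PROK_ONLY = "BACTERIA",
                  ALGA_ONLY = "ALGA",
                  PROK_ALGA_ONLY = "EITHER",
                  stop("donor classification needs an accepted record"))
  } else {
    stop("donor classification needs an accepted record")
  }
  if (!is.null(margin) && !is.null(tops) && cls %in% c("ALGA", "BACTERIA")) {
    bA <- tops$bitscore[tops$group == "ALGA"]
    bP <- tops$bitscore[tops$group == "PROKARYOTE"]
    if (length(bA) && length(bP) &&
        max(bA, bP) / min(bA, bP) < margin) {
      cls <- "EITHER"
    }
  }
  cls
}

#' Curate genes into a per-gene ledger
#'
#' Combines the homology evidence and the gene trees into final calls. A gene
#' is \code{ACCEPTED} when its tree shows a supported query + donor clade
#' excluding kin at the curation threshold (default 70), or when its phyletic
#' distribution is restricted to the focal lineage plus donor groups (both
#' evidence routes are recorded); genes with no non-self homology are
#' \code{NO_CALL}; everything else is \code{REJECTED}. Donor class and
#' direction are filled in for accepted genes. Manual-evidence checklist
#' columns (shared indels, conserved residues, gene structure, alignment
#' quality, contamination) are initialized to \code{NA} for an operator to
#' set.
#'
#' @param x a filtered \linkS4class{HitTable}.
#' @param trees named list of \linkS4class{GeneTree}s, keyed by gene id;
#'   genes without a tree are curated on the phyletic pattern alone.
#' @param geneIds genes to curate; defaults to the union of hit-table queries
#'   and tree names.
#' @param minSupport curation support threshold (default 70).
#' @param donorGroups donor analysis groups.
#' @param allowOtherEuk clade policy, as in \code{\link{cladeTest}}.
#' @param donorMargin optional bitscore-ratio margin passed to
#'   \code{\link{classifyDonor}}.
#' @return a \linkS4class{CurationLedger}.
#' @seealso \code{\link{attachVerdicts}}, \code{\link{collapseEvents}},
#'   \code{\link{homologSharing}}, \code{\link{summarizeLedger}}
#' @export
curateGenes <- function(x, trees = list(), geneIds = NULL, minSupport = 70,
                        donorGroups = c("PROKARYOTE", "ALGA"),
                        allowOtherEuk = TRUE, donorMargin = NULL) {
  geneIds <- geneIds %||% union(queries(x), names(trees))
  n <- length(geneIds)
  rec <- data.frame(
    gene_id = geneIds, status = NA_character_,
    phyletic_pattern = NA_character_, tree_passed = NA,
    tree_support = NA_real_, clade_size = NA_integer_,
    evidence = NA_character_, donor_class = NA_character_,
    direction = NA_character_, event_id = NA_character_,
    shared_second = NA,
    chk_indels = NA, chk_residues = NA, chk_structure = NA,
    chk_alignment = NA, chk_contamination = NA,
    stringsAsFactors = FALSE)
  inTable <- geneIds %in% hits(x)$query_id
  for (i in seq_len(n)) {
    g <- geneIds[i]
    pat <- if (inTable[i]) phyleticPattern(x, g) else "NO_HOMOLOGY"
    rec$phyletic_pattern[i] <- pat
    tr <- trees[[g]]
    res <- NULL
    if (!is.null(tr)) {
      res <- cladeTest(tr, donorGroups = donorGroups,
                       minSupport = minSupport,
                       allowOtherEuk = allowOtherEuk)
      rec$tree_passed[i] <- res@passed
      rec$tree_support[i] <- res@support
      rec$clade_size[i] <- length(res@cladeLeaves)
    }
    restricted <- pat %in% c("PROK_ONLY", "ALGA_ONLY", "PROK_ALGA_ONLY")
    treeOk <- !is.null(res) && res@passed
    if (pat == "NO_HOMOLOGY" && !treeOk) {
      rec$status[i] <- "NO_CALL"
      next
    }
    if (treeOk || restricted) {
      rec$status[i] <- "ACCEPTED"
      rec$evidence[i] <- paste(c(if (treeOk) "tree",
                                 if (restricted) "pattern"),
                               collapse = "+")
      tops <- if (inTable[i]) topHitPerGroup(x, g) else NULL
      rec$donor_class[i] <- classifyDonor(
        treeResult = res, pattern = if (restricted) pat else NULL,
        tops = tops, margin = donorMargin)
      rec$direction[i] <- inferDirection(pat, treeOk)
    } else {
      rec$status[i] <- "REJECTED"
      rec$direction[i] <- inferDirection(pat, FALSE)
    }
  }
  new("CurationLedger", records = rec)
}

#' Attach detector verdicts to a ledger
#'
#' Adds one \code{det_<name>} column per detector with the tri-state flag for
#' each gene (\code{not_run} where the detector has no verdict), enabling
#' consensus accounting from the ledger alone.
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param v a \linkS4class{DetectorVerdicts}.
#' @return the updated \linkS4class{CurationLedger}.
#' @export
attachVerdicts <- function(ledger, v) {
  rec <- ledger@records
  vv <- verdicts(v)
  for (d in unique(vv$detector)) {
    sub <- vv[vv$detector == d, , drop = FALSE]
    col <- paste0("det_", d)
    rec[[col]] <- sub$flag[match(rec$gene_id, sub$query_id)]
    rec[[col]][is.na(rec[[col]])] <- "not_run"
  }
  new("CurationLedger", records = rec)
}

## cluster focal leaves of a tree into maximal pure-focal clades (unrooted);
## returns a named integer vector: focal leaf label -> cluster index
.focalClusters <- function(phy, focal) {
  tl <- phy$tip.label
  ftips <- which(tl %in% focal)
  nonf <- setdiff(seq_along(tl), ftips)
  if (!length(ftips)) return(stats::setNames(integer(0), character(0)))
  if (!length(nonf)) return(stats::setNames(rep(1L, length(ftips)), tl[ftips]))
  ## root at a non-focal leaf so rooted clades == unrooted splits without it
  phy <- ape::root(phy, outgroup = tl[nonf[1]], resolve.root = TRUE)
  tl <- phy$tip.label
  nt <- length(tl)
  isFocal <- tl %in% focal
  sets <- .tipSets(phy)
  pure <- logical(nt + phy$Nnode)
  pure[seq_len(nt)] <- isFocal
  for (v in seq(nt + 1L, nt + phy$Nnode)) pure[v] <- all(isFocal[sets[[v]]])
  parent <- integer(nt + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  heads <- integer(0)
  cluster <- stats::setNames(integer(sum(isFocal)), tl[isFocal])
  for (t in which(isFocal)) {
    h <- t
    while (parent[h] != 0L && pure[parent[h]]) h <- parent[h]
    k <- match(h, heads)
    if (is.na(k)) {
      heads <- c(heads, h)
      k <- length(heads)
    }
    cluster[tl[t]] <- k
  }
  cluster
}

#' Collapse accepted genes into transfer events
#'
#' Gene duplication after a transfer leaves several focal paralogs descending
#' from one acquisition, so accepted genes of one family that form a single
#' focal clade in the family tree (no donor or other non-focal leaf inside)
#' count as one event; focal leaves separated by non-focal leaves yield
#' separate events, and genes of different families are never merged. All
#' focal-genome leaves participate in the clustering, but only clusters
#' containing accepted genes become events. Singleton families without a tree
#' are one event each. The result is invariant under re-rooting and child
#' permutation of the family trees. An accepted gene missing from its family
#' tree is recorded in \code{attr(, "errors")} (and assigned its own event).
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param trees named list of family trees (\linkS4class{GeneTree} or
#'   \code{phylo}), keyed by family id.
#' @param familyMap named character vector gene id -> family id; unmapped
#'   genes are singleton families.
#' @return an \linkS4class{EventClusters}; the ledger's \code{event_id} can be
#'   filled from it via \code{\link{assignEvents}}.
#' @export
collapseEvents <- function(ledger, trees = list(), familyMap = NULL) {
  rec <- ledger@records
  acc <- rec$gene_id[rec$status == "ACCEPTED"]
  familyMap <- familyMap %||% stats::setNames(character(0), character(0))
  fam <- familyMap[acc]
  fam[is.na(fam)] <- acc[is.na(fam)]
  allGenes <- union(names(familyMap), rec$gene_id)
  errors <- data.frame(gene_id = character(0), reason = character(0),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (f in unique(fam)) {
    members <- acc[fam == f]
    tr <- trees[[f]]
    if (is.null(tr) || length(members) == 0) {
      for (k in seq_along(members)) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = sprintf("%s.e%d", f, k), gene_id = members[k],
          stringsAsFactors = FALSE)
      }
      next
    }
    phy <- if (is(tr, "GeneTree")) tr@tree else tr
    missing <- setdiff(members, phy$tip.label)
    if (length(missing)) {
      errors <- rbind(errors, data.frame(
        gene_id = missing,
        reason = rep(sprintf("absent from family tree '%s'", f),
                     length(missing))))
      for (m in missing) {
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = sprintf("%s.missing.%s", f, m), gene_id = m,
          stringsAsFactors = FALSE)
      }
      members <- setdiff(members, missing)
      if (!length(members)) next
    }
    focal <- intersect(phy$tip.label, allGenes)
    cl <- .focalClusters(phy, focal)
    memberCl <- cl[members]
    ids <- sort(unique(memberCl))
    for (k in seq_along(ids)) {
      gs <- members[memberCl == ids[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = rep(sprintf("%s.e%d", f, k), length(gs)), gene_id = gs,
        stringsAsFactors = FALSE)
    }
  }
  cl <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(event_id = character(0), gene_id = character(0),
               stringsAsFactors = FALSE)
  }
  donor <- rec$donor_class[match(cl$gene_id, rec$gene_id)]
  evDonor <- vapply(split(donor, cl$event_id), function(d) {
    u <- unique(d[!is.na(d)])
    if (length(u) == 1) u else "EITHER"
  }, character(1))
  cl$donor_class <- unname(evDonor[cl$event_id])
  rownames(cl) <- NULL
  if (nrow(errors)) {
    warning(nrow(errors), " accepted gene(s) missing from family trees")
  }
  out <- new("EventClusters", clusters = cl)
  attr(out, "errors") <- errors
  out
}

#' Fill a ledger's event ids from collapsed events
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param events an \linkS4class{EventClusters}.
#' @return the updated \linkS4class{CurationLedger}.
#' @export
assignEvents <- function(ledger, events) {
  rec <- ledger@records
  cl <- clusters(events)
  rec$event_id <- cl$event_id[match(rec$gene_id, cl$gene_id)]
  new("CurationLedger", records = rec)
}

#' Homolog sharing with a second proteome
#'
#' Flags each gene as shared when its best hit against the second (sister
#' species) proteome has E-value at or below the cutoff (default 1e-40).
#' Sharing is read as acquisition before the split of the two species; absence
#' as post-split acquisition or loss in the sister.
#'
#' @param geneIds genes to flag.
#' @param secondHits hits of the genes against the second proteome: a
#'   \linkS4class{HitTable} or a data.frame with columns \code{query_id} and
#'   \code{evalue}.
#' @param evalueMax sharing cutoff (default \code{1e-40}).
#' @return named logical vector over \code{geneIds}.
#' @export
homologSharing <- function(geneIds, secondHits, evalueMax = 1e-40) {
  h <- if (is(secondHits, "HitTable")) hits(secondHits) else secondHits
  best <- vapply(geneIds, function(g) {
    e <- h$evalue[h$query_id == g]
    if (length(e)) min(e) else Inf
  }, numeric(1))
  stats::setNames(best <= evalueMax, geneIds)
}

#' Attach homolog-sharing flags to a ledger
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param shared named logical vector from \code{\link{homologSharing}}.
#' @return the updated \linkS4class{CurationLedger}.
#' @export
assignSharing <- function(ledger, shared) {
  rec <- ledger@records
  rec$shared_second <- unname(shared[rec$gene_id])
  new("CurationLedger", records = rec)
}

#' Detector-overlap accounting against the curated set
#'
#' For each detector: how many of its candidates survived curation (the
#' positive rate, accepted-and-predicted over predicted, \code{NA} when the
#' detector predicted nothing), and how many curated genes it missed (the
#' false-negative rate, one minus accepted-and-predicted over accepted). Also
#' reports the number of curated genes predicted by no detector at all.
#'
#' @param v a \linkS4class{DetectorVerdicts} covering all detectors.
#' @param ledger the final \linkS4class{CurationLedger}.
#' @return a list with \code{perDetector} (data.frame: detector, predicted,
#'   predicted_accepted, positive_rate, false_negative_rate),
#'   \code{acceptedTotal}, \code{unionPredictedAccepted} and
#'   \code{missedByAll}.
#' @export
consensusAccounting <- function(v, ledger) {
  vv <- verdicts(v)
  rec <- ledger@records
  acc <- rec$gene_id[rec$status == "ACCEPTED"]
  dets <- unique(vv$detector)
  per <- do.call(rbind, lapply(dets, function(d) {
    pred <- vv$query_id[vv$detector == d & vv$flag == "predicted"]
    pa <- length(intersect(pred, acc))
    data.frame(
      detector = d, predicted = length(pred), predicted_accepted = pa,
      positive_rate = if (length(pred)) pa / length(pred) else NA_real_,
      false_negative_rate = if (length(acc)) 1 - pa / length(acc)
                            else NA_real_,
      stringsAsFactors = FALSE)
  }))
  unionPred <- unique(vv$query_id[vv$flag == "predicted"])
  list(perDetector = per,
       acceptedTotal = length(acc),
       unionPredictedAccepted = length(intersect(unionPred, acc)),
       missedByAll = length(setdiff(acc, unionPred)))
}

#' Scaffold-neighbor contamination heuristic
#'
#' A curated gene sitting on a scaffold whose neighboring genes all lack kin
#' (metazoan/fungal) affiliation cannot be cleared of being assembly
#' contamination by its genomic context. Given a gene-order table, this
#' helper flags accepted genes whose adjacent genes (both sides, or the single
#' neighbor at a scaffold end) are all non-kin-affiliated. It is an aid for
#' the manual checklist, not an automatic rejection.
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param geneOrder data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{position} (numeric order on the scaffold) and
#'   \code{kin_affiliated} (logical: does the gene have metazoan/fungal
#'   homologs).
#' @return named logical vector over accepted genes present in
#'   \code{geneOrder}: \code{TRUE} means the contamination check fails to
#'   clear the gene.
#' @export
flagContamination <- function(ledger, geneOrder) {
  stopifnot(all(c("gene_id", "scaffold", "position", "kin_affiliated") %in%
                names(geneOrder)))
  rec <- ledger@records
  acc <- rec$gene_id[rec$status == "ACCEPTED"]
  acc <- intersect(acc, geneOrder$gene_id)
  out <- stats::setNames(logical(length(acc)), acc)
  for (g in acc) {
    i <- match(g, geneOrder$gene_id)
    sc <- geneOrder[geneOrder$scaffold == geneOrder$scaffold[i], , drop = FALSE]
    sc <- sc[order(sc$position), , drop = FALSE]
    j <- match(g, sc$gene_id)
    nb <- sc$kin_affiliated[c(j - 1, j + 1)]
    nb <- nb[!is.na(nb)]
    out[g] <- length(nb) > 0 && !any(nb)
  }
  out
}
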