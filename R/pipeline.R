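## end-to-end convenience: filter -> screen -> tree scan -> curate -> events

#' Run the full detection and curation pipeline on a simulation
#'
#' Chains the stages on a simulated genome: hit filtering with the standard
#' exclusions, alien-index screening, batch tree screening at the screening
#' support threshold, curation at the curation threshold, detector
#' attachment, event collapsing, and sister-proteome homolog sharing.
#'
#' @param sim an \code{HgtSimulation} from \code{\link{simulateGenome}}.
#' @param aiThreshold alien-index candidate threshold (default 1.2).
#' @param screenSupport bootstrap threshold for batch tree screening
#'   (default 50).
#' @param curationSupport bootstrap threshold for curation (default 70).
#' @param allowOtherEuk clade policy, as in \code{\link{cladeTest}}.
#' @return a list: \code{hits} (filtered \linkS4class{HitTable}),
#'   \code{verdicts} (\linkS4class{DetectorVerdicts} of both detectors),
#'   \code{ledger} (\linkS4class{CurationLedger} with verdicts, events and
#'   sharing attached), \code{events} (\linkS4class{EventClusters}).
#' @seealso \code{\link{classificationRates}}
#' @export
runPipeline <- function(sim, aiThreshold = 1.2, screenSupport = 50,
                        curationSupport = 70, allowOtherEuk = TRUE) {
  ft <- filterHits(sim$hits)
  genes <- sim$truth$gene_id
  geneTrees <- stats::setNames(lapply(genes, geneTreeFor, sim = sim), genes)
  vAI <- screenGenome(ft, queryIds = genes, threshold = aiThreshold)
  vTree <- batchScreen(geneTrees, minSupport = screenSupport,
                       allowOtherEuk = allowOtherEuk)
  v <- mergeVerdicts(vAI, vTree, queryIds = genes)
  ledger <- curateGenes(ft, trees = geneTrees, geneIds = genes,
                        minSupport = curationSupport,
                        allowOtherEuk = allowOtherEuk)
  ledger <- attachVerdicts(ledger, v)
  ev <- collapseEvents(ledger, trees = sim$trees, familyMap = sim$familyMap)
  ledger <- assignEvents(ledger, ev)
  ledger <- assignSharing(ledger, homologSharing(genes, sim$secondHits))
  list(hits = ft, verdicts = v, ledger = ledger, events = ev)
}

#' Sensitivity and specificity of pipeline calls against truth
#'
#' Compares the accepted set of a pipeline run with a simulation's planted
#' transfers.
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param truth the simulation truth data.frame.
#' @return named numeric vector: \code{sensitivity} (accepted fraction of
#'   planted transfers) and \code{specificity} (rejected fraction of vertical
#'   genes).
#' @export
classificationRates <- function(ledger, truth) {
  rec <- records(ledger)
  acc <- rec$gene_id[rec$status == "ACCEPTED"]
  pos <- truth$gene_id[truth$is_hgt]
  neg <- truth$gene_id[!truth$is_hgt]
  c(sensitivity = if (length(pos)) length(intersect(acc, pos)) / length(pos)
                  else NA_real_,
    specificity = if (length(neg)) 1 - length(intersect(acc, neg)) / length(neg)
                  else NA_real_)
}
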