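## report module: headline statistics of a curation ledger

#' Synthetic reference ledger matching the curated Monosiga survey margins
#'
#' A packaged, fully synthetic 405-gene curation ledger whose marginal counts
#' reproduce the published survey of acquired genes in the *Monosiga
#' brevicollis* genome: 240 algal, 139 bacterial and 26 ambiguous-donor genes
#' collapsing to 210/100/20 events; per-detector totals of 358 (AlienG-style),
#' 345 (DarkHorse) and 204 (PhyloGenie) among the 388 genes predicted by at
#' least one program, leaving 17 genes missed by all; 213 genes shared with
#' the sister species *S. rosetta* and 192 not; and 193 functionally
#' categorized genes (62 carbohydrate metabolism, 22 amino acid metabolism,
#' 12 protein degradation, 10 lipid metabolism, 45 transporter/stress, 42
#' other) beside 89 genes with known domains only and 123 fully unknown.
#' Only these marginal totals are meaningful; the joint assignment of flags
#' to individual rows (including one consistent three-way detector overlap)
#' is an arbitrary deterministic construction, and gene ids are synthetic.
#'
#' @return a list: \code{ledger} (a \linkS4class{CurationLedger}),
#'   \code{categories} (data.frame \code{gene_id}, \code{category}), and
#'   \code{genomeTotal} (9200, the focal proteome size).
#' @seealso \code{\link{summarizeLedger}}
#' @export
referenceLedger <- function() {
  n <- 405L
  ids <- sprintf("MBRE%04d", seq_len(n))
  donor <- rep(c("ALGA", "BACTERIA", "EITHER"), c(240L, 139L, 26L))
  ## one consistent three-way overlap with the published marginals
  ## (A = AlienG-style 358, D = DarkHorse 345, P = PhyloGenie 204, union 388)
  reg <- rep(c("ADP", "AD", "AP", "DP", "A", "D", "P", "none"),
             c(190L, 130L, 5L, 4L, 33L, 21L, 5L, 17L))
  flagOf <- function(letter) {
    ifelse(grepl(letter, reg, fixed = TRUE), "predicted", "not_predicted")
  }
  ## events: paralogous genes collapse so that 240/139/26 genes give
  ## 210/100/20 events per donor class
  eventWithin <- function(m, e) {
    c(seq_len(e), seq_len(m - e))  # last m-e genes join the first families
  }
  event_id <- c(sprintf("alga.e%03d", eventWithin(240L, 210L)),
                sprintf("bact.e%03d", eventWithin(139L, 100L)),
                sprintf("either.e%03d", eventWithin(26L, 20L)))
  rec <- data.frame(
    gene_id = ids, status = "ACCEPTED", phyletic_pattern = "BROAD",
    tree_passed = TRUE, tree_support = 85, clade_size = NA_integer_,
    evidence = "tree", donor_class = donor, direction = "INTO_FOCAL",
    event_id = event_id,
    shared_second = seq_len(n) <= 213L,
    chk_indels = NA, chk_residues = NA, chk_structure = NA,
    chk_alignment = NA, chk_contamination = NA,
    det_alieng = flagOf("A"), det_darkhorse = flagOf("D"),
    det_phylogenie = flagOf("P"),
    stringsAsFactors = FALSE)
  categories <- data.frame(
    gene_id = ids,
    category = rep(c("carbohydrate_metabolism", "amino_acid_metabolism",
                     "protein_degradation", "lipid_metabolism",
                     "transporter_stress", "other_function",
                     "domain_only", "unknown"),
                   c(62L, 22L, 12L, 10L, 45L, 42L, 89L, 123L)),
    stringsAsFactors = FALSE)
  list(ledger = new("CurationLedger", records = rec),
       categories = categories, genomeTotal = 9200L)
}

#' Summarize a curation ledger
#'
#' Computes the headline statistics of a curated gene set: the genome
#' fraction of acquired genes, donor-class and event counts, per-detector
#' overlap with the curated set (as percentages of the genes predicted by at
#' least one detector, plus false-negative rates against the accepted total),
#' the number of curated genes missed by every detector, the
#' sister-species sharing split, and functional-category counts with
#' percentages over the categorized subset only (genes labelled
#' \code{unknown} or \code{domain_only} are reported as separate buckets and
#' excluded from the category denominator). All percentages are rounded
#' half-up to one decimal. The function is pure: the same ledger always gives
#' the same report.
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param genomeTotal genes in the focal genome; must be at least the
#'   accepted count.
#' @param categories optional data.frame (\code{gene_id}, \code{category});
#'   multiple rows per gene are allowed for overlapping category schemes, in
#'   which case \code{exclusive} should be \code{FALSE}.
#' @param exclusive is the category scheme a partition (one category per
#'   gene)? Recorded on the report; percentage-sum checks only hold for
#'   exclusive schemes.
#' @return a \linkS4class{SummaryReport}.
#' @export
summarizeLedger <- function(ledger, genomeTotal, categories = NULL,
                            exclusive = TRUE) {
  rec <- records(ledger)
  acc <- rec[rec$status == "ACCEPTED", , drop = FALSE]
  nAcc <- nrow(acc)
  if (genomeTotal < nAcc) {
    stop("genomeTotal (", genomeTotal, ") is less than the accepted count (",
         nAcc, ")")
  }
  stats <- list(
    accepted_total = nAcc,
    genome_total = as.numeric(genomeTotal),
    genome_fraction = if (genomeTotal > 0) {
      roundHalfUp(100 * nAcc / genomeTotal, 1)
    } else 0,
    donor_counts = list(
      ALGA = sum(acc$donor_class == "ALGA"),
      BACTERIA = sum(acc$donor_class == "BACTERIA"),
      EITHER = sum(acc$donor_class == "EITHER")))
  if ("event_id" %in% names(acc) && any(!is.na(acc$event_id))) {
    ev <- acc[!is.na(acc$event_id), , drop = FALSE]
    cnt <- function(cl) length(unique(ev$event_id[ev$donor_class == cl]))
    stats$event_counts <- list(ALGA = cnt("ALGA"), BACTERIA = cnt("BACTERIA"),
                               EITHER = cnt("EITHER"),
                               total = length(unique(ev$event_id)))
  }
  detCols <- grep("^det_", names(acc), value = TRUE)
  if (length(detCols)) {
    pred <- acc[detCols] == "predicted"
    nUnion <- sum(apply(pred, 1, any))
    stats$detector_overlap <- data.frame(
      detector = sub("^det_", "", detCols),
      predicted_accepted = as.numeric(colSums(pred)),
      pct_of_union = if (nUnion > 0) {
        roundHalfUp(100 * colSums(pred) / nUnion, 1)
      } else rep(NA_real_, length(detCols)),
      fnr_pct = if (nAcc > 0) {
        roundHalfUp(100 * (nAcc - colSums(pred)) / nAcc, 1)
      } else rep(NA_real_, length(detCols)),
      stringsAsFactors = FALSE, row.names = NULL)
    stats$union_predicted_accepted = as.numeric(nUnion)
    stats$missed_by_all = as.numeric(nAcc - nUnion)
  }
  if ("shared_second" %in% names(acc)) {
    sh <- sum(acc$shared_second %in% TRUE)
    stats$shared_second <- as.numeric(sh)
    stats$not_shared_second <- as.numeric(nAcc - sh)
  }
  if (!is.null(categories)) {
    cat <- categories[categories$gene_id %in% acc$gene_id, , drop = FALSE]
    uncat <- c("unknown", "domain_only")
    stats$n_domain_only <- as.numeric(
      length(unique(cat$gene_id[cat$category == "domain_only"])))
    stats$n_unknown <- as.numeric(
      length(unique(cat$gene_id[cat$category == "unknown"])))
    cc <- cat[!(cat$category %in% uncat), , drop = FALSE]
    nCat <- length(unique(cc$gene_id))
    stats$n_categorized <- as.numeric(nCat)
    if (nCat > 0) {
      tab <- table(cc$category)
      stats$category_table <- data.frame(
        category = names(tab), n = as.numeric(tab),
        pct = roundHalfUp(100 * as.numeric(tab) / nCat, 1),
        stringsAsFactors = FALSE, row.names = NULL)
    } else {
      stats$category_table <- data.frame(category = character(0),
                                         n = numeric(0), pct = numeric(0),
                                         stringsAsFactors = FALSE)
    }
    stats$category_partition_exclusive <- isTRUE(exclusive)
  }
  new("SummaryReport", stats = stats)
}

.flattenStats <- function(stats) {
  rows <- list()
  add <- function(section, key, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      section = section, key = key, value = as.character(value),
      stringsAsFactors = FALSE)
  }
  for (nm in names(stats)) {
    v <- stats[[nm]]
    if (is.data.frame(v)) {
      for (i in seq_len(nrow(v))) {
        for (col in names(v)[-1]) {
          add(nm, paste(v[[1]][i], col, sep = "."),
              format(v[[col]][i], digits = 15))
        }
      }
    } else if (is.list(v)) {
      for (k in names(v)) add(nm, k, format(v[[k]], digits = 15))
    } else {
      add("scalar", nm, if (is.numeric(v)) format(v, digits = 15) else v)
    }
  }
  do.call(rbind, rows)
}

#' Render a summary report
#'
#' \code{json} and \code{tsv} are lossless: \code{readReport} reconstructs an
#' equal report. \code{text} is a stable human-readable layout.
#'
#' @param report a \linkS4class{SummaryReport}.
#' @param format one of \code{"json"}, \code{"tsv"}, \code{"text"}.
#' @param path output file; for \code{text}, \code{NULL} prints to the
#'   console.
#' @return \code{path} (or the text lines for \code{format = "text"} with
#'   \code{path = NULL}), invisibly.
#' @export
renderReport <- function(report, format = c("json", "tsv", "text"),
                         path = NULL) {
  format <- match.arg(format)
  s <- reportStats(report)
  if (format == "json") {
    stopifnot(!is.null(path))
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
    return(invisible(path))
  }
  if (format == "tsv") {
    stopifnot(!is.null(path))
    utils::write.table(.flattenStats(s), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  lines <- c(
    sprintf("Acquired genes: %d of %d (%s%% of the genome)",
            s$accepted_total, as.integer(s$genome_total),
            format(s$genome_fraction, nsmall = 1)),
    sprintf("Donors: %d algal, %d bacterial, %d either",
            s$donor_counts$ALGA, s$donor_counts$BACTERIA,
            s$donor_counts$EITHER))
  if (!is.null(s$event_counts)) {
    lines <- c(lines, sprintf(
      "Events: %d from algae, %d from bacteria, %d from either (%d total)",
      s$event_counts$ALGA, s$event_counts$BACTERIA, s$event_counts$EITHER,
      s$event_counts$total))
  }
  if (!is.null(s$detector_overlap)) {
    d <- s$detector_overlap
    lines <- c(lines,
               sprintf("Predicted by >=1 detector: %d; missed by all: %d",
                       as.integer(s$union_predicted_accepted),
                       as.integer(s$missed_by_all)),
               sprintf("  %s: %d (%s%%)", d$detector,
                       as.integer(d$predicted_accepted),
                       format(d$pct_of_union, nsmall = 1)))
  }
  if (!is.null(s$shared_second)) {
    lines <- c(lines, sprintf(
      "Shared with the sister species: %d; not shared: %d",
      as.integer(s$shared_second), as.integer(s$not_shared_second)))
  }
  if (!is.null(s$category_table) && nrow(s$category_table)) {
    ct <- s$category_table
    lines <- c(lines,
               sprintf("Categorized genes: %d", as.integer(s$n_categorized)),
               sprintf("  %s: %d (%s%%)", ct$category, as.integer(ct$n),
                       format(ct$pct, nsmall = 1)))
  }
  if (is.null(path)) {
    cat(lines, sep = "\n")
    return(invisible(lines))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a rendered summary report back
#'
#' @param path file written by \code{\link{renderReport}}.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return a \linkS4class{SummaryReport} equal (up to numeric representation)
#'   to the one rendered.
#' @export
readReport <- function(path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    for (nm in c("detector_overlap", "category_table")) {
      if (!is.null(s[[nm]])) s[[nm]] <- as.data.frame(s[[nm]])
    }
    return(new("SummaryReport", stats = s))
  }
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  s <- list()
  num <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_len(nrow(tab))) {
    sec <- tab$section[i]; key <- tab$key[i]; val <- tab$value[i]
    if (sec == "scalar") {
      s[[key]] <- if (key == "category_partition_exclusive") {
        as.logical(val)
      } else if (is.na(num(val))) val else num(val)
    } else if (sec %in% c("donor_counts", "event_counts")) {
      s[[sec]][[key]] <- num(val)
    } else {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      id <- paste(parts[-length(parts)], collapse = ".")
      col <- parts[length(parts)]
      s[[sec]][[id]][[col]] <- val
    }
  }
  for (nm in c("detector_overlap", "category_table")) {
    if (!is.null(s[[nm]])) {
      ids <- names(s[[nm]])
      cols <- names(s[[nm]][[1]])
      df <- data.frame(ids, stringsAsFactors = FALSE)
      names(df) <- if (nm == "detector_overlap") "detector" else "category"
      for (col in cols) {
        vals <- vapply(s[[nm]], function(r) r[[col]], character(1))
        df[[col]] <- if (all(!is.na(num(vals)))) num(vals) else vals
      }
      rownames(df) <- NULL
      s[[nm]] <- df
    }
  }
  new("SummaryReport", stats = s)
}
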