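## blast_tab module: reading, labelling and filtering tabular homology hits

.HIT_COLUMNS <- c("qseqid", "sseqid", "bitscore", "evalue", "coverage",
                  "staxon", "stitle")

.labelHits <- function(df, scheme) {
  i <- match(df$subject_taxon, scheme@assignments$taxon)
  df$group <- scheme@assignments$group[i]
  df
}

.newHitTable <- function(df, filters = character(0), errors = NULL) {
  rownames(df) <- NULL
  obj <- new("HitTable", hits = df, filters = filters)
  attr(obj, "errors") <- errors %||%
    data.frame(line = integer(0), reason = character(0))
  obj
}

#' Construct a HitTable from an in-memory data.frame
#'
#' Validates per-hit invariants (finite non-negative bitscore, non-negative
#' E-value, coverage a fraction in [0, 1]), drops offending rows with a
#' warning, labels every hit with its subject's analysis group (rows whose
#' taxon is absent from the scheme are dropped and logged), and returns an
#' unfiltered \linkS4class{HitTable}.
#'
#' @param df data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{bitscore}, \code{evalue}, \code{coverage}, \code{subject_taxon},
#'   \code{subject_annotation}.
#' @param scheme a \linkS4class{TaxonomyScheme}.
#' @return a \linkS4class{HitTable}; dropped rows are recorded in
#'   \code{attr(, "errors")}.
#' @export
hitTable <- function(df, scheme) {
  need <- c("query_id", "subject_id", "bitscore", "evalue", "coverage",
            "subject_taxon", "subject_annotation")
  if (!all(need %in% names(df))) {
    stop("hit data.frame needs columns ", paste(need, collapse = ", "))
  }
  df <- df[need]
  for (col in c("bitscore", "evalue", "coverage")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  reasons <- rep(NA_character_, nrow(df))
  reasons[!is.finite(df$bitscore) | df$bitscore < 0] <- "invalid bitscore"
  reasons[is.na(df$evalue) | df$evalue < 0] <- "invalid evalue"
  reasons[is.na(df$coverage) | df$coverage < 0 | df$coverage > 1] <-
    "coverage outside [0, 1]"
  known <- df$subject_taxon %in% scheme@assignments$taxon
  reasons[is.na(reasons) & !known] <- "unknown taxon"
  bad <- !is.na(reasons)
  errors <- data.frame(line = which(bad), reason = reasons[bad],
                       stringsAsFactors = FALSE)
  if (any(bad)) {
    warning(sum(bad), " hit row(s) dropped: ",
            paste(unique(reasons[bad]), collapse = "; "))
    df <- df[!bad, , drop = FALSE]
  }
  .newHitTable(.labelHits(df, scheme), errors = errors)
}

#' Parse a tabular homology hit file
#'
#' Reads a BLAST outfmt-6-style TSV extended with subject-taxon and
#' subject-title columns. The column order is configurable through
#' \code{columns}, which must name at least \code{qseqid}, \code{sseqid},
#' \code{bitscore}, \code{evalue}, \code{coverage}, \code{staxon} and
#' \code{stitle} (coverage is the aligned fraction of the query length, in
#' [0, 1]). Lines starting with \code{#} are skipped. Malformed rows and rows
#' violating hit invariants are dropped with their line numbers recorded in
#' \code{attr(, "errors")}; an empty file yields an empty table with a
#' warning. No filtering is applied at parse time, so valid row counts are
#' preserved.
#'
#' @param path TSV file, no header.
#' @param scheme a \linkS4class{TaxonomyScheme} used to label subjects.
#' @param columns character vector naming the file's columns in order.
#' @return a \linkS4class{HitTable}.
#' @seealso \code{\link{filterHits}}, \code{\link{writeHits}}
#' @export
parseHits <- function(path, scheme, columns = .HIT_COLUMNS) {
  need <- .HIT_COLUMNS
  if (!all(need %in% columns)) {
    stop("'columns' must include ", paste(need, collapse = ", "))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty hit file: ", path)
    empty <- data.frame(query_id = character(0), subject_id = character(0),
                        bitscore = numeric(0), evalue = numeric(0),
                        coverage = numeric(0), subject_taxon = character(0),
                        subject_annotation = character(0),
                        stringsAsFactors = FALSE)
    return(.newHitTable(.labelHits(empty, scheme)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == length(columns)
  errors <- data.frame(line = lineNo[!ok],
                       reason = rep("wrong field count", sum(!ok)),
                       stringsAsFactors = FALSE)
  if (any(!ok)) {
    warning(sum(!ok), " malformed row(s) skipped in ", path)
  }
  mat <- do.call(rbind, parts[ok])
  colnames(mat) <- columns
  df <- data.frame(
    query_id = mat[, "qseqid"], subject_id = mat[, "sseqid"],
    bitscore = mat[, "bitscore"], evalue = mat[, "evalue"],
    coverage = mat[, "coverage"], subject_taxon = mat[, "staxon"],
    subject_annotation = mat[, "stitle"], stringsAsFactors = FALSE)
  tab <- withCallingHandlers(
    hitTable(df, scheme),
    warning = function(w) invokeRestart("muffleWarning"))
  moreErr <- attr(tab, "errors")
  moreErr$line <- lineNo[ok][moreErr$line]
  allErr <- rbind(errors, moreErr)
  if (nrow(moreErr)) {
    warning(nrow(moreErr), " row(s) dropped while validating ", path, ": ",
            paste(unique(moreErr$reason), collapse = "; "))
  }
  attr(tab, "errors") <- allErr
  tab
}

#' Filter a hit table with the standard exclusion rules
#'
#' Applies, in a single stable pass (relative hit order is preserved and the
#' rules commute), the exclusions used before alien-index screening: an
#' E-value ceiling, a minimum query-length coverage (default 10%), removal of
#' hits whose annotation matches any pattern on the artificial-sequence list
#' (case-insensitive substring match, since annotation strings in the wild
#' vary in case), and removal of whole groups (default \code{SELF}, i.e. hits
#' back to the focal lineage). Applied filters are appended to the table's
#' provenance.
#'
#' @param x a \linkS4class{HitTable}.
#' @param evalueMax maximum E-value retained (default \code{1e-5}).
#' @param minCoverage minimum query coverage fraction retained (default 0.10).
#' @param excludeAnnotations character patterns; a hit is removed when its
#'   annotation contains any of them (default: artificial sequence, synthetic
#'   construct, plasmid).
#' @param excludeGroups analysis groups removed wholesale (default
#'   \code{"SELF"}).
#' @param ... unused.
#' @return the filtered \linkS4class{HitTable}; an empty result is valid.
#' @rdname filterHits
#' @export
setMethod("filterHits", "HitTable", function(x,
    evalueMax = 1e-5, minCoverage = 0.10,
    excludeAnnotations = c("artificial sequence", "synthetic construct",
                           "plasmid"),
    excludeGroups = "SELF", ...) {
  stopifnot(evalueMax >= 0, minCoverage >= 0)
  h <- x@hits
  keep <- rep(TRUE, nrow(h))
  keep <- keep & h$evalue <= evalueMax
  keep <- keep & h$coverage >= minCoverage
  if (length(excludeAnnotations)) {
    ann <- tolower(h$subject_annotation)
    for (pat in tolower(excludeAnnotations)) {
      keep <- keep & !grepl(pat, ann, fixed = TRUE)
    }
  }
  if (length(excludeGroups)) keep <- keep & !(h$group %in% excludeGroups)
  prov <- c(x@filters, sprintf(
    "evalue<=%g; coverage>=%g; annotations!~{%s}; groups-!{%s}",
    evalueMax, minCoverage, paste(excludeAnnotations, collapse = ","),
    paste(excludeGroups, collapse = ",")))
  .newHitTable(h[keep, , drop = FALSE], filters = prov)
})

#' Read filter settings from a YAML config
#'
#' Convenience reader for a YAML file with any of the keys \code{evalue_max},
#' \code{min_coverage}, \code{exclude_annotations}, \code{exclude_groups};
#' missing keys fall back to the \code{\link{filterHits}} defaults.
#'
#' @param path YAML file.
#' @return a named list suitable for \code{do.call(filterHits, c(list(x), cfg))}.
#' @export
readFilterConfig <- function(path) {
  y <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(y$evalue_max)) out$evalueMax <- as.numeric(y$evalue_max)
  if (!is.null(y$min_coverage)) out$minCoverage <- as.numeric(y$min_coverage)
  if (!is.null(y$exclude_annotations)) {
    out$excludeAnnotations <- as.character(unlist(y$exclude_annotations))
  }
  if (!is.null(y$exclude_groups)) {
    out$excludeGroups <- as.character(unlist(y$exclude_groups))
  }
  out
}

#' Best hit per analysis group for one query
#'
#' For every group with at least one hit to \code{query}, returns the hit with
#' the maximal bitscore; ties are broken by lower E-value, then by
#' lexicographic subject id. Groups without hits are absent from the result.
#'
#' @param x a \linkS4class{HitTable}.
#' @param query a query id present in the table (absence is an error).
#' @return data.frame with one row per represented group.
#' @rdname topHitPerGroup
#' @export
setMethod("topHitPerGroup", "HitTable", function(x, query) {
  h <- x@hits[x@hits$query_id == query, , drop = FALSE]
  if (!nrow(h)) stop("query not present in hit table: ", query)
  picked <- lapply(split(seq_len(nrow(h)), h$group), function(idx) {
    hh <- h[idx, , drop = FALSE]
    hh[order(-hh$bitscore, hh$evalue, hh$subject_id)[1], , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
})

#' Write a hit table back to TSV
#'
#' Emits the outfmt-6-style columns with an audit header (comment lines)
#' listing the filters applied, so filtered tables are self-describing.
#'
#' @param x a \linkS4class{HitTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# HGTscan hit table; %d hits", nrow(x@hits)), con)
  for (f in x@filters) writeLines(paste("# filter:", f), con)
  h <- x@hits
  utils::write.table(
    data.frame(h$query_id, h$subject_id, h$bitscore, h$evalue, h$coverage,
               h$subject_taxon, h$subject_annotation),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
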