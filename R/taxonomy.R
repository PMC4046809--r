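## taxonomy module: lineage-prefix grouping of taxa into analysis groups

.splitLineage <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Default group definitions
#'
#' Lineage prefixes defining the five analysis groups for a choanoflagellate
#' focal genome. \code{SELF} is the choanoflagellates (so a second
#' choanoflagellate species counts as self: shared presence is read as
#' pre-divergence acquisition, not as evidence against transfer); \code{KIN}
#' covers metazoans and fungi; \code{PROKARYOTE} covers both bacteria and
#' archaea; \code{ALGA} is defined sensu lato: green plants, glaucophytes, red
#' algae, alveolates, cryptophytes, euglenids, haptophytes,
#' chlorarachniophytes and stramenopiles, plus oomycetes and ciliates (already
#' nested in stramenopiles/alveolates but listed explicitly). Any other
#' eukaryote falls through to \code{OTHER_EUK}.
#'
#' @return data.frame with columns \code{group}, \code{prefix}.
#' @export
defaultGroupDefs <- function() {
  data.frame(
    group = c(
      "SELF",
      "KIN", "KIN",
      "PROKARYOTE", "PROKARYOTE",
      rep("ALGA", 11),
      "OTHER_EUK"),
    prefix = c(
      "Eukaryota;Choanoflagellida",
      "Eukaryota;Metazoa", "Eukaryota;Fungi",
      "Bacteria", "Archaea",
      "Eukaryota;Viridiplantae", "Eukaryota;Glaucophyta",
      "Eukaryota;Rhodophyta", "Eukaryota;Alveolata",
      "Eukaryota;Cryptophyta", "Eukaryota;Euglenozoa;Euglenida",
      "Eukaryota;Haptophyta", "Eukaryota;Cercozoa;Chlorarachniophyta",
      "Eukaryota;Stramenopiles", "Eukaryota;Stramenopiles;Oomycetes",
      "Eukaryota;Alveolata;Ciliophora",
      "Eukaryota"),
    stringsAsFactors = FALSE)
}

.matchGroup <- function(lineage, defs) {
  parts <- .splitLineage(lineage)
  bestLen <- 0L
  bestGroup <- NA_character_
  for (i in seq_len(nrow(defs))) {
    p <- .splitLineage(defs$prefix[i])
    if (length(p) <= length(parts) && length(p) > bestLen &&
        identical(p, parts[seq_along(p)])) {
      bestLen <- length(p)
      bestGroup <- defs$group[i]
    }
  }
  bestGroup
}

#' Load a taxonomy scheme from a lineage table
#'
#' Reads a two-column TSV (\code{taxon}, \code{lineage}; the lineage is a
#' semicolon-delimited path from domain to leaf) and assigns every taxon to an
#' analysis group by longest-prefix match against the group definitions.
#' Longest-prefix matching is robust to ranks missing from some records.
#' Lineages rooted at Eukaryota that match no specific group fall back to
#' \code{OTHER_EUK}; rows whose domain cannot be resolved at all are dropped
#' with a warning (recorded in \code{attr(, "errors")}). A taxon listed twice
#' with conflicting lineages is an error.
#'
#' @param path TSV file with a header row naming columns \code{taxon} and
#'   \code{lineage}.
#' @param groupDefs data.frame of \code{group}/\code{prefix} rows; defaults to
#'   \code{\link{defaultGroupDefs}}.
#' @return a \linkS4class{TaxonomyScheme}.
#' @seealso \code{\link{defaultScheme}}, \code{\link{writeScheme}}
#' @examples
#' scheme <- defaultScheme()
#' groupOf(scheme, "Phytophthora")  # oomycete -> ALGA sensu lato
#' @export
loadScheme <- function(path, groupDefs = defaultGroupDefs()) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("taxon", "lineage") %in% names(tab))) {
    stop("scheme file needs columns 'taxon' and 'lineage'")
  }
  tab$taxon <- trimws(tab$taxon)
  tab$lineage <- trimws(tab$lineage)
  ## duplicates: identical rows collapse; conflicting lineages are fatal
  if (anyDuplicated(tab$taxon)) {
    for (t in unique(tab$taxon[duplicated(tab$taxon)])) {
      if (length(unique(tab$lineage[tab$taxon == t])) > 1) {
        stop("taxon '", t, "' listed with conflicting lineages")
      }
    }
    tab <- tab[!duplicated(tab$taxon), , drop = FALSE]
  }
  grp <- vapply(tab$lineage, .matchGroup, character(1), defs = groupDefs)
  bad <- is.na(grp)
  errors <- data.frame(taxon = tab$taxon[bad], lineage = tab$lineage[bad],
                       reason = rep("unresolvable domain", sum(bad)),
                       stringsAsFactors = FALSE)
  if (any(bad)) {
    warning(sum(bad), " taxa dropped (unresolvable domain): ",
            paste(utils::head(tab$taxon[bad], 5), collapse = ", "))
    tab <- tab[!bad, , drop = FALSE]
    grp <- grp[!bad]
  }
  assignments <- data.frame(
    taxon = tab$taxon, lineage = tab$lineage, group = unname(grp),
    domain = vapply(tab$lineage, function(l) .splitLineage(l)[1],
                    character(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  obj <- new("TaxonomyScheme",
             assignments = assignments, groupDefs = groupDefs,
             selfLineage = groupDefs$prefix[groupDefs$group == "SELF"][1],
             kinLineages = groupDefs$prefix[groupDefs$group == "KIN"],
             algalGroups = groupDefs$prefix[groupDefs$group == "ALGA"])
  attr(obj, "errors") <- errors
  obj
}

#' Build a scheme from an in-memory lineage table
#'
#' Programmatic counterpart of \code{\link{loadScheme}} for a data.frame with
#' columns \code{taxon} and \code{lineage}.
#'
#' @param tab data.frame with columns \code{taxon}, \code{lineage}.
#' @param groupDefs group definitions, as in \code{\link{loadScheme}}.
#' @return a \linkS4class{TaxonomyScheme}.
#' @export
taxonomyScheme <- function(tab, groupDefs = defaultGroupDefs()) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(tab, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  loadScheme(tmp, groupDefs)
}

#' The packaged default taxonomy scheme
#'
#' A compact scheme of 23 representative taxa spanning all five analysis
#' groups (the focal choanoflagellates plus a sister species, metazoans,
#' fungi, bacteria, archaea, algae sensu lato including an oomycete and a
#' ciliate, and non-kin heterotrophic eukaryotes). It is the scaffold the
#' simulator plants transfers onto and a ready-made scheme for examples.
#'
#' @return a \linkS4class{TaxonomyScheme}.
#' @export
defaultScheme <- function() {
  loadScheme(system.file("extdata", "default_scheme.tsv",
                         package = "HGTscan", mustWork = TRUE))
}

#' Serialize a taxonomy scheme back to TSV
#'
#' Writes the \code{taxon}/\code{lineage} table; reloading the file with the
#' same group definitions reproduces the group assignments exactly.
#'
#' @param scheme a \linkS4class{TaxonomyScheme}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScheme <- function(scheme, path) {
  utils::write.table(scheme@assignments[c("taxon", "lineage")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up a taxon's analysis group
#'
#' @param scheme a \linkS4class{TaxonomyScheme}.
#' @param taxon taxon name (must be present in the scheme).
#' @return one of \code{\link{GROUP_LEVELS}}.
#' @examples
#' groupOf(defaultScheme(), "Escherichia")  # "PROKARYOTE"
#' @rdname groupOf
#' @export
setMethod("groupOf", "TaxonomyScheme", function(scheme, taxon) {
  i <- match(taxon, scheme@assignments$taxon)
  if (anyNA(i)) {
    stop("unknown taxon: ", paste(taxon[is.na(i)], collapse = ", "))
  }
  stats::setNames(scheme@assignments$group[i], taxon)
})
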