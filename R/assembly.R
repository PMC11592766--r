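# Herb -> compound -> target integration and disease-association curation.
# Input tables are plain TSV; all loaders validate headers, reject malformed
# rows with row numbers, and deduplicate exact association duplicates.

#' Load the herb-compound, compound-target and disease tables
#'
#' Reads the three TSV inputs, validating headers and rows. Duplicate
#' (herb, compound) and (compound, protein) rows are collapsed. Compounds
#' whose ids are not PubChem-CID-style (`CID` followed by digits) are
#' dropped with a warning.
#'
#' @param herb_compounds_path TSV with columns herb, compound
#' @param compound_targets_path TSV with columns compound, protein
#' @param disease_path TSV with columns disease, protein, evidence
#' @return list with `herb_compounds` (named list herb -> compound ids),
#'   `compound_targets` (named list compound -> protein ids), and the raw
#'   `disease` data frame
#' @export
load_tables <- function(herb_compounds_path, compound_targets_path,
                        disease_path) {
  hc <- read_tsv_checked(herb_compounds_path, c("herb", "compound"))
  ct <- read_tsv_checked(compound_targets_path, c("compound", "protein"))
  dz <- read_tsv_checked(disease_path, c("disease", "protein", "evidence"))

  bad_cid <- !grepl("^CID[0-9]+$", hc$compound)
  note_drop("load", "compound(s) without PubChem-CID-style ids",
            length(unique(hc$compound[bad_cid])))
  hc <- hc[!bad_cid, , drop = FALSE]
  if (nrow(hc) == 0L) stop("no herb-compound rows left after CID filter",
                           call. = FALSE)
  hc <- hc[!duplicated(hc[c("herb", "compound")]), , drop = FALSE]
  ct <- ct[!duplicated(ct[c("compound", "protein")]), , drop = FALSE]

  list(herb_compounds = split(hc$compound, hc$herb),
       compound_targets = split(ct$protein, ct$compound),
       disease = dz)
}

#' Retain herbs with enough compounds
#'
#' The default of 6 encodes the "more than five compounds" inclusion rule.
#'
#' @param herb_compounds named list herb -> compound ids
#' @param min_compounds minimum panel size to retain a herb (default 6)
#' @return filtered named list
#' @export
filter_herbs_min_compounds <- function(herb_compounds, min_compounds = 6L) {
  if (min_compounds < 1L) stop("min_compounds must be >= 1", call. = FALSE)
  keep <- vapply(herb_compounds, function(x) length(unique(x)),
                 integer(1)) >= min_compounds
  herb_compounds[keep]
}

#' Rank each herb's protein targets by compound support
#'
#' For every herb, each protein target is scored by the number of distinct
#' compounds of that herb hitting it; targets are ordered by support
#' descending with ties broken by protein id ascending, and truncated to the
#' `top_n` best (default 50). Herbs whose compounds carry no target data are
#' dropped with a warning.
#'
#' @param herb_compounds named list herb -> compound ids
#' @param compound_targets named list compound -> protein ids
#' @param top_n targets kept per herb (default 50)
#' @return data frame (herb, protein, support, rank), class
#'   `herb_target_table`
#' @export
integrate_targets <- function(herb_compounds, compound_targets,
                              top_n = 50L) {
  if (length(herb_compounds) == 0L) stop("no herbs to integrate",
                                         call. = FALSE)
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  no_target_compounds <- 0L
  rows <- lapply(names(herb_compounds), function(h) {
    comps <- unique(herb_compounds[[h]])
    known <- comps[comps %in% names(compound_targets)]
    no_target_compounds <<- no_target_compounds + (length(comps) -
                                                   length(known))
    if (length(known) == 0L) return(NULL)
    # distinct supporting compounds per target
    pairs <- unique(do.call(rbind, lapply(known, function(cmp) {
      data.frame(compound = cmp, protein = unique(compound_targets[[cmp]]),
                 stringsAsFactors = FALSE)
    })))
    support <- table(pairs$protein)
    ord <- order(-as.integer(support), names(support))
    n_keep <- min(top_n, length(support))
    sel <- ord[seq_len(n_keep)]
    data.frame(herb = h, protein = names(support)[sel],
               support = as.integer(support)[sel],
               rank = seq_len(n_keep), stringsAsFactors = FALSE)
  })
  dropped_herbs <- sum(vapply(rows, is.null, logical(1)))
  note_drop("integrate", "compound(s) lacking target data",
            no_target_compounds)
  note_drop("integrate", "herb(s) with zero mapped targets", dropped_herbs)
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(out) || nrow(out) == 0L) {
    stop("no herb has any mapped target", call. = FALSE)
  }
  structure(out, class = c("herb_target_table", "data.frame"))
}

#' Curate disease proteins by evidence class
#'
#' Retains association rows whose evidence flag is in `keep_flags`
#' (default: `curated` only, excluding animal-model, literature-mined and
#' therapeutic evidence). Proteins absent from the interactome are dropped
#' later, at network-attachment time.
#'
#' @param disease data frame (disease, protein, evidence)
#' @param keep_flags character vector of evidence flags to retain
#' @return list with `disease_id`, `proteins` (unique, sorted) and the
#'   retained `rows`
#' @export
curate_disease_proteins <- function(disease, keep_flags = "curated") {
  keep <- disease$evidence %in% keep_flags
  if (!any(keep)) {
    stop("no disease association passes the evidence filter (flags kept: ",
         paste(keep_flags, collapse = ", "), ")", call. = FALSE)
  }
  rows <- disease[keep, , drop = FALSE]
  list(disease_id = unique(rows$disease)[1],
       proteins = sort(unique(rows$protein)),
       rows = rows)
}
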