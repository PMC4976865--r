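#' Construct an occurrence table
#'
#' An occurrence table holds one row per (group, species, site) with a
#' non-negative record count.  It is the raw input of the whole pipeline:
#' presence/absence is derived from it by thresholding records at >= 1, and
#' record counts feed the sample-coverage estimator.
#'
#' Duplicate (group, species, site) triples -- compared after trimming,
#' whitespace collapsing and case-folding -- are an error rather than being
#' silently summed, because duplicated rows in field databases usually signal
#' an upstream join mistake.
#'
#' @param df data frame with columns `group`, `species`, `site`, `records`.
#' @return an object of class `occurrence_table` (a data frame).
#' @examples
#' occ <- occurrence_table(data.frame(
#'   group = "amphibians",
#'   species = c("Lithobates berlandieri", "Hyla eximia"),
#'   site = c("MF", "VB"),
#'   records = c(3L, 1L)
#' ))
#' @export
occurrence_table <- function(df) {
  required <- c("group", "species", "site", "records")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    bt_stop(
      sprintf("occurrence table is missing column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "betataxa_schema_error"
    )
  }
  df <- as.data.frame(df)[required]
  df$group <- as.character(df$group)
  df$species <- as.character(df$species)
  df$site <- as.character(df$site)
  if (any(is.na(df$records)) || any(df$records < 0) ||
      any(df$records != floor(df$records))) {
    bt_stop("records must be non-negative integers",
            "betataxa_validation_error")
  }
  df$records <- as.integer(df$records)
  key <- paste(normalize_label(df$group), normalize_label(df$species),
               normalize_label(df$site), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- which(dup)[1]
    bt_stop(
      sprintf("duplicate (group, species, site) triple: (%s, %s, %s)",
              df$group[first], df$species[first], df$site[first]),
      "betataxa_duplicate_error"
    )
  }
  rownames(df) <- NULL
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read an occurrence table from a delimited text file
#'
#' @param path path to a CSV/TSV file (UTF-8).
#' @param delim field delimiter, `","` by default.
#' @param schema named character vector remapping file column names to the
#'   canonical `group`, `species`, `site`, `records`; names are the canonical
#'   names, values the names found in the file.  Unmentioned columns are
#'   assumed to already carry canonical names.
#' @return an `occurrence_table`.
#' @seealso [occurrence_table()] for validation rules.
#' @export
read_occurrences <- function(path, delim = ",", schema = NULL) {
  if (!file.exists(path)) {
    bt_stop(sprintf("file not found: %s", path), "betataxa_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(df)) {
        bt_stop(sprintf("mapped column '%s' not found in %s", src, path),
                "betataxa_schema_error")
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  occurrence_table(df)
}

#' Construct a taxonomy table for one group
#'
#' A taxonomy table maps each species of a faunal group to its names at a
#' fixed, ordered list of Linnaean ranks (coarse to fine, ending in
#' `"species"`).  Hierarchies may be ragged: a blank or `NA` cell means the
#' rank is not applicable for that lineage (e.g. no subfamily) and that rank
#' contributes no taxon for the species.
#'
#' @param group group label.
#' @param assignments data frame whose columns are the ranks in coarse-to-fine
#'   order; the last column must be named `species`.  One row per species.
#' @return an object of class `taxonomy_table`.
#' @export
taxonomy_table <- function(group, assignments) {
  assignments <- as.data.frame(assignments)
  ranks <- names(assignments)
  if (length(ranks) < 1 || ranks[length(ranks)] != "species") {
    bt_stop("taxonomy ranks must end in 'species'", "betataxa_schema_error")
  }
  for (r in ranks) assignments[[r]] <- as.character(assignments[[r]])
  sp <- assignments$species
  if (any(is.na(sp)) || any(trimws(sp) == "")) {
    bt_stop("every taxonomy row needs a species name", "betataxa_validation_error")
  }
  if (anyDuplicated(normalize_label(sp))) {
    bt_stop("duplicated species in taxonomy table", "betataxa_duplicate_error")
  }
  structure(
    list(group = as.character(group), ranks = ranks, assignments = assignments),
    class = "taxonomy_table"
  )
}

#' Read a per-group taxonomy table from a delimited file
#'
#' The header row gives the rank names, coarse to fine, the last column being
#' `species`; each subsequent row is one species' lineage.  Blank cells denote
#' ranks not applicable to that lineage.
#'
#' @param path path to a CSV/TSV file.
#' @param group group label to attach.
#' @param delim field delimiter.
#' @return a `taxonomy_table`.
#' @export
read_taxonomy <- function(path, group, delim = ",") {
  if (!file.exists(path)) {
    bt_stop(sprintf("file not found: %s", path), "betataxa_io_error")
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8", check.names = FALSE,
                          colClasses = "character")
  taxonomy_table(group, df)
}

#' @export
print.taxonomy_table <- function(x, ...) {
  cat(sprintf("Taxonomy for group '%s': %d species over ranks %s\n",
              x$group, nrow(x$assignments), paste(x$ranks, collapse = " > ")))
  invisible(x)
}

#' Build a site-by-species incidence matrix for one group
#'
#' A species is scored present at a site iff it has at least one record
#' there; the analysis is incidence-based throughout, record counts are never
#' used as abundance weights downstream of this step.  Sites with zero
#' presences are retained (and flagged) rather than dropped, so that pairwise
#' comparisons involving them can be reported as undefined downstream.
#'
#' @param occ an `occurrence_table`.
#' @param group group label to slice out.
#' @param sites optional character vector fixing site order (and retaining
#'   sites absent from the slice); defaults to order of appearance.
#' @return binary matrix (sites x species) of class `incidence_matrix`, with
#'   attributes `group` and `empty_sites`.
#' @export
build_incidence <- function(occ, group, sites = NULL) {
  stopifnot(inherits(occ, "occurrence_table"))
  keep <- normalize_label(occ$group) == normalize_label(group)
  if (!any(keep) && is.null(sites)) {
    bt_stop(sprintf("group '%s' not present in occurrence table", group),
            "betataxa_lookup_error")
  }
  slice <- occ[keep, , drop = FALSE]
  if (is.null(sites)) sites <- unique(slice$site)
  present <- slice[slice$records >= 1L, , drop = FALSE]
  species <- unique(present$species)
  m <- matrix(0L, nrow = length(sites), ncol = length(species),
              dimnames = list(sites, species))
  if (nrow(present) > 0) {
    i <- match(normalize_label(present$site), normalize_label(sites))
    if (anyNA(i)) {
      bt_stop("occurrence rows reference sites outside the requested site list",
              "betataxa_lookup_error")
    }
    j <- match(present$species, species)
    m[cbind(i, j)] <- 1L
  }
  empty <- rownames(m)[rowSums(m) == 0]
  if (length(empty) > 0) {
    bt_warn(sprintf("group '%s': site(s) with no presences: %s",
                    group, paste(empty, collapse = ", ")),
            "betataxa_empty_site_warning")
  }
  structure(m, group = as.character(group), empty_sites = empty,
            class = c("incidence_matrix", class(m)))
}

#' Expand a species set to the upward-closed set of taxa at all ranks
#'
#' Pools a set of species with every non-blank higher taxon on their lineages.
#' The result is a set of (rank, name) pairs: identity is the *pair*, so a
#' name reused at two ranks counts as two distinct taxa, while a genus shared
#' by several species in the set is counted once.  This pooled taxon set is
#' the unit over which taxonomic dissimilarity is computed.
#'
#' @param species_set character vector of species labels (a set; duplicates
#'   are ignored).
#' @param tax a `taxonomy_table` covering all the species.
#' @return object of class `taxon_set`: a data frame with columns `rank` and
#'   `name`, one row per distinct taxon.
#' @examples
#' tax <- taxonomy_table("demo", data.frame(
#'   family = c("f1", "f1"), genus = c("g1", "g1"),
#'   species = c("s1", "s2")
#' ))
#' nrow(expand_taxa(c("s1", "s2"), tax))  # 4: two species, one genus, one family
#' @export
expand_taxa <- function(species_set, tax) {
  stopifnot(inherits(tax, "taxonomy_table"))
  species_set <- unique(as.character(species_set))
  if (length(species_set) == 0) {
    out <- data.frame(rank = character(0), name = character(0))
    class(out) <- c("taxon_set", "data.frame")
    return(out)
  }
  idx <- match(normalize_label(species_set),
               normalize_label(tax$assignments$species))
  if (anyNA(idx)) {
    bt_stop(sprintf("species missing from taxonomy for group '%s': %s",
                    tax$group,
                    paste(species_set[is.na(idx)], collapse = ", ")),
            "betataxa_unassigned_species_error")
  }
  rows <- tax$assignments[idx, , drop = FALSE]
  pieces <- lapply(tax$ranks, function(r) {
    nm <- rows[[r]]
    nm <- nm[!is.na(nm) & trimws(nm) != ""]
    if (length(nm) == 0) return(NULL)
    data.frame(rank = r, name = unique(nm))
  })
  out <- unique(do.call(rbind, pieces))
  rownames(out) <- NULL
  class(out) <- c("taxon_set", "data.frame")
  out
}
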