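# Partitioning of incidence-based dissimilarity into turnover and
# richness-difference components, at the species level and over the pooled
# Linnaean taxon set.

taxon_key <- function(ts) paste(ts$rank, ts$name, sep = "\r")

#' Matching components of two element sets
#'
#' Counts the shared (`a`) and site-exclusive (`b`, `c`) elements of two sets,
#' the triplet from which every dissimilarity in the package is computed.  At
#' the species level the elements are species; at the taxonomic level they are
#' (rank, name) pairs pooled over all ranks, in which case `a`, `b`, `c` are
#' the shared / exclusive taxon counts.
#'
#' @param setA,setB character vectors (treated as sets) or `taxon_set`
#'   objects from [expand_taxa()].
#' @return object of class `pair_components`: list with integer fields `a`
#'   (shared), `b` (only in `setA`), `c` (only in `setB`).  Two empty sets
#'   yield the degenerate triple (0, 0, 0), which downstream partitioning
#'   reports as undefined.
#' @examples
#' pair_components(c("s1", "s2", "s3", "s4"), c("s1", "s2", "s5"))
#' @export
pair_components <- function(setA, setB) {
  if (inherits(setA, "taxon_set")) setA <- taxon_key(setA)
  if (inherits(setB, "taxon_set")) setB <- taxon_key(setB)
  setA <- unique(as.character(setA))
  setB <- unique(as.character(setB))
  a <- length(intersect(setA, setB))
  structure(
    list(a = a, b = length(setA) - a, c = length(setB) - a),
    class = "pair_components"
  )
}

#' Partition total dissimilarity into turnover and richness difference
#'
#' From matching components (a, b, c), total dissimilarity is the Jaccard
#' complement beta_cc = (b + c) / (a + b + c), split additively into a
#' turnover (replacement) component beta_3 = 2 min(b, c) / (a + b + c) and a
#' richness-difference component beta_rich = |b - c| / (a + b + c).  The
#' identity beta_cc = beta_3 + beta_rich holds exactly since
#' (b + c) = 2 min(b, c) + |b - c|.
#'
#' @param components a `pair_components` object, or a list with fields
#'   `a`, `b`, `c`.
#' @return object of class `beta_partition`: list with `beta_cc`, `beta_3`,
#'   `beta_rich`, all in \[0, 1\].  If a + b + c = 0 the partition is
#'   undefined and all three are `NA` (with a warning).
#' @examples
#' beta_partition(pair_components(c("s1", "s2", "s3", "s4"), c("s1", "s2", "s5")))
#' @export
beta_partition <- function(components) {
  a <- components$a; b <- components$b; cc <- components$c
  stopifnot(a >= 0, b >= 0, cc >= 0)
  denom <- a + b + cc
  if (denom == 0) {
    bt_warn("dissimilarity undefined for two empty communities",
            "betataxa_undefined_pair_warning")
    out <- list(beta_cc = NA_real_, beta_3 = NA_real_, beta_rich = NA_real_)
  } else {
    out <- list(
      beta_cc = (b + cc) / denom,
      beta_3 = 2 * min(b, cc) / denom,
      beta_rich = abs(b - cc) / denom
    )
  }
  class(out) <- "beta_partition"
  out
}

#' Taxonomic dissimilarity partition between two species sets
#'
#' Expands each species set to its upward-closed set of taxa at all
#' configured ranks (species included), then partitions the Jaccard-type
#' dissimilarity over those pooled taxon sets: beta_ccT = 1 - Ta / (Ta + Tb +
#' Tc) where Ta is the count of taxa shared between the two communities and
#' Tb, Tc the counts exclusive to each.  Because higher taxa are often shared
#' even when species are not, beta_ccT is typically (not provably) lower than
#' the species-level dissimilarity of the same pair.
#'
#' @param speciesA,speciesB character vectors of species labels.
#' @param tax a `taxonomy_table` covering all the species.
#' @return a `beta_partition` (fields beta_cc, beta_3, beta_rich, here
#'   playing the roles of beta_ccT, beta_3T, beta_richT).
#' @seealso [expand_taxa()], [beta_partition()]
#' @export
taxonomic_partition <- function(speciesA, speciesB, tax) {
  beta_partition(pair_components(expand_taxa(speciesA, tax),
                                 expand_taxa(speciesB, tax)))
}

site_species_sets <- function(inc) {
  lapply(seq_len(nrow(inc)), function(i) colnames(inc)[inc[i, ] >= 1L])
}

#' Pairwise dissimilarity partitions for every site pair
#'
#' Computes one beta partition per unordered site pair of an incidence
#' matrix, either on species sets (`level = "species"`) or on pooled taxon
#' sets (`level = "taxonomic"`, requires a taxonomy).  Pairs involving a site
#' with zero presences are reported as missing (`NA`) with a warning rather
#' than as zeros.
#'
#' @param inc an `incidence_matrix` from [build_incidence()].
#' @param level `"species"` or `"taxonomic"`.
#' @param tax `taxonomy_table`, required when `level = "taxonomic"`.
#' @return data frame of class `pairwise_beta` with one row per unordered
#'   pair: columns `group`, `level`, `site_i`, `site_j`, `a`, `b`, `c`,
#'   `beta_cc`, `beta_3`, `beta_rich`.
#' @export
pairwise_beta <- function(inc, level = c("species", "taxonomic"), tax = NULL) {
  level <- match.arg(level)
  if (nrow(inc) < 2) {
    bt_stop("pairwise dissimilarity needs at least 2 sites", "betataxa_size_error")
  }
  if (level == "taxonomic" && is.null(tax)) {
    bt_stop("taxonomic level requires a taxonomy table", "betataxa_schema_error")
  }
  sets <- site_species_sets(inc)
  if (level == "taxonomic") {
    sets <- lapply(sets, function(s) taxon_key(expand_taxa(s, tax)))
  }
  sites <- rownames(inc)
  empty <- which(rowSums(inc) == 0)
  pairs <- utils::combn(length(sites), 2)
  n_pairs <- ncol(pairs)
  out <- data.frame(
    group = rep(attr(inc, "group") %||% NA_character_, n_pairs),
    level = level,
    site_i = sites[pairs[1, ]], site_j = sites[pairs[2, ]],
    a = NA_integer_, b = NA_integer_, c = NA_integer_,
    beta_cc = NA_real_, beta_3 = NA_real_, beta_rich = NA_real_,
    stringsAsFactors = FALSE
  )
  n_dropped <- 0L
  for (k in seq_len(n_pairs)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (i %in% empty || j %in% empty) {
      n_dropped <- n_dropped + 1L
      next
    }
    comp <- pair_components(sets[[i]], sets[[j]])
    part <- beta_partition(comp)
    out$a[k] <- comp$a; out$b[k] <- comp$b; out$c[k] <- comp$c
    out$beta_cc[k] <- part$beta_cc
    out$beta_3[k] <- part$beta_3
    out$beta_rich[k] <- part$beta_rich
  }
  if (n_dropped > 0) {
    bt_warn(sprintf("%d pair(s) involve an empty site; reported as NA", n_dropped),
            "betataxa_empty_site_warning")
  }
  class(out) <- c("pairwise_beta", "data.frame")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Multiple-site dissimilarity partition
#'
#' Summarizes compositional variation across all T sites in one partition.
#' The default `"component-sum"` variant generalizes the pairwise partition
#' by summing matching components over all T(T-1)/2 pairs:
#' beta_cc = sum(b + c) / sum(a + b + c), beta_3 = sum(2 min(b, c)) /
#' sum(a + b + c), beta_rich = sum(|b - c|) / sum(a + b + c).  Additivity
#' beta_cc = beta_3 + beta_rich then holds by construction and the T = 2 case
#' reduces exactly to the pairwise partition.  The `"pair-mean"` variant
#' instead averages the pairwise values arithmetically (also additive, and
#' also reducing to the pairwise partition at T = 2); it is provided as a
#' sensitivity check on the aggregation choice.
#'
#' @param inc an `incidence_matrix`.
#' @param level `"species"` or `"taxonomic"`.
#' @param tax `taxonomy_table`, required for taxonomic level.
#' @param variant `"component-sum"` (default) or `"pair-mean"`.
#' @return object of class `multi_site_beta`: list with `group`, `level`,
#'   `variant`, `n_sites`, `beta_cc`, `beta_3`, `beta_rich`,
#'   `pct_turnover`, `pct_rich`.  Contribution percentages are `NA` (with a
#'   warning) when beta_cc = 0.
#' @export
multi_site_beta <- function(inc, level = c("species", "taxonomic"), tax = NULL,
                            variant = c("component-sum", "pair-mean")) {
  level <- match.arg(level)
  variant <- match.arg(variant)
  non_empty <- sum(rowSums(inc) > 0)
  if (non_empty < 2) {
    bt_stop("multiple-site dissimilarity needs at least 2 non-empty sites",
            "betataxa_size_error")
  }
  pw <- pairwise_beta(inc, level = level, tax = tax)
  ok <- !is.na(pw$beta_cc)
  pw <- pw[ok, , drop = FALSE]
  if (variant == "component-sum") {
    denom <- sum(pw$a + pw$b + pw$c)
    beta_cc <- sum(pw$b + pw$c) / denom
    beta_3 <- sum(2 * pmin(pw$b, pw$c)) / denom
    beta_rich <- sum(abs(pw$b - pw$c)) / denom
  } else {
    beta_cc <- mean(pw$beta_cc)
    beta_3 <- mean(pw$beta_3)
    beta_rich <- mean(pw$beta_rich)
  }
  out <- structure(
    list(group = attr(inc, "group") %||% NA_character_, level = level,
         variant = variant, n_sites = nrow(inc),
         beta_cc = beta_cc, beta_3 = beta_3, beta_rich = beta_rich,
         pct_turnover = NA_real_, pct_rich = NA_real_),
    class = "multi_site_beta"
  )
  if (beta_cc > 0) {
    pct <- contribution_percentages(out)
    out$pct_turnover <- pct[["turnover"]]
    out$pct_rich <- pct[["richness_difference"]]
  } else {
    bt_warn("all sites compositionally identical; contributions undefined",
            "betataxa_undefined_contribution_warning")
  }
  out
}

#' @export
print.multi_site_beta <- function(x, ...) {
  cat(sprintf(
    "Multiple-site %s dissimilarity (%s, T = %d)\n  beta_cc = %.4f = beta_3 %.4f + beta_rich %.4f\n",
    x$level, x$variant, x$n_sites, x$beta_cc, x$beta_3, x$beta_rich))
  if (!is.na(x$pct_turnover)) {
    cat(sprintf("  turnover %.2f%% | richness difference %.2f%%\n",
                x$pct_turnover, x$pct_rich))
  }
  invisible(x)
}

#' Percentage contributions of turnover and richness difference
#'
#' @param msb a `multi_site_beta` (or any list with `beta_cc` and `beta_3`).
#' @return named numeric vector `c(turnover=, richness_difference=)`, in
#'   percent, summing to 100.
#' @export
contribution_percentages <- function(msb) {
  if (is.na(msb$beta_cc) || msb$beta_cc == 0) {
    bt_stop("contributions undefined when total dissimilarity is zero",
            "betataxa_undefined_contribution_error")
  }
  turn <- 100 * msb$beta_3 / msb$beta_cc
  c(turnover = turn, richness_difference = 100 - turn)
}

#' Coerce a pairwise beta table to a square dissimilarity matrix
#'
#' @param pw a `pairwise_beta` data frame.
#' @param field which component to extract: `"beta_cc"`, `"beta_3"` or
#'   `"beta_rich"`.
#' @return symmetric numeric matrix with zero diagonal, sites as dimnames.
#' @export
beta_matrix <- function(pw, field = c("beta_cc", "beta_3", "beta_rich")) {
  field <- match.arg(field)
  sites <- unique(c(pw$site_i, pw$site_j))
  m <- matrix(0, length(sites), length(sites), dimnames = list(sites, sites))
  for (k in seq_len(nrow(pw))) {
    m[pw$site_i[k], pw$site_j[k]] <- m[pw$site_j[k], pw$site_i[k]] <- pw[[field]][k]
  }
  m
}
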