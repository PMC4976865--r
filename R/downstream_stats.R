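# Ordination of dissimilarity matrices and correlation between the species
# and taxonomic dissimilarity of the same site pairs.

as_beta_dissim <- function(d, field) {
  if (inherits(d, "pairwise_beta")) d <- beta_matrix(d, field)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) {
    bt_stop("dissimilarity input must be a square symmetric matrix",
            "betataxa_shape_error")
  }
  if (anyNA(d)) {
    bt_stop(paste("dissimilarity matrix has missing entries;",
                  "exclude the affected sites or impute before ordination"),
            "betataxa_completeness_error")
  }
  if (max(abs(d - t(d))) > 1e-12) {
    bt_stop("dissimilarity input must be a square symmetric matrix",
            "betataxa_shape_error")
  }
  d
}

#' Non-metric multidimensional scaling of a beta-diversity matrix
#'
#' Finds a low-dimensional configuration of the sites whose inter-point
#' distances are monotonically related to the input dissimilarities,
#' minimizing Kruskal's stress-1.  The optimization (isotonic regression
#' alternated with gradient steps on the configuration) is delegated to
#' `vegan::monoMDS`; this wrapper adds best-of-`restarts` random
#' initializations (plus a metric-scaling start) under a fixed seed, so
#' results are reproducible and stress can only improve with more restarts.
#'
#' Coordinates are identified only up to rotation, reflection and
#' translation; compare inter-site distances or stress, never raw axes.
#'
#' @param d a `pairwise_beta` table or a square symmetric dissimilarity
#'   matrix with no missing entries.
#' @param field component used when `d` is a `pairwise_beta` table.
#' @param dims number of ordination dimensions (default 2).
#' @param seed integer seed controlling all random starts.
#' @param restarts number of random initial configurations (default 50).
#' @param maxit maximum iterations per start (default 300).
#' @return object of class `nmds_result`: list with `coordinates`
#'   (sites x dims matrix), `stress` (Kruskal stress-1 in \[0, 1\]),
#'   `converged`, `seed`, `restarts`.
#' @export
beta_nmds <- function(d, field = c("beta_cc", "beta_3", "beta_rich"),
                      dims = 2, seed = 1L, restarts = 50L, maxit = 300L) {
  field <- match.arg(field)
  d <- as_beta_dissim(d, field)
  n <- nrow(d)
  if (n < 3) {
    bt_stop("NMDS needs at least 3 sites", "betataxa_size_error")
  }
  if (max(d) <= 0) {
    bt_stop("all dissimilarities are zero: configuration is degenerate",
            "betataxa_degenerate_error")
  }
  dd <- stats::as.dist(d)
  set.seed(as.integer(seed))
  best <- suppressWarnings(
    vegan::monoMDS(dd, k = dims, model = "global", maxit = maxit)
  )
  for (r in seq_len(max(0L, restarts))) {
    y0 <- matrix(stats::runif(n * dims, -1, 1), n, dims)
    fit <- suppressWarnings(
      vegan::monoMDS(dd, y = y0, k = dims, model = "global", maxit = maxit)
    )
    if (fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  dimnames(coords) <- list(rownames(d), paste0("axis", seq_len(dims)))
  structure(
    list(coordinates = coords, stress = best$stress,
         converged = isTRUE(best$maxits < maxit) || best$stress < 1e-6,
         seed = as.integer(seed), restarts = as.integer(restarts)),
    class = "nmds_result"
  )
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS configuration: %d sites, %d dims, stress-1 = %.4g\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}

pair_key <- function(tab) {
  i <- normalize_label(tab$site_i); j <- normalize_label(tab$site_j)
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}

#' Correlation between species-level and taxonomic dissimilarity
#'
#' Pearson correlation across site pairs between one component of the
#' species-level partition and the same component of the taxonomic
#' partition.  Pairs missing in either table are dropped pairwise (with a
#' message).  The default two-sided p-value comes from the usual t transform
#' on n - 2 degrees of freedom, treating the pairs as independent
#' observations; because the T(T-1)/2 pairs share sites they are not truly
#' independent, so a Mantel-style permutation p-value (site-label
#' permutation) is available via `permutations`.
#'
#' @param species_table,taxo_table `pairwise_beta` tables over the same
#'   sites, at species and taxonomic level respectively.
#' @param field which component to correlate.
#' @param permutations if > 0, additionally compute a permutation p-value
#'   with this many site-label permutations.
#' @param seed seed for the permutation test.
#' @return object of class `correlation_result`: list with `r`, `p`, `n`,
#'   `field`, and `p_perm` (NA unless permutations requested).
#' @export
correlate_levels <- function(species_table, taxo_table,
                             field = c("beta_cc", "beta_3", "beta_rich"),
                             permutations = 0L, seed = 1L) {
  field <- match.arg(field)
  kx <- pair_key(species_table); ky <- pair_key(taxo_table)
  if (!setequal(kx, ky)) {
    bt_stop("the two tables cover different site pairs", "betataxa_shape_error")
  }
  x <- species_table[[field]]
  y <- taxo_table[[field]][match(kx, ky)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(!ok) > 0) {
    message(sprintf("dropping %d pair(s) with missing values", sum(!ok)))
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    bt_stop("need at least 3 complete pairs for a correlation",
            "betataxa_insufficient_pairs_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    bt_stop("zero variance in a dissimilarity vector; correlation undefined",
            "betataxa_zero_variance_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  p_perm <- NA_real_
  if (permutations > 0) {
    ms <- beta_matrix(species_table, field)
    mt <- beta_matrix(taxo_table, field)
    mt <- mt[rownames(ms), rownames(ms)]
    if (anyNA(ms) || anyNA(mt)) {
      bt_stop("permutation p-value requires complete pairwise tables",
              "betataxa_completeness_error")
    }
    obs <- ct$estimate
    set.seed(as.integer(seed))
    ut <- upper.tri(ms)
    exceed <- 0L
    for (b in seq_len(permutations)) {
      perm <- sample(nrow(mt))
      r_b <- stats::cor(ms[ut], mt[perm, perm][ut])
      if (abs(r_b) >= abs(obs)) exceed <- exceed + 1L
    }
    p_perm <- (exceed + 1) / (permutations + 1)
  }
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = n, field = field,
         p_perm = p_perm),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (p = %.3g, n = %d pairs, %s)\n",
              x$r, x$p, x$n, x$field))
  invisible(x)
}
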