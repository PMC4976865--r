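# Inventory completeness via abundance-based sample coverage.

#' Summarize record abundances for one group x site cell
#'
#' Tallies the quantities the coverage estimator needs: total records `n`,
#' singletons `f1` (species with exactly one record) and doubletons `f2`
#' (exactly two records) among the species of a group at a site.
#'
#' @param occ an `occurrence_table`.
#' @param group group label.
#' @param site site label.
#' @return object of class `abundance_summary`: list with integer `n`, `f1`,
#'   `f2` and `s_obs` (number of species with >= 1 record).
#' @export
summarize_abundance <- function(occ, group, site) {
  stopifnot(inherits(occ, "occurrence_table"))
  keep <- normalize_label(occ$group) == normalize_label(group) &
    normalize_label(occ$site) == normalize_label(site)
  counts <- occ$records[keep]
  counts <- counts[counts >= 1L]
  if (length(counts) == 0) {
    bt_warn(sprintf("no records for group '%s' at site '%s'", group, site),
            "betataxa_empty_summary_warning")
  }
  structure(
    list(n = sum(counts), f1 = sum(counts == 1L), f2 = sum(counts == 2L),
         s_obs = length(counts)),
    class = "abundance_summary"
  )
}

#' Abundance-based sample coverage
#'
#' Estimates the proportion of individuals in the assemblage that belong to
#' species already detected in the sample -- the standard completeness
#' measure built from total records and the singleton/doubleton counts:
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2}.}
#' With no singletons the sample is judged complete (coverage 1).  The edge
#' case n = 1 with f1 = 1 yields coverage 0 and a small-sample warning.
#'
#' @param s an `abundance_summary`, or a list with fields `n`, `f1`, `f2`.
#' @return object of class `coverage_estimate`: list with `coverage` in
#'   \[0, 1\] and `percent` (coverage x 100, rounded to 2 decimals).
#' @examples
#' sample_coverage(list(n = 100, f1 = 10, f2 = 5))  # 0.901
#' @export
sample_coverage <- function(s) {
  n <- s$n; f1 <- s$f1; f2 <- s$f2
  if (n < 1) {
    bt_stop("coverage undefined for an empty sample", "betataxa_undefined_error")
  }
  if (f1 == 0) {
    cov <- 1
  } else if ((n - 1) * f1 + 2 * f2 == 0) {
    cov <- 1 - f1 / n  # n = 1 with a lone singleton: estimator floor of 0
  } else {
    cov <- 1 - (f1 / n) * ((n - 1) * f1 / ((n - 1) * f1 + 2 * f2))
  }
  if (n == 1 && f1 == 1) {
    bt_warn("single-record sample: coverage estimate is 0 and uninformative",
            "betataxa_small_sample_warning")
  }
  structure(list(coverage = cov, percent = round(100 * cov, 2)),
            class = "coverage_estimate")
}

#' Completeness table across groups and sites
#'
#' Convenience wrapper computing, for every requested group x site cell,
#' observed richness, record totals, singleton/doubleton counts and the
#' sample-coverage completeness percentage.
#'
#' @param occ an `occurrence_table`.
#' @param groups character vector of groups (default: all in `occ`).
#' @param sites character vector of sites (default: all in `occ`).
#' @return data frame with columns `group`, `site`, `S`, `R`, `f1`, `f2`,
#'   `completeness_pct`.
#' @export
coverage_table <- function(occ, groups = unique(occ$group),
                           sites = unique(occ$site)) {
  rows <- list()
  for (g in groups) {
    for (s in sites) {
      ab <- withCallingHandlers(
        summarize_abundance(occ, g, s),
        betataxa_empty_summary_warning = function(w) invokeRestart("muffleWarning")
      )
      pct <- if (ab$n >= 1) sample_coverage(ab)$percent else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        group = g, site = s, S = ab$s_obs, R = ab$n,
        f1 = ab$f1, f2 = ab$f2, completeness_pct = pct,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
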