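# End-to-end orchestration: coverage -> pairwise partitions -> multiple-site
# summary -> NMDS -> species-vs-taxonomic correlations, with CSV outputs and
# a machine-readable manifest.

#' Assemble a run configuration
#'
#' @param mode `"simulate"` (generate the bundled multi-group preset) or
#'   `"files"` (read occurrence and taxonomy tables from disk).
#' @param occurrences path to the occurrence CSV (mode `"files"`).
#' @param taxonomies named list of per-group taxonomy CSV paths (mode
#'   `"files"`).
#' @param groups groups to analyze; default: all available.
#' @param variant multiple-site aggregation variant, `"component-sum"` or
#'   `"pair-mean"`.
#' @param nmds_restarts,nmds_dims NMDS settings.
#' @param correlation_permutations if > 0, also compute permutation p-values.
#' @param seed master seed recorded in all outputs.
#' @param outdir output directory (created if absent).
#' @return object of class `run_config` (a list).
#' @export
run_config <- function(mode = c("simulate", "files"), occurrences = NULL,
                       taxonomies = NULL, groups = NULL,
                       variant = c("component-sum", "pair-mean"),
                       nmds_restarts = 50L, nmds_dims = 2L,
                       correlation_permutations = 0L,
                       seed = 1L, outdir = tempfile("betataxa_run")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (mode == "files") {
    if (is.null(occurrences) || !file.exists(occurrences)) {
      bt_stop("mode 'files' needs an existing occurrences path",
              "betataxa_config_error")
    }
  }
  structure(
    list(mode = mode, occurrences = occurrences, taxonomies = taxonomies,
         groups = groups, variant = variant,
         nmds_restarts = as.integer(nmds_restarts),
         nmds_dims = as.integer(nmds_dims),
         correlation_permutations = as.integer(correlation_permutations),
         seed = as.integer(seed), outdir = outdir),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      stop(errorCondition(
        sprintf("[stage: %s] %s", stage, conditionMessage(e)),
        class = c("betataxa_stage_error", class(e))
      ))
    }
  )
}

#' Run the full beta-diversity analysis
#'
#' Executes every stage for each group and writes, under `cfg$outdir`:
#' `coverage.csv` (completeness per group x site), `pairwise_beta.csv`
#' (species and taxonomic partitions per site pair), `multisite_beta.csv`
#' (multiple-site partitions with contribution percentages),
#' `nmds_<group>_<field>.csv` (2-D taxonomic ordinations for beta_cc,
#' beta_3 and beta_rich), `correlations.csv` (species vs taxonomic Pearson
#' correlations per component) and `manifest.json` (config, seed, versions,
#' warning tallies).  Values are written at full precision; rounding is left
#' to presentation.  Identical config + seed give byte-identical outputs.
#'
#' @param cfg a `run_config`, or a path to a YAML config file.
#' @return (invisibly) a list with all in-memory results and the manifest.
#' @export
run_all <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character(0)
  note_warning <- function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  result <- tryCatch(withCallingHandlers({
    if (cfg$mode == "simulate") {
      designs <- with_stage("simulate", hidalgo_like_designs(cfg$seed))
      if (!is.null(cfg$groups)) designs <- designs[cfg$groups]
      taxa <- with_stage("simulate", lapply(designs, generate_taxonomy))
      occ <- with_stage("simulate", {
        parts <- Map(generate_occurrences, designs, taxa)
        occurrence_table(do.call(rbind, lapply(parts, as.data.frame)))
      })
      groups <- names(designs)
    } else {
      occ <- with_stage("ingest", read_occurrences(cfg$occurrences))
      groups <- cfg$groups %||% unique(occ$group)
      taxa <- list()
      for (g in groups) {
        taxa[[g]] <- with_stage("taxonomy", {
          path <- cfg$taxonomies[[g]]
          if (is.null(path)) {
            bt_stop(sprintf("no taxonomy configured for group '%s'", g),
                    "betataxa_config_error")
          }
          read_taxonomy(path, g)
        })
      }
    }

    coverage <- with_stage("coverage", coverage_table(occ, groups = groups))
    utils::write.csv(coverage, file.path(cfg$outdir, "coverage.csv"),
                     row.names = FALSE)

    sites <- unique(occ$site)
    pairwise <- list(); multisite <- list()
    nmds_fits <- list(); correlations <- list()
    for (g in groups) {
      inc <- with_stage("incidence", build_incidence(occ, g, sites = sites))
      tax <- taxa[[g]]
      if (is.null(tax)) {
        bt_stop(sprintf("no taxonomy available for group '%s'", g),
                "betataxa_config_error")
      }
      pw_sp <- with_stage("pairwise", pairwise_beta(inc, "species"))
      pw_tx <- with_stage("pairwise", pairwise_beta(inc, "taxonomic", tax))
      pairwise[[g]] <- rbind(pw_sp, pw_tx)
      ms_sp <- with_stage("multisite",
                          multi_site_beta(inc, "species", variant = cfg$variant))
      ms_tx <- with_stage("multisite",
                          multi_site_beta(inc, "taxonomic", tax, cfg$variant))
      multisite[[g]] <- do.call(rbind, lapply(list(ms_sp, ms_tx), function(m) {
        data.frame(group = m$group, level = m$level, variant = m$variant,
                   n_sites = m$n_sites, beta_cc = m$beta_cc,
                   beta_3 = m$beta_3, beta_rich = m$beta_rich,
                   pct_turnover = m$pct_turnover, pct_rich = m$pct_rich,
                   stringsAsFactors = FALSE)
      }))
      for (field in c("beta_cc", "beta_3", "beta_rich")) {
        fit <- with_stage("nmds", beta_nmds(
          pw_tx, field = field, dims = cfg$nmds_dims,
          seed = derive_seed(cfg$seed, 100L + match(field, c(
            "beta_cc", "beta_3", "beta_rich"))),
          restarts = cfg$nmds_restarts))
        nmds_fits[[g]][[field]] <- fit
        out <- data.frame(site = rownames(fit$coordinates),
                          fit$coordinates, stress = fit$stress,
                          stringsAsFactors = FALSE)
        utils::write.csv(out, file.path(
          cfg$outdir, sprintf("nmds_%s_%s.csv", gsub("\\s+", "_", g), field)),
          row.names = FALSE)
      }
      for (field in c("beta_cc", "beta_3", "beta_rich")) {
        cr <- with_stage("correlate", correlate_levels(
          pw_sp, pw_tx, field = field,
          permutations = cfg$correlation_permutations,
          seed = derive_seed(cfg$seed, 200L)))
        correlations[[length(correlations) + 1]] <- data.frame(
          group = g, field = field, r = cr$r, p = cr$p, n = cr$n,
          p_perm = cr$p_perm, stringsAsFactors = FALSE)
      }
    }
    pairwise_df <- do.call(rbind, pairwise); rownames(pairwise_df) <- NULL
    multisite_df <- do.call(rbind, multisite); rownames(multisite_df) <- NULL
    correlations_df <- do.call(rbind, correlations)
    utils::write.csv(pairwise_df, file.path(cfg$outdir, "pairwise_beta.csv"),
                     row.names = FALSE)
    utils::write.csv(multisite_df, file.path(cfg$outdir, "multisite_beta.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations_df,
                     file.path(cfg$outdir, "correlations.csv"),
                     row.names = FALSE)
    list(occurrences = occ, taxonomies = taxa, coverage = coverage,
         pairwise = pairwise_df, multisite = multisite_df,
         nmds = nmds_fits, correlations = correlations_df)
  }, warning = note_warning),
  error = function(e) {
    # mark partial outputs as unusable before propagating the failure
    writeLines(conditionMessage(e), file.path(cfg$outdir, "INVALID"))
    stop(e)
  })

  manifest <- list(
    package = "betataxa",
    version = as.character(utils::packageVersion("betataxa")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[c("mode", "groups", "variant", "nmds_restarts",
                   "nmds_dims", "correlation_permutations")],
    groups = unique(result$multisite$group),
    n_warnings = length(warn_log),
    warnings = warn_log
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}
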