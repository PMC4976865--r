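# Synthetic taxonomies and multi-site occurrence tables with known
# compositional structure, so every pipeline stage can be tested against
# ground truth.

#' Specify a synthetic multi-site community
#'
#' A community design fixes the compositional skeleton of a simulated group:
#' a shared core present at every site, per-site exclusive species, and an
#' optional pool of "patchy" species occupying random subsets of sites.  The
#' realized presence sets (and hence all pairwise matching components) are
#' recorded by the generator as ground truth.
#'
#' Record counts follow a geometric-series rank-abundance model: within a
#' site the k-th ranked species has relative abundance proportional to
#' `abundance_ratio^(k-1)`, and its count is drawn as 1 + Poisson around the
#' scaled expectation -- guaranteeing presence while producing the singletons
#' and doubletons the coverage estimator feeds on.
#'
#' @param n_sites number of sites (>= 2).
#' @param n_core species present at every site.
#' @param n_exclusive per-site exclusive species counts; either a vector of
#'   length `n_sites` or a scalar that is spread across sites according to
#'   `turnover_bias`.
#' @param turnover_bias in \[0, 1\]; with a scalar `n_exclusive`, 1 gives
#'   every site the same number of exclusives (pure turnover, beta_rich = 0
#'   for every pair) and smaller values tilt the counts into a linear
#'   gradient across sites (mean preserved), raising the richness-difference
#'   component.
#' @param n_patchy species occupying a random subset of sites (>= 2 sites,
#'   < all sites).
#' @param patchy_memberships total number of site occupancies to distribute
#'   over the patchy species (default 3 per species).
#' @param site_weights relative weights steering which sites patchy species
#'   land in (default uniform).
#' @param site_names optional site labels.
#' @param group group label for the generated tables.
#' @param ranks ordered rank names, coarse to fine, ending in `"species"`.
#' @param branching integer vector, one entry per rank: number of children
#'   under each parent taxon (first entry = taxa at the coarsest rank).
#' @param ragged_drop named numeric vector of per-lineage drop probabilities
#'   for intermediate ranks (e.g. `c(subfamily = 0.5)`); dropped cells are
#'   blank, emulating ragged real classifications.
#' @param abundance_ratio geometric-series ratio in (0, 1); smaller values
#'   give steeper rank-abundance curves and more rare species.
#' @param mean_records target mean number of records per species per site.
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `community_design` (a list of the above).
#' @export
community_design <- function(n_sites = 6, n_core = 5, n_exclusive = 3,
                             turnover_bias = 1, n_patchy = 0,
                             patchy_memberships = 3 * n_patchy,
                             site_weights = NULL, site_names = NULL,
                             group = "group1",
                             ranks = c("family", "genus", "species"),
                             branching = c(3, 3, 4),
                             ragged_drop = NULL,
                             abundance_ratio = 0.9, mean_records = 10,
                             seed = 1L) {
  if (n_sites < 2) bt_stop("need at least 2 sites", "betataxa_design_error")
  if (abundance_ratio <= 0 || abundance_ratio >= 1) {
    bt_stop("abundance_ratio must be in (0, 1)", "betataxa_design_error")
  }
  if (length(ranks) != length(branching)) {
    bt_stop("branching must give one count per rank", "betataxa_design_error")
  }
  if (ranks[length(ranks)] != "species") {
    bt_stop("ranks must end in 'species'", "betataxa_design_error")
  }
  if (length(n_exclusive) == 1) {
    base <- n_exclusive
    grad <- seq(-1, 1, length.out = n_sites)
    n_exclusive <- pmax(0L, as.integer(round(
      base * (1 + (1 - turnover_bias) * grad))))
  } else if (length(n_exclusive) != n_sites) {
    bt_stop("n_exclusive must be scalar or length n_sites",
            "betataxa_design_error")
  }
  if (is.null(site_names)) site_names <- paste0("site", seq_len(n_sites))
  if (is.null(site_weights)) site_weights <- rep(1, n_sites)
  structure(
    list(n_sites = n_sites, n_core = as.integer(n_core),
         n_exclusive = as.integer(n_exclusive),
         turnover_bias = turnover_bias, n_patchy = as.integer(n_patchy),
         patchy_memberships = as.integer(patchy_memberships),
         site_weights = site_weights, site_names = site_names,
         group = group, ranks = ranks, branching = as.integer(branching),
         ragged_drop = ragged_drop, abundance_ratio = abundance_ratio,
         mean_records = mean_records, seed = as.integer(seed)),
    class = "community_design"
  )
}

#' Generate a taxonomy with fixed branching
#'
#' Builds a fully factorial rooted classification from the design's
#' `branching` vector: `branching[1]` taxa at the coarsest rank, each with
#' `branching[2]` children, and so on down to species.  In ragged mode
#' (`ragged_drop`), intermediate-rank cells are blanked independently per
#' lineage with the given probabilities, so lineages differ in depth as real
#' classifications do.  Deterministic given the design seed.
#'
#' @param design a `community_design`.
#' @return a `taxonomy_table` with `prod(branching)` species.
#' @export
generate_taxonomy <- function(design) {
  stopifnot(inherits(design, "community_design"))
  counts <- cumprod(design$branching)
  n_species <- counts[length(counts)]
  if (n_species < 1) {
    bt_stop("branching produces zero species", "betataxa_design_error")
  }
  L <- length(design$ranks)
  # mixed-radix path of each species through the hierarchy
  assignments <- data.frame(row.names = seq_len(n_species))
  idx <- seq_len(n_species) - 1L
  for (r in seq_len(L)) {
    stride <- n_species / counts[r]
    taxon_id <- idx %/% stride + 1L
    assignments[[design$ranks[r]]] <-
      paste0(gsub("[^a-z]", "", tolower(design$ranks[r])), taxon_id)
  }
  assignments$species <- paste0("sp", seq_len(n_species))
  if (!is.null(design$ragged_drop)) {
    set.seed(derive_seed(design$seed, 11L))
    for (r in names(design$ragged_drop)) {
      if (!r %in% design$ranks || r == "species" || r == design$ranks[1]) next
      drop <- stats::runif(n_species) < design$ragged_drop[[r]]
      assignments[[r]][drop] <- ""
    }
  }
  taxonomy_table(design$group, assignments)
}

# Poisson rates of the geometric-series abundance model for a site holding
# s species with a target of mean_records per species.
abundance_lambda <- function(s, mean_records, ratio) {
  w <- ratio^(seq_len(s) - 1)
  w <- w / sum(w)
  extra <- max(mean_records * s - s, 0)
  extra * w
}

#' Generate a multi-site occurrence table from a design
#'
#' Realizes the design's compositional skeleton on the species of a
#' taxonomy: the shared core occupies every site, each site gains its
#' exclusive species, and patchy species are placed on weighted random
#' subsets of 2..(n_sites - 1) sites.  Record counts are drawn from the
#' geometric-series abundance model (see [community_design()]).  The realized
#' per-pair matching components are attached as attribute
#' `"true_components"` (a data frame with `site_i`, `site_j`, `a`, `b`, `c`)
#' and the presence sets as attribute `"presence"` -- the ground truth
#' against which the dissimilarity pipeline can be validated end to end.
#'
#' @param design a `community_design`.
#' @param tax a `taxonomy_table` with at least `n_core + sum(n_exclusive) +
#'   n_patchy` species (default: generated from the design).
#' @return an `occurrence_table` with attributes `true_components` and
#'   `presence`.
#' @export
generate_occurrences <- function(design, tax = generate_taxonomy(design)) {
  stopifnot(inherits(design, "community_design"))
  need <- design$n_core + sum(design$n_exclusive) + design$n_patchy
  pool <- tax$assignments$species
  if (length(pool) < need) {
    bt_stop(sprintf("design needs %d species but taxonomy has %d",
                    need, length(pool)),
            "betataxa_design_error")
  }
  set.seed(derive_seed(design$seed, 23L))
  pool <- sample(pool)
  core <- pool[seq_len(design$n_core)]
  used <- design$n_core
  presence <- stats::setNames(
    rep(list(character(0)), design$n_sites), design$site_names)
  for (i in seq_len(design$n_sites)) presence[[i]] <- core
  for (i in seq_len(design$n_sites)) {
    k <- design$n_exclusive[i]
    if (k > 0) {
      presence[[i]] <- c(presence[[i]], pool[used + seq_len(k)])
      used <- used + k
    }
  }
  if (design$n_patchy > 0) {
    n_p <- design$n_patchy
    k_min <- 2L
    k_max <- design$n_sites - 1L
    ks <- rep(k_min, n_p)
    extra <- design$patchy_memberships - k_min * n_p
    if (extra < 0 || extra > n_p * (k_max - k_min)) {
      bt_stop("patchy_memberships incompatible with 2..(n_sites-1) occupancy",
              "betataxa_design_error")
    }
    while (extra > 0) {
      candidates <- which(ks < k_max)
      bump <- candidates[sample.int(length(candidates),
                                    min(extra, length(candidates)))]
      ks[bump] <- ks[bump] + 1L
      extra <- extra - length(bump)
    }
    w <- design$site_weights
    for (m in seq_len(n_p)) {
      sp <- pool[used + m]
      sites_m <- sample.int(design$n_sites, ks[m], prob = w)
      for (i in sites_m) presence[[i]] <- c(presence[[i]], sp)
    }
    used <- used + n_p
  }
  # record counts: geometric-series rank abundance per site, presence kept
  rows <- list()
  for (i in seq_len(design$n_sites)) {
    spp <- presence[[i]]
    s <- length(spp)
    if (s == 0) next
    lambda <- abundance_lambda(s, design$mean_records, design$abundance_ratio)
    ord <- sample.int(s)  # random assignment of abundance ranks to species
    counts <- 1L + stats::rpois(s, lambda[ord])
    rows[[i]] <- data.frame(group = design$group, species = spp,
                            site = design$site_names[i], records = counts,
                            stringsAsFactors = FALSE)
  }
  occ <- occurrence_table(do.call(rbind, rows))
  prs <- utils::combn(design$n_sites, 2)
  truth <- data.frame(
    site_i = design$site_names[prs[1, ]], site_j = design$site_names[prs[2, ]],
    a = NA_integer_, b = NA_integer_, c = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(prs))) {
    comp <- pair_components(presence[[prs[1, k]]], presence[[prs[2, k]]])
    truth$a[k] <- comp$a; truth$b[k] <- comp$b; truth$c[k] <- comp$c
  }
  attr(occ, "true_components") <- truth
  attr(occ, "presence") <- presence
  occ
}

#' Hidalgo-like simulation preset
#'
#' Four vertebrate-like groups across six ecoregion-like sites, with per-site
#' richness and record magnitudes on the scale of a state-level terrestrial
#' vertebrate survey in central Mexico (tens of amphibian species to hundreds
#' of bird species per site, record totals in the thousands), and per-group
#' Linnaean rank lists of realistic, ragged depth (5 ranks for amphibians up
#' to 15 for birds).  Species, taxa and sites are synthetic labels; only the
#' magnitudes and the structure are emulated.
#'
#' @param seed master seed; each group derives its own sub-seed.
#' @return named list of `community_design` objects, one per group.
#' @export
hidalgo_like_designs <- function(seed = 1L) {
  sites <- c("Montane Forests", "Moist Forests", "Volcanic Belt",
             "Mexican Matorral", "Meseta Central", "Sierra Madre")
  richness <- list(
    amphibians = c(29, 21, 18, 13, 9, 28),
    reptiles   = c(66, 53, 30, 47, 36, 58),
    birds      = c(267, 217, 189, 211, 213, 309),
    mammals    = c(69, 32, 22, 48, 45, 47)
  )
  totals <- c(amphibians = 50, reptiles = 131, birds = 515, mammals = 104)
  mean_recs <- c(amphibians = 13, reptiles = 13, birds = 23, mammals = 14)
  # steeper rank-abundance curves for the species-poor groups so that
  # singletons and doubletons occur at realistic rates at every richness scale
  ratios <- c(amphibians = 0.8, reptiles = 0.9, birds = 0.97, mammals = 0.9)
  ranks <- list(
    amphibians = c("order", "family", "subfamily", "genus", "species"),
    reptiles = c("subclass", "order", "suborder", "infraorder", "superfamily",
                 "family", "subfamily", "genus", "species"),
    birds = c("subclass", "infraclass", "parvclass", "superdivision",
              "division", "subdivision", "infradivision", "superorder",
              "order", "suborder", "superfamily", "family", "subfamily",
              "genus", "species"),
    mammals = c("order", "suborder", "infraorder", "superfamily", "family",
                "subfamily", "tribe", "genus", "species")
  )
  branching <- list(
    amphibians = c(2, 5, 1, 3, 2),                       # 60 species
    reptiles   = c(1, 2, 2, 2, 1, 2, 1, 3, 3),           # 144 species
    birds      = c(1, 1, 1, 1, 1, 2, 1, 2, 3, 2, 1, 3, 1, 3, 3),  # 648
    mammals    = c(3, 2, 1, 1, 2, 2, 1, 3, 2)            # 144 species
  )
  ragged <- list(
    amphibians = c(subfamily = 0.4),
    reptiles = c(infraorder = 0.3, superfamily = 0.5, subfamily = 0.4),
    birds = c(parvclass = 0.3, superdivision = 0.5, division = 0.5,
              subdivision = 0.5, infradivision = 0.5, superfamily = 0.4,
              subfamily = 0.4),
    mammals = c(superfamily = 0.5, subfamily = 0.4, tribe = 0.6)
  )
  designs <- list()
  for (g in names(richness)) {
    s_i <- richness[[g]]
    core <- min(s_i) %/% 2
    excl <- pmin(round(0.2 * s_i), s_i - core)
    n_p <- totals[[g]] - core - sum(excl)
    memberships <- sum(s_i) - length(sites) * core - sum(excl)
    w <- pmax(s_i - core - excl, 1)
    designs[[g]] <- community_design(
      n_sites = length(sites), n_core = core, n_exclusive = excl,
      n_patchy = n_p, patchy_memberships = memberships,
      site_weights = w, site_names = sites, group = g,
      ranks = ranks[[g]], branching = branching[[g]],
      ragged_drop = ragged[[g]],
      abundance_ratio = ratios[[g]], mean_records = mean_recs[[g]],
      seed = derive_seed(seed, match(g, names(richness)))
    )
  }
  designs
}
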