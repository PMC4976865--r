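test_that("matching components follow set algebra", {
  comp <- pair_components(c("s1", "s2", "s3", "s4"), c("s1", "s2", "s5"))
  expect_equal(comp[c("a", "b", "c")], list(a = 2L, b = 2L, c = 1L))
  same <- pair_components(letters[1:5], letters[1:5])
  expect_equal(same[c("a", "b", "c")], list(a = 5L, b = 0L, c = 0L))
})

test_that("pair components agree with a brute-force double loop", {
  set.seed(101)
  for (i in 1:50) {
    A <- sample(paste0("e", 1:40), 20)
    B <- sample(paste0("e", 1:40), 20)
    got <- pair_components(A, B)
    want <- brute_components(A, B)
    expect_equal(got$a, want$a)
    expect_equal(got$b, want$b)
    expect_equal(got$c, want$c)
  }
})

test_that("the partition matches its closed forms and known cases", {
  p <- beta_partition(list(a = 2, b = 2, c = 1))
  expect_equal(p$beta_cc, 0.6)
  expect_equal(p$beta_3, 0.4)
  expect_equal(p$beta_rich, 0.2)

  disjoint <- beta_partition(list(a = 0, b = 2, c = 3))
  expect_equal(disjoint$beta_cc, 1.0)
  expect_equal(disjoint$beta_3, 0.8)
  expect_equal(disjoint$beta_rich, 0.2)

  identical_sites <- beta_partition(list(a = 5, b = 0, c = 0))
  expect_equal(unlist(identical_sites[c("beta_cc", "beta_3", "beta_rich")]),
               c(beta_cc = 0, beta_3 = 0, beta_rich = 0))

  expect_warning(und <- beta_partition(list(a = 0, b = 0, c = 0)),
                 class = "betataxa_undefined_pair_warning")
  expect_true(all(is.na(unlist(und))))
})

test_that("partition additivity, range, symmetry and monotonicity hold", {
  set.seed(7)
  for (i in 1:500) {
    abc <- sample(0:50, 3, replace = TRUE)
    if (sum(abc) == 0) abc[1] <- 1
    p <- beta_partition(list(a = abc[1], b = abc[2], c = abc[3]))
    expect_equal(p$beta_3 + p$beta_rich, p$beta_cc, tolerance = 1e-12)
    expect_true(all(unlist(p) >= 0 & unlist(p) <= 1))
    expect_lte(p$beta_3, p$beta_cc + 1e-15)
    expect_lte(p$beta_rich, p$beta_cc + 1e-15)
    # symmetry in (b, c)
    q <- beta_partition(list(a = abc[1], b = abc[3], c = abc[2]))
    expect_equal(unlist(p), unlist(q))
    # total dissimilarity is 1 iff nothing is shared
    expect_identical(p$beta_cc == 1, abc[1] == 0L)
    # adding a shared element never increases total dissimilarity
    p2 <- beta_partition(list(a = abc[1] + 1, b = abc[2], c = abc[3]))
    expect_lte(p2$beta_cc, p$beta_cc)
  }
})

test_that("species-level beta_cc equals the binary Jaccard of vegan", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(rbinom(6 * 25, 1, 0.5), nrow = 6,
                dimnames = list(paste0("S", 1:6), paste0("sp", 1:25)))
    m[1, ] <- pmax(m[1, ], 1L)  # avoid empty sites
    inc <- structure(m, group = "g", empty_sites = character(0),
                     class = c("incidence_matrix", "matrix", "array"))
    pw <- pairwise_beta(inc, "species")
    ref <- as.matrix(vegan::vegdist(m, method = "jaccard", binary = TRUE))
    for (k in seq_len(nrow(pw))) {
      expect_equal(pw$beta_cc[k], ref[pw$site_i[k], pw$site_j[k]],
                   tolerance = 1e-12)
    }
  }
})

test_that("contrasting taxonomic arrangements separate equal species dissimilarity", {
  shared <- fig1_case_shared_taxa()
  split <- fig1_case_split_taxa()

  sp_beta <- beta_partition(pair_components(shared$siteA, shared$siteB))
  expect_equal(sp_beta$beta_cc, 11 / 15)

  t1 <- taxonomic_partition(shared$siteA, shared$siteB, shared$tax)
  t2 <- taxonomic_partition(split$siteA, split$siteB, split$tax)
  expect_equal(t1$beta_cc, 11 / 26)
  expect_equal(round(t1$beta_cc, 3), 0.423)
  expect_equal(t2$beta_cc, 20 / 26)
  expect_equal(round(t2$beta_cc, 3), 0.769)
  # both arrangements leave the species-level dissimilarity untouched
  sp2 <- beta_partition(pair_components(split$siteA, split$siteB))
  expect_equal(sp_beta$beta_cc, sp2$beta_cc)

  # identical species lists give a null partition at every rank
  t0 <- taxonomic_partition(shared$siteA, shared$siteA, shared$tax)
  expect_equal(unlist(t0), c(beta_cc = 0, beta_3 = 0, beta_rich = 0))
})

test_that("taxonomic dissimilarity can exceed species dissimilarity (no enforced order)", {
  # species-level: 1 of 3 shared.  The shared species sits on a ragged,
  # shallow lineage (no named higher taxa) while the two unshared species
  # carry deep exclusive lineages, so unshared taxa dominate the pooled
  # taxon set and beta_ccT > beta_cc.  The empirical pattern that taxonomic
  # dissimilarity is lower than species dissimilarity is a property of real
  # data, not a theorem, and the code must not enforce it.
  deep <- paste0("r", 1:8)
  mk <- function(vals) stats::setNames(as.list(vals), deep)
  rows <- rbind(
    data.frame(mk(rep("", 8)), species = "s1"),
    data.frame(mk(paste0("Aclade", 1:8)), species = "s2"),
    data.frame(mk(paste0("Bclade", 1:8)), species = "s3")
  )
  tax <- taxonomy_table("counterexample", rows)
  sp <- beta_partition(pair_components(c("s1", "s2"), c("s1", "s3")))
  tx <- taxonomic_partition(c("s1", "s2"), c("s1", "s3"), tax)
  expect_equal(sp$beta_cc, 2 / 3)
  expect_equal(tx$beta_cc, 18 / 19)  # 1 shared taxon, 9 + 9 exclusive
  expect_gt(tx$beta_cc, sp$beta_cc)
})

test_that("pairwise tables enumerate unordered pairs and compose correctly", {
  set.seed(5)
  m <- matrix(rbinom(18, 1, 0.6), nrow = 3,
              dimnames = list(paste0("S", 1:3), paste0("sp", 1:6)))
  m[, 1] <- 1L
  inc <- structure(m, group = "g", empty_sites = character(0),
                   class = c("incidence_matrix", "matrix", "array"))
  pw <- pairwise_beta(inc, "species")
  expect_equal(nrow(pw), 3)

  m6 <- matrix(1L, nrow = 6, ncol = 2,
               dimnames = list(paste0("S", 1:6), c("sp1", "sp2")))
  inc6 <- structure(m6, group = "g", empty_sites = character(0),
                    class = c("incidence_matrix", "matrix", "array"))
  expect_equal(nrow(pairwise_beta(inc6, "species")), 15)

  # compositional oracle: table rows equal partition(pair_components(...))
  sets <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] == 1])
  for (k in seq_len(nrow(pw))) {
    i <- match(pw$site_i[k], rownames(m)); j <- match(pw$site_j[k], rownames(m))
    want <- beta_partition(pair_components(sets[[i]], sets[[j]]))
    expect_equal(pw$beta_cc[k], want$beta_cc)
    expect_equal(pw$beta_3[k], want$beta_3)
    expect_equal(pw$beta_rich[k], want$beta_rich)
  }

  expect_error(pairwise_beta(inc[1, , drop = FALSE], "species"),
               class = "betataxa_size_error")
  expect_error(pairwise_beta(inc, "taxonomic"),
               class = "betataxa_schema_error")
})

test_that("pairs involving an empty site are missing, not zero", {
  m <- rbind(S1 = c(1L, 1L, 0L), S2 = c(0L, 1L, 1L), S3 = c(0L, 0L, 0L))
  colnames(m) <- paste0("sp", 1:3)
  inc <- structure(m, group = "g", empty_sites = "S3",
                   class = c("incidence_matrix", "matrix", "array"))
  expect_warning(pw <- pairwise_beta(inc, "species"),
                 class = "betataxa_empty_site_warning")
  expect_true(all(is.na(pw$beta_cc[pw$site_i == "S3" | pw$site_j == "S3"])))
  expect_false(anyNA(pw$beta_cc[pw$site_i != "S3" & pw$site_j != "S3"]))
})

test_that("multiple-site partition reduces to pairwise at T = 2", {
  m <- rbind(A = c(1L, 1L, 1L, 0L), B = c(1L, 0L, 0L, 1L))
  colnames(m) <- paste0("sp", 1:4)
  inc <- structure(m, group = "g", empty_sites = character(0),
                   class = c("incidence_matrix", "matrix", "array"))
  pw <- pairwise_beta(inc, "species")
  for (variant in c("component-sum", "pair-mean")) {
    ms <- multi_site_beta(inc, "species", variant = variant)
    expect_equal(ms$beta_cc, pw$beta_cc[1])
    expect_equal(ms$beta_3, pw$beta_3[1])
    expect_equal(ms$beta_rich, pw$beta_rich[1])
  }
})

test_that("three-site worked example and degenerate cases", {
  m <- rbind(A = c(1L, 1L, 0L, 0L), B = c(0L, 1L, 1L, 0L),
             C = c(0L, 0L, 1L, 1L))
  colnames(m) <- paste0("sp", 1:4)
  inc <- structure(m, group = "g", empty_sites = character(0),
                   class = c("incidence_matrix", "matrix", "array"))
  ms <- multi_site_beta(inc, "species")
  expect_equal(ms$beta_cc, 0.8)
  expect_equal(ms$beta_3, 0.8)
  expect_equal(ms$beta_rich, 0.0)
  expect_equal(ms$pct_turnover, 100)

  ident <- matrix(1L, 3, 4, dimnames = list(LETTERS[1:3], paste0("sp", 1:4)))
  inc_id <- structure(ident, group = "g", empty_sites = character(0),
                      class = c("incidence_matrix", "matrix", "array"))
  expect_warning(ms0 <- multi_site_beta(inc_id, "species"),
                 class = "betataxa_undefined_contribution_warning")
  expect_equal(ms0$beta_cc, 0)
  expect_true(is.na(ms0$pct_turnover))
})

test_that("contribution percentages split total dissimilarity", {
  expect_equal(contribution_percentages(list(beta_cc = 0.8, beta_3 = 0.8)),
               c(turnover = 100, richness_difference = 0))
  expect_equal(contribution_percentages(list(beta_cc = 0.5, beta_3 = 0.25)),
               c(turnover = 50, richness_difference = 50))
  expect_error(contribution_percentages(list(beta_cc = 0, beta_3 = 0)),
               class = "betataxa_undefined_contribution_error")
})
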