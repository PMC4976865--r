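# Independent brute-force oracles kept deliberately naive.

# Matching components by explicit double-loop membership tests.
brute_components <- function(A, B) {
  A <- unique(A); B <- unique(B)
  a <- 0L; b <- 0L
  for (x in A) {
    found <- FALSE
    for (y in B) if (identical(x, y)) found <- TRUE
    if (found) a <- a + 1L else b <- b + 1L
  }
  cc <- 0L
  for (y in B) {
    found <- FALSE
    for (x in A) if (identical(y, x)) found <- TRUE
    if (!found) cc <- cc + 1L
  }
  list(a = a, b = b, c = cc)
}

# Kruskal stress-1 of a configuration against a dissimilarity matrix,
# recomputed from scratch with stats::isoreg (monotone regression of
# configuration distances on the input dissimilarities).
kruskal_stress <- function(d, coords) {
  d <- as.matrix(d)
  dd <- d[lower.tri(d)]
  conf <- as.matrix(stats::dist(coords))[lower.tri(d)]
  ord <- order(dd, conf)
  fit <- stats::isoreg(conf[ord])$yf
  sqrt(sum((conf[ord] - fit)^2) / sum(conf^2))
}

random_community <- function(universe_size = 30, max_size = 20) {
  universe <- paste0("e", seq_len(universe_size))
  sample(universe, sample.int(max_size, 1))
}
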