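# Two-site configurations with identical species-level dissimilarity but
# contrasting taxonomic structure: 15 species (4 shared, 5 exclusive to A,
# 6 exclusive to B) arranged either so that every genus and family occurs at
# both sites, or so that only one genus and one family do.

fig1_species <- function() {
  list(
    shared = paste0("sh", 1:4),
    onlyA = paste0("a", 1:5),
    onlyB = paste0("b", 1:6)
  )
}

# all 8 genera and all 3 families present at both sites: G1..G4 each hold a
# shared species, G5..G8 each hold one A-exclusive and one B-exclusive
# species, and the leftover exclusives ride along in G1..G3
fig1_case_shared_taxa <- function() {
  sp <- fig1_species()
  genus <- c(
    "G1", "G2", "G3", "G4",              # sh1..sh4
    "G5", "G6", "G7", "G8", "G1",        # a1..a5
    "G5", "G6", "G7", "G8", "G2", "G3"   # b1..b6
  )
  family_of <- c(G1 = "F1", G2 = "F1", G3 = "F1", G4 = "F2",
                 G5 = "F2", G6 = "F2", G7 = "F3", G8 = "F3")
  assignments <- data.frame(
    family = unname(family_of[genus]),
    genus = genus,
    species = c(sp$shared, sp$onlyA, sp$onlyB),
    stringsAsFactors = FALSE
  )
  list(
    siteA = c(sp$shared, sp$onlyA),
    siteB = c(sp$shared, sp$onlyB),
    tax = taxonomy_table("fig1", assignments)
  )
}

# only one genus (holding the 4 shared species) and one family shared
fig1_case_split_taxa <- function() {
  sp <- fig1_species()
  assignments <- data.frame(
    family = c(rep("F1", 4),                    # shared genus G0 in F1
               rep("F1", 5),                    # A-only genera also in F1
               rep("F2", 6)),                   # B-only genera in B-only F2
    genus = c(rep("G0", 4),
              c("GA1", "GA1", "GA2", "GA3", "GA4"),
              c("GB1", "GB1", "GB1", "GB2", "GB3", "GB4")),
    species = c(sp$shared, sp$onlyA, sp$onlyB),
    stringsAsFactors = FALSE
  )
  list(
    siteA = c(sp$shared, sp$onlyA),
    siteB = c(sp$shared, sp$onlyB),
    tax = taxonomy_table("fig1", assignments)
  )
}
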