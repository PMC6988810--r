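lineage_for <- function(group, genus = paste0(group, "_gen"),
                        species = paste0(group, "_sp")) {
  c("Eukaryota", "SG", group, paste0(group, "_X"), paste0(group, "_XX"),
    paste0(group, "_fam"), genus, species)
}

test_that("built-in group conventions assign the four trophic modes", {
  taxa <- taxonomy_table(
    paste0("o", 1:6),
    list(lineage_for("Bacillariophyta"), lineage_for("Mamiellophyceae"),
         lineage_for("Labyrinthulea"), lineage_for("Oomycota"),
         lineage_for("Ciliophora"), lineage_for("Cryptophyceae")),
    group = c("Bacillariophyta", "Mamiellophyceae", "Labyrinthulea",
              "Oomycota", "Ciliophora", "Cryptophyceae"))
  got <- assign_trophic(taxa)
  expect_identical(unname(got),
                   c("autotroph", "autotroph", "parasite", "parasite",
                     "heterotroph", "mixotroph"))
})

test_that("unresolved dinoflagellate placeholders stay unassigned", {
  taxa <- taxonomy_table("o1", list(c("Eukaryota", "Alveolata", "Dinophyceae",
                                      "Dinophyceae_X", "Dinophyceae_XX",
                                      "Dinophyceae_XXX", "Dinophyceae_XXXX",
                                      "Dinophyceae_XXX_sp")),
                         group = "Dinophyceae")
  expect_identical(unname(assign_trophic(taxa)), "NA")
  # but a species-level rule resolves it
  rules <- trophic_rules(rbind(as.data.frame(default_trophic_rules()),
                               data.frame(taxon = "Dinophyceae_XXX_sp",
                                          rank = "species",
                                          category = "mixotroph")))
  expect_identical(unname(assign_trophic(taxa, rules)), "mixotroph")
})

test_that("more specific ranks win and rule order never matters", {
  base <- as.data.frame(default_trophic_rules())
  extra <- data.frame(taxon = c("Bacillariophyta_gen", "Bacillariophyta_sp"),
                      rank = c("genus", "species"),
                      category = c("mixotroph", "heterotroph"))
  taxa <- taxonomy_table("o1", list(lineage_for("Bacillariophyta")),
                         group = "Bacillariophyta")
  r1 <- trophic_rules(rbind(base, extra))
  r2 <- trophic_rules(rbind(extra[2:1, ], base))
  expect_identical(unname(assign_trophic(taxa, r1)), "heterotroph")
  expect_identical(assign_trophic(taxa, r1), assign_trophic(taxa, r2))
})

test_that("conflicting rules at equal rank are rejected", {
  bad <- data.frame(taxon = c("Foo", "Foo"), rank = c("group", "group"),
                    category = c("autotroph", "parasite"))
  expect_error(trophic_rules(bad), "conflicting")
  # exact duplicates are tolerated
  ok <- data.frame(taxon = c("Foo", "Foo"), rank = c("group", "group"),
                   category = c("autotroph", "autotroph"))
  expect_identical(nrow(trophic_rules(ok)), 1L)
})

test_that("empty lineages warn and become NA", {
  taxa <- taxonomy_table("o1", list(character(0)))
  expect_warning(got <- assign_trophic(taxa), "empty lineage")
  expect_identical(unname(got), "NA")
})

test_that("trophic composition fractions match hand-computed values", {
  meta <- toy_design(n_dates = 1L)
  one <- meta[meta$replicate == 1L, ]
  m <- otu_table(matrix(c(6L, 2L, 0L, 0L,
                          2L, 2L, 5L, 0L,
                          2L, 0L, 5L, 10L), 3, 4, byrow = TRUE,
                        dimnames = list(c("aut", "het", "par"),
                                        one$sample_id)))
  cats <- c(aut = "autotroph", het = "heterotroph", par = "parasite")
  comp <- trophic_composition(m, one, cats)
  a <- comp[comp$habitat == "A", ]
  expect_equal(a$fraction[a$category == "autotroph"], 8 / 14, tolerance = 1e-12)
  expect_equal(a$fraction[a$category == "heterotroph"], 4 / 14, tolerance = 1e-12)
  expect_equal(sum(a$fraction), 1, tolerance = 1e-9)
  b <- comp[comp$habitat == "B", ]
  expect_equal(b$fraction[b$category == "parasite"], 15 / 20, tolerance = 1e-12)
  # invariant to OTU row order
  comp2 <- trophic_composition(m[c(3, 1, 2), ], one, cats)
  expect_equal(comp$fraction, comp2$fraction, tolerance = 1e-12)
  # an all-autotroph table is 1 everywhere
  all_a <- trophic_composition(m, one, setNames(rep("autotroph", 3),
                                                rownames(m)))
  expect_true(all(all_a$fraction[all_a$category == "autotroph"] == 1))
  # a sample group without reads is an error naming the group
  m0 <- otu_table(matrix(c(1L, 1L, 0L, 0L), 1, 4,
                         dimnames = list("aut", one$sample_id)))
  expect_error(trophic_composition(m0, one, cats["aut"]), "zero reads")
})

test_that("missing categories for table OTUs are an error", {
  meta <- toy_design(n_dates = 1L)
  one <- meta[meta$replicate == 1L, ]
  m <- otu_table(matrix(1L, 2, 4, dimnames = list(c("x", "y"),
                                                  one$sample_id)))
  expect_error(trophic_composition(m, one, c(x = "autotroph")),
               "without a trophic category")
})
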