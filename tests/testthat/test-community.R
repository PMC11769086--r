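test_that("richness counts present taxa", {
  expect_equal(taxon_richness(c(0, 0, 0)), 0)
  expect_equal(taxon_richness(c(1, 0, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0)), 5)
  m <- rbind(a = c(1, 1, 0), b = c(0, 0, 0))
  expect_equal(unname(taxon_richness(m)), c(2, 0))
  # binarized abundance gives the same count
  expect_equal(taxon_richness(c(7, 0, 3)), taxon_richness(c(1, 0, 1)))
})

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_diversity(c(10)), 0)
  expect_equal(shannon_diversity(rep(3, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(1, 1, 2)),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_equal(shannon_diversity(c(2, 2), base = 2), 1)
  expect_error(shannon_diversity(c(0, 0)), "undefined")
})

test_that("Simpson dominance matches closed forms", {
  expect_equal(dominance_index(c(5)), 1)
  expect_equal(dominance_index(rep(2, 4)), 0.25)
  expect_equal(dominance_index(c(7, 7)), 0.5)
  expect_error(dominance_index(numeric(3) * 0), "undefined")
})

test_that("uniform communities maximize H (= ln T) and minimize D (= 1/T)", {
  set.seed(81)
  for (T in 2:10) {
    uni <- rep(5, T)
    expect_equal(shannon_diversity(uni), log(T), tolerance = 1e-12)
    expect_equal(dominance_index(uni), 1 / T, tolerance = 1e-12)
    for (rep in 1:5) {
      skewed <- rpois(T, 5) + 1
      if (length(unique(skewed)) == 1) next
      expect_lt(shannon_diversity(skewed), log(T))
      expect_gt(dominance_index(skewed), 1 / T)
    }
  }
})

test_that("metrics agree with vegan on random abundance vectors", {
  skip_if_not_installed("vegan")
  set.seed(91)
  for (rep in 1:10) {
    counts <- rpois(12, 4)
    if (sum(counts) == 0) counts[1] <- 1
    expect_equal(shannon_diversity(counts),
                 unname(vegan::diversity(counts, index = "shannon")),
                 tolerance = 1e-12)
    expect_equal(dominance_index(counts),
                 unname(1 - vegan::diversity(counts, index = "simpson")),
                 tolerance = 1e-12)
  }
})

test_that("bio_metrics tabulates T, H, D per site", {
  ab <- rbind(s1 = c(4, 4, 0), s2 = c(1, 1, 2))
  colnames(ab) <- paste0("t", 1:3)
  occ <- occurrence_matrix(abundance = ab)
  bm <- bio_metrics(occ)
  expect_equal(bm$T, c(2L, 3L))
  expect_equal(bm$H[1], log(2), tolerance = 1e-12)
  expect_equal(bm$D[2], 0.25 + 0.0625 + 0.0625, tolerance = 1e-12)
})

make_tax_occ <- function(phyla, subgroups = NULL, counts = NULL) {
  n <- length(phyla)
  ids <- sprintf("t%03d", seq_len(n))
  pres <- matrix(1, 1, n, dimnames = list("s1", ids))
  tax <- data.frame(taxon_id = ids, phylum = phyla,
                    subgroup = if (is.null(subgroups)) "x" else subgroups,
                    stringsAsFactors = FALSE)
  ab <- if (!is.null(counts)) matrix(counts, 1, n, dimnames = list("s1", ids))
  occurrence_matrix(pres, abundance = ab, taxonomy = tax)
}

test_that("phylum-level shares are percentages of taxonomic units", {
  occ <- make_tax_occ(c("Mollusca", "Mollusca", "Annelida", "Arthropoda"))
  br <- composition_breakdown(occ, "phylum")
  expect_equal(br$percent[br$label == "Mollusca"], 50)
  expect_equal(br$percent[br$label == "Annelida"], 25)
  expect_equal(sum(br$percent), 100, tolerance = 0.05)

  single <- make_tax_occ(rep("Mollusca", 3))
  expect_equal(composition_breakdown(single, "phylum")$percent, 100)
})

test_that("within-phylum shares and the residual 'other' total 100", {
  occ <- make_tax_occ(rep("Arthropoda", 1000),
                      subgroups = rep(c("Insecta", "Crustacea", "other"),
                                      c(843, 89, 68)))
  br <- composition_breakdown(occ, "within_phylum", phylum = "Arthropoda",
                              keep = c("Insecta", "Crustacea"))
  expect_equal(br$percent[br$label == "Insecta"], 84.3, tolerance = 1e-9)
  expect_equal(br$percent[br$label == "Crustacea"], 8.9, tolerance = 1e-9)
  expect_equal(br$percent[br$label == "other"], 6.8, tolerance = 1e-9)
  expect_equal(sum(br$percent), 100, tolerance = 0.05)
  expect_error(composition_breakdown(occ, "within_phylum", phylum = "Mollusca"),
               "not present")
})

test_that("per-site shares use individuals and need abundance", {
  occ <- make_tax_occ(c("Mollusca", "Annelida"), counts = c(70, 30))
  br <- composition_breakdown(occ, "per_site")
  expect_equal(br$percent[br$label == "Mollusca"], 70)
  no_ab <- make_tax_occ(c("Mollusca", "Annelida"))
  expect_error(composition_breakdown(no_ab, "per_site"), "abundance")
})

test_that("composition percentages are invariant to taxon order", {
  set.seed(101)
  occ <- random_occurrence(4, 12, abundance = TRUE)
  br1 <- composition_breakdown(occ, "phylum")
  perm <- sample(12)
  occ2 <- occurrence_matrix(presence = occ$presence[, perm],
                            abundance = occ$abundance[, perm],
                            taxonomy = occ$taxonomy[perm, ])
  br2 <- composition_breakdown(occ2, "phylum")
  br2 <- br2[match(br1$label, br2$label), ]
  expect_equal(br1$percent, br2$percent, tolerance = 1e-9)
  expect_equal(sum(br1$percent), 100, tolerance = 0.05)
})
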