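test_that("Sorensen dissimilarity matches the 2a/(2a+b+c) formula", {
  m <- matrix(c(1, 1, 1, 0,   # shares t1,t2 with s2; t3 unique
                1, 1, 0, 1),  # t4 unique: a=2, b=1, c=1
              nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), paste0("t", 1:4)))
  d <- sorensen_dissimilarity(m)
  expect_equal(d["s1", "s2"], 1 - 4 / 6, tolerance = 1e-12)

  same <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3, byrow = TRUE,
                 dimnames = list(c("a", "b"), paste0("t", 1:3)))
  expect_equal(sorensen_dissimilarity(same)["a", "b"], 0)

  disj <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 2, 4, byrow = TRUE,
                 dimnames = list(c("a", "b"), paste0("t", 1:4)))
  expect_equal(sorensen_dissimilarity(disj)["a", "b"], 1)
})

test_that("Sorensen empty-site conventions: both empty 0 (warning), one empty 1", {
  m <- matrix(c(0, 0, 0, 0, 1, 1), 3, 2, byrow = TRUE,
              dimnames = list(c("e1", "e2", "full"), c("t1", "t2")))
  expect_warning(d <- sorensen_dissimilarity(m), "no taxa")
  expect_equal(d["e1", "e2"], 0)
  expect_equal(d["e1", "full"], 1)
  expect_equal(d["e2", "full"], 1)
})

test_that("Sorensen matrix invariants hold and agree with vegan on random data", {
  skip_if_not_installed("vegan")
  set.seed(11)
  for (rep in 1:10) {
    p <- matrix(rbinom(6 * 10, 1, 0.6), 6, 10,
                dimnames = list(paste0("s", 1:6), paste0("t", 1:10)))
    if (any(rowSums(p) == 0)) p[rowSums(p) == 0, 1] <- 1
    d <- sorensen_dissimilarity(p)
    expect_true(isSymmetric(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d >= 0 & d <= 1))
    v <- as.matrix(vegan::vegdist(p, method = "bray", binary = TRUE))
    expect_equal(unname(d), unname(v), tolerance = 1e-12)
  }
})

test_that("rare-taxon exclusion removes taxa at or below the frequency cutoff", {
  set.seed(3)
  pres <- matrix(1, 30, 3, dimnames = list(paste0("s", 1:30), c("common", "rare", "mid")))
  pres[, "rare"] <- 0; pres[1, "rare"] <- 1          # 1/30 = 3.3% -> out
  pres[, "mid"] <- 0; pres[1:3, "mid"] <- 1          # 10% -> retained
  occ <- occurrence_matrix(pres)
  filt <- filter_rare_taxa(occ, 0.05)
  expect_identical(attr(filt, "retained_taxa"), c("common", "mid"))

  # exactly 5% occurrence is excluded ("less than or equal to")
  pres2 <- matrix(1, 20, 2, dimnames = list(paste0("s", 1:20), c("a", "edge")))
  pres2[, "edge"] <- 0; pres2[1, "edge"] <- 1        # 1/20 = 5%
  filt2 <- filter_rare_taxa(occurrence_matrix(pres2), 0.05)
  expect_identical(attr(filt2, "retained_taxa"), "a")

  allrare <- occurrence_matrix(matrix(0, 20, 1, dimnames = list(paste0("s", 1:20), "t")))
  expect_error(filter_rare_taxa(allrare, 0.05), "every taxon")
})

test_that("group frequencies are within-group occurrence proportions", {
  pres <- rbind(matrix(c(1, 1, 1, 1), 4, 1), matrix(c(1, 1, 0, 0, 0), 5, 1))
  pres <- cbind(pres, 0)
  dimnames(pres) <- list(paste0("s", 1:9), c("tA", "tB"))
  labels <- c(rep(1, 4), rep(2, 5)); names(labels) <- rownames(pres)
  f <- group_frequencies(occurrence_matrix(pres), labels)
  expect_equal(f["tA", "g1"], 1.0)
  expect_equal(f["tA", "g2"], 0.4)
  expect_equal(f["tB", "g1"], 0.0)
  labels_bad <- labels[1:5]
  expect_error(group_frequencies(occurrence_matrix(pres), labels_bad), "cover")
})

test_that("capture probabilities are the membership-weighted frequencies", {
  freqs <- matrix(c(0.8, 0, 0.2, 0), 2, 2,
                  dimnames = list(c("t1", "t2"), c("g1", "g2")))
  m_deg <- matrix(c(1, 0), 1, 2, dimnames = list("s", c("g1", "g2")))
  expect_equal(capture_probabilities(m_deg, freqs)["s", "t1"], 0.8)
  m_half <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("s", c("g1", "g2")))
  pc <- capture_probabilities(m_half, freqs)
  expect_equal(pc["s", "t1"], 0.5)
  expect_equal(pc["s", "t2"], 0)   # absent from all groups -> 0
  bad <- matrix(0.5, 1, 2, dimnames = list("s", c("g1", "g3")))
  expect_error(capture_probabilities(bad, freqs), "group set")
})

test_that("E sums passing pc; O counts observed passing taxa", {
  pc <- c(A = 0.8, B = 0.6, C = 0.3)
  expect_equal(expected_richness(pc, 0.5), 1.4)
  expect_equal(expected_richness(pc, 0), 1.7)
  expect_equal(expected_richness(numeric(0), 0.5), 0)
  expect_equal(observed_richness(c("A", "C"), pc, 0.5), 1)
  expect_equal(observed_richness(c("A", "C"), pc, 0), 2)
  expect_equal(observed_richness(character(0), pc, 0.5), 0)
  # a named presence vector works too
  expect_equal(observed_richness(c(A = 1, B = 0, C = 1), pc, 0.5), 1)
})

test_that("pc in [0,1] and E at threshold 0.5 never exceeds E at threshold 0", {
  set.seed(21)
  for (rep in 1:20) {
    g <- sample(2:4, 1); nt <- sample(5:15, 1)
    freqs <- matrix(runif(nt * g), nt, g,
                    dimnames = list(paste0("t", 1:nt), paste0("g", 1:g)))
    w <- runif(g); w <- w / sum(w)
    mem <- matrix(w, 1, g, dimnames = list("s", paste0("g", 1:g)))
    pc <- capture_probabilities(mem, freqs)
    expect_true(all(pc >= 0 & pc <= 1))
    expect_lte(expected_richness(pc[1, ], 0.5), expected_richness(pc[1, ], 0))
  }
})

test_that("O/E score is the unclamped ratio with a division guard", {
  expect_equal(oe_score(7, 10), 0.7)
  expect_equal(oe_score(10, 10), 1)
  expect_equal(oe_score(12, 10), 1.2)
  expect_error(oe_score(3, 0), "undefined")
})

test_that("O/E grades follow the five-level band table", {
  expect_equal(as.character(grade_oe(0.85)), "Excellent")
  expect_equal(as.character(grade_oe(0.79)), "Excellent")   # lower-inclusive top
  expect_equal(as.character(grade_oe(0.70)), "Healthy")
  expect_equal(as.character(grade_oe(0.50)), "Sub-healthy")
  expect_equal(as.character(grade_oe(0.25)), "General")
  expect_equal(as.character(grade_oe(0.19)), "Poor")        # printed "<= 0.19"
  expect_equal(as.character(grade_oe(0.10)), "Poor")
  expect_error(grade_oe(-0.1), "negative")
})
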