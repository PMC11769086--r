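test_that("standardizations hit their bounds, midpoints, and clamp outside", {
  expect_equal(standardize_decreasing(2.0, 0.2, 2.0), 0)
  expect_equal(standardize_decreasing(0.2, 0.2, 2.0), 1)
  expect_equal(standardize_decreasing(1.1, 0.2, 2.0), 0.5)
  expect_equal(standardize_decreasing(5, 0.2, 2.0), 0)    # clamped
  expect_error(standardize_decreasing(1, 1, 1), "degenerate")

  expect_equal(standardize_increasing(2, 2, 7.5), 0)
  expect_equal(standardize_increasing(7.5, 2, 7.5), 1)
  expect_equal(standardize_increasing(4.75, 2, 7.5), 0.5)

  expect_equal(standardize_dominance(0.9, 0.2, 0.9), 0)
  expect_equal(standardize_dominance(0.2, 0.2, 0.9), 1)
  expect_equal(standardize_dominance(0.1, 0.2, 0.9), 1)   # below Q5, clamped
  expect_error(standardize_dominance(0.5, 0.3, 0.3), "Q95")

  expect_equal(standardize_richness(5, 5, 25), 0)
  expect_equal(standardize_richness(25, 5, 25), 1)
  expect_equal(standardize_richness(15, 5, 25), 0.5)
})

test_that("factor and criterion layers are equal-weight means", {
  expect_equal(nutrient_score(1, 1), 1)
  expect_equal(nutrient_score(0.2, 0.6), 0.4)
  expect_equal(nutrient_score(0, 0), 0)
  expect_equal(oxygen_score(0.3, 0.6, 0.9), 0.6)
  expect_equal(oxygen_score(1, 1, 1), 1)
  expect_equal(biology_score(0.5, 0.7, 0.9), 0.7)
  expect_equal(chemical_score(1, 1), 1)
  expect_equal(chemical_score(0.4, 0.8), 0.6)
  expect_equal(chemical_score(0, 0), 0)
  # the printed-sum variant overshoots and is opt-in only
  expect_equal(chemical_score(1, 1, sum = TRUE), 2)
})

test_that("composite index maps perfect scores to 1 under a = 0.5, n = 2", {
  expect_equal(composite_index(1, 1, a = 0.5), 1.0)
  expect_equal(composite_index(0.6, 0.8), 0.7)
  expect_equal(composite_index(0, 0), 0)
  expect_error(composite_index(0.5, 0.5, n = 3), "n = 2")
})

test_that("composite grades follow the printed bands (lower-inclusive)", {
  expect_equal(as.character(grade_composite(0.85)), "healthy")
  expect_equal(as.character(grade_composite(0.8)), "healthy")
  expect_equal(as.character(grade_composite(0.6)), "sub-healthy")
  expect_equal(as.character(grade_composite(0.4)), "general")
  expect_equal(as.character(grade_composite(0.2)), "poor")
  expect_equal(as.character(grade_composite(0.15)), "very poor")
  expect_error(grade_composite(1.2), "0, 1")
})

make_composite_fixture <- function(tn, tp, nh, cod, do, t, h, d) {
  wq <- data.frame(site_id = "P1", year = 2020L, quarter = 1L,
                   TN = tn, TP = tp, NH3N = nh, CODMn = cod, DO = do)
  bio <- data.frame(site_id = "P1", year = 2020L, quarter = 1L,
                    T = t, H = h, D = d)
  pct <- data.frame(metric = c("T", "H", "D"), Q5 = c(5, 0.5, 0.2),
                    Q95 = c(25, 2.5, 0.9))
  assess_composite(wq, bio, percentiles = pct)
}

test_that("all-best and all-worst indicator values span the composite range", {
  b <- default_standard_bounds()
  g <- function(ind, col) b[[col]][b$indicator == ind]
  best <- make_composite_fixture(g("TN", "Cmin"), g("TP", "Cmin"),
                                 g("NH3N", "Cmin"), g("CODMn", "Cmin"),
                                 g("DO", "Cmax"), 25, 2.5, 0.2)
  expect_equal(best$I, 1.0)
  expect_equal(as.character(best$grade), "healthy")
  worst <- make_composite_fixture(g("TN", "Cmax"), g("TP", "Cmax"),
                                  g("NH3N", "Cmax"), g("CODMn", "Cmax"),
                                  g("DO", "Cmin"), 5, 0.5, 0.9)
  expect_equal(worst$I, 0.0)
  expect_equal(as.character(worst$grade), "very poor")
})

test_that("the composite index responds monotonically to each indicator", {
  base <- list(tn = 1, tp = 0.1, nh = 1, cod = 8, do = 5, t = 15, h = 1.5, d = 0.5)
  I0 <- do.call(make_composite_fixture, unname(base))$I
  worse <- function(field, value) {
    args <- base; args[[field]] <- value
    do.call(make_composite_fixture, unname(args))$I
  }
  expect_lt(worse("tn", 1.5), I0)   # more nitrogen -> worse
  expect_lt(worse("tp", 0.15), I0)
  expect_lt(worse("nh", 1.5), I0)
  expect_lt(worse("cod", 12), I0)
  expect_gt(worse("do", 7), I0)     # more oxygen -> better
  expect_gt(worse("t", 20), I0)
  expect_gt(worse("h", 2), I0)
  expect_lt(worse("d", 0.7), I0)    # more dominance -> worse
})

test_that("equal weights: permuting indicators within a factor leaves I unchanged", {
  a <- make_composite_fixture(0.6, 0.05, 1.2, 6, 5, 15, 1.5, 0.5)
  # swap TN <-> TP on the standardized scale: choose concentrations whose
  # standardized scores swap (S_TN = (2-C)/1.8, S_TP = (0.2-C)/0.19)
  s1 <- (2 - 0.6) / 1.8; s2 <- (0.2 - 0.05) / 0.19
  tn2 <- 2 - 1.8 * s2; tp2 <- 0.2 - 0.19 * s1
  b <- make_composite_fixture(tn2, tp2, 1.2, 6, 5, 15, 1.5, 0.5)
  expect_equal(a$I, b$I, tolerance = 1e-12)
})

test_that("records with missing indicators are skipped, not imputed", {
  wq <- data.frame(site_id = c("P1", "P2"), year = 2020L, quarter = 1L,
                   TN = c(1, NA), TP = 0.1, NH3N = 1, CODMn = 8, DO = 5)
  bio <- data.frame(site_id = c("P1", "P2"), year = 2020L, quarter = 1L,
                    T = c(15, 16), H = 1.5, D = 0.5)
  pct <- data.frame(metric = c("T", "H", "D"), Q5 = c(5, 0.5, 0.2),
                    Q95 = c(25, 2.5, 0.9))
  expect_message(res <- assess_composite(wq, bio, percentiles = pct), "skipped")
  expect_equal(nrow(res), 1)
  expect_equal(res$site_id, "P1")
})

test_that("noise-free seasonal series recovers the planted quarter ordering exactly", {
  s <- generate_waterquality_series(world_spec(seed = 5), paste0("P", 1:11),
                                    years = 5, noise = 0)
  res <- assess_composite(s$wq, s$bio)
  qm <- tapply(res$I, res$quarter, mean)
  expect_true(qm["1"] > qm["4"] && qm["4"] > qm["2"] && qm["2"] > qm["3"])
})
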