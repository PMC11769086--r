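#' Specification of a synthetic lake-survey world
#'
#' Describes a survey world with known ground truth: reference sites fall
#' into `n_groups` biotic groups, each with a disjoint set of characteristic
#' taxa occurring at high probability within the group and low probability
#' elsewhere, plus a few ubiquitous taxa; natural predictors cluster around
#' group centroids; quarterly water quality follows planted degradation
#' levels ordered Q1 best, then Q4, Q2, Q3 (spring best, autumn worst).
#' Every draw is reproducible from the seed.
#'
#' @param n_groups number of reference groups.
#' @param n_ref_per_group reference (training) sites per group.
#' @param n_val_per_group held-out validation sites per group, drawn from the
#'   same group distributions.
#' @param n_taxa total taxa in the regional pool; must admit
#'   `n_groups * n_char_per_group` characteristic taxa.
#' @param n_char_per_group characteristic taxa per group.
#' @param p_high occurrence probability of a characteristic taxon within its
#'   group.
#' @param p_low occurrence probability of a characteristic taxon outside its
#'   group.
#' @param p_common occurrence probability of the ubiquitous taxa (everywhere).
#' @param predictor_noise relative (coefficient-of-variation) noise on the
#'   six natural predictors around their group centroids.
#' @param quarter_levels planted degradation level per quarter (Q1..Q4),
#'   each in `[0, 1)`; the default `c(0.02, 0.18, 0.26, 0.10)` keeps
#'   undisturbed sites near the healthy end of the standard envelope and
#'   orders implied health Q1 > Q4 > Q2 > Q3.
#' @param wq_noise water-quality noise as a fraction of each indicator's
#'   standard envelope range.
#' @param seed master seed.
#' @return object of class `world_spec`.
#' @export
world_spec <- function(n_groups = 3, n_ref_per_group = 5, n_val_per_group = 2,
                       n_taxa = 40, n_char_per_group = 12,
                       p_high = 0.9, p_low = 0.05, p_common = 0.7,
                       predictor_noise = 0.08,
                       quarter_levels = c(0.02, 0.18, 0.26, 0.10),
                       wq_noise = 0.08,
                       seed = 1L) {
  if (n_groups * n_char_per_group > n_taxa)
    stop("n_taxa too small for ", n_groups, " groups of ", n_char_per_group,
         " characteristic taxa", call. = FALSE)
  probs <- c(p_high, p_low, p_common)
  if (any(probs < 0 | probs > 1))
    stop("occurrence probabilities must lie in [0, 1]", call. = FALSE)
  if (length(quarter_levels) != 4 || any(quarter_levels < 0 | quarter_levels >= 1))
    stop("quarter_levels must be four values in [0, 1)", call. = FALSE)
  structure(list(
    n_groups = as.integer(n_groups),
    n_ref_per_group = as.integer(n_ref_per_group),
    n_val_per_group = as.integer(n_val_per_group),
    n_taxa = as.integer(n_taxa),
    n_char_per_group = as.integer(n_char_per_group),
    p_high = p_high, p_low = p_low, p_common = p_common,
    predictor_noise = predictor_noise,
    quarter_levels = quarter_levels,
    wq_noise = wq_noise,
    seed = as.integer(seed)
  ), class = "world_spec")
}

taxon_labels <- function(n) sprintf("t%02d", seq_len(n))

# occurrence probability profile per taxon per group, plus which taxa are
# characteristic of which group
group_profiles <- function(spec) {
  n_char <- spec$n_char_per_group
  profiles <- matrix(spec$p_low, nrow = spec$n_taxa, ncol = spec$n_groups,
                     dimnames = list(taxon_labels(spec$n_taxa),
                                     paste0("g", seq_len(spec$n_groups))))
  char <- vector("list", spec$n_groups)
  for (g in seq_len(spec$n_groups)) {
    idx <- ((g - 1) * n_char + 1):(g * n_char)
    profiles[idx, g] <- spec$p_high
    char[[g]] <- rownames(profiles)[idx]
  }
  common <- setdiff(seq_len(spec$n_taxa), seq_len(spec$n_groups * n_char))
  profiles[common, ] <- spec$p_common
  list(profiles = profiles, characteristic = char,
       common = rownames(profiles)[common])
}

predictor_centroids <- function(spec) {
  base <- c(lake_area = 150, shoreline_length = 60, mean_depth = 5,
            retention_time = 30, mean_temperature = 17.6, mean_rainfall = 1680)
  centroids <- t(vapply(seq_len(spec$n_groups),
                        function(g) base * (1 + 0.5 * (g - 1)),
                        numeric(length(base))))
  rownames(centroids) <- paste0("g", seq_len(spec$n_groups))
  centroids
}

default_taxonomy <- function(n_taxa) {
  phyla <- c("Mollusca", "Annelida", "Arthropoda")
  subs <- list(Mollusca = c("Gastropoda", "Valvularia"),
               Annelida = c("Oligochaeta", "Polychaeta"),
               Arthropoda = c("Insecta", "Crustacea"))
  ph <- rep_len(phyla, n_taxa)
  sg <- vapply(seq_len(n_taxa), function(i)
    subs[[ph[i]]][(i %/% 3) %% 2 + 1], character(1))
  data.frame(taxon_id = taxon_labels(n_taxa), phylum = ph, subgroup = sg,
             stringsAsFactors = FALSE)
}

draw_sites <- function(spec, groups, ids, prof) {
  presence <- t(vapply(groups, function(g)
    as.numeric(stats::runif(spec$n_taxa) < prof$profiles[, g]),
    numeric(spec$n_taxa)))
  abundance <- presence * (1 + stats::rpois(length(presence), 9))
  dimnames(presence) <- dimnames(abundance) <-
    list(ids, rownames(prof$profiles))
  centroids <- predictor_centroids(spec)
  pred <- t(vapply(groups, function(g) {
    mu <- centroids[g, ]
    stats::rnorm(length(mu), mean = mu, sd = spec$predictor_noise * abs(mu))
  }, numeric(ncol(centroids))))
  pred <- as.data.frame(pred, row.names = ids)
  names(pred) <- colnames(centroids)
  list(presence = presence, abundance = abundance, predictors = pred)
}

#' Generate a reference world with known group structure
#'
#' Draws the reference (training) and held-out validation sites of a
#' [world_spec()]: each site's presence vector is drawn independently per
#' taxon from its group's occurrence profile, abundances are Poisson counts
#' for present taxa, and predictors are Gaussian around the group centroid.
#'
#' @param spec a [world_spec()].
#' @param seed seed override (defaults to the seed in the world specification).
#' @return list with `occurrence` ([occurrence_matrix()] over reference and
#'   validation sites), `predictors` (data.frame, row names are site ids),
#'   `sites` (data.frame `site_id`, `role` = reference/test, `group` = true
#'   label), and `spec`.
#' @export
generate_reference_world <- function(spec = world_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(seed)
  prof <- group_profiles(spec)
  groups <- rep(seq_len(spec$n_groups), each = spec$n_ref_per_group)
  ids <- sprintf("ref_g%d_%d", groups, sequence(rep(spec$n_ref_per_group,
                                                    spec$n_groups)))
  vgroups <- rep(seq_len(spec$n_groups), each = spec$n_val_per_group)
  vids <- sprintf("val_g%d_%d", vgroups, sequence(rep(spec$n_val_per_group,
                                                      spec$n_groups)))
  drawn <- draw_sites(spec, c(groups, vgroups), c(ids, vids), prof)
  occurrence <- occurrence_matrix(presence = drawn$presence,
                                  abundance = drawn$abundance,
                                  taxonomy = default_taxonomy(spec$n_taxa))
  sites <- data.frame(
    site_id = c(ids, vids),
    role = c(rep("reference", length(ids)), rep("test", length(vids))),
    group = c(groups, vgroups),
    stringsAsFactors = FALSE
  )
  list(occurrence = occurrence, predictors = drawn$predictors, sites = sites,
       spec = spec, profiles = prof)
}

subset_occurrence <- function(x, sites) {
  occurrence_matrix(
    presence = x$presence[sites, , drop = FALSE],
    abundance = if (!is.null(x$abundance)) x$abundance[sites, , drop = FALSE],
    taxonomy = x$taxonomy
  )
}

#' Generate impaired sites with a known impairment level
#'
#' Starts from a reference group's occurrence profile and suppresses each
#' high-occurrence taxon (the group's characteristic taxa and the ubiquitous
#' ones) independently with probability equal to the impairment fraction, so observed richness of
#' expected taxa drops faster than the model's expectation — the regime the
#' O/E index is designed to detect. Sites with impairment of 0.75 or more
#' take the role `severely_damaged`, positive lower levels `damaged`,
#' impairment 0 `test`.
#'
#' @param world a world from [generate_reference_world()].
#' @param impairment impairment fraction(s) in `[0, 1]`, recycled over
#'   sites.
#' @param n_sites number of impaired sites (assigned to groups cyclically).
#' @param seed seed for the draws.
#' @return list with `occurrence`, `predictors` and `sites` (including the
#'   realized `impairment` per site).
#' @export
generate_impaired_sites <- function(world, impairment, n_sites,
                                    seed = world$spec$seed + 1L) {
  spec <- world$spec
  impairment <- rep_len(impairment, n_sites)
  if (any(impairment < 0 | impairment > 1))
    stop("impairment must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  prof <- world$profiles
  groups <- rep_len(seq_len(spec$n_groups), n_sites)
  ids <- sprintf("imp_g%d_%d", groups, seq_len(n_sites))
  drawn <- draw_sites(spec, groups, ids, prof)
  for (i in seq_len(n_sites)) {
    ct <- c(prof$characteristic[[groups[i]]], prof$common)
    kill <- stats::runif(length(ct)) < impairment[i]
    drawn$presence[i, ct[kill]] <- 0
    drawn$abundance[i, ct[kill]] <- 0
  }
  occurrence <- occurrence_matrix(presence = drawn$presence,
                                  abundance = drawn$abundance,
                                  taxonomy = default_taxonomy(spec$n_taxa))
  sites <- data.frame(
    site_id = ids,
    role = ifelse(impairment >= 0.75, "severely_damaged",
                  ifelse(impairment > 0, "damaged", "test")),
    group = groups,
    impairment = impairment,
    stringsAsFactors = FALSE
  )
  list(occurrence = occurrence, predictors = drawn$predictors, sites = sites)
}

#' Generate a seasonal water-quality and biology series
#'
#' For every site, year and quarter, draws the five chemistry indicators and
#' the three biological metrics around means set by the quarter's planted
#' degradation level (optionally shifted upward by a per-site severity).
#' Pollutant means interpolate the standard envelope from `Cmin` (level 0)
#' to `Cmax` (level 1); DO runs the opposite way; richness and diversity
#' fall, and dominance rises, with the level. Gaussian noise is truncated so
#' concentrations stay non-negative (DO strictly positive).
#'
#' @param spec a [world_spec()] (supplies quarter levels, noise and seed).
#' @param sites character vector of site ids.
#' @param years number of survey years.
#' @param site_severity optional named severity in `[0, 1]` per site, added
#'   (scaled by 0.6) to every quarter's level; encodes site-level
#'   degradation coupled to biological impairment.
#' @param noise noise override (fraction of each indicator's range).
#' @param bounds standard envelope used to place the means.
#' @param seed seed override.
#' @return list with `wq` (columns `site_id`, `year`, `quarter`, `TN`, `TP`,
#'   `NH3N`, `CODMn`, `DO`) and `bio` (`site_id`, `year`, `quarter`, `T`,
#'   `H`, `D`).
#' @export
generate_waterquality_series <- function(spec, sites, years = 5,
                                         site_severity = NULL,
                                         noise = spec$wq_noise,
                                         bounds = default_standard_bounds(),
                                         seed = spec$seed + 2L) {
  stopifnot(inherits(spec, "world_spec"))
  if (is.null(site_severity)) {
    site_severity <- rep(0, length(sites))
    names(site_severity) <- sites
  }
  if (!all(sites %in% names(site_severity)))
    stop("site_severity must be named for every site", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(site_id = sites, year = seq_len(years), quarter = 1:4,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  level <- pmin(0.95, spec$quarter_levels[grid$quarter] +
                  0.6 * site_severity[grid$site_id])
  n <- nrow(grid)
  b <- function(ind, what) bounds[[what]][match(ind, bounds$indicator)]
  draw_chem <- function(ind, increasing = FALSE) {
    rng <- b(ind, "Cmax") - b(ind, "Cmin")
    mu <- if (increasing) b(ind, "Cmax") - level * rng else
      b(ind, "Cmin") + level * rng
    pmax(if (increasing) 0.01 else 0, mu + stats::rnorm(n, sd = noise * rng))
  }
  wq <- data.frame(
    grid,
    TN = draw_chem("TN"), TP = draw_chem("TP"), NH3N = draw_chem("NH3N"),
    CODMn = draw_chem("CODMn"), DO = draw_chem("DO", increasing = TRUE),
    stringsAsFactors = FALSE
  )
  bio <- data.frame(
    grid,
    T = pmax(1, round(25 * (1 - 0.7 * level) + stats::rnorm(n, sd = noise * 25))),
    H = pmax(0, 2.5 * (1 - 0.8 * level) + stats::rnorm(n, sd = noise * 2.5)),
    D = pmin(1, pmax(0.01, 0.2 + 0.6 * level + stats::rnorm(n, sd = noise * 0.6))),
    stringsAsFactors = FALSE
  )
  list(wq = wq, bio = bio)
}
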