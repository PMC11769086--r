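#' Sorensen dissimilarity between sites
#'
#' Pairwise Sorensen dissimilarity on presence/absence vectors,
#' `D = 1 - 2a / (2a + b + c)`, where `a` is the number of shared taxa and
#' `b`, `c` count taxa unique to each site. Two empty sites get dissimilarity
#' 0 (with a warning: the formula is 0/0 there); an empty site against a
#' non-empty one gets 1.
#'
#' @param x an [occurrence_matrix()] or a binary sites x taxa matrix.
#' @param sites optional site ids to restrict to.
#' @return symmetric matrix of dissimilarities in `[0, 1]` with zero diagonal
#'   and site ids as dimnames.
#' @examples
#' m <- matrix(c(1,1,0, 1,0,1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a","b"), c("t1","t2","t3")))
#' sorensen_dissimilarity(m)["a", "b"]  # 1 - 2/3
#' @export
sorensen_dissimilarity <- function(x, sites = NULL) {
  p <- if (is.occurrence_matrix(x)) x$presence else as.matrix(x)
  if (!is.null(sites)) p <- p[sites, , drop = FALSE]
  if (nrow(p) < 2) stop("need at least two sites", call. = FALSE)
  if (!all(p %in% c(0, 1))) stop("presence data must be binary", call. = FALSE)
  shared <- p %*% t(p)                       # a
  n <- rowSums(p)                            # a + b per site
  tot <- outer(n, n, `+`)                    # 2a + b + c
  d <- 1 - 2 * shared / tot
  both_empty <- outer(n == 0, n == 0, `&`)
  if (any(both_empty[upper.tri(both_empty)])) {
    warning("sites with no taxa compared: dissimilarity set to 0 for empty pairs")
    d[both_empty] <- 0
  }
  one_empty <- outer(n == 0, n == 0, xor)
  d[one_empty] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(p), rownames(p))
  d
}

#' Exclude rare taxa before clustering
#'
#' Removes taxa whose occurrence frequency across the given (reference) sites
#' is at or below `max_freq`; the published rule excludes occurrences of 5%
#' or less. The retained-taxon list is recorded as an attribute.
#'
#' @param x an [occurrence_matrix()].
#' @param max_freq maximum retained occurrence frequency, in `[0, 1)`.
#' @return filtered [occurrence_matrix()] with attribute `retained_taxa`.
#' @export
filter_rare_taxa <- function(x, max_freq = 0.05) {
  stopifnot(is.occurrence_matrix(x))
  if (max_freq < 0 || max_freq >= 1) stop("max_freq must lie in [0, 1)", call. = FALSE)
  freq <- colMeans(x$presence)
  keep <- freq > max_freq
  if (!any(keep))
    stop("rare-taxon exclusion removed every taxon; model cannot be built",
         call. = FALSE)
  out <- occurrence_matrix(
    presence = x$presence[, keep, drop = FALSE],
    abundance = if (!is.null(x$abundance)) x$abundance[, keep, drop = FALSE],
    taxonomy = if (!is.null(x$taxonomy))
      x$taxonomy[x$taxonomy$taxon_id %in% colnames(x$presence)[keep], , drop = FALSE]
  )
  attr(out, "retained_taxa") <- colnames(x$presence)[keep]
  out
}

# Agglomerative merge tree under the Lance-Williams recurrence with
# alpha_i = alpha_j = (1 - beta)/2, gamma = 0 (the "flexible beta" family).
flexible_beta_tree <- function(d, beta = -0.5) {
  if (beta >= 1) stop("beta must be < 1", call. = FALSE)
  dd <- stats::as.dist(d)
  alpha <- (1 - beta) / 2
  ag <- cluster::agnes(dd, diss = TRUE, method = "flexible",
                       par.method = c(alpha, alpha, beta))
  stats::as.hclust(ag)
}

#' Flexible-beta agglomerative clustering of reference sites
#'
#' Builds the agglomerative merge tree under the Lance-Williams recurrence
#' with `alpha_i = alpha_j = (1 - beta)/2`, `gamma = 0` — for the default
#' `beta = -0.5` each merge updates
#' `d(k, ij) = 0.75 d(k,i) + 0.75 d(k,j) - 0.5 d(i,j)` — and cuts it at
#' `n_groups`. Deterministic for fixed input.
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [sorensen_dissimilarity()]) or a `dist` object.
#' @param n_groups number of groups to cut the tree at.
#' @param beta flexible-beta parameter, `beta < 1`.
#' @return integer group labels (1-based) named by site id.
#' @export
flexible_beta_cluster <- function(d, n_groups, beta = -0.5) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n_groups < 1 || n_groups > n)
    stop("n_groups must lie in [1, number of sites]", call. = FALSE)
  if (n_groups == n) {
    labels <- seq_len(n)
    names(labels) <- rownames(dm)
    return(labels)
  }
  tree <- flexible_beta_tree(dm, beta)
  stats::cutree(tree, k = n_groups)
}

#' Select the number of reference groups by mean silhouette width
#'
#' Cuts the flexible-beta tree at each candidate count and returns the one
#' maximizing the mean silhouette width computed from the dissimilarity
#' matrix; ties break toward the smaller count.
#'
#' @inheritParams flexible_beta_cluster
#' @param candidates integer candidate group counts, each in
#'   `[2, n_sites - 1]`.
#' @return the selected group count, with attribute `silhouette` holding the
#'   mean widths per candidate.
#' @export
select_n_groups <- function(d, candidates = NULL, beta = -0.5) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) stop("need at least three reference sites to select a group count",
                  call. = FALSE)
  if (is.null(candidates)) candidates <- 2:min(8, n - 1)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 2 | candidates > n - 1))
    stop("candidates must lie in [2, n_sites - 1]", call. = FALSE)
  tree <- flexible_beta_tree(dm, beta)
  width <- vapply(candidates, function(k) {
    sil <- cluster::silhouette(stats::cutree(tree, k = k), dmatrix = dm)
    mean(sil[, "sil_width"])
  }, numeric(1))
  best <- candidates[which.max(width)]   # which.max takes the first maximum:
  names(width) <- candidates             # ascending candidates => smaller count
  structure(best, silhouette = width)
}

#' Per-group taxon occurrence frequencies
#'
#' For every retained taxon and reference group, the fraction of the group's
#' sites where the taxon occurs: `f(t|g) = #\{group-g sites with t\} / #group-g
#' sites`. These are the group-conditional occurrence probabilities that the
#' capture probabilities weight.
#'
#' @param x an [occurrence_matrix()] restricted to the reference sites.
#' @param labels group labels named by site id (see
#'   [flexible_beta_cluster()]).
#' @return taxa x groups matrix of frequencies in `[0, 1]`.
#' @export
group_frequencies <- function(x, labels) {
  p <- if (is.occurrence_matrix(x)) x$presence else as.matrix(x)
  labels <- labels[rownames(p)]
  if (any(is.na(labels))) stop("labels must cover all reference sites", call. = FALSE)
  groups <- sort(unique(labels))
  f <- vapply(groups, function(g) {
    rows <- p[labels == g, , drop = FALSE]
    if (nrow(rows) == 0) stop("empty reference group ", g, call. = FALSE)
    colMeans(rows)
  }, numeric(ncol(p)))
  dimnames(f) <- list(colnames(p), paste0("g", groups))
  f
}

#' Random-forest classifier from natural predictors to reference groups
#'
#' Fits a 100-tree (configurable) random forest of unlimited depth mapping
#' the natural predictors (geomorphological and climatic) to the reference
#' groups, and reports stratified cross-validated accuracy. Membership
#' probabilities for any predictor vector are tree-vote fractions and sum
#' to 1.
#'
#' @param predictors data.frame of numeric predictors, one row per reference
#'   site (row names are site ids).
#' @param labels group labels named by site id.
#' @param n_trees number of trees.
#' @param cv_folds requested cross-validation folds; reduced with a warning
#'   when the smallest group has fewer sites than folds.
#' @param seed RNG seed for the forest and the fold assignment.
#' @return object of class `group_classifier` with elements `forest`,
#'   `cv_accuracy`, `cv_folds`, `groups`.
#' @export
fit_group_classifier <- function(predictors, labels, n_trees = 100,
                                 cv_folds = 5, seed = 1L) {
  predictors <- as.data.frame(predictors)
  labels <- labels[rownames(predictors)]
  if (any(is.na(labels))) stop("labels must cover all predictor rows", call. = FALSE)
  if (any(is.na(as.matrix(predictors))))
    stop("predictors must be complete (no missing values)", call. = FALSE)
  y <- factor(labels)
  if (nlevels(y) < 2) stop("need at least two groups to fit a classifier", call. = FALSE)
  min_group <- min(table(y))
  folds <- cv_folds
  if (min_group < folds) {
    folds <- max(2L, as.integer(min_group))
    warning("smallest group has ", min_group,
            " sites; cross-validation reduced to ", folds, " folds")
  }
  set.seed(seed)
  # stratified fold assignment
  fold_id <- integer(length(y))
  for (g in levels(y)) {
    idx <- which(y == g)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  correct <- logical(length(y))
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    if (!any(hold)) next
    fit <- randomForest::randomForest(
      x = predictors[!hold, , drop = FALSE], y = droplevels(y[!hold]),
      ntree = n_trees)
    pred <- as.character(stats::predict(fit, predictors[hold, , drop = FALSE]))
    correct[hold] <- pred == as.character(y[hold])
  }
  forest <- randomForest::randomForest(x = predictors, y = y, ntree = n_trees)
  structure(list(forest = forest, cv_accuracy = mean(correct),
                 cv_folds = folds, groups = levels(y)),
            class = "group_classifier")
}

#' Predict reference-group membership probabilities
#'
#' @param classifier a `group_classifier` from [fit_group_classifier()].
#' @param predictors data.frame of predictor rows for new sites.
#' @return sites x groups matrix of membership probabilities, each row
#'   non-negative and summing to 1.
#' @export
predict_membership <- function(classifier, predictors) {
  stopifnot(inherits(classifier, "group_classifier"))
  p <- stats::predict(classifier$forest, as.data.frame(predictors), type = "prob")
  p <- as.matrix(p)
  colnames(p) <- paste0("g", colnames(p))
  rownames(p) <- rownames(predictors)
  p
}

#' Capture probabilities for each taxon at each site
#'
#' The probability of capture of taxon `t` at a site is its group-conditional
#' occurrence frequency weighted by the site's group-membership
#' probabilities: `pc(t) = sum_g p_g f(t|g)`. Larger pc means the taxon is
#' more likely to occur at the site under reference conditions.
#'
#' @param membership sites x groups probability matrix
#'   ([predict_membership()]).
#' @param freqs taxa x groups frequency matrix ([group_frequencies()]).
#' @return sites x taxa matrix of capture probabilities in `[0, 1]`.
#' @export
capture_probabilities <- function(membership, freqs) {
  membership <- as.matrix(membership)
  freqs <- as.matrix(freqs)
  if (!identical(sort(colnames(membership)), sort(colnames(freqs))))
    stop("membership and frequencies must share the same group set", call. = FALSE)
  membership[, colnames(freqs), drop = FALSE] %*% t(freqs)
}

passes_threshold <- function(pc, threshold) {
  if (threshold > 0) pc >= threshold else pc > 0
}

#' Expected taxon richness E
#'
#' Sum of the capture probabilities that pass the threshold: taxa with
#' `pc >= threshold` (for a positive threshold) or `pc > 0` (at threshold 0,
#' where a pc of exactly zero carries no information).
#'
#' @param pc named capture-probability vector for one site.
#' @param threshold pc threshold in `[0, 1)`.
#' @return `E`, the expected richness (a sum of probabilities).
#' @export
expected_richness <- function(pc, threshold = 0.5) {
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)", call. = FALSE)
  sum(pc[passes_threshold(pc, threshold)])
}

#' Observed taxon richness O
#'
#' Count of taxa actually observed at the site whose capture probability
#' passes the threshold. Observed taxa absent from the model's retained set
#' have pc 0 and never count.
#'
#' @param observed character vector of observed taxon ids (or a named 0/1
#'   presence vector).
#' @param pc named capture-probability vector for the site.
#' @inheritParams expected_richness
#' @return integer count `O`.
#' @export
observed_richness <- function(observed, pc, threshold = 0.5) {
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)", call. = FALSE)
  if (!is.character(observed)) {
    if (is.null(names(observed))) stop("presence vector must be named", call. = FALSE)
    observed <- names(observed)[observed > 0]
  }
  obs_pc <- pc[intersect(observed, names(pc))]
  sum(passes_threshold(obs_pc, threshold))
}

#' O/E taxonomic-completeness score
#'
#' @param O observed richness (count of passing observed taxa).
#' @param E expected richness (sum of passing capture probabilities);
#'   must be positive.
#' @return `O/E`, unclamped — values above 1 occur in practice and are
#'   reported as-is.
#' @export
oe_score <- function(O, E) {
  if (any(E <= 0))
    stop("E is zero: O/E undefined (no taxon passes the capture threshold)",
         call. = FALSE)
  O / E
}

#' Grade an O/E score on the five-level scale
#'
#' Bands: `>= 0.79` Excellent; `[0.59, 0.79)` Healthy; `[0.39, 0.59)`
#' Sub-healthy; `(0.19, 0.39)` General; `<= 0.19` Poor. Bands are
#' lower-inclusive except Poor, whose printed bound is "<= 0.19".
#'
#' @param score O/E score(s), non-negative.
#' @param breaks ascending band edges (Poor/General, General/Sub-healthy,
#'   Sub-healthy/Healthy, Healthy/Excellent).
#' @return factor with levels Excellent, Healthy, Sub-healthy, General, Poor.
#' @export
grade_oe <- function(score, breaks = c(0.19, 0.39, 0.59, 0.79)) {
  if (any(score < 0)) stop("O/E score cannot be negative", call. = FALSE)
  stopifnot(length(breaks) == 4, !is.unsorted(breaks))
  lv <- c("Excellent", "Healthy", "Sub-healthy", "General", "Poor")
  g <- ifelse(score >= breaks[4], "Excellent",
       ifelse(score >= breaks[3], "Healthy",
       ifelse(score >= breaks[2], "Sub-healthy",
       ifelse(score >  breaks[1], "General", "Poor"))))
  factor(g, levels = lv)
}

#' Fit the O/E predictive model from reference sites
#'
#' End-to-end model build: rare taxa are excluded over the reference sites,
#' pairwise Sorensen dissimilarities are clustered with the flexible-beta
#' method (group count fixed in the configuration or selected by silhouette),
#' per-group taxon frequencies are tabulated, and a random forest is fitted
#' from the natural predictors to the group labels. The fitted object scores
#' new sites via [predict.oe_model()] / [assess_sites()].
#'
#' @param occurrence [occurrence_matrix()] of the reference sites.
#' @param predictors data.frame of natural predictors, one row per reference
#'   site, row names matching the occurrence site ids.
#' @param config an [analysis_config()].
#' @return object of class `oe_model` with elements `retained_taxa`,
#'   `labels`, `n_groups`, `freqs`, `classifier`, `config`.
#' @examples
#' w <- generate_reference_world(world_spec(seed = 7))
#' m <- oe_model(w$occurrence, w$predictors)
#' m
#' @export
oe_model <- function(occurrence, predictors, config = analysis_config()) {
  stopifnot(is.occurrence_matrix(occurrence), inherits(config, "analysis_config"))
  predictors <- as.data.frame(predictors)
  if (!setequal(rownames(predictors), site_ids(occurrence)))
    stop("predictor rows must match occurrence sites", call. = FALSE)
  predictors <- predictors[site_ids(occurrence), , drop = FALSE]

  filtered <- filter_rare_taxa(occurrence, config$rare_taxon_max_freq)
  d <- sorensen_dissimilarity(filtered)
  n_groups <- config$n_groups
  sil <- NULL
  if (is.null(n_groups)) {
    sel <- select_n_groups(d, config$n_groups_candidates, beta = config$beta)
    n_groups <- as.integer(sel)
    sil <- attr(sel, "silhouette")
  }
  labels <- flexible_beta_cluster(d, n_groups = n_groups, beta = config$beta)
  freqs <- group_frequencies(filtered, labels)
  classifier <- fit_group_classifier(predictors, labels,
                                     n_trees = config$n_trees,
                                     cv_folds = config$cv_folds,
                                     seed = config$seed)
  structure(list(
    retained_taxa = attr(filtered, "retained_taxa"),
    all_taxa = taxon_ids(occurrence),
    reference_sites = site_ids(occurrence),
    labels = labels,
    n_groups = n_groups,
    silhouette = sil,
    freqs = freqs,
    classifier = classifier,
    config = config
  ), class = "oe_model")
}

#' @export
print.oe_model <- function(x, ...) {
  cat("O/E predictive model (RIVPACS-style)\n")
  cat("  reference sites: ", length(x$reference_sites), "\n")
  cat("  retained taxa:   ", length(x$retained_taxa), "of", length(x$all_taxa),
      "after rare-taxon exclusion (freq <=", x$config$rare_taxon_max_freq, ")\n")
  cat("  groups:          ", x$n_groups,
      if (is.null(x$config$n_groups)) "(silhouette-selected)" else "(fixed)", "\n")
  cat("  classifier:      ", x$config$n_trees, "-tree random forest, CV accuracy ",
      round(x$classifier$cv_accuracy, 3), "\n", sep = "")
  cat("  pc threshold:    ", x$config$pc_threshold, "\n")
  invisible(x)
}

#' @export
summary.oe_model <- function(object, ...) {
  out <- list(
    n_reference = length(object$reference_sites),
    n_taxa = length(object$all_taxa),
    n_retained = length(object$retained_taxa),
    n_groups = object$n_groups,
    group_sizes = table(object$labels),
    cv_accuracy = object$classifier$cv_accuracy,
    silhouette = object$silhouette,
    pc_threshold = object$config$pc_threshold
  )
  class(out) <- "summary.oe_model"
  out
}

#' @export
print.summary.oe_model <- function(x, ...) {
  cat("O/E model summary\n")
  cat("  reference sites:", x$n_reference, " | taxa:", x$n_retained, "retained of",
      x$n_taxa, "\n")
  cat("  group sizes:", paste(sprintf("g%s=%d", names(x$group_sizes), x$group_sizes),
                              collapse = ", "), "\n")
  if (!is.null(x$silhouette)) {
    cat("  mean silhouette by candidate k:\n")
    print(round(x$silhouette, 3))
  }
  cat("  classifier CV accuracy:", round(x$cv_accuracy, 3), "\n")
  invisible(x)
}

#' Score sites with a fitted O/E model
#'
#' For each site the model predicts group membership from the predictors,
#' computes per-taxon capture probabilities, sums the passing pc into E,
#' counts the observed passing taxa into O, and grades O/E on the five-level
#' scale.
#'
#' @param model an [oe_model()].
#' @param occurrence [occurrence_matrix()] of the sites to score.
#' @param predictors predictor data.frame for the same sites.
#' @param threshold pc threshold; defaults to the model configuration.
#' @return data.frame of class `oe_assessment` with columns `site_id`,
#'   `threshold`, `O`, `E`, `OE`, `grade`.
#' @export
assess_sites <- function(model, occurrence, predictors,
                         threshold = model$config$pc_threshold) {
  stopifnot(inherits(model, "oe_model"), is.occurrence_matrix(occurrence))
  predictors <- as.data.frame(predictors)
  ids <- site_ids(occurrence)
  if (!all(ids %in% rownames(predictors)))
    stop("predictors missing for sites: ",
         paste(setdiff(ids, rownames(predictors)), collapse = ", "), call. = FALSE)
  membership <- predict_membership(model$classifier,
                                   predictors[ids, , drop = FALSE])
  pc <- capture_probabilities(membership, model$freqs)
  res <- lapply(ids, function(s) {
    pcs <- pc[s, ]
    E <- expected_richness(pcs, threshold)
    obs <- names(which(occurrence$presence[s, ] > 0))
    O <- observed_richness(obs, pcs, threshold)
    if (E <= 0) {
      warning("site ", s, ": no taxon passes the capture threshold; O/E undefined")
      data.frame(site_id = s, threshold = threshold, O = O, E = E,
                 OE = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(site_id = s, threshold = threshold, O = O, E = E,
                 OE = oe_score(O, E), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$grade <- grade_oe(ifelse(is.na(out$OE), 0, out$OE),
                        breaks = model$config$oe_breaks)
  out$grade[is.na(out$OE)] <- NA
  class(out) <- c("oe_assessment", "data.frame")
  out
}

#' @rdname assess_sites
#' @param object an [oe_model()].
#' @param ... passed on to [assess_sites()].
#' @export
predict.oe_model <- function(object, occurrence, predictors, ...) {
  assess_sites(object, occurrence, predictors, ...)
}

#' O/E performance test: reference validation vs severely damaged sites
#'
#' A useful completeness index must separate minimally disturbed sites from
#' severely damaged ones. Given scored assessments of a validation set of
#' reference sites and of the severely damaged set, reports mean and
#' standard deviation of O/E per set, their difference, and whether the
#' reference mean exceeds the damaged mean.
#'
#' @param reference an `oe_assessment` for held-out reference sites.
#' @param damaged an `oe_assessment` for (severely) damaged sites.
#' @return list of class `oe_performance`: `mean_reference`, `sd_reference`,
#'   `mean_damaged`, `sd_damaged`, `difference`, `separated`.
#' @export
performance_test <- function(reference, damaged) {
  stopifnot(inherits(reference, "oe_assessment"), inherits(damaged, "oe_assessment"))
  if (nrow(reference) == 0 || nrow(damaged) == 0)
    stop("both site sets must be non-empty and scored", call. = FALSE)
  safe_sd <- function(x, label) {
    if (length(x) < 2) {
      warning("single-site ", label, " set: SD reported as 0")
      return(0)
    }
    stats::sd(x)
  }
  mr <- mean(reference$OE, na.rm = TRUE)
  md <- mean(damaged$OE, na.rm = TRUE)
  structure(list(
    mean_reference = mr,
    sd_reference = safe_sd(reference$OE[!is.na(reference$OE)], "reference"),
    mean_damaged = md,
    sd_damaged = safe_sd(damaged$OE[!is.na(damaged$OE)], "damaged"),
    difference = mr - md,
    separated = mr > md
  ), class = "oe_performance")
}

#' @export
print.oe_performance <- function(x, ...) {
  cat("O/E performance test\n")
  cat(sprintf("  reference:        mean O/E = %.3f (sd %.3f)\n",
              x$mean_reference, x$sd_reference))
  cat(sprintf("  severely damaged: mean O/E = %.3f (sd %.3f)\n",
              x$mean_damaged, x$sd_damaged))
  cat(sprintf("  difference %.3f — reference %s damaged\n", x$difference,
              if (x$separated) "separated from" else "NOT separated from"))
  invisible(x)
}
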