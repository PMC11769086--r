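#' Build a validated site-by-taxon occurrence matrix
#'
#' The occurrence matrix is the biological substrate of both evaluations: a
#' binary sites x taxa presence matrix, optionally backed by abundance counts,
#' together with a taxonomy table mapping every taxon to a phylum and a
#' subgroup (class/order level).
#'
#' @param presence numeric sites x taxa matrix of 0/1 values with site ids as
#'   row names and taxon ids as column names. May be omitted when `abundance`
#'   is given, in which case presence is `abundance > 0`.
#' @param abundance optional non-negative sites x taxa count matrix with the
#'   same dimnames as `presence`.
#' @param taxonomy data.frame with columns `taxon_id`, `phylum`, `subgroup`
#'   covering every taxon in the matrix.
#' @return An object of class `occurrence_matrix`: a list with elements
#'   `presence`, `abundance` (or `NULL`) and `taxonomy`.
#' @examples
#' pres <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'                dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
#' tax <- data.frame(taxon_id = c("t1", "t2", "t3"),
#'                   phylum = "Mollusca", subgroup = "Gastropoda")
#' occurrence_matrix(pres, taxonomy = tax)
#' @export
occurrence_matrix <- function(presence = NULL, abundance = NULL, taxonomy = NULL) {
  if (is.null(presence) && is.null(abundance))
    stop("either `presence` or `abundance` must be supplied", call. = FALSE)
  if (!is.null(abundance)) {
    abundance <- as.matrix(abundance)
    if (any(is.na(abundance)) || any(abundance < 0))
      stop("abundance must be non-negative with no missing values", call. = FALSE)
    if (is.null(presence)) presence <- (abundance > 0) + 0
  }
  presence <- as.matrix(presence)
  if (!all(presence %in% c(0, 1)))
    stop("presence must contain only 0/1 values", call. = FALSE)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence must carry site ids (rownames) and taxon ids (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(presence)))
    stop("duplicate site ids in occurrence table", call. = FALSE)
  if (anyDuplicated(colnames(presence)))
    stop("duplicate taxon ids in occurrence table", call. = FALSE)
  if (!is.null(abundance)) {
    if (!identical(dim(abundance), dim(presence)))
      stop("abundance and presence dimensions differ", call. = FALSE)
    dimnames(abundance) <- dimnames(presence)
    if (!identical(unname(presence), unname((abundance > 0) + 0)))
      stop("presence must equal (abundance > 0)", call. = FALSE)
  }
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    need <- c("taxon_id", "phylum", "subgroup")
    if (!all(need %in% names(taxonomy)))
      stop("taxonomy needs columns taxon_id, phylum, subgroup", call. = FALSE)
    missing_tax <- setdiff(colnames(presence), taxonomy$taxon_id)
    if (length(missing_tax))
      stop("taxa missing from taxonomy: ", paste(missing_tax, collapse = ", "),
           call. = FALSE)
    taxonomy <- taxonomy[match(colnames(presence), taxonomy$taxon_id), , drop = FALSE]
    rownames(taxonomy) <- NULL
  }
  structure(list(presence = presence, abundance = abundance, taxonomy = taxonomy),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat("Occurrence matrix:", nrow(x$presence), "sites x", ncol(x$presence), "taxa\n")
  cat("  abundance counts:", if (is.null(x$abundance)) "absent" else "present", "\n")
  if (!is.null(x$taxonomy))
    cat("  phyla:", paste(unique(x$taxonomy$phylum), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname occurrence_matrix
#' @param x object to test or print
#' @export
is.occurrence_matrix <- function(x) inherits(x, "occurrence_matrix")

site_ids <- function(x) rownames(x$presence)
taxon_ids <- function(x) colnames(x$presence)

#' Read / write occurrence tables
#'
#' Tables are comma-separated text with a header row of taxon ids and site ids
#' in the first column. Cells may hold abundance counts; any value above one
#' marks the table as abundance data and presence is derived by binarization.
#' The taxonomy sidecar has columns `taxon_id`, `phylum`, `subgroup`.
#'
#' @param path path to the site x taxon table.
#' @param taxonomy_path optional path to the taxonomy sidecar.
#' @return `read_occurrence_table` returns an [occurrence_matrix()];
#'   `write_occurrence_table` returns `path` invisibly.
#' @export
read_occurrence_table <- function(path, taxonomy_path = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("occurrence table needs site ids plus >= 1 taxon", call. = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m))) stop("non-numeric or missing cells in occurrence table", call. = FALSE)
  rownames(m) <- ids
  taxonomy <- if (!is.null(taxonomy_path))
    utils::read.csv(taxonomy_path, stringsAsFactors = FALSE)
  if (all(m %in% c(0, 1)))
    occurrence_matrix(presence = m, taxonomy = taxonomy)
  else
    occurrence_matrix(abundance = m, taxonomy = taxonomy)
}

#' @rdname read_occurrence_table
#' @param x an [occurrence_matrix()].
#' @export
write_occurrence_table <- function(x, path, taxonomy_path = NULL) {
  stopifnot(is.occurrence_matrix(x))
  m <- if (is.null(x$abundance)) x$presence else x$abundance
  df <- data.frame(site_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(taxonomy_path) && !is.null(x$taxonomy))
    utils::write.csv(x$taxonomy, taxonomy_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map a calendar month or date to the sampling quarter
#'
#' Quarters follow the calendar convention used throughout the package:
#' January-March is Q1 (spring), April-June Q2 (summer), July-September Q3
#' (autumn), October-December Q4 (winter).
#'
#' @param month integer month 1-12, or a `Date` (month is extracted).
#' @return integer quarter in 1:4.
#' @examples
#' quarter_of(as.Date("2010-02-15"))  # 1
#' quarter_of(11)                     # 4
#' @export
quarter_of <- function(month) {
  if (inherits(month, "Date")) month <- as.integer(format(month, "%m"))
  month <- as.integer(month)
  if (any(is.na(month)) || any(month < 1L | month > 12L))
    stop("month must be in 1..12", call. = FALSE)
  (month - 1L) %/% 3L + 1L
}

#' Read a water-quality table
#'
#' Expects comma-separated text with columns `site_id`, either `date`
#' (ISO `YYYY-MM-DD`) or `quarter` (1-4, optionally with a `year` column), and
#' the five chemistry indicators `TN`, `TP`, `NH3N`, `CODMn`, `DO` in mg/L.
#' The quarter is derived from the date when a date is given.
#'
#' @param path path to the table.
#' @return data.frame with columns `site_id`, `year`, `quarter`, `TN`, `TP`,
#'   `NH3N`, `CODMn`, `DO`; one row per sample.
#' @export
read_waterquality_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ind <- c("TN", "TP", "NH3N", "CODMn", "DO")
  miss <- setdiff(c("site_id", ind), names(df))
  if (length(miss))
    stop("water-quality table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("date" %in% names(df)) {
    d <- tryCatch(as.Date(df$date), error = function(e) NA)
    if (any(is.na(d))) stop("unparseable date in water-quality table", call. = FALSE)
    df$quarter <- quarter_of(d)
    df$year <- as.integer(format(d, "%Y"))
  } else if (!"quarter" %in% names(df)) {
    stop("water-quality table needs a date or quarter column", call. = FALSE)
  }
  if (!"year" %in% names(df)) df$year <- NA_integer_
  df$quarter <- as.integer(df$quarter)
  if (any(is.na(df$quarter)) || any(df$quarter < 1L | df$quarter > 4L))
    stop("quarter must be in 1..4", call. = FALSE)
  for (v in ind) {
    if (any(is.na(df[[v]])))
      stop("missing ", v, " values in water-quality table", call. = FALSE)
    if (any(df[[v]] < 0))
      stop("negative ", v, " concentration", call. = FALSE)
  }
  if (any(df$DO <= 0)) stop("DO must be strictly positive", call. = FALSE)
  df[c("site_id", "year", "quarter", ind)]
}

#' @rdname read_waterquality_table
#' @param wq a water-quality data.frame as returned by
#'   `read_waterquality_table`.
#' @export
write_waterquality_table <- function(wq, path) {
  utils::write.csv(wq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Surface-water standard concentration envelopes
#'
#' The class I-V envelope (Cmin, Cmax, in mg/L) of the Chinese surface-water
#' quality standard GB3838-2002 for the five chemistry indicators, using the
#' lake/reservoir column for total phosphorus. These are editable defaults:
#' standardization always takes the bounds from configuration, never from
#' constants baked into the formulas.
#'
#' @return data.frame with columns `indicator`, `Cmin`, `Cmax`, `direction`
#'   (`"decreasing"` for pollutants, `"increasing"` for DO).
#' @export
default_standard_bounds <- function() {
  data.frame(
    indicator = c("TN", "TP", "NH3N", "CODMn", "DO"),
    Cmin = c(0.2, 0.01, 0.15, 2, 2),
    Cmax = c(2.0, 0.2, 2.0, 15, 7.5),
    direction = c("decreasing", "decreasing", "decreasing", "decreasing",
                  "increasing"),
    stringsAsFactors = FALSE
  )
}

validate_bounds <- function(bounds) {
  bounds <- as.data.frame(bounds)
  need <- c("indicator", "Cmin", "Cmax")
  if (!all(need %in% names(bounds)))
    stop("bounds need columns indicator, Cmin, Cmax", call. = FALSE)
  if (any(bounds$Cmax <= bounds$Cmin))
    stop("Cmax must exceed Cmin for every indicator", call. = FALSE)
  bounds
}

#' Analysis configuration
#'
#' Collects every tunable of the dual evaluation in one validated object.
#' Defaults encode the published study conditions: capture-probability
#' threshold 0.5 (0 also supported), rare-taxon exclusion at a 5% occurrence
#' frequency, flexible-beta clustering with beta = -0.5, a 100-tree random
#' forest of unlimited depth, and the equal-weight composite with correction
#' multiplier a = 0.5 over n = 2 criterion layers.
#'
#' @param pc_threshold capture-probability threshold in `[0, 1)`; taxa whose
#'   pc passes it contribute to O and E. The published choices are 0 and 0.5.
#' @param rare_taxon_max_freq taxa occurring at no more than this fraction of
#'   reference sites are excluded before clustering.
#' @param beta flexible-beta clustering parameter, `beta < 1`.
#' @param n_groups fixed number of reference groups, or `NULL` to select by
#'   mean silhouette width over `n_groups_candidates`.
#' @param n_groups_candidates integer candidates for the group count; default
#'   `2:min(8, n_ref - 1)` at fit time.
#' @param n_trees number of random-forest trees.
#' @param cv_folds cross-validation folds for the classifier accuracy report.
#' @param seed master seed; every stochastic component derives from it.
#' @param a composite-index correction multiplier.
#' @param n_layers number of criterion layers in the composite (fixed at 2:
#'   chemistry and biology).
#' @param chemical_sum if `TRUE`, the chemical layer score is the printed sum
#'   `i_N + i_O` instead of their mean (see the methods vignette; the sum
#'   pushes perfect scores to I = 1.5 and is kept only for fidelity
#'   experiments).
#' @param bounds standard-bounds data.frame, see [default_standard_bounds()].
#' @param oe_breaks,composite_breaks ascending grade-band edges for the two
#'   grading schemes.
#' @return object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(pc_threshold = 0.5,
                            rare_taxon_max_freq = 0.05,
                            beta = -0.5,
                            n_groups = NULL,
                            n_groups_candidates = NULL,
                            n_trees = 100,
                            cv_folds = 5,
                            seed = 1L,
                            a = 0.5,
                            n_layers = 2L,
                            chemical_sum = FALSE,
                            bounds = default_standard_bounds(),
                            oe_breaks = c(0.19, 0.39, 0.59, 0.79),
                            composite_breaks = c(0.2, 0.4, 0.6, 0.8)) {
  if (pc_threshold < 0 || pc_threshold >= 1)
    stop("pc_threshold must lie in [0, 1)", call. = FALSE)
  if (rare_taxon_max_freq < 0 || rare_taxon_max_freq >= 1)
    stop("rare_taxon_max_freq must lie in [0, 1)", call. = FALSE)
  if (beta >= 1) stop("beta must be < 1", call. = FALSE)
  if (!is.null(n_groups) && n_groups < 1)
    stop("n_groups must be a positive integer", call. = FALSE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (n_layers != 2L) stop("the composite index is defined for n_layers = 2", call. = FALSE)
  bounds <- validate_bounds(bounds)
  structure(list(
    pc_threshold = pc_threshold,
    rare_taxon_max_freq = rare_taxon_max_freq,
    beta = beta,
    n_groups = n_groups,
    n_groups_candidates = n_groups_candidates,
    n_trees = as.integer(n_trees),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    a = a,
    n_layers = as.integer(n_layers),
    chemical_sum = isTRUE(chemical_sum),
    bounds = bounds,
    oe_breaks = sort(oe_breaks),
    composite_breaks = sort(composite_breaks)
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat("  pc threshold:       ", x$pc_threshold, "\n")
  cat("  rare-taxon cutoff:  ", x$rare_taxon_max_freq, "\n")
  cat("  clustering beta:    ", x$beta, "\n")
  cat("  groups:             ",
      if (is.null(x$n_groups)) "silhouette-selected" else x$n_groups, "\n")
  cat("  forest:             ", x$n_trees, "trees, unlimited depth\n")
  cat("  composite:           a =", x$a, ", n =", x$n_layers,
      if (x$chemical_sum) "(printed-sum chemical layer)" else "", "\n")
  cat("  seed:               ", x$seed, "\n")
  invisible(x)
}

#' Load / save an analysis configuration
#'
#' Configurations are YAML files; keys absent from the file fall back to the
#' [analysis_config()] defaults, so an empty file yields the default study
#' conditions. `bounds` may be given as a list of
#' `indicator: {Cmin: ..., Cmax: ...}` entries.
#'
#' @param path path to a YAML configuration file.
#' @return [analysis_config()] object.
#' @export
load_config <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("config file not found: ", path, call. = FALSE)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$bounds)) {
    b <- default_standard_bounds()
    for (ind in names(raw$bounds)) {
      i <- match(ind, b$indicator)
      if (is.na(i)) stop("unknown indicator in bounds: ", ind, call. = FALSE)
      if (!is.null(raw$bounds[[ind]]$Cmin)) b$Cmin[i] <- raw$bounds[[ind]]$Cmin
      if (!is.null(raw$bounds[[ind]]$Cmax)) b$Cmax[i] <- raw$bounds[[ind]]$Cmax
    }
    raw$bounds <- b
  }
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(analysis_config, raw)
}

#' @rdname load_config
#' @param config an [analysis_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  out <- unclass(config)
  out$bounds <- split(
    lapply(seq_len(nrow(config$bounds)), function(i)
      list(Cmin = config$bounds$Cmin[i], Cmax = config$bounds$Cmax[i])),
    config$bounds$indicator
  )
  out$bounds <- lapply(out$bounds, `[[`, 1L)
  yaml::write_yaml(out, path)
  invisible(path)
}
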