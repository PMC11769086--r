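#' Standardize a chemistry or biology indicator to [0, 1]
#'
#' Four linear standardizations place every indicator on a common 0-1 health
#' scale before equal-weight aggregation:
#' \describe{
#'   \item{`standardize_decreasing`}{pollutant concentrations (TN, TP, NH3-N,
#'     CODMn), `S = (Cmax - C)/(Cmax - Cmin)`: lower is healthier.}
#'   \item{`standardize_increasing`}{dissolved oxygen,
#'     `S = (C - Cmin)/(Cmax - Cmin)`: higher is healthier.}
#'   \item{`standardize_dominance`}{the dominance metric D,
#'     `S = (Q95 - M)/(Q95 - Q5)`: concentrated, uneven communities score
#'     low.}
#'   \item{`standardize_richness`}{richness T and diversity H,
#'     `S = (M - Q5)/(Q95 - Q5)`.}
#' }
#' `Cmin`/`Cmax` are the class I-V envelope of the surface-water standard
#' (mg/L); `Q5`/`Q95` are the 5th and 95th percentiles of the biological
#' metric over all sampling points. Scores are clamped to `[0, 1]` when a
#' measurement falls outside its envelope.
#'
#' @param C measured concentration in mg/L.
#' @param Cmin,Cmax standard envelope bounds, `Cmax > Cmin`.
#' @param M measured biological metric value.
#' @param Q5,Q95 percentile envelope, `Q95 > Q5`.
#' @param metric metric name used in error messages.
#' @return standardized score(s) in `[0, 1]`.
#' @examples
#' standardize_decreasing(1.1, 0.2, 2.0)  # TN midpoint -> 0.5
#' standardize_increasing(7.5, 2, 7.5)    # DO at the top bound -> 1
#' @name standardize
NULL

clamp01 <- function(x) pmin(1, pmax(0, x))

#' @rdname standardize
#' @export
standardize_decreasing <- function(C, Cmin, Cmax) {
  if (any(Cmax <= Cmin))
    stop("degenerate bounds: Cmax must exceed Cmin", call. = FALSE)
  clamp01((Cmax - C) / (Cmax - Cmin))
}

#' @rdname standardize
#' @export
standardize_increasing <- function(C, Cmin, Cmax) {
  if (any(Cmax <= Cmin))
    stop("degenerate bounds: Cmax must exceed Cmin", call. = FALSE)
  clamp01((C - Cmin) / (Cmax - Cmin))
}

#' @rdname standardize
#' @export
standardize_dominance <- function(M, Q5, Q95, metric = "D") {
  if (any(Q95 <= Q5))
    stop("degenerate percentiles (Q95 = Q5) for metric ", metric, call. = FALSE)
  clamp01((Q95 - M) / (Q95 - Q5))
}

#' @rdname standardize
#' @export
standardize_richness <- function(M, Q5, Q95, metric = "T") {
  if (any(Q95 <= Q5))
    stop("degenerate percentiles (Q95 = Q5) for metric ", metric, call. = FALSE)
  clamp01((M - Q5) / (Q95 - Q5))
}

#' Factor-layer and criterion-layer scores of the composite index
#'
#' Equal-weight aggregation of the standardized scores:
#' the nutrient score is `i_N = (S_TN + S_TP)/2`, the oxygen-balance score
#' `i_O = (S_DO + S_NH3N + S_CODMn)/3`, the biology score
#' `i_B = (S_T + S_H + S_D)/3`, and the chemical criterion layer combines
#' nutrients and oxygen balance. The chemical layer uses the mean
#' `(i_N + i_O)/2` by default so that perfect scores map to 1; the plain sum
#' (which reaches 2 and pushes the composite past its grade bands) is
#' available with `sum = TRUE` for fidelity experiments.
#'
#' @param S_TN,S_TP,S_DO,S_NH3N,S_CODMn,S_T,S_H,S_D standardized scores in
#'   `[0, 1]`.
#' @param i_N,i_O nutrient and oxygen-balance factor scores.
#' @param sum if `TRUE`, return `i_N + i_O` instead of their mean.
#' @return score in `[0, 1]` (the chemical sum variant may reach 2).
#' @name factor_scores
NULL

#' @rdname factor_scores
#' @export
nutrient_score <- function(S_TN, S_TP) (S_TN + S_TP) / 2

#' @rdname factor_scores
#' @export
oxygen_score <- function(S_DO, S_NH3N, S_CODMn) (S_DO + S_NH3N + S_CODMn) / 3

#' @rdname factor_scores
#' @export
biology_score <- function(S_T, S_H, S_D) (S_T + S_H + S_D) / 3

#' @rdname factor_scores
#' @export
chemical_score <- function(i_N, i_O, sum = FALSE) {
  if (isTRUE(sum)) i_N + i_O else (i_N + i_O) / 2
}

#' Chemical-biological composite index
#'
#' `I = a * (i_C + i_B)` over the two criterion layers (chemistry and
#' biology). With the default correction multiplier `a = 0.5`, all-perfect
#' indicator scores give exactly `I = 1`, the top of the healthy band.
#'
#' @param i_C chemical criterion-layer score.
#' @param i_B biological criterion-layer score.
#' @param a correction multiplier (default 0.5).
#' @param n criterion-layer count; the index is defined for `n = 2`.
#' @return composite index `I`.
#' @export
composite_index <- function(i_C, i_B, a = 0.5, n = 2L) {
  if (n != 2L) stop("the composite index is defined for n = 2 criterion layers",
                    call. = FALSE)
  a * (i_C + i_B)
}

#' Grade the composite index on the five-level scale
#'
#' Bands (lower-inclusive): `[0.8, 1]` healthy, `[0.6, 0.8)` sub-healthy,
#' `[0.4, 0.6)` general, `[0.2, 0.4)` poor, `< 0.2` very poor.
#'
#' @param I composite index value(s) in `[0, 1]`.
#' @param breaks ascending band edges.
#' @return factor with levels healthy, sub-healthy, general, poor, very poor.
#' @export
grade_composite <- function(I, breaks = c(0.2, 0.4, 0.6, 0.8)) {
  if (any(I < 0 | I > 1))
    stop("composite index must lie in [0, 1]; got values outside the band range",
         call. = FALSE)
  stopifnot(length(breaks) == 4, !is.unsorted(breaks))
  lv <- c("healthy", "sub-healthy", "general", "poor", "very poor")
  g <- ifelse(I >= breaks[4], "healthy",
       ifelse(I >= breaks[3], "sub-healthy",
       ifelse(I >= breaks[2], "general",
       ifelse(I >= breaks[1], "poor", "very poor"))))
  factor(g, levels = lv)
}

#' Percentile envelope of the biological metrics
#'
#' 5th and 95th percentiles of richness T, diversity H and dominance D over
#' all sampling points (pooled across periods), using the linear-interpolation
#' quantile definition.
#'
#' @param bio data.frame with columns `T`, `H`, `D` (one row per
#'   site/period).
#' @return data.frame with columns `metric`, `Q5`, `Q95`.
#' @export
bio_percentiles <- function(bio) {
  metrics <- c("T", "H", "D")
  if (!all(metrics %in% names(bio)))
    stop("bio data needs columns T, H, D", call. = FALSE)
  out <- data.frame(
    metric = metrics,
    Q5 = vapply(metrics, function(m)
      stats::quantile(bio[[m]], 0.05, type = 7, names = FALSE), numeric(1)),
    Q95 = vapply(metrics, function(m)
      stats::quantile(bio[[m]], 0.95, type = 7, names = FALSE), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Composite health assessment per site and period
#'
#' Joins the water-quality samples with the biological metrics on site and
#' period, standardizes every indicator, aggregates the factor and criterion
#' layers with equal weights, and grades the composite index. Percentile
#' envelopes for the biological metrics are computed over all supplied
#' sampling points unless given. Records with missing indicators are skipped
#' with a message; no imputation is attempted.
#'
#' @param wq water-quality data.frame (`site_id`, `year`, `quarter`, `TN`,
#'   `TP`, `NH3N`, `CODMn`, `DO`), e.g. from [read_waterquality_table()] or
#'   [generate_waterquality_series()].
#' @param bio data.frame of biological metrics (`site_id`, `year`, `quarter`,
#'   `T`, `H`, `D`).
#' @param bounds standard envelope, see [default_standard_bounds()].
#' @param percentiles optional precomputed [bio_percentiles()] table.
#' @param a correction multiplier for [composite_index()].
#' @param chemical_sum use the printed-sum chemical layer (see
#'   [chemical_score()]); the composite is then clamped into `[0, 1]` only
#'   for grading and reported unclamped in column `I`.
#' @return data.frame of class `composite_assessment`: one row per
#'   site/period with the eight standardized scores, `i_N`, `i_O`, `i_C`,
#'   `i_B`, `I` and `grade`.
#' @export
assess_composite <- function(wq, bio, bounds = default_standard_bounds(),
                             percentiles = NULL, a = 0.5,
                             chemical_sum = FALSE) {
  bounds <- validate_bounds(bounds)
  key <- c("site_id", "year", "quarter")
  if (!all(key %in% names(wq)) || !all(key %in% names(bio)))
    stop("wq and bio need site_id, year, quarter columns", call. = FALSE)
  dat <- merge(wq, bio, by = key)
  if (nrow(dat) == 0) stop("no matching site/period records between wq and bio",
                           call. = FALSE)
  ind_cols <- c("TN", "TP", "NH3N", "CODMn", "DO", "T", "H", "D")
  complete <- stats::complete.cases(dat[, ind_cols])
  if (any(!complete)) {
    message(sum(!complete), " record(s) skipped for missing indicators")
    dat <- dat[complete, , drop = FALSE]
  }
  if (is.null(percentiles)) percentiles <- bio_percentiles(bio)
  b <- function(ind, what) bounds[[what]][match(ind, bounds$indicator)]
  q <- function(m, what) percentiles[[what]][match(m, percentiles$metric)]

  out <- dat[, key]
  out$S_TN    <- standardize_decreasing(dat$TN, b("TN", "Cmin"), b("TN", "Cmax"))
  out$S_TP    <- standardize_decreasing(dat$TP, b("TP", "Cmin"), b("TP", "Cmax"))
  out$S_NH3N  <- standardize_decreasing(dat$NH3N, b("NH3N", "Cmin"), b("NH3N", "Cmax"))
  out$S_CODMn <- standardize_decreasing(dat$CODMn, b("CODMn", "Cmin"), b("CODMn", "Cmax"))
  out$S_DO    <- standardize_increasing(dat$DO, b("DO", "Cmin"), b("DO", "Cmax"))
  out$S_T     <- standardize_richness(dat$T, q("T", "Q5"), q("T", "Q95"), "T")
  out$S_H     <- standardize_richness(dat$H, q("H", "Q5"), q("H", "Q95"), "H")
  out$S_D     <- standardize_dominance(dat$D, q("D", "Q5"), q("D", "Q95"), "D")
  out$i_N <- nutrient_score(out$S_TN, out$S_TP)
  out$i_O <- oxygen_score(out$S_DO, out$S_NH3N, out$S_CODMn)
  out$i_C <- chemical_score(out$i_N, out$i_O, sum = chemical_sum)
  out$i_B <- biology_score(out$S_T, out$S_H, out$S_D)
  out$I <- composite_index(out$i_C, out$i_B, a = a)
  out$grade <- grade_composite(clamp01(out$I))
  class(out) <- c("composite_assessment", "data.frame")
  out
}
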