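#' Community metrics: richness, diversity, dominance
#'
#' The three biological indicators feeding the composite index:
#' \describe{
#'   \item{`taxon_richness`}{`T`, the number of taxonomic units present.}
#'   \item{`shannon_diversity`}{`H = -sum p_i ln p_i` over taxa with positive
#'     abundance (natural-log Shannon-Wiener).}
#'   \item{`dominance_index`}{`D = sum p_i^2`, the Simpson concentration;
#'     high values mean a few taxa dominate the community.}
#' }
#'
#' @param presence 0/1 presence vector (or matrix, one site per row).
#' @param counts non-negative abundance vector for one site; total must be
#'   positive for `H` and `D`.
#' @param base logarithm base for `H` (default `exp(1)`).
#' @return `taxon_richness`: integer count(s); `shannon_diversity`,
#'   `dominance_index`: a single numeric value.
#' @examples
#' shannon_diversity(c(1, 1, 2))   # ~1.0397
#' dominance_index(c(5, 5))        # 0.5
#' @name community_metrics
NULL

#' @rdname community_metrics
#' @export
taxon_richness <- function(presence) {
  if (is.matrix(presence)) return(rowSums(presence > 0))
  sum(presence > 0)
}

#' @rdname community_metrics
#' @export
shannon_diversity <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("abundances must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("diversity undefined for a site with no individuals",
                       call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' @rdname community_metrics
#' @export
dominance_index <- function(counts) {
  if (any(counts < 0)) stop("abundances must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("dominance undefined for a site with no individuals",
                       call. = FALSE)
  p <- counts[counts > 0] / total
  sum(p^2)
}

#' Biological metrics table per site
#'
#' Computes T, H and D for every site of an occurrence matrix. H and D need
#' abundance counts; with presence-only data they are computed on the 0/1
#' values (every present taxon equally abundant) with a warning.
#'
#' @param x an [occurrence_matrix()].
#' @return data.frame with columns `site_id`, `T`, `H`, `D`.
#' @export
bio_metrics <- function(x) {
  stopifnot(is.occurrence_matrix(x))
  counts <- x$abundance
  if (is.null(counts)) {
    warning("no abundance data: H and D computed from presence (equal abundances)")
    counts <- x$presence
  }
  data.frame(
    site_id = site_ids(x),
    T = as.integer(taxon_richness(x$presence)),
    H = apply(counts, 1, shannon_diversity),
    D = apply(counts, 1, dominance_index),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Taxonomic composition breakdown
#'
#' Percentage composition of the community:
#' \describe{
#'   \item{`level = "phylum"`}{share of each phylum in the total number of
#'     taxonomic units.}
#'   \item{`level = "within_phylum"`}{share of each subgroup within one
#'     phylum, again over taxonomic units.}
#'   \item{`level = "per_site"`}{share of individuals per phylum at each
#'     site; requires abundance data.}
#' }
#' With `keep`, labels outside the kept set are collapsed into a residual
#' `"other"` category so the percentages still total 100.
#'
#' @param x an [occurrence_matrix()] with a taxonomy table.
#' @param level one of `"phylum"`, `"within_phylum"`, `"per_site"`.
#' @param phylum phylum name, required for `level = "within_phylum"`.
#' @param keep optional labels to report individually; the rest become
#'   `"other"`.
#' @return for the first two levels, a data.frame `label`, `percent`
#'   (summing to 100); for `per_site`, a long data.frame `site_id`, `label`,
#'   `percent` summing to 100 within each site.
#' @export
composition_breakdown <- function(x, level = c("phylum", "within_phylum", "per_site"),
                                  phylum = NULL, keep = NULL) {
  stopifnot(is.occurrence_matrix(x))
  level <- match.arg(level)
  tax <- x$taxonomy
  if (is.null(tax)) stop("occurrence matrix has no taxonomy table", call. = FALSE)

  collapse <- function(labels) {
    if (is.null(keep)) return(labels)
    ifelse(labels %in% keep, labels, "other")
  }
  as_pct <- function(tab) {
    pct <- 100 * tab / sum(tab)
    data.frame(label = names(pct), percent = as.numeric(pct),
               row.names = NULL, stringsAsFactors = FALSE)
  }

  if (level == "phylum") {
    return(as_pct(table(collapse(tax$phylum))))
  }
  if (level == "within_phylum") {
    if (is.null(phylum)) stop("within_phylum breakdown needs a phylum", call. = FALSE)
    sub <- tax[tax$phylum == phylum, , drop = FALSE]
    if (nrow(sub) == 0) stop("phylum not present in taxonomy: ", phylum, call. = FALSE)
    return(as_pct(table(collapse(sub$subgroup))))
  }
  # per_site: shares of individuals
  if (is.null(x$abundance))
    stop("per-site composition needs abundance data", call. = FALSE)
  labels <- collapse(tax$phylum[match(colnames(x$abundance), tax$taxon_id)])
  res <- lapply(site_ids(x), function(s) {
    counts <- tapply(x$abundance[s, ], labels, sum)
    counts[is.na(counts)] <- 0
    if (sum(counts) == 0)
      return(data.frame(site_id = character(0), label = character(0),
                        percent = numeric(0)))
    data.frame(site_id = s, label = names(counts),
               percent = 100 * as.numeric(counts) / sum(counts),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
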