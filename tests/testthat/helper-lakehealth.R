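# Brute-force Lance-Williams agglomeration: naive re-scan of the full
# distance matrix at every merge. Independent oracle for the flexible-beta
# clustering path.
lw_flexible_oracle <- function(d, k, beta = -0.5) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  alpha <- (1 - beta) / 2
  members <- as.list(seq_len(n))
  while (length(members) > k) {
    m <- length(members)
    best <- c(1L, 2L)
    bestd <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        if (dm[i, j] < bestd) {
          bestd <- dm[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    newd <- alpha * dm[i, ] + alpha * dm[j, ] + beta * dm[i, j]
    members[[i]] <- c(members[[i]], members[[j]])
    dm[i, ] <- newd
    dm[, i] <- newd
    dm[i, i] <- 0
    dm <- dm[-j, -j, drop = FALSE]
    members <- members[-j]
  }
  labels <- integer(n)
  for (g in seq_along(members)) labels[members[[g]]] <- g
  labels
}

# partitions equal up to relabeling
same_partition <- function(a, b) {
  isTRUE(all(outer(a, a, `==`) == outer(b, b, `==`)))
}

random_dissimilarity <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2)
  d <- d + t(d)
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  d
}

random_occurrence <- function(n_sites, n_taxa, p = 0.5, abundance = FALSE) {
  pres <- matrix(rbinom(n_sites * n_taxa, 1, p), n_sites, n_taxa,
                 dimnames = list(paste0("s", seq_len(n_sites)),
                                 sprintf("t%02d", seq_len(n_taxa))))
  tax <- data.frame(taxon_id = colnames(pres),
                    phylum = rep_len(c("Mollusca", "Annelida", "Arthropoda"),
                                     n_taxa),
                    subgroup = rep_len(c("a", "b"), n_taxa),
                    stringsAsFactors = FALSE)
  if (abundance) {
    ab <- pres * (1 + matrix(rpois(n_sites * n_taxa, 5), n_sites, n_taxa))
    occurrence_matrix(abundance = ab, taxonomy = tax)
  } else {
    occurrence_matrix(presence = pres, taxonomy = tax)
  }
}

# block-structured dissimilarity: tight within blocks, far between
block_dissimilarity <- function(sizes, within = c(0, 0.1), between = c(0.9, 1)) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      rng <- if (labels[i] == labels[j]) within else between
      d[i, j] <- d[j, i] <- runif(1, rng[1], rng[2])
    }
  }
  dimnames(d) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  list(d = d, labels = labels)
}
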