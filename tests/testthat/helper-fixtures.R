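# Shared fixtures and independent oracles for the test suite.

# small OtuTable from a plain matrix
makeTable <- function(counts, taxonomy = NULL, domain = "bacteria") {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("OTU_%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  OtuTable(counts, taxonomy = taxonomy, domain = domain)
}

randomTable <- function(n_otus, n_samples, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples)
    # avoid degenerate all-zero rows/columns
    m[cbind(seq_len(n_otus), rep_len(seq_len(n_samples), n_otus))] <-
      m[cbind(seq_len(n_otus), rep_len(seq_len(n_samples), n_otus))] + 1L
    makeTable(m)
  })
}

# a scaled-down study configuration used where full size is not the point
smallStudyConfig <- function(seed = 1L, ...) {
  studyConfig(n_areas_per_system = 1L, n_subsites_per_area = 2L,
              n_plants_per_subsite = 2L, n_reference_samples_per_subsite = 1L,
              n_otus_total = 200L, n_core_shared = 20L,
              n_system_specific_per_system = 40L, n_endophyte_enriched = 8L,
              seed = seed, ...)
}

# O(n^3) brute-force UPGMA oracle, independent of cluster::agnes: repeatedly
# merges the closest pair, averaging distances weighted by cluster sizes.
bruteUpgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  dd <- d
  heights <- numeric(n - 1)
  firstMerge <- rep(NA_real_, n)
  sizes <- rep(1L, n)
  merges <- list()
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (dd[i, j] < bestD - 1e-12) { bestD <- dd[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- bestD
    for (lf in c(active[[i]], active[[j]])) {
      if (is.na(firstMerge[lf])) firstMerge[lf] <- bestD
    }
    merges[[step]] <- sort(c(active[[i]], active[[j]]))
    newRow <- (sizes[i] * dd[i, ] + sizes[j] * dd[j, ]) / (sizes[i] + sizes[j])
    newSize <- sizes[i] + sizes[j]
    newSet <- c(active[[i]], active[[j]])
    keep <- setdiff(seq_len(k), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], newRow[keep]),
                c(newRow[keep], 0))
    sizes <- c(sizes[keep], newSize)
    active <- c(active[keep], list(newSet))
  }
  ac <- mean(1 - firstMerge / heights[n - 1])
  list(heights = heights, ac = ac, merges = merges, firstMerge = firstMerge)
}

# leaf sets below each internal node of an hclust-convention merge matrix
mergeLeafSets <- function(merge) {
  sets <- vector("list", nrow(merge))
  for (i in seq_len(nrow(merge))) {
    l <- merge[i, 1]; r <- merge[i, 2]
    sets[[i]] <- sort(c(if (l < 0) -l else sets[[l]],
                        if (r < 0) -r else sets[[r]]))
  }
  sets
}

# exact conditional p-value for a 2x2 table: hypergeometric enumeration of
# the top-left cell, two-sided via the chi-square ordering
exactChisqP <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) return(1)
  E <- outer(rs, cs) / N
  x2 <- function(a) {
    m <- matrix(c(a, cs[1] - a, rs[1] - a, N - rs[1] - cs[1] + a), 2, 2)
    sum((m - E)^2 / E)
  }
  lo <- max(0, rs[1] - cs[2]); hi <- min(rs[1], cs[1])
  obs <- x2(tab[1, 1])
  pr <- dhyper(lo:hi, cs[1], cs[2], rs[1])
  min(1, sum(pr[vapply(lo:hi, x2, numeric(1)) >= obs - 1e-9]))
}

# checks the two compact-letter-display invariants
cldValid <- function(letters, p, alpha = 0.05) {
  k <- length(letters)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(strsplit(letters[i], "")[[1]],
                              strsplit(letters[j], "")[[1]])) > 0
    pij <- p[i, j]
    if (is.na(pij)) next
    if (pij < alpha && share) return(FALSE)
    if (pij >= alpha && !share) return(FALSE)
  }
  TRUE
}
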