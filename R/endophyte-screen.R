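#' 2x2 contingency table for one OTU in one plant unit
#'
#' Rows: the pooled endophyte libraries (technical replicates summed) and the
#' epiphyte library of the plant; columns: this OTU's counts versus all other
#' OTUs' counts. The marginals therefore equal the library totals.
#'
#' @param x an [OtuTable-class].
#' @param metadata sample metadata.
#' @param plant_unit plant-unit identifier with >= 1 endophyte and >= 1
#'   epiphyte library.
#' @param otu_id OTU identifier.
#' @return 2x2 integer matrix with rows `endo`, `epi` and columns `otu`,
#'   `other`, plus attribute `untestable` (TRUE when the OTU is absent from
#'   the whole unit).
#' @export
buildContingency <- function(x, metadata, plant_unit, otu_id) {
  stopifnot(is(x, "OtuTable"))
  md <- metadata[match(sampleIds(x), metadata$sample_id), ]
  endoIds <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == plant_unit &
                            md$fraction == "endophyte"]
  epiIds <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == plant_unit &
                           md$fraction == "epiphyte"]
  if (!length(endoIds) || !length(epiIds)) {
    stop("plant unit '", plant_unit, "' lacks an endophyte or epiphyte library")
  }
  if (!otu_id %in% otuIds(x)) stop("unknown OTU id: ", otu_id)
  cnt <- counts(x)
  endoOtu <- sum(cnt[otu_id, endoIds])
  epiOtu <- sum(cnt[otu_id, epiIds])
  endoTot <- sum(cnt[, endoIds])
  epiTot <- sum(cnt[, epiIds])
  tab <- matrix(as.integer(c(endoOtu, epiOtu, endoTot - endoOtu, epiTot - epiOtu)),
                2, 2, dimnames = list(c("endo", "epi"), c("otu", "other")))
  attr(tab, "untestable") <- endoOtu + epiOtu == 0L
  tab
}

.pearsonX2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

#' Monte-Carlo chi-square test for a contingency table
#'
#' Pearson's X2 without continuity correction; the null distribution is
#' sampled from random tables with both margins fixed (conditional,
#' Patefield-style sampling; for 2x2 tables this is exactly a hypergeometric
#' draw of the top-left cell). `p = (1 + #(X2* >= X2)) / (n_rep + 1)`, so p
#' is never below `1/(n_rep + 1)`. Tables with a zero row or column margin
#' leave X2 undefined and are flagged untestable with `p = 1` by convention.
#'
#' @param tab non-negative integer matrix.
#' @param n_rep Monte-Carlo replicates (default 5000).
#' @param seed optional RNG seed.
#' @return list: `statistic`, `p_value`, `n_rep`, `untestable`.
#' @export
monteCarloChisq <- function(tab, n_rep = 5000, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(!.isWholeNumber(tab))) {
    stop("contingency table must hold non-negative integers")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    return(list(statistic = NA_real_, p_value = 1, n_rep = as.integer(n_rep),
                untestable = TRUE))
  }
  run <- function() {
    if (all(dim(tab) == c(2L, 2L))) {
      # X2 of a 2x2 table with fixed margins as a function of its [1,1] cell
      N <- sum(tab)
      x2of <- function(a) {
        N * (a * (N - rs[1] - cs[1] + a) - (rs[1] - a) * (cs[1] - a))^2 /
          (rs[1] * rs[2] * cs[1] * cs[2])
      }
      obs <- x2of(tab[1, 1])
      aStar <- stats::rhyper(n_rep, cs[1], cs[2], rs[1])
      stat <- x2of(aStar)
    } else {
      obs <- .pearsonX2(tab)
      stat <- vapply(stats::r2dtable(n_rep, rs, cs), .pearsonX2, numeric(1))
    }
    list(statistic = unname(obs),
         p_value = (1 + sum(stat >= obs - 1e-9)) / (n_rep + 1),
         n_rep = as.integer(n_rep), untestable = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Paired endophyte-versus-epiphyte OTU screen
#'
#' For each candidate OTU and each moss plant unit, tests whether the OTU's
#' abundance differs between the pooled endophyte libraries and the epiphyte
#' library of the same plant with a Monte-Carlo chi-square contingency test,
#' and records the direction (endophyte versus epiphyte relative abundance;
#' the chi-square itself is direction-blind). An OTU qualifies as a putative
#' endophyte when (a) it is endophyte-higher with `p < alpha` in at least
#' `min_significant_units` plant units and (b) its endophyte-mean relative
#' abundance (average of the two technical replicates) exceeds
#' `min_relabund` in at least `min_samples` plant units.
#'
#' Only OTUs meeting criterion (b) are tested by default, since no other OTU
#' can qualify; set `test_all = TRUE` to test every OTU in every unit.
#'
#' @param x an [OtuTable-class].
#' @param metadata sample metadata with the paired design.
#' @param alpha significance threshold (default 0.001).
#' @param min_relabund endophyte-mean relative-abundance threshold
#'   (default 0.005, i.e. 0.5 percent).
#' @param min_samples minimum number of plant units above `min_relabund`
#'   (default 4).
#' @param min_significant_units units that must individually reach
#'   significance (default 1).
#' @param n_rep Monte-Carlo replicates per test (default 5000).
#' @param seed RNG seed (the screen is deterministic under it).
#' @param test_all test every OTU instead of only abundance-qualified ones.
#' @return list with `calls` (per-OTU `data.frame`: `otu_id`,
#'   `n_significant_endo_higher`, `n_samples_above_abundance`, `qualifies`),
#'   `tests` (per OTU x unit: `p_value`, `direction`, `endo_mean_relabund`,
#'   `epi_relabund`, `untestable`), and the screen parameters.
#' @export
classifyEndophytes <- function(x, metadata = sampleData(x), alpha = 0.001,
                               min_relabund = 0.005, min_samples = 4L,
                               min_significant_units = 1L,
                               n_rep = 5000, seed = 1L, test_all = FALSE) {
  stopifnot(is(x, "OtuTable"))
  design <- checkPairedDesign(metadata)
  units <- design$plant_unit[design$n_endophyte >= 1L & design$n_epiphyte >= 1L]
  if (!length(units)) stop("no plant units with a paired endophyte/epiphyte design")
  md <- metadata[match(sampleIds(x), metadata$sample_id), ]
  rel <- relativeAbundance(x)
  cnt <- counts(x)

  endoRel <- vapply(units, function(u) {
    ids <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == u &
                          md$fraction == "endophyte"]
    rowMeans(rel[, ids, drop = FALSE])
  }, numeric(nrow(x)))
  epiRel <- vapply(units, function(u) {
    ids <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == u &
                          md$fraction == "epiphyte"]
    rowMeans(rel[, ids, drop = FALSE])
  }, numeric(nrow(x)))

  nAbove <- rowSums(endoRel > min_relabund)
  candidates <- if (test_all) otuIds(x) else otuIds(x)[nAbove >= min_samples]

  # pooled per-unit counts: endo technical replicates summed, epi as is
  endoCnt <- vapply(units, function(u) {
    ids <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == u &
                          md$fraction == "endophyte"]
    rowSums(cnt[, ids, drop = FALSE])
  }, numeric(nrow(x)))
  epiCnt <- vapply(units, function(u) {
    ids <- md$sample_id[!is.na(md$plant_unit) & md$plant_unit == u &
                          md$fraction == "epiphyte"]
    rowSums(cnt[, ids, drop = FALSE])
  }, numeric(nrow(x)))
  endoTot <- colSums(endoCnt)
  epiTot <- colSums(epiCnt)

  runScreen <- function() {
    nT <- length(candidates) * length(units)
    pvals <- numeric(nT); dirs <- chars <- character(nT)
    unt <- logical(nT); ers <- prs <- numeric(nT)
    otuCol <- rep(candidates, each = length(units))
    unitCol <- rep(units, times = length(candidates))
    for (ti in seq_len(nT)) {
      otu <- otuCol[ti]; u <- unitCol[ti]
      tab <- matrix(as.integer(c(endoCnt[otu, u], epiCnt[otu, u],
                                 endoTot[u] - endoCnt[otu, u],
                                 epiTot[u] - epiCnt[otu, u])), 2, 2)
      mc <- monteCarloChisq(tab, n_rep = n_rep)
      pvals[ti] <- mc$p_value
      unt[ti] <- mc$untestable || (tab[1, 1] + tab[2, 1] == 0L)
      er <- endoRel[otu, u]; pr <- epiRel[otu, u]
      ers[ti] <- er; prs[ti] <- pr
      dirs[ti] <- if (unt[ti] || er == pr) "tie" else
        if (er > pr) "endo_higher" else "epi_higher"
    }
    data.frame(otu_id = otuCol, plant_unit = unitCol, p_value = pvals,
               direction = dirs, endo_mean_relabund = ers, epi_relabund = prs,
               untestable = unt, stringsAsFactors = FALSE)
  }
  tests <- withr::with_seed(seed, runScreen())

  nSig <- vapply(candidates, function(otu) {
    tt <- tests[tests$otu_id == otu, ]
    sum(tt$direction == "endo_higher" & tt$p_value < alpha & !tt$untestable)
  }, integer(1))
  calls <- data.frame(
    otu_id = candidates,
    n_significant_endo_higher = nSig,
    n_samples_above_abundance = nAbove[candidates],
    qualifies = nSig >= min_significant_units &
      nAbove[candidates] >= min_samples,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, tests = tests,
       params = list(alpha = alpha, min_relabund = min_relabund,
                     min_samples = as.integer(min_samples),
                     min_significant_units = as.integer(min_significant_units),
                     n_rep = as.integer(n_rep), seed = seed,
                     n_units = length(units)))
}

#' Heatmap matrix of qualifying endophyte OTUs
#'
#' Entries are `log2(endophyte-mean relative abundance x 100000)` per
#' qualifying OTU (rows) and plant unit (columns); zero abundances are
#' mapped to a floor (default: half the smallest nonzero relative abundance
#' in the matrix) before taking the log. Rows and columns are hierarchically
#' clustered on Pearson correlation (dissimilarity `1 - r`, average linkage).
#'
#' @param screen result of [classifyEndophytes()].
#' @param zero_floor optional abundance floor for zeros.
#' @return list: `matrix`, `row_dendrogram`, `col_dendrogram` (the
#'   dendrograms are `NULL` when fewer than 3 rows/columns are available or
#'   a profile is constant).
#' @export
heatmapMatrix <- function(screen, zero_floor = NULL) {
  calls <- screen$calls
  qual <- calls$otu_id[calls$qualifies]
  if (!length(qual)) stop("no qualifying OTUs to plot")
  tt <- screen$tests[screen$tests$otu_id %in% qual, ]
  units <- unique(tt$plant_unit)
  m <- matrix(0, length(qual), length(units), dimnames = list(qual, units))
  for (i in seq_len(nrow(tt))) {
    m[tt$otu_id[i], tt$plant_unit[i]] <- tt$endo_mean_relabund[i]
  }
  if (is.null(zero_floor)) {
    nz <- m[m > 0]
    zero_floor <- if (length(nz)) min(nz) / 2 else 1e-6
  }
  m[m == 0] <- zero_floor
  lm <- log2(m * 1e5)
  clusterSide <- function(mat) {
    if (nrow(mat) < 3L) return(NULL)
    r <- tryCatch(correlationMatrix(t(mat), method = "pearson"),
                  error = function(e) NULL)
    if (is.null(r) || anyNA(r)) return(NULL)
    agnesCluster(corToDissimilarity(r), linkage = "average")
  }
  list(matrix = lm,
       row_dendrogram = clusterSide(lm),
       col_dendrogram = clusterSide(t(lm)),
       zero_floor = zero_floor)
}
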