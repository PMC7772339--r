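#' Inverse Simpson diversity index
#'
#' `1 / sum(p_i^2)` with `p_i` the relative abundances of one sample; the
#' effective number of equally abundant OTUs. Always >= 1, and equal to the
#' richness exactly when all present OTUs are equally abundant.
#'
#' @param counts numeric vector of one sample's counts, at least one positive.
#' @return scalar index.
#' @examples
#' inverseSimpson(c(5, 5, 5, 5))  # 4
#' @export
inverseSimpson <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts)) {
    stop("'counts' must be non-negative and complete")
  }
  tot <- sum(counts)
  if (tot == 0) stop("all-zero sample: inverse Simpson undefined")
  p <- counts / tot
  1 / sum(p^2)
}

#' OTU richness
#'
#' Number of OTUs with a strictly positive count.
#'
#' @param counts numeric vector of one sample's counts.
#' @return integer richness.
#' @export
richness <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts)) {
    stop("'counts' must be non-negative and complete")
  }
  sum(counts > 0)
}

#' Per-sample diversity of an OTU table
#'
#' @param x an [OtuTable-class].
#' @param index `"invsimpson"` or `"richness"`.
#' @return named numeric vector, one value per sample.
#' @export
sampleDiversity <- function(x, index = c("invsimpson", "richness")) {
  stopifnot(is(x, "OtuTable"))
  index <- match.arg(index)
  f <- if (index == "invsimpson") inverseSimpson else richness
  apply(counts(x), 2L, f)
}

.checkGroups <- function(values, groups) {
  if (length(values) != length(groups)) stop("'values' and 'groups' lengths differ")
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  n <- table(g)
  small <- names(n)[n < 2L]
  if (length(small)) {
    stop("group(s) with fewer than 2 observations: ", paste(small, collapse = ", "))
  }
  g
}

.fullPMatrix <- function(pw, levelsAll) {
  k <- length(levelsAll)
  p <- matrix(NA_real_, k, k, dimnames = list(levelsAll, levelsAll))
  m <- pw$p.value
  for (i in rownames(m)) for (j in colnames(m)) {
    if (!is.na(m[i, j])) p[i, j] <- p[j, i] <- m[i, j]
  }
  p
}

#' Pairwise Mann-Whitney-Wilcoxon tests with letter display
#'
#' Two-sided rank-sum tests for every pair of groups (exact when both group
#' sizes are below 50 and there are no ties, otherwise the normal
#' approximation with tie correction), adjusted over all pairs, with a
#' compact letter display at `alpha`. Used for diversity indices.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor); every group needs >= 2
#'   observations.
#' @param adjust `"holm"` (default) or `"none"`.
#' @param alpha significance level for the letter display.
#' @return a [GroupTestResult-class].
#' @export
pairwiseWilcoxon <- function(values, groups, adjust = c("holm", "none"),
                             alpha = 0.05) {
  adjust <- match.arg(adjust)
  g <- .checkGroups(values, groups)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(values, g, p.adjust.method = adjust,
                                exact = NULL))
  p <- .fullPMatrix(pw, levels(g))
  new("GroupTestResult", groups = levels(g), pMatrix = p,
      method = "wilcoxon", adjust = adjust,
      letters = compactLetterDisplay(p, alpha = alpha), alpha = alpha)
}

#' Pairwise t tests with letter display
#'
#' Two-sided t tests for every pair of groups using, by default, the standard
#' deviation pooled across all groups, adjusted over all pairs. Used for
#' environmental variables.
#'
#' @inheritParams pairwiseWilcoxon
#' @param pooled_sd pool the SD across all groups (default); `FALSE` gives
#'   Welch tests per pair.
#' @return a [GroupTestResult-class].
#' @export
pairwiseTTest <- function(values, groups, adjust = c("holm", "none"),
                          pooled_sd = TRUE, alpha = 0.05) {
  adjust <- match.arg(adjust)
  g <- .checkGroups(values, groups)
  if (pooled_sd) {
    ss <- tapply(values, g, function(v) sum((v - mean(v))^2))
    df <- length(values) - nlevels(g)
    if (sum(ss) / df <= 0) stop("zero pooled variance: t tests undefined")
  }
  pw <- stats::pairwise.t.test(values, g, p.adjust.method = adjust,
                               pool.sd = pooled_sd)
  p <- .fullPMatrix(pw, levels(g))
  new("GroupTestResult", groups = levels(g), pMatrix = p,
      method = "t", adjust = adjust,
      letters = compactLetterDisplay(p, alpha = alpha), alpha = alpha)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: starting from a single letter shared
#' by all groups, every significant pair splits each letter containing both
#' members, and letters that become subsets of others are absorbed. The
#' result satisfies both display invariants -- groups sharing no letter
#' differ at `p < alpha`, and groups with `p >= alpha` share at least one
#' letter. Letter assignments are not unique, so results should be checked
#' against these constraints rather than by string comparison.
#'
#' @param p_matrix symmetric matrix of pairwise p-values (`NA` diagonal;
#'   `NA` off-diagonal entries are treated as non-significant).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter strings, one per group.
#' @export
compactLetterDisplay <- function(p_matrix, alpha = 0.05) {
  if (!is.matrix(p_matrix) || nrow(p_matrix) != ncol(p_matrix)) {
    stop("'p_matrix' must be a square matrix")
  }
  off <- upper.tri(p_matrix)
  if (!isTRUE(all.equal(p_matrix[off], t(p_matrix)[off]))) {
    stop("'p_matrix' must be symmetric")
  }
  k <- nrow(p_matrix)
  labs <- rownames(p_matrix)
  if (is.null(labs)) labs <- as.character(seq_len(k))
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    pij <- p_matrix[i, j]
    if (is.na(pij) || pij >= alpha) next
    newSets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        newSets <- c(newSets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        newSets <- c(newSets, list(s))
      }
    }
    # absorb letters that are (duplicates or) subsets of other letters
    keep <- rep(TRUE, length(newSets))
    for (a in seq_along(newSets)) for (b in seq_along(newSets)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(newSets[[a]] %in% newSets[[b]]) &&
          (length(newSets[[a]]) < length(newSets[[b]]) || a > b)) {
        keep[a] <- FALSE
      }
    }
    sets <- newSets[keep]
    sets <- sets[lengths(sets) > 0L]
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  lab <- .letterLabels(length(sets))
  out <- vapply(seq_len(k), function(i) {
    paste(lab[vapply(sets, function(s) i %in% s, logical(1))], collapse = "")
  }, character(1))
  names(out) <- labs
  out
}

setMethod("show", "GroupTestResult", function(object) {
  cat("GroupTestResult: pairwise ", object@method, " tests (",
      object@adjust, " adjustment)\n", sep = "")
  print(data.frame(group = object@groups, letters = object@letters,
                   row.names = NULL))
})

#' @rdname GroupTestResult-class
#' @param x a `GroupTestResult`.
#' @export
setMethod("groupLetters", "GroupTestResult", function(x) {
  stats::setNames(x@letters, x@groups)
})

#' @rdname GroupTestResult-class
#' @export
setMethod("pMatrix", "GroupTestResult", function(x) x@pMatrix)
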