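#' Sample-by-sample correlation matrix of community profiles
#'
#' Correlations between per-sample relative-abundance profiles over the same
#' OTU set; the basis for community dendrograms. Spearman uses mid-ranks for
#' tied abundances.
#'
#' @param x an [OtuTable-class] (converted to relative abundances) or a
#'   numeric matrix of profiles (OTUs x samples).
#' @param method `"spearman"` (default, as used for community profiles) or
#'   `"pearson"`.
#' @return symmetric samples x samples correlation matrix, unit diagonal.
#' @export
correlationMatrix <- function(x, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- if (is(x, "OtuTable")) relativeAbundance(x) else as.matrix(x)
  if (ncol(m) < 2L) stop("need at least two samples")
  constant <- apply(m, 2L, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    stop("constant profile (zero variance): ",
         paste(colnames(m)[constant], collapse = ", "))
  }
  stats::cor(m, method = method)
}

#' Correlation to dissimilarity
#'
#' `d = 1 - r`: zero for perfectly correlated profiles, 2 for perfectly
#' anti-correlated ones. This is the minimal monotone transform of a
#' correlation matrix into a dissimilarity and is the convention used for all
#' correlation-based clustering in this package.
#'
#' @param cor_matrix symmetric correlation matrix with entries between -1 and 1.
#' @return dissimilarity matrix, zero diagonal.
#' @export
corToDissimilarity <- function(cor_matrix) {
  if (any(cor_matrix < -1 - 1e-8 | cor_matrix > 1 + 1e-8, na.rm = FALSE)) {
    stop("correlations outside [-1, 1]")
  }
  d <- 1 - cor_matrix
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Agglomerative nesting (AGNES) of samples
#'
#' Hierarchical agglomerative clustering of a dissimilarity matrix via
#' [cluster::agnes()] with average linkage (UPGMA) by default, returning the
#' merge structure together with the agglomerative coefficient
#' AC = mean over leaves of `1 - (height of the leaf's first merge) /
#' (height of the final merge)`. AC is 0 for equidistant data and approaches
#' 1 when one merge height dominates, i.e. when cluster structure is strong.
#'
#' @param dissimilarity square, symmetric, non-negative matrix with zero
#'   diagonal (e.g. from [corToDissimilarity()]).
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return a [DendrogramResult-class].
#' @export
agnesCluster <- function(dissimilarity, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (nrow(d) < 2L) stop("need at least two samples to cluster")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (any(abs(diag(d)) > 1e-10)) stop("dissimilarity diagonal must be zero")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric")
  }
  labs <- rownames(d)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(d)))
  ag <- cluster::agnes(stats::as.dist(d), diss = TRUE, method = linkage)
  hc <- stats::as.hclust(ag)
  new("DendrogramResult", merge = hc$merge, height = hc$height,
      labels = labs, linkage = linkage, ac = unname(ag$ac))
}

#' @rdname DendrogramResult-class
#' @param x a `DendrogramResult`.
#' @export
setMethod("agCoefficient", "DendrogramResult", function(x) x@ac)

setMethod("show", "DendrogramResult", function(object) {
  cat("DendrogramResult: ", length(object@labels), " leaves, ",
      object@linkage, " linkage\n", sep = "")
  cat("  agglomerative coefficient: ", round(object@ac, 4), "\n", sep = "")
})

#' Convert a DendrogramResult to hclust
#'
#' @param x a [DendrogramResult-class].
#' @param ... ignored.
#' @return an object of class `hclust`.
#' @export
asHclust <- function(x, ...) {
  stopifnot(is(x, "DendrogramResult"))
  structure(list(merge = x@merge, height = x@height,
                 order = .dendLeafOrder(x@merge),
                 labels = x@labels, method = x@linkage,
                 call = match.call(), dist.method = "user-supplied"),
            class = "hclust")
}

.dendLeafOrder <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(i) {
    if (i < 0L) return(-i)
    c(walk(merge[i, 1L]), walk(merge[i, 2L]))
  }
  walk(nrow(merge))
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric branch lengths: each node sits at half its merge height, so a
#' two-leaf tree merged at height `h` becomes `(A:h/2,B:h/2);`.
#'
#' @param dendrogram a [DendrogramResult-class].
#' @return single Newick string (with trailing `;`).
#' @export
exportNewick <- function(dendrogram) {
  phy <- ape::as.phylo(asHclust(dendrogram))
  ape::write.tree(phy)
}
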