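#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData "assay<-" "colData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats var sd cor setNames quantile rnorm runif rgamma rmultinom
#'   rhyper r2dtable p.adjust pairwise.t.test pairwise.wilcox.test
#'   model.matrix as.dist as.hclust cophenetic
#' @importFrom utils read.delim write.table packageVersion
NULL

#' OTU count table with taxonomy
#'
#' `OtuTable` extends [SummarizedExperiment::SummarizedExperiment] and stores a
#' non-negative integer count matrix (OTUs as rows, sequencing libraries as
#' columns) in the `"counts"` assay, per-OTU Greengenes-style lineage strings
#' in `rowData(x)$taxonomy`, and, once attached, per-sample design factors and
#' covariates in `colData`. The `domainLabel` slot records whether the table
#' holds bacterial or archaeal 16S libraries, which drives the
#' cross-domain-contamination filter in [filterTaxa()].
#'
#' @slot domainLabel `"bacteria"` or `"archaea"`.
#' @seealso [OtuTable()] (constructor), [readOtuTable()], [filterTaxa()],
#'   [filterRare()], [relativeAbundance()], [hellinger()]
#' @exportClass OtuTable
setClass("OtuTable",
  contains = "SummarizedExperiment",
  slots = c(domainLabel = "character")
)

setValidity("OtuTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'counts' is missing")
  } else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (anyNA(cnt) || any(!is.finite(cnt))) {
      msg <- c(msg, "counts contain missing/non-finite values")
    } else {
      if (any(cnt < 0)) msg <- c(msg, "counts contain negative values")
      if (any(!.isWholeNumber(cnt))) msg <- c(msg, "counts contain non-integer values")
    }
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
    msg <- c(msg, "OTU identifiers must be present and unique")
  }
  if (is.null(colnames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "sample identifiers must be present and unique")
  }
  if (!"taxonomy" %in% colnames(SummarizedExperiment::rowData(object))) {
    msg <- c(msg, "rowData must contain a 'taxonomy' column")
  }
  if (length(object@domainLabel) != 1L ||
      !object@domainLabel %in% c("bacteria", "archaea")) {
    msg <- c(msg, "domainLabel must be 'bacteria' or 'archaea'")
  }
  if (length(msg)) msg else TRUE
})

#' Ordination result (CA / CCA / partial CCA)
#'
#' Holds the chi-square inertia decomposition of a community table together
#' with eigenvalues and scores. The decomposition always satisfies
#' `conditioned + constrained + residual == total` (up to 1e-8 relative).
#' For plain correspondence analysis the conditioned and constrained parts are
#' zero and all axes are unconstrained.
#'
#' @slot totalInertia,conditionedInertia,constrainedInertia,residualInertia
#'   the inertia decomposition.
#' @slot eigConstrained,eigUnconstrained non-negative, non-increasing
#'   eigenvalues of the constrained and unconstrained axis blocks.
#' @slot siteScores sample (site) scores, principal scaling, one row per sample.
#' @slot speciesScores OTU (species) scores, standard scaling.
#' @slot biplotScores correlations of constraint columns with constrained axes
#'   (empty matrix for plain CA).
#' @slot nSamples,nOtus dimensions of the analysed table.
#' @exportClass OrdinationResult
setClass("OrdinationResult", slots = c(
  totalInertia = "numeric",
  conditionedInertia = "numeric",
  constrainedInertia = "numeric",
  residualInertia = "numeric",
  eigConstrained = "numeric",
  eigUnconstrained = "numeric",
  siteScores = "matrix",
  speciesScores = "matrix",
  biplotScores = "matrix",
  nSamples = "integer",
  nOtus = "integer"
))

#' Core microbiome result
#'
#' A prevalence-threshold core OTU set with its provenance: the threshold, the
#' integer sample count it translates to, the sample scope it was computed
#' over, any group-presence constraint, and the per-group range (min, max over
#' samples) of the summed relative abundance contributed by the core set, in
#' percent.
#'
#' @exportClass CoreResult
setClass("CoreResult", slots = c(
  coreIds = "character",
  threshold = "numeric",
  minCount = "integer",
  sampleScope = "character",
  groupConstraint = "character",
  contribution = "matrix",  # groups x c(min, max), percent
  label = "character"
))

#' Community dendrogram with agglomerative coefficient
#'
#' Wraps an agglomerative-nesting (AGNES) clustering of sample community
#' profiles: the merge table in [stats::hclust()] convention, merge heights,
#' leaf labels, the linkage used, and the agglomerative coefficient
#' AC = mean over leaves of 1 - (first-merge height / final-merge height).
#'
#' @exportClass DendrogramResult
setClass("DendrogramResult", slots = c(
  merge = "matrix",
  height = "numeric",
  labels = "character",
  linkage = "character",
  ac = "numeric"
))

#' Pairwise group-test result with compact letter display
#'
#' @slot groups group labels.
#' @slot pMatrix symmetric matrix of (adjusted) pairwise p-values, `NA` diagonal.
#' @slot method test used (`"wilcoxon"` or `"t"`), `adjust` the p-adjustment.
#' @slot letters per-group compact letter display at level `alpha`: groups
#'   sharing no letter differ at adjusted p < alpha.
#' @exportClass GroupTestResult
setClass("GroupTestResult", slots = c(
  groups = "character",
  pMatrix = "matrix",
  method = "character",
  adjust = "character",
  letters = "character",
  alpha = "numeric"
))
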