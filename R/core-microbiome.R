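#' Per-OTU prevalence over a sample scope
#'
#' Number of scoped samples in which each OTU has a nonzero count. Presence
#' is evaluated on the table as given, i.e. after whatever filtering the
#' caller applied.
#'
#' @param x an [OtuTable-class].
#' @param scope character vector of sample ids (default: all samples).
#' @return named integer vector in `[0, length(scope)]`.
#' @export
prevalence <- function(x, scope = sampleIds(x)) {
  stopifnot(is(x, "OtuTable"))
  if (!length(scope)) stop("empty sample scope")
  unknown <- setdiff(scope, sampleIds(x))
  if (length(unknown)) {
    stop("unknown sample id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  rowSums(counts(x)[, scope, drop = FALSE] > 0)
}

#' Prevalence threshold as an integer sample count
#'
#' `floor(threshold * n_samples)`: the minimum number of samples an OTU must
#' be present in to meet a proportional prevalence threshold. The floor
#' convention makes a 66 percent threshold over 122 samples a requirement of
#' presence in 80 samples.
#'
#' @param n_samples number of samples in scope (>= 1).
#' @param threshold prevalence proportion in (0, 1].
#' @return integer count.
#' @examples
#' minPrevalenceCount(122, 0.66)  # 80
#' @export
minPrevalenceCount <- function(n_samples, threshold) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  # small guard so thresholds stored in binary floating point (0.66 * 100)
  # floor to the intended integer
  as.integer(floor(threshold * n_samples + 1e-9))
}

#' Construct a prevalence-threshold core OTU set
#'
#' The core is the set of OTUs present (count > 0) in at least
#' `minPrevalenceCount(|scope|, threshold)` samples of the scope and,
#' if a grouping is supplied, present in at least one sample of every group
#' (e.g. both peatland systems). The per-group abundance contribution of the
#' core -- the range over samples of the summed relative abundance of core
#' OTUs, in percent -- is computed alongside.
#'
#' @param x an [OtuTable-class].
#' @param metadata sample metadata (needed when grouping).
#' @param scope sample ids defining the prevalence scope (default: all).
#' @param threshold prevalence proportion in (0, 1].
#' @param require_presence_in_groups optional metadata column name; the core
#'   OTU must then be present in >= 1 scoped sample of every level.
#' @param label optional label stored on the result.
#' @return a [CoreResult-class].
#' @export
coreSet <- function(x, metadata = sampleData(x), scope = sampleIds(x),
                    threshold = 0.66, require_presence_in_groups = NULL,
                    label = "core") {
  stopifnot(is(x, "OtuTable"))
  if (!length(scope)) stop("empty sample scope")
  prev <- prevalence(x, scope)
  minCount <- minPrevalenceCount(length(scope), threshold)
  core <- prev >= minCount
  groupLabels <- character()
  if (!is.null(require_presence_in_groups)) {
    grp <- metadata[match(scope, metadata$sample_id), require_presence_in_groups]
    if (anyNA(grp)) stop("grouping variable missing for some scoped samples")
    groupLabels <- unique(as.character(grp))
    cnt <- counts(x)[, scope, drop = FALSE]
    for (gl in groupLabels) {
      inG <- rowSums(cnt[, grp == gl, drop = FALSE] > 0) > 0
      core <- core & inG
    }
  }
  ids <- otuIds(x)[core]
  contrib <- .coreContribution(x, ids, scope,
    if (length(groupLabels)) metadata[match(scope, metadata$sample_id),
                                      require_presence_in_groups] else NULL)
  new("CoreResult", coreIds = ids, threshold = threshold,
      minCount = minCount, sampleScope = scope,
      groupConstraint = groupLabels, contribution = contrib, label = label)
}

.coreContribution <- function(x, ids, scope, groups) {
  rel <- relativeAbundance(x[, scope])
  per <- if (length(ids)) 100 * colSums(rel[ids, , drop = FALSE]) else rep(0, length(scope))
  if (is.null(groups)) {
    m <- matrix(c(min(per), max(per)), 1, 2,
                dimnames = list("all", c("min", "max")))
  } else {
    lv <- unique(as.character(groups))
    m <- t(vapply(lv, function(gl) {
      v <- per[groups == gl]
      c(min = min(v), max = max(v))
    }, numeric(2)))
  }
  m
}

#' @rdname CoreResult-class
#' @param x,object a `CoreResult`.
#' @export
setMethod("coreIds", "CoreResult", function(x) x@coreIds)

setMethod("show", "CoreResult", function(object) {
  cat("CoreResult '", object@label, "': ", length(object@coreIds),
      " core OTUs (threshold ", object@threshold, " -> >= ", object@minCount,
      " of ", length(object@sampleScope), " samples", sep = "")
  if (length(object@groupConstraint)) {
    cat("; present in all of: ", paste(object@groupConstraint, collapse = ", "), sep = "")
  }
  cat(")\n")
  cat("  summed relative-abundance contribution (% per group):\n")
  print(round(object@contribution, 2))
})

#' Intersection of two core sets
#'
#' @param a,b [CoreResult-class] objects over the same OTU universe.
#' @return list: `shared` (OTU ids), `n_a`, `n_b`, `n_shared`.
#' @export
coreIntersection <- function(a, b) {
  stopifnot(is(a, "CoreResult"), is(b, "CoreResult"))
  shared <- intersect(coreIds(a), coreIds(b))
  list(shared = shared, n_a = length(coreIds(a)), n_b = length(coreIds(b)),
       n_shared = length(shared))
}

#' Standard core-microbiome profiles
#'
#' The three core constructions used for moss surveys:
#' * `total`: one core at threshold 0.66 over all samples, additionally
#'   required present in both systems;
#' * `per_system`: one core per system at 0.66 over that system's samples;
#' * `per_species`: one core per moss species at the more restrictive 0.75
#'   over that species' moss samples (species with < 2 samples are skipped
#'   with a warning).
#'
#' @param preset `"total"`, `"per_system"` or `"per_species"`.
#' @param x an [OtuTable-class].
#' @param metadata sample metadata.
#' @return named list of [CoreResult-class] objects.
#' @export
coreProfiles <- function(preset = c("total", "per_system", "per_species"),
                         x, metadata = sampleData(x)) {
  preset <- match.arg(preset)
  validateSampleMetadata(metadata, table = x)
  md <- metadata[match(sampleIds(x), metadata$sample_id), ]
  if (preset == "total") {
    return(list(total = coreSet(x, md, threshold = 0.66,
                                require_presence_in_groups = "system",
                                label = "total")))
  }
  if (preset == "per_system") {
    out <- lapply(unique(md$system), function(sys) {
      coreSet(x, md, scope = md$sample_id[md$system == sys],
              threshold = 0.66, label = sys)
    })
    names(out) <- unique(md$system)
    return(out)
  }
  moss <- md[md$sample_class == "moss", ]
  out <- list()
  for (sp in unique(moss$plant_label)) {
    sc <- moss$sample_id[moss$plant_label == sp]
    if (length(sc) < 2L) {
      warning("species '", sp, "' has fewer than 2 samples; skipped")
      next
    }
    out[[sp]] <- coreSet(x, md, scope = sc, threshold = 0.75, label = sp)
  }
  out
}
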