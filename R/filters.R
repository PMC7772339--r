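#' Filter OTUs by taxonomy
#'
#' Drops OTUs whose lineage matches any exclude pattern (by default
#' chloroplast sequences, which are amplified by bacterial 16S primers but are
#' not bacteria of interest) and OTUs whose top-rank domain contradicts the
#' expected domain of the libraries (bacterial OTUs in archaeal tables and
#' vice versa). Matching is a case-insensitive substring test on the
#' rank-prefixed lineage string.
#'
#' @param x an [OtuTable-class].
#' @param exclude_patterns character vector of lineage substrings to drop.
#' @param expected_domain `"bacteria"` or `"archaea"`; defaults to the
#'   table's own `domainLabel`.
#' @return the filtered `OtuTable`; counts of retained OTUs are untouched.
#'   Removing every OTU is an error.
#' @examples
#' m <- matrix(1L, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' tab <- OtuTable(m, taxonomy = c(
#'   "k__Bacteria; p__Cyanobacteria; c__Chloroplast",
#'   "k__Bacteria; p__Acidobacteria"))
#' nrow(filterTaxa(tab))  # 1
#' @export
filterTaxa <- function(x, exclude_patterns = "chloroplast",
                       expected_domain = domainLabel(x)) {
  stopifnot(is(x, "OtuTable"))
  expected_domain <- match.arg(expected_domain, c("bacteria", "archaea"))
  lin <- tolower(taxonomy(x))
  hit <- rep(FALSE, length(lin))
  for (p in tolower(exclude_patterns)) {
    hit <- hit | grepl(p, lin, fixed = TRUE)
  }
  top <- sub(";.*$", "", lin)
  wrong <- if (expected_domain == "bacteria") {
    grepl("archaea", top, fixed = TRUE)
  } else {
    grepl("bacteria", top, fixed = TRUE)
  }
  keep <- !(hit | wrong)
  if (!any(keep)) stop("taxonomy filter removed every OTU")
  out <- x[keep, ]
  S4Vectors::metadata(out)$taxaFilter <- list(
    exclude_patterns = exclude_patterns,
    expected_domain = expected_domain,
    n_removed_pattern = sum(hit),
    n_removed_domain = sum(wrong & !hit)
  )
  out
}

#' Filter rare counts by sample-wise relative abundance
#'
#' Every count whose relative abundance within its own library (computed
#' against the library size *before* any zeroing) is strictly below
#' `min_fraction` is set to zero; entries exactly at the threshold are kept.
#' OTU rows that become all-zero are dropped. With `action = "drop"` whole
#' OTUs are removed instead when their relative abundance is below the
#' threshold in every library (no per-entry zeroing).
#'
#' A report (`entries_zeroed`, `otus_dropped`, parameters) is stored in
#' `metadata(result)$rareFilter`.
#'
#' @param x an [OtuTable-class] with positive library sizes.
#' @param min_fraction strict lower relative-abundance bound, in (0, 1);
#'   default `1e-4`, i.e. 0.01 percent.
#' @param action `"zero"` (default, per-entry zeroing) or `"drop"`
#'   (whole-OTU removal).
#' @return the filtered `OtuTable`.
#' @export
filterRare <- function(x, min_fraction = 1e-4, action = c("zero", "drop")) {
  stopifnot(is(x, "OtuTable"))
  action <- match.arg(action)
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction >= 1) {
    stop("'min_fraction' must be a single value in (0, 1)")
  }
  cnt <- counts(x)
  tot <- colSums(cnt)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  }
  # strict "<" with a relative guard so entries exactly at the threshold
  # survive floating-point representation of min_fraction * total
  thr <- matrix(min_fraction * tot, nrow(cnt), ncol(cnt), byrow = TRUE)
  below <- cnt > 0 & cnt < thr * (1 - 1e-9)
  if (action == "zero") {
    cnt[below] <- 0L
    keep <- rowSums(cnt) > 0
    report <- list(min_fraction = min_fraction, action = action,
                   entries_zeroed = sum(below),
                   otus_dropped = rownames(x)[!keep])
  } else {
    present <- counts(x) > 0
    keep <- rowSums(present & !below) > 0
    report <- list(min_fraction = min_fraction, action = action,
                   entries_zeroed = 0L,
                   otus_dropped = rownames(x)[!keep])
  }
  out <- x[keep, ]
  if (action == "zero") {
    SummarizedExperiment::assay(out, "counts") <- cnt[keep, , drop = FALSE]
  }
  S4Vectors::metadata(out)$rareFilter <- report
  out
}

#' Per-sample relative abundances
#'
#' @param x an [OtuTable-class] or a non-negative matrix (OTUs x samples)
#'   with positive column sums.
#' @return matrix of column-wise proportions; every column sums to 1.
#' @export
relativeAbundance <- function(x) {
  cnt <- if (is(x, "OtuTable")) counts(x) else as.matrix(x)
  .assertCountMatrix(cnt * 1.0)
  tot <- colSums(cnt)
  if (any(tot == 0)) {
    stop("cannot compute relative abundance for all-zero sample(s): ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  }
  sweep(cnt, 2L, tot, "/")
}

#' Hellinger transformation
#'
#' Square root of per-sample relative abundances,
#' `sqrt(count / library size)`. The squared entries of each column sum to 1,
#' which moderates the leverage of highly abundant OTUs in chi-square-based
#' ordination.
#'
#' @inheritParams relativeAbundance
#' @return transformed matrix.
#' @export
hellinger <- function(x) {
  sqrt(relativeAbundance(x))
}
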