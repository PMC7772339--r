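#' Construct an OtuTable
#'
#' @param counts numeric matrix of non-negative integer counts, OTUs as rows
#'   and sequencing libraries as columns, with row and column names.
#' @param taxonomy character vector of semicolon-separated, rank-prefixed
#'   lineage strings (Greengenes style, e.g.
#'   `"k__Bacteria; p__Proteobacteria; ..."`), one per OTU. If `NULL`, all
#'   OTUs are labelled `"Unassigned"`.
#' @param domain `"bacteria"` or `"archaea"`; the domain the libraries were
#'   amplified for.
#' @param sampleData optional `data.frame` of per-sample metadata (see
#'   [readSampleMetadata()]); attached as `colData`.
#' @return A validated [OtuTable-class] object.
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'             dimnames = list(c("OTU_1", "OTU_2"), c("s1", "s2")))
#' tab <- OtuTable(m, taxonomy = c("k__Bacteria; p__Acidobacteria",
#'                                 "k__Bacteria; p__Proteobacteria"))
#' otuIds(tab)
#' @export
OtuTable <- function(counts, taxonomy = NULL, domain = c("bacteria", "archaea"),
                     sampleData = NULL) {
  domain <- match.arg(domain)
  .assertCountMatrix(counts)
  if (is.null(rownames(counts))) stop("'counts' must have OTU row names")
  if (is.null(colnames(counts))) stop("'counts' must have sample column names")
  if (is.null(taxonomy)) taxonomy <- rep("Unassigned", nrow(counts))
  if (length(taxonomy) != nrow(counts)) {
    stop("taxonomy length (", length(taxonomy), ") does not match the number of OTUs (",
         nrow(counts), ")")
  }
  storage.mode(counts) <- "integer"
  rd <- S4Vectors::DataFrame(taxonomy = as.character(taxonomy),
                             row.names = rownames(counts))
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    .orderSampleData(sampleData, colnames(counts))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("OtuTable", se, domainLabel = domain)
}

.orderSampleData <- function(sampleData, ids) {
  sampleData <- as.data.frame(sampleData)
  key <- if ("sample_id" %in% colnames(sampleData)) sampleData$sample_id else rownames(sampleData)
  miss <- setdiff(ids, key)
  if (length(miss)) {
    stop("no metadata row for sample(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  out <- sampleData[match(ids, key), , drop = FALSE]
  rownames(out) <- ids
  S4Vectors::DataFrame(out)
}

#' @rdname OtuTable-class
#' @param x,object an `OtuTable`.
#' @export
setMethod("otuIds", "OtuTable", function(x) rownames(x))

#' @rdname OtuTable-class
#' @export
setMethod("sampleIds", "OtuTable", function(x) colnames(x))

#' @rdname OtuTable-class
#' @export
setMethod("taxonomy", "OtuTable", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$taxonomy, rownames(x))
})

#' @rdname OtuTable-class
#' @export
setMethod("domainLabel", "OtuTable", function(x) x@domainLabel)

#' @rdname OtuTable-class
#' @importFrom BiocGenerics counts
#' @exportMethod counts
setMethod("counts", "OtuTable", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname OtuTable-class
#' @export
setMethod("librarySizes", "OtuTable", function(x) colSums(counts(x)))

#' @rdname OtuTable-class
#' @export
setMethod("sampleData", "OtuTable", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

setMethod("show", "OtuTable", function(object) {
  cat("OtuTable (", object@domainLabel, "): ",
      nrow(object), " OTUs x ", ncol(object), " samples\n", sep = "")
  ls <- librarySizes(object)
  cat("  library sizes: ", min(ls), "-", max(ls),
      " (median ", round(stats::median(ls)), ")\n", sep = "")
  md <- colnames(SummarizedExperiment::colData(object))
  if (length(md)) cat("  sample metadata:", paste(md, collapse = ", "), "\n")
})

#' Read an OTU table from disk
#'
#' The canonical on-disk dialect is TSV: first column the OTU identifier,
#' header row the sample identifiers, and an optional trailing `taxonomy`
#' column. BIOM 2.x files are supported through the `biomformat` package and
#' converted on read.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom"`.
#' @param domain domain label for the resulting table.
#' @return An [OtuTable-class].
#' @details Duplicate OTU identifiers and negative or non-integer counts are
#'   hard errors (the offending cell is named). A missing taxonomy column is
#'   tolerated with a warning; taxonomy is then filled with `"Unassigned"`.
#' @export
readOtuTable <- function(path, format = c("tsv", "biom"),
                         domain = c("bacteria", "archaea")) {
  format <- match.arg(format)
  domain <- match.arg(domain)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("BIOM import requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    cnt <- as(biomformat::biom_data(b), "matrix")
    om <- biomformat::observation_metadata(b)
    tax <- if (is.null(om)) NULL else
      apply(as.data.frame(om), 1L, function(r) paste(r[!is.na(r)], collapse = "; "))
    if (is.null(tax)) warning("BIOM file has no observation metadata; taxonomy set to 'Unassigned'")
    return(OtuTable(cnt, taxonomy = tax, domain = domain))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate OTU identifier(s): ", paste(unique(dup), collapse = ", "))
  hasTax <- tolower(colnames(df)[ncol(df)]) == "taxonomy"
  tax <- NULL
  lastCount <- ncol(df)
  if (hasTax) {
    tax <- as.character(df[[ncol(df)]])
    lastCount <- ncol(df) - 1L
  } else {
    warning("no 'taxonomy' column found; taxonomy set to 'Unassigned'")
  }
  if (lastCount < 2L) stop("no sample columns found in ", path)
  cnt <- as.matrix(df[, 2:lastCount, drop = FALSE])
  rownames(cnt) <- ids
  if (!is.numeric(cnt)) {
    bad <- which(is.na(suppressWarnings(apply(cnt, 2, as.numeric))), arr.ind = TRUE)
    stop("non-numeric count at ", .cellName(cnt, bad[1L, ]))
  }
  badNeg <- which(cnt < 0, arr.ind = TRUE)
  if (nrow(badNeg)) stop("negative count at ", .cellName(cnt, badNeg[1L, ]))
  badInt <- which(!.isWholeNumber(cnt), arr.ind = TRUE)
  if (nrow(badInt)) stop("non-integer count at ", .cellName(cnt, badInt[1L, ]))
  empty <- colnames(cnt)[colSums(cnt) == 0]
  if (length(empty)) stop("sample(s) with zero total counts: ", paste(empty, collapse = ", "))
  OtuTable(cnt, taxonomy = tax, domain = domain)
}

#' Write an OTU table as TSV
#'
#' Writes the canonical TSV dialect read by [readOtuTable()]: OTU ids in the
#' first column, one column per sample, taxonomy last. UTF-8, LF line endings,
#' `.` decimal separator.
#'
#' @param x an [OtuTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path) {
  stopifnot(is(x, "OtuTable"))
  df <- data.frame(otu_id = otuIds(x), counts(x),
                   taxonomy = unname(taxonomy(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read or validate per-sample metadata
#'
#' Sample metadata is a TSV with one row per sequencing library and the
#' columns `sample_id`, `system` (amb/sph), `area`, `subsite`, `plant_label`,
#' `sample_class` (moss/vascular/sediment), `fraction`
#' (endophyte/epiphyte/reference), `plant_unit` (identifier linking the
#' libraries of one physical moss plant), `hydrology`
#' (submerged/emerged/unknown), and the continuous covariates `pH`,
#' `temperature` (deg C) and `ch4` (uM), which may be missing (`NA`).
#'
#' @param path TSV file path.
#' @param validate check the design invariants via [validateSampleMetadata()].
#' @return a `data.frame` with `sample_id` row names.
#' @export
readSampleMetadata <- function(path, validate = TRUE) {
  md <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (validate) validateSampleMetadata(md)
  rownames(md) <- md$sample_id
  md
}

#' @rdname readSampleMetadata
#' @param metadata a metadata `data.frame`.
#' @param table optional [OtuTable-class]; when given, every table sample must
#'   resolve to exactly one metadata row.
#' @export
validateSampleMetadata <- function(metadata, table = NULL) {
  req <- c("sample_id", "system", "area", "subsite", "plant_label",
           "sample_class", "fraction", "plant_unit", "hydrology",
           "pH", "temperature", "ch4")
  miss <- setdiff(req, colnames(metadata))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]), collapse = ", "))
  }
  ee <- metadata$fraction %in% c("endophyte", "epiphyte")
  bad <- ee & (metadata$sample_class != "moss" | is.na(metadata$plant_unit))
  if (any(bad)) {
    stop("endophyte/epiphyte libraries must be moss samples with a plant_unit: ",
         paste(utils::head(metadata$sample_id[bad], 5), collapse = ", "))
  }
  ph <- metadata$pH
  if (any(!is.na(ph) & (ph < 0 | ph > 14))) stop("pH outside [0, 14]")
  if (any(!is.na(metadata$ch4) & metadata$ch4 < 0)) stop("negative CH4 concentration")
  if (!is.null(table)) {
    unmatched <- setdiff(sampleIds(table), metadata$sample_id)
    if (length(unmatched)) {
      stop("table sample(s) without metadata: ",
           paste(utils::head(unmatched, 5), collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Attach sample metadata to an OtuTable
#'
#' @param x an [OtuTable-class].
#' @param metadata a metadata `data.frame` (see [readSampleMetadata()]);
#'   rows are matched to table samples by `sample_id`.
#' @return `x` with populated `colData`.
#' @export
attachSampleData <- function(x, metadata) {
  stopifnot(is(x, "OtuTable"))
  validateSampleMetadata(metadata, table = x)
  SummarizedExperiment::colData(x) <- .orderSampleData(metadata, sampleIds(x))
  validObject(x)
  x
}

#' Check the paired endophyte/epiphyte design
#'
#' In a complete design every moss plant yields two endophyte technical
#' replicate libraries and one epiphyte (wash-off) library. Returns, per
#' plant unit, the observed counts of each fraction.
#'
#' @param metadata sample metadata.
#' @return `data.frame` with columns `plant_unit`, `n_endophyte`,
#'   `n_epiphyte`, `complete`.
#' @export
checkPairedDesign <- function(metadata) {
  moss <- metadata[metadata$sample_class == "moss" & !is.na(metadata$plant_unit), ]
  units <- unique(moss$plant_unit)
  res <- data.frame(
    plant_unit = units,
    n_endophyte = vapply(units, function(u)
      sum(moss$plant_unit == u & moss$fraction == "endophyte"), integer(1)),
    n_epiphyte = vapply(units, function(u)
      sum(moss$plant_unit == u & moss$fraction == "epiphyte"), integer(1)),
    stringsAsFactors = FALSE
  )
  res$complete <- res$n_endophyte == 2L & res$n_epiphyte == 1L
  rownames(res) <- NULL
  res
}
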