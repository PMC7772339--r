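#' @rdname OtuTable-class
#' @export
setGeneric("otuIds", function(x) standardGeneric("otuIds"))

#' @rdname OtuTable-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OtuTable-class
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname OtuTable-class
#' @export
setGeneric("domainLabel", function(x) standardGeneric("domainLabel"))

#' @rdname OtuTable-class
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname OtuTable-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname CoreResult-class
#' @export
setGeneric("coreIds", function(x) standardGeneric("coreIds"))

#' @rdname DendrogramResult-class
#' @export
setGeneric("agCoefficient", function(x) standardGeneric("agCoefficient"))

#' @rdname OrdinationResult-class
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))

#' @rdname OrdinationResult-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname OrdinationResult-class
#' @export
setGeneric("siteScores", function(x) standardGeneric("siteScores"))

#' @rdname OrdinationResult-class
#' @export
setGeneric("speciesScores", function(x) standardGeneric("speciesScores"))

#' @rdname GroupTestResult-class
#' @export
setGeneric("groupLetters", function(x) standardGeneric("groupLetters"))

#' @rdname GroupTestResult-class
#' @export
setGeneric("pMatrix", function(x) standardGeneric("pMatrix"))
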