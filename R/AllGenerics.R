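#' @import methods
NULL

#' @rdname BarcodeAlignment-class
#' @param x a \code{BarcodeAlignment}
#' @export
setGeneric("alnSeqs", function(x) standardGeneric("alnSeqs"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("taxonomy", function(x) standardGeneric("taxonomy"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("alignedLength", function(x) standardGeneric("alignedLength"))

#' @rdname BarcodeAlignment-class
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname filterValid
#' @export
setGeneric("exclusionLog", function(x) standardGeneric("exclusionLog"))

#' @rdname filterValid
#' @export
setGeneric("filterValid", function(x) standardGeneric("filterValid"))

#' @rdname subsetByLevel
#' @export
setGeneric("subsetByLevel",
    function(x, level, group = NULL) standardGeneric("subsetByLevel"))

#' @rdname subsetByLevel
#' @export
setGeneric("groupNames", function(x, level) standardGeneric("groupNames"))

#' @rdname k2pMatrix
#' @export
setGeneric("k2pMatrix", function(x) standardGeneric("k2pMatrix"))

#' @rdname K2PMatrix-class
#' @param x a \code{K2PMatrix}
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname K2PMatrix-class
#' @export
setGeneric("comparableSites", function(x) standardGeneric("comparableSites"))

#' @rdname K2PMatrix-class
#' @export
setGeneric("definedPairs", function(x) standardGeneric("definedPairs"))

#' @rdname siteStats
#' @export
setGeneric("siteStats", function(x, ...) standardGeneric("siteStats"))

#' @rdname divergenceSummary
#' @export
setGeneric("divergenceSummary",
    function(x, ...) standardGeneric("divergenceSummary"))

#' @rdname distanceHistogram
#' @export
setGeneric("distanceHistogram",
    function(x, ...) standardGeneric("distanceHistogram"))

#' @rdname identificationReport
#' @export
setGeneric("identificationReport",
    function(x, ...) standardGeneric("identificationReport"))
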