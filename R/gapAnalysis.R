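#' Intra/interspecific distance-frequency distribution
#'
#' Splits the defined pairwise distances into conspecific (intraspecific)
#' and heterospecific (interspecific) classes, expresses them in percent
#' (d x 100) and bins them into half-open intervals [lo, hi) of fixed
#' width, the terminal bin closed so the maximum distance is counted.
#' Relative abundance is 100 x count / total defined pairs of that class.
#' An empty class yields zero bins for that class (flagged by the absence
#' of rows).
#'
#' @param x a \code{K2PMatrix} (carries the species labels).
#' @param binWidth bin width in percentage points; must be positive
#'   (default 1).
#' @return a \code{\linkS4class{DistanceHistogram}}.
#' @seealso \code{\link{rangeShare}}, \code{\link{barcodeGapSummary}}
#' @export
setMethod("distanceHistogram", "K2PMatrix", function(x, binWidth = 1) {
    if (!is.numeric(binWidth) || binWidth <= 0)
        stop("bin width must be positive")
    pc <- .pairClasses(x)
    intra <- pc$intra * 100
    inter <- pc$inter * 100
    binify <- function(v, cls) {
        if (!length(v)) return(NULL)
        hi <- max(v)
        nbins <- max(1L, ceiling((hi + 1e-12) / binWidth))
        edges <- seq(0, by = binWidth, length.out = nbins + 1L)
        idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE),
            nbins)
        cnt <- tabulate(idx, nbins)
        data.frame(class = cls, lo = edges[-length(edges)],
            hi = edges[-1L], count = cnt,
            relAbund = 100 * cnt / length(v), stringsAsFactors = FALSE)
    }
    bins <- rbind(binify(intra, "intraspecific"),
        binify(inter, "interspecific"))
    if (is.null(bins))
        bins <- data.frame(class = character(0), lo = numeric(0),
            hi = numeric(0), count = integer(0), relAbund = numeric(0))
    new("DistanceHistogram", binWidth = binWidth, bins = bins,
        intra = intra, inter = inter)
})

#' @rdname distanceHistogram
#' @param object,h a \code{DistanceHistogram}
#' @export
histogramBins <- function(h) h@bins

setMethod("show", "DistanceHistogram", function(object) {
    cat(sprintf(
        "DistanceHistogram: %d intraspecific, %d interspecific pairs (bin %.3g%%)\n",
        length(object@intra), length(object@inter), object@binWidth))
    if (length(object@intra))
        cat(sprintf("  intra: max %.2f%%\n", max(object@intra)))
    if (length(object@inter))
        cat(sprintf("  inter: min %.2f%%, max %.2f%%\n",
            min(object@inter), max(object@inter)))
})

#' Share of a distance class inside a percent range
#'
#' The percentage of one class's defined pairs whose distance (in percent)
#' lies in the half-open range [lo, hi). Computed from the raw distances
#' held by the histogram, so it is exact regardless of binning.
#'
#' @param h a \code{DistanceHistogram}.
#' @param class \code{"intraspecific"} or \code{"interspecific"}.
#' @param lo,hi range bounds in percent, \code{lo < hi} (use \code{Inf}
#'   for an open top).
#' @return a percentage in [0, 100]; \code{NA} if the class is empty.
#' @examples
#' # rangeShare(h, "intraspecific", 0, 2) ~ share of conspecific pairs
#' # diverging by less than 2%
#' @export
rangeShare <- function(h, class = c("intraspecific", "interspecific"),
    lo, hi) {
    class <- match.arg(class)
    if (!(lo < hi)) stop("lo must be < hi")
    v <- if (class == "intraspecific") h@intra else h@inter
    if (!length(v)) return(NA_real_)
    100 * sum(v >= lo & v < hi) / length(v)
}

#' Barcode-gap summary
#'
#' Quantifies the separation between the intraspecific and interspecific
#' distance distributions: the maximum intraspecific distance, the minimum
#' interspecific distance, their difference (the barcode gap; negative
#' means the distributions overlap), and the share of interspecific pairs
#' lying below the 95th percentile of the intraspecific distances (an
#' overlap measure robust to single outliers). All values in percent.
#'
#' @param h a \code{DistanceHistogram}.
#' @return a list with elements \code{maxIntra}, \code{minInter},
#'   \code{gap}, \code{overlapShare} and \code{ok}; when either class is
#'   empty, \code{ok} is \code{FALSE} and the numeric fields are \code{NA}.
#' @export
barcodeGapSummary <- function(h) {
    if (!length(h@intra) || !length(h@inter))
        return(list(maxIntra = NA_real_, minInter = NA_real_,
            gap = NA_real_, overlapShare = NA_real_, ok = FALSE))
    maxIntra <- max(h@intra)
    minInter <- min(h@inter)
    q95 <- stats::quantile(h@intra, 0.95, names = FALSE, type = 7)
    list(maxIntra = maxIntra, minInter = minInter,
        gap = minInter - maxIntra,
        overlapShare = 100 * mean(h@inter < q95), ok = TRUE)
}
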