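# Half-up rounding for report percentages (base round() is half-even).
.round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Classify one alignment column
#'
#' Site categories follow the MEGA-like convention: gaps and ambiguity
#' codes are ignored when counting base types at a column. With fewer than
#' two usable residues the column is \emph{indeterminate} (counted in the
#' aligned length but in neither the conserved nor the variable tally).
#' Otherwise: \emph{conserved} if exactly one base type is present;
#' \emph{parsimony-informative} if at least two base types each occur in at
#' least two sequences; \emph{singleton} if variable but at most one base
#' type occurs more than once. Under this rule every variable column is
#' either parsimony-informative or a singleton; the level
#' \code{"variable-other"} is kept in the factor for forward compatibility
#' with conventions that leave some variable columns unassigned.
#'
#' @param column character vector: the residues at one alignment position
#'   (one per sequence).
#' @return a length-1 factor with levels \code{conserved},
#'   \code{singleton}, \code{parsimony-informative}, \code{variable-other},
#'   \code{indeterminate}.
#' @examples
#' classifySite(c("A", "A", "G", "G"))  # parsimony-informative
#' classifySite(c("A", "A", "A", "G"))  # singleton
#' @export
classifySite <- function(column) {
    if (!length(column)) stop("empty column")
    lv <- c("conserved", "singleton", "parsimony-informative",
        "variable-other", "indeterminate")
    res <- .asResidues(column)
    usable <- res[res %in% names(.BASES)]
    cls <- if (length(usable) < 2L) {
        "indeterminate"
    } else {
        tab <- table(usable)
        if (length(tab) == 1L) "conserved"
        else if (sum(tab >= 2L) >= 2L) "parsimony-informative"
        else if (sum(tab > 1L) <= 1L) "singleton"
        else "variable-other"
    }
    factor(cls, levels = lv)
}

#' Alignment variability statistics
#'
#' Tallies every column of the alignment with \code{\link{classifySite}}
#' and computes the overall mean distance (OMD): the arithmetic mean of all
#' defined pairwise K2P distances (pairwise deletion; undefined pairs are
#' excluded and counted). Variable sites are the union of
#' parsimony-informative and singleton columns; indeterminate columns
#' (fewer than two unambiguous residues) complete the aligned length, so
#' AL = CS + VS + indeterminate always holds.
#'
#' @param x a \code{BarcodeAlignment} with at least 2 sequences.
#' @param group,level labels stored in the result (purely descriptive).
#' @param dm optionally, a precomputed \code{K2PMatrix} for \code{x} (to
#'   avoid recomputing distances).
#' @return a \code{\linkS4class{SiteStats}}.
#' @seealso \code{\link{siteStatsTable}} for the per-group report table.
#' @export
setMethod("siteStats", "BarcodeAlignment",
    function(x, group = "all", level = "family", dm = NULL) {
    if (length(x) < 2L) stop("need at least 2 sequences")
    m <- as.matrix(alnSeqs(x))
    cls <- apply(m, 2L, function(col) as.character(classifySite(col)))
    tab <- table(factor(cls, levels = c("conserved", "singleton",
        "parsimony-informative", "variable-other", "indeterminate")))
    vs <- tab[["singleton"]] + tab[["parsimony-informative"]] +
        tab[["variable-other"]]
    counts <- c(CS = tab[["conserved"]], VS = vs,
        PIS = tab[["parsimony-informative"]], SS = tab[["singleton"]],
        indeterminate = tab[["indeterminate"]])
    if (is.null(dm)) dm <- k2pMatrix(x)
    up <- upper.tri(dm@d)
    def <- dm@defined[up]
    dd <- dm@d[up][def]
    omd <- if (length(dd)) mean(dd) else NA_real_
    new("SiteStats", group = group, level = level,
        nSeq = length(x), AL = ncol(m),
        counts = as.integer(counts) |> stats::setNames(names(counts)),
        OMD = omd, nPairsDefined = length(dd),
        nPairsDropped = sum(!def))
})

#' @rdname siteStats
#' @param row.names,optional,... passed through (see
#'   \code{\link[base]{as.data.frame}}).
#' @export
setMethod("as.data.frame", "SiteStats",
    function(x, row.names = NULL, optional = FALSE, ...) {
    cnt <- x@counts
    pct <- .round2(100 * cnt[c("CS", "VS", "PIS", "SS")] / x@AL)
    data.frame(level = x@level, group = x@group, nSeq = x@nSeq,
        AL = x@AL,
        CS = cnt[["CS"]], CSpct = pct[["CS"]],
        VS = cnt[["VS"]], VSpct = pct[["VS"]],
        PIS = cnt[["PIS"]], PISpct = pct[["PIS"]],
        SS = cnt[["SS"]], SSpct = pct[["SS"]],
        indeterminate = cnt[["indeterminate"]],
        OMD = x@OMD, row.names = row.names, stringsAsFactors = FALSE)
})

setMethod("show", "SiteStats", function(object) {
    df <- as.data.frame(object)
    cat(sprintf("SiteStats [%s / %s]: %d seqs\n", object@level,
        object@group, object@nSeq))
    cat(sprintf(
        "  AL %d | CS %d (%.2f%%) | VS %d (%.2f%%) | PIS %d (%.2f%%) | SS %d (%.2f%%)\n",
        df$AL, df$CS, df$CSpct, df$VS, df$VSpct, df$PIS, df$PISpct,
        df$SS, df$SSpct))
    cat(sprintf("  OMD %.3f (%d defined pairs, %d dropped)\n",
        object@OMD, object@nPairsDefined, object@nPairsDropped))
})

#' Per-group site-statistics table at one taxonomic level
#'
#' Convenience report builder: subsets the dataset to every group at the
#' requested level (each view with its group-specific aligned length after
#' all-gap-column removal) and stacks the \code{\link{siteStats}} rows into
#' one table of AL, CS/VS/PIS/SS counts with percentages, and OMD.
#'
#' @param x a validated \code{BarcodeAlignment}.
#' @param level one of \code{"complex"}, \code{"genus"},
#'   \code{"subfamily"}, \code{"family"}.
#' @return a \code{data.frame}, one row per group.
#' @export
siteStatsTable <- function(x, level = "family") {
    level <- match.arg(level, .LEVELS)
    rows <- lapply(groupNames(x, level), function(g) {
        v <- subsetByLevel(x, level, g)
        if (length(v) < 2L) return(NULL)
        as.data.frame(siteStats(v, group = g, level = level))
    })
    do.call(rbind, rows)
}
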