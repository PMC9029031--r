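.sd0 <- function(v) if (length(v) >= 2L) stats::sd(v) else 0
.se0 <- function(v) if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else 0

.idxRow <- function(index, values) {
    if (!length(values))
        return(data.frame(index = index, mean = 0, sd = 0, se = 0, n = 0L,
            stringsAsFactors = FALSE))
    data.frame(index = index, mean = mean(values), sd = .sd0(values),
        se = .se0(values), n = length(values), stringsAsFactors = FALSE)
}

#' Group-level divergence indices
#'
#' Computes the five divergence indices for a group of sequences from its
#' K2P distance matrix:
#' \itemize{
#'   \item \emph{all interspecific distance}: mean over all defined
#'     heterospecific pairs in the group;
#'   \item \emph{minimum interspecific distance}: for each species, the
#'     smallest defined distance from any of its sequences to any
#'     non-conspecific sequence, averaged over species;
#'   \item \emph{all intraspecific distance}: mean over all defined
#'     conspecific pairs, pooled;
#'   \item \emph{theta}: per species with >= 2 sequences, the mean
#'     conspecific distance, averaged over those species (equal weight per
#'     species, so uneven sampling does not bias it);
#'   \item \emph{coalescent depth}: per species with >= 2 sequences, the
#'     maximum conspecific distance, averaged over those species.
#' }
#' The dispersion printed alongside each mean is the sample standard
#' deviation of the constituent values (pairwise distances for the two
#' pooled indices, per-species values for the rest); the standard error is
#' also carried in the result. Species with a single sequence contribute to
#' the interspecific indices but are skipped (not zero-filled) for theta
#' and coalescent depth. Undefined pairs are excluded everywhere and
#' counted. A single-species group, or one with no defined pairs of a
#' class, reports 0 for the affected indices (matching the convention that
#' a one-taxon group has zero divergence).
#'
#' @param x a \code{BarcodeAlignment} (distances computed on its own
#'   alignment view) or a \code{K2PMatrix}.
#' @param group,level descriptive labels stored in the result.
#' @param dm optional precomputed \code{K2PMatrix} (BarcodeAlignment
#'   method only).
#' @return a \code{\linkS4class{DivergenceSummary}}.
#' @seealso \code{\link{divergenceTable}}
#' @export
setMethod("divergenceSummary", "BarcodeAlignment",
    function(x, group = "all", level = "family", dm = NULL) {
    if (is.null(dm)) dm <- k2pMatrix(x)
    divergenceSummary(dm, group = group, level = level)
})

#' @rdname divergenceSummary
#' @export
setMethod("divergenceSummary", "K2PMatrix",
    function(x, group = "all", level = "family") {
    sp <- x@species
    d <- x@d
    def <- x@defined
    up <- upper.tri(d)
    same <- outer(sp, sp, "==")
    interAll <- d[up & !same & def]
    intraAll <- d[up & same & def]
    nDropped <- sum(!def[up])

    species <- unique(sp)
    minInter <- vapply(species, function(s) {
        block <- d[sp == s, sp != s, drop = FALSE]
        ok <- def[sp == s, sp != s, drop = FALSE]
        v <- block[ok]
        if (length(v)) min(v) else NA_real_
    }, numeric(1))
    minInter <- minInter[!is.na(minInter)]

    perSpIntra <- lapply(species, function(s) {
        i <- which(sp == s)
        if (length(i) < 2L) return(NULL)
        sub <- d[i, i, drop = FALSE]
        okk <- def[i, i, drop = FALSE] & upper.tri(sub)
        sub[okk]
    })
    perSpIntra <- Filter(function(v) !is.null(v) && length(v) > 0,
        perSpIntra)
    theta <- vapply(perSpIntra, mean, numeric(1))
    coalDepth <- vapply(perSpIntra, max, numeric(1))

    idx <- rbind(
        .idxRow("allInterspecific", interAll),
        .idxRow("minInterspecific", unname(minInter)),
        .idxRow("allIntraspecific", intraAll),
        .idxRow("theta", theta),
        .idxRow("coalescentDepth", coalDepth))
    new("DivergenceSummary", group = group, level = level,
        indices = idx, nPairsDropped = as.integer(nDropped))
})

#' @rdname divergenceSummary
#' @param row.names,optional,... see \code{\link[base]{as.data.frame}}.
#' @export
setMethod("as.data.frame", "DivergenceSummary",
    function(x, row.names = NULL, optional = FALSE, ...) {
    cbind(data.frame(level = x@level, group = x@group,
        stringsAsFactors = FALSE), x@indices)
})

setMethod("show", "DivergenceSummary", function(object) {
    cat(sprintf("DivergenceSummary [%s / %s]\n", object@level,
        object@group))
    for (i in seq_len(nrow(object@indices))) {
        r <- object@indices[i, ]
        cat(sprintf("  %-18s %.4f ± %.4f  (n=%d)\n", r$index,
            r$mean, r$sd, r$n))
    }
    if (object@nPairsDropped)
        cat(sprintf("  undefined pairs dropped: %d\n",
            object@nPairsDropped))
})

#' Divergence table across all groups of a level
#'
#' Runs \code{\link{divergenceSummary}} for every group at the requested
#' taxonomic level (each on its own alignment view) and returns one long
#' table with a formatted "mean ± sd" column plus the raw numeric
#' columns.
#'
#' @param x a validated \code{BarcodeAlignment}.
#' @param level one of \code{"complex"}, \code{"genus"},
#'   \code{"subfamily"}, \code{"family"}.
#' @return a \code{data.frame}, five rows (indices) per group.
#' @export
divergenceTable <- function(x, level = "family") {
    level <- match.arg(level, .LEVELS)
    rows <- lapply(groupNames(x, level), function(g) {
        v <- subsetByLevel(x, level, g)
        if (length(v) < 2L) return(NULL)
        df <- as.data.frame(divergenceSummary(v, group = g,
            level = level))
        df$meanSd <- sprintf("%.4f ± %.4f", df$mean, df$sd)
        df
    })
    do.call(rbind, rows)
}
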