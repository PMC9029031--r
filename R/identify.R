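.verdictFromSet <- function(bestSpecies, querySpecies) {
    hit <- bestSpecies == querySpecies
    if (all(hit)) "correct"
    else if (!any(hit)) "incorrect"
    else "ambiguous"
}

.queryIndex <- function(dm, query) {
    if (is.character(query)) {
        i <- match(query, rownames(dm@d))
        if (is.na(i)) stop("unknown query id: ", query)
        i
    } else as.integer(query)
}

#' Best Match verdict for one query
#'
#' Leave-one-out nearest-neighbour identification: the query is removed
#' from the reference pool and its best-match set is every remaining
#' sequence at the minimum defined K2P distance (ties kept; distances are
#' compared exactly, since they derive from identical arithmetic). The
#' verdict is \emph{correct} if every best match is conspecific,
#' \emph{incorrect} if none is, \emph{ambiguous} if the set mixes
#' conspecific and heterospecific references, and \emph{no-match} if every
#' distance to the references is undefined.
#'
#' @param dm a \code{K2PMatrix} over the group (queries and references).
#' @param query a sequence id (row name) or index.
#' @return a list: \code{id}, \code{species}, \code{verdict},
#'   \code{bestIds}, \code{bestSpecies}, \code{bestDistance},
#'   \code{threshold} (\code{NA} for BM).
#' @seealso \code{\link{bestCloseMatch}}, \code{\link{blast1Classify}},
#'   \code{\link{identificationReport}}
#' @export
bestMatch <- function(dm, query) {
    .bestWithin(dm, query, threshold = Inf, method = "BM")
}

#' Best Close Match verdict for one query
#'
#' As \code{\link{bestMatch}}, but references farther from the query than
#' the threshold are discarded before the best set is formed (matches at
#' exactly the threshold survive); if no reference survives, the verdict is
#' \emph{no-match}. The standard threshold is the 95th percentile of the
#' pooled intraspecific distances, see \code{\link{bcmThreshold}}.
#'
#' @inheritParams bestMatch
#' @param threshold maximum allowed distance to a reference.
#' @return as \code{\link{bestMatch}}.
#' @export
bestCloseMatch <- function(dm, query, threshold) {
    .bestWithin(dm, query, threshold = threshold, method = "BCM")
}

.bestWithin <- function(dm, query, threshold, method) {
    i <- .queryIndex(dm, query)
    ids <- rownames(dm@d)
    sp <- dm@species
    drow <- dm@d[i, -i]
    def <- dm@defined[i, -i]
    refIds <- ids[-i]
    refSp <- sp[-i]
    ok <- def & drow <= threshold
    base <- list(id = ids[i], species = sp[i],
        threshold = if (is.finite(threshold)) threshold else NA_real_)
    if (!any(ok))
        return(c(base, list(verdict = "no-match",
            bestIds = character(0), bestSpecies = character(0),
            bestDistance = NA_real_)))
    dmin <- min(drow[ok])
    best <- ok & drow == dmin
    c(base, list(
        verdict = .verdictFromSet(refSp[best], sp[i]),
        bestIds = refIds[best], bestSpecies = unique(refSp[best]),
        bestDistance = dmin))
}

#' Best Close Match distance threshold
#'
#' The 95th percentile (by default; linearly interpolated) of all pooled
#' defined intraspecific K2P distances — the standard cutoff separating
#' plausible conspecific matches from everything else.
#'
#' @param dm a \code{K2PMatrix}.
#' @param percentile probability in (0, 1]; default 0.95.
#' @return a distance (substitutions/site).
#' @export
bcmThreshold <- function(dm, percentile = 0.95) {
    intra <- .pairClasses(dm)$intra
    if (!length(intra))
        stop("no defined intraspecific pairs; cannot derive a threshold")
    stats::quantile(intra, percentile, names = FALSE, type = 7)
}

#' Best-hit (BLAST1-style) verdict for one query
#'
#' Classifies a query by the species composition of its top-scoring hit
#' set, ties kept: \emph{correct} when the best hits are all from the
#' expected (query's) species, \emph{ambiguous} when they span several
#' species including the expected one, \emph{incorrect} when the expected
#' species is absent from the best hits, and \emph{no-match} when the hit
#' set is empty.
#'
#' The default scorer ranks references by pairwise similarity on the
#' aligned sequences: the fraction of matching comparable sites (pairwise
#' deletion), so no external search engine is needed. Alternatively a
#' tabular hit list from a real BLAST run can be supplied via \code{hits}
#' (tab-separated outfmt-6 dialect: columns query id, subject id,
#' bit score — higher is better).
#'
#' @param x a \code{BarcodeAlignment}.
#' @param query a sequence id or index.
#' @param hits optional \code{data.frame} with columns \code{query},
#'   \code{subject}, \code{score}; overrides the internal scorer.
#' @param simMatrix internal-use precomputed similarity matrix.
#' @return as \code{\link{bestMatch}} with \code{bestDistance} holding the
#'   best similarity score.
#' @export
blast1Classify <- function(x, query, hits = NULL, simMatrix = NULL) {
    ids <- names(alnSeqs(x))
    sp <- speciesLabels(x)
    i <- if (is.character(query)) match(query, ids) else as.integer(query)
    if (is.na(i)) stop("unknown query id: ", query)
    if (!is.null(hits)) {
        hh <- hits[hits$query == ids[i] & hits$subject != ids[i], ,
            drop = FALSE]
        if (!nrow(hh))
            return(list(id = ids[i], species = sp[i],
                verdict = "no-match", bestIds = character(0),
                bestSpecies = character(0), bestDistance = NA_real_,
                threshold = NA_real_))
        top <- hh[hh$score == max(hh$score), , drop = FALSE]
        topSp <- sp[match(top$subject, ids)]
        return(list(id = ids[i], species = sp[i],
            verdict = .verdictFromSet(topSp, sp[i]),
            bestIds = top$subject, bestSpecies = unique(topSp),
            bestDistance = max(hh$score), threshold = NA_real_))
    }
    if (is.null(simMatrix)) simMatrix <- .similarityMatrix(x)
    srow <- simMatrix[i, -i]
    refIds <- ids[-i]
    refSp <- sp[-i]
    ok <- !is.na(srow)
    if (!any(ok))
        return(list(id = ids[i], species = sp[i], verdict = "no-match",
            bestIds = character(0), bestSpecies = character(0),
            bestDistance = NA_real_, threshold = NA_real_))
    smax <- max(srow[ok])
    best <- ok & srow == smax
    list(id = ids[i], species = sp[i],
        verdict = .verdictFromSet(refSp[best], sp[i]),
        bestIds = refIds[best], bestSpecies = unique(refSp[best]),
        bestDistance = smax, threshold = NA_real_)
}

# Fraction of matching comparable sites per pair (NA when no comparable
# sites). This is 1 - p-distance under pairwise deletion.
.similarityMatrix <- function(x) {
    enc <- .encodeAlignment(alnSeqs(x))
    n <- nrow(enc)
    sim <- matrix(NA_real_, n, n,
        dimnames = list(rownames(enc), rownames(enc)))
    for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
            ok <- !is.na(enc[i, ]) & !is.na(enc[j, ])
            L <- sum(ok)
            if (L)
                sim[i, j] <- sim[j, i] <-
                    sum(enc[i, ok] == enc[j, ok]) / L
        }
    }
    diag(sim) <- 1
    sim
}

#' Leave-one-out identification report for a group
#'
#' Runs one identification method (Best Match, Best Close Match or the
#' best-hit BLAST1-style criterion) for every eligible query in the group
#' and summarises the verdicts as percentages. Eligible queries are the
#' sequences whose species has at least two sequences in the group (a
#' species represented once can never be matched to a conspecific and is
#' excluded from the denominator).
#'
#' @param x a \code{BarcodeAlignment} (the group view to score).
#' @param method \code{"BM"}, \code{"BCM"} or \code{"BLAST1"}.
#' @param group,level descriptive labels stored in the report.
#' @param dm optional precomputed \code{K2PMatrix} for \code{x}.
#' @param threshold BCM distance threshold; when \code{NULL} it is derived
#'   as \code{bcmThreshold(dm, bcmPercentile)}.
#' @param bcmPercentile percentile used to derive the BCM threshold.
#' @param hits optional external hit table for BLAST1 (see
#'   \code{\link{blast1Classify}}).
#' @return an \code{\linkS4class{IdentificationReport}}.
#' @export
setMethod("identificationReport", "BarcodeAlignment",
    function(x, method = c("BM", "BCM", "BLAST1"), group = "all",
        level = "family", dm = NULL, threshold = NULL,
        bcmPercentile = 0.95, hits = NULL) {
    method <- match.arg(method)
    sp <- speciesLabels(x)
    cnt <- table(sp)
    eligible <- which(sp %in% names(cnt)[cnt >= 2L])
    if (!length(eligible))
        stop("no eligible queries: every species has a single sequence")
    if (method %in% c("BM", "BCM") && is.null(dm)) dm <- k2pMatrix(x)
    simM <- NULL
    if (method == "BLAST1" && is.null(hits))
        simM <- .similarityMatrix(x)
    if (method == "BCM" && is.null(threshold))
        threshold <- bcmThreshold(dm, bcmPercentile)
    vds <- lapply(eligible, function(i) {
        switch(method,
            BM = bestMatch(dm, i),
            BCM = bestCloseMatch(dm, i, threshold),
            BLAST1 = blast1Classify(x, i, hits = hits, simMatrix = simM))
    })
    verdicts <- data.frame(
        id = vapply(vds, `[[`, character(1), "id"),
        species = vapply(vds, `[[`, character(1), "species"),
        verdict = vapply(vds, `[[`, character(1), "verdict"),
        bestDistance = vapply(vds, `[[`, numeric(1), "bestDistance"),
        bestSpecies = vapply(vds, function(v)
            paste(v$bestSpecies, collapse = ","), character(1)),
        nBest = vapply(vds, function(v) length(v$bestIds), integer(1)),
        stringsAsFactors = FALSE)
    nq <- nrow(verdicts)
    pct <- function(v) .round2(100 * sum(verdicts$verdict == v) / nq)
    summ <- c(correct = pct("correct"), incorrect = pct("incorrect"),
        ambiguous = pct("ambiguous"), noMatch = pct("no-match"))
    new("IdentificationReport", group = group, level = level,
        method = method,
        threshold = if (is.null(threshold)) NA_real_ else threshold,
        verdicts = verdicts, summary = summ)
})

#' @rdname identificationReport
#' @param report an \code{IdentificationReport}
#' @export
verdicts <- function(report) report@verdicts

#' @rdname identificationReport
#' @param row.names,optional,... see \code{\link[base]{as.data.frame}}.
#' @export
setMethod("as.data.frame", "IdentificationReport",
    function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(level = x@level, group = x@group, method = x@method,
        nQueries = nrow(x@verdicts),
        correct = x@summary[["correct"]],
        incorrect = x@summary[["incorrect"]],
        ambiguous = x@summary[["ambiguous"]],
        noMatch = x@summary[["noMatch"]],
        threshold = x@threshold, stringsAsFactors = FALSE)
})

setMethod("show", "IdentificationReport", function(object) {
    s <- object@summary
    cat(sprintf("IdentificationReport [%s / %s] %s: %d queries\n",
        object@level, object@group, object@method,
        nrow(object@verdicts)))
    cat(sprintf(
        "  correct %.2f%% | incorrect %.2f%% | ambiguous %.2f%% | no match %.2f%%\n",
        s[["correct"]], s[["incorrect"]], s[["ambiguous"]],
        s[["noMatch"]]))
    if (!is.na(object@threshold))
        cat(sprintf("  BCM threshold: %.6f\n", object@threshold))
})
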