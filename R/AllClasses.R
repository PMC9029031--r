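#' BarcodeAlignment: an alignment plus per-sequence taxonomy
#'
#' The central data container of the package: a multiple sequence alignment
#' (equal-width \link[Biostrings]{DNAStringSet}) together with a per-sequence
#' taxonomy table assigning each sequence to a species, genus, subfamily and,
#' optionally, a named species complex. Every downstream stage (site
#' statistics, K2P distances, divergence indices, barcode-gap histograms,
#' identification scoring) consumes this object.
#'
#' @slot seqs A \code{DNAStringSet} of equal-width aligned sequences; names
#'   are the sequence identifiers (accession-like, unique, nonempty).
#' @slot taxonomy A \code{data.frame} with columns \code{id}, \code{species},
#'   \code{genus}, \code{subfamily}, \code{complex} (\code{NA} when the
#'   species is not in a named complex), one row per sequence.
#' @slot exclusionLog A \code{data.frame} with columns \code{id},
#'   \code{reason}, recording sequences removed by \code{\link{filterValid}}.
#'
#' @seealso \code{\link{readBarcodeData}}, \code{\link{filterValid}},
#'   \code{\link{subsetByLevel}}
#' @exportClass BarcodeAlignment
setClass("BarcodeAlignment",
    representation(
        seqs = "DNAStringSet",
        taxonomy = "data.frame",
        exclusionLog = "data.frame"
    )
)

.TAX_COLS <- c("id", "species", "genus", "subfamily", "complex")

setValidity("BarcodeAlignment", function(object) {
    s <- object@seqs
    tax <- object@taxonomy
    msgs <- character(0)
    if (length(s)) {
        if (length(unique(Biostrings::width(s))) != 1L)
            msgs <- c(msgs, "all sequences must have equal aligned length")
        ids <- names(s)
        if (is.null(ids) || any(!nzchar(ids)))
            msgs <- c(msgs, "every sequence must have a nonempty id")
        else if (anyDuplicated(ids))
            msgs <- c(msgs, sprintf("duplicate sequence ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    if (!all(.TAX_COLS %in% colnames(tax)))
        msgs <- c(msgs, sprintf("taxonomy must have columns %s",
            paste(.TAX_COLS, collapse = ", ")))
    else {
        missing <- setdiff(names(s), tax$id)
        if (length(missing))
            msgs <- c(msgs, sprintf("sequences missing from taxonomy: %s",
                paste(missing, collapse = ", ")))
        sp2gen <- unique(tax[, c("species", "genus", "subfamily")])
        if (anyDuplicated(sp2gen$species))
            msgs <- c(msgs,
                "a species maps to more than one genus or subfamily")
    }
    if (length(msgs)) msgs else TRUE
})

#' K2PMatrix: pairwise Kimura two-parameter distances
#'
#' Symmetric pairwise K2P distances under pairwise deletion, with the full
#' per-pair bookkeeping the downstream analyses need: the number of
#' comparable sites L (sites where neither sequence has a gap or ambiguity),
#' the transition and transversion proportions P and Q, and a defined flag.
#' A pair is undefined when L = 0 or the logarithm argument of the K2P
#' correction is non-positive (saturation); undefined distances are stored
#' as \code{NA} and excluded from every summary, never clamped.
#'
#' @slot d numeric matrix of distances (substitutions/site); \code{NA} where
#'   undefined; zero diagonal.
#' @slot L integer matrix of per-pair comparable-site counts.
#' @slot P,Q numeric matrices of per-pair transition/transversion
#'   proportions (\code{NA} when L = 0).
#' @slot defined logical matrix; \code{TRUE} on the diagonal.
#' @slot species character vector of species labels aligned with the matrix
#'   rows (carried from the source \code{BarcodeAlignment}).
#'
#' @seealso \code{\link{k2pMatrix}}, \code{\link{k2pPair}}
#' @exportClass K2PMatrix
setClass("K2PMatrix",
    representation(
        d = "matrix", L = "matrix", P = "matrix", Q = "matrix",
        defined = "matrix", species = "character"
    )
)

setValidity("K2PMatrix", function(object) {
    n <- nrow(object@d)
    msgs <- character(0)
    dims <- vapply(list(object@d, object@L, object@P, object@Q,
        object@defined), function(m) all(dim(m) == c(n, n)), logical(1))
    if (!all(dims)) msgs <- c(msgs, "all component matrices must be n x n")
    if (length(object@species) != n)
        msgs <- c(msgs, "species labels must match matrix dimension")
    if (n) {
        if (!isTRUE(all.equal(object@d, t(object@d))))
            msgs <- c(msgs, "distance matrix must be symmetric")
        if (any(diag(object@d) != 0) || !all(diag(object@defined)))
            msgs <- c(msgs, "diagonal must be zero and defined")
        dd <- object@d[object@defined]
        if (any(dd < 0, na.rm = TRUE))
            msgs <- c(msgs, "defined distances must be non-negative")
    }
    if (length(msgs)) msgs else TRUE
})

#' SiteStats: alignment variability statistics for one group
#'
#' Per-group alignment length and site-category tallies: conserved (CS),
#' variable (VS), parsimony-informative (PIS) and singleton (SS) sites,
#' plus an "indeterminate" count for columns with fewer than two usable
#' (unambiguous, non-gap) residues, and the overall mean distance (OMD,
#' mean of all defined pairwise K2P distances). Invariant:
#' AL = CS + VS + indeterminate and PIS + SS <= VS.
#'
#' @slot group,level character labels for the group summarised.
#' @slot nSeq number of sequences.
#' @slot AL aligned length (columns).
#' @slot counts named integer vector (CS, VS, PIS, SS, indeterminate).
#' @slot OMD overall mean K2P distance; \code{NA} if no defined pairs.
#' @slot nPairsDefined,nPairsDropped defined/undefined pair counts behind OMD.
#' @exportClass SiteStats
setClass("SiteStats",
    representation(
        group = "character", level = "character", nSeq = "integer",
        AL = "integer", counts = "integer", OMD = "numeric",
        nPairsDefined = "integer", nPairsDropped = "integer"
    )
)

setValidity("SiteStats", function(object) {
    cnt <- object@counts
    need <- c("CS", "VS", "PIS", "SS", "indeterminate")
    if (!all(need %in% names(cnt)))
        return("counts must be named CS, VS, PIS, SS, indeterminate")
    if (any(cnt < 0)) return("counts must be non-negative")
    if (object@AL != cnt["CS"] + cnt["VS"] + cnt["indeterminate"])
        return("AL must equal CS + VS + indeterminate")
    if (cnt["PIS"] + cnt["SS"] > cnt["VS"])
        return("PIS + SS must not exceed VS")
    TRUE
})

#' DivergenceSummary: the five divergence indices for one group
#'
#' Group-level genetic divergence: all interspecific distance (mean over
#' heterospecific pairs), minimum interspecific distance (per-species
#' nearest non-conspecific, averaged over species), all intraspecific
#' distance (pooled conspecific pairs), theta (per-species mean conspecific
#' distance, averaged over species with >= 2 sequences) and coalescent
#' depth (per-species maximum conspecific distance, likewise averaged).
#' Each index carries the sample SD and SE of its constituents and the
#' count of contributing pairs or species.
#'
#' @slot group,level character labels.
#' @slot indices data.frame with columns \code{index}, \code{mean},
#'   \code{sd}, \code{se}, \code{n}.
#' @slot nPairsDropped undefined pairs excluded from all indices.
#' @exportClass DivergenceSummary
setClass("DivergenceSummary",
    representation(
        group = "character", level = "character",
        indices = "data.frame", nPairsDropped = "integer"
    )
)

#' DistanceHistogram: intra/interspecific distance-frequency distribution
#'
#' Distances are expressed in percent (d x 100) and binned into half-open
#' intervals [lo, hi) of fixed width (default one percentage point); the
#' terminal bin is closed so the largest distance is counted. Raw per-class
#' distance vectors are retained so range shares and barcode-gap summaries
#' are exact, not re-binned.
#'
#' @slot binWidth bin width in percentage points.
#' @slot bins data.frame with columns \code{class} ("intraspecific" or
#'   "interspecific"), \code{lo}, \code{hi}, \code{count}, \code{relAbund}.
#' @slot intra,inter raw defined pairwise distances in percent.
#' @exportClass DistanceHistogram
setClass("DistanceHistogram",
    representation(
        binWidth = "numeric", bins = "data.frame",
        intra = "numeric", inter = "numeric"
    )
)

setValidity("DistanceHistogram", function(object) {
    if (object@binWidth <= 0) return("bin width must be positive")
    b <- object@bins
    for (cls in c("intraspecific", "interspecific")) {
        raw <- if (cls == "intraspecific") object@intra else object@inter
        sub <- b[b$class == cls, , drop = FALSE]
        if (nrow(sub)) {
            if (sum(sub$count) != length(raw))
                return("bin counts must sum to the number of defined pairs")
            if (abs(sum(sub$relAbund) - 100) > 1e-9)
                return("relative abundances must sum to 100")
        }
    }
    TRUE
})

#' IdentificationReport: leave-one-out identification outcomes for a group
#'
#' Per-query verdicts (correct / incorrect / ambiguous / no match) under one
#' method (BM, BCM or BLAST1) plus the group-level percentage summary.
#' Queries are the sequences whose species has at least two sequences in
#' the group.
#'
#' @slot group,level,method character labels.
#' @slot threshold BCM distance threshold used (\code{NA} for BM/BLAST1).
#' @slot verdicts data.frame with one row per query: \code{id},
#'   \code{species}, \code{verdict}, \code{bestDistance} (or similarity
#'   score for BLAST1), \code{bestSpecies} (comma-collapsed), \code{nBest}.
#' @slot summary named numeric percentages (correct, incorrect, ambiguous,
#'   noMatch) rounded half-up to 2 decimals.
#' @exportClass IdentificationReport
setClass("IdentificationReport",
    representation(
        group = "character", level = "character", method = "character",
        threshold = "numeric", verdicts = "data.frame", summary = "numeric"
    )
)

setValidity("IdentificationReport", function(object) {
    if (!object@method %in% c("BM", "BCM", "BLAST1"))
        return("method must be one of BM, BCM, BLAST1")
    s <- object@summary
    if (nrow(object@verdicts) && abs(sum(s) - 100) > 0.05)
        return("summary percentages must sum to 100 (within rounding)")
    TRUE
})
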