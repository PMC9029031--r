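# Base encoding shared by the distance and simulation code: A=1 C=2 G=3 T=4,
# anything else (gap, N, IUPAC ambiguity) NA -> excluded by pairwise deletion.
.BASES <- c(A = 1L, C = 2L, G = 3L, T = 4L)
.PURINE <- c(TRUE, FALSE, TRUE, FALSE)

.encodeAlignment <- function(seqs) {
    m <- as.matrix(seqs)
    enc <- matrix(.BASES[m], nrow = nrow(m),
        dimnames = list(rownames(m), NULL))
    enc
}

# Core pair computation on encoded integer vectors.
.k2pCore <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    L <- sum(ok)
    if (L == 0L)
        return(list(d = NA_real_, L = 0L, P = NA_real_, Q = NA_real_,
            defined = FALSE))
    a <- a[ok]; b <- b[ok]
    mism <- a != b
    samClass <- .PURINE[a] == .PURINE[b]
    ts <- sum(mism & samClass)
    tv <- sum(mism & !samClass)
    P <- ts / L
    Q <- tv / L
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0)
        return(list(d = NA_real_, L = L, P = P, Q = Q, defined = FALSE))
    # + 0 normalises IEEE negative zero when the pair is identical
    list(d = -0.5 * log(w1 * sqrt(w2)) + 0, L = L, P = P, Q = Q,
        defined = TRUE)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P distance under pairwise deletion: sites where either
#' sequence carries a gap or an ambiguity code are excluded, leaving L
#' comparable sites; P and Q are the proportions of transitions (A-G, C-T)
#' and transversions among them, and
#' \deqn{d = -\tfrac12 \ln\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].}
#' When L = 0 or the logarithm argument is non-positive (saturated pair)
#' the distance is undefined: \code{d} is \code{NA} and \code{defined} is
#' \code{FALSE}. Undefined distances are never clamped to a finite value.
#'
#' @param a,b equal-length aligned sequences (character strings,
#'   \code{DNAString}s, or character vectors of single residues).
#' @return a list with elements \code{d}, \code{L}, \code{P}, \code{Q},
#'   \code{defined}.
#' @examples
#' k2pPair("ACGTACGT", "ACGTACGT")$d     # 0
#' k2pPair("AAAA", "GGGG")$defined       # FALSE: P = 1 saturates the model
#' @export
k2pPair <- function(a, b) {
    a <- .asResidues(a)
    b <- .asResidues(b)
    if (length(a) != length(b))
        stop("sequences must have equal aligned length")
    .k2pCore(unname(.BASES[a]), unname(.BASES[b]))
}

.asResidues <- function(x) {
    if (is(x, "XString")) x <- as.character(x)
    if (is.character(x) && length(x) == 1L)
        x <- strsplit(x, "", fixed = TRUE)[[1L]]
    gsub("U", "T", toupper(x), fixed = TRUE)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' Fills every unordered pair of sequences via the K2P/pairwise-deletion
#' computation of \code{\link{k2pPair}} and returns a
#' \code{\linkS4class{K2PMatrix}} carrying, per pair, the distance, the
#' comparable-site count L, the transition/transversion proportions P and
#' Q, and a defined flag. Undefined pairs are excluded from all downstream
#' means; their count is reported by \code{show} and by the pipeline log.
#'
#' @param x a \code{BarcodeAlignment} with at least 2 sequences.
#' @return a \code{\linkS4class{K2PMatrix}}.
#' @seealso \code{\link{exportDistances}}
#' @export
setMethod("k2pMatrix", "BarcodeAlignment", function(x) {
    n <- length(x)
    if (n < 2L) stop("need at least 2 sequences")
    enc <- .encodeAlignment(alnSeqs(x))
    ids <- names(alnSeqs(x))
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    L <- matrix(0L, n, n, dimnames = list(ids, ids))
    P <- matrix(0, n, n, dimnames = list(ids, ids))
    Q <- matrix(0, n, n, dimnames = list(ids, ids))
    def <- matrix(TRUE, n, n, dimnames = list(ids, ids))
    rows <- lapply(seq_len(n), function(i) enc[i, ])
    for (i in seq_len(n - 1L)) {
        ri <- rows[[i]]
        for (j in seq.int(i + 1L, n)) {
            p <- .k2pCore(ri, rows[[j]])
            d[i, j] <- d[j, i] <- if (p$defined) p$d else NA_real_
            L[i, j] <- L[j, i] <- p$L
            P[i, j] <- P[j, i] <- if (is.na(p$P)) NA_real_ else p$P
            Q[i, j] <- Q[j, i] <- if (is.na(p$Q)) NA_real_ else p$Q
            def[i, j] <- def[j, i] <- p$defined
        }
    }
    diag(L) <- Biostrings::width(alnSeqs(x))[1L]
    new("K2PMatrix", d = d, L = L, P = P, Q = Q, defined = def,
        species = speciesLabels(x))
})

#' @rdname K2PMatrix-class
#' @export
setMethod("distances", "K2PMatrix", function(x) x@d)

#' @rdname K2PMatrix-class
#' @export
setMethod("comparableSites", "K2PMatrix", function(x) x@L)

#' @rdname K2PMatrix-class
#' @export
setMethod("definedPairs", "K2PMatrix", function(x) x@defined)

#' @rdname K2PMatrix-class
#' @export
setMethod("speciesLabels", "K2PMatrix", function(x) x@species)

#' @rdname K2PMatrix-class
#' @export
setMethod("length", "K2PMatrix", function(x) nrow(x@d))

setMethod("show", "K2PMatrix", function(object) {
    n <- nrow(object@d)
    up <- upper.tri(object@d)
    nd <- sum(!object@defined[up])
    cat(sprintf("K2PMatrix: %d sequences, %d pairs (%d undefined)\n",
        n, sum(up), nd))
    dd <- object@d[up][object@defined[up]]
    if (length(dd))
        cat(sprintf("  defined distances: mean %.4f, range [%.4f, %.4f]\n",
            mean(dd), min(dd), max(dd)))
})

#' Export pairwise distances
#'
#' Writes a \code{K2PMatrix} either as a PHYLIP square distance matrix
#' (undefined pairs written as -1, flagged in a comment-free format
#' consumers must check) or as a long-form TSV with one row per unordered
#' pair and full bookkeeping columns.
#'
#' @param x a \code{K2PMatrix}.
#' @param path output file path.
#' @param format \code{"tsv"} (default) or \code{"phylip"}.
#' @return invisibly, the path.
#' @export
exportDistances <- function(x, path, format = c("tsv", "phylip")) {
    format <- match.arg(format)
    if (format == "phylip") {
        d <- x@d
        d[!x@defined] <- -1
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(sprintf("%5d", nrow(d)), con)
        for (i in seq_len(nrow(d)))
            writeLines(paste(c(sprintf("%-10s", rownames(d)[i]),
                sprintf("%.6f", d[i, ])), collapse = "  "), con)
    } else {
        up <- which(upper.tri(x@d), arr.ind = TRUE)
        out <- data.frame(
            idA = rownames(x@d)[up[, 1L]],
            idB = colnames(x@d)[up[, 2L]],
            d = x@d[up], L = x@L[up], P = x@P[up], Q = x@Q[up],
            defined = x@defined[up], stringsAsFactors = FALSE)
        utils::write.table(out, path, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(path)
}

# Pooled intra/interspecific defined distances from a K2PMatrix; used by
# the divergence, gap-analysis and identification stages.
.pairClasses <- function(dm) {
    sp <- dm@species
    n <- length(sp)
    up <- which(upper.tri(dm@d), arr.ind = TRUE)
    same <- sp[up[, 1L]] == sp[up[, 2L]]
    def <- dm@defined[up]
    list(
        intra = dm@d[up][same & def],
        inter = dm@d[up][!same & def],
        nDropped = sum(!def),
        nIntraPairs = sum(same), nInterPairs = sum(!same))
}
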