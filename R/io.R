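#' Construct a BarcodeAlignment
#'
#' Builds the central alignment-plus-taxonomy container from in-memory
#' objects. Sequences are normalised on construction: upper-cased and with
#' U replaced by T (GenBank RNA-style dialects). The taxonomy is matched to
#' the sequences by id and reordered to sequence order.
#'
#' @param seqs a named \code{DNAStringSet} or named character vector of
#'   equal-length aligned sequences over A, C, G, T, gap (\code{-}) and
#'   IUPAC ambiguity codes.
#' @param taxonomy a \code{data.frame} with columns \code{id},
#'   \code{species}, \code{genus}, \code{subfamily} and optionally
#'   \code{complex}; one row per sequence id.
#' @return a validated \code{\linkS4class{BarcodeAlignment}}.
#' @examples
#' aln <- BarcodeAlignment(
#'   c(s1 = "ACGT", s2 = "ACGA", s3 = "ACTA"),
#'   data.frame(id = c("s1", "s2", "s3"),
#'              species = c("A x", "A x", "A y"),
#'              genus = "A", subfamily = "S"))
#' alignedLength(aln)
#' @export
BarcodeAlignment <- function(seqs, taxonomy) {
    if (is.character(seqs)) {
        seqs <- .normalizeSeqChars(seqs)
        seqs <- Biostrings::DNAStringSet(seqs)
    } else {
        seqs <- Biostrings::DNAStringSet(seqs)
    }
    taxonomy <- .normalizeTaxonomy(taxonomy)
    ids <- names(seqs)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("sequences must be named by id")
    if (anyDuplicated(ids))
        stop("duplicate sequence ids: ",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    missing <- setdiff(ids, taxonomy$id)
    if (length(missing))
        stop("no taxonomy row for id(s): ", paste(missing, collapse = ", "))
    taxonomy <- taxonomy[match(ids, taxonomy$id), , drop = FALSE]
    rownames(taxonomy) <- NULL
    new("BarcodeAlignment", seqs = seqs, taxonomy = taxonomy,
        exclusionLog = .emptyLog())
}

.normalizeSeqChars <- function(x) {
    x <- toupper(x)
    gsub("U", "T", x, fixed = TRUE)
}

.normalizeTaxonomy <- function(tax) {
    tax <- as.data.frame(tax, stringsAsFactors = FALSE)
    need <- c("id", "species", "genus", "subfamily")
    if (!all(need %in% colnames(tax)))
        stop("taxonomy must have columns ", paste(need, collapse = ", "))
    if (!"complex" %in% colnames(tax)) tax$complex <- NA_character_
    tax$complex[!is.na(tax$complex) & !nzchar(tax$complex)] <- NA_character_
    for (cc in .TAX_COLS) tax[[cc]] <- as.character(tax[[cc]])
    if (anyDuplicated(tax$id))
        stop("duplicate ids in taxonomy: ",
            paste(unique(tax$id[duplicated(tax$id)]), collapse = ", "))
    tax[, .TAX_COLS, drop = FALSE]
}

.emptyLog <- function() {
    data.frame(id = character(0), reason = character(0),
        stringsAsFactors = FALSE)
}

#' Read a FASTA alignment and its taxonomy table
#'
#' Reads a multi-record FASTA (wrapped or unwrapped) and a tab-separated
#' taxonomy table (header required; columns \code{id}, \code{species},
#' \code{genus}, \code{subfamily} and optionally \code{complex}) and pairs
#' them into a \code{BarcodeAlignment}. Record order follows the FASTA
#' file. Sequence case and U are normalised on read. A FASTA id without a
#' taxonomy row, or a duplicated id, is a hard error naming the id.
#'
#' @param fastaPath path to the FASTA file.
#' @param taxonomyPath path to the taxonomy TSV.
#' @return a \code{\linkS4class{BarcodeAlignment}}.
#' @seealso \code{\link{writeBarcodeData}}, \code{\link{filterValid}}
#' @export
readBarcodeData <- function(fastaPath, taxonomyPath) {
    raw <- Biostrings::readBStringSet(fastaPath)
    names(raw) <- sub("\\s.*$", "", names(raw))
    seqs <- .normalizeSeqChars(as.character(raw))
    names(seqs) <- names(raw)
    tax <- utils::read.delim(taxonomyPath, stringsAsFactors = FALSE,
        colClasses = "character")
    BarcodeAlignment(seqs, tax)
}

#' Write a BarcodeAlignment back to FASTA + taxonomy TSV
#'
#' Inverse of \code{\link{readBarcodeData}}; a write/read round trip
#' preserves ids, sequences and taxonomic labels exactly.
#'
#' @param x a \code{BarcodeAlignment}.
#' @param fastaPath,taxonomyPath output paths.
#' @return invisibly, \code{x}.
#' @export
writeBarcodeData <- function(x, fastaPath, taxonomyPath) {
    Biostrings::writeXStringSet(alnSeqs(x), fastaPath)
    utils::write.table(taxonomy(x), taxonomyPath, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(x)
}

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alnSeqs", "BarcodeAlignment", function(x) x@seqs)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("taxonomy", "BarcodeAlignment", function(x) x@taxonomy)

#' @rdname BarcodeAlignment-class
#' @export
setMethod("alignedLength", "BarcodeAlignment", function(x) {
    if (!length(x@seqs)) return(0L)
    Biostrings::width(x@seqs)[1L]
})

#' @rdname BarcodeAlignment-class
#' @export
setMethod("speciesLabels", "BarcodeAlignment",
    function(x) x@taxonomy$species)

#' @rdname BarcodeAlignment-class
#' @param object a \code{BarcodeAlignment}
#' @export
setMethod("length", "BarcodeAlignment", function(x) length(x@seqs))

setMethod("show", "BarcodeAlignment", function(object) {
    tax <- object@taxonomy
    cat(sprintf(
        "BarcodeAlignment: %d sequences x %d bp; %d species, %d genera, %d subfamilies\n",
        length(object@seqs), alignedLength(object),
        length(unique(tax$species)), length(unique(tax$genus)),
        length(unique(tax$subfamily))))
    ncx <- sum(!is.na(unique(tax[, c("species", "complex")])$complex))
    if (ncx) cat(sprintf("  species in named complexes: %d\n", ncx))
    if (nrow(object@exclusionLog))
        cat(sprintf("  excluded during validation: %d\n",
            nrow(object@exclusionLog)))
})

#' Validation filters: discard ambiguous sequences and singleton species
#'
#' Applies the two data-validation rules of the analysis: (1) sequences
#' containing any character outside A, C, G, T and the gap symbol
#' (case-insensitive) are discarded as ambiguous; (2) after that, every
#' species left with exactly one sequence is removed (a single sequence
#' supports no intraspecific comparison and cannot be queried leave-one-out
#' against a conspecific). Removals are recorded in the exclusion log with
#' their reason. The operation is idempotent.
#'
#' @param x a \code{BarcodeAlignment}.
#' @return a filtered \code{BarcodeAlignment}; \code{exclusionLog(x)}
#'   retrieves the removal log (columns \code{id}, \code{reason}).
#' @export
setMethod("filterValid", "BarcodeAlignment", function(x) {
    seqs <- as.character(x@seqs)
    amb <- grepl("[^ACGT-]", seqs)
    log <- data.frame(id = names(seqs)[amb],
        reason = rep("ambiguous bases", sum(amb)),
        stringsAsFactors = FALSE)
    keep <- x@seqs[!amb]
    tax <- x@taxonomy[!amb, , drop = FALSE]
    cnt <- table(tax$species)
    single <- tax$species %in% names(cnt)[cnt == 1L]
    if (any(single))
        log <- rbind(log, data.frame(id = names(keep)[single],
            reason = "singleton species", stringsAsFactors = FALSE))
    keep <- keep[!single]
    tax <- tax[!single, , drop = FALSE]
    if (!length(keep)) stop("empty dataset after validation")
    rownames(tax) <- NULL
    new("BarcodeAlignment", seqs = keep, taxonomy = tax,
        exclusionLog = rbind(x@exclusionLog, log))
})

#' @rdname filterValid
#' @export
setMethod("exclusionLog", "BarcodeAlignment", function(x) x@exclusionLog)

.LEVELS <- c("complex", "genus", "subfamily", "family")

.levelColumn <- function(level) {
    switch(level, complex = "complex", genus = "genus",
        subfamily = "subfamily", family = NULL)
}

#' Subset an alignment by taxonomic level and group
#'
#' Returns the group view of the dataset at one of the four nested levels:
#' species complex, genus, subfamily or family. The family level returns
#' the dataset unchanged (one group, all sequences). For the other levels,
#' columns that are gap in every remaining sequence are removed, so the
#' aligned length is group-specific; under pairwise deletion this stripping
#' never changes any pairwise K2P distance (gap columns are already
#' excluded per pair).
#'
#' The group views are produced from a single master alignment. Strict
#' replication of a per-group re-alignment workflow can be had by writing
#' the view out with \code{\link{writeBarcodeData}}, re-aligning externally
#' and reading the result back; the core stays deterministic and
#' dependency-free.
#'
#' @param x a \code{BarcodeAlignment}.
#' @param level one of \code{"complex"}, \code{"genus"},
#'   \code{"subfamily"}, \code{"family"}.
#' @param group group name at that level (ignored at family level). Unknown
#'   names raise an error listing the available groups.
#' @return a \code{BarcodeAlignment} restricted to the group.
#' @export
setMethod("subsetByLevel", "BarcodeAlignment",
    function(x, level, group = NULL) {
    level <- match.arg(level, .LEVELS)
    if (level == "family") return(x)
    col <- .levelColumn(level)
    avail <- groupNames(x, level)
    if (is.null(group) || !group %in% avail)
        stop(sprintf("unknown %s group '%s'; available: %s", level,
            if (is.null(group)) "" else group,
            paste(avail, collapse = ", ")))
    sel <- !is.na(x@taxonomy[[col]]) & x@taxonomy[[col]] == group
    if (!any(sel)) stop(sprintf("no sequences in %s '%s'", level, group))
    seqs <- x@seqs[sel]
    tax <- x@taxonomy[sel, , drop = FALSE]
    rownames(tax) <- NULL
    m <- as.matrix(seqs)
    allGap <- colSums(m != "-") == 0L
    if (any(allGap)) {
        kept <- apply(m[, !allGap, drop = FALSE], 1L, paste0,
            collapse = "")
        seqs <- Biostrings::DNAStringSet(kept)
        names(seqs) <- tax$id
    }
    new("BarcodeAlignment", seqs = seqs, taxonomy = tax,
        exclusionLog = .emptyLog())
})

#' @rdname subsetByLevel
#' @export
setMethod("groupNames", "BarcodeAlignment", function(x, level) {
    level <- match.arg(level, .LEVELS)
    if (level == "family") return("all")
    col <- .levelColumn(level)
    v <- unique(x@taxonomy[[col]])
    sort(v[!is.na(v)])
})
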