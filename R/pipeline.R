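#' Run the full multi-level barcode evaluation
#'
#' Orchestrates every stage of the analysis for each requested taxonomic
#' level: validation (ambiguous-base and singleton-species filters), per
#' group alignment view, site statistics, divergence indices, the
#' intra/interspecific distance histogram with barcode-gap summary, and
#' the leave-one-out identification reports for each requested method.
#' Results are returned as one nested list; when \code{outDir} is given
#' the standard report files are also written: \code{exclusion_log.tsv},
#' \code{site_stats_<level>.tsv}, \code{divergence_<level>.tsv},
#' \code{histogram_<level>_<group>.csv},
#' \code{identification_<level>.tsv}, \code{verdicts_<level>.tsv} and a
#' machine-readable \code{bundle.json}. The computation is deterministic:
#' rerunning the same inputs reproduces the outputs byte-for-byte.
#' Internal values are kept at full precision; rounding happens only at
#' the report-writing boundary.
#'
#' @param x a \code{BarcodeAlignment}, or a FASTA path (then
#'   \code{taxonomyPath} is required).
#' @param taxonomyPath taxonomy TSV path when \code{x} is a FASTA path.
#' @param levels taxonomic levels to analyse (subset of
#'   \code{"complex"}, \code{"genus"}, \code{"subfamily"},
#'   \code{"family"}). Levels with no groups (e.g. no named complex) are
#'   skipped with a log line.
#' @param methods identification methods to run (subset of \code{"BM"},
#'   \code{"BCM"}, \code{"BLAST1"}).
#' @param binWidth histogram bin width in percentage points.
#' @param bcmPercentile percentile for the BCM threshold.
#' @param outDir output directory (created if needed); \code{NULL} to
#'   skip file output.
#' @param validate apply \code{\link{filterValid}} first (default TRUE).
#' @param verbose print one structured log line per stage.
#' @return invisibly, a nested list:
#'   \code{$validation} (exclusion log), and \code{$levels[[level]]
#'   [[group]]} with elements \code{siteStats}, \code{divergence},
#'   \code{histogram}, \code{gap}, \code{identification[[method]]}.
#' @export
runBarcodePipeline <- function(x, taxonomyPath = NULL,
    levels = c("complex", "genus", "subfamily", "family"),
    methods = c("BM", "BCM"), binWidth = 1, bcmPercentile = 0.95,
    outDir = NULL, validate = TRUE, verbose = FALSE) {
    if (is.character(x)) {
        if (is.null(taxonomyPath))
            stop("taxonomyPath is required when x is a FASTA path")
        x <- readBarcodeData(x, taxonomyPath)
    }
    if (!length(levels) || !length(methods))
        stop("select at least one level and one method")
    levels <- match.arg(levels, .LEVELS, several.ok = TRUE)
    methods <- match.arg(methods, c("BM", "BCM", "BLAST1"),
        several.ok = TRUE)
    say <- function(...) if (verbose) message(sprintf(...))

    if (validate) {
        x <- filterValid(x)
        say("validate: kept %d sequences, excluded %d", length(x),
            nrow(exclusionLog(x)))
    }
    out <- list(validation = exclusionLog(x), levels = list())

    for (lvl in levels) {
        groups <- groupNames(x, lvl)
        if (!length(groups)) {
            say("%s: no groups, skipped", lvl)
            next
        }
        lvlRes <- list()
        for (g in groups) {
            v <- subsetByLevel(x, lvl, g)
            if (length(v) < 2L) {
                say("%s/%s: <2 sequences, skipped", lvl, g)
                next
            }
            dm <- k2pMatrix(v)
            nUndef <- sum(!dm@defined[upper.tri(dm@defined)])
            ss <- siteStats(v, group = g, level = lvl, dm = dm)
            dv <- divergenceSummary(dm, group = g, level = lvl)
            h <- distanceHistogram(dm, binWidth = binWidth)
            gap <- barcodeGapSummary(h)
            idr <- list()
            spCnt <- table(speciesLabels(v))
            if (any(spCnt >= 2L)) {
                for (m in methods)
                    idr[[m]] <- identificationReport(v, method = m,
                        group = g, level = lvl, dm = dm,
                        bcmPercentile = bcmPercentile)
            } else say("%s/%s: no eligible queries", lvl, g)
            say("%s/%s: n=%d AL=%d undefined-pairs=%d", lvl, g,
                length(v), alignedLength(v), nUndef)
            lvlRes[[g]] <- list(siteStats = ss, divergence = dv,
                histogram = h, gap = gap, identification = idr)
        }
        if (length(lvlRes)) out$levels[[lvl]] <- lvlRes
    }

    if (!is.null(outDir)) .writeBundle(out, outDir)
    invisible(out)
}

.writeBundle <- function(out, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, name, sep = "\t")
        utils::write.table(df, file.path(outDir, name), sep = sep,
            quote = FALSE, row.names = FALSE)
    w(out$validation, "exclusion_log.tsv")
    json <- list(validation = out$validation, levels = list())
    for (lvl in names(out$levels)) {
        res <- out$levels[[lvl]]
        ssT <- do.call(rbind, lapply(res, function(r)
            as.data.frame(r$siteStats)))
        dvT <- do.call(rbind, lapply(res, function(r) {
            df <- as.data.frame(r$divergence)
            df$meanSd <- sprintf("%.4f ± %.4f", df$mean, df$sd)
            df
        }))
        idT <- do.call(rbind, lapply(res, function(r)
            do.call(rbind, lapply(r$identification, as.data.frame))))
        vdT <- do.call(rbind, lapply(names(res), function(g) {
            do.call(rbind, lapply(names(res[[g]]$identification),
                function(m) {
                    vv <- verdicts(res[[g]]$identification[[m]])
                    if (!nrow(vv)) return(NULL)
                    cbind(level = lvl, group = g, method = m, vv)
                }))
        }))
        w(ssT, sprintf("site_stats_%s.tsv", lvl))
        w(dvT, sprintf("divergence_%s.tsv", lvl))
        if (!is.null(idT)) w(idT, sprintf("identification_%s.tsv", lvl))
        if (!is.null(vdT)) w(vdT, sprintf("verdicts_%s.tsv", lvl))
        for (g in names(res))
            w(histogramBins(res[[g]]$histogram),
                sprintf("histogram_%s_%s.csv", lvl, g), sep = ",")
        json$levels[[lvl]] <- list(siteStats = ssT, divergence = dvT,
            identification = idT,
            gap = lapply(res, function(r) r$gap))
    }
    jsonlite::write_json(json, file.path(outDir, "bundle.json"),
        auto_unbox = TRUE, digits = NA, na = "null")
    invisible(outDir)
}
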