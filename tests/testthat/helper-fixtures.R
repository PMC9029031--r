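# Shared fixture builders and independent oracles. The oracles deliberately
# re-derive everything from first principles (character-level loops, direct
# closed-form evaluation) so they share no code path with the package.

makeAln <- function(seqs, species, genus = NULL, subfamily = NULL,
    complex = NA_character_) {
    n <- length(seqs)
    if (is.null(names(seqs))) names(seqs) <- sprintf("s%02d", seq_len(n))
    if (is.null(genus)) genus <- sub("[ _].*$", "", species)
    if (is.null(subfamily)) subfamily <- rep("SF", n)
    BarcodeAlignment(seqs, data.frame(id = names(seqs),
        species = species, genus = genus, subfamily = subfamily,
        complex = complex, stringsAsFactors = FALSE))
}

# Brute-force K2P oracle: explicit per-site loop over the two character
# vectors, then direct evaluation of the closed form.
oracleK2P <- function(a, b) {
    a <- strsplit(toupper(a), "")[[1]]
    b <- strsplit(toupper(b), "")[[1]]
    stopifnot(length(a) == length(b))
    pur <- c("A", "G")
    pyr <- c("C", "T")
    L <- 0L; ts <- 0L; tv <- 0L
    for (k in seq_along(a)) {
        x <- a[k]; y <- b[k]
        if (!(x %in% c(pur, pyr)) || !(y %in% c(pur, pyr))) next
        L <- L + 1L
        if (x == y) next
        if ((x %in% pur && y %in% pur) || (x %in% pyr && y %in% pyr))
            ts <- ts + 1L
        else tv <- tv + 1L
    }
    if (L == 0L) return(list(d = NA_real_, L = 0L, defined = FALSE))
    P <- ts / L; Q <- tv / L
    arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
    if (arg1 <= 0 || arg2 <= 0)
        return(list(d = NA_real_, L = L, P = P, Q = Q, defined = FALSE))
    list(d = -0.5 * log(arg1 * sqrt(arg2)), L = L, P = P, Q = Q,
        defined = TRUE)
}

# Random aligned sequences with controlled mismatch structure.
randomSeqs <- function(n, len, gapProb = 0, ambProb = 0) {
    alphabet <- c("A", "C", "G", "T")
    vapply(seq_len(n), function(i) {
        ch <- sample(alphabet, len, replace = TRUE)
        if (gapProb > 0) {
            g <- runif(len) < gapProb
            ch[g] <- "-"
        }
        if (ambProb > 0) {
            a <- runif(len) < ambProb
            ch[a] <- sample(c("N", "R", "Y"), sum(a), replace = TRUE)
        }
        paste(ch, collapse = "")
    }, character(1))
}

# Low-divergence related sequences: a shared root with `subs` random
# substitutions per sequence. Keeps every pair inside the defined domain
# of the K2P correction (unrelated uniform sequences sit at saturation).
relatedSeqs <- function(n, len, subs = 3) {
    root <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    out <- vapply(seq_len(n), function(i) {
        ch <- root
        pos <- sample(len, subs)
        for (p in pos)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        paste(ch, collapse = "")
    }, character(1))
    names(out) <- sprintf("s%02d", seq_len(n))
    out
}

# Naive per-column site classification oracle (independent logic).
oracleClassify <- function(col) {
    col <- toupper(col)
    usable <- col[col %in% c("A", "C", "G", "T")]
    if (length(usable) < 2) return("indeterminate")
    tab <- table(usable)
    if (length(tab) == 1) return("conserved")
    if (sum(tab >= 2) >= 2) return("parsimony-informative")
    "singleton"
}
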