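# Enumeration oracle: recompute the five indices from a plain distance
# matrix by explicit loops over pairs and species.
oracleDivergence <- function(d, species) {
    n <- nrow(d)
    intra <- c(); inter <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (is.na(d[i, j])) next
        if (species[i] == species[j]) intra <- c(intra, d[i, j])
        else inter <- c(inter, d[i, j])
    }
    sps <- unique(species)
    minInter <- c(); theta <- c(); coal <- c()
    for (s in sps) {
        own <- which(species == s); oth <- which(species != s)
        v <- as.vector(d[own, oth])
        v <- v[!is.na(v)]
        if (length(v)) minInter <- c(minInter, min(v))
        if (length(own) >= 2) {
            dd <- c()
            for (i in own) for (j in own) if (i < j && !is.na(d[i, j]))
                dd <- c(dd, d[i, j])
            if (length(dd)) {
                theta <- c(theta, mean(dd))
                coal <- c(coal, max(dd))
            }
        }
    }
    list(allInter = if (length(inter)) mean(inter) else 0,
        minInter = if (length(minInter)) mean(minInter) else 0,
        allIntra = if (length(intra)) mean(intra) else 0,
        theta = if (length(theta)) mean(theta) else 0,
        coal = if (length(coal)) mean(coal) else 0)
}

idxGet <- function(ds, name) {
    df <- ds@indices
    df$mean[df$index == name]
}

test_that("all five indices match a brute-force enumeration on random data", {
    set.seed(41)
    for (rep in 1:3) {
        seqs <- randomSeqs(10, 60)
        names(seqs) <- sprintf("d%02d", 1:10)
        species <- rep(sprintf("sp%d", 1:4), c(3, 3, 2, 2))
        aln <- makeAln(seqs, species)
        dm <- k2pMatrix(aln)
        ds <- divergenceSummary(dm)
        o <- oracleDivergence(distances(dm), species)
        expect_equal(idxGet(ds, "allInterspecific"), o$allInter,
            tolerance = 1e-12)
        expect_equal(idxGet(ds, "minInterspecific"), o$minInter,
            tolerance = 1e-12)
        expect_equal(idxGet(ds, "allIntraspecific"), o$allIntra,
            tolerance = 1e-12)
        expect_equal(idxGet(ds, "theta"), o$theta, tolerance = 1e-12)
        expect_equal(idxGet(ds, "coalescentDepth"), o$coal,
            tolerance = 1e-12)
    }
})

test_that("2 species x 2 sequences with hand-set distances enumerate correctly", {
    # d(a1,a2)=0.02 intra A; d(b1,b2)=0.04 intra B; four inter pairs
    # 0.10, 0.12, 0.14, 0.16
    # build sequences realising close to these via mismatch counts on
    # 100 sites is fiddly; instead drive the K2PMatrix class directly.
    ids <- c("a1", "a2", "b1", "b2")
    d <- matrix(0, 4, 4, dimnames = list(ids, ids))
    d["a1", "a2"] <- d["a2", "a1"] <- 0.02
    d["b1", "b2"] <- d["b2", "b1"] <- 0.04
    d["a1", "b1"] <- d["b1", "a1"] <- 0.10
    d["a1", "b2"] <- d["b2", "a1"] <- 0.12
    d["a2", "b1"] <- d["b1", "a2"] <- 0.14
    d["a2", "b2"] <- d["b2", "a2"] <- 0.16
    dm <- new("K2PMatrix", d = d, L = matrix(100L, 4, 4),
        P = d / 2, Q = d / 2, defined = matrix(TRUE, 4, 4),
        species = c("A", "A", "B", "B"))
    ds <- divergenceSummary(dm)
    expect_equal(idxGet(ds, "allInterspecific"), mean(c(.10, .12, .14, .16)))
    # per species minima: A -> 0.10, B -> 0.10
    expect_equal(idxGet(ds, "minInterspecific"), 0.10)
    expect_equal(idxGet(ds, "allIntraspecific"), 0.03)
    expect_equal(idxGet(ds, "theta"), mean(c(0.02, 0.04)))
    expect_equal(idxGet(ds, "coalescentDepth"), mean(c(0.02, 0.04)))
    # dispersion: sample SD of the constituents
    df <- ds@indices
    expect_equal(df$sd[df$index == "allInterspecific"],
        sd(c(.10, .12, .14, .16)))
})

test_that("identical sequences across several species zero every index", {
    seqs <- setNames(rep(paste(rep("ACGT", 20), collapse = ""), 8),
        sprintf("z%d", 1:8))
    aln <- makeAln(seqs, rep(sprintf("cx sp%d", 1:4), 2))
    ds <- divergenceSummary(aln)
    for (nm in c("allInterspecific", "minInterspecific",
        "allIntraspecific", "theta", "coalescentDepth")) {
        expect_equal(idxGet(ds, nm), 0)
        expect_equal(ds@indices$sd[ds@indices$index == nm], 0)
    }
})

test_that("a single-species group reports zero for all five indices", {
    set.seed(43)
    seqs <- setNames(rep(randomSeqs(1, 50), 4), sprintf("w%d", 1:4))
    aln <- makeAln(seqs, rep("only one", 4))
    ds <- divergenceSummary(aln)
    expect_equal(idxGet(ds, "allInterspecific"), 0)
    expect_equal(idxGet(ds, "minInterspecific"), 0)
    expect_equal(ds@indices$n[ds@indices$index == "allInterspecific"], 0)
})

test_that("theta equals pooled intraspecific mean under balanced sampling", {
    set.seed(47)
    seqs <- relatedSeqs(12, 80, subs = 3)
    names(seqs) <- sprintf("b%02d", 1:12)
    aln <- makeAln(seqs, rep(sprintf("sp%d", 1:4), each = 3))
    ds <- divergenceSummary(aln)
    # 3 sequences per species -> 3 conspecific pairs each, equal weights
    expect_equal(idxGet(ds, "theta"), idxGet(ds, "allIntraspecific"),
        tolerance = 1e-12)
})

test_that("coalescent depth dominates theta", {
    set.seed(53)
    for (rep in 1:5) {
        seqs <- randomSeqs(10, 60)
        names(seqs) <- sprintf("c%02d", 1:10)
        aln <- makeAln(seqs, rep(sprintf("sp%d", 1:5), each = 2))
        ds <- divergenceSummary(aln)
        expect_gte(idxGet(ds, "coalescentDepth"), idxGet(ds, "theta"))
        expect_gte(idxGet(ds, "theta"), 0)
    }
})

test_that("shared identical haplotypes force a zero minimum interspecific distance", {
    set.seed(59)
    pool <- unname(relatedSeqs(3, 70, subs = 4))
    hap <- pool[1]
    other <- pool[2:3]
    seqs <- c(s1a = hap, s1b = hap, s2a = hap, s2b = other[1],
        s3a = other[2], s3b = other[2])
    aln <- makeAln(seqs, c("spA", "spA", "spB", "spB", "spC", "spC"))
    dm <- k2pMatrix(aln)
    ds <- divergenceSummary(dm)
    d <- distances(dm)
    expect_equal(d["s1a", "s2a"], 0)   # the shared haplotype pair
    sp <- speciesLabels(dm)
    minA <- min(d[sp == "spA", sp != "spA"], na.rm = TRUE)
    minB <- min(d[sp == "spB", sp != "spB"], na.rm = TRUE)
    expect_equal(minA, 0)
    expect_equal(minB, 0)
})

test_that("minimum interspecific never exceeds all interspecific", {
    set.seed(61)
    for (rep in 1:5) {
        seqs <- relatedSeqs(12, 60, subs = 3)
        names(seqs) <- sprintf("e%02d", 1:12)
        aln <- makeAln(seqs, rep(sprintf("sp%d", 1:6), 2))
        ds <- divergenceSummary(aln)
        expect_lte(idxGet(ds, "minInterspecific"),
            idxGet(ds, "allInterspecific") + 1e-12)
    }
})
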