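.roundPct <- function(f) floor(100 * f * 100 + 0.5) / 100

mkDM2 <- function(d, species, ids = NULL) {
    n <- nrow(d)
    if (is.null(ids)) ids <- sprintf("q%d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    new("K2PMatrix", d = d, L = matrix(50L, n, n), P = d, Q = d * 0,
        defined = matrix(!is.na(d), n, n), species = species)
}

test_that("best match follows the tie-kept nearest-neighbour rule", {
    # query q1: nearest neighbour heterospecific at 0.01, conspecific at
    # 0.02 -> incorrect
    d <- matrix(0.5, 3, 3); diag(d) <- 0
    d[1, 2] <- d[2, 1] <- 0.02   # conspecific
    d[1, 3] <- d[3, 1] <- 0.01   # heterospecific
    dm <- mkDM2(d, c("A", "A", "B"))
    v <- bestMatch(dm, "q1")
    expect_equal(v$verdict, "incorrect")
    expect_equal(v$bestIds, "q3")
    expect_equal(v$bestDistance, 0.01)

    # tie between conspecific and heterospecific -> ambiguous
    d[1, 2] <- d[2, 1] <- 0.01
    v2 <- bestMatch(mkDM2(d, c("A", "A", "B")), "q1")
    expect_equal(v2$verdict, "ambiguous")
    expect_setequal(v2$bestSpecies, c("A", "B"))

    # all best matches conspecific -> correct
    d[1, 2] <- d[2, 1] <- 0.005
    v3 <- bestMatch(mkDM2(d, c("A", "A", "B")), "q1")
    expect_equal(v3$verdict, "correct")
})

test_that("undefined distances to every reference give a no-match flag", {
    d <- matrix(NA_real_, 3, 3); diag(d) <- 0
    d[2, 3] <- d[3, 2] <- 0.1
    dm <- mkDM2(d, c("A", "A", "B"))
    expect_equal(bestMatch(dm, "q1")$verdict, "no-match")
})

test_that("BCM threshold is the interpolated 95th percentile of intraspecific distances", {
    set.seed(73)
    # 12 hand-set intraspecific distances across two species of four
    # sequences each; the threshold must be the order-statistics
    # interpolation of the pooled sorted values.
    n <- 8
    d <- matrix(0.5, n, n); diag(d) <- 0
    sp <- rep(c("A", "B"), each = 4)
    ids <- sprintf("q%d", 1:n)
    k <- 1
    vals <- sort(runif(12, 0, 0.05))
    for (s in c("A", "B")) {
        own <- which(sp == s)
        for (i in own) for (j in own) if (i < j) {
            d[i, j] <- d[j, i] <- vals[k]; k <- k + 1
        }
    }
    dm <- mkDM2(d, sp, ids)
    expect_equal(bcmThreshold(dm), quantile(vals, 0.95, names = FALSE),
        tolerance = 1e-12)
    # degenerate cases
    d1 <- matrix(0, 2, 2)
    expect_equal(bcmThreshold(mkDM2(d1, c("A", "A"))), 0)
    d2 <- matrix(c(0, 0.03, 0.03, 0), 2, 2)
    expect_equal(bcmThreshold(mkDM2(d2, c("A", "A"))), 0.03)
    expect_error(bcmThreshold(mkDM2(d2, c("A", "B"))), "intraspecific")
})

test_that("best close match discards far references and can return no-match", {
    d <- matrix(0.5, 3, 3); diag(d) <- 0
    d[1, 2] <- d[2, 1] <- 0.30
    d[1, 3] <- d[3, 1] <- 0.40
    dm <- mkDM2(d, c("A", "A", "B"))
    expect_equal(bestCloseMatch(dm, "q1", 0.05)$verdict, "no-match")
    # matches at exactly the threshold survive
    expect_equal(bestCloseMatch(dm, "q1", 0.30)$verdict, "correct")
    # threshold between 1st and 2nd neighbour: verdict decided by 1st only
    v <- bestCloseMatch(dm, "q1", 0.35)
    expect_equal(v$verdict, "correct")
    expect_equal(v$bestIds, "q2")
})

test_that("identical sequences across species are ambiguous even at threshold zero", {
    seqs <- setNames(rep("ACGTACGTACGT", 6), sprintf("z%d", 1:6))
    aln <- makeAln(seqs, rep(c("cx a", "cx b", "cx c"), 2))
    dm <- k2pMatrix(aln)
    expect_equal(bcmThreshold(dm), 0)
    for (i in 1:6) {
        expect_equal(bestMatch(dm, i)$verdict, "ambiguous")
        expect_equal(bestCloseMatch(dm, i, 0)$verdict, "ambiguous")
    }
    rep <- identificationReport(aln, "BCM", dm = dm)
    expect_equal(unname(rep@summary["ambiguous"]), 100)
    expect_equal(unname(rep@summary["noMatch"]), 0)
})

test_that("BLAST1 classification follows the three-way best-hit rule", {
    # private unique haplotypes -> every query correct
    seqs <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA",
        b1 = "GGGGGGGGGG", b2 = "GGGGGGGGGG")
    aln <- makeAln(seqs, c("A", "A", "B", "B"))
    for (i in 1:4)
        expect_equal(blast1Classify(aln, i)$verdict, "correct")

    # top hits span the expected and another species -> ambiguous
    seqs2 <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA", b1 = "AAAAAAAAAA")
    aln2 <- makeAln(seqs2, c("A", "A", "B"))
    expect_equal(blast1Classify(aln2, "a1")$verdict, "ambiguous")
    # top hit heterospecific only -> incorrect
    expect_equal(blast1Classify(aln2, "b1")$verdict, "incorrect")
})

test_that("BLAST1 accepts an external outfmt-6-style hit table", {
    seqs <- c(a1 = "AAAAAAAAAA", a2 = "AAAAAAAAAA", b1 = "GGGGGGGGGG")
    aln <- makeAln(seqs, c("A", "A", "B"))
    hits <- data.frame(query = c("a1", "a1"), subject = c("a2", "b1"),
        score = c(50, 20))
    expect_equal(blast1Classify(aln, "a1", hits = hits)$verdict,
        "correct")
    hits2 <- data.frame(query = "a1", subject = "b1", score = 30)
    expect_equal(blast1Classify(aln, "a1", hits = hits2)$verdict,
        "incorrect")
    hits3 <- data.frame(query = "zz", subject = "b1", score = 30)
    expect_equal(blast1Classify(aln, "a1", hits = hits3)$verdict,
        "no-match")
})

test_that("report rates match hand-enumerated verdicts on a 3-species toy", {
    # species A: identical pair -> both correct under BM
    # species B: b1's nearest is heterospecific -> incorrect; b2 ties -> ?
    seqs <- c(
        a1 = "AAAAAAAAAACCCCC", a2 = "AAAAAAAAAACCCCC",
        b1 = "GGGGGGGGGGCCCCC", b2 = "GGGGGGGGGGCCCGC",
        c1 = "GGGGGGGGGGCCCAC", c2 = "TTTTTTTTTTCCCCC")
    aln <- makeAln(seqs, c("A", "A", "B", "B", "C", "C"))
    dm <- k2pMatrix(aln)
    rep <- identificationReport(aln, "BM", dm = dm)
    v <- verdicts(rep)
    expect_equal(v$verdict[v$id == "a1"], "correct")
    expect_equal(v$verdict[v$id == "a2"], "correct")
    # b1's closest: b2 and c1 both one substitution away -> ambiguous
    expect_equal(v$verdict[v$id == "b1"], "ambiguous")
    # c1's closest is b2 (1 diff) closer than c2 -> incorrect
    expect_equal(v$verdict[v$id == "c1"], "incorrect")
    expect_equal(nrow(v), 6)
    s <- rep@summary
    expect_equal(unname(s["correct"]),
        .roundPct(sum(v$verdict == "correct") / 6))
})

test_that("queries from species with fewer than two sequences are excluded", {
    seqs <- c(a1 = "AAAAA", a2 = "AAAAA", b1 = "GGGGG")
    aln <- makeAln(seqs, c("A", "A", "B"))
    rep <- identificationReport(aln, "BM")
    expect_equal(nrow(verdicts(rep)), 2)
    expect_false("b1" %in% verdicts(rep)$id)
    solo <- makeAln(c(x = "AAAA", y = "GGGG"), c("X", "Y"))
    expect_error(identificationReport(solo, "BM"), "eligible")
})

test_that("BCM only ever converts verdicts to no-match, never improves them", {
    set.seed(79)
    for (rep in 1:5) {
        seqs <- relatedSeqs(12, 50, subs = 4)
        names(seqs) <- sprintf("p%02d", 1:12)
        aln <- makeAln(seqs, base::rep(sprintf("sp%d", 1:4), each = 3))
        dm <- k2pMatrix(aln)
        thr <- bcmThreshold(dm)
        for (i in 1:12) {
            bm <- bestMatch(dm, i)
            bcm <- bestCloseMatch(dm, i, thr)
            if (bcm$verdict != "no-match")
                expect_equal(bcm$verdict, bm$verdict)
            if (bm$verdict == "incorrect")
                expect_true(bcm$verdict %in% c("incorrect", "no-match"))
        }
    }
})

test_that("rates are invariant to relabeling ids within species", {
    set.seed(83)
    seqs <- randomSeqs(9, 60)
    names(seqs) <- sprintf("n%d", 1:9)
    species <- rep(c("A", "B", "C"), each = 3)
    aln <- makeAln(seqs, species)
    r1 <- identificationReport(aln, "BM")
    # permute ids within each species (sequence content moves with id)
    perm <- as.vector(vapply(split(seq_len(9), species),
        sample, integer(3)))
    seqs2 <- seqs[perm]
    names(seqs2) <- sprintf("n%d", 1:9)
    r2 <- identificationReport(makeAln(seqs2, species), "BM")
    expect_equal(r2@summary, r1@summary)
})

test_that("BM and BLAST1 verdicts coincide on gap-free transition-only data", {
    # On gap-free equal-length data the default BLAST1 scorer ranks by
    # 1 - p-distance. K2P is a strictly monotone function of the
    # mismatch proportion when all mismatches are transitions (Q = 0),
    # so the two rankings — including ties — coincide exactly. (On mixed
    # transition/transversion data, equal p-distances with different
    # transition content give unequal K2P distances, so similarity ties
    # can be split differently by the two methods.)
    set.seed(89)
    tsPartner <- c(A = "G", G = "A", C = "T", T = "C")
    root <- sample(c("A", "C", "G", "T"), 200, replace = TRUE)
    seqs <- vapply(1:10, function(i) {
        ch <- root
        pos <- sample(200, 6)
        ch[pos] <- tsPartner[ch[pos]]
        paste(ch, collapse = "")
    }, character(1))
    names(seqs) <- sprintf("g%02d", 1:10)
    aln <- makeAln(seqs, rep(sprintf("sp%d", 1:5), each = 2))
    bm <- verdicts(identificationReport(aln, "BM"))
    bl <- verdicts(identificationReport(aln, "BLAST1"))
    expect_equal(bl$verdict, bm$verdict)
})
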