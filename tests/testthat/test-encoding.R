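test_that("clone tables are filtered of non-standard residues on load", {
    tmp <- tempfile(fileext = ".tsv")
    writeLines(c("cdr3\tv\tfrequency",
                 "CASSF\tTRBV1\t3",
                 "CAX*S\tTRBV2\t1",
                 "CASRG\tTRBV1\t2"), tmp)
    expect_message(rep <- readRepertoire(tmp), "Dropped 1")
    expect_equal(nClones(rep), 2L)
    expect_equal(cdr3s(rep), c("CASSF", "CASRG"))
    expect_true(hasV(rep))
    expect_equal(cloneFreqs(rep), c(3, 2))

    # no invalid rows: everything retained
    tmp2 <- tempfile(fileext = ".tsv")
    writeLines(c("cdr3", "CASSF", "CASRG"), tmp2)
    expect_equal(nClones(readRepertoire(tmp2)), 2L)
    expect_false(hasV(readRepertoire(tmp2)))

    # lowercase letters are uppercased before validation; verified
    # against a hand-filtered copy of a 10-row fixture
    rows <- c("cassf", "caX_g", "CARGY", "cas#t", "CGGGT", "casrk",
              "CA*SS", "cayeqy", "CSARD", "cw_tt")
    handFiltered <- toupper(c("cassf", "CARGY", "CGGGT", "casrk",
                              "cayeqy", "CSARD"))
    tmp3 <- tempfile(fileext = ".csv")
    writeLines(c("cdr3", rows), tmp3)
    suppressMessages(rep3 <- readRepertoire(tmp3, format = "csv"))
    expect_equal(cdr3s(rep3), handFiltered)

    # errors: missing CDR3 column; nothing left after filtering
    tmp4 <- tempfile(fileext = ".tsv")
    writeLines(c("sequence\tv", "CASSF\tTRBV1"), tmp4)
    expect_error(readRepertoire(tmp4), "CDR3 column")
    tmp5 <- tempfile(fileext = ".tsv")
    writeLines(c("cdr3", "CAX*"), tmp5)
    expect_error(suppressMessages(readRepertoire(tmp5)), "no clones")
})

test_that("FASTA input and TSV round trip work", {
    tmp <- tempfile(fileext = ".fasta")
    writeLines(c(">c1", "CASSF", ">c2", "CAR", "GY"), tmp)
    rep <- readRepertoire(tmp)
    expect_equal(cdr3s(rep), c("CASSF", "CARGY"))

    out <- tempfile(fileext = ".tsv")
    orig <- TCRRepertoire(c("CASSF", "CARGY"), vGene = c("TRBV1", "TRBV2"),
                          frequency = c(5, 1), sampleId = "s1")
    writeRepertoire(orig, out)
    back <- readRepertoire(out, sampleId = "s1")
    expect_equal(clones(back), clones(orig))
})

test_that("scheme dimensions follow m and the V catalogue", {
    reps <- TCRRepertoire(c("CASS", "CARGYT", "CASSF"))
    sc <- buildScheme(reps)
    expect_equal(maxLen(sc), 6L)
    expect_equal(schemeDim(sc), 21L * 7L)

    repV <- TCRRepertoire(c("CASS", "CARGYT"), vGene = c("TRBV5", "TRBV7"))
    scV <- buildScheme(repV, useV = TRUE)
    expect_equal(vCatalogue(scV), c("TRBV5", "TRBV7"))
    expect_equal(schemeDim(scV), 21L * 7L + 2L)

    # degenerate single-residue clone
    sc1 <- buildScheme(TCRRepertoire("C"))
    expect_equal(maxLen(sc1), 1L)
    expect_equal(schemeDim(sc1), 42L)

    # V requested but absent
    expect_error(buildScheme(reps, useV = TRUE), "lack a V gene")
})

test_that("encoding lays out residues, stop, padding and V as specified", {
    sc <- new("EncodingScheme", maxLen = 3L, vCatalogue = character(0))
    x <- encodeClones("CA", sc)
    expect_equal(ncol(x), 84L)
    expect_equal(sum(x), 3)  # C, A, stop
    expect_equal(which(x[1, ] == 1),
                 c(which(AA_ALPHABET == "C"),
                   21L + which(AA_ALPHABET == "A"),
                   2L * 21L + 21L))          # stop at index 21 of block 3
    expect_true(all(x[1, (3L * 21L + 1L):84L] == 0))  # right padding

    # exactly l+1 occupied blocks (+1 V entry when applicable)
    scV <- new("EncodingScheme", maxLen = 5L, vCatalogue = c("a", "b"))
    xv <- encodeClones(data.frame(cdr3 = "CASS", vGene = "b"), scV)
    expect_equal(sum(xv), 4 + 1 + 1)
    expect_equal(unname(xv[1, 21L * 6L + 1:2]), c(0, 1))

    # too-long CDR3 and unknown V are errors, not truncations
    expect_error(encodeClones("CASSF", sc), "longer than")
    expect_error(encodeClones(data.frame(cdr3 = "CA", vGene = "z"), scV),
                 "not in the scheme")
})

test_that("encode/decode round-trips clones and respects the stop rule", {
    set.seed(5)
    seqs <- randomCdr3(1000)
    sc <- new("EncodingScheme", maxLen = 14L, vCatalogue = character(0))
    dec <- decodeOneHot(encodeClones(seqs, sc), sc)
    expect_equal(dec$cdr3, seqs)

    # with V genes
    scV <- new("EncodingScheme", maxLen = 14L,
               vCatalogue = sprintf("TRBV%d", 1:7))
    tab <- data.frame(cdr3 = seqs[1:200],
                      vGene = sample(sprintf("TRBV%d", 1:7), 200, TRUE))
    decV <- decodeOneHot(encodeClones(tab, scV), scV)
    expect_equal(decV$cdr3, tab$cdr3)
    expect_equal(decV$vGene, tab$vGene)

    # a stop argmax in block 2 ends the sequence regardless of later blocks
    x <- encodeClones("CASS", sc)
    x[1, 21L + 1:21] <- 0; x[1, 21L + 21L] <- 1   # block 2 -> stop
    expect_equal(decodeOneHot(x, sc)$cdr3, "C")

    # soft values decode by per-block argmax, ties to the lowest index
    soft <- matrix(0, 1, schemeDim(sc))
    soft[1, which(AA_ALPHABET == "C")] <- 0.6
    soft[1, which(AA_ALPHABET == "A")] <- 0.4
    soft[1, 21L + 21L] <- 0.9
    expect_equal(decodeOneHot(soft, sc)$cdr3, "C")
})

test_that("one-hot distances reflect Hamming distances", {
    # equal-length sequences differing at h positions: distance sqrt(2h)
    sc <- new("EncodingScheme", maxLen = 10L, vCatalogue = character(0))
    set.seed(9)
    for (i in 1:20) {
        a <- randomCdr3(1, 8, 8)
        ach <- strsplit(a, "")[[1]]
        h <- sample(1:8, 1)
        pos <- sample(8, h)
        bch <- ach
        for (p in pos)
            bch[p] <- sample(setdiff(AA_ALPHABET, ach[p]), 1)
        X <- encodeClones(c(a, paste(bch, collapse = "")), sc)
        expect_equal(as.numeric(dist(X)), sqrt(2 * h))
    }
})

test_that("encoded matrices round-trip through the sidecar container", {
    sc <- new("EncodingScheme", maxLen = 6L, vCatalogue = c("TRBV1"))
    tab <- data.frame(cdr3 = c("CASS", "CAR"), vGene = "TRBV1")
    X <- encodeClones(tab, sc)
    path <- tempfile(fileext = ".tsv")
    saveEncoded(X, sc, path)
    back <- loadEncoded(path)
    expect_equal(back$X, X)
    expect_equal(maxLen(back$scheme), 6L)
    expect_equal(vCatalogue(back$scheme), "TRBV1")
})
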