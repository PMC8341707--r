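test_that("architecture matches the configured layer sizes and scheme", {
    sc <- new("EncodingScheme", maxLen = 6L, vCatalogue = character(0))
    m <- buildAutoencoder(sc, aeConfig("E", seed = 1))
    expect_equal(dim(m@weights$W1), c(147L, 300L))
    expect_equal(dim(m@weights$W2), c(300L, 100L))
    expect_equal(dim(m@weights$W3), c(100L, 30L))
    expect_equal(dim(m@weights$W6), c(300L, 147L))

    # untrained forward pass: every 21-block of the output is a softmax
    x <- encodeClones(c("CASS", "CAR"), sc)
    fw <- TCRdens:::.aeForward(x, m@weights, TCRdens:::.blockIndices(sc))
    for (b in 0:6) {
        blk <- fw$Yhat[, (b * 21 + 1):((b + 1) * 21)]
        expect_equal(rowSums(blk), c(1, 1), tolerance = 1e-12)
        expect_true(all(blk > 0))
    }

    # V-flavored model: the V block is softmaxed separately
    scV <- new("EncodingScheme", maxLen = 6L,
               vCatalogue = sprintf("TRBV%d", 1:10))
    mv <- buildAutoencoder(scV, aeConfig("VE", seed = 1))
    xv <- encodeClones(data.frame(cdr3 = "CASS", vGene = "TRBV3"), scV)
    fwv <- TCRdens:::.aeForward(xv, mv@weights, TCRdens:::.blockIndices(scV))
    expect_equal(sum(fwv$Yhat[1, 148:157]), 1, tolerance = 1e-12)

    # flavor/scheme mismatch
    expect_error(buildAutoencoder(sc, aeConfig("VE")), "requires")
    expect_error(buildAutoencoder(scV, aeConfig("E")), "forbids")
})

test_that("MSE loss follows the documented averaging convention", {
    expect_equal(lossMSE(c(1, 0), c(1, 0)), 0)
    # y = [1,0], yhat = [0,1]: 1 under mean-over-components,
    # 2 under sum-over-components — this asserts the chosen convention
    expect_equal(lossMSE(c(1, 0), c(0, 1)), 1)
    expect_equal(lossMSE(c(1, 0), c(0, 1), componentMean = FALSE), 2)
    expect_error(lossMSE(c(1, 0), c(1, 0, 0)), "shape")
})

test_that("distance loss is zero exactly on isometries and matches brute force", {
    expect_equal(lossDis(matrix(1, 1, 30), matrix(0, 1, 1)), 0)  # no pairs

    # an embedding reproducing all pairwise distances gives exactly 0
    set.seed(2)
    Z <- matrix(rnorm(10 * 30), 10, 30)
    expect_equal(lossDis(Z, as.matrix(dist(Z))), 0)
    expect_equal(lossDis(Z, as.matrix(dist(Z))^2, squared = TRUE), 0)

    # 3 points, hand-computed double loop
    z <- matrix(c(0, 0, 3, 0, 0, 4), 3, 2, byrow = TRUE)
    D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
    want <- (3 - 1)^2 + (4 - 2)^2 + (5 - 3)^2
    expect_equal(lossDis(z, D), want)
    expect_equal(lossDis(z, D, normalize = TRUE), want / 3)
    wantSq <- (9 - 1)^2 + (16 - 2)^2 + (25 - 3)^2
    expect_equal(lossDis(z, D, squared = TRUE), wantSq)

    expect_error(lossDis(z, D[1:2, 1:2]), "match")
})

test_that("training reduces the loss and can overfit a small corpus", {
    set.seed(77)
    seqs <- unique(randomCdr3(60, 6, 10))[1:50]
    # overfit configuration: regularization off, small batches and a
    # faster learning rate so a 50-clone corpus is memorized
    m <- trainAutoencoder(seqs, aeConfig("E", epochs = 500, seed = 5,
                                         dropout = 0, batchSize = 10,
                                         learningRate = 1e-3))
    # training loss decreased substantially and monotonically in trend
    h <- m@history$loss
    expect_lt(mean(tail(h, 20)), mean(head(h, 20)) / 2)
    # exact-length reconstruction of the training set (overfit check)
    acc <- reconstructionAccuracy(m, seqs, k = 0)
    expect_gte(unname(acc), 0.95)
})

test_that("distance loss declines during EM training", {
    cfg <- generatorConfig(clonesPerSample = 200L, nHosts = 1L,
                           samplesPerHost = 2L, seed = 88L)
    reps <- generateRepertoire(cfg)
    m <- trainAutoencoder(reps, aeConfig("EM", epochs = 40, seed = 3))
    expect_lt(tail(m@history$dis, 1), m@history$dis[1])
})

test_that("training is bitwise reproducible for a fixed seed", {
    seqs <- randomCdr3(40)
    m1 <- trainAutoencoder(seqs, aeConfig("EM", epochs = 5, seed = 99))
    m2 <- trainAutoencoder(seqs, aeConfig("EM", epochs = 5, seed = 99))
    expect_identical(m1@history, m2@history)
    expect_identical(m1@weights, m2@weights)
})

test_that("the distance term with zero weight reproduces the plain trajectory", {
    seqs <- randomCdr3(60)
    mE <- trainAutoencoder(seqs, aeConfig("E", epochs = 8, seed = 4))
    suppressMessages(cfg0 <- aeConfig("EM", epochs = 8, disWeight = 0,
                                      seed = 4))
    mM0 <- trainAutoencoder(seqs, cfg0)
    expect_equal(mM0@history$mse, mE@history$mse, tolerance = 1e-12)
})

test_that("embedding is 30-dimensional, deterministic and order-preserving", {
    model <- smallModelE()
    reps <- smallCorpus()
    cl <- clones(reps[[1]])[1:20, ]
    Z <- embedTCR(model, cl)
    expect_equal(dim(Z), c(20L, 30L))
    expect_true(all(is.finite(Z)))
    # duplicates embed identically
    Zdup <- embedTCR(model, rbind(cl[1, ], cl[1, ]))
    expect_identical(Zdup[1, ], Zdup[2, ])
    # permutation of inputs permutes outputs
    p <- sample(20)
    expect_equal(embedTCR(model, cl[p, ]), Z[p, ], tolerance = 1e-12)
})

test_that("reconstruction accuracy counts length errors and is monotone in k", {
    model <- smallModelE()
    reps <- smallCorpus()
    # identity reconstruction: accuracy 1 for all k
    sc <- model@scheme
    X <- encodeClones(clones(reps[[1]])[1:10, ], sc)
    dec <- decodeOneHot(X, sc)
    expect_equal(dec$cdr3, cdr3s(reps[[1]])[1:10])

    # hand count: "CASS" vs reconstruction "CAST"
    mism <- sum(strsplit("CASS", "")[[1]] != strsplit("CAST", "")[[1]])
    expect_equal(mism, 1)  # k=0 would reject, k=1 accepts

    acc <- reconstructionAccuracy(model, reps[[2]], k = 0:18)
    expect_true(all(diff(acc) >= 0))
    # on same-length reconstructions, k >= m accepts everything length-matched
    rec <- reconstructTCR(model, reps[[2]])
    lenOk <- mean(nchar(rec$cdr3) == nchar(cdr3s(reps[[2]])))
    expect_equal(unname(acc["k18"]), lenOk)
    expect_error(reconstructionAccuracy(model,
        data.frame(cdr3 = character(0))), "empty")
})

test_that("distance correlation is 1 for isometries and ~0 for shuffles", {
    # exact isometry: classical MDS reproduces the pairwise geometry of a
    # tiny one-hot set exactly in 5 dimensions; distances are rounded
    # before ranking so exact ties stay tied under floating point
    set.seed(10)
    sc <- new("EncodingScheme", maxLen = 2L, vCatalogue = character(0))
    seqs <- c("CA", "CY", "AW", "KK", "C", "W")
    X <- encodeClones(seqs, sc)
    Y <- cmdscale(dist(X), k = 5)
    dx <- round(as.numeric(dist(X)), 9)
    dy <- round(as.numeric(dist(Y)), 9)
    expect_equal(cor(dx, dy, method = "spearman"), 1)

    # shuffled pairing of distances decorrelates (permutation null band;
    # only 15 pairs, so the band is wide)
    set.seed(11)
    rhos <- replicate(200, cor(dx, sample(dy), method = "spearman"))
    expect_lt(abs(mean(rhos)), 0.15)
    expect_gt(mean(abs(rhos) < 0.6), 0.9)

    model <- smallModelE()
    expect_error(distanceCorrelation(model, randomCdr3(2)), "at least 3")
})

test_that("models survive a save/load round trip", {
    model <- smallModelE()
    dir <- tempfile()
    saveAutoencoder(model, dir)
    back <- loadAutoencoder(dir)
    expect_equal(back@weights, model@weights)
    expect_equal(maxLen(back@scheme), maxLen(model@scheme))
    expect_equal(back@config$flavor, "E")
    cl <- clones(smallCorpus()[[1]])[1:5, ]
    expect_equal(embedTCR(back, cl), embedTCR(model, cl))
})

test_that("divergent or empty training inputs raise errors", {
    expect_error(trainAutoencoder(data.frame(cdr3 = character(0)),
                                  aeConfig("E")), "empty")
    # an absurd learning rate overflows the distance term to non-finite
    # values; the divergence guard reports the epoch
    cfgBad <- aeConfig("EM", epochs = 5, learningRate = 1e155, seed = 1)
    expect_error(trainAutoencoder(randomCdr3(30), cfgBad),
                 "diverged.*epoch")
})
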