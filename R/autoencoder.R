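#' @include AllClasses.R encoding.R
NULL

#' Autoencoder training configuration
#'
#' The four flavors: `E` (plain autoencoder), `VE` (V gene concatenated to
#' the input), `EM` (distance-preservation loss added at the embedding) and
#' `VEM` (both). The encoder has three fully connected layers of 300, 100
#' and 30 nodes, each with Elu activation and dropout 0.1 during training;
#' the decoder mirrors them and ends in a per-21-block softmax (the V block,
#' when present, is softmaxed separately). Training uses Adam at learning
#' rate 1e-4 on the mean squared error between input and reconstruction;
#' for `EM`/`VEM` the per-batch pairwise-distance loss is added with weight
#' `disWeight` after per-pair normalization, which makes the two terms
#' scale-comparable across batch sizes.
#'
#' @param flavor One of `"E"`, `"VE"`, `"EM"`, `"VEM"`.
#' @param layerSizes Encoder layer sizes; the last is the embedding
#'   dimension Z and must be 30.
#' @param dropout Dropout rate applied after every hidden layer in training.
#' @param learningRate Adam learning rate.
#' @param batchSize Batch size `b`.
#' @param epochs Training epochs.
#' @param disWeight Weight of the (per-pair normalized) distance loss.
#' @param squaredDis If `TRUE`, use the literal squared-distance inner term
#'   `(d_z^2 - D)^2`; default compares unsquared Euclidean distances on
#'   both sides, since distance conservation is the stated goal.
#' @param vInDistance Include the V block in the per-batch input distance
#'   matrix (only relevant for `VEM`).
#' @param earlyStopping Monitor total loss on a held-out fraction and stop
#'   when it has not improved for `patience` epochs (best weights kept).
#' @param validFraction,patience Early-stopping split and patience.
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return Named list with class `"aeConfig"`.
#' @examples
#' aeConfig("EM", epochs = 50, seed = 7)
#' @export
aeConfig <- function(flavor = c("E", "VE", "EM", "VEM"),
                     layerSizes = c(300L, 100L, 30L), dropout = 0.1,
                     learningRate = 1e-4, batchSize = 50L, epochs = 300L,
                     disWeight = 1, squaredDis = FALSE, vInDistance = TRUE,
                     earlyStopping = FALSE, validFraction = 0.1,
                     patience = 20L, seed = 1L) {
    flavor <- match.arg(flavor)
    stopifnot(length(layerSizes) == 3L,
              layerSizes[3L] == 30L,
              dropout >= 0, dropout < 1,
              learningRate > 0, batchSize >= 1L, epochs >= 1L,
              disWeight >= 0)
    cfg <- list(flavor = flavor, layerSizes = as.integer(layerSizes),
                dropout = dropout, learningRate = learningRate,
                batchSize = as.integer(batchSize),
                epochs = as.integer(epochs), disWeight = disWeight,
                squaredDis = isTRUE(squaredDis),
                vInDistance = isTRUE(vInDistance),
                earlyStopping = isTRUE(earlyStopping),
                validFraction = validFraction,
                patience = as.integer(patience), seed = as.integer(seed),
                useV = flavor %in% c("VE", "VEM"),
                useDis = flavor %in% c("EM", "VEM"))
    if (cfg$useDis && disWeight == 0)
        message("distance-loss flavor with disWeight = 0: ",
                "reduces to the plain reconstruction objective")
    class(cfg) <- "aeConfig"
    cfg
}

.elu <- function(x) {
    neg <- x < 0
    x[neg] <- expm1(x[neg])
    x
}
# bias addition without sweep(): b recycled down each column
.addBias <- function(M, b) M + rep(b, each = nrow(M))

.blockIndices <- function(scheme) {
    m <- scheme@maxLen
    nV <- length(scheme@vCatalogue)
    blocks <- lapply(seq_len(m + 1L),
                     function(b) ((b - 1L) * 21L + 1L):(b * 21L))
    if (nV > 0L)
        blocks <- c(blocks, list((21L * (m + 1L) + 1L):(21L * (m + 1L) + nV)))
    blocks
}

# pairwise Euclidean distance matrix (rows of X)
.pdist <- function(X) {
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    D2[D2 < 0] <- 0
    sqrt(D2)
}

#' Reconstruction loss: mean squared error
#'
#' The squared error is averaged over the batch and over vector components
#' (the chosen convention; it rescales only the effective learning rate).
#' With `componentMean = FALSE` the per-vector squared errors are summed
#' over components and averaged over the batch only.
#'
#' @param y,yhat Matrices (or vectors) of equal shape: targets and decoder
#'   outputs.
#' @param componentMean Average over components as well as the batch.
#' @return Non-negative scalar.
#' @export
lossMSE <- function(y, yhat, componentMean = TRUE) {
    if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
    if (is.null(dim(yhat))) yhat <- matrix(yhat, nrow = 1L)
    if (!all(dim(y) == dim(yhat))) stop("shape mismatch")
    if (componentMean) mean((y - yhat)^2)
    else mean(rowSums((y - yhat)^2))
}

#' Distance-preservation loss over a batch
#'
#' Sum over unordered pairs of the squared difference between the
#' embedded-pair distance and the original one-hot distance:
#' `sum_{i<j} (d_z(i,j) - D_ij)^2` with unsquared Euclidean distances on
#' both sides; with `squared = TRUE` the inner term is the literal squared
#' embedded distance, `(d_z(i,j)^2 - D_ij)^2`. Zero iff the embedding is a
#' pairwise isometry of the batch (under the chosen convention).
#'
#' @param z Matrix of embedded vectors (rows = batch).
#' @param D Distance matrix (or `dist`) of the batch's one-hot inputs.
#' @param squared Use the literal squared-distance inner term.
#' @param normalize Divide by the number of pairs (the form entering the
#'   training objective).
#' @return Non-negative scalar; 0 when the batch has fewer than 2 points.
#' @export
lossDis <- function(z, D, squared = FALSE, normalize = FALSE) {
    if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
    b <- nrow(z)
    if (b < 2L) return(0)
    D <- as.matrix(D)
    if (!all(dim(D) == b)) stop("batch size does not match distance matrix")
    dz <- .pdist(z)
    if (squared) dz <- dz^2
    ut <- upper.tri(dz)
    s <- sum((dz[ut] - D[ut])^2)
    if (normalize) s / sum(ut) else s
}

.initAeWeights <- function(n, sizes, nV = 0L) {
    dims <- c(n, sizes, rev(sizes)[-1L], n)   # n 300 100 30 100 300 n
    W <- list()
    glorot <- function(fin, fout) {
        lim <- sqrt(6 / (fin + fout))
        matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
    }
    for (i in seq_len(6L)) {
        W[[paste0("W", i)]] <- glorot(dims[i], dims[i + 1L])
        W[[paste0("b", i)]] <- numeric(dims[i + 1L])
    }
    # trainable output layer applied to each 21-row separately (shared
    # across positions), softmax on top; the V block, having a different
    # width, gets its own layer
    W$W7 <- glorot(21L, 21L); W$b7 <- numeric(21L)
    if (nV > 0L) { W$W8 <- glorot(nV, nV); W$b8 <- numeric(nV) }
    W
}

#' Build an (untrained) autoencoder for a scheme
#'
#' Initializes Glorot-uniform weights for the encoder
#' `n -> 300 -> 100 -> 30` and the mirrored decoder `30 -> 100 -> 300 -> n`
#' under the configuration seed.
#'
#' @param scheme An [EncodingScheme]; must carry a V catalogue iff the
#'   flavor uses V.
#' @param config An [aeConfig()].
#' @return An untrained [TCRAutoencoder].
#' @export
buildAutoencoder <- function(scheme, config = aeConfig()) {
    stopifnot(is(scheme, "EncodingScheme"), inherits(config, "aeConfig"))
    if (config$useV != hasV(scheme))
        stop("flavor ", config$flavor, if (config$useV) " requires" else
             " forbids", " a V catalogue in the scheme")
    set.seed(config$seed)
    W <- .initAeWeights(schemeDim(scheme), config$layerSizes,
                        nV = length(scheme@vCatalogue))
    new("TCRAutoencoder", weights = W, scheme = scheme, config = config,
        history = data.frame(), trained = FALSE)
}

# full forward pass without dropout; returns embedding and reconstruction
.aeForward <- function(X, P, blocks) {
    H1 <- .elu(.addBias(X %*% P$W1, P$b1))
    H2 <- .elu(.addBias(H1 %*% P$W2, P$b2))
    Z <- .elu(.addBias(H2 %*% P$W3, P$b3))
    H4 <- .elu(.addBias(Z %*% P$W4, P$b4))
    H5 <- .elu(.addBias(H4 %*% P$W5, P$b5))
    A6 <- .addBias(H5 %*% P$W6, P$b6)
    Yhat <- A6
    for (blk in blocks) {
        B <- A6[, blk, drop = FALSE]
        W <- if (length(blk) == 21L) P$W7 else P$W8
        bb <- if (length(blk) == 21L) P$b7 else P$b8
        Yhat[, blk] <- .rowSoftmax(.addBias(B %*% W, bb))
    }
    list(Z = Z, Yhat = Yhat)
}

.rowSoftmax <- function(A) {
    mx <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
    E <- exp(A - mx)
    E / rowSums(E)
}

.evalLoss <- function(X, P, blocks, cfg) {
    fw <- .aeForward(X, P, blocks)
    mse <- lossMSE(X, fw$Yhat)
    dis <- 0
    if (cfg$useDis && nrow(X) >= 2L)
        dis <- lossDis(fw$Z, .pdist(X), squared = cfg$squaredDis,
                       normalize = TRUE)
    c(mse = mse, dis = dis, loss = mse + cfg$disWeight * dis)
}

#' Train an autoencoder on repertoire samples
#'
#' Minimizes the reconstruction MSE (plus, for `EM`/`VEM`, the per-pair
#' normalized distance loss weighted by `disWeight`) with Adam. The
#' per-batch input distance matrix `D_b` is computed on the fly from the
#' batch's one-hot rows; its entries are identical to the corresponding
#' entries of the full training-set distance matrix. Fully reproducible
#' from the configuration seed.
#'
#' @param samples A [TCRRepertoire], list of them, character vector of
#'   CDR3s, or clone `data.frame`.
#' @param config An [aeConfig()].
#' @param scheme Optional [EncodingScheme]; built from `samples` when
#'   `NULL`.
#' @return A trained [TCRAutoencoder] with per-epoch history (columns
#'   `epoch`, `mse`, `dis`, `loss`, and validation columns under early
#'   stopping).
#' @export
trainAutoencoder <- function(samples, config = aeConfig(), scheme = NULL) {
    stopifnot(inherits(config, "aeConfig"))
    tab <- .cloneTable(samples)
    if (nrow(tab) == 0L) stop("empty training set")
    if (is.null(scheme)) {
        if (is(samples, "TCRRepertoire") ||
            (is.list(samples) && !is.data.frame(samples) &&
             all(vapply(samples, is, TRUE, "TCRRepertoire"))))
            scheme <- buildScheme(samples, useV = config$useV)
        else {
            vcat <- character(0)
            if (config$useV) {
                if (anyNA(tab$vGene)) stop("flavor needs V genes")
                vcat <- sort(unique(tab$vGene))
            }
            scheme <- new("EncodingScheme",
                          maxLen = max(nchar(tab$cdr3)), vCatalogue = vcat)
        }
    }
    model <- buildAutoencoder(scheme, config)   # seeds the RNG
    X <- encodeClones(tab, scheme)
    blocks <- .blockIndices(scheme)
    n <- ncol(X)
    nV <- length(scheme@vCatalogue)
    Xval <- NULL
    if (config$earlyStopping) {
        nv <- max(2L, round(config$validFraction * nrow(X)))
        vi <- sample.int(nrow(X), nv)
        Xval <- X[vi, , drop = FALSE]
        X <- X[-vi, , drop = FALSE]
        if (nrow(X) < 2L) stop("training set too small for validation split")
    }

    P <- model@weights
    # flat parameter vector; the compiled step views weight matrices
    # directly in this memory and updates it in place (fused Adam)
    pdims <- lapply(P, dim)
    plens <- vapply(P, length, 1L)
    pends <- cumsum(plens)
    pstarts <- pends - plens + 1L
    theta <- unlist(P, use.names = FALSE)
    mAd <- numeric(length(theta))
    vAd <- numeric(length(theta))
    tAd <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    lr <- config$learningRate
    lam <- config$disWeight
    layerDims <- c(n, config$layerSizes)
    vInDist <- !(config$useDis && config$useV && !config$vInDistance)
    N <- nrow(X)
    hist <- vector("list", config$epochs)
    relist <- function(theta) {
        for (i in seq_along(P)) {
            w <- theta[pstarts[i]:pends[i]]
            if (!is.null(pdims[[i]])) dim(w) <- pdims[[i]]
            P[[i]] <- w
        }
        P
    }
    best <- list(loss = Inf, theta = theta, wait = 0L)

    for (ep in seq_len(config$epochs)) {
        perm <- sample.int(N)
        starts <- seq(1L, N, by = config$batchSize)
        epMse <- epDis <- 0; nb <- 0L
        for (s in starts) {
            idx <- perm[s:min(s + config$batchSize - 1L, N)]
            tAd <- tAd + 1L
            corr <- sqrt(1 - b2^tAd) / (1 - b1^tAd)
            res <- cpp_ae_step(X[idx, , drop = FALSE], theta, mAd, vAd,
                               layerDims, scheme@maxLen + 1L, nV,
                               config$dropout, lr, corr, b1, b2, eps,
                               lam, config$useDis, config$squaredDis,
                               vInDist)
            if (!is.finite(res[1L] + lam * res[2L]))
                stop(sprintf(
                    "training diverged (non-finite loss) at epoch %d", ep))
            epMse <- epMse + res[1L]; epDis <- epDis + res[2L]
            nb <- nb + 1L
        }
        row <- data.frame(epoch = ep, mse = epMse / nb, dis = epDis / nb,
                          loss = (epMse + lam * epDis) / nb)
        if (config$earlyStopping) {
            vl <- .evalLoss(Xval, relist(theta), blocks, config)
            row$valMse <- vl[["mse"]]; row$valDis <- vl[["dis"]]
            row$valLoss <- vl[["loss"]]
            hist[[ep]] <- row
            if (vl[["loss"]] < best$loss) {
                best$loss <- vl[["loss"]]
                best$theta <- theta + 0   # snapshot (theta mutates in place)
                best$wait <- 0L
            } else {
                best$wait <- best$wait + 1L
                if (best$wait >= config$patience) { theta <- best$theta; break }
            }
        } else hist[[ep]] <- row
    }
    model@weights <- relist(theta)
    model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
    model@trained <- TRUE
    model
}

#' Embed clones into the 30-dimensional space
#'
#' Deterministic encoder forward pass (dropout disabled at inference),
#' order-preserving: row `i` of the result embeds clone `i`.
#'
#' @param model A [TCRAutoencoder].
#' @param x Clones in any form accepted by [encodeClones()], or an
#'   already-encoded matrix with `matrixInput = TRUE`.
#' @param matrixInput Treat `x` as an encoded one-hot matrix.
#' @return Numeric matrix, one 30-dimensional row per clone.
#' @export
embedTCR <- function(model, x, matrixInput = FALSE) {
    stopifnot(is(model, "TCRAutoencoder"))
    X <- if (matrixInput) x else encodeClones(x, model@scheme)
    if (ncol(X) != schemeDim(model@scheme)) stop("scheme mismatch")
    P <- model@weights
    .elu(.addBias(.elu(.addBias(.elu(.addBias(X %*% P$W1, P$b1)) %*% P$W2,
        P$b2)) %*% P$W3, P$b3))
}

#' Reconstruct clones through the full autoencoder
#'
#' Forward pass through encoder and decoder (no dropout), then a rigid
#' argmax decode per 21-block, stopping at the leftmost stop symbol.
#'
#' @inheritParams embedTCR
#' @return `data.frame` with columns `cdr3` and `vGene`.
#' @export
reconstructTCR <- function(model, x, matrixInput = FALSE) {
    stopifnot(is(model, "TCRAutoencoder"))
    X <- if (matrixInput) x else encodeClones(x, model@scheme)
    fw <- .aeForward(X, model@weights, .blockIndices(model@scheme))
    decodeOneHot(fw$Yhat, model@scheme)
}

#' Fraction of clones reconstructed with at most k mismatches
#'
#' A reconstruction whose decoded length differs from the original counts
#' as an error for every `k`; otherwise the error level is the number of
#' differing positions. Accuracy is non-decreasing in `k`.
#'
#' @param model A trained [TCRAutoencoder].
#' @param x Test clones (any form accepted by [encodeClones()]).
#' @param k Maximal mismatch count(s); may be a vector.
#' @return Named numeric vector of accuracies in `[0, 1]`, one per `k`.
#' @export
reconstructionAccuracy <- function(model, x, k = 2L) {
    tab <- .cloneTable(x)
    if (nrow(tab) == 0L) stop("empty test set")
    rec <- reconstructTCR(model, tab)
    orig <- tab$cdr3
    sameLen <- nchar(rec$cdr3) == nchar(orig)
    mism <- rep(Inf, length(orig))
    if (any(sameLen)) {
        a <- strsplit(orig[sameLen], "")
        b <- strsplit(rec$cdr3[sameLen], "")
        mism[sameLen] <- mapply(function(u, v) sum(u != v), a, b)
    }
    out <- vapply(k, function(kk) mean(mism <= kk), numeric(1))
    names(out) <- paste0("k", k)
    out
}

#' Spearman correlation between one-hot and embedded pairwise distances
#'
#' Over all unordered pairs of the given clones, correlates the Euclidean
#' distance between one-hot encodings with the Euclidean distance between
#' the 30-dimensional embeddings (rank correlation).
#'
#' @param model A trained [TCRAutoencoder].
#' @param x Held-out clones (at least 3).
#' @return Spearman rho in `[-1, 1]`.
#' @export
distanceCorrelation <- function(model, x) {
    X <- encodeClones(.cloneTable(x), model@scheme)
    if (nrow(X) < 3L) stop("need at least 3 clones")
    dx <- stats::dist(X)
    dz <- stats::dist(embedTCR(model, X, matrixInput = TRUE))
    if (stats::sd(dx) == 0 || stats::sd(dz) == 0)
        stop("all pairwise distances identical; correlation undefined")
    stats::cor(as.numeric(dx), as.numeric(dz), method = "spearman")
}

#' Save / load a trained autoencoder
#'
#' Writes the weight container (`weights.rds`) together with JSON sidecars
#' for the scheme (`m`, alphabet order with the stop symbol at index 21,
#' V catalogue) and the training configuration, plus the per-epoch history
#' as TSV.
#'
#' @param model A [TCRAutoencoder].
#' @param dir Directory to create/use.
#' @return `dir` (or, for `loadAutoencoder`, the model), invisibly.
#' @export
saveAutoencoder <- function(model, dir) {
    stopifnot(is(model, "TCRAutoencoder"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(model@weights, file.path(dir, "weights.rds"))
    jsonlite::write_json(
        list(m = model@scheme@maxLen,
             alphabet = c(AA_ALPHABET, STOP_SYMBOL),
             vCatalogue = model@scheme@vCatalogue,
             config = model@config[setdiff(names(model@config), "")],
             trained = model@trained),
        file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
    if (nrow(model@history))
        utils::write.table(model@history, file.path(dir, "history.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname saveAutoencoder
#' @export
loadAutoencoder <- function(dir) {
    side <- jsonlite::read_json(file.path(dir, "model.json"),
                                simplifyVector = TRUE)
    cfg <- side$config
    config <- aeConfig(flavor = cfg$flavor,
                       layerSizes = as.integer(cfg$layerSizes),
                       dropout = cfg$dropout, learningRate = cfg$learningRate,
                       batchSize = cfg$batchSize, epochs = cfg$epochs,
                       disWeight = cfg$disWeight, squaredDis = cfg$squaredDis,
                       vInDistance = cfg$vInDistance,
                       earlyStopping = cfg$earlyStopping,
                       validFraction = cfg$validFraction,
                       patience = cfg$patience, seed = cfg$seed)
    scheme <- new("EncodingScheme", maxLen = as.integer(side$m),
                  vCatalogue = as.character(side$vCatalogue))
    hist <- data.frame()
    hp <- file.path(dir, "history.tsv")
    if (file.exists(hp))
        hist <- utils::read.table(hp, sep = "\t", header = TRUE)
    new("TCRAutoencoder", weights = readRDS(file.path(dir, "weights.rds")),
        scheme = scheme, config = config, history = hist,
        trained = isTRUE(side$trained))
}
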