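#' @include AllClasses.R autoencoder.R
NULL

#' Per-sample train/test split for one-vs-all classification
#'
#' Draws `perSample` clones (seeded, without replacement) from each sample
#' into the training fraction; all remaining clones form the test fraction.
#' A sample smaller than `perSample` contributes all its clones to the
#' training fraction (with a message). A category with no test clones at
#' all is an error, since the classifier could not be evaluated on it.
#'
#' @param samples List of [TCRRepertoire] with category labels.
#' @param perSample Training clones per sample (default 500).
#' @param seed Seed for the draws.
#' @return A [LabeledSplit].
#' @export
makeSplit <- function(samples, perSample = 500L, seed = 1L) {
    samples <- .asRepList(samples)
    if (perSample < 1L) stop("perSample must be >= 1")
    set.seed(seed)
    tr <- list(); te <- list()
    for (rep in samples) {
        cl <- rep@clones
        cl$sampleId <- sampleId(rep)
        cl$category <- category(rep)
        n <- nrow(cl)
        if (n <= perSample) {
            message(sprintf(
                "sample '%s' has %d <= %d clones; all go to training",
                sampleId(rep), n, perSample))
            tr[[length(tr) + 1L]] <- cl
        } else {
            idx <- sample.int(n, perSample)
            tr[[length(tr) + 1L]] <- cl[idx, , drop = FALSE]
            te[[length(te) + 1L]] <- cl[-idx, , drop = FALSE]
        }
    }
    train <- do.call(rbind, tr)
    test <- if (length(te)) do.call(rbind, te) else
        train[0, , drop = FALSE]
    lost <- setdiff(unique(train$category), unique(test$category))
    if (length(lost))
        stop("categories with zero test clones: ",
             paste(lost, collapse = ", "))
    rownames(train) <- rownames(test) <- NULL
    new("LabeledSplit", train = train, test = test)
}

#' Weighted binary cross-entropy
#'
#' `-1/N sum_i w_i [y_i log p_i + (1 - y_i) log(1 - p_i)]`; probabilities
#' are clamped away from 0/1 for finiteness.
#'
#' @param y 0/1 labels.
#' @param p Predicted probabilities.
#' @param w Optional per-observation weights (default 1).
#' @return Non-negative scalar (0 when `p = y` exactly).
#' @export
lossBCE <- function(y, p, w = NULL) {
    if (length(y) != length(p)) stop("length mismatch")
    if (is.null(w)) w <- rep(1, length(y))
    eps <- 1e-12
    p <- pmin(pmax(p, eps), 1 - eps)
    -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
}

.headForward <- function(Z, H, masks = NULL) {
    T1 <- tanh(sweep(Z %*% H$W1, 2, H$b1, "+"))
    T2 <- tanh(sweep(T1 %*% H$W2, 2, H$b2, "+"))
    if (!is.null(masks)) T2d <- T2 * masks$M2 else T2d <- T2
    T3 <- tanh(sweep(T2d %*% H$W3, 2, H$b3, "+"))
    if (!is.null(masks)) T3d <- T3 * masks$M3 else T3d <- T3
    A4 <- sweep(T3d %*% H$W4, 2, H$b4, "+")
    list(T1 = T1, T2 = T2, T2d = T2d, T3 = T3, T3d = T3d, A4 = A4,
         p = 1 / (1 + exp(-A4)))
}

#' Train the one-vs-all classifier head on a frozen encoder
#'
#' The head (four fully connected layers of 30, 15, 10 and 1 nodes; Tanh
#' activations, sigmoid output, dropout 0.1 after the second and third
#' layers) is trained with Adam at the encoder's learning rate on a
#' class-weighted binary cross-entropy for `targetClass` vs all other
#' categories pooled. The encoder weights are never touched: embeddings
#' are computed once up front and the head is optimized on them.
#'
#' @param model A trained [TCRAutoencoder] (the frozen encoder).
#' @param split A [LabeledSplit] from [makeSplit()].
#' @param targetClass Positive-class category label.
#' @param epochs Training epochs (early stopping may end sooner).
#' @param batchSize,learningRate,dropout Optimization settings (defaults
#'   match the autoencoder's).
#' @param earlyStopping,validFraction,patience Early stopping on
#'   validation BCE.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A [TCRClassifier].
#' @export
trainClassifier <- function(model, split, targetClass, epochs = 400L,
                            batchSize = 50L, learningRate = 1e-4,
                            dropout = 0.1, earlyStopping = TRUE,
                            validFraction = 0.1, patience = 10L,
                            seed = 1L) {
    stopifnot(is(model, "TCRAutoencoder"), is(split, "LabeledSplit"))
    tr <- split@train
    y <- as.numeric(tr$category == targetClass)
    if (length(unique(y)) < 2L)
        stop("training data contain a single class")
    Z <- embedTCR(model, tr)
    set.seed(seed)
    sizes <- c(30L, 30L, 15L, 10L, 1L)
    H <- list()
    for (i in 1:4) {
        lim <- sqrt(6 / (sizes[i] + sizes[i + 1L]))
        H[[paste0("W", i)]] <- matrix(
            stats::runif(sizes[i] * sizes[i + 1L], -lim, lim),
            sizes[i], sizes[i + 1L])
        H[[paste0("b", i)]] <- numeric(sizes[i + 1L])
    }
    # inverse-frequency class weights
    wPos <- length(y) / (2 * sum(y == 1))
    wNeg <- length(y) / (2 * sum(y == 0))
    w <- ifelse(y == 1, wPos, wNeg)

    Zval <- NULL; yval <- NULL; wval <- NULL
    if (earlyStopping) {
        nv <- max(2L, round(validFraction * nrow(Z)))
        vi <- sample.int(nrow(Z), nv)
        if (length(unique(y[-vi])) == 2L && length(unique(y[vi])) == 2L) {
            Zval <- Z[vi, , drop = FALSE]; yval <- y[vi]; wval <- w[vi]
            Z <- Z[-vi, , drop = FALSE]; y <- y[-vi]; w <- w[-vi]
        } else earlyStopping <- FALSE   # split would lose a class
    }

    mAd <- lapply(H, function(x) x * 0)
    vAd <- lapply(H, function(x) x * 0)
    tAd <- 0L; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    N <- nrow(Z)
    hist <- vector("list", epochs)
    best <- list(loss = Inf, H = H, wait = 0L)
    for (ep in seq_len(epochs)) {
        perm <- sample.int(N)
        epLoss <- 0; nb <- 0L
        for (s in seq(1L, N, by = batchSize)) {
            idx <- perm[s:min(s + batchSize - 1L, N)]
            Zb <- Z[idx, , drop = FALSE]
            yb <- y[idx]; wb <- w[idx]
            bsz <- length(idx)
            masks <- list(
                M2 = matrix((stats::runif(bsz * 15L) >= dropout) /
                            (1 - dropout), bsz, 15L),
                M3 = matrix((stats::runif(bsz * 10L) >= dropout) /
                            (1 - dropout), bsz, 10L))
            fw <- .headForward(Zb, H, masks)
            p <- as.numeric(fw$p)
            epLoss <- epLoss + lossBCE(yb, p, wb); nb <- nb + 1L
            # dBCE/dA4 for sigmoid output
            dA4 <- matrix(wb * (p - yb) / bsz, ncol = 1L)
            gW4 <- crossprod(fw$T3d, dA4); gb4 <- colSums(dA4)
            dT3 <- (dA4 %*% t(H$W4)) * masks$M3
            dA3 <- dT3 * (1 - fw$T3^2)
            gW3 <- crossprod(fw$T2d, dA3); gb3 <- colSums(dA3)
            dT2 <- (dA3 %*% t(H$W3)) * masks$M2
            dA2 <- dT2 * (1 - fw$T2^2)
            gW2 <- crossprod(fw$T1, dA2); gb2 <- colSums(dA2)
            dT1 <- dA2 %*% t(H$W2)
            dA1 <- dT1 * (1 - fw$T1^2)
            gW1 <- crossprod(Zb, dA1); gb1 <- colSums(dA1)
            grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                          W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
            tAd <- tAd + 1L
            corr <- sqrt(1 - b2^tAd) / (1 - b1^tAd)
            for (k in names(H)) {
                g <- grads[[k]]
                mAd[[k]] <- b1 * mAd[[k]] + (1 - b1) * g
                vAd[[k]] <- b2 * vAd[[k]] + (1 - b2) * g^2
                H[[k]] <- H[[k]] - learningRate * corr * mAd[[k]] /
                    (sqrt(vAd[[k]]) + eps)
            }
        }
        row <- data.frame(epoch = ep, bce = epLoss / nb)
        if (earlyStopping) {
            pv <- as.numeric(.headForward(Zval, H)$p)
            row$valBce <- lossBCE(yval, pv, wval)
            hist[[ep]] <- row
            if (row$valBce < best$loss) {
                best$loss <- row$valBce; best$H <- H; best$wait <- 0L
            } else {
                best$wait <- best$wait + 1L
                if (best$wait >= patience) { H <- best$H; break }
            }
        } else hist[[ep]] <- row
    }
    new("TCRClassifier", head = H, encoder = model,
        targetClass = as.character(targetClass),
        history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
}

#' Predict one-vs-all class probabilities for clones
#'
#' Deterministic at inference (dropout off); order-preserving. Scores are
#' sigmoid outputs in (0, 1).
#'
#' @param classifier A [TCRClassifier].
#' @param x Clones in any form accepted by [encodeClones()].
#' @return Numeric vector of probabilities.
#' @export
predictClones <- function(classifier, x) {
    stopifnot(is(classifier, "TCRClassifier"))
    Z <- embedTCR(classifier@encoder, x)
    as.numeric(.headForward(Z, classifier@head)$p)
}

#' Test-set AUC of a one-vs-all classifier
#'
#' Area under the ROC curve of the predicted probability against the
#' one-vs-all label on the test fraction of the split.
#'
#' @param classifier A [TCRClassifier].
#' @param split The [LabeledSplit] whose test fraction to score.
#' @return AUC in `[0, 1]`.
#' @export
evaluateAUC <- function(classifier, split) {
    stopifnot(is(split, "LabeledSplit"))
    te <- split@test
    y <- as.numeric(te$category == classifier@targetClass)
    if (length(unique(y)) < 2L) stop("single-class test set")
    p <- predictClones(classifier, te)
    as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
}

#' ROC curve points for a one-vs-all classifier
#'
#' @inheritParams evaluateAUC
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
rocPoints <- function(classifier, split) {
    te <- split@test
    y <- as.numeric(te$category == classifier@targetClass)
    p <- predictClones(classifier, te)
    r <- pROC::roc(y, p, quiet = TRUE, direction = "<", levels = c(0, 1))
    data.frame(threshold = r$thresholds, fpr = 1 - r$specificities,
               tpr = r$sensitivities)
}
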