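#' @include AllClasses.R autoencoder.R
NULL

.logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix, with optional per-column log offsets
.rowLogSumExp <- function(M, logw = NULL) {
    if (!is.null(logw)) M <- sweep(M, 2, logw, "+")
    mx <- apply(M, 1, max)
    fin <- is.finite(mx)
    out <- mx
    if (any(fin))
        out[fin] <- mx[fin] + log(rowSums(exp(M[fin, , drop = FALSE] -
                                              mx[fin])))
    out
}

# squared cross-distances between rows of A and rows of B
.crossDist2 <- function(A, B) {
    D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    D2[D2 < 0] <- 0
    D2
}

#' Rule-of-thumb kernel bandwidth for a set of embeddings
#'
#' `h = 1.06 * STD(S) * |S|^(-1/5)`, where for multivariate embeddings
#' `STD(S)` is, by default, the mean of the per-dimension standard
#' deviations (`std = "perDimension"`); `std = "global"` uses the standard
#' deviation of the flattened matrix instead.
#'
#' @param S Numeric matrix of embedded vectors (rows = clones).
#' @param std Multivariate spread convention.
#' @return Positive bandwidth `h`.
#' @examples
#' S <- matrix(rnorm(32 * 30), 32)   # per-dim sd ~ 1 -> h ~ 1.06 * 32^-0.2
#' kdeBandwidth(S)
#' @export
kdeBandwidth <- function(S, std = c("perDimension", "global")) {
    std <- match.arg(std)
    S <- as.matrix(S)
    if (nrow(S) < 2L) stop("bandwidth needs at least 2 points")
    s <- if (std == "perDimension") mean(apply(S, 2, stats::sd))
         else stats::sd(as.numeric(S))
    if (s == 0) stop("zero spread: degenerate bandwidth")
    1.06 * s * nrow(S)^(-1 / 5)
}

.kdeLog <- function(S1, S2, h, freq = NULL, normalized = FALSE,
                    excludeSelf = FALSE) {
    S1 <- as.matrix(S1); S2 <- as.matrix(S2)
    if (ncol(S1) != ncol(S2)) stop("dimension mismatch")
    Z <- ncol(S1)
    R <- nrow(S2)
    if (!is.null(freq)) {
        if (length(freq) != R) stop("freq must align with the reference set")
        if (any(freq <= 0)) stop("frequencies must be positive")
    }
    logK <- -(Z / 2) * log(2 * pi) - .crossDist2(S1, S2) / (2 * h^2)
    if (excludeSelf) {
        if (nrow(S1) != R) stop("leave-self-out needs S1 = S2")
        diag(logK) <- -Inf
    }
    pref <- if (normalized) -log(R) - Z * log(h) else -log(R) - log(h)
    .rowLogSumExp(logK, logw = if (is.null(freq)) NULL else log(freq)) + pref
}

#' Cross-density of query embeddings with respect to a reference set
#'
#' Gaussian-kernel density of each query point `x` in `S1` against the
#' reference points `y_i` in `S2`:
#' `f_h(x) = 1/(R h) * sum_i w_i K((x - y_i)/h)` with radial kernel
#' `K(u) = (2 pi)^(-Z/2) exp(-||u||^2 / 2)` and weights `w_i = 1` or the
#' clone frequencies. The `1/(R h)` prefactor follows the defining formula
#' literally; `normalized = TRUE` switches to the fully normalized
#' `1/(R h^Z)` form (all comparative results are invariant to this
#' constant). Values are computed and stored on the log scale.
#'
#' @param S1 Query embeddings (matrix, rows = points).
#' @param S2 Reference embeddings.
#' @param h Bandwidth; default [kdeBandwidth()] of `S2`.
#' @param freq Optional positive weights aligned with `S2`.
#' @param normalized Use the `1/(R h^Z)` prefactor.
#' @return A [DensityEstimate] (log-scale values via [logDensity()]).
#' @export
crossDensity <- function(S1, S2, h = NULL, freq = NULL, normalized = FALSE) {
    if (is.null(h)) h <- kdeBandwidth(S2)
    new("DensityEstimate",
        logDensity = .kdeLog(S1, S2, h, freq = freq, normalized = normalized),
        bandwidth = h, weighted = !is.null(freq))
}

#' Leave-self-out density of a sample's embeddings against themselves
#'
#' As [crossDensity()] with `S1 = S2 = S`, except that the `i`-th value
#' excludes point `i`'s own kernel contribution. The `1/(R h)` prefactor
#' keeps `R = |S|`.
#'
#' @param S Sample embeddings (at least 2 points).
#' @inheritParams crossDensity
#' @return A [DensityEstimate].
#' @export
selfDensity <- function(S, h = NULL, freq = NULL, normalized = FALSE) {
    S <- as.matrix(S)
    if (nrow(S) < 2L) stop("self-density needs at least 2 points")
    if (is.null(h)) h <- kdeBandwidth(S)
    new("DensityEstimate",
        logDensity = .kdeLog(S, S, h, freq = freq, normalized = normalized,
                             excludeSelf = TRUE),
        bandwidth = h, weighted = !is.null(freq))
}

.subsampleRep <- function(rep, R, seed, strict = FALSE) {
    n <- nClones(rep)
    if (!is.null(R) && n < R) {
        if (strict)
            stop(sprintf("sample '%s' has %d < R = %d clones",
                         sampleId(rep), n, R))
        R <- n
    }
    if (is.null(R) || R >= n)   # full sample: keep the original order
        return(rep@clones)
    set.seed(seed)
    idx <- sample.int(n, R)
    rep@clones[idx, , drop = FALSE]
}

#' KDE similarity of sample A with respect to sample B
#'
#' Subsamples `R` clones from each sample (seeded, without replacement),
#' embeds them with the model, takes the bandwidth from B's projections,
#' and returns the mean cross-density of A's projections in B — a
#' directional similarity (higher = closer). A constant subsample size
#' (default 100) avoids sample-size bias. The mean is computed in log
#' space; set `log = FALSE` for the natural scale (may underflow in 30
#' dimensions).
#'
#' @param A,B [TCRRepertoire] samples (query and reference).
#' @param model A trained [TCRAutoencoder].
#' @param R Subsample size per sample (`NULL` = all clones).
#' @param useFreq Weight B's kernel contributions by clone frequency.
#' @param seed Seed for the subsampling.
#' @param strict Error (instead of shrinking `R`) when a sample is smaller
#'   than `R`.
#' @param selfExclude Leave each point's own contribution out when A and B
#'   are the same sample (matched by `sampleId`).
#' @param log Return the log mean density (default) or the natural scale.
#' @param normalized Fully normalized kernel prefactor (see
#'   [crossDensity()]).
#' @return Scalar similarity.
#' @export
sampleCrossSimilarity <- function(A, B, model, R = 100L, useFreq = FALSE,
                                  seed = 1L, strict = FALSE,
                                  selfExclude = TRUE, log = TRUE,
                                  normalized = FALSE) {
    stopifnot(is(A, "TCRRepertoire"), is(B, "TCRRepertoire"))
    same <- identical(sampleId(A), sampleId(B))
    clA <- .subsampleRep(A, R, seed, strict)
    clB <- if (same) clA else .subsampleRep(B, R, seed + 1L, strict)
    if (useFreq && anyNA(clB$frequency))
        stop("useFreq requires clone frequencies in the reference sample")
    SA <- embedTCR(model, clA)
    SB <- if (same) SA else embedTCR(model, clB)
    h <- kdeBandwidth(SB)
    ld <- .kdeLog(SA, SB, h,
                  freq = if (useFreq) clB$frequency else NULL,
                  normalized = normalized,
                  excludeSelf = same && selfExclude)
    lm <- .logSumExp(ld) - base::log(length(ld))
    if (log) lm else exp(lm)
}
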