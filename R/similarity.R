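#' @include AllClasses.R density.R
NULL

#' Kullback-Leibler divergence of V-gene usage between two samples
#'
#' V-usage distributions are computed from `R` seeded random clones per
#' sample; `D(p||q) = sum_v p(v) log(p(v)/q(v))` (natural log) over the
#' union of V genes seen in either subsample. An additive pseudocount
#' (default 1) on the V counts before normalization keeps `q(v) > 0`;
#' with `pseudocount = 0`, zero-probability terms on `p`'s support follow
#' the usual `0 log 0 = 0` convention.
#'
#' @param A,B [TCRRepertoire] samples carrying V genes (`p` and `q`).
#' @param R Subsample size (`NULL` = all clones).
#' @param seed Subsampling seed.
#' @param pseudocount Additive smoothing on V counts.
#' @return Non-negative divergence (0 for identical usage).
#' @export
klSimilarity <- function(A, B, R = 100L, seed = 1L, pseudocount = 1) {
    stopifnot(is(A, "TCRRepertoire"), is(B, "TCRRepertoire"))
    if (!hasV(A) || !hasV(B)) stop("KL similarity requires V genes")
    vA <- .subsampleRep(A, R, seed)$vGene
    vB <- .subsampleRep(B, R, seed + 1L)$vGene
    .klDivergence(vA, vB, pseudocount)
}

.klDivergence <- function(vA, vB, pseudocount = 1) {
    lev <- sort(unique(c(vA, vB)))
    cA <- table(factor(vA, levels = lev)) + pseudocount
    cB <- table(factor(vB, levels = lev)) + pseudocount
    p <- as.numeric(cA) / sum(cA)
    q <- as.numeric(cB) / sum(cB)
    if (any(q == 0 & p > 0))
        stop("q(v) = 0 on p's support; use a positive pseudocount")
    pos <- p > 0
    sum(p[pos] * log(p[pos] / q[pos]))
}

#' Mean nearest-neighbour edit distance between two samples
#'
#' Builds the `R x R` Levenshtein matrix `E` between seeded subsamples of
#' the CDR3s of A (rows) and B (columns) and returns the mean over rows of
#' the row minimum. For a self-comparison (same `sampleId`, or
#' `self = TRUE`) the diagonal is excluded, so the value is the mean
#' distance to the nearest *other* clone.
#'
#' @param A,B [TCRRepertoire] samples.
#' @param R Subsample size (`NULL` = all clones).
#' @param seed Subsampling seed.
#' @param self Force self-comparison handling; default: detected by
#'   matching sample ids.
#' @return Non-negative mean edit distance (0 iff every sampled clone of A
#'   occurs verbatim in B's subsample).
#' @export
edSimilarity <- function(A, B, R = 100L, seed = 1L, self = NULL) {
    stopifnot(is(A, "TCRRepertoire"), is(B, "TCRRepertoire"))
    if (!is.null(R) && R < 1L) stop("R must be >= 1")
    same <- if (is.null(self)) identical(sampleId(A), sampleId(B)) else self
    sA <- .subsampleRep(A, R, seed)$cdr3
    sB <- if (same && identical(sampleId(A), sampleId(B)))
        sA else .subsampleRep(B, R, seed + 1L)$cdr3
    E <- utils::adist(sA, sB)
    if (same) diag(E) <- NA
    mean(apply(E, 1, min, na.rm = TRUE))
}

#' Pairwise sample similarity / distance matrix
#'
#' Entry `(i, j)` is, per method: `kde` — the directional KDE similarity
#' [sampleCrossSimilarity()] of sample `i` in sample `j` (log scale, higher
#' = closer; may be asymmetric, `symmetrize` averages the two directions);
#' `kl` — the V-usage KL divergence (distance); `ed` — the mean
#' nearest-neighbour edit distance (distance, diagonal leave-self-out).
#'
#' @param samples List of [TCRRepertoire] with distinct sample ids.
#' @param method `"kde"`, `"kl"` or `"ed"`.
#' @param model Trained [TCRAutoencoder] (required for `"kde"`).
#' @param R Subsample size per sample.
#' @param useFreq Frequency-weight the KDE reference kernels.
#' @param seed Base seed; each sample's subsample seed is derived from it.
#' @param symmetrize Average the two directions (KDE only).
#' @return A [SampleSimilarityMatrix].
#' @export
similarityMatrix <- function(samples, method = c("kde", "kl", "ed"),
                             model = NULL, R = 100L, useFreq = FALSE,
                             seed = 1L, symmetrize = FALSE) {
    method <- match.arg(method)
    samples <- .asRepList(samples)
    ids <- vapply(samples, sampleId, "")
    if (anyDuplicated(ids)) stop("sample ids must be distinct")
    ns <- length(samples)
    M <- matrix(0, ns, ns, dimnames = list(ids, ids))
    if (method == "kde") {
        stopifnot(is(model, "TCRAutoencoder"))
        # one seeded subsample + embedding per sample, reused across pairs
        cl <- lapply(seq_len(ns), function(i)
            .subsampleRep(samples[[i]], R, seed + i))
        emb <- lapply(cl, function(ci) embedTCR(model, ci))
        hs <- vapply(emb, kdeBandwidth, numeric(1))
        for (i in seq_len(ns)) for (j in seq_len(ns)) {
            ld <- .kdeLog(emb[[i]], emb[[j]], hs[j],
                          freq = if (useFreq) cl[[j]]$frequency else NULL,
                          excludeSelf = i == j)
            M[i, j] <- .logSumExp(ld) - log(length(ld))
        }
        if (symmetrize) M <- (M + t(M)) / 2
        return(new("SampleSimilarityMatrix", values = M, method = "KDE",
                   direction = "similarity", logScale = TRUE))
    }
    for (i in seq_len(ns)) for (j in seq_len(ns)) {
        M[i, j] <- if (method == "kl")
            klSimilarity(samples[[i]], samples[[j]], R = R,
                         seed = seed + i * ns + j)
        else
            edSimilarity(samples[[i]], samples[[j]], R = R,
                         seed = seed + i * ns + j, self = i == j)
    }
    new("SampleSimilarityMatrix", values = M, method = toupper(method),
        direction = "distance", logScale = FALSE)
}

#' Distance form of a similarity matrix
#'
#' Similarity matrices are converted for linkage as
#' `distance = -log(similarity)` (a negation when the values are already
#' log-scale similarities, as for KDE), after flooring at machine epsilon
#' on the natural scale; distance matrices pass through. The result is
#' symmetrized by averaging the two directions and has a zero diagonal.
#'
#' @param M A [SampleSimilarityMatrix].
#' @return A symmetric `dist` object.
#' @export
asDistance <- function(M) {
    stopifnot(is(M, "SampleSimilarityMatrix"))
    V <- M@values
    if (M@direction == "similarity") {
        V <- if (M@logScale) -V else -log(pmax(V, .Machine$double.eps))
    }
    V <- (V + t(V)) / 2
    diag(V) <- 0
    stats::as.dist(V)
}

#' Average-linkage hierarchical clustering of samples
#'
#' Agglomerates the distance form of the matrix with average linkage
#' (UPGMA) and cuts the tree into `k` clusters.
#'
#' @param M A [SampleSimilarityMatrix].
#' @param k Number of clusters (`1 <= k <=` number of samples).
#' @return A [ClusterAssignment].
#' @export
hierarchicalCluster <- function(M, k) {
    stopifnot(is(M, "SampleSimilarityMatrix"))
    ns <- nrow(M@values)
    if (k < 1L || k > ns) stop("k must be between 1 and the number of samples")
    hc <- stats::hclust(asDistance(M), method = "average")
    new("ClusterAssignment", clusters = stats::cutree(hc, k = k),
        tree = hc, k = as.integer(k))
}

#' Shannon entropy of category labels across clusters
#'
#' For each label, the entropy (base 2) of the distribution of its samples
#' across clusters: 0 when the label is confined to one cluster, `log2(c)`
#' when split evenly over `c` clusters. Reported per label plus an
#' unweighted mean summary.
#'
#' @param assignment A [ClusterAssignment] (or named integer vector of
#'   cluster indices).
#' @param labels Per-sample category labels, aligned with the assignment
#'   (or named by sample id).
#' @return List with `perLabel` (named numeric) and `mean`.
#' @export
clusterEntropy <- function(assignment, labels) {
    cl <- if (is(assignment, "ClusterAssignment"))
        clusterIndices(assignment) else assignment
    if (length(cl) == 0L) stop("empty assignment")
    if (!is.null(names(cl)) && !is.null(names(labels)))
        labels <- labels[names(cl)]
    if (length(labels) != length(cl))
        stop("labels must cover all samples")
    per <- vapply(unique(labels), function(l) {
        p <- table(cl[labels == l])
        p <- as.numeric(p) / sum(p)
        -sum(p * log2(p))
    }, numeric(1))
    names(per) <- unique(labels)
    list(perLabel = per, mean = mean(per))
}

#' Export a linkage tree in Newick format
#'
#' @param assignment A [ClusterAssignment].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(assignment, path) {
    stopifnot(is(assignment, "ClusterAssignment"))
    ape::write.tree(ape::as.phylo(assignment@tree), file = path)
    invisible(path)
}
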