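#' @include AllClasses.R density.R
NULL

#' Publicity of each distinct clone across samples
#'
#' The publicity of a clone is the number of samples whose clone set
#' contains it. Identity is the exact CDR3 string by default; `byV = TRUE`
#' uses the (CDR3, V) pair instead.
#'
#' @param samples List of [TCRRepertoire].
#' @param byV Match on (CDR3, V gene) pairs.
#' @return `data.frame` with columns `cdr3` (and `vGene` if `byV`) and
#'   `publicity`, one row per distinct clone.
#' @export
publicity <- function(samples, byV = FALSE) {
    samples <- .asRepList(samples)
    keys <- lapply(samples, function(rep) {
        if (byV) unique(paste(cdr3s(rep), vGenes(rep), sep = "\r"))
        else unique(cdr3s(rep))
    })
    tab <- table(unlist(keys, use.names = FALSE))
    out <- data.frame(key = names(tab), publicity = as.integer(tab),
                      stringsAsFactors = FALSE)
    if (byV) {
        parts <- strsplit(out$key, "\r", fixed = TRUE)
        out$cdr3 <- vapply(parts, `[`, "", 1L)
        out$vGene <- vapply(parts, `[`, "", 2L)
        out <- out[, c("cdr3", "vGene", "publicity")]
    } else {
        names(out)[1L] <- "cdr3"
    }
    rownames(out) <- NULL
    out
}

#' Distance of each embedding from the center of mass
#'
#' Euclidean distance of every embedded clone from the unweighted mean
#' embedding. Translation-covariant: adding a constant vector to all
#' embeddings leaves the radii unchanged.
#'
#' @param emb Numeric matrix of embeddings (rows = clones).
#' @return Non-negative numeric vector of radii.
#' @export
radiusFromCenter <- function(emb) {
    emb <- as.matrix(emb)
    if (nrow(emb) < 1L) stop("need at least one embedding")
    ctr <- colMeans(emb)
    sqrt(rowSums(sweep(emb, 2, ctr)^2))
}

#' Mean self-density stratified by residue occurrence count
#'
#' Partitions a sample's clones by how many times `residue` occurs in the
#' CDR3 (counted beyond the first `offset` positions; the Cysteine analysis
#' conventionally skips position 1, so `offset` defaults to 1 for `C` and 0
#' otherwise), computes the leave-self-out log self-density of each clone
#' in the embedding space, and reports the group means together with a
#' two-sample t-test between the two groups named in `testGroups`.
#'
#' @param sample A [TCRRepertoire].
#' @param model A trained [TCRAutoencoder].
#' @param residue Single amino-acid letter.
#' @param offset Number of leading CDR3 positions to skip when counting.
#' @param R Optional seeded subsample size (`NULL` = all clones).
#' @param seed Subsampling seed.
#' @param testGroups Two occurrence counts to compare (default 0 vs 1).
#' @return List with `groups` (`data.frame`: `count`, `n`,
#'   `meanLogDensity`), `test` (the `htest`, or `NULL` when either test
#'   group is missing or too small) and `logDensity` (per-clone values,
#'   aligned with `counts`).
#' @export
featureDensity <- function(sample, model, residue,
                           offset = if (residue == "C") 1L else 0L,
                           R = NULL, seed = 1L, testGroups = c(0L, 1L)) {
    stopifnot(is(sample, "TCRRepertoire"), residue %in% AA_ALPHABET)
    cl <- .subsampleRep(sample, R, seed)
    tails <- substring(cl$cdr3, offset + 1L)
    counts <- nchar(tails) - nchar(gsub(residue, "", tails, fixed = TRUE))
    ld <- logDensity(selfDensity(embedTCR(model, cl)))
    grp <- sort(unique(counts))
    groups <- data.frame(
        count = grp,
        n = vapply(grp, function(g) sum(counts == g), integer(1)),
        meanLogDensity = vapply(grp, function(g) mean(ld[counts == g]),
                                numeric(1)))
    test <- NULL
    a <- ld[counts == testGroups[1L]]
    b <- ld[counts == testGroups[2L]]
    if (length(a) >= 2L && length(b) >= 2L)
        test <- stats::t.test(a, b)
    else if (length(grp) > 1L)
        warning("test groups missing or too small; t-test skipped")
    list(groups = groups, test = test, logDensity = ld, counts = counts)
}

#' Spearman correlation between two per-clone statistics
#'
#' Rank correlation (with p-value from the standard routine) between two
#' aligned per-clone quantities, e.g. publicity vs radius from center, or
#' publicity vs log self-density.
#'
#' @param x,y Aligned numeric vectors (at least 3 values).
#' @return List with `rho` and `p`.
#' @export
correlateStats <- function(x, y) {
    if (length(x) != length(y)) stop("inputs must be aligned")
    if (length(x) < 3L) stop("need at least 3 values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
}

#' 2-D t-SNE projection of embeddings for visualization
#'
#' Wraps the standard Barnes-Hut t-SNE implementation; seeded and
#' deterministic given the seed. The perplexity is capped at the maximum
#' the point count allows.
#'
#' @param emb Numeric matrix of embeddings (at least 4 rows).
#' @param seed Random seed.
#' @param perplexity t-SNE perplexity (capped automatically).
#' @return Numeric matrix with 2 columns, one row per input row.
#' @export
project2D <- function(emb, seed = 1L, perplexity = 30) {
    emb <- as.matrix(emb)
    if (nrow(emb) < 4L) stop("too few points for a 2-D projection")
    perplexity <- min(perplexity, floor((nrow(emb) - 1) / 3))
    set.seed(seed)
    out <- Rtsne::Rtsne(emb, dims = 2, perplexity = perplexity,
                        check_duplicates = FALSE, pca = FALSE,
                        verbose = FALSE)
    out$Y
}
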