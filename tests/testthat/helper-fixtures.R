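# Shared fixtures. Small trained models are built once per test run and
# memoized here, so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# small default-structure corpus: 4 samples x 150 clones, two hosts
smallCorpus <- function() {
    if (is.null(.fixtures$corpus)) {
        cfg <- generatorConfig(clonesPerSample = 150L, seed = 101L)
        .fixtures$corpus <- generateRepertoire(cfg)
    }
    .fixtures$corpus
}

# a quick E model trained on the small corpus (enough to be non-trivial)
smallModelE <- function() {
    if (is.null(.fixtures$modelE))
        .fixtures$modelE <- trainAutoencoder(
            smallCorpus(), aeConfig("E", epochs = 60, seed = 7))
    .fixtures$modelE
}

# random valid clone strings (uniform letters, lengths 6-14)
randomCdr3 <- function(n, minLen = 6, maxLen = 14) {
    lens <- minLen + sample.int(maxLen - minLen + 1L, n, replace = TRUE) - 1L
    vapply(lens, function(L)
        paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = ""),
        character(1))
}

# textbook Levenshtein dynamic program, independent of utils::adist
levenshteinDP <- function(a, b) {
    u <- strsplit(a, "")[[1]]; v <- strsplit(b, "")[[1]]
    n <- length(u); m <- length(v)
    d <- matrix(0L, n + 1L, m + 1L)
    d[, 1L] <- 0:n; d[1L, ] <- 0:m
    for (i in seq_len(n)) for (j in seq_len(m))
        d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                                 d[i, j] + (u[i] != v[j]))
    d[n + 1L, m + 1L]
}

# brute-force Gaussian KDE on the natural scale (tiny inputs only)
bruteKde <- function(S1, S2, h, freq = NULL, normalized = FALSE,
                     excludeSelf = FALSE) {
    Z <- ncol(S1); R <- nrow(S2)
    if (is.null(freq)) freq <- rep(1, R)
    sapply(seq_len(nrow(S1)), function(i) {
        tot <- 0
        for (j in seq_len(R)) {
            if (excludeSelf && i == j) next
            u2 <- sum((S1[i, ] - S2[j, ])^2) / h^2
            tot <- tot + freq[j] * (2 * pi)^(-Z / 2) * exp(-u2 / 2)
        }
        tot / (R * if (normalized) h^Z else h)
    })
}
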