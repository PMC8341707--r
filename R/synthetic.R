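#' @include AllClasses.R encoding.R
NULL

# realistic CDR3 amino-acid usage: glycine/serine-rich, cysteine-poor
.defaultAaFreqs <- function() {
    f <- c(A = 0.055, C = 0.005, D = 0.030, E = 0.055, F = 0.030,
           G = 0.130, H = 0.010, I = 0.020, K = 0.020, L = 0.060,
           M = 0.010, N = 0.035, P = 0.045, Q = 0.060, R = 0.070,
           S = 0.130, T = 0.070, V = 0.045, W = 0.010, Y = 0.060)
    f / sum(f)
}

#' Configure the synthetic repertoire generator
#'
#' Defaults emulate the gross statistics of beta-chain rep-seq clone
#' tables: total CDR3 lengths 8-18 with a unimodal peak at 13, conserved
#' `CASS...F` termini, glycine/serine-rich amino-acid usage, a 20-gene V
#' catalogue with geometrically decaying usage, Pareto clone sizes (tail
#' exponent 2.5), and two hosts of two samples each sharing clones from a
#' per-host public pool of 100 with inclusion probability 0.5.
#'
#' @param nHosts,samplesPerHost,clonesPerSample Repertoire layout.
#' @param lengths,lengthProbs Total CDR3 length distribution
#'   (`lengthProbs` defaults to a discretized normal peaked at 13).
#' @param aaFreqs Named amino-acid frequency vector (normalized).
#' @param prefix,suffix Conserved terminal sequences.
#' @param nVGenes V-catalogue size (0 disables V genes).
#' @param cloneSizeAlpha Pareto tail exponent of clone sizes (> 1).
#' @param publicPoolSize,sharingProb Per-host public pool size and
#'   per-sample inclusion probability of each pool clone.
#' @param motifClasses List of `list(name=, consensus=, mutationRate=)`
#'   specificity groups for [generateLabeledClasses()].
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A [GeneratorConfig].
#' @export
generatorConfig <- function(nHosts = 2L, samplesPerHost = 2L,
                            clonesPerSample = 500L, lengths = 8:18,
                            lengthProbs = NULL,
                            aaFreqs = .defaultAaFreqs(),
                            prefix = "CASS", suffix = "F",
                            nVGenes = 20L, cloneSizeAlpha = 2.5,
                            publicPoolSize = 100L, sharingProb = 0.5,
                            motifClasses = list(), seed = 1L) {
    if (is.null(lengthProbs)) {
        lengthProbs <- stats::dnorm(lengths, mean = 13, sd = 2)
        lengthProbs <- lengthProbs / sum(lengthProbs)
    }
    new("GeneratorConfig", nHosts = as.integer(nHosts),
        samplesPerHost = as.integer(samplesPerHost),
        clonesPerSample = as.integer(clonesPerSample),
        lengths = as.integer(lengths), lengthProbs = lengthProbs,
        aaFreqs = aaFreqs[AA_ALPHABET], prefix = prefix, suffix = suffix,
        nVGenes = as.integer(nVGenes),
        cloneSizeAlpha = cloneSizeAlpha,
        publicPoolSize = as.integer(publicPoolSize),
        sharingProb = sharingProb, motifClasses = motifClasses,
        seed = as.integer(seed))
}

.drawLengths <- function(cfg, n) {
    sample(cfg@lengths, n, replace = TRUE, prob = cfg@lengthProbs)
}

.drawV <- function(cfg, n) {
    if (cfg@nVGenes == 0L) return(rep(NA_character_, n))
    probs <- 0.85^(seq_len(cfg@nVGenes) - 1L)
    sample(sprintf("TRBV%02d", seq_len(cfg@nVGenes)), n, replace = TRUE,
           prob = probs / sum(probs))
}

# Pareto(1, alpha - 1) clone sizes, rounded up to integer counts
.drawSizes <- function(cfg, n) {
    ceiling(stats::runif(n)^(-1 / (cfg@cloneSizeAlpha - 1)))
}

# n CDR3s of the generator's structural form, unique w.r.t. `seen`
.drawUniqueCdr3 <- function(cfg, n, seen) {
    out <- character(n)
    fixed <- nchar(cfg@prefix) + nchar(cfg@suffix)
    i <- 0L
    while (i < n) {
        L <- .drawLengths(cfg, 1L)
        core <- paste(sample(AA_ALPHABET, L - fixed, replace = TRUE,
                             prob = cfg@aaFreqs), collapse = "")
        s <- paste0(cfg@prefix, core, cfg@suffix)
        if (!exists(s, envir = seen, inherits = FALSE)) {
            i <- i + 1L
            out[i] <- s
            assign(s, TRUE, envir = seen)
        }
    }
    out
}

#' Generate synthetic repertoire samples
#'
#' Produces `nHosts * samplesPerHost` samples. Each host owns a public
#' pool of `publicPoolSize` clones; every sample of that host includes
#' each pool clone independently with probability `sharingProb` and fills
#' up to `clonesPerSample` with private clones. All distinct clones are
#' globally unique apart from the deliberate public sharing, so with
#' `sharingProb = 0` no clone appears in two samples. Clone sizes are
#' Pareto-distributed (redrawn per sample); V genes are attached when the
#' catalogue is non-empty. Category labels are host ids.
#'
#' @param config A [GeneratorConfig].
#' @return List of [TCRRepertoire] with an attribute `"publicPools"`
#'   (per-host character vectors of pool CDR3s).
#' @export
generateRepertoire <- function(config) {
    stopifnot(is(config, "GeneratorConfig"))
    set.seed(config@seed)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    samples <- list()
    pools <- list()
    for (h in seq_len(config@nHosts)) {
        host <- sprintf("host%d", h)
        poolCdr3 <- .drawUniqueCdr3(config, config@publicPoolSize, seen)
        poolV <- .drawV(config, config@publicPoolSize)
        pools[[host]] <- poolCdr3
        for (s in seq_len(config@samplesPerHost)) {
            inPool <- stats::runif(config@publicPoolSize) < config@sharingProb
            nPub <- sum(inPool)
            nPriv <- max(0L, config@clonesPerSample - nPub)
            privCdr3 <- .drawUniqueCdr3(config, nPriv, seen)
            cdr3 <- c(poolCdr3[inPool], privCdr3)
            vG <- c(poolV[inPool], .drawV(config, nPriv))
            freq <- .drawSizes(config, length(cdr3))
            samples[[length(samples) + 1L]] <- new("TCRRepertoire",
                sampleId = sprintf("%s_s%d", host, s), category = host,
                clones = data.frame(cdr3 = cdr3, vGene = vG,
                                    frequency = as.numeric(freq),
                                    stringsAsFactors = FALSE))
        }
    }
    attr(samples, "publicPools") <- pools
    samples
}

#' Generate labeled samples from motif-defined specificity classes
#'
#' One sample per motif class: each CDR3 core carries the class consensus,
#' mutated per position with probability `mutationRate` (replacement drawn
#' from the amino-acid frequencies, so rate 1 destroys the motif entirely
#' and rate 0 reproduces the consensus exactly), flanked by random residues
#' up to the drawn total length, between the conserved termini. Class
#' separability is controlled by the mutation rate.
#'
#' @param config A [GeneratorConfig] with at least 2 `motifClasses`.
#' @return List of [TCRRepertoire], one per class, with the class name as
#'   category.
#' @export
generateLabeledClasses <- function(config) {
    stopifnot(is(config, "GeneratorConfig"))
    if (length(config@motifClasses) < 2L)
        stop("need at least 2 motif classes")
    cons <- vapply(config@motifClasses, `[[`, "", "consensus")
    rates <- vapply(config@motifClasses, `[[`, numeric(1), "mutationRate")
    if (anyDuplicated(cons) && any(rates[duplicated(cons) |
                                         duplicated(cons, fromLast = TRUE)] == 0))
        warning("identical consensus with mutation rate 0: degenerate labels")
    set.seed(config@seed)
    fixed <- nchar(config@prefix) + nchar(config@suffix)
    samples <- list()
    for (mc in config@motifClasses) {
        k <- nchar(mc$consensus)
        consChars <- strsplit(mc$consensus, "")[[1L]]
        cdr3 <- character(config@clonesPerSample)
        for (i in seq_len(config@clonesPerSample)) {
            L <- .drawLengths(config, 1L)
            extra <- L - fixed - k
            left <- if (extra > 0L) sample.int(extra + 1L, 1L) - 1L else 0L
            core <- consChars
            mut <- stats::runif(k) < mc$mutationRate
            if (any(mut))
                core[mut] <- sample(AA_ALPHABET, sum(mut), replace = TRUE,
                                    prob = config@aaFreqs)
            lf <- if (left > 0L) paste(sample(AA_ALPHABET, left,
                replace = TRUE, prob = config@aaFreqs), collapse = "") else ""
            rt <- if (extra - left > 0L) paste(sample(AA_ALPHABET,
                extra - left, replace = TRUE, prob = config@aaFreqs),
                collapse = "") else ""
            cdr3[i] <- paste0(config@prefix, lf, paste(core, collapse = ""),
                              rt, config@suffix)
        }
        vG <- .drawV(config, config@clonesPerSample)
        freq <- as.numeric(.drawSizes(config, config@clonesPerSample))
        samples[[length(samples) + 1L]] <- new("TCRRepertoire",
            sampleId = sprintf("class_%s", mc$name), category = mc$name,
            clones = data.frame(cdr3 = cdr3, vGene = vG, frequency = freq,
                                stringsAsFactors = FALSE))
    }
    samples
}
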