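#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib TCRdens, .registration = TRUE
NULL

setOldClass("hclust")
setOldClass(c("aeConfig", "list"))

#' The 20 standard amino acids, in the fixed alphabet order used throughout
#'
#' One-hot 21-blocks are laid out as these 20 residues followed by the stop
#' symbol `"!"` at index 21. The order is fixed so that saved models and
#' encodings are interchangeable.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Stop symbol appended to every CDR3 before one-hot encoding
#' @format Character scalar.
#' @export
STOP_SYMBOL <- "!"

#' Fixed one-hot encoding layout for a set of repertoires
#'
#' An `EncodingScheme` pins down everything needed to map a clone to its
#' fixed-length one-hot vector and back: the maximal CDR3 length `m`, the
#' 21-letter alphabet (20 amino acids + stop symbol), and the ordered V-gene
#' catalogue (empty when V genes are not encoded). The total dimension is
#' `n = 21 * (m + 1) + n_V`: one 21-block per CDR3 position, one block for
#' the appended stop symbol and right zero-padding, then the V one-hot.
#'
#' Any cross-sample operation (embedding, density, similarity) requires the
#' same scheme for all samples involved.
#'
#' @slot maxLen Integer, maximal CDR3 length `m` the scheme can encode.
#' @slot vCatalogue Character vector of V-gene names (possibly empty).
#' @export
setClass("EncodingScheme",
    representation(maxLen = "integer", vCatalogue = "character"),
    validity = function(object) {
        if (length(object@maxLen) != 1L || is.na(object@maxLen) ||
            object@maxLen < 1L)
            return("maxLen must be a single positive integer")
        if (anyDuplicated(object@vCatalogue))
            return("vCatalogue must not contain duplicates")
        TRUE
    })

#' A repertoire sample: a named collection of TCR clones
#'
#' One sequenced library. Each clone has a CDR3 amino-acid sequence over the
#' 20-letter alphabet, and optionally a V-gene name and a positive clone
#' frequency (raw count or proportion, stored as given). All clones in one
#' sample share the same presence/absence pattern for the V gene and the
#' frequency columns.
#'
#' @slot sampleId Character scalar identifying the sample.
#' @slot category Character scalar label (host, time point, specificity, ...).
#' @slot clones `data.frame` with columns `cdr3` (character), `vGene`
#'   (character or all `NA`), `frequency` (numeric or all `NA`).
#' @export
setClass("TCRRepertoire",
    representation(sampleId = "character", category = "character",
                   clones = "data.frame"),
    validity = function(object) {
        cl <- object@clones
        if (!all(c("cdr3", "vGene", "frequency") %in% names(cl)))
            return("clones must have columns cdr3, vGene, frequency")
        if (nrow(cl) == 0L)
            return("a repertoire must contain at least one clone")
        bad <- !grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                      cl$cdr3)
        if (any(bad))
            return(sprintf("%d CDR3(s) contain non-standard residues", sum(bad)))
        nav <- is.na(cl$vGene)
        if (any(nav) && !all(nav))
            return("vGene must be present for all clones or for none")
        naf <- is.na(cl$frequency)
        if (any(naf) && !all(naf))
            return("frequency must be present for all clones or for none")
        if (!all(naf) && any(cl$frequency <= 0))
            return("frequencies must be positive")
        TRUE
    })

#' Autoencoder model for TCR clones
#'
#' Holds the encoder/decoder weights, the [EncodingScheme] the model was
#' built for, the training configuration (see [aeConfig()]), and the
#' per-epoch training history. The four flavors are `E` (plain), `VE`
#' (+V gene), `EM` (+distance-preservation loss) and `VEM` (both).
#'
#' @slot weights Named list of weight matrices/bias vectors `W1..W6, b1..b6`.
#' @slot scheme [EncodingScheme] the model encodes under.
#' @slot config Named list, the training configuration.
#' @slot history `data.frame` of per-epoch losses (possibly empty if untrained).
#' @slot trained Logical scalar.
#' @export
setClass("TCRAutoencoder",
    representation(weights = "list", scheme = "EncodingScheme",
                   config = "list", history = "data.frame",
                   trained = "logical"))

#' One-vs-all clone classifier (frozen encoder + fully connected head)
#'
#' The head has four fully connected layers of sizes 30, 15, 10 and 1 with
#' Tanh activations (sigmoid on the last layer) and dropout 0.1 after the
#' second and third layers. It is trained on the frozen encoder's
#' 30-dimensional embeddings with a class-weighted binary cross-entropy.
#'
#' @slot head Named list of head weight matrices/bias vectors.
#' @slot encoder The [TCRAutoencoder] whose (frozen) encoder feeds the head.
#' @slot targetClass Character scalar: the positive class label.
#' @slot history `data.frame` of per-epoch training losses.
#' @export
setClass("TCRClassifier",
    representation(head = "list", encoder = "TCRAutoencoder",
                   targetClass = "character", history = "data.frame"))

#' Train/test split for one-vs-all classification
#'
#' Seeded without-replacement draw of `perSample` clones from each sample
#' into the training fraction; all remaining clones form the test fraction.
#'
#' @slot train,test `data.frame`s with columns `cdr3`, `vGene`, `frequency`,
#'   `sampleId`, `category`; disjoint at the clone-row level.
#' @export
setClass("LabeledSplit",
    representation(train = "data.frame", test = "data.frame"))

#' Kernel density estimate over embedded clones
#'
#' Per-query-point Gaussian-kernel density, stored on the log scale for
#' numerical stability (densities in 30 dimensions underflow the double
#' range on the natural scale).
#'
#' @slot logDensity Numeric vector, log density per query point.
#' @slot bandwidth Numeric scalar `h` used.
#' @slot weighted Logical, whether clone frequencies weighted the kernel sum.
#' @export
setClass("DensityEstimate",
    representation(logDensity = "numeric", bandwidth = "numeric",
                   weighted = "logical"),
    validity = function(object) {
        if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
            return("bandwidth must be a single positive number")
        TRUE
    })

#' Pairwise sample-by-sample similarity or distance matrix
#'
#' Square matrix over a fixed sample order, tagged with the method that
#' produced it (`KDE`, `KL` or `ED`) and its direction: `similarity`
#' (higher = closer; KDE log mean cross-density) or `distance` (lower =
#' closer; KL divergence, mean nearest-neighbour edit distance). KDE
#' matrices may be asymmetric (cross-density is directional).
#'
#' @slot values Numeric matrix with sample ids as dimnames.
#' @slot method Character, one of `"KDE"`, `"KL"`, `"ED"`.
#' @slot direction Character, `"similarity"` or `"distance"`.
#' @slot logScale Logical, whether `values` are on the log scale.
#' @export
setClass("SampleSimilarityMatrix",
    representation(values = "matrix", method = "character",
                   direction = "character", logScale = "logical"),
    validity = function(object) {
        v <- object@values
        if (nrow(v) != ncol(v)) return("matrix must be square")
        if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
            return("row and column names must be identical sample ids")
        if (!object@method %in% c("KDE", "KL", "ED"))
            return("method must be KDE, KL or ED")
        if (!object@direction %in% c("similarity", "distance"))
            return("direction must be similarity or distance")
        TRUE
    })

#' Hierarchical clustering of repertoire samples
#'
#' Average-linkage agglomeration of the distance form of a
#' [SampleSimilarityMatrix], cut into `k` clusters.
#'
#' @slot clusters Named integer vector, cluster index per sample.
#' @slot tree The `hclust` linkage tree.
#' @slot k Integer, number of clusters the tree was cut into.
#' @export
setClass("ClusterAssignment",
    representation(clusters = "integer", tree = "hclust", k = "integer"),
    validity = function(object) {
        if (length(unique(object@clusters)) > length(object@clusters))
            return("more clusters than samples")
        if (object@k < 1L) return("k must be >= 1")
        TRUE
    })

#' Configuration of the synthetic repertoire generator
#'
#' Defines the statistical structure of generated repertoires: CDR3s are a
#' conserved N-terminal prefix + a random core (length drawn from a unimodal
#' distribution over total lengths 8-18, letters from a realistic amino-acid
#' frequency vector, optionally seeded from a motif-class consensus with
#' per-position mutation) + a conserved C-terminal suffix; V genes drawn
#' from a catalogue with geometrically decaying usage; clone sizes from a
#' heavy-tailed (Pareto) law; host groups share clones from a per-host
#' public pool with a fixed inclusion probability.
#'
#' @slot nHosts,samplesPerHost,clonesPerSample Integers.
#' @slot lengths Integer vector of admissible total CDR3 lengths.
#' @slot lengthProbs Numeric, probabilities over `lengths` (normalized).
#' @slot aaFreqs Named numeric vector of 20 amino-acid frequencies.
#' @slot prefix,suffix Conserved terminal sequences.
#' @slot nVGenes Integer, size of the V-gene catalogue.
#' @slot cloneSizeAlpha Numeric > 1, Pareto tail exponent of clone sizes.
#' @slot publicPoolSize Integer, clones in each host's public pool.
#' @slot sharingProb Numeric in \[0,1\], per-sample inclusion probability of
#'   each public-pool clone.
#' @slot motifClasses List of `list(name=, consensus=, mutationRate=)`
#'   specificity groups (may be empty).
#' @slot seed Integer random seed.
#' @export
setClass("GeneratorConfig",
    representation(nHosts = "integer", samplesPerHost = "integer",
                   clonesPerSample = "integer", lengths = "integer",
                   lengthProbs = "numeric", aaFreqs = "numeric",
                   prefix = "character", suffix = "character",
                   nVGenes = "integer", cloneSizeAlpha = "numeric",
                   publicPoolSize = "integer", sharingProb = "numeric",
                   motifClasses = "list", seed = "integer"),
    validity = function(object) {
        if (length(object@lengths) != length(object@lengthProbs))
            return("lengths and lengthProbs must align")
        if (abs(sum(object@lengthProbs) - 1) > 1e-8)
            return("lengthProbs must sum to 1")
        if (!setequal(names(object@aaFreqs), AA_ALPHABET))
            return("aaFreqs must be named by the 20 standard amino acids")
        if (abs(sum(object@aaFreqs) - 1) > 1e-8)
            return("aaFreqs must sum to 1")
        if (object@cloneSizeAlpha <= 1)
            return("cloneSizeAlpha must exceed 1")
        if (object@sharingProb < 0 || object@sharingProb > 1)
            return("sharingProb must be in [0, 1]")
        nfix <- nchar(object@prefix) + nchar(object@suffix)
        if (any(object@lengths <= nfix))
            return("every admissible length must exceed prefix+suffix length")
        for (mc in object@motifClasses) {
            if (!all(c("name", "consensus", "mutationRate") %in% names(mc)))
                return("motif classes need name, consensus, mutationRate")
            if (mc$mutationRate < 0 || mc$mutationRate > 1)
                return("mutationRate must be in [0, 1]")
            if (nchar(mc$consensus) > min(object@lengths) - nfix)
                return("motif consensus longer than the shortest random core")
        }
        TRUE
    })
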