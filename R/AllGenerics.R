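#' @include AllClasses.R
NULL

#' Accessors for repertoire and scheme objects
#'
#' Small accessor generics, in place of direct slot access: `sampleId()` and
#' `category()` return the sample's identifiers, `clones()` its clone table,
#' `nClones()` the clone count, `cdr3s()` the CDR3 strings, `vGenes()` the
#' V-gene names (or `NA`s), `cloneFreqs()` the clone frequencies (or `NA`s);
#' `maxLen()`, `vCatalogue()` and `schemeDim()` describe an
#' [EncodingScheme]; `hasV()` reports whether V information is present.
#'
#' @param x A [TCRRepertoire] or [EncodingScheme].
#' @return See the individual descriptions above.
#' @name accessors
#' @examples
#' rep <- TCRRepertoire(c("CASSF", "CARGY"), sampleId = "s1")
#' nClones(rep)
#' cdr3s(rep)
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("category", function(x) standardGeneric("category"))
#' @rdname accessors
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))
#' @rdname accessors
#' @export
setGeneric("nClones", function(x) standardGeneric("nClones"))
#' @rdname accessors
#' @export
setGeneric("cdr3s", function(x) standardGeneric("cdr3s"))
#' @rdname accessors
#' @export
setGeneric("vGenes", function(x) standardGeneric("vGenes"))
#' @rdname accessors
#' @export
setGeneric("cloneFreqs", function(x) standardGeneric("cloneFreqs"))
#' @rdname accessors
#' @export
setGeneric("hasV", function(x) standardGeneric("hasV"))
#' @rdname accessors
#' @export
setGeneric("maxLen", function(x) standardGeneric("maxLen"))
#' @rdname accessors
#' @export
setGeneric("vCatalogue", function(x) standardGeneric("vCatalogue"))
#' @rdname accessors
#' @export
setGeneric("schemeDim", function(x) standardGeneric("schemeDim"))

#' @rdname accessors
setMethod("sampleId", "TCRRepertoire", function(x) x@sampleId)
#' @rdname accessors
setMethod("category", "TCRRepertoire", function(x) x@category)
#' @rdname accessors
setMethod("clones", "TCRRepertoire", function(x) x@clones)
#' @rdname accessors
setMethod("nClones", "TCRRepertoire", function(x) nrow(x@clones))
#' @rdname accessors
setMethod("cdr3s", "TCRRepertoire", function(x) x@clones$cdr3)
#' @rdname accessors
setMethod("vGenes", "TCRRepertoire", function(x) x@clones$vGene)
#' @rdname accessors
setMethod("cloneFreqs", "TCRRepertoire", function(x) x@clones$frequency)
#' @rdname accessors
setMethod("hasV", "TCRRepertoire", function(x) !anyNA(x@clones$vGene))
#' @rdname accessors
setMethod("maxLen", "EncodingScheme", function(x) x@maxLen)
#' @rdname accessors
setMethod("vCatalogue", "EncodingScheme", function(x) x@vCatalogue)
#' @rdname accessors
setMethod("hasV", "EncodingScheme", function(x) length(x@vCatalogue) > 0L)
#' @rdname accessors
setMethod("schemeDim", "EncodingScheme",
    function(x) 21L * (x@maxLen + 1L) + length(x@vCatalogue))

#' Matrix of similarity/distance values
#' @param x A [SampleSimilarityMatrix].
#' @return Numeric matrix with sample ids as dimnames.
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))
#' @rdname similarityValues
setMethod("similarityValues", "SampleSimilarityMatrix", function(x) x@values)

#' Per-sample cluster indices
#' @param x A [ClusterAssignment].
#' @return Named integer vector.
#' @export
setGeneric("clusterIndices", function(x) standardGeneric("clusterIndices"))
#' @rdname clusterIndices
setMethod("clusterIndices", "ClusterAssignment", function(x) x@clusters)

#' Log-scale density values of a kernel density estimate
#' @param x A [DensityEstimate].
#' @return Numeric vector of per-point log densities.
#' @export
setGeneric("logDensity", function(x) standardGeneric("logDensity"))
#' @rdname logDensity
setMethod("logDensity", "DensityEstimate", function(x) x@logDensity)

setMethod("show", "EncodingScheme", function(object) {
    cat(sprintf("EncodingScheme: m = %d, n = %d (%d 21-blocks%s)\n",
        object@maxLen, schemeDim(object), object@maxLen + 1L,
        if (hasV(object))
            sprintf(" + %d V genes", length(object@vCatalogue)) else ""))
})

setMethod("show", "TCRRepertoire", function(object) {
    cat(sprintf("TCRRepertoire '%s' (category '%s'): %d clones%s%s\n",
        object@sampleId, object@category, nClones(object),
        if (hasV(object)) ", with V genes" else "",
        if (!anyNA(object@clones$frequency)) ", with frequencies" else ""))
    cat("  CDR3 lengths:", paste(range(nchar(object@clones$cdr3)),
        collapse = "-"), "\n")
})

setMethod("show", "TCRAutoencoder", function(object) {
    cfg <- object@config
    cat(sprintf("TCRAutoencoder [%s]%s: n = %d -> %s -> n\n", cfg$flavor,
        if (object@trained) " (trained)" else " (untrained)",
        schemeDim(object@scheme),
        paste(cfg$layerSizes, collapse = " -> ")))
    if (object@trained && nrow(object@history))
        cat(sprintf("  %d epochs, final loss %.6g\n", nrow(object@history),
            object@history$loss[nrow(object@history)]))
})

setMethod("show", "TCRClassifier", function(object) {
    cat(sprintf("TCRClassifier: '%s' vs all, on a frozen %s encoder\n",
        object@targetClass, object@encoder@config$flavor))
})

setMethod("show", "SampleSimilarityMatrix", function(object) {
    cat(sprintf("SampleSimilarityMatrix [%s, %s%s]: %d x %d samples\n",
        object@method, object@direction,
        if (object@logScale) ", log scale" else "",
        nrow(object@values), ncol(object@values)))
})

setMethod("show", "ClusterAssignment", function(object) {
    cat(sprintf("ClusterAssignment: %d samples in %d clusters\n",
        length(object@clusters), object@k))
})

setMethod("show", "DensityEstimate", function(object) {
    cat(sprintf("DensityEstimate: %d points, h = %.4g%s\n",
        length(object@logDensity), object@bandwidth,
        if (object@weighted) ", frequency-weighted" else ""))
})

setMethod("show", "GeneratorConfig", function(object) {
    cat(sprintf(
        "GeneratorConfig: %d host(s) x %d sample(s) x %d clones, lengths %d-%d\n",
        object@nHosts, object@samplesPerHost, object@clonesPerSample,
        min(object@lengths), max(object@lengths)))
    if (length(object@motifClasses))
        cat("  motif classes:", paste(vapply(object@motifClasses, `[[`,
            "", "name"), collapse = ", "), "\n")
})
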