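#' @include AllClasses.R
NULL

.aaRegex <- function() paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")

#' Construct a repertoire sample from clone vectors
#'
#' Sequences are uppercased before validation; any clone whose CDR3 contains
#' a character outside the 20 standard amino acids (the non-IUPAC markers
#' `X`, `*`, `_`, `#`, but also any other residue) is dropped with a
#' message. V genes and frequencies must be given for all clones or none.
#'
#' @param cdr3 Character vector of CDR3 amino-acid sequences.
#' @param vGene Optional character vector of V-gene names, same length.
#' @param frequency Optional numeric vector of positive clone counts/weights.
#' @param sampleId Sample identifier (default `"sample"`).
#' @param category Category label (default `""`).
#' @return A [TCRRepertoire].
#' @examples
#' TCRRepertoire(c("CASSF", "CAX*S", "CASRG"), sampleId = "s1")  # one dropped
#' @export
TCRRepertoire <- function(cdr3, vGene = NULL, frequency = NULL,
                          sampleId = "sample", category = "") {
    cdr3 <- toupper(as.character(cdr3))
    if (is.null(vGene)) vGene <- rep(NA_character_, length(cdr3))
    if (is.null(frequency)) frequency <- rep(NA_real_, length(cdr3))
    stopifnot(length(vGene) == length(cdr3),
              length(frequency) == length(cdr3))
    keep <- grepl(.aaRegex(), cdr3)
    nd <- sum(!keep)
    if (nd > 0L)
        message(sprintf("Dropped %d clone(s) with non-standard residues", nd))
    if (!any(keep))
        stop("no clones remain after filtering non-standard residues")
    new("TCRRepertoire", sampleId = as.character(sampleId),
        category = as.character(category),
        clones = data.frame(cdr3 = cdr3[keep],
                            vGene = as.character(vGene)[keep],
                            frequency = as.numeric(frequency)[keep],
                            stringsAsFactors = FALSE))
}

#' Read a repertoire clone table or FASTA file
#'
#' Reads one sample from a TSV/CSV clone table with a header (column names
#' configurable) or from a FASTA file of bare CDR3 sequences (one per
#' record). Rows whose CDR3 contains a character outside the 20 standard
#' amino acids are dropped, and the drop count reported.
#'
#' @param path Path to the file.
#' @param cdr3Col,vCol,freqCol Column names (defaults `"cdr3"`, `"v"`,
#'   `"frequency"`). `vCol`/`freqCol` are used only when present in the
#'   header.
#' @param sampleId Sample identifier; defaults to the file name without
#'   extension.
#' @param category Category label.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"fasta"`.
#' @return A [TCRRepertoire].
#' @export
readRepertoire <- function(path, cdr3Col = "cdr3", vCol = "v",
                           freqCol = "frequency", sampleId = NULL,
                           category = "",
                           format = c("auto", "tsv", "csv", "fasta")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    if (format == "auto") {
        ext <- tolower(sub(".*\\.", "", path))
        format <- switch(ext, csv = "csv", fa = "fasta", fasta = "fasta",
                         "tsv")
    }
    if (format == "fasta") {
        lines <- readLines(path)
        seqs <- character(0); cur <- NULL
        for (ln in lines) {
            if (startsWith(ln, ">")) {
                if (!is.null(cur)) seqs <- c(seqs, cur)
                cur <- ""
            } else if (!is.null(cur)) cur <- paste0(cur, trimws(ln))
        }
        if (!is.null(cur)) seqs <- c(seqs, cur)
        if (!length(seqs)) stop("no sequences in FASTA file: ", path)
        return(TCRRepertoire(seqs, sampleId = sampleId, category = category))
    }
    tab <- utils::read.table(path, header = TRUE,
                             sep = if (format == "csv") "," else "\t",
                             stringsAsFactors = FALSE, comment.char = "",
                             quote = "\"")
    if (!cdr3Col %in% names(tab))
        stop(sprintf("CDR3 column '%s' not found in %s", cdr3Col, path))
    vG <- if (vCol %in% names(tab)) as.character(tab[[vCol]]) else NULL
    fq <- if (freqCol %in% names(tab)) as.numeric(tab[[freqCol]]) else NULL
    TCRRepertoire(tab[[cdr3Col]], vGene = vG, frequency = fq,
                  sampleId = sampleId, category = category)
}

#' Write a repertoire sample to a TSV clone table
#'
#' Columns `cdr3`, and `v` / `frequency` when present; readable back with
#' [readRepertoire()].
#'
#' @param rep A [TCRRepertoire].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRepertoire <- function(rep, path) {
    stopifnot(is(rep, "TCRRepertoire"))
    tab <- data.frame(cdr3 = cdr3s(rep), stringsAsFactors = FALSE)
    if (hasV(rep)) tab$v <- vGenes(rep)
    if (!anyNA(cloneFreqs(rep))) tab$frequency <- cloneFreqs(rep)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Build the one-hot encoding scheme for a set of samples
#'
#' Fixes `m` as the maximal CDR3 length over all clones and, when `useV`,
#' the V catalogue as the sorted distinct V names. The scheme must be built
#' once from the training corpus and shared by every sample that enters a
#' cross-sample operation; encoding a longer CDR3 under the scheme is an
#' error (silent truncation would corrupt distances).
#'
#' @param samples A [TCRRepertoire] or list of them.
#' @param useV Logical, include a V-gene one-hot block.
#' @return An [EncodingScheme] with dimension `21 * (m + 1) + n_V`.
#' @examples
#' reps <- TCRRepertoire(c("CASS", "CASSQY", "CASSF"))
#' buildScheme(reps)   # m = 6, n = 21 * 7 = 147
#' @export
buildScheme <- function(samples, useV = FALSE) {
    samples <- .asRepList(samples)
    allCdr3 <- unlist(lapply(samples, cdr3s), use.names = FALSE)
    if (!length(allCdr3)) stop("no clones present")
    vcat <- character(0)
    if (useV) {
        if (!all(vapply(samples, hasV, TRUE)))
            stop("useV requested but some clones lack a V gene")
        vcat <- sort(unique(unlist(lapply(samples, vGenes),
                                   use.names = FALSE)))
    }
    new("EncodingScheme", maxLen = max(nchar(allCdr3)), vCatalogue = vcat)
}

.asRepList <- function(samples) {
    if (is(samples, "TCRRepertoire")) return(list(samples))
    stopifnot(is.list(samples),
              all(vapply(samples, is, TRUE, "TCRRepertoire")))
    samples
}

# clone table (cdr3, vGene) from a repertoire, list, or data.frame
.cloneTable <- function(x) {
    if (is(x, "TCRRepertoire"))
        return(x@clones)
    if (is.data.frame(x)) {
        stopifnot("cdr3" %in% names(x))
        if (is.null(x$vGene)) x$vGene <- rep(NA_character_, nrow(x))
        if (is.null(x$frequency)) x$frequency <- rep(NA_real_, nrow(x))
        return(x)
    }
    if (is.character(x))
        return(data.frame(cdr3 = x, vGene = NA_character_,
                          frequency = NA_real_, stringsAsFactors = FALSE))
    if (is.list(x))
        return(do.call(rbind, lapply(x, .cloneTable)))
    stop("cannot interpret clones input")
}

#' One-hot encode clones under a scheme
#'
#' Each CDR3 of length `l` becomes `m + 1` blocks of 21: blocks `1..l`
#' one-hot encode the residues, block `l + 1` encodes the appended stop
#' symbol, blocks `l + 2 .. m + 1` are all-zero right padding; the V-gene
#' one-hot (when the scheme carries a catalogue) is concatenated last.
#'
#' @param x A [TCRRepertoire], character vector of CDR3s, or clone
#'   `data.frame` with columns `cdr3` (and `vGene` if the scheme uses V).
#' @param scheme An [EncodingScheme].
#' @return Numeric matrix, one row per clone, `schemeDim(scheme)` columns.
#' @examples
#' sc <- new("EncodingScheme", maxLen = 3L, vCatalogue = character(0))
#' encodeClones("CA", sc)  # 84 columns: C, A, stop, all-zero block
#' @export
encodeClones <- function(x, scheme) {
    stopifnot(is(scheme, "EncodingScheme"))
    tab <- .cloneTable(x)
    m <- scheme@maxLen
    lens <- nchar(tab$cdr3)
    if (any(lens > m))
        stop(sprintf("%d CDR3(s) longer than scheme maxLen = %d",
                     sum(lens > m), m))
    nV <- length(scheme@vCatalogue)
    if (nV > 0L) {
        if (anyNA(tab$vGene))
            stop("scheme has a V block but some clones lack a V gene")
        vIdx <- match(tab$vGene, scheme@vCatalogue)
        if (anyNA(vIdx))
            stop("V gene(s) not in the scheme catalogue: ",
                 paste(unique(tab$vGene[is.na(vIdx)]), collapse = ", "))
    }
    n <- 21L * (m + 1L) + nV
    N <- nrow(tab)
    X <- matrix(0, N, n)
    alpha <- c(AA_ALPHABET, STOP_SYMBOL)
    # residue indices per clone, vectorized over a flat position list
    chars <- strsplit(paste0(tab$cdr3, STOP_SYMBOL), "")
    rows <- rep.int(seq_len(N), lens + 1L)
    pos <- sequence(lens + 1L)
    aidx <- match(unlist(chars, use.names = FALSE), alpha)
    X[cbind(rows, (pos - 1L) * 21L + aidx)] <- 1
    if (nV > 0L)
        X[cbind(seq_len(N), 21L * (m + 1L) + vIdx)] <- 1
    X
}

#' Decode one-hot (or soft decoder-output) vectors back to sequences
#'
#' Per 21-block, the residue is the argmax (ties broken toward the lowest
#' index). The reconstructed sequence ends at the leftmost block whose
#' argmax is the stop symbol, or at block `m + 1`; everything to the right
#' of the stop is ignored. The V gene, when the scheme has a V block, is
#' the argmax of that block. Any real-valued matrix decodes.
#'
#' @param X Numeric matrix with `schemeDim(scheme)` columns (rows = clones).
#' @param scheme An [EncodingScheme].
#' @return `data.frame` with columns `cdr3` and `vGene` (`NA` without V).
#' @export
decodeOneHot <- function(X, scheme) {
    stopifnot(is(scheme, "EncodingScheme"))
    if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
    m <- scheme@maxLen
    nV <- length(scheme@vCatalogue)
    if (ncol(X) != 21L * (m + 1L) + nV)
        stop(sprintf("expected %d columns, got %d", 21L * (m + 1L) + nV,
                     ncol(X)))
    N <- nrow(X)
    alpha <- c(AA_ALPHABET, STOP_SYMBOL)
    # argmax per 21-block: N x (m+1) matrix of alphabet indices
    am <- matrix(0L, N, m + 1L)
    for (b in seq_len(m + 1L)) {
        block <- X[, ((b - 1L) * 21L + 1L):(b * 21L), drop = FALSE]
        am[, b] <- max.col(block, ties.method = "first")
    }
    isStop <- am == 21L
    cdr3 <- vapply(seq_len(N), function(i) {
        stopAt <- which(isStop[i, ])
        end <- if (length(stopAt)) stopAt[1L] - 1L else m + 1L
        if (end == 0L) "" else
            paste(alpha[am[i, seq_len(end)]], collapse = "")
    }, character(1))
    vG <- rep(NA_character_, N)
    if (nV > 0L) {
        vb <- X[, (21L * (m + 1L) + 1L):ncol(X), drop = FALSE]
        vG <- scheme@vCatalogue[max.col(vb, ties.method = "first")]
    }
    data.frame(cdr3 = cdr3, vGene = vG, stringsAsFactors = FALSE)
}

#' Save / load an encoded matrix with its scheme sidecar
#'
#' Writes the encoded matrix as TSV together with a JSON sidecar recording
#' the scheme (`m`, alphabet order, V catalogue) so the encoding is
#' self-describing.
#'
#' @param X Encoded matrix from [encodeClones()].
#' @param scheme The [EncodingScheme] used.
#' @param path Output path for the matrix; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
saveEncoded <- function(X, scheme, path) {
    utils::write.table(X, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(
        list(m = scheme@maxLen, alphabet = c(AA_ALPHABET, STOP_SYMBOL),
             vCatalogue = scheme@vCatalogue),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveEncoded
#' @return `loadEncoded`: list with elements `X` (matrix) and `scheme`.
#' @export
loadEncoded <- function(path) {
    X <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(X) <- NULL
    side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    scheme <- new("EncodingScheme", maxLen = as.integer(side$m),
                  vCatalogue = as.character(side$vCatalogue))
    list(X = X, scheme = scheme)
}
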