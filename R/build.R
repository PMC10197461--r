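# --- Concatenation -----------------------------------------------------------

# Concatenate documents (integer symbol vectors, codes >= 1) into one text,
# appending one sentinel per document. Sentinels are negative (-D .. -1,
# ascending with document order), so they rank below every data symbol and
# among themselves by document order, giving a deterministic suffix order.
.buildConcat <- function(documents, labels0) {
    D <- length(documents)
    stopifnot(D >= 1L, length(labels0) == D)
    lens <- vapply(documents, length, integer(1))
    if (any(lens == 0L)) stop("empty document in collection")
    if (any(vapply(documents, function(d) any(d < 1L), logical(1))))
        stop("document symbols must be positive integers")
    sent <- seq_len(D) - D - 1L
    text <- unlist(mapply(function(d, s) c(d, s), documents, sent,
                          SIMPLIFY = FALSE), use.names = FALSE)
    docStart0 <- cumsum(c(0L, (lens + 1L)[-D]))
    list(symbols = text, docStart0 = as.integer(docStart0),
         docLabels0 = as.integer(labels0), n = length(text), nDocs = D)
}

# Split a concatenated text back into its documents (inverse of .buildConcat).
.splitConcat <- function(concat) {
    ends <- which(concat$symbols < 0L)
    starts <- c(1L, head(ends, -1L) + 1L)
    mapply(function(s, e) concat$symbols[s:(e - 1L)], starts, ends,
           SIMPLIFY = FALSE)
}

# --- Core construction -------------------------------------------------------

# Build the run-length BWT, thresholds, per-symbol run directory and
# (optionally) the sampled document array and SA samples over a
# concatenated text. All rows and text offsets in the result are 0-based.
.buildCore <- function(concat, docArray = TRUE, msSupport = FALSE) {
    text <- concat$symbols
    n <- length(text)
    sa0 <- sa_build_cpp(text)
    bwt <- text[ifelse(sa0 == 0L, n, sa0)]

    rl <- rle(bwt)
    runChars <- as.integer(rl$values)
    runLengths <- as.integer(rl$lengths)
    r <- length(runChars)
    runStarts0 <- cumsum(c(0L, runLengths[-r]))
    # occurrences of each run's character before the run's first row
    occBefore <- as.integer(ave(runLengths, runChars,
                                FUN = function(x) cumsum(x) - x))

    symVals <- sort(unique(text))
    counts <- tabulate(match(text, symVals), nbins = length(symVals))
    countsBelow <- as.integer(cumsum(c(0L, counts[-length(counts)])))

    # per-symbol run directory, runs in BWT row order within each symbol
    ord <- order(runChars, runStarts0)
    oChar <- runChars[ord]
    si <- match(oChar, symVals)
    nRunsPerSym <- tabulate(si, nbins = length(symVals))
    symOff <- as.integer(cumsum(c(0L, nRunsPerSym)))
    cStart <- as.integer(runStarts0[ord])
    cEnd <- as.integer(runStarts0[ord] + runLengths[ord] - 1L)
    cIdx <- as.integer(ord - 1L) # 0-based global run index

    # thresholds: one per gap between consecutive same-character runs
    nGaps <- pmax(nRunsPerSym - 1L, 0L)
    thrOff <- as.integer(cumsum(c(0L, nGaps)))
    if (sum(nGaps) > 0L) {
        gi <- sequence(nGaps) + rep(symOff[-length(symOff)], nGaps)
        gapE <- cEnd[gi]
        gapS <- cStart[gi + 1L]
        lcp <- lcp_kasai_cpp(text, sa0)
        thrRows <- thresholds_build_cpp(lcp, gapE, gapS)
    } else {
        thrRows <- integer(0)
    }

    core <- list(n = as.integer(n), runStarts = as.integer(runStarts0),
                 runChars = runChars, runLengths = runLengths,
                 occBefore = occBefore, symVals = as.integer(symVals),
                 countsBelow = countsBelow, symOff = symOff,
                 cStart = cStart, cEnd = cEnd, cIdx = cIdx,
                 thrOff = thrOff, thrRows = as.integer(thrRows))

    saF <- sa0[runStarts0 + 1L]
    saL <- sa0[runStarts0 + runLengths]
    if (docArray) {
        docOf <- function(p0) findInterval(p0, concat$docStart0)
        core$firstLabel <- concat$docLabels0[docOf(saF)]
        core$lastLabel <- concat$docLabels0[docOf(saL)]
    }
    if (msSupport) {
        core$saFirst <- as.integer(saF)
        core$saLast <- as.integer(saL)
        core$text <- as.integer(text)
    }
    core
}

# --- User-facing builder -----------------------------------------------------

#' Build a pangenome index
#'
#' Digests the reference documents (unless \code{digest = FALSE}), adds the
#' reverse complement of each document under the same class label (so reads
#' can be queried in their given orientation), concatenates everything with
#' per-document sentinels, and constructs the run-length BWT with thresholds,
#' the sampled document array and, optionally, SA samples plus text access
#' for exact matching statistics. A null pseudomatching-length (PML)
#' threshold is derived from character-reversed reference substrings unless
#' \code{nullReads = 0}.
#'
#' @param sequences character vector or \code{DNAStringSet} of reference
#'   documents.
#' @param labels class label per document (character or factor); defaults to
#'   a single class \code{"ref"}.
#' @param scheme \linkS4class{MinimizerScheme} used for digestion.
#' @param alphabet \code{"minimizer"} (each k-mer one symbol) or \code{"dna"}.
#' @param digest digest the documents (TRUE) or index the raw DNA (FALSE;
#'   forces the DNA alphabet).
#' @param includeRevComp add the reverse complement of every document.
#' @param docArray build the sampled document array (2r class labels).
#' @param msSupport retain SA samples at run boundaries and the text, enabling
#'   \code{\link{computeMs}}.
#' @param nullReads,nullReadLength,nullMinCount,nullSeed parameters of the
#'   null PML distribution used to set the classification threshold: number
#'   of reversed substrings, their length in bases, the occurrence floor of
#'   the threshold rule, and the sampling seed.
#' @return A \linkS4class{PangenomeIndex}.
#' @examples
#' idx <- buildIndex(c(a = strrep("ACGTTGCA", 50)), nullReads = 50,
#'                   nullReadLength = 100)
#' idx
#' @export
buildIndex <- function(sequences, labels = NULL,
                       scheme = MinimizerScheme(),
                       alphabet = c("minimizer", "dna"),
                       digest = TRUE, includeRevComp = TRUE,
                       docArray = TRUE, msSupport = FALSE,
                       nullReads = 500L, nullReadLength = 2000L,
                       nullMinCount = 5L, nullSeed = 7L) {
    alphabet <- match.arg(alphabet)
    seqs <- as.character(sequences)
    if (length(seqs) == 0L) stop("no reference sequences given")
    if (is.null(labels)) labels <- rep("ref", length(seqs))
    labels <- as.character(labels)
    stopifnot(length(labels) == length(seqs))
    if (!digest) alphabet <- "dna"

    classNames <- sort(unique(labels))
    labels0 <- match(labels, classNames) - 1L

    docSeqs <- seqs
    docLabels0 <- labels0
    if (includeRevComp) {
        docSeqs <- c(docSeqs, revComp(seqs))
        docLabels0 <- c(docLabels0, labels0)
    }

    documents <- lapply(docSeqs, function(s) {
        if (digest) digestSequence(s, scheme, alphabet)@symbols
        else .dnaCodes(s)
    })
    if (!digest && any(vapply(documents, function(d) any(d == 0L), logical(1))))
        stop("undigested references must be ACGT-only")
    keep <- vapply(documents, length, integer(1)) > 0L
    if (!any(keep)) stop("all documents digest to the empty sequence")
    if (!all(keep))
        warning(sum(!keep), " document(s) shorter than w dropped from the index")
    concat <- .buildConcat(documents[keep], docLabels0[keep])

    core <- .buildCore(concat, docArray = docArray, msSupport = msSupport)
    idx <- new("PangenomeIndex",
               scheme = if (digest) scheme else NULL,
               alphabet = alphabet, digested = digest, core = core,
               nDocs = concat$nDocs, docLabels = concat$docLabels0,
               classNames = classNames, docArray = docArray,
               msSupport = msSupport, nullDist = integer(0),
               nullThreshold = NA_integer_, version = 1L)
    validObject(idx)
    if (nullReads > 0L) {
        nd <- sampleNullPmls(idx, seqs, nReads = nullReads,
                             readLength = nullReadLength, seed = nullSeed)
        idx@nullDist <- nd
        idx@nullThreshold <- pmlThreshold(nd, minCount = nullMinCount)
    }
    idx
}

# --- Accessors ---------------------------------------------------------------

#' Index accessors
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @return \code{indexLength}: total length n of the concatenated (digested)
#'   text including sentinels. \code{bwtRunCount}: the number r of maximal
#'   same-character BWT runs. \code{compressionRatio}: n/r.
#'   \code{classLabels}: the class names. \code{nullThreshold}: the stored
#'   null PML threshold (NA if not computed).
#' @export
indexLength <- function(index) index@core$n

#' @rdname indexLength
#' @export
bwtRunCount <- function(index) length(index@core$runStarts)

#' @rdname indexLength
#' @export
compressionRatio <- function(index) index@core$n / length(index@core$runStarts)

#' @rdname indexLength
#' @export
classLabels <- function(index) index@classNames

#' @rdname indexLength
#' @export
nullThreshold <- function(index) index@nullThreshold
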