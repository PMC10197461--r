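#' @import methods
NULL

#' Minimizer scheme
#'
#' Parameters of a minimizer digestion scheme: within every window of
#' \code{w} consecutive bases, the constituent k-mer with the minimal hash
#' value (leftmost on ties) is selected as that window's minimizer.
#'
#' @slot k small window size in bases (k-mer length).
#' @slot w large window size in bases; must exceed \code{k}.
#' @slot seed integer seed mixed into the k-mer hash; fixed per index so that
#'   digests (and hence indexes) are reproducible.
#' @export
setClass("MinimizerScheme",
         representation(k = "integer", w = "integer", seed = "integer"),
         prototype(k = 4L, w = 11L, seed = 42L))

setValidity("MinimizerScheme", function(object) {
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        return("k must be a single integer >= 1")
    if (length(object@w) != 1L || is.na(object@w) || object@w <= object@k)
        return("w must be a single integer > k")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed must be a single integer")
    TRUE
})

#' Construct a MinimizerScheme
#'
#' @param k k-mer length in bases (default 4).
#' @param w window length in bases (default 11, the package default scheme).
#' @param seed hash seed (default 42).
#' @return A \linkS4class{MinimizerScheme} object.
#' @examples
#' MinimizerScheme(k = 4, w = 11)
#' @export
MinimizerScheme <- function(k = 4L, w = 11L, seed = 42L) {
    new("MinimizerScheme", k = as.integer(k), w = as.integer(w),
        seed = as.integer(seed))
}

setMethod("show", "MinimizerScheme", function(object) {
    cat(sprintf("MinimizerScheme(k = %d, w = %d, seed = %d)\n",
                object@k, object@w, object@seed))
})

#' Digested (or plain-encoded) sequence
#'
#' Integer symbol encoding of a DNA sequence: either its minimizer digest
#' (one symbol per retained minimizer, equal-minimizer runs collapsed) or a
#' direct base encoding when digestion is disabled.
#'
#' @slot symbols integer symbol codes (1..4^k over the minimizer alphabet,
#'   1..4 over the DNA alphabet).
#' @slot sourceLength original sequence length in bases.
#' @slot alphabet \code{"minimizer"} or \code{"dna"}.
#' @slot scheme the \linkS4class{MinimizerScheme} used, or \code{NULL} when
#'   the sequence was not digested.
#' @export
setClass("DigestSequence",
         representation(symbols = "integer", sourceLength = "integer",
                        alphabet = "character", scheme = "ANY"))

setMethod("show", "DigestSequence", function(object) {
    cat(sprintf("DigestSequence: %d symbols (%s alphabet) from %d bases\n",
                length(object@symbols), object@alphabet, object@sourceLength))
})

#' Pangenome index: run-length BWT, thresholds, sampled document array
#'
#' The compressed index over a (optionally minimizer-digested) concatenated
#' document collection. The core slot holds flat integer arrays (all rows and
#' text offsets 0-based): the run-length encoded BWT (\code{runStarts},
#' \code{runChars}, \code{runLengths}, \code{occBefore}), the symbol table
#' (\code{symVals}, \code{countsBelow}), per-symbol run directories and
#' threshold rows (\code{symOff}, \code{cStart}, \code{cEnd}, \code{cIdx},
#' \code{thrOff}, \code{thrRows}), optional sampled document array
#' (\code{firstLabel}, \code{lastLabel}; 2r entries) and optional SA samples
#' plus text for matching-statistics support.
#'
#' @slot scheme MinimizerScheme (or NULL when digestion is disabled).
#' @slot alphabet "minimizer" or "dna".
#' @slot digested logical; whether documents and queries are digested.
#' @slot core list of integer vectors (see Description).
#' @slot nDocs number of indexed documents (after adding reverse complements).
#' @slot docLabels 0-based class id per document.
#' @slot classNames class label names (length c).
#' @slot docArray logical; sampled document array present.
#' @slot msSupport logical; SA samples + text retained for exact MS.
#' @slot nullDist named integer vector of null PML counts (may be empty).
#' @slot nullThreshold integer classification threshold (NA if not computed).
#' @slot version index format version.
#' @export
setClass("PangenomeIndex",
         representation(scheme = "ANY", alphabet = "character",
                        digested = "logical", core = "list",
                        nDocs = "integer", docLabels = "integer",
                        classNames = "character", docArray = "logical",
                        msSupport = "logical", nullDist = "integer",
                        nullThreshold = "integer", version = "integer"))

setValidity("PangenomeIndex", function(object) {
    core <- object@core
    need <- c("n", "runStarts", "runChars", "runLengths", "occBefore",
              "symVals", "countsBelow", "symOff", "cStart", "cEnd", "cIdx",
              "thrOff", "thrRows")
    if (!all(need %in% names(core)))
        return(paste("core is missing:", paste(setdiff(need, names(core)), collapse = ", ")))
    r <- length(core$runStarts)
    if (sum(core$runLengths) != core$n)
        return("sum(runLengths) != n")
    if (r > 1L && any(core$runChars[-1] == core$runChars[-r]))
        return("adjacent BWT runs share a character")
    if (object@docArray) {
        if (is.null(core$firstLabel) || length(core$firstLabel) != r ||
            length(core$lastLabel) != r)
            return("sampled document array must hold 2r labels")
        labs <- c(core$firstLabel, core$lastLabel)
        if (any(labs < 0L) || any(labs >= length(object@classNames)))
            return("document-array labels out of range")
    }
    if (object@msSupport &&
        (is.null(core$saFirst) || is.null(core$text)))
        return("msSupport requires SA samples and text access")
    if (length(object@docLabels) != object@nDocs)
        return("docLabels must have one entry per document")
    TRUE
})

setMethod("show", "PangenomeIndex", function(object) {
    core <- object@core
    r <- length(core$runStarts)
    cat("PangenomeIndex\n")
    cat(sprintf("  alphabet: %s%s\n", object@alphabet,
                if (object@digested) sprintf(" (digested, k = %d, w = %d, seed = %d)",
                                             object@scheme@k, object@scheme@w,
                                             object@scheme@seed)
                else " (no digestion)"))
    cat(sprintf("  documents: %d in %d class(es): %s\n", object@nDocs,
                length(object@classNames),
                paste(object@classNames, collapse = ", ")))
    cat(sprintf("  n = %d, r = %d, n/r = %.2f\n", core$n, r, core$n / r))
    cat(sprintf("  doc array: %s; MS support: %s; null PML threshold: %s\n",
                object@docArray, object@msSupport,
                ifelse(is.na(object@nullThreshold), "not set",
                       object@nullThreshold)))
})
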