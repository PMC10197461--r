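#' Hash a k-mer
#'
#' Deterministic 53-bit hash of a DNA k-mer under an integer seed. Equal
#' k-mers hash equally under equal seeds, across processes; the hash is the
#' one used for minimizer selection.
#'
#' @param kmer character vector of ACGT-only k-mers.
#' @param seed integer seed (default: the seed of the default scheme).
#' @return numeric vector of hash values (exactly representable integers
#'   below 2^53).
#' @examples
#' kmerHash("ACGT")
#' @export
kmerHash <- function(kmer, seed = 42L) {
    kmer_hash_cpp(as.character(kmer), as.integer(seed))
}

#' Select the minimizer of one window
#'
#' Among the \code{w - k + 1} constituent k-mers of a length-\code{w} window,
#' returns the one with minimal hash value, breaking ties by leftmost offset.
#'
#' @param window single ACGT string of length exactly \code{w}.
#' @param scheme a \linkS4class{MinimizerScheme}.
#' @return list with elements \code{kmer} and \code{offset} (0-based offset
#'   of the minimizer within the window).
#' @examples
#' windowMinimizer("ACGTACGT", MinimizerScheme(k = 4, w = 8))
#' @export
windowMinimizer <- function(window, scheme = MinimizerScheme()) {
    window <- as.character(window)
    if (length(window) != 1L || nchar(window) != scheme@w)
        stop("window must be a single string of length w = ", scheme@w)
    starts <- seq_len(scheme@w - scheme@k + 1L)
    kmers <- substring(window, starts, starts + scheme@k - 1L)
    h <- kmerHash(kmers, scheme@seed)
    i <- which.min(h) # leftmost minimum
    list(kmer = kmers[i], offset = i - 1L)
}

#' Encode / decode a minimizer as an alphabet symbol
#'
#' Bijective map between ACGT k-mers and the contiguous symbol codes
#' \code{1..4^k} of the minimizer alphabet (A=0, C=1, G=2, T=3, base 4,
#' most-significant base first). Sentinel codes used by the index are
#' negative, so the data range is never shadowed.
#'
#' @param kmer character vector of ACGT k-mers.
#' @return integer symbol codes.
#' @examples
#' encodeMinimizer("AAAA") # 1
#' decodeMinimizer(256, k = 4) # "TTTT"
#' @export
encodeMinimizer <- function(kmer) {
    kmer <- as.character(kmer)
    vapply(kmer, function(km) {
        b <- match(strsplit(km, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
        if (anyNA(b)) stop("k-mer contains a non-ACGT character: '", km, "'")
        as.integer(sum(b * 4^(rev(seq_along(b)) - 1)) + 1L)
    }, integer(1), USE.NAMES = FALSE)
}

#' @param code integer symbol codes in 1..4^k.
#' @param k k-mer length.
#' @rdname encodeMinimizer
#' @export
decodeMinimizer <- function(code, k = 4L) {
    vapply(as.integer(code), function(x) {
        if (is.na(x) || x < 1L || x > 4^k) stop("code out of range for k = ", k)
        x <- x - 1L
        b <- integer(k)
        for (i in k:1) { b[i] <- x %% 4L; x <- x %/% 4L }
        paste(c("A", "C", "G", "T")[b + 1L], collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Reverse-complement DNA
#'
#' Thin wrapper over \code{Biostrings::reverseComplement}; \code{N} maps to
#' \code{N}.
#'
#' @param seq character vector of DNA strings (ACGTN).
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGT")
#' @export
revComp <- function(seq) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Digest a sequence into minimizer symbols
#'
#' Slides the length-\code{w} window one base at a time over \code{seq}; at
#' each position the window minimizer is selected (leftmost minimal hash) and
#' appended whenever its value differs from the previously appended one
#' (equal-minimizer runs collapse to a single symbol). Windows containing
#' non-ACGT characters are skipped, equivalent to digesting ACGT segments
#' independently. A sequence shorter than \code{w} digests to the empty
#' sequence.
#'
#' Under the \code{"minimizer"} alphabet each selected k-mer becomes one
#' symbol (code in 1..4^k); under the \code{"dna"} alphabet the selected
#' k-mers are concatenated and re-encoded base by base (codes 1..4).
#'
#' @param seq single DNA string (or DNAString).
#' @param scheme a \linkS4class{MinimizerScheme}.
#' @param alphabet \code{"minimizer"} (default) or \code{"dna"}.
#' @return A \linkS4class{DigestSequence}.
#' @examples
#' digestSequence(strrep("A", 10), MinimizerScheme(k = 4, w = 8))
#' @export
digestSequence <- function(seq, scheme = MinimizerScheme(),
                           alphabet = c("minimizer", "dna")) {
    alphabet <- match.arg(alphabet)
    seq <- as.character(seq)
    stopifnot(length(seq) == 1L)
    codes <- digest_cpp(seq, scheme@k, scheme@w, scheme@seed)
    if (alphabet == "dna" && length(codes)) {
        bases <- paste(decodeMinimizer(codes, scheme@k), collapse = "")
        codes <- .dnaCodes(bases)
    }
    new("DigestSequence", symbols = codes, sourceLength = nchar(seq),
        alphabet = alphabet, scheme = scheme)
}

# Base encoding for undigested DNA: A,C,G,T -> 1..4; anything else -> 0
# (an unknown symbol at query time; rejected at build time).
.dnaCodes <- function(seq) {
    x <- utf8ToInt(toupper(seq))
    codes <- integer(length(x))
    codes[x == utf8ToInt("A")] <- 1L
    codes[x == utf8ToInt("C")] <- 2L
    codes[x == utf8ToInt("G")] <- 3L
    codes[x == utf8ToInt("T")] <- 4L
    codes
}
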