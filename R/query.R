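# Encode a read into the index's symbol space. Digested indexes digest the
# read with the index's own scheme; undigested DNA indexes pass bases through
# (non-ACGT becomes the unknown symbol 0). Accepts a character string,
# DNAString, DigestSequence, or an already-encoded integer vector.
.encodeRead <- function(index, read) {
    if (is.integer(read)) return(read)
    if (methods::is(read, "DigestSequence")) {
        if (index@digested) {
            s <- index@scheme
            rs <- read@scheme
            if (read@alphabet != index@alphabet || is.null(rs) ||
                rs@k != s@k || rs@w != s@w || rs@seed != s@seed)
                stop("digest scheme/alphabet does not match the index")
        }
        return(read@symbols)
    }
    read <- as.character(read)
    stopifnot(length(read) == 1L)
    if (index@digested)
        digestSequence(read, index@scheme, index@alphabet)@symbols
    else .dnaCodes(read)
}

.freshState <- function(index) {
    sa0 <- if (index@msSupport) index@core$saFirst[1L] else -1L
    structure(list(row = 0L, len = 0L, lastLabel = -1L, sa = sa0,
                   consumed = 0L), class = "minidex_state")
}

#' LF mapping
#'
#' Maps a BWT row to the row of the suffix extended one character to the
#' left, computed from the run-length encoded BWT.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param rows integer vector of 0-based BWT rows.
#' @return integer vector of 0-based rows (a permutation of 0..n-1 when
#'   applied to all rows).
#' @export
lfMap <- function(index, rows) {
    rows <- as.integer(rows)
    if (any(rows < 0L | rows >= index@core$n)) stop("row out of range")
    lf_cpp(index@core, rows)
}

#' Compute pseudomatching lengths (PMLs)
#'
#' Streams the read right-to-left over the run-length BWT. At each step, if
#' the current BWT row's character equals the next read symbol (case 1) the
#' match length increments and the LF mapping advances the row; otherwise
#' (case 2) the thresholds pick the nearer same-character run boundary that
#' preserves the longer match, the length resets to 0, and (when the sampled
#' document array is present) the boundary's class label is recorded. The
#' emitted lengths, reported in left-to-right read order, are the PMLs; the
#' recorded labels form the class vector \code{ca} (NA before the first
#' case 2). A symbol absent from the index alphabet emits 0 and leaves the
#' row unchanged.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param read character DNA string, \linkS4class{DigestSequence}, or integer
#'   symbol vector.
#' @param state optional state returned by a previous call on a later
#'   (rightward) portion of the same read; see \code{\link{resumePmls}}.
#' @return list with \code{pml} (integer, one value per processed symbol),
#'   \code{ca} (integer class ids, 1-based into \code{classLabels(index)},
#'   NA for "none"), and \code{state} (resumable).
#' @examples
#' idx <- buildIndex(c(a = strrep("ACGGTTAC", 40)), nullReads = 0)
#' computePmls(idx, "ACGGTTACACGGTTAC")$pml
#' @export
computePmls <- function(index, read, state = NULL) {
    symbols <- .encodeRead(index, read)
    if (is.null(state)) state <- .freshState(index)
    if (!inherits(state, "minidex_state")) stop("invalid resume state")
    res <- query_run_cpp(index@core, symbols, state$row, state$len,
                         state$lastLabel, state$sa, FALSE)
    ca <- res$ca
    ca[ca < 0L] <- NA_integer_
    newState <- structure(c(res$state,
                            list(consumed = state$consumed + length(symbols))),
                          class = "minidex_state")
    list(pml = res$pml, ca = ca + 1L, state = newState)
}

#' Resume a paused PML computation
#'
#' The matching process consumes the read right-to-left, so a read arriving
#' in chunks is processed right chunk first; \code{resumePmls} extends the
#' computation with the next chunk to the left. Concatenating the outputs
#' (left chunk's vectors first) is identical to a single-shot computation on
#' the full read.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param state state returned by \code{\link{computePmls}} or a previous
#'   \code{resumePmls} on the rightward portion of the same read.
#' @param read the additional, left-extending chunk.
#' @return As \code{\link{computePmls}}: vectors for the new chunk only,
#'   plus the updated state.
#' @export
resumePmls <- function(index, state, read) {
    if (!inherits(state, "minidex_state")) stop("resume requires a state from computePmls")
    computePmls(index, read, state = state)
}

#' Compute exact matching statistics (MS)
#'
#' Two-pass computation: the first pass is the threshold-guided PML pass,
#' additionally tracking a text offset for the current row via SA samples at
#' run boundaries; the second pass turns each offset into the exact matching
#' statistic by direct longest-common-extension against the stored text.
#' \code{MS[i]} is the length of the longest prefix of the read's i-th
#' suffix occurring anywhere in the indexed collection (matches never span
#' documents). Requires an index built with \code{msSupport = TRUE}.
#'
#' @inheritParams computePmls
#' @return list with \code{ms} and \code{pml} integer vectors (both in
#'   left-to-right read order; \code{pml <= ms} positionwise).
#' @export
computeMs <- function(index, read) {
    if (!index@msSupport)
        stop("index lacks matching-statistics support; rebuild with msSupport = TRUE")
    symbols <- .encodeRead(index, read)
    state <- .freshState(index)
    res <- query_run_cpp(index@core, symbols, state$row, state$len,
                         state$lastLabel, state$sa, TRUE)
    ms <- ms_extend_cpp(index@core$text, symbols, res$off)
    list(ms = ms, pml = res$pml)
}
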