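# Run a function with a temporary RNG state so library calls do not disturb
# the caller's random stream.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Sample the null PML distribution
#'
#' Extracts substrings uniformly from the original (pre-digest) reference
#' documents, character-reverses them (not reverse-complement), pushes them
#' through the same digestion and query path as real reads, and pools the
#' resulting PML values. Reversed substrings keep the reference's base
#' composition but should not match it, so their PMLs estimate the lengths
#' expected by chance.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param sequences the original reference sequences (character or
#'   DNAStringSet).
#' @param nReads number of substrings to draw (default 500).
#' @param readLength substring length in bases (default 2000); references
#'   shorter than this are used whole, with a warning.
#' @param seed sampling seed.
#' @return named integer vector: counts of each observed null PML value
#'   (names are the values).
#' @export
sampleNullPmls <- function(index, sequences, nReads = 500L,
                           readLength = 2000L, seed = 7L) {
    seqs <- as.character(sequences)
    stopifnot(length(seqs) >= 1L, nReads >= 1L, readLength >= 1L)
    lens <- nchar(seqs)
    if (readLength > max(lens)) {
        warning("references shorter than readLength; shortening null reads to ",
                max(lens))
        readLength <- max(lens)
    }
    vals <- .withSeed(seed, {
        docs <- sample.int(length(seqs), nReads, replace = TRUE,
                           prob = pmax(lens - readLength + 1L, 1L))
        unlist(lapply(docs, function(d) {
            rl <- min(readLength, lens[d])
            s <- sample.int(lens[d] - rl + 1L, 1L)
            sub <- substr(seqs[d], s, s + rl - 1L)
            rev <- paste(rev(strsplit(sub, "", fixed = TRUE)[[1]]), collapse = "")
            computePmls(index, rev)$pml
        }), use.names = FALSE)
    })
    if (length(vals) == 0L) return(integer(0))
    tab <- table(vals)
    stats::setNames(as.integer(tab), names(tab))
}

#' Null PML classification threshold
#'
#' The threshold is the largest PML value occurring at least \code{minCount}
#' times in the null distribution; 0 if no value qualifies.
#'
#' @param nullDist named integer vector of counts (names = PML values), as
#'   returned by \code{\link{sampleNullPmls}}.
#' @param minCount occurrence floor (default 5).
#' @return integer threshold.
#' @examples
#' pmlThreshold(c(`1` = 10, `2` = 7, `3` = 4)) # 2
#' @export
pmlThreshold <- function(nullDist, minCount = 5L) {
    if (length(nullDist) == 0L) stop("empty null distribution")
    vals <- as.integer(names(nullDist))
    ok <- nullDist >= minCount
    if (!any(ok)) return(0L)
    max(vals[ok])
}

# Window bounds for a PML vector: non-overlapping windows of `window`
# symbols from the left end; a trailing window shorter than `window` merges
# into the previous one; a read shorter than `window` is a single window.
.windowBounds <- function(m, window) {
    k <- max(1L, m %/% window)
    starts <- (seq_len(k) - 1L) * window + 1L
    ends <- c(starts[-1L] - 1L, m)
    cbind(start = starts, end = ends)
}

#' Classify one read from its PML vector
#'
#' The PML vector is split into non-overlapping windows of \code{window}
#' symbols starting at the left end (a trailing short window merges into the
#' previous one; a read shorter than \code{window} symbols is one window).
#' A window counts as "above" iff its maximum PML strictly exceeds the
#' threshold; the read is called \code{"present"} iff strictly more than
#' half of its windows are above.
#'
#' @param pmls integer PML vector of one read.
#' @param threshold integer null PML threshold.
#' @param window window size in symbols (default 150).
#' @return list: \code{verdict} ("present"/"absent"), \code{windowsTotal},
#'   \code{windowsAbove}, \code{windowMax} (per-window maxima),
#'   \code{maxPml}.
#' @export
classifyRead <- function(pmls, threshold, window = 150L) {
    m <- length(pmls)
    if (m == 0L)
        return(list(verdict = "absent", windowsTotal = 0L, windowsAbove = 0L,
                    windowMax = integer(0), maxPml = NA_integer_))
    b <- .windowBounds(m, window)
    wmax <- vapply(seq_len(nrow(b)),
                   function(i) max(pmls[b[i, 1L]:b[i, 2L]]), integer(1))
    above <- sum(wmax > threshold)
    list(verdict = if (above > nrow(b) / 2) "present" else "absent",
         windowsTotal = nrow(b), windowsAbove = as.integer(above),
         windowMax = wmax, maxPml = max(wmax))
}

#' Multi-class call from a class-label vector
#'
#' Aggregates the class labels emitted by the sampled document array over a
#' read: the fraction of each class among non-NA labels is computed and the
#' argmax is the call (ties broken by the smallest class id, flagged).
#'
#' @param ca integer class ids (1-based, NA = none), as returned by
#'   \code{\link{computePmls}}.
#' @param classNames optional class names for the fractions.
#' @return list: \code{class} (called class id or NA if all labels are NA),
#'   \code{className}, \code{fraction} (the winning fraction), \code{tie}
#'   (logical), \code{fractions} (named vector over observed classes).
#' @export
classifyMulticlass <- function(ca, classNames = NULL) {
    ca <- ca[!is.na(ca)]
    if (length(ca) == 0L)
        return(list(class = NA_integer_, className = NA_character_,
                    fraction = NA_real_, tie = FALSE, fractions = numeric(0)))
    tab <- table(ca)
    frac <- as.numeric(tab) / length(ca)
    ids <- as.integer(names(tab))
    names(frac) <- if (!is.null(classNames)) classNames[ids] else names(tab)
    best <- which(frac == max(frac))
    win <- best[which.min(ids[best])] # smallest class id on ties
    list(class = ids[win],
         className = if (!is.null(classNames)) classNames[ids[win]]
                     else as.character(ids[win]),
         fraction = frac[[win]], tie = length(best) > 1L, fractions = frac)
}

#' Classify a read set against an index
#'
#' Computes PMLs (and, with \code{multiclass = TRUE} on a doc-array index,
#' class labels) for each read and applies the windowed threshold rule.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param reads character vector or DNAStringSet of reads.
#' @param threshold null PML threshold; defaults to the one stored in the
#'   index.
#' @param window window size in symbols (default 150).
#' @param multiclass also report the argmax document-array class per read.
#' @return data.frame: read_id, verdict, windows_above, windows_total,
#'   max_pml, and (multiclass) called_class, class_fraction.
#' @export
classifyReads <- function(index, reads, threshold = nullThreshold(index),
                          window = 150L, multiclass = FALSE) {
    if (is.na(threshold))
        stop("no threshold: build the index with nullReads > 0 or pass one")
    if (multiclass && !index@docArray)
        stop("multiclass calls need an index built with docArray = TRUE")
    ids <- names(reads)
    reads <- as.character(reads)
    if (is.null(ids)) ids <- names(reads) # DNAStringSet keeps names here
    if (is.null(ids)) ids <- sprintf("read%d", seq_along(reads))
    rows <- lapply(seq_along(reads), function(i) {
        res <- computePmls(index, reads[[i]])
        call <- classifyRead(res$pml, threshold, window)
        out <- data.frame(read_id = ids[i], verdict = call$verdict,
                          windows_above = call$windowsAbove,
                          windows_total = call$windowsTotal,
                          max_pml = ifelse(is.na(call$maxPml), NA_integer_,
                                           call$maxPml),
                          stringsAsFactors = FALSE)
        if (multiclass) {
            mc <- classifyMulticlass(res$ca, classLabels(index))
            out$called_class <- mc$className
            out$class_fraction <- mc$fraction
        }
        out
    })
    do.call(rbind, rows)
}

#' Scan assembly contigs for contamination
#'
#' Each contig is digested and streamed as one read against an index of the
#' contaminant pangenome; a contig is flagged \code{"suspicious"} iff the
#' 25th percentile of its PML distribution is at or above the cutoff
#' (inclusive). Contigs digesting to the empty sequence get a
#' \code{"no_data"} flag. The percentile is the inverse-ECDF quantile
#' (\code{type = 1}), so it is always an observed integer PML.
#'
#' @param index index over the contaminant collection.
#' @param contigs character vector or DNAStringSet of assembly contigs.
#' @param percentile percentile of the PML distribution to test (default 25).
#' @param cutoff flag threshold (default 2; inclusive).
#' @return data.frame: contig, n_symbols, p_pml (the percentile), flag.
#' @export
contaminationScan <- function(index, contigs, percentile = 25, cutoff = 2) {
    ids <- names(contigs)
    contigs <- as.character(contigs)
    if (is.null(ids)) ids <- names(contigs)
    if (is.null(ids)) ids <- sprintf("contig%d", seq_along(contigs))
    rows <- lapply(seq_along(contigs), function(i) {
        pml <- computePmls(index, contigs[[i]])$pml
        if (length(pml) == 0L)
            return(data.frame(contig = ids[i], n_symbols = 0L,
                              p_pml = NA_real_, flag = "no_data",
                              stringsAsFactors = FALSE))
        p <- as.numeric(stats::quantile(pml, percentile / 100, type = 1))
        data.frame(contig = ids[i], n_symbols = length(pml), p_pml = p,
                   flag = if (p >= cutoff) "suspicious" else "normal",
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Adaptive-sampling batch classification
#'
#' Emulates the decision protocol of nanopore adaptive sampling on
#' basecalled data: bases arrive in batches of \code{batchBases}; after each
#' accumulated prefix of b batches (b = 1..\code{maxBatches}) the prefix is
#' classified with the windowed threshold rule, and the first
#' \code{"present"} verdict ejects the read. A read never called present
#' through \code{maxBatches} batches is retained. PMLs are recomputed on the
#' accumulated prefix at each batch, since batches extend the read on the
#' side the right-to-left matching pass consumes last.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param read single read (character or DNAString).
#' @param threshold null PML threshold (default: stored in the index).
#' @param batchBases bases per batch (default 180).
#' @param maxBatches number of batches examined (default 4).
#' @param window classification window in symbols (default 150).
#' @return list: \code{decision} ("eject"/"retain"), \code{decisionBatch}
#'   (NA when retained), \code{trace} data.frame (batch, bases, verdict).
#' @export
adaptiveBatches <- function(index, read, threshold = nullThreshold(index),
                            batchBases = 180L, maxBatches = 4L,
                            window = 150L) {
    if (is.na(threshold)) stop("no threshold available")
    read <- as.character(read)
    stopifnot(length(read) == 1L, nchar(read) >= 1L)
    m <- nchar(read)
    nb <- min(maxBatches, ceiling(m / batchBases))
    trace <- data.frame(batch = integer(0), bases = integer(0),
                        verdict = character(0), stringsAsFactors = FALSE)
    decision <- "retain"; decisionBatch <- NA_integer_
    for (b in seq_len(nb)) {
        bases <- min(b * batchBases, m)
        prefix <- substr(read, 1L, bases)
        call <- classifyRead(computePmls(index, prefix)$pml, threshold, window)
        trace <- rbind(trace, data.frame(batch = b, bases = bases,
                                         verdict = call$verdict,
                                         stringsAsFactors = FALSE))
        if (call$verdict == "present") {
            decision <- "eject"; decisionBatch <- b
            break
        }
    }
    list(decision = decision, decisionBatch = decisionBatch, trace = trace)
}
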