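# Index directory layout (documented in the README):
#   header.txt     key=value metadata (magic, version, scheme, flags, sizes)
#   classes.txt    one class name per line
#   doclabels.txt  one 0-based class id per document line
#   <name>.bin     little-endian int32 arrays for every core component
#   docarray.bin   first/last run-boundary labels, packed ceil(log2 c) bits
# All files are written deterministically, so identical inputs give
# byte-identical index directories.

.MAGIC <- "MINIDEX"

.packLabels <- function(labels0, nClasses) {
    width <- max(1L, ceiling(log2(max(nClasses, 2L))))
    bits <- as.logical(vapply(labels0, function(x)
        as.integer(intToBits(x))[seq_len(width)], integer(width)))
    pad <- (-length(bits)) %% 8L
    packBits(c(bits, rep(FALSE, pad)), type = "raw")
}

.unpackLabels <- function(raw, nLabels, nClasses) {
    width <- max(1L, ceiling(log2(max(nClasses, 2L))))
    bits <- as.integer(rawToBits(raw))[seq_len(nLabels * width)]
    m <- matrix(bits, nrow = width)
    as.integer(colSums(m * 2^(seq_len(width) - 1L)))
}

#' Save / load a pangenome index
#'
#' Serializes the index into a directory of little-endian binary arrays plus
#' a text header; \code{loadIndex} restores it and validates magic and
#' version, failing with an explicit error on mismatch or truncation.
#' Serialization is deterministic: the same index writes byte-identical
#' files.
#'
#' @param index a \linkS4class{PangenomeIndex}.
#' @param path index directory (created by \code{saveIndex}).
#' @return \code{saveIndex}: \code{path}, invisibly. \code{loadIndex}: the
#'   restored \linkS4class{PangenomeIndex}.
#' @export
saveIndex <- function(index, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    core <- index@core
    sch <- index@scheme
    hdr <- c(magic = .MAGIC, version = index@version,
             alphabet = index@alphabet, digested = index@digested,
             k = if (is.null(sch)) NA else sch@k,
             w = if (is.null(sch)) NA else sch@w,
             seed = if (is.null(sch)) NA else sch@seed,
             n = core$n, r = length(core$runStarts),
             nDocs = index@nDocs, nClasses = length(index@classNames),
             docArray = index@docArray, msSupport = index@msSupport,
             nullThreshold = index@nullThreshold)
    writeLines(paste0(names(hdr), "=", unname(hdr)),
               file.path(path, "header.txt"))
    writeLines(index@classNames, file.path(path, "classes.txt"))
    writeLines(as.character(index@docLabels), file.path(path, "doclabels.txt"))
    if (length(index@nullDist))
        writeLines(paste0(names(index@nullDist), "\t", index@nullDist),
                   file.path(path, "nulldist.txt"))
    intParts <- c("runStarts", "runChars", "runLengths", "occBefore",
                  "symVals", "countsBelow", "symOff", "cStart", "cEnd",
                  "cIdx", "thrOff", "thrRows")
    if (index@msSupport) intParts <- c(intParts, "saFirst", "saLast", "text")
    for (nm in intParts) {
        con <- file(file.path(path, paste0(nm, ".bin")), "wb")
        writeBin(core[[nm]], con, size = 4L, endian = "little")
        close(con)
    }
    if (index@docArray) {
        raw <- .packLabels(c(core$firstLabel, core$lastLabel),
                           length(index@classNames))
        con <- file(file.path(path, "docarray.bin"), "wb")
        writeBin(raw, con)
        close(con)
    }
    invisible(path)
}

#' @rdname saveIndex
#' @export
loadIndex <- function(path) {
    hf <- file.path(path, "header.txt")
    if (!file.exists(hf)) stop("not an index directory (no header.txt): ", path)
    kv <- strsplit(readLines(hf), "=", fixed = TRUE)
    hdr <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    if (!identical(unname(hdr["magic"]), .MAGIC))
        stop("bad index magic: expected '", .MAGIC, "', found '",
             hdr["magic"], "'")
    if (as.integer(hdr["version"]) != 1L)
        stop("unsupported index version: expected 1, found ", hdr["version"])
    n <- as.integer(hdr["n"]); r <- as.integer(hdr["r"])
    nClasses <- as.integer(hdr["nClasses"])
    docArray <- as.logical(hdr["docArray"])
    msSupport <- as.logical(hdr["msSupport"])
    readArr <- function(nm, expectLen) {
        f <- file.path(path, paste0(nm, ".bin"))
        if (!file.exists(f)) stop("index component missing: ", nm, ".bin")
        nInt <- file.size(f) / 4L
        if (!is.na(expectLen) && nInt != expectLen)
            stop("index component ", nm, ".bin is truncated: expected ",
                 expectLen, " integers, found ", nInt)
        con <- file(f, "rb")
        on.exit(close(con))
        readBin(con, "integer", n = nInt, size = 4L, endian = "little")
    }
    core <- list(n = n, runStarts = readArr("runStarts", r),
                 runChars = readArr("runChars", r),
                 runLengths = readArr("runLengths", r),
                 occBefore = readArr("occBefore", r),
                 symVals = readArr("symVals", NA),
                 countsBelow = readArr("countsBelow", NA),
                 symOff = readArr("symOff", NA),
                 cStart = readArr("cStart", r), cEnd = readArr("cEnd", r),
                 cIdx = readArr("cIdx", r), thrOff = readArr("thrOff", NA),
                 thrRows = readArr("thrRows", NA))
    if (docArray) {
        f <- file.path(path, "docarray.bin")
        if (!file.exists(f)) stop("index component missing: docarray.bin")
        raw <- readBin(f, "raw", n = file.size(f))
        labs <- .unpackLabels(raw, 2L * r, nClasses)
        core$firstLabel <- labs[seq_len(r)]
        core$lastLabel <- labs[r + seq_len(r)]
    }
    if (msSupport) {
        core$saFirst <- readArr("saFirst", r)
        core$saLast <- readArr("saLast", r)
        core$text <- readArr("text", n)
    }
    nullDist <- integer(0)
    ndf <- file.path(path, "nulldist.txt")
    if (file.exists(ndf)) {
        lines <- strsplit(readLines(ndf), "\t", fixed = TRUE)
        nullDist <- stats::setNames(
            as.integer(vapply(lines, `[`, "", 2L)),
            vapply(lines, `[`, "", 1L))
    }
    digested <- as.logical(hdr["digested"])
    scheme <- if (digested)
        MinimizerScheme(as.integer(hdr["k"]), as.integer(hdr["w"]),
                        as.integer(hdr["seed"])) else NULL
    idx <- new("PangenomeIndex", scheme = scheme,
               alphabet = unname(hdr["alphabet"]), digested = digested,
               core = core, nDocs = as.integer(hdr["nDocs"]),
               docLabels = as.integer(readLines(file.path(path, "doclabels.txt"))),
               classNames = readLines(file.path(path, "classes.txt")),
               docArray = docArray, msSupport = msSupport,
               nullDist = nullDist,
               nullThreshold = suppressWarnings(as.integer(hdr["nullThreshold"])),
               version = 1L)
    validObject(idx)
    idx
}

#' Serialized component sizes
#'
#' Byte counts of each file of a saved index directory, for reporting index
#' composition (e.g., the overhead the sampled document array adds).
#'
#' @param path an index directory written by \code{\link{saveIndex}}.
#' @return named numeric vector of byte counts, plus a \code{total}.
#' @export
indexComponentSizes <- function(path) {
    files <- list.files(path, full.names = TRUE)
    sizes <- stats::setNames(file.size(files), basename(files))
    c(sizes, total = sum(sizes))
}
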