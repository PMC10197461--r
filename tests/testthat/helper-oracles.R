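# Independent naive oracles used throughout the suite. These deliberately
# avoid the package's index machinery: suffix sorting is a plain
# lexicographic sort of suffix strings, matching statistics are computed by
# repeated fixed-string search, and digestion re-scans every window.

BASES <- c("A", "C", "G", "T")

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# naive minimizer digest: hash every k-mer of every window via kmerHash,
# select the leftmost minimum, collapse equal adjacent values
naiveDigest <- function(seq, k, w, seed) {
    n <- nchar(seq)
    if (n < w) return(integer(0))
    out <- integer(0); last <- -1L
    for (s in seq_len(n - w + 1L)) {
        win <- substr(seq, s, s + w - 1L)
        if (grepl("[^ACGT]", win)) next
        starts <- seq_len(w - k + 1L)
        kmers <- substring(win, starts, starts + k - 1L)
        km <- kmers[which.min(kmerHash(kmers, seed))]
        code <- encodeMinimizer(km)
        if (code != last) { out <- c(out, code); last <- code }
    }
    out
}

# map an integer text (sentinels negative) to a fixed-width string whose
# C-locale order matches integer order, for radix-sorted suffix oracles
.sufStrings <- function(text) {
    offset <- min(text)
    toks <- sprintf("%04d", text - offset)
    n <- length(text)
    vapply(seq_len(n), function(i) paste(toks[i:n], collapse = ""),
           character(1))
}

naiveSuffixArray <- function(text) {
    order(.sufStrings(text), method = "radix") - 1L
}

# BWT via explicit rotation sort of the text (rotations of the
# sentinel-terminated text sort identically to suffixes)
naiveBwtRotations <- function(text) {
    n <- length(text)
    rots <- vapply(seq_len(n), function(i) {
        rot <- c(text[i:n], text[seq_len(i - 1L)])
        paste(sprintf("%04d", rot - min(text)), collapse = "")
    }, character(1))
    ord <- order(rots, method = "radix")
    vapply(ord, function(i) text[(i - 2L) %% n + 1L], integer(1))
}

# longest common prefix of two integer suffixes by direct comparison
naiveLcpPair <- function(text, i0, j0) {
    n <- length(text); l <- 0L
    while (i0 + l < n && j0 + l < n && text[i0 + l + 1L] == text[j0 + l + 1L])
        l <- l + 1L
    l
}

# naive matching statistics of pattern P against text T (both DNA strings):
# for each i, the longest prefix of P[i..] found by fixed-string search
naiveMs <- function(P, T) {
    m <- nchar(P)
    out <- integer(m)
    for (i in seq_len(m)) {
        l <- 0L
        while (i + l <= m && grepl(substr(P, i, i + l), T, fixed = TRUE))
            l <- l + 1L
        out[i] <- l
    }
    out
}

# fraction of mismatching bases between two equal-length strings
mismatchFrac <- function(a, b) {
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    mean(av != bv)
}

# shorthands poking at build internals
bc <- function(docs, labels0 = rep(0L, length(docs)))
    minidex:::.buildConcat(docs, labels0)
core_of <- function(concat, ...) minidex:::.buildCore(concat, ...)

# decode the jump the stored thresholds dictate from row q for symbol c:
# returns the boundary row chosen and the rejected alternative (NA when the
# direction is forced)
thresholdJump <- function(core, q, c) {
    ci <- match(c, core$symVals)
    if (is.na(ci)) return(NULL)
    lo <- core$symOff[ci] + 1L; hi <- core$symOff[ci + 1L]
    if (hi < lo) return(NULL)
    runs <- lo:hi
    a <- sum(core$cStart[runs] <= q)
    if (a == 0L) return(list(chosen = core$cStart[runs[1L]], rejected = NA))
    if (a == length(runs)) return(list(chosen = core$cEnd[runs[a]], rejected = NA))
    t <- core$thrRows[core$thrOff[ci] + a]
    up <- core$cEnd[runs[a]]; down <- core$cStart[runs[a + 1L]]
    if (q < t) list(chosen = up, rejected = down)
    else list(chosen = down, rejected = up)
}

# small undigested index over explicit DNA documents
dnaIndex <- function(seqs, ..., revcomp = FALSE) {
    buildIndex(seqs, digest = FALSE, includeRevComp = revcomp,
               nullReads = 0L, ...)
}
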