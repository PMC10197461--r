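test_that("concatenation appends ranked sentinels and round-trips", {
    cc <- bc(list(c(1L, 2L)))
    expect_identical(cc$symbols, c(1L, 2L, -1L))
    expect_identical(cc$n, 3L)
    cc2 <- bc(list(c(1L, 2L, 3L), c(4L, 1L)), c(0L, 1L))
    expect_identical(sum(cc2$symbols < 0L), 2L)
    expect_identical(cc2$docStart0, c(0L, 4L))
    expect_identical(minidex:::.splitConcat(cc2),
                     list(c(1L, 2L, 3L), c(4L, 1L)))
    expect_error(bc(list(integer(0))), "empty document")
})

test_that("suffix array and BWT agree with brute-force oracles", {
    # T = "AAA$" (A=1, sentinel -1): SA is [3,2,1,0]
    t1 <- c(1L, 1L, 1L, -1L)
    expect_identical(minidex:::sa_build_cpp(t1), c(3L, 2L, 1L, 0L))
    set.seed(23)
    for (i in 1:30) {
        docs <- replicate(sample(1:3, 1), sample(1:4, sample(20:160, 1),
                                                 replace = TRUE),
                          simplify = FALSE)
        cc <- bc(docs, seq_along(docs) - 1L)
        sa <- minidex:::sa_build_cpp(cc$symbols)
        expect_identical(sa, naiveSuffixArray(cc$symbols))
        n <- cc$n
        bwt <- cc$symbols[ifelse(sa == 0L, n, sa)]
        expect_identical(bwt, naiveBwtRotations(cc$symbols))
    }
    # one larger instance
    cc <- bc(list(sample(1:4, 500, replace = TRUE)))
    expect_identical(minidex:::sa_build_cpp(cc$symbols),
                     naiveSuffixArray(cc$symbols))
})

test_that("LF iteration inverts the BWT and visits every row once", {
    set.seed(31)
    for (i in 1:10) {
        doc <- sample(1:4, sample(30:120, 1), replace = TRUE)
        idx <- dnaIndex(setNames(paste(BASES[doc], collapse = ""), "d"))
        core <- idx@core
        n <- core$n
        lf <- lfMap(idx, 0:(n - 1))
        expect_identical(sort(lf), 0:(n - 1)) # permutation
        # walking LF from row 0 (the sentinel's suffix) emits the data text
        # right-to-left and finally the sentinel itself
        row <- 0L
        rc <- rep(core$runChars, core$runLengths)
        out <- integer(n)
        for (s in seq_len(n)) {
            out[s] <- rc[row + 1L]
            row <- lfMap(idx, row)
        }
        text <- c(minidex:::.dnaCodes(paste(BASES[doc], collapse = "")), -1L)
        expect_identical(out, c(rev(text[-n]), -1L))
    }
})

test_that("run-length encoding is maximal and repetition drives n/r", {
    cc <- bc(list(c(1L, 1L, 1L, 2L)))
    core <- core_of(cc)
    expect_identical(sum(core$runLengths), core$n)
    expect_true(all(diff(core$runChars) != 0L))
    # 10 near-identical strains compress far better than 10 random strings
    set.seed(41)
    base <- randomDna(5000)
    strains <- vapply(1:10, function(i) {
        b <- strsplit(base, "")[[1]]
        hit <- sample(5000, 25) # 0.5% divergence
        b[hit] <- sample(BASES, 25, replace = TRUE)
        paste(b, collapse = "")
    }, character(1))
    rand <- replicate(10, randomDna(5000))
    iRep <- dnaIndex(strains)
    iRnd <- dnaIndex(rand)
    expect_gt(compressionRatio(iRep), 5 * compressionRatio(iRnd))
})

test_that("thresholds sit at the LCP minimum between same-character runs", {
    # constructed text with two A-runs in its BWT: verify against a direct
    # argmin over the LCP array between the runs
    set.seed(43)
    for (i in 1:20) {
        cc <- bc(list(sample(1:4, 20, replace = TRUE)))
        core <- core_of(cc)
        sa <- minidex:::sa_build_cpp(cc$symbols)
        lcp <- minidex:::lcp_kasai_cpp(cc$symbols, sa)
        bad <- 0L
        for (ci in seq_along(core$symVals)) {
            lo <- core$symOff[ci] + 1L; hi <- core$symOff[ci + 1L]
            if (hi - lo < 1L) next
            for (g in seq_len(hi - lo)) {
                e <- core$cEnd[lo + g - 1L]; s <- core$cStart[lo + g]
                seg <- lcp[(e + 2L):(s + 1L)] # rows e+1..s, 1-based lcp
                t <- core$thrRows[core$thrOff[ci] + g]
                if (t != e + 1L + (which.min(seg) - 1L)) bad <- bad + 1L
            }
        }
        expect_identical(bad, 0L)
    }
})

test_that("threshold-directed jumps beat or match the rejected direction", {
    # exhaustive optimality check on random small texts: the suffix at the
    # chosen boundary shares >= as long a prefix with the current row's
    # suffix as the rejected boundary's suffix does
    set.seed(47)
    nTexts <- 100
    for (i in seq_len(nTexts)) {
        cc <- bc(list(sample(1:4, sample(50:200, 1), replace = TRUE)))
        core <- core_of(cc)
        sa <- minidex:::sa_build_cpp(cc$symbols)
        rc <- rep(core$runChars, core$runLengths)
        violations <- 0L; checked <- 0L
        for (q in 0:(core$n - 1L)) {
            for (c in 1:4) {
                if (rc[q + 1L] == c) next
                j <- thresholdJump(core, q, c)
                if (is.null(j) || is.na(j$rejected)) next
                checked <- checked + 1L
                lChosen <- naiveLcpPair(cc$symbols, sa[q + 1L], sa[j$chosen + 1L])
                lRejected <- naiveLcpPair(cc$symbols, sa[q + 1L], sa[j$rejected + 1L])
                if (lChosen < lRejected) violations <- violations + 1L
            }
        }
        expect_gt(checked, 0L)
        expect_identical(violations, 0L)
    }
})

test_that("sampled document array labels equal direct SA lookups", {
    set.seed(53)
    # 2 documents over disjoint alphabets: every non-sentinel run boundary
    # labels the document owning that symbol
    d0 <- sample(1:2, 60, replace = TRUE)
    d1 <- sample(3:4, 60, replace = TRUE)
    cc <- bc(list(d0, d1), c(0L, 1L))
    core <- core_of(cc, docArray = TRUE)
    sa <- naiveSuffixArray(cc$symbols)
    docOf <- function(p0) findInterval(p0, cc$docStart0) - 1L
    saF <- sa[core$runStarts + 1L]
    saL <- sa[core$runStarts + core$runLengths]
    expect_identical(core$firstLabel, docOf(saF))
    expect_identical(core$lastLabel, docOf(saL))
    nonSent <- core$runChars > 0L
    ownDoc <- ifelse(core$runChars %in% 1:2, 0L, 1L)[nonSent]
    expect_identical(core$firstLabel[nonSent], ownDoc)
    expect_identical(core$lastLabel[nonSent], ownDoc)
    # single-document index: all 2r labels are that document's class
    cc1 <- bc(list(d0))
    core1 <- core_of(cc1, docArray = TRUE)
    expect_true(all(core1$firstLabel == 0L) && all(core1$lastLabel == 0L))
})

test_that("document-array labels pack into ceil(log2 c) bits", {
    labs <- sample(0:7, 40, replace = TRUE)
    raw <- minidex:::.packLabels(labs, 8L)
    expect_identical(length(raw), as.integer(ceiling(40 * 3 / 8))) # 3 bits each
    expect_identical(minidex:::.unpackLabels(raw, 40L, 8L), as.integer(labs))
})

test_that("index serialization round-trips, is deterministic, rejects damage", {
    set.seed(59)
    pg <- simulatePangenome(2, 2, 800, 0.01, 0.1, seed = 3)
    idx <- buildIndex(pg$sequences, pg$labels, scheme = MinimizerScheme(4L, 8L),
                      msSupport = TRUE, nullReads = 20L, nullReadLength = 200L)
    d1 <- file.path(tempdir(), "idx1"); d2 <- file.path(tempdir(), "idx2")
    saveIndex(idx, d1)
    idx2 <- loadIndex(d1)
    expect_identical(idx2@core, idx@core)
    expect_identical(idx2@nullThreshold, idx@nullThreshold)
    expect_identical(idx2@classNames, idx@classNames)
    expect_identical(idx2@docLabels, idx@docLabels)
    # byte-identical re-serialization
    saveIndex(idx2, d2)
    for (f in list.files(d1)) {
        expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                         readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))))
    }
    # queries agree after a round trip
    rd <- substr(pg$sequences[[1]], 101, 400)
    expect_identical(computePmls(idx2, rd)$pml, computePmls(idx, rd)$pml)
    # damage: truncation and magic mismatch produce explicit errors
    tf <- file.path(d1, "runChars.bin")
    writeBin(readBin(tf, "raw", 5), tf)
    expect_error(loadIndex(d1), "truncated")
    hf <- file.path(d2, "header.txt")
    h <- readLines(hf); h[1] <- "magic=BOGUS"; writeLines(h, hf)
    expect_error(loadIndex(d2), "magic")
    expect_error(loadIndex(file.path(tempdir(), "nosuchidx")), "header")
})
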