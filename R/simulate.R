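# Mutate a DNA string by independent per-base substitutions at `rate`
# (substituted bases are drawn uniformly from the three other bases).
.mutateSeq <- function(seq, rate) {
    if (rate <= 0) return(seq)
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    if (length(hit)) {
        alt <- c("A", "C", "G", "T")
        b[hit] <- vapply(b[hit], function(x) sample(setdiff(alt, x), 1L),
                         character(1), USE.NAMES = FALSE)
    }
    paste(b, collapse = "")
}

.randomSeq <- function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Simulate a synthetic pangenome
#'
#' Generates a class-structured strain collection: a random ancestor genome
#' is mutated once per class (at \code{interDivergence}) to give each class
#' its base genome, and each strain is an independent mutation of its class
#' base (at \code{intraDivergence}). Substitution-only; deterministic under
#' \code{seed}.
#'
#' @param nClasses number of classes.
#' @param strainsPerClass strains generated per class.
#' @param genomeLength genome length in bases.
#' @param intraDivergence per-base substitution rate strain vs class base.
#' @param interDivergence per-base substitution rate class base vs ancestor.
#' @param seed RNG seed.
#' @return list: \code{sequences} (named character vector,
#'   "class<i>_strain<j>"), \code{labels} (class name per sequence).
#' @examples
#' pg <- simulatePangenome(2, 2, 1000, 0.01, 0.1, seed = 1)
#' table(pg$labels)
#' @export
simulatePangenome <- function(nClasses = 1L, strainsPerClass = 5L,
                              genomeLength = 5000L, intraDivergence = 0.01,
                              interDivergence = 0.1, seed = 1L) {
    stopifnot(intraDivergence >= 0, intraDivergence < 1,
              interDivergence >= 0, interDivergence < 1, genomeLength >= 1)
    .withSeed(seed, {
        ancestor <- .randomSeq(genomeLength)
        seqs <- character(0); labels <- character(0)
        for (ci in seq_len(nClasses)) {
            base <- if (nClasses > 1L) .mutateSeq(ancestor, interDivergence)
                    else ancestor
            for (si in seq_len(strainsPerClass)) {
                seqs <- c(seqs, .mutateSeq(base, intraDivergence))
                labels <- c(labels, sprintf("class%d", ci))
            }
        }
        names(seqs) <- sprintf("%s_strain%d", labels,
                               sequence(rep(strainsPerClass, nClasses)))
        list(sequences = seqs, labels = labels)
    })
}

#' Simulate reads from a document collection
#'
#' Draws substrings at uniform positions from the given documents (either
#' strand with probability 0.5), injects independent per-base substitution
#' errors, and records the truth. With \code{origin = "random"} the reads
#' are i.i.d. uniform draws from the DNA alphabet instead.
#'
#' @param sequences named character vector of source documents (ignored for
#'   random reads).
#' @param labels class label per document (recycled into the truth table).
#' @param nReads number of reads.
#' @param readLength read length in bases.
#' @param errorRate per-base substitution error rate.
#' @param origin \code{"document"} (default) or \code{"random"}.
#' @param seed RNG seed.
#' @return list: \code{reads} (named character vector), \code{truth}
#'   data.frame (read_id, doc, class, strand, start).
#' @export
simulateReads <- function(sequences = NULL, labels = NULL, nReads = 100L,
                          readLength = 1000L, errorRate = 0.05,
                          origin = c("document", "random"), seed = 1L) {
    origin <- match.arg(origin)
    stopifnot(errorRate >= 0, errorRate < 1, readLength >= 1)
    .withSeed(seed, {
        if (origin == "random") {
            reads <- vapply(seq_len(nReads), function(i) .randomSeq(readLength),
                            character(1))
            names(reads) <- sprintf("rand%d", seq_len(nReads))
            truth <- data.frame(read_id = names(reads), doc = NA_character_,
                                class = "random", strand = NA_character_,
                                start = NA_integer_, stringsAsFactors = FALSE)
            return(list(reads = reads, truth = truth))
        }
        seqs <- as.character(sequences)
        stopifnot(length(seqs) >= 1L)
        if (any(nchar(seqs) < readLength))
            stop("readLength exceeds the length of a source document")
        if (is.null(labels)) labels <- rep("ref", length(seqs))
        docIds <- if (!is.null(names(sequences))) names(sequences)
                  else sprintf("doc%d", seq_along(seqs))
        di <- sample.int(length(seqs), nReads, replace = TRUE)
        starts <- vapply(di, function(d)
            sample.int(nchar(seqs[d]) - readLength + 1L, 1L), integer(1))
        strands <- sample(c("+", "-"), nReads, replace = TRUE)
        reads <- vapply(seq_len(nReads), function(i) {
            s <- substr(seqs[di[i]], starts[i], starts[i] + readLength - 1L)
            if (strands[i] == "-") s <- revComp(s)
            .mutateSeq(s, errorRate)
        }, character(1))
        names(reads) <- sprintf("read%d", seq_len(nReads))
        truth <- data.frame(read_id = names(reads), doc = docIds[di],
                            class = as.character(labels)[di],
                            strand = strands, start = starts,
                            stringsAsFactors = FALSE)
        list(reads = reads, truth = truth)
    })
}

#' Write reads to FASTA / FASTQ
#'
#' Convenience writers over Biostrings (gzip-transparent: a path ending in
#' \code{.gz} is compressed). FASTQ qualities are constant Phred 30.
#'
#' @param reads named character vector of sequences.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
    invisible(path)
}

#' @rdname writeFasta
#' @export
writeFastq <- function(reads, path) {
    x <- Biostrings::DNAStringSet(reads)
    q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
        strrep("?", n), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                                compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Read sequences from FASTA or FASTQ
#'
#' @param path FASTA/FASTQ path (optionally gzipped); format sniffed from
#'   the first non-empty character.
#' @return named character vector of sequences.
#' @export
readSequences <- function(path) {
    con <- gzfile(path, "r"); first <- readLines(con, n = 1L); close(con)
    fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
    x <- Biostrings::readDNAStringSet(path, format = fmt)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    out
}
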