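#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' pipeline's format contract: records must have non-empty, unique ids and
#' non-empty sequences; lower-case bases are upper-cased; multi-line sequences
#' are concatenated. Violations raise an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], order-preserving.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    nonblank <- which(nzchar(trimws(lines)))
    if (length(nonblank) == 0) stop("empty FASTA file: ", path)
    first <- nonblank[1]
    if (!startsWith(lines[first], ">"))
        stop("malformed FASTA header at line ", first, ": expected '>'")
    hdr <- which(startsWith(lines, ">"))
    if (any(nchar(trimws(sub("^>", "", lines[hdr]))) == 0))
        stop("malformed FASTA header at line ",
             hdr[nchar(trimws(sub("^>", "", lines[hdr]))) == 0][1],
             ": empty id")
    x <- Biostrings::readDNAStringSet(path)
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    # ids: token up to first whitespace
    full <- names(x)
    ids <- sub("\\s.*$", "", full)
    names(x) <- ids
    if (any(width(x) == 0)) {
        bad <- which(width(x) == 0)[1]
        stop("empty sequence for record '", ids[bad], "' (header line ",
             hdr[bad], ")")
    }
    if (anyDuplicated(ids))
        stop("duplicate FASTA ids: ", ids[duplicated(ids)][1])
    x
}

#' Write a FASTA file
#'
#' @param x A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
writeFasta <- function(x, path) {
    if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(as.character(x))
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Four-line FASTQ records; framing is by record structure, so '@' characters
#' inside quality lines are handled correctly. A sequence/quality length
#' mismatch is a format error.
#'
#' @param path Path to a FASTQ file.
#' @return A list with character vectors `id`, `seq` and `qual` (Phred+33
#'   encoded quality strings) plus integer-decoded qualities via
#'   [phredToInt()].
#' @export
readFastq <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    if (length(lines) %% 4 != 0)
        stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
    n <- length(lines) / 4
    at <- seq_len(n) * 4 - 3
    if (!all(startsWith(lines[at], "@")))
        stop("malformed FASTQ header at line ",
             at[!startsWith(lines[at], "@")][1])
    ids <- sub("\\s.*$", "", sub("^@", "", lines[at]))
    seqs <- toupper(lines[at + 1])
    quals <- lines[at + 3]
    bad <- which(nchar(seqs) != nchar(quals))
    if (length(bad))
        stop("sequence/quality length mismatch for record '", ids[bad[1]],
             "' at line ", at[bad[1]])
    if (any(nchar(seqs) == 0))
        stop("empty sequence at line ", at[nchar(seqs) == 0][1] + 1)
    list(id = ids, seq = seqs, qual = quals)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param reads Character vector of sequences.
#' @param quals Character vector of Phred+33 quality strings.
#' @param ids Read ids (default `read1..readN`).
#' @param path Output path.
#' @export
writeFastq <- function(reads, quals, path, ids = NULL) {
    if (length(reads) != length(quals))
        stop("reads and quals must have equal length")
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    out <- character(4 * length(reads))
    idx <- seq_along(reads) * 4 - 3
    out[idx] <- paste0("@", ids)
    out[idx + 1] <- reads
    out[idx + 2] <- "+"
    out[idx + 3] <- quals
    writeLines(out, path)
    invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual A quality string.
#' @return Integer vector of per-base Phred scores.
#' @export
phredToInt <- function(qual) {
    if (nchar(qual) == 0) return(integer(0))
    utf8ToInt(qual) - 33L
}

#' Write a numeric matrix as TSV
#'
#' First column holds the row id, the header row the column (sample) ids.
#' Rows and columns are written in lexicographic order so diffs are
#' reproducible. `readMatrixTsv(writeMatrixTsv(M))` round-trips.
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the row-id column (default "id").
#' @export
writeMatrixTsv <- function(mat, path, id_col = "id") {
    if (is.null(rownames(mat)) && nrow(mat) > 0)
        stop("matrix must have row ids")
    if (anyDuplicated(rownames(mat)))
        stop("duplicate row ids: ", rownames(mat)[duplicated(rownames(mat))][1])
    if (nrow(mat) > 0) mat <- mat[order(rownames(mat)), , drop = FALSE]
    if (ncol(mat) > 0 && !is.null(colnames(mat)))
        mat <- mat[, order(colnames(mat)), drop = FALSE]
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- id_col
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV matrix written by [writeMatrixTsv()]
#' @param path Input path.
#' @return Matrix with row and column names.
#' @export
readMatrixTsv <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    m
}

#' Pipeline configuration with the standard filter defaults
#'
#' Bundles every tunable threshold of the pipeline, initialised to the
#' standard defaults: mapping identity 94%, alignment coverage 70%, mapping
#' quality 20, mean read quality 20, per-base quality 30 (SNP pileups),
#' copy-number presence cutoff 0.35, core genome defined as depth > 10 in at
#' least 95% of samples, allele presence at >= 3 reads and >= 10% frequency,
#' at least 10 marker alleles per donor, and > 5% sharing for a transmission
#' call.
#'
#' @param ... Named overrides for any of the defaults.
#' @return A named list of validated thresholds.
#' @export
runConfig <- function(...) {
    cfg <- list(
        map_pid = 94, aln_cov = 0.70, mapq_min = 20, read_qual_min = 20,
        base_qual_min = 30, marker_aln_cov = 0.70, marker_cutoff = 95,
        lenient_pid = 75,
        species_cov_min = 1, snp_cov_min = 10,
        copynum_cutoff = 0.35, core_depth = 10, core_fraction = 0.95,
        allele_min_reads = 3, allele_min_freq = 0.10,
        marker_min_count = 10, transmission_cutoff = 5.0,
        seed = 1L
    )
    ov <- list(...)
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown)) stop("unknown config keys: ",
                              paste(unknown, collapse = ", "))
    cfg[names(ov)] <- ov
    rng <- list(
        map_pid = c(0, 100), aln_cov = c(0, 1), mapq_min = c(0, 60),
        read_qual_min = c(0, 60), base_qual_min = c(0, 60),
        marker_aln_cov = c(0, 1), marker_cutoff = c(50, 100),
        lenient_pid = c(0, 100),
        species_cov_min = c(0, Inf), snp_cov_min = c(0, Inf),
        copynum_cutoff = c(0, Inf), core_depth = c(0, Inf),
        core_fraction = c(0, 1),
        allele_min_reads = c(0, Inf), allele_min_freq = c(0, 1),
        marker_min_count = c(0, Inf), transmission_cutoff = c(0, 100)
    )
    for (k in names(rng)) {
        v <- cfg[[k]]
        if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
            v < rng[[k]][1] || v > rng[[k]][2])
            stop("config value out of range: ", k, " = ", v)
    }
    cfg
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are ignored.
#' Values override the [runConfig()] defaults.
#'
#' @param path Config file path.
#' @return A validated configuration list.
#' @export
readConfigFile <- function(path) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(runConfig())
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed config line: ", lines[bad][1])
    vals <- lapply(kv, function(p) as.numeric(p[2]))
    names(vals) <- vapply(kv, `[`, "", 1)
    do.call(runConfig, vals)
}
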