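#' Map reads against a small reference set
#'
#' Self-contained seed-and-extend mapper: targets are indexed by exact k-mers
#' (default k = 15); candidate (target, diagonal) pairs are scored by banded
#' dynamic programming (match +1, mismatch -2, gap -3) and at most one best
#' alignment is reported per read. Co-optimal hits are all emitted and flagged
#' as ties. `mapq` is 60 when the best score beats the runner-up by at least
#' one mismatch-swap penalty, else 3 — so the downstream `mapq >= 20` filter
#' implements "discard non-unique best hits".
#'
#' Both strands are searched; reverse-strand hits are reported in target
#' coordinates with the read reverse-complemented, so `rstart`/`rend` and the
#' CIGAR always refer to the target-strand orientation of the read.
#' `N` bases never count as matches.
#'
#' @param reads Character vector of read sequences (or a list with `seq` and
#'   `qual` elements as returned by [readFastq()]).
#' @param targets Named [Biostrings::DNAStringSet] or named character vector.
#' @param mode `"local"` (soft-clipped ends are free; genes/markers) or
#'   `"global"` (the entire read must align; representative genomes).
#' @param quals Optional character vector of Phred+33 quality strings; enables
#'   the `mean_qual` column.
#' @param k Seed k-mer length.
#' @param band Half-width of the DP band around the seeded diagonal.
#' @param max_ties Cap on the number of co-optimal hits reported per read.
#' @param seed_step Spacing between successive seed k-mers along the read
#'   (default 2; 1 = every position).
#' @return data.frame with one row per reported alignment: `read_id`,
#'   `target_id`, `strand`, 0-based half-open `tstart`/`tend` and
#'   `rstart`/`rend`, `matches`, `cols` (alignment columns), `pid` (percent
#'   identity), `read_cov` (aligned fraction of the read), `score`, `mapq`,
#'   `tie`, `nbest`, `mean_qual`, `cigar`. Empty reads give an empty
#'   data.frame, not an error.
#' @export
mapReads <- function(reads, targets, mode = c("local", "global"),
                     quals = NULL, k = 15, band = 8, max_ties = 16,
                     seed_step = 2) {
    mode <- match.arg(mode)
    if (is.list(reads) && !is.null(reads$seq)) {
        if (is.null(quals)) quals <- reads$qual
        reads <- reads$seq
    }
    reads <- as.character(reads)
    if (is(targets, "DNAStringSet")) {
        tnames <- names(targets)
        targets <- as.character(targets)
    } else {
        tnames <- names(targets)
        targets <- as.character(targets)
    }
    if (length(targets) == 0) stop("empty target set")
    if (is.null(tnames)) tnames <- paste0("target", seq_along(targets))
    rnames <- names(reads)
    if (is.null(rnames)) rnames <- paste0("read", seq_along(reads))
    if (length(reads) == 0) {
        return(data.frame(read_id = character(0), target_id = character(0),
                          strand = character(0), tstart = integer(0),
                          tend = integer(0), rstart = integer(0),
                          rend = integer(0), matches = integer(0),
                          cols = integer(0), pid = numeric(0),
                          read_cov = numeric(0), score = integer(0),
                          mapq = integer(0), tie = logical(0),
                          nbest = integer(0), mean_qual = numeric(0),
                          cigar = character(0), stringsAsFactors = FALSE))
    }
    if (is.null(quals)) quals <- character(0)
    df <- cpp_map_reads(reads, quals, unname(targets),
                        if (mode == "local") 0L else 1L,
                        as.integer(k), as.integer(band), as.integer(max_ties),
                        as.integer(seed_step))
    rl <- nchar(reads)[df$read]
    out <- data.frame(
        read_id = rnames[df$read],
        read = df$read,
        target_id = tnames[df$target],
        target = df$target,
        strand = df$strand,
        tstart = df$tstart, tend = df$tend,
        rstart = df$rstart, rend = df$rend,
        matches = df$matches, cols = df$cols,
        pid = 100 * df$matches / pmax(df$cols, 1L),
        read_cov = (df$rend - df$rstart) / pmax(rl, 1L),
        score = df$score, mapq = df$mapq,
        tie = df$tie == 1L, nbest = df$nbest,
        mean_qual = df$mean_qual,
        cigar = df$cigar,
        stringsAsFactors = FALSE)
    out
}

#' Apply the standard alignment filters
#'
#' Keeps alignments with mapping percent identity `>= map_pid`, alignment
#' coverage `>= aln_cov`, mapping quality `>= mapq_min` and mean read quality
#' `>= read_qual_min` (defaults 94 / 0.70 / 20 / 20). Filtering is monotone:
#' tightening any threshold never enlarges the kept set. Alignments without
#' quality information (`mean_qual` NA) pass the read-quality filter.
#'
#' @param aln Alignment data.frame from [mapReads()].
#' @param map_pid Minimum percent identity.
#' @param aln_cov Minimum aligned fraction of the read.
#' @param mapq_min Minimum mapping quality.
#' @param read_qual_min Minimum mean read quality.
#' @return The filtered data.frame.
#' @export
filterAlignments <- function(aln, map_pid = 94, aln_cov = 0.70,
                             mapq_min = 20, read_qual_min = 20) {
    keep <- aln$pid >= map_pid &
        aln$read_cov >= aln_cov &
        aln$mapq >= mapq_min &
        (is.na(aln$mean_qual) | aln$mean_qual >= read_qual_min)
    aln[keep, , drop = FALSE]
}
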