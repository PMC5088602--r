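#' Estimate species coverage and relative abundance from USCG markers
#'
#' Reads are mapped locally against the marker database; alignments covering
#' less than `aln_cov` of the read or failing the family-specific percent
#' identity cutoff are discarded. Reads whose best hit is unique to one
#' species count fully for it; reads tying across species are split
#' fractionally in proportion to each tied species' uniquely-mapped read
#' counts (uniformly when all tied species have zero unique reads). Species
#' coverage is total aligned read bases on the species' markers divided by
#' total marker length; relative abundance normalises coverages to sum to 1.
#'
#' @param reads Character vector of read sequences, or a [readFastq()] list.
#' @param db A [MarkerDb-class].
#' @param quals Optional Phred+33 quality strings.
#' @param aln_cov Minimum aligned fraction of the read (default 0.70).
#' @param aln Optional precomputed alignments from [mapReads()] against
#'   `markerSequences(db)` (skips mapping).
#' @return A [SpeciesProfile-class]; when no read passes the filters all
#'   coverages are zero and the profile is flagged "no species detected".
#' @export
profileSpecies <- function(reads, db, quals = NULL, aln_cov = 0.70,
                           aln = NULL) {
    if (length(markerSequences(db)) == 0) stop("empty marker database")
    if (is.null(aln))
        aln <- mapReads(reads, markerSequences(db), mode = "local",
                        quals = quals)
    species <- sort(unique(db@species))
    mlen <- tapply(width(db@sequences), db@species, sum)[species]
    empty <- data.frame(species = species, coverage = 0,
                        relative_abundance = 0, count_reads = 0,
                        stringsAsFactors = FALSE)
    if (nrow(aln) == 0)
        return(new("SpeciesProfile", profile = empty, noSpeciesDetected = TRUE))

    fam <- db@family[aln$target]
    sp <- db@species[aln$target]
    keep <- aln$read_cov >= aln_cov & aln$pid >= db@cutoffs[fam]
    aln <- aln[keep, , drop = FALSE]
    sp <- sp[keep]
    if (nrow(aln) == 0)
        return(new("SpeciesProfile", profile = empty, noSpeciesDetected = TRUE))

    # one row per (read, species): a read tying between two markers of the
    # same species is still unique to that species
    first <- !duplicated(paste(aln$read, sp))
    aln <- aln[first, , drop = FALSE]
    sp <- sp[first]
    nsp <- table(aln$read)[as.character(aln$read)]
    weight <- numeric(nrow(aln))
    uniq <- nsp == 1
    weight[uniq] <- 1
    if (any(!uniq)) {
        ucount <- tapply(rep(1, sum(uniq)), sp[uniq], sum)
        uc <- ifelse(is.na(ucount[sp]), 0, ucount[sp])
        denom <- tapply(uc[!uniq], aln$read[!uniq], sum)[
            as.character(aln$read[!uniq])]
        w <- ifelse(denom > 0, uc[!uniq] / denom,
                    1 / as.numeric(nsp[!uniq]))
        weight[!uniq] <- w
    }
    bases <- (aln$rend - aln$rstart) * weight
    cov_bp <- tapply(bases, sp, sum)
    nreads <- tapply(weight, sp, sum)
    prof <- empty
    hit <- match(names(cov_bp), prof$species)
    prof$coverage[hit] <- as.numeric(cov_bp) / as.numeric(mlen[names(cov_bp)])
    prof$count_reads[hit] <- as.numeric(nreads)
    tot <- sum(prof$coverage)
    if (tot > 0) prof$relative_abundance <- prof$coverage / tot
    new("SpeciesProfile", profile = prof, noSpeciesDetected = tot == 0)
}

#' Select species above a coverage threshold
#'
#' @param profile A [SpeciesProfile-class].
#' @param min_coverage Strict lower bound on fold coverage (e.g. 1 for gene
#'   content, 10 for SNP calling).
#' @return Character vector of species ids, sorted by descending coverage.
#' @export
selectSpecies <- function(profile, min_coverage = 1) {
    if (min_coverage < 0) stop("min_coverage must be >= 0")
    p <- profileTable(profile)
    p <- p[p$coverage > min_coverage, , drop = FALSE]
    p$species[order(-p$coverage, p$species)]
}

#' Estimate total fold coverage of all cellular genomes in a sample
#'
#' `lenient_markers`: re-screen the marker alignments with the per-family
#' identity cutoff relaxed to `lenient_pid` (default 75%), so reads from
#' species missing from the database are still recruited to the family; for
#' each USCG family, aligned bases are divided by the family's mean marker
#' length, and the median across families is reported. `known_ags`: total
#' read bases divided by a supplied average genome size.
#'
#' @param reads Character vector of reads, or a [readFastq()] list.
#' @param db A [MarkerDb-class].
#' @param strategy `"lenient_markers"` or `"known_ags"`.
#' @param quals Optional quality strings.
#' @param ags Average genome size in bp (required for `known_ags`).
#' @param lenient_pid Relaxed identity cutoff.
#' @param aln_cov Alignment-coverage filter.
#' @param aln Optional precomputed marker alignments.
#' @return list with `total` (fold coverage), `strategy` and `flagged`
#'   (TRUE when no marker hit survived).
#' @export
estimateTotalCoverage <- function(reads, db,
                                  strategy = c("lenient_markers", "known_ags"),
                                  quals = NULL, ags = NULL, lenient_pid = 75,
                                  aln_cov = 0.70, aln = NULL) {
    strategy <- match.arg(strategy)
    if (is.list(reads) && !is.null(reads$seq)) reads <- reads$seq
    if (strategy == "known_ags") {
        if (is.null(ags) || ags <= 0)
            stop("known_ags strategy requires an average genome size")
        total <- sum(nchar(reads)) / ags
        return(list(total = total, strategy = strategy, flagged = total == 0))
    }
    if (is.null(aln))
        aln <- mapReads(reads, markerSequences(db), mode = "local",
                        quals = quals)
    fams <- sort(unique(db@family))
    if (nrow(aln) > 0) {
        keep <- aln$read_cov >= aln_cov & aln$pid >= lenient_pid
        aln <- aln[keep, , drop = FALSE]
        # best (first) surviving hit per read
        aln <- aln[!duplicated(aln$read), , drop = FALSE]
    }
    if (nrow(aln) == 0)
        return(list(total = 0, strategy = strategy, flagged = TRUE))
    fam <- db@family[aln$target]
    bp <- tapply(aln$rend - aln$rstart, fam, sum)
    mean_len <- tapply(width(db@sequences), db@family, mean)
    fold <- setNames(rep(0, length(fams)), fams)
    fold[names(bp)] <- as.numeric(bp) / as.numeric(mean_len[names(bp)])
    list(total = median(fold), strategy = strategy, flagged = all(fold == 0))
}

#' Database coverage of a sample
#'
#' The percentage of a community's total cellular genome coverage that is
#' attributable to species present in the reference database: 100 x (sum of
#' database species coverages) / (total coverage), capped at 100. Undefined
#' (`NA`) when the total is zero.
#'
#' @param profile A [SpeciesProfile-class].
#' @param total_coverage Denominator from [estimateTotalCoverage()].
#' @return Percentage in \[0, 100\] or `NA`.
#' @export
databaseCoverage <- function(profile, total_coverage) {
    if (total_coverage < 0) stop("total_coverage must be >= 0")
    if (total_coverage == 0) return(NA_real_)
    min(100, 100 * sum(speciesCoverage(profile)) / total_coverage)
}
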