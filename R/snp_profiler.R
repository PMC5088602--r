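#' Pileup of quality-filtered bases against representative genomes
#'
#' Reads are mapped globally (the whole read must align) against the
#' representative genome of each selected species, the standard alignment
#' filters (94 / 0.70 / 20 / 20) are applied, and per-position base counts
#' are accumulated from bases with quality `>= base_qual_min` (default 30).
#' `N` bases never contribute. Pileups are strand-agnostic.
#'
#' @param reads Character vector of reads, or a [readFastq()] list.
#' @param repGenomes Named [Biostrings::DNAStringSet] of representative
#'   genomes (one per species; the name is the contig/species id).
#' @param quals Phred+33 quality strings (required for the base filter; if
#'   missing, all bases pass).
#' @param map_pid,aln_cov,mapq_min,read_qual_min Alignment filters.
#' @param base_qual_min Per-base quality cutoff for the pileup.
#' @param aln Optional precomputed global alignments.
#' @return Named list per genome of 4 x L integer count matrices (rows
#'   A, C, G, T).
#' @export
pileupSites <- function(reads, repGenomes, quals = NULL,
                        map_pid = 94, aln_cov = 0.70, mapq_min = 20,
                        read_qual_min = 20, base_qual_min = 30, aln = NULL) {
    if (is.list(reads) && !is.null(reads$seq)) {
        if (is.null(quals)) quals <- reads$qual
        reads <- reads$seq
    }
    if (is.null(aln))
        aln <- mapReads(reads, repGenomes, mode = "global", quals = quals)
    aln <- filterAlignments(aln, map_pid = map_pid, aln_cov = aln_cov,
                            mapq_min = mapq_min, read_qual_min = read_qual_min)
    if (is.null(quals) || length(quals) == 0)
        quals <- vapply(nchar(reads), function(n)
            paste(rep("I", n), collapse = ""), "")
    counts <- cpp_pileup(aln$target, aln$strand, aln$tstart, aln$rstart,
                         aln$cigar, reads[aln$read], quals[aln$read],
                         setNames(width(repGenomes), NULL),
                         as.integer(base_qual_min))
    names(counts) <- names(repGenomes)
    counts
}

#' Per-site summary table from a pileup
#'
#' @param counts A 4 x L count matrix from [pileupSites()].
#' @param refseq Reference sequence of the contig (character or DNAString).
#' @param contig Contig id.
#' @return data.frame with `contig`, `pos` (0-based), `pos_1based`, `ref`,
#'   counts `A`, `C`, `G`, `T`, `depth` and the `consensus` allele (ties and
#'   zero depth give `NA`).
#' @export
siteSummary <- function(counts, refseq, contig = "contig") {
    L <- ncol(counts)
    ref <- strsplit(toupper(as.character(refseq)), "")[[1]]
    depth <- colSums(counts)
    top <- do.call(pmax, lapply(1:4, function(i) counts[i, ]))
    n_top <- colSums(counts == rep(top, each = 4)) # ties share the max
    cons <- rownames(counts)[max.col(t(counts), ties.method = "first")]
    cons[depth == 0 | n_top > 1] <- NA_character_
    data.frame(contig = contig, pos = seq_len(L) - 1L,
               pos_1based = seq_len(L),
               ref = ref[seq_len(L)],
               A = counts["A", ], C = counts["C", ],
               G = counts["G", ], T = counts["T", ],
               depth = depth, consensus = cons,
               stringsAsFactors = FALSE)
}

#' Identify the core genome from per-sample depth
#'
#' A site is core iff its depth is strictly greater than `min_depth` in at
#' least `sample_fraction` of the samples (defaults: > 10x in >= 95%).
#' Raising either parameter never grows the core set.
#'
#' @param depth Sites x samples numeric matrix of (quality-filtered) depths.
#' @param min_depth Strict depth lower bound.
#' @param sample_fraction Inclusive fraction of samples.
#' @return Integer vector of 0-based core positions.
#' @export
identifyCore <- function(depth, min_depth = 10, sample_fraction = 0.95) {
    if (is.null(dim(depth))) depth <- matrix(depth, ncol = 1)
    if (ncol(depth) == 0) stop("zero samples")
    frac <- rowMeans(depth > min_depth)
    which(frac >= sample_fraction) - 1L
}

#' Merge per-sample pileups into SNP matrices
#'
#' Pools counts across samples to define the cohort-wide major (highest
#' pooled count) and minor (second highest) allele at each site, then builds
#' sites x samples matrices of minor-allele frequency and depth. Zero depth
#' in a sample is encoded as `NA` frequency (missing), distinct from
#' frequency 0. Sites covered in no sample are excluded.
#'
#' @param countsList Named list (sample id) of 4 x L count matrices for one
#'   contig.
#' @param core Optional 0-based positions restricting the output to the core
#'   genome; `NULL` emits all covered sites.
#' @param refseq Optional reference sequence for the `ref` column.
#' @param contig Contig id.
#' @return A [SnpExperiment-class].
#' @export
mergeSnps <- function(countsList, core = NULL, refseq = NULL,
                      contig = "contig") {
    if (length(countsList) == 0) stop("no samples")
    if (is.null(names(countsList)))
        names(countsList) <- paste0("sample", seq_along(countsList))
    pooled <- Reduce(`+`, countsList)
    L <- ncol(pooled)
    sites <- if (is.null(core)) which(colSums(pooled) > 0) - 1L
             else sort(as.integer(core))
    bases <- c("A", "C", "G", "T")
    ord <- apply(pooled[, sites + 1L, drop = FALSE], 2, order,
                 decreasing = TRUE)
    major <- bases[ord[1, ]]
    minor <- bases[ord[2, ]]
    minor[pooled[cbind(ord[2, ], sites + 1L)] == 0] <- NA_character_
    nsamp <- length(countsList)
    freq <- depth <- matrix(NA_real_, length(sites), nsamp,
                            dimnames = list(sites + 1L, names(countsList)))
    for (j in seq_len(nsamp)) {
        cc <- countsList[[j]][, sites + 1L, drop = FALSE]
        d <- colSums(cc)
        mc <- ifelse(is.na(minor), 0,
                     cc[cbind(match(minor, bases), seq_along(sites))])
        depth[, j] <- d
        freq[, j] <- ifelse(d > 0, mc / d, NA_real_)
    }
    rd <- S4Vectors::DataFrame(contig = contig, pos = sites,
                               pos_1based = sites + 1L,
                               major = major, minor = minor)
    if (!is.null(refseq)) {
        ref <- strsplit(toupper(as.character(refseq)), "")[[1]]
        rd$ref <- ref[sites + 1L]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(freq = freq, depth = depth), rowData = rd,
        colData = S4Vectors::DataFrame(sample_id = names(countsList),
                                       row.names = names(countsList)))
    new("SnpExperiment", se)
}

#' Consensus SNP calls against the reference
#'
#' At every position with depth >= 1, the consensus (highest-count) allele is
#' compared with the reference; a disagreement is a SNP call. Ties for the
#' top count are conservative: no call.
#'
#' @param counts 4 x L count matrix from [pileupSites()].
#' @param refseq Reference sequence.
#' @return data.frame (`pos` 0-based, `ref`, `allele`) of called SNPs.
#' @export
consensusSnpCalls <- function(counts, refseq) {
    ref <- strsplit(toupper(as.character(refseq)), "")[[1]]
    depth <- colSums(counts)
    mx <- do.call(pmax, lapply(1:4, function(i) counts[i, ]))
    nt <- colSums(counts == rep(mx, each = 4))
    cons <- rownames(counts)[max.col(t(counts), ties.method = "first")]
    call <- depth >= 1 & nt == 1 & cons != ref[seq_len(ncol(counts))] &
        ref[seq_len(ncol(counts))] %in% rownames(counts)
    data.frame(pos = which(call) - 1L, ref = ref[call], allele = cons[call],
               stringsAsFactors = FALSE)
}

#' Export a per-sample site summary as VCF 4.2
#'
#' Minimal single-sample VCF export of variable sites (consensus differs from
#' the reference or more than one allele observed), with allelic depths.
#' Positions are 1-based per VCF convention.
#'
#' @param summary data.frame from [siteSummary()].
#' @param path Output path.
#' @param sample Sample id for the header.
#' @export
writeVcf <- function(summary, path, sample = "sample1") {
    bases <- c("A", "C", "G", "T")
    cnt <- as.matrix(summary[, bases])
    nallele <- rowSums(cnt > 0)
    variable <- summary$depth > 0 &
        (nallele > 1 | (!is.na(summary$consensus) &
                        summary$consensus != summary$ref))
    v <- summary[variable, , drop = FALSE]
    hdr <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tFORMAT\t", sample))
    rows <- vapply(seq_len(nrow(v)), function(i) {
        cc <- cnt[variable, , drop = FALSE][i, ]
        alts <- bases[cc > 0 & bases != v$ref[i]]
        if (length(alts) == 0) alts <- "."
        ad <- c(cc[v$ref[i]], cc[setdiff(bases[cc > 0], v$ref[i])])
        paste(v$contig[i], v$pos_1based[i], ".", v$ref[i],
              paste(alts, collapse = ","), ".", "PASS", "DP:AD",
              paste0(v$depth[i], ":", paste(ad, collapse = ",")),
              sep = "\t")
    }, "")
    writeLines(c(hdr, rows), path)
    invisible(path)
}
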