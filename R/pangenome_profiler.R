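#' Gene coverage from filtered pan-genome alignments
#'
#' Coverage of each 99% gene cluster: total aligned read bases on the cluster
#' centroid divided by centroid length. Alignments must already carry the
#' standard filters (identity 94, coverage 0.70, mapq 20, read quality 20);
#' the mapq filter removes reads tying across clusters, so each read counts
#' once, for its best hit.
#'
#' @param aln Filtered alignment data.frame whose `target_id` values are
#'   cluster ids of `pg`.
#' @param pg A [PanGenome-class].
#' @return Named numeric vector: fold coverage per cluster (0 for unmapped
#'   clusters).
#' @export
geneCoverage <- function(aln, pg) {
    cids <- names(pg@centroids)
    cov <- setNames(rep(0, length(cids)), cids)
    if (nrow(aln) > 0) {
        hit <- aln$target_id %in% cids
        bp <- tapply((aln$rend - aln$rstart)[hit], aln$target_id[hit], sum)
        clen <- setNames(width(pg@centroids), cids)
        cov[names(bp)] <- as.numeric(bp) / clen[names(bp)]
    }
    cov
}

#' Median USCG coverage of a species
#'
#' The copy-number normaliser: per USCG family, the summed coverage of the
#' clusters flagged with the family; the median across the panel's families
#' (families without any mapped cluster count as 0). A normaliser of 0 flags
#' the species as unusable at the sample's depth.
#'
#' @param cov Named cluster coverages from [geneCoverage()].
#' @param pg A [PanGenome-class] with USCG flags.
#' @return Single numeric fold coverage.
#' @export
uscgNormalizer <- function(cov, pg) {
    flags <- uscgFlags(pg)
    fams <- sort(unique(flags[!is.na(flags)]))
    if (length(fams) == 0) stop("pan-genome carries no USCG flags")
    per_fam <- vapply(fams, function(f)
        sum(cov[names(flags)[!is.na(flags) & flags == f]]), numeric(1))
    median(per_fam)
}

#' Gene copy number per cell
#'
#' Gene coverage divided by the species' median USCG coverage. Undefined
#' (`NA`) for every gene when the normaliser is 0.
#'
#' @param cov Named cluster coverages.
#' @param normalizer Median USCG coverage from [uscgNormalizer()].
#' @return Named numeric copy numbers.
#' @export
copyNumber <- function(cov, normalizer) {
    if (normalizer < 0) stop("normalizer must be >= 0")
    if (normalizer == 0) return(setNames(rep(NA_real_, length(cov)), names(cov)))
    cov / normalizer
}

#' Threshold copy numbers into presence-absence calls
#'
#' A gene with copy number below the cutoff (default 0.35) is absent;
#' `copy_number >= cutoff` is present (closed lower bound).
#'
#' @param copy_number Numeric vector (NAs stay NA).
#' @param cutoff Copy-number cutoff.
#' @return Logical vector.
#' @export
presenceAbsence <- function(copy_number, cutoff = 0.35) {
    if (any(copy_number < 0, na.rm = TRUE)) stop("copy numbers must be >= 0")
    copy_number >= cutoff
}

#' Aggregate cluster coverages into coarser families
#'
#' Family coverage is the sum of its member clusters' coverages; copy number
#' and presence are then computed on the aggregated values. Total coverage is
#' conserved.
#'
#' @param cov Named cluster coverages.
#' @param familyMap Named character vector (cluster id -> family id) from
#'   [aggregateFamilies()].
#' @return Named numeric vector of family coverages.
#' @export
aggregateCoverage <- function(cov, familyMap) {
    unmapped <- setdiff(names(cov), names(familyMap))
    if (length(unmapped))
        stop("cluster not in family map: ", unmapped[1])
    out <- tapply(cov, familyMap[names(cov)], sum)
    setNames(as.numeric(out), names(out))
}

#' Per-sample gene content of selected species
#'
#' Maps reads locally against the pooled pan-genome centroids of the selected
#' species, applies the standard filters, and computes per-species cluster
#' coverage, copy number (median-USCG normalised) and presence-absence.
#'
#' @param reads Character vector of reads, or a [readFastq()] list.
#' @param pangenomes Named list of [PanGenome-class] objects (the selected
#'   species).
#' @param quals Optional Phred+33 quality strings.
#' @param map_pid,aln_cov,mapq_min,read_qual_min Filter thresholds
#'   (defaults 94 / 0.70 / 20 / 20).
#' @param copynum_cutoff Presence cutoff on copy number (default 0.35).
#' @return Named list per species: data.frame (`gene_id`, `coverage`,
#'   `copy_number`, `presence`) plus attributes `normalizer` and `flagged`.
#' @export
profileGenes <- function(reads, pangenomes, quals = NULL,
                         map_pid = 94, aln_cov = 0.70, mapq_min = 20,
                         read_qual_min = 20, copynum_cutoff = 0.35) {
    if (is(pangenomes, "PanGenome")) pangenomes <- list(pangenomes)
    if (is.null(names(pangenomes)))
        names(pangenomes) <- vapply(pangenomes, function(p) p@speciesId, "")
    targets <- do.call(c, lapply(names(pangenomes), function(s) {
        ctr <- pangenomes[[s]]@centroids
        names(ctr) <- paste(s, names(ctr), sep = "|")
        ctr
    }))
    aln <- mapReads(reads, targets, mode = "local", quals = quals)
    aln <- filterAlignments(aln, map_pid = map_pid, aln_cov = aln_cov,
                            mapq_min = mapq_min, read_qual_min = read_qual_min)
    sp_of <- sub("\\|.*$", "", aln$target_id)
    gene_of <- sub("^[^|]*\\|", "", aln$target_id)
    out <- list()
    for (s in names(pangenomes)) {
        pg <- pangenomes[[s]]
        sub <- aln[sp_of == s, , drop = FALSE]
        sub$target_id <- gene_of[sp_of == s]
        cov <- geneCoverage(sub, pg)
        norm <- uscgNormalizer(cov, pg)
        cn <- copyNumber(cov, norm)
        pres <- presenceAbsence(cn, copynum_cutoff)
        df <- data.frame(gene_id = names(cov), coverage = unname(cov),
                         copy_number = unname(cn), presence = unname(pres),
                         stringsAsFactors = FALSE)
        attr(df, "normalizer") <- norm
        attr(df, "flagged") <- norm == 0
        out[[s]] <- df
    }
    out
}

#' Merge per-sample gene content into matrices
#'
#' Builds genes x samples matrices of coverage, copy number and presence for
#' one species across samples.
#'
#' @param samples Named list (sample id) of per-species data.frames as
#'   produced by [profileGenes()] (the element for this species).
#' @param speciesId Species id recorded in the result.
#' @return A [GeneContentExperiment-class].
#' @export
mergeGeneContent <- function(samples, speciesId = "species") {
    if (length(samples) == 0) stop("no samples to merge")
    if (is.null(names(samples)))
        names(samples) <- paste0("sample", seq_along(samples))
    genes <- sort(unique(unlist(lapply(samples, function(d) d$gene_id))))
    mk <- function(col, default) {
        m <- matrix(default, length(genes), length(samples),
                    dimnames = list(genes, names(samples)))
        for (s in names(samples)) {
            d <- samples[[s]]
            m[d$gene_id, s] <- d[[col]]
        }
        m
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(coverage = mk("coverage", 0),
                      copy_number = mk("copy_number", NA_real_),
                      presence = mk("presence", NA)),
        rowData = S4Vectors::DataFrame(gene_id = genes),
        colData = S4Vectors::DataFrame(sample_id = names(samples),
                                       row.names = names(samples)))
    out <- new("GeneContentExperiment", se)
    S4Vectors::metadata(out)$species_id <- speciesId
    out
}

#' Jaccard distances between samples on gene presence
#'
#' Distance = 1 - |intersection| / |union| of the presence sets; undefined
#' (`NA`) when both sets are empty.
#'
#' @param gce A [GeneContentExperiment-class] (or a logical genes x samples
#'   presence matrix).
#' @return Symmetric samples x samples distance matrix.
#' @export
jaccardDistances <- function(gce) {
    P <- if (is(gce, "GeneContentExperiment"))
        SummarizedExperiment::assay(gce, "presence") else gce
    P[is.na(P)] <- FALSE
    n <- ncol(P)
    D <- matrix(0, n, n, dimnames = list(colnames(P), colnames(P)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i) next
        inter <- sum(P[, i] & P[, j])
        uni <- sum(P[, i] | P[, j])
        D[i, j] <- D[j, i] <- if (uni == 0) NA_real_ else 1 - inter / uni
    }
    D
}
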