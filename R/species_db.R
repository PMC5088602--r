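#' Percent identity between two marker genes
#'
#' Best seeded local alignment between two nucleotide sequences; identity is
#' matches / alignment columns x 100. The value is undefined (NA) when the
#' alignment covers less than `min_cov` (default 70%) of either sequence, or
#' when the sequences share no seed k-mer at all.
#'
#' @param seq_a,seq_b Nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param min_cov Mutual alignment-coverage threshold.
#' @param k Seed k-mer length.
#' @param band DP band half-width.
#' @return Percent identity in \[0, 100\], or `NA` when masked.
#' @export
markerPercentIdentity <- function(seq_a, seq_b, min_cov = 0.70,
                                  k = 12, band = 8) {
    a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
    if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
    cpp_pid_query(a, b, as.integer(k), as.integer(band), min_cov)[1, 1]
}

#' Convert percent identity to distance
#'
#' `D = (100 - P) / 100`, so the species cutoff of 0.035 corresponds to
#' 96.5% nucleotide identity.
#'
#' @param p Percent identity (0-100); vectorised, NAs pass through.
#' @return Distance in \[0, 1\].
#' @export
percentIdentityToDistance <- function(p) {
    bad <- !is.na(p) & (p < 0 | p > 100)
    if (any(bad)) stop("percent identity out of [0, 100]: ", p[bad][1])
    (100 - p) / 100
}

#' Per-family marker distance matrices
#'
#' For each marker family, computes the pairwise percent-identity matrix over
#' all genomes carrying the family and converts it to distances. Entries are
#' `NA` (masked) where the alignment-coverage filter failed or a genome lacks
#' the family.
#'
#' @param markerSets Named list (genome id) of named character vectors
#'   (family id -> marker sequence).
#' @param min_cov Mutual alignment-coverage threshold.
#' @param k,band Aligner parameters.
#' @return Named list (family id) of symmetric distance matrices over the full
#'   genome universe.
#' @export
markerDistanceMatrices <- function(markerSets, min_cov = 0.70,
                                   k = 12, band = 8) {
    if (length(markerSets) == 0) stop("no genomes")
    genomes <- names(markerSets)
    fams <- sort(unique(unlist(lapply(markerSets, names))))
    out <- list()
    for (f in fams) {
        has <- vapply(markerSets, function(m) f %in% names(m), logical(1))
        D <- matrix(NA_real_, length(genomes), length(genomes),
                    dimnames = list(genomes, genomes))
        gs <- genomes[has]
        if (length(gs) >= 1) {
            seqs <- vapply(markerSets[gs], function(m) unname(m[[f]]), "")
            P <- cpp_pid_matrix(unname(seqs), as.integer(k),
                                as.integer(band), min_cov)
            D[gs, gs] <- percentIdentityToDistance(P)
        }
        out[[f]] <- D
    }
    out
}

#' Average distances across marker families
#'
#' Entry (a, b) is the mean of the defined per-family distances; it stays
#' masked (`NA`) only when no family defines a distance for the pair.
#'
#' @param matrices Non-empty list of equally-dimensioned distance matrices
#'   (NA = masked).
#' @return A single averaged distance matrix.
#' @export
averageMarkerDistance <- function(matrices) {
    if (length(matrices) == 0) stop("empty matrix collection")
    dims <- dim(matrices[[1]])
    sum_ <- matrix(0, dims[1], dims[2], dimnames = dimnames(matrices[[1]]))
    n_ <- matrix(0L, dims[1], dims[2])
    for (m in matrices) {
        ok <- !is.na(m)
        sum_[ok] <- sum_[ok] + m[ok]
        n_ <- n_ + ok
    }
    avg <- sum_ / n_
    avg[n_ == 0] <- NA_real_
    diag(avg) <- 0
    avg
}

#' Delineate species by average-linkage clustering
#'
#' UPGMA agglomeration on the averaged marker distance matrix; merging stops
#' once the minimum inter-cluster average distance exceeds the cutoff
#' (default 0.035, i.e. 96.5% identity). Masked pairwise distances are treated
#' as 1.0 (never mergeable). Species ids are assigned from the
#' lexicographically smallest member genome id, so the labelling is invariant
#' to input order.
#'
#' @param D Symmetric distance matrix (genomes x genomes; NA = masked).
#' @param cutoff Distance cutoff in \[0, 1\].
#' @return data.frame (`genome_id`, `species_id`) with the cutoff stored in
#'   attribute `"cutoff"`.
#' @export
averageLinkageCluster <- function(D, cutoff = 0.035) {
    if (is.null(dim(D)) || nrow(D) == 0) stop("no genomes to cluster")
    if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
    genomes <- rownames(D)
    if (is.null(genomes)) genomes <- paste0("g", seq_len(nrow(D)))
    if (nrow(D) == 1) {
        memb <- setNames(1L, genomes)
    } else {
        D2 <- D
        D2[is.na(D2)] <- 1.0
        hc <- hclust(as.dist(D2), method = "average")
        memb <- cutree(hc, h = cutoff)
        names(memb) <- genomes
    }
    # stable species ids: order clusters by smallest member genome id
    mins <- tapply(genomes, memb, min)
    ord <- order(mins)
    relab <- setNames(seq_along(ord), names(mins)[ord])
    out <- data.frame(
        genome_id = genomes,
        species_id = paste0("s", relab[as.character(memb)]),
        stringsAsFactors = FALSE)
    attr(out, "cutoff") <- cutoff
    out
}

#' Score a species assignment against ANI labels
#'
#' Genome pairs with ANI >= 95% are labelled same-species. A clustered pair
#' with ANI >= 95 is a true positive, clustered with ANI < 95 a false
#' positive, split with ANI >= 95 a false negative, split with ANI < 95 a
#' true negative. Returns TPR, PPV and F1 with the underlying counts.
#'
#' @param assignment data.frame (`genome_id`, `species_id`) from
#'   [averageLinkageCluster()].
#' @param ani_labels data.frame with columns `genome_a`, `genome_b`, `ani`.
#' @return list with `counts` (TP, FP, FN, TN), `TPR`, `PPV`, `F1`.
#' @export
evaluateAgainstAni <- function(assignment, ani_labels) {
    if (nrow(ani_labels) == 0) stop("no labeled genome pairs")
    sp <- setNames(assignment$species_id, assignment$genome_id)
    clustered <- sp[ani_labels$genome_a] == sp[ani_labels$genome_b]
    same <- ani_labels$ani >= 95
    TP <- sum(clustered & same); FP <- sum(clustered & !same)
    FN <- sum(!clustered & same); TN <- sum(!clustered & !same)
    TPR <- if (TP + FN > 0) TP / (TP + FN) else NaN
    PPV <- if (TP + FP > 0) TP / (TP + FP) else NaN
    F1 <- if (!is.nan(TPR) && !is.nan(PPV) && (TPR + PPV) > 0)
        2 * TPR * PPV / (TPR + PPV) else 0
    if (TP == 0) F1 <- 0
    list(counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
         TPR = TPR, PPV = PPV, F1 = F1)
}

#' Select the representative genome of a species
#'
#' The member maximising the mean identity (averaged marker identity) to all
#' other members; singletons represent themselves; ties break to the
#' lexicographically smallest genome id.
#'
#' @param members Character vector of member genome ids.
#' @param identity Symmetric percent-identity matrix covering the members
#'   (typically `100 * (1 - averaged distance)`).
#' @return A single genome id.
#' @export
selectRepresentative <- function(members, identity = NULL) {
    if (length(members) == 0) stop("no genomes in species")
    if (length(members) == 1) return(members)
    mean_id <- vapply(members, function(g) {
        others <- setdiff(members, g)
        mean(identity[g, others], na.rm = TRUE)
    }, numeric(1))
    members[order(-mean_id, members)][1]
}

#' Build a species pan-genome by greedy centroid clustering
#'
#' Genes are sorted by decreasing length (ties lexicographic by id) and each
#' gene joins the first existing centroid with `>= identity` percent identity
#' over `>= min_cov` mutual coverage, else founds a new cluster. Cluster ids
#' equal the centroid gene id.
#'
#' @param genes Named [Biostrings::DNAStringSet] (or named character vector)
#'   of all annotated genes of the species.
#' @param speciesId Species id.
#' @param identity Clustering identity threshold in percent (default 99).
#' @param min_cov Mutual coverage threshold.
#' @param uscgFamily Optional named character vector mapping gene ids to USCG
#'   family ids; clusters whose centroid carries a flag are marked.
#' @param k,band Aligner parameters.
#' @return A [PanGenome-class] object.
#' @export
buildPangenome <- function(genes, speciesId = "species", identity = 99,
                           min_cov = 0.70, uscgFamily = NULL,
                           k = 12, band = 8) {
    if (length(genes) == 0) stop("no genes")
    seqs <- toupper(as.character(genes))
    ids <- names(genes)
    if (is.null(ids)) ids <- paste0("gene", seq_along(seqs))
    ord <- order(-nchar(seqs), ids)
    seqs <- seqs[ord]; ids <- ids[ord]
    assign_ <- greedyCentroidCluster(seqs, ids, identity, min_cov, k, band)
    cent_idx <- assign_$centroid_index
    members <- split(ids, assign_$cluster_of)
    cids <- ids[cent_idx]
    members <- members[cids]  # founding order
    centroids <- Biostrings::DNAStringSet(seqs[cent_idx])
    names(centroids) <- cids
    uf <- rep(NA_character_, length(cids))
    if (!is.null(uscgFamily)) {
        # a cluster is USCG-flagged when any member carries a flag
        for (i in seq_along(cids)) {
            flagged <- intersect(members[[i]], names(uscgFamily))
            if (length(flagged)) uf[i] <- unname(uscgFamily[flagged[1]])
        }
    }
    new("PanGenome", speciesId = speciesId, centroids = centroids,
        members = members, uscgFamily = uf, familyMaps = list())
}

# greedy length-sorted first-fit clustering; inputs already sorted
greedyCentroidCluster <- function(seqs, ids, identity, min_cov, k, band) {
    n <- length(seqs)
    cent_idx <- integer(0)
    cluster_of <- character(n)
    for (i in seq_len(n)) {
        hit <- NA_integer_
        if (length(cent_idx)) {
            p <- cpp_pid_query(seqs[i], seqs[cent_idx], as.integer(k),
                               as.integer(band), min_cov)[1, ]
            ok <- which(!is.na(p) & p >= identity)
            if (length(ok)) hit <- ok[1]
        }
        if (is.na(hit)) {
            cent_idx <- c(cent_idx, i)
            cluster_of[i] <- ids[i]
        } else {
            cluster_of[i] <- ids[cent_idx[hit]]
        }
    }
    list(centroid_index = cent_idx, cluster_of = factor(cluster_of,
        levels = ids[cent_idx]))
}

#' Aggregate 99% gene clusters into coarser families
#'
#' Greedy centroid clustering of the 99% centroids at a coarser identity
#' level (75, 80, 85, 90 or 95% identity). Downstream coverage aggregation
#' sums member-cluster coverages. The map is also stored in the returned
#' PanGenome's `familyMaps`.
#'
#' @param pg A [PanGenome-class].
#' @param level Aggregation identity level, one of 75, 80, 85, 90, 95.
#' @param min_cov,k,band Aligner parameters.
#' @return Named character vector mapping 99% cluster id to coarse family id
#'   (the founding centroid's cluster id prefixed with the level).
#' @export
aggregateFamilies <- function(pg, level, min_cov = 0.70, k = 12, band = 8) {
    if (!level %in% c(75, 80, 85, 90, 95))
        stop("invalid aggregation level: ", level)
    seqs <- as.character(pg@centroids)
    ids <- names(pg@centroids)
    ord <- order(-nchar(seqs), ids)
    a <- greedyCentroidCluster(seqs[ord], ids[ord], level, min_cov, k, band)
    map <- setNames(paste0("fam", level, "_", as.character(a$cluster_of)),
                    ids[ord])
    map[ids]
}

#' Consensus Latin name of a species
#'
#' Modal non-empty genome label; ties break lexicographically; if every label
#' is empty the species is named `unnamed_<species_id>`.
#'
#' @param labels Character vector of per-genome labels (may be empty strings).
#' @param speciesId Species id used for the unnamed fallback.
#' @return A single name.
#' @export
consensusName <- function(labels, speciesId = "s1") {
    labels <- labels[!is.na(labels) & nzchar(labels)]
    if (length(labels) == 0) return(paste0("unnamed_", speciesId))
    tab <- table(labels)
    cand <- names(tab)[tab == max(tab)]
    sort(cand)[1]
}
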