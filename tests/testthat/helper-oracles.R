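# Independent oracles used to freeze expected values: a brute-force UPGMA
# agglomerator and full (unbanded) dynamic-programming aligners.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_seq <- function(seq, positions, bases) {
    v <- strsplit(seq, "")[[1]]
    v[positions] <- bases
    paste(v, collapse = "")
}

# exhaustive average-linkage agglomeration: at each step merge the pair of
# clusters with the smallest mean pairwise distance, stopping when that
# minimum exceeds the cutoff. Returns a membership vector.
brute_force_upgma <- function(D, cutoff) {
    D[is.na(D)] <- 1
    ids <- rownames(D)
    clusters <- as.list(ids)
    repeat {
        if (length(clusters) == 1) break
        bestd <- Inf; best <- NULL
        for (i in 2:length(clusters)) for (j in 1:(i - 1)) {
            d <- mean(D[clusters[[i]], clusters[[j]]])
            if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
        }
        if (bestd > cutoff) break
        clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
        clusters[[best[1]]] <- NULL
    }
    m <- character(length(ids)); names(m) <- ids
    for (i in seq_along(clusters)) m[clusters[[i]]] <- paste0("c", i)
    m
}

# two partitions (membership vectors over the same ids) are equal up to label
same_partition <- function(a, b) {
    a <- a[sort(names(a))]; b <- b[sort(names(b))]
    length(unique(paste(a, b))) == length(unique(a)) &&
        length(unique(a)) == length(unique(b))
}

# full Smith-Waterman local alignment score (linear gaps), no banding
sw_score <- function(a, b, match = 1, mismatch = -2, gap = -3) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    la <- length(a); lb <- length(b)
    prev <- numeric(lb + 1); best <- 0
    for (i in seq_len(la)) {
        cur <- numeric(lb + 1)
        for (j in seq_len(lb)) {
            s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
            cur[j + 1] <- max(0, prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
        }
        best <- max(best, max(cur))
        prev <- cur
    }
    best
}

# full glocal score: entire read a must align; target gaps free at both ends
glocal_score <- function(a, b, match = 1, mismatch = -2, gap = -3) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    la <- length(a); lb <- length(b)
    prev <- numeric(lb + 1)   # row 0: free target prefix
    for (i in seq_len(la)) {
        cur <- rep(-Inf, lb + 1)
        cur[1] <- prev[1] + gap
        for (j in seq_len(lb)) {
            s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
            cur[j + 1] <- max(prev[j] + s, prev[j + 1] + gap, cur[j] + gap)
        }
        prev <- cur
    }
    max(prev)
}

# small end-to-end fixture: one species set shared across tests
tiny_species_set <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulateSpeciesSet(99, n_species = 3, n_genes = 8,
                                         marker_len = 1000,
                                         n_families = 6,
                                         n_abundance_families = 4)
        cache
    }
})
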