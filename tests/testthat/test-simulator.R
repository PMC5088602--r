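test_that("exponential abundances follow the halving series", {
    a <- exponentialAbundances(20)
    expect_equal(a[1], 0.50, tolerance = 1e-5)
    expect_equal(a[2], 0.25, tolerance = 1e-5)
    expect_equal(a[3], 0.125, tolerance = 1e-4)
    expect_equal(a[4], 0.0625, tolerance = 1e-4)
    expect_equal(sum(a), 1)
    expect_equal(exponentialAbundances(1), 1)
    expect_equal(sum(exponentialAbundances(7)), 1)
    expect_error(exponentialAbundances(0), ">= 1")
})

test_that("species sets are deterministic under a fixed seed", {
    s1 <- simulateSpeciesSet(7, n_species = 2, n_genes = 4,
                             n_families = 4, n_abundance_families = 2,
                             marker_len = 300)
    s2 <- simulateSpeciesSet(7, n_species = 2, n_genes = 4,
                             n_families = 4, n_abundance_families = 2,
                             marker_len = 300)
    expect_equal(as.character(s1@repGenomes), as.character(s2@repGenomes))
    expect_equal(s1@clusterMarkers, s2@clusterMarkers)
    c1 <- simulateCommunity(s1, setNames(c(0.7, 0.3), s1@species),
                            total_coverage = 5, seed = 71)
    c2 <- simulateCommunity(s2, setNames(c(0.7, 0.3), s2@species),
                            total_coverage = 5, seed = 71)
    expect_equal(c1$reads, c2$reads)
    expect_equal(c1$quals, c2$quals)
})

test_that("marker divergence bands hold on the emitted sequences", {
    set <- simulateSpeciesSet(8, n_species = 4, n_strains = 3,
                              markers_only = TRUE, marker_len = 400)
    cm <- set@clusterMarkers
    sp_of <- setNames(set@genomes$species_id, set@genomes$genome_id)
    g <- names(cm)
    for (f in c("fam01", "fam07")) {
        seqs <- vapply(cm[g], function(m) m[[f]], "")
        P <- outer(seq_along(g), seq_along(g), Vectorize(function(i, j)
            if (i >= j) NA_real_ else markerPercentIdentity(seqs[i], seqs[j])))
        same <- outer(sp_of[g], sp_of[g], "==")
        # pairwise divergence targets: ~2% within, ~10% between; the bands
        # must stay separated by the 96.5% species boundary
        expect_gte(mean(P[!is.na(P) & same]), 97.5)
        expect_true(all(P[!is.na(P) & same] > 96))
        expect_true(all(P[!is.na(P) & !same] < 95))
    }
})

test_that("strain truth is consistent with the species pan-genome", {
    set <- tiny_species_set()
    set.seed(72)
    st <- simulateStrain(set, "sp01")
    pg_ids <- names(centroids(set@pangenomes[["sp01"]]))
    expect_true(all(st$genes %in% pg_ids))
    # all markers and core genes retained; length shrinks only by lost genes
    anc <- set@ancestors[["sp01"]]
    expect_true(all(anc$core_genes %in% st$genes))
    lost <- setdiff(anc$accessory_genes, st$genes)
    seg <- anc$segments
    expect_equal(st$length,
                 length(anc$codes) - sum(seg$end[seg$id %in% lost] -
                                         seg$start[seg$id %in% lost]))
    # SNP truth never points into a dropped gene
    for (g in lost) {
        i <- which(seg$id == g)
        expect_false(any(st$snps$pos >= seg$start[i] &
                         st$snps$pos < seg$end[i]))
    }
})

test_that("read simulation matches its own error and count models", {
    set.seed(73)
    genome <- list(g = random_seq(20000))
    rd <- simulateReads(genome, c(g = 10), error_rate = 0.01)
    expected_n <- 10 * 20000 / 100
    expect_lt(abs(length(rd$reads) - expected_n) / expected_n, 0.1)

    # mismatch fraction vs the source, 0.01 +- 0.002 over ~2e5 bases
    src <- strsplit(genome$g, "")[[1]]
    mm <- 0; tot <- 0
    for (i in seq_along(rd$reads)) {
        r <- rd$reads[i]
        if (rd$strand[i] == "-")
            r <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(r)))
        v <- strsplit(r, "")[[1]]
        ref <- src[(rd$start[i] + 1):(rd$start[i] + 100)]
        mm <- mm + sum(v != ref); tot <- tot + 100
    }
    expect_lt(abs(mm / tot - 0.01), 0.002)

    # error-free reads are exact substrings
    rd0 <- simulateReads(genome, c(g = 1), error_rate = 0)
    i <- which(rd0$strand == "+")[1]
    expect_equal(rd0$reads[i],
                 substr(genome$g, rd0$start[i] + 1, rd0$start[i] + 100))

    # zero coverage: no reads
    expect_equal(length(simulateReads(genome, c(g = 0))$reads), 0L)
})

test_that("classification metrics reproduce the confusion-matrix formulas", {
    u <- paste0("x", 1:20)
    m <- classificationMetrics(u[1:10], u[1:10], u)
    expect_equal(m$sensitivity, 1)
    expect_equal(m$specificity, 1)
    expect_equal(m$balanced_accuracy, 1)
    expect_equal(m$FDR, 0)

    # TP=9, FP=1, FN=1, TN=9
    m2 <- classificationMetrics(c(u[1:9], u[11]), u[1:10], u)
    expect_equal(unname(m2$counts), c(9, 1, 1, 9))
    expect_equal(m2$sensitivity, 0.9)
    expect_equal(m2$specificity, 0.9)
    expect_equal(m2$precision, 0.9)
    expect_equal(m2$FDR, 0.1)
    expect_equal(m2$F1, 0.9)
    expect_equal(m2$balanced_accuracy, 0.9)

    expect_equal((1 + 0.92) / 2, 0.96)  # balanced-accuracy arithmetic
    expect_error(classificationMetrics("a", "a", character(0)), "empty")
})

test_that("r-squared is scale invariant and matches the closed form", {
    x <- c(1, 2, 3, 4, 7)
    expect_equal(rSquared(x, x), 1)
    expect_equal(rSquared(x, 2 * x), 1)
    y <- c(1.2, 1.9, 3.4, 3.9, 6.8)
    manual <- (sum((x - mean(x)) * (y - mean(y))))^2 /
        (sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(rSquared(x, y), manual)
    expect_true(is.na(rSquared(rep(1, 5), x)))
    expect_error(rSquared(1, c(1, 2)), "equal-length")
})

test_that("overlapping divergence bands are rejected", {
    expect_error(simulateSpeciesSet(1, n_species = 2, within_div = 0.04,
                                    between_div = 0.06),
                 "bands overlap")
})
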