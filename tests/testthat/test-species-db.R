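test_that("marker percent identity matches a DP oracle and masks low coverage", {
    set.seed(11)
    a <- random_seq(300)
    expect_equal(markerPercentIdentity(a, a), 100)

    # 6 substitutions over a 300-bp full-length alignment -> 98.0
    pos <- sample(300, 6)
    old <- strsplit(a, "")[[1]][pos]
    subs <- vapply(old, function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    b <- mutate_seq(a, pos, subs)
    expect_equal(markerPercentIdentity(a, b), 98.0)

    # alignment covering 50% of the longer sequence is masked
    expect_true(is.na(markerPercentIdentity(a, substr(a, 1, 150))))
    expect_error(markerPercentIdentity("", a), "empty")
})

test_that("identity-to-distance conversion is (100 - P) / 100", {
    expect_equal(percentIdentityToDistance(96.5), 0.035)
    expect_equal(percentIdentityToDistance(100), 0)
    expect_equal(percentIdentityToDistance(0), 1)
    expect_error(percentIdentityToDistance(101), "out of")
})

test_that("family distances average over defined entries only", {
    g <- c("g1", "g2")
    m1 <- matrix(c(0, 0.02, 0.02, 0), 2, dimnames = list(g, g))
    m2 <- matrix(c(0, 0.04, 0.04, 0), 2, dimnames = list(g, g))
    expect_equal(averageMarkerDistance(list(m1, m2))["g1", "g2"], 0.03)

    m2[1, 2] <- m2[2, 1] <- NA
    expect_equal(averageMarkerDistance(list(m1, m2))["g1", "g2"], 0.02)

    m1[1, 2] <- m1[2, 1] <- NA
    expect_true(is.na(averageMarkerDistance(list(m1, m2))["g1", "g2"]))
    expect_error(averageMarkerDistance(list()), "empty")
})

test_that("average-linkage clustering matches the spec'd examples", {
    g <- c("A", "B", "C")
    D <- matrix(c(0, 0.01, 0.05,
                  0.01, 0, 0.05,
                  0.05, 0.05, 0), 3, dimnames = list(g, g))
    asg <- averageLinkageCluster(D, cutoff = 0.035)
    sp <- setNames(asg$species_id, asg$genome_id)
    expect_equal(sp[["A"]], sp[["B"]])
    expect_false(sp[["A"]] == sp[["C"]])

    # all distances above the cutoff: singletons
    D2 <- matrix(0.5, 3, 3, dimnames = list(g, g)); diag(D2) <- 0
    expect_equal(length(unique(averageLinkageCluster(D2, 0.035)$species_id)), 3)

    # all zero: one species
    D3 <- matrix(0, 3, 3, dimnames = list(g, g))
    expect_equal(length(unique(averageLinkageCluster(D3, 0.035)$species_id)), 1)
})

test_that("UPGMA equals brute-force agglomeration and is order invariant", {
    set.seed(12)
    for (rep in 1:20) {
        n <- sample(3:8, 1)
        ids <- paste0("g", seq_len(n))
        D <- matrix(0, n, n, dimnames = list(ids, ids))
        v <- runif(n * (n - 1) / 2, 0, 0.08)
        D[lower.tri(D)] <- v
        D <- D + t(D)
        cutoff <- runif(1, 0.01, 0.06)
        got <- averageLinkageCluster(D, cutoff)
        want <- brute_force_upgma(D, cutoff)
        expect_true(same_partition(setNames(got$species_id, got$genome_id),
                                   want))
        # permutation invariance of the partition and of the species ids
        perm <- sample(n)
        Dp <- D[perm, perm]
        got2 <- averageLinkageCluster(Dp, cutoff)
        m1 <- setNames(got$species_id, got$genome_id)
        m2 <- setNames(got2$species_id, got2$genome_id)
        expect_equal(m1[sort(names(m1))], m2[sort(names(m2))])
    }
})

test_that("raising the cutoff never increases the species count", {
    set.seed(13)
    n <- 12
    ids <- paste0("g", seq_len(n))
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    v <- runif(n * (n - 1) / 2, 0, 0.1)
    D[lower.tri(D)] <- v
    D <- D + t(D)
    ks <- vapply(seq(0, 0.1, by = 0.01), function(ct)
        length(unique(averageLinkageCluster(D, ct)$species_id)), numeric(1))
    expect_true(all(diff(ks) <= 0))
})

test_that("ANI evaluation computes TPR, PPV and F1 from pair counts", {
    asg <- data.frame(genome_id = c("a", "b", "c", "d"),
                      species_id = c("s1", "s1", "s2", "s2"))
    perfect <- data.frame(genome_a = c("a", "a", "a", "b", "b", "c"),
                          genome_b = c("b", "c", "d", "c", "d", "d"),
                          ani = c(97, 90, 90, 90, 90, 97))
    ev <- evaluateAgainstAni(asg, perfect)
    expect_equal(ev$TPR, 1); expect_equal(ev$PPV, 1); expect_equal(ev$F1, 1)

    # TP=8, FP=2, FN=0 -> TPR 1, PPV 0.8, F1 = 2*1*0.8/1.8
    asg2 <- data.frame(genome_id = paste0("g", 1:5),
                       species_id = rep("s1", 5))
    pairs <- t(combn(paste0("g", 1:5), 2))
    lab <- data.frame(genome_a = pairs[, 1], genome_b = pairs[, 2],
                      ani = c(rep(96, 8), rep(90, 2)))
    ev2 <- evaluateAgainstAni(asg2, lab)
    expect_equal(unname(ev2$counts["TP"]), 8)
    expect_equal(unname(ev2$counts["FP"]), 2)
    expect_equal(ev2$TPR, 1)
    expect_equal(ev2$PPV, 0.8)
    expect_equal(ev2$F1, 2 * 0.8 / 1.8, tolerance = 1e-12)

    # everything split but labelled same-species: TPR 0, F1 0
    asg3 <- data.frame(genome_id = c("a", "b"), species_id = c("s1", "s2"))
    lab3 <- data.frame(genome_a = "a", genome_b = "b", ani = 99)
    ev3 <- evaluateAgainstAni(asg3, lab3)
    expect_equal(ev3$TPR, 0)
    expect_equal(ev3$F1, 0)
    expect_error(evaluateAgainstAni(asg3, lab3[0, ]), "no labeled")
})

test_that("representative selection maximises mean identity, ties lexicographic", {
    expect_equal(selectRepresentative("only"), "only")
    ids <- c("A", "B", "C")
    M <- matrix(c(100, 98.1, 98.1,
                  99.0, 100, 99.0,
                  98.5, 98.5, 100), 3, byrow = TRUE,
                dimnames = list(ids, ids))
    # mean identity to others: A 98.1, B 99.0, C 98.5
    expect_equal(selectRepresentative(ids, M), "B")
    Mt <- matrix(99, 3, 3, dimnames = list(ids, ids)); diag(Mt) <- 100
    expect_equal(selectRepresentative(ids, Mt), "A")
    expect_error(selectRepresentative(character(0)), "no genomes")
})

test_that("pan-genome clustering is greedy at 99% identity", {
    set.seed(14)
    g1 <- random_seq(500)
    genes <- c(a = g1, b = g1)
    pg <- buildPangenome(genes, "sp")
    expect_equal(length(centroids(pg)), 1L)
    expect_equal(sort(clusterMembers(pg)[[1]]), c("a", "b"))

    # 95% identity stays below the 99% threshold: two clusters
    pos <- sample(500, 25)
    old <- strsplit(g1, "")[[1]][pos]
    g2 <- mutate_seq(g1, pos, vapply(old, function(x)
        sample(setdiff(c("A","C","G","T"), x), 1), ""))
    pg2 <- buildPangenome(c(a = g1, b = g2), "sp")
    expect_equal(length(centroids(pg2)), 2L)
    expect_error(buildPangenome(character(0)), "no genes")
})

test_that("pan-genome clustering recovers the generating gene families", {
    set.seed(15)
    originals <- vapply(1:10, function(i) random_seq(400), "")
    n <- 300
    genes <- character(n)
    for (i in seq_len(n)) {
        src <- originals[((i - 1) %% 10) + 1]
        npos <- min(rbinom(1, 400, 0.004), 2)  # <= 0.5% mutation
        if (npos > 0) {
            pos <- sample(400, npos)
            old <- strsplit(src, "")[[1]][pos]
            src <- mutate_seq(src, pos, vapply(old, function(x)
                sample(setdiff(c("A","C","G","T"), x), 1), ""))
        }
        genes[i] <- src
    }
    names(genes) <- sprintf("gene%03d", seq_len(n))
    pg <- buildPangenome(genes, "sp")
    expect_equal(length(centroids(pg)), 10L)
})

test_that("family aggregation is nested across levels and validated", {
    set.seed(16)
    base <- random_seq(400)
    variant <- function(s, rate) {
        npos <- round(400 * rate)
        pos <- sample(400, npos)
        old <- strsplit(s, "")[[1]][pos]
        mutate_seq(s, pos, vapply(old, function(x)
            sample(setdiff(c("A","C","G","T"), x), 1), ""))
    }
    # two tight groups (~2% apart inside, ~30% between)
    g <- c(c1 = base, c2 = variant(base, 0.02),
           c3 = random_seq(400), c4 = random_seq(400))
    pg <- buildPangenome(g, "sp")
    map95 <- aggregateFamilies(pg, 95)
    expect_equal(unname(map95["c1"]), unname(map95["c2"]))
    map75 <- aggregateFamilies(pg, 75)
    # nesting: 95%-families refine 75%-families
    for (f in unique(map95)) {
        members <- names(map95)[map95 == f]
        expect_equal(length(unique(map75[members])), 1L)
    }
    expect_error(aggregateFamilies(pg, 83), "invalid")
})

test_that("consensus naming is modal with lexicographic ties", {
    expect_equal(consensusName(c("X", "X", "Y")), "X")
    expect_equal(consensusName(c("", ""), "s1"), "unnamed_s1")
    expect_equal(consensusName(c("X", "Y")), "X")
    expect_equal(consensusName(c("Z", "Y")), "Y")
})
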