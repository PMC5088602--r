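test_that("pileup counts quality-filtered bases at the right positions", {
    set.seed(51)
    ref <- random_seq(400)
    reads <- c(substr(ref, 101, 200), substr(ref, 101, 200),
               substr(ref, 151, 250), substr(ref, 151, 250))
    # read 2 carries a C at reference position 160 (0-based 159)
    v <- strsplit(reads[2], "")[[1]]
    truth_base <- v[60]
    alt <- setdiff(c("A", "C", "G", "T"), truth_base)[1]
    v[60] <- alt
    reads[2] <- paste(v, collapse = "")
    counts <- pileupSites(reads, c(chr = ref),
                          quals = rep(strrep("I", 100), 4))$chr
    # 0-based position 159 is covered by all four reads; read 2 dissents
    expect_equal(sum(counts[, 160]), 4)
    expect_equal(unname(counts[truth_base, 160]), 3)
    expect_equal(unname(counts[alt, 160]), 1)
    # depth profile: 100 reads nowhere, 2 reads on 100..149, 4 on 150..199
    expect_true(all(colSums(counts)[101:150] == 2))
    expect_true(all(colSums(counts)[251:300] == 0))
})

test_that("pileup honours the per-base quality cutoff of 30", {
    ref <- strrep("A", 60)
    read <- strrep("A", 60)
    q_hi <- strrep("I", 60)                      # q40 everywhere
    q_mix <- paste0(strrep("I", 30), strrep(">", 30))  # q29 tail
    counts_hi <- pileupSites(c(read, read), c(chr = ref),
                             quals = c(q_hi, q_hi))$chr
    expect_true(all(counts_hi["A", ] == 2))
    counts_mix <- pileupSites(c(read, read), c(chr = ref),
                              quals = c(q_hi, q_mix))$chr
    expect_true(all(counts_mix["A", 1:30] == 2))
    expect_true(all(counts_mix["A", 31:60] == 1))  # q29 bases excluded
})

test_that("error-free pileups are monoallelic and match the strain sequence", {
    set <- tiny_species_set()
    strain <- local({ set.seed(52); simulateStrain(set, "sp01",
                                                   p_accessory = 1) })
    rd <- simulateReads(list(sp01 = strain$codes), c(sp01 = 20),
                        error_rate = 0, seed = 53)
    counts <- pileupSites(rd$reads, set@repGenomes["sp01"],
                          quals = rd$quals)$sp01
    depth <- colSums(counts)
    mono <- colSums(counts > 0)
    expect_true(all(mono[depth > 0] == 1))
    # consensus calls reproduce the true strain/representative differences
    calls <- consensusSnpCalls(counts, set@repGenomes[["sp01"]])
    truth <- strain$snps
    covered <- truth[depth[truth$pos + 1] > 0, ]
    expect_true(all(covered$pos %in% calls$pos))
    expect_equal(nrow(calls), nrow(merge(calls, covered, by = "pos")))  # FDR 0
})

test_that("consensus calling is conservative on ties and reference matches", {
    counts <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts["A", 1] <- 7; counts["G", 1] <- 1   # ref G -> call A
    counts["G", 2] <- 8                        # ref G -> no call
    counts["A", 3] <- 4; counts["C", 3] <- 4   # tie -> no call
    calls <- consensusSnpCalls(counts, "GGG")
    expect_equal(calls$pos, 0L)
    expect_equal(calls$allele, "A")
})

test_that("core-genome identification follows the strict depth rule", {
    d <- matrix(c(12, 11, 15, 9), 1)
    expect_equal(length(identifyCore(d)), 0L)          # 0.75 < 0.95
    expect_equal(identifyCore(d, sample_fraction = 0.75), 0L)
    expect_equal(identifyCore(matrix(11, 1, 1)), 0L)   # single sample, >10
    expect_equal(length(identifyCore(matrix(10, 1, 1))), 0L)  # 10 not > 10
    expect_error(identifyCore(matrix(numeric(0), 5, 0)), "zero samples")
})

test_that("raising core thresholds only shrinks the core", {
    set.seed(54)
    depth <- matrix(rpois(500 * 6, 12), 500, 6)
    base <- identifyCore(depth)
    expect_true(all(identifyCore(depth, min_depth = 15) %in% base))
    expect_true(all(identifyCore(depth, sample_fraction = 1) %in% base))
})

test_that("merged SNP matrices use cohort-wide major/minor alleles", {
    mk <- function(...) {
        m <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
        vals <- list(...)
        for (v in vals) m[v[[1]], v[[2]]] <- v[[3]]
        m
    }
    sA <- mk(list("G", 1, 10), list("A", 2, 30), list("G", 2, 5))
    sB <- mk(list("T", 1, 10), list("A", 2, 0), list("G", 2, 5), list("T", 2, 2))
    snps <- mergeSnps(list(A = sA, B = sB))
    expect_s4_class(snps, "SnpExperiment")
    rd <- SummarizedExperiment::rowData(snps)
    # site 0: sample A all G, sample B all T -> pooled major is tied G/T,
    # order-statistic tie break is alphabetical: G major, T minor
    i1 <- which(rd$pos == 0)
    expect_equal(rd$major[i1], "G")
    expect_equal(rd$minor[i1], "T")
    f <- SummarizedExperiment::assay(snps, "freq")
    expect_equal(unname(f[i1, "A"]), 0)   # no minor allele in A
    expect_equal(unname(f[i1, "B"]), 1)   # all minor in B
    # site 1: pooled {A:30, G:10, T:2} -> major A, minor G
    i2 <- which(rd$pos == 1)
    expect_equal(rd$major[i2], "A")
    expect_equal(rd$minor[i2], "G")
    # monoallelic site everywhere -> minor frequency 0 where covered
    sC <- mk(list("C", 3, 9)); sD <- mk(list("C", 3, 4))
    snps2 <- mergeSnps(list(x = sC, y = sD))
    f2 <- SummarizedExperiment::assay(snps2, "freq")
    expect_true(all(f2 == 0))
})

test_that("per-sample frequencies at covered sites sum to one", {
    set.seed(55)
    counts <- matrix(rpois(4 * 50, 3), 4, 50,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    depth <- colSums(counts)
    freqs <- sweep(counts, 2, pmax(depth, 1), "/")
    expect_true(all(abs(colSums(freqs)[depth > 0] - 1) < 1e-12))
})

test_that("zero depth is encoded as missing, not frequency zero", {
    m <- matrix(0L, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
    m2 <- m; m2["A", 1] <- 5; m2["C", 1] <- 5
    snps <- mergeSnps(list(a = m2, b = m))
    f <- SummarizedExperiment::assay(snps, "freq")
    expect_true(is.na(f[1, "b"]))
    expect_false(is.na(f[1, "a"]))
})

test_that("strain SNPs are detected with high TPR and low FDR at 20x", {
    set <- tiny_species_set()
    # full gene complement: substitutions are the only strain/reference
    # differences, so TPR/FDR measure SNP calling alone
    strain <- local({ set.seed(56); simulateStrain(set, "sp02",
                                                   p_accessory = 1) })
    rd <- simulateReads(list(sp02 = strain$codes), c(sp02 = 20),
                        error_rate = 0.005, seed = 57)
    counts <- pileupSites(rd$reads, set@repGenomes["sp02"],
                          quals = rd$quals)$sp02
    calls <- consensusSnpCalls(counts, set@repGenomes[["sp02"]])
    truth_keys <- paste(strain$snps$pos, strain$snps$alt)
    call_keys <- paste(calls$pos, calls$allele)
    tpr <- mean(truth_keys %in% call_keys)
    fdr <- if (length(call_keys)) mean(!(call_keys %in% truth_keys)) else 0
    expect_gte(tpr, 0.9)
    expect_lte(fdr, 0.05)
})

test_that("VCF export writes valid records for variable sites", {
    f <- withr::local_tempfile(fileext = ".vcf")
    counts <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts["A", 1] <- 10
    counts["A", 2] <- 7; counts["C", 2] <- 3
    ss <- siteSummary(counts, "GAAT", contig = "chr1")
    writeVcf(ss, f, sample = "s1")
    lines <- readLines(f)
    expect_equal(lines[1], "##fileformat=VCFv4.2")
    body <- lines[!startsWith(lines, "#")]
    expect_equal(length(body), 2L)  # pos 1 (A vs ref G) and pos 2 (A/C)
    expect_match(body[1], "^chr1\t1\t")
})
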