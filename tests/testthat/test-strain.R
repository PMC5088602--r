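cnt <- function(spec) {
    # spec: list of list(base, pos_1based, count)
    L <- max(vapply(spec, function(v) v[[2]], numeric(1)))
    m <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (v in spec) m[v[[1]], v[[2]]] <- v[[3]]
    m
}

test_that("allele presence needs 3 reads and 10% frequency", {
    m <- cnt(list(list("A", 1, 17), list("C", 1, 3),
                  list("A", 2, 37), list("C", 2, 3),
                  list("A", 3, 18), list("C", 3, 2)))
    p <- detectAlleles(m)
    k <- paste(p$pos, p$allele)
    expect_true("0 A" %in% k && "0 C" %in% k)   # 3 reads, 15%
    expect_false("1 C" %in% k)                  # 7.5% < 10%
    expect_false("2 C" %in% k)                  # 2 < 3 reads
    expect_true("2 A" %in% k)
    # zero-depth matrix yields no entries
    expect_equal(nrow(detectAlleles(matrix(0L, 4, 5,
        dimnames = list(c("A", "C", "G", "T"), NULL)))), 0L)
})

test_that("marker alleles are private to one unit at biallelic sites", {
    mk <- function(pos, alleles) data.frame(pos = pos, allele = alleles,
                                            count = 5, depth = 20, freq = .25)
    pres <- list(
        m1 = mk(c(0, 1, 2), c("A", "C", "G")),
        m2 = mk(c(0, 1, 2), c("A", "T", "G")),
        m3 = mk(c(0, 1, 2, 3), c("A", "C", "T", "C")))
    units <- c(m1 = "u1", m2 = "u2", m3 = "u3")
    mark <- findMarkerAlleles(pres, units)
    # site 0: single allele everywhere -> not biallelic -> no markers
    expect_false(0 %in% mark$u1$pos)
    # site 1: alleles C (u1, u3) and T (u2): T is private to u2; C is not
    expect_true(any(mark$u2$pos == 1 & mark$u2$allele == "T"))
    expect_false(any(mark$u1$pos == 1))
    # site 2: G (u1, u2) + T (u3): T private to u3
    expect_true(any(mark$u3$pos == 2 & mark$u3$allele == "T"))
    # site 3: only u3 covered it -> single allele, not biallelic
    expect_false(any(mark$u3$pos == 3))
    expect_error(findMarkerAlleles(pres["m1"], units), "2 units")
})

test_that("triallelic sites contribute no markers", {
    mk <- function(a) data.frame(pos = 0L, allele = a, count = 5,
                                 depth = 20, freq = .25)
    pres <- list(s1 = mk("A"), s2 = mk("C"), s3 = mk("G"))
    units <- c(s1 = "u1", s2 = "u2", s3 = "u3")
    mark <- findMarkerAlleles(pres, units)
    expect_true(all(vapply(mark, nrow, 1L) == 0))
})

test_that("sharing percentages and the exclusion rule are exact", {
    donor <- data.frame(pos = 0:19, allele = rep(c("A", "C"), 10))
    rec <- data.frame(pos = 0:15, allele = rep(c("A", "C"), 8),
                      count = 5, depth = 20, freq = .25)
    sh <- alleleSharing(donor, rec)
    expect_equal(sh$n_markers, 20L)
    expect_equal(sh$n_shared, 16L)
    expect_equal(sh$sharing_percent, 80)
    expect_false(sh$excluded)

    small <- donor[1:8, ]
    sh2 <- alleleSharing(small, rec)
    expect_true(sh2$excluded)
    expect_true(is.na(sh2$sharing_percent))

    # self-sharing is 100%
    self <- alleleSharing(donor, data.frame(pos = donor$pos,
                                            allele = donor$allele,
                                            count = 5, depth = 9, freq = 1))
    expect_equal(self$sharing_percent, 100)
})

test_that("transmission classification is strictly greater than 5%", {
    expect_false(classifyTransmission(5.0))
    expect_true(classifyTransmission(5.1))
    expect_true(classifyTransmission(72))
    excl <- data.frame(n_markers = 4, n_shared = NA, sharing_percent = NA,
                       excluded = TRUE)
    expect_error(classifyTransmission(excl), "excluded")
})

test_that("cohort summaries report transmitted over evaluable pairs", {
    res <- data.frame(
        species = rep("sp1", 111),
        donor = paste0("d", 1:111), recipient = paste0("r", 1:111),
        sharing_percent = c(rep(50, 101), rep(1, 10)),
        transmitted = c(rep(TRUE, 101), rep(FALSE, 10)),
        excluded = FALSE)
    s <- cohortTransmissionSummary(res)
    expect_equal(round(s$overall, 2), 0.91)
    expect_equal(s$per_species$n_evaluable, 111L)

    res2 <- data.frame(species = "sp1", donor = "d", recipient = "r",
                       sharing_percent = c(1, 2, 1, 3, 2),
                       transmitted = FALSE, excluded = FALSE)
    expect_equal(cohortTransmissionSummary(res2)$overall, 0)

    res3 <- res2; res3$excluded <- TRUE; res3$transmitted <- NA
    expect_true(is.na(cohortTransmissionSummary(res3)$overall))
})

test_that("adding cohort samples never increases a unit's marker count", {
    set.seed(61)
    # every sample carries the shared allele A at all 100 sites plus a
    # private C at a random 30; sites stay at most biallelic throughout
    mk <- function() {
        own <- sort(sample(0:99, 30))
        rbind(data.frame(pos = 0:99, allele = "A", count = 20, depth = 25,
                         freq = 0.8),
              data.frame(pos = own, allele = "C", count = 5, depth = 25,
                         freq = 0.2))
    }
    pres <- lapply(1:6, function(i) mk())
    names(pres) <- paste0("s", 1:6)
    units <- setNames(paste0("u", 1:6), names(pres))
    small <- findMarkerAlleles(pres[1:4], units[1:4])
    full <- findMarkerAlleles(pres, units)
    for (u in paste0("u", 1:4))
        expect_lte(nrow(full[[u]]), nrow(small[[u]]))
})
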