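#' Species abundance recovery on mock communities
#'
#' Simulates `n_communities` mock metagenomes (each a fresh strain per
#' species, exponentially decreasing abundances shuffled over the species,
#' 100x total coverage, 100-bp reads at 1% substitution error), profiles
#' each with the USCG species profiler and pools (true, estimated) relative
#' abundance pairs over all communities.
#'
#' @param seed Integer seed; community i uses `seed + i`.
#' @param n_communities Number of mock communities.
#' @param n_species Species per community.
#' @param total_coverage,read_len,error_rate Community parameters.
#' @param set Optional prebuilt [MockSpeciesSet-class] (built from `seed`
#'   otherwise).
#' @return list with `r_squared`, and `pairs` (data.frame `community`,
#'   `species`, `true`, `estimated`).
#' @export
abundanceRecoveryExperiment <- function(seed, n_communities = 20,
                                        n_species = 20,
                                        total_coverage = 100,
                                        read_len = 100, error_rate = 0.01,
                                        set = NULL) {
    if (is.null(set))
        set <- simulateSpeciesSet(seed, n_species = n_species)
    db <- set@markerDb
    rows <- list()
    for (i in seq_len(n_communities)) {
        set.seed(seed + i)
        ab <- setNames(sample(exponentialAbundances(n_species)),
                       set@species)
        comm <- simulateCommunity(set, abundances = ab,
                                  total_coverage = total_coverage,
                                  read_len = read_len,
                                  error_rate = error_rate)
        prof <- profileSpecies(comm$reads, db, quals = comm$quals)
        est <- relativeAbundance(prof)
        rows[[i]] <- data.frame(community = i, species = set@species,
                                true = unname(ab[set@species]),
                                estimated = unname(est[set@species]),
                                stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, rows)
    list(r_squared = rSquared(pairs$true, pairs$estimated), pairs = pairs)
}

#' Gene presence-absence accuracy across coverage tiers
#'
#' Builds one community whose species sit at fixed coverage tiers, with each
#' strain carrying a known subset of its species pan-genome (all core genes
#' plus a random half of the accessory genes). Runs the species profiler,
#' selects species above `select_cov` estimated coverage, profiles their
#' pan-genomes, and scores presence calls against the true gene sets for
#' species whose estimated coverage exceeds `eval_cov` (default 3x). Also
#' sweeps the copy-number cutoff to locate the optimum plateau.
#'
#' @param seed Integer seed.
#' @param tiers Fold-coverage tiers, one species per tier.
#' @param error_rate Read error rate.
#' @param select_cov Coverage gate for running the gene profiler.
#' @param eval_cov Coverage gate for evaluation (strict).
#' @param cutoff Copy-number presence cutoff to report.
#' @param sweep Cutoffs for the sweep.
#' @param n_genes Pool genes per species.
#' @return list with `balanced_accuracy` (at `cutoff`), `metrics`,
#'   `sweep` (data.frame `cutoff`, `balanced_accuracy`),
#'   `evaluated_species`.
#' @export
genePresenceExperiment <- function(seed,
                                   tiers = c(0.5, 1, 2, 3, 4, 5, 8, 10,
                                             15, 20, 25, 30),
                                   error_rate = 0.01, select_cov = 1,
                                   eval_cov = 3, cutoff = 0.35,
                                   sweep = seq(0.05, 0.95, by = 0.05),
                                   n_genes = 40) {
    n_species <- length(tiers)
    set <- simulateSpeciesSet(seed, n_species = n_species, n_genes = n_genes)
    ab <- setNames(tiers / sum(tiers), set@species)
    comm <- simulateCommunity(set, abundances = ab,
                              total_coverage = sum(tiers),
                              error_rate = error_rate, seed = seed + 1)
    prof <- profileSpecies(comm$reads, set@markerDb, quals = comm$quals)
    sel <- selectSpecies(prof, min_coverage = select_cov)
    gc <- profileGenes(comm$reads, set@pangenomes[sel], quals = comm$quals)
    cov_est <- speciesCoverage(prof)
    eval_sp <- sel[cov_est[sel] > eval_cov]

    score <- function(cut) {
        pred <- truth <- universe <- character(0)
        for (s in eval_sp) {
            d <- gc[[s]]
            pres <- presenceAbsence(d$copy_number, cut)
            pred <- c(pred, paste(s, d$gene_id[!is.na(pres) & pres]))
            truth <- c(truth, paste(s, comm$truth@geneSets[[s]]))
            universe <- c(universe, paste(s, d$gene_id))
        }
        classificationMetrics(pred, truth, universe)
    }
    main <- score(cutoff)
    sw <- data.frame(cutoff = sweep,
                     balanced_accuracy = vapply(sweep, function(ct)
                         score(ct)$balanced_accuracy, numeric(1)))
    list(balanced_accuracy = main$balanced_accuracy, metrics = main,
         sweep = sw, evaluated_species = eval_sp)
}

#' Species clustering recovery against the generating partition
#'
#' Simulates `n_species` species with `n_strains` database genomes each
#' (within-species pairwise marker divergence `within_div`, between-species
#' `between_div`), computes per-family marker distances, averages them over
#' the families, clusters by average linkage at `cutoff`, and scores all
#' genome pairs against the generating partition using ANI-style labels
#' (same species = ANI 96, different = ANI 90).
#'
#' @param seed Integer seed.
#' @param n_species,n_strains Partition shape (default 25 x 8 = 200 genomes).
#' @param cutoff Distance cutoff.
#' @param within_div,between_div Pairwise divergence bands.
#' @return list with `F1`, `TPR`, `PPV`, `assignment`, `n_species_found`.
#' @export
clusteringExperiment <- function(seed, n_species = 25, n_strains = 8,
                                 cutoff = 0.035, within_div = 0.02,
                                 between_div = 0.10, marker_len = 400) {
    set <- simulateSpeciesSet(seed, n_species = n_species,
                              n_strains = n_strains, markers_only = TRUE,
                              within_div = within_div,
                              between_div = between_div,
                              marker_len = marker_len)
    dists <- markerDistanceMatrices(set@clusterMarkers)
    D <- averageMarkerDistance(dists)
    asg <- averageLinkageCluster(D, cutoff = cutoff)
    truth_sp <- setNames(set@genomes$species_id, set@genomes$genome_id)
    g <- asg$genome_id
    pairs <- t(utils::combn(g, 2))
    labels <- data.frame(genome_a = pairs[, 1], genome_b = pairs[, 2],
                         ani = ifelse(truth_sp[pairs[, 1]] ==
                                      truth_sp[pairs[, 2]], 96, 90),
                         stringsAsFactors = FALSE)
    ev <- evaluateAgainstAni(asg, labels)
    list(F1 = ev$F1, TPR = ev$TPR, PPV = ev$PPV, counts = ev$counts,
         assignment = asg,
         n_species_found = length(unique(asg$species_id)),
         distance = D)
}

#' Transmission-classification controls (replicate and unrelated pairs)
#'
#' Simulates a cohort of `n_units` units, each carrying its own strain of
#' every species, sequenced twice (independent read samplings at `coverage`
#' fold). Marker alleles are discovered from the first sample of every unit
#' (biallelic sites, alleles at >= 3 reads and >= 10% frequency, private to
#' one unit, >= 10 markers per donor). Sensitivity is the fraction of
#' replicate pairs (first vs second sample of the same unit) classified as
#' transmissions at the 5% sharing cutoff; specificity the fraction of
#' unrelated pairs (donor unit vs another unit's second sample) classified
#' as non-transmissions.
#'
#' @param seed Integer seed.
#' @param n_units Cohort size.
#' @param n_species Shared species.
#' @param coverage Per-species fold coverage of every sample.
#' @param n_unrelated Number of unrelated pairs sampled.
#' @param error_rate Read error rate.
#' @param min_depth Species coverage gate (mean pileup depth must exceed it).
#' @return list with `sensitivity_percent`, `specificity_percent`, and the
#'   per-pair `results` table.
#' @export
transmissionControlExperiment <- function(seed, n_units = 30, n_species = 2,
                                          coverage = 20, n_unrelated = 30,
                                          error_rate = 0.01,
                                          min_depth = 10) {
    set <- simulateSpeciesSet(seed, n_species = n_species, n_families = 5,
                              n_abundance_families = 5, n_genes = 10)
    reps <- set@repGenomes
    units <- sprintf("unit%02d", seq_len(n_units))
    # per unit: one strain per species, two independent read samplings
    set.seed(seed + 7)
    piles <- list()   # piles[[sample]][[species]] = counts
    for (u in units) {
        strains <- lapply(set@species, function(s) simulateStrain(set, s))
        names(strains) <- set@species
        for (rep_i in 1:2) {
            smp <- paste0(u, "_t", rep_i)
            rd <- simulateReads(lapply(strains, `[[`, "codes"),
                                setNames(rep(coverage, n_species),
                                         set@species),
                                error_rate = error_rate)
            piles[[smp]] <- pileupSites(rd$reads, reps, quals = rd$quals)
        }
    }
    samples <- names(piles)
    unit_of <- setNames(sub("_t[12]$", "", samples), samples)
    results <- list()
    for (s in set@species) {
        depth_ok <- vapply(samples, function(x)
            mean(colSums(piles[[x]][[s]])) > min_depth, logical(1))
        pres <- lapply(samples, function(x) detectAlleles(piles[[x]][[s]]))
        names(pres) <- samples
        t1 <- samples[endsWith(samples, "_t1") & depth_ok]
        markers <- findMarkerAlleles(pres[t1], unit_of[t1])
        # replicate pairs: donor unit -> its own second sample
        for (u in units) {
            rec <- paste0(u, "_t2")
            if (!depth_ok[rec] || !depth_ok[paste0(u, "_t1")]) next
            sh <- alleleSharing(markers[[u]], pres[[rec]])
            results[[length(results) + 1L]] <- data.frame(
                species = s, donor = u, recipient = rec, kind = "replicate",
                sh, stringsAsFactors = FALSE)
        }
        # unrelated pairs: fixed deterministic draw
        set.seed(seed + 13)
        di <- sample.int(n_units, n_unrelated, replace = TRUE)
        rj <- ((di - 1L + sample.int(n_units - 1L, n_unrelated,
                                     replace = TRUE)) %% n_units) + 1L
        for (p in seq_len(n_unrelated)) {
            u <- units[di[p]]; rec <- paste0(units[rj[p]], "_t2")
            if (!depth_ok[rec] || !depth_ok[paste0(u, "_t1")]) next
            sh <- alleleSharing(markers[[u]], pres[[rec]])
            results[[length(results) + 1L]] <- data.frame(
                species = s, donor = u, recipient = rec, kind = "unrelated",
                sh, stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, results)
    res$transmitted <- ifelse(res$excluded, NA,
                              res$sharing_percent > 5.0)
    rep_ok <- res$kind == "replicate" & !res$excluded
    unr_ok <- res$kind == "unrelated" & !res$excluded
    list(
        sensitivity_percent = 100 * mean(res$transmitted[rep_ok]),
        specificity_percent = 100 * mean(!res$transmitted[unr_ok]),
        n_replicate = sum(rep_ok), n_unrelated = sum(unr_ok),
        results = res)
}
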