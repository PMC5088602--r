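#' Exponentially decreasing community abundances
#'
#' Abundance of the i-th organism is proportional to 2^-i, normalised to sum
#' to one — 50%, 25%, 12.5%, 6.25%, ... for the default community size.
#'
#' @param n Number of organisms (>= 1).
#' @return Numeric abundance vector summing to 1.
#' @export
exponentialAbundances <- function(n = 20) {
    if (n < 1) stop("n must be >= 1")
    a <- 2^-(seq_len(n))
    a / sum(a)
}

# -- internal helpers (integer base codes 0=A 1=C 2=G 3=T) -------------------

random_codes <- function(n) sample.int(4L, n, replace = TRUE) - 1L

# point mutation at a per-site rate; returns codes and the mutation table
mutate_codes <- function(codes, rate) {
    L <- length(codes)
    pos <- which(runif(L) < rate)
    if (length(pos) == 0)
        return(list(codes = codes,
                    muts = data.frame(pos = integer(0), ref = character(0),
                                      alt = character(0))))
    old <- codes[pos]
    codes[pos] <- (old + sample.int(3L, length(pos), replace = TRUE)) %% 4L
    bases <- c("A", "C", "G", "T")
    list(codes = codes,
         muts = data.frame(pos = pos - 1L, ref = bases[old + 1L],
                           alt = bases[codes[pos] + 1L],
                           stringsAsFactors = FALSE))
}

codes_to_string <- function(codes) cpp_code_vector_to_string(codes)[1]

#' Simulate a synthetic species reference set
#'
#' Builds, per species, an ancestral genome composed of marker genes
#' (`n_families` clustering markers of which the first
#' `n_abundance_families` form the single-copy abundance panel), a pool of
#' pan-genome genes (a core fraction plus accessory genes), and random
#' spacers. Database strains diverge from the species marker set at
#' `within_div` pairwise divergence; species marker sets diverge from shared
#' family ancestors at `between_div` pairwise divergence (per-lineage
#' mutation rates are half the pairwise targets). The species representative
#' genome is the ancestral genome itself, the single database genome per
#' species. Community strains are drawn later with [simulateStrain()].
#'
#' All outputs are deterministic functions of the seed.
#'
#' @param seed Integer seed.
#' @param n_species Number of species.
#' @param n_strains Database strains per species (used for the clustering
#'   marker sets; `markers_only = TRUE` for clustering experiments).
#' @param n_families Clustering marker families per genome.
#' @param n_abundance_families Families flagged as the abundance (USCG)
#'   panel.
#' @param marker_len,gene_len,spacer_len Element lengths in bp.
#' @param n_genes Pan-genome pool genes per species.
#' @param accessory_frac Fraction of pool genes that are accessory.
#' @param within_div Pairwise within-species divergence (<= 0.02).
#' @param between_div Pairwise between-species divergence (>= 0.05).
#' @param cutoff Per-family percent-identity cutoff stored in the marker
#'   database.
#' @param markers_only Skip genomes/pan-genomes; emit clustering markers only.
#' @return A [MockSpeciesSet-class].
#' @export
simulateSpeciesSet <- function(seed, n_species = 20, n_strains = 1,
                               n_families = 30, n_abundance_families = 15,
                               marker_len = 1000, n_genes = 16,
                               gene_len = 400, spacer_len = 60,
                               accessory_frac = 0.30,
                               within_div = 0.02, between_div = 0.10,
                               cutoff = 95, markers_only = FALSE) {
    if (between_div <= 2 * within_div)
        stop("divergence bands overlap: between_div must exceed 2 * within_div")
    if (n_abundance_families > n_families)
        stop("abundance panel cannot exceed the marker panel")
    set.seed(seed)
    sp_ids <- sprintf("sp%02d", seq_len(n_species))
    fam_ids <- sprintf("fam%02d", seq_len(n_families))
    ab_fams <- fam_ids[seq_len(n_abundance_families)]

    fam_anc <- lapply(fam_ids, function(f) random_codes(marker_len))
    names(fam_anc) <- fam_ids

    species_markers <- list()   # species -> list(family -> codes)
    ancestors <- list()
    pangenomes <- list()
    rep_list <- character(0)
    cluster_markers <- list()
    genome_rows <- list()
    db_seqs <- character(0); db_sp <- character(0); db_fam <- character(0)

    n_core <- ceiling((1 - accessory_frac) * n_genes)

    for (sp in sp_ids) {
        mk <- lapply(fam_anc, function(a) mutate_codes(a, between_div / 2)$codes)
        species_markers[[sp]] <- mk

        for (j in seq_len(n_strains)) {
            gid <- paste0(sp, "_g", j)
            strain_mk <- vapply(fam_ids, function(f)
                codes_to_string(mutate_codes(mk[[f]], within_div / 2)$codes), "")
            cluster_markers[[gid]] <- strain_mk
            genome_rows[[gid]] <- data.frame(genome_id = gid, species_id = sp,
                                             stringsAsFactors = FALSE)
        }
        if (markers_only) next

        gene_ids <- sprintf("%s_gene%03d", sp, seq_len(n_genes))
        genes <- lapply(seq_len(n_genes), function(i) random_codes(gene_len))
        names(genes) <- gene_ids

        # ancestral genome: markers then genes, separated by spacers
        segs <- list(); codes <- integer(0); pos <- 0L
        add_seg <- function(type, id, family, s) {
            segs[[length(segs) + 1L]] <<- data.frame(
                type = type, id = id, family = family,
                start = pos, end = pos + length(s),
                stringsAsFactors = FALSE)
            codes <<- c(codes, s); pos <<- pos + length(s)
        }
        for (f in fam_ids) {
            add_seg("marker", paste0(sp, "|", f), f, mk[[f]])
            add_seg("spacer", NA_character_, NA_character_,
                    random_codes(spacer_len))
        }
        for (g in gene_ids) {
            add_seg("gene", g, NA_character_, genes[[g]])
            add_seg("spacer", NA_character_, NA_character_,
                    random_codes(spacer_len))
        }
        segments <- do.call(rbind, segs)
        ancestors[[sp]] <- list(
            codes = codes, segments = segments,
            core_genes = gene_ids[seq_len(n_core)],
            accessory_genes = if (n_core < n_genes)
                gene_ids[(n_core + 1):n_genes] else character(0),
            within_div = within_div)
        rep_list[sp] <- codes_to_string(codes)

        # pan-genome: markers plus pool genes, clustered at 99%
        pool <- c(setNames(vapply(fam_ids, function(f)
                      codes_to_string(mk[[f]]), ""),
                  paste0(sp, "|", fam_ids)),
                  vapply(gene_ids, function(g) codes_to_string(genes[[g]]), ""))
        flags <- setNames(ab_fams, paste0(sp, "|", ab_fams))
        pangenomes[[sp]] <- buildPangenome(pool, speciesId = sp,
                                           identity = 99,
                                           uscgFamily = flags)

        # abundance-panel entries of the marker database
        db_seqs <- c(db_seqs, vapply(ab_fams, function(f)
            codes_to_string(mk[[f]]), ""))
        db_sp <- c(db_sp, rep(sp, length(ab_fams)))
        db_fam <- c(db_fam, ab_fams)
    }

    db <- if (markers_only)
        markerDb(Biostrings::DNAStringSet(), character(0), character(0),
                 cutoffs = setNames(numeric(0), character(0)))
    else markerDb(db_seqs, db_sp, db_fam, cutoffs = cutoff)
    reps <- Biostrings::DNAStringSet(rep_list)
    new("MockSpeciesSet",
        species = sp_ids,
        genomes = do.call(rbind, genome_rows),
        markerDb = db,
        pangenomes = pangenomes,
        repGenomes = reps,
        clusterMarkers = cluster_markers,
        ancestors = ancestors,
        params = list(seed = seed, n_species = n_species,
                      n_strains = n_strains, n_families = n_families,
                      n_abundance_families = n_abundance_families,
                      marker_len = marker_len, n_genes = n_genes,
                      gene_len = gene_len, spacer_len = spacer_len,
                      accessory_frac = accessory_frac,
                      within_div = within_div, between_div = between_div,
                      markers_only = markers_only))
}

#' Draw a community strain of a species
#'
#' A strain is the species' ancestral genome with point substitutions at
#' half the pairwise within-species divergence (so strain-vs-representative
#' divergence is `within_div / 2`), with each accessory pool gene retained
#' independently with probability 0.5. The true gene set (pan-genome cluster
#' ids), true SNPs relative to the representative genome (in representative
#' coordinates, restricted to retained segments) and the genome sequence are
#' returned.
#'
#' @param set A [MockSpeciesSet-class] (not `markers_only`).
#' @param species_id Species to draw from.
#' @param p_accessory Retention probability for accessory genes.
#' @return list with `codes` (integer genome encoding), `seq`, `genes`,
#'   `snps` (data.frame `pos`, `ref`, `alt`) and `length`.
#' @export
simulateStrain <- function(set, species_id, p_accessory = 0.5) {
    anc <- set@ancestors[[species_id]]
    if (is.null(anc)) stop("unknown or markers-only species: ", species_id)
    mut <- mutate_codes(anc$codes, anc$within_div / 2)
    keep_acc <- anc$accessory_genes[
        runif(length(anc$accessory_genes)) < p_accessory]
    segs <- anc$segments
    drop <- segs$type == "gene" & !(segs$id %in% c(anc$core_genes, keep_acc))
    keep_rows <- which(!drop)
    codes <- unlist(lapply(keep_rows, function(i)
        mut$codes[(segs$start[i] + 1L):segs$end[i]]), use.names = FALSE)
    in_kept <- rep(FALSE, length(anc$codes))
    for (i in keep_rows)
        in_kept[(segs$start[i] + 1L):segs$end[i]] <- TRUE
    snps <- mut$muts[in_kept[mut$muts$pos + 1L], , drop = FALSE]
    genes <- c(segs$id[segs$type == "marker"],
               intersect(segs$id[segs$type == "gene"],
                         c(anc$core_genes, keep_acc)))
    list(codes = codes, seq = codes_to_string(codes), genes = genes,
         snps = snps, length = length(codes))
}

#' Simulate shotgun reads from a set of genomes
#'
#' Per-genome read counts are Poisson with mean coverage x length /
#' read length; start positions are uniform, strands equiprobable.
#' Substitution errors occur independently per base at `error_rate`;
#' correct bases draw qualities uniformly from `q_correct`, errored bases
#' from `q_error`, so both the mean-read-quality (20) and per-base (30)
#' filters are exercised.
#'
#' @param genomes Named list of genome sequences (character) or integer code
#'   vectors.
#' @param coverages Named numeric fold coverage per genome.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error rate.
#' @param q_correct,q_error Quality ranges (integer vectors to sample from).
#' @param seed Optional seed.
#' @return list with `reads`, `quals` (character vectors), `id`, `origin`
#'   (source genome per read), `start` (0-based), `strand`.
#' @export
simulateReads <- function(genomes, coverages, read_len = 100,
                          error_rate = 0.01, q_correct = 30:40,
                          q_error = 2:35, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    reads <- quals <- ids <- origin <- strand <- list()
    starts <- list()
    for (g in names(genomes)) {
        gen <- genomes[[g]]
        if (is.character(gen)) {
            codes <- match(strsplit(toupper(gen), "")[[1]],
                           c("A", "C", "G", "T")) - 1L
            codes[is.na(codes)] <- 4L
        } else codes <- as.integer(gen)
        L <- length(codes)
        if (L < read_len) next
        cv <- coverages[[g]]
        if (is.null(cv) || is.na(cv) || cv <= 0) next
        n <- rpois(1, cv * L / read_len)
        if (n == 0) next
        st <- sample.int(L - read_len + 1L, n, replace = TRUE)
        idx <- rep(st, times = read_len) +
            rep(0:(read_len - 1L), each = n)
        m <- matrix(codes[idx], nrow = n)
        rev <- runif(n) < 0.5
        if (any(rev)) {
            sub <- m[rev, , drop = FALSE]
            sub <- sub[, read_len:1, drop = FALSE]
            low <- sub <= 3L
            sub[low] <- 3L - sub[low]
            m[rev, ] <- sub
        }
        q <- matrix(sample(q_correct, n * read_len, replace = TRUE),
                    nrow = n)
        if (error_rate > 0) {
            err <- matrix(runif(n * read_len) < error_rate, nrow = n)
            err <- err & m <= 3L
            ne <- sum(err)
            if (ne > 0) {
                m[err] <- (m[err] + sample.int(3L, ne, replace = TRUE)) %% 4L
                q[err] <- sample(q_error, ne, replace = TRUE)
            }
        }
        reads[[g]] <- cpp_codes_to_strings(m)
        quals[[g]] <- cpp_quals_to_strings(q)
        ids[[g]] <- sprintf("%s_r%06d", g, seq_len(n))
        origin[[g]] <- rep(g, n)
        strand[[g]] <- ifelse(rev, "-", "+")
        starts[[g]] <- st - 1L
    }
    list(reads = unlist(reads, use.names = FALSE),
         quals = unlist(quals, use.names = FALSE),
         id = unlist(ids, use.names = FALSE),
         origin = unlist(origin, use.names = FALSE),
         start = unlist(starts, use.names = FALSE),
         strand = unlist(strand, use.names = FALSE))
}

#' Simulate a mock metagenomic community
#'
#' Draws one strain per species (for species with non-zero abundance),
#' allocates per-genome coverage as total coverage x abundance, simulates
#' reads, and returns the complete ground truth.
#'
#' @param set A [MockSpeciesSet-class].
#' @param abundances Named relative abundances over `set@species` (default:
#'   exponentially decreasing over all species). Must sum to 1.
#' @param total_coverage Total genome coverage of the community.
#' @param read_len,error_rate,q_correct,q_error Read-simulation parameters.
#' @param seed Optional seed.
#' @return list with `reads`, `quals`, `id`, `strains` (per species) and
#'   `truth` (a [MockTruth-class]).
#' @export
simulateCommunity <- function(set, abundances = NULL, total_coverage = 100,
                              read_len = 100, error_rate = 0.01,
                              q_correct = 30:40, q_error = 2:35,
                              seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(abundances)) {
        abundances <- setNames(exponentialAbundances(length(set@species)),
                               set@species)
    }
    if (abs(sum(abundances) - 1) > 1e-9)
        stop("abundances must sum to 1")
    sp <- names(abundances)[abundances > 0]
    strains <- lapply(sp, function(s) simulateStrain(set, s))
    names(strains) <- sp
    coverages <- total_coverage * abundances
    rd <- simulateReads(lapply(strains, `[[`, "codes"), coverages[sp],
                        read_len = read_len, error_rate = error_rate,
                        q_correct = q_correct, q_error = q_error)
    truth <- new("MockTruth",
                 abundances = abundances,
                 coverages = coverages,
                 geneSets = lapply(strains, `[[`, "genes"),
                 snpSets = lapply(strains, `[[`, "snps"),
                 readOrigin = if (length(rd$origin)) rd$origin else character(0))
    c(rd[c("reads", "quals", "id")], list(strains = strains, truth = truth))
}

#' Confusion-matrix metrics for set predictions
#'
#' Standard classification metrics over a finite universe: sensitivity
#' (TP / (TP + FN)), specificity (TN / (TN + FP)), balanced accuracy
#' ((sensitivity + specificity) / 2), precision, false discovery rate
#' (FP / (TP + FP)) and F1.
#'
#' @param predicted Character vector (or set) of predicted-positive items.
#' @param truth Character vector of truly positive items.
#' @param universe All items under consideration; `predicted` and `truth`
#'   must be subsets.
#' @return list of metrics with the underlying counts.
#' @export
classificationMetrics <- function(predicted, truth, universe) {
    if (length(universe) == 0) stop("empty universe")
    predicted <- unique(predicted); truth <- unique(truth)
    if (!all(predicted %in% universe) || !all(truth %in% universe))
        stop("predicted and truth must be subsets of the universe")
    TP <- length(intersect(predicted, truth))
    FP <- length(setdiff(predicted, truth))
    FN <- length(setdiff(truth, predicted))
    TN <- length(universe) - TP - FP - FN
    sens <- if (TP + FN > 0) TP / (TP + FN) else NaN
    spec <- if (TN + FP > 0) TN / (TN + FP) else NaN
    prec <- if (TP + FP > 0) TP / (TP + FP) else NaN
    fdr <- if (TP + FP > 0) FP / (TP + FP) else NaN
    f1 <- if (!is.nan(sens) && !is.nan(prec) && sens + prec > 0)
        2 * sens * prec / (sens + prec) else 0
    list(counts = c(TP = TP, FP = FP, FN = FN, TN = TN),
         sensitivity = sens, specificity = spec,
         balanced_accuracy = (sens + spec) / 2,
         precision = prec, FDR = fdr, F1 = f1)
}

#' Squared Pearson correlation
#'
#' @param true,estimated Equal-length numeric vectors (length >= 2).
#' @return r^2, or `NA` when either vector is constant.
#' @export
rSquared <- function(true, estimated) {
    if (length(true) != length(estimated) || length(true) < 2)
        stop("need two equal-length vectors of length >= 2")
    if (stats::sd(true) == 0 || stats::sd(estimated) == 0) return(NA_real_)
    cor(true, estimated)^2
}
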