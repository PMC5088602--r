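#' Marker-gene database for species abundance profiling
#'
#' Holds one universal single-copy gene (USCG) sequence per (species, family)
#' pair together with the family-specific percent-identity cutoffs used when
#' recruiting metagenomic reads. Reads whose best hit fails the cutoff of the
#' family it maps to are not assigned to any species.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of marker genes, named
#'   `"<species>|<family>"`.
#' @slot species Character vector, parallel to `sequences`: species of each
#'   marker.
#' @slot family Character vector, parallel to `sequences`: USCG family of each
#'   marker.
#' @slot cutoffs Named numeric vector of per-family species-level percent
#'   identity cutoffs (percent, one entry per family).
#'
#' @seealso [markerDb()], [profileSpecies()]
#' @export
setClass("MarkerDb",
    slots = c(
        sequences = "DNAStringSet",
        species = "character",
        family = "character",
        cutoffs = "numeric"
    )
)

setValidity("MarkerDb", function(object) {
    n <- length(object@sequences)
    if (length(object@species) != n || length(object@family) != n)
        return("species/family annotations must parallel the sequences")
    if (n > 0 && any(width(object@sequences) < 1))
        return("marker sequences must be non-empty")
    if (anyNA(object@cutoffs) || is.null(names(object@cutoffs)))
        return("cutoffs must be a named numeric vector")
    if (any(object@cutoffs < 50 | object@cutoffs > 100))
        return("per-family cutoffs must lie in [50, 100] percent")
    if (!all(object@family %in% names(object@cutoffs)))
        return("every family must have a cutoff")
    if (anyDuplicated(paste(object@species, object@family)))
        return("at most one marker per (species, family) pair")
    TRUE
})

#' Construct a marker database
#'
#' @param sequences [Biostrings::DNAStringSet] (or character vector) of marker
#'   gene sequences.
#' @param species Character vector: species id of each marker.
#' @param family Character vector: USCG family id of each marker.
#' @param cutoffs Named numeric vector of per-family percent-identity cutoffs;
#'   a single unnamed value is recycled to all families (default 95).
#' @return A [MarkerDb-class] object.
#' @export
markerDb <- function(sequences, species, family, cutoffs = 95) {
    if (!is(sequences, "DNAStringSet"))
        sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
    names(sequences) <- paste(species, family, sep = "|")
    fams <- unique(family)
    if (is.null(names(cutoffs)))
        cutoffs <- setNames(rep(cutoffs, length.out = length(fams)), fams)
    new("MarkerDb", sequences = sequences, species = species,
        family = family, cutoffs = cutoffs)
}

#' Pan-genome of a species
#'
#' The non-redundant set of gene clusters (by default at 99% nucleotide
#' identity) across all genomes of one species. Each cluster is represented by
#' a centroid sequence; clusters corresponding to the 15 USCG abundance
#' families are flagged so gene coverages can be normalised into copy numbers.
#'
#' @slot speciesId Single species id.
#' @slot centroids [Biostrings::DNAStringSet] of cluster centroid sequences,
#'   named by cluster id.
#' @slot members List (one element per cluster) of member gene ids; the
#'   centroid is always a member.
#' @slot uscgFamily Character vector parallel to `centroids`: USCG family id of
#'   the cluster, or `NA` for ordinary genes.
#' @slot familyMaps Named list of coarser aggregation maps (levels "75".."95"),
#'   each a named character vector mapping cluster id to coarse family id.
#'
#' @seealso [buildPangenome()], [aggregateFamilies()], [profileGenes()]
#' @export
setClass("PanGenome",
    slots = c(
        speciesId = "character",
        centroids = "DNAStringSet",
        members = "list",
        uscgFamily = "character",
        familyMaps = "list"
    )
)

setValidity("PanGenome", function(object) {
    n <- length(object@centroids)
    if (length(object@speciesId) != 1L) return("speciesId must be a single id")
    if (length(object@members) != n || length(object@uscgFamily) != n)
        return("members/uscgFamily must parallel the centroids")
    cid <- names(object@centroids)
    if (n > 0 && (is.null(cid) || anyDuplicated(cid)))
        return("centroids must have unique cluster ids")
    ok <- vapply(seq_len(n), function(i) cid[i] %in% object@members[[i]], logical(1))
    if (n > 0 && !all(ok)) return("each centroid must be a member of its cluster")
    all_members <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(all_members))
        return("every gene must belong to exactly one cluster")
    TRUE
})

#' Per-sample species abundance profile
#'
#' Coverage (fold), relative abundance and (fractional) mapped-read counts per
#' species, estimated from reads recruited to the USCG marker database.
#' Relative abundances over detected species sum to one; when no read passes
#' the filters the profile is flagged as "no species detected".
#'
#' @slot profile data.frame with columns `species`, `coverage`,
#'   `relative_abundance`, `count_reads`.
#' @slot noSpeciesDetected Logical flag.
#'
#' @seealso [profileSpecies()], [selectSpecies()]
#' @export
setClass("SpeciesProfile",
    slots = c(profile = "data.frame", noSpeciesDetected = "logical")
)

setValidity("SpeciesProfile", function(object) {
    p <- object@profile
    need <- c("species", "coverage", "relative_abundance", "count_reads")
    if (!all(need %in% names(p))) return("missing profile columns")
    if (any(p$coverage < 0)) return("coverage must be non-negative")
    s <- sum(p$relative_abundance)
    if (nrow(p) > 0 && s > 0 && abs(s - 1) > 1e-9)
        return("relative abundances must sum to 1 over detected species")
    if (any((p$coverage == 0) != (p$relative_abundance == 0)))
        return("coverage 0 must coincide with abundance 0")
    TRUE
})

#' Ground truth emitted by the mock-community simulator
#'
#' @slot abundances Named numeric: true relative abundances (sum to 1).
#' @slot coverages Named numeric: true fold coverage per community genome.
#' @slot geneSets List per genome: true pan-genome cluster ids carried.
#' @slot snpSets List per genome: data.frame (`pos` 0-based, `ref`, `alt`) of
#'   true substitutions relative to the species representative genome.
#' @slot readOrigin Character: source genome of each simulated read.
#' @export
setClass("MockTruth",
    slots = c(
        abundances = "numeric",
        coverages = "numeric",
        geneSets = "list",
        snpSets = "list",
        readOrigin = "character"
    )
)

setValidity("MockTruth", function(object) {
    if (length(object@abundances) &&
        abs(sum(object@abundances) - 1) > 1e-9)
        return("true abundances must sum to 1")
    TRUE
})

#' Synthetic species reference set
#'
#' Container for everything the simulator knows about a set of synthetic
#' species: the USCG marker database, per-species pan-genomes, representative
#' genomes, per-genome clustering marker genes, and the internal ancestral
#' genomes from which community strains are drawn.
#'
#' @slot species Character vector of species ids.
#' @slot genomes data.frame (`genome_id`, `species_id`) of database genomes.
#' @slot markerDb [MarkerDb-class] over the abundance panel families.
#' @slot pangenomes Named list of [PanGenome-class] objects.
#' @slot repGenomes [Biostrings::DNAStringSet] of representative genomes.
#' @slot clusterMarkers Named list (genome id) of named character vectors
#'   (family id -> marker sequence) used for species clustering.
#' @slot ancestors Internal per-species ancestral genome encodings.
#' @slot params Simulation parameters (including the seed).
#' @export
setClass("MockSpeciesSet",
    slots = c(
        species = "character",
        genomes = "data.frame",
        markerDb = "MarkerDb",
        pangenomes = "list",
        repGenomes = "DNAStringSet",
        clusterMarkers = "list",
        ancestors = "list",
        params = "list"
    )
)

#' Gene-content matrices as a SummarizedExperiment
#'
#' Genes x samples container with assays `coverage`, `copy_number` and
#' `presence` for one species.
#' @export
setClass("GeneContentExperiment", contains = "SummarizedExperiment")

setValidity("GeneContentExperiment", function(object) {
    need <- c("coverage", "copy_number", "presence")
    if (!all(need %in% names(SummarizedExperiment::assays(object))))
        return("assays coverage, copy_number, presence are required")
    TRUE
})

#' Core-genome SNP matrices as a SummarizedExperiment
#'
#' Sites x samples container with assays `freq` (minor-allele frequency;
#' `NA` marks missing data, i.e. zero depth) and `depth`. Row metadata gives
#' the contig, 0-based position, reference allele and the cohort-wide
#' major/minor allele definitions.
#' @export
setClass("SnpExperiment", contains = "SummarizedExperiment")

setValidity("SnpExperiment", function(object) {
    need <- c("freq", "depth")
    if (!all(need %in% names(SummarizedExperiment::assays(object))))
        return("assays freq and depth are required")
    f <- SummarizedExperiment::assay(object, "freq")
    if (any(f < 0 | f > 1, na.rm = TRUE))
        return("minor-allele frequencies must lie in [0, 1]")
    TRUE
})

# ---------------------------------------------------------------------------
# generics and accessors

#' @describeIn MarkerDb-class marker sequences
#' @param x object
#' @export
setGeneric("markerSequences", function(x) standardGeneric("markerSequences"))
#' @export
setMethod("markerSequences", "MarkerDb", function(x) x@sequences)

#' @describeIn MarkerDb-class species annotation of each marker
#' @export
setGeneric("markerSpecies", function(x) standardGeneric("markerSpecies"))
#' @export
setMethod("markerSpecies", "MarkerDb", function(x) x@species)

#' @describeIn MarkerDb-class family annotation of each marker
#' @export
setGeneric("markerFamilies", function(x) standardGeneric("markerFamilies"))
#' @export
setMethod("markerFamilies", "MarkerDb", function(x) x@family)

#' @describeIn MarkerDb-class per-family percent-identity cutoffs
#' @export
setGeneric("familyCutoffs", function(x) standardGeneric("familyCutoffs"))
#' @export
setMethod("familyCutoffs", "MarkerDb", function(x) x@cutoffs)

#' @describeIn PanGenome-class centroid sequences
#' @param x object
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @export
setMethod("centroids", "PanGenome", function(x) x@centroids)

#' @describeIn PanGenome-class USCG family flags (NA for ordinary genes)
#' @export
setGeneric("uscgFlags", function(x) standardGeneric("uscgFlags"))
#' @export
setMethod("uscgFlags", "PanGenome", function(x)
    setNames(x@uscgFamily, names(x@centroids)))

#' @describeIn PanGenome-class cluster membership list
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @export
setMethod("clusterMembers", "PanGenome", function(x)
    setNames(x@members, names(x@centroids)))

#' @describeIn SpeciesProfile-class the per-species table
#' @param x object
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))
#' @export
setMethod("profileTable", "SpeciesProfile", function(x) x@profile)

#' @describeIn SpeciesProfile-class named vector of fold coverages
#' @export
setGeneric("speciesCoverage", function(x) standardGeneric("speciesCoverage"))
#' @export
setMethod("speciesCoverage", "SpeciesProfile", function(x)
    setNames(x@profile$coverage, x@profile$species))

#' @describeIn SpeciesProfile-class named vector of relative abundances
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))
#' @export
setMethod("relativeAbundance", "SpeciesProfile", function(x)
    setNames(x@profile$relative_abundance, x@profile$species))

#' @describeIn SpeciesProfile-class TRUE when no read passed the filters
#' @export
setGeneric("noSpeciesDetected", function(x) standardGeneric("noSpeciesDetected"))
#' @export
setMethod("noSpeciesDetected", "SpeciesProfile", function(x) x@noSpeciesDetected)

setMethod("show", "MarkerDb", function(object) {
    cat("MarkerDb with", length(object@sequences), "markers:",
        length(unique(object@species)), "species x",
        length(unique(object@family)), "USCG families\n")
    cat("  per-family identity cutoffs:",
        paste0(range(object@cutoffs), collapse = "-"), "%\n")
})

setMethod("show", "PanGenome", function(object) {
    cat("PanGenome of", object@speciesId, "with",
        length(object@centroids), "gene clusters (",
        sum(!is.na(object@uscgFamily)), "USCG-flagged )\n")
    if (length(object@familyMaps))
        cat("  aggregation levels:",
            paste(names(object@familyMaps), collapse = ", "), "\n")
})

setMethod("show", "SpeciesProfile", function(object) {
    p <- object@profile
    det <- sum(p$coverage > 0)
    cat("SpeciesProfile:", det, "of", nrow(p), "species detected")
    if (object@noSpeciesDetected) cat("  [no species detected]")
    cat("\n")
    if (det > 0) {
        top <- p[order(-p$coverage), , drop = FALSE]
        print(utils::head(top, 5), row.names = FALSE)
    }
})

setMethod("show", "MockSpeciesSet", function(object) {
    cat("MockSpeciesSet:", length(object@species), "species,",
        nrow(object@genomes), "database genomes",
        if (length(object@pangenomes)) "(with pan-genomes)" else "(markers only)",
        "\n")
})
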