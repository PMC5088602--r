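#' Detect alleles present in a sample
#'
#' An allele is present at a site iff it is supported by at least
#' `min_reads` reads (default 3) and by at least `min_freq` (default 10%) of
#' the quality-filtered reads mapped at the site.
#'
#' @param counts 4 x L count matrix from [pileupSites()].
#' @param min_reads Minimum supporting reads.
#' @param min_freq Minimum within-site frequency.
#' @return data.frame (`pos` 0-based, `allele`, `count`, `depth`, `freq`).
#' @export
detectAlleles <- function(counts, min_reads = 3, min_freq = 0.10) {
    depth <- colSums(counts)
    freq <- sweep(counts, 2, pmax(depth, 1), "/")
    ok <- counts >= min_reads & freq >= min_freq &
        rep(depth > 0, each = 4)
    idx <- which(ok, arr.ind = TRUE)
    data.frame(pos = idx[, 2] - 1L,
               allele = rownames(counts)[idx[, 1]],
               count = counts[idx],
               depth = depth[idx[, 2]],
               freq = counts[idx] / depth[idx[, 2]],
               stringsAsFactors = FALSE)
}

#' Find marker alleles private to single units
#'
#' Considering only biallelic sites (exactly two distinct alleles present
#' cohort-wide after the presence thresholds), a (site, allele) pair is a
#' marker allele for unit U iff it is present in at least one sample of U
#' and in no sample outside U. Units group samples (an individual, or a
#' mother-infant pair during transmission discovery).
#'
#' @param presenceList Named list (sample id) of [detectAlleles()] tables.
#' @param units Named character vector mapping sample id to unit id.
#' @return Named list (unit id) of data.frames (`pos`, `allele`); units
#'   without markers get zero-row entries.
#' @export
findMarkerAlleles <- function(presenceList, units) {
    if (length(presenceList) == 0) stop("no samples")
    miss <- setdiff(names(presenceList), names(units))
    if (length(miss)) stop("sample without unit: ", miss[1])
    all_units <- sort(unique(unname(units[names(presenceList)])))
    if (length(all_units) < 2)
        stop("marker-allele privacy needs at least 2 units")
    tab <- do.call(rbind, lapply(names(presenceList), function(s) {
        d <- presenceList[[s]]
        if (nrow(d) == 0) return(NULL)
        data.frame(pos = d$pos, allele = d$allele,
                   unit = unname(units[s]), stringsAsFactors = FALSE)
    }))
    empty <- setNames(lapply(all_units, function(u)
        data.frame(pos = integer(0), allele = character(0))), all_units)
    if (is.null(tab) || nrow(tab) == 0) return(empty)
    key <- paste(tab$pos, tab$allele)
    # biallelic: exactly two distinct present alleles at the site, cohort-wide
    site_alleles <- tapply(tab$allele, tab$pos, function(a) length(unique(a)))
    biallelic <- as.integer(names(site_alleles)[site_alleles == 2])
    tab <- tab[tab$pos %in% biallelic, , drop = FALSE]
    if (nrow(tab) == 0) return(empty)
    key <- paste(tab$pos, tab$allele)
    n_units <- tapply(tab$unit, key, function(u) length(unique(u)))
    private <- names(n_units)[n_units == 1]
    tab <- tab[key %in% private & !duplicated(paste(key, tab$unit)), ,
               drop = FALSE]
    out <- empty
    for (u in unique(tab$unit))
        out[[u]] <- tab[tab$unit == u, c("pos", "allele"), drop = FALSE]
    out
}

#' Marker-allele sharing between a donor unit and a recipient sample
#'
#' Sharing is 100 x (donor marker alleles present in the recipient) /
#' (donor marker alleles). Donors with fewer than `marker_min_count`
#' (default 10) markers are excluded, not scored.
#'
#' @param donorMarkers data.frame (`pos`, `allele`) of the donor unit's
#'   marker alleles.
#' @param recipientPresence [detectAlleles()] table of the recipient sample.
#' @param marker_min_count Minimum donor marker count.
#' @return One-row data.frame (`n_markers`, `n_shared`, `sharing_percent`,
#'   `excluded`).
#' @export
alleleSharing <- function(donorMarkers, recipientPresence,
                          marker_min_count = 10) {
    n <- nrow(donorMarkers)
    if (n < marker_min_count)
        return(data.frame(n_markers = n, n_shared = NA_integer_,
                          sharing_percent = NA_real_, excluded = TRUE))
    dk <- paste(donorMarkers$pos, donorMarkers$allele)
    rk <- paste(recipientPresence$pos, recipientPresence$allele)
    shared <- sum(dk %in% rk)
    data.frame(n_markers = n, n_shared = shared,
               sharing_percent = 100 * shared / n, excluded = FALSE)
}

#' Classify a sharing result as transmission
#'
#' Transmission iff sharing is strictly greater than the cutoff (default 5%).
#'
#' @param sharing A one-row [alleleSharing()] result (or a numeric sharing
#'   percentage).
#' @param transmission_cutoff Sharing percentage cutoff.
#' @return Logical.
#' @export
classifyTransmission <- function(sharing, transmission_cutoff = 5.0) {
    if (is.data.frame(sharing)) {
        if (isTRUE(sharing$excluded))
            stop("cannot classify an excluded sharing result")
        sharing <- sharing$sharing_percent
    }
    sharing > transmission_cutoff
}

#' Summarise transmission rates over a cohort
#'
#' Rate = transmitted pairs / evaluable (non-excluded) pairs, per species and
#' pooled. Zero evaluable pairs give an undefined (`NA`) rate.
#'
#' @param results data.frame with columns `species`, `donor`, `recipient`,
#'   `sharing_percent`, `transmitted`, `excluded`.
#' @return list with `per_species` (data.frame `species`, `n_evaluable`,
#'   `n_transmitted`, `rate`) and `overall` (single rate).
#' @export
cohortTransmissionSummary <- function(results) {
    ev <- results[!results$excluded, , drop = FALSE]
    per <- do.call(rbind, lapply(split(ev, results$species[!results$excluded]),
        function(d) data.frame(species = d$species[1],
                               n_evaluable = nrow(d),
                               n_transmitted = sum(d$transmitted),
                               rate = sum(d$transmitted) / nrow(d),
                               stringsAsFactors = FALSE)))
    overall <- if (nrow(ev) == 0) NA_real_ else
        sum(ev$transmitted) / nrow(ev)
    list(per_species = per, overall = overall)
}
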