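# Turning denoised per-group variant counts into verified (gDNA) and
# expressed (cDNA) alleles: length/frame filtering, a per-primer frequency
# threshold set from the repeatability of duplicated samples, and the
# gDNA/cDNA comparison with a 100-read minimum for cDNA-only alleles.

#' Per-amplicon variant frequencies
#'
#' Adds a `frequency` column (read count over group total) to a count
#' table, computed within each (individual, primer combination, DNA type,
#' replicate) group.
#'
#' @param tab An `amplicon_counts` table.
#' @return Data frame with the count-table columns plus `frequency`.
#' @export
group_profiles <- function(tab) {
  tab <- as_amplicon_counts(tab)
  key <- group_key(tab)
  totals <- tapply(tab$read_count, key, sum)
  out <- as.data.frame(tab)
  out$frequency <- out$read_count / as.numeric(totals[key])
  out
}

#' Length/frame filter
#'
#' Keeps variants whose length differs from the primer combination's
#' expected amplicon length by a multiple of three (including zero), i.e.
#' length variants that preserve the reading frame; removes all others.
#' Optionally also removes variants whose translation in the amplicon frame
#' contains a stop codon.
#'
#' @param tab An `amplicon_counts` table.
#' @param expected_length Named vector of expected lengths per primer
#'   combination (must cover every combination present).
#' @param stop_codon_screen Logical, see [mhc_config()].
#' @return The filtered `amplicon_counts` table.
#' @export
length_filter <- function(tab, expected_length,
                          stop_codon_screen = FALSE) {
  tab <- as_amplicon_counts(tab)
  missing_combo <- setdiff(unique(tab$primer_combo), names(expected_length))
  if (length(missing_combo) > 0)
    stop("no expected length configured for primer combination(s): ",
         paste(missing_combo, collapse = ", "), call. = FALSE)
  diff <- nchar(tab$sequence) - expected_length[tab$primer_combo]
  keep <- diff %% 3 == 0
  if (stop_codon_screen) {
    seqs <- unique(tab$sequence[keep])
    stops <- vapply(seqs, has_internal_stop, logical(1))
    keep[keep] <- !stops[tab$sequence[keep]]
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("amplicon_counts", "data.frame")
  out
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Duplicate-repeatability frequency threshold
#'
#' For each primer combination with duplicated gDNA samples, grid-searches
#' the minimum per-amplicon frequency threshold: variants at or above a
#' candidate threshold form a set per replicate, and the chosen threshold is
#' the smallest grid value maximising the mean Jaccard index between the
#' sets of each duplicate pair.  Deterministic given the grid.
#'
#' @param tab An `amplicon_counts` table (gDNA rows are used).
#' @param grid Numeric `c(min, max, step)` of candidate frequency
#'   thresholds.
#' @return Named numeric vector of thresholds per primer combination, with
#'   attribute `mean_jaccard` (the achieved concordance at the optimum).
#' @export
duplicate_repeatability_threshold <- function(tab,
                                              grid = c(0, 0.05, 1e-4)) {
  prof <- group_profiles(tab)
  prof <- prof[prof$dna_type == "gDNA", , drop = FALSE]
  ts <- seq(grid[1], grid[2], by = grid[3])
  combos <- sort(unique(prof$primer_combo))
  thresholds <- numeric(0)
  achieved <- numeric(0)
  for (combo in combos) {
    p <- prof[prof$primer_combo == combo, , drop = FALSE]
    reps <- unique(p[, c("individual_id", "replicate")])
    dup_ind <- names(which(table(reps$individual_id) >= 2))
    if (length(dup_ind) == 0) next
    pairs <- lapply(dup_ind, function(id) {
      rs <- sort(unique(p$replicate[p$individual_id == id]))[1:2]
      list(a = p[p$individual_id == id & p$replicate == rs[1], ],
           b = p[p$individual_id == id & p$replicate == rs[2], ])
    })
    mean_j <- vapply(ts, function(t) {
      mean(vapply(pairs, function(pr)
        jaccard(pr$a$variant_id[pr$a$frequency >= t],
                pr$b$variant_id[pr$b$frequency >= t]), numeric(1)))
    }, numeric(1))
    best <- which.max(mean_j)          # first maximum = smallest threshold
    if (mean_j[best] == 0)
      warning("no shared variants between duplicates for ", combo,
              "; returning the grid minimum", call. = FALSE)
    thresholds[combo] <- ts[best]
    achieved[combo] <- mean_j[best]
  }
  if (length(thresholds) == 0)
    stop("no duplicate pairs found in gDNA data; set a manual threshold",
         call. = FALSE)
  attr(thresholds, "mean_jaccard") <- achieved
  thresholds
}

#' Verify gDNA alleles against per-combination thresholds
#'
#' A variant is a verified gDNA allele for an individual when its
#' per-amplicon frequency reaches the primer combination's threshold in at
#' least one gDNA group of that individual (union over combinations and
#' replicates).
#'
#' @param tab An `amplicon_counts` table.
#' @param thresholds Named numeric vector from
#'   [duplicate_repeatability_threshold()] (or a manual override).
#' @return Data frame `individual_id`, `variant_id` of verified alleles;
#'   attribute `cohort_alleles` is the union over individuals.
#' @export
verify_gdna_alleles <- function(tab, thresholds) {
  prof <- group_profiles(tab)
  prof <- prof[prof$dna_type == "gDNA", , drop = FALSE]
  missing_combo <- setdiff(unique(prof$primer_combo), names(thresholds))
  if (length(missing_combo) > 0)
    stop("no threshold for primer combination(s): ",
         paste(missing_combo, collapse = ", "), call. = FALSE)
  hit <- prof$frequency >= thresholds[prof$primer_combo]
  verified <- unique(prof[hit, c("individual_id", "variant_id")])
  verified <- verified[order(verified$individual_id, verified$variant_id), ]
  rownames(verified) <- NULL
  attr(verified, "cohort_alleles") <- sort(unique(verified$variant_id))
  verified
}

#' Call expressed alleles from cDNA data
#'
#' A cDNA variant already verified in the individual's gDNA set is
#' expressed at any read count.  A cDNA-only variant is expressed when, in
#' at least one cDNA group, it has at least `cdna_min_reads` reads and its
#' per-amplicon frequency (or read depth, depending on
#' `config$cdna_only_rule`) reaches the mean per-variant frequency (depth)
#' of that primer combination's cDNA groups.  Individuals without any cDNA
#' group are flagged and excluded from expression analyses.
#'
#' @param tab An `amplicon_counts` table.
#' @param gdna_sets Data frame `individual_id`, `variant_id` from
#'   [verify_gdna_alleles()].
#' @param config An [mhc_config()].
#' @return Data frame `individual_id`, `variant_id`, `source`
#'   (`"gdna_match"` or `"cdna_only"`); attribute `no_cdna_individuals`.
#' @export
call_expressed_alleles <- function(tab, gdna_sets, config = mhc_config()) {
  prof <- group_profiles(tab)
  cdna <- prof[prof$dna_type == "cDNA", , drop = FALSE]
  gdna_ind <- unique(prof$individual_id[prof$dna_type == "gDNA"])
  no_cdna <- setdiff(gdna_ind, unique(cdna$individual_id))
  if (length(no_cdna) > 0)
    warning("individual(s) without cDNA data excluded from expression ",
            "analyses: ", paste(no_cdna, collapse = ", "), call. = FALSE)

  mean_freq <- tapply(cdna$frequency, cdna$primer_combo, mean)
  mean_depth <- tapply(cdna$read_count, cdna$primer_combo, mean)
  gkey <- paste(gdna_sets$individual_id, gdna_sets$variant_id, sep = "\r")
  in_gdna <- paste(cdna$individual_id, cdna$variant_id, sep = "\r") %in% gkey

  passes <- if (config$cdna_only_rule == "frequency") {
    cdna$read_count >= config$cdna_min_reads &
      cdna$frequency >= mean_freq[cdna$primer_combo]
  } else {
    cdna$read_count >= config$cdna_min_reads &
      cdna$read_count >= mean_depth[cdna$primer_combo]
  }
  keep <- in_gdna | passes
  expressed <- unique(cdna[keep, c("individual_id", "variant_id")])
  expressed$source <- ifelse(
    paste(expressed$individual_id, expressed$variant_id, sep = "\r") %in% gkey,
    "gdna_match", "cdna_only")
  expressed <- expressed[order(expressed$individual_id, expressed$variant_id), ]
  rownames(expressed) <- NULL
  attr(expressed, "no_cdna_individuals") <- no_cdna
  expressed
}

#' Verify and call alleles in one step
#'
#' Chains [length_filter()], [duplicate_repeatability_threshold()],
#' [verify_gdna_alleles()] and [call_expressed_alleles()] into a
#' per-individual verified-allele table.
#'
#' @param tab An `amplicon_counts` table.
#' @param config An [mhc_config()].
#' @param thresholds Optional manual threshold override (named by primer
#'   combination).
#' @return List of class `mhc_verified`: `table` (rows individual_id,
#'   variant_id, verified_gdna, expressed), `thresholds`, `filtered` (the
#'   length-filtered counts), `no_cdna_individuals`.
#' @export
verify_alleles <- function(tab, config = mhc_config(), thresholds = NULL) {
  filtered <- length_filter(tab, config$expected_length,
                            config$stop_codon_screen)
  if (is.null(thresholds))
    thresholds <- duplicate_repeatability_threshold(filtered,
                                                    config$threshold_grid)
  gdna <- verify_gdna_alleles(filtered, thresholds)
  expressed <- call_expressed_alleles(filtered, gdna, config)
  both <- merge(transform(gdna, verified_gdna = TRUE),
                transform(expressed[, c("individual_id", "variant_id")],
                          expressed = TRUE),
                by = c("individual_id", "variant_id"), all = TRUE)
  both$verified_gdna[is.na(both$verified_gdna)] <- FALSE
  both$expressed[is.na(both$expressed)] <- FALSE
  both <- both[order(both$individual_id, both$variant_id), ]
  rownames(both) <- NULL
  structure(list(table = both, thresholds = thresholds, filtered = filtered,
                 no_cdna_individuals = attr(expressed, "no_cdna_individuals")),
            class = "mhc_verified")
}
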