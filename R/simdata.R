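# Synthetic cohorts with planted truth: an allele pool split into a
# divergent "classical" set and a near-identical monophyletic
# "non-classical" set, individuals carrying 6-16 alleles, and replicated
# amplicon read-count tables with tier-scaled cDNA depths, low-frequency
# error variants and primer-specific allele dropout.

random_orf <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# One random synonymous single-nucleotide change, if the codon has one.
mutate_synonymous <- function(seq) {
  codons <- split_codons(seq)
  gc <- genetic_code()
  for (i in sample(seq_along(codons))) {
    for (pos in sample(3)) {
      nb <- codon_neighbours(codons[i], pos)
      syn <- nb[gc[nb] == gc[codons[i]] & gc[nb] != "*"]
      if (length(syn) > 0) {
        codons[i] <- sample(syn, 1)
        return(paste(codons, collapse = ""))
      }
    }
  }
  seq
}

# One random non-synonymous single-nucleotide change (codon stays sense).
mutate_nonsynonymous <- function(seq) {
  codons <- split_codons(seq)
  gc <- genetic_code()
  repeat {
    i <- sample(length(codons), 1)
    pos <- sample(3, 1)
    nb <- codon_neighbours(codons[i], pos)
    nonsyn <- nb[gc[nb] != gc[codons[i]] & gc[nb] != "*"]
    if (length(nonsyn) > 0) {
      codons[i] <- sample(nonsyn, 1)
      return(paste(codons, collapse = ""))
    }
  }
}

mean_aa_pdist <- function(seqs) {
  aa <- vapply(seqs, translate_dna, character(1))
  if (length(aa) < 2) return(0)
  amino_pdistance(aa, bootstrap = 0)$mean
}

#' Simulate an MHC-I allele pool with planted classes and expression tiers
#'
#' The classical pool is strongly diverged (independent non-synonymous and
#' synonymous codon changes from a common ancestor); the non-classical pool
#' descends from a single separate ancestor by a handful of mostly
#' synonymous changes, so that it forms a low-divergence monophyletic clade.
#' A fraction of classical alleles (default 8/88) carries an in-frame 3-nt
#' insertion.  Every sequence is an open reading frame.
#'
#' @param n_classical,n_nonclassical Pool sizes (each >= 2).
#' @param seed Integer seed; the same seed reproduces the same pool.
#' @param amplicon_length Base amplicon length in nt (multiple of 3).
#' @param insertion_fraction Fraction of the pool carrying the 3-nt
#'   insertion.
#' @param insertion_codon Codon after which the insertion is placed.
#' @param classical_nonsyn_codons,classical_syn_codons Per-allele numbers of
#'   non-synonymous / synonymous codon changes in the classical pool.
#' @param nonclassical_divergence_nt Substitutions separating the
#'   non-classical ancestor from the classical ancestor (the clade stem).
#' @param nonsyn_fraction_nonclassical Fraction of non-classical alleles
#'   carrying one non-synonymous change (the rest differ synonymously,
#'   which drives the low haplotype degeneracy of the clade).
#' @param high_fraction_classical Fraction of expressed classical alleles
#'   assigned the high-expression tier.
#' @param n_none Named integer vector: number of never-expressed alleles in
#'   each class.
#' @return Data frame with columns `allele_id`, `sequence`, `class_truth`,
#'   `expression_tier`, `has_insertion`; attributes `outgroup` (a divergent
#'   MHC-I-like outgroup sequence), `insertion_codon`, `amplicon_length`.
#' @export
simulate_allele_pool <- function(n_classical = 70, n_nonclassical = 18,
                                 seed = 1,
                                 amplicon_length = 258,
                                 insertion_fraction = 8 / 88,
                                 insertion_codon = 30,
                                 classical_nonsyn_codons = 8,
                                 classical_syn_codons = 4,
                                 nonclassical_divergence_nt = 24,
                                 nonsyn_fraction_nonclassical = 1 / 3,
                                 high_fraction_classical = 0.47,
                                 n_none = c(classical = 2, nonclassical = 2)) {
  stopifnot(n_classical >= 2, n_nonclassical >= 2)
  if (amplicon_length %% 3 != 0)
    stop("amplicon_length must be a multiple of 3", call. = FALSE)
  n_codons <- amplicon_length / 3
  if (n_codons < 2 * classical_nonsyn_codons)
    stop("requested classical divergence unreachable at this amplicon length",
         call. = FALSE)
  set.seed(seed)

  anc_cl <- random_orf(n_codons)
  anc_nc <- anc_cl
  for (i in seq_len(ceiling(nonclassical_divergence_nt / 2))) {
    anc_nc <- mutate_nonsynonymous(anc_nc)
    anc_nc <- mutate_synonymous(anc_nc)
  }

  draw_unique <- function(n, gen) {
    out <- character(0)
    guard <- 0
    while (length(out) < n) {
      s <- gen()
      if (!s %in% out) out <- c(out, s)
      guard <- guard + 1
      if (guard > 50 * n)
        stop("could not generate enough unique sequences", call. = FALSE)
    }
    out
  }

  classical <- draw_unique(n_classical, function() {
    s <- anc_cl
    for (i in seq_len(classical_nonsyn_codons)) s <- mutate_nonsynonymous(s)
    for (i in seq_len(classical_syn_codons)) s <- mutate_synonymous(s)
    s
  })

  n_nonsyn_nc <- max(1, round(nonsyn_fraction_nonclassical * n_nonclassical))
  nonsyn_flag <- seq_len(n_nonclassical) %in%
    sample(n_nonclassical, min(n_nonsyn_nc, n_nonclassical))
  k <- 0
  nonclassical <- draw_unique(n_nonclassical, function() {
    k <<- k + 1
    idx <- ((k - 1) %% n_nonclassical) + 1
    s <- anc_nc
    if (nonsyn_flag[idx]) s <- mutate_nonsynonymous(s)
    for (i in seq_len(sample(1:2, 1))) s <- mutate_synonymous(s)
    s
  })

  pool <- data.frame(
    allele_id = sprintf("A%03d", seq_len(n_classical + n_nonclassical)),
    sequence = c(classical, nonclassical),
    class_truth = rep(c("classical", "nonclassical"),
                      c(n_classical, n_nonclassical)),
    stringsAsFactors = FALSE
  )

  # expression tiers: a couple of never-expressed alleles per class, the
  # rest split into high/low for classical, all low for non-classical
  tier <- character(nrow(pool))
  cl_idx <- which(pool$class_truth == "classical")
  nc_idx <- which(pool$class_truth == "nonclassical")
  none_cl <- if (n_classical >= 4) min(n_none[["classical"]], n_classical - 2) else 0
  none_nc <- if (n_nonclassical >= 4) min(n_none[["nonclassical"]], n_nonclassical - 2) else 0
  tier[cl_idx] <- "low"
  tier[nc_idx] <- "low"
  if (none_cl > 0) tier[sample(cl_idx, none_cl)] <- "none"
  if (none_nc > 0) tier[sample(nc_idx, none_nc)] <- "none"
  expressed_cl <- cl_idx[tier[cl_idx] != "none"]
  n_high <- max(2, round(high_fraction_classical * length(expressed_cl)))
  tier[sample(expressed_cl, min(n_high, length(expressed_cl)))] <- "high"
  pool$expression_tier <- tier

  # post-conditions on planted divergence (before insertions perturb lengths)
  if (mean_aa_pdist(pool$sequence[nc_idx]) > 0.02)
    stop("non-classical pool exceeded the planted divergence ceiling",
         call. = FALSE)
  if (mean_aa_pdist(pool$sequence[cl_idx]) < 0.10)
    stop("requested classical divergence unreachable at this amplicon length",
         call. = FALSE)

  # in-frame insertions, classical pool only
  n_ins <- min(round(insertion_fraction * nrow(pool)), n_classical)
  pool$has_insertion <- FALSE
  if (n_ins > 0) {
    ins_idx <- sample(cl_idx, n_ins)
    at <- 3 * insertion_codon
    for (i in ins_idx) {
      s <- pool$sequence[i]
      repeat {
        cand <- paste0(substr(s, 1, at), sample(sense_codons(), 1),
                       substr(s, at + 1, nchar(s)))
        if (!cand %in% pool$sequence) break
      }
      pool$sequence[i] <- cand
      pool$has_insertion[i] <- TRUE
    }
  }

  out <- anc_cl
  for (i in seq_len(round(0.4 * n_codons))) {
    out <- mutate_nonsynonymous(out)
    out <- mutate_synonymous(out)
  }
  attr(pool, "outgroup") <- c(OUTGROUP = out)
  attr(pool, "insertion_codon") <- insertion_codon
  attr(pool, "amplicon_length") <- amplicon_length
  pool
}

#' Simulate individual genotypes over an allele pool
#'
#' Each individual carries between `allele_range[1]` and `allele_range[2]`
#' alleles sampled without replacement: 2-5 high-tier classical alleles,
#' 2-6 non-classical alleles and the remainder low/none-tier classical
#' alleles.  The number of high-expression alleles scales with the total
#' allele count, mirroring the observed joint pattern of allele counts and
#' high-expression counts.
#'
#' @param pool Allele pool from [simulate_allele_pool()].
#' @param n_individuals Cohort size.
#' @param allele_range Inclusive range of per-individual allele counts.
#' @param seed Integer seed.
#' @param mean_alleles,sd_alleles Target mean and SD of the per-individual
#'   allele count (defaults 11 and 3).
#' @return Data frame with one row per carried allele: `individual_id`,
#'   `allele_id`, `class_truth`, `expression_tier`.
#' @export
simulate_individuals <- function(pool, n_individuals = 18,
                                 allele_range = c(6, 16), seed = 1,
                                 mean_alleles = 11, sd_alleles = 3) {
  set.seed(seed)
  high_pool <- pool$allele_id[pool$class_truth == "classical" &
                                pool$expression_tier == "high"]
  lownone_pool <- pool$allele_id[pool$class_truth == "classical" &
                                   pool$expression_tier != "high"]
  nc_pool <- pool$allele_id[pool$class_truth == "nonclassical"]
  if (length(high_pool) < 2 || length(nc_pool) < 2)
    stop("allele range infeasible: pool too small for the per-individual ",
         "high/non-classical minima", call. = FALSE)
  if (nrow(pool) < allele_range[1])
    stop("allele range infeasible: pool smaller than the minimum allele count",
         call. = FALSE)

  rows <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    k <- round(rnorm(1, mean_alleles, sd_alleles))
    k <- max(allele_range[1], min(allele_range[2], k, nrow(pool)))
    h <- round(0.30 * k + rnorm(1, 0, 0.6))
    h <- max(2, min(5, h, length(high_pool)))
    nc <- round(0.25 * k + rnorm(1, 0, 0.6))
    nc <- max(2, min(6, nc, length(nc_pool)))
    while (k - h - nc < 0) {
      if (nc > 2) nc <- nc - 1 else if (h > 2) h <- h - 1 else
        k <- h + nc
    }
    low <- min(k - h - nc, length(lownone_pool))
    ids <- c(sample(high_pool, h), sample(nc_pool, nc),
             if (low > 0) sample(lownone_pool, low))
    rows[[i]] <- data.frame(individual_id = sprintf("ind%02d", i),
                            allele_id = ids, stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, rows)
  ind <- merge(ind, pool[, c("allele_id", "class_truth", "expression_tier")],
               by = "allele_id", sort = FALSE)
  ind <- ind[order(ind$individual_id, ind$allele_id),
             c("individual_id", "allele_id", "class_truth", "expression_tier")]
  rownames(ind) <- NULL

  # guarantee at least one never-expressed allele in the cohort
  if (!any(ind$expression_tier == "none") &&
      any(pool$expression_tier == "none")) {
    none_ids <- pool$allele_id[pool$expression_tier == "none"]
    first <- ind$individual_id == ind$individual_id[1]
    repl <- which(first & ind$expression_tier == "low" &
                    ind$class_truth == "classical")[1]
    if (!is.na(repl)) {
      new_id <- setdiff(none_ids, ind$allele_id[first])[1]
      if (!is.na(new_id)) {
        ind$allele_id[repl] <- new_id
        ind$class_truth[repl] <-
          pool$class_truth[pool$allele_id == new_id]
        ind$expression_tier[repl] <- "none"
      }
    }
  }

  counts <- table(ind$individual_id)
  if (any(counts < allele_range[1]) || any(counts > allele_range[2]))
    stop("allele range infeasible under the given pool", call. = FALSE)
  ind
}

new_error_registry <- function() new.env(parent = emptyenv())

error_variant <- function(parent_seq, registry, forbidden) {
  repeat {
    s <- parent_seq
    for (j in seq_len(sample(1:2, 1))) {
      pos <- sample(nchar(s), 1)
      substr(s, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(s, pos, pos)), 1)
    }
    if (s %in% forbidden) next
    id <- registry[[s]]
    if (is.null(id)) {
      id <- sprintf("E%04d", length(ls(registry)) + 1L)
      registry[[s]] <- id
    }
    return(c(id = id, sequence = s))
  }
}

#' Simulate replicated amplicon read counts for a cohort
#'
#' Groups are emitted per (individual, primer combination, DNA type,
#' replicate): gDNA on PC1 and PC2, cDNA on PC2 and PC3.  Within a group,
#' true-allele counts are multinomial around expected relative depths
#' (equal for gDNA; tier-scaled 2.5/n vs 0.4/n for cDNA, never-expressed
#' alleles absent), modulated by a per-(individual, combination, allele)
#' lognormal amplification bias shared across technical replicates.  Each
#' group additionally receives low-frequency error variants (Poisson count,
#' frequencies decaying below a 0.5% cap, the most abundant one at the cap)
#' that are essentially never shared between duplicate replicates.  A
#' configurable fraction of alleles is dropped from one primer combination
#' to mimic primer mismatch.
#'
#' @param truth List with elements `pool` and `individuals` (see
#'   [simulate_allele_pool()], [simulate_individuals()]).
#' @param depth_per_group Total reads per amplicon group (>= 100 x the
#'   maximum per-individual allele count).
#' @param error_rate Expected number of error variants per group (Poisson);
#'   0 disables error injection.
#' @param seed Integer seed.
#' @param duplicates Named integer vector: how many individuals are run
#'   twice for each (combination, DNA type).
#' @param dropout_fraction Fraction of pool alleles invisible to one primer
#'   combination.
#' @param jitter_sd Lognormal SD of the per-allele amplification bias.
#' @param tier_weights Relative cDNA depth multipliers for the high and low
#'   expression tiers.
#' @param error_freq_cap Frequency ceiling for injected error variants.
#' @return A validated `amplicon_counts` table; attributes `dropout`
#'   (data frame allele_id/primer_combo) and `duplicated_individuals`.
#' @export
simulate_counts <- function(truth, depth_per_group = 50000, error_rate = 2,
                            seed = 1,
                            duplicates = c(gDNA.PC1 = 4, gDNA.PC2 = 4,
                                           cDNA.PC2 = 3, cDNA.PC3 = 3),
                            dropout_fraction = 0.25,
                            jitter_sd = 0.15,
                            tier_weights = c(high = 2.5, low = 0.4),
                            error_freq_cap = 0.005) {
  pool <- truth$pool
  ind <- truth$individuals
  max_alleles <- max(table(ind$individual_id))
  if (depth_per_group < 100 * max_alleles)
    stop("depth_per_group must be at least 100 x the maximum allele count",
         call. = FALSE)
  set.seed(seed)

  n_drop <- round(dropout_fraction * nrow(pool))
  dropout <- data.frame(allele_id = character(0), primer_combo = character(0))
  if (n_drop > 0) {
    dropout <- data.frame(
      allele_id = sample(pool$allele_id, n_drop),
      primer_combo = sample(c("PC1", "PC3", "PC2"), n_drop, replace = TRUE,
                            prob = c(0.4, 0.4, 0.2)),
      stringsAsFactors = FALSE
    )
  }
  dropped <- function(ids, combo)
    ids %in% dropout$allele_id[dropout$primer_combo == combo]

  layouts <- data.frame(dna_type = c("gDNA", "gDNA", "cDNA", "cDNA"),
                        primer_combo = c("PC1", "PC2", "PC2", "PC3"),
                        stringsAsFactors = FALSE)
  individuals <- unique(ind$individual_id)
  dup_ids <- lapply(seq_len(nrow(layouts)), function(l) {
    key <- paste(layouts$dna_type[l], layouts$primer_combo[l], sep = ".")
    d <- if (key %in% names(duplicates)) duplicates[[key]] else 0
    sample(individuals, min(d, length(individuals)))
  })
  names(dup_ids) <- paste(layouts$dna_type, layouts$primer_combo, sep = ".")

  registry <- new_error_registry()
  seq_of <- stats::setNames(pool$sequence, pool$allele_id)
  tier_of <- stats::setNames(pool$expression_tier, pool$allele_id)
  rows <- list()

  for (id in individuals) {
    carried <- ind$allele_id[ind$individual_id == id]
    for (l in seq_len(nrow(layouts))) {
      combo <- layouts$primer_combo[l]
      dtype <- layouts$dna_type[l]
      present <- carried[!dropped(carried, combo)]
      w <- if (dtype == "gDNA") {
        stats::setNames(rep(1, length(present)), present)
      } else {
        tw <- tier_weights[tier_of[present]]
        stats::setNames(ifelse(is.na(tw), 0, tw), present)
      }
      w <- w[w > 0]
      if (length(w) == 0) next
      w <- w * exp(rnorm(length(w), 0, jitter_sd))  # shared across replicates
      n_reps <- 1L + (id %in% dup_ids[[paste(dtype, combo, sep = ".")]])
      for (r in seq_len(n_reps)) {
        n_err <- if (error_rate > 0) stats::rpois(1, error_rate) else 0L
        err_rows <- NULL
        if (n_err > 0) {
          freqs <- error_freq_cap * c(1, runif(n_err - 1)^2)
          err_counts <- pmax(1L, round(freqs * depth_per_group))
          parents <- sample(names(w), n_err, replace = TRUE)
          errs <- lapply(seq_len(n_err), function(e)
            error_variant(seq_of[[parents[e]]], registry, pool$sequence))
          err_rows <- data.frame(
            individual_id = id, primer_combo = combo, dna_type = dtype,
            replicate = r,
            variant_id = vapply(errs, `[[`, character(1), "id"),
            sequence = vapply(errs, `[[`, character(1), "sequence"),
            read_count = as.integer(err_counts),
            stringsAsFactors = FALSE
          )
          # identical error sequences drawn twice in one group: merge
          if (anyDuplicated(err_rows$variant_id)) {
            agg <- stats::aggregate(read_count ~ variant_id + sequence,
                                    err_rows, sum)
            err_rows <- data.frame(individual_id = id, primer_combo = combo,
                                   dna_type = dtype, replicate = r,
                                   variant_id = agg$variant_id,
                                   sequence = agg$sequence,
                                   read_count = agg$read_count,
                                   stringsAsFactors = FALSE)
          }
        }
        true_depth <- depth_per_group - sum(err_rows$read_count)
        cnt <- as.integer(stats::rmultinom(1, true_depth, w / sum(w)))
        keep <- cnt > 0
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, primer_combo = combo, dna_type = dtype,
          replicate = r, variant_id = names(w)[keep],
          sequence = unname(seq_of[names(w)[keep]]),
          read_count = cnt[keep], stringsAsFactors = FALSE
        )
        if (!is.null(err_rows)) rows[[length(rows) + 1L]] <- err_rows
      }
    }
  }
  tab <- as_amplicon_counts(do.call(rbind, rows))
  attr(tab, "dropout") <- dropout
  attr(tab, "duplicated_individuals") <- dup_ids
  tab
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [simulate_allele_pool()],
#' [simulate_individuals()] and [simulate_counts()] with consistent
#' sub-seeds derived from `seed`.
#'
#' @param n_individuals Cohort size (default 18).
#' @param seed Integer seed.
#' @param config An [mhc_config()]; supplies the insertion codon.
#' @param n_classical,n_nonclassical Pool sizes.
#' @param depth_per_group,error_rate,... Passed to [simulate_counts()].
#' @return List of class `mhc_sim`: `pool`, `individuals`, `counts`,
#'   `outgroup`, `insertion_codon`.
#' @export
simulate_cohort <- function(n_individuals = 18, seed = 1,
                            config = mhc_config(),
                            n_classical = 70, n_nonclassical = 18,
                            depth_per_group = 50000, error_rate = 2, ...) {
  pool <- simulate_allele_pool(n_classical, n_nonclassical, seed = seed,
                               insertion_codon = config$insertion_codon)
  ind <- simulate_individuals(pool, n_individuals, seed = seed + 1L)
  counts <- simulate_counts(list(pool = pool, individuals = ind),
                            depth_per_group = depth_per_group,
                            error_rate = error_rate, seed = seed + 2L, ...)
  structure(list(pool = pool, individuals = ind, counts = counts,
                 outgroup = attr(pool, "outgroup"),
                 insertion_codon = attr(pool, "insertion_codon")),
            class = "mhc_sim")
}
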