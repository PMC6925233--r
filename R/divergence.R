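# Divergence statistics per allele class: unique-allele counts after
# trimming to a common region, haplotype degeneracy (AA/NA), amino-acid
# P-distance with a site-bootstrap standard error, and Nei-Gojobori (1986)
# pathway-counting dN/dS with optional Jukes-Cantor correction.

#' Trim aligned alleles to a common region and translate
#'
#' Trims every allele to the configured codon range, drops alleles whose
#' trimmed translation contains a stop codon (with a warning), collapses
#' the result to unique nucleotide sequences, and translates them.
#'
#' @param aligned Named character vector of aligned nucleotide sequences
#'   (gap triplets allowed).
#' @param trim_codons Integer `c(first, last)` codon range (1-based).
#' @return List of class `trimmed_alignment`: `nt` (unique trimmed
#'   nucleotide sequences named by a representative allele id), `aa`
#'   (their translations), `n_nt` (NA: unique nucleotide alleles), `n_full`
#'   (alleles unique at original lengths), `n_aa` (AA: unique amino-acid
#'   alleles), `membership` (allele id -> representative id).
#' @export
trim_and_translate <- function(aligned, trim_codons = c(16L, 72L)) {
  start <- 3L * (trim_codons[1] - 1L) + 1L
  end <- 3L * trim_codons[2]
  if (end > min(nchar(aligned)))
    stop("trim region extends beyond the alignment", call. = FALSE)
  trimmed <- substr(aligned, start, end)
  aa <- vapply(trimmed, translate_dna, character(1))
  stops <- grepl("\\*", aa)
  if (any(stops)) {
    warning("excluding allele(s) with a stop codon in the trimmed region: ",
            paste(names(aligned)[stops], collapse = ", "), call. = FALSE)
    trimmed <- trimmed[!stops]
    aa <- aa[!stops]
    aligned <- aligned[!stops]
  }
  reps <- tapply(names(trimmed), trimmed, function(ids) sort(ids)[1])
  uniq_seq <- names(reps)
  uniq_ids <- as.character(reps)
  ord <- order(uniq_ids)
  nt <- stats::setNames(uniq_seq[ord], uniq_ids[ord])
  membership <- stats::setNames(as.character(reps[trimmed]), names(trimmed))
  structure(list(
    nt = nt,
    aa = vapply(nt, translate_dna, character(1)),
    n_nt = length(nt),
    n_full = length(unique(aligned)),
    n_aa = length(unique(vapply(nt, translate_dna, character(1)))),
    membership = membership
  ), class = "trimmed_alignment")
}

#' Haplotype degeneracy of a trimmed alignment
#'
#' Ratio of unique amino-acid alleles to unique nucleotide alleles; values
#' well below one indicate synonymous redundancy.
#'
#' @param trimmed A `trimmed_alignment` from [trim_and_translate()].
#' @return `AA / NA` in (0, 1].
#' @export
haplotype_degeneracy <- function(trimmed) {
  if (trimmed$n_nt < 1) stop("empty alignment", call. = FALSE)
  trimmed$n_aa / trimmed$n_nt
}

aa_matrix <- function(aa) do.call(rbind, strsplit(aa, ""))

pdist_from_matrix <- function(m) {
  n <- nrow(m)
  good <- matrix(m != "-" & m != "X" & m != "*", nrow = n)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- good[i, ] & good[j, ]
    if (!any(ok)) { vals <- c(vals, NA_real_); next }
    vals <- c(vals, sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  vals
}

#' Mean amino-acid P-distance with site-bootstrap standard error
#'
#' The mean over all unordered pairs of the proportion of differing sites
#' (sites with a gap in either sequence excluded pairwise).  The standard
#' error is the standard deviation of the mean across site-bootstrap
#' replicates (columns resampled with replacement), seed-deterministic.
#'
#' @param aa Character vector of aligned amino-acid sequences (>= 2).
#' @param bootstrap Number of bootstrap replicates (default 500; 0 skips
#'   the SE).
#' @param seed Integer seed for the bootstrap.
#' @return List `mean`, `se`, `pairwise` (vector of pairwise distances).
#' @export
amino_pdistance <- function(aa, bootstrap = 500, seed = 1) {
  if (length(aa) < 2) stop("need at least 2 sequences", call. = FALSE)
  m <- aa_matrix(aa)
  pw <- pdist_from_matrix(m)
  mean_p <- mean(pw, na.rm = TRUE)
  se <- NA_real_
  if (bootstrap > 0) {
    set.seed(seed)
    reps <- vapply(seq_len(bootstrap), function(b) {
      cols <- sample(ncol(m), replace = TRUE)
      mean(pdist_from_matrix(m[, cols, drop = FALSE]), na.rm = TRUE)
    }, numeric(1))
    se <- stats::sd(reps)
  }
  list(mean = mean_p, se = se, pairwise = pw)
}

# ---- Nei-Gojobori (1986) pathway counting ------------------------------

# Fraction of the three possible changes at each codon position that are
# synonymous; changes to stop codons count as non-synonymous.
ng_syn_sites <- function(codon) {
  gc <- genetic_code()
  sum(vapply(1:3, function(pos) {
    nb <- codon_neighbours(codon, pos)
    mean(gc[nb] == gc[codon] & gc[nb] != "*")
  }, numeric(1)))
}

ng_sites_table <- function() {
  cache <- get0("ng_sites_cache", envir = .mhc_cache)
  if (is.null(cache)) {
    cache <- vapply(sense_codons(), ng_syn_sites, numeric(1))
    assign("ng_sites_cache", cache, envir = .mhc_cache)
  }
  cache
}

# Average synonymous/non-synonymous difference counts between two codons
# over all shortest substitution pathways, excluding pathways through stop
# codons (falling back to all pathways when every one hits a stop).
ng_codon_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste(sort(c(c1, c2)), collapse = "")
  hit <- .mhc_cache$ng_path[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- all_permutations(pos)
  step_counts <- function(order_vec, allow_stops) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order_vec) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && gc[nxt] == "*" && nxt != c2) return(NULL)
      if (gc[cur] == gc[nxt]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  counts <- Filter(Negate(is.null),
                   lapply(perms, step_counts, allow_stops = FALSE))
  if (length(counts) == 0)
    counts <- lapply(perms, step_counts, allow_stops = TRUE)
  out <- colMeans(do.call(rbind, counts))
  .mhc_cache$ng_path[[key]] <- out
  out
}

all_permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in all_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

ng_pair <- function(s1, s2) {
  c1 <- split_codons(s1); c2 <- split_codons(s2)
  ok <- !grepl("-", c1) & !grepl("-", c2)
  c1 <- c1[ok]; c2 <- c2[ok]
  sites <- ng_sites_table()
  S <- (sum(sites[c1]) + sum(sites[c2])) / 2
  N <- 3 * length(c1) - S
  diffs <- mapply(function(a, b) ng_codon_diffs(a, b), c1, c2)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  c(S = S, N = N, Sd = Sd, Nd = Nd,
    pS = if (S > 0) Sd / S else NA_real_,
    pN = if (N > 0) Nd / N else NA_real_)
}

jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

#' Nei-Gojobori dN and dS for a codon-aligned allele set
#'
#' Pathway-counting method: per-codon synonymous site fractions averaged
#' over each pair, multi-substitution codons averaged over all shortest
#' substitution pathways with stop-traversing pathways excluded, pairwise
#' proportions optionally Jukes-Cantor corrected, and the cohort value
#' reported as the mean over all pairs.  Pairs whose correction is
#' undefined (proportion >= 3/4) are excluded with a warning.
#'
#' @param seqs Named character vector of codon-aligned nucleotide
#'   sequences (length multiple of 3, no internal stops; codons with gaps
#'   are skipped pairwise).
#' @param correction `"jc"` (default) or `"none"`.
#' @return List `dN`, `dS` (cohort means), `pairs` (data frame of per-pair
#'   S, N, Sd, Nd, pS, pN, dS, dN), `n_excluded`.
#' @export
nei_gojobori_dnds <- function(seqs, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    st <- ng_pair(seqs[[i]], seqs[[j]])
    rows[[length(rows) + 1L]] <-
      data.frame(a = ids[i], b = ids[j], t(st), stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  if (correction == "jc") {
    pairs$dS <- jc_correct(pairs$pS)
    pairs$dN <- jc_correct(pairs$pN)
  } else {
    pairs$dS <- pairs$pS
    pairs$dN <- pairs$pN
  }
  bad <- is.na(pairs$dS) | is.na(pairs$dN)
  if (any(bad))
    warning(sum(bad), " pair(s) excluded (correction undefined)",
            call. = FALSE)
  list(dN = mean(pairs$dN[!bad]), dS = mean(pairs$dS[!bad]),
       pairs = pairs, n_excluded = sum(bad))
}

#' Divergence summary per allele class
#'
#' Computes, for the non-classical alleles, all classical alleles, and the
#' high- and low-expression classical subsets (not-expressed and
#' undetermined alleles excluded from the subsets), the unique-allele
#' counts after trimming, haplotype degeneracy, amino-acid P-distance with
#' SE, and Nei-Gojobori dN/dS.
#'
#' @param aligned Named character vector of aligned allele sequences.
#' @param classes Data frame from [classify_alleles()].
#' @param consolidated Cohort expression calls (from
#'   [classify_expression()]).
#' @param config An [mhc_config()].
#' @return Data frame, one row per group, columns `group`, `n_nt`,
#'   `n_full`, `n_aa`, `degeneracy`, `pdist`, `pdist_se`, `dN`, `dS`.
#' @export
divergence_report <- function(aligned, classes, consolidated,
                              config = mhc_config()) {
  calls <- stats::setNames(consolidated$cohort_call, consolidated$variant_id)
  cls <- stats::setNames(classes$class, classes$variant_id)
  ids <- names(aligned)
  groups <- list(
    nonclassical = ids[cls[ids] == "nonclassical"],
    classical_all = ids[cls[ids] == "classical"],
    classical_high = ids[cls[ids] == "classical" &
                           calls[ids] %in% "high"],
    classical_low = ids[cls[ids] == "classical" & calls[ids] %in% "low"]
  )
  rows <- lapply(names(groups), function(g) {
    members <- groups[[g]]
    if (length(members) == 0)
      return(data.frame(group = g, n_nt = 0L, n_full = 0L, n_aa = 0L,
                        degeneracy = NA_real_, pdist = NA_real_,
                        pdist_se = NA_real_, dN = NA_real_, dS = NA_real_,
                        stringsAsFactors = FALSE))
    tr <- trim_and_translate(aligned[members], config$trim_codons)
    if (tr$n_nt < 2) {
      pd <- list(mean = NA_real_, se = NA_real_)
      dnds <- list(dN = NA_real_, dS = NA_real_)
    } else {
      pd <- amino_pdistance(tr$aa, bootstrap = config$pdist_bootstrap,
                            seed = config$rng_seed)
      dnds <- nei_gojobori_dnds(tr$nt, config$dnds_correction)
    }
    data.frame(group = g, n_nt = tr$n_nt, n_full = tr$n_full,
               n_aa = tr$n_aa,
               degeneracy = if (tr$n_nt >= 1) tr$n_aa / tr$n_nt else NA_real_,
               pdist = pd$mean, pdist_se = pd$se,
               dN = dnds$dN, dS = dnds$dS, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.mhc_cache <- new.env(parent = emptyenv())
.mhc_cache$ng_path <- new.env(parent = emptyenv())
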