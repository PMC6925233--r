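# Fixture builders and independent oracles used across test files.

count_row <- function(ind, combo, dtype, rep, vid, seq, n) {
  data.frame(individual_id = ind, primer_combo = combo, dna_type = dtype,
             replicate = rep, variant_id = vid, sequence = seq,
             read_count = n, stringsAsFactors = FALSE)
}

# A minimal hand-built table: one individual, two variants, gDNA + cDNA.
tiny_counts <- function() {
  rbind(
    count_row("i1", "PC2", "gDNA", 1, "v1", "ACGTAA", 60),
    count_row("i1", "PC2", "gDNA", 1, "v2", "ACGTCC", 40),
    count_row("i1", "PC2", "cDNA", 1, "v1", "ACGTAA", 150),
    count_row("i1", "PC2", "cDNA", 1, "v2", "ACGTCC", 50)
  )
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Cached small simulated cohorts so several tests can share one run.
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(seed = 1, n_individuals = 8, n_classical = 30,
                       n_nonclassical = 8, depth = 20000, ...) {
  key <- paste(seed, n_individuals, n_classical, n_nonclassical, depth,
               sep = "_")
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_cohort(
      n_individuals, seed = seed, n_classical = n_classical,
      n_nonclassical = n_nonclassical, depth_per_group = depth, ...)
  .sim_cache[[key]]
}

# ---- independent oracles -----------------------------------------------

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pool), n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Ws <= obs), mean(Ws >= obs)))
}

# Brute-force Nei-Gojobori oracle: explicit recursive enumeration of
# substitution orders per codon, independent of the package's
# permutation-table implementation.
oracle_codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  function() gc
})

oracle_paths <- function(c1, c2, allow_stop = FALSE) {
  gc <- oracle_codon_table()
  if (c1 == c2) return(list(c(sd = 0, nd = 0)))
  out <- list()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  for (p in pos) {
    nxt <- c1
    substr(nxt, p, p) <- substr(c2, p, p)
    if (!allow_stop && gc[[nxt]] == "*" && nxt != c2) next
    step <- if (gc[[c1]] == gc[[nxt]]) c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
    for (rest in oracle_paths(nxt, c2, allow_stop))
      out[[length(out) + 1L]] <- step + rest
  }
  out
}

oracle_ng_pair <- function(s1, s2) {
  gc <- oracle_codon_table()
  codons1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  codons2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  syn_sites <- function(codon) {
    s <- 0
    for (p in 1:3) {
      base <- substr(codon, p, p)
      for (b in setdiff(c("A", "C", "G", "T"), base)) {
        mut <- codon
        substr(mut, p, p) <- b
        if (gc[[mut]] != "*" && gc[[mut]] == gc[[codon]]) s <- s + 1 / 3
      }
    }
    s
  }
  S <- 0; Sd <- 0; Nd <- 0; L <- 0
  for (k in seq_along(codons1)) {
    if (grepl("-", codons1[k]) || grepl("-", codons2[k])) next
    L <- L + 3
    S <- S + (syn_sites(codons1[k]) + syn_sites(codons2[k])) / 2
    paths <- oracle_paths(codons1[k], codons2[k])
    if (length(paths) == 0) paths <- oracle_paths(codons1[k], codons2[k], TRUE)
    m <- colMeans(do.call(rbind, paths))
    Sd <- Sd + m[["sd"]]; Nd <- Nd + m[["nd"]]
  }
  N <- L - S
  c(S = S, N = N, Sd = Sd, Nd = Nd, pS = Sd / S, pN = Nd / N)
}

# Random pair of codon sequences without internal stops.
random_codon_pair <- function(n_codons, n_mut = 8) {
  gc <- oracle_codon_table()
  sense <- names(gc)[gc != "*"]
  a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  b <- a
  for (i in seq_len(n_mut)) {
    repeat {
      pos <- sample(nchar(b), 1)
      cand <- b
      substr(cand, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      cod <- ((pos - 1) %/% 3) + 1
      codon <- substr(cand, 3 * cod - 2, 3 * cod)
      if (gc[[codon]] != "*") { b <- cand; break }
    }
  }
  c(a, b)
}

# Least-squares residual of fitting a distance matrix on a topology: the
# additive (generating) topology is the unique one with ~zero residual.
topology_residual <- function(tree, d) {
  tips <- tree$tip.label
  n <- length(tips)
  m <- as.matrix(d)[tips, tips]
  pairs <- utils::combn(n, 2)
  tips_under <- function(node) {
    if (node <= n) return(tips[node])
    unlist(lapply(tree$edge[tree$edge[, 1] == node, 2], tips_under))
  }
  A <- sapply(seq_len(nrow(tree$edge)), function(e) {
    below <- tips_under(tree$edge[e, 2])
    apply(pairs, 2, function(pr)
      as.numeric(xor(tips[pr[1]] %in% below, tips[pr[2]] %in% below)))
  })
  y <- apply(pairs, 2, function(pr) m[pr[1], pr[2]])
  fit <- stats::lm.fit(A, y)
  sqrt(sum(fit$residuals^2))
}
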