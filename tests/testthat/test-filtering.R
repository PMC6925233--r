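variant_seqs <- local({
  set.seed(99)
  vapply(c(A = "A", B = "B", X = "X", rest = "rest", big = "big",
           small = "small"), function(i) random_dna(30), character(1))
})

make_profile_counts <- function() {
  # duplicate pair sharing two real variants; one-sided noise at 0.1%
  rbind(
    count_row("i1", "PC2", "gDNA", 1, "A", variant_seqs[["A"]], 500),
    count_row("i1", "PC2", "gDNA", 1, "B", variant_seqs[["B"]], 499),
    count_row("i1", "PC2", "gDNA", 1, "X", variant_seqs[["X"]], 1),
    count_row("i1", "PC2", "gDNA", 2, "A", variant_seqs[["A"]], 600),
    count_row("i1", "PC2", "gDNA", 2, "B", variant_seqs[["B"]], 400)
  )
}

test_that("length filter keeps frame-preserving length variants only", {
  set.seed(42)
  tab <- rbind(
    count_row("i1", "PC1", "gDNA", 1, "ok258", random_dna(258), 10),
    count_row("i1", "PC1", "gDNA", 1, "ins261", random_dna(261), 10),
    count_row("i1", "PC1", "gDNA", 1, "shift260", random_dna(260), 10),
    count_row("i1", "PC1", "gDNA", 1, "del255", random_dna(255), 10)
  )
  out <- length_filter(tab, c(PC1 = 258))
  expect_setequal(out$variant_id, c("ok258", "ins261", "del255"))

  expect_error(length_filter(tab, c(PC2 = 258)), "PC1")
})

test_that("stop-codon screening removes pseudogene-like variants when on", {
  clean <- "ATGAAACCCGGG"
  stopped <- "ATGTAACCCGGG"  # TAA at codon 2
  tab <- rbind(
    count_row("i1", "PC1", "gDNA", 1, "v1", clean, 10),
    count_row("i1", "PC1", "gDNA", 1, "v2", stopped, 10)
  )
  expect_setequal(length_filter(tab, c(PC1 = 12))$variant_id, c("v1", "v2"))
  expect_equal(length_filter(tab, c(PC1 = 12),
                             stop_codon_screen = TRUE)$variant_id, "v1")
})

test_that("duplicate repeatability threshold lands just above the noise", {
  set.seed(1)
  thr <- duplicate_repeatability_threshold(make_profile_counts(),
                                           grid = c(0, 0.05, 1e-4))
  expect_gt(thr[["PC2"]], 0.001)
  expect_lte(thr[["PC2"]], 0.0012)
  expect_equal(attr(thr, "mean_jaccard")[["PC2"]], 1)
})

test_that("concordant duplicates give the grid minimum; disjoint warn", {
  tab <- rbind(
    count_row("i1", "PC1", "gDNA", 1, "A", variant_seqs[["A"]], 70),
    count_row("i1", "PC1", "gDNA", 1, "B", variant_seqs[["B"]], 30),
    count_row("i1", "PC1", "gDNA", 2, "A", variant_seqs[["A"]], 65),
    count_row("i1", "PC1", "gDNA", 2, "B", variant_seqs[["B"]], 35)
  )
  thr <- duplicate_repeatability_threshold(tab, grid = c(0.001, 0.05, 1e-3))
  expect_equal(thr[["PC1"]], 0.001)

  disjoint <- rbind(
    count_row("i1", "PC1", "gDNA", 1, "A", variant_seqs[["A"]], 100),
    count_row("i1", "PC1", "gDNA", 2, "B", variant_seqs[["B"]], 100)
  )
  expect_warning(thr2 <- duplicate_repeatability_threshold(
    disjoint, grid = c(0.001, 0.05, 1e-3)), "no shared")
  expect_equal(thr2[["PC1"]], 0.001)

  no_dup <- count_row("i1", "PC1", "gDNA", 1, "A", variant_seqs[["A"]], 100)
  expect_error(duplicate_repeatability_threshold(no_dup), "manual")
})

test_that("gDNA verification applies the threshold per group", {
  tab <- rbind(
    count_row("i1", "PC2", "gDNA", 1, "big", variant_seqs[["big"]], 50),
    count_row("i1", "PC2", "gDNA", 1, "rest", variant_seqs[["rest"]], 945),
    count_row("i1", "PC2", "gDNA", 1, "small", variant_seqs[["small"]], 5),
    count_row("i1", "PC2", "gDNA", 2, "rest", variant_seqs[["rest"]], 1000)
  )
  v <- verify_gdna_alleles(tab, c(PC2 = 0.01))
  expect_setequal(v$variant_id, c("big", "rest"))  # 0.5% variant dropped
  expect_error(verify_gdna_alleles(tab, c(PC1 = 0.01)), "threshold")
})

test_that("cDNA expressed calls follow the gDNA-match and 100-read rules", {
  set.seed(4)
  seqs <- vapply(1:4, function(i) random_dna(30), character(1))
  tab <- rbind(
    count_row("i1", "PC2", "gDNA", 1, "g1", seqs[1], 900),
    count_row("i1", "PC2", "gDNA", 1, "g2", seqs[2], 100),
    count_row("i1", "PC2", "cDNA", 1, "g1", seqs[1], 3),
    count_row("i1", "PC2", "cDNA", 1, "only99", seqs[3], 99),
    count_row("i1", "PC2", "cDNA", 1, "only5k", seqs[4], 5000),
    count_row("i2", "PC2", "gDNA", 1, "g2", seqs[2], 500)
  )
  gdna <- verify_gdna_alleles(tab, c(PC2 = 0.01))
  expect_warning(expr <- call_expressed_alleles(tab, gdna), "i2")
  expect_identical(attr(expr, "no_cdna_individuals"), "i2")
  # gDNA match expressed at any count; 99 reads below the minimum; the
  # abundant cDNA-only variant clears both the 100-read and mean-frequency bars
  expect_setequal(expr$variant_id, c("g1", "only5k"))
  expect_equal(expr$source[expr$variant_id == "only5k"], "cdna_only")
})

test_that("raising the threshold never adds a verified allele", {
  sim <- cached_sim(seed = 6)
  filtered <- length_filter(sim$counts, mhc_config()$expected_length)
  prev <- NULL
  for (t in c(0.001, 0.005, 0.02, 0.05)) {
    v <- verify_gdna_alleles(filtered, c(PC1 = t, PC2 = t))
    cur <- paste(v$individual_id, v$variant_id)
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("duplicate pairs call identical allele sets on synthetic data", {
  sim <- cached_sim(seed = 6)
  cfg <- mhc_config()
  ver <- verify_alleles(sim$counts, cfg)
  prof <- group_profiles(ver$filtered)
  prof <- prof[prof$dna_type == "gDNA", ]
  thr <- ver$thresholds
  for (combo in names(thr)) {
    p <- prof[prof$primer_combo == combo, ]
    for (id in unique(p$individual_id)) {
      reps <- sort(unique(p$replicate[p$individual_id == id]))
      if (length(reps) < 2) next
      sets <- lapply(reps, function(r)
        sort(p$variant_id[p$individual_id == id & p$replicate == r &
                            p$frequency >= thr[[combo]]]))
      expect_identical(sets[[1]], sets[[2]])
    }
  }
})

test_that("verification recovers the planted alleles with no false calls", {
  sim <- cached_sim(seed = 6)
  ver <- verify_alleles(sim$counts, mhc_config())
  verified <- unique(ver$table$variant_id[ver$table$verified_gdna])
  planted <- unique(sim$individuals$allele_id)
  expect_setequal(verified, planted)
})
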