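test_that("trimming collapses alleles identical within the region", {
  set.seed(21)
  base <- random_dna(60)
  twin <- paste0(substr(base, 1, 57), "AAA")  # differs after the region
  if (twin == base) twin <- paste0(substr(base, 1, 57), "CCC")
  third <- base
  substr(third, 10, 10) <- if (substr(base, 10, 10) == "A") "C" else "A"
  aligned <- c(x1 = base, x2 = twin, x3 = third)
  # make sure nothing has stops in codons 1..19
  aligned <- vapply(aligned, function(s) {
    aa <- translate_dna(s)
    if (grepl("\\*", aa)) gsub("TAA|TAG|TGA", "CAA", s) else s
  }, character(1))

  tr <- trim_and_translate(aligned, trim_codons = c(1L, 19L))
  expect_equal(tr$n_full, 3L)
  expect_equal(tr$n_nt, 2L)  # x1 and x2 merge inside the region
  expect_true(all(tr$n_aa <= tr$n_nt))
})

test_that("alleles with stops inside the trimmed region are excluded", {
  good <- "ATGAAACCCGGGTTT"
  bad <- "ATGTAACCCGGGTTT"
  expect_warning(tr <- trim_and_translate(c(a = good, b = bad),
                                          trim_codons = c(1L, 5L)),
                 "stop")
  expect_equal(tr$n_nt, 1L)
  expect_equal(names(tr$nt), "a")
})

test_that("haplotype degeneracy is AA/NA and 1 without synonymy", {
  # three synonymous variants of one protein: ratio 1/NA
  syn <- c(s1 = "TTAAAACCC", s2 = "TTGAAACCC", s3 = "CTAAAACCC")  # all Leu-Lys-Pro
  tr <- trim_and_translate(syn, trim_codons = c(1L, 3L))
  expect_equal(tr$n_nt, 3L)
  expect_equal(tr$n_aa, 1L)
  expect_equal(haplotype_degeneracy(tr), 1 / 3)

  distinct <- c(d1 = "ATGAAACCC", d2 = "ATGCGGCCC", d3 = "ATGAAAGAC")
  tr2 <- trim_and_translate(distinct, trim_codons = c(1L, 3L))
  expect_equal(haplotype_degeneracy(tr2), 1)
})

test_that("amino-acid P-distance matches a brute-force pair average", {
  expect_equal(amino_pdistance(c("MKLV", "MKLV"), bootstrap = 50)$mean, 0)

  a <- strrep("A", 56)
  b <- paste0(strrep("R", 7), strrep("A", 49))
  expect_equal(amino_pdistance(c(a, b), bootstrap = 0)$mean, 0.125)

  set.seed(22)
  aas <- replicate(5, paste(sample(c("A", "R", "N", "D", "C"), 40,
                                   replace = TRUE), collapse = ""))
  got <- amino_pdistance(aas, bootstrap = 0)$mean
  # independent double-loop oracle
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    x <- strsplit(aas[i], "")[[1]]; y <- strsplit(aas[j], "")[[1]]
    vals <- c(vals, mean(x != y))
  }
  expect_equal(got, mean(vals), tolerance = 1e-12)

  # SE is seed-deterministic
  se1 <- amino_pdistance(aas, bootstrap = 100, seed = 3)$se
  se2 <- amino_pdistance(aas, bootstrap = 100, seed = 3)$se
  expect_identical(se1, se2)
  expect_gt(se1, 0)
})

test_that("Nei-Gojobori handles the canonical small cases", {
  r <- nei_gojobori_dnds(c("TTTAAA", "TTTAAA"))
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)

  r <- nei_gojobori_dnds(c("TTTAAACCC", "TTCAAACCC"))  # Phe -> Phe, synonymous
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)

  # site-count conservation: S + N equals the compared length
  p <- r$pairs
  expect_equal(p$S + p$N, 9)
})

test_that("Nei-Gojobori equals the pathway-enumeration oracle", {
  set.seed(23)
  for (i in 1:12) {
    pr <- random_codon_pair(20, n_mut = sample(4:10, 1))
    got <- nei_gojobori_dnds(pr, correction = "none")$pairs
    want <- oracle_ng_pair(pr[1], pr[2])
    expect_equal(got$S, want[["S"]], tolerance = 1e-12)
    expect_equal(got$Sd, want[["Sd"]], tolerance = 1e-12)
    expect_equal(got$Nd, want[["Nd"]], tolerance = 1e-12)
    expect_equal(got$pN, want[["pN"]], tolerance = 1e-12)
    expect_equal(got$pS, want[["pS"]], tolerance = 1e-12)
  }
})

test_that("dN/dS is symmetric and invariant to codon-column permutation", {
  set.seed(24)
  pr <- random_codon_pair(15, n_mut = 6)
  ab <- nei_gojobori_dnds(pr)$pairs
  ba <- nei_gojobori_dnds(rev(pr))$pairs
  expect_equal(ab[, c("S", "N", "Sd", "Nd")], ba[, c("S", "N", "Sd", "Nd")])

  perm <- sample(15)
  shuffle <- function(s) {
    cods <- substring(s, seq(1, 45, 3), seq(3, 45, 3))
    paste(cods[perm], collapse = "")
  }
  sh <- nei_gojobori_dnds(c(shuffle(pr[1]), shuffle(pr[2])))$pairs
  expect_equal(ab$dN, sh$dN, tolerance = 1e-12)
  expect_equal(ab$dS, sh$dS, tolerance = 1e-12)
})

test_that("saturated pairs are excluded from the correction with a warning", {
  # force pN >= 3/4: every codon differs at all three positions
  a <- strrep("TTA", 10)
  b <- strrep("CAC", 10)
  expect_warning(r <- nei_gojobori_dnds(c(a, b, a)), "excluded")
  expect_equal(r$n_excluded, 2L)
})

test_that("the class-level divergence table reproduces the planted ordering", {
  sim <- cached_sim(seed = 8, n_individuals = 5)
  cfg <- mhc_config()
  pool <- sim$pool
  carried <- unique(sim$individuals$allele_id)
  aligned <- align_alleles(setNames(pool$sequence, pool$allele_id)[carried],
                           sim$insertion_codon)
  classes <- data.frame(variant_id = carried,
                        class = pool$class_truth[match(carried,
                                                       pool$allele_id)],
                        stringsAsFactors = FALSE)
  tier <- pool$expression_tier[match(carried, pool$allele_id)]
  cons <- data.frame(variant_id = carried,
                     cohort_call = ifelse(tier == "none", "not_expressed",
                                          tier),
                     stringsAsFactors = FALSE)
  div <- divergence_report(aligned, classes, cons, cfg)
  expect_equal(div$group, c("nonclassical", "classical_all",
                            "classical_high", "classical_low"))
  expect_lt(div$pdist[div$group == "nonclassical"],
            div$pdist[div$group == "classical_all"])
  expect_gte(div$dN[div$group == "classical_all"],
             10 * div$dN[div$group == "nonclassical"])
  # the high/low subsets partition the expressed classical alleles
  n_expr_classical <- sum(classes$class == "classical" &
                            cons$cohort_call %in% c("high", "low"))
  expect_equal(div$n_full[div$group == "classical_high"] +
                 div$n_full[div$group == "classical_low"], n_expr_classical)

  single <- divergence_report(aligned[1], classes[1, ], cons[1, ], cfg)
  expect_true(is.na(single$pdist[single$group == "classical_all"]) ||
                single$n_nt[single$group == "classical_all"] <= 1)
})
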