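test_that("the K80 closed form matches its definition", {
  expect_equal(k80_distance("ACGT", "ACGT"), 0)

  # P = 0.1 (10 transitions), Q = 0.05 (5 transversions) over 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(k80_distance(a, b), -0.5 * log(0.75 * sqrt(0.90)))

  # saturation flags as infinite
  expect_equal(k80_distance("AAAA", "GGGG"), Inf)
  expect_error(k80_distance("ACG", "ACGT"), "equal length")

  # gap columns excluded pairwise
  expect_equal(k80_distance("AC-T", "ACGT"), 0)
})

test_that("scalar K80 agrees with the ape distance implementation", {
  set.seed(11)
  for (i in 1:5) {
    a <- random_dna(300)
    b <- a
    for (k in sample(300, 25)) {
      substr(b, k, k) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, k, k)), 1)
    }
    m <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    ref <- ape::dist.dna(ape::as.DNAbin(m), model = "K80")
    expect_equal(k80_distance(a, b), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("neighbor joining recovers additive four-taxon splits", {
  # additive matrix with split {A,B} | {C,D}
  d <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(d)
  # the AB|CD bipartition must be present
  parts <- ape::prop.part(tree)
  tips <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(tips[p]))
  expect_true(any(vapply(sets, identical, logical(1), c("A", "B"))) ||
                any(vapply(sets, identical, logical(1), c("C", "D"))))

  expect_equal(ape::Ntip(neighbor_joining(d[1:3, 1:3])), 3)
  d[1, 2] <- d[2, 1] <- NaN
  expect_error(neighbor_joining(d), "NaN")
})

test_that("neighbor joining recovers random tree topologies from path distances", {
  skip_if_not_installed("phangorn")
  set.seed(12)
  for (n in c(5, 6)) {
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- runif(nrow(true$edge), 0.5, 2)
    d <- stats::cophenetic(true)
    est <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(true), ape::unroot(est)), 0)
  }
})

test_that("bootstrap supports are deterministic and strong for clean clades", {
  pool <- simulate_allele_pool(8, 6, seed = 13)
  seqs <- align_alleles(setNames(pool$sequence, pool$allele_id),
                        attr(pool, "insertion_codon"))
  t1 <- bootstrap_supports(seqs, n_reps = 100, seed = 5)
  t2 <- bootstrap_supports(seqs, n_reps = 100, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  # the planted non-classical clade must be near-unanimously supported
  clusters <- find_supported_clusters(t1, support_min = 95,
                                      root_method = "midpoint")
  nc <- sort(pool$allele_id[pool$class_truth == "nonclassical"])
  expect_true(any(vapply(clusters, function(cl) identical(sort(cl), nc),
                         logical(1))))
})

test_that("bootstrap supports are invariant under column permutation", {
  set.seed(14)
  pool <- simulate_allele_pool(6, 4, seed = 14, insertion_fraction = 0)
  seqs <- setNames(pool$sequence, pool$allele_id)
  perm <- sample(nchar(seqs[1]))
  shuffled <- vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][perm], collapse = ""), character(1))
  t1 <- bootstrap_supports(seqs, n_reps = 50, seed = 9)
  t2 <- bootstrap_supports(shuffled, n_reps = 50, seed = 9)
  sup <- function(tr, tips) {
    cl <- find_supported_clusters(tr, support_min = 0, root_method = "midpoint")
    vapply(cl, function(x) identical(sort(x), sort(tips)), logical(1))
  }
  nc <- pool$allele_id[pool$class_truth == "nonclassical"]
  # same column multiset -> same distances -> same supported clade
  expect_equal(any(sup(t1, nc)), any(sup(t2, nc)))
})

test_that("supported clusters are maximal, rooted on the outgroup", {
  txt <- "(((a:1,b:1)987:1,(c:1,d:1)999:1)400:1,(e:1,f:1)200:1,OG:5);"
  tree <- ape::read.tree(text = txt)
  cl <- find_supported_clusters(tree, support_min = 950, outgroup = "OG")
  sets <- lapply(cl, sort)
  expect_equal(length(cl), 2)
  expect_true(any(vapply(sets, identical, logical(1), c("a", "b"))))
  expect_true(any(vapply(sets, identical, logical(1), c("c", "d"))))

  expect_equal(length(find_supported_clusters(tree, support_min = 1000,
                                              outgroup = "OG")), 0)

  # nested supported clades: only the maximal one is reported
  txt2 <- "(((a:1,b:1)990:1,c:1)980:1,(d:1,e:1)100:1,OG:5);"
  tree2 <- ape::read.tree(text = txt2)
  cl2 <- find_supported_clusters(tree2, support_min = 950, outgroup = "OG")
  expect_equal(length(cl2), 1)
  expect_setequal(cl2[[1]], c("a", "b", "c"))
  expect_equal(attr(cl2[[1]], "support"), 980)

  expect_error(find_supported_clusters(tree2, 950, outgroup = "missing"),
               "midpoint")
})

test_that("non-classical calls require all three criteria", {
  pool <- simulate_allele_pool(10, 6, seed = 15, insertion_fraction = 0)
  seqs <- setNames(pool$sequence, pool$allele_id)
  nc <- pool$allele_id[pool$class_truth == "nonclassical"]
  clusters <- list(structure(sort(nc), support = 987))

  cons <- data.frame(variant_id = pool$allele_id,
                     cohort_call = ifelse(pool$expression_tier == "high",
                                          "high", "low"),
                     stringsAsFactors = FALSE)
  cons$cohort_call[pool$expression_tier == "none"] <- "not_expressed"
  cons$cohort_call[pool$allele_id %in% nc] <- "low"
  cons$cohort_call[pool$allele_id == nc[1]] <- "not_expressed"

  cls <- classify_alleles(clusters, cons, seqs, mhc_config())
  expect_setequal(cls$variant_id[cls$class == "nonclassical"], nc)
  # partition: every allele is exactly one class
  expect_true(all(cls$class %in% c("classical", "nonclassical")))

  # one high-expression member disqualifies the whole cluster
  cons2 <- cons
  cons2$cohort_call[cons2$variant_id == nc[2]] <- "high"
  cls2 <- classify_alleles(clusters, cons2, seqs, mhc_config())
  expect_true(all(cls2$class == "classical"))

  # excessive within-cluster divergence disqualifies too
  cl_cluster <- list(structure(sort(pool$allele_id[pool$class_truth ==
                                                     "classical"][1:4]),
                               support = 999))
  cls3 <- classify_alleles(cl_cluster, cons, seqs, mhc_config())
  expect_true(all(cls3$class == "classical"))
})

test_that("support trees round-trip through newick", {
  txt <- "((a:1,b:1)987:1,(c:1,d:1)999:1,OG:5);"
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(txt, path)
  tree <- read_support_tree(path)
  expect_true("987" %in% tree$node.label)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  write_support_tree(tree, path2)
  expect_identical(ape::write.tree(read_support_tree(path2)),
                   ape::write.tree(tree))

  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  path3 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(star, path3)
  expect_error(read_support_tree(path3), "labels")
})
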