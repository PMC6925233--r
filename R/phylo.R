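# Bootstrap-supported neighbor-joining tree over verified alleles and the
# three-criterion classical/non-classical classification (supported
# cluster + no high-expression member + low amino-acid divergence).

#' Align amplicon alleles that differ by an in-frame 3-nt insertion
#'
#' Alleles are either the base amplicon length or three nucleotides longer.
#' When both lengths are present, a gap triplet is inserted into the
#' shorter sequences at the configured codon boundary so all rows share one
#' length; gapped columns are excluded pairwise by the distance functions.
#'
#' @param seqs Named character vector of allele sequences.
#' @param insertion_codon Codon after which the insertion sits.
#' @return Named character vector of equal-length (possibly gapped)
#'   sequences.
#' @export
align_alleles <- function(seqs, insertion_codon = 30) {
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1) return(seqs)
  base <- min(lens)
  if (!all(lens %in% c(base, base + 3)))
    stop("alleles must be the base amplicon length or 3 nt longer",
         call. = FALSE)
  at <- 3 * insertion_codon
  if (at > base) stop("insertion codon outside the amplicon", call. = FALSE)
  short <- lens == base
  seqs[short] <- paste0(substr(seqs[short], 1, at), "---",
                        substring(seqs[short], at + 1))
  seqs
}

#' Kimura 1980 two-parameter distance between two aligned sequences
#'
#' Computes `d = -1/2 log((1 - 2P - Q) * sqrt(1 - 2Q))` from the
#' transition proportion `P` and transversion proportion `Q`, excluding
#' sites with a gap or ambiguous base in either sequence.  Saturated pairs
#' (log argument <= 0) return `Inf`.
#'
#' @param seq_a,seq_b Aligned nucleotide strings of equal length.
#' @return The K80 distance (substitutions per site), `Inf` if saturated.
#' @export
k80_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must be aligned to equal length", call. = FALSE)
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no comparable sites", call. = FALSE)
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1 * sqrt(w2))
}

alignment_to_dnabin <- function(seqs) {
  m <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(m) <- names(seqs)
  ape::as.DNAbin(m)
}

k80_dist_matrix <- function(seqs) {
  ape::dist.dna(alignment_to_dnabin(seqs), model = "K80",
                pairwise.deletion = TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (additive matrices are recovered exactly),
#' with input validation: the matrix must be symmetric with a zero
#' diagonal, at least three taxa, and no missing or infinite entries.
#'
#' @param d A `dist` object or symmetric matrix of pairwise distances.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (any(!is.finite(m)))
    stop("distance matrix contains NaN or infinite entries", call. = FALSE)
  if (any(abs(m - t(m)) > 1e-8) || any(diag(m) != 0))
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  ape::nj(stats::as.dist(m))
}

#' Bootstrap clade supports for the NJ tree of an alignment
#'
#' Builds the reference NJ tree from K80 distances, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds the tree per
#' replicate, and counts how many replicates contain each bipartition of
#' the reference topology.  Deterministic given `seed`.
#'
#' @param seqs Named character vector of aligned sequences (include the
#'   outgroup if the tree is to be rooted later).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return A `phylo` tree whose `node.label` holds the bootstrap counts
#'   (out of `n_reps`); attribute `n_reps`.
#' @export
bootstrap_supports <- function(seqs, n_reps = 1000, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (min(nchar(seqs)) < 2) stop("alignment too short", call. = FALSE)
  bin <- alignment_to_dnabin(seqs)
  build <- function(x) ape::nj(ape::dist.dna(x, model = "K80",
                                             pairwise.deletion = TRUE))
  ref <- build(bin)
  set.seed(seed)
  counts <- ape::boot.phylo(ref, bin, build, B = n_reps, quiet = TRUE,
                            rooted = FALSE)
  ref$node.label <- as.character(counts)
  attr(ref, "n_reps") <- n_reps
  ref
}

#' Read an externally built support tree (import hook)
#'
#' Accepts a newick file with bootstrap supports as internal node labels,
#' e.g. a maximum-likelihood tree built outside the pipeline, for use in
#' place of the in-repo NJ tree.
#'
#' @param path Newick file path.
#' @param n_reps The support scale (bootstrap replicates the labels are
#'   counts of).
#' @return A `phylo` tree with `node.label` supports.
#' @export
read_support_tree <- function(path, n_reps = 1000) {
  tree <- ape::read.tree(path)
  if (is.null(tree$node.label))
    stop("tree has no internal node labels (bootstrap supports)", call. = FALSE)
  attr(tree, "n_reps") <- n_reps
  tree
}

#' Write a support tree to newick
#'
#' @param tree A `phylo` tree with `node.label` supports.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  tips <- character(0)
  for (k in kids) {
    tips <- c(tips, if (k <= ntip) tree$tip.label[k] else
      clade_tips(tree, k))
  }
  tips
}

#' Extract maximal highly supported clusters
#'
#' Roots the tree on the outgroup, then reports the tip sets of the
#' maximal clades (not nested inside another reported clade, outgroup
#' excluded) whose subtending edge has bootstrap support at least
#' `support_min`.
#'
#' @param tree A `phylo` tree with `node.label` bootstrap counts.
#' @param support_min Minimum support count.
#' @param outgroup Tip label used for rooting; must be present unless
#'   `root_method = "midpoint"`.
#' @param root_method `"outgroup"` (default) or `"midpoint"` (fallback
#'   when no outgroup is available; requires phangorn).
#' @return List of character vectors (tip sets), each with attribute
#'   `support`.
#' @export
find_supported_clusters <- function(tree, support_min, outgroup = NULL,
                                    root_method = c("outgroup", "midpoint")) {
  root_method <- match.arg(root_method)
  if (root_method == "outgroup") {
    if (is.null(outgroup) || !outgroup %in% tree$tip.label)
      stop("outgroup tip not present in the tree; pass root_method = ",
           "\"midpoint\" to midpoint-root instead", call. = FALSE)
    rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                        edgelabel = TRUE)
  } else {
    if (!requireNamespace("phangorn", quietly = TRUE))
      stop("midpoint rooting requires the phangorn package", call. = FALSE)
    rooted <- phangorn::midpoint(tree)
  }
  ntip <- length(rooted$tip.label)
  root_node <- ntip + 1L
  supports <- suppressWarnings(as.numeric(rooted$node.label))

  clusters <- list()
  visit <- function(node) {
    if (node <= ntip) return(invisible())
    sup <- supports[node - ntip]
    tips <- clade_tips(rooted, node)
    if (node != root_node && !is.na(sup) && sup >= support_min &&
        !(!is.null(outgroup) && outgroup %in% tips) && length(tips) >= 2) {
      clusters[[length(clusters) + 1L]] <<- structure(sort(tips),
                                                      support = sup)
      return(invisible())  # maximality: do not descend
    }
    for (k in rooted$edge[rooted$edge[, 1] == node, 2]) visit(k)
  }
  visit(root_node)
  clusters
}

#' Classify alleles as putatively classical or non-classical
#'
#' A highly supported cluster is non-classical iff (i) its edge support
#' reaches `cluster_support_min`, (ii) no member allele has a high cohort
#' expression call, and (iii) its mean within-cluster amino-acid P-distance
#' is at most `cluster_pdist_max`.  Members of qualifying clusters are
#' non-classical; every other allele is classical.
#'
#' @param clusters Supported clusters from [find_supported_clusters()]
#'   (already filtered at `cluster_support_min`).
#' @param consolidated Cohort-level expression calls
#'   (from [classify_expression()]'s `consolidated` element).
#' @param aligned Named character vector of aligned allele nucleotide
#'   sequences (for the divergence criterion).
#' @param config An [mhc_config()].
#' @return Data frame per allele: `variant_id`, `class`, and the three
#'   criteria flags `in_supported_cluster`, `low_expression`,
#'   `low_divergence` of the cluster the allele belongs to (FALSE/NA when
#'   unclustered).
#' @export
classify_alleles <- function(clusters, consolidated, aligned,
                             config = mhc_config()) {
  calls <- stats::setNames(consolidated$cohort_call, consolidated$variant_id)
  alleles <- sort(unique(names(aligned)))
  res <- data.frame(variant_id = alleles, class = "classical",
                    in_supported_cluster = FALSE, low_expression = NA,
                    low_divergence = NA, stringsAsFactors = FALSE)
  for (cl in clusters) {
    members <- intersect(cl, alleles)
    if (length(members) < 2) next
    member_calls <- calls[members]
    low_expr <- !any(member_calls == "high", na.rm = TRUE)
    aa <- vapply(aligned[members], translate_dna, character(1))
    pd <- amino_pdistance(aa, bootstrap = 0)$mean
    low_div <- pd <= config$cluster_pdist_max
    idx <- res$variant_id %in% members
    res$in_supported_cluster[idx] <- TRUE
    res$low_expression[idx] <- low_expr
    res$low_divergence[idx] <- low_div
    if (low_expr && low_div) res$class[idx] <- "nonclassical"
  }
  res
}
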