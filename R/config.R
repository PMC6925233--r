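#' Pipeline configuration
#'
#' Assembles the run configuration for the genotyping/expression pipeline.
#' Defaults are the constants of the study design: a 100-read minimum for
#' cDNA-only alleles, a one-fourth ("25%") cDNA-over-gDNA margin for the
#' expression ratio rule, and 1000 bootstrap replicates for cluster support.
#' Everything else is a declared, overridable default.
#'
#' @param expected_length Named integer vector of expected amplicon lengths
#'   (nt) per primer combination, e.g. `c(PC1 = 258, PC2 = 258, PC3 = 258)`.
#' @param threshold_grid Numeric `c(min, max, step)` frequency grid searched
#'   when setting the duplicate-repeatability threshold.
#' @param cdna_min_reads Minimum read count for a cDNA-only variant to be
#'   called expressed (default 100).
#' @param cdna_only_rule How the "average read depth" criterion for
#'   cDNA-only variants is operationalised: `"frequency"` compares the
#'   variant's per-amplicon frequency with the mean per-variant frequency of
#'   its primer combination's cDNA groups; `"depth"` compares raw counts
#'   with the mean per-variant read depth.
#' @param high_expression_ratio_margin Multiplicative margin of the ratio
#'   rule: an allele is rescued as highly expressed when its cDNA relative
#'   depth is at least `(1 + margin)` times its gDNA relative depth
#'   (default 0.25, i.e. one fourth higher).
#' @param barely_amplified_fraction An allele counts as "barely amplified"
#'   in a DNA type when its relative depth is below this fraction of the
#'   equal-expression threshold 1/n (default 0.5).
#' @param near_threshold_band Relative half-width of the band around 1/n
#'   within which a call is regarded as near-threshold during
#'   cross-individual consolidation (default 0.10).
#' @param bootstrap_replicates Number of bootstrap replicates for clade
#'   support (default 1000).
#' @param cluster_support_min Minimum bootstrap count (out of
#'   `bootstrap_replicates`) for a clade to count as highly supported in the
#'   classical/non-classical classification (default 950).
#' @param display_support_min Support cutoff used for figure-style reporting
#'   of the tree (default 700).
#' @param cluster_pdist_max Maximum mean within-cluster amino-acid
#'   P-distance for a supported cluster to qualify as non-classical
#'   (default 0.05).
#' @param stop_codon_screen Logical; additionally remove variants whose
#'   translation in the amplicon frame contains a stop codon during length
#'   filtering.  Off by default for strict parity with pure length/frame
#'   filtering; the recommended profile turns it on.
#' @param trim_codons Integer `c(first, last)` codon range (1-based, in the
#'   aligned amplicon) to which alleles are trimmed before divergence
#'   statistics.
#' @param insertion_codon Codon after which the in-frame 3-nt insertion is
#'   placed/aligned (gap triplet inserted into non-insertion alleles).
#' @param dnds_correction `"jc"` (Jukes-Cantor corrected dN/dS, default) or
#'   `"none"` (uncorrected pN/pS).
#' @param pdist_bootstrap Site-bootstrap replicates for the standard error
#'   of the amino-acid P-distance (default 500).
#' @param rng_seed Integer seed used by seeded operations when no explicit
#'   seed is passed.
#'
#' @return An object of class `mhc_config` (a validated named list).
#' @export
#' @examples
#' cfg <- mhc_config()
#' cfg$cdna_min_reads
mhc_config <- function(expected_length = c(PC1 = 258L, PC2 = 258L, PC3 = 258L),
                       threshold_grid = c(min = 0, max = 0.05, step = 1e-4),
                       cdna_min_reads = 100L,
                       cdna_only_rule = c("frequency", "depth"),
                       high_expression_ratio_margin = 0.25,
                       barely_amplified_fraction = 0.5,
                       near_threshold_band = 0.10,
                       bootstrap_replicates = 1000L,
                       cluster_support_min = 950L,
                       display_support_min = 700L,
                       cluster_pdist_max = 0.05,
                       stop_codon_screen = FALSE,
                       trim_codons = c(16L, 72L),
                       insertion_codon = 30L,
                       dnds_correction = c("jc", "none"),
                       pdist_bootstrap = 500L,
                       rng_seed = 1L) {
  cdna_only_rule <- match.arg(cdna_only_rule)
  dnds_correction <- match.arg(dnds_correction)
  cfg <- list(
    expected_length = expected_length,
    threshold_grid = threshold_grid,
    cdna_min_reads = as.integer(cdna_min_reads),
    cdna_only_rule = cdna_only_rule,
    high_expression_ratio_margin = high_expression_ratio_margin,
    barely_amplified_fraction = barely_amplified_fraction,
    near_threshold_band = near_threshold_band,
    bootstrap_replicates = as.integer(bootstrap_replicates),
    cluster_support_min = as.integer(cluster_support_min),
    display_support_min = as.integer(display_support_min),
    cluster_pdist_max = cluster_pdist_max,
    stop_codon_screen = isTRUE(stop_codon_screen),
    trim_codons = as.integer(trim_codons),
    insertion_codon = as.integer(insertion_codon),
    dnds_correction = dnds_correction,
    pdist_bootstrap = as.integer(pdist_bootstrap),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "mhc_config")
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$expected_length), length(cfg$expected_length) >= 1)
  if (is.null(names(cfg$expected_length)) || any(!nzchar(names(cfg$expected_length))))
    stop("expected_length must be named by primer combination", call. = FALSE)
  if (any(cfg$expected_length <= 0))
    stop("expected_length entries must be positive", call. = FALSE)
  g <- cfg$threshold_grid
  if (length(g) != 3 || any(!is.finite(g)))
    stop("threshold_grid must be c(min, max, step)", call. = FALSE)
  if (g[1] < 0 || g[2] > 1 || g[2] <= g[1] || g[3] <= 0)
    stop("threshold_grid must satisfy 0 <= min < max <= 1, step > 0", call. = FALSE)
  for (nm in c("barely_amplified_fraction", "near_threshold_band",
               "cluster_pdist_max")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(nm, " must be a frequency in [0, 1]", call. = FALSE)
  }
  if (cfg$high_expression_ratio_margin < 0)
    stop("high_expression_ratio_margin must be >= 0", call. = FALSE)
  if (cfg$cdna_min_reads < 0)
    stop("cdna_min_reads must be >= 0", call. = FALSE)
  if (cfg$bootstrap_replicates < 1)
    stop("bootstrap_replicates must be >= 1", call. = FALSE)
  if (cfg$cluster_support_min < 0 ||
      cfg$cluster_support_min > cfg$bootstrap_replicates)
    stop("cluster_support_min must be in [0, bootstrap_replicates]", call. = FALSE)
  if (cfg$pdist_bootstrap < 1)
    stop("pdist_bootstrap must be >= 1", call. = FALSE)
  if (length(cfg$trim_codons) != 2 || cfg$trim_codons[1] < 1 ||
      cfg$trim_codons[2] < cfg$trim_codons[1])
    stop("trim_codons must be c(first, last) with 1 <= first <= last", call. = FALSE)
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys take the documented [mhc_config()] defaults; unknown
#' keys raise a warning and are ignored; out-of-range values are an error.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML key-value file.
#' @return An `mhc_config` object.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain a key-value mapping", call. = FALSE)
  known <- names(formals(mhc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
    vals <- vals[intersect(names(vals), known)]
  }
  if (!is.null(vals$expected_length)) vals$expected_length <- unlist(vals$expected_length)
  if (!is.null(vals$threshold_grid)) vals$threshold_grid <- unlist(vals$threshold_grid)
  if (!is.null(vals$trim_codons)) vals$trim_codons <- unlist(vals$trim_codons)
  do.call(mhc_config, vals)
}

#' @export
print.mhc_config <- function(x, ...) {
  cat("MHC-I pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm, paste(format(v), collapse = " ")))
  }
  invisible(x)
}
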