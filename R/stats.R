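# Cohort-level statistics and the consolidated run report.

#' Mann-Whitney U test on relative read depths
#'
#' Two-sided rank-sum test comparing high- and low-expression allele
#' depths: the exact distribution for combined sample sizes up to 20
#' (without ties), the normal approximation with tie correction otherwise.
#'
#' @param high,low Numeric vectors of relative read depths (both
#'   non-empty).
#' @return List `W`, `p`, `method`.
#' @export
mannwhitney_depths <- function(high, low) {
  if (length(high) == 0 || length(low) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  n <- length(high) + length(low)
  ties <- anyDuplicated(c(high, low)) > 0
  exact <- n <= 20 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(high, low, exact = exact, correct = TRUE))
  list(W = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Fligner-Killeen test of homogeneity of variances
#'
#' Median-centred, normal-score ranked statistic against a chi-squared
#' reference with k-1 degrees of freedom.  Groups with fewer than two
#' observations are an error; groups of constant values are legal and give
#' a zero statistic.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group membership, >= 2 levels.
#' @return List `chi2`, `df`, `p`.
#' @export
fligner_killeen <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("degenerate group(s) with fewer than 2 observations: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  res <- stats::fligner.test(values, groups)
  chi2 <- unname(res$statistic)
  if (is.nan(chi2)) chi2 <- 0  # all groups constant
  list(chi2 = chi2, df = unname(res$parameter),
       p = if (is.nan(res$p.value)) 1 else res$p.value)
}

#' Fraction of cohort alleles that are expressed
#'
#' @param consolidated Cohort-level calls (data frame with a `cohort_call`
#'   column; see [classify_expression()]).
#' @return Proportion of alleles whose call is not `"not_expressed"`.
#' @export
expressed_fraction <- function(consolidated) {
  if (nrow(consolidated) == 0) stop("no alleles", call. = FALSE)
  mean(consolidated$cohort_call != "not_expressed")
}

msd <- function(x) {
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    min = suppressWarnings(min(x)), max = suppressWarnings(max(x)))
}

#' Consolidated cohort report
#'
#' Per-individual allele tallies (gDNA, cDNA, classical, non-classical,
#' high, low) with mean +/- SD and range, the cohort partition, QC metrics
#' (duplicate concordance, between-combination agreement, undetermined
#' count), and the study's cohort tests: Mann-Whitney on PC2 relative
#' depths of high vs low alleles in cDNA and in gDNA, and Fligner-Killeen
#' on cDNA relative depths of classical vs non-classical alleles.
#'
#' @param verified An `mhc_verified` object.
#' @param expression An `mhc_expression` object.
#' @param classes Data frame from [classify_alleles()] (optional; class
#'   tallies and the Fligner-Killeen test are skipped when absent).
#' @return List of class `mhc_cohort_report`.
#' @export
cohort_summary <- function(verified, expression, classes = NULL) {
  if (is.null(verified) || is.null(expression))
    stop("missing stage output: ",
         if (is.null(verified)) "verify" else "express", call. = FALSE)
  vt <- verified$table
  cons <- expression$consolidated
  call_of <- stats::setNames(cons$cohort_call, cons$variant_id)
  cls_of <- if (!is.null(classes))
    stats::setNames(classes$class, classes$variant_id) else NULL

  per_ind <- do.call(rbind, lapply(split(vt, vt$individual_id), function(d) {
    data.frame(
      individual_id = d$individual_id[1],
      n_gdna = sum(d$verified_gdna),
      n_cdna = sum(d$expressed),
      n_classical = if (is.null(cls_of)) NA_integer_ else
        sum(cls_of[d$variant_id] == "classical", na.rm = TRUE),
      n_nonclassical = if (is.null(cls_of)) NA_integer_ else
        sum(cls_of[d$variant_id] == "nonclassical", na.rm = TRUE),
      n_high = sum(call_of[d$variant_id] == "high" & d$expressed,
                   na.rm = TRUE),
      n_low = sum(call_of[d$variant_id] == "low" & d$expressed,
                  na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(per_ind) <- NULL

  summaries <- lapply(per_ind[, -1], msd)

  pi <- expression$per_individual
  det <- pi[pi$call %in% c("high", "low") & !is.na(pi$pc2_cdna_rel), ]
  tests <- list(mw_cdna = NULL, mw_gdna = NULL, fk_class = NULL)
  if (any(det$call == "high") && any(det$call == "low")) {
    tests$mw_cdna <- mannwhitney_depths(det$pc2_cdna_rel[det$call == "high"],
                                        det$pc2_cdna_rel[det$call == "low"])
    detg <- det[!is.na(det$pc2_gdna_rel), ]
    if (any(detg$call == "high") && any(detg$call == "low"))
      tests$mw_gdna <- mannwhitney_depths(
        detg$pc2_gdna_rel[detg$call == "high"],
        detg$pc2_gdna_rel[detg$call == "low"])
  }
  if (!is.null(cls_of)) {
    expr <- pi[!is.na(pi$pc2_cdna_rel), ]
    grp <- cls_of[expr$variant_id]
    ok <- !is.na(grp)
    if (length(unique(grp[ok])) == 2 && all(table(grp[ok]) >= 2))
      tests$fk_class <- fligner_killeen(expr$pc2_cdna_rel[ok], grp[ok])
  }

  expressed_total <- sum(cons$cohort_call != "not_expressed")
  qc <- list(
    duplicate_jaccard = attr(verified$thresholds, "mean_jaccard"),
    combo_agreement = expression$agreement,
    ratio_validation = expression$ratio_validation,
    n_alleles = nrow(cons),
    n_expressed = expressed_total,
    expressed_fraction = expressed_total / nrow(cons),
    n_undetermined = sum(cons$cohort_call %in%
                           c("undetermined", "locus_conflict")),
    partition = expression$partition)

  structure(list(per_individual = per_ind, summaries = summaries,
                 tests = tests, qc = qc),
            class = "mhc_cohort_report")
}

#' @export
print.mhc_cohort_report <- function(x, ...) {
  cat("MHC-I cohort report\n")
  cat(sprintf("  individuals: %d; alleles: %d (%d expressed, %.0f%%)\n",
              nrow(x$per_individual), x$qc$n_alleles, x$qc$n_expressed,
              100 * x$qc$expressed_fraction))
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-15s %4.1f +/- %3.1f  (min %d, max %d)\n",
                nm, s[["mean"]], s[["sd"]], as.integer(s[["min"]]),
                as.integer(s[["max"]])))
  }
  p <- x$qc$partition
  cat(sprintf("  expression partition: %d high / %d low / %d undetermined\n",
              p[["high"]], p[["low"]], p[["undetermined"]]))
  if (!is.null(x$qc$combo_agreement$fraction) &&
      !is.na(x$qc$combo_agreement$fraction))
    cat(sprintf("  primer-combination agreement: %.0f%% (%d of %d)\n",
                100 * x$qc$combo_agreement$fraction,
                x$qc$combo_agreement$n_agree, x$qc$combo_agreement$n_compared))
  if (!is.null(x$tests$mw_cdna))
    cat(sprintf("  Mann-Whitney cDNA high vs low: W = %.0f, p = %.3g\n",
                x$tests$mw_cdna$W, x$tests$mw_cdna$p))
  if (!is.null(x$tests$mw_gdna))
    cat(sprintf("  Mann-Whitney gDNA high vs low: W = %.0f, p = %.3g\n",
                x$tests$mw_gdna$W, x$tests$mw_gdna$p))
  if (!is.null(x$tests$fk_class))
    cat(sprintf("  Fligner-Killeen classical vs non-classical: chi2(%d) = %.2f, p = %.3g\n",
                x$tests$fk_class$df, x$tests$fk_class$chi2, x$tests$fk_class$p))
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `report.tsv` (per-individual tallies) and `report.txt` (the
#' printed report) under `dir`.
#'
#' @param report An `mhc_cohort_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$per_individual, file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
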