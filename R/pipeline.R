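# End-to-end orchestration: counts -> verified alleles -> expression calls
# -> support tree -> classical/non-classical classes -> divergence table ->
# cohort report; plus truth-recovery scoring against a simulated cohort.

#' Run the full MHC-I pipeline on a count table
#'
#' @param counts An `amplicon_counts` table.
#' @param config An [mhc_config()].
#' @param outgroup Optional named character vector of length 1: the
#'   outgroup sequence used to root the tree.  Without it the tree stage
#'   midpoint-roots.
#' @param tree Optional externally built support tree (see
#'   [read_support_tree()]); when supplied the bootstrap stage is skipped.
#' @param stages Character vector of stages to run, in pipeline order
#'   (`"verify"`, `"express"`, `"classify"`, `"diverge"`, `"report"`).
#'   Later stages require earlier ones.
#' @return List of class `mhc_run` with elements `verified`, `expression`,
#'   `aligned`, `tree`, `clusters`, `classes`, `divergence`, `report`
#'   (those not run are `NULL`).
#' @export
run_mhc_pipeline <- function(counts, config = mhc_config(), outgroup = NULL,
                             tree = NULL,
                             stages = c("verify", "express", "classify",
                                        "diverge", "report")) {
  res <- list(verified = NULL, expression = NULL, aligned = NULL,
              tree = NULL, clusters = NULL, classes = NULL,
              divergence = NULL, report = NULL)
  res$verified <- verify_alleles(counts, config)
  if (!"express" %in% stages) return(structure(res, class = "mhc_run"))
  res$expression <- classify_expression(res$verified, config)

  if ("classify" %in% stages || "diverge" %in% stages) {
    vt <- res$verified$table
    keep <- setdiff(unique(vt$variant_id), res$expression$removed_everywhere)
    seq_map <- unique(as.data.frame(res$verified$filtered)[,
                                                           c("variant_id", "sequence")])
    seqs <- stats::setNames(seq_map$sequence, seq_map$variant_id)[keep]
    aligned <- align_alleles(seqs, config$insertion_codon)
    res$aligned <- aligned

    if ("classify" %in% stages) {
      if (is.null(tree)) {
        tree_input <- aligned
        if (!is.null(outgroup)) {
          og <- align_alleles(c(aligned, outgroup), config$insertion_codon)
          tree_input <- og
        }
        tree <- bootstrap_supports(tree_input, config$bootstrap_replicates,
                                   seed = config$rng_seed)
      }
      res$tree <- tree
      res$clusters <- find_supported_clusters(
        tree, config$cluster_support_min,
        outgroup = if (!is.null(outgroup)) names(outgroup)[1] else NULL,
        root_method = if (is.null(outgroup)) "midpoint" else "outgroup")
      res$classes <- classify_alleles(res$clusters,
                                      res$expression$consolidated,
                                      aligned, config)
    }
    if ("diverge" %in% stages && !is.null(res$classes))
      res$divergence <- divergence_report(aligned, res$classes,
                                          res$expression$consolidated,
                                          config)
  }
  if ("report" %in% stages)
    res$report <- cohort_summary(res$verified, res$expression, res$classes)
  structure(res, class = "mhc_run")
}

#' Score a pipeline run against the planted truth of a simulated cohort
#'
#' @param run An `mhc_run` from [run_mhc_pipeline()].
#' @param sim An `mhc_sim` from [simulate_cohort()].
#' @return List: `recall` (verified / planted carried alleles),
#'   `false_alleles` (verified alleles not in the pool),
#'   `tier_accuracy` (determined cohort calls matching the planted tier),
#'   `n_determined`, `class_accuracy` (classical/non-classical labels
#'   matching truth), `expressed_recall` (expressed planted alleles
#'   recovered as expressed).
#' @export
evaluate_recovery <- function(run, sim) {
  planted <- sort(unique(sim$individuals$allele_id))
  verified <- sort(unique(run$verified$table$variant_id[
    run$verified$table$verified_gdna]))
  recall <- mean(planted %in% verified)
  false_alleles <- setdiff(verified, sim$pool$allele_id)

  tier <- stats::setNames(sim$pool$expression_tier, sim$pool$allele_id)
  cons <- run$expression$consolidated
  det <- cons[cons$cohort_call %in% c("high", "low"), ]
  tier_acc <- if (nrow(det) > 0)
    mean(det$cohort_call == tier[det$variant_id], na.rm = TRUE) else NA_real_

  class_acc <- NA_real_
  if (!is.null(run$classes)) {
    truth_cls <- stats::setNames(sim$pool$class_truth, sim$pool$allele_id)
    cc <- run$classes
    class_acc <- mean(cc$class == truth_cls[cc$variant_id], na.rm = TRUE)
  }

  expressed_truth <- unique(sim$individuals$allele_id[
    sim$individuals$expression_tier != "none"])
  expressed_called <- unique(run$verified$table$variant_id[
    run$verified$table$expressed])
  list(recall = recall, false_alleles = false_alleles,
       tier_accuracy = tier_acc, n_determined = nrow(det),
       class_accuracy = class_acc,
       expressed_recall = mean(expressed_truth %in% expressed_called))
}
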