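# High/low expression classification: per-individual, per-primer
# equal-expression threshold (1/n), agreement between the two cDNA primer
# combinations, the cDNA-over-gDNA ratio rule and the amplification-error
# cleaning rule for discrepancies, and cross-individual consolidation.

#' Equal-expression threshold
#'
#' The relative read depth expected if an individual's `n` expressed
#' alleles were transcribed equally; an allele is highly expressed when its
#' relative depth strictly exceeds this.
#'
#' @param n_expressed_alleles Number of expressed alleles amplified for the
#'   individual by the primer combination (>= 1).
#' @return `1 / n_expressed_alleles`.
#' @export
#' @examples
#' equal_expression_threshold(11)  # 0.0909...
equal_expression_threshold <- function(n_expressed_alleles) {
  if (length(n_expressed_alleles) != 1 || is.na(n_expressed_alleles) ||
      n_expressed_alleles < 1)
    stop("n_expressed_alleles must be a positive integer", call. = FALSE)
  1 / n_expressed_alleles
}

#' Pooled relative read depths per allele
#'
#' Pools technical replicates by summed counts within each (individual,
#' primer combination, DNA type), restricts to the individual's verified
#' (gDNA) or expressed (cDNA) alleles, and computes relative depths within
#' the amplified subset.
#'
#' @param tab A (length-filtered) `amplicon_counts` table.
#' @param verified Data frame `individual_id`, `variant_id`,
#'   `verified_gdna`, `expressed` (from [verify_alleles()]).
#' @return Data frame `individual_id`, `primer_combo`, `dna_type`,
#'   `variant_id`, `count`, `rel_depth`, `n_amplified`.
#' @export
allele_depths <- function(tab, verified) {
  tab <- as.data.frame(tab)
  pooled <- stats::aggregate(
    read_count ~ individual_id + primer_combo + dna_type + variant_id,
    tab, sum)
  names(pooled)[names(pooled) == "read_count"] <- "count"
  vk <- paste(verified$individual_id, verified$variant_id, sep = "\r")
  pk <- paste(pooled$individual_id, pooled$variant_id, sep = "\r")
  keep_g <- pooled$dna_type == "gDNA" &
    pk %in% vk[verified$verified_gdna]
  keep_c <- pooled$dna_type == "cDNA" &
    pk %in% vk[verified$expressed]
  pooled <- pooled[(keep_g | keep_c) & pooled$count >= 1, , drop = FALSE]
  gkey <- paste(pooled$individual_id, pooled$primer_combo, pooled$dna_type,
                sep = "\r")
  totals <- tapply(pooled$count, gkey, sum)
  sizes <- tapply(pooled$count, gkey, length)
  pooled$rel_depth <- pooled$count / as.numeric(totals[gkey])
  pooled$n_amplified <- as.integer(sizes[gkey])
  rownames(pooled) <- NULL
  pooled
}

#' Classify alleles of one (individual, primer combination) as high or low
#'
#' High iff the relative cDNA depth strictly exceeds the equal-expression
#' threshold `1/n` (ties are low).  Calls within `near_band` of the
#' threshold are flagged near-threshold for the cross-individual
#' consolidation step.
#'
#' @param rel_depths Named numeric vector of relative cDNA depths (names
#'   are variant ids); must sum to ~1 over the amplified set.
#' @param near_band Relative half-width of the near-threshold band.
#' @return Data frame `variant_id`, `rel_depth`, `call`, `near_threshold`.
#' @export
classify_per_combo <- function(rel_depths, near_band = 0.10) {
  n <- length(rel_depths)
  thr <- equal_expression_threshold(n)
  data.frame(
    variant_id = names(rel_depths),
    rel_depth = unname(rel_depths),
    call = ifelse(rel_depths > thr, "high", "low"),
    near_threshold = abs(rel_depths - thr) <= near_band * thr,
    stringsAsFactors = FALSE
  )
}

#' Reconcile the calls of the two cDNA primer combinations
#'
#' Agreement gives that call; an allele amplified by one combination only
#' takes that combination's call; disagreements are forwarded to the
#' discrepancy rules.
#'
#' @param call_pc2,call_pc3 Character vectors of per-combination calls
#'   (`"high"`/`"low"`, `NA` when the combination did not amplify the
#'   allele).
#' @return Character vector: the reconciled call, or `"conflict"` where the
#'   combinations disagree.
#' @export
reconcile_combos <- function(call_pc2, call_pc3) {
  ifelse(is.na(call_pc2), call_pc3,
         ifelse(is.na(call_pc3), call_pc2,
                ifelse(call_pc2 == call_pc3, call_pc2, "conflict")))
}

#' Resolve a between-combination discrepancy for one allele
#'
#' Rule A (ratio rule): the allele is highly expressed if its PC2 cDNA
#' relative depth is at least `(1 + margin)` times its PC2 gDNA relative
#' depth.  Rule B (cleaning rule): if the allele is barely amplified in
#' both DNA types (relative depth below `barely_fraction` of the respective
#' equal-expression threshold), it is an amplification error and removed.
#' Otherwise the call is undetermined, pending the cross-individual step.
#' When the gDNA depth is unavailable Rule A is skipped and Rule B applies
#' on the cDNA side only.
#'
#' @param cdna_rel,gdna_rel PC2 relative depths (gdna_rel may be `NA`).
#' @param n_cdna,n_gdna Numbers of alleles amplified in the respective PC2
#'   DNA-type groups.
#' @param margin Ratio-rule margin (default 0.25).
#' @param barely_fraction "Barely amplified" fraction of 1/n (default 0.5).
#' @return List with `call` (`"high"`, `"removed"` or `"undetermined"`) and
#'   `rule` (which rule fired).
#' @export
resolve_discrepancy <- function(cdna_rel, gdna_rel, n_cdna, n_gdna,
                                margin = 0.25, barely_fraction = 0.5) {
  if (!is.na(gdna_rel) && !is.na(cdna_rel) &&
      cdna_rel >= (1 + margin) * gdna_rel)
    return(list(call = "high", rule = "ruleA_ratio"))
  barely_c <- !is.na(cdna_rel) &&
    cdna_rel < barely_fraction * equal_expression_threshold(n_cdna)
  barely_g <- is.na(gdna_rel) ||
    gdna_rel < barely_fraction * equal_expression_threshold(n_gdna)
  if (barely_c && barely_g)
    return(list(call = "removed", rule = "ruleB_cleaning"))
  list(call = "undetermined", rule = "unresolved")
}

#' Consolidate per-individual expression calls across the cohort
#'
#' Unanimous calls stand.  When individuals disagree and exactly one side
#' of the conflict lies entirely within the near-threshold band of its
#' equal-expression threshold, the other side's call wins (the "just
#' barely under the limit" rescue).  Remaining conflicts are undetermined;
#' balanced ones (|#high - #low| <= 1, both sides occupied) are flagged as
#' possible multi-locus alleles (`locus_conflict`).
#'
#' @param per_individual Data frame `individual_id`, `variant_id`, `call`
#'   (`high`/`low`/`undetermined`/`removed`), `near_threshold`.
#' @return Data frame per variant: `variant_id`, `n_high`, `n_low`,
#'   `n_undetermined`, `cohort_call`
#'   (`high`/`low`/`undetermined`/`locus_conflict`), `rule`.
#' @export
consolidate_across_individuals <- function(per_individual) {
  out <- lapply(split(per_individual, per_individual$variant_id), function(d) {
    d <- d[d$call != "removed", , drop = FALSE]
    nh <- sum(d$call == "high"); nl <- sum(d$call == "low")
    nu <- sum(d$call == "undetermined")
    if (nh + nl == 0) {
      call <- "undetermined"; rule <- "no_determined_call"
    } else if (nh == 0 || nl == 0) {
      call <- if (nh > 0) "high" else "low"
      rule <- if (nrow(d) == 1) "single_carrier" else "unanimous"
    } else {
      high_near <- all(d$near_threshold[d$call == "high"])
      low_near <- all(d$near_threshold[d$call == "low"])
      if (low_near && !high_near) {
        call <- "high"; rule <- "near_threshold_rescue"
      } else if (high_near && !low_near) {
        call <- "low"; rule <- "near_threshold_rescue"
      } else if (abs(nh - nl) <= 1) {
        call <- "locus_conflict"; rule <- "balanced_conflict"
      } else {
        call <- "undetermined"; rule <- "unresolved_conflict"
      }
    }
    data.frame(variant_id = d$variant_id[1], n_high = nh, n_low = nl,
               n_undetermined = nu, cohort_call = call, rule = rule,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Check the ratio rule against the PC2 high-expression calls
#'
#' Fraction of alleles called high by PC2 (and with a PC2 gDNA depth) whose
#' cDNA relative depth is at least `(1 + margin)` times the gDNA one; the
#' study design expects full agreement on clean data.
#'
#' @param per_individual Data frame with columns `pc2_call`,
#'   `pc2_cdna_rel`, `pc2_gdna_rel` (one row per individual x allele).
#' @param margin Ratio-rule margin.
#' @return List `fraction` (NA when there is no PC2 high call to check),
#'   `n`, and `failures` (the offending rows).
#' @export
validate_ratio_rule <- function(per_individual, margin = 0.25) {
  d <- per_individual[!is.na(per_individual$pc2_call) &
                        per_individual$pc2_call == "high" &
                        !is.na(per_individual$pc2_gdna_rel), , drop = FALSE]
  if (nrow(d) == 0) return(list(fraction = NA_real_, n = 0L,
                                failures = d))
  ok <- d$pc2_cdna_rel >= (1 + margin) * d$pc2_gdna_rel
  list(fraction = mean(ok), n = nrow(d), failures = d[!ok, , drop = FALSE])
}

#' Classify expression for a verified cohort
#'
#' Runs the full expression stage: pooled relative depths, per-combination
#' classification against the per-individual equal-expression threshold,
#' reconciliation of the two cDNA primer combinations, discrepancy
#' resolution (ratio rule, cleaning rule) and cross-individual
#' consolidation.
#'
#' @param verified An `mhc_verified` object from [verify_alleles()].
#' @param config An [mhc_config()].
#' @return List of class `mhc_expression`: `depths`, `per_combo`,
#'   `per_individual` (with `rule_trace`), `consolidated` (cohort-level
#'   call per allele, including `not_expressed`), `partition` (cohort
#'   tallies over expressed alleles), `agreement` (between-combination
#'   agreement before reconciliation), `ratio_validation`.
#' @export
classify_expression <- function(verified, config = mhc_config()) {
  vt <- verified$table
  vt <- vt[!vt$individual_id %in% verified$no_cdna_individuals, , drop = FALSE]
  depths <- allele_depths(verified$filtered, vt)

  cdna <- depths[depths$dna_type == "cDNA", , drop = FALSE]
  per_combo <- do.call(rbind, lapply(
    split(cdna, list(cdna$individual_id, cdna$primer_combo), drop = TRUE),
    function(d) {
      cls <- classify_per_combo(stats::setNames(d$rel_depth, d$variant_id),
                                config$near_threshold_band)
      cbind(individual_id = d$individual_id[1],
            primer_combo = d$primer_combo[1], cls,
            stringsAsFactors = FALSE)
    }))
  rownames(per_combo) <- NULL

  wide <- function(combo, col) {
    d <- per_combo[per_combo$primer_combo == combo, ]
    stats::setNames(d[[col]], paste(d$individual_id, d$variant_id, sep = "\r"))
  }
  pc2_call <- wide("PC2", "call"); pc3_call <- wide("PC3", "call")
  pc2_rel <- wide("PC2", "rel_depth")
  pc2_near <- wide("PC2", "near_threshold")
  pc3_near <- wide("PC3", "near_threshold")
  gdna2 <- depths[depths$dna_type == "gDNA" & depths$primer_combo == "PC2", ]
  g2_rel <- stats::setNames(gdna2$rel_depth,
                            paste(gdna2$individual_id, gdna2$variant_id,
                                  sep = "\r"))
  g2_n <- stats::setNames(gdna2$n_amplified,
                          paste(gdna2$individual_id, gdna2$variant_id,
                                sep = "\r"))
  c2sizes <- cdna[cdna$primer_combo == "PC2", ]
  n_c2 <- stats::setNames(c2sizes$n_amplified,
                          paste(c2sizes$individual_id, c2sizes$variant_id,
                                sep = "\r"))

  keys <- sort(unique(c(names(pc2_call), names(pc3_call))))
  per_individual <- do.call(rbind, lapply(keys, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    p2 <- if (k %in% names(pc2_call)) pc2_call[[k]] else NA_character_
    p3 <- if (k %in% names(pc3_call)) pc3_call[[k]] else NA_character_
    trace <- character(0)
    if (!is.na(p2)) trace <- c(trace, paste0("combo:PC2=", p2))
    if (!is.na(p3)) trace <- c(trace, paste0("combo:PC3=", p3))
    rec <- reconcile_combos(p2, p3)
    if (rec != "conflict") {
      call <- rec
      trace <- c(trace, if (is.na(p2) || is.na(p3)) "single_combo" else "agreement")
    } else {
      res <- resolve_discrepancy(
        cdna_rel = if (k %in% names(pc2_rel)) pc2_rel[[k]] else NA_real_,
        gdna_rel = if (k %in% names(g2_rel)) g2_rel[[k]] else NA_real_,
        n_cdna = if (k %in% names(n_c2)) n_c2[[k]] else 1L,
        n_gdna = if (k %in% names(g2_n)) g2_n[[k]] else 1L,
        margin = config$high_expression_ratio_margin,
        barely_fraction = config$barely_amplified_fraction)
      call <- res$call
      trace <- c(trace, res$rule)
    }
    near <- any(c(if (k %in% names(pc2_near)) pc2_near[[k]],
                  if (k %in% names(pc3_near)) pc3_near[[k]]), na.rm = TRUE)
    data.frame(individual_id = parts[1], variant_id = parts[2],
               pc2_call = p2, pc3_call = p3, call = call,
               near_threshold = near,
               pc2_cdna_rel = if (k %in% names(pc2_rel)) pc2_rel[[k]] else NA_real_,
               pc2_gdna_rel = if (k %in% names(g2_rel)) g2_rel[[k]] else NA_real_,
               rule_trace = paste(trace, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(per_individual) <- NULL

  consolidated <- consolidate_across_individuals(per_individual)

  # cohort alleles never expressed (verified gDNA only, or removed everywhere)
  removed_everywhere <- setdiff(unique(per_individual$variant_id),
                                consolidated$variant_id)
  all_alleles <- sort(unique(verified$table$variant_id))
  not_expr <- setdiff(all_alleles, consolidated$variant_id)
  if (length(not_expr) > 0) {
    consolidated <- rbind(consolidated, data.frame(
      variant_id = not_expr, n_high = 0L, n_low = 0L, n_undetermined = 0L,
      cohort_call = "not_expressed", rule = "never_expressed",
      stringsAsFactors = FALSE))
  }
  consolidated <- consolidated[order(consolidated$variant_id), ]
  rownames(consolidated) <- NULL

  expressed_calls <- consolidated$cohort_call[consolidated$cohort_call !=
                                                "not_expressed"]
  partition <- c(high = sum(expressed_calls == "high"),
                 low = sum(expressed_calls == "low"),
                 undetermined = sum(expressed_calls %in%
                                      c("undetermined", "locus_conflict")))

  comparable <- !is.na(per_individual$pc2_call) &
    !is.na(per_individual$pc3_call)
  agreement <- list(
    n_compared = sum(comparable),
    n_agree = sum(comparable &
                    per_individual$pc2_call == per_individual$pc3_call),
    fraction = if (any(comparable))
      mean(per_individual$pc2_call[comparable] ==
             per_individual$pc3_call[comparable]) else NA_real_)

  structure(list(depths = depths, per_combo = per_combo,
                 per_individual = per_individual,
                 consolidated = consolidated, partition = partition,
                 agreement = agreement,
                 ratio_validation = validate_ratio_rule(
                   per_individual, config$high_expression_ratio_margin),
                 removed_everywhere = removed_everywhere),
            class = "mhc_expression")
}
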