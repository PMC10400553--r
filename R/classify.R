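#' Predictor-ensemble vote
#'
#' Counts how many of the seven ensemble tools (SIFT, Polyphen2, LRT,
#' MutationAssessor, MutationTaster, FATHMM, PROVEAN) call a variant
#' deleterious, and evaluates the combined ensemble rule:
#' CADD >= `cadd_min` AND M-CAP >= `mcap_min` AND at least `votes_min`
#' deleterious tool calls. CADD and M-CAP are required: a call with either
#' score missing cannot pass. Missing tool calls count as non-deleterious.
#'
#' @param calls A validated call table (any number of rows).
#' @param thr An [default_thresholds()] object.
#' @return data.frame with columns `vote_count` (0..7) and `passes`
#'   (logical), one row per input call.
#' @export
ensemble_vote <- function(calls, thr = default_thresholds()) {
  tools <- tool_columns()
  del <- vapply(tools, function(tc) calls[[tc]] == "DELETERIOUS",
                logical(nrow(calls)))
  votes <- if (nrow(calls) == 1L) sum(del) else rowSums(del, na.rm = TRUE)
  passes <- !is.na(calls$cadd) & calls$cadd >= thr$cadd_min &
    !is.na(calls$mcap) & calls$mcap >= thr$mcap_min &
    votes >= thr$votes_min
  data.frame(vote_count = as.integer(votes), passes = passes)
}

#' Assign interpretation tiers to high-confidence calls
#'
#' Each post-QC call receives exactly one tier — `PATHOGENIC`,
#' `NOVEL_LOF`, `STRONG_VUS` or `EXCLUDED` — by the first matching rule:
#'
#' 1. Whitelisted recurring disease allele -> `PATHOGENIC`
#'    (bypasses the rarity cut-off).
#' 2. ClinVar benign / likely benign -> `EXCLUDED`
#'    (database-benign override; disable with `thr$benign_override`).
#' 3. MAF above `maf_max` -> `EXCLUDED` (common allele). A missing MAF
#'    counts as 0 (the allele is unobserved in gnomAD, hence very rare).
#' 4. Loss-of-function and (ClinVar P or HGMD DM) -> `PATHOGENIC`
#'    (PVS1 + PM2 with prior disease association).
#' 5. Non-LOF, ClinVar P and HGMD DM with sufficient supporting
#'    information (not `clinvar_limited`) -> `PATHOGENIC`.
#' 6. LOF with a ClinVar VUS assertion -> `STRONG_VUS`.
#' 7. LOF absent from both ClinVar and HGMD -> `NOVEL_LOF`.
#' 8. ClinVar LP with limited supporting information -> `STRONG_VUS`.
#' 9. HGMD DM or DM? (without ClinVar P) -> `STRONG_VUS`.
#' 10. Predictor ensemble passes ([ensemble_vote()]) -> `STRONG_VUS`.
#' 11. Otherwise -> `EXCLUDED`.
#'
#' ClinVar `CONFLICTING` counts as unclassified for the pathogenic rules
#' (conflicts are mostly VUS-vs-P/LP) but does not make a LOF variant
#' "novel"; such calls remain eligible for rules 9-10.
#'
#' @param calls A validated post-QC call table.
#' @param whitelist An [as_whitelist()] data.frame, or `NULL`.
#' @param thr An [default_thresholds()] object.
#' @return The input table with added columns `tier`, `fired_criteria`
#'   (comma-separated rule identifiers, empty only for `EXCLUDED`) and
#'   `reportable` (`TRUE` for `PATHOGENIC` and `NOVEL_LOF`).
#' @export
classify_calls <- function(calls, whitelist = NULL,
                           thr = default_thresholds()) {
  n <- nrow(calls)
  tier <- rep(NA_character_, n)
  crit <- rep("", n)
  if (n == 0L) {
    calls$tier <- character(0); calls$fired_criteria <- character(0)
    calls$reportable <- logical(0)
    return(calls)
  }

  maf <- ifelse(is.na(calls$maf), 0, calls$maf)
  lof <- is_lof(calls$consequence)
  ev <- ensemble_vote(calls, thr)

  wl_hit <- rep(FALSE, n)
  if (!is.null(whitelist) && nrow(whitelist)) {
    wl_hit <- paste(calls$gene, calls$variant_key) %in%
      paste(whitelist$gene, whitelist$variant_key)
    if (!is.null(whitelist$hgvs) && "hgvs" %in% names(calls)) {
      wl_hit <- wl_hit | (!is.na(calls$hgvs) &
        paste(calls$gene, calls$hgvs) %in%
          paste(whitelist$gene, whitelist$hgvs))
    }
  }

  assign_tier <- function(cond, value, criteria) {
    todo <- is.na(tier) & cond
    tier[todo] <<- value
    crit[todo] <<- criteria
  }

  # rule 1: whitelist
  assign_tier(wl_hit, "PATHOGENIC", "WHITELIST")
  # rule 2: database-benign override
  if (thr$benign_override) {
    assign_tier(calls$clinvar %in% c("B", "LB"), "EXCLUDED", "BENIGN_DB")
  }
  # rule 3: common allele
  assign_tier(maf > thr$maf_max, "EXCLUDED", "COMMON_ALLELE")
  # rule 4: known LOF disease allele (PVS1 + PM2 + database support)
  r4 <- lof & (calls$clinvar == "P" | calls$hgmd == "DM")
  crit4 <- paste0("PVS1,PM2",
                  ifelse(calls$clinvar == "P", ",CLINVAR_P", ""),
                  ifelse(calls$hgmd == "DM", ",HGMD_DM", ""))
  todo <- is.na(tier) & r4
  tier[todo] <- "PATHOGENIC"; crit[todo] <- crit4[todo]
  # rule 5: concordant databases for a non-LOF variant
  assign_tier(!lof & calls$clinvar == "P" & calls$hgmd == "DM" &
                !calls$clinvar_limited,
              "PATHOGENIC", "CLINVAR_P,HGMD_DM")
  # rule 6: LOF with an uncertain ClinVar assertion
  assign_tier(lof & calls$clinvar == "VUS", "STRONG_VUS", "CLINVAR_VUS_LOF")
  # rule 7: novel LOF
  assign_tier(lof & calls$clinvar == "ABSENT" & calls$hgmd == "ABSENT",
              "NOVEL_LOF", "PVS1,PM2")
  # rule 8: ClinVar LP with limited supporting information
  assign_tier(calls$clinvar == "LP" & calls$clinvar_limited,
              "STRONG_VUS", "CLINVAR_LP_LIMITED")
  # rule 9: HGMD-only disease assertion
  assign_tier(calls$hgmd %in% c("DM", "DM_QUERY"),
              "STRONG_VUS", "HGMD_DM_ONLY")
  # rule 10: predictor ensemble
  assign_tier(ev$passes, "STRONG_VUS", "ENSEMBLE")
  # rule 11: everything else
  tier[is.na(tier)] <- "EXCLUDED"

  calls$tier <- tier
  calls$fired_criteria <- crit
  calls$reportable <- tier %in% c("PATHOGENIC", "NOVEL_LOF")
  calls
}

#' @rdname classify_calls
#' @param call A single-row call table.
#' @export
classify_variant <- function(call, whitelist = NULL,
                             thr = default_thresholds()) {
  stopifnot(nrow(call) == 1L)
  classify_calls(call, whitelist, thr)
}

#' Classify a cohort and tabulate tier counts
#'
#' Runs [classify_calls()] over a post-QC cohort table and summarizes the
#' per-tier totals with the loss-of-function vs missense/non-coding/
#' in-frame breakdown. Every input call appears exactly once in the
#' output.
#'
#' @inheritParams classify_calls
#' @return List with `calls` (the tiered table) and `counts`, a data.frame
#'   with one row per tier: `n`, `n_lof`, `n_other`.
#' @export
classify_cohort <- function(calls, whitelist = NULL,
                            thr = default_thresholds()) {
  tiered <- classify_calls(calls, whitelist, thr)
  lof <- is_lof(tiered$consequence)
  counts <- do.call(rbind, lapply(TIER_LEVELS, function(tl) {
    sel <- tiered$tier == tl
    data.frame(tier = tl, n = sum(sel), n_lof = sum(sel & lof),
               n_other = sum(sel & !lof), stringsAsFactors = FALSE)
  }))
  list(calls = tiered, counts = counts)
}
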