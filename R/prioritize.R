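#' Per-gene missense score
#'
#' The missense score of a gene is m / M: the number of missense
#' pathogenic/likely-pathogenic disease alleles over all P/LP alleles
#' described for that gene. It captures whether missense variation is a
#' plausible disease mechanism — a novel missense VUS in a gene whose
#' known disease alleles are almost all truncating is unlikely to be a
#' disease allele. Genes with no described P/LP alleles (M = 0) have an
#' undefined score and are flagged `NO_PLP_DATA`.
#'
#' @param panel A gene panel table ([read_gene_panel()]).
#' @return data.frame with columns `gene`, `ms_score` (`NA` when
#'   undefined) and `note` (`NA` or `"NO_PLP_DATA"`).
#' @export
missense_score <- function(panel) {
  panel <- validate_gene_panel(panel)
  ms <- ifelse(panel$n_total_plp > 0,
               panel$n_missense_plp / panel$n_total_plp, NA_real_)
  data.frame(gene = panel$gene, ms_score = ms,
             note = ifelse(panel$n_total_plp > 0, NA_character_,
                           "NO_PLP_DATA"),
             stringsAsFactors = FALSE)
}

#' Categorize a structure-based deleteriousness score
#'
#' The structural scoring system emits a score in \[0, 1\] per variant: a
#' score above 0.7 strongly suggests deleteriousness, above 0.5 suggests
#' it, at or below 0.5 is neutral. Variants without structural coverage
#' carry no score and are `UNSCORED`. Both cut-offs are strict
#' inequalities (a score of exactly 0.5 is `NEUTRAL`).
#'
#' @param score Numeric vector of scores in \[0, 1\]; `NA` = no score.
#' @param thr An [default_thresholds()] object.
#' @return Character vector: `STRONG_DELETERIOUS`, `DELETERIOUS`,
#'   `NEUTRAL` or `UNSCORED`.
#' @export
vipur_category <- function(score, thr = default_thresholds()) {
  range_check(score, "vipur", 0, 1)
  ifelse(is.na(score), "UNSCORED",
         ifelse(score > thr$vipur_strong, "STRONG_DELETERIOUS",
                ifelse(score > thr$vipur_deleterious, "DELETERIOUS",
                       "NEUTRAL")))
}

#' Prioritize strong VUS for functional follow-up
#'
#' Combines the per-gene missense score with the per-variant structural
#' category: a VUS is *first priority* when its gene's missense score
#' exceeds `ms_min` (more than 10% of described disease alleles are
#' missense) AND its structural score exceeds `vipur_strong` (> 0.7,
#' strongly deleterious). Variants without structural coverage cannot
#' qualify. Output is sorted first-priority first, then by structural
#' score descending, ties broken by (gene, variant_key); recurrent
#' observations are collapsed to unique variants before counting.
#'
#' @param vus A tiered call table restricted to tier `STRONG_VUS`.
#' @param gene_scores Output of [missense_score()].
#' @param thr An [default_thresholds()] object.
#' @return data.frame with one row per unique variant: `variant_key`,
#'   `gene`, `ms_score`, `vipur`, `vipur_category`, `first_priority`.
#' @export
prioritize <- function(vus, gene_scores, thr = default_thresholds()) {
  if (nrow(vus) && !all(vus$tier == "STRONG_VUS")) {
    stop("prioritize() expects calls of tier STRONG_VUS only", call. = FALSE)
  }
  dedup <- vus[!duplicated(vus$variant_key), , drop = FALSE]
  ms <- gene_scores$ms_score[match(dedup$gene, gene_scores$gene)]
  cat_ <- vipur_category(dedup$vipur, thr)
  fp <- !is.na(ms) & ms > thr$ms_min & cat_ == "STRONG_DELETERIOUS"
  out <- data.frame(variant_key = dedup$variant_key, gene = dedup$gene,
                    ms_score = ms, vipur = dedup$vipur,
                    vipur_category = cat_, first_priority = fp,
                    stringsAsFactors = FALSE)
  ord <- order(!out$first_priority,
               -ifelse(is.na(out$vipur), -Inf, out$vipur),
               out$gene, out$variant_key)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare the cohort variant-type spectrum with patient cohorts
#'
#' For each panel gene with patient-spectrum data and at least one cohort
#' variant, computes the proportions of truncating vs
#' missense/non-coding/in-frame variants in the screened (healthy) cohort
#' and in the patient cohort, and their divergence (total-variation
#' distance over the two categories, i.e. the absolute difference of the
#' missense proportions). A divergence near 1 is the pattern of genes
#' whose disease alleles are almost exclusively truncating while healthy
#' carriers show missense variants — such genes' missense VUS are likely
#' benign.
#'
#' @param tiered A tiered call table (reportable + strong-VUS calls are
#'   used; `EXCLUDED` rows are ignored).
#' @param panel A gene panel table with `spectrum_truncating` /
#'   `spectrum_missense`.
#' @return data.frame with one row per gene: cohort and patient
#'   truncating/missense proportions and `divergence`.
#' @export
spectrum_comparison <- function(tiered, panel) {
  panel <- validate_gene_panel(panel)
  keep <- tiered$tier != "EXCLUDED"
  tv <- tiered[keep, , drop = FALSE]
  genes <- intersect(unique(tv$gene),
                     panel$gene[!is.na(panel$spectrum_truncating)])
  rows <- lapply(genes, function(g) {
    sel <- tv$gene == g
    n <- sum(sel)
    trunc_prop <- sum(is_lof(tv$consequence[sel])) / n
    mis_prop <- 1 - trunc_prop
    pe <- panel[panel$gene == g, ][1L, ]
    data.frame(gene = g, n_cohort = n,
               cohort_truncating_prop = trunc_prop,
               cohort_missense_prop = mis_prop,
               patient_truncating_prop = pe$spectrum_truncating,
               patient_missense_prop = pe$spectrum_missense,
               divergence = abs(mis_prop - pe$spectrum_missense),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(gene = character(0), n_cohort = integer(0),
                      cohort_truncating_prop = numeric(0),
                      cohort_missense_prop = numeric(0),
                      patient_truncating_prop = numeric(0),
                      patient_missense_prop = numeric(0),
                      divergence = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
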