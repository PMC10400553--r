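#' Resolve a tier-set name
#'
#' @param tier_set Either a character vector of tier names, or one of the
#'   shorthand names `"pathogenic"` (PATHOGENIC only), `"reportable"`
#'   (PATHOGENIC + NOVEL_LOF) or `"vus"` (STRONG_VUS only).
#' @return Character vector of tier names.
#' @export
tier_set <- function(tier_set) {
  if (length(tier_set) == 1L && tier_set %in% c("pathogenic", "reportable",
                                                "vus")) {
    return(switch(tier_set,
                  pathogenic = "PATHOGENIC",
                  reportable = c("PATHOGENIC", "NOVEL_LOF"),
                  vus = "STRONG_VUS"))
  }
  bad <- setdiff(tier_set, TIER_LEVELS)
  if (length(bad)) stop("unknown tier(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tier_set
}

#' Carrier count and carrier frequency
#'
#' An individual is a carrier for a tier set when they hold at least one
#' variant whose tier lies in the set; zygosity does not change carrier
#' status. The frequency is carriers / N over the post-gate sample set.
#'
#' @param tiered A tiered call table.
#' @param sample_ids Character vector of individuals passing the sample
#'   gate (the denominator N).
#' @param tiers A tier set (see [tier_set()]).
#' @return List with `n_carriers`, `n` and `frequency` (`NA` when N = 0).
#' @export
carrier_frequency <- function(tiered, sample_ids, tiers = "pathogenic") {
  tiers <- tier_set(tiers)
  carriers <- unique(tiered$sample_id[tiered$tier %in% tiers])
  carriers <- intersect(carriers, sample_ids)
  n <- length(sample_ids)
  list(n_carriers = length(carriers), n = n,
       frequency = if (n == 0L) NA_real_ else length(carriers) / n,
       carriers = carriers)
}

#' Infer cis/trans phase of a same-gene variant pair from a child
#'
#' For a parent heterozygous for two variants in one gene, the child's
#' genotypes resolve the phase: if the child inherited both or neither
#' variant, the pair is in *cis* in the parent; if exactly one, in
#' *trans*. A missing child genotype at either site is uninformative.
#'
#' @param parent_id Sample id of the parent carrying both variants.
#' @param gene Gene symbol.
#' @param variant_keys Character vector of length 2.
#' @param child_carries Logical vector of length 2 (`NA` = genotype
#'   missing): does the child carry each variant?
#' @return data.frame row: `sample_id`, `gene`, `variant_key_1`,
#'   `variant_key_2`, `phase` (`CIS`, `TRANS`, `UNINFORMATIVE`).
#' @export
infer_phase <- function(parent_id, gene, variant_keys, child_carries) {
  stopifnot(length(variant_keys) == 2L, length(child_carries) == 2L)
  phase <- if (anyNA(child_carries)) {
    "UNINFORMATIVE"
  } else if (sum(child_carries) == 1L) {
    "TRANS"
  } else {
    "CIS"
  }
  data.frame(sample_id = parent_id, gene = gene,
             variant_key_1 = variant_keys[1L],
             variant_key_2 = variant_keys[2L],
             phase = phase, stringsAsFactors = FALSE)
}

#' Phase all same-gene variant pairs in a cohort using trio data
#'
#' Enumerates individuals carrying two or more variants in one gene and,
#' where a child genotype table is available, calls the phase of each
#' pair with [infer_phase()].
#'
#' @param tiered A call table; when a `tier` column is present, calls of
#'   tier `EXCLUDED` are ignored.
#' @param ped An `ecs_pedigree`.
#' @param child_genotypes data.frame with columns `sample_id` (the child)
#'   and `variant_key`, one row per variant the child carries. Children
#'   listed in `ped$trios` but absent from this table are treated as
#'   having no genotype data (uninformative).
#' @return data.frame of phase calls (possibly zero rows).
#' @export
phase_cohort <- function(tiered, ped, child_genotypes = NULL) {
  keep <- if ("tier" %in% names(tiered)) tiered$tier != "EXCLUDED" else
    rep(TRUE, nrow(tiered))
  tv <- tiered[keep, , drop = FALSE]
  out <- list()
  key <- paste(tv$sample_id, tv$gene)
  multi <- names(which(table(key) >= 2L))
  genotyped <- if (is.null(child_genotypes)) character(0) else
    unique(child_genotypes$sample_id)
  for (k in multi) {
    rows <- tv[key == k, , drop = FALSE]
    parent <- rows$sample_id[1L]
    gene <- rows$gene[1L]
    children <- ped$trios$child_id[ped$trios$father_id == parent |
                                     ped$trios$mother_id == parent]
    vks <- unique(rows$variant_key)
    if (length(vks) < 2L) next
    pairs <- utils::combn(sort(vks), 2L, simplify = FALSE)
    for (vk in pairs) {
      call_row <- NULL
      for (ch in children) {
        if (!ch %in% genotyped) next
        ch_keys <- child_genotypes$variant_key[
          child_genotypes$sample_id == ch]
        carries <- vk %in% ch_keys
        call_row <- infer_phase(parent, gene, vk, carries)
        if (call_row$phase != "UNINFORMATIVE") break
      }
      if (is.null(call_row)) {
        call_row <- infer_phase(parent, gene, vk, c(NA, NA))
      }
      out[[length(out) + 1L]] <- call_row
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      variant_key_1 = character(0),
                      variant_key_2 = character(0), phase = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Couples at reproductive risk
#'
#' A couple is at risk for a tier set when there is at least one gene in
#' which each partner carries at least one variant of the set: only then
#' can a child inherit one qualifying allele from each side. Two
#' same-gene variants proven to be in *cis* within one partner collapse
#' to a single carrier allele and do not put a couple at risk on their
#' own. Risk is prospective; existing offspring genotypes never remove a
#' couple.
#'
#' @param ped An `ecs_pedigree`.
#' @param tiered A tiered call table.
#' @param tiers A tier set (see [tier_set()]).
#' @param phase_calls Optional output of [phase_cohort()] (used only for
#'   reporting the cis-collapse; the both-partner rule is unaffected).
#' @return List with `couples` (data.frame of at-risk couples and the
#'   shared genes), `n_at_risk`, `n_couples`, `fraction`, and the
#'   consanguineous stratum (`n_at_risk_consanguineous`,
#'   `n_consanguineous`).
#' @export
couples_at_risk <- function(ped, tiered, tiers = "reportable",
                            phase_calls = NULL) {
  tiers <- tier_set(tiers)
  tv <- tiered[tiered$tier %in% tiers, , drop = FALSE]
  gene_sets <- split(tv$gene, tv$sample_id)
  couples <- ped$couples
  shared <- character(nrow(couples))
  at_risk <- logical(nrow(couples))
  for (i in seq_len(nrow(couples))) {
    g1 <- unique(gene_sets[[couples$father_id[i]]])
    g2 <- unique(gene_sets[[couples$mother_id[i]]])
    common <- intersect(g1, g2)
    if (length(common)) {
      at_risk[i] <- TRUE
      shared[i] <- paste(sort(common), collapse = ",")
    }
  }
  res <- couples[at_risk, , drop = FALSE]
  res$shared_genes <- shared[at_risk]
  rownames(res) <- NULL
  n_c <- nrow(couples)
  list(couples = res, n_at_risk = sum(at_risk), n_couples = n_c,
       fraction = if (n_c == 0L) NA_real_ else sum(at_risk) / n_c,
       n_at_risk_consanguineous = sum(at_risk & couples$consanguineous),
       n_consanguineous = sum(couples$consanguineous))
}

#' Variant recurrence and unique-variant accounting
#'
#' @param tiered A tiered call table.
#' @param tiers A tier set (see [tier_set()]).
#' @return List with `n_observations` (carrier observations over unique
#'   variants), `n_unique` (distinct variant keys), and `recurrence`
#'   (data.frame of variants carried by two or more distinct
#'   individuals, with their carrier counts).
#' @export
recurrence_and_unique <- function(tiered, tiers = "vus") {
  tiers <- tier_set(tiers)
  tv <- tiered[tiered$tier %in% tiers, , drop = FALSE]
  # one observation per distinct (variant, carrier) pair
  obs <- unique(tv[, c("variant_key", "sample_id")])
  counts <- table(obs$variant_key)
  rec <- counts[counts >= 2L]
  recurrence <- data.frame(variant_key = as.character(names(rec)),
                           n_carriers = as.integer(rec),
                           stringsAsFactors = FALSE)
  if (nrow(recurrence)) {
    recurrence <- recurrence[order(-recurrence$n_carriers,
                                   recurrence$variant_key), , drop = FALSE]
  }
  rownames(recurrence) <- NULL
  list(n_observations = nrow(obs), n_unique = length(counts),
       recurrence = recurrence)
}

#' Per-individual variant burden
#'
#' @param calls A call table (typically the high-confidence set).
#' @param sample_ids The post-gate sample set (individuals without calls
#'   count with burden 0 unless absent from the call table because they
#'   truly have none).
#' @return List with `mean` (raw), `mean_display` (half-up rounded to 2
#'   decimals), `min`, `max`.
#' @export
burden_stats <- function(calls, sample_ids) {
  n <- length(sample_ids)
  if (n == 0L) stop("burden_stats requires at least one individual",
                    call. = FALSE)
  counts <- table(factor(calls$sample_id, levels = sample_ids))
  m <- nrow(calls) / n
  list(mean = m, mean_display = round_half_up(m, 2L),
       min = as.integer(min(counts)), max = as.integer(max(counts)))
}

# display rounding: half-up at `digits` decimals (R's round() is
# round-half-even)
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Expected carrier frequency under Hardy-Weinberg equilibrium
#'
#' For a fully penetrant single-locus recessive disease of prevalence K,
#' the disease-allele frequency is q = sqrt(K) and the expected carrier
#' (heterozygote) fraction is 2q(1-q). Observed carrier frequencies far
#' above this expectation indicate that either prevalence is
#' underestimated, some genotype combinations are not viable, or not all
#' presumed disease alleles are truly pathogenic.
#'
#' @param prevalence Disease prevalence K in \[0, 1\] (vectorized).
#' @return Expected carrier fraction 2*sqrt(K)*(1-sqrt(K)).
#' @examples
#' expected_carrier_frequency(1e-4)  # q = 0.01 -> 0.0198
#' @export
expected_carrier_frequency <- function(prevalence) {
  range_check(prevalence, "prevalence", 0, 1)
  q <- sqrt(prevalence)
  2 * q * (1 - q)
}

#' Assemble the cohort report
#'
#' Runs every cohort-level statistic over a tiered call table and a
#' pedigree and cross-checks the totals (tier counts must sum to the
#' post-QC call count).
#'
#' @param tiered A tiered call table (output of [classify_cohort()]).
#' @param ped An `ecs_pedigree`.
#' @param sample_ids Character vector of individuals passing the sample
#'   gate. Defaults to all pedigree individuals appearing in the call
#'   table's sample universe.
#' @param panel Optional gene panel table; when it carries `prevalence`,
#'   per-gene observed vs Hardy-Weinberg-expected carrier frequencies are
#'   reported.
#' @param phase_calls Optional output of [phase_cohort()].
#' @return A list of class `ecs_report`.
#' @export
build_report <- function(tiered, ped, sample_ids = NULL, panel = NULL,
                         phase_calls = NULL) {
  if (is.null(sample_ids)) sample_ids <- ped$individuals$sample_id
  extra <- setdiff(unique(tiered$sample_id), sample_ids)
  if (length(extra)) {
    stop("call table contains samples outside the post-gate sample set: ",
         paste(utils::head(extra, 3L), collapse = ", "), call. = FALSE)
  }
  counts <- do.call(rbind, lapply(TIER_LEVELS, function(tl) {
    sel <- tiered$tier == tl
    data.frame(tier = tl, n = sum(sel),
               n_lof = sum(sel & is_lof(tiered$consequence)),
               n_other = sum(sel & !is_lof(tiered$consequence)),
               stringsAsFactors = FALSE)
  }))
  stopifnot(sum(counts$n) == nrow(tiered))

  sets <- list(pathogenic = "pathogenic", reportable = "reportable",
               vus = "vus")
  cf <- lapply(sets, function(s) {
    x <- carrier_frequency(tiered, sample_ids, s)
    x[c("n_carriers", "n", "frequency")]
  })
  risk <- lapply(sets, function(s)
    couples_at_risk(ped, tiered, s, phase_calls))
  rec <- recurrence_and_unique(tiered, "vus")
  rec_rep <- recurrence_and_unique(tiered, "reportable")
  non_excluded <- tiered[tiered$tier != "EXCLUDED", , drop = FALSE]
  burden <- list(
    high_confidence = burden_stats(tiered, sample_ids),
    reportable = burden_stats(
      tiered[tiered$tier %in% tier_set("reportable"), , drop = FALSE],
      sample_ids),
    vus = burden_stats(
      tiered[tiered$tier == "STRONG_VUS", , drop = FALSE], sample_ids))

  per_gene <- per_gene_summary(non_excluded, sample_ids, panel)

  report <- list(
    n_individuals = length(sample_ids),
    n_calls = nrow(tiered),
    tier_counts = counts,
    carrier = cf,
    couples = lapply(risk, function(r)
      r[c("n_at_risk", "n_couples", "fraction",
          "n_at_risk_consanguineous", "n_consanguineous")]),
    couples_at_risk_detail = lapply(risk, `[[`, "couples"),
    recurrence_vus = rec,
    recurrence_reportable = rec_rep,
    burden = burden,
    per_gene = per_gene,
    phase_calls = if (is.null(phase_calls)) NULL else phase_calls)
  class(report) <- "ecs_report"
  report
}

per_gene_summary <- function(non_excluded, sample_ids, panel) {
  genes <- sort(unique(non_excluded$gene))
  n <- length(sample_ids)
  rows <- lapply(genes, function(g) {
    sel <- non_excluded$gene == g
    rep_sel <- sel & non_excluded$tier %in% tier_set("reportable")
    carriers <- length(unique(non_excluded$sample_id[rep_sel]))
    data.frame(gene = g, n_calls = sum(sel),
               n_reportable = sum(rep_sel),
               n_carriers_reportable = carriers,
               carrier_frequency = if (n > 0) carriers / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  pg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), n_calls = integer(0),
               n_reportable = integer(0), n_carriers_reportable = integer(0),
               carrier_frequency = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(panel) && "prevalence" %in% names(panel)) {
    prev <- panel$prevalence[match(pg$gene, panel$gene)]
    pg$expected_carrier_frequency <- ifelse(
      is.na(prev), NA_real_, expected_carrier_frequency(ifelse(is.na(prev),
                                                               0, prev)))
    pg$obs_over_expected <- pg$carrier_frequency /
      pg$expected_carrier_frequency
  }
  pg
}

#' @export
print.ecs_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d individuals, %d post-QC calls\n",
              x$n_individuals, x$n_calls))
  tc <- x$tier_counts
  for (i in seq_len(nrow(tc))) {
    cat(sprintf("  %-11s %4d (LOF %d / other %d)\n", tc$tier[i], tc$n[i],
                tc$n_lof[i], tc$n_other[i]))
  }
  for (s in names(x$carrier)) {
    cf <- x$carrier[[s]]
    cat(sprintf("  carriers [%s]: %d/%d (%.1f%%)\n", s, cf$n_carriers,
                cf$n, 100 * cf$frequency))
  }
  for (s in names(x$couples)) {
    cp <- x$couples[[s]]
    cat(sprintf("  couples at risk [%s]: %d/%d (consanguineous %d/%d)\n",
                s, cp$n_at_risk, cp$n_couples,
                cp$n_at_risk_consanguineous, cp$n_consanguineous))
  }
  invisible(x)
}
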