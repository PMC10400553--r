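#' Simulation parameters for a synthetic screening cohort
#'
#' Defaults emulate the primary (local) study cohort: 395 screened
#' individuals forming 177 couples (21 consanguineous, a fraction of
#' ~0.119) and 41 single parents, one sequenced child per couple, a mean
#' of 9.3 high-confidence calls per individual in the range 1-24, mean
#' exome coverage of ~287x, and a tier mix dominated by excluded/benign
#' calls (48 pathogenic, 38 novel LOF and 265 strong VUS out of 3702
#' high-confidence calls gives roughly 1.3% / 1% / 7.2% / 90.5%).
#' Predictor scores are driven by a latent per-variant deleteriousness so
#' that pairwise correlations of the continuous scores span roughly -0.1
#' to 0.7. Use `uk_cohort_params()` for the confirmation-cohort settings
#' (999 individuals, ~57x coverage, 7.4 calls/individual).
#'
#' @param n_individuals,n_couples,consanguineous_fraction,n_trios Cohort
#'   structure; `n_trios <= n_couples`.
#' @param panel Gene panel table; defaults to [ciliopathy_panel()].
#' @param mean_calls_per_individual Target mean high-confidence calls.
#' @param rare_fraction Fraction of calls with MAF <= 0.1%.
#' @param tier_mix Named proportions (`pathogenic`, `novel_lof`, `vus`,
#'   `benign`) summing to 1; pathogenic + novel_lof + vus must not exceed
#'   `rare_fraction` (qualifying tiers require rare alleles).
#' @param latent_correlation Scale on the latent-factor loadings
#'   controlling inter-predictor correlation (1 = calibrated range).
#' @param db_conflict_rate Probability that an HGMD-DM variant carries a
#'   ClinVar benign assertion (database conflict).
#' @param mean_coverage Mean read depth per call.
#' @param artifact_rate Fraction of calls violating the 16%/20x per-call
#'   cut-offs.
#' @param seed Integer seed propagated to all draws.
#' @return A list of class `ecs_sim_params`.
#' @export
cohort_sim_params <- function(n_individuals = 395L,
                              n_couples = 177L,
                              consanguineous_fraction = 21 / 177,
                              n_trios = n_couples,
                              panel = ciliopathy_panel(),
                              mean_calls_per_individual = 9.32,
                              rare_fraction = 0.35,
                              tier_mix = c(pathogenic = 0.013,
                                           novel_lof = 0.010,
                                           vus = 0.072,
                                           benign = 0.905),
                              latent_correlation = 1,
                              db_conflict_rate = 0.05,
                              mean_coverage = 286.9,
                              artifact_rate = 0.1,
                              seed = 1L) {
  p <- list(n_individuals = as.integer(n_individuals),
            n_couples = as.integer(n_couples),
            consanguineous_fraction = consanguineous_fraction,
            n_trios = as.integer(n_trios), panel = panel,
            mean_calls_per_individual = mean_calls_per_individual,
            rare_fraction = rare_fraction, tier_mix = tier_mix,
            latent_correlation = latent_correlation,
            db_conflict_rate = db_conflict_rate,
            mean_coverage = mean_coverage, artifact_rate = artifact_rate,
            seed = as.integer(seed))
  fracs <- c("consanguineous_fraction", "rare_fraction",
             "db_conflict_rate", "artifact_rate")
  for (f in fracs) {
    if (p[[f]] < 0 || p[[f]] > 1) stop(f, " must lie in [0, 1]",
                                       call. = FALSE)
  }
  if (!setequal(names(tier_mix), c("pathogenic", "novel_lof", "vus",
                                   "benign"))) {
    stop("tier_mix must name pathogenic, novel_lof, vus and benign",
         call. = FALSE)
  }
  if (abs(sum(tier_mix) - 1) > 1e-8) stop("tier_mix must sum to 1",
                                          call. = FALSE)
  if (any(tier_mix < 0)) stop("tier_mix proportions must be non-negative",
                              call. = FALSE)
  if (p$n_trios > p$n_couples) stop("n_trios cannot exceed n_couples",
                                    call. = FALSE)
  if (sum(tier_mix[c("pathogenic", "novel_lof", "vus")]) >
      p$rare_fraction + 1e-8) {
    stop("infeasible tier_mix: qualifying tiers require more rare ",
         "alleles than rare_fraction allows", call. = FALSE)
  }
  if (2L * p$n_couples > p$n_individuals) {
    stop("cohort too small for the requested number of couples",
         call. = FALSE)
  }
  class(p) <- "ecs_sim_params"
  p
}

#' @rdname cohort_sim_params
#' @param ... Overrides passed to [cohort_sim_params()].
#' @export
uk_cohort_params <- function(...) {
  defaults <- list(n_individuals = 999L, n_couples = 0L,
                   consanguineous_fraction = 0, n_trios = 0L,
                   mean_calls_per_individual = 7.38,
                   mean_coverage = 57.2)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_sim_params, args)
}

# latent-factor loadings of the nine continuous predictor scores; pairwise
# correlation of scores i, j is lambda_i * lambda_j, spanning ~ -0.13..0.68
predictor_loadings <- function(scale = 1) {
  scale * c(SIFT = 0.85, Polyphen2 = 0.80, LRT = 0.60,
            MutationAssessor = 0.75, MutationTaster = 0.70,
            FATHMM = -0.15, PROVEAN = 0.80, CADD = 0.85, MCAP = 0.70)
}

#' Generate a synthetic annotated screening cohort
#'
#' Simulates an annotated call table, pedigree, per-sample coverage
#' metrics and hidden truth tiers with the statistical structure the
#' pipeline assumes:
#'
#' * each individual draws a 1-24-truncated negative-binomial number of
#'   calls around the target mean;
#' * each call has a hidden truth tier drawn from `tier_mix`, and its
#'   annotation fields (consequence, MAF, databases, predictor calls) are
#'   generated to match that tier;
#' * continuous predictor scores derive from a latent per-variant
#'   deleteriousness z plus independent noise (score_t = lambda_t z +
#'   sqrt(1 - lambda_t^2) eps), then thresholded to categorical calls, so
#'   pairwise score correlations fall in the calibrated range;
#' * a `db_conflict_rate` fraction of HGMD-DM variants receive a ClinVar
#'   benign assertion;
#' * an `artifact_rate` fraction of calls violate the per-call QC
#'   cut-offs (low depth or low alternate-read fraction);
#' * parents with two or more heterozygous variants in one gene have the
#'   variants placed on haplotypes, and each trio child inherits one
#'   haplotype per parent (Mendelian transmission), enabling phase
#'   recovery.
#'
#' Output is deterministic for a fixed seed.
#'
#' @param params An [cohort_sim_params()] object.
#' @return List with `calls` (validated call table, including QC feature
#'   columns), `pedigree`, `metrics`, `truth` (data.frame `call_id`,
#'   `sample_id`, `variant_key`, `truth_tier`, `artifact`),
#'   `child_genotypes` (data.frame `sample_id`, `variant_key` for trio
#'   children), `haplotypes` (the planted parental phase assignments) and
#'   `scores` (the continuous predictor scores behind the categorical
#'   calls).
#' @export
generate_cohort <- function(params = cohort_sim_params()) {
  set.seed(params$seed)
  n <- params$n_individuals
  adults <- sprintf("I%04d", seq_len(n))
  genes <- params$panel$gene

  ## pedigree ------------------------------------------------------------
  n_cpl <- params$n_couples
  fathers <- adults[seq_len(n_cpl) * 2L - 1L]
  mothers <- adults[seq_len(n_cpl) * 2L]
  n_consang <- round(params$consanguineous_fraction * n_cpl)
  consang <- seq_len(n_cpl) <= n_consang
  children <- if (params$n_trios > 0L)
    sprintf("C%04d", seq_len(params$n_trios)) else character(0)
  individuals <- data.frame(
    sample_id = c(adults, children),
    sex = c(rep(c("1", "2"), n_cpl), rep("0", n - 2L * n_cpl),
            rep("0", length(children))),
    consanguineous = c(rep(consang, each = 2L),
                       rep(FALSE, n - 2L * n_cpl),
                       rep(FALSE, length(children))),
    stringsAsFactors = FALSE)
  couples <- data.frame(father_id = fathers, mother_id = mothers,
                        consanguineous = consang, stringsAsFactors = FALSE)
  trios <- if (params$n_trios > 0L) {
    data.frame(father_id = fathers[seq_len(params$n_trios)],
               mother_id = mothers[seq_len(params$n_trios)],
               child_id = children, stringsAsFactors = FALSE)
  } else NULL
  ped <- pedigree_set(individuals, couples, trios)

  ## per-individual call counts: negative binomial truncated to [1, 24] --
  draw_counts <- function(m) {
    x <- stats::rnbinom(m, size = 3, mu = params$mean_calls_per_individual)
    while (any(bad <- x < 1L | x > 24L)) {
      x[bad] <- stats::rnbinom(sum(bad), size = 3,
                               mu = params$mean_calls_per_individual)
    }
    x
  }
  counts <- draw_counts(n)
  total <- sum(counts)
  sample_id <- rep(adults, counts)

  ## truth tiers and annotation ------------------------------------------
  tiers <- c("PATHOGENIC", "NOVEL_LOF", "STRONG_VUS", "BENIGN")
  truth <- sample(tiers, total, replace = TRUE, prob = params$tier_mix)

  # latent deleteriousness: high for qualifying tiers, low for benign
  z <- stats::rnorm(total, mean = ifelse(truth == "BENIGN", -0.8, 1.6),
                    sd = 0.8)
  lam <- predictor_loadings(params$latent_correlation)
  scores <- vapply(names(lam), function(t)
    lam[[t]] * z + sqrt(max(0, 1 - lam[[t]]^2)) * stats::rnorm(total),
    numeric(total))

  gene <- sample(genes, total, replace = TRUE)
  pos <- sample.int(5e7L, total, replace = TRUE)
  chrom <- paste0("chr", (match(gene, genes) %% 22L) + 1L)
  ref <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  alt_base <- c(A = "G", C = "T", G = "A", T = "C")
  alt <- unname(alt_base[ref])

  rare <- stats::runif(total) < params$rare_fraction
  rare[truth != "BENIGN"] <- TRUE
  maf <- ifelse(rare,
                ifelse(stats::runif(total) < 0.3, NA_real_,
                       stats::runif(total, 0, 1e-3)),
                stats::runif(total, 2e-3, 0.4))

  lof_cons <- sample(LOF_CONSEQUENCES, total, replace = TRUE)
  benign_cons <- sample(c("MISSENSE", "SYNONYMOUS", "NONCODING", "OTHER"),
                        total, replace = TRUE,
                        prob = c(0.45, 0.3, 0.2, 0.05))
  vus_cons <- sample(c("MISSENSE", "NONCODING", "INFRAME_INDEL"), total,
                     replace = TRUE, prob = c(0.92, 0.05, 0.03))
  consequence <- ifelse(truth %in% c("NOVEL_LOF"), lof_cons,
                        ifelse(truth == "STRONG_VUS", vus_cons,
                               ifelse(truth == "BENIGN", benign_cons,
                                      "MISSENSE")))
  # half the pathogenic calls are LOF disease alleles
  path_lof <- truth == "PATHOGENIC" & stats::runif(total) < 0.5
  consequence[path_lof] <- lof_cons[path_lof]

  clinvar <- rep("ABSENT", total)
  clinvar_limited <- rep(FALSE, total)
  hgmd <- rep("ABSENT", total)
  # pathogenic: database-supported
  p_sel <- truth == "PATHOGENIC"
  clinvar[p_sel] <- "P"
  hgmd[p_sel] <- ifelse(stats::runif(sum(p_sel)) < 0.8, "DM", "DM")
  # non-LOF pathogenic requires both databases; LOF needs at least one
  hgmd[p_sel & !is_lof(consequence)] <- "DM"
  drop_hgmd <- p_sel & is_lof(consequence) & stats::runif(total) < 0.3
  hgmd[drop_hgmd] <- "ABSENT"
  # strong VUS: mixture of HGMD-DM-only, LP-limited and ensemble-only
  v_sel <- which(truth == "STRONG_VUS")
  v_kind <- sample(c("dm", "lp", "ensemble"), length(v_sel),
                   replace = TRUE, prob = c(0.15, 0.02, 0.83))
  hgmd[v_sel[v_kind == "dm"]] <- "DM"
  clinvar[v_sel[v_kind == "dm"]] <-
    sample(c("VUS", "CONFLICTING", "ABSENT"), sum(v_kind == "dm"),
           replace = TRUE)
  clinvar[v_sel[v_kind == "lp"]] <- "LP"
  clinvar_limited[v_sel[v_kind == "lp"]] <- TRUE
  clinvar[v_sel[v_kind == "ensemble"]] <-
    sample(c("VUS", "CONFLICTING", "ABSENT"), sum(v_kind == "ensemble"),
           replace = TRUE, prob = c(0.4, 0.2, 0.4))
  # benign: some known-benign assertions, occasionally conflicting DM
  b_sel <- which(truth == "BENIGN")
  b_db <- stats::runif(length(b_sel))
  clinvar[b_sel[b_db < 0.3]] <- sample(c("B", "LB"), sum(b_db < 0.3),
                                       replace = TRUE)
  conflict <- b_sel[b_db < 0.3 &
                      stats::runif(length(b_sel)) < params$db_conflict_rate]
  hgmd[conflict] <- "DM"

  ## categorical predictor calls from the continuous scores --------------
  # thresholds chosen so calls with high latent z mostly vote deleterious
  tool_cut <- 0.5
  tool_call <- function(s, lam_t) {
    dir_del <- if (lam_t >= 0) s > tool_cut else s < -tool_cut
    out <- ifelse(dir_del, "DELETERIOUS", "TOLERATED")
    out[stats::runif(length(s)) < 0.05] <- "MISSING"
    out
  }
  tool_mat <- vapply(PREDICTOR_TOOLS, function(t)
    tool_call(scores[, t], lam[[t]]), character(total))
  # CADD on a phred-like scale, M-CAP in [0, 1]
  cadd <- pmax(0, 15 + 8 * scores[, "CADD"])
  mcap <- stats::plogis(1.2 * scores[, "MCAP"] - 1)
  # ensure ensemble-kind strong VUS actually pass the ensemble rule
  ens_idx <- v_sel[v_kind == "ensemble"]
  cadd[ens_idx] <- pmax(cadd[ens_idx], 21)
  mcap[ens_idx] <- pmax(mcap[ens_idx], 0.03)
  for (i in ens_idx) {
    del <- tool_mat[i, ] == "DELETERIOUS"
    if (sum(del) < 4L) {
      flip <- which(!del)[seq_len(4L - sum(del))]
      tool_mat[i, flip] <- "DELETERIOUS"
    }
  }
  # benign calls must fail the ensemble (matching their truth tier)
  low_cadd <- b_sel[stats::runif(length(b_sel)) < 0.5]
  cadd[low_cadd] <- pmin(cadd[low_cadd], 15)
  mcap_low <- b_sel[!b_sel %in% low_cadd]
  mcap[mcap_low] <- pmin(mcap[mcap_low], 0.02)

  vipur <- ifelse(stats::runif(total) < 0.3, NA_real_,
                  stats::plogis(1.5 * z - 1))

  ## QC features ----------------------------------------------------------
  depth <- pmax(1L, as.integer(round(stats::rnorm(
    total, params$mean_coverage, params$mean_coverage / 4))))
  alt_fraction <- pmin(1, pmax(0.2, stats::rnorm(total, 0.48, 0.08)))
  strand_balance <- pmin(1, pmax(0, stats::rnorm(total, 0.5, 0.05)))
  mean_base_quality <- stats::rnorm(total, 36, 1.5)
  artifact <- stats::runif(total) < params$artifact_rate
  # artifacts violate the 16% / 20x cut-offs (and look artefactual in the
  # auxiliary features too)
  art_kind <- stats::runif(total)
  low_af <- artifact & art_kind < 0.5
  alt_fraction[low_af] <- stats::runif(sum(low_af), 0.01, 0.15)
  depth[artifact & !low_af] <- sample.int(19L, sum(artifact & !low_af),
                                          replace = TRUE)
  strand_balance[artifact] <- stats::runif(sum(artifact), 0, 0.15)
  mean_base_quality[artifact] <- stats::rnorm(sum(artifact), 24, 2)

  zyg <- ifelse(stats::runif(total) < 0.03, "HOM", "HET")

  calls <- data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
                      pos = pos, ref = ref, alt = alt,
                      consequence = consequence, maf = maf, cadd = cadd,
                      mcap = mcap, stringsAsFactors = FALSE)
  for (i in seq_along(PREDICTOR_TOOLS)) {
    calls[[tool_columns()[i]]] <- tool_mat[, PREDICTOR_TOOLS[i]]
  }
  calls$clinvar <- clinvar
  calls$clinvar_limited <- clinvar_limited
  calls$hgmd <- hgmd
  calls$vipur <- vipur
  calls$depth <- depth
  calls$alt_fraction <- alt_fraction
  calls$zygosity <- zyg
  calls$strand_balance <- strand_balance
  calls$mean_base_quality <- mean_base_quality
  calls <- validate_calls(calls)

  ## haplotypes and trio transmission ------------------------------------
  hap <- data.frame(sample_id = calls$sample_id,
                    variant_key = calls$variant_key, gene = calls$gene,
                    haplotype = sample(c("A", "B"), total, replace = TRUE),
                    stringsAsFactors = FALSE)
  child_rows <- list()
  if (params$n_trios > 0L) {
    for (ti in seq_len(params$n_trios)) {
      ch <- trios$child_id[ti]
      for (par in c(trios$father_id[ti], trios$mother_id[ti])) {
        sel <- hap$sample_id == par & calls$zygosity == "HET"
        hom <- hap$sample_id == par & calls$zygosity == "HOM"
        transmitted <- sample(c("A", "B"), 1L)
        keys <- c(hap$variant_key[sel & hap$haplotype == transmitted],
                  hap$variant_key[hom])
        if (length(keys)) {
          child_rows[[length(child_rows) + 1L]] <-
            data.frame(sample_id = ch, variant_key = keys,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  child_genotypes <- if (length(child_rows)) do.call(rbind, child_rows) else
    data.frame(sample_id = character(0), variant_key = character(0),
               stringsAsFactors = FALSE)

  metrics <- data.frame(
    sample_id = adults,
    mean_coverage = stats::rnorm(n, params$mean_coverage,
                                 params$mean_coverage / 10),
    fraction_exome_at_depth = pmin(1, stats::rbeta(n, 60, 2)),
    stringsAsFactors = FALSE)

  truth_df <- data.frame(call_id = seq_len(total), sample_id = sample_id,
                         variant_key = calls$variant_key,
                         truth_tier = truth, artifact = artifact,
                         stringsAsFactors = FALSE)
  list(calls = calls, pedigree = ped, metrics = metrics, truth = truth_df,
       child_genotypes = child_genotypes, haplotypes = hap,
       scores = as.data.frame(scores))
}

#' Generate a labeled QC-classifier training set
#'
#' Draws true calls and artifact calls from two multivariate feature
#' distributions (depth, alternate-read fraction, strand balance, mean
#' base quality) whose means differ by `separation` within-class standard
#' deviations in every feature. `separation = 0` makes the classes
#' indistinguishable; large values make them linearly separable.
#'
#' @param n_true,n_false Class sizes (> 0).
#' @param separation Class-mean separation in within-class SD units.
#' @param seed Integer seed.
#' @return data.frame with the four feature columns and a `label` column
#'   (`TRUE_CALL` / `FALSE_CALL`).
#' @export
generate_qc_training_set <- function(n_true, n_false, separation = 4,
                                     seed = 1L) {
  stopifnot(n_true > 0L, n_false > 0L, separation >= 0)
  set.seed(seed)
  base <- c(depth = 150, alt_fraction = 0.45, strand_balance = 0.5,
            mean_base_quality = 36)
  sds <- c(depth = 30, alt_fraction = 0.08, strand_balance = 0.06,
           mean_base_quality = 1.5)
  draw <- function(m, shift) {
    cols <- lapply(names(base), function(f)
      stats::rnorm(m, base[[f]] + shift * sds[[f]] * c(depth = -1,
        alt_fraction = -1, strand_balance = -1,
        mean_base_quality = -1)[[f]], sds[[f]]))
    names(cols) <- names(base)
    as.data.frame(cols)
  }
  true_df <- draw(n_true, 0)
  false_df <- draw(n_false, separation)
  true_df$label <- "TRUE_CALL"
  false_df$label <- "FALSE_CALL"
  out <- rbind(true_df, false_df)
  rownames(out) <- NULL
  out
}
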