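# Deterministic benchmark cohort ------------------------------------------
#
# A hand-constructed, fully deterministic cohort of 395 screened
# individuals (177 couples, 21 of them consanguineous, 41 single parents)
# whose post-QC call table classifies to an exactly known accounting:
# 48 pathogenic calls (26 LOF / 22 missense, non-coding or in-frame) in 43
# individuals, 38 novel LOF calls, 265 strong VUS (262 missense/nc/
# in-frame observations over 239 unique variants, 23 of them recurring in
# exactly two individuals, plus 3 LOF variants with a ClinVar VUS
# assertion) in 197 individuals each carrying 1-5, with 2 consanguineous
# couples sharing reportable variants in one gene and 7 non-consanguineous
# couples sharing strong VUS in one gene. Distractor calls violating each
# individual tier rule are interleaved. Every row passes the per-call QC
# cut-offs, so the table can be fed to the classifier directly.

fixture_env <- function() {
  env <- new.env()
  env$pos <- 1000000L
  env$rows <- vector("list", 512L)
  env$n <- 0L
  env
}

fixture_key <- function(env, gene_idx) {
  pos <- env$pos
  env$pos <- env$pos + 37L
  list(chrom = paste0("chr", (gene_idx %% 22L) + 1L), pos = pos)
}

fixture_tools <- function(n_del, missing = FALSE) {
  if (missing) return(rep("MISSING", 7L))
  c(rep("DELETERIOUS", n_del), rep("TOLERATED", 7L - n_del))
}

fixture_add <- function(env, sample_id, gene, chrom, pos, ref, alt,
                        consequence, maf = 5e-4, cadd = 26, mcap = 0.4,
                        tools = fixture_tools(5L), clinvar = "ABSENT",
                        clinvar_limited = FALSE, hgmd = "ABSENT",
                        vipur = NA_real_, depth = 180L,
                        alt_fraction = 0.47, zygosity = "HET") {
  row <- data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
                    pos = as.integer(pos), ref = ref, alt = alt,
                    consequence = consequence, maf = maf, cadd = cadd,
                    mcap = mcap, stringsAsFactors = FALSE)
  tl <- as.list(tools)
  names(tl) <- tool_columns()
  row <- cbind(row, as.data.frame(tl, stringsAsFactors = FALSE))
  row$clinvar <- clinvar
  row$clinvar_limited <- clinvar_limited
  row$hgmd <- hgmd
  row$vipur <- vipur
  row$depth <- as.integer(depth)
  row$alt_fraction <- alt_fraction
  row$zygosity <- zygosity
  env$n <- env$n + 1L
  env$rows[[env$n]] <- row
  invisible(row)
}

# adds a fresh singleton variant for `gene` and returns its key parts
fixture_add_new <- function(env, sample_id, gene, panel_genes, ...) {
  gi <- match(gene, panel_genes)
  k <- fixture_key(env, gi)
  fixture_add(env, sample_id, gene, k$chrom, k$pos, "C", "T", ...)
  list(chrom = k$chrom, pos = k$pos, ref = "C", alt = "T")
}

#' Deterministic benchmark cohort with exact tier accounting
#'
#' Builds, without any randomness, a 395-individual screening cohort
#' (177 couples, 21 consanguineous, 41 single parents) whose annotated
#' call table reproduces an exactly known tier accounting when classified
#' with [classify_cohort()], [default_thresholds()] and the two-entry
#' recurring-allele whitelist: 48 pathogenic calls (26 LOF, 22 other) in
#' 43 carriers, 38 novel-LOF calls, 265 strong VUS in 197 carriers (each
#' carrying 1-5), with 2 consanguineous couples at reportable risk and 7
#' non-consanguineous couples sharing strong VUS in one gene, and 262
#' missense/non-coding/in-frame VUS observations collapsing to 239 unique
#' variants of which 23 recur in exactly two individuals. Distractor
#' calls failing each tier rule (common allele, ClinVar-benign override,
#' too few ensemble votes, CADD or M-CAP below cut-off, conflicting
#' ClinVar on a LOF variant) are interleaved and classify as EXCLUDED.
#'
#' @return List with elements `calls` (validated call table), `pedigree`
#'   (`ecs_pedigree` including one child per couple, enabling trio
#'   derivation), `metrics` (per-sample coverage metrics for the 395
#'   screened adults), `sample_ids` (the 395 adults) and `whitelist`.
#' @export
generate_table1_fixture <- function() {
  panel <- ciliopathy_panel()
  genes <- panel$gene
  env <- fixture_env()
  odd <- function(a, b) sprintf("S%03d", seq(a, b, 2L))
  even <- function(a, b) sprintf("S%03d", seq(a, b, 2L))

  ## --- pathogenic tier: 48 calls in 43 carriers -------------------------
  # couple 1 (consanguineous): both partners pathogenic missense in DYNC2H1
  fixture_add_new(env, "S001", "DYNC2H1", genes, consequence = "MISSENSE",
                  clinvar = "P", hgmd = "DM")
  fixture_add_new(env, "S002", "DYNC2H1", genes, consequence = "MISSENSE",
                  clinvar = "P", hgmd = "DM")
  # couple 2 (consanguineous): pathogenic LOF in CEP290 ...
  fixture_add_new(env, "S003", "CEP290", genes, consequence = "NONSENSE",
                  clinvar = "P", hgmd = "DM", cadd = 38, mcap = NA,
                  tools = fixture_tools(0L, missing = TRUE))
  # one individual with two pathogenic variants in the same gene (in cis)
  fixture_add_new(env, "S005", "CC2D2A", genes, consequence = "FRAMESHIFT",
                  clinvar = "P", cadd = 34, mcap = NA,
                  tools = fixture_tools(0L, missing = TRUE))
  fixture_add_new(env, "S005", "CC2D2A", genes, consequence = "FRAMESHIFT",
                  clinvar = "P", cadd = 33, mcap = NA,
                  tools = fixture_tools(0L, missing = TRUE))
  # four individuals with one LOF + one missense pathogenic call each
  dbl <- list(
    list(id = "S007", lof = "NPHP1", mis = "TMEM67"),
    list(id = "S009", lof = "TMEM216", mis = "MKS1"),
    list(id = "S011", lof = "RPGRIP1L", mis = "AHI1"),
    list(id = "S013", lof = "BBS10", mis = "BBS2"))
  for (d in dbl) {
    fixture_add_new(env, d$id, d$lof, genes, consequence = "NONSENSE",
                    clinvar = "P", hgmd = "DM", cadd = 36, mcap = NA,
                    tools = fixture_tools(0L, missing = TRUE))
    fixture_add_new(env, d$id, d$mis, genes, consequence = "MISSENSE",
                    clinvar = "P", hgmd = "DM")
  }
  # whitelisted recurring alleles (gnomAD frequency above the 0.1%
  # cut-off): BBS1 p.M309R in three individuals, KIAA0586 c.428delG in
  # three individuals
  wl <- recurring_allele_whitelist()
  for (s in c("S015", "S017", "S019")) {
    fixture_add(env, s, "BBS1", "chr11", 66278121L, "T", "G",
                consequence = "MISSENSE", maf = 0.0019,
                clinvar = "CONFLICTING", hgmd = "DM")
  }
  for (s in c("S021", "S023", "S025")) {
    fixture_add(env, s, "KIAA0586", "chr14", 58899550L, "AG", "A",
                consequence = "FRAMESHIFT", maf = 0.0013, cadd = 33,
                mcap = NA, tools = fixture_tools(0L, missing = TRUE),
                clinvar = "P", hgmd = "DM")
  }
  # sixteen further single-carrier LOF pathogenic calls
  lof_seq <- c("NONSENSE", "FRAMESHIFT", "CANONICAL_SPLICE")
  lof_db <- list(c("P", "ABSENT"), c("ABSENT", "DM"), c("P", "DM"))
  lof_car <- odd(27, 57)
  for (i in seq_along(lof_car)) {
    db <- lof_db[[(i - 1L) %% 3L + 1L]]
    fixture_add_new(env, lof_car[i], genes[30L + i], genes,
                    consequence = lof_seq[(i - 1L) %% 3L + 1L],
                    clinvar = db[1L], hgmd = db[2L], cadd = 30 + i,
                    mcap = NA, tools = fixture_tools(0L, missing = TRUE))
  }
  # thirteen further non-LOF pathogenic calls (ClinVar P + HGMD DM)
  mis_car <- odd(59, 83)
  mis_seq <- c(rep("MISSENSE", 10L), "NONCODING", "NONCODING",
               "INFRAME_INDEL")
  for (i in seq_along(mis_car)) {
    fixture_add_new(env, mis_car[i], genes[50L + i], genes,
                    consequence = mis_seq[i], clinvar = "P", hgmd = "DM")
  }

  ## --- novel LOF tier: 38 calls in 37 carriers --------------------------
  # partner of S003 carries a novel frameshift in the same gene, putting
  # consanguineous couple 2 at reportable (but not pathogenic-only) risk
  fixture_add_new(env, "S004", "CEP290", genes, consequence = "FRAMESHIFT",
                  maf = NA, cadd = 32, mcap = NA,
                  tools = fixture_tools(0L, missing = TRUE))
  for (g in c("WDR19", "IFT140")) {
    fixture_add_new(env, "S085", g, genes, consequence = "NONSENSE",
                    maf = 0, cadd = 35, mcap = NA,
                    tools = fixture_tools(0L, missing = TRUE))
  }
  nl_car <- odd(87, 155)
  for (i in seq_along(nl_car)) {
    fixture_add_new(env, nl_car[i], genes[70L + (i %% 40L)], genes,
                    consequence = lof_seq[(i - 1L) %% 3L + 1L],
                    maf = if (i %% 2L) NA else 2e-4, cadd = 25 + i %% 10L,
                    mcap = NA, tools = fixture_tools(0L, missing = TRUE))
  }

  ## --- strong VUS tier: 265 calls in 197 carriers -----------------------
  shared_genes <- c("USH2A", "ADGRV1", "DYNC2H1", "IFT81", "CEP290",
                    "KIF7", "IFT172")
  risk_partners <- sprintf("S%03d", 179:192)         # couples 90..96
  others <- c(even(58, 178), even(194, 354), sprintf("S%03d", 355:395))
  carriers <- c(risk_partners, others)               # 197 carriers
  burden <- c(rep(5L, 2L), rep(4L, 5L), rep(3L, 8L), rep(2L, 26L),
              rep(1L, 156L))
  stopifnot(length(carriers) == 197L, sum(burden) == 262L)

  # per-variant annotation category: 4 ClinVar-LP-limited singletons, 40
  # HGMD-DM singletons, 218 ensemble observations (23 recurrent variants
  # x2 + 172 singletons)
  vus_slots <- rep(list(NULL), 197L)   # one list of variant specs per carrier
  vseq <- 0L
  new_vus_variant <- function(category, gene) {
    vseq <<- vseq + 1L
    gi <- match(gene, genes)
    k <- fixture_key(env, gi)
    cons <- "MISSENSE"
    if (category == "ensemble") {
      if (vseq %% 37L == 0L) cons <- "NONCODING"
      if (vseq %% 41L == 0L) cons <- "INFRAME_INDEL"
    }
    list(gene = gene, chrom = k$chrom, pos = k$pos, ref = "G", alt = "A",
         consequence = cons, category = category,
         maf = c(0, 5e-4, 1e-3, NA)[[vseq %% 4L + 1L]],
         vipur = c(NA, 0.2, 0.55, 0.75, 0.9)[[vseq %% 5L + 1L]],
         votes = 4L + vseq %% 4L,
         cadd = c(20, 24.5, 33.5)[[vseq %% 3L + 1L]],
         mcap = c(0.025, 0.08, 0.6)[[vseq %% 3L + 1L]])
  }
  emit_vus <- function(carrier, v, zygosity = "HET") {
    cl <- switch(v$category,
                 lp = list(clinvar = "LP", limited = TRUE, hgmd = "ABSENT",
                           votes = 3L, cadd = 25, mcap = 0.3),
                 dm = list(clinvar = c("VUS", "CONFLICTING",
                                       "ABSENT")[[v$pos %% 3L + 1L]],
                           limited = FALSE, hgmd = "DM",
                           votes = if (v$pos %% 2L) 2L else 5L,
                           cadd = if (v$pos %% 2L) NA else 26, mcap = 0.3),
                 ensemble = list(clinvar = c("VUS", "CONFLICTING",
                                             "ABSENT")[[v$pos %% 3L + 1L]],
                                 limited = FALSE, hgmd = "ABSENT",
                                 votes = v$votes, cadd = v$cadd,
                                 mcap = v$mcap))
    fixture_add(env, carrier, v$gene, v$chrom, v$pos, v$ref, v$alt,
                consequence = v$consequence, maf = v$maf, cadd = cl$cadd,
                mcap = cl$mcap, tools = fixture_tools(cl$votes),
                clinvar = cl$clinvar, clinvar_limited = cl$limited,
                hgmd = cl$hgmd, vipur = v$vipur, zygosity = zygosity)
  }

  gene_cycle <- genes[setdiff(seq_along(genes), match("TCTN4", genes))]
  gpick <- function(i) gene_cycle[(i - 1L) %% length(gene_cycle) + 1L]

  # slot 1 of the 14 at-risk partners: a singleton ensemble variant in the
  # couple's shared gene
  for (k in seq_len(7L)) {
    for (p in c(2L * k - 1L, 2L * k)) {
      v <- new_vus_variant("ensemble", shared_genes[k])
      v$consequence <- "MISSENSE"
      vus_slots[[p]] <- c(vus_slots[[p]], list(v))
    }
  }
  # 23 recurrent ensemble variants: carried by carriers i and i + 100
  recurrent <- lapply(seq_len(23L), function(i) {
    v <- new_vus_variant("ensemble", gpick(i * 5L))
    v$consequence <- "MISSENSE"
    v
  })
  for (i in seq_len(23L)) {
    vus_slots[[i]] <- c(vus_slots[[i]], list(recurrent[[i]]))
    vus_slots[[i + 100L]] <- c(vus_slots[[i + 100L]], list(recurrent[[i]]))
  }
  # remaining slots: singleton variants; the first 4 are ClinVar-LP with
  # limited evidence, the next 40 HGMD-DM, the rest pass the ensemble
  singleton_categories <- c(rep("lp", 4L), rep("dm", 40L),
                            rep("ensemble", 158L))
  sc <- 0L
  for (p in seq_len(197L)) {
    while (length(vus_slots[[p]]) < burden[p]) {
      sc <- sc + 1L
      v <- new_vus_variant(singleton_categories[sc], gpick(sc * 3L + 1L))
      vus_slots[[p]] <- c(vus_slots[[p]], list(v))
    }
  }
  stopifnot(sc == 202L)
  for (p in seq_len(197L)) {
    for (j in seq_along(vus_slots[[p]])) {
      zyg <- if (p == 160L && j == 1L) "HOM" else "HET"
      emit_vus(carriers[p], vus_slots[[p]][[j]], zygosity = zyg)
    }
  }
  # three LOF variants with a ClinVar VUS assertion, carried by
  # individuals already among the 197 VUS carriers
  for (i in seq_len(3L)) {
    fixture_add_new(env, carriers[149L + i], genes[100L + i], genes,
                    consequence = lof_seq[i], clinvar = "VUS",
                    cadd = 30, mcap = NA,
                    tools = fixture_tools(0L, missing = TRUE))
  }

  ## --- distractors: one violation per rule, all EXCLUDED ----------------
  dis <- function(s, gene, ...) fixture_add_new(env, s, gene, genes, ...)
  dis("S006", "BBS4", consequence = "MISSENSE", maf = 0.05,
      cadd = 30, mcap = 0.6, tools = fixture_tools(7L))        # common
  dis("S008", "BBS5", consequence = "MISSENSE", maf = 0.0011,
      cadd = 30, mcap = 0.6, tools = fixture_tools(7L))        # just common
  dis("S010", "BBS7", consequence = "MISSENSE", clinvar = "B",
      hgmd = "DM")                                             # benign override
  dis("S012", "BBS9", consequence = "MISSENSE", clinvar = "LB",
      cadd = 30, mcap = 0.6, tools = fixture_tools(7L))
  dis("S014", "BBS12", consequence = "MISSENSE", cadd = 30, mcap = 0.5,
      tools = fixture_tools(3L))                               # 3/7 votes
  dis("S016", "MKKS", consequence = "MISSENSE", cadd = 19, mcap = 0.9,
      tools = fixture_tools(7L))                               # CADD below 20
  dis("S018", "ARL6", consequence = "MISSENSE", cadd = 25, mcap = 0.01,
      tools = fixture_tools(7L))                               # M-CAP low
  dis("S020", "TTC8", consequence = "MISSENSE", cadd = NA, mcap = 0.5,
      tools = fixture_tools(7L))                               # CADD missing
  dis("S022", "INVS", consequence = "NONSENSE", clinvar = "CONFLICTING",
      cadd = NA, mcap = NA,
      tools = fixture_tools(0L, missing = TRUE))  # LOF, conflicting: not novel
  dis("S024", "NEK8", consequence = "MISSENSE", clinvar = "P",
      hgmd = "ABSENT", cadd = 18, mcap = 0.01,
      tools = fixture_tools(0L))                  # P without DM, no ensemble
  dis("S026", "GLIS2", consequence = "SYNONYMOUS", maf = 0.2,
      cadd = 2, mcap = NA, tools = fixture_tools(0L, missing = TRUE))
  dis("S028", "IQCB1", consequence = "MISSENSE", clinvar = "LP",
      clinvar_limited = FALSE, cadd = 18, mcap = 0.01,
      tools = fixture_tools(1L))                  # LP without limited flag
  dis("S030", "NPHP3", consequence = "MISSENSE", clinvar = "VUS",
      hgmd = "OTHER", cadd = 15, mcap = 0.01, tools = fixture_tools(2L))
  dis("S032", "NPHP4", consequence = "FRAMESHIFT", maf = 0.005,
      cadd = 30, mcap = NA,
      tools = fixture_tools(0L, missing = TRUE))  # common LOF
  dis("S034", "SDCCAG8", consequence = "MISSENSE", cadd = 20,
      mcap = 0.0249, tools = fixture_tools(4L))   # M-CAP just below cut-off

  calls <- validate_calls(do.call(rbind, env$rows[seq_len(env$n)]))

  ## --- pedigree and per-sample metrics ----------------------------------
  adults <- sprintf("S%03d", 1:395)
  children <- sprintf("K%03d", 1:177)
  fathers <- sprintf("S%03d", seq(1L, 353L, 2L))
  mothers <- sprintf("S%03d", seq(2L, 354L, 2L))
  consang <- c(rep(TRUE, 21L), rep(FALSE, 156L))
  individuals <- data.frame(
    sample_id = c(adults, children),
    sex = c(rep(c("1", "2"), 177L), rep("0", 41L), rep("0", 177L)),
    consanguineous = c(rep(consang, each = 2L), rep(FALSE, 41L),
                       rep(FALSE, 177L)),
    stringsAsFactors = FALSE)
  couples <- data.frame(father_id = fathers, mother_id = mothers,
                        consanguineous = consang, stringsAsFactors = FALSE)
  trios <- data.frame(father_id = fathers, mother_id = mothers,
                      child_id = children, stringsAsFactors = FALSE)
  ped <- pedigree_set(individuals, couples, trios)

  metrics <- data.frame(sample_id = adults, mean_coverage = 286.9,
                        fraction_exome_at_depth = 0.992,
                        stringsAsFactors = FALSE)

  list(calls = calls, pedigree = ped, metrics = metrics,
       sample_ids = adults, whitelist = wl)
}
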