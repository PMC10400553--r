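thr <- default_thresholds()

test_that("ensemble vote counts tools and applies the combined rule", {
  v <- ensemble_vote(make_call(cadd = 25, mcap = 0.03, votes = 4L), thr)
  expect_equal(v$vote_count, 4L)
  expect_true(v$passes)
  v <- ensemble_vote(make_call(cadd = 19.9, mcap = 0.9, votes = 7L), thr)
  expect_equal(v$vote_count, 7L)
  expect_false(v$passes)
  v <- ensemble_vote(make_call(cadd = 30, mcap = 0.5, votes = 3L), thr)
  expect_equal(v$vote_count, 3L)
  expect_false(v$passes)
  # boundary values are inclusive; missing scores cannot pass
  expect_true(ensemble_vote(make_call(cadd = 20, mcap = 0.025,
                                      votes = 4L), thr)$passes)
  expect_false(ensemble_vote(make_call(cadd = NA, mcap = 0.5,
                                       votes = 7L), thr)$passes)
  expect_false(ensemble_vote(make_call(cadd = 30, mcap = NA,
                                       votes = 7L), thr)$passes)
})

test_that("tier rules fire in order with an audit trail", {
  wl <- recurring_allele_whitelist()
  # whitelisted recurring allele stays pathogenic above the MAF cut-off
  bbs1 <- make_call(gene = "BBS1", chrom = "chr11", pos = 66278121L,
                    ref = "T", alt = "G", maf = 0.002,
                    clinvar = "CONFLICTING", hgmd = "DM")
  out <- classify_variant(bbs1, wl, thr)
  expect_equal(out$tier, "PATHOGENIC")
  expect_equal(out$fired_criteria, "WHITELIST")
  expect_true(out$reportable)
  # novel very rare LOF
  out <- classify_variant(make_call(consequence = "FRAMESHIFT",
                                    maf = 5e-4, tools_missing = TRUE,
                                    cadd = NA, mcap = NA), NULL, thr)
  expect_equal(out$tier, "NOVEL_LOF")
  expect_equal(out$fired_criteria, "PVS1,PM2")
  # a missing MAF counts as novel (very rare)
  out <- classify_variant(make_call(consequence = "NONSENSE", maf = NA,
                                    tools_missing = TRUE, cadd = NA,
                                    mcap = NA), NULL, thr)
  expect_equal(out$tier, "NOVEL_LOF")
  # ClinVar LP with limited information is a strong VUS, not reportable
  out <- classify_variant(make_call(clinvar = "LP",
                                    clinvar_limited = TRUE), NULL, thr)
  expect_equal(out$tier, "STRONG_VUS")
  expect_equal(out$fired_criteria, "CLINVAR_LP_LIMITED")
  expect_false(out$reportable)
  # common synonymous allele
  out <- classify_variant(make_call(consequence = "SYNONYMOUS",
                                    maf = 0.05), NULL, thr)
  expect_equal(out$tier, "EXCLUDED")
  # HGMD DM but ClinVar benign: the benign assertion wins
  out <- classify_variant(make_call(hgmd = "DM", clinvar = "B"), NULL, thr)
  expect_equal(out$tier, "EXCLUDED")
  expect_equal(out$fired_criteria, "BENIGN_DB")
  # ... unless the benign override is disabled
  thr2 <- default_thresholds(benign_override = FALSE)
  out <- classify_variant(make_call(hgmd = "DM", clinvar = "B"), NULL, thr2)
  expect_equal(out$tier, "STRONG_VUS")
  # LOF with a ClinVar VUS assertion
  out <- classify_variant(make_call(consequence = "NONSENSE",
                                    clinvar = "VUS", tools_missing = TRUE,
                                    cadd = NA, mcap = NA), NULL, thr)
  expect_equal(out$tier, "STRONG_VUS")
  expect_equal(out$fired_criteria, "CLINVAR_VUS_LOF")
  # conflicting ClinVar does not make a LOF variant novel
  out <- classify_variant(make_call(consequence = "NONSENSE",
                                    clinvar = "CONFLICTING",
                                    tools_missing = TRUE, cadd = NA,
                                    mcap = NA), NULL, thr)
  expect_equal(out$tier, "EXCLUDED")
})

test_that("tiers partition post-QC calls with a consistent audit trail", {
  calls <- random_calls(2000L, seed = 31L)
  out <- classify_calls(calls, recurring_allele_whitelist(), thr)
  expect_equal(nrow(out), nrow(calls))
  expect_true(all(out$tier %in% TIER_LEVELS))
  expect_equal(out$reportable, out$tier %in% c("PATHOGENIC", "NOVEL_LOF"))
  expect_true(all(out$fired_criteria != "" | out$tier == "EXCLUDED"))
  cc <- classify_cohort(calls, NULL, thr)
  expect_equal(sum(cc$counts$n), nrow(calls))
  expect_equal(cc$counts$n, cc$counts$n_lof + cc$counts$n_other)
})

test_that("classification agrees with an unordered brute-force oracle", {
  calls <- random_calls(5000L, seed = 33L)
  wl <- recurring_allele_whitelist()
  got <- classify_calls(calls, wl, thr)$tier
  want <- oracle_classify(calls, wl, thr)
  expect_equal(got, want)
})

test_that("rarer is never worse and extra votes never exclude a VUS", {
  rank <- c(EXCLUDED = 0L, STRONG_VUS = 1L, NOVEL_LOF = 2L,
            PATHOGENIC = 2L)
  calls <- random_calls(600L, seed = 35L)
  base <- classify_calls(calls, NULL, thr)$tier
  lowered <- calls
  lowered$maf <- ifelse(is.na(calls$maf), NA, calls$maf / 100)
  low <- classify_calls(lowered, NULL, thr)$tier
  expect_true(all(rank[low] >= rank[base]))
  # flipping one tool to DELETERIOUS never demotes a strong VUS
  flipped <- calls
  flipped$sift <- "DELETERIOUS"
  flip <- classify_calls(flipped, NULL, thr)$tier
  was_vus <- base == "STRONG_VUS"
  expect_true(all(flip[was_vus] != "EXCLUDED"))
})

test_that("whitelist entries classify pathogenic at any MAF", {
  wl <- recurring_allele_whitelist()
  for (maf in c(0, 0.001, 0.01, 0.3, 1)) {
    call <- make_call(gene = "KIAA0586", chrom = "chr14", pos = 58899550L,
                      ref = "AG", alt = "A", consequence = "FRAMESHIFT",
                      maf = maf, clinvar = "B")
    expect_equal(classify_variant(call, wl, thr)$tier, "PATHOGENIC")
  }
})
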