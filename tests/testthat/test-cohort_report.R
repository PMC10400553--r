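tiered_demo <- function() {
  calls <- rbind(
    make_call(sample_id = "F1", gene = "DYNC2H1", pos = 1L, clinvar = "P",
              hgmd = "DM"),
    make_call(sample_id = "M1", gene = "DYNC2H1", pos = 2L, clinvar = "P",
              hgmd = "DM"),
    make_call(sample_id = "F2", gene = "CEP290", pos = 3L,
              consequence = "NONSENSE", clinvar = "P",
              tools_missing = TRUE, cadd = NA, mcap = NA),
    make_call(sample_id = "M2", gene = "BBS1", pos = 4L, clinvar = "P",
              hgmd = "DM"),
    make_call(sample_id = "F3", gene = "USH2A", pos = 5L, clinvar = "VUS"),
    make_call(sample_id = "M3", gene = "USH2A", pos = 6L, clinvar = "VUS"))
  classify_calls(calls, NULL, default_thresholds())
}

demo_ped <- function() {
  ids <- c("F1", "M1", "F2", "M2", "F3", "M3", "K1", "K2", "K3")
  pedigree_set(
    data.frame(sample_id = ids, stringsAsFactors = FALSE),
    couples = data.frame(father_id = c("F1", "F2", "F3"),
                         mother_id = c("M1", "M2", "M3"),
                         consanguineous = c(TRUE, FALSE, FALSE),
                         stringsAsFactors = FALSE),
    trios = data.frame(father_id = c("F1", "F2", "F3"),
                       mother_id = c("M1", "M2", "M3"),
                       child_id = c("K1", "K2", "K3"),
                       stringsAsFactors = FALSE))
}

test_that("carrier frequency counts individuals, not observations", {
  tiered <- tiered_demo()
  ids <- c("F1", "M1", "F2", "M2", "F3", "M3")
  cf <- carrier_frequency(tiered, ids, "pathogenic")
  expect_equal(cf$n_carriers, 4L)
  expect_equal(cf$frequency, 4 / 6)
  expect_lte(cf$frequency,
             carrier_frequency(tiered, ids, "reportable")$frequency)
  none <- carrier_frequency(tiered[0, ], ids, "pathogenic")
  expect_equal(none$frequency, 0)
  expect_true(is.na(carrier_frequency(tiered, character(0),
                                      "vus")$frequency))
})

test_that("phase is called from child transmission", {
  expect_equal(infer_phase("P", "G", c("k1", "k2"),
                           c(TRUE, TRUE))$phase, "CIS")
  expect_equal(infer_phase("P", "G", c("k1", "k2"),
                           c(FALSE, FALSE))$phase, "CIS")
  expect_equal(infer_phase("P", "G", c("k1", "k2"),
                           c(TRUE, FALSE))$phase, "TRANS")
  expect_equal(infer_phase("P", "G", c("k1", "k2"),
                           c(TRUE, NA))$phase, "UNINFORMATIVE")
})

test_that("phasing recovers planted haplotype configurations on trios", {
  sim <- generate_cohort(cohort_sim_params(n_individuals = 200L,
                                           n_couples = 100L,
                                           n_trios = 100L, seed = 19L))
  ph <- phase_cohort(sim$calls, sim$pedigree, sim$child_genotypes)
  informative <- ph[ph$phase != "UNINFORMATIVE", ]
  expect_gt(nrow(informative), 0L)
  hap <- sim$haplotypes
  zyg <- stats::setNames(sim$calls$zygosity,
                         paste(sim$calls$sample_id, sim$calls$variant_key))
  checked <- 0L
  for (i in seq_len(nrow(informative))) {
    r <- informative[i, ]
    # homozygous variants are always transmitted; the cis/trans call then
    # reflects the haplotype only for het-het pairs
    if (zyg[paste(r$sample_id, r$variant_key_1)] != "HET" ||
        zyg[paste(r$sample_id, r$variant_key_2)] != "HET") next
    h1 <- hap$haplotype[hap$sample_id == r$sample_id &
                          hap$variant_key == r$variant_key_1]
    h2 <- hap$haplotype[hap$sample_id == r$sample_id &
                          hap$variant_key == r$variant_key_2]
    expect_equal(r$phase, if (h1[1L] == h2[1L]) "CIS" else "TRANS")
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("couples at risk require both partners hit in one gene", {
  tiered <- tiered_demo()
  ped <- demo_ped()
  risk <- couples_at_risk(ped, tiered, "pathogenic")
  expect_equal(risk$n_at_risk, 1L)
  expect_equal(risk$couples$shared_genes, "DYNC2H1")
  expect_equal(risk$n_at_risk_consanguineous, 1L)
  # partners carrying different genes are not at risk
  expect_false("F2" %in% risk$couples$father_id)
  # VUS tier set picks up the USH2A couple
  riskv <- couples_at_risk(ped, tiered, "vus")
  expect_equal(riskv$n_at_risk, 1L)
  expect_equal(riskv$couples$father_id, "F3")
  # invariant under partner order
  ped2 <- ped
  ped2$couples <- data.frame(father_id = ped$couples$mother_id,
                             mother_id = ped$couples$father_id,
                             consanguineous = ped$couples$consanguineous,
                             stringsAsFactors = FALSE)
  risk2 <- couples_at_risk(ped2, tiered, "pathogenic")
  expect_equal(risk2$n_at_risk, risk$n_at_risk)
})

test_that("recurrence collapses observations to unique variants", {
  calls <- rbind(
    make_call(sample_id = "A", pos = 1L, clinvar = "VUS"),
    make_call(sample_id = "B", pos = 1L, clinvar = "VUS"),
    make_call(sample_id = "C", pos = 1L, clinvar = "VUS"),
    make_call(sample_id = "A", pos = 2L, clinvar = "VUS"),
    make_call(sample_id = "B", pos = 3L, clinvar = "VUS"))
  tiered <- classify_calls(calls, NULL, default_thresholds())
  r <- recurrence_and_unique(tiered, "vus")
  expect_equal(r$n_observations, 5L)
  expect_equal(r$n_unique, 3L)
  expect_equal(nrow(r$recurrence), 1L)
  expect_equal(r$recurrence$n_carriers, 3L)
  # all singletons: empty recurrence table
  singles <- classify_calls(
    do.call(rbind, lapply(1:10, function(i)
      make_call(sample_id = sprintf("S%d", i), pos = i, clinvar = "VUS"))),
    NULL, default_thresholds())
  rs <- recurrence_and_unique(singles, "vus")
  expect_equal(rs$n_observations, 10L)
  expect_equal(rs$n_unique, 10L)
  expect_equal(nrow(rs$recurrence), 0L)
})

test_that("burden statistics use half-up display rounding", {
  calls <- do.call(rbind, lapply(1:4, function(i)
    make_call(sample_id = "X", pos = i)))
  calls <- rbind(calls, make_call(sample_id = "Y", pos = 5L),
                 do.call(rbind, lapply(6:10, function(i)
                   make_call(sample_id = "Z", pos = i))))
  b <- burden_stats(calls, c("X", "Y", "Z", "W"))
  expect_equal(b$mean, 10 / 4)
  expect_equal(b$mean_display, 2.5)
  expect_equal(b$min, 0L)
  expect_equal(b$max, 5L)
  b2 <- burden_stats(do.call(rbind, lapply(1:9, function(i)
    make_call(sample_id = sprintf("S%d", (i - 1L) %% 3L + 1L), pos = i))),
    c("S1", "S2", "S3"))
  expect_equal(b2$mean_display, 3)
  expect_equal(b2$min, 3L)
  expect_equal(b2$max, 3L)
  # half-up, not banker's rounding
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(7.375, 2), 7.38)
})

test_that("Hardy-Weinberg expectation matches exhaustive enumeration", {
  expect_equal(expected_carrier_frequency(0), 0)
  expect_equal(expected_carrier_frequency(1e-4), 0.0198)
  expect_equal(expected_carrier_frequency(1e-5), 0.006304555320336759,
               tolerance = 1e-12)
  # enumeration oracle: genotype frequencies of a biallelic locus
  enumerate_carrier_fraction <- function(K) {
    q <- sqrt(K)
    p <- 1 - q
    geno <- c(AA = p * p, Aa = p * q, aA = q * p, aa = q * q)
    sum(geno[c("Aa", "aA")])
  }
  ks <- c(1e-6, 1e-5, 1e-4, 1e-3, 0.01, 0.04, 0.2)
  for (K in ks) {
    expect_lt(abs(expected_carrier_frequency(K) -
                    enumerate_carrier_fraction(K)), 1e-9)
  }
  # monotone increasing on [0, 0.25]
  grid <- expected_carrier_frequency(seq(0, 0.25, length.out = 200L))
  expect_true(all(diff(grid) > 0))
  expect_error(expected_carrier_frequency(1.1), "prevalence")
})

test_that("the assembled report cross-checks against a brute-force recount", {
  fx <- generate_table1_fixture()
  tiered <- classify_cohort(fx$calls, fx$whitelist)$calls
  rep <- build_report(tiered, fx$pedigree, fx$sample_ids,
                      panel = ciliopathy_panel())
  # independent recount straight off the tiered table
  for (tl in TIER_LEVELS) {
    expect_equal(rep$tier_counts$n[rep$tier_counts$tier == tl],
                 sum(tiered$tier == tl))
  }
  expect_equal(rep$carrier$reportable$n_carriers,
               length(unique(tiered$sample_id[tiered$reportable])))
  expect_equal(rep$burden$high_confidence$mean, nrow(tiered) / 395)
  # per-gene observed vs expected uses the panel prevalence
  pg <- rep$per_gene
  dync <- pg[pg$gene == "DYNC2H1", ]
  expect_equal(dync$expected_carrier_frequency,
               expected_carrier_frequency(1e-5))
  expect_gt(dync$obs_over_expected, 1)
  # sample-set consistency is enforced
  expect_error(build_report(tiered, fx$pedigree,
                            fx$sample_ids[1:10]), "outside")
})
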