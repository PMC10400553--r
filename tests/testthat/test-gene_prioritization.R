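mini_panel <- function(m, M) {
  data.frame(gene = sprintf("G%d", seq_along(m)), n_missense_plp = m,
             n_total_plp = M, stringsAsFactors = FALSE)
}

test_that("missense score is m/M with degenerate genes flagged", {
  gs <- missense_score(mini_panel(c(0L, 5L, 0L), c(10L, 10L, 0L)))
  expect_equal(gs$ms_score, c(0, 0.5, NA))
  expect_equal(gs$note, c(NA, NA, "NO_PLP_DATA"))
  expect_error(missense_score(mini_panel(11L, 10L)), "exceed")
})

test_that("structural score categories use strict cut-offs", {
  expect_equal(vipur_category(c(0.71, 0.60, 0.50, NA, 0.7, 0, 1)),
               c("STRONG_DELETERIOUS", "DELETERIOUS", "NEUTRAL",
                 "UNSCORED", "DELETERIOUS", "NEUTRAL",
                 "STRONG_DELETERIOUS"))
  expect_error(vipur_category(1.2), "vipur")
})

test_that("first-priority VUS require both gene and structural evidence", {
  gs <- missense_score(mini_panel(c(2L, 0L, 0L), c(10L, 10L, 0L)))
  vus <- rbind(
    make_call(gene = "G1", pos = 1L, clinvar = "VUS", vipur = 0.8),
    make_call(gene = "G1", pos = 2L, clinvar = "VUS", vipur = 0.6),
    make_call(gene = "G2", pos = 3L, clinvar = "VUS", vipur = 0.9),
    make_call(gene = "G3", pos = 4L, clinvar = "VUS", vipur = 0.95),
    make_call(gene = "G1", pos = 5L, clinvar = "VUS", vipur = NA))
  vus <- classify_calls(vus, NULL, default_thresholds())
  expect_true(all(vus$tier == "STRONG_VUS"))
  pr <- prioritize(vus, gs)
  expect_equal(pr$first_priority,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # G1: ms 0.2 and vipur 0.8 qualifies; G2: ms 0 fails; G3: undefined ms
  expect_equal(pr$variant_key[1L], "chr12:1:C:T")
  # unscored structural data cannot qualify
  expect_equal(pr$vipur_category[pr$variant_key == "chr12:5:C:T"],
               "UNSCORED")
  expect_error(prioritize(make_call(clinvar = "P", hgmd = "DM") |>
                            classify_calls(NULL, default_thresholds()),
                          gs), "STRONG_VUS")
})

test_that("priority set is monotone in the missense-score cut-off", {
  fx <- generate_table1_fixture()
  tiered <- classify_cohort(fx$calls, fx$whitelist)$calls
  vus <- tiered[tiered$tier == "STRONG_VUS", ]
  gs <- missense_score(ciliopathy_panel())
  strict <- prioritize(vus, gs, default_thresholds(ms_min = 0.3))
  loose <- prioritize(vus, gs, default_thresholds(ms_min = 0.05))
  expect_true(all(strict$variant_key[strict$first_priority] %in%
                    loose$variant_key[loose$first_priority]))
  # first-priority is a subset of strongly-deleterious in qualifying genes
  pr <- prioritize(vus, gs)
  fp <- pr[pr$first_priority, ]
  expect_true(all(fp$vipur_category == "STRONG_DELETERIOUS"))
  expect_true(all(fp$ms_score > 0.1))
  # sorting is a deterministic total order
  pr2 <- prioritize(vus[sample.int(nrow(vus)), ], gs)
  expect_equal(pr$variant_key, pr2$variant_key)
})

test_that("spectrum divergence contrasts cohort and patient variant types", {
  panel <- data.frame(gene = c("CEP290", "INPP5E", "TMEM67"),
                      n_missense_plp = 1L, n_total_plp = 10L,
                      spectrum_truncating = c(1.0, 0.5, 0.5),
                      spectrum_missense = c(0.0, 0.5, 0.5),
                      stringsAsFactors = FALSE)
  calls <- rbind(
    make_call(gene = "CEP290", pos = 1L, clinvar = "VUS"),
    make_call(gene = "CEP290", pos = 2L, clinvar = "VUS"),
    make_call(gene = "INPP5E", pos = 3L, clinvar = "VUS"),
    make_call(gene = "INPP5E", pos = 4L, consequence = "NONSENSE",
              clinvar = "VUS", tools_missing = TRUE, cadd = NA, mcap = NA),
    make_call(gene = "TMEM67", pos = 5L, clinvar = "VUS"),
    make_call(gene = "TMEM67", pos = 6L, clinvar = "VUS"),
    make_call(gene = "TMEM67", pos = 7L, clinvar = "VUS"),
    make_call(gene = "TMEM67", pos = 8L, clinvar = "VUS"),
    make_call(gene = "TMEM67", pos = 9L, clinvar = "VUS"),
    make_call(gene = "TMEM67", pos = 10L, clinvar = "VUS"),
    make_call(gene = "TMEM67", pos = 11L, consequence = "FRAMESHIFT",
              clinvar = "VUS", tools_missing = TRUE, cadd = NA, mcap = NA),
    make_call(gene = "TMEM67", pos = 12L, consequence = "FRAMESHIFT",
              clinvar = "VUS", tools_missing = TRUE, cadd = NA, mcap = NA),
    make_call(gene = "TMEM67", pos = 13L, consequence = "NONSENSE",
              clinvar = "VUS", tools_missing = TRUE, cadd = NA, mcap = NA),
    make_call(gene = "TMEM67", pos = 14L, consequence = "CANONICAL_SPLICE",
              clinvar = "VUS", tools_missing = TRUE, cadd = NA, mcap = NA))
  tiered <- classify_calls(calls, NULL, default_thresholds())
  sp <- spectrum_comparison(tiered, panel)
  # healthy cohort all missense vs patients all truncating: divergence 1
  expect_equal(sp$divergence[sp$gene == "CEP290"], 1.0)
  # identical spectra: divergence 0
  expect_equal(sp$divergence[sp$gene == "INPP5E"], 0.0)
  # 6 missense + 4 truncating vs 50/50 patients: divergence 0.1
  expect_equal(sp$divergence[sp$gene == "TMEM67"], 0.1)
  # genes without cohort variants are omitted
  expect_setequal(sp$gene, c("CEP290", "INPP5E", "TMEM67"))
})
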