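test_that("TSV variant tables round-trip through write and read", {
  calls <- rbind(make_call(sample_id = "A", pos = 1L),
                 make_call(sample_id = "B", pos = 2L, maf = NA,
                           cadd = NA, tools_missing = TRUE),
                 make_call(sample_id = "C", pos = 3L, clinvar = "P",
                           hgmd = "DM", vipur = 0.8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, path)
  back <- read_variant_table(path, "tsv")
  expect_equal(nrow(back), 3L)
  expect_equal(back$sample_id, calls$sample_id)
  expect_equal(back$maf, calls$maf)
  expect_equal(back$vipur, calls$vipur)
  expect_equal(back$sift, calls$sift)
  expect_equal(back$variant_key, calls$variant_key)
})

test_that("validation rejects out-of-range and malformed input", {
  expect_error(make_call(maf = 1.7), "maf")
  expect_error(make_call(alt_fraction = -0.1), "alt_fraction")
  expect_error(make_call(consequence = "STOPGAIN"), "consequence")
  calls <- make_call()
  calls$maf <- NULL
  expect_error(validate_calls(calls), "maf")
})

test_that("multi-allelic VCF records split into one call per alt allele", {
  skip_if_not_installed("vcfR")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=AF_G,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    paste0("chr1\t100\t.\tA\tG,T\t50\tPASS\t",
           "GENE=CEP290;CSQ=MISSENSE;AF_G=0.0005,0.002\tGT:DP:AD\t",
           "0/1:60:40,20,0\t1/2:80:10,30,40"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  km <- list(gene = "GENE", consequence = "CSQ", maf = "AF_G")
  calls <- read_variant_table(path, "vcf", key_map = km)
  # hand decomposition: S1 carries alt1 only; S2 carries alt1 and alt2
  expect_equal(nrow(calls), 3L)
  s1 <- calls[calls$sample_id == "S1", ]
  expect_equal(s1$alt, "G")
  expect_equal(s1$maf, 0.0005)
  expect_equal(s1$alt_fraction, 20 / 60)
  s2 <- calls[calls$sample_id == "S2", ]
  expect_setequal(s2$alt, c("G", "T"))
  expect_equal(s2$maf[s2$alt == "T"], 0.002)
  expect_equal(s2$alt_fraction[s2$alt == "T"], 40 / 80)
  expect_true(all(calls$gene == "CEP290"))
})

test_that("pedigree parsing derives couples and trios from PED rows", {
  ped_lines <- c("F1\tDAD\t0\t0\t1\t0\t0",
                 "F1\tMUM\t0\t0\t2\t0\t1",
                 "F1\tKID\tDAD\tMUM\t1\t0\t0",
                 "F2\tSOLO\t0\t0\t2\t0\t0",
                 "F2\tKID2\t0\tSOLO\t1\t0\t0")
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(ped_lines, path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped$couples), 1L)
  expect_equal(nrow(ped$trios), 1L)
  expect_true(ped$couples$consanguineous[1L])  # MUM is flagged
  bad <- c("F1\tKID\tGHOST\tMUM\t1\t0", "F1\tMUM\t0\t0\t2\t0")
  writeLines(bad, path)
  expect_error(read_pedigree(path), "unknown")
})

test_that("the fixture pedigree round-trips with 177 couples, 21 consanguineous", {
  fx <- generate_table1_fixture()
  path <- withr::local_tempfile(fileext = ".ped")
  write_pedigree(fx$pedigree, path)
  ped <- read_pedigree(path)
  expect_equal(nrow(ped$couples), 177L)
  expect_equal(sum(ped$couples$consanguineous), 21L)
  expect_equal(nrow(ped$trios), 177L)
})

test_that("cohort reports round-trip through JSON", {
  fx <- generate_table1_fixture()
  tiered <- classify_cohort(fx$calls, fx$whitelist)$calls
  rep1 <- build_report(tiered, fx$pedigree, fx$sample_ids)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep1, path, "json")
  rep2 <- read_report(path)
  expect_equal(rep2$n_individuals, rep1$n_individuals)
  expect_equal(rep2$tier_counts$n, rep1$tier_counts$n)
  for (s in names(rep1$carrier)) {
    expect_equal(rep2$carrier[[s]]$n_carriers, rep1$carrier[[s]]$n_carriers)
    expect_equal(rep2$carrier[[s]]$frequency, rep1$carrier[[s]]$frequency)
    expect_equal(rep2$couples[[s]]$n_at_risk, rep1$couples[[s]]$n_at_risk)
    expect_equal(rep2$couples[[s]]$fraction, rep1$couples[[s]]$fraction)
  }
  expect_equal(rep2$recurrence_vus$n_unique, rep1$recurrence_vus$n_unique)
  expect_equal(rep2$burden$vus$mean, rep1$burden$vus$mean)
})

test_that("an empty cohort yields a valid all-zero report", {
  calls <- classify_cohort(empty_call_table())$calls
  ped <- pedigree_set(data.frame(sample_id = c("A", "B"),
                                 stringsAsFactors = FALSE))
  rep0 <- build_report(calls, ped)
  expect_equal(sum(rep0$tier_counts$n), 0L)
  expect_equal(rep0$carrier$pathogenic$n_carriers, 0L)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep0, path, "json")
  rep0b <- read_report(path)
  expect_equal(sum(rep0b$tier_counts$n), 0L)
})
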