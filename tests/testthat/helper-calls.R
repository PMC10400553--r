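# Programmatic call-table builders shared across the suite.

make_call <- function(sample_id = "S1", gene = "CEP290", chrom = "chr12",
                      pos = 1000L, ref = "C", alt = "T",
                      consequence = "MISSENSE", maf = 5e-4, cadd = 26,
                      mcap = 0.4, votes = 5L, tools_missing = FALSE,
                      clinvar = "ABSENT", clinvar_limited = FALSE,
                      hgmd = "ABSENT", vipur = NA_real_, depth = 100L,
                      alt_fraction = 0.5, zygosity = "HET") {
  tools <- if (tools_missing) rep("MISSING", 7L) else
    c(rep("DELETERIOUS", votes), rep("TOLERATED", 7L - votes))
  df <- data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
                   pos = pos, ref = ref, alt = alt,
                   consequence = consequence, maf = maf, cadd = cadd,
                   mcap = mcap, stringsAsFactors = FALSE)
  tl <- as.list(tools)
  names(tl) <- c("sift", "polyphen2", "lrt", "mutationassessor",
                 "mutationtaster", "fathmm", "provean")
  df <- cbind(df, as.data.frame(tl, stringsAsFactors = FALSE))
  df$clinvar <- clinvar
  df$clinvar_limited <- clinvar_limited
  df$hgmd <- hgmd
  df$vipur <- vipur
  df$depth <- depth
  df$alt_fraction <- alt_fraction
  df$zygosity <- zygosity
  validate_calls(df)
}

# randomized call tables spanning every vocabulary level and missingness
# pattern, for property-style tests
random_calls <- function(n, seed = 1L) {
  set.seed(seed)
  maybe_na <- function(x, p = 0.2) {
    x[stats::runif(length(x)) < p] <- NA
    x
  }
  df <- data.frame(
    sample_id = sprintf("S%d", sample.int(50L, n, replace = TRUE)),
    gene = sample(c("CEP290", "BBS1", "USH2A", "INPP5E", "KIF7"), n,
                  replace = TRUE),
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "G",
    consequence = sample(CONSEQUENCE_LEVELS, n, replace = TRUE),
    maf = maybe_na(stats::runif(n)^4, 0.25),
    cadd = maybe_na(stats::runif(n, 0, 45), 0.2),
    mcap = maybe_na(stats::runif(n), 0.2),
    stringsAsFactors = FALSE)
  for (tc in c("sift", "polyphen2", "lrt", "mutationassessor",
               "mutationtaster", "fathmm", "provean")) {
    df[[tc]] <- sample(c("DELETERIOUS", "TOLERATED", "MISSING"), n,
                       replace = TRUE)
  }
  df$clinvar <- sample(CLINVAR_LEVELS, n, replace = TRUE)
  df$clinvar_limited <- sample(c(TRUE, FALSE), n, replace = TRUE)
  df$hgmd <- sample(HGMD_LEVELS, n, replace = TRUE)
  df$vipur <- maybe_na(stats::runif(n), 0.3)
  df$depth <- sample.int(400L, n, replace = TRUE)
  df$alt_fraction <- stats::runif(n)
  df$zygosity <- sample(c("HET", "HOM"), n, replace = TRUE,
                        prob = c(0.95, 0.05))
  validate_calls(df)
}
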