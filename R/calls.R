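#' Annotated variant call table schema
#'
#' An annotated call table is a plain `data.frame`, one row per
#' sample x variant observation, with the columns listed below. It is the
#' central container every pipeline stage consumes.
#'
#' Mandatory columns:
#' * `sample_id` — opaque sample identifier.
#' * `gene` — gene symbol from the screening panel.
#' * `chrom`, `pos`, `ref`, `alt` — 1-based VCF-style coordinates; the
#'   derived `variant_key` is `chrom:pos:ref:alt`.
#' * `consequence` — one of [CONSEQUENCE_LEVELS].
#' * `maf` — gnomAD minor allele frequency in \[0, 1\]; `NA` means the
#'   allele is unobserved in gnomAD and is treated as 0 (novel) by the
#'   rarity rule.
#' * `cadd` — CADD phred-like score (>= 0, `NA` allowed).
#' * `mcap` — M-CAP score in \[0, 1\] (`NA` allowed).
#' * `sift`, `polyphen2`, `lrt`, `mutationassessor`, `mutationtaster`,
#'   `fathmm`, `provean` — categorical predictor calls, each one of
#'   `DELETERIOUS`, `TOLERATED`, `MISSING`.
#' * `clinvar` — one of [CLINVAR_LEVELS]; `clinvar_limited` — logical,
#'   `TRUE` when the assertion comes with limited supporting information.
#' * `hgmd` — one of [HGMD_LEVELS].
#' * `vipur` — structure-based deleteriousness score in \[0, 1\]
#'   (`NA` = no structural coverage).
#' * `depth` — read depth at the site (integer >= 0).
#' * `alt_fraction` — alternate-read fraction in \[0, 1\].
#' * `zygosity` — `HET` or `HOM`.
#'
#' Optional columns `hgvs` (transcript-level HGVS string), `strand_balance`
#' and `mean_base_quality` (call-quality proxies) are carried through when
#' present.
#'
#' @name call-table
NULL

call_table_columns <- function() {
  c("sample_id", "gene", "chrom", "pos", "ref", "alt", "consequence",
    "maf", "cadd", "mcap", tool_columns(), "clinvar", "clinvar_limited",
    "hgmd", "vipur", "depth", "alt_fraction", "zygosity")
}

#' Build the canonical variant key
#'
#' @param chrom,pos,ref,alt Vectors of equal length; `pos` is the 1-based
#'   position matching VCF POS. Indels are expected left-aligned upstream.
#' @return Character vector `chrom:pos:ref:alt`.
#' @examples
#' variant_key("chr12", 76740878, "A", "C")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

range_check <- function(x, field, lo, hi, rows_offset = 0L) {
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    stop(sprintf("field '%s' out of range [%g, %g] at row %d (value %g)",
                 field, lo, hi, bad[1L] + rows_offset, x[bad[1L]]),
         call. = FALSE)
  }
}

level_check <- function(x, field, levels) {
  bad <- which(!x %in% levels)
  if (length(bad)) {
    stop(sprintf("field '%s' has invalid value '%s' at row %d",
                 field, x[bad[1L]], bad[1L]), call. = FALSE)
  }
}

#' Validate an annotated call table
#'
#' Checks the column set, controlled vocabularies and numeric ranges, adds
#' the derived `variant_key` column and coerces types. Fails with an error
#' naming the offending column or row; no row is ever silently dropped.
#'
#' @param calls A data.frame following the [call-table] schema.
#' @return The validated data.frame with a `variant_key` column.
#' @export
validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing_cols <- setdiff(call_table_columns(), names(calls))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  calls$pos <- as.integer(calls$pos)
  calls$depth <- as.integer(calls$depth)
  for (f in c("maf", "cadd", "mcap", "vipur", "alt_fraction")) {
    calls[[f]] <- as.numeric(calls[[f]])
  }
  calls$clinvar_limited <- as.logical(calls$clinvar_limited)
  calls$clinvar_limited[is.na(calls$clinvar_limited)] <- FALSE

  range_check(calls$maf, "maf", 0, 1)
  range_check(calls$mcap, "mcap", 0, 1)
  range_check(calls$vipur, "vipur", 0, 1)
  range_check(calls$alt_fraction, "alt_fraction", 0, 1)
  if (any(!is.na(calls$cadd) & calls$cadd < 0)) {
    stop("field 'cadd' must be >= 0", call. = FALSE)
  }
  if (any(is.na(calls$depth) | calls$depth < 0)) {
    stop("field 'depth' must be a non-negative integer", call. = FALSE)
  }
  level_check(calls$consequence, "consequence", CONSEQUENCE_LEVELS)
  level_check(calls$clinvar, "clinvar", CLINVAR_LEVELS)
  level_check(calls$hgmd, "hgmd", HGMD_LEVELS)
  level_check(calls$zygosity, "zygosity", c("HET", "HOM"))
  for (tc in tool_columns()) {
    x <- calls[[tc]]
    x[is.na(x) | x == ""] <- "MISSING"
    level_check(x, tc, TOOL_CALL_LEVELS)
    calls[[tc]] <- x
  }
  calls$variant_key <- variant_key(calls$chrom, calls$pos, calls$ref,
                                   calls$alt)
  rownames(calls) <- NULL
  calls
}

is_lof <- function(consequence) consequence %in% LOF_CONSEQUENCES

#' Read an annotated variant call table
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (the native tab-separated format, header row,
#'   empty cells for missing values) or `"vcf"` (a VCF whose INFO/FORMAT
#'   keys are mapped to call-table fields through `key_map`; requires the
#'   vcfR package). Multi-allelic VCF records are split into one call per
#'   alternate allele.
#' @param key_map For the VCF dialect: a named list (or path to a YAML
#'   file) mapping call-table fields to INFO keys, e.g.
#'   `list(gene = "GENE", maf = "GNOMAD_AF", ...)`. Depth and alternate
#'   fraction are taken from the per-sample FORMAT fields `DP` and `AD`.
#' @return A validated call table (see [call-table]).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               key_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") {
    raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             na.strings = c("", "NA"), colClasses = "character")
    validate_calls(raw)
  } else {
    read_variant_vcf(path, key_map)
  }
}

read_variant_vcf <- function(path, key_map) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("the 'vcfR' package is required for the VCF dialect", call. = FALSE)
  }
  if (is.character(key_map) && length(key_map) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read a key-map file",
           call. = FALSE)
    }
    key_map <- yaml::read_yaml(key_map)
  }
  if (is.null(key_map)) key_map <- list()
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info_get <- function(key) vcfR::extract.info(v, element = key)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  samples <- colnames(gt)

  field_or <- function(field, default) {
    key <- key_map[[field]]
    if (is.null(key)) rep(default, nrow(fix)) else info_get(key)
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    for (ai in seq_along(alts)) {
      for (s in samples) {
        g <- gt[i, s]
        if (is.na(g)) next
        alleles <- strsplit(g, "[/|]")[[1L]]
        n_alt <- sum(alleles == as.character(ai))
        if (n_alt == 0L) next
        ad_i <- if (is.null(ad)) NA_character_ else ad[i, s]
        ad_counts <- if (is.na(ad_i)) NA else
          suppressWarnings(as.numeric(strsplit(ad_i, ",")[[1L]]))
        depth_s <- if (!all(is.na(ad_counts))) sum(ad_counts, na.rm = TRUE)
                   else dp[i, s]
        altf <- if (!all(is.na(ad_counts)) && depth_s > 0)
          ad_counts[ai + 1L] / depth_s else NA_real_
        grab <- function(field, default) {
          val <- field_or(field, default)[i]
          # comma-separated per-alt INFO values follow VCF Number=A
          if (!is.null(key_map[[field]]) && grepl(",", val %||% "")) {
            strsplit(val, ",")[[1L]][ai]
          } else val
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, gene = grab("gene", NA_character_),
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[ai],
          consequence = grab("consequence", "OTHER"),
          maf = as.numeric(grab("maf", NA)),
          cadd = as.numeric(grab("cadd", NA)),
          mcap = as.numeric(grab("mcap", NA)),
          stringsAsFactors = FALSE)
        tool_vals <- lapply(tool_columns(), function(tc)
          grab(tc, "MISSING") %||% "MISSING")
        names(tool_vals) <- tool_columns()
        n <- length(rows)
        rows[[n]] <- cbind(rows[[n]], as.data.frame(tool_vals,
                                                    stringsAsFactors = FALSE))
        rows[[n]]$clinvar <- grab("clinvar", "ABSENT")
        rows[[n]]$clinvar_limited <-
          as.logical(grab("clinvar_limited", FALSE))
        rows[[n]]$hgmd <- grab("hgmd", "ABSENT")
        rows[[n]]$vipur <- as.numeric(grab("vipur", NA))
        rows[[n]]$depth <- as.integer(round(depth_s))
        rows[[n]]$alt_fraction <- altf
        rows[[n]]$zygosity <- if (n_alt >= 2L) "HOM" else "HET"
      }
    }
  }
  if (!length(rows)) {
    return(validate_calls(empty_call_table()))
  }
  validate_calls(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' An empty call table with the full schema
#' @return A zero-row data.frame with all mandatory columns.
#' @export
empty_call_table <- function() {
  cols <- call_table_columns()
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df$pos <- integer(0); df$depth <- integer(0)
  for (f in c("maf", "cadd", "mcap", "vipur", "alt_fraction"))
    df[[f]] <- numeric(0)
  df$clinvar_limited <- logical(0)
  validate_calls(df)
}

#' Write an annotated call table as TSV
#'
#' @param calls A validated call table.
#' @param path Output path. Missing values become empty cells.
#' @export
write_variant_table <- function(calls, path) {
  out <- calls[, intersect(c(call_table_columns(), "hgvs"), names(calls))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a pathogenic-variant whitelist
#'
#' Known recurring disease alleles whose population frequency exceeds the
#' rarity cut-off (e.g. *BBS1* p.M309R, *KIAA0586* c.428delG) are kept
#' pathogenic through an explicit whitelist. TSV columns: `gene`,
#' `variant_key`, optional `hgvs`, optional `rationale`.
#'
#' @param path TSV file path.
#' @return A data.frame with class `ecs_whitelist`.
#' @export
read_whitelist <- function(path) {
  wl <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  as_whitelist(wl)
}

#' @rdname read_whitelist
#' @param wl A data.frame with columns `gene` and `variant_key` (plus
#'   optional `hgvs`, `rationale`).
#' @export
as_whitelist <- function(wl) {
  stopifnot(all(c("gene", "variant_key") %in% names(wl)))
  if (anyDuplicated(wl[, c("gene", "variant_key")])) {
    stop("whitelist entries must be unique by (gene, variant_key)",
         call. = FALSE)
  }
  class(wl) <- c("ecs_whitelist", "data.frame")
  wl
}

#' Read a gene panel table
#'
#' TSV columns: `gene`, `n_missense_plp` (count m of missense
#' pathogenic/likely-pathogenic disease alleles), `n_total_plp` (count M of
#' all P/LP alleles), optional `prevalence` (disease prevalence as a
#' fraction), optional `spectrum_truncating` / `spectrum_missense`
#' (proportions of truncating vs missense/non-coding/in-frame alleles in a
#' patient cohort; must sum to 1 when present).
#'
#' @param path TSV file path.
#' @return A validated panel data.frame.
#' @export
read_gene_panel <- function(path) {
  panel <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
  validate_gene_panel(panel)
}

#' @rdname read_gene_panel
#' @param panel A data.frame with the columns described above.
#' @export
validate_gene_panel <- function(panel) {
  stopifnot(all(c("gene", "n_missense_plp", "n_total_plp") %in% names(panel)))
  if (!"prevalence" %in% names(panel)) panel$prevalence <- NA_real_
  if (!"spectrum_truncating" %in% names(panel))
    panel$spectrum_truncating <- NA_real_
  if (!"spectrum_missense" %in% names(panel))
    panel$spectrum_missense <- NA_real_
  if (any(panel$n_missense_plp > panel$n_total_plp, na.rm = TRUE)) {
    stop("n_missense_plp cannot exceed n_total_plp", call. = FALSE)
  }
  if (any(panel$n_missense_plp < 0 | panel$n_total_plp < 0, na.rm = TRUE)) {
    stop("P/LP counts must be non-negative", call. = FALSE)
  }
  range_check(panel$prevalence, "prevalence", 0, 1)
  spec_ok <- is.na(panel$spectrum_truncating) |
    abs(panel$spectrum_truncating + panel$spectrum_missense - 1) < 1e-8
  if (!all(spec_ok)) {
    stop("patient spectrum proportions must sum to 1", call. = FALSE)
  }
  panel
}
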