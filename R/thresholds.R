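#' Interpretation and quality-control thresholds
#'
#' Bundles every numeric cut-off the pipeline uses. Defaults follow the
#' operational definitions of the screening workflow:
#'
#' * `maf_max` — rarity cut-off on the gnomAD minor allele frequency
#'   (PM2-style evidence): variants with MAF above 0.1% are excluded
#'   unless whitelisted.
#' * `cadd_min`, `mcap_min`, `votes_min` — the predictor-ensemble rule for
#'   "strong" VUS: CADD >= 20, M-CAP >= 0.025 and at least 4 of the 7
#'   remaining tools calling the variant deleterious.
#' * `alt_fraction_min`, `depth_min` — per-call quality cut-offs (16% of
#'   supporting reads, 20x read depth), read as inclusive minima.
#' * `exome_cov_fraction_min`, `exome_cov_depth` — sample-level gate: a
#'   sample fails when less than 85% of the exome target is covered at
#'   >= 20x.
#' * `ms_min` — per-gene missense-score cut-off for first-priority VUS
#'   (more than 10% of known disease alleles are missense).
#' * `vipur_strong`, `vipur_deleterious` — structure-based score
#'   categories: > 0.7 strongly suggests deleteriousness, > 0.5 suggests
#'   it.
#' * `benign_override` — when `TRUE` (default), a ClinVar benign or likely
#'   benign assertion excludes a variant even if HGMD labels it DM.
#'
#' @param maf_max,cadd_min,mcap_min,votes_min,alt_fraction_min,depth_min
#'   Numeric cut-offs, see Details.
#' @param exome_cov_fraction_min,exome_cov_depth Sample-level coverage gate.
#' @param ms_min,vipur_strong,vipur_deleterious Prioritization cut-offs.
#' @param benign_override Logical flag, see Details.
#' @return An object of class `ecs_thresholds` (a named list).
#' @examples
#' thr <- default_thresholds()
#' thr$cadd_min
#' @export
default_thresholds <- function(maf_max = 0.001,
                               cadd_min = 20,
                               mcap_min = 0.025,
                               votes_min = 4L,
                               alt_fraction_min = 0.16,
                               depth_min = 20L,
                               exome_cov_fraction_min = 0.85,
                               exome_cov_depth = 20L,
                               ms_min = 0.1,
                               vipur_strong = 0.7,
                               vipur_deleterious = 0.5,
                               benign_override = TRUE) {
  thr <- list(
    maf_max = maf_max,
    cadd_min = cadd_min,
    mcap_min = mcap_min,
    votes_min = as.integer(votes_min),
    alt_fraction_min = alt_fraction_min,
    depth_min = depth_min,
    exome_cov_fraction_min = exome_cov_fraction_min,
    exome_cov_depth = as.integer(exome_cov_depth),
    ms_min = ms_min,
    vipur_strong = vipur_strong,
    vipur_deleterious = vipur_deleterious,
    benign_override = isTRUE(benign_override)
  )
  validate_thresholds(thr)
  class(thr) <- "ecs_thresholds"
  thr
}

validate_thresholds <- function(thr) {
  num <- c("maf_max", "cadd_min", "mcap_min", "votes_min",
           "alt_fraction_min", "depth_min", "exome_cov_fraction_min",
           "exome_cov_depth", "ms_min", "vipur_strong", "vipur_deleterious")
  for (f in num) {
    v <- thr[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("threshold '", f, "' must be a single non-negative number",
           call. = FALSE)
    }
  }
  frac <- c("maf_max", "mcap_min", "alt_fraction_min",
            "exome_cov_fraction_min", "ms_min", "vipur_strong",
            "vipur_deleterious")
  for (f in frac) {
    if (thr[[f]] > 1) {
      stop("threshold '", f, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (!thr$votes_min %in% 0:7) {
    stop("threshold 'votes_min' must be an integer in 0..7", call. = FALSE)
  }
  invisible(thr)
}

#' @export
print.ecs_thresholds <- function(x, ...) {
  cat("Carrier-screening thresholds:\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}
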