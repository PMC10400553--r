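#' Write / read a cohort report
#'
#' JSON is the machine format and round-trips exactly: reading a written
#' report reproduces every count and frequency. The TSV format writes a
#' set of flat tables (`<stem>_tiers.tsv`, `<stem>_carriers.tsv`,
#' `<stem>_couples.tsv`, `<stem>_recurrence.tsv`, `<stem>_per_gene.tsv`)
#' for spreadsheet use and does not round-trip the full structure.
#'
#' @param report An `ecs_report` from [build_report()].
#' @param path Output path (for TSV, the stem to which table suffixes are
#'   appended).
#' @param format `"json"` or `"tsv"`.
#' @return Invisibly, the path(s) written.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- unclass(report)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", null = "null")
    return(invisible(path))
  }
  stem <- sub("\\.tsv$", "", path)
  paths <- character(0)
  wt <- function(df, suffix) {
    p <- paste0(stem, "_", suffix, ".tsv")
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(report$tier_counts, "tiers")
  carriers <- do.call(rbind, lapply(names(report$carrier), function(s)
    data.frame(tier_set = s, as.data.frame(report$carrier[[s]]),
               stringsAsFactors = FALSE)))
  wt(carriers, "carriers")
  couples <- do.call(rbind, lapply(names(report$couples), function(s)
    data.frame(tier_set = s, as.data.frame(report$couples[[s]]),
               stringsAsFactors = FALSE)))
  wt(couples, "couples")
  wt(report$recurrence_vus$recurrence, "recurrence")
  wt(report$per_gene, "per_gene")
  invisible(paths)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("tier_counts", "per_gene")) {
    p[[f]] <- as.data.frame(p[[f]], stringsAsFactors = FALSE)
  }
  for (s in names(p$carrier)) {
    if (is.null(p$carrier[[s]]$frequency)) p$carrier[[s]]$frequency <- NA_real_
  }
  for (f in c("recurrence_vus", "recurrence_reportable")) {
    rec <- p[[f]]$recurrence
    p[[f]]$recurrence <- if (is.null(rec) || !length(rec)) {
      data.frame(variant_key = character(0), n_carriers = integer(0),
                 stringsAsFactors = FALSE)
    } else as.data.frame(rec, stringsAsFactors = FALSE)
  }
  class(p) <- "ecs_report"
  p
}
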