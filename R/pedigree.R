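#' Read a PED pedigree into a pedigree set
#'
#' Parses a standard whitespace-separated 6-column PED file (family,
#' individual, father, mother, sex, phenotype). An optional 7th column (or
#' a sidecar table supplied via `consanguinity`) flags consanguineous
#' individuals; a couple is consanguineous when either partner is flagged.
#'
#' Couples are derived as (father, mother) pairs that share at least one
#' child; trios as (father, mother, child) triplets with both parents
#' known. A child whose named parent is not itself a row of the file is a
#' referential error.
#'
#' @param path PED file path.
#' @param consanguinity Optional data.frame with columns `sample_id` and
#'   `consanguineous` (logical), overriding/augmenting the 7th column.
#' @return A list of class `ecs_pedigree` with elements `individuals`
#'   (sample_id, sex, consanguineous), `couples` (father_id, mother_id,
#'   consanguineous) and `trios` (father_id, mother_id, child_id).
#' @export
read_pedigree <- function(path, consanguinity = NULL) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6L) {
    stop("PED file must have at least 6 columns", call. = FALSE)
  }
  names(raw)[1:6] <- c("family", "sample_id", "father", "mother", "sex",
                       "phenotype")
  flag <- if (ncol(raw) >= 7L) raw[[7L]] %in% c("1", "TRUE", "true") else
    rep(FALSE, nrow(raw))
  if (!is.null(consanguinity)) {
    idx <- match(raw$sample_id, consanguinity$sample_id)
    hit <- !is.na(idx)
    flag[hit] <- as.logical(consanguinity$consanguineous[idx[hit]])
  }
  build_pedigree(raw, flag)
}

build_pedigree <- function(raw, flag) {
  known <- raw$sample_id
  for (col in c("father", "mother")) {
    ref <- raw[[col]]
    bad <- ref != "0" & !ref %in% known
    if (any(bad)) {
      stop("child '", raw$sample_id[which(bad)[1L]], "' references unknown ",
           col, " '", ref[which(bad)[1L]], "'", call. = FALSE)
    }
  }
  individuals <- data.frame(sample_id = raw$sample_id, sex = raw$sex,
                            consanguineous = flag,
                            stringsAsFactors = FALSE)
  complete <- raw$father != "0" & raw$mother != "0"
  trios <- data.frame(father_id = raw$father[complete],
                      mother_id = raw$mother[complete],
                      child_id = raw$sample_id[complete],
                      stringsAsFactors = FALSE)
  pairs <- unique(trios[, c("father_id", "mother_id")])
  cons_of <- function(id) individuals$consanguineous[match(id, known)]
  couples <- data.frame(
    father_id = pairs$father_id, mother_id = pairs$mother_id,
    consanguineous = cons_of(pairs$father_id) | cons_of(pairs$mother_id),
    stringsAsFactors = FALSE)
  rownames(couples) <- NULL
  ped <- list(individuals = individuals, couples = couples, trios = trios)
  class(ped) <- "ecs_pedigree"
  ped
}

#' Construct a pedigree set directly from tables
#'
#' @param individuals data.frame with `sample_id`, optional `sex`,
#'   optional `consanguineous`.
#' @param couples data.frame with `father_id`, `mother_id`, optional
#'   `consanguineous`.
#' @param trios data.frame with `father_id`, `mother_id`, `child_id`.
#' @return An `ecs_pedigree` list.
#' @export
pedigree_set <- function(individuals, couples = NULL, trios = NULL) {
  if (is.null(individuals$sex)) individuals$sex <- "0"
  if (is.null(individuals$consanguineous))
    individuals$consanguineous <- FALSE
  if (is.null(couples)) {
    couples <- data.frame(father_id = character(0), mother_id = character(0),
                          consanguineous = logical(0),
                          stringsAsFactors = FALSE)
  }
  if (is.null(couples$consanguineous)) couples$consanguineous <- FALSE
  if (is.null(trios)) {
    trios <- data.frame(father_id = character(0), mother_id = character(0),
                        child_id = character(0), stringsAsFactors = FALSE)
  }
  ids <- individuals$sample_id
  for (col in c(couples$father_id, couples$mother_id, trios$father_id,
                trios$mother_id, trios$child_id)) {
    if (length(col) && any(!col %in% ids)) {
      stop("couple/trio references an individual not in the pedigree",
           call. = FALSE)
    }
  }
  if (anyDuplicated(couples[, c("father_id", "mother_id")])) {
    stop("a couple may appear at most once", call. = FALSE)
  }
  ped <- list(individuals = individuals, couples = couples, trios = trios)
  class(ped) <- "ecs_pedigree"
  ped
}

#' Write a pedigree set as a PED file
#'
#' Emits one row per individual; children carry their parent ids so the
#' couples can be re-derived on reading. The 7th column carries the
#' consanguinity flag.
#'
#' @param ped An `ecs_pedigree`.
#' @param path Output path.
#' @export
write_pedigree <- function(ped, path) {
  ind <- ped$individuals
  parent_of <- function(id, col) {
    hit <- match(id, ped$trios$child_id)
    ifelse(is.na(hit), "0", ped$trios[[col]][hit])
  }
  rows <- data.frame(
    family = paste0("F", seq_len(nrow(ind))),
    sample_id = ind$sample_id,
    father = parent_of(ind$sample_id, "father_id"),
    mother = parent_of(ind$sample_id, "mother_id"),
    sex = ind$sex, phenotype = "0",
    consang = as.integer(ind$consanguineous),
    stringsAsFactors = FALSE)
  # keep family ids consistent within trios
  for (i in seq_len(nrow(ped$trios))) {
    fam <- rows$family[match(ped$trios$child_id[i], rows$sample_id)]
    rows$family[rows$sample_id %in% unlist(ped$trios[i, ])] <- fam
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.ecs_pedigree <- function(x, ...) {
  cat(sprintf(
    "Pedigree set: %d individuals, %d couples (%d consanguineous), %d trios\n",
    nrow(x$individuals), nrow(x$couples), sum(x$couples$consanguineous),
    nrow(x$trios)))
  invisible(x)
}
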