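#' Sample-level coverage gate
#'
#' A sample is of insufficient quality when less than
#' `exome_cov_fraction_min` (default 85%) of the exome target is covered
#' at `exome_cov_depth` (default 20x). Failing samples are excluded from
#' all downstream statistics. The cut-off is read strictly: a fraction of
#' exactly 0.85 passes.
#'
#' @param metrics data.frame with columns `sample_id`, `mean_coverage`,
#'   `fraction_exome_at_depth`.
#' @param thr An [default_thresholds()] object.
#' @return `metrics` with an added `gate` column (`"PASS"`/`"FAIL"`).
#' @export
sample_quality_gate <- function(metrics, thr = default_thresholds()) {
  stopifnot(all(c("sample_id", "fraction_exome_at_depth") %in% names(metrics)))
  range_check(metrics$fraction_exome_at_depth, "fraction_exome_at_depth", 0, 1)
  metrics$gate <- ifelse(
    metrics$fraction_exome_at_depth < thr$exome_cov_fraction_min,
    "FAIL", "PASS")
  metrics
}

#' Rule-based pre-processing of variant calls
#'
#' Excludes calls failing the per-call quality cut-offs: alternate-read
#' fraction below 16% or read depth below 20x (both inclusive minima: a
#' call exactly at a cut-off is retained). An optional blacklist of
#' variant keys models manual exclusion of known calling artefacts.
#'
#' @param calls A validated call table.
#' @param thr An [default_thresholds()] object.
#' @param blacklist Optional character vector of `variant_key`s to drop.
#' @return List with `retained` (call table) and `excluded` (call table
#'   with an added `reason` column, one of `ALT_FRACTION`, `DEPTH`,
#'   `BLACKLIST`). Counts are conserved: every input row appears in
#'   exactly one of the two.
#' @export
preprocess_filter <- function(calls, thr = default_thresholds(),
                              blacklist = NULL) {
  reason <- rep(NA_character_, nrow(calls))
  reason[calls$depth < thr$depth_min] <- "DEPTH"
  reason[calls$alt_fraction < thr$alt_fraction_min] <- "ALT_FRACTION"
  if (!is.null(blacklist)) {
    reason[calls$variant_key %in% blacklist] <- "BLACKLIST"
  }
  excluded <- calls[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  list(retained = calls[is.na(reason), , drop = FALSE], excluded = excluded)
}

qc_feature_names <- function() {
  c("depth", "alt_fraction", "strand_balance", "mean_base_quality")
}

extract_qc_features <- function(x) {
  feats <- intersect(qc_feature_names(), names(x))
  if (length(feats) < 2L) {
    stop("call table lacks QC feature columns", call. = FALSE)
  }
  m <- as.matrix(as.data.frame(lapply(x[feats], as.numeric)))
  colnames(m) <- feats
  m
}

#' Train the linear SVM call-quality classifier
#'
#' Fits a linear maximum-margin classifier (hinge loss with L2 penalty of
#' strength 1/C, via libsvm) separating true calls from calling
#' artefacts. Features are z-standardized internally; the standardization
#' constants are stored with the model so scoring is self-contained. The
#' fit is deterministic for a fixed training table.
#'
#' @param training data.frame with the QC feature columns (`depth`,
#'   `alt_fraction` and optionally `strand_balance`,
#'   `mean_base_quality`) and a `label` column coded `TRUE_CALL` /
#'   `FALSE_CALL`.
#' @param C Soft-margin cost parameter (default 1).
#' @param seed Integer seed (kept for provenance; the linear fit itself is
#'   deterministic).
#' @return An object of class `ecs_call_model` with elements `w` (named
#'   weight vector), `b` (bias), `center`, `scale`, `C`, `seed`. Decision:
#'   a call is TRUE_CALL iff `w . z(x) + b >= 0`.
#' @export
train_call_classifier <- function(training, C = 1, seed = 1L) {
  stopifnot("label" %in% names(training))
  lab <- training$label
  if (length(unique(lab)) < 2L) {
    stop("training set must contain both TRUE_CALL and FALSE_CALL labels",
         call. = FALSE)
  }
  x <- extract_qc_features(training)
  if (any(!is.finite(x))) stop("non-finite training features", call. = FALSE)
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- scale(x, center = center, scale = scl)
  y <- factor(lab, levels = c("FALSE_CALL", "TRUE_CALL"))
  set.seed(seed)
  fit <- e1071::svm(x = z, y = y, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision for its internal first class; flip so
  # that positive decision values always mean TRUE_CALL
  dec <- drop(z %*% w) + b
  pred_true <- mean(dec[y == "TRUE_CALL"])
  pred_false <- mean(dec[y == "FALSE_CALL"])
  if (pred_true < pred_false) {
    w <- -w
    b <- -b
  }
  model <- list(w = stats::setNames(as.numeric(w), colnames(x)), b = b,
                center = center, scale = scl, C = C, seed = as.integer(seed))
  class(model) <- "ecs_call_model"
  model
}

model_decision <- function(model, features) {
  feats <- names(model$w)
  missing <- setdiff(feats, colnames(features))
  if (length(missing)) {
    stop("feature schema mismatch: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- features[, feats, drop = FALSE]
  z <- scale(x, center = model$center[feats], scale = model$scale[feats])
  drop(z %*% model$w) + model$b
}

#' Score calls with a trained call-quality model
#'
#' Partitions calls into high-confidence ("true") calls and rejected false
#' calls by the sign of the linear decision value. Decision ties
#' (`w . x + b == 0`) are kept as true calls: at the QC stage the
#' screening favors sensitivity.
#'
#' @param model An `ecs_call_model` from [train_call_classifier()].
#' @param calls A call table (or feature data.frame) carrying the model's
#'   feature columns.
#' @return List with `high_confidence` and `rejected` call tables plus a
#'   `decision` numeric vector aligned with the input rows.
#' @export
score_calls <- function(model, calls) {
  if (nrow(calls) == 0L) {
    return(list(high_confidence = calls, rejected = calls,
                decision = numeric(0)))
  }
  dec <- model_decision(model, extract_qc_features(calls))
  keep <- dec >= 0
  list(high_confidence = calls[keep, , drop = FALSE],
       rejected = calls[!keep, , drop = FALSE],
       decision = dec)
}

#' Persist / reload a call-quality model as JSON
#'
#' @param model An `ecs_call_model`.
#' @param path JSON file path.
#' @return `read_call_model` returns a model whose decisions are identical
#'   to the saved one.
#' @export
write_call_model <- function(model, path) {
  payload <- list(feature_names = names(model$w),
                  w = unname(model$w), b = model$b,
                  center = unname(model$center), scale = unname(model$scale),
                  C = model$C, seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_call_model
#' @export
read_call_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(
    w = stats::setNames(as.numeric(p$w), p$feature_names), b = p$b,
    center = stats::setNames(as.numeric(p$center), p$feature_names),
    scale = stats::setNames(as.numeric(p$scale), p$feature_names),
    C = p$C, seed = as.integer(p$seed))
  class(model) <- "ecs_call_model"
  model
}
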