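# Independent brute-force tier oracle: evaluates every rule predicate on
# its own (no ordering shortcuts, no shared code with classify_calls) and
# resolves the tier by rule precedence afterwards.

oracle_tools <- c("sift", "polyphen2", "lrt", "mutationassessor",
                  "mutationtaster", "fathmm", "provean")

oracle_classify <- function(calls, whitelist, thr) {
  n <- nrow(calls)
  wl_keys <- if (is.null(whitelist)) character(0) else
    paste(whitelist$gene, whitelist$variant_key)
  out <- character(n)
  cols <- as.list(calls)
  for (i in seq_len(n)) {
    maf <- cols$maf[i]
    if (is.na(maf)) maf <- 0
    lof <- cols$consequence[i] %in% c("NONSENSE", "FRAMESHIFT",
                                      "CANONICAL_SPLICE")
    votes <- 0L
    for (tc in oracle_tools) {
      if (identical(cols[[tc]][i], "DELETERIOUS")) votes <- votes + 1L
    }
    ens <- !is.na(cols$cadd[i]) && cols$cadd[i] >= thr$cadd_min &&
      !is.na(cols$mcap[i]) && cols$mcap[i] >= thr$mcap_min &&
      votes >= thr$votes_min
    cv <- cols$clinvar[i]
    hg <- cols$hgmd[i]
    lim <- isTRUE(cols$clinvar_limited[i])
    fired <- list()
    if (paste(cols$gene[i], cols$variant_key[i]) %in% wl_keys) {
      fired[["1"]] <- "PATHOGENIC"
    }
    if (thr$benign_override && cv %in% c("B", "LB")) {
      fired[["2"]] <- "EXCLUDED"
    }
    if (maf > thr$maf_max) fired[["3"]] <- "EXCLUDED"
    if (lof && (cv == "P" || hg == "DM")) fired[["4"]] <- "PATHOGENIC"
    if (!lof && cv == "P" && hg == "DM" && !lim) {
      fired[["5"]] <- "PATHOGENIC"
    }
    if (lof && cv == "VUS") fired[["6"]] <- "STRONG_VUS"
    if (lof && cv == "ABSENT" && hg == "ABSENT") {
      fired[["7"]] <- "NOVEL_LOF"
    }
    if (cv == "LP" && lim) fired[["8"]] <- "STRONG_VUS"
    if (hg %in% c("DM", "DM_QUERY")) fired[["9"]] <- "STRONG_VUS"
    if (ens) fired[["10"]] <- "STRONG_VUS"
    out[i] <- if (length(fired)) {
      fired[[as.character(min(as.integer(names(fired))))]]
    } else "EXCLUDED"
  }
  out
}
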