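#' Spectral-count table for the CoTrIP proteomics screen
#'
#' @param df A data.frame with columns `protein`, `sample`, `group`,
#'   `count` (spectral counts >= 0).
#' @return The validated data.frame with class `spectral_table`.
#' @export
spectral_table <- function(df) {
  need <- c("protein", "sample", "group", "count")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("spectral_table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$count < 0)) stop("spectral counts must be >= 0")
  if (anyDuplicated(unique(df[, c("sample", "group")])$sample))
    stop("a sample cannot belong to more than one group")
  class(df) <- c("spectral_table", "data.frame")
  df
}

#' Promoter-specific protein enrichment (volcano coordinates)
#'
#' Per protein, the fold change of mean spectral counts between two
#' promoter groups (with pseudocount) and a Welch two-sample t-test on
#' the counts; unequal replicate numbers (e.g. 2 vs 3) are allowed.
#' Candidates are proteins with `p < p_threshold`, ordered by fold
#' change descending (ties broken by protein id).
#'
#' @param table A [spectral_table()].
#' @param group_a,group_b Group labels (numerator, denominator).
#' @param pseudocount Added to both group means; default 0.5.
#' @param p_threshold Candidate p-value cutoff; default 0.05.
#' @param log_counts Run the t-test on log2(count + pseudocount)
#'   instead of raw counts.
#' @return A list of class `volcano_result`: `results` (data.frame with
#'   `protein`, `mean_a`, `mean_b`, `log2_fc`, `p`, `neg_log10_p`,
#'   `qc_flag`) and `candidates` (the ordered significant subset).
#' @export
enrichment_volcano <- function(table, group_a, group_b, pseudocount = 0.5,
                               p_threshold = 0.05, log_counts = FALSE) {
  stopifnot(inherits(table, "spectral_table"))
  proteins <- sort(unique(table$protein))
  rows <- lapply(proteins, function(pr) {
    xa <- table$count[table$protein == pr & table$group == group_a]
    xb <- table$count[table$protein == pr & table$group == group_b]
    if (length(xa) == 0L || length(xb) == 0L)
      stop("protein ", pr, " lacks records in a compared group")
    if (max(length(xa), length(xb)) < 2L)
      stop("at least one group needs >= 2 replicates")
    ta <- if (log_counts) log2(xa + pseudocount) else xa
    tb <- if (log_counts) log2(xb + pseudocount) else xb
    flag <- "ok"
    p <- tryCatch(stats::t.test(ta, tb)$p.value, error = function(e) {
      NA_real_
    })
    if (is.na(p)) {
      # degenerate spread (e.g. a singleton group against zero variance)
      flag <- "p_undefined"
      if (isTRUE(all.equal(mean(ta), mean(tb)))) p <- 1
    }
    if (length(xa) == 0L || length(xb) == 0L) flag <- "missing_group"
    if (all(xa == 0) || all(xb == 0)) flag <- "zero_counts"
    data.frame(protein = pr, mean_a = mean(xa), mean_b = mean(xb),
               log2_fc = log2((mean(xa) + pseudocount) /
                                (mean(xb) + pseudocount)),
               p = p, neg_log10_p = -log10(p), qc_flag = flag,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  cand <- res[!is.na(res$p) & res$p < p_threshold, , drop = FALSE]
  cand <- cand[order(-cand$log2_fc, cand$protein), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(results = res, candidates = cand,
                 group_a = group_a, group_b = group_b),
            class = "volcano_result")
}

#' @export
print.volcano_result <- function(x, ...) {
  cat(sprintf(
    "Enrichment volcano %s vs %s: %d proteins, %d candidate(s)\n",
    x$group_a, x$group_b, nrow(x$results), nrow(x$candidates)))
  invisible(x)
}

#' Filter screen candidates against a background proteome table
#'
#' Retains candidates whose fold of observed mean counts over a
#' user-supplied background (e.g. a contaminant repository export) is at
#' least `min_fc`; proteins missing from the background are retained
#' and flagged.
#'
#' @param volcano A [enrichment_volcano()] result.
#' @param background_table A [spectral_table()] of background counts
#'   (all rows per protein are averaged), or `NULL` for an identity
#'   filter.
#' @param min_fc Minimum fold over background; default 2.
#' @param pseudocount Added to numerator and denominator; default 0.5.
#' @return The candidate data.frame with added `background_mean`,
#'   `fc_over_background`, `background_flag` columns, filtered to
#'   `fc_over_background >= min_fc` (or flagged-missing rows).
#' @export
background_filter <- function(volcano, background_table, min_fc = 2,
                              pseudocount = 0.5) {
  stopifnot(inherits(volcano, "volcano_result"))
  cand <- volcano$candidates
  if (is.null(background_table) || nrow(background_table) == 0L) {
    cand$background_mean <- NA_real_
    cand$fc_over_background <- NA_real_
    cand$background_flag <- "no_background"
    return(cand)
  }
  stopifnot(inherits(background_table, "spectral_table"))
  bg <- tapply(background_table$count, background_table$protein, mean)
  cand$background_mean <- as.numeric(bg[cand$protein])
  cand$fc_over_background <- (cand$mean_a + pseudocount) /
    (cand$background_mean + pseudocount)
  cand$background_flag <- ifelse(is.na(cand$background_mean),
                                 "missing_from_background", "ok")
  keep <- is.na(cand$background_mean) | cand$fc_over_background >= min_fc
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
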